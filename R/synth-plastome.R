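#' Generate a quadripartite plastome
#'
#' Builds a circular chloroplast-like genome LSC + IRa + SSC + IRb with
#' i.i.d. bases at the requested GC content; IRb is the exact reverse
#' complement of IRa.  Defaults reproduce the region lengths and mean GC of
#' the aspen plastome this package's analyses are calibrated on (LSC 84,367
#' bp, SSC 16,670 bp, IRs 27,509 bp each, GC 36.76%).
#'
#' @param lsc_len large single-copy length (bp, > 0).
#' @param ssc_len small single-copy length (bp, > 0).
#' @param ir_len inverted-repeat length (bp, >= 0; 0 gives a repeat-free
#'   circle with the whole genome recorded as LSC).
#' @param gc GC fraction in \[0, 1\].
#' @param seed integer seed; the same seed yields the identical genome.
#' @param id genome identifier.
#' @return an [org_genome()] with regions `LSC`, `IRa`, `SSC`, `IRb`.
#' @export
gen_plastome <- function(lsc_len = 84367, ssc_len = 16670, ir_len = 27509,
                         gc = 0.3676, seed = 1, id = "plastome") {
  stopifnot(lsc_len > 0, ssc_len > 0, ir_len >= 0, gc >= 0, gc <= 1)
  set.seed(seed)
  lsc <- random_dna(lsc_len, gc)
  ira <- random_dna(ir_len, gc)
  ssc <- random_dna(ssc_len, gc)
  if (ir_len > 0) {
    # make the planted repeat pair maximal: the single-copy bases flanking
    # the IRs must not extend the reverse-complement match by chance
    lsc <- break_flank(lsc)
    ssc <- break_flank(ssc)
  }
  irb <- revcomp(ira)
  seq <- paste0(lsc, ira, ssc, irb)
  regions <- if (ir_len > 0) {
    data.frame(
      name = c("LSC", "IRa", "SSC", "IRb"),
      start = cumsum(c(0, lsc_len, ir_len, ssc_len)),
      end = cumsum(c(lsc_len, ir_len, ssc_len, ir_len)),
      strand = c("+", "+", "+", "-"))
  } else {
    data.frame(name = "LSC", start = 0L, end = lsc_len + ssc_len, strand = "+")
  }
  org_genome(seq, id = id, circular = TRUE, regions = regions,
             truth = list(lsc_len = lsc_len, ssc_len = ssc_len,
                          ir_len = ir_len, gc = gc, seed = seed))
}

# adjust the terminal bases of a single-copy region so they do not
# reverse-complement its leading bases: an IR flanked by such a region is
# exactly the maximal repeat pair, and planted region lengths are truth
break_flank <- function(x, depth = 2L) {
  n <- nchar(x)
  if (n < 2L * depth) return(x)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (t in seq_len(depth)) {
    bad <- comp[[substr(x, t, t)]]
    if (substr(x, n - t + 1L, n - t + 1L) == bad)
      substr(x, n - t + 1L, n - t + 1L) <- sample(setdiff(DNA_BASES, bad), 1L)
  }
  x
}
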