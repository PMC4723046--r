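#' Generate a circular mitogenome with plastid-derived insertions
#'
#' Builds a random circular mitochondrial-like genome and replaces
#' non-overlapping segments with copies of plastome intervals mutated down
#' to a target identity, emulating the chloroplast-like regions that make up
#' roughly 2% of real aspen mitochondrial DNA.  Truth intervals record mito
#' coordinates, source plastome coordinates, strand and realized identity.
#'
#' @param length genome length in bp (the full-size molecule is ~780 kb;
#'   the desk-scale default is 80 kb).
#' @param insert_lens integer vector of plastid-derived segment lengths (bp).
#' @param insert_identity target identity of each insert to its plastome
#'   source, in \[0, 1\] (default 0.95; real chloroplast-like regions are at
#'   least 90% identical).
#' @param plastome source [org_genome()]; required when inserts are
#'   requested.
#' @param gc backbone GC fraction (plant mtDNA is ~45%).
#' @param seed integer seed.
#' @param id genome identifier.
#' @param max_retries placement attempts before giving up on a
#'   non-overlapping layout.
#' @return an [org_genome()]; `$truth$inserts` is a data.frame with columns
#'   `name`, `start`, `end` (0-based half-open mito coordinates),
#'   `src_start`, `src_end`, `strand`, `identity`.
#' @export
gen_mitogenome <- function(length = 80000, insert_lens = integer(),
                           insert_identity = 0.95, plastome = NULL,
                           gc = 0.45, seed = 1, id = "mito",
                           max_retries = 100) {
  stopifnot(length > 0, insert_identity >= 0, insert_identity <= 1)
  n_ins <- base::length(insert_lens)
  if (n_ins > 0 && is.null(plastome)) stop("plastome source required for inserts")
  if (n_ins > 0 && any(insert_lens > nchar(genome_seq(plastome))))
    stop("insert longer than the source plastome")
  if (sum(insert_lens) >= length) stop("inserts exceed the genome length")
  set.seed(seed)
  backbone <- seq_chars(random_dna(length, gc))
  inserts <- data.frame(name = character(), start = integer(), end = integer(),
                        src_start = integer(), src_end = integer(),
                        strand = character(), identity = numeric())
  if (n_ins > 0) {
    cp <- genome_seq(plastome)
    placed <- matrix(numeric(0), ncol = 2)   # occupied [start, end)
    for (i in seq_len(n_ins)) {
      len <- insert_lens[i]
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        st <- sample.int(length - len + 1L, 1L) - 1L
        if (nrow(placed) == 0 ||
            all(st + len <= placed[, 1] | st >= placed[, 2])) { ok <- TRUE; break }
      }
      if (!ok) stop("could not place insert ", i, " without overlap after ",
                    max_retries, " retries")
      src_start <- sample.int(nchar(cp) - len + 1L, 1L) - 1L
      src <- substr(cp, src_start + 1L, src_start + len)
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") src <- revcomp(src)
      sc <- seq_chars(src)
      n_mut <- rbinom(1L, len, 1 - insert_identity)
      if (n_mut > 0) {
        pos <- sample.int(len, n_mut)
        for (p in pos) sc[p] <- sample(setdiff(DNA_BASES, sc[p]), 1L)
      }
      backbone[(st + 1L):(st + len)] <- sc
      placed <- rbind(placed, c(st, st + len))
      inserts <- rbind(inserts, data.frame(
        name = sprintf("region_cp_%d", i), start = st, end = st + len,
        src_start = src_start, src_end = src_start + len, strand = strand,
        identity = (len - n_mut) / len))
    }
    inserts <- inserts[order(inserts$start), ]
    rownames(inserts) <- NULL
  }
  org_genome(paste(backbone, collapse = ""), id = id, circular = TRUE,
             regions = if (n_ins > 0)
               data.frame(name = inserts$name, start = inserts$start,
                          end = inserts$end, strand = inserts$strand)
             else NULL,
             truth = list(inserts = inserts, seed = seed,
                          insert_identity = insert_identity))
}
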