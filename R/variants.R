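#' Variant-calling parameters
#'
#' Quality-based variant detection: only bases at or above
#' `min_base_quality` are tallied, and a non-reference allele is called
#' when its frequency among counted bases reaches `min_freq` at depth
#' `min_cov` or more.  The 90% minimum variant frequency is the organelle
#' setting this pipeline is built around (one allele per organelle genome;
#' anything well below 100% is mapping noise or plastid/mitochondrial
#' cross-talk).
#'
#' @param min_freq minimum variant frequency.
#' @param min_cov minimum counted depth.
#' @param min_base_quality minimum Phred base quality counted.
#' @return list of class `variant_params`.
#' @export
variant_params <- function(min_freq = 0.90, min_cov = 10,
                           min_base_quality = 20) {
  stopifnot(min_freq > 0, min_freq <= 1, min_cov >= 1)
  structure(list(min_freq = min_freq, min_cov = min_cov,
                 min_base_quality = min_base_quality),
            class = "variant_params")
}

#' Quality-based variant calling from mapped reads
#'
#' Per reference column, bases with quality at or above
#' `min_base_quality` are tallied; a non-reference allele with frequency at
#' least `min_freq` and counted depth at least `min_cov` is called.
#' Adjacent called SNV columns merge into one MNV record; deletion and
#' insertion evidence passing the same thresholds becomes InDel records,
#' left-aligned in the VCF convention.
#'
#' @param alignments `org_alnset` from [map_reads()] (the variant-mapping
#'   acceptance preset is `mapping_params(0.95, 0.99)`).
#' @param reference the mapped reference ([org_genome()] or string).
#' @param params [variant_params()].
#' @return data.frame of records: `position` (0-based on the reference),
#'   `ref_allele`, `alt_allele`, `class` (`SNV`/`MNV`/`InDel`),
#'   `frequency`, `depth`, `mean_quality`.
#' @export
call_variants <- function(alignments, reference, params = variant_params()) {
  refseq <- genome_seq(reference)
  L <- attr(alignments, "ref_len")
  if (L != nchar(refseq)) stop("reference length does not match the alignment set")
  p <- pileup_matrices(alignments, min_qual = params$min_base_quality)
  depth <- colSums(p$counts)
  refv <- seq_chars(refseq)
  bases <- c("A", "C", "G", "T", "-")
  ref_row <- match(refv, bases)

  # per-column best non-reference allele
  counts <- p$counts
  idx <- (seq_len(L) - 1L) * 5L + ref_row
  counts_nr <- counts
  counts_nr[idx] <- -1L
  alt_row <- max.col(t(counts_nr), ties.method = "first")
  alt_cnt <- counts[(seq_len(L) - 1L) * 5L + alt_row]
  callable <- depth >= params$min_cov & alt_cnt >= params$min_freq * depth &
    alt_cnt > 0
  cols <- which(callable)

  rec <- list()
  if (length(cols) > 0) {
    allele <- bases[alt_row[cols]]
    freq <- alt_cnt[cols] / depth[cols]
    mq <- p$qsum[(cols - 1L) * 5L + alt_row[cols]] / alt_cnt[cols]
    is_del <- allele == "-"
    # group adjacent called columns of the same kind
    grp <- cumsum(c(TRUE, diff(cols) != 1L | diff(is_del) != 0L))
    for (g in unique(grp)) {
      sel <- which(grp == g)
      pos <- cols[sel][1] - 1L
      n <- length(sel)
      if (is_del[sel][1]) {
        del_ref <- paste(refv[cols[sel]], collapse = "")
        al <- left_align_del(refv, pos, del_ref)
        rec[[length(rec) + 1L]] <- data.frame(
          position = al$pos, ref_allele = al$ref, alt_allele = "",
          class = "InDel", frequency = mean(freq[sel]),
          depth = as.integer(round(mean(depth[cols[sel]]))),
          mean_quality = mean(mq[sel]))
      } else {
        rec[[length(rec) + 1L]] <- data.frame(
          position = pos,
          ref_allele = paste(refv[cols[sel]], collapse = ""),
          alt_allele = paste(allele[sel], collapse = ""),
          class = if (n == 1L) "SNV" else "MNV",
          frequency = mean(freq[sel]),
          depth = as.integer(round(mean(depth[cols[sel]]))),
          mean_quality = mean(mq[sel]))
      }
    }
  }

  # insertion evidence from the alignment set
  ins <- parse_insertions(alignments)
  if (nrow(ins) > 0) {
    key <- paste(ins$pos, ins$seq)
    for (k in unique(key)) {
      sel <- key == k
      pos <- ins$pos[sel][1]
      d <- depth[pos + 1L]
      n <- sum(sel)
      if (d >= params$min_cov && n >= params$min_freq * d) {
        al <- left_align_ins(refv, pos, ins$seq[sel][1])
        rec[[length(rec) + 1L]] <- data.frame(
          position = al$pos, ref_allele = "", alt_allele = al$alt,
          class = "InDel", frequency = n / d, depth = as.integer(d),
          mean_quality = mean(ins$mq[sel]))
      }
    }
  }
  if (length(rec) == 0)
    return(data.frame(position = integer(), ref_allele = character(),
                      alt_allele = character(), class = character(),
                      frequency = numeric(), depth = integer(),
                      mean_quality = numeric()))
  out <- do.call(rbind, rec)
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# shift a deletion left through repeated sequence (VCF normalization)
left_align_del <- function(refv, pos, del) {
  n <- nchar(del)
  while (pos > 0 && refv[pos] == substr(del, n, n)) {
    del <- paste0(refv[pos], substr(del, 1L, n - 1L))
    pos <- pos - 1L
  }
  list(pos = pos, ref = del)
}

left_align_ins <- function(refv, pos, alt) {
  n <- nchar(alt)
  while (pos > 0 && refv[pos] == substr(alt, n, n)) {
    alt <- paste0(refv[pos], substr(alt, 1L, n - 1L))
    pos <- pos - 1L
  }
  list(pos = pos, alt = alt)
}

# insertion events "pos:seq:qual;..." recorded by the mapper
parse_insertions <- function(alignments) {
  has <- which(nzchar(alignments$ins))
  if (length(has) == 0)
    return(data.frame(pos = integer(), seq = character(), mq = numeric()))
  parts <- strsplit(alignments$ins[has], ";", fixed = TRUE)
  ev <- unlist(parts, use.names = FALSE)
  f <- strsplit(ev, ":", fixed = TRUE)
  data.frame(pos = as.integer(vapply(f, `[`, character(1), 1L)),
             seq = vapply(f, `[`, character(1), 2L),
             mq = vapply(f, function(x)
               mean(utf8ToInt(x[3]) - 33), numeric(1)))
}

#' Count SNP positions among variant records
#'
#' The counting rule for SNP-frequency statistics: every reference position
#' covered by an SNV or MNV record counts (an MNV of length L contributes
#' L positions); InDels are excluded.
#'
#' @param records variant records from [call_variants()] (or any data.frame
#'   with `class` and `ref_allele` columns).
#' @return integer count of SNP positions.
#' @export
count_snp_positions <- function(records) {
  if (nrow(records) == 0) return(0L)
  sum(records$class == "SNV") +
    sum(nchar(records$ref_allele[records$class == "MNV"]))
}

#' SNP frequency in SNPs per kilobase
#'
#' `1000 * snp_count / ref_len`, rounded half-up to 3 decimals.
#'
#' @param snp_count SNP position count.
#' @param ref_len reference length in bp (> 0).
#' @return SNPs/kb, 3 decimals.
#' @export
snp_frequency <- function(snp_count, ref_len) {
  stopifnot(ref_len > 0, snp_count >= 0)
  x <- 1000 * snp_count / ref_len
  floor(x * 1000 + 0.5) / 1000
}
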