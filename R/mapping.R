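#' Mapping parameters
#'
#' The two-threshold acceptance contract used throughout: a read placement
#' is accepted iff its aligned read fraction is at least `length_fraction`
#' and its identity over aligned columns is at least `similarity_fraction`.
#' The defaults (0.95, 0.99) are the variant-mapping setting; chloroplast
#' read subtraction uses the stricter (0.99, 0.99) preset.
#'
#' @param length_fraction minimum aligned fraction of the read.
#' @param similarity_fraction minimum identity over aligned columns.
#' @param seed_k exact-seed word length.
#' @param max_hits maximum candidate placements evaluated per read.
#' @return list of class `mapping_params`.
#' @export
mapping_params <- function(length_fraction = 0.95, similarity_fraction = 0.99,
                           seed_k = 21, max_hits = 8) {
  stopifnot(length_fraction >= 0, length_fraction <= 1,
            similarity_fraction >= 0, similarity_fraction <= 1, seed_k >= 4)
  structure(list(length_fraction = length_fraction,
                 similarity_fraction = similarity_fraction,
                 seed_k = seed_k, max_hits = max_hits),
            class = "mapping_params")
}

#' Map reads against a reference
#'
#' Exact-seed candidate generation followed by per-candidate scoring: an
#' ungapped check on the seed diagonal, falling back to a banded
#' end-space-free alignment (band = 10% of read length) when indels are
#' needed.  Identity is computed over aligned columns.  A read is reported
#' iff some placement satisfies both acceptance fractions; the best
#' placement is chosen by identity, ties resolved to the leftmost start and
#' then the forward strand, so multi-mapping reads (e.g. inside an inverted
#' repeat) contribute depth at exactly one placement.  Circular references
#' are handled by internal doubling up to the read length.
#'
#' @param reads data.frame with `id`, `seq` and optionally `qual` (constant
#'   Q30 assumed when absent), or the list returned by [simulate_reads()].
#' @param reference [org_genome()] or sequence string.
#' @param params [mapping_params()].
#' @return object of class `org_alnset`: a data.frame of accepted placements
#'   (`id`, `start`, `end` 0-based half-open — `end` past the reference
#'   length wraps on a circle —, `strand`, `identity`, `frac`, plus
#'   reference-projected read/quality strings used for pileups), with the
#'   reference kept as attributes.
#' @export
map_reads <- function(reads, reference, params = mapping_params()) {
  reads <- as_reads(reads)
  refseq <- genome_seq(reference)
  circular <- if (inherits(reference, "org_genome")) reference$circular else TRUE
  if (nchar(refseq) == 0) stop("empty reference")
  if (any(nchar(reads$seq) < params$seed_k))
    stop("seed length exceeds the shortest read")
  stride <- max(5L, as.integer(params$seed_k))
  hits <- cpp_map_reads(refseq, reads$seq, reads$qual,
                        as.integer(params$seed_k), stride,
                        params$length_fraction, params$similarity_fraction,
                        circular, as.integer(params$max_hits), 1000L)
  aln <- data.frame(id = reads$id[hits$read], start = hits$start,
                    end = hits$end, strand = hits$strand,
                    identity = hits$identity, frac = hits$frac,
                    proj = hits$proj, pqual = hits$pqual, ins = hits$ins)
  structure(aln, class = c("org_alnset", "data.frame"),
            ref_len = nchar(refseq), circular = circular,
            ref_id = if (inherits(reference, "org_genome")) reference$id else "ref",
            n_reads = nrow(reads), read_ids = reads$id,
            mapped_idx = hits$read, params = params)
}

#' @export
print.org_alnset <- function(x, ...) {
  cat(sprintf("<org_alnset> %d/%d reads mapped to %s (%d bp)\n",
              nrow(x), attr(x, "n_reads"), attr(x, "ref_id"),
              attr(x, "ref_len")))
  invisible(x)
}

#' Per-base coverage profile of an alignment set
#'
#' Depth counts aligned read bases per reference position (deleted
#' reference positions are not covered), so the profile sums to the total
#' number of aligned bases.
#'
#' @param alignments `org_alnset` from [map_reads()].
#' @return integer vector of depth, one entry per reference position.
#' @export
coverage_profile <- function(alignments) {
  L <- attr(alignments, "ref_len")
  if (nrow(alignments) == 0) return(integer(L))
  p <- cpp_pileup(L, alignments$start, alignments$proj, alignments$pqual, 0L)
  as.integer(colSums(p$counts[1:4, , drop = FALSE]))
}

# pileup matrices (5 x L; rows A,C,G,T,-) of counts and quality sums
pileup_matrices <- function(alignments, min_qual = 0L) {
  L <- attr(alignments, "ref_len")
  if (nrow(alignments) == 0)
    return(list(counts = matrix(0L, 5, L), qsum = matrix(0, 5, L)))
  p <- cpp_pileup(L, alignments$start, alignments$proj, alignments$pqual,
                  as.integer(min_qual))
  rownames(p$counts) <- rownames(p$qsum) <- c("A", "C", "G", "T", "-")
  p
}

#' Remove reads that map to a reference (chloroplast-read subtraction)
#'
#' Returns exactly the reads with no accepted placement at the given
#' (identity, overlap) thresholds, preserving input order.  The defaults
#' are the strict chloroplast-subtraction preset.
#'
#' @param reads as in [map_reads()].
#' @param reference [org_genome()] or string.
#' @param identity minimum identity (similarity fraction).
#' @param overlap minimum aligned read fraction (length fraction).
#' @param seed_k exact-seed word length.
#' @return data.frame of surviving reads (`id`, `seq`, `qual`).
#' @export
subtract_reads <- function(reads, reference, identity = 0.99, overlap = 0.99,
                           seed_k = 21) {
  reads <- as_reads(reads)
  aln <- map_reads(reads, reference,
                   mapping_params(length_fraction = overlap,
                                  similarity_fraction = identity,
                                  seed_k = seed_k))
  keep <- setdiff(seq_len(nrow(reads)), attr(aln, "mapped_idx"))
  reads[sort(keep), , drop = FALSE]
}

as_reads <- function(reads) {
  if (is.list(reads) && !is.data.frame(reads) && !is.null(reads$reads))
    reads <- reads$reads
  stopifnot(is.data.frame(reads), all(c("id", "seq") %in% names(reads)))
  if (!"qual" %in% names(reads) || anyNA(reads$qual))
    reads$qual <- vapply(nchar(reads$seq),
                         function(n) phred_char(rep(30L, n)), character(1))
  reads$seq <- toupper(reads$seq)
  reads
}
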