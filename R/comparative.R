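#' Consensus sequence of an alignment
#'
#' Per column, the most frequent non-gap symbol wins, ties alphabetically;
#' all-gap columns are dropped.  Consensus coordinates are 1-based over the
#' retained columns and are the coordinate system of [variant_matrix()]
#' positions and window scans.
#'
#' @param aln character matrix (rows = genomes) from [read_alignment()] or
#'   [evolve_lineage()].
#' @return list with `seq` (consensus string) and `col_map` (for each
#'   alignment column, its 1-based consensus coordinate; an all-gap column
#'   maps to the preceding consensus position).
#' @export
consensus_from_alignment <- function(aln) {
  if (is.null(dim(aln)) || nrow(aln) < 2) stop("alignment needs >= 2 rows")
  cnt <- vapply(DNA_BASES, function(b) colSums(aln == b), numeric(ncol(aln)))
  cnt <- matrix(cnt, ncol = 4, dimnames = list(NULL, DNA_BASES))
  keep <- rowSums(cnt) > 0                      # all-gap/N columns dropped
  win <- max.col(cnt, ties.method = "first")    # alphabetical tie-break
  col_map <- cumsum(keep)
  list(seq = paste(DNA_BASES[win[keep]], collapse = ""), col_map = col_map)
}

#' Variant matrix from an alignment
#'
#' Every alignment column carrying at least two distinct symbols (the gap
#' counts as a symbol, `N` is treated as missing) becomes a variable
#' position, classified `SNP` when no gap is involved and `InDel`
#' otherwise.  Positions are reported on 1-based consensus coordinates.
#'
#' @param aln character matrix (rows = genomes).
#' @return data.frame of class `variant_matrix`: `position` (consensus
#'   coordinate), `column` (alignment column), `class`, one allele column
#'   per genome.
#' @export
variant_matrix <- function(aln) {
  if (is.null(dim(aln)) || nrow(aln) < 2) stop("alignment needs >= 2 rows")
  n <- nrow(aln)
  # variable columns: any row differing from the first non-N symbol
  diff_any <- rep(FALSE, ncol(aln))
  for (r in seq2(2, n))
    diff_any <- diff_any | (aln[r, ] != aln[1, ])
  cand <- which(diff_any)
  variable <- cand[vapply(cand, function(j) {
    cc <- aln[, j]
    length(unique(cc[cc != "N"])) >= 2
  }, logical(1))]
  cons <- consensus_from_alignment(aln)
  out <- data.frame(position = cons$col_map[variable], column = variable)
  if (length(variable) > 0) {
    alle <- aln[, variable, drop = FALSE]
    out$class <- ifelse(apply(alle == "-", 2, any), "InDel", "SNP")
    out <- cbind(out, as.data.frame(t(alle), row.names = NULL))
  } else {
    out$class <- character(0)
    out <- cbind(out, as.data.frame(matrix(character(), 0, n,
                                           dimnames = list(NULL, rownames(aln)))))
  }
  rownames(out) <- NULL
  class(out) <- c("variant_matrix", "data.frame")
  attr(out, "genomes") <- rownames(aln)
  attr(out, "consensus_len") <- nchar(cons$seq)
  out
}

#' Build a variant matrix from a genotyping table
#'
#' For encoding externally genotyped variable positions (e.g. a printed
#' validation table: alleles per species at named positions) in the same
#' container [group_specific_positions()] consumes.
#'
#' @param position numeric/integer vector of 1-based consensus coordinates.
#' @param class character vector, `"SNP"`/`"InDel"` per position.
#' @param alleles matrix or data.frame of alleles, rows = positions,
#'   columns = genome ids (use `"-"` for a deleted allele).
#' @return `variant_matrix` object.
#' @export
variant_matrix_from_alleles <- function(position, class, alleles) {
  alleles <- as.data.frame(alleles)
  stopifnot(length(position) == nrow(alleles))
  class <- rep(class, length.out = nrow(alleles))
  out <- cbind(data.frame(position = position, column = position, class = class),
               alleles)
  class(out) <- c("variant_matrix", "data.frame")
  attr(out, "genomes") <- colnames(alleles)
  out
}

#' Filter a variant matrix for group-specific (barcode) positions
#'
#' Retains the positions where every allele carried by the target group is
#' absent from all non-target genomes — the whole-plastome barcode filter.
#' Also returns the SNP-class subset (the barcode SNPs proper).
#'
#' @param matrix `variant_matrix`.
#' @param target_group character vector of genome ids; must be a proper
#'   nonempty subset of the matrix genomes.
#' @return list with `positions` (filtered `variant_matrix` rows) and
#'   `snp_positions` (its SNP-class subset).
#' @export
group_specific_positions <- function(matrix, target_group) {
  genomes <- attr(matrix, "genomes")
  if (!all(target_group %in% genomes))
    stop("target group is not a subset of the matrix genomes")
  if (length(target_group) == 0 || length(target_group) == length(genomes))
    stop("target group must be a proper nonempty subset of the genomes")
  rest <- setdiff(genomes, target_group)
  keep <- vapply(seq_len(nrow(matrix)), function(i) {
    tg <- unique(unlist(matrix[i, target_group], use.names = FALSE))
    ot <- unique(unlist(matrix[i, rest], use.names = FALSE))
    tg <- tg[tg != "N"]; ot <- ot[ot != "N"]
    length(tg) > 0 && !any(tg %in% ot)
  }, logical(1))
  pos <- matrix[keep, , drop = FALSE]
  list(positions = pos,
       snp_positions = pos[pos$class == "SNP", , drop = FALSE])
}

#' Window parameters for hotspot scans
#'
#' @param window window width (bp), default 10 kb.
#' @param step step between window starts; defaults to `window`
#'   (non-overlapping tiling).
#' @return list of class `window_params`.
#' @export
window_params <- function(window = 10000, step = window) {
  stopifnot(window > 0, step > 0)
  structure(list(window = window, step = step), class = "window_params")
}

#' Windowed variable-position counts (variation hotspots)
#'
#' Counts variable positions per window of the consensus (1-based closed
#' intervals: 1–10,000, 10,001–20,000, ...), ranked by descending count
#' with ties broken by window start.
#'
#' @param matrix `variant_matrix`.
#' @param consensus_len consensus sequence length (bp).
#' @param params [window_params()].
#' @return data.frame `start`, `end` (1-based closed), `count`, `rank`,
#'   ordered by rank.
#' @export
window_scan <- function(matrix, consensus_len, params = window_params()) {
  if (params$window > consensus_len)
    warning("window larger than the consensus; using a single window")
  starts <- seq.int(1L, consensus_len, by = params$step)
  ends <- pmin(starts + params$window - 1L, consensus_len)
  counts <- vapply(seq_along(starts), function(i)
    sum(matrix$position >= starts[i] & matrix$position <= ends[i]), integer(1))
  out <- data.frame(start = starts, end = ends, count = counts)
  out <- out[order(-out$count, out$start), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Pairwise percent identity of aligned genomes
#'
#' Per pair: matches over the aligned columns where neither row has a gap,
#' times 100, 2 decimals.  Diagonal is 100.
#'
#' @param aln character matrix (rows = genomes).
#' @return symmetric numeric matrix of percent identities.
#' @export
pairwise_identity <- function(aln) {
  if (is.null(dim(aln)) || nrow(aln) < 2) stop("alignment needs >= 2 rows")
  n <- nrow(aln)
  ids <- rownames(aln)
  M <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- aln[i, ] != "-" & aln[j, ] != "-"
    if (!any(ok)) stop("pair (", ids[i], ", ", ids[j],
                       ") has no gap-free aligned columns")
    M[i, j] <- M[j, i] <- round(100 * sum(aln[i, ok] == aln[j, ok]) / sum(ok), 2)
  }
  M
}

#' Export barcode positions onto a reference genome
#'
#' Maps consensus positions through the alignment onto an aligned reference
#' genome and writes a BED record per barcode SNP (plus an optional minimal
#' VCF).  Positions falling in a reference gap are skipped and counted.
#'
#' @param positions `variant_matrix` rows to export (e.g.
#'   `$snp_positions` from [group_specific_positions()]).
#' @param aln the alignment the positions came from.
#' @param reference_id row name of the reference genome in `aln`.
#' @param bed_path output BED path, or `NULL` to skip writing.
#' @return list with `intervals` (0-based reference coordinates, data.frame
#'   `chrom`, `start`, `end`, `name`) and `skipped` (count of positions in
#'   reference gaps), invisibly writing BED when `bed_path` is given.
#' @export
barcode_export <- function(positions, aln, reference_id, bed_path = NULL) {
  stopifnot(reference_id %in% rownames(aln))
  refrow <- aln[reference_id, ]
  # reference coordinate of each alignment column (0-based; gap -> NA)
  refpos <- cumsum(refrow != "-") - 1L
  refpos[refrow == "-"] <- NA_integer_
  cols <- positions$column
  if (length(cols) == 0)
    return(list(intervals = data.frame(chrom = character(), start = integer(),
                                       end = integer(), name = character()),
                skipped = 0L))
  hit <- !is.na(refpos[cols])
  intervals <- data.frame(chrom = reference_id,
                          start = refpos[cols[hit]],
                          end = refpos[cols[hit]] + 1L,
                          name = sprintf("barcode_%d", positions$position[hit]))
  intervals <- intervals[order(intervals$start), , drop = FALSE]
  rownames(intervals) <- NULL
  if (!is.null(bed_path) && nrow(intervals) > 0)
    write_intervals(intervals, bed_path)
  list(intervals = intervals, skipped = sum(!hit))
}
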