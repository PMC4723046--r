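#' Consensus-calling policy
#'
#' @param min_cov minimum depth for a consensus column; "low coverage" has
#'   no canonical definition, so the threshold is explicit configuration
#'   (default 5).
#' @param low_cov_action `"split"` (segment boundaries at low-coverage
#'   columns; never emits N) or `"n_fill"` (low-coverage columns become N,
#'   preserving reference length).
#' @return list of class `consensus_policy`.
#' @export
consensus_policy <- function(min_cov = 5, low_cov_action = c("split", "n_fill")) {
  structure(list(min_cov = min_cov,
                 low_cov_action = match.arg(low_cov_action)),
            class = "consensus_policy")
}

#' Quality-voting consensus from mapped reads
#'
#' At each reference column the base maximizing the summed Phred quality of
#' its supporting reads wins; ties go to the higher read count, then
#' alphabetically.  Columns with depth below `min_cov` are removed: in
#' split mode they break the consensus into segments, in n_fill mode they
#' are replaced by `N`.  A winning deletion drops the column in split mode
#' and is written `N` in n_fill mode (which must preserve length).
#'
#' @param alignments `org_alnset` from [map_reads()].
#' @param reference the mapped reference (for length checking only).
#' @param policy [consensus_policy()].
#' @return data.frame of consensus segments: `start`, `end` (0-based
#'   half-open reference interval), `seq`.
#' @export
call_consensus <- function(alignments, reference, policy = consensus_policy()) {
  if (nrow(alignments) == 0) stop("empty alignment set")
  L <- attr(alignments, "ref_len")
  stopifnot(L == nchar(genome_seq(reference)))
  p <- pileup_matrices(alignments)
  depth <- colSums(p$counts)
  win <- apply_quality_vote(p)
  covered <- depth >= policy$min_cov
  if (policy$low_cov_action == "n_fill") {
    out <- win
    out[!covered] <- "N"
    out[covered & win == "-"] <- "N"
    return(data.frame(start = 0L, end = L, seq = paste(out, collapse = "")))
  }
  # split mode: runs of covered columns; deletions drop within a run
  r <- rle(covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- which(r$values)
  if (length(segs) == 0)
    return(data.frame(start = integer(), end = integer(), seq = character()))
  data.frame(
    start = starts[segs] - 1L,
    end = ends[segs],
    seq = vapply(segs, function(s) {
      cols <- win[starts[s]:ends[s]]
      paste(cols[cols != "-"], collapse = "")
    }, character(1)))
}

# winner per column: max quality sum, tie -> higher count, tie ->
# alphabetical; a deletion loses a full tie against any base
apply_quality_vote <- function(p) {
  bases <- c("A", "C", "G", "T", "-")   # row order of the pileup matrices
  score <- p$qsum * 1e6 + p$counts      # lexicographic (qsum, count)
  w <- max.col(t(score), ties.method = "first")
  bases[w]
}

#' Coverage-tier classification of contigs
#'
#' Discards contigs shorter than `min_len` (presets used by the pipeline:
#' 1000 bp for chloroplast contig selection, 300 bp for consensus
#' re-scaffolding, 2000 bp for mitochondrial scaffold keeping), then
#' clusters the survivors on log2 mean coverage into up to three tiers
#' (high/mid/low) by cutting the largest gaps in the sorted log-coverages.
#' Tier boundaries are returned for audit.
#'
#' @param contigs data.frame with `id` and `length` columns.
#' @param coverage named numeric vector of mean coverages (names = contig
#'   ids), computed from a common read pool.
#' @param min_len minimum contig length kept (bp).
#' @return list with `table` (id, length, coverage, tier), `tiers` (named
#'   list of contig ids) and `boundaries` (log2-coverage cut points).
#' @export
classify_by_coverage <- function(contigs, coverage, min_len = 1000) {
  stopifnot(all(c("id", "length") %in% names(contigs)),
            all(contigs$id %in% names(coverage)))
  keep <- contigs$length >= min_len
  if (!any(keep)) stop("all contigs are below min_len")
  tab <- contigs[keep, c("id", "length")]
  tab$coverage <- unname(coverage[tab$id])
  lg <- log2(tab$coverage + 1e-9)
  n_tier <- min(3L, length(unique(lg)))
  if (n_tier == 1L) {
    tab$tier <- "high"
    return(list(table = tab, tiers = list(high = tab$id), boundaries = numeric()))
  }
  o <- order(lg)
  gaps <- diff(lg[o])
  cut_idx <- sort(order(gaps, decreasing = TRUE)[seq_len(n_tier - 1L)])
  boundaries <- (lg[o][cut_idx] + lg[o][cut_idx + 1L]) / 2
  tier_num <- findInterval(lg, sort(boundaries))   # 0 = lowest
  labels <- rev(c("high", "mid", "low")[seq_len(n_tier)])
  tab$tier <- labels[tier_num + 1L]
  tiers <- split(tab$id, factor(tab$tier, levels = c("high", "mid", "low")))
  tiers <- tiers[vapply(tiers, length, integer(1)) > 0]
  list(table = tab, tiers = tiers, boundaries = sort(boundaries, decreasing = TRUE))
}
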