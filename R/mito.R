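#' Iteratively extend, merge and circularize mitochondrial scaffolds
#'
#' Each round first merges scaffolds whose ends share an overlap of at
#' least `min_overlap` bp at >= 99% identity (exact-seed anchored), then —
#' when reads are supplied — extends every scaffold end by quality-voting
#' consensus over the overhangs of reads anchored with at least
#' `min_anchor` matching bases inside the end, at depth >= `min_cov`.
#' Rounds stop at `max_rounds` or at a fixpoint.  If a single sequence
#' remains whose two ends overlap, the circle is closed and the overlap
#' deduplicated.  An end with more than one merge partner (three-way
#' overlap) is reported as an error rather than silently resolved.
#'
#' @param scaffolds character vector of scaffold sequences (chloroplast
#'   reads should have been subtracted from `reads` beforehand).
#' @param reads optional read set (as in [map_reads()]) for end extension.
#' @param max_rounds maximum extension/merge rounds.
#' @param min_anchor minimum matching bases of a read inside a scaffold end.
#' @param min_overlap minimum scaffold end overlap for merging/closure (bp).
#' @param min_cov minimum overhang depth for consensus extension.
#' @return list with `genome` ([org_genome()]; circular on success),
#'   `status` (`"circular"`, `"gap"` when a single linear sequence could
#'   not be closed, or `"fragmented"`), `scaffolds` (remaining sequences)
#'   and `rounds` used.
#' @export
iterative_extend_and_close <- function(scaffolds, reads = NULL, max_rounds = 20,
                                       min_anchor = 50, min_overlap = 100,
                                       min_cov = 5) {
  sc <- toupper(vapply(scaffolds, genome_seq, character(1)))
  names(sc) <- NULL
  stopifnot(length(sc) >= 1, all(nchar(sc) > 0))
  rd <- if (!is.null(reads)) as_reads(reads)
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    sc <- merge_scaffolds(sc, min_overlap)
    if (length(sc) == 1L) {
      closed <- close_circle(sc[1], min_overlap)
      if (!is.null(closed)) {
        return(list(genome = org_genome(closed, id = "mito_finished",
                                        circular = TRUE),
                    status = "circular", scaffolds = closed, rounds = rounds))
      }
    }
    grown <- FALSE
    if (!is.null(rd)) {
      for (i in seq_along(sc)) {
        ext <- extend_ends(sc[i], rd, min_anchor, min_cov)
        if (nchar(ext) > nchar(sc[i])) { sc[i] <- ext; grown <- TRUE }
      }
    }
    if (rounds >= max_rounds || !grown) break
  }
  sc <- merge_scaffolds(sc, min_overlap)
  if (length(sc) == 1L) {
    closed <- close_circle(sc[1], min_overlap)
    if (!is.null(closed)) {
      return(list(genome = org_genome(closed, id = "mito_finished",
                                      circular = TRUE),
                  status = "circular", scaffolds = closed, rounds = rounds))
    }
    return(list(genome = org_genome(sc[1], id = "mito_unclosed", circular = FALSE),
                status = "gap", scaffolds = sc, rounds = rounds))
  }
  longest <- sc[which.max(nchar(sc))]
  list(genome = org_genome(longest, id = "mito_unclosed", circular = FALSE),
       status = "fragmented", scaffolds = sc, rounds = rounds)
}

# merge scaffolds sharing end overlaps until no merge applies; considers
# both orientations of the incoming scaffold
merge_scaffolds <- function(sc, min_overlap) {
  repeat {
    n <- length(sc)
    if (n < 2L) return(sc)
    cands <- list()
    for (x in seq_len(n)) for (y in seq_len(n)) {
      if (x == y) next
      for (ori in c("+", "-")) {
        ys <- if (ori == "+") sc[y] else revcomp(sc[y])
        ov <- cpp_find_overlap(sc[x], ys, 31L, as.integer(min_overlap),
                               min(nchar(sc[x]), nchar(ys)) - 1L, 0.01)
        if (ov[1] > 0)
          cands[[length(cands) + 1L]] <- list(x = x, y = y, ori = ori, ov = ov[1])
      }
    }
    if (length(cands) == 0) return(sc)
    # conflict check: each scaffold end may have at most one partner
    right_ends <- vapply(cands, function(cc) cc$x, integer(1))
    if (anyDuplicated(right_ends)) {
      dup <- right_ends[duplicated(right_ends)][1]
      stop("conflicting merge: scaffold ", dup,
           " has multiple end-overlap partners (three-way overlap)")
    }
    cand <- cands[[order(-vapply(cands, function(cc) cc$ov, numeric(1)),
                         vapply(cands, function(cc) cc$x, integer(1)))[1]]]
    ys <- if (cand$ori == "+") sc[cand$y] else revcomp(sc[cand$y])
    merged <- paste0(sc[cand$x], substr(ys, cand$ov + 1L, nchar(ys)))
    sc <- c(merged, sc[-c(cand$x, cand$y)])
  }
}

# returns the deduplicated circle sequence, or NULL if the ends do not overlap
close_circle <- function(s, min_overlap) {
  ov <- cpp_find_overlap(s, s, 31L, as.integer(min_overlap),
                         nchar(s) - 1L, 0.01)
  if (ov[1] <= 0) return(NULL)
  substr(s, 1L, nchar(s) - ov[1])
}

# one round of quality-voting end extension from read overhangs
extend_ends <- function(s, rd, min_anchor, min_cov) {
  n <- nchar(s)
  win <- min(n, 800L)
  right <- substr(s, n - win + 1L, n)
  left <- substr(s, 1L, win)
  rseq <- c(rd$seq, vapply(rd$seq, cpp_revcomp, character(1), USE.NAMES = FALSE))
  rqual <- c(rd$qual, vapply(rd$qual, function(q)
    paste(rev(seq_chars(q)), collapse = ""), character(1), USE.NAMES = FALSE))
  # right end: suffix(window) / prefix(read)
  r_over <- r_qual <- character(0)
  l_over <- l_qual <- character(0)
  for (i in seq_along(rseq)) {
    m <- nchar(rseq[i])
    ov <- cpp_find_overlap(right, rseq[i], 15L, as.integer(min_anchor),
                           m - 1L, 0.02)
    if (ov[1] > 0) {
      r_over <- c(r_over, substr(rseq[i], ov[1] + 1L, m))
      r_qual <- c(r_qual, substr(rqual[i], ov[1] + 1L, m))
    }
    ov <- cpp_find_overlap(rseq[i], left, 15L, as.integer(min_anchor),
                           m - 1L, 0.02)
    if (ov[1] > 0) {
      l_over <- c(l_over, substr(rseq[i], 1L, m - ov[1]))
      l_qual <- c(l_qual, substr(rqual[i], 1L, m - ov[1]))
    }
  }
  ext_r <- overhang_consensus(r_over, r_qual, from_right = FALSE, min_cov)
  ext_l <- overhang_consensus(l_over, l_qual, from_right = TRUE, min_cov)
  paste0(ext_l, s, ext_r)
}

# quality-voting consensus of overhang strings; columns counted away from
# the scaffold end, truncated at the first column below min_cov
overhang_consensus <- function(over, qual, from_right, min_cov) {
  if (length(over) == 0) return("")
  if (from_right) {   # left-end overhangs: align on their right edge
    wmax <- max(nchar(over))
    over <- vapply(seq_along(over), function(i)
      paste0(strrep(" ", wmax - nchar(over[i])), over[i]), character(1))
    qual <- vapply(seq_along(qual), function(i)
      paste0(strrep("!", wmax - nchar(qual[i])), qual[i]), character(1))
  }
  wmax <- max(nchar(over))
  out <- character(0)
  for (col in seq_len(wmax)) {
    cc <- if (from_right) wmax - col + 1L else col
    b <- substr(over, cc, cc)
    qch <- substr(qual, cc, cc)
    keep <- b %in% DNA_BASES & nchar(qch) == 1L
    if (sum(keep) < min_cov) break
    b <- b[keep]
    q <- utf8ToInt(paste(qch[keep], collapse = "")) - 33L
    qs <- vapply(DNA_BASES, function(x) sum(q[b == x]), numeric(1))
    ct <- vapply(DNA_BASES, function(x) sum(b == x), numeric(1))
    out <- c(out, DNA_BASES[which.max(qs * 1e6 + ct)])
  }
  if (from_right) paste(rev(out), collapse = "") else paste(out, collapse = "")
}

#' Chloroplast-like-region detection parameters
#'
#' Defaults reproduce the screen used for real aspen mitochondria: BlastN
#' at word size 25 and e-value 1e-18, keeping hits of at least 100 bp and
#' at least 90% identity.
#'
#' @param min_identity minimum hit identity (fraction).
#' @param min_hit_len minimum hit length (bp).
#' @param word_size exact word size of the search.
#' @param evalue_max maximum e-value.
#' @return list of class `cplike_params`.
#' @export
cplike_params <- function(min_identity = 0.90, min_hit_len = 100,
                          word_size = 25, evalue_max = 1e-18) {
  structure(list(min_identity = min_identity, min_hit_len = min_hit_len,
                 word_size = word_size, evalue_max = evalue_max),
            class = "cplike_params")
}

#' Detect chloroplast-like regions in a mitochondrial genome
#'
#' Local alignment of the mitogenome against the chloroplast genome (BlastN
#' via the command-line `blastn`, both strands), followed by the
#' identity/length/e-value filter and merging of overlapping hits on the
#' mitogenome.
#'
#' @param mito,cp [org_genome()] or sequence strings (standardized
#'   linearizations).
#' @param params [cplike_params()].
#' @return list of class `cplike_regions`: `regions` (data.frame `start`,
#'   `end` 0-based half-open on the mitogenome, `length`, `identity` = best
#'   hit identity), `total_bp` and `fraction` of the mitogenome.
#' @export
find_cp_like_regions <- function(mito, cp, params = cplike_params()) {
  mseq <- genome_seq(mito); cseq <- genome_seq(cp)
  if (nchar(mseq) == 0 || nchar(cseq) == 0) stop("empty genome")
  if (Sys.which("blastn") == "" || Sys.which("makeblastdb") == "")
    stop("blastn/makeblastdb not found on PATH")
  td <- tempfile("cplike")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  qf <- file.path(td, "mito.fa"); sf <- file.path(td, "cp.fa")
  writeLines(c(">mito", mseq), qf)
  writeLines(c(">cp", cseq), sf)
  system2("makeblastdb", c("-in", sf, "-dbtype", "nucl"), stdout = FALSE)
  out <- system2("blastn",
                 c("-query", qf, "-db", sf, "-task", "blastn",
                   "-word_size", params$word_size, "-evalue",
                   format(params$evalue_max, scientific = TRUE),
                   "-dust", "no",
                   "-outfmt", shQuote("6 qstart qend pident length evalue")),
                 stdout = TRUE)
  empty <- list(regions = data.frame(start = integer(), end = integer(),
                                     length = integer(), identity = numeric()),
                total_bp = 0L, fraction = 0)
  class(empty) <- "cplike_regions"
  if (length(out) == 0) return(empty)
  hits <- read.table(text = out, col.names = c("qstart", "qend", "pident",
                                               "length", "evalue"))
  hits <- hits[hits$pident >= params$min_identity * 100 &
                 hits$length >= params$min_hit_len &
                 hits$evalue <= params$evalue_max, , drop = FALSE]
  if (nrow(hits) == 0) return(empty)
  ir <- IRanges::reduce(IRanges::IRanges(start = hits$qstart, end = hits$qend))
  regions <- data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  regions$length <- regions$end - regions$start
  regions$identity <- vapply(seq_len(nrow(regions)), function(i) {
    sel <- hits$qstart - 1L < regions$end[i] & hits$qend > regions$start[i]
    max(hits$pident[sel]) / 100
  }, numeric(1))
  res <- list(regions = regions, total_bp = sum(regions$length),
              fraction = sum(regions$length) / nchar(mseq))
  class(res) <- "cplike_regions"
  res
}

#' @export
print.cplike_regions <- function(x, ...) {
  cat(sprintf("<cplike_regions> %d region(s), %d bp (%.2f%% of the genome)\n",
              nrow(x$regions), x$total_bp, 100 * x$fraction))
  invisible(x)
}

#' Flag chloroplast-like regions with elevated read coverage
#'
#' Returns the chloroplast-like regions whose mean depth is at least `fold`
#' times the genome-wide median depth (the signature of chloroplast-derived
#' reads mapping unspecifically), plus any other interval of at least
#' `min_len` bp meeting the same criterion (unexplained anomaly).
#'
#' @param coverage integer vector of per-base depth from mapping the
#'   unsubtracted read pool to the mitogenome.
#' @param regions `cplike_regions` from [find_cp_like_regions()].
#' @param fold fold-change threshold over the median.
#' @param min_len minimum length of a flagged non-chloroplast-like interval.
#' @return data.frame `start`, `end`, `type` (`"cp_like"`/`"anomaly"`),
#'   `mean_depth`.
#' @export
flag_cp_coverage_regions <- function(coverage, regions, fold = 2.0,
                                     min_len = 100) {
  med <- median(coverage)
  if (med == 0) stop("zero median coverage")
  thr <- fold * med
  out <- data.frame(start = integer(), end = integer(), type = character(),
                    mean_depth = numeric())
  reg <- regions$regions
  in_cp <- rep(FALSE, length(coverage))
  for (i in seq_len(nrow(reg))) {
    iv <- (reg$start[i] + 1L):reg$end[i]
    in_cp[iv] <- TRUE
    md <- mean(coverage[iv])
    if (is.finite(thr) && md >= thr)
      out <- rbind(out, data.frame(start = reg$start[i], end = reg$end[i],
                                   type = "cp_like", mean_depth = md))
  }
  if (is.finite(thr)) {
    hi <- coverage >= thr & !in_cp
    r <- rle(hi)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (s in which(r$values & r$lengths >= min_len)) {
      iv <- starts[s]:ends[s]
      out <- rbind(out, data.frame(start = starts[s] - 1L, end = ends[s],
                                   type = "anomaly",
                                   mean_depth = mean(coverage[iv])))
    }
  }
  rownames(out) <- NULL
  out[order(out$start), , drop = FALSE]
}
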