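#' Detect the inverted-repeat pair of a circular genome
#'
#' Finds the maximal-length disjoint interval pair related by reverse
#' complement at `min_identity` or better, using exact-seed matching
#' (word length `seed_k`) on the doubled circle followed by greedy
#' identity-bounded outward extension.  The two single-copy arcs between
#' the repeats are derived and the longer one labeled LSC.  The repeat
#' following the LSC in forward orientation is labeled IRa.
#'
#' @param genome [org_genome()] (circular) or sequence string.
#' @param min_ir minimum repeat length reported (bp).
#' @param min_identity minimum identity between the two copies.
#' @param seed_k exact-seed word length.
#' @return object of class `quadripartite`: intervals `lsc`, `ira`, `ssc`,
#'   `irb` as `c(start, end)` 0-based half-open on the circle (an end past
#'   the sequence length wraps), `total_len`, and `has_ir`.  When no repeat
#'   of at least `min_ir` exists the IR intervals are empty and the whole
#'   circle is reported as LSC.
#' @export
detect_inverted_repeat <- function(genome, min_ir = 1000, min_identity = 0.99,
                                   seed_k = 25) {
  seq <- genome_seq(genome)
  L <- nchar(seq)
  if (L < 2 * seed_k) stop("genome shorter than two seed words")
  s2 <- paste0(seq, seq)
  seeds <- cpp_ir_seeds(s2, as.integer(seed_k), 200L)
  no_ir <- structure(list(total_len = L, has_ir = FALSE,
                          lsc = c(0L, L), ira = NULL, ssc = NULL, irb = NULL),
                     class = "quadripartite")
  if (length(seeds$i) == 0) return(no_ir)
  keep <- seeds$i < L & (seeds$j - seeds$i) < L & (seeds$j + seed_k) <= (seeds$i + L)
  si <- seeds$i[keep]; sj <- seeds$j[keep]
  if (length(si) == 0) return(no_ir)
  raw2 <- charToRaw(s2)

  best <- NULL
  for (d in unique(si + sj)) {
    sel <- (si + sj) == d
    ii <- sort(si[sel])
    # split seed runs at large gaps (separate repeats on one anti-diagonal)
    brk <- c(0L, which(diff(ii) > 2000L), length(ii))
    for (b in seq_len(length(brk) - 1L)) {
      run <- ii[(brk[b] + 1L):brk[b + 1L]]
      a1 <- run[1]; a2 <- run[length(run)] + seed_k             # copy1 [a1, a2)
      c1 <- d - run[length(run)]; c2 <- d - run[1] + seed_k     # copy2 [c1, c2)
      if (c1 < a2) next                                          # overlapping: skip
      ext <- extend_ir_pair(raw2, a1, a2, c1, c2, min_identity, L)
      len <- (ext[2] - ext[1]) + (ext[4] - ext[3])
      if (is.null(best) || len > best$len ||
          (len == best$len && ext[1] < best$iv[1])) {
        best <- list(len = len, iv = ext)
      }
    }
  }
  if (is.null(best)) return(no_ir)
  iv <- best$iv
  ir1_len <- iv[2] - iv[1]
  ir2_len <- iv[4] - iv[3]
  if (ir1_len < min_ir || ir2_len < min_ir) return(no_ir)
  rep1 <- c(iv[1], iv[2])
  rep2 <- c(iv[3], iv[4])
  # single-copy arcs between the copies (circle order rep1, arc1, rep2, arc2)
  arc1 <- c(rep1[2], rep2[1])
  arc2 <- c(rep2[2], rep1[1] + L)
  if (diff(arc1) >= diff(arc2)) {
    lsc <- arc1; ssc <- arc2; ira <- rep2; irb <- c(rep1[1] + L, rep1[2] + L)
  } else {
    lsc <- arc2; ssc <- arc1; ira <- c(rep1[1] + L, rep1[2] + L); irb <- rep2 + L
  }
  norm <- function(x) {
    o <- (x[1] %/% L) * L
    as.integer(x - o)
  }
  structure(list(total_len = L, has_ir = TRUE, lsc = norm(lsc),
                 ira = norm(ira), ssc = norm(ssc), irb = norm(irb)),
            class = "quadripartite")
}

#' @export
print.quadripartite <- function(x, ...) {
  if (!x$has_ir) {
    cat(sprintf("<quadripartite> %d bp, no inverted repeat\n", x$total_len))
    return(invisible(x))
  }
  cat(sprintf("<quadripartite> %d bp: LSC %d bp, IR %d bp (x2), SSC %d bp\n",
              x$total_len, diff(x$lsc), diff(x$ira), diff(x$ssc)))
  invisible(x)
}

# Outward extension of a seed-chained inverted pair [a1,a2) / [b1,b2)
# (0-based on the doubled sequence) by X-drop scoring (match +1, mismatch
# -2): each flank extends to its maximal-score point and stops once the
# running score falls `xdrop` below the best seen, so the boundary cannot
# drift into random flanking sequence.  The overall identity floor is
# still enforced column-by-column.
extend_ir_pair <- function(raw2, a1, a2, b1, b2, min_identity, L, xdrop = 12L) {
  comp_int <- integer(256)
  comp_int[as.integer(charToRaw("ACGTN-"))] <- as.integer(charToRaw("TGCAN-"))
  n2 <- length(raw2)
  cols <- a2 - a1
  mism <- sum(raw2[(a1 + 1L):a2] !=
                as.raw(comp_int[as.integer(rev(raw2[(b1 + 1L):b2]))]))
  # left flank of copy1 paired with right flank of copy2
  score <- 0L; chk <- c(a1, b2, cols, mism)
  while (a1 >= 1L && b2 < n2 && (b2 + 1L - a1) <= L) {
    m <- as.integer(as.integer(raw2[a1]) != comp_int[as.integer(raw2[b2 + 1L])])
    if ((cols + 1L - (mism + m)) / (cols + 1L) < min_identity) break
    score <- score + (if (m > 0L) -2L else 1L)
    if (score < -xdrop) break
    a1 <- a1 - 1L; b2 <- b2 + 1L; cols <- cols + 1L; mism <- mism + m
    if (score >= 0L) { score <- 0L; chk <- c(a1, b2, cols, mism) }
  }
  a1 <- chk[1]; b2 <- chk[2]; cols <- chk[3]; mism <- chk[4]
  # right flank of copy1 paired with left flank of copy2
  score <- 0L; chk <- c(a2, b1, cols, mism)
  while (b1 - a2 >= 2L) {
    m <- as.integer(as.integer(raw2[a2 + 1L]) != comp_int[as.integer(raw2[b1])])
    if ((cols + 1L - (mism + m)) / (cols + 1L) < min_identity) break
    score <- score + (if (m > 0L) -2L else 1L)
    if (score < -xdrop) break
    a2 <- a2 + 1L; b1 <- b1 - 1L; cols <- cols + 1L; mism <- mism + m
    if (score >= 0L) { score <- 0L; chk <- c(a2, b1, cols, mism) }
  }
  a2 <- chk[1]; b1 <- chk[2]
  c(a1, a2, b1, b2)
}

#' Collapse a quadripartite plastome into an assembly-style scaffold
#'
#' Emulates the collapsed-inverted-repeat artifact of de novo assembly: the
#' two identical IR copies assemble as a single internal copy, and short
#' stretches of the missing copy remain at both scaffold ends.  The inverse
#' of [expand_collapsed_ir()]; used for round-trip validation.
#'
#' @param genome standardized quadripartite [org_genome()] (regions LSC,
#'   IRa, SSC, IRb present).
#' @param stub length (bp) of the terminal IR stubs retained.
#' @return linear scaffold sequence (character string).
#' @export
collapse_plastome <- function(genome, stub = 300) {
  lsc <- region_seq(genome, "LSC"); ira <- region_seq(genome, "IRa")
  ssc <- region_seq(genome, "SSC"); irb <- region_seq(genome, "IRb")
  stopifnot(stub > 0, stub < nchar(irb))
  b_head <- substr(irb, 1L, stub)
  b_tail <- substr(irb, nchar(irb) - stub + 1L, nchar(irb))
  paste0(b_tail, lsc, ira, ssc, b_head)
}

#' Expand a collapsed-inverted-repeat scaffold into the full circle
#'
#' The scaffold must carry exactly one full IR copy internally (between LSC
#' and SSC) and terminal stubs of the second copy at both ends (at least
#' `min_stub` bp each).  The missing copy is synthesized as the reverse
#' complement of the internal copy and joined through exact matches of the
#' terminal stubs; the result is a circular genome.  IR boundary placements
#' that differ only by bases shared between a single-copy end and the
#' repeat produce the identical circle up to rotation.
#'
#' @param scaffold linear sequence string.
#' @param min_stub minimum terminal stub length used as the exact probe.
#' @return circular [org_genome()] (LSC/IRa/SSC/IRb regions set).
#' @export
expand_collapsed_ir <- function(scaffold, min_stub = 100) {
  s <- toupper(genome_seq(scaffold))
  n <- nchar(s)
  if (n < 4 * min_stub) stop("scaffold too short for the requested stub length")
  raw <- charToRaw(s)
  comp_int <- integer(256)
  comp_int[as.integer(charToRaw("ACGTN-"))] <- as.integer(charToRaw("TGCAN-"))

  probe_p <- revcomp(substr(s, 1L, min_stub))
  hit_p <- find_internal(s, probe_p, min_stub)
  if (length(hit_p) == 0) stop("no collapsed IR detected: prefix stub not found")
  if (length(hit_p) > 1) stop("ambiguous prefix stub: multiple matches")
  probe_q <- revcomp(substr(s, n - min_stub + 1L, n))
  hit_q <- find_internal(s, probe_q, min_stub)
  if (length(hit_q) == 0) stop("no collapsed IR detected: suffix stub not found")
  if (length(hit_q) > 1) stop("ambiguous suffix stub: multiple matches")

  # extend prefix stub: s[0..p) == revcomp of region ending at x_end
  x <- hit_p - 1L                       # 0-based start of revcomp(prefix probe)
  p <- min_stub
  while (p < n && x >= 1L &&
         as.integer(raw[p + 1L]) == comp_int[as.integer(raw[x])]) {
    p <- p + 1L; x <- x - 1L
  }
  ira_start <- x                        # 0-based: matched region is [x, hit_p-1+min_stub)
  # extend suffix stub: s[n-q..n) == revcomp of region starting at y
  y <- hit_q - 1L
  q <- min_stub
  while (q < n && (y + q) < n &&
         as.integer(raw[n - q]) == comp_int[as.integer(raw[y + q + 1L])]) {
    q <- q + 1L
  }
  ira_end <- y + q                      # 0-based half-open end of internal IR
  if (!(p <= ira_start && ira_start < ira_end && ira_end <= n - q))
    stop("no collapsed IR detected: stub matches are not internal LSC/IR/SSC layout")
  lsc <- substr(s, p + 1L, ira_start)
  ira <- substr(s, ira_start + 1L, ira_end)
  ssc <- substr(s, ira_end + 1L, n - q)
  irb <- revcomp(ira)
  lens <- c(nchar(lsc), nchar(ira), nchar(ssc), nchar(irb))
  org_genome(paste0(lsc, ira, ssc, irb), id = "expanded", circular = TRUE,
             regions = data.frame(name = c("LSC", "IRa", "SSC", "IRb"),
                                  start = cumsum(c(0L, lens[1:3])),
                                  end = cumsum(lens),
                                  strand = c("+", "+", "+", "-")))
}

# 1-based match positions of a probe strictly inside s (not at the ends)
find_internal <- function(s, probe, min_stub) {
  m <- gregexpr(probe, s, fixed = TRUE)[[1]]
  if (m[1] == -1) return(integer(0))
  m <- as.integer(m)
  m[m > min_stub & (m + nchar(probe) - 1L) <= (nchar(s) - min_stub)]
}

#' Standardize a plastome's rotation and strand
#'
#' Rotates the circle so position 0 is the first LSC base following IRb and
#' fixes the strand: with an `anchor` sequence supplied, the strand whose
#' standardized sequence begins with the reverse complement of the anchor
#' is chosen (the conventional LSC start of finished plastomes begins with
#' the reverse complement of the trnH gene); without one, the strand giving
#' the lexicographically smaller LSC.  Idempotent, and invariant under any
#' rotation or strand flip of the input.
#'
#' @param genome circular [org_genome()] or sequence string.
#' @param anchor optional short anchor sequence.
#' @param min_ir,min_identity,seed_k passed to [detect_inverted_repeat()].
#' @return list with `genome` (standardized [org_genome()]) and `structure`
#'   ([detect_inverted_repeat()] result on the standardized genome).
#' @export
standardize_plastome <- function(genome, anchor = NULL, min_ir = 1000,
                                 min_identity = 0.99, seed_k = 25) {
  seq <- genome_seq(genome)
  id <- if (inherits(genome, "org_genome")) genome$id else "plastome"
  qs <- detect_inverted_repeat(seq, min_ir, min_identity, seed_k)
  if (!qs$has_ir) stop("no inverted repeat detected; cannot standardize")
  cand_fwd <- orient_on_structure(seq, qs)
  rc <- revcomp(seq)
  qs_rc <- flip_structure(qs)
  cand_rev <- orient_on_structure(rc, qs_rc)
  pick <- if (!is.null(anchor)) {
    anchor <- toupper(anchor)
    tgt <- revcomp(anchor)
    hit_f <- startsWith(cand_fwd$seq, tgt)
    hit_r <- startsWith(cand_rev$seq, tgt)
    if (!hit_f && !hit_r) stop("anchor not found at the LSC start on either strand")
    if (hit_f) cand_fwd else cand_rev
  } else {
    lsc_f <- substr(cand_fwd$seq, 1L, diff(cand_fwd$structure$lsc))
    lsc_r <- substr(cand_rev$seq, 1L, diff(cand_rev$structure$lsc))
    if (lsc_f <= lsc_r) cand_fwd else cand_rev
  }
  g <- org_genome(pick$seq, id = id, circular = TRUE,
                  regions = structure_regions(pick$structure))
  list(genome = g, structure = pick$structure)
}

# rotate so that the LSC starts at 0; rebuild interval set
orient_on_structure <- function(seq, qs) {
  L <- nchar(seq)
  rot <- rotate_seq(seq, qs$lsc[1])
  lens <- c(diff(qs$lsc), diff(qs$ira), diff(qs$ssc), diff(qs$irb))
  st <- structure(list(total_len = L, has_ir = TRUE,
                       lsc = c(0L, lens[1]),
                       ira = c(lens[1], lens[1] + lens[2]),
                       ssc = c(lens[1] + lens[2], lens[1] + lens[2] + lens[3]),
                       irb = c(lens[1] + lens[2] + lens[3], L)),
                  class = "quadripartite")
  list(seq = rot, structure = st)
}

# structure of the reverse-complemented sequence: interval [s,e) -> [L-e, L-s);
# circle order reverses, IR labels swap, LSC stays LSC
flip_structure <- function(qs) {
  L <- qs$total_len
  fl <- function(x) {
    x <- c(L - x[2], L - x[1])
    if (x[1] < 0) x + L else x
  }
  structure(list(total_len = L, has_ir = TRUE, lsc = fl(qs$lsc),
                 ira = fl(qs$irb), ssc = fl(qs$ssc), irb = fl(qs$ira)),
            class = "quadripartite")
}

structure_regions <- function(qs) {
  data.frame(name = c("LSC", "IRa", "SSC", "IRb"),
             start = c(qs$lsc[1], qs$ira[1], qs$ssc[1], qs$irb[1]),
             end = c(qs$lsc[2], qs$ira[2], qs$ssc[2], qs$irb[2]),
             strand = c("+", "+", "+", "-"))
}

#' Compare two quadripartite structures
#'
#' Signed per-region length differences (b minus a) and the cumulative
#' border shifts; the region deltas sum to the total length delta.
#'
#' @param a,b `quadripartite` structures of standardized genomes.
#' @return list with `regions` (data.frame region, len_a, len_b, delta),
#'   `borders` (data.frame border, shift) and `total_delta`.
#' @export
compare_structures <- function(a, b) {
  stopifnot(inherits(a, "quadripartite"), inherits(b, "quadripartite"))
  if (!a$has_ir || !b$has_ir) stop("both structures must have inverted repeats")
  if (a$lsc[1] != 0 || b$lsc[1] != 0) stop("structures must be standardized (LSC at 0)")
  reg <- c("LSC", "IRa", "SSC", "IRb")
  la <- c(diff(a$lsc), diff(a$ira), diff(a$ssc), diff(a$irb))
  lb <- c(diff(b$lsc), diff(b$ira), diff(b$ssc), diff(b$irb))
  regions <- data.frame(region = reg, len_a = la, len_b = lb, delta = lb - la)
  borders <- data.frame(border = c("LSC/IRa", "IRa/SSC", "SSC/IRb", "IRb/LSC"),
                        shift = cumsum(lb - la))
  list(regions = regions, borders = borders,
       total_delta = b$total_len - a$total_len)
}
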