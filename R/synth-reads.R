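#' Simulate sequencing reads from labeled genomes with per-read truth
#'
#' Draws reads uniformly around each genome (reads may span the origin of
#' circular molecules) at label-specific fold coverages, emulating
#' organelle-typical high coverage over a low-coverage nuclear background.
#' Substitution errors are uniform; indel errors are applied only in
#' `"single"` mode (IonTorrent-like), while `"paired"` mode emulates 2x250
#' MiSeq pairs drawn from ~550 bp fragments.  Base qualities are constant
#' Q30 with simulated errors written at Q12, so downstream quality voting
#' has signal to act on.
#'
#' @param genomes named list of [org_genome()] (or plain sequences); names
#'   are the coverage labels.
#' @param coverage_weights named numeric vector, fold coverage per label;
#'   must cover every genome label.
#' @param mode `"single"` or `"paired"`.
#' @param read_len_mean,read_len_sd read length distribution (bp).
#' @param sub_error,indel_error per-base error rates in \[0, 1).
#' @param fragment_mean,fragment_sd paired-mode fragment length (bp).
#' @param seed integer seed; identical seeds give byte-identical output.
#' @return list with `reads` (data.frame `id`, `seq`, `qual`) and `truth`
#'   (data.frame `id`, `label`, `start`, `end`, `strand`; 0-based half-open
#'   on the source genome, end may wrap past the origin).
#' @export
simulate_reads <- function(genomes, coverage_weights, mode = c("paired", "single"),
                           read_len_mean = 250, read_len_sd = 0,
                           sub_error = 0.005, indel_error = 0,
                           fragment_mean = 550, fragment_sd = 60, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(sub_error >= 0, sub_error < 1, indel_error >= 0, indel_error < 1,
            all(coverage_weights > 0))
  if (!all(names(genomes) %in% names(coverage_weights)))
    stop("coverage_weights must cover every genome label")
  set.seed(seed)
  q_hi <- 30L; q_lo <- 12L
  per_label <- lapply(names(genomes), function(label) {
    g <- genomes[[label]]
    seq <- genome_seq(g)
    circ <- if (inherits(g, "org_genome")) g$circular else TRUE
    L <- nchar(seq)
    if (read_len_mean > L) stop("read length exceeds genome length for '", label, "'")
    cov <- coverage_weights[[label]]
    n <- max(1L, round(cov * L / read_len_mean))
    if (mode == "paired") {
      n <- as.integer(ceiling(n / 2))
      m <- 2L * n
      id <- seqv <- qualv <- strandv <- character(m)
      startv <- endv <- integer(m)
      for (i in seq_len(n)) {
        frag <- max(100L, round(rnorm(1, fragment_mean, fragment_sd)))
        frag <- min(frag, L)
        st <- sample.int(if (circ) L else L - frag + 1L, 1L) - 1L
        fseq <- subseq_circ(seq, st, st + frag, circ)
        flip <- runif(1) < 0.5
        if (flip) fseq <- revcomp(fseq)
        rl <- pmin(read_len(2L, read_len_mean, read_len_sd), frag)
        e1 <- apply_errors(substr(fseq, 1L, rl[1]), sub_error, 0, q_hi, q_lo)
        e2 <- apply_errors(revcomp(substr(fseq, frag - rl[2] + 1L, frag)),
                           sub_error, 0, q_hi, q_lo)
        # truth in forward-genome coordinates
        rs1 <- if (!flip) st else st + frag - rl[1]
        rs2 <- if (!flip) st + frag - rl[2] else st
        j <- 2L * i - 1L
        id[j:(j + 1L)] <- sprintf("%s_%d/%d", label, i, 1:2)
        seqv[j] <- e1$seq; seqv[j + 1L] <- e2$seq
        qualv[j] <- e1$qual; qualv[j + 1L] <- e2$qual
        startv[j] <- rs1 %% L; startv[j + 1L] <- rs2 %% L
        endv[j] <- rs1 %% L + rl[1]; endv[j + 1L] <- rs2 %% L + rl[2]
        strandv[j:(j + 1L)] <- if (!flip) c("+", "-") else c("-", "+")
      }
      data.frame(id = id, seq = seqv, qual = qualv, start = startv,
                 end = endv, strand = strandv)
    } else {
      id <- seqv <- qualv <- strandv <- character(n)
      startv <- endv <- integer(n)
      for (i in seq_len(n)) {
        rl <- min(read_len(1L, read_len_mean, read_len_sd), L)
        st <- sample.int(if (circ) L else L - rl + 1L, 1L) - 1L
        rseq <- subseq_circ(seq, st, st + rl, circ)
        strand <- sample(c("+", "-"), 1L)
        if (strand == "-") rseq <- revcomp(rseq)
        e <- apply_errors(rseq, sub_error, indel_error, q_hi, q_lo)
        id[i] <- sprintf("%s_%d", label, i)
        seqv[i] <- e$seq; qualv[i] <- e$qual
        startv[i] <- st; endv[i] <- st + rl; strandv[i] <- strand
      }
      data.frame(id = id, seq = seqv, qual = qualv, start = startv,
                 end = endv, strand = strandv)
    }
  })
  names(per_label) <- names(genomes)
  tab <- do.call(rbind, lapply(names(per_label), function(label)
    cbind(per_label[[label]], label = label)))
  rownames(tab) <- NULL
  list(reads = tab[, c("id", "seq", "qual")],
       truth = tab[, c("id", "label", "start", "end", "strand")])
}

read_len <- function(n, mean, sd) {
  if (sd <= 0) return(rep(as.integer(mean), n))
  pmax(30L, as.integer(round(rnorm(n, mean, sd))))
}

# substitution + (optional) indel errors; error bases get quality q_lo
apply_errors <- function(rseq, sub_error, indel_error, q_hi, q_lo) {
  n <- nchar(rseq)
  qual <- rep(q_hi, n)
  if (sub_error > 0) {
    nerr <- rbinom(1L, n, sub_error)
    if (nerr > 0) {
      sc <- seq_chars(rseq)
      pos <- sample.int(n, nerr)
      for (p in pos) sc[p] <- sample(setdiff(DNA_BASES, sc[p]), 1L)
      qual[pos] <- q_lo
      rseq <- paste(sc, collapse = "")
    }
  }
  if (indel_error > 0) {
    nind <- rbinom(1L, n, indel_error)
    if (nind > 0) {
      sc <- seq_chars(rseq)
      qc <- qual
      for (p in sort(sample.int(length(sc), nind), decreasing = TRUE)) {
        if (runif(1) < 0.5) {               # deletion
          sc <- sc[-p]; qc <- qc[-p]
        } else {                            # insertion of one random base
          sc <- append(sc, sample(DNA_BASES, 1L), after = p)
          qc <- append(qc, q_lo, after = p)
        }
      }
      rseq <- paste(sc, collapse = "")
      qual <- qc
    }
  }
  list(seq = rseq, qual = phred_char(qual))
}
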