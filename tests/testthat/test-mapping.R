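test_that("exact and near-threshold reads obey the two-threshold contract", {
  g <- small_plastome(seed = 4)
  read <- substr(g$seq, 501, 600)                  # exact 100 bp substring
  aln <- map_reads(data.frame(id = "r1", seq = read), g)
  expect_equal(nrow(aln), 1)
  expect_equal(aln$start, 500)
  expect_equal(aln$identity, 1.0)
  # two substitutions in 100 bp: identity 0.98 < 0.99 -> rejected
  ch <- strsplit(read, "")[[1]]
  for (p in c(30, 70)) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  aln2 <- map_reads(data.frame(id = "r2", seq = paste(ch, collapse = "")),
                    g, mapping_params(0.95, 0.99))
  expect_equal(nrow(aln2), 0)
  # one substitution: identity 0.99 -> accepted
  ch <- strsplit(read, "")[[1]]
  ch[30] <- setdiff(c("A", "C", "G", "T"), ch[30])[1]
  aln3 <- map_reads(data.frame(id = "r3", seq = paste(ch, collapse = "")),
                    g, mapping_params(0.95, 0.99))
  expect_equal(nrow(aln3), 1)
  expect_equal(aln3$identity, 0.99)
})

test_that("acceptance decisions match a brute-force placement oracle", {
  set.seed(21)
  ref <- random_dna(450, 0.4)
  rref <- charToRaw(ref)
  brute_best_identity <- function(read) {
    # identity of the best ungapped placement, exhaustive over offsets
    m <- nchar(read)
    rr <- charToRaw(read)
    best <- 0
    for (p in 0:(nchar(ref) - m)) {
      mm <- sum(rref[(p + 1):(p + m)] != rr)
      best <- max(best, (m - mm) / m)
    }
    rc <- charToRaw(revcomp(read))
    for (p in 0:(nchar(ref) - m)) {
      mm <- sum(rref[(p + 1):(p + m)] != rc)
      best <- max(best, (m - mm) / m)
    }
    best
  }
  gl <- org_genome(ref, id = "lin", circular = FALSE)
  for (case in 1:40) {
    m <- sample(60:100, 1)
    p <- sample(0:(450 - m), 1)
    read <- substr(ref, p + 1, p + m)
    nerr <- sample(0:3, 1)
    if (nerr > 0) {
      ch <- strsplit(read, "")[[1]]
      for (q in sample(m, nerr)) ch[q] <- setdiff(c("A", "C", "G", "T"), ch[q])[1]
      read <- paste(ch, collapse = "")
    }
    if (runif(1) < 0.5) read <- revcomp(read)
    thr <- sample(c(0.95, 0.97, 0.99), 1)
    oracle <- brute_best_identity(read) >= thr
    got <- nrow(map_reads(data.frame(id = "r", seq = read), gl,
                          mapping_params(0.95, thr))) == 1
    expect_equal(got, oracle, info = sprintf("case %d", case))
  }
})

test_that("simulated reads map back to their true positions", {
  g <- gen_plastome(lsc_len = 10000, ssc_len = 3000, ir_len = 0, seed = 9)
  sim <- simulate_reads(list(g = g), c(g = 50), mode = "paired",
                        sub_error = 0.005, seed = 2)
  aln <- map_reads(sim, g, mapping_params(0.95, 0.99))
  tr <- sim$truth[match(aln$id, sim$truth$id), ]
  expect_gt(mean(abs(aln$start - tr$start) <= 2), 0.95)
  # coverage sums to the aligned bases
  cov <- coverage_profile(aln)
  expect_equal(sum(cov), sum(nchar(aln$proj) -
                               vapply(strsplit(aln$proj, ""), function(x)
                                 sum(x == "-"), integer(1))))
})

test_that("reads with indels are recovered by the banded alignment", {
  g <- small_plastome(seed = 12)
  read <- substr(g$seq, 2001, 2200)
  ch <- strsplit(read, "")[[1]]
  read_del <- paste(ch[-100], collapse = "")        # 1 bp deletion
  aln <- map_reads(data.frame(id = "d", seq = read_del), g,
                   mapping_params(0.95, 0.97))
  expect_equal(nrow(aln), 1)
  expect_equal(aln$start, 2000)
  expect_equal(aln$end - aln$start, 200)            # reference span keeps the base
  expect_match(aln$proj, "-", fixed = TRUE)
})

test_that("quality-voting consensus follows the quality-sum rule", {
  ref <- org_genome(random_dna(120, 0.5), id = "r", circular = FALSE)
  mk_reads <- function(base, n, q, pos = 60) {
    ch <- strsplit(ref$seq, "")[[1]]; ch[pos] <- base
    data.frame(id = sprintf("%s%d", base, seq_len(n)),
               seq = paste(ch, collapse = ""),
               qual = strrep(intToUtf8(q + 33), 120))
  }
  # 10x A(Q30) vs 2x G(Q30): majority and quality agree
  aln <- map_reads(rbind(mk_reads("A", 10, 30), mk_reads("G", 2, 30)), ref,
                   mapping_params(0.5, 0.5))
  cons <- call_consensus(aln, ref, consensus_policy(5, "n_fill"))
  expect_identical(substr(cons$seq, 60, 60), "A")
  # 3x A(Q40)=120 vs 4x G(Q20)=80: quality sum beats read count
  aln2 <- map_reads(rbind(mk_reads("A", 3, 40), mk_reads("G", 4, 20)), ref,
                    mapping_params(0.5, 0.5))
  cons2 <- call_consensus(aln2, ref, consensus_policy(2, "n_fill"))
  expect_identical(substr(cons2$seq, 60, 60), "A")
})

test_that("split-mode consensus breaks at uncovered columns and never emits N", {
  g <- org_genome(random_dna(3000, 0.4), id = "g", circular = FALSE)
  # reads tiling everything except a 50 bp central window
  mk <- function(s, e) substring(g$seq, seq(s, e - 150, by = 50),
                                 seq(s + 149, e - 1, by = 50))
  seqs <- c(mk(1, 1400), mk(1451, 3001))
  reads <- data.frame(id = sprintf("r%d", seq_along(seqs)), seq = seqs)
  reads <- reads[rep(seq_len(nrow(reads)), each = 6), ]
  reads$id <- sprintf("%s_%d", reads$id, seq_len(nrow(reads)))
  aln <- map_reads(reads, g, mapping_params(0.95, 0.99))
  segs <- call_consensus(aln, g, consensus_policy(5, "split"))
  expect_equal(nrow(segs), 2)
  expect_false(any(grepl("N", segs$seq)))
  # n_fill mode preserves reference length
  nf <- call_consensus(aln, g, consensus_policy(5, "n_fill"))
  expect_equal(nchar(nf$seq), 3000)
  expect_match(nf$seq, "N")
})

test_that("consensus of error-free reads reproduces a repeat-free reference", {
  g <- gen_plastome(lsc_len = 6000, ssc_len = 1500, ir_len = 0, seed = 3)
  sim <- simulate_reads(list(g = g), c(g = 30), mode = "paired",
                        sub_error = 0, seed = 5)
  aln <- map_reads(sim, g)
  cons <- call_consensus(aln, g, consensus_policy(5, "n_fill"))
  expect_identical(cons$seq, g$seq)
})

test_that("coverage classification tiers contigs and audits boundaries", {
  cl <- classify_by_coverage(
    data.frame(id = c("c1", "c2", "c3", "c4"), length = c(5000, 4000, 3000, 2000)),
    c(c1 = 200, c2 = 195, c3 = 3, c4 = 2), min_len = 1000)
  expect_setequal(cl$tiers$high, c("c1", "c2"))
  expect_equal(length(cl$boundaries), 2)
  single <- classify_by_coverage(data.frame(id = "c", length = 2000), c(c = 10))
  expect_identical(single$tiers$high, "c")
  expect_error(classify_by_coverage(data.frame(id = "c", length = 10),
                                    c(c = 5), min_len = 1000), "below min_len")
})

test_that("simulated organelle/nuclear pools classify with no misassignment", {
  cp <- small_plastome(seed = 2)
  mt <- gen_mitogenome(length = 12000, seed = 3)
  nuc <- org_genome(random_dna(15000, 0.36), id = "nuc")
  sim <- simulate_reads(list(cp = cp, mt = mt, nuc = nuc),
                        c(cp = 200, mt = 30, nuc = 2),
                        mode = "paired", sub_error = 0.002, seed = 6)
  contigs <- data.frame(id = c("cp", "mt", "nuc"),
                        length = c(length(cp), length(mt), length(nuc)))
  covs <- vapply(c(cp = "cp", mt = "mt", nuc = "nuc"), function(lb) {
    sum(nchar(sim$reads$seq[sim$truth$label == lb])) /
      contigs$length[contigs$id == lb]
  }, numeric(1))
  cl <- classify_by_coverage(contigs, covs, min_len = 1000)
  expect_identical(cl$tiers$high, "cp")
  expect_identical(cl$tiers$mid, "mt")
  expect_identical(cl$tiers$low, "nuc")
})

test_that("chloroplast subtraction removes exactly the accepted reads", {
  cp <- small_plastome(seed = 2)
  sim <- simulate_reads(list(cp = cp), c(cp = 10), mode = "paired",
                        sub_error = 0, seed = 4)
  surv <- subtract_reads(sim$reads, cp)
  expect_equal(nrow(surv), 0)                      # all error-free cp reads removed
  # mapped + surviving partition the input
  mt <- gen_mitogenome(length = 12000, insert_lens = 600, insert_identity = 0.95,
                       plastome = cp, seed = 5)
  pool <- simulate_reads(list(cp = cp, mt = mt), c(cp = 15, mt = 15),
                         mode = "paired", sub_error = 0.001, seed = 7)
  surv2 <- subtract_reads(pool$reads, cp)
  aln <- map_reads(pool$reads, cp, mapping_params(0.99, 0.99))
  expect_equal(sort(c(surv2$id, aln$id)), sort(pool$reads$id))
  expect_equal(length(intersect(surv2$id, aln$id)), 0)
  # the surviving pool is essentially chloroplast-free
  lab <- pool$truth$label[match(surv2$id, pool$truth$id)]
  expect_gte(mean(lab == "mt"), 0.99)
  # reads from the 95%-identity insert are below 0.99 and retained
  ins <- mt$truth$inserts
  ins_read <- substr(mt$seq, ins$start[1] + 26, ins$start[1] + 275)
  kept <- subtract_reads(data.frame(id = "ins", seq = ins_read), cp)
  expect_equal(nrow(kept), 1)
})
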