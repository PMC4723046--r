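test_that("scaffolds tiling a circle merge and close to the exact truth length", {
  for (s in 1:5) {
    cp <- small_plastome(seed = s)
    mt <- gen_mitogenome(length = 16000, insert_lens = 400,
                         insert_identity = 0.95, plastome = cp, seed = s + 10)
    sc <- shred_circle(mt, n = 8, overlap = 300)
    res <- iterative_extend_and_close(sample(sc))
    expect_identical(res$status, "circular")
    expect_equal(length(res$genome), length(mt))
    doubled <- paste0(mt$seq, mt$seq)
    expect_true(grepl(res$genome$seq, doubled, fixed = TRUE) ||
                  grepl(revcomp(res$genome$seq), doubled, fixed = TRUE))
  }
})

test_that("a single self-overlapping scaffold closes without read mapping", {
  mt <- gen_mitogenome(length = 9000, seed = 3)
  sc <- organellum:::subseq_circ(mt$seq, 0, 9000 + 250, TRUE)
  res <- iterative_extend_and_close(sc)
  expect_identical(res$status, "circular")
  expect_equal(length(res$genome), 9000)
})

test_that("read extension crosses scaffold gaps and closes the circle", {
  mt <- gen_mitogenome(length = 12000, seed = 5)
  sim <- simulate_reads(list(mt = mt), c(mt = 40), mode = "paired",
                        sub_error = 0, seed = 6)
  sc <- substr(mt$seq, 1501, 6000)                 # one 4.5 kb seed scaffold
  res <- iterative_extend_and_close(sc, reads = sim, max_rounds = 150)
  expect_identical(res$status, "circular")
  expect_equal(length(res$genome), length(mt))
})

test_that("withholding reads from a window yields a linear result with a gap", {
  mt <- gen_mitogenome(length = 12000, seed = 7)
  sim <- simulate_reads(list(mt = mt), c(mt = 40), mode = "paired",
                        sub_error = 0, seed = 8)
  gap <- c(4000, 6000)
  keep <- sim$truth$end <= gap[1] | sim$truth$start >= gap[2]
  reads <- sim$reads[keep, ]
  # two scaffolds covering everything outside the withheld window
  sc <- c(organellum:::subseq_circ(mt$seq, 6000, 12000 + 1500, TRUE),
          organellum:::subseq_circ(mt$seq, 1200, 4000, TRUE))
  res <- iterative_extend_and_close(sc, reads = reads, max_rounds = 40)
  expect_identical(res$status, "gap")
  expect_false(res$genome$circular)
  # recovered sequence stops at the withheld window: ~2 kb missing
  expect_lt(length(res$genome), length(mt) - 1500)
  expect_gt(length(res$genome), length(mt) - 2600)
})

test_that("three-way end overlaps are reported, not silently resolved", {
  mt <- gen_mitogenome(length = 8000, seed = 9)
  a <- substr(mt$seq, 1, 3000)
  b <- substr(mt$seq, 2701, 5500)
  b2 <- paste0(substr(mt$seq, 2701, 5500), random_dna(800, 0.4))
  expect_error(iterative_extend_and_close(c(a, b, b2)), "conflicting merge")
})

test_that("chloroplast-like region detection recovers planted inserts", {
  cp <- gen_plastome(seed = 17)
  mt <- gen_mitogenome(length = 30000, insert_lens = c(500, 700, 400),
                       insert_identity = 0.95, plastome = cp, seed = 18)
  cl <- find_cp_like_regions(mt, cp)
  expect_equal(nrow(cl$regions), 3)
  tr <- mt$truth$inserts
  expect_true(all(abs(cl$regions$start - tr$start) <= 25))
  expect_true(all(abs(cl$regions$end - tr$end) <= 25))
  expect_equal(cl$fraction, 1600 / 30000, tolerance = 0.05)
  expect_true(all(cl$regions$identity >= 0.90))
})

test_that("cp-like detection handles empty and self cases", {
  cp <- small_plastome(seed = 4)
  mt0 <- gen_mitogenome(length = 20000, seed = 5)
  cl0 <- find_cp_like_regions(mt0, cp)
  expect_equal(nrow(cl0$regions), 0)
  expect_equal(cl0$fraction, 0)
  self <- find_cp_like_regions(cp, cp)
  expect_equal(nrow(self$regions), 1)
  expect_equal(self$fraction, 1.0, tolerance = 1e-3)
  expect_error(find_cp_like_regions(org_genome(""), cp), "empty")
})

test_that("cp-like fraction grows with the number of planted inserts", {
  cp <- gen_plastome(seed = 21)
  f <- vapply(c(1, 3), function(k) {
    mt <- gen_mitogenome(length = 30000, insert_lens = rep(500, k),
                         insert_identity = 0.95, plastome = cp, seed = 22)
    find_cp_like_regions(mt, cp)$fraction
  }, numeric(1))
  expect_true(f[2] > f[1])
})

test_that("coverage flagging marks cp-like regions with doubled depth", {
  regions <- structure(list(regions = data.frame(
    start = c(1000L, 5000L), end = c(1500L, 5600L),
    length = c(500L, 600L), identity = c(0.95, 0.93)),
    total_bp = 1100L, fraction = 1100 / 10000), class = "cplike_regions")
  cov <- rep(30L, 10000)
  expect_equal(nrow(flag_cp_coverage_regions(cov, regions)), 0)  # uniform
  cov[1001:1500] <- 75L                                # leaking cp reads
  cov[8001:8300] <- 90L                                # unexplained anomaly
  fl <- flag_cp_coverage_regions(cov, regions, fold = 2)
  expect_equal(fl$type, c("cp_like", "anomaly"))
  expect_equal(fl$start, c(1000L, 8000L))
  expect_equal(nrow(flag_cp_coverage_regions(cov, regions, fold = Inf)), 0)
  expect_error(flag_cp_coverage_regions(rep(0L, 100), regions), "median")
})
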