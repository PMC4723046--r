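test_that("gen_plastome builds the quadripartite circle it promises", {
  g <- small_plastome(seed = 3)
  expect_s3_class(g, "org_genome")
  expect_equal(length(g), 8000 + 2000 + 2 * 3000)
  expect_identical(organellum:::region_seq(g, "IRb"),
                   revcomp(organellum:::region_seq(g, "IRa")))
  # degenerate case: no inverted repeat
  g0 <- gen_plastome(lsc_len = 1000, ssc_len = 500, ir_len = 0, seed = 1)
  expect_equal(length(g0), 1500)
  expect_false(any(c("IRa", "IRb") %in% g0$regions$name))
  # default spec reproduces the calibrated region lengths
  gd <- gen_plastome(seed = 5)
  expect_equal(length(gd), 84367 + 16670 + 2 * 27509)
  expect_identical(organellum:::region_seq(gd, "IRb"),
                   revcomp(organellum:::region_seq(gd, "IRa")))
  # determinism and validation
  expect_identical(small_plastome(seed = 7)$seq, small_plastome(seed = 7)$seq)
  expect_error(gen_plastome(lsc_len = 0), "lsc_len")
})

test_that("evolve_lineage with zero rates returns the ancestor everywhere", {
  anc <- small_plastome(seed = 2)
  ev <- evolve_lineage(anc, "((A:0,B:0):0,(C:0,D:0):0);", seed = 1)
  expect_equal(nrow(ev$variants), 0)
  for (tp in names(ev$leaves))
    expect_identical(ev$leaves[[tp]]$seq, anc$seq)
})

test_that("substitution counts follow the Poisson branch model", {
  anc <- gen_plastome(lsc_len = 1500, ssc_len = 500, ir_len = 0, seed = 4)
  L <- length(anc); r <- 0.01
  counts <- vapply(1:200, function(s) {
    ev <- evolve_lineage(anc, sprintf("(A:%g,B:0);", r), seed = s)
    sum(ev$alignment["A", ] != ev$alignment["B", ])
  }, numeric(1))
  lambda <- r * L
  # mean of 200 replicates within 4 sigma of the Poisson mean
  expect_lt(abs(mean(counts) - lambda), 4 * sqrt(lambda / 200))
  expect_lt(abs(var(counts) - lambda), lambda)  # variance of the right order
})

test_that("mutations in IRa are mirrored exactly into IRb", {
  anc <- small_plastome(seed = 6)
  ev <- evolve_lineage(anc, "((A:0.004,B:0.004):0.004,(C:0.004,D:0.004):0.004);",
                       indel_rate = 1e-5, seed = 3)
  ira <- organellum:::region_of(anc, "IRa")
  irb <- organellum:::region_of(anc, "IRb")
  for (tp in rownames(ev$alignment)) {
    a <- paste(ev$alignment[tp, (ira[1] + 1):ira[2]], collapse = "")
    b <- paste(ev$alignment[tp, (irb[1] + 1):irb[2]], collapse = "")
    expect_identical(b, revcomp(a))
  }
  # and the leaf genomes each still carry a detectable IR of the planted size
  q <- detect_inverted_repeat(ev$leaves$A, min_ir = 500)
  expect_equal(diff(q$ira), 3000)
})

test_that("clade-private sites round-trip through the barcode filter", {
  anc <- small_plastome(seed = 8)
  ev <- evolve_lineage(anc, flat_quartet(), seed = 11,
                       clade_private = list(clade = c("A", "B"), n_snp = 4))
  vm <- variant_matrix(ev$alignment)
  gs <- group_specific_positions(vm, c("A", "B"))
  expect_setequal(gs$positions$column, ev$private_cols)
  expect_equal(nrow(gs$snp_positions), 4)
})

test_that("gen_mitogenome plants inserts with exact truth accounting", {
  cp <- small_plastome(seed = 1)
  m0 <- gen_mitogenome(length = 20000, seed = 2)
  expect_equal(nrow(m0$truth$inserts), 0)
  m <- gen_mitogenome(length = 80000, insert_lens = c(500, 700, 400),
                      insert_identity = 1.0, plastome = cp, seed = 3)
  tr <- m$truth$inserts
  expect_equal(sum(tr$end - tr$start) / length(m), 1600 / 80000)
  for (i in seq_len(nrow(tr))) {
    planted <- substr(m$seq, tr$start[i] + 1, tr$end[i])
    src <- substr(cp$seq, tr$src_start[i] + 1, tr$src_end[i])
    if (tr$strand[i] == "-") src <- revcomp(src)
    expect_identical(planted, src)      # identity 1.0: zero mismatches
  }
  m2 <- gen_mitogenome(length = 20000, insert_lens = 600, insert_identity = 0.9,
                       plastome = cp, seed = 4)
  expect_equal(m2$truth$inserts$identity, 0.9, tolerance = 0.01)
  expect_error(gen_mitogenome(length = 1000, insert_lens = 2000,
                              plastome = cp), "exceed")
})

test_that("simulate_reads honors truth, circularity and coverage weights", {
  cp <- small_plastome(seed = 5)
  mt <- gen_mitogenome(length = 10000, seed = 6)
  nuc <- org_genome(random_dna(15000, 0.36), id = "nuc")
  sim <- simulate_reads(list(cp = cp, mt = mt, nuc = nuc),
                        c(cp = 200, mt = 30, nuc = 2),
                        mode = "paired", sub_error = 0, seed = 9)
  # error-free reads are exact substrings of their (rotated) source
  seqs <- list(cp = paste0(cp$seq, cp$seq), mt = paste0(mt$seq, mt$seq),
               nuc = paste0(nuc$seq, nuc$seq))
  idx <- sample(nrow(sim$reads), 200)
  for (i in idx) {
    tr <- sim$truth[i, ]
    src <- substr(seqs[[tr$label]], tr$start + 1, tr$end)
    if (tr$strand == "-") src <- revcomp(src)
    expect_identical(sim$reads$seq[i], src)
  }
  # realized coverage: ordered cp > mt > nuclear; within 10% at >= 20x
  bases <- tapply(nchar(sim$reads$seq), sim$truth$label, sum)
  cov <- c(bases[["cp"]] / length(cp), bases[["mt"]] / length(mt),
           bases[["nuc"]] / length(nuc))
  expect_true(cov[1] > cov[2] && cov[2] > cov[3])
  expect_lt(abs(cov[1] - 200) / 200, 0.10)
  expect_lt(abs(cov[2] - 30) / 30, 0.10)
})

test_that("read simulation is seed-deterministic to the byte", {
  cp <- small_plastome(seed = 5)
  f1 <- tempfile(fileext = ".fq"); f2 <- tempfile(fileext = ".fq")
  sim1 <- simulate_reads(list(cp = cp), c(cp = 5), mode = "single",
                         sub_error = 0.01, indel_error = 0.002, seed = 42)
  sim2 <- simulate_reads(list(cp = cp), c(cp = 5), mode = "single",
                         sub_error = 0.01, indel_error = 0.002, seed = 42)
  write_seqs(sim1$reads, f1, "fastq")
  write_seqs(sim2$reads, f2, "fastq")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
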