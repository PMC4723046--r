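test_that("alignment consensus follows majority with alphabetical ties", {
  aln <- rbind(a = c("A", "A", "A", "-"),
               b = c("A", "A", "G", "-"),
               c = c("A", "G", "G", "-"))
  cons <- consensus_from_alignment(aln)
  # col2 {A,A,G} -> A; col3 {A,G,G} -> G; all-gap col4 dropped
  expect_identical(cons$seq, "AAG")
  tie <- rbind(a = c("A"), b = c("G"))
  expect_identical(consensus_from_alignment(tie)$seq, "A")
  idd <- rbind(a = c("A", "C"), b = c("A", "C"))
  expect_identical(consensus_from_alignment(idd)$seq, "AC")
})

test_that("the variant matrix captures exactly the variable columns", {
  idd <- rbind(a = strsplit("ACGTACGT", "")[[1]],
               b = strsplit("ACGTACGT", "")[[1]])
  expect_equal(nrow(variant_matrix(idd)), 0)
  gapcol <- rbind(a = strsplit("ACGTA", "")[[1]],
                  b = strsplit("AC-TA", "")[[1]])
  vm <- variant_matrix(gapcol)
  expect_equal(nrow(vm), 1)
  expect_identical(vm$class, "InDel")
  # planted truth round-trip through the lineage simulator
  anc <- small_plastome(seed = 3)
  ev <- evolve_lineage(anc, "((A:0.002,B:0.002):0.002,(C:0.002,D:0.002):0.002);",
                       indel_rate = 5e-6, seed = 5)
  vm2 <- variant_matrix(ev$alignment)
  expect_setequal(vm2$column, ev$variants$column)
  expect_identical(vm2$class[order(vm2$column)],
                   ev$variants$class[order(ev$variants$column)])
})

test_that("the validated marker genotypes are all recovered as group-specific", {
  vm <- table1_matrix()
  gs <- group_specific_positions(vm, "P.tremula")
  expect_equal(nrow(gs$positions), 4)
  expect_equal(nrow(gs$snp_positions), 3)
  expect_setequal(gs$positions$position, c(160, 312, 324, 343))
})

test_that("group-specific filtering is strict and validates its inputs", {
  aln <- rbind(A = c("A", "C", "G"), B = c("A", "C", "G"),
               C = c("A", "C", "T"), D = c("A", "T", "G"))
  vm <- variant_matrix(aln)
  # no alleles private to {A,B}: C/D alleles differ but A,B carry shared ones
  gs <- group_specific_positions(vm, c("A", "B"))
  expect_equal(nrow(gs$positions), 0)
  expect_error(group_specific_positions(vm, c("A", "X")), "subset")
  expect_error(group_specific_positions(vm, c("A", "B", "C", "D")), "proper")
  # singleton target: returns at least the uniquely-alleled positions
  gsC <- group_specific_positions(vm, "C")
  expect_true(3 %in% gsC$positions$column)
})

test_that("planted clade-private positions survive the cascade exactly", {
  anc <- small_plastome(seed = 9)
  ev <- evolve_lineage(anc, flat_quartet(), seed = 21,
                       clade_private = list(clade = c("A", "B"),
                                            n_snp = 9, n_indel = 3))
  vm <- variant_matrix(ev$alignment)
  gs <- group_specific_positions(vm, c("A", "B"))
  expect_equal(nrow(gs$positions), 12)
  expect_equal(nrow(gs$snp_positions), 9)
  expect_setequal(gs$positions$column, ev$private_cols)
  # barcode positions are a subset of the matrix positions
  expect_true(all(gs$positions$position %in% vm$position))
})

test_that("window scans count and rank on 1-based closed intervals", {
  vm <- variant_matrix_from_alleles(
    position = c(10000, 10001, seq(12000, 17800, by = 200), 25000, 30001, 30500),
    class = "SNP",
    alleles = cbind(A = "A", B = "G")[rep(1, 35), , drop = FALSE])
  ws <- window_scan(vm, consensus_len = 40000, window_params(10000))
  expect_equal(sum(ws$count), nrow(vm))
  # window 2 (10,001-20,000) holds the planted cluster and ranks first
  expect_equal(ws$start[1], 10001)
  expect_equal(ws$count[1], 31)
  # boundary convention: 10,000 in window 1, 10,001 in window 2
  w1 <- ws[ws$start == 1, ]
  expect_equal(w1$count, 1)
  empty <- window_scan(vm[0, ], 40000, window_params(10000))
  expect_true(all(empty$count == 0))
  expect_warning(window_scan(vm, 5000, window_params(10000)), "single window")
})

test_that("pairwise identity ignores gapped columns and is symmetric", {
  rows <- rbind(A = strsplit(strrep("ACGTT", 20), "")[[1]],
                B = strsplit(strrep("ACGTT", 20), "")[[1]])
  expect_equal(pairwise_identity(rows)["A", "B"], 100)
  rows["B", 7] <- "A"
  expect_equal(pairwise_identity(rows)["A", "B"], 99.00)
  rows["B", 8] <- "-"                              # gapped column excluded
  expect_equal(pairwise_identity(rows)["A", "B"], round(100 * 98 / 99, 2))
  set.seed(2)
  rnd <- matrix(sample(c("A", "C", "G", "T", "-"), 300, TRUE), nrow = 3,
                dimnames = list(c("x", "y", "z"), NULL))
  M <- pairwise_identity(rnd)
  expect_true(isSymmetric(M))
  expect_true(all(diag(M) == 100))
})

test_that("gc_content matches its definition and excludes ambiguity", {
  expect_equal(gc_content("GATC"), 0.5)
  expect_equal(gc_content("AAAA"), 0)
  expect_equal(gc_content("GGNNCC"), 1.0)          # N outside the denominator
  expect_error(gc_content("NNNN"), "unambiguous")
  g <- gen_plastome(seed = 33)
  expect_lt(abs(gc_content(g$seq) - 0.3676), 0.005)
})

test_that("barcode export maps consensus positions to reference coordinates", {
  anc <- small_plastome(seed = 10)
  ev <- evolve_lineage(anc, flat_quartet(), seed = 31,
                       clade_private = list(clade = c("A", "B"), n_snp = 9))
  vm <- variant_matrix(ev$alignment)
  gs <- group_specific_positions(vm, c("A", "B"))
  bed <- tempfile(fileext = ".bed")
  be <- barcode_export(gs$snp_positions, ev$alignment, "A", bed_path = bed)
  expect_equal(nrow(be$intervals), 9)
  expect_equal(be$skipped, 0)
  # each exported coordinate carries the planted private allele in the leaf
  leafA <- ev$leaves$A$seq
  alleles <- substr(rep(leafA, 9), be$intervals$start + 1, be$intervals$start + 1)
  aln_alleles <- ev$alignment["A", sort(gs$snp_positions$column)]
  expect_identical(alleles, unname(aln_alleles))
  expect_equal(nrow(read_intervals(bed)), 9)
  # a position deleted in the chosen reference is skipped and counted
  aln2 <- rbind(A = c("A", "-", "G"), B = c("A", "C", "T"))
  vm2 <- variant_matrix(aln2)
  be2 <- barcode_export(vm2, aln2, "A")
  expect_equal(be2$skipped, 1)
  # empty set -> empty export
  be0 <- barcode_export(vm2[0, ], aln2, "A")
  expect_equal(nrow(be0$intervals), 0)
})

test_that("barcode SNP density inside the IRs stays at or below the outside", {
  anc <- small_plastome(seed = 12)
  ev <- evolve_lineage(anc, "((A:0.004,B:0.004):0.008,(C:0.006,D:0.006):0.006);",
                       seed = 41)
  vm <- variant_matrix(ev$alignment)
  gs <- group_specific_positions(vm, c("A", "B"))
  ira <- organellum:::region_of(anc, "IRa")
  irb <- organellum:::region_of(anc, "IRb")
  in_ir <- (gs$snp_positions$column > ira[1] & gs$snp_positions$column <= ira[2]) |
    (gs$snp_positions$column > irb[1] & gs$snp_positions$column <= irb[2])
  ir_len <- 2 * diff(ira)
  dens_ir <- sum(in_ir) / ir_len
  dens_sc <- sum(!in_ir) / (length(anc) - ir_len)
  expect_lte(dens_ir, dens_sc + 1e-9)
})
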