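# Small shared fixtures; everything is generated in code, full ground truth.

# desk-scale plastome: 16 kb quadripartite circle
small_plastome <- function(seed = 1) {
  gen_plastome(lsc_len = 8000, ssc_len = 2000, ir_len = 3000, seed = seed)
}

# introduce n substitutions at given (or spaced random) 1-based positions
plant_snvs <- function(genome, n, positions = NULL, spacing = 400, seed = 99) {
  set.seed(seed)
  ch <- strsplit(genome$seq, "")[[1]]
  if (is.null(positions)) {
    cand <- seq(spacing, length(ch) - spacing, by = spacing)
    positions <- sort(sample(cand, n))
  }
  for (p in positions) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  list(genome = org_genome(paste(ch, collapse = ""), id = "mutant",
                           circular = genome$circular),
       positions0 = positions - 1L)   # 0-based truth
}

# shred a circular genome into n scaffolds with fixed overlaps
shred_circle <- function(genome, n, overlap = 300) {
  L <- length(genome)
  starts <- round(seq(0, L, length.out = n + 1))[seq_len(n)]
  vapply(seq_len(n), function(i) {
    e <- if (i < n) starts[i + 1] + overlap else L + overlap
    organellum:::subseq_circ(genome$seq, starts[i], e, TRUE)
  }, character(1))
}

# a 4-taxon tree whose internal branches have zero length, so planted
# clade-private sites are the only group-specific positions
flat_quartet <- function(r = 0.001) {
  sprintf("((A:%g,B:%g):0,(C:%g,D:%g):0);", r, r, r, r)
}

# exact ultrametric distance matrix from a rooted topology: tip height 0,
# internal node height = 1 + max child height, d(i,j) = 2 * height(mrca)
ultrametric_from_topology <- function(tr) {
  tr <- ape::reorder.phylo(tr, "cladewise")
  ntip <- length(tr$tip.label)
  nn <- ntip + tr$Nnode
  kids <- split(tr$edge[, 2], tr$edge[, 1])
  h <- numeric(nn)
  height <- function(v) {
    if (v <= ntip) return(0)
    hv <- 1 + max(vapply(kids[[as.character(v)]], height, numeric(1)))
    h[v] <<- hv
    hv
  }
  root <- setdiff(tr$edge[, 1], tr$edge[, 2])[1]
  height(root)
  mr <- ape::mrca(tr)
  M <- 2 * matrix(h[mr], ntip, ntip)
  diag(M) <- 0
  dimnames(M) <- list(tr$tip.label, tr$tip.label)
  M
}

# Genotypes of the four Sanger-validated marker positions in the trnH-psbA
# linker across 13 species (three SNPs and one 6 bp InDel); the allele
# absent from the non-target species is encoded as the gap allele.
table1_matrix <- function() {
  species <- c("P.tremula", "P.tremuloides", "P.alba", "P.trichocarpa",
               "P.maximowiczii", "P.cathayana", "P.simonii", "P.szechuanica",
               "P.ussuriensis", "P.koreana", "P.nigra", "P.deltoides",
               "P.wilsonii")
  alle <- rbind(
    V_06 = c("A", rep("G", 12)),
    V_18 = c("G", rep("A", 12)),
    V_20 = c("C", rep("T", 12)),
    V_21 = c("GTCTTA", rep("-", 12)))
  colnames(alle) <- species
  variant_matrix_from_alleles(position = c(160, 312, 324, 343),
                              class = c("SNP", "SNP", "SNP", "InDel"),
                              alleles = alle)
}
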