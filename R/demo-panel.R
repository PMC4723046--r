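#' Simulate the nine-plastome comparison panel
#'
#' A ready-made study design for the comparative and phylogeny modules: a
#' full-size quadripartite plastome ancestor evolved into nine genomes —
#' two nearly identical aspen-like target genomes (`tremula_W52`,
#' `tremula_717`) and seven diverged relatives — with a 5-prime LSC
#' variation hotspot (rate doubled over the first 10 kb), occasional short
#' indels, and clade-private alleles planted for the target pair (163
#' SNP-class and 69 InDel-class sites, the size of a whole-plastome
#' barcode).  Branch lengths are chosen so that the panel carries on the
#' order of three thousand variable positions, the scale at which such
#' comparisons operate; the target stem and the stem of the remaining
#' clade have zero length so that the planted sites are the only
#' target-specific alleles by construction.
#'
#' @param seed integer seed.
#' @param n_snp,n_indel planted target-private SNP / InDel counts.
#' @param lsc_len,ssc_len,ir_len ancestor region sizes (bp); defaults are
#'   full plastome scale.
#' @return the [evolve_lineage()] result, plus `target` (the two target
#'   genome ids) and `ancestor`.
#' @export
simulate_aspen_panel <- function(seed = 1, n_snp = 163, n_indel = 69,
                                 lsc_len = 84367, ssc_len = 16670,
                                 ir_len = 27509) {
  ancestor <- gen_plastome(lsc_len = lsc_len, ssc_len = ssc_len,
                           ir_len = ir_len, seed = seed)
  tree <- paste0(
    "((tremula_W52:0.0002,tremula_717:0.0002):0,",
    "(((alba:0.0025,yunnanensis:0.0025):0.0007,cathayana:0.0030):0.0003,",
    "(trichocarpa:0.0025,balsamifera:0.0025):0.0005,",
    "(euphratica:0.0027,fremontii:0.0026):0.0004):0);")
  target <- c("tremula_W52", "tremula_717")
  ev <- evolve_lineage(
    ancestor, tree, indel_rate = 0.05,
    hotspot = list(start = 0, end = 10000, mult = 1.65),
    clade_private = list(clade = target, n_snp = n_snp, n_indel = n_indel),
    seed = seed + 1)
  ev$target <- target
  ev$ancestor <- ancestor
  ev
}
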