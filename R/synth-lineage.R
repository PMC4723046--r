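#' Evolve a plastome along a lineage tree with full ground truth
#'
#' Simulates leaf genomes from an ancestor down a rooted tree whose branch
#' lengths are expected substitutions per site, under an HKY-like scheme
#' (transition/transversion ratio `kappa`).  Indels (geometric lengths,
#' insertions and deletions equally likely) are restricted to single-copy
#' regions; substitutions drawn in IRa are mirrored into IRb after
#' simulation so the two inverted repeats of every leaf stay exactly
#' reverse-complementary.  A hotspot interval multiplies the local
#' substitution rate, emulating the elevated variability of the 5-prime LSC.
#' Clade-private sites force alleles carried only by a named clade, as
#' planted truth for barcode-filter validation.
#'
#' Inserted sequence does not mutate further down the tree, and indel and
#' clade-private edits never touch the IRs; both are deliberate
#' simplifications that keep the truth alignment exact.
#'
#' @param ancestor [org_genome()], linearized at its canonical start.
#' @param tree rooted [ape::phylo] tree (or newick string) with branch
#'   lengths in expected substitutions/site; tip labels name the leaves.
#' @param indel_rate expected indels per site per unit branch length
#'   (an indel-to-substitution ratio; 0 disables indels).
#' @param hotspot `list(start, end, mult)`, 0-based half-open on the
#'   ancestor, or `NULL`.
#' @param clade_private `list(clade = <tip labels>, n_snp =, n_indel =)` or
#'   `NULL`; plants alleles private to the clade at invariant single-copy
#'   columns.
#' @param kappa transition/transversion ratio (default 2).
#' @param ir_rate_scale multiplier on the substitution rate inside the
#'   inverted repeats (default 0.25: plastome IRs evolve several-fold
#'   slower than single-copy regions, consistent with the sparse IR signal
#'   of real whole-plastome barcodes).
#' @param seed integer seed.
#' @return list with `leaves` (named list of [org_genome()], gaps removed),
#'   `alignment` (true alignment matrix, rows = leaves), `variants` (true
#'   variant table: 1-based alignment column, class, one allele column per
#'   leaf), `private_cols` (alignment columns of planted clade-private
#'   sites) and `tree`.
#' @export
evolve_lineage <- function(ancestor, tree, indel_rate = 0, hotspot = NULL,
                           clade_private = NULL, kappa = 2,
                           ir_rate_scale = 0.25, seed = 1) {
  stopifnot(inherits(ancestor, "org_genome"))
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  if (any(tree$edge.length < 0)) stop("negative branch length")
  set.seed(seed)

  anc <- seq_chars(ancestor$seq)
  L <- length(anc)
  ira <- region_of(ancestor, "IRa")
  irb <- region_of(ancestor, "IRb")
  in_ir <- rep(FALSE, L)
  if (!is.null(ira)) in_ir[(ira[1] + 1):ira[2]] <- TRUE
  if (!is.null(irb)) in_ir[(irb[1] + 1):irb[2]] <- TRUE

  rate_mult <- rep(1, L)
  if (!is.null(hotspot)) {
    if (hotspot$start < 0 || hotspot$end > L || hotspot$start >= hotspot$end)
      stop("hotspot interval outside ancestor")
    rate_mult[(hotspot$start + 1):hotspot$end] <- hotspot$mult
  }
  if (!is.null(ira)) rate_mult[(ira[1] + 1):ira[2]] <- ir_rate_scale
  if (!is.null(irb)) rate_mult[(irb[1] + 1):irb[2]] <- 0  # mirrored, not drawn

  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  children <- split(tree$edge[, 2], tree$edge[, 1])
  blen <- setNames(tree$edge.length, tree$edge[, 2])

  transition <- c(A = "G", G = "A", C = "T", T = "C")
  tv <- list(A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G"))
  mutate_base <- function(b) {
    if (runif(1) < kappa / (kappa + 2)) transition[[b]] else sample(tv[[b]], 1)
  }

  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- anc
  ins_events <- list()   # each: list(node, anchor, seq)
  touched <- integer(0)  # ancestor columns hit by any event

  visit <- function(node) {
    for (child in children[[as.character(node)]]) {
      s <- seqs[[node]]
      bl <- blen[[as.character(child)]]
      alive <- s != "-"
      w <- rate_mult * alive
      nsub <- rpois(1, bl * sum(w))
      if (nsub > 0) {
        pos <- sample.int(L, nsub, replace = TRUE, prob = w)
        for (p in pos) s[p] <- mutate_base(s[p])
        touched <<- c(touched, pos)
      }
      w_ind <- alive & !in_ir
      nind <- if (indel_rate > 0) rpois(1, indel_rate * bl * sum(w_ind)) else 0
      if (nind > 0) {
        pos <- sample(which(w_ind), nind)
        for (p in pos) {
          len <- min(1 + rgeom(1, 0.5), 8)
          if (runif(1) < 0.5) {            # deletion of ancestor columns
            cols <- p:min(p + len - 1, L)
            cols <- cols[!in_ir[cols] & s[cols] != "-"]
            s[cols] <- "-"
            touched <<- c(touched, cols)
          } else {                          # insertion after column p
            ins_events[[length(ins_events) + 1]] <<-
              list(node = child, anchor = p,
                   seq = seq_chars(random_dna(len, 0.35)))
          }
        }
      }
      seqs[[child]] <<- s
      if (child > ntip) visit(child)
    }
  }
  if (!is.null(children[[as.character(root)]])) visit(root)

  tips <- tree$tip.label
  leaf_mat <- do.call(rbind, seqs[seq_len(ntip)])
  rownames(leaf_mat) <- tips

  # mirror IRa substitutions into IRb (exact reverse complement)
  if (!is.null(ira) && !is.null(irb)) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", "-" = "-")
    ira_cols <- (ira[1] + 1):ira[2]
    irb_cols <- (irb[1] + 1):irb[2]
    for (r in seq_len(ntip))
      leaf_mat[r, irb_cols] <- comp[leaf_mat[r, rev(ira_cols)]]
    touched <- c(touched, irb_cols[in_touched_ir(touched, ira, irb)])
  }

  private_anc_cols <- integer(0)
  if (!is.null(clade_private)) {
    clade <- clade_private$clade
    if (!all(clade %in% tips)) stop("clade tips absent from tree")
    if (length(clade) == 0 || all(tips %in% clade))
      stop("clade must be a proper nonempty subset of the tips")
    n_snp <- clade_private$n_snp %||% 0
    n_indel <- clade_private$n_indel %||% 0
    n_tot <- n_snp + n_indel
    if (n_tot > 0) {
      same <- rep(TRUE, L)
      for (r in seq2(2, ntip)) same <- same & (leaf_mat[r, ] == leaf_mat[1, ])
      cand <- which(!in_ir & same & leaf_mat[1, ] != "-")
      if (length(cand) < n_tot) stop("too few invariant columns for private sites")
      cols <- sort(sample(cand, n_tot))
      is_snp <- c(rep(TRUE, n_snp), rep(FALSE, n_indel))[sample(n_tot)]
      in_clade <- tips %in% clade
      for (t in seq_len(n_tot)) {
        p <- cols[t]
        shared <- leaf_mat[which(!in_clade)[1], p]
        leaf_mat[in_clade, p] <- if (is_snp[t]) transition[[shared]] else "-"
      }
      private_anc_cols <- cols
      touched <- c(touched, cols)
    }
  }

  # assemble alignment: ancestor columns + insertion columns after anchors
  desc_tips <- function(node) {
    if (node <= ntip) return(tips[node])
    unlist(lapply(children[[as.character(node)]], desc_tips))
  }
  n_ins <- length(ins_events)
  if (n_ins > 0) {
    ord <- order(vapply(ins_events, `[[`, numeric(1), "anchor"), seq_len(n_ins))
    ins_events <- ins_events[ord]
    blocks <- vector("list", 2 * n_ins + 1)
    prev <- 0L
    bi <- 1L
    ins_col_anchor <- integer(0)
    for (e in ins_events) {
      blocks[[bi]] <- leaf_mat[, seq2(prev + 1L, e$anchor), drop = FALSE]
      m <- matrix("-", ntip, length(e$seq))
      m[tips %in% desc_tips(e$node), ] <- rep(e$seq, each = sum(tips %in% desc_tips(e$node)))
      blocks[[bi + 1L]] <- m
      ins_col_anchor <- c(ins_col_anchor, rep(e$anchor, length(e$seq)))
      prev <- e$anchor
      bi <- bi + 2L
    }
    blocks[[bi]] <- leaf_mat[, seq2(prev + 1L, L), drop = FALSE]
    aln <- do.call(cbind, blocks)
    # alignment column index of each ancestor column
    n_ins_before <- cumsum(tabulate(ins_col_anchor + 1L, nbins = L + 1L))
    anc2aln <- seq_len(L) + n_ins_before[seq_len(L)]
    ins_cols <- setdiff(seq_len(ncol(aln)), anc2aln)
  } else {
    aln <- leaf_mat
    anc2aln <- seq_len(L)
    ins_cols <- integer(0)
  }
  colnames(aln) <- NULL

  cand_cols <- sort(unique(c(anc2aln[unique(touched)], ins_cols)))
  variable <- cand_cols[vapply(cand_cols, function(j) {
    cc <- aln[, j]
    length(unique(cc[cc != "N"])) >= 2
  }, logical(1))]
  variants <- if (length(variable) > 0) {
    cls <- ifelse(apply(aln[, variable, drop = FALSE] == "-", 2, any), "InDel", "SNP")
    cbind(data.frame(column = variable, class = cls),
          as.data.frame(t(aln[, variable, drop = FALSE])))
  } else {
    cbind(data.frame(column = integer(), class = character()),
          as.data.frame(matrix(character(), 0, ntip, dimnames = list(NULL, tips))))
  }

  leaves <- lapply(tips, function(tp) {
    org_genome(paste(leaf_mat[tp, leaf_mat[tp, ] != "-"], collapse = ""),
               id = tp, circular = ancestor$circular)
  })
  names(leaves) <- tips

  list(leaves = leaves, alignment = aln, variants = variants,
       private_cols = if (length(private_anc_cols)) anc2aln[private_anc_cols] else integer(0),
       tree = tree)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

seq2 <- function(from, to) if (from > to) integer(0) else seq.int(from, to)

# ancestor IRa columns among `touched`, mapped to their IRb mirrors
in_touched_ir <- function(touched, ira, irb) {
  tt <- unique(touched)
  tt <- tt[tt > ira[1] & tt <= ira[2]]
  if (length(tt) == 0) return(integer(0))
  # offset within IRa (1-based) t - ira[1]; mirror index in irb_cols vector
  (ira[2] - tt) + 1L
}
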