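#' Pairwise evolutionary distances from an alignment
#'
#' Per pair, only columns where neither row carries a gap or `N` are used.
#' Models: `jc69` and `k80` by their closed forms, `logdet` as the
#' paralinear determinant distance, and `gtr_gamma` by numerical
#' maximum likelihood on the pairwise count matrix with empirical
#' exchangeabilities and 4 discrete gamma rate categories of shape 1 (the
#' whole-plastome tree setting).  A saturated pair (logarithm of a
#' non-positive argument) yields `NA` and is flagged.
#'
#' @param aln character matrix (rows = genomes).
#' @param model one of `"jc69"`, `"k80"`, `"logdet"`, `"gtr_gamma"`.
#' @return object of class `org_dist`: the symmetric distance matrix with
#'   attributes `model` and `saturated` (logical matrix).
#' @export
pairwise_distance <- function(aln, model = c("jc69", "k80", "logdet", "gtr_gamma")) {
  model <- match.arg(model)
  if (is.null(dim(aln)) || nrow(aln) < 2) stop("alignment needs >= 2 rows")
  n <- nrow(aln)
  ids <- rownames(aln)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  sat <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  gtr <- if (model == "gtr_gamma") gtr_setup(aln)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- aln[i, ] %in% DNA_BASES & aln[j, ] %in% DNA_BASES
    if (!any(ok)) stop("pair without comparable columns")
    x <- aln[i, ok]; y <- aln[j, ok]
    d <- switch(model,
      jc69 = dist_jc69(mean(x != y)),
      k80 = dist_k80(x, y),
      logdet = dist_logdet(x, y),
      gtr_gamma = dist_gtr_gamma(x, y, gtr))
    if (!is.finite(d)) { sat[i, j] <- sat[j, i] <- TRUE; d <- NA_real_ }
    D[i, j] <- D[j, i] <- d
  }
  structure(D, model = model, saturated = sat, class = c("org_dist", "matrix"))
}

dist_jc69 <- function(p) {
  if (p == 0) return(0)
  a <- 1 - 4 * p / 3
  if (a <= 0) return(NA_real_)
  -3 / 4 * log(a)
}

dist_k80 <- function(x, y) {
  if (all(x == y)) return(0)
  ts_pairs <- c("AG", "GA", "CT", "TC")
  pair <- paste0(x, y)
  P <- mean(pair %in% ts_pairs)
  Q <- mean(x != y) - P
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0) return(NA_real_)
  -0.5 * log(a1) - 0.25 * log(a2)
}

# paralinear / LogDet distance from the 4x4 joint proportion matrix
dist_logdet <- function(x, y) {
  if (all(x == y)) return(0)
  F <- unclass(table(factor(x, DNA_BASES), factor(y, DNA_BASES))) / length(x)
  dt <- det(F)
  fx <- rowSums(F); fy <- colSums(F)
  if (dt <= 0 || any(fx <= 0) || any(fy <= 0)) return(NA_real_)
  -(log(dt) - 0.5 * (sum(log(fx)) + sum(log(fy)))) / 4
}

# pooled empirical GTR rate matrix and discrete-gamma rates (shape 1, 4 cats)
gtr_setup <- function(aln, shape = 1, ncat = 4) {
  n <- nrow(aln)
  FF <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- aln[i, ] %in% DNA_BASES & aln[j, ] %in% DNA_BASES
    FF <- FF + table(factor(aln[i, ok], DNA_BASES), factor(aln[j, ok], DNA_BASES))
  }
  FF <- (FF + t(FF)) / (2 * sum(FF))
  pi <- rowSums(FF)
  pi <- pmax(pi, 1e-9); pi <- pi / sum(pi)
  # exchangeabilities s_ij = F_ij / (pi_i pi_j); floor off-diagonals
  S <- FF / outer(pi, pi)
  S[S <= 0] <- 1e-6
  Q <- S * rep(pi, each = 4)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q <- Q / sum(pi * -diag(Q))               # mean rate 1
  # symmetrized eigendecomposition for stable matrix exponentials
  sp <- sqrt(pi)
  B <- diag(sp) %*% Q %*% diag(1 / sp)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  rates <- discrete_gamma_rates(shape, ncat)
  list(pi = pi, evec = diag(1 / sp) %*% e$vectors,
       ivec = t(e$vectors) %*% diag(sp), eval = e$values, rates = rates)
}

# mean rates of equal-probability gamma quantile slices (Yang's method)
discrete_gamma_rates <- function(shape, ncat) {
  q <- stats::qgamma(seq(0, 1, length.out = ncat + 1), shape, shape)
  r <- vapply(seq_len(ncat), function(k) {
    stats::pgamma(q[k + 1], shape + 1, shape) - stats::pgamma(q[k], shape + 1, shape)
  }, numeric(1)) * ncat
  r / mean(r)
}

dist_gtr_gamma <- function(x, y, gtr) {
  if (all(x == y)) return(0)
  N <- table(factor(x, DNA_BASES), factor(y, DNA_BASES))
  N <- (N + t(N)) / 2
  nll <- function(t) {
    P <- matrix(0, 4, 4)
    for (r in gtr$rates)
      P <- P + gtr$evec %*% diag(exp(gtr$eval * r * t)) %*% gtr$ivec / length(gtr$rates)
    P[P < 1e-12] <- 1e-12
    J <- gtr$pi * P
    -sum(N * log(J))
  }
  opt <- optimize(nll, c(1e-8, 15))
  if (opt$minimum > 14.5) return(NA_real_)
  opt$minimum
}

#' UPGMA tree from a distance matrix
#'
#' Standard unweighted pair group agglomeration with arithmetic-mean
#' linkage; cluster heights are halved into an ultrametric tree.  Ties are
#' broken deterministically by the lexicographically smallest pair of
#' cluster labels (a cluster is labeled by its smallest member).
#'
#' @param d `org_dist` or plain symmetric matrix with dimnames.
#' @return rooted ultrametric [ape::phylo] tree.
#' @export
upgma_tree <- function(d) {
  D <- unclass(d)
  if (anyNA(D)) stop("distance matrix contains NA (saturated pairs?)")
  n <- nrow(D)
  stopifnot(n >= 2, identical(rownames(D), colnames(D)))
  labels <- rownames(D)
  nodes <- as.list(labels)                 # newick fragment per cluster
  sizes <- rep(1L, n)
  heights <- rep(0, n)
  key <- labels                            # smallest member label
  active <- rep(TRUE, n)
  Dw <- D
  for (step in seq_len(n - 1)) {
    idx <- which(active)
    best <- NULL
    for (ai in seq_along(idx)) for (aj in seq2(ai + 1, length(idx))) {
      i <- idx[ai]; j <- idx[aj]
      dij <- Dw[i, j]
      pair_key <- sort(c(key[i], key[j]))
      if (is.null(best) || dij < best$d - 1e-12 ||
          (abs(dij - best$d) <= 1e-12 &&
           (pair_key[1] < best$key[1] ||
            (pair_key[1] == best$key[1] && pair_key[2] < best$key[2])))) {
        best <- list(i = i, j = j, d = dij, key = pair_key)
      }
    }
    i <- best$i; j <- best$j
    h <- best$d / 2
    left <- if (key[i] <= key[j]) i else j
    rght <- if (left == i) j else i
    newick <- sprintf("(%s:%s,%s:%s)",
                      nodes[[left]], format(h - heights[left], digits = 12),
                      nodes[[rght]], format(h - heights[rght], digits = 12))
    # UPGMA update: size-weighted arithmetic mean
    for (k in which(active)) {
      if (k == i || k == j) next
      Dw[i, k] <- Dw[k, i] <-
        (sizes[i] * Dw[i, k] + sizes[j] * Dw[j, k]) / (sizes[i] + sizes[j])
    }
    nodes[[i]] <- newick
    sizes[i] <- sizes[i] + sizes[j]
    heights[i] <- h
    key[i] <- min(key[i], key[j])
    active[j] <- FALSE
  }
  ape::read.tree(text = paste0(nodes[[which(active)]], ";"))
}

#' Bootstrap supports for a UPGMA tree
#'
#' Resamples alignment columns with replacement, rebuilds the tree per
#' replicate, and scores each clade of the point-estimate tree by the
#' percentage of replicates containing it.  Replicates with a saturated
#' pair are dropped and the denominator adjusted.
#'
#' @param aln character matrix (rows = genomes).
#' @param model distance model, as in [pairwise_distance()].
#' @param n_reps bootstrap replicates (default 100).
#' @param seed integer seed (supports are seed-deterministic).
#' @return list with `tree` (point-estimate [ape::phylo] with node labels =
#'   support percentages; `n_reps = 0` leaves them empty), `supports`
#'   (numeric per internal node) and `n_dropped` saturated replicates.
#' @export
bootstrap_support <- function(aln, model = "jc69", n_reps = 100, seed = 1) {
  point <- upgma_tree(pairwise_distance(aln, model))
  if (n_reps == 0)
    return(list(tree = point, supports = numeric(0), n_dropped = 0L))
  set.seed(seed)
  reps <- vector("list", n_reps)
  dropped <- 0L
  for (b in seq_len(n_reps)) {
    cols <- sample.int(ncol(aln), ncol(aln), replace = TRUE)
    db <- tryCatch(pairwise_distance(aln[, cols, drop = FALSE], model),
                   error = function(e) NULL)
    if (is.null(db) || anyNA(db)) { dropped <- dropped + 1L; next }
    reps[[b]] <- upgma_tree(db)
  }
  reps <- reps[!vapply(reps, is.null, logical(1))]
  if (length(reps) == 0) stop("all bootstrap replicates were saturated")
  counts <- ape::prop.clades(point, reps, rooted = TRUE)
  counts[is.na(counts)] <- 0L
  supports <- round(100 * counts / length(reps), 1)
  point$node.label <- as.character(supports)
  list(tree = point, supports = supports, n_dropped = dropped)
}
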