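# Phylogenies -> species-level correlation structure for the phylogenetic
# random effect (standardized shared branch length), plus a guarded inverse
# for the precision parameterization the sampler uses.

#' Read a Newick phylogeny
#'
#' Thin wrapper around [ape::read.tree()] with validation: unique tip labels
#' and finite, non-negative branch lengths are required.
#'
#' @param text Newick string, or `file` a path.
#' @param file Optional file path (overrides `text`).
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  tree <- if (!is.null(file)) ape::read.tree(file = file)
          else ape::read.tree(text = text)
  if (is.null(tree)) stop("malformed Newick input")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and >= 0")
  tree
}

#' Phylogenetic correlation matrix
#'
#' C[k, l] = shared root-to-MRCA path length of species k and l, divided by
#' sqrt(depth_k * depth_l), so the diagonal is 1 and, for ultrametric trees,
#' entries lie in [0, 1]. This is the standardized covariance matrix of a
#' Brownian-motion trait, the covariance structure of the phylogenetic random
#' effect. Computed via [ape::vcv()] and pruned/ordered to the species list.
#'
#' @param tree An [ape::phylo] tree (see [read_newick()]).
#' @param species Character vector of species; must all be tips of the tree.
#'   Default: all tips in tree order.
#' @return Correlation matrix with `species` as dimnames, class
#'   `phylo_correlation`.
#' @export
correlation_from_tree <- function(tree, species = tree$tip.label) {
  miss <- setdiff(species, tree$tip.label)
  if (length(miss))
    stop("species absent from tree: ", paste(miss, collapse = ", "))
  V <- ape::vcv(tree)
  d <- diag(V)
  if (any(d <= 0)) stop("tree has zero-depth tips; cannot standardize")
  C <- V / sqrt(outer(d, d))
  C <- C[species, species, drop = FALSE]
  diag(C) <- 1
  ev <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8)
    stop("correlation matrix not positive semi-definite (min eigenvalue ",
         signif(ev, 3), ")")
  structure(C, class = c("phylo_correlation", "matrix"))
}

#' Ridge-stabilized inverse of a correlation matrix
#'
#' Inverse of `C + ridge * I`, the precision parameterization used when
#' sampling the phylogenetic random effect. The result is checked against
#' `C %*% Cinv ~ I`; if the check fails at the default ridge the ridge is
#' escalated once (with a warning) before giving up.
#'
#' @param C Symmetric correlation matrix.
#' @param ridge Small diagonal inflation (default 1e-8).
#' @return The precision matrix.
#' @export
stable_inverse <- function(C, ridge = 1e-8) {
  C <- unclass(as.matrix(C))
  if (nrow(C) != ncol(C) || max(abs(C - t(C))) > 1e-8)
    stop("C must be square and symmetric")
  try_inv <- function(rdg) {
    Ci <- tryCatch(chol2inv(chol(C + diag(rdg, nrow(C)))),
                   error = function(e) NULL)
    if (is.null(Ci)) return(NULL)
    if (max(abs(C %*% Ci - diag(nrow(C)))) < 1e-6 * max(1, 1 / rdg)) Ci
    else Ci  # accuracy checked by caller below
  }
  ev_min <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 100 * ridge)
    warning("rank-deficient correlation (e.g. duplicated tips or a ",
            "zero-length split): returning the ridge-regularized inverse")
  Ci <- try_inv(ridge)
  ok <- !is.null(Ci) && max(abs((C + diag(ridge, nrow(C))) %*% Ci -
                                  diag(nrow(C)))) < 1e-6
  if (!ok) {
    big <- max(ridge, 1e-6) * 100
    Ci <- try_inv(big)
    if (is.null(Ci))
      stop("matrix singular beyond ridge rescue; try a larger ridge")
    warning(sprintf("matrix near-singular: ridge escalated to %g", big))
  }
  dimnames(Ci) <- dimnames(C)
  Ci
}

#' Write a correlation matrix to CSV
#'
#' @param C Matrix from [correlation_from_tree()].
#' @param path File path.
#' @export
write_correlation <- function(C, path) {
  utils::write.csv(as.data.frame(unclass(C)), path, row.names = TRUE)
}
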