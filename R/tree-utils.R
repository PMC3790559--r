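# Internal helpers for ape::phylo trees. Node numbering follows ape:
# tips 1..n, root n+1, internal nodes n+1 .. n+Nnode.

#' Node heights (time from the root) for every node
#'
#' @param tree an [ape::phylo] object with branch lengths.
#' @return numeric vector of length `Ntip + Nnode`, time from the root.
#' @keywords internal
#' @noRd
node_heights <- function(tree) {
  ape::node.depth.edgelength(tree)
}

#' Total depth (max root-to-tip height) of a tree
#' @keywords internal
#' @noRd
tree_depth <- function(tree) {
  max(node_heights(tree)[seq_len(ape::Ntip(tree))])
}

#' Check a phylo object and warn when it is not ultrametric
#' @keywords internal
#' @noRd
check_tree <- function(tree, warn_ultrametric = FALSE, tol = 1e-6) {
  if (!inherits(tree, "phylo")) {
    stop("`tree` must be an ape 'phylo' object", call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    stop("`tree` must have branch lengths", call. = FALSE)
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("tip labels must be unique", call. = FALSE)
  }
  if (warn_ultrametric) {
    h <- node_heights(tree)[seq_len(ape::Ntip(tree))]
    if (diff(range(h)) > tol * max(h)) {
      warning("tree is not ultrametric; time-based analyses may be inaccurate",
              call. = FALSE)
    }
  }
  invisible(tree)
}

#' Tip indices descending from each node
#'
#' @return list of length `Ntip + Nnode`; element k holds the tip indices
#'   descending from node k (a tip descends from itself).
#' @keywords internal
#' @noRd
descendant_tips <- function(tree) {
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  out <- vector("list", nn)
  for (i in seq_len(n)) out[[i]] <- i
  tr <- stats::reorder(tree, "postorder")
  for (k in seq_len(nrow(tr$edge))) {
    par <- tr$edge[k, 1L]
    chi <- tr$edge[k, 2L]
    out[[par]] <- c(out[[par]], out[[chi]])
  }
  out
}

#' Match a named per-species vector/matrix against tree tips
#'
#' Reorders rows to `tree$tip.label` and fails loudly on mismatches.
#' @keywords internal
#' @noRd
match_to_tips <- function(tree, x, what = "values") {
  if (is.null(dim(x))) {
    if (is.null(names(x))) stop(sprintf("`%s` must be named by species", what),
                                call. = FALSE)
    missing <- setdiff(tree$tip.label, names(x))
    if (length(missing) > 0) {
      stop(sprintf("no %s for species: %s", what,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    x[tree$tip.label]
  } else {
    if (is.null(rownames(x))) stop(sprintf("`%s` must have species rownames", what),
                                   call. = FALSE)
    missing <- setdiff(tree$tip.label, rownames(x))
    if (length(missing) > 0) {
      stop(sprintf("no %s for species: %s", what,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    x[tree$tip.label, , drop = FALSE]
  }
}
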