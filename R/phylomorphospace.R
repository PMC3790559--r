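# Phylomorphospace: maximum-likelihood ancestral states under BM and the
# projection of tips plus internal nodes into a plane of eigenshape axes.

#' Maximum-likelihood ancestral states under Brownian motion
#'
#' Computes the ML reconstruction of ancestral states for a continuous
#' character under BM, equivalently branch-length-weighted squared-change
#' parsimony: the states minimize `sum over edges of (change)^2 / branch
#' length`. Solved exactly as the sparse linear system in which every
#' internal node's state is the inverse-branch-length-weighted mean of its
#' neighbors' states.
#'
#' @param tree an [ape::phylo] with branch lengths.
#' @param tip_values named per-species numeric vector (every tip present).
#' @return numeric vector of states for internal nodes, named by ape node
#'   number (`Ntip + 1` is the root).
#' @export
ancestral_states <- function(tree, tip_values) {
  check_tree(tree)
  x <- match_to_tips(tree, tip_values, "tip values")
  n <- ape::Ntip(tree)
  N <- tree$Nnode
  A <- matrix(0, N, N)
  b <- numeric(N)
  el <- pmax(tree$edge.length, 1e-12)
  for (k in seq_len(nrow(tree$edge))) {
    u <- tree$edge[k, 1L]; v <- tree$edge[k, 2L]; w <- 1 / el[k]
    ui <- u - n
    A[ui, ui] <- A[ui, ui] + w
    if (v <= n) {
      b[ui] <- b[ui] + w * x[v]
    } else {
      vi <- v - n
      A[ui, vi] <- A[ui, vi] - w
      A[vi, vi] <- A[vi, vi] + w
      A[vi, ui] <- A[vi, ui] - w
    }
  }
  states <- solve(A, b)
  names(states) <- as.character(n + seq_len(N))
  states
}

#' Project species and ancestors into a phylomorphospace
#'
#' Builds the coordinates of a phylomorphospace plot for one pair of score
#' axes: tip coordinates are the per-species mean scores, internal-node
#' coordinates are ML-under-BM ancestral states reconstructed per axis with
#' [ancestral_states()], and edges enumerate every branch parent -> child.
#'
#' @param tree an [ape::phylo] with branch lengths.
#' @param scores matrix of per-species scores (species rownames; one row
#'   per species, i.e. specimens already averaged).
#' @param axis_pair integer pair of column indices to project (default
#'   `c(1, 2)`).
#' @return object of class `"phylomorphospace"`: `axis_pair`, `tip_coords`
#'   (species x 2), `node_coords` (internal nodes x 2), `edges` (the ape
#'   edge matrix), `tree`.
#' @export
phylomorphospace <- function(tree, scores, axis_pair = c(1L, 2L)) {
  check_tree(tree)
  scores <- as.matrix(scores)
  if (any(axis_pair < 1L) || any(axis_pair > ncol(scores))) {
    stop("`axis_pair` indices outside the available score axes")
  }
  scores <- match_to_tips(tree, scores, "scores")
  tip_coords <- scores[, axis_pair, drop = FALSE]
  node_coords <- vapply(axis_pair, function(j) {
    ancestral_states(tree, setNames(scores[, j], rownames(scores)))
  }, numeric(tree$Nnode))
  node_coords <- matrix(node_coords, nrow = tree$Nnode)
  colnames(tip_coords) <- colnames(node_coords) <-
    paste0("axis", seq_along(axis_pair))
  structure(
    list(axis_pair = axis_pair, tip_coords = tip_coords,
         node_coords = node_coords, edges = tree$edge, tree = tree),
    class = "phylomorphospace")
}

#' @export
print.phylomorphospace <- function(x, ...) {
  cat(sprintf("phylomorphospace of axes (%s): %d tips, %d internal nodes, %d edges\n",
              paste(x$axis_pair, collapse = ", "), nrow(x$tip_coords),
              nrow(x$node_coords), nrow(x$edges)))
  invisible(x)
}

#' @export
plot.phylomorphospace <- function(x, xlab = NULL, ylab = NULL, ...) {
  n <- nrow(x$tip_coords)
  all_xy <- rbind(x$tip_coords, x$node_coords)
  rownames(all_xy) <- NULL
  coord_of <- function(node) {
    if (node <= n) x$tip_coords[node, ] else x$node_coords[node - n, ]
  }
  plot(all_xy, type = "n",
       xlab = xlab %||% paste0("axis ", x$axis_pair[1L]),
       ylab = ylab %||% paste0("axis ", x$axis_pair[2L]), ...)
  for (k in seq_len(nrow(x$edges))) {
    a <- coord_of(x$edges[k, 1L]); b <- coord_of(x$edges[k, 2L])
    graphics::segments(a[1L], a[2L], b[1L], b[2L], col = "grey60")
  }
  graphics::points(x$node_coords, pch = 21, bg = "white", cex = 0.7)
  graphics::points(x$tip_coords, pch = 19)
  invisible(x)
}
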