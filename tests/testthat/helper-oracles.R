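# Shared fixtures and independent oracles used across test files.

# dense multivariate-normal log-density, built directly from the
# covariance matrix (independent of the pruning implementation)
dense_mvn_loglik <- function(x, mean, V) {
  n <- length(x)
  r <- x - mean
  as.numeric(-0.5 * (n * log(2 * pi) +
                       determinant(V, logarithm = TRUE)$modulus +
                       t(r) %*% solve(V, r)))
}

# dense BM log-likelihood from the tree covariance matrix
dense_bm_loglik <- function(tree, x, sigma2, z0) {
  C <- ape::vcv(tree)
  x <- x[rownames(C)]
  dense_mvn_loglik(x, rep(z0, length(x)), sigma2 * C)
}

# dense OU log-likelihood from the fixed-root OU covariance formula
dense_ou_loglik <- function(tree, x, sigma2, alpha, z0) {
  S <- ape::vcv(tree)   # shared root-to-divergence times
  x <- x[rownames(S)]
  h <- ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))]
  Tmax <- max(h)
  V <- sigma2 / (2 * alpha) * (1 - exp(-2 * alpha * S)) *
    exp(-2 * alpha * (Tmax - S))
  dense_mvn_loglik(x, rep(z0, length(x)), V)
}

# unit square traversed counter-clockwise from a corner
square_outline <- function(id = "square") {
  outline(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)), specimen_id = id)
}

# regular p-gon (discrete circle), counter-clockwise from angle 0
polygon_outline <- function(p = 100, r = 1, id = "polygon") {
  th <- 2 * pi * (seq_len(p) - 1) / p
  outline(cbind(r * cos(th), r * sin(th)), specimen_id = id)
}

# random ultrametric tree with named tips
random_tree <- function(n, depth = 1) {
  generate_tree(n, depth = depth)
}

# brute-force DTT curve: explicit enumeration of lineages at each internal
# node time, written independently of the package implementation
brute_dtt <- function(tree, scores) {
  n <- ape::Ntip(tree)
  h <- ape::node.depth.edgelength(tree)
  depth <- max(h[seq_len(n)])
  scores <- as.matrix(scores)[tree$tip.label, , drop = FALSE]
  avg_pd <- function(idx) {
    if (length(idx) < 2) return(0)
    pts <- scores[idx, , drop = FALSE]
    mean(dist(pts))
  }
  total <- avg_pd(seq_len(n))
  tips_below <- function(node) {
    if (node <= n) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_below))
  }
  int_nodes <- (n + 1):(n + tree$Nnode)
  ord <- int_nodes[order(h[int_nodes])]
  times <- h[ord] / depth
  vals <- numeric(length(ord))
  vals[1] <- 1
  for (i in seq_along(ord)[-1]) {
    tk <- h[ord[i]]
    cross <- which(h[tree$edge[, 1]] < tk - 1e-10 &
                     h[tree$edge[, 2]] >= tk - 1e-10)
    subs <- vapply(tree$edge[cross, 2],
                   function(v) avg_pd(tips_below(v)), numeric(1))
    vals[i] <- mean(subs) / total
  }
  list(node_times = times, observed = vals)
}
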