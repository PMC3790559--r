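# Morphological disparity: average pairwise distances, per-clade tip
# disparity, disparity-through-time (DTT) curves against a Brownian-motion
# simulation envelope, and the morphological disparity index (MDI).

#' Average pairwise disparity of a point cloud
#'
#' Mean Euclidean distance over all unordered pairs of rows; with
#' `squared = TRUE`, the mean squared distance. A single point has
#' disparity 0.
#'
#' @param points numeric matrix (n x d) or vector (treated as n x 1).
#' @param squared use mean squared distances (default `FALSE`).
#' @return scalar disparity.
#' @export
pairwise_disparity <- function(points, squared = FALSE) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 1L)
  points <- as.matrix(points)
  if (ncol(points) == 0L) stop("`points` must have at least one column")
  if (nrow(points) < 2L) return(0)
  d <- dist(points)
  if (squared) mean(d^2) else mean(d)
}

#' Per-tip disparity contributions
#'
#' Each tip's contribution is its mean squared distance to all other tips,
#' divided by the mean of those per-tip values across the whole sample, so
#' that contributions average 1 and clade sums are comparable across data
#' scales.
#'
#' @param scores per-species score matrix (species rownames).
#' @return named per-species numeric vector.
#' @export
tip_disparity <- function(scores) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  if (n < 2L) stop("need at least 2 species")
  D2 <- as.matrix(dist(scores))^2
  d <- rowSums(D2) / (n - 1L)
  m <- mean(d)
  if (m == 0) return(setNames(rep(0, n), rownames(scores)))
  setNames(d / m, rownames(scores))
}

#' Per-clade disparity with per-species standardization
#'
#' Sums [tip_disparity()] contributions within each clade, and standardizes
#' each clade value by its number of sampled species to yield an average
#' per species (see [standardize_clade_disparity()]), so that clades with
#' unequal sampling can be compared.
#'
#' @param scores per-species score matrix (species rownames).
#' @param clade_map named character vector mapping species to clade.
#' @return data.frame with columns clade, disparity, n_species,
#'   per_species, ordered by decreasing disparity.
#' @export
clade_disparity <- function(scores, clade_map) {
  scores <- as.matrix(scores)
  sp <- rownames(scores)
  if (is.null(sp)) stop("`scores` must have species rownames")
  missing <- setdiff(sp, names(clade_map))
  if (length(missing) > 0) {
    stop("species without clade assignment: ", paste(missing, collapse = ", "))
  }
  clades <- clade_map[sp]
  if (any(table(clades) == 0)) stop("empty clade")
  td <- tip_disparity(scores)
  vals <- tapply(td, clades, sum)
  ns <- as.integer(table(clades)[names(vals)])
  out <- data.frame(clade = names(vals), disparity = as.numeric(vals),
                    n_species = ns,
                    per_species = standardize_clade_disparity(as.numeric(vals), ns),
                    stringsAsFactors = FALSE)
  out[order(-out$disparity), , drop = FALSE]
}

#' Standardize clade disparities by species count
#'
#' Divides each clade's summed disparity by the number of sampled species
#' in that clade, yielding an average disparity per species. This is the
#' standardization used when sampling is unequal across clades.
#'
#' @param disparity numeric vector of per-clade disparity values.
#' @param n_species integer vector of species sampled per clade.
#' @return numeric vector of per-species disparity values.
#' @export
standardize_clade_disparity <- function(disparity, n_species) {
  if (length(disparity) != length(n_species)) {
    stop("`disparity` and `n_species` lengths differ")
  }
  if (any(n_species < 1)) stop("species counts must be >= 1")
  disparity / n_species
}

# Precompute, for a tree, what each DTT evaluation needs: internal node
# times (ascending), and for each time the tip sets of the lineages
# crossing it.
dtt_skeleton <- function(tree) {
  n <- ape::Ntip(tree)
  h <- node_heights(tree)
  depth <- max(h[seq_len(n)])
  int_nodes <- (n + 1L):(n + tree$Nnode)
  ord <- int_nodes[order(h[int_nodes])]
  times <- h[ord]
  dt <- descendant_tips(tree)
  eps <- 1e-10 * depth
  crossing <- lapply(seq_along(ord), function(i) {
    t_k <- times[i]
    if (i == 1L) return(list(dt[[ord[1L]]]))   # root: the whole clade
    rows <- which(h[tree$edge[, 1L]] < t_k - eps &
                    h[tree$edge[, 2L]] >= t_k - eps)
    lapply(tree$edge[rows, 2L], function(v) dt[[v]])
  })
  list(times = times / depth, crossing = crossing, n = n)
}

# Evaluate the relative-subclade-disparity curve for one data set, given a
# precomputed skeleton. Disparity of any subset is read off one full
# pairwise distance matrix.
dtt_eval <- function(skel, scores, squared = FALSE) {
  D <- as.matrix(dist(scores))
  if (squared) D <- D^2
  sub_disp <- function(tips) {
    m <- length(tips)
    if (m < 2L) return(0)
    sum(D[tips, tips]) / (m * (m - 1L))
  }
  total <- sub_disp(seq_len(skel$n))
  if (total == 0) stop("total disparity is zero; all species identical")
  vapply(skel$crossing, function(lineages) {
    mean(vapply(lineages, sub_disp, numeric(1))) / total
  }, numeric(1))
}

#' Observed disparity-through-time curve
#'
#' At each internal node time (root first, ascending), computes for every
#' lineage crossing that time the disparity of its tip descendants divided
#' by the disparity of the entire clade, and averages over lineages. Times
#' are reported as relative time in `[0, 1]` (0 = root, 1 = tips). The
#' curve starts at exactly 1: at the root the whole clade is the only
#' subclade.
#'
#' @param tree an ultrametric [ape::phylo] with at least 3 tips.
#' @param scores per-species score matrix (species rownames) or named
#'   vector.
#' @param squared use mean squared distances as the disparity metric.
#' @return list with `node_times` (relative) and `observed`.
#' @export
dtt_curve <- function(tree, scores, squared = FALSE) {
  check_tree(tree, warn_ultrametric = TRUE)
  if (ape::Ntip(tree) < 3L) stop("need at least 3 tips")
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = 1L,
                                             dimnames = list(names(scores), NULL))
  scores <- match_to_tips(tree, scores, "scores")
  skel <- dtt_skeleton(tree)
  list(node_times = skel$times, observed = dtt_eval(skel, scores, squared))
}

#' Brownian-motion null envelope for DTT
#'
#' Estimates the multivariate BM rate structure of the score columns from
#' the tip data via phylogenetically independent contrasts (preserving
#' trait correlations), simulates `n_sim` multivariate BM data sets on the
#' tree, and computes the DTT curve of each.
#'
#' @inheritParams dtt_curve
#' @param n_sim number of simulations (>= 1).
#' @param seed optional integer seed.
#' @return list with `null_curves` (n_sim x times) and `null_median`.
#' @export
bm_null_envelope <- function(tree, scores, n_sim = 1000L, seed = NULL,
                             squared = FALSE) {
  check_tree(tree, warn_ultrametric = TRUE)
  n_sim <- as.integer(n_sim)
  if (n_sim < 1L) stop("n_sim must be >= 1")
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = 1L,
                                             dimnames = list(names(scores), NULL))
  scores <- match_to_tips(tree, scores, "scores")
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- nrow(scores); d <- ncol(scores)
  pics <- vapply(seq_len(d), function(j) ape::pic(scores[, j], tree),
                 numeric(n - 1L))
  R <- crossprod(as.matrix(pics)) / (n - 1L)
  eg <- eigen(R, symmetric = TRUE)
  Rhalf <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), d) %*% t(eg$vectors)
  C <- ape::vcv(tree)
  Lc <- t(chol(C + diag(1e-12 * max(diag(C)), n)))
  skel <- dtt_skeleton(tree)
  null_curves <- matrix(NA_real_, n_sim, length(skel$times))
  for (s in seq_len(n_sim)) {
    X <- Lc %*% matrix(rnorm(n * d), n, d) %*% Rhalf
    null_curves[s, ] <- dtt_eval(skel, X, squared)
  }
  list(null_curves = null_curves,
       null_median = apply(null_curves, 2L, median))
}

#' Morphological disparity index (MDI)
#'
#' Signed area between the observed DTT curve and the null median,
#' integrated by the trapezoid rule over relative time, restricted to
#' `node_times <= 1 - truncation`. By default the most recent 20% of the
#' time axis is omitted to avoid tip-overdispersion artifacts from missing
#' terminal taxa. Positive MDI means observed disparity sits above the
#' null expectation.
#'
#' @param observed observed relative-disparity values.
#' @param null_median null median values at the same `node_times`.
#' @param node_times relative node times in `[0, 1]`.
#' @param truncation fraction of recent time omitted (default 0.2).
#' @return scalar signed area.
#' @export
mdi <- function(observed, null_median, node_times, truncation = 0.2) {
  stopifnot(length(observed) == length(node_times),
            length(null_median) == length(node_times))
  keep <- node_times <= 1 - truncation + 1e-12
  t <- node_times[keep]
  dif <- (observed - null_median)[keep]
  if (length(t) < 2L) return(0)
  sum(diff(t) * (head(dif, -1L) + dif[-1L]) / 2)
}

#' Disparity through time with BM null envelope and MDI
#'
#' Convenience wrapper running [dtt_curve()], [bm_null_envelope()] and
#' [mdi()] in one call.
#'
#' @inheritParams bm_null_envelope
#' @param truncation fraction of recent time omitted from the MDI (default
#'   0.2).
#' @return object of class `"dtt_result"`: `node_times`, `observed`,
#'   `null_median`, `null_curves`, `MDI`, `truncation`, `n_sim`, `seed`.
#' @export
disparity_through_time <- function(tree, scores, n_sim = 1000L,
                                   truncation = 0.2, seed = NULL,
                                   squared = FALSE) {
  obs <- dtt_curve(tree, scores, squared)
  env <- bm_null_envelope(tree, scores, n_sim = n_sim, seed = seed,
                          squared = squared)
  structure(
    list(node_times = obs$node_times, observed = obs$observed,
         null_median = env$null_median, null_curves = env$null_curves,
         MDI = mdi(obs$observed, env$null_median, obs$node_times, truncation),
         truncation = truncation, n_sim = n_sim, seed = seed),
    class = "dtt_result")
}

#' @export
print.dtt_result <- function(x, ...) {
  cat(sprintf(
    "disparity through time: %d node times, %d BM simulations\nMDI = %.4f (truncation %.0f%%)\n",
    length(x$node_times), x$n_sim, x$MDI, 100 * x$truncation))
  invisible(x)
}
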