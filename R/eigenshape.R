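# Outline processing: equidistant resampling, Zahn-Roskies phi-star shape
# functions, SVD eigenshape decomposition, shape model reconstruction and
# broken-stick axis selection.

signed_area <- function(pts) {
  x <- pts[, 1L]; y <- pts[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

#' Resample an outline to equidistant points
#'
#' Resamples a closed outline to exactly `p` points at equal arc-length
#' spacing along the polygonal boundary, by linear interpolation of the
#' cumulative arc length. Resampling starts exactly at the designated
#' starting landmark, and traversal direction is standardized to
#' counter-clockwise (the point order is reversed when the signed area is
#' negative). The perimeter is preserved to within numerical interpolation
#' error.
#'
#' @param outline an [outline] object with at least 3 points.
#' @param p number of equidistant points to return (default 100, minimum 8).
#' @return a new [outline] with `p` points, starting landmark at index 1.
#' @export
resample_equidistant <- function(outline, p = 100L) {
  stopifnot(inherits(outline, "outline"))
  p <- as.integer(p)
  if (p < 8L) stop("`p` must be at least 8")
  pts <- outline$points
  n <- nrow(pts)
  # rotate so the start landmark comes first
  idx <- c(outline$start_index:n, seq_len(outline$start_index - 1L))
  pts <- pts[idx, , drop = FALSE]
  # drop consecutive duplicate points (zero-length segments)
  d <- sqrt(rowSums((pts - pts[c(2:nrow(pts), 1L), , drop = FALSE])^2))
  keep <- c(TRUE, d[-length(d)] > 0)
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) < 3L) stop("degenerate outline: fewer than 3 distinct points")
  # standardize to counter-clockwise, keeping the start point first
  if (signed_area(pts) < 0) {
    pts <- pts[c(1L, nrow(pts):2L), , drop = FALSE]
  }
  seg <- sqrt(rowSums((pts[c(2:nrow(pts), 1L), , drop = FALSE] - pts)^2))
  L <- sum(seg)
  if (L <= 0) stop("degenerate outline: zero perimeter")
  cum <- c(0, cumsum(seg))            # arc length at vertex 1..n and closure
  target <- L * (seq_len(p) - 1L) / p
  ptsc <- rbind(pts, pts[1L, ])       # closed vertex list for interpolation
  xi <- stats::approx(cum, ptsc[, 1L], xout = target, method = "linear")$y
  yi <- stats::approx(cum, ptsc[, 2L], xout = target, method = "linear")$y
  outline(cbind(xi, yi), specimen_id = outline$specimen_id, start_index = 1L)
}

#' Zahn-Roskies phi-star shape function of a resampled outline
#'
#' Converts an equidistantly resampled, counter-clockwise outline into the
#' circle-normalized tangent-angle representation: `phi_star[j]` is the
#' unwrapped cumulative turning direction at step `j`, minus the direction
#' of the first step, minus `(j-1) * 2*pi/p` (the expected turning of a
#' circle). Step-to-step turning angles are accumulated in `(-pi, pi]`,
#' which prevents artificial `2*pi` jumps on concave outlines. The result
#' is invariant to rotation, translation and uniform scaling of the
#' outline; size is carried separately as perimeter and centroid size.
#'
#' @param outline an [outline], already resampled with
#'   [resample_equidistant()] (equal spacing is assumed, not re-checked
#'   beyond a soft warning).
#' @return an object of class `"shape_function"` with elements
#'   `specimen_id`, `phi_star` (length `p`, radians, first element exactly
#'   0), `perimeter`, `centroid_size` and `p`.
#' @export
zahn_roskies <- function(outline) {
  stopifnot(inherits(outline, "outline"))
  pts <- outline$points
  p <- nrow(pts)
  steps <- pts[c(2:p, 1L), , drop = FALSE] - pts
  len <- sqrt(rowSums(steps^2))
  if (any(len == 0)) stop("outline has zero-length segments; resample first")
  if (sd(len) / mean(len) > 0.1) {
    warning("outline steps deviate from equidistant spacing; ",
            "apply resample_equidistant() first", call. = FALSE)
  }
  theta_raw <- atan2(steps[, 2L], steps[, 1L])
  turn <- diff(theta_raw)
  turn <- ((turn + pi) %% (2 * pi)) - pi       # wrap each turn into (-pi, pi]
  turn[turn == -pi] <- pi
  theta <- cumsum(c(theta_raw[1L], turn))      # unwrapped directions
  phi_star <- theta - theta[1L] - (seq_len(p) - 1L) * 2 * pi / p
  ctr <- colMeans(pts)
  csize <- sqrt(sum((pts[, 1L] - ctr[1L])^2 + (pts[, 2L] - ctr[2L])^2))
  structure(
    list(specimen_id = outline$specimen_id, phi_star = phi_star,
         perimeter = sum(len), centroid_size = csize, p = p),
    class = "shape_function")
}

#' @export
print.shape_function <- function(x, ...) {
  cat(sprintf("phi-star shape function '%s': p = %d, perimeter = %.4g\n",
              x$specimen_id, x$p, x$perimeter))
  invisible(x)
}

#' Eigenshape decomposition of a set of shape functions
#'
#' Column-centers the specimen-by-point matrix of phi-star values and
#' decomposes it by singular value decomposition. The right singular
#' vectors are the eigenshape (ES) axes: mutually orthonormal latent shape
#' vectors ordered by decreasing explained variance. Scores are the
#' projections of the centered shape functions onto the axes; eigenvalues
#' are squared singular values divided by `n - 1`. The sign of each axis is
#' fixed so that its largest-magnitude loading is positive, making scores
#' reproducible across runs.
#'
#' @param shape_functions list of [zahn_roskies()] shape functions sharing
#'   the same number of points.
#' @return object of class `"eigenshape"`: `axes` (p x n_axes), `scores`
#'   (n x n_axes), `eigenvalues`, `variance_fraction`, `mean_phi`,
#'   `specimen_ids`, plus `perimeters` and `centroid_sizes` carried through
#'   for convenience.
#' @export
eigenshape <- function(shape_functions) {
  if (inherits(shape_functions, "shape_function")) {
    shape_functions <- list(shape_functions)
  }
  n <- length(shape_functions)
  if (n < 2L) stop("eigenshape analysis needs at least 2 specimens")
  ps <- vapply(shape_functions, function(s) s$p, integer(1))
  if (length(unique(ps)) != 1L) {
    stop("all shape functions must have the same number of points; got p = ",
         paste(sort(unique(ps)), collapse = ", "))
  }
  p <- ps[1L]
  X <- t(vapply(shape_functions, function(s) s$phi_star, numeric(p)))
  ids <- vapply(shape_functions, function(s) s$specimen_id, character(1))
  mean_phi <- colMeans(X)
  Xc <- sweep(X, 2L, mean_phi)
  k <- min(n - 1L, p)
  sv <- svd(Xc, nu = 0L, nv = k)
  axes <- sv$v
  d <- sv$d[seq_len(k)]
  # sign convention: largest-magnitude loading of each axis is positive
  for (j in seq_len(k)) {
    i0 <- which.max(abs(axes[, j]))
    if (axes[i0, j] < 0) axes[, j] <- -axes[, j]
  }
  scores <- Xc %*% axes
  eigenvalues <- d^2 / (n - 1L)
  total <- sum(eigenvalues)
  variance_fraction <- if (total > 0) eigenvalues / total else rep(0, k)
  colnames(axes) <- colnames(scores) <- paste0("ES", seq_len(k))
  rownames(scores) <- ids
  structure(
    list(axes = axes, scores = scores, eigenvalues = eigenvalues,
         variance_fraction = variance_fraction, mean_phi = mean_phi,
         specimen_ids = ids,
         perimeters = vapply(shape_functions, function(s) s$perimeter, numeric(1)),
         centroid_sizes = vapply(shape_functions, function(s) s$centroid_size,
                                 numeric(1))),
    class = "eigenshape")
}

#' @export
print.eigenshape <- function(x, ...) {
  k <- min(5L, length(x$variance_fraction))
  cat(sprintf("eigenshape analysis: %d specimens, p = %d\n",
              length(x$specimen_ids), length(x$mean_phi)))
  cat("variance fractions:",
      paste(sprintf("%s %.1f%%", names(x$variance_fraction)[seq_len(k)] %||%
                      paste0("ES", seq_len(k)),
                    100 * x$variance_fraction[seq_len(k)]), collapse = ", "),
      if (length(x$variance_fraction) > k) "..." else "", "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reconstruct an outline from a shape model along an eigenshape axis
#'
#' Converts `phi_star = mean_phi + score * axis` back into coordinates by
#' integrating unit steps of length `perimeter / p` at directions
#' `theta_j = phi_star[j] + (j-1) * 2*pi/p`. The residual closure gap is
#' distributed linearly over the points, so reconstructed shape models
#' close exactly; this induces small deviations from a strict inverse of
#' [zahn_roskies()].
#'
#' @param mean_phi mean phi-star vector (length p).
#' @param axis eigenshape axis loading vector (length p), or `NULL` for the
#'   mean shape alone.
#' @param score scalar position along `axis` (default 0, the mean shape).
#' @param perimeter outline perimeter used for the reconstruction scale.
#' @param specimen_id id for the returned outline.
#' @return an [outline] with `length(mean_phi)` points.
#' @export
reconstruct_outline <- function(mean_phi, axis = NULL, score = 0,
                                perimeter = 1, specimen_id = "model") {
  p <- length(mean_phi)
  if (is.null(axis)) axis <- rep(0, p)
  if (length(axis) != p) stop("`axis` and `mean_phi` lengths differ")
  phi <- mean_phi + score * axis
  theta <- phi + (seq_len(p) - 1L) * 2 * pi / p
  step <- perimeter / p
  dx <- step * cos(theta)
  dy <- step * sin(theta)
  x <- cumsum(c(0, dx[-p]))
  y <- cumsum(c(0, dy[-p]))
  gap <- c(x[p] + dx[p], y[p] + dy[p])   # endpoint after the closing step
  j <- seq_len(p) - 1L
  x <- x - gap[1L] * j / p
  y <- y - gap[2L] * j / p
  outline(cbind(x, y), specimen_id = specimen_id, start_index = 1L)
}

#' Broken-stick selection of significant eigenshape axes
#'
#' Compares observed variance fractions to the broken-stick expectation
#' `b_k = (1/p') * sum(1/i, i = k..p')`, where `p'` is the number of axes
#' with nonzero variance. Returns the largest `m` such that every axis
#' `k <= m` exceeds its threshold strictly.
#'
#' @param variance_fraction vector of per-axis variance fractions (should
#'   sum to 1).
#' @return integer count of significant axes (possibly 0).
#' @export
broken_stick <- function(variance_fraction) {
  vf <- variance_fraction
  if (abs(sum(vf) - 1) > 1e-6) {
    stop("`variance_fraction` must sum to 1")
  }
  pp <- sum(vf > 1e-12)
  if (pp == 0L) return(0L)
  b <- vapply(seq_len(pp), function(k) sum(1 / (k:pp)) / pp, numeric(1))
  ok <- vf[seq_len(pp)] > b
  if (!ok[1L]) return(0L)
  m <- which(!ok)
  if (length(m) == 0L) pp else m[1L] - 1L
}
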