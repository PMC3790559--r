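# Specimen-level group statistics: per-axis ANOVA with Bonferroni
# correction, canonical variates analysis with Wilks' Lambda, and
# measurement-error repeatability from replicated digitizations.

#' One-way ANOVA per score axis with Bonferroni correction
#'
#' Runs a one-way ANOVA of each selected score axis against the group
#' labels, multiplying each axis's p-value by the number of axes tested
#' (Bonferroni). Post hoc pairwise Welch t-tests are Bonferroni-corrected
#' within each axis.
#'
#' @param scores per-specimen score matrix.
#' @param groups group labels (e.g. clade/family), one per specimen.
#' @param axes indices of axes to test (default: all columns).
#' @return list with `anova` (data.frame: axis, F, df1, df2, p,
#'   p_adjusted) and `posthoc` (per-axis matrices of adjusted pairwise
#'   p-values).
#' @export
anova_per_axis <- function(scores, groups, axes = NULL) {
  scores <- as.matrix(scores)
  groups <- factor(groups)
  if (length(groups) != nrow(scores)) {
    stop("`groups` must have one label per specimen")
  }
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (is.null(axes)) axes <- seq_len(ncol(scores))
  n_tests <- length(axes)
  rows <- vector("list", n_tests)
  posthoc <- vector("list", n_tests)
  axis_names <- colnames(scores) %||% paste0("axis", seq_len(ncol(scores)))
  for (i in seq_along(axes)) {
    j <- axes[i]
    y <- scores[, j]
    fit <- aov(y ~ groups)
    tab <- anova(fit)
    if (tab["Residuals", "Df"] < 1L) {
      stop("zero within-group degrees of freedom on axis ", axis_names[j])
    }
    p <- tab[1L, "Pr(>F)"]
    rows[[i]] <- data.frame(axis = axis_names[j], F = tab[1L, "F value"],
                            df1 = tab[1L, "Df"], df2 = tab["Residuals", "Df"],
                            p = p, p_adjusted = min(1, p * n_tests),
                            stringsAsFactors = FALSE)
    # Welch pairwise tests need >= 2 observations per group; fall back to
    # pooled-variance tests when a group is represented by one specimen
    welch_ok <- all(table(groups) >= 2L)
    posthoc[[i]] <- pairwise.t.test(y, groups, p.adjust.method = "bonferroni",
                                    pool.sd = !welch_ok)$p.value
  }
  names(posthoc) <- axis_names[axes]
  list(anova = do.call(rbind, rows), posthoc = posthoc)
}

#' Canonical variates analysis with Wilks' Lambda tests
#'
#' Canonical variates from the eigen-decomposition of
#' `within^-1 %*% between` scatter; the number of canonical functions is
#' `min(groups - 1, n_axes)`. Coefficients are scaled so canonical scores
#' have unit pooled within-group variance. Successive-root Wilks' Lambda
#' tests use Bartlett's chi-squared approximation with the standard
#' degrees of freedom.
#'
#' @param scores per-specimen score matrix (n x k).
#' @param groups group labels, one per specimen.
#' @return object of class `"cva_result"`: `coefficients` (k x m),
#'   `eigenvalues`, `variance_pct`, `wilks` (data.frame: root, lambda,
#'   chisq, df, p), `scores` (canonical scores, n x m), `groups`.
#' @export
cva_wilks <- function(scores, groups) {
  X <- as.matrix(scores)
  groups <- factor(groups)
  n <- nrow(X); k <- ncol(X); g <- nlevels(groups)
  if (g < 2L) stop("need at least 2 groups")
  if (n <= k + g) stop("need more specimens than axes + groups")
  grand <- colMeans(X)
  W <- matrix(0, k, k)
  B <- matrix(0, k, k)
  for (lev in levels(groups)) {
    Xi <- X[groups == lev, , drop = FALSE]
    mi <- colMeans(Xi)
    Xc <- sweep(Xi, 2L, mi)
    W <- W + crossprod(Xc)
    B <- B + nrow(Xi) * tcrossprod(mi - grand)
  }
  WB <- tryCatch(solve(W, B), error = function(e) {
    stop("singular within-group scatter; reduce the number of axes",
         call. = FALSE)
  })
  eg <- eigen(WB)
  m <- min(g - 1L, k)
  lambda <- Re(eg$values[seq_len(m)])
  A <- Re(eg$vectors[, seq_len(m), drop = FALSE])
  # scale: unit pooled within-group variance of each canonical score
  for (j in seq_len(m)) {
    s <- sqrt(drop(t(A[, j]) %*% (W / (n - g)) %*% A[, j]))
    A[, j] <- A[, j] / s
    i0 <- which.max(abs(A[, j]))
    if (A[i0, j] < 0) A[, j] <- -A[, j]
  }
  wilks <- data.frame(root = seq_len(m), lambda = NA_real_, chisq = NA_real_,
                      df = NA_integer_, p = NA_real_)
  cfac <- n - 1 - (k + g) / 2
  for (j in seq_len(m)) {
    L <- prod(1 / (1 + lambda[j:m]))
    chisq <- -cfac * log(L)
    df <- (k - j + 1L) * (g - j)
    wilks[j, c("lambda", "chisq", "df", "p")] <-
      c(L, chisq, df, pchisq(chisq, df, lower.tail = FALSE))
  }
  can_scores <- sweep(X, 2L, grand) %*% A
  colnames(can_scores) <- colnames(A) <- paste0("CV", seq_len(m))
  structure(
    list(coefficients = A, eigenvalues = lambda,
         variance_pct = 100 * lambda / sum(lambda), wilks = wilks,
         scores = can_scores, groups = groups),
    class = "cva_result")
}

#' @export
print.cva_result <- function(x, ...) {
  cat(sprintf("canonical variates analysis: %d functions, %d groups\n",
              length(x$eigenvalues), nlevels(x$groups)))
  cat("eigenvalues:", paste(sprintf("%.3f", x$eigenvalues), collapse = ", "),
      "\nvariance %:", paste(sprintf("%.1f", x$variance_pct), collapse = ", "),
      "\n")
  print(x$wilks, row.names = FALSE)
  invisible(x)
}

#' Measurement-error repeatability from replicated measurements
#'
#' One-way ANOVA with individuals as groups, per axis. The within-
#' individual variance component is `MS_within`; the among-individual
#' component is `(MS_among - MS_within) / n0` with `n0` the standard
#' effective replicate count for unbalanced designs,
#' `n0 = (N - sum(n_i^2) / N) / (a - 1)`. Repeatability is
#' `R = s2_among / (s2_among + s2_within)`, clamped to `[0, 1]` (negative
#' among-individual variance estimates are set to 0).
#'
#' @param scores replicate measurement matrix (rows = measurements) or
#'   vector.
#' @param individual_ids individual identifier per measurement (>= 2
#'   individuals; at least one with >= 2 replicates).
#' @return data.frame with one row per axis: axis, MS_among, MS_within,
#'   n0, R.
#' @export
repeatability <- function(scores, individual_ids) {
  if (is.null(dim(scores))) scores <- matrix(scores, ncol = 1L)
  scores <- as.matrix(scores)
  ids <- factor(individual_ids)
  if (length(ids) != nrow(scores)) {
    stop("`individual_ids` must have one entry per measurement")
  }
  a <- nlevels(ids)
  if (a < 2L) stop("need at least 2 individuals")
  ni <- as.numeric(table(ids))
  N <- sum(ni)
  if (N - a < 1L) stop("need at least one individual with >= 2 replicates")
  n0 <- (N - sum(ni^2) / N) / (a - 1)
  axis_names <- colnames(scores) %||% paste0("axis", seq_len(ncol(scores)))
  out <- lapply(seq_len(ncol(scores)), function(j) {
    tab <- anova(aov(scores[, j] ~ ids))
    ms_a <- tab[1L, "Mean Sq"]
    ms_w <- tab["Residuals", "Mean Sq"]
    s2a <- max(0, (ms_a - ms_w) / n0)
    denom <- s2a + ms_w
    R <- if (denom == 0) 0 else s2a / denom
    data.frame(axis = axis_names[j], MS_among = ms_a, MS_within = ms_w,
               n0 = n0, R = min(1, max(0, R)), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
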