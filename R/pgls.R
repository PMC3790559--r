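# Phylogenetic generalized least squares with a Brownian-motion
# correlation structure.

#' PGLS regression under Brownian-motion residual covariance
#'
#' Generalized least squares in which residuals covary proportionally to
#' the BM tree covariance `C` (shared root-to-divergence path lengths,
#' scaled by tree depth). Species absent from the response or any
#' predictor are pruned from the tree before fitting (complete-case
#' analysis), and the dropped species are reported in the result. Two r2
#' conventions are returned: a GLS sums-of-squares r2 against the
#' intercept-only GLS model, and a likelihood-ratio generalized r2,
#' `1 - exp(-2 (logL_model - logL_null) / n)`.
#'
#' @param tree an [ape::phylo] with branch lengths covering all species.
#' @param response named per-species numeric vector.
#' @param predictors per-species matrix or data.frame (species rownames),
#'   e.g. eigenshape score columns.
#' @return object of class `"pgls_fit"`: `coefficients` (estimate, se, t,
#'   p), `r2_ss`, `r2_lik`, `F`, `df`, `p_value`, `n`, `dropped_species`,
#'   `logL`.
#' @export
pgls <- function(tree, response, predictors) {
  check_tree(tree)
  if (is.null(names(response))) stop("`response` must be named by species")
  predictors <- as.matrix(predictors)
  if (is.null(rownames(predictors))) {
    stop("`predictors` must have species rownames")
  }
  if (is.null(colnames(predictors))) {
    colnames(predictors) <- paste0("x", seq_len(ncol(predictors)))
  }
  common <- intersect(names(response)[is.finite(response)],
                      rownames(predictors)[complete.cases(predictors)])
  absent <- setdiff(common, tree$tip.label)
  if (length(absent) > 0) {
    stop("species not in tree: ", paste(absent, collapse = ", "))
  }
  dropped <- setdiff(tree$tip.label, common)
  if (length(dropped) > 0) {
    tree <- ape::drop.tip(tree, dropped)
  }
  spp <- tree$tip.label
  y <- response[spp]
  X <- cbind(`(Intercept)` = 1, predictors[spp, , drop = FALSE])
  n <- length(y)
  k <- ncol(X)
  if (n <= k) stop("more coefficients than species after pruning")
  C <- ape::vcv(tree) / tree_depth(tree)
  U <- chol(C)
  ys <- backsolve(U, y, transpose = TRUE)
  Xs <- backsolve(U, X, transpose = TRUE)
  qrX <- qr(Xs)
  if (qrX$rank < k) {
    bad <- colnames(X)[-seq_len(qrX$rank)]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, ys)
  res <- ys - Xs %*% beta
  rss <- sum(res^2)
  df_res <- n - k
  sigma2 <- rss / df_res
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * diag(XtXinv))
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df_res)
  # null (intercept-only) GLS model
  X0s <- Xs[, 1L, drop = FALSE]
  b0 <- qr.coef(qr(X0s), ys)
  rss0 <- sum((ys - X0s %*% b0)^2)
  df_num <- k - 1L
  Fstat <- if (df_num > 0) ((rss0 - rss) / df_num) / (rss / df_res) else NA_real_
  p_value <- if (df_num > 0) pf(Fstat, df_num, df_res, lower.tail = FALSE)
  else NA_real_
  logdetC <- 2 * sum(log(diag(U)))
  loglik <- function(r) -0.5 * (n * log(2 * pi * r / n) + logdetC + n)
  logL <- loglik(rss)
  logL0 <- loglik(rss0)
  structure(
    list(coefficients = data.frame(estimate = as.numeric(beta),
                                   se = as.numeric(se),
                                   t = as.numeric(tval),
                                   p = as.numeric(pval),
                                   row.names = colnames(X)),
         r2_ss = 1 - rss / rss0,
         r2_lik = 1 - exp(-2 * (logL - logL0) / n),
         F = Fstat, df = c(df_num, df_res), p_value = p_value,
         n = n, dropped_species = dropped, logL = logL),
    class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, digits = 4, ...) {
  cat(sprintf("PGLS (BM correlation), n = %d species", x$n))
  if (length(x$dropped_species) > 0) {
    cat(sprintf(" (%d pruned: %s)", length(x$dropped_species),
                paste(x$dropped_species, collapse = ", ")))
  }
  cat("\n")
  print(round(x$coefficients, digits))
  cat(sprintf("r2 (SS) = %.4f, r2 (likelihood) = %.4f\n", x$r2_ss, x$r2_lik))
  cat(sprintf("F(%d, %d) = %.4f, p = %.4g\n", x$df[1L], x$df[2L], x$F,
              x$p_value))
  invisible(x)
}
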