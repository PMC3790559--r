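# Maximum-likelihood fitting of Brownian-motion (BM), Ornstein-Uhlenbeck
# (OU) and early-burst (EB) models of continuous trait evolution, with
# AICc / Akaike-weight model comparison.
#
# All likelihoods run through a single linear-time pruning recursion for
# BM; OU and EB are handled by branch-length transforms that map them onto
# BM, so one engine serves all three models.

# Pruning pass for BM at unit rate. Returns the independent normal
# components of the likelihood: n-1 contrasts with their variances, plus
# the root value and its accumulated variance. log|C| of the unit-rate tip
# covariance equals sum(log(contrast variances)) + log(root variance).
bm_pruning <- function(tree, x) {
  n <- ape::Ntip(tree)
  x <- match_to_tips(tree, x, "trait values")
  nn <- n + tree$Nnode
  val <- numeric(nn)
  extra <- numeric(nn)               # variance accumulated above each node
  val[seq_len(n)] <- x
  tr <- stats::reorder(tree, "postorder")
  contrasts <- numeric(0)
  cvars <- numeric(0)
  # group edges by parent, in postorder
  parents <- unique(tr$edge[, 1L])
  for (par in parents) {
    rows <- which(tr$edge[, 1L] == par)
    ch <- tr$edge[rows, 2L]
    tv <- tr$edge.length[rows] + extra[ch]
    m <- val[ch[1L]]
    mv <- tv[1L]
    if (length(ch) > 1L) {
      for (j in 2L:length(ch)) {
        cv <- mv + tv[j]
        if (cv <= 0) {
          stop("singular phylogenetic covariance: zero-length sister branches",
               call. = FALSE)
        }
        contrasts <- c(contrasts, val[ch[j]] - m)
        cvars <- c(cvars, cv)
        m <- (m * tv[j] + val[ch[j]] * mv) / cv
        mv <- mv * tv[j] / cv
      }
    }
    val[par] <- m
    extra[par] <- mv
  }
  root <- n + 1L
  list(contrasts = contrasts, cvars = cvars,
       root_value = val[root], root_var = extra[root], n = n)
}

# Profiled GLS statistics from a pruning pass at unit rate:
# z0_hat = GLS mean, rss = (x - z0_hat)' C^-1 (x - z0_hat), logdetC.
bm_gls_stats <- function(tree, x) {
  pr <- bm_pruning(tree, x)
  if (pr$root_var <= 0) {
    stop("singular phylogenetic covariance at the root", call. = FALSE)
  }
  list(z0 = pr$root_value,
       rss = sum(pr$contrasts^2 / pr$cvars),
       logdetC = sum(log(pr$cvars)) + log(pr$root_var),
       n = pr$n)
}

#' Brownian-motion log-likelihood of tip data
#'
#' Log-density of the tip vector under a multivariate normal with mean
#' `z0` and covariance `sigma2 * C`, where `C[i, j]` is the shared path
#' length from the root. Computed by the linear-time pruning recursion;
#' equal to the dense matrix form.
#'
#' @param tree an [ape::phylo] with branch lengths.
#' @param trait named per-species numeric vector.
#' @param sigma2 BM rate (> 0), trait units squared per time.
#' @param z0 root state.
#' @return log-likelihood (natural log).
#' @export
bm_loglik <- function(tree, trait, sigma2, z0) {
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  check_tree(tree)
  pr <- bm_pruning(tree, trait)
  if (pr$root_var <= 0) {
    stop("singular phylogenetic covariance at the root", call. = FALSE)
  }
  ll <- sum(dnorm(pr$contrasts, 0, sqrt(sigma2 * pr$cvars), log = TRUE))
  ll + dnorm(pr$root_value, z0, sqrt(sigma2 * pr$root_var), log = TRUE)
}

#' Ornstein-Uhlenbeck log-likelihood of tip data
#'
#' Single-optimum, fixed-root OU with the optimum tied to the root state
#' `z0`. Tip covariance is
#' `sigma2/(2 alpha) * (1 - exp(-2 alpha s)) * exp(-2 alpha (T - s))` for
#' shared root-to-divergence time `s` and depth `T`, implemented as BM on a
#' node-height-transformed tree. The `alpha -> 0` limit reduces analytically
#' to BM.
#'
#' @inheritParams bm_loglik
#' @param alpha attraction strength (>= 0), 1/time.
#' @return log-likelihood (natural log).
#' @export
ou_loglik <- function(tree, trait, sigma2, alpha, z0) {
  if (alpha < 0) stop("alpha must be >= 0")
  check_tree(tree, warn_ultrametric = TRUE)
  if (alpha < 1e-12) return(bm_loglik(tree, trait, sigma2, z0))
  bm_loglik(ou_transform(tree, alpha), trait, sigma2, z0)
}

# Node-height transform mapping fixed-root OU (unit sigma2) onto BM:
# g(h) = exp(-2 alpha T) * (exp(2 alpha h) - 1) / (2 alpha).
ou_transform <- function(tree, alpha) {
  h <- node_heights(tree)
  Tmax <- max(h[seq_len(ape::Ntip(tree))])
  g <- function(hh) exp(-2 * alpha * Tmax) * expm1(2 * alpha * hh) / (2 * alpha)
  tree$edge.length <- g(h[tree$edge[, 2L]]) - g(h[tree$edge[, 1L]])
  tree
}

#' Early-burst branch-length transform
#'
#' Rescales each branch spanning node heights `(t1, t2)` to
#' `(exp(a t2) - exp(a t1)) / a` (unchanged for `a = 0`), so that BM on the
#' transformed tree equals an early-burst process whose rate declines as
#' `sigma2 * exp(a t)` with `a <= 0`.
#'
#' @param tree an [ape::phylo] with branch lengths.
#' @param a exponential rate-change parameter (<= 0), 1/time.
#' @return the transformed tree.
#' @export
eb_transform <- function(tree, a) {
  check_tree(tree)
  if (a > 0) stop("EB rate-change parameter `a` must be <= 0")
  if (a == 0) return(tree)
  h <- node_heights(tree)
  tree$edge.length <- (exp(a * h[tree$edge[, 2L]]) -
                         exp(a * h[tree$edge[, 1L]])) / a
  tree
}

# Profile fit of BM on a (possibly transformed) unit-rate tree: z0 and
# sigma2 have closed-form ML estimates given the tree.
profile_bm <- function(tree, trait) {
  st <- bm_gls_stats(tree, trait)
  n <- st$n
  sigma2 <- st$rss / n
  if (sigma2 <= 0) {
    return(list(sigma2 = 0, z0 = st$z0, logL = Inf, degenerate = TRUE))
  }
  logL <- -0.5 * (n * log(2 * pi * sigma2) + st$logdetC + n)
  list(sigma2 = sigma2, z0 = st$z0, logL = logL, degenerate = FALSE)
}

#' Fit an evolutionary model to one trait by maximum likelihood
#'
#' Fits BM, OU or EB to a named per-species trait vector. The root state
#' and rate are profiled analytically by GLS at each value of the shape
#' parameter (`alpha` for OU, `a` for EB), which is then optimized by a
#' deterministic log-spaced grid search refined with [stats::optimize()].
#' Parameter counts are BM = 2, OU = 3, EB = 3; AICc uses the number of
#' species as the sample size.
#'
#' @param tree an ultrametric [ape::phylo] (>= 4 tips).
#' @param trait named per-species numeric vector.
#' @param model one of "BM", "OU", "EB".
#' @param alpha_max upper search bound for OU alpha (default `50 / depth`).
#' @param a_min lower search bound for EB `a` (default `log(1e-5) / depth`,
#'   i.e. a 10^5-fold rate decline over the tree).
#' @param grid_size number of grid points for the shape-parameter search.
#' @return object of class `"trait_fit"`: `model`, `params` (sigma2, z0,
#'   and alpha or a), `logL`, `k`, `n`, `AIC`, `AICc`, `converged`.
#' @export
fit_trait_model <- function(tree, trait, model = c("BM", "OU", "EB"),
                            alpha_max = NULL, a_min = NULL, grid_size = 24L) {
  model <- match.arg(model)
  check_tree(tree, warn_ultrametric = (model != "BM"))
  trait <- match_to_tips(tree, trait, "trait values")
  n <- ape::Ntip(tree)
  if (n < 4L) stop("need at least 4 tips to fit evolutionary models")
  Tmax <- tree_depth(tree)

  make_fit <- function(par_val, prof, k, converged) {
    params <- list(sigma2 = prof$sigma2, z0 = prof$z0)
    if (model == "OU") params$alpha <- par_val
    if (model == "EB") params$a <- par_val
    logL <- prof$logL
    aic <- 2 * k - 2 * logL
    aicc <- aic + 2 * k * (k + 1) / (n - k - 1)
    structure(list(model = model, params = params, logL = logL, k = k,
                   n = n, AIC = aic, AICc = aicc,
                   converged = converged && !prof$degenerate),
              class = "trait_fit")
  }

  if (model == "BM") {
    prof <- profile_bm(tree, trait)
    return(make_fit(NULL, prof, k = 2L, converged = TRUE))
  }

  transform_fun <- if (model == "OU") {
    function(par) if (par == 0) tree else ou_transform(tree, par)
  } else {
    function(par) eb_transform(tree, par)
  }
  objective <- function(par) profile_bm(transform_fun(par), trait)$logL

  if (model == "OU") {
    if (is.null(alpha_max)) alpha_max <- 50 / Tmax
    grid <- c(0, exp(seq(log(1e-3 / Tmax), log(alpha_max), length.out = grid_size)))
  } else {
    if (is.null(a_min)) a_min <- log(1e-5) / Tmax
    grid <- c(0, -exp(seq(log(1e-4 / Tmax), log(-a_min), length.out = grid_size)))
    grid <- sort(grid, decreasing = TRUE)
  }
  ll_grid <- vapply(grid, function(g) {
    out <- tryCatch(objective(g), error = function(e) -Inf)
    if (!is.finite(out)) -Inf else out
  }, numeric(1))
  if (all(!is.finite(ll_grid))) {
    prof <- list(sigma2 = NA_real_, z0 = NA_real_, logL = -Inf, degenerate = TRUE)
    return(make_fit(grid[1L], prof, k = 3L, converged = FALSE))
  }
  i_best <- which.max(ll_grid)
  lo <- grid[max(1L, i_best - 1L)]
  hi <- grid[min(length(grid), i_best + 1L)]
  best_par <- grid[i_best]
  best_ll <- ll_grid[i_best]
  if (lo != hi) {
    opt <- tryCatch(
      optimize(objective, interval = sort(c(lo, hi)), maximum = TRUE,
               tol = 1e-8),
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$objective) && opt$objective > best_ll) {
      best_par <- opt$maximum
      best_ll <- opt$objective
    }
  }
  if (model == "OU" && best_par < 1e-10) best_par <- 0
  prof <- profile_bm(transform_fun(best_par), trait)
  at_bound <- if (model == "OU") {
    isTRUE(all.equal(best_par, alpha_max, tolerance = 1e-6))
  } else {
    isTRUE(all.equal(best_par, a_min, tolerance = 1e-6))
  }
  make_fit(best_par, prof, k = 3L, converged = !at_bound)
}

#' @export
print.trait_fit <- function(x, ...) {
  extra <- if (x$model == "OU") sprintf(", alpha = %.4g", x$params$alpha)
  else if (x$model == "EB") sprintf(", a = %.4g", x$params$a) else ""
  cat(sprintf("%s fit (n = %d): sigma2 = %.4g, z0 = %.4g%s\n",
              x$model, x$n, x$params$sigma2, x$params$z0, extra))
  cat(sprintf("  logL = %.4f, k = %d, AIC = %.4f, AICc = %.4f, converged: %s\n",
              x$logL, x$k, x$AIC, x$AICc, x$converged))
  invisible(x)
}

#' Compare fitted models by AICc differences and Akaike weights
#'
#' Transforms AICc values into differences from the minimum,
#' `delta_i = AICc_i - min(AICc)`, and into Akaike weights
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)`, the proportional
#' support received by each candidate model.
#'
#' @param fits either a list of `"trait_fit"` objects fitted to the same
#'   data, or a (possibly named) numeric vector of AICc values.
#' @return a `"model_comparison"` data.frame with columns model, logL, k,
#'   AIC, AICc, delta, weight (logL/k/AIC are `NA` when raw AICc values
#'   were supplied).
#' @export
compare_models <- function(fits) {
  if (is.numeric(fits)) {
    tab <- data.frame(
      model = if (!is.null(names(fits))) names(fits) else
        paste0("model", seq_along(fits)),
      logL = NA_real_, k = NA_integer_, AIC = NA_real_,
      AICc = as.numeric(fits), stringsAsFactors = FALSE)
  } else {
    if (length(fits) < 2L) stop("need at least 2 fits to compare")
    stopifnot(all(vapply(fits, inherits, logical(1), "trait_fit")))
    ns <- vapply(fits, function(f) f$n, integer(1))
    if (length(unique(ns)) != 1L) {
      stop("fits were made on different numbers of species")
    }
    tab <- data.frame(
      model = vapply(fits, function(f) f$model, character(1)),
      logL = vapply(fits, function(f) f$logL, numeric(1)),
      k = vapply(fits, function(f) f$k, integer(1)),
      AIC = vapply(fits, function(f) f$AIC, numeric(1)),
      AICc = vapply(fits, function(f) f$AICc, numeric(1)),
      stringsAsFactors = FALSE)
  }
  tab$delta <- tab$AICc - min(tab$AICc)
  w <- exp(-tab$delta / 2)
  tab$weight <- w / sum(w)
  class(tab) <- c("model_comparison", "data.frame")
  tab
}

#' @export
print.model_comparison <- function(x, digits = 3, ...) {
  cat("model comparison (AICc / Akaike weights):\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
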