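# PGLS regression, per-axis ANOVA, CVA with Wilks' Lambda, repeatability.

test_that("PGLS on a star tree equals ordinary least squares", {
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1,e:1,f:1,g:1,h:1);")
  set.seed(31)
  X <- matrix(rnorm(16), 8, 2, dimnames = list(star$tip.label, c("x1", "x2")))
  y <- setNames(rnorm(8), star$tip.label)
  fit <- pgls(star, y, X)
  ols <- lm(y ~ X[names(y), 1] + X[names(y), 2])
  expect_lt(max(abs(fit$coefficients$estimate - unname(coef(ols)))), 1e-10)
  expect_equal(fit$r2_ss, summary(ols)$r.squared, tolerance = 1e-10)
  expect_equal(fit$F, summary(ols)$fstatistic[["value"]], tolerance = 1e-10)
})

test_that("PGLS agrees with nlme::gls under a Brownian correlation", {
  skip_if_not_installed("nlme")
  set.seed(32)
  tr <- random_tree(20)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(tr$tip.label, c("x1", "x2")))
  y <- setNames(simulate_traits(tr, "BM")[, 1] + 0.5 * X[, 1], tr$tip.label)
  fit <- pgls(tr, y, X)
  df <- data.frame(y = y, x1 = X[, 1], x2 = X[, 2], species = tr$tip.label)
  ref <- nlme::gls(y ~ x1 + x2, data = df,
                   correlation = ape::corBrownian(phy = tr, form = ~species))
  expect_equal(fit$coefficients$estimate, unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$coefficients$se,
               unname(sqrt(diag(stats::vcov(ref)))), tolerance = 1e-6)
})

test_that("PGLS prunes incomplete species and reports them", {
  tr <- random_tree(12)
  X <- matrix(rnorm(24), 12, 2, dimnames = list(tr$tip.label, c("x1", "x2")))
  y <- setNames(rnorm(12), tr$tip.label)
  y4 <- y[-(1:4)]
  fit <- pgls(tr, y4, X)
  expect_equal(fit$n, 8)
  expect_setequal(fit$dropped_species, tr$tip.label[1:4])

  # collinear design named in the error
  Xbad <- cbind(X, x3 = X[, 1] * 2)
  expect_error(pgls(tr, y, Xbad), "collinear")
  # species missing from the tree
  names(y)[1] <- "nosuch"
  expect_error(pgls(tr, y, rbind(X, nosuch = c(0, 0))), "nosuch")
})

test_that("PGLS recovers a known shape-isotope coupling", {
  # generator ground truth: response = 10 + 0.5 * axis + BM residual on the
  # same tree, the structure the BM correlation model assumes
  set.seed(33)
  slopes <- replicate(60, {
    tr <- generate_tree(21, depth = 1, seed = sample.int(1e6, 1))
    axis <- setNames(simulate_traits(tr, "BM")[, 1], tr$tip.label)
    resid <- setNames(simulate_traits(tr, "BM", list(sigma2 = 0.25, z0 = 0))[, 1],
                      tr$tip.label)
    y <- 10 + 0.5 * axis + resid
    pgls(tr, y, cbind(ES1 = axis))$coefficients["ES1", "estimate"]
  })
  expect_equal(mean(slopes), 0.5, tolerance = 0.1)
})

test_that("per-axis ANOVA applies Bonferroni and detects generated group structure", {
  set.seed(34)
  # power: strong clade effect, low noise
  cfg <- synthetic_config(n_species = 12, n_clades = 3,
                          specimens_per_species = c(4, 4),
                          clade_effect_size = 0.2, outline_noise_sd = 0.005,
                          seed = 34)
  ds <- generate_dataset(cfg)
  es <- eigenshape(lapply(ds$outlines, function(o)
    zahn_roskies(resample_equidistant(o, 100))))
  groups <- ds$specimens$clade
  res <- anova_per_axis(es$scores[, 1:4], groups)
  expect_equal(nrow(res$anova), 4)
  expect_lt(res$anova$p_adjusted[1], 0.001)
  expect_true(all(res$anova$p_adjusted >= res$anova$p))
  expect_true(all(res$anova$p_adjusted <= 1))
  expect_equal(res$anova$df2[1], nrow(es$scores) - length(unique(groups)))

  expect_error(anova_per_axis(es$scores[, 1:2], rep("one", nrow(es$scores))),
               "2 groups")
})

test_that("ANOVA p-values are uniform under the null", {
  set.seed(35)
  pvals <- replicate(400, {
    y <- rnorm(24)
    g <- rep(c("A", "B"), each = 12)
    anova_per_axis(matrix(y, ncol = 1), g)$anova$p[1]
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("CVA yields groups-1 functions and matches the two-group t statistic", {
  set.seed(36)
  # 4 groups on 8 axes: exactly 3 canonical functions summing to 100%
  n <- 60
  X <- matrix(rnorm(n * 8), n, 8)
  g <- rep(c("A", "B", "C", "D"), length.out = n)
  X[, 1] <- X[, 1] + as.numeric(factor(g))
  cv <- cva_wilks(X, g)
  expect_equal(length(cv$eigenvalues), 3L)
  expect_equal(sum(cv$variance_pct), 100)
  expect_equal(nrow(cv$wilks), 3L)
  expect_equal(cv$wilks$df, c(8 * 3, 7 * 2, 6 * 1))
  # canonical scores have unit pooled within-group variance
  W <- matrix(0, 3, 3)
  for (lev in unique(g)) {
    S <- cv$scores[g == lev, , drop = FALSE]
    W <- W + crossprod(sweep(S, 2, colMeans(S)))
  }
  expect_equal(unname(W / (n - 4)), diag(3), tolerance = 1e-8)

  # two groups, one axis: squared canonical correlation equals t^2/(t^2+df)
  y <- rnorm(30) + rep(c(0, 1), each = 15)
  g2 <- rep(c("A", "B"), each = 15)
  cv2 <- cva_wilks(matrix(y, ncol = 1), g2)
  tt <- t.test(y ~ g2, var.equal = TRUE)
  lam <- cv2$eigenvalues[1]
  expect_equal(lam / (1 + lam),
               tt$statistic^2 / (tt$statistic^2 + 28),
               tolerance = 1e-8, ignore_attr = TRUE)

  expect_error(cva_wilks(X[1:10, ], g[1:10]), "more specimens")
})

test_that("Wilks' Lambda p-values are calibrated under the null", {
  set.seed(37)
  pvals <- replicate(300, {
    X <- matrix(rnorm(40 * 3), 40, 3)
    g <- rep(c("A", "B"), each = 20)
    cva_wilks(X, g)$wilks$p[1]
  })
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("repeatability reproduces hand-computed variance components", {
  # balanced toy: individuals (1,1,1) and (2,2,4)
  r <- repeatability(c(1, 1, 1, 2, 2, 4), rep(c("A", "B"), each = 3))
  expect_equal(r$MS_among, 25 / 6)
  expect_equal(r$MS_within, 2 / 3)
  expect_equal(r$n0, 3)
  expect_equal(r$R, 7 / 11, tolerance = 1e-12)

  # identical replicates, distinct individuals: R = 1
  r1 <- suppressWarnings(
    repeatability(c(1, 1, 2, 2, 5, 5), rep(c("A", "B", "C"), each = 2)))
  expect_equal(r1$R, 1)

  # identical individual means, noisy replicates: R clamped at 0
  r0 <- repeatability(c(0, 1, 1, 0, 0.5, 0.5), rep(c("A", "B", "C"), each = 2))
  expect_equal(r0$R, 0)

  # affine invariance of the measurement scale
  set.seed(38)
  y <- rnorm(12)
  ids <- rep(letters[1:4], each = 3)
  expect_equal(repeatability(y, ids)$R, repeatability(5 * y + 3, ids)$R,
               tolerance = 1e-10)

  expect_error(repeatability(1:3, rep("A", 3)), "2 individuals")
})
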