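# Resampling, Zahn-Roskies shape functions, eigenshape decomposition,
# shape models and broken-stick axis selection.

test_that("resample_equidistant spaces points equally from the start landmark", {
  rs <- resample_equidistant(square_outline(), p = 8)
  # perimeter 4, steps of 0.5 from the corner: all 4 corners present
  expect_equal(rs$points,
               rbind(c(0, 0), c(0.5, 0), c(1, 0), c(1, 0.5), c(1, 1),
                     c(0.5, 1), c(0, 1), c(0, 0.5)))
  seg <- sqrt(rowSums((rs$points[c(2:8, 1), ] - rs$points)^2))
  expect_equal(sum(seg), 4, tolerance = 1e-6)

  # idempotence on already-equidistant counter-clockwise input
  circ <- polygon_outline(p = 64)
  rs2 <- resample_equidistant(circ, p = 64)
  expect_equal(rs2$points, circ$points, tolerance = 1e-12)
})

test_that("clockwise input is standardized to counter-clockwise", {
  ccw <- square_outline()
  cw <- outline(ccw$points[c(1, 4, 3, 2), ], specimen_id = "cw")
  expect_equal(resample_equidistant(cw, 16)$points,
               resample_equidistant(ccw, 16)$points)
})

test_that("resampling rejects degenerate input", {
  degen <- outline(rbind(c(0, 0), c(0, 0), c(0, 0)), "z")
  expect_error(resample_equidistant(degen, 8), "degenerate")
  expect_error(resample_equidistant(square_outline(), p = 4), "at least 8")
})

test_that("phi-star of a regular polygon is identically zero", {
  zr <- zahn_roskies(polygon_outline(p = 100))
  expect_equal(zr$phi_star, rep(0, 100), tolerance = 1e-9)
  expect_identical(zr$phi_star[1], 0)
})

test_that("phi-star of a square is a four-level staircase against the circle trend", {
  rs <- resample_equidistant(square_outline(), p = 100)
  zr <- zahn_roskies(rs)
  expect_identical(zr$phi_star[1], 0)
  # adding back the circle trend recovers the cumulative corner turning:
  # a step function on levels 0, pi/2, pi, 3pi/2
  cumturn <- zr$phi_star + (seq_len(100) - 1) * 2 * pi / 100
  lev <- sort(unique(round(cumturn / (pi / 2))))
  expect_equal(lev, 0:3)
  expect_equal(cumturn, round(cumturn / (pi / 2)) * pi / 2, tolerance = 1e-9)
  expect_equal(zr$perimeter, 4, tolerance = 1e-6)
})

test_that("phi-star is rotation- and scale-invariant; size fields scale linearly", {
  rs <- resample_equidistant(square_outline(), p = 40)
  zr <- zahn_roskies(rs)

  ang <- 0.83
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  rot <- outline(rs$points %*% R, "rot")
  expect_equal(zahn_roskies(rot)$phi_star, zr$phi_star, tolerance = 1e-9)

  big <- outline(rs$points * 3.5, "big")
  zb <- zahn_roskies(big)
  expect_equal(zb$phi_star, zr$phi_star, tolerance = 1e-12)
  expect_equal(zb$perimeter, 3.5 * zr$perimeter)
  expect_equal(zb$centroid_size, 3.5 * zr$centroid_size)
})

test_that("eigenshape handles degenerate and rank-1 inputs", {
  circ <- zahn_roskies(polygon_outline(p = 50))
  es_same <- eigenshape(list(circ, circ, circ))
  expect_true(all(es_same$eigenvalues < 1e-20))
  expect_true(all(abs(es_same$scores) < 1e-10))

  sq <- zahn_roskies(resample_equidistant(square_outline(), p = 50))
  es2 <- eigenshape(list(circ, sq))
  expect_equal(sum(es2$eigenvalues > 1e-12), 1L)
  expect_equal(es2$scores[1, 1], -es2$scores[2, 1])

  short <- zahn_roskies(polygon_outline(p = 40))
  expect_error(eigenshape(list(circ, short)), "same number of points")
})

test_that("eigenshape axes are orthonormal with conserved variance and fixed signs", {
  set.seed(5)
  cfg <- synthetic_config(n_species = 6, n_clades = 2, p_points = 60,
                          specimens_per_species = c(2, 2),
                          outline_noise_sd = 0.02, seed = 5)
  og <- generate_outlines(cfg, setNames(rnorm(6), paste0("s", 1:6)), seed = 5)
  sfs <- lapply(og$outlines, function(o)
    zahn_roskies(resample_equidistant(o, 60)))
  es <- eigenshape(sfs)

  G <- t(es$axes) %*% es$axes
  expect_equal(unname(G), diag(ncol(es$axes)), tolerance = 1e-8)
  expect_equal(sum(es$variance_fraction), 1, tolerance = 1e-8)
  expect_true(all(diff(es$variance_fraction) <= 1e-12))
  # total variance conservation against the centered phi-star matrix
  X <- t(vapply(sfs, function(s) s$phi_star, numeric(60)))
  expect_equal(sum(es$eigenvalues), sum(apply(X, 2, var)), tolerance = 1e-8)
  # sign convention: largest-magnitude loading positive
  for (j in seq_len(ncol(es$axes))) {
    expect_gt(es$axes[which.max(abs(es$axes[, j])), j], 0)
  }
  # scores reproduce the centered data in the axis basis
  expect_equal(unname(es$scores %*% t(es$axes)),
               sweep(X, 2, colMeans(X)), tolerance = 1e-8)
})

test_that("rigid rotation of all outlines leaves the eigenvalues unchanged", {
  cfg <- synthetic_config(n_species = 5, n_clades = 1, p_points = 50,
                          specimens_per_species = c(1, 1),
                          outline_noise_sd = 0.03, seed = 9)
  og <- generate_outlines(cfg, setNames(rnorm(5), paste0("s", 1:5)), seed = 9)
  es1 <- eigenshape(lapply(og$outlines, function(o)
    zahn_roskies(resample_equidistant(o, 50))))
  ang <- 1.1
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  es2 <- eigenshape(lapply(og$outlines, function(o)
    zahn_roskies(resample_equidistant(
      outline(o$points %*% R, o$specimen_id), 50))))
  expect_equal(es1$eigenvalues, es2$eigenvalues, tolerance = 1e-6)
})

test_that("reconstruct_outline inverts zahn_roskies up to closure corrections", {
  rs <- resample_equidistant(square_outline(), p = 100)
  zr <- zahn_roskies(rs)

  # score 0 returns the mean shape
  m <- reconstruct_outline(zr$phi_star, perimeter = zr$perimeter)
  expect_equal(max(abs(zahn_roskies(m)$phi_star - zr$phi_star)), 0,
               tolerance = 1e-2)

  # round trip through an eigenshape model
  circ <- zahn_roskies(polygon_outline(p = 100))
  es <- eigenshape(list(circ, zr))
  s <- es$scores[2, 1]
  rec <- reconstruct_outline(es$mean_phi, es$axes[, 1], s, perimeter = 4)
  phi_back <- zahn_roskies(rec)$phi_star
  phi_target <- es$mean_phi + s * es$axes[, 1]
  expect_lt(sqrt(mean((phi_back - phi_target)^2)), 1e-3)
})

test_that("mean reconstructed shape approximates the coordinate-space mean for low variance", {
  # small deformations: phi-star averaging is nearly linear
  cfg <- synthetic_config(n_species = 4, n_clades = 1, p_points = 80,
                          specimens_per_species = c(1, 1),
                          clade_effect_size = 0.02, outline_noise_sd = 0,
                          seed = 2)
  og <- generate_outlines(cfg, setNames(c(-1, -0.3, 0.3, 1), paste0("s", 1:4)),
                          seed = 2)
  resampled <- lapply(og$outlines, function(o) resample_equidistant(o, 80))
  sfs <- lapply(resampled, zahn_roskies)
  es <- eigenshape(sfs)
  rec <- reconstruct_outline(es$mean_phi,
                             perimeter = mean(vapply(sfs, `[[`, numeric(1),
                                                     "perimeter")))
  coord_mean <- Reduce(`+`, lapply(resampled, function(o) o$points)) /
    length(resampled)
  # the reconstruction's first step points along phi[1] = 0; rotate it to
  # the coordinate mean's first-step direction, and center both
  step1 <- coord_mean[2, ] - coord_mean[1, ]
  a <- atan2(step1[2], step1[1])
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2)
  ctr <- function(p) sweep(p, 2, colMeans(p))
  scale <- mean(sqrt(rowSums(ctr(coord_mean)^2)))
  expect_lt(max(sqrt(rowSums((ctr(rec$points %*% t(R)) - ctr(coord_mean))^2))),
            0.05 * scale)
})

test_that("broken_stick applies the strict threshold rule", {
  expect_equal(broken_stick(c(0.8, 0.2)), 1L)
  expect_equal(broken_stick(c(0.75, 0.25)), 0L)   # boundary: strict inequality
  expect_equal(broken_stick(c(0.9, 0.06, 0.04)), 1L)
  expect_equal(broken_stick(c(0.5, 0.3, 0.2)), 0L)
  expect_error(broken_stick(c(0.5, 0.2)), "sum to 1")
})
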