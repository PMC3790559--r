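# Synthetic data generator: trees, traits, outlines, isotopes.

test_that("generate_tree builds ultrametric pure-birth trees with the right shape", {
  expect_error(generate_tree(1), "n_taxa")

  cherry <- generate_tree(2, depth = 1, seed = 1)
  expect_equal(ape::Ntip(cherry), 2L)
  expect_equal(sort(cherry$edge.length), c(1, 1))

  tr <- generate_tree(25, depth = 23, seed = 1)
  expect_equal(tr$Nnode, 24L)
  expect_true(ape::is.binary(tr))
  tip_h <- ape::node.depth.edgelength(tr)[1:25]
  expect_lt(diff(range(tip_h)), 1e-9 * 23)
  expect_equal(max(tip_h), 23, tolerance = 1e-12)
  expect_equal(tr$tip.label[1:3], c("sp001", "sp002", "sp003"))

  # determinism
  expect_equal(generate_tree(25, 23, seed = 5), generate_tree(25, 23, seed = 5))
})

test_that("lineage-through-time growth matches the pure-birth expectation", {
  # on a depth-1 pure-birth tree with n tips the implied birth rate is
  # about log(n/2) per unit time (2 lineages leave the root, n reach the
  # tips); the mean log lineage count should grow linearly at that rate
  n <- 50
  times <- c(0.3, 0.5, 0.7)
  counts <- matrix(NA_real_, 100, length(times))
  for (s in 1:100) {
    tr <- generate_tree(n, depth = 1, seed = s)
    h <- ape::node.depth.edgelength(tr)
    for (j in seq_along(times)) {
      counts[s, j] <- sum(h[tr$edge[, 1]] <= times[j] & h[tr$edge[, 2]] > times[j])
    }
  }
  slope <- coef(lm(colMeans(log(counts)) ~ times))[2]
  expect_equal(unname(slope), log(n / 2), tolerance = 0.2)
})

test_that("simulate_traits matches the BM and OU variance structure", {
  cherry <- ape::read.tree(text = "(a:1,b:1);")

  # degenerate variance: every tip equals the root state
  x0 <- simulate_traits(cherry, "BM", list(sigma2 = 0, z0 = 3), seed = 1)
  expect_equal(unname(x0[, 1]), c(3, 3))

  # var(x1 - x2) = sigma2 * (t1 + t2) = 2
  x <- simulate_traits(cherry, "BM", list(sigma2 = 1, z0 = 0),
                       n_traits = 10000, seed = 2)
  expect_equal(var(x["a", ] - x["b", ]), 2, tolerance = 0.05)

  # strong OU: tips diverging at the root are nearly independent
  xo <- simulate_traits(cherry, "OU", list(sigma2 = 1, z0 = 0, alpha = 5),
                        n_traits = 10000, seed = 3)
  expect_lt(abs(cov(xo["a", ], xo["b", ])),
            0.01 * mean(c(var(xo["a", ]), var(xo["b", ]))))

  expect_error(simulate_traits(cherry, "wiener"), "arg")
})

test_that("BM tip covariance matches sigma2 times shared path length", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,c:2);")
  x <- simulate_traits(tr, "BM", list(sigma2 = 1.5, z0 = 0),
                       n_traits = 10000, seed = 4)
  emp <- cov(t(x))
  expect_equal(emp, 1.5 * ape::vcv(tr)[rownames(emp), colnames(emp)],
               tolerance = 0.08)
})

test_that("generate_outlines is deterministic and respects signal/noise limits", {
  cfg0 <- synthetic_config(n_species = 4, n_clades = 2,
                           specimens_per_species = c(2, 2),
                           clade_effect_size = 0, outline_noise_sd = 0,
                           seed = 1)
  v <- setNames(c(-1, -0.5, 0.5, 1), paste0("sp", 1:4))
  og <- generate_outlines(cfg0, v, seed = 1)
  pts <- lapply(og$outlines, function(o) o$points)
  for (p in pts[-1]) expect_equal(p, pts[[1]])   # no signal, no noise

  cfg <- synthetic_config(n_species = 4, n_clades = 2,
                          specimens_per_species = c(1, 3), seed = 1)
  a <- generate_outlines(cfg, v, seed = 7)
  b <- generate_outlines(cfg, v, seed = 7)
  expect_identical(a, b)

  # counter-clockwise simple loops
  area <- function(p) {
    x <- p[, 1]; y <- p[, 2]
    sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
  }
  expect_true(all(vapply(a$outlines, function(o) area(o$points) > 0, logical(1))))
  expect_true(all(table(a$specimens$species) >= 1 &
                    table(a$specimens$species) <= 3))
})

test_that("two species with opposite axis values land on opposite sides of ES1", {
  cfg <- synthetic_config(n_species = 2, n_clades = 1,
                          specimens_per_species = c(3, 3),
                          outline_noise_sd = 0, seed = 1)
  og <- generate_outlines(cfg, c(spA = -1, spB = 1), seed = 2)
  es <- eigenshape(lapply(og$outlines, function(o)
    zahn_roskies(resample_equidistant(o, 100))))
  s1 <- es$scores[og$specimens$species == "spA", 1]
  s2 <- es$scores[og$specimens$species == "spB", 1]
  expect_true(all(sign(s1) == sign(s1[1])))
  expect_true(all(sign(s2) == -sign(s1[1])))
})

test_that("generate_isotopes couples the axis linearly", {
  v <- setNames(rnorm(21), paste0("sp", 1:21))
  iso0 <- generate_isotopes(v, coupling = 0, noise_sd = 0, coupling_d13C = 0,
                            seed = 1)
  expect_true(all(iso0$d15N == iso0$d15N[1]))
  expect_true(all(iso0$d13C == iso0$d13C[1]))

  iso1 <- generate_isotopes(v, coupling = 1, noise_sd = 0, seed = 1)
  expect_equal(cor(iso1$d15N, v), 1)
  expect_error(generate_isotopes(v, noise_sd = -1), "noise_sd")
})

test_that("whole data sets are byte-identical under a fixed seed", {
  cfg <- synthetic_config(n_species = 8, n_clades = 2, p_points = 40,
                          specimens_per_species = c(1, 3), seed = 7)
  d1 <- file.path(tempdir(), "synth_a")
  d2 <- file.path(tempdir(), "synth_b")
  generate_dataset(cfg, dir = d1)
  generate_dataset(cfg, dir = d2)
  for (f in c("outlines.tps", "tree.nwk", "specimens.csv", "isotopes.csv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("synthetic_config validates its invariants", {
  expect_error(synthetic_config(n_species = 3, n_clades = 5), "n_clades")
  expect_error(synthetic_config(p_points = 4), "p_points")
  expect_error(synthetic_config(outline_noise_sd = -0.1), "outline_noise_sd")
  expect_error(synthetic_config(specimens_per_species = c(3, 1)),
               "specimens_per_species")
})
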