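test_that("pooled supports follow the pooled quantiles", {
  set.seed(2)
  tables <- list(data.frame(id = 1:5000, v = runif(5000, 0, 10)),
                 data.frame(id = 1:5000, v = runif(5000, 0, 10)))
  sp <- pooled_support(tables, "v")
  # quantile oracle: q(0.005)/q(0.995) widened by 5% of the spread
  vals <- c(tables[[1]]$v, tables[[2]]$v)
  qs <- quantile(vals, c(0.005, 0.995), names = FALSE)
  expect_equal(sp$lower, qs[1] - 0.05 * diff(qs), tolerance = 1e-12)
  expect_equal(sp$upper, qs[2] + 0.05 * diff(qs), tolerance = 1e-12)
  expect_equal(sp$lower, -0.45, tolerance = 0.1)
  expect_equal(sp$upper, 10.45, tolerance = 0.1)
  # identical biofilms give the same support as either alone
  sp1 <- pooled_support(list(tables[[1]], tables[[1]]), "v")
  expect_equal(sp1$lower, pooled_support(tables[1], "v")$lower)
  # integer counts 0..30 covered
  cnt <- list(data.frame(id = 1:3100, v = rep(0:30, each = 100)))
  spc <- pooled_support(cnt, "v")
  expect_lte(spc$lower, 0)
  expect_gte(spc$upper, 30)
  # constant-valued property is degenerate
  expect_error(pooled_support(list(data.frame(id = 1:50, v = rep(1, 50))), "v"),
               "degenerate support")
})

test_that("degree-20 fits have 21 coefficients and hit the flat-density limit", {
  set.seed(4)
  sp <- make_support("u", 0, 1)
  rep_ <- fit_chebyshev(runif(10000), sp, bandwidth = 0.01)
  expect_length(rep_$coef, 21)
  expect_length(fit_chebyshev(runif(500), sp, degree = 12)$coef, 13)
  # uniform data at small bandwidth: canonical density 1/2 -> c0 ~ 0.5
  # (the KDE loses a little mass at the interval ends, depressing the node
  # values nearest the boundary)
  expect_lt(abs(rep_$coef[1] - 0.5), 0.05)
  expect_true(all(abs(rep_$coef[-1]) < 0.05))
  expect_error(fit_chebyshev(runif(9), sp), "insufficient sample")
})

test_that("a Gaussian mixture is reconstructed with small L1 error", {
  set.seed(9)
  n <- 2000
  comp <- rbinom(n, 1, 0.4)
  v <- ifelse(comp == 1, rnorm(n, 2, 0.5), rnorm(n, 6, 0.8))
  sp <- make_support("v", -1, 9)
  rep_ <- fit_chebyshev(v, sp)
  # true mixture density mapped to the canonical interval
  x <- seq(-1, 1, length.out = 4001)
  vx <- (x + 1) / 2 * (sp$upper - sp$lower) + sp$lower
  truth <- (0.4 * dnorm(vx, 2, 0.5) + 0.6 * dnorm(vx, 6, 0.8)) *
    (sp$upper - sp$lower) / 2
  err <- abs(reconstruct_density(rep_, x) - truth)
  l1 <- sum((err[-1] + err[-4001]) / 2) * (2 / 4000)
  expect_lt(l1, 0.15)
  # reconstructed density integrates to ~1
  f <- reconstruct_density(rep_, x)
  expect_equal(sum((f[-1] + f[-4001]) / 2) * (2 / 4000), 1, tolerance = 0.05)
})

test_that("reconstruction interpolates the KDE nodes and matches direct summation", {
  rep0 <- structure(list(property = "p", support = c(lower = 0, upper = 1),
                         degree = 20, coef = c(0.5, rep(0, 20)), n = 100),
                    class = "cheb_rep")
  expect_equal(reconstruct_density(rep0, c(-1, -0.3, 0.8)), rep(0.5, 3))
  set.seed(10)
  coef <- rnorm(21)
  repr <- structure(list(property = "p", support = c(lower = 0, upper = 1),
                         degree = 20, coef = coef, n = 100),
                    class = "cheb_rep")
  x <- runif(50, -1, 1)
  expect_equal(reconstruct_density(repr, x), oracle_cheb_sum(coef, x),
               tolerance = 1e-9)
  expect_error(reconstruct_density(repr, 1.2), "outside")
  # interpolation property: evaluation at the fitting nodes reproduces the
  # KDE values there
  sp <- make_support("v", 0, 10)
  v <- rnorm(400, 5, 1.5)
  repf <- fit_chebyshev(v, sp)
  nodes <- cos(pi * (0:20) / 20)
  t <- 2 * (pmin(pmax(v, 0), 10) - 0) / 10 - 1
  kde <- vapply(nodes, function(xi) mean(dnorm(xi, t, repf$bandwidth)),
                numeric(1))
  expect_equal(reconstruct_density(repf, nodes), kde, tolerance = 1e-9)
})

test_that("fits are deterministic bit for bit", {
  set.seed(11)
  v <- rnorm(500, 3, 1)
  sp <- make_support("v", -2, 8)
  expect_identical(fit_chebyshev(v, sp)$coef, fit_chebyshev(v, sp)$coef)
})

test_that("cd is a metric that upper-bounds the L1 distance", {
  set.seed(13)
  sp <- make_support("v", -4, 12)
  reps <- lapply(1:30, function(i) {
    fit_chebyshev(rnorm(300, runif(1, 0, 8), runif(1, 0.3, 2)), sp)
  })
  # identity and symmetry
  expect_equal(cd_property(reps[[1]], reps[[1]]), 0)
  for (i in 1:10) {
    a <- reps[[sample(30, 1)]]; b <- reps[[sample(30, 1)]]
    expect_equal(cd_property(a, b), cd_property(b, a))
  }
  # triangle inequality on random triples
  for (i in 1:20) {
    idx <- sample(30, 3)
    ab <- cd_property(reps[[idx[1]]], reps[[idx[2]]])
    bc <- cd_property(reps[[idx[2]]], reps[[idx[3]]])
    ac <- cd_property(reps[[idx[1]]], reps[[idx[3]]])
    expect_lte(ac, ab + bc + 1e-12)
    expect_gte(ab, 0)
  }
  # upper bound: cd >= fine-grid L1 distance of the reconstructions
  for (i in 1:20) {
    idx <- sample(30, 2)
    expect_gte(cd_property(reps[[idx[1]]], reps[[idx[2]]]) + 1e-6,
               oracle_l1(reps[[idx[1]]], reps[[idx[2]]]))
  }
  # well-separated Gaussians: the bound is comfortably satisfied
  ra <- fit_chebyshev(rnorm(2000, 1, 0.4), sp)
  rb <- fit_chebyshev(rnorm(2000, 7, 0.4), sp)
  expect_gte(cd_property(ra, rb), oracle_l1(ra, rb))
  # mismatched supports refuse to compare
  rb2 <- fit_chebyshev(rnorm(300, 3, 1), make_support("v", -4, 13))
  expect_error(cd_property(ra, rb2), "mismatched")
})

test_that("biofilm-level cd decomposes over properties", {
  col <- compute_features(biofilm_collection(list(
    a = random_sample(150, seed = 21), b = random_sample(150, seed = 22))))
  cheb <- suppressWarnings(collection_chebyshev(col, drop_degenerate = TRUE))
  A <- cheb$matrices[[1]]
  B <- cheb$matrices[[2]]
  expect_equal(cd_biofilm(A, A), 0)
  # restriction to one property equals cd_property on it
  p1 <- cheb$properties[1]
  ra <- fit_chebyshev(col$tables[[1]][[p1]], cheb$supports[[p1]])
  rb <- fit_chebyshev(col$tables[[2]][[p1]], cheb$supports[[p1]])
  expect_equal(cd_biofilm(A, B, p1), cd_property(ra, rb), tolerance = 1e-12)
  # the full sum equals the sum of per-property cds
  per <- vapply(cheb$properties, function(p) cd_biofilm(A, B, p), numeric(1))
  expect_equal(cd_biofilm(A, B), sum(per), tolerance = 1e-12)
  expect_error(cd_biofilm(A, B, character(0)), "empty property subset")
})

test_that("the pairwise cd matrix is symmetric, zero-diagonal and group-structured", {
  s <- random_sample(150, seed = 30)
  col <- compute_features(biofilm_collection(list(a = s, b = s)))
  cheb <- suppressWarnings(collection_chebyshev(col, drop_degenerate = TRUE))
  expect_equal(unname(cd_matrix(cheb)), matrix(0, 2, 2))
  # two synthetic density groups: within-group cd below between-group cd
  specs <- list(group_spec("dense", 3, 250, spacing = 1.0, seed = 5),
                group_spec("sparse", 3, 250, spacing = 2.0, seed = 6))
  col2 <- compute_features(generate_collection(specs))
  cheb2 <- suppressWarnings(collection_chebyshev(col2, drop_degenerate = TRUE))
  M <- cd_matrix(cheb2)
  expect_equal(M, t(M))
  expect_true(all(diag(M) == 0))
  g <- collection_groups(col2)
  same <- outer(g, g, "==") & upper.tri(M)
  diff_ <- outer(g, g, "!=") & upper.tri(M)
  expect_lt(mean(M[same]), mean(M[diff_]))
})

test_that("a chebyshev collection round-trips through JSON", {
  col <- compute_features(biofilm_collection(list(
    a = random_sample(120, seed = 61), b = random_sample(120, seed = 62),
    c = random_sample(120, seed = 63))))
  cheb <- suppressWarnings(collection_chebyshev(col, drop_degenerate = TRUE))
  f <- file.path(tempdir(), "cheb.json")
  write_chebyshev(cheb, f)
  back <- read_chebyshev(f)
  expect_equal(back$properties, cheb$properties)
  expect_equal(back$degree, cheb$degree)
  expect_equal(unname(back$groups), unname(cheb$groups))
  for (nm in names(cheb$matrices)) {
    expect_equal(unclass(back$matrices[[nm]]), unclass(cheb$matrices[[nm]]),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # dissimilarities computed from the reloaded file agree exactly
  expect_equal(cd_matrix(back), cd_matrix(cheb), tolerance = 1e-12)
})
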