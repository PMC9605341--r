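test_that("aspect ratio is length over width", {
  s <- biofilm_sample(data.frame(id = 1:3, x = 0:2 * 3, y = 0, z = 1,
                                 nx = 1, ny = 0, nz = 0,
                                 length = c(2, 1, 3.5),
                                 width = c(1, 1, 0.8)))
  expect_equal(aspect_ratio(s), c(2, 1, 4.375))
})

test_that("local density counts neighbours within the radius", {
  one <- biofilm_sample(toy_cells()[1, ])
  expect_equal(local_density(one), 0L)
  two <- biofilm_sample(data.frame(id = 1:2, x = c(0, 1.5), y = 0, z = 1,
                                   nx = 1, ny = 0, nz = 0, length = 1,
                                   width = 0.8))
  expect_equal(local_density(two, radius = 2), c(1L, 1L))
  # 5x5x5 lattice at 1 um spacing vs brute-force all-pairs tally
  g <- expand.grid(x = 0:4, y = 0:4, z = 0:4)
  lat <- biofilm_sample(data.frame(id = seq_len(125), g, nx = 1, ny = 0,
                                   nz = 0, length = 1, width = 0.8))
  counts <- local_density(lat, radius = 2)
  pos <- as.matrix(g)
  brute <- vapply(seq_len(125), function(i) {
    sum(sqrt(colSums((t(pos) - pos[i, ])^2)) <= 2) - 1L
  }, numeric(1))
  expect_equal(counts, as.integer(brute))
})

test_that("local density is monotone in the radius", {
  s <- random_sample(80, seed = 5)
  radii <- c(1, 2, 3, 5)
  counts <- vapply(radii, function(r) local_density(s, r), integer(80))
  expect_true(all(diff(t(counts)) >= 0))
})

test_that("nematic order matches the Q-tensor eigen oracle and its symmetries", {
  # all identical orientations -> S = 1 everywhere
  par <- biofilm_sample(data.frame(id = 1:5, x = seq(0, 2, length.out = 5),
                                   y = 0, z = 1, nx = 1, ny = 0, nz = 0,
                                   length = 2, width = 0.8))
  expect_equal(local_nematic_order(par), rep(1, 5), tolerance = 1e-12)
  expect_equal(nematic_order_variance(par), 0, tolerance = 1e-12)
  # 50 random orientations, one neighbourhood covering all cells:
  # matches the direct eigen-decomposition of the pooled Q tensor
  cells <- random_cells(50, seed = 8, box = 1)
  s <- biofilm_sample(cells)
  S <- local_nematic_order(s, radius = 10)
  N <- as.matrix(cells[, c("nx", "ny", "nz")])
  N <- N / sqrt(rowSums(N^2))
  Q <- (3 * crossprod(N) / 50 - diag(3)) / 2
  expect_equal(S, rep(max(eigen(Q)$values), 50), tolerance = 1e-9)
  # nematic symmetry: flipping orientation signs changes nothing
  flip <- cells
  flip[c(3, 17, 40), c("nx", "ny", "nz")] <-
    -flip[c(3, 17, 40), c("nx", "ny", "nz")]
  expect_equal(local_nematic_order(biofilm_sample(flip), radius = 2),
               local_nematic_order(s, radius = 2), tolerance = 1e-12)
  expect_error(nematic_order_variance(biofilm_sample(toy_cells()[1, ])),
               "single cell")
})

test_that("features are invariant under rigid motions", {
  s <- random_sample(60, seed = 12)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  cells <- s$cells
  pos <- as.matrix(cells[, c("x", "y", "z")]) %*% t(R)
  ori <- as.matrix(cells[, c("nx", "ny", "nz")]) %*% t(R)
  rot <- cells
  rot[, c("x", "y", "z")] <- sweep(pos, 2, c(5, -3, 0), "+")
  rot[, c("nx", "ny", "nz")] <- ori
  s2 <- biofilm_sample(rot)
  expect_equal(local_density(s2), local_density(s))
  expect_equal(local_nematic_order(s2), local_nematic_order(s),
               tolerance = 1e-9)
  expect_equal(nematic_order_variance(s2), nematic_order_variance(s),
               tolerance = 1e-9)
  # in-plane rotation preserves heights, hence distance_to_surface
  expect_equal(distance_to_surface(s2), distance_to_surface(s))
  expect_equal(distance_to_centroid(s2), distance_to_centroid(s),
               tolerance = 1e-9)
  expect_equal(surface_area_per_volume(s2), surface_area_per_volume(s),
               tolerance = 1e-9)
})

test_that("surface area per volume matches closed forms and the hull oracle", {
  # points on a sphere of radius R: area/volume -> 3/R
  set.seed(21)
  R <- 4
  u <- matrix(rnorm(3 * 2000), ncol = 3)
  u <- R * u / sqrt(rowSums(u^2))
  sph <- biofilm_sample(data.frame(id = seq_len(2000), x = u[, 1],
                                   y = u[, 2], z = u[, 3] + R + 1,
                                   nx = 1, ny = 0, nz = 0, length = 1,
                                   width = 0.8))
  expect_equal(surface_area_per_volume(sph), 3 / R, tolerance = 0.02)
  # scaling all coordinates by c scales the ratio by 1/c
  s <- random_sample(120, seed = 31)
  sc <- s$cells
  sc[, c("x", "y", "z")] <- 2.5 * sc[, c("x", "y", "z")]
  expect_equal(surface_area_per_volume(biofilm_sample(sc)),
               surface_area_per_volume(s) / 2.5, tolerance = 1e-9)
  # independent brute-force facet-enumeration oracle on a random blob
  blob <- random_sample(60, seed = 44)
  o <- oracle_hull(as.matrix(blob$cells[, c("x", "y", "z")]))
  expect_equal(surface_area_per_volume(blob), o$area / o$volume,
               tolerance = 0.01)
  # degenerate: coplanar centroids
  flat <- toy_cells()
  expect_error(surface_area_per_volume(biofilm_sample(flat)), "degenerate")
})

test_that("property table composes the individual operations", {
  s <- biofilm_sample(toy_cells())
  tab <- compute_property_table(s)
  expect_equal(names(tab),
               c("id", "aspect_ratio", "length", "width", "local_density",
                 "local_nematic_order", "distance_to_surface",
                 "distance_to_centroid"))
  expect_equal(tab$aspect_ratio, aspect_ratio(s))
  expect_equal(tab$local_density, as.numeric(local_density(s)))
  expect_equal(tab$distance_to_surface, s$cells$z)
  # extras pass through verbatim; unknown names error
  cells <- toy_cells()
  cells$convexity <- c(0.9, 0.8, 0.95)
  s2 <- biofilm_sample(cells)
  tab2 <- compute_property_table(s2, c("aspect_ratio", "convexity"))
  expect_equal(tab2$convexity, cells$convexity)
  expect_error(compute_property_table(s, c("aspect_ratio", "bogus")),
               "unknown property")
})

test_that("permuting cell order permutes but does not change the table", {
  s <- random_sample(40, seed = 6)
  perm <- sample(40)
  s2 <- biofilm_sample(s$cells[perm, ])
  t1 <- compute_property_table(s)
  t2 <- compute_property_table(s2)
  t2 <- t2[order(t2$id), ]
  rownames(t2) <- NULL
  expect_equal(t2, t1, tolerance = 1e-12)
})

test_that("mean local density tracks the prescribed packing density", {
  spacings <- c(1.0, 1.3, 1.6, 1.9, 2.2)
  means <- vapply(seq_along(spacings), function(i) {
    mean(vapply(1:3, function(r) {
      s <- generate_packing(group_spec("g", n_cells = 200, ar_median = 2,
                                       spacing = spacings[i],
                                       seed = 100 * i + r))
      mean(local_density(s))
    }, numeric(1)))
  }, numeric(1))
  expect_gt(abs(cor(means, 1 / spacings, method = "spearman")), 0.9)
})
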