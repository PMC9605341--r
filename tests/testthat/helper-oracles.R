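# Shared fixtures and independent oracles used across the suite.
# Oracles are deliberately naive (brute force / closed form / fine grids)
# and never share code with the implementation they check.

toy_cells <- function() {
  data.frame(id = 1:3,
             x = c(0, 1.5, 3), y = c(0, 0.2, -0.2), z = c(0.4, 0.5, 0.6),
             nx = c(1, 0, 1), ny = c(0, 1, 1), nz = c(0, 0, 0),
             length = c(2, 2.5, 3), width = c(0.8, 0.8, 0.8))
}

random_cells <- function(n, seed = 1, box = 10) {
  set.seed(seed)
  d <- matrix(rnorm(3 * n), n, 3)
  d <- d / sqrt(rowSums(d^2))
  data.frame(id = seq_len(n),
             x = runif(n, 0, box), y = runif(n, 0, box),
             z = runif(n, 0.4, box),
             nx = d[, 1], ny = d[, 2], nz = d[, 3],
             length = runif(n, 1, 4), width = runif(n, 0.6, 0.9))
}

random_sample <- function(n, seed = 1, box = 10) {
  biofilm_sample(random_cells(n, seed, box), group = "rand",
                 provenance = "synthetic")
}

# brute-force mean silhouette for a clustering of a dissimilarity matrix
oracle_silhouette <- function(assign, D) {
  n <- length(assign)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(assign == assign[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(assign), assign[i]), function(cl) {
      mean(D[i, assign == cl])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# exhaustive-search optimal k for average-linkage + mean silhouette
oracle_best_k <- function(D, k_range) {
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  sil <- vapply(k_range, function(k) {
    oracle_silhouette(stats::cutree(hc, k = k), D)
  }, numeric(1))
  k_range[which.max(sil)]
}

# brute-force 3D convex hull by facet enumeration (all point triples whose
# plane has every other point on one side); returns area and volume
oracle_hull <- function(P) {
  n <- nrow(P)
  cen <- colMeans(P)
  area <- 0
  vol <- 0
  eps <- 1e-9 * max(apply(P, 2, function(c) diff(range(c))))
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- P[i, ]; b <- P[j, ]; c <- P[k, ]
    nrm <- c((b[2] - a[2]) * (c[3] - a[3]) - (b[3] - a[3]) * (c[2] - a[2]),
             (b[3] - a[3]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[3] - a[3]),
             (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
    side <- (P[, 1] - a[1]) * nrm[1] + (P[, 2] - a[2]) * nrm[2] +
            (P[, 3] - a[3]) * nrm[3]
    if (all(side <= eps) || all(side >= -eps)) {
      fa <- 0.5 * sqrt(sum(nrm^2))
      area <- area + fa
      # signed tetra volume against the centroid, oriented outward
      sgn <- if (sum((a - cen) * nrm) >= 0) 1 else -1
      vol <- vol + sgn * sum((a - cen) *
        c((b[2] - cen[2]) * (c[3] - cen[3]) - (b[3] - cen[3]) * (c[2] - cen[2]),
          (b[3] - cen[3]) * (c[1] - cen[1]) - (b[1] - cen[1]) * (c[3] - cen[3]),
          (b[1] - cen[1]) * (c[2] - cen[2]) - (b[2] - cen[2]) * (c[1] - cen[1]))) / 6
    }
  }
  list(area = area, volume = abs(vol))
}

# fine-grid minimisation of the distance between two cell axis segments
oracle_segdist <- function(cellA, cellB, ngrid = 401) {
  hA <- (cellA$length - cellA$width) / 2
  hB <- (cellB$length - cellB$width) / 2
  s <- seq(-1, 1, length.out = ngrid)
  best <- Inf
  for (si in s) {
    p <- cellA$pos + si * hA * cellA$dir
    q <- outer(rep(1, ngrid), cellB$pos) + (s * hB) %o% cellB$dir
    d2 <- rowSums(sweep(q, 2, p)^2)
    best <- min(best, min(d2))
  }
  sqrt(best)
}

# trapezoidal L1 distance between two reconstructed canonical densities
oracle_l1 <- function(repA, repB, ngrid = 4001) {
  x <- seq(-1, 1, length.out = ngrid)
  f <- abs(reconstruct_density(repA, x) - reconstruct_density(repB, x))
  sum((f[-1] + f[-ngrid]) / 2) * (2 / (ngrid - 1))
}

# direct Chebyshev series summation (vs Clenshaw)
oracle_cheb_sum <- function(coef, x) {
  k <- seq_along(coef) - 1
  vapply(x, function(xi) sum(coef * cos(k * acos(xi))), numeric(1))
}

make_support <- function(property, lower, upper) {
  structure(list(property = property, lower = lower, upper = upper),
            class = "property_support")
}

# four-group synthetic collection used by the phase-diagram checks:
# aspect-ratio medians bracket the mreB-mutant range, spacings span a
# roughly 2-4x density range, local-orientation packing
four_group_specs <- function(n_biofilms = 5, n_cells = 500, seed = 11) {
  list(
    group_spec("lowAR_lowD", n_biofilms, n_cells, ar_median = 2.0,
               spacing = 2.1, seed = seed),
    group_spec("lowAR_highD", n_biofilms, n_cells, ar_median = 2.0,
               spacing = 1.0, seed = seed + 1),
    group_spec("highAR_lowD", n_biofilms, n_cells, ar_median = 3.2,
               spacing = 2.1, seed = seed + 2),
    group_spec("highAR_highD", n_biofilms, n_cells, ar_median = 3.2,
               spacing = 1.0, seed = seed + 3))
}

fast_params <- function(...) {
  sim_params(n_target = 60, seed = 42, ...)
}
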