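# Chebyshev representation of property distributions and the Cd
# dissimilarity.
#
# Each property distribution of one biofilm is smoothed by a Gaussian KDE on
# a shared canonical interval [-1, 1] and interpolated by a first-kind
# Chebyshev polynomial of degree d (default 20) through the d+1
# Chebyshev-Gauss-Lobatto nodes. Two representations on the same support are
# compared by cd = 2 * sum_k |c_k^A - c_k^B|; since |T_k| <= 1 and the
# canonical interval has length 2, cd upper-bounds the L1 distance between
# the reconstructed densities, and summing over properties bounds the
# cumulative L1 distance between the collections of distributions.

#' Pooled property support for a collection
#'
#' Coefficients of different biofilms are comparable only if fitted on a
#' common domain, so the support of each property is pooled over all cells of
#' all biofilms in the collection: the `[q_lo, q_hi]` quantile range, widened
#' by a 5% margin on each side.
#'
#' @param collection a `biofilm_collection` with computed features
#'   ([compute_features()]).
#' @param property property name.
#' @param q_lo,q_hi pooled quantiles bounding the support.
#' @return list with `property`, `lower`, `upper` (class `property_support`).
#' @export
pooled_support <- function(collection, property, q_lo = 0.005, q_hi = 0.995) {
  tables <- collection_tables(collection)
  vals <- unlist(lapply(tables, function(tb) {
    if (!property %in% names(tb)) {
      stop("property '", property, "' missing from a sample's table")
    }
    tb[[property]]
  }), use.names = FALSE)
  qs <- stats::quantile(vals, c(q_lo, q_hi), names = FALSE, type = 7)
  rng <- qs[2] - qs[1]
  if (rng <= 0) {
    stop("degenerate support for property '", property,
         "': zero spread across the collection")
  }
  structure(list(property = property,
                 lower = qs[1] - 0.05 * rng,
                 upper = qs[2] + 0.05 * rng),
            class = "property_support")
}

collection_tables <- function(collection) {
  if (inherits(collection, "biofilm_collection")) {
    if (is.null(collection$tables)) {
      stop("collection has no property tables; run compute_features() first")
    }
    return(collection$tables)
  }
  if (is.list(collection) && all(vapply(collection, is.data.frame, logical(1)))) {
    return(collection)
  }
  stop("expected a biofilm_collection with features or a list of tables")
}

cheb_nodes <- function(degree) cos(pi * (0:degree) / degree)

# Chebyshev interpolation through values f at the CGL nodes (j = 0..d):
# discrete cosine transform with the standard half-weights at the interval
# ends, yielding coefficients of sum_k c_k T_k(x).
cheb_coef_from_nodes <- function(f) {
  d <- length(f) - 1L
  j <- 0:d
  wj <- rep(1, d + 1)
  wj[c(1, d + 1)] <- 0.5
  C <- cos(pi * outer(j, j) / d)
  ck <- (2 / d) * as.vector(C %*% (wj * f))
  ck[c(1, d + 1)] <- ck[c(1, d + 1)] / 2
  ck
}

silverman_bw <- function(t) {
  n <- length(t)
  s <- stats::sd(t)
  iqr <- diff(stats::quantile(t, c(0.25, 0.75), names = FALSE))
  spread <- min(s, iqr / 1.34)
  if (!is.finite(spread) || spread <= 0) spread <- s
  bw <- 0.9 * spread * n^(-1 / 5)
  # Discrete-valued properties (e.g. integer neighbour counts) need the
  # kernel to bridge the value grid, or the KDE degenerates into a comb
  # whose Chebyshev coefficients carry gridding artifacts instead of the
  # distribution shape: floor the bandwidth at half the minimal gap
  # between distinct values (a Gaussian of that sd leaves < 1% ripple).
  gaps <- diff(sort(unique(t)))
  gaps <- gaps[gaps > 1e-12]
  if (length(gaps) > 0) bw <- max(bw, 0.5 * min(gaps))
  max(bw, 0.01, na.rm = TRUE)
}

#' Fit the Chebyshev representation of one property distribution
#'
#' Values are clamped to the support edges, mapped affinely onto the
#' canonical interval \[-1, 1\], smoothed by a Gaussian kernel density
#' estimate (Silverman bandwidth on the canonical data, floored at 0.01
#' canonical units), evaluated at the d + 1 Chebyshev-Gauss-Lobatto nodes and
#' interpolated exactly by a degree-d Chebyshev polynomial. The default
#' degree 20 yields 21 coefficients per property; a biofilm described by p
#' properties is thus compressed to (d + 1) * p numbers regardless of its
#' cell count. The fit is fully deterministic: identical inputs give
#' bit-identical coefficients.
#'
#' @param values numeric vector of at least 10 finite per-cell values.
#' @param support a `property_support` (see [pooled_support()]).
#' @param degree polynomial degree d (>= 2); default 20.
#' @param bandwidth optional fixed KDE bandwidth in canonical units.
#' @return object of class `cheb_rep`: coefficients, support, degree,
#'   bandwidth, sample size.
#' @export
fit_chebyshev <- function(values, support, degree = 20, bandwidth = NULL) {
  stopifnot(inherits(support, "property_support"), degree >= 2)
  values <- values[is.finite(values)]
  if (length(values) < 10) {
    stop("insufficient sample: need >= 10 finite values, got ", length(values))
  }
  lo <- support$lower
  hi <- support$upper
  v <- pmin(pmax(values, lo), hi)
  t <- 2 * (v - lo) / (hi - lo) - 1
  bw <- if (is.null(bandwidth)) silverman_bw(t) else max(bandwidth, 1e-6)
  x <- cheb_nodes(degree)
  # KDE on the canonical scale, evaluated at the nodes
  f <- vapply(x, function(xi) mean(stats::dnorm(xi, mean = t, sd = bw)),
              numeric(1))
  structure(list(property = support$property,
                 support = c(lower = lo, upper = hi),
                 degree = degree,
                 coef = cheb_coef_from_nodes(f),
                 bandwidth = bw,
                 n = length(values)),
            class = "cheb_rep")
}

clenshaw <- function(coef, x) {
  d <- length(coef) - 1L
  b1 <- rep(0, length(x))
  b2 <- rep(0, length(x))
  if (d >= 1) {
    for (k in seq(d, 1)) {
      b0 <- 2 * x * b1 - b2 + coef[k + 1]
      b2 <- b1
      b1 <- b0
    }
  }
  coef[1] + x * b1 - b2
}

#' Evaluate a Chebyshev representation
#'
#' Clenshaw evaluation of the fitted density at canonical coordinates.
#' Truncation can make reconstructed densities slightly negative; values are
#' reported as-is.
#'
#' @param rep a `cheb_rep`.
#' @param x canonical coordinates in \[-1, 1\].
#' @return density values on the canonical scale.
#' @export
reconstruct_density <- function(rep, x) {
  stopifnot(inherits(rep, "cheb_rep"))
  if (any(x < -1 - 1e-12 | x > 1 + 1e-12)) {
    stop("canonical coordinate outside [-1, 1]")
  }
  clenshaw(rep$coef, pmin(pmax(x, -1), 1))
}

same_support <- function(a, b, tol = 1e-9) {
  a$degree == b$degree &&
    abs(a$support[["lower"]] - b$support[["lower"]]) <= tol &&
    abs(a$support[["upper"]] - b$support[["upper"]]) <= tol
}

#' Chebyshev dissimilarity between two fitted distributions
#'
#' `cd = 2 * sum_k |c_k^A - c_k^B|`. Because every Chebyshev polynomial is
#' bounded by 1 in modulus and the canonical interval has length 2, cd is an
#' upper bound on the L1 distance between the two reconstructed densities; it
#' is a metric (a weighted L1 norm on coefficient space).
#'
#' @param repA,repB `cheb_rep` objects fitted for the same property on the
#'   same support and degree.
#' @return scalar dissimilarity.
#' @export
cd_property <- function(repA, repB) {
  stopifnot(inherits(repA, "cheb_rep"), inherits(repB, "cheb_rep"))
  if (!identical(repA$property, repB$property)) {
    stop("cannot compare representations of different properties ('",
         repA$property, "' vs '", repB$property, "')")
  }
  if (!same_support(repA, repB)) {
    stop("mismatched supports or degrees")
  }
  2 * sum(abs(repA$coef - repB$coef))
}

#' Chebyshev coefficient matrix of one biofilm
#'
#' Stacks one fitted representation per property into a (d + 1) x m
#' coefficient matrix, the compressed architectural fingerprint of the
#' biofilm.
#'
#' @param table per-cell property table ([compute_property_table()]).
#' @param supports named list of `property_support`, one per property;
#'   defines the property order of the columns.
#' @param degree polynomial degree.
#' @return object of class `cheb_matrix`: numeric matrix with properties as
#'   columns, plus support metadata.
#' @export
chebyshev_matrix <- function(table, supports, degree = 20) {
  props <- vapply(supports, `[[`, character(1), "property")
  reps <- lapply(supports, function(sp) {
    fit_chebyshev(table[[sp$property]], sp, degree = degree)
  })
  m <- vapply(reps, `[[`, numeric(degree + 1), "coef")
  colnames(m) <- props
  structure(m, class = c("cheb_matrix", "matrix"),
            supports = supports, degree = degree)
}

#' Fit Chebyshev matrices for a whole collection
#'
#' Computes pooled supports for the requested properties (optionally dropping
#' properties whose pooled values are constant) and fits the coefficient
#' matrix of every biofilm on those shared supports.
#'
#' @param collection a `biofilm_collection` with computed features.
#' @param properties properties to represent (default: all computed).
#' @param degree polynomial degree.
#' @param q_lo,q_hi support quantiles (see [pooled_support()]).
#' @param drop_degenerate if `TRUE`, constant-valued properties are dropped
#'   with a warning instead of raising an error.
#' @return object of class `cheb_collection`: list of `cheb_matrix`, shared
#'   supports, property order, group labels.
#' @export
collection_chebyshev <- function(collection, properties = NULL, degree = 20,
                                 q_lo = 0.005, q_hi = 0.995,
                                 drop_degenerate = FALSE) {
  tables <- collection_tables(collection)
  if (is.null(properties)) {
    properties <- setdiff(names(tables[[1]]), "id")
  }
  supports <- list()
  for (p in properties) {
    sp <- tryCatch(pooled_support(collection, p, q_lo, q_hi),
                   error = function(e) e)
    if (inherits(sp, "error")) {
      if (drop_degenerate && grepl("degenerate support", conditionMessage(sp))) {
        warning("dropping property '", p, "': ", conditionMessage(sp))
        next
      }
      stop(sp)
    }
    supports[[p]] <- sp
  }
  if (length(supports) == 0) stop("no usable properties left")
  matrices <- lapply(tables, chebyshev_matrix, supports = supports,
                     degree = degree)
  groups <- if (inherits(collection, "biofilm_collection")) {
    collection_groups(collection)
  } else {
    rep("unknown", length(matrices))
  }
  structure(list(matrices = matrices, supports = supports,
                 properties = names(supports), degree = degree,
                 groups = groups),
            class = "cheb_collection")
}

#' Serialize / read a Chebyshev collection
#'
#' Writes the shared supports, property order, degree, group labels and all
#' per-biofilm coefficient matrices of a `cheb_collection` to one JSON file
#' (numbers at full precision), and reads it back.
#'
#' @param chebcol a `cheb_collection`.
#' @param path JSON file path.
#' @return `write_chebyshev()` returns `path` invisibly;
#'   `read_chebyshev()` the reconstructed `cheb_collection`.
#' @export
write_chebyshev <- function(chebcol, path) {
  stopifnot(inherits(chebcol, "cheb_collection"))
  payload <- list(
    degree = chebcol$degree,
    properties = chebcol$properties,
    groups = as.list(chebcol$groups),
    supports = lapply(chebcol$supports, function(sp) {
      list(property = sp$property, lower = sp$lower, upper = sp$upper)
    }),
    matrices = lapply(chebcol$matrices, function(M) {
      apply(unclass(M), 2, identity, simplify = FALSE)
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_chebyshev
#' @export
read_chebyshev <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  supports <- lapply(p$supports, function(sp) {
    structure(list(property = sp$property, lower = sp$lower,
                   upper = sp$upper), class = "property_support")
  })
  matrices <- lapply(p$matrices, function(cols) {
    M <- do.call(cbind, cols)
    structure(M, class = c("cheb_matrix", "matrix"),
              supports = supports, degree = p$degree)
  })
  structure(list(matrices = matrices, supports = supports,
                 properties = p$properties, degree = p$degree,
                 groups = unlist(p$groups)),
            class = "cheb_collection")
}

#' Chebyshev dissimilarity between two biofilms
#'
#' Sum of the per-property dissimilarities over the selected properties,
#' giving the cumulative L1 upper bound between the two sets of property
#' distributions.
#'
#' @param matA,matB `cheb_matrix` objects on identical supports.
#' @param properties property subset (default: all shared columns).
#' @return scalar dissimilarity.
#' @export
cd_biofilm <- function(matA, matB, properties = NULL) {
  if (is.null(properties)) properties <- colnames(matA)
  if (length(properties) == 0) stop("empty property subset")
  if (!all(properties %in% colnames(matA)) ||
      !all(properties %in% colnames(matB))) {
    stop("property subset not present in both matrices")
  }
  spA <- attr(matA, "supports")
  spB <- attr(matB, "supports")
  for (p in properties) {
    if (!same_support(list(degree = attr(matA, "degree"),
                           support = c(lower = spA[[p]]$lower,
                                       upper = spA[[p]]$upper)),
                      list(degree = attr(matB, "degree"),
                           support = c(lower = spB[[p]]$lower,
                                       upper = spB[[p]]$upper)))) {
      stop("mismatched support for property '", p, "'")
    }
  }
  sum(vapply(properties, function(p) {
    2 * sum(abs(matA[, p] - matB[, p]))
  }, numeric(1)))
}

#' Pairwise biofilm dissimilarity matrix
#'
#' @param chebcol a `cheb_collection`.
#' @param properties property subset used for the comparison.
#' @return symmetric matrix with zero diagonal, one row/column per biofilm.
#' @export
cd_matrix <- function(chebcol, properties = NULL) {
  stopifnot(inherits(chebcol, "cheb_collection"))
  mats <- chebcol$matrices
  n <- length(mats)
  if (n < 2) stop("need at least 2 biofilms")
  out <- matrix(0, n, n, dimnames = list(names(mats), names(mats)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      out[i, j] <- out[j, i] <- cd_biofilm(mats[[i]], mats[[j]], properties)
    }
  }
  out
}

#' Cross-property dissimilarity matrix
#'
#' Treats each property as a long vector of Chebyshev coefficients across all
#' biofilms and compares properties with the same cd construction. Before the
#' comparison every coefficient index is z-normalised across biofilms (per
#' property), so that properties measured in different units become
#' comparable; coefficient indices with zero variance are set to zero.
#' Properties whose distributions co-vary across the collection (e.g. cell
#' length and aspect ratio at fixed width) end up close to each other.
#'
#' @param chebcol a `cheb_collection`.
#' @return symmetric m x m matrix of property dissimilarities.
#' @export
property_dissimilarity <- function(chebcol) {
  stopifnot(inherits(chebcol, "cheb_collection"))
  props <- chebcol$properties
  m <- length(props)
  # array biofilms x coefficients per property, z-scored per coefficient
  zmat <- lapply(props, function(p) {
    A <- t(vapply(chebcol$matrices, function(M) M[, p],
                  numeric(chebcol$degree + 1)))
    scale_safe(A)
  })
  names(zmat) <- props
  out <- matrix(0, m, m, dimnames = list(props, props))
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (j > i) {
        out[i, j] <- out[j, i] <- 2 * sum(abs(zmat[[i]] - zmat[[j]]))
      }
    }
  }
  out
}

scale_safe <- function(A) {
  mu <- colMeans(A)
  sdv <- apply(A, 2, stats::sd)
  sdv[!is.finite(sdv) | sdv <= 0] <- Inf   # zero-variance index -> all zeros
  sweep(sweep(A, 2, mu), 2, sdv, "/")
}

#' Reduce redundant properties by Cd clustering
#'
#' Average-linkage hierarchical clustering of the cross-property
#' dissimilarity matrix; the cluster number k (searched over `k_range`) is
#' chosen to maximise the mean silhouette coefficient (ties broken towards
#' the smallest k). Each cluster is represented by its medoid (minimal summed
#' dissimilarity to the cluster members; ties broken by input order), so
#' highly correlated properties are counted once in downstream analyses.
#'
#' @param prop_cd symmetric property dissimilarity matrix
#'   ([property_dissimilarity()]), m >= 3.
#' @param k_range candidate cluster numbers (default 2..m-1).
#' @return list: `selected` (medoid property names in input order),
#'   `clusters` (named assignment vector), `k`, `silhouette` (mean silhouette
#'   per candidate k).
#' @export
reduce_properties <- function(prop_cd, k_range = NULL) {
  stopifnot(is.matrix(prop_cd), nrow(prop_cd) == ncol(prop_cd))
  m <- nrow(prop_cd)
  if (m < 3) stop("need at least 3 properties to reduce")
  props <- rownames(prop_cd)
  if (is.null(props)) props <- paste0("p", seq_len(m))
  if (is.null(k_range)) k_range <- 2:(m - 1)
  k_range <- sort(unique(pmin(pmax(k_range, 2), m - 1)))
  d <- stats::as.dist(prop_cd)
  hc <- stats::hclust(d, method = "average")
  sil <- vapply(k_range, function(k) {
    cut <- stats::cutree(hc, k = k)
    mean(cluster::silhouette(cut, d)[, "sil_width"])
  }, numeric(1))
  names(sil) <- k_range
  k_best <- k_range[which.max(sil)]   # which.max takes the first maximum
  cut <- stats::cutree(hc, k = k_best)
  names(cut) <- props
  medoids <- vapply(seq_len(k_best), function(cl) {
    idx <- which(cut == cl)
    if (length(idx) == 1) return(idx)
    sums <- rowSums(prop_cd[idx, idx, drop = FALSE])
    idx[which.min(sums)]
  }, integer(1))
  list(selected = props[sort(medoids)],
       clusters = cut,
       k = k_best,
       silhouette = sil)
}
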