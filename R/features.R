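# Per-cell architectural properties and per-biofilm emergent summaries.
# These are the observables the distributional statistics are built on.

#' Standard architectural property set
#'
#' The per-cell properties computed by default throughout the package:
#' the single-cell shape properties (aspect ratio, length, width) and the
#' emergent neighbourhood properties (local density, local nematic order,
#' distance to the substrate, distance to the colony centroid).
#'
#' @format character vector of property names.
#' @export
DEFAULT_PROPERTIES <- c("aspect_ratio", "length", "width", "local_density",
                        "local_nematic_order", "distance_to_surface",
                        "distance_to_centroid")

cell_positions <- function(sample) {
  as.matrix(sample$cells[, c("x", "y", "z")])
}
cell_orientations <- function(sample) {
  as.matrix(sample$cells[, c("nx", "ny", "nz")])
}

#' Cell aspect ratio
#'
#' Ratio of pole-to-pole cell length to cell width, the basic shape
#' parameter of a rod-shaped bacterium (1 for a sphere).
#'
#' @param sample a `biofilm_sample`.
#' @return numeric vector, one value per cell (>= 1 for valid samples).
#' @export
aspect_ratio <- function(sample) {
  sample$cells$length / sample$cells$width
}

#' Local number density
#'
#' For each cell, the number of *other* cells whose centroids lie within
#' Euclidean distance `radius` of its centroid. The 2-micrometre default is
#' the neighbourhood used throughout the package.
#'
#' @param sample a `biofilm_sample`.
#' @param radius neighbourhood radius in micrometres (> 0).
#' @return integer vector of neighbour counts, one per cell.
#' @export
local_density <- function(sample, radius = 2.0) {
  stopifnot(radius > 0)
  pos <- cell_positions(sample)
  n <- nrow(pos)
  if (n == 1) return(0L)
  d <- as.matrix(stats::dist(pos))
  as.integer(rowSums(d <= radius) - 1L)
}

neighbour_lists <- function(pos, radius) {
  d <- as.matrix(stats::dist(pos))
  apply(d <= radius, 1, which, simplify = FALSE)
}

#' Local nematic order parameter
#'
#' For each cell i the scalar S_i is the largest eigenvalue of the local
#' orientational order tensor Q_i = (3<n n^T> - I)/2, averaged over the focal
#' cell and its neighbours within `radius` (de Gennes convention: S = 1 for
#' perfect alignment, 0 for an isotropic neighbourhood; the analytic range is
#' \[-1/2, 1\] and values are reported unclipped). Because the tensor is
#' quadratic in the orientations, S is invariant under flipping the sign of
#' any orientation vector (nematic symmetry).
#'
#' @inheritParams local_density
#' @return numeric vector of order parameters, one per cell.
#' @export
local_nematic_order <- function(sample, radius = 2.0) {
  stopifnot(radius > 0)
  pos <- cell_positions(sample)
  ori <- cell_orientations(sample)
  n <- nrow(pos)
  nb <- if (n == 1) list(1L) else neighbour_lists(pos, radius)
  vapply(seq_len(n), function(i) {
    N <- ori[nb[[i]], , drop = FALSE]
    Q <- (3 * crossprod(N) / nrow(N) - diag(3)) / 2
    max(eigen(Q, symmetric = TRUE, only.values = TRUE)$values)
  }, numeric(1))
}

#' Variance of the nematic order parameter
#'
#' Population variance (denominator n) of the per-cell local nematic order
#' values: an emergent, whole-biofilm measure of how heterogeneous the
#' orientational ordering is across the colony.
#'
#' @inheritParams local_density
#' @return scalar variance.
#' @export
nematic_order_variance <- function(sample, radius = 2.0) {
  if (nrow(sample$cells) < 2) {
    stop("nematic order variance undefined for a single cell")
  }
  s <- local_nematic_order(sample, radius)
  mean((s - mean(s))^2)
}

#' Surface area per biofilm volume
#'
#' Ratio of the surface area to the enclosed volume of the 3D convex hull of
#' the cell centroids (units 1/micrometre). Early microcolonies are compact
#' domes, for which the centroid hull is a faithful geometric proxy of the
#' colony envelope; for a ball of radius R the ratio converges to 3/R.
#'
#' @param sample a `biofilm_sample` with at least 4 non-coplanar centroids.
#' @return scalar, 1/micrometre.
#' @export
surface_area_per_volume <- function(sample) {
  pos <- cell_positions(sample)
  if (nrow(pos) < 4) stop("degenerate geometry: need >= 4 centroids")
  h <- hull_area_volume_cpp(pos)
  h$area / h$volume
}

#' Distance to the substrate / to the colony centroid
#'
#' `distance_to_surface` is the centroid height above the substrate plane
#' z = 0; `distance_to_centroid` the Euclidean distance to the (unweighted)
#' mean of all cell centroids.
#'
#' @inheritParams aspect_ratio
#' @return numeric vector, micrometres.
#' @export
distance_to_surface <- function(sample) {
  sample$cells$z
}

#' @rdname distance_to_surface
#' @export
distance_to_centroid <- function(sample) {
  pos <- cell_positions(sample)
  cen <- colMeans(pos)
  sqrt(rowSums(sweep(pos, 2, cen)^2))
}

#' Compute the per-cell property table of a biofilm
#'
#' Evaluates the configured architectural properties for every cell. The
#' default set covers the single-cell shape properties (aspect ratio, length,
#' width) and the emergent neighbourhood properties (local density, local
#' nematic order, distance to surface, distance to colony centroid). Any
#' other requested name must be an extras column of the cell table, which is
#' then passed through verbatim (e.g. segmentation-derived convexity).
#'
#' @param sample a `biofilm_sample`.
#' @param properties character vector of property names.
#' @param radius neighbourhood radius (micrometres) for density and nematic
#'   order.
#' @return data.frame with column `id` plus one column per property, ordered
#'   as requested.
#' @export
compute_property_table <- function(sample, properties = DEFAULT_PROPERTIES,
                                   radius = 2.0) {
  stopifnot(length(properties) >= 1)
  out <- data.frame(id = sample$cells$id)
  for (p in properties) {
    out[[p]] <- switch(
      p,
      aspect_ratio = aspect_ratio(sample),
      length = sample$cells$length,
      width = sample$cells$width,
      local_density = as.numeric(local_density(sample, radius)),
      local_nematic_order = local_nematic_order(sample, radius),
      distance_to_surface = distance_to_surface(sample),
      distance_to_centroid = distance_to_centroid(sample),
      {
        if (!p %in% names(sample$cells)) {
          stop("unknown property '", p,
               "' (not built in and not an extras column)")
        }
        sample$cells[[p]]
      })
  }
  out
}

#' Emergent whole-biofilm summary
#'
#' The scalar collective observables of one biofilm: mean aspect ratio, mean
#' local number density, variance of the nematic order parameter, surface
#' area per volume, and cell count.
#'
#' @inheritParams compute_property_table
#' @return one-row data.frame.
#' @export
emergent_summary <- function(sample, radius = 2.0) {
  data.frame(
    mean_aspect_ratio = mean(aspect_ratio(sample)),
    mean_local_density = mean(local_density(sample, radius)),
    nematic_order_variance = nematic_order_variance(sample, radius),
    surface_area_per_volume = surface_area_per_volume(sample),
    n_cells = nrow(sample$cells))
}

#' Compute property tables for a whole collection
#'
#' @param collection a `biofilm_collection`.
#' @inheritParams compute_property_table
#' @return the collection with a `tables` element (named list of property
#'   tables) attached.
#' @export
compute_features <- function(collection, properties = DEFAULT_PROPERTIES,
                             radius = 2.0) {
  stopifnot(inherits(collection, "biofilm_collection"))
  collection$tables <- lapply(collection$samples, compute_property_table,
                              properties = properties, radius = radius)
  collection$properties <- properties
  collection$radius <- radius
  collection
}
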