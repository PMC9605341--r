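# Fast statistical generator of biofilm-like cell packings.
#
# Unlike the mechanistic simulator, this generator places non-overlapping
# rod-shaped cells by random sequential addition around a founder on the
# substrate, with prescribed aspect-ratio distribution and neighbour
# spacing. It emulates the statistical structure of a microcolony (compact
# dome, controllable density and cell shape) without any dynamics, so every
# analysis stage can be exercised quickly and with known ground truth.

#' Specification of one synthetic biofilm group
#'
#' @param label group label (must be unique within a collection).
#' @param n_biofilms number of replicate biofilms to generate.
#' @param n_cells cells per biofilm.
#' @param ar_median median of the lognormal aspect-ratio distribution
#'   (>= 1).
#' @param ar_sigma lognormal sigma of the aspect ratio.
#' @param spacing attempted centroid spacing to an existing neighbour,
#'   micrometres; smaller spacing gives denser packings.
#' @param orientation orientation model: `"local"` (default; each new cell
#'   inherits the orientation of the neighbour it is placed against, tilted
#'   by Gaussian noise — growth-induced local nematic domains, which also
#'   lets elongated cells pack densely), `"isotropic"` (in-plane near the
#'   substrate, uniform on the sphere above one cell width) or `"aligned"`
#'   (one common director with Gaussian tilt noise).
#' @param tilt_sd tilt noise (radians) for the local and aligned models.
#' @param width cell width, micrometres.
#' @param seed group seed; per-sample seeds are derived deterministically.
#' @return list of class `group_spec`.
#' @export
group_spec <- function(label, n_biofilms = 5, n_cells = 500,
                       ar_median = 2.5, ar_sigma = 0.15, spacing = 1.3,
                       orientation = c("local", "isotropic", "aligned"),
                       tilt_sd = 0.35, width = 0.8, seed = 1L) {
  orientation <- match.arg(orientation)
  stopifnot(n_biofilms >= 1, n_cells >= 1, ar_median >= 1, ar_sigma >= 0,
            spacing > 0, width > 0)
  structure(list(label = as.character(label), n_biofilms = as.integer(n_biofilms),
                 n_cells = as.integer(n_cells), ar_median = ar_median,
                 ar_sigma = ar_sigma, spacing = spacing,
                 orientation = orientation, tilt_sd = tilt_sd,
                 width = width, seed = as.integer(seed)),
            class = "group_spec")
}

runif_sphere <- function() {
  z <- stats::runif(1, -1, 1)
  phi <- stats::runif(1, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  c(r * cos(phi), r * sin(phi), z)
}

tilt_vector <- function(d, sd) {
  # rotate unit vector d by an angle ~ N(0, sd) about a random axis
  # perpendicular to it
  theta <- stats::rnorm(1, 0, sd)
  phi <- stats::runif(1, 0, 2 * pi)
  ref <- if (abs(d[3]) > 0.9) c(1, 0, 0) else c(0, 0, 1)
  u <- c(d[2] * ref[3] - d[3] * ref[2],
         d[3] * ref[1] - d[1] * ref[3],
         d[1] * ref[2] - d[2] * ref[1])
  u <- u / sqrt(sum(u^2))
  v <- c(d[2] * u[3] - d[3] * u[2],
         d[3] * u[1] - d[1] * u[3],
         d[1] * u[2] - d[2] * u[1])
  out <- cos(theta) * d + sin(theta) * (cos(phi) * u + sin(phi) * v)
  out / sqrt(sum(out^2))
}

sample_orientation <- function(z, spec, ref_dir = NULL) {
  if (spec$orientation == "local" && !is.null(ref_dir)) {
    return(tilt_vector(ref_dir, spec$tilt_sd))
  }
  if (spec$orientation == "aligned") {
    theta <- stats::rnorm(1, 0, spec$tilt_sd)
    phi <- stats::runif(1, 0, 2 * pi)
    # aligned model: common director along x, tilted by theta
    d <- c(cos(theta), sin(theta) * cos(phi), sin(theta) * sin(phi))
    return(d / sqrt(sum(d^2)))
  }
  if (z < spec$width) {
    phi <- stats::runif(1, 0, 2 * pi)
    c(cos(phi), sin(phi), 0)
  } else {
    runif_sphere()
  }
}

#' Generate one synthetic biofilm packing
#'
#' Random sequential addition of non-overlapping rod-shaped cells into a
#' dome on the substrate: each candidate is placed at the prescribed spacing
#' from a randomly chosen existing cell (heights below half a width are
#' reflected back above the substrate) and rejected on steric overlap
#' (axis-segment separation below the cell width). Lengths are width times a
#' lognormal aspect ratio; orientations follow the spec's orientation model.
#'
#' @param spec a `group_spec` (its `n_cells` is used).
#' @param replicate replicate id recorded in the metadata.
#' @param seed RNG seed (defaults to the spec seed).
#' @param max_attempts placement attempts per cell before declaring the
#'   packing jammed.
#' @return a `biofilm_sample` with provenance `"synthetic"`.
#' @export
generate_packing <- function(spec, replicate = 1L, seed = spec$seed,
                             max_attempts = 400) {
  stopifnot(inherits(spec, "group_spec"))
  set.seed(seed)
  n <- spec$n_cells
  w <- spec$width
  pos <- matrix(NA_real_, n, 3)
  dir <- matrix(NA_real_, n, 3)
  len <- numeric(n)
  draw_ar <- function() max(1, spec$ar_median * exp(stats::rnorm(1, 0, spec$ar_sigma)))
  pos[1, ] <- c(0, 0, w / 2)
  phi <- stats::runif(1, 0, 2 * pi)
  dir[1, ] <- sample_orientation(w / 2, spec)
  len[1] <- w * draw_ar()
  maxlen <- len[1]
  for (i in seq_len(n)[-1]) {
    placed <- FALSE
    for (att in seq_len(max_attempts)) {
      ref <- sample.int(i - 1L, 1)
      u <- runif_sphere()
      cand <- pos[ref, ] + spec$spacing * u
      if (cand[3] < w / 2) cand[3] <- w - cand[3]   # reflect above substrate
      d <- sample_orientation(cand[3], spec, ref_dir = dir[ref, ])
      ar <- draw_ar()
      l <- w * ar
      # cheap centre-distance prefilter, then exact axis-segment distances
      prev <- seq_len(i - 1L)
      dc2 <- (pos[prev, 1] - cand[1])^2 + (pos[prev, 2] - cand[2])^2 +
             (pos[prev, 3] - cand[3])^2
      reach <- (0.5 * (l + maxlen) + w)^2
      near <- prev[dc2 <= reach]
      ok <- TRUE
      if (length(near) > 0) {
        dists <- segdist_many_cpp(cand, d, l, w,
                                  pos[near, , drop = FALSE],
                                  dir[near, , drop = FALSE],
                                  len[near], rep(w, length(near)))
        ok <- all(dists >= w)   # delta = dist - w >= 0: no steric overlap
      }
      if (ok) {
        pos[i, ] <- cand
        dir[i, ] <- d
        len[i] <- l
        maxlen <- max(maxlen, l)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("jammed: could not place cell ", i, " after ", max_attempts,
           " attempts (spacing too small for these aspect ratios)")
    }
  }
  cells <- data.frame(id = seq_len(n),
                      x = pos[, 1], y = pos[, 2], z = pos[, 3],
                      nx = dir[, 1], ny = dir[, 2], nz = dir[, 3],
                      length = len, width = w)
  biofilm_sample(cells, group = spec$label, condition = "synthetic",
                 replicate = replicate, provenance = "synthetic",
                 params = unclass(spec))
}

#' Generate a labelled synthetic collection
#'
#' Generates `n_biofilms` packings per group spec; per-sample seeds are
#' derived deterministically from each group seed, so the same specs always
#' yield the identical collection.
#'
#' @param specs list of `group_spec` objects with unique labels.
#' @return a `biofilm_collection`.
#' @export
generate_collection <- function(specs) {
  stopifnot(length(specs) >= 1)
  labels <- vapply(specs, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicate group labels")
  samples <- list()
  for (spec in specs) {
    for (r in seq_len(spec$n_biofilms)) {
      s <- generate_packing(spec, replicate = r,
                            seed = (spec$seed * 1009L + r) %% 2147483647L)
      samples[[paste(spec$label, r, sep = ".")]] <- s
    }
  }
  biofilm_collection(samples)
}
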