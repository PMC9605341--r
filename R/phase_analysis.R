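# PCA on flattened Chebyshev coefficient vectors, the biofilm architecture
# index (BAI), per-property contributions, and the aspect-ratio vs density
# phase diagram.

#' PCA embedding of a biofilm collection
#'
#' Each biofilm's coefficient matrix is flattened (property blocks of d + 1
#' coefficients each) into one (d + 1) * p vector; dimensions are centred
#' (zero-variance dimensions are dropped with a warning and recorded) and a
#' principal component analysis is performed via singular value
#' decomposition on the raw coefficient covariance. No per-dimension
#' rescaling is applied: Chebyshev coefficients of canonical-interval
#' densities are already unit-free and mutually comparable (every
#' represented distribution integrates to one over \[-1, 1\]), so the
#' coefficient variance directly measures how much a property's
#' distribution moves across the collection, whereas z-scoring would
#' inflate noise-dominated high-order coefficients to the same weight as
#' the informative ones. The signed first principal component score is the
#' biofilm architecture index (BAI): a single scalar summarising the
#' architecture of a microcolony. PCA signs are arbitrary, so the sign is
#' fixed by the convention that the summed PC1 loading of the local-density
#' coefficient block is non-negative — denser biofilms get larger BAI by
#' construction.
#'
#' @param chebcol a `cheb_collection` (at least 3 biofilms).
#' @param properties property subset to embed (default: all).
#' @return object of class `phase_embedding`: `scores` (biofilms x
#'   components), `bai`, `loadings`, `explained` (variance ratios summing to
#'   1), `columns` (property of every kept dimension), `preprocess` (means,
#'   scales, kept-dimension index).
#' @export
pca_embed <- function(chebcol, properties = NULL) {
  stopifnot(inherits(chebcol, "cheb_collection"))
  if (is.null(properties)) properties <- chebcol$properties
  stopifnot(length(properties) >= 1)
  if (!all(properties %in% chebcol$properties)) {
    stop("unknown properties: ",
         paste(setdiff(properties, chebcol$properties), collapse = ", "))
  }
  mats <- chebcol$matrices
  if (length(mats) < 3) stop("need at least 3 biofilms for a PCA embedding")
  X <- t(vapply(mats, function(M) {
    as.vector(M[, properties, drop = FALSE])
  }, numeric((chebcol$degree + 1) * length(properties))))
  colprop <- rep(properties, each = chebcol$degree + 1)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  keep <- which(is.finite(sdv) & sdv > 0)
  if (length(keep) < ncol(X)) {
    warning(ncol(X) - length(keep),
            " zero-variance dimension(s) dropped before PCA")
  }
  if (length(keep) == 0) stop("all dimensions have zero variance")
  Z <- sweep(X[, keep, drop = FALSE], 2, mu[keep])
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- pc$x
  loadings <- pc$rotation
  # BAI sign convention: local-density loading block sums non-negative
  dens_block <- which(colprop[keep] == "local_density")
  if (length(dens_block) > 0 && sum(loadings[dens_block, 1]) < 0) {
    scores[, 1] <- -scores[, 1]
    loadings[, 1] <- -loadings[, 1]
  }
  rownames(scores) <- names(mats)
  structure(list(scores = scores,
                 bai = stats::setNames(scores[, 1], names(mats)),
                 loadings = loadings,
                 explained = explained,
                 columns = colprop[keep],
                 properties = properties,
                 groups = chebcol$groups,
                 preprocess = list(mean = mu, scale = sdv, kept = keep)),
            class = "phase_embedding")
}

#' @export
print.phase_embedding <- function(x, ...) {
  cat(sprintf("<phase_embedding> %d biofilms, %d dims; PC1 explains %.1f%%\n",
              nrow(x$scores), length(x$columns), 100 * x$explained[1]))
  invisible(x)
}

#' Property contributions to the biofilm architecture index
#'
#' Contribution of property j = sum of squared PC1 loadings over its
#' coefficient block, normalised to sum to 1. Properties whose dimensions
#' were all dropped as zero-variance contribute 0.
#'
#' @param embedding a `phase_embedding`.
#' @return named numeric vector sorted in descending order.
#' @export
property_contributions <- function(embedding) {
  stopifnot(inherits(embedding, "phase_embedding"))
  l1 <- embedding$loadings[, 1]
  contrib <- vapply(embedding$properties, function(p) {
    sum(l1[embedding$columns == p]^2)
  }, numeric(1))
  sort(contrib / sum(contrib), decreasing = TRUE)
}

#' Phase diagram of a biofilm collection
#'
#' One point per biofilm in the mean aspect ratio vs mean local number
#' density plane — the two control parameters of early microcolony
#' architecture — coloured by a chosen architectural metric.
#'
#' @param collection a `biofilm_collection`.
#' @param color one of `"bai"`, `"nematic_order_variance"`,
#'   `"surface_area_per_volume"`.
#' @param embedding a `phase_embedding` for the same collection; required
#'   when `color = "bai"`.
#' @param radius neighbourhood radius (micrometres).
#' @return data.frame: `sample`, `group`, `mean_aspect_ratio`,
#'   `mean_local_density`, `color_metric`, `color_value`.
#' @export
phase_diagram <- function(collection, color = c("bai",
                                                "nematic_order_variance",
                                                "surface_area_per_volume"),
                          embedding = NULL, radius = 2.0) {
  stopifnot(inherits(collection, "biofilm_collection"))
  color <- match.arg(color)
  samples <- collection$samples
  mar <- vapply(samples, function(s) mean(aspect_ratio(s)), numeric(1))
  mld <- vapply(samples, function(s) mean(local_density(s, radius)),
                numeric(1))
  cv <- switch(color,
    bai = {
      if (is.null(embedding)) {
        stop("color = 'bai' requires an embedding (see pca_embed)")
      }
      if (!all(names(samples) %in% names(embedding$bai))) {
        stop("embedding does not cover all samples in the collection")
      }
      embedding$bai[names(samples)]
    },
    nematic_order_variance = vapply(samples, nematic_order_variance,
                                    numeric(1), radius = radius),
    surface_area_per_volume = vapply(samples, surface_area_per_volume,
                                     numeric(1)))
  data.frame(sample = names(samples),
             group = collection_groups(collection),
             mean_aspect_ratio = mar,
             mean_local_density = mld,
             color_metric = color,
             color_value = as.numeric(cv),
             row.names = NULL)
}
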