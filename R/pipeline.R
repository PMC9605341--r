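# End-to-end analysis pipeline: features -> supports -> Chebyshev matrices
# -> property redundancy reduction -> biofilm dissimilarities -> PCA/BAI ->
# phase diagram.

#' Analyse a biofilm collection end to end
#'
#' Runs the full distributional analysis workflow on a collection: per-cell
#' property tables, pooled supports, Chebyshev coefficient matrices,
#' cross-property dissimilarity and silhouette-based redundancy reduction,
#' the pairwise biofilm dissimilarity matrix over the retained properties,
#' the PCA embedding (biofilm architecture index), its property
#' contributions, and the aspect-ratio vs density phase diagram.
#'
#' @param collection a `biofilm_collection`.
#' @param properties properties to compute (default standard set).
#' @param degree Chebyshev degree.
#' @param radius neighbourhood radius, micrometres.
#' @param q_lo,q_hi support quantiles.
#' @param reduce apply redundancy reduction before the embedding (needs at
#'   least 3 usable properties).
#' @return list with elements `collection` (with tables), `cheb`,
#'   `property_cd`, `reduction`, `selected`, `cd`, `embedding`,
#'   `contributions`, `phase`.
#' @export
analyze_collection <- function(collection, properties = DEFAULT_PROPERTIES,
                               degree = 20, radius = 2.0,
                               q_lo = 0.005, q_hi = 0.995, reduce = TRUE) {
  stopifnot(inherits(collection, "biofilm_collection"))
  collection <- compute_features(collection, properties = properties,
                                 radius = radius)
  cheb <- collection_chebyshev(collection, degree = degree,
                               q_lo = q_lo, q_hi = q_hi,
                               drop_degenerate = TRUE)
  prop_cd <- property_dissimilarity(cheb)
  reduction <- NULL
  selected <- cheb$properties
  if (reduce && length(cheb$properties) >= 3) {
    reduction <- reduce_properties(prop_cd)
    selected <- reduction$selected
  }
  cdm <- cd_matrix(cheb, properties = selected)
  embedding <- pca_embed(cheb, properties = selected)
  contributions <- property_contributions(embedding)
  phase <- phase_diagram(collection, color = "bai", embedding = embedding,
                         radius = radius)
  list(collection = collection, cheb = cheb, property_cd = prop_cd,
       reduction = reduction, selected = selected, cd = cdm,
       embedding = embedding, contributions = contributions, phase = phase)
}

#' Mean silhouette of an embedding against known labels
#'
#' Scores how well a 2D embedding separates labelled groups: the mean
#' silhouette width of the (PC1, PC2) scores under the given labels.
#'
#' @param embedding a `phase_embedding`.
#' @param labels group labels (default: the collection's group labels).
#' @param dims which score dimensions to use.
#' @return mean silhouette width in \[-1, 1\].
#' @export
label_silhouette <- function(embedding, labels = embedding$groups,
                             dims = 1:2) {
  stopifnot(inherits(embedding, "phase_embedding"))
  dims <- dims[dims <= ncol(embedding$scores)]
  x <- embedding$scores[, dims, drop = FALSE]
  cl <- as.integer(factor(labels))
  if (length(unique(cl)) < 2) stop("need at least two groups")
  mean(cluster::silhouette(cl, stats::dist(x))[, "sil_width"])
}

#' Benchmark the pipeline on a locally deposited dataset
#'
#' Runs the full analysis on a directory of experimentally segmented cell
#' tables (a local copy of the study's deposited source data, converted to
#' the package's cell-table format) and reports the number of retained
#' properties, the PC1 explained-variance fraction, and the label silhouette
#' of the species clusters. The deposited data are not shipped with the
#' package; this helper exists so the published benchmarks can be reproduced
#' when a local copy is available.
#'
#' @param dir directory of cell tables (see [read_collection()]).
#' @param ... passed to [analyze_collection()].
#' @return list with `p_selected`, `pc1_explained`, `silhouette`,
#'   `analysis`.
#' @export
deposited_benchmark <- function(dir, ...) {
  if (!dir.exists(dir)) {
    stop("deposited dataset directory not found: ", dir,
         " (download the study source data and convert to cell tables)")
  }
  collection <- read_collection(dir)
  an <- analyze_collection(collection, ...)
  list(p_selected = length(an$selected),
       pc1_explained = an$embedding$explained[1],
       silhouette = label_silhouette(an$embedding),
       analysis = an)
}
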