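# Parameter scans of the growth simulator and best-fit selection by minimal
# Chebyshev dissimilarity between simulated and target biofilms.

#' Define a simulation scan grid
#'
#' Cartesian product over the four scanned mechanical parameters (division
#' length, repulsion range, attraction range, attraction strength), repeated
#' over one or more seeds per grid point, with all remaining parameters held
#' fixed.
#'
#' @param L_div,r_rep,r_att,f_att numeric vectors of scanned values (all
#'   non-empty).
#' @param seeds integer vector of seeds per grid point.
#' @param base a `sim_params` providing the non-scanned parameters.
#' @return object of class `scan_grid`: data.frame `points` (one row per
#'   run) plus the base parameters.
#' @export
scan_grid <- function(L_div, r_rep, r_att, f_att, seeds = 1L,
                      base = sim_params()) {
  stopifnot(length(L_div) >= 1, length(r_rep) >= 1, length(r_att) >= 1,
            length(f_att) >= 1, length(seeds) >= 1)
  pts <- expand.grid(L_div = L_div, r_rep = r_rep, r_att = r_att,
                     f_att = f_att, seed = as.integer(seeds),
                     KEEP.OUT.ATTRS = FALSE)
  pts$run_id <- sprintf("Ld%g_rr%g_ra%g_fa%g_s%d", pts$L_div, pts$r_rep,
                        pts$r_att, pts$f_att, pts$seed)
  structure(list(points = pts, base = base), class = "scan_grid")
}

#' Run a simulation scan
#'
#' Runs one simulation per (grid point, seed) and stores the resulting cell
#' tables plus a manifest CSV in `out_dir`. The scan is resumable: runs whose
#' output already exists (per the manifest) are skipped, and simulator
#' failures are recorded in the manifest without aborting the scan.
#'
#' @param grid a `scan_grid`.
#' @param out_dir output directory (created if missing).
#' @param quiet suppress progress messages.
#' @return the manifest data.frame (columns: run parameters, seed, `file`,
#'   `status`, `n_cells`).
#' @export
run_scan <- function(grid, out_dir, quiet = TRUE) {
  stopifnot(inherits(grid, "scan_grid"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest_path <- file.path(out_dir, "manifest.csv")
  done <- if (file.exists(manifest_path)) {
    utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  } else {
    NULL
  }
  rows <- list()
  for (i in seq_len(nrow(grid$points))) {
    pt <- grid$points[i, ]
    fn <- paste0(pt$run_id, ".csv")
    if (!is.null(done) && pt$run_id %in% done$run_id[done$status == "ok"] &&
        file.exists(file.path(out_dir, fn))) {
      rows[[i]] <- done[done$run_id == pt$run_id, , drop = FALSE][1, ]
      next
    }
    if (!quiet) message("scan: ", pt$run_id)
    res <- tryCatch({
      args <- unclass(grid$base)
      args$L_div <- pt$L_div
      args$r_rep <- pt$r_rep
      args$r_att <- pt$r_att
      args$f_att <- pt$f_att
      args$seed <- pt$seed
      params <- do.call(sim_params, args)  # re-validates the invariants
      s <- run_simulation(params,
                          group = sprintf("Ld%g_fa%g", pt$L_div, pt$f_att),
                          replicate = pt$seed)
      write_cell_table(s, file.path(out_dir, fn))
      data.frame(pt, file = fn, status = "ok", n_cells = nrow(s$cells),
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(pt, file = fn, status = paste0("error: ", conditionMessage(e)),
                 n_cells = NA_integer_, stringsAsFactors = FALSE)
    })
    rows[[i]] <- res
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  manifest
}

#' Load a scan library
#'
#' Reads the successful runs of a scan directory back into a
#' `biofilm_collection`; the scanned parameter values of every run are kept
#' in the sample metadata.
#'
#' @param out_dir scan directory written by [run_scan()].
#' @return a `biofilm_collection`.
#' @export
read_scan <- function(out_dir) {
  manifest_path <- file.path(out_dir, "manifest.csv")
  if (!file.exists(manifest_path)) stop("no manifest.csv in ", out_dir)
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  ok <- manifest[manifest$status == "ok", , drop = FALSE]
  if (nrow(ok) == 0) stop("scan contains no successful runs")
  samples <- lapply(seq_len(nrow(ok)), function(i) {
    read_cell_table(file.path(out_dir, ok$file[i]))
  })
  names(samples) <- ok$run_id
  biofilm_collection(samples)
}

scanned_params_of <- function(sample) {
  p <- sample$metadata$params
  data.frame(L_div = p$L_div %||% NA_real_, r_rep = p$r_rep %||% NA_real_,
             r_att = p$r_att %||% NA_real_, f_att = p$f_att %||% NA_real_,
             seed = p$seed %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Best-fit simulations for target biofilms
#'
#' Ranks every library simulation against each target group by Chebyshev
#' dissimilarity and retains the top `k`. Supports are pooled jointly over
#' targets and library (coefficients are only comparable on a common
#' domain, so library dissimilarities change if the targets change), and the
#' dissimilarity to a group is the arithmetic mean of the dissimilarities to
#' its replicates; set `per_replicate = TRUE` to fit each target replicate
#' separately.
#'
#' @param targets a `biofilm_collection` of target biofilms (grouped by
#'   their metadata group label).
#' @param library a `biofilm_collection` of simulated biofilms (e.g. from
#'   [read_scan()]).
#' @param properties properties used for the comparison (default: the
#'   standard property set minus constant ones).
#' @param k number of best fits to retain per group.
#' @param degree Chebyshev degree.
#' @param radius neighbourhood radius, micrometres.
#' @param per_replicate fit each target replicate separately.
#' @return object of class `fit_result`: data.frame with columns `group`,
#'   `rank`, the scanned parameters, `seed`, `run_id`, `cd`.
#' @export
best_fit <- function(targets, library, properties = NULL, k = 5,
                     degree = 20, radius = 2.0, per_replicate = FALSE) {
  stopifnot(inherits(targets, "biofilm_collection"),
            inherits(library, "biofilm_collection"))
  nlib <- length(library$samples)
  if (k > nlib) stop("k = ", k, " exceeds library size ", nlib)
  all_samples <- c(targets$samples, library$samples)
  names(all_samples) <- make.unique(names(all_samples), sep = "#")
  joint <- biofilm_collection(all_samples)
  props <- properties %||% DEFAULT_PROPERTIES
  joint <- compute_features(joint, properties = props, radius = radius)
  cheb <- collection_chebyshev(joint, degree = degree, drop_degenerate = TRUE)
  nt <- length(targets$samples)
  tmats <- cheb$matrices[seq_len(nt)]
  lmats <- cheb$matrices[seq(nt + 1, nt + nlib)]
  tgroups <- if (per_replicate) {
    names(targets$samples)
  } else {
    collection_groups(targets)
  }
  libinfo <- do.call(rbind, lapply(library$samples, scanned_params_of))
  libinfo$run_id <- names(library$samples)
  res <- list()
  for (g in unique(tgroups)) {
    idx <- which(tgroups == g)
    cds <- vapply(seq_len(nlib), function(j) {
      mean(vapply(idx, function(i) {
        cd_biofilm(tmats[[i]], lmats[[j]])
      }, numeric(1)))
    }, numeric(1))
    ord <- order(cds)[seq_len(k)]
    res[[g]] <- data.frame(group = g, rank = seq_len(k),
                           libinfo[ord, , drop = FALSE],
                           cd = cds[ord], row.names = NULL)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, class = c("fit_result", "data.frame"),
            properties = cheb$properties)
}
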