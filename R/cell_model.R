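#' @useDynLib biofilmarch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dnorm quantile sd prcomp var dist cor
#' @importFrom utils read.csv write.csv head modifyList
NULL

REQUIRED_COLS <- c("id", "x", "y", "z", "nx", "ny", "nz", "length", "width")

#' Construct a biofilm sample
#'
#' A biofilm sample is the basic container of the package: one segmented (or
#' simulated, or synthetic) microcolony, holding one row per cell plus
#' sample-level metadata. Positions are cell centroids in micrometres with the
#' substrate at the plane z = 0; orientations are unit vectors and are only
#' defined up to sign (a rod has no head or tail).
#'
#' @param cells data.frame with columns `id`, `x`, `y`, `z`, `nx`, `ny`, `nz`,
#'   `length`, `width` and optionally further per-cell scalar columns
#'   ("extras", e.g. convexity) carried through from segmentation.
#' @param group group label (species or strain).
#' @param condition growth condition label (e.g. an inducer level).
#' @param replicate replicate identifier.
#' @param provenance one of `"experiment"`, `"simulation"`, `"synthetic"`.
#' @param params optional list of generating parameters (recorded verbatim).
#' @param validate if `TRUE` (default), reject samples violating invariants.
#' @return An object of class `biofilm_sample`.
#' @export
biofilm_sample <- function(cells, group = "unknown", condition = "none",
                           replicate = 1L, provenance = "experiment",
                           params = NULL, validate = TRUE) {
  stopifnot(is.data.frame(cells))
  missing_cols <- setdiff(REQUIRED_COLS, names(cells))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  cells <- cells[, c(REQUIRED_COLS, setdiff(names(cells), REQUIRED_COLS)),
                 drop = FALSE]
  num_cols <- setdiff(names(cells), "id")
  for (cn in num_cols) cells[[cn]] <- as.numeric(cells[[cn]])
  cells$id <- as.integer(cells$id)
  nrm <- sqrt(cells$nx^2 + cells$ny^2 + cells$nz^2)
  if (any(!is.finite(nrm)) || any(nrm < 1e-12)) {
    stop("zero-length or non-finite orientation vector(s) at row(s): ",
         paste(which(!is.finite(nrm) | nrm < 1e-12), collapse = ", "))
  }
  cells$nx <- cells$nx / nrm
  cells$ny <- cells$ny / nrm
  cells$nz <- cells$nz / nrm
  rownames(cells) <- NULL
  s <- structure(
    list(cells = cells,
         metadata = list(group = as.character(group),
                         condition = as.character(condition),
                         replicate = replicate,
                         provenance = as.character(provenance),
                         params = params)),
    class = "biofilm_sample")
  if (validate) {
    rep_ <- validate_sample(s)
    if (nrow(rep_) > 0) {
      stop("invalid biofilm sample:\n",
           paste(sprintf("  cell %s: %s", rep_$id, rep_$violation),
                 collapse = "\n"))
    }
  }
  s
}

#' @export
print.biofilm_sample <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("<biofilm_sample> %d cells | group=%s condition=%s replicate=%s | %s\n",
              nrow(x$cells), md$group, md$condition,
              as.character(md$replicate), md$provenance))
  invisible(x)
}

#' Validate a biofilm sample
#'
#' Checks every container invariant and reports all violations instead of
#' stopping at the first: unit orientations (within 1e-9), `length >= width > 0`,
#' centroid `z >= 0` (cells cannot sit below the substrate), finite values,
#' unique cell ids, and at least one cell.
#'
#' @param sample a `biofilm_sample` (validation is tolerant: any list with a
#'   `cells` data.frame is accepted).
#' @return data.frame with columns `id` and `violation`; zero rows iff valid.
#' @export
validate_sample <- function(sample) {
  cells <- sample$cells
  out <- list()
  add <- function(id, msg) out[[length(out) + 1]] <<- data.frame(
    id = id, violation = msg, stringsAsFactors = FALSE)
  if (is.null(cells) || nrow(cells) == 0) {
    add(NA_integer_, "sample has no cells")
  } else {
    num <- cells[, setdiff(names(cells), "id"), drop = FALSE]
    bad_fin <- which(!apply(num, 1, function(r) all(is.finite(r))))
    for (i in bad_fin) add(cells$id[i], "non-finite value")
    nrm <- sqrt(cells$nx^2 + cells$ny^2 + cells$nz^2)
    for (i in which(is.finite(nrm) & abs(nrm - 1) > 1e-9)) {
      add(cells$id[i], "orientation not unit length")
    }
    for (i in which(is.finite(cells$width) &
                    (cells$width <= 0 | cells$length < cells$width))) {
      add(cells$id[i], "length/width invariant violated (need length >= width > 0)")
    }
    for (i in which(is.finite(cells$z) & cells$z < 0)) {
      add(cells$id[i], "below substrate (z < 0)")
    }
    dup <- cells$id[duplicated(cells$id)]
    for (d in unique(dup)) add(d, "duplicate id")
  }
  if (length(out) == 0) {
    data.frame(id = integer(0), violation = character(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out)
  }
}

fmt_num <- function(x) {
  # deterministic 12-significant-digit formatting for byte-stable output
  out <- formatC(x, digits = 12, format = "g", mode = "double")
  gsub(" ", "", out)
}

#' Write a cell table to disk
#'
#' Writes the sample as a comma-separated cell table (UTF-8, '.' decimal,
#' header row, floats at 12 significant digits so that a write/read round trip
#' reproduces every field to well below 1e-9) plus a JSON metadata sidecar
#' `<name>.meta.json` holding group, condition, replicate, provenance and any
#' generating parameters.
#'
#' @param sample a `biofilm_sample`.
#' @param path output CSV path; the sidecar path is derived from it.
#' @return `path`, invisibly.
#' @export
write_cell_table <- function(sample, path) {
  stopifnot(inherits(sample, "biofilm_sample"))
  dir <- dirname(path)
  if (!dir.exists(dir)) {
    stop("cannot write cell table: directory does not exist: ", dir)
  }
  cells <- sample$cells
  cols <- names(cells)
  mat <- vapply(cols, function(cn) {
    if (cn == "id") as.character(cells[[cn]]) else fmt_num(cells[[cn]])
  }, character(nrow(cells)))
  if (nrow(cells) == 1L) mat <- matrix(mat, nrow = 1, dimnames = list(NULL, cols))
  lines <- c(paste(cols, collapse = ","),
             apply(mat, 1, paste, collapse = ","))
  writeLines(lines, path, useBytes = TRUE)
  md <- sample$metadata
  jsonlite::write_json(
    list(group = md$group, condition = md$condition,
         replicate = md$replicate, provenance = md$provenance,
         params = md$params),
    meta_path(path), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

meta_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".meta.json")
}

#' Read a cell table from disk
#'
#' Reads a cell-table CSV written by [write_cell_table()] (or produced by any
#' segmentation export with the same columns) together with its JSON metadata
#' sidecar. Orientations are renormalised to unit length; the sample is
#' validated on construction.
#'
#' @param path CSV path.
#' @return a `biofilm_sample`.
#' @export
read_cell_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cells <- utils::read.csv(path, check.names = FALSE)
  missing_cols <- setdiff(REQUIRED_COLS, names(cells))
  if (length(missing_cols) > 0) {
    stop("cell table ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  num <- cells[, setdiff(names(cells), "id"), drop = FALSE]
  bad <- which(!apply(num, 1, function(r) all(is.finite(as.numeric(r)))))
  if (length(bad) > 0) {
    stop("non-finite value(s) in ", path, " at data row(s): ",
         paste(bad, collapse = ", "))
  }
  md <- list(group = "unknown", condition = "none", replicate = 1L,
             provenance = "experiment", params = NULL)
  mp <- meta_path(path)
  if (file.exists(mp)) {
    md <- modifyList(md, jsonlite::read_json(mp, simplifyVector = TRUE))
  }
  biofilm_sample(cells, group = md$group, condition = md$condition,
                 replicate = md$replicate, provenance = md$provenance,
                 params = md$params)
}

#' Construct a biofilm collection
#'
#' A named list of biofilm samples analysed jointly (shared property supports,
#' pairwise dissimilarities, one embedding). Names default to
#' `group.condition.replicate` and must be unique.
#'
#' @param samples list of `biofilm_sample` objects.
#' @return object of class `biofilm_collection`.
#' @export
biofilm_collection <- function(samples) {
  stopifnot(length(samples) >= 1)
  ok <- vapply(samples, inherits, logical(1), what = "biofilm_sample")
  if (!all(ok)) stop("all elements must be biofilm_sample objects")
  if (is.null(names(samples)) || any(names(samples) == "")) {
    names(samples) <- vapply(samples, function(s) {
      paste(s$metadata$group, s$metadata$condition, s$metadata$replicate,
            sep = ".")
    }, character(1))
  }
  if (anyDuplicated(names(samples))) {
    names(samples) <- make.unique(names(samples), sep = "_")
  }
  structure(list(samples = samples, tables = NULL),
            class = "biofilm_collection")
}

#' @export
print.biofilm_collection <- function(x, ...) {
  groups <- vapply(x$samples, function(s) s$metadata$group, character(1))
  cat(sprintf("<biofilm_collection> %d samples, %d group(s): %s\n",
              length(x$samples), length(unique(groups)),
              paste(unique(groups), collapse = ", ")))
  invisible(x)
}

#' @rdname biofilm_collection
#' @param collection a `biofilm_collection`.
#' @export
collection_groups <- function(collection) {
  vapply(collection$samples, function(s) s$metadata$group, character(1))
}

#' Write / read a collection directory
#'
#' A collection on disk is a directory of cell-table CSV + sidecar pairs and
#' a `manifest.json` listing the sample files in order.
#'
#' @param collection a `biofilm_collection`.
#' @param dir directory (created if missing).
#' @return `write_collection()` returns `dir`; `read_collection()` the
#'   collection.
#' @export
write_collection <- function(collection, dir) {
  stopifnot(inherits(collection, "biofilm_collection"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (nm in names(collection$samples)) {
    fn <- paste0(gsub("[^A-Za-z0-9_.-]", "_", nm), ".csv")
    write_cell_table(collection$samples[[nm]], file.path(dir, fn))
    files <- c(files, fn)
  }
  jsonlite::write_json(list(samples = files), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_collection
#' @export
read_collection <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (file.exists(mf)) {
    files <- jsonlite::read_json(mf, simplifyVector = TRUE)$samples
  } else {
    files <- sort(list.files(dir, pattern = "\\.csv$"))
  }
  if (length(files) == 0) stop("no cell tables found in ", dir)
  samples <- lapply(file.path(dir, files), read_cell_table)
  names(samples) <- tools::file_path_sans_ext(files)
  biofilm_collection(samples)
}
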