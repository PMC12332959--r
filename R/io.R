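#' Persist intermediate analysis objects as plain-text files
#'
#' Writers/readers for the pipeline's intermediate containers.  Every
#' format is a flat CSV of numbers next to a JSON header that records the
#' dimension order and axis labels, so results can be inspected or
#' consumed outside R.
#'
#' * `write_rate_tensor()`: `values.csv` holds the dense array flattened
#'   with cell as the fastest dimension (one row per (trial, bin), columns
#'   = cells); `header.json` lists cell ids, trial metadata, bin centers,
#'   window/step and stage.
#' * `write_responsiveness_report()`: per-(cell, image) table and the
#'   per-cell summary as two CSVs.
#' * `write_population_dataset()`: `vectors.csv` (rows = (image,
#'   pseudo-trial) x bins stacked, columns = roster cells) plus
#'   `manifest.json` with the roster order, row metadata and bin centers.
#' * `write_split_plan()`: the fold-assignment matrix and plan parameters
#'   as JSON.
#'
#' @param x The object to write.
#' @param dir,path Output directory (tensor/dataset) or file path
#'   (report prefix, plan JSON).
#' @return The input, invisibly; readers return the reconstructed object.
#' @name viewdecode-io
NULL

#' @rdname viewdecode-io
#' @export
write_rate_tensor <- function(x, dir) {
  stopifnot(inherits(x, "rate_tensor"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(x$values)
  # one row per (trial, bin) with trial fastest; columns = cells
  flat <- matrix(as.vector(x$values), nrow = d[2] * d[3], ncol = d[1],
                 byrow = TRUE)
  colnames(flat) <- x$cells$cell_id
  write.csv(flat, file.path(dir, "values.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(dimension_order = c("cell", "trial", "bin"),
         n_cells = d[1], n_trials = d[2], n_bins = d[3],
         cells = x$cells, trials = x$trials,
         bin_centers_ms = x$bin_centers,
         window_ms = x$window_ms, step_ms = x$step_ms, stage = x$stage,
         baseline_window_ms = x$baseline_window_ms),
    file.path(dir, "header.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA)
  write.csv(as.data.frame(x$baseline_rate),
            file.path(dir, "baseline_rate.csv"), row.names = FALSE)
  invisible(x)
}

#' @rdname viewdecode-io
#' @export
read_rate_tensor <- function(dir) {
  hdr <- jsonlite::read_json(file.path(dir, "header.json"),
                             simplifyVector = TRUE)
  flat <- as.matrix(read.csv(file.path(dir, "values.csv"),
                             check.names = FALSE))
  values <- array(t(flat), dim = c(hdr$n_cells, hdr$n_trials, hdr$n_bins),
                  dimnames = list(hdr$cells$cell_id, NULL,
                                  hdr$bin_centers_ms))
  baseline <- as.matrix(read.csv(file.path(dir, "baseline_rate.csv")))
  dimnames(baseline) <- NULL
  structure(list(values = values, cells = as_tibble(hdr$cells),
                 trials = as_tibble(hdr$trials),
                 bin_centers = hdr$bin_centers_ms,
                 window_ms = hdr$window_ms, step_ms = hdr$step_ms,
                 stage = hdr$stage, baseline_rate = baseline,
                 baseline_window_ms = hdr$baseline_window_ms),
            class = "rate_tensor")
}

#' @rdname viewdecode-io
#' @export
write_responsiveness_report <- function(x, path) {
  stopifnot(inherits(x, "responsiveness_report"))
  write.csv(as.data.frame(x$table), paste0(path, "_images.csv"),
            row.names = FALSE)
  write.csv(as.data.frame(x$cells), paste0(path, "_cells.csv"),
            row.names = FALSE)
  invisible(x)
}

#' @rdname viewdecode-io
#' @export
write_population_dataset <- function(x, dir) {
  stopifnot(inherits(x, "population_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- dim(x$vectors)
  # rows stacked with (image, pseudo-trial) fastest, then bin; cols = cells
  flat <- matrix(aperm(x$vectors, c(1L, 3L, 2L)), nrow = d[1] * d[3],
                 ncol = d[2])
  colnames(flat) <- x$roster
  write.csv(flat, file.path(dir, "vectors.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(roster = x$roster, rows = x$rows, bin_centers_ms = x$bin_centers,
         n_rows = d[1], n_cells = d[2], n_bins = d[3],
         condition = x$condition, n_pseudo_trials = x$n_pseudo_trials,
         seed = x$seed),
    file.path(dir, "manifest.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(x)
}

#' @rdname viewdecode-io
#' @export
read_population_dataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  flat <- as.matrix(read.csv(file.path(dir, "vectors.csv"),
                             check.names = FALSE))
  vectors <- aperm(array(flat, dim = c(man$n_rows, man$n_bins, man$n_cells)),
                   c(1L, 3L, 2L))
  dimnames(vectors) <- list(NULL, man$roster, man$bin_centers_ms)
  structure(list(vectors = vectors, rows = as_tibble(man$rows),
                 roster = man$roster, cells = NULL,
                 condition = man$condition,
                 bin_centers = man$bin_centers_ms,
                 n_pseudo_trials = as.integer(man$n_pseudo_trials),
                 seed = man$seed),
            class = "population_dataset")
}

#' @rdname viewdecode-io
#' @export
write_split_plan <- function(x, path) {
  stopifnot(inherits(x, "split_plan"))
  jsonlite::write_json(
    list(folds = x$folds, repeats = x$repeats,
         n_pseudo_trials = x$n_pseudo_trials, seed = x$seed,
         assignment = x$assignment),
    path, auto_unbox = TRUE, digits = NA)
  invisible(x)
}

#' @rdname viewdecode-io
#' @export
read_split_plan <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(folds = as.integer(p$folds),
                 repeats = as.integer(p$repeats),
                 n_pseudo_trials = as.integer(p$n_pseudo_trials),
                 assignment = matrix(as.integer(p$assignment),
                                     p$n_pseudo_trials, p$repeats),
                 seed = p$seed),
            class = "split_plan")
}
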