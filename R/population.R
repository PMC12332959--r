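#' Assemble pseudo-population response vectors
#'
#' Builds population vectors by aligning the normalized responses of
#' individual cells to each stimulus image.  Cells were (conceptually)
#' recorded in separate sessions, so no simultaneity is assumed: pseudo-trial
#' `j` of an image takes, for each cell independently, that cell's response
#' on its own trial `j` after a per-cell, per-image random permutation of
#' trial indices.  The roster fixes the component order of every vector.
#'
#' @param rates A normalized `rate_tensor` (see [normalize_cells()]).
#' @param area,experience Optional condition filters on the cell metadata;
#'   `experience` also selects the images entering the dataset.
#' @param report Optional [screen_responsive()] report; when supplied only
#'   responsive cells are used.
#' @param roster Optional character vector of cell ids fixing the roster and
#'   its order explicitly (applied after the filters).
#' @param n_pseudo_trials Pseudo-trials per image (must not exceed the number
#'   of recorded trials per image), default 20.
#' @param seed Seed for the per-cell trial permutations.
#' @return An object of class `population_dataset`: list with `vectors`
#'   (3-d array (image x pseudo-trial) x cell x bin), `rows` (tibble
#'   describing the first dimension), `roster`, `cells`, `condition`,
#'   `bin_centers`, `n_pseudo_trials` and `seed`.
#' @export
assemble <- function(rates, area = NULL, experience = NULL, report = NULL,
                     roster = NULL, n_pseudo_trials = 20L, seed = 1L) {
  stopifnot(inherits(rates, "rate_tensor"))
  if (rates$stage != "normalized") {
    stop_user("assemble() expects a normalized rate tensor")
  }
  cells <- rates$cells
  keep <- rep(TRUE, nrow(cells))
  if (!is.null(area)) keep <- keep & cells$area %in% area
  if (!is.null(experience)) keep <- keep & cells$experience %in% experience
  if (!is.null(report)) {
    resp <- report$cells$cell_id[report$cells$responsive]
    keep <- keep & cells$cell_id %in% resp
  }
  ids <- cells$cell_id[keep]
  if (!is.null(roster)) {
    missing <- setdiff(roster, ids)
    if (length(missing)) {
      stop_user("roster cells not available: ", paste(missing, collapse = ", "))
    }
    ids <- roster
  }
  if (length(ids) == 0L) stop_user("empty roster after filtering")
  cell_idx <- match(ids, cells$cell_id)

  trials <- rates$trials
  img_keep <- if (is.null(experience)) unique(trials$image_index) else
    unique(trials$image_index[trials$experience %in% experience])
  img_keep <- sort(img_keep)
  n_img <- length(img_keep)
  n_tr <- max(trials$trial_id)
  if (n_pseudo_trials > n_tr) {
    stop_user("n_pseudo_trials (", n_pseudo_trials,
              ") exceeds recorded trials per image (", n_tr, ")")
  }
  n_bins <- length(rates$bin_centers)
  np <- as.integer(n_pseudo_trials)

  rows <- tibble(
    image_index = rep(img_keep, each = np),
    pseudo_trial = rep(seq_len(np), n_img)
  )
  first <- match(rows$image_index, trials$image_index)
  rows$set_id <- trials$set_id[first]
  rows$object_id <- trials$object_id[first]
  rows$view_angle_deg <- trials$view_angle_deg[first]
  rows$image_id <- trials$image_id[first]

  vectors <- array(NA_real_, dim = c(n_img * np, length(ids), n_bins),
                   dimnames = list(NULL, ids, rates$bin_centers))
  trial_rows_of_img <- lapply(img_keep, function(ii) {
    trials$trial_index[trials$image_index == ii]
  })
  # trial permutations are drawn per (cell, image) of the full tensor in a
  # fixed order, so the draw a cell receives does not depend on the roster
  # selection or its ordering (alignment is then roster-order invariant)
  n_all_img <- max(trials$image_index)
  perms <- with_seed(seed, {
    lapply(seq_len(nrow(cells) * n_all_img), function(i) sample.int(n_tr))
  })
  for (k in seq_along(cell_idx)) {
    ci <- cell_idx[k]
    for (gi in seq_len(n_img)) {
      perm <- perms[[(ci - 1L) * n_all_img + img_keep[gi]]][seq_len(np)]
      src <- trial_rows_of_img[[gi]][perm]
      dst <- (gi - 1L) * np + seq_len(np)
      vectors[dst, k, ] <- rates$values[ci, src, ]
    }
  }
  if (anyNA(vectors)) {
    stop_user("selected cells lack trials for some selected images")
  }
  structure(list(vectors = vectors, rows = rows, roster = ids,
                 cells = cells[cell_idx, ],
                 condition = list(area = area, experience = experience),
                 bin_centers = rates$bin_centers,
                 n_pseudo_trials = np, seed = seed),
            class = "population_dataset")
}

#' Assemble one pseudo-population per analysis repeat
#'
#' The trial alignment behind a pseudo-population is arbitrary (cells were
#' recorded separately), so repeating the analysis with reassigned data
#' draws a fresh alignment for every repeat.  Returns a list of
#' [assemble()] datasets — one per repeat, sharing roster and row layout —
#' which [decode_timecourses()] accepts in place of a single dataset,
#' using alignment r for split repeat r.
#'
#' @inheritParams assemble
#' @param repeats Number of alignments (match the split plan's repeats).
#' @param seed Base seed; repeat r uses a seed derived from it.
#' @return List of `population_dataset`s of length `repeats`.
#' @export
assemble_repeats <- function(rates, area = NULL, experience = NULL,
                             report = NULL, roster = NULL,
                             n_pseudo_trials = 20L, repeats = 5L,
                             seed = 1L) {
  lapply(seq_len(repeats), function(r) {
    assemble(rates, area = area, experience = experience, report = report,
             roster = roster, n_pseudo_trials = n_pseudo_trials,
             seed = derive_seed(seed, 7000L + r))
  })
}

#' Restrict a population dataset to a subset of cells
#'
#' @param dataset A `population_dataset`.
#' @param cells Integer indices or cell ids (kept in the given order).
#' @return A `population_dataset` with the reduced roster.
#' @export
subset_cells <- function(dataset, cells) {
  stopifnot(inherits(dataset, "population_dataset"))
  idx <- if (is.character(cells)) match(cells, dataset$roster) else
    as.integer(cells)
  if (anyNA(idx) || any(idx < 1 | idx > length(dataset$roster))) {
    stop_user("unknown cells in subset")
  }
  dataset$vectors <- dataset$vectors[, idx, , drop = FALSE]
  dataset$roster <- dataset$roster[idx]
  dataset$cells <- dataset$cells[idx, ]
  dataset
}

#' Plan train/test reassignments
#'
#' Partitions the pseudo-trial indices into `folds` test folds, independently
#' re-drawn `repeats` times.  The same fold assignment of pseudo-trial
#' indices is applied to every image, so each image's pseudo-trials are
#' spread across folds as evenly as possible (stratification by image).
#' The 25 (repeat, fold) pairs of the default plan yield the 25 d' estimates
#' per time bin.
#'
#' @param n_pseudo_trials Number of pseudo-trials per image (>= `folds`).
#' @param folds,repeats Cross-validation structure, default 5 x 5.
#' @param seed RNG seed.
#' @return An object of class `split_plan`: list with `folds`, `repeats`,
#'   `n_pseudo_trials`, `assignment` (pseudo-trial x repeat matrix of fold
#'   labels) and `seed`.
#' @export
plan_splits <- function(n_pseudo_trials, folds = 5L, repeats = 5L, seed = 1L) {
  if (n_pseudo_trials < folds) {
    stop_user("n_pseudo_trials (", n_pseudo_trials,
              ") must be at least the number of folds (", folds, ")")
  }
  assignment <- with_seed(seed, {
    vapply(seq_len(repeats), function(r) {
      sample(rep_len(seq_len(folds), n_pseudo_trials))
    }, integer(n_pseudo_trials))
  })
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 n_pseudo_trials = as.integer(n_pseudo_trials),
                 assignment = assignment, seed = seed),
            class = "split_plan")
}

#' Ordered viewing-angle pairs at a given difference
#'
#' Enumerates all ordered (train, test) pairs of viewing angles from
#' \{0, 30, 60, 90\} with `|train - test| == delta_deg`.  Both rotation
#' directions are included, giving `8 - 2 * delta/30` pairs for
#' `delta_deg > 0`; `delta_deg = 0` returns the 4 identity pairs (the
#' same-angle baseline).
#'
#' @param delta_deg Viewing-angle difference: 0, 30, 60 or 90.
#' @return A tibble with columns `train_angle_deg` and `test_angle_deg` and
#'   attribute `delta_deg`.
#' @export
angle_pairs <- function(delta_deg) {
  if (length(delta_deg) != 1L || !delta_deg %in% VIEW_ANGLES) {
    stop_user("delta_deg must be one of ",
              paste(VIEW_ANGLES, collapse = ", "))
  }
  grid <- expand.grid(train_angle_deg = VIEW_ANGLES,
                      test_angle_deg = VIEW_ANGLES, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[abs(grid$train_angle_deg - grid$test_angle_deg) == delta_deg, ]
  out <- as_tibble(grid[order(grid$train_angle_deg, grid$test_angle_deg), ])
  attr(out, "delta_deg") <- as.integer(delta_deg)
  out
}
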