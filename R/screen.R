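#' Paired Wilcoxon signed-rank p-value
#'
#' Two-sided paired signed-rank test of `x` against `y`.  Zero differences
#' are dropped (returning p = 1 when none remain); the exact distribution is
#' used for up to 25 non-zero tie-free pairs, and the normal approximation
#' with tie and continuity correction otherwise.
#'
#' @param x,y Paired observations.
#' @return Two-sided p-value.
#' @export
signed_rank_p <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[d != 0]
  if (length(d) == 0L) return(1)
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  suppressWarnings(
    wilcox.test(d, exact = exact, correct = TRUE)$p.value
  )
}

#' Two-sample Mann-Whitney p-value
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test.  Tie-free samples use
#' the exact distribution; ties fall back to the normal approximation with
#' tie and continuity correction.  Identical multisets return p = 1.
#'
#' @param x,y Independent samples.
#' @return Two-sided p-value.
#' @export
rank_test_p <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop_user("empty sample")
  pooled <- c(x, y)
  if (max(pooled) == min(pooled)) return(1)
  exact <- !any(duplicated(pooled))
  p <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
  )
  if (!is.finite(p)) p <- 1
  min(p, 1)
}

#' Screen cells for stimulus responsiveness
#'
#' For each (cell, image) pair, compares per-trial evoked rates (spike count
#' in `evoked_window_ms` divided by its duration) against the per-trial
#' spontaneous rates in the 500 ms preceding stimulus onset with a paired
#' Wilcoxon signed-rank test, Bonferroni-corrected over the images tested for
#' that cell.  A cell is responsive if at least one image is significant at
#' `alpha` after correction.
#'
#' @param x A `spike_events` object.
#' @param evoked_window_ms Evoked-rate window, default `[0, 600)` ms.
#' @param alpha Significance level after Bonferroni correction, default 0.05.
#' @param baseline_window_ms Spontaneous-rate window, default `[-500, 0)`.
#' @return An object of class `responsiveness_report`: list with `table`
#'   (tibble: `cell_id`, `image_id`, `p`, `p_adj`, `significant`) and `cells`
#'   (tibble: `cell_id`, `n_images`, `responsive`).
#' @export
screen_responsive <- function(x, evoked_window_ms = c(0, 600), alpha = 0.05,
                              baseline_window_ms = c(-500, 0)) {
  stopifnot(inherits(x, "spike_events"))
  n_tr <- x$n_trials_per_image
  if (n_tr < 6) {
    warning("fewer than 6 trials per image: the signed-rank test cannot ",
            "reach Bonferroni-corrected significance; all cells dropped")
    return(structure(list(
      table = tibble(cell_id = character(), image_id = character(),
                     p = numeric(), p_adj = numeric(),
                     significant = logical()),
      cells = tibble(cell_id = x$cells$cell_id, n_images = 0L,
                     responsive = FALSE),
      alpha = alpha), class = "responsiveness_report"))
  }
  catalog <- x$catalog
  cells <- x$cells
  n_cells <- nrow(cells)
  n_img <- nrow(catalog)
  sp <- x$spikes

  cidx <- match(sp$cell_id, cells$cell_id)
  iidx <- match(image_key(sp$set_id, sp$object_id, sp$view_angle_deg),
                catalog$image_id)
  lin <- cidx + ((iidx - 1L) * n_tr + (sp$trial_id - 1L)) * n_cells
  n_lin <- n_cells * n_img * n_tr
  ev_dur <- (evoked_window_ms[2] - evoked_window_ms[1]) / 1000
  bl_dur <- (baseline_window_ms[2] - baseline_window_ms[1]) / 1000
  in_ev <- sp$spike_time_ms >= evoked_window_ms[1] &
    sp$spike_time_ms < evoked_window_ms[2]
  in_bl <- sp$spike_time_ms >= baseline_window_ms[1] &
    sp$spike_time_ms < baseline_window_ms[2]
  ev_rate <- array(tabulate(lin[in_ev], nbins = n_lin) / ev_dur,
                   dim = c(n_cells, n_tr, n_img))
  bl_rate <- array(tabulate(lin[in_bl], nbins = n_lin) / bl_dur,
                   dim = c(n_cells, n_tr, n_img))

  presented <- if (is.null(cells$experience)) {
    matrix(TRUE, n_cells, n_img)
  } else {
    outer(cells$experience, catalog$experience, "==")
  }
  rows <- which(presented, arr.ind = TRUE)
  rows <- rows[order(rows[, 1L], rows[, 2L]), , drop = FALSE]
  p <- vapply(seq_len(nrow(rows)), function(k) {
    signed_rank_p(ev_rate[rows[k, 1L], , rows[k, 2L]],
                  bl_rate[rows[k, 1L], , rows[k, 2L]])
  }, numeric(1))
  m_per_cell <- tabulate(rows[, 1L], nbins = n_cells)
  p_adj <- pmin(1, p * m_per_cell[rows[, 1L]])
  tab <- tibble(cell_id = cells$cell_id[rows[, 1L]],
                image_id = catalog$image_id[rows[, 2L]],
                p = p, p_adj = p_adj, significant = p_adj < alpha)
  responsive <- vapply(seq_len(n_cells), function(i) {
    any(tab$significant[rows[, 1L] == i])
  }, logical(1))
  structure(list(table = tab,
                 cells = tibble(cell_id = cells$cell_id,
                                n_images = m_per_cell,
                                responsive = responsive),
                 alpha = alpha),
            class = "responsiveness_report")
}

#' @export
print.responsiveness_report <- function(x, ...) {
  cat("<responsiveness_report> ", sum(x$cells$responsive), "/",
      nrow(x$cells), " cells responsive (alpha = ", x$alpha,
      ", Bonferroni)\n", sep = "")
  invisible(x)
}
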