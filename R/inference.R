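#' Per-bin test of real vs random-labeling d' values
#'
#' Two-sided Mann-Whitney U test of the 25 real d' estimates of one time bin
#' against the 25 matched random-labeling estimates (exact distribution when
#' tie-free, tie-corrected normal approximation otherwise).
#'
#' @param real,null Numeric vectors of 25 d' estimates each.
#' @return Two-sided p-value.
#' @export
per_bin_test <- function(real, null) {
  if (length(real) != 25L || length(null) != 25L) {
    stop_user("per_bin_test expects 25 real and 25 null d' values, got ",
              length(real), " and ", length(null))
  }
  rank_test_p(real, null)
}

#' Significant time intervals under the consecutive-bin rule
#'
#' Finds maximal runs of consecutive bins with p strictly below `alpha`
#' (p-values exactly at `alpha` do not count) and keeps runs of at least
#' `min_run` bins.  Intervals are reported by the bin-center labels of their
#' first and last bin.
#'
#' @param pvalues Per-bin p-values on the analysis grid.
#' @param bin_centers Bin-center labels (ms), same length as `pvalues`.
#' @param alpha Per-bin threshold, default 0.001.
#' @param min_run Minimum run length in bins, default 5.
#' @return A tibble with columns `start_ms`, `end_ms`, `n_bins`.
#' @export
significant_runs <- function(pvalues, bin_centers = NULL, alpha = 0.001,
                             min_run = 5L) {
  if (is.null(bin_centers)) bin_centers <- as.numeric(names(pvalues))
  if (length(bin_centers) != length(pvalues) || anyNA(bin_centers)) {
    stop_user("bin_centers must label every p-value")
  }
  hit <- pvalues < alpha
  runs <- rle(hit)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_run
  tibble(start_ms = bin_centers[starts[keep]],
         end_ms = bin_centers[ends[keep]],
         n_bins = runs$lengths[keep])
}

#' Per-bin significance track of a decode result
#'
#' Applies the per-bin Mann-Whitney test row-wise to matched real and null
#' d' matrices and extracts the significant intervals.
#'
#' @param real,null d' matrices (bins x estimates) from
#'   [decode_timecourse()] and [null_timecourse()].
#' @param bin_centers Bin centers; defaults to the matrices' attribute.
#' @param alpha,min_run See [significant_runs()].
#' @return An object of class `significance_track`: list with `pvalues`,
#'   `bin_centers`, `intervals`, `alpha`, `min_run`.
#' @export
significance_track <- function(real, null, bin_centers = NULL,
                               alpha = 0.001, min_run = 5L) {
  if (!all(dim(real) == dim(null))) {
    stop_user("real and null matrices must have matching shapes")
  }
  if (is.null(bin_centers)) bin_centers <- attr(real, "bin_centers")
  if (is.null(bin_centers)) bin_centers <- as.numeric(rownames(real))
  p <- vapply(seq_len(nrow(real)), function(b) {
    rank_test_p(real[b, ], null[b, ])
  }, numeric(1))
  structure(list(pvalues = p, bin_centers = bin_centers,
                 intervals = significant_runs(p, bin_centers, alpha, min_run),
                 alpha = alpha, min_run = as.integer(min_run)),
            class = "significance_track")
}

#' @export
print.significance_track <- function(x, ...) {
  cat("<significance_track> ", length(x$pvalues), " bins, alpha = ",
      x$alpha, ", min run = ", x$min_run, " bins\n", sep = "")
  if (nrow(x$intervals) == 0L) {
    cat("no significant intervals\n")
  } else {
    for (i in seq_len(nrow(x$intervals))) {
      cat(sprintf("significant: %g-%g ms (%d bins)\n",
                  x$intervals$start_ms[i], x$intervals$end_ms[i],
                  x$intervals$n_bins[i]))
    }
  }
  invisible(x)
}

#' Decoding performance vs population size
#'
#' Randomly draws `n_draws` cell subsets (without replacement) at each
#' roster size, reruns the decoder on a single wide analysis window for each
#' draw, and summarizes the mean d' per draw as mean and standard error
#' (SD / sqrt(n_draws)) across draws.
#'
#' @param dataset A single-bin `population_dataset` (e.g. assembled from
#'   rates binned with one 500 ms window spanning 100-600 ms).
#' @param sizes Strictly increasing roster sizes, each at most the roster
#'   size of `dataset`.
#' @param delta_deg Viewing-angle difference tested.
#' @param plan A `split_plan`.
#' @param n_draws Random draws per size, default 5.
#' @param seed Seed for the cell draws.
#' @param cost,class_weights Passed to the decoder.
#' @return An object of class `subsample_curve`: tibble with columns
#'   `n_cells`, `mean_dprime`, `se_dprime`, plus a `draws` attribute (sizes x
#'   draws matrix of per-draw mean d').
#' @export
subsample_curve <- function(dataset, sizes, delta_deg, plan, n_draws = 5L,
                            seed = 1L, cost = 1, class_weights = NULL) {
  stopifnot(inherits(dataset, "population_dataset"))
  n_roster <- length(dataset$roster)
  sizes <- as.integer(sizes)
  if (any(diff(sizes) <= 0)) stop_user("sizes must be strictly increasing")
  if (max(sizes) > n_roster) {
    stop_user("requested size ", max(sizes), " exceeds the roster (",
              n_roster, " cells)")
  }
  if (dim(dataset$vectors)[3L] != 1L) {
    stop_user("subsample_curve expects a single-window dataset")
  }
  draws <- matrix(NA_real_, length(sizes), n_draws,
                  dimnames = list(sizes, NULL))
  with_seed(seed, {
    for (si in seq_along(sizes)) {
      for (dr in seq_len(n_draws)) {
        idx <- sort(sample.int(n_roster, sizes[si]))
        sub <- subset_cells(dataset, idx)
        m <- decode_timecourse(sub, delta_deg, plan, cost = cost,
                               class_weights = class_weights)
        draws[si, dr] <- mean(m)
      }
    }
  })
  out <- tibble(n_cells = sizes,
                mean_dprime = unname(rowMeans(draws)),
                se_dprime = unname(apply(draws, 1L, sd)) / sqrt(n_draws))
  attr(out, "draws") <- draws
  attr(out, "delta_deg") <- as.integer(delta_deg)
  class(out) <- c("subsample_curve", class(out))
  out
}
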