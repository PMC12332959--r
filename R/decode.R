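#' Time-resolved cross-view decoding
#'
#' For every time bin and every (repeat, fold) of the split plan, trains
#' one-vs-rest linear SVM hyperplanes on the training pseudo-trials at each
#' anchor viewing angle (one classifier per target object per object set),
#' tests them on the held-out pseudo-trials at the viewing angle(s) shifted
#' by `delta_deg`, and converts the confusion proportions to d'.  The d'
#' values are averaged over the four target objects, both rotation
#' directions of every angle pair, and object sets, giving one estimate per
#' (bin, repeat, fold): a bins x 25 matrix under the default 5 x 5 plan.
#'
#' Training and testing always use the same time bin.  Classifiers at one
#' anchor angle are trained once per (bin, repeat, fold) and reused across
#' the angle differences requested in `decode_timecourses()`.
#'
#' @param dataset A `population_dataset`, or a list of them (one per
#'   repeat, sharing roster and row layout, see [assemble_repeats()]) to
#'   give every repeat its own pseudo-trial alignment.
#' @param delta_deg Viewing-angle difference(s) to test (subset of
#'   0/30/60/90).
#' @param plan A `split_plan`.
#' @param null Logical: if `TRUE`, run the random-labeling control in which
#'   the object-identity labels of whole images are randomly permuted
#'   across the four objects within each (set, viewing angle) stratum —
#'   preserving the exact 1:3 class balance while destroying object
#'   identity — with a fresh relabeling per (repeat, fold), the pipeline
#'   otherwise re-run unchanged.  Within a set the four angles receive distinct powers of
#'   one random 4-cycle, so the composite relabeling between any two
#'   angles has no fixed point and no true cross-view correspondence
#'   survives into the null.
#' @param null_seed Seed for the label permutations.
#' @param cost,class_weights Passed to [linear_svc()].
#' @return `decode_timecourses()`: a named list (one element per delta) of
#'   bins x (repeats * folds) d' matrices with attributes `delta_deg`,
#'   `bin_centers` and `null`.  `decode_timecourse()` /
#'   `null_timecourse()`: the single matrix.
#' @export
decode_timecourses <- function(dataset, delta_deg, plan, null = FALSE,
                               null_seed = 1L, cost = 1,
                               class_weights = NULL) {
  stopifnot(inherits(plan, "split_plan"))
  # a list of datasets supplies one independent pseudo-trial alignment per
  # repeat (see assemble_repeats); a single dataset is reused for all
  shared_alignment <- inherits(dataset, "population_dataset")
  if (shared_alignment) {
    datasets <- rep(list(dataset), plan$repeats)
  } else {
    datasets <- dataset
    if (length(datasets) != plan$repeats ||
        !all(vapply(datasets, inherits, logical(1), "population_dataset"))) {
      stop_user("dataset must be a population_dataset or a list of one ",
                "per repeat")
    }
    for (d in datasets[-1L]) {
      if (!identical(d$roster, datasets[[1L]]$roster) ||
          !identical(d$rows, datasets[[1L]]$rows)) {
        stop_user("per-repeat datasets must share roster and row layout")
      }
    }
  }
  dataset <- datasets[[1L]]
  if (plan$n_pseudo_trials != dataset$n_pseudo_trials) {
    stop_user("split plan was made for ", plan$n_pseudo_trials,
              " pseudo-trials but the dataset has ", dataset$n_pseudo_trials)
  }
  deltas <- as.integer(delta_deg)
  pairs_by_delta <- lapply(deltas, angle_pairs)
  names(pairs_by_delta) <- paste0("delta", deltas)
  anchors <- sort(unique(unlist(lapply(pairs_by_delta,
                                       function(p) p$train_angle_deg))))

  rows <- dataset$rows
  V <- dataset$vectors
  n_bins <- dim(V)[3L]
  n_rows <- nrow(rows)
  sets <- unique(rows$set_id)
  objects <- sort(unique(rows$object_id))
  reps <- plan$repeats
  folds <- plan$folds

  # row indices per (set, angle)
  row_idx <- list()
  for (s in sets) for (a in VIEW_ANGLES) {
    row_idx[[paste(s, a)]] <-
      which(rows$set_id == s & rows$view_angle_deg == a)
  }

  # object labels per repeat (identity for real data; random image
  # relabelings for the null).  Each (set, angle) stratum gets a bijective
  # relabeling of the four objects, so whole images keep coherent labels
  # and every train/test fold keeps the exact 1:3 class balance.  Within a
  # set the four angles receive distinct powers of one random 4-cycle:
  # the composite relabeling between any two different angles is then a
  # nontrivial power of that cycle and has no fixed points, so no object's
  # true cross-view correspondence survives into the null.
  labels <- vector("list", reps * folds)
  if (null) {
    with_seed(null_seed, {
      for (k in seq_len(reps * folds)) {
        lab <- rows$object_id
        for (s in sets) {
          cyc <- sample(objects)                  # a random 4-cycle
          step <- sample(length(objects)) - 1L    # distinct power per angle
          for (ai in seq_along(VIEW_ANGLES)) {
            idx <- row_idx[[paste(s, VIEW_ANGLES[ai])]]
            if (length(idx)) {
              pos <- match(rows$object_id[idx], cyc)
              lab[idx] <- cyc[(pos - 1L + step[ai]) %% length(cyc) + 1L]
            }
          }
        }
        labels[[k]] <- lab
      }
    })
  } else {
    for (k in seq_len(reps * folds)) labels[[k]] <- rows$object_id
  }

  fold_of <- plan$assignment[rows$pseudo_trial, , drop = FALSE]
  n_obj <- length(objects)
  cw0 <- cw1 <- 1
  if (!is.null(class_weights)) {
    if (!is.null(class_weights[["0"]])) cw0 <- class_weights[["0"]]
    if (!is.null(class_weights[["1"]])) cw1 <- class_weights[["1"]]
  }
  out <- lapply(deltas, function(d) {
    matrix(NA_real_, n_bins, reps * folds,
           dimnames = list(dimnames(V)[[3L]], NULL))
  })
  names(out) <- names(pairs_by_delta)

  # per (repeat, fold): training rows per (set, anchor), test rows and
  # positive-class masks per (set, angle) — none of it depends on the bin
  prep <- vector("list", reps * folds)
  for (r in seq_len(reps)) {
    frow <- fold_of[, r]
    for (f in seq_len(folds)) {
      lab <- labels[[(r - 1L) * folds + f]]
      is_test <- frow == f
      train <- list()
      for (s in sets) for (a in anchors) {
        idx <- row_idx[[paste(s, a)]]
        tr <- idx[!is_test[idx]]
        train[[paste(s, a)]] <- list(rows = tr, lab = as.integer(lab[tr]))
      }
      test <- list()
      for (s in sets) for (a in VIEW_ANGLES) {
        idx <- row_idx[[paste(s, a)]]
        te <- idx[is_test[idx]]
        if (length(te) == 0L) next
        pos <- outer(lab[te], objects, "==")  # rows x objects
        test[[paste(s, a)]] <- list(rows = te, pos = pos,
                                    n_pos = colSums(pos),
                                    n_neg = nrow(pos) - colSums(pos))
      }
      prep[[(r - 1L) * folds + f]] <- list(train = train, test = test)
    }
  }

  for (b in seq_len(n_bins)) {
    M_rep <- if (shared_alignment) {
      M <- datasets[[1L]]$vectors[, , b, drop = FALSE]
      dim(M) <- dim(datasets[[1L]]$vectors)[1:2]
      rep(list(M), reps)
    } else {
      lapply(datasets, function(ds) {
        M <- ds$vectors[, , b, drop = FALSE]
        dim(M) <- dim(ds$vectors)[1:2]
        M
      })
    }
    for (col in seq_len(reps * folds)) {
      M <- M_rep[[((col - 1L) %/% folds) + 1L]]
      pp <- prep[[col]]
      # one classifier per (set, anchor, object); the four one-vs-rest
      # problems of a training set share one Gram matrix
      W <- lapply(pp$train, function(tr) {
        svc_train_ovr_cpp(M[tr$rows, , drop = FALSE], tr$lab,
                          as.integer(objects), cost * cw1, cost * cw0,
                          1e-3, 200000L)
      })
      for (di in seq_along(deltas)) {
        pr <- pairs_by_delta[[di]]
        acc <- 0
        cnt <- 0L
        for (pi in seq_len(nrow(pr))) {
          a <- pr$train_angle_deg[pi]
          t <- pr$test_angle_deg[pi]
          for (s in sets) {
            fit <- W[[paste(s, a)]]
            te <- pp$test[[paste(s, t)]]
            pred <- M[te$rows, , drop = FALSE] %*% fit$W >
              rep(-fit$b, each = length(te$rows))
            # proportions for all four objects at once
            tp <- colSums(pred & te$pos) / te$n_pos
            fp <- colSums(pred & !te$pos) / te$n_neg
            ok <- te$n_pos > 0L & te$n_neg > 0L
            if (any(ok)) {
              d_obj <- dprime_stat(tp[ok], fp[ok], te$n_pos[ok],
                                   te$n_neg[ok])
              acc <- acc + mean(d_obj)
              cnt <- cnt + 1L
            }
          }
        }
        out[[di]][b, col] <- acc / cnt
      }
    }
  }
  for (di in seq_along(out)) {
    attr(out[[di]], "delta_deg") <- deltas[di]
    attr(out[[di]], "bin_centers") <- dataset$bin_centers
    attr(out[[di]], "null") <- null
  }
  out
}

#' @rdname decode_timecourses
#' @export
decode_timecourse <- function(dataset, delta_deg, plan, cost = 1,
                              class_weights = NULL) {
  stopifnot(length(delta_deg) == 1L)
  decode_timecourses(dataset, delta_deg, plan, null = FALSE,
                     cost = cost, class_weights = class_weights)[[1L]]
}

#' @param seed Seed for the null's label permutations.
#' @rdname decode_timecourses
#' @export
null_timecourse <- function(dataset, delta_deg, plan, seed = 1L, cost = 1,
                            class_weights = NULL) {
  stopifnot(length(delta_deg) == 1L)
  decode_timecourses(dataset, delta_deg, plan, null = TRUE, null_seed = seed,
                     cost = cost, class_weights = class_weights)[[1L]]
}
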