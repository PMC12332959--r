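#' Viewing angles used throughout the package
#'
#' The stimulus geometry rotates each object in 30 degree steps, giving four
#' views per object at 0, 30, 60 and 90 degrees.
#' @export
VIEW_ANGLES <- c(0L, 30L, 60L, 90L)

#' Experience conditions
#'
#' `"object_task"` marks object sets whose views were experienced in a task
#' requiring association of different views of the same object;
#' `"across_set_task"` marks sets whose images were merely viewed.
#' @export
EXPERIENCE_LEVELS <- c("object_task", "across_set_task")

#' Generate a stimulus catalog
#'
#' Builds the catalog of stimulus images: each object set contains 4 similar
#' objects, each rendered at the 4 viewing angles (0, 30, 60, 90 degrees),
#' i.e. 16 images per set.
#'
#' @param n_sets Number of object sets (>= 1).
#' @param experience Experience condition per set: either a single value
#'   recycled to all sets or a character vector of length `n_sets` with
#'   values in `EXPERIENCE_LEVELS`.
#' @return A tibble with one row per image and columns `set_id`, `object_id`
#'   (1-4), `view_angle_deg` (0/30/60/90), `experience` and `image_id`.
#' @examples
#' cat1 <- generate_catalog(1)
#' nrow(cat1)  # 16
#' @export
generate_catalog <- function(n_sets, experience = "object_task") {
  if (length(n_sets) != 1L || is.na(n_sets) || n_sets < 1) {
    stop_user("n_sets must be a single integer >= 1")
  }
  n_sets <- as.integer(n_sets)
  if (length(experience) == 1L) experience <- rep(experience, n_sets)
  if (length(experience) != n_sets) {
    stop_user("invalid experience assignment: need one condition per set, got ",
              length(experience), " for ", n_sets, " sets")
  }
  bad <- !experience %in% EXPERIENCE_LEVELS
  if (any(bad)) {
    stop_user("invalid experience assignment: unknown condition '",
              experience[which(bad)[1L]], "'")
  }
  set_id <- sprintf("set%02d", seq_len(n_sets))
  grid <- expand.grid(view_angle_deg = VIEW_ANGLES, object_id = 1:4,
                      set_idx = seq_len(n_sets), KEEP.OUT.ATTRS = FALSE)
  out <- tibble(
    set_id = set_id[grid$set_idx],
    object_id = as.integer(grid$object_id),
    view_angle_deg = as.integer(grid$view_angle_deg),
    experience = experience[grid$set_idx]
  )
  out$image_id <- image_key(out$set_id, out$object_id, out$view_angle_deg)
  out[order(out$set_id, out$object_id, out$view_angle_deg), ]
}

image_key <- function(set_id, object_id, view_angle_deg) {
  sprintf("%s_obj%d_v%02d", set_id, object_id, view_angle_deg)
}
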