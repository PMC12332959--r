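# Small simulated fixtures shared across test files.  Kept deliberately
# tiny; heavier end-to-end simulations live in test-acceptance.R.

tiny_groups <- function(n_te = 8L, n_teo = 6L, alpha_te = 0.8,
                        alpha_teo = 0.1) {
  tibble::tibble(
    area = c("TE", "TEO"),
    experience = "object_task",
    n_cells = c(n_te, n_teo),
    alpha_mean = c(alpha_te, alpha_teo),
    animal = "simA"
  )
}

tiny_spikes <- function(seed = 1L, n_trials = 8L, ...) {
  cfg <- sim_config(groups = tiny_groups(...), n_trials_per_image = n_trials,
                    seed = seed)
  simulate_spikes(build_population(cfg))
}

# a hand-built spike_events object with full control over spike times
manual_spikes <- function(spike_df, n_trials, trial_window = c(-500, 1000),
                          n_cells = NULL, experience = "object_task") {
  if (is.null(spike_df)) {
    spike_df <- data.frame(cell_id = character(), area = character(),
                           animal = character(), experience = character(),
                           set_id = character(), object_id = integer(),
                           view_angle_deg = integer(), trial_id = integer(),
                           spike_time_ms = numeric())
  }
  catalog <- generate_catalog(1, experience)
  ids <- if (is.null(n_cells)) unique(spike_df$cell_id) else
    sprintf("c%02d", seq_len(n_cells))
  cells <- tibble::tibble(cell_id = ids, area = "TE", animal = "m1",
                          experience = experience)
  structure(list(spikes = spike_df, cells = cells, catalog = catalog,
                 n_trials_per_image = as.integer(n_trials),
                 trial_window_ms = trial_window, config = NULL),
            class = "spike_events")
}

# spike rows for one cell/image across trials, given spike times per trial
spike_rows <- function(cell_id, object_id, view, times_by_trial,
                       set_id = "set01") {
  do.call(rbind, lapply(seq_along(times_by_trial), function(tr) {
    tms <- times_by_trial[[tr]]
    if (length(tms) == 0) return(NULL)
    data.frame(cell_id = cell_id, area = "TE", animal = "m1",
               experience = "object_task", set_id = set_id,
               object_id = object_id, view_angle_deg = view, trial_id = tr,
               spike_time_ms = tms)
  }))
}

image_key_test <- function(sp) {
  sprintf("%s_obj%d_v%02d", sp$set_id, sp$object_id, sp$view_angle_deg)
}
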