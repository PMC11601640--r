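# Small movie configurations shared across tests. Everything is generated
# in code; no fixture files.

tiny_movie_config <- function(n_cells = 1, n_frames = 3, seed = 11, ...) {
  sim_movie_config(field_size_px = c(120, 120), n_frames = n_frames,
                   n_cells_initial = n_cells, motion_sd_px = 0, seed = seed,
                   ...)
}

# a single static cell with a fixed prescribed activity, rendered clean
render_single_cell <- function(activity_fate = "prolonged_g0", seed = 11,
                               traj_params = cdk2_params(), ...) {
  cfg <- tiny_movie_config(n_cells = 1, seed = seed,
                           fate_assignment = c("1" = activity_fate),
                           traj_params = traj_params, ...)
  render_movie(cfg)
}

# corrected (flattened, background-subtracted) first-frame channels
corrected_first_frame <- function(movie) {
  bias <- estimate_illumination_bias(list(movie$stack[, , 1, 1]))
  list(marker = flatten_and_subtract(movie$stack[, , 1, 1], bias),
       sensor = flatten_and_subtract(movie$stack[, , 2, 1], bias),
       bias = bias)
}
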