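# Small simulation configurations shared across test files. Sizes are kept
# desk-scale; the full-scale (3000-frame) runs live in test-acceptance.R.

tiny_sim_config <- function(...) {
  args <- utils::modifyList(list(
    n_cells = 3L, fov_shape = c(80L, 120L), n_frames = 40L,
    cell_radius_px = c(10, 14), seed = 7L), list(...))
  do.call(simulation_config, args)
}

noiseless_sim_config <- function(...) {
  tiny_sim_config(shot_noise = FALSE, read_noise_sd = 0,
                  bleach_cell_sdlog = 0, ...)
}

# two non-touching rectangular "cells" on a constant background, by hand
two_blob_image <- function(H = 40L, W = 60L, bg = 10, v1 = 100, v2 = 120) {
  img <- matrix(bg, H, W)
  img[5:15, 5:20] <- v1
  img[25:35, 35:55] <- v2
  img
}
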