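# Synthetic split-FOV imaging simulator.
#
# The generator emulates the three experiment designs the analysis targets:
# (1) single/short acquisitions of control vs cyanide-perturbed cells at a
# given illumination power and exposure, (2) 30-s continuous photobleaching
# stacks (3000 frames at 99.4 Hz), and (3) glucose-bolus dynamics (3000
# frames at 99.6 Hz, stimulus at ~8 s). Cell phantoms have a dim nucleus,
# bright cytoplasm and punctate mitochondria; the camera model is
# counts = Poisson(signal) + N(0, read_noise_sd) + background_offset,
# clipped to [0, 65535] and quantized to the bit depth.

#' Simulation configuration
#'
#' Defines the full generative world for [simulate_timelapse()]. The defaults
#' describe the photobleaching acquisition: 12 cells, 3000 frames at 99.4 Hz,
#' 10-ms exposure, 4.14 mW illumination. Expected cytoplasm intensity scales
#' linearly with `illumination_mw * exposure_ms` relative to
#' `reference_mw * reference_exposure_ms`.
#'
#' @param n_cells number of non-touching cell phantoms.
#' @param fov_shape `c(H, W)` of each channel half, pixels.
#' @param pixel_size_um sample-plane pixel size (the desk-scale default of
#'   0.65 um corresponds to 4x-binned sCMOS sampling).
#' @param n_frames,frame_rate_hz record length and rate.
#' @param illumination_mw,exposure_ms acquisition settings.
#' @param base_intensity_451,base_intensity_560 expected photon counts per
#'   cytoplasm pixel per frame at the reference power x exposure.
#' @param reference_mw,reference_exposure_ms reference point for the
#'   linear power x exposure intensity scaling.
#' @param nucleus_factor nucleus dimming factor, in (0, 1].
#' @param mito_density number of mitochondrial puncta per cell.
#' @param mito_factor brightness multiplier of punctum pixels.
#' @param bleach_rate_451,bleach_rate_560 monoexponential photobleaching
#'   decay constants, per second, at the configured illumination.
#' @param bleach_cell_sdlog sdlog of the per-cell lognormal multiplier on
#'   both bleach rates (mean 1); models cell-to-cell bleaching spread.
#' @param background_offset camera offset, counts.
#' @param read_noise_sd Gaussian read noise sd, counts.
#' @param shot_noise apply Poisson shot noise to the signal.
#' @param quantize round and clip counts to the 16-bit range; `NULL` (auto)
#'   quantizes iff any noise source is on, so noise-free runs return exact
#'   expected intensities.
#' @param image_jitter_sdlog sdlog of a per-run lognormal gain applied
#'   independently to each channel; models dish-to-dish biological intensity
#'   variation between images of a group experiment (0 = off).
#' @param cell_radius_px range of cytoplasm semi-major axes, pixels.
#' @param perturbation `"none"`, `"cyanide"` (static intensity elevation) or
#'   `"glucose_bolus"` (delayed per-cell ramp response).
#' @param perturbation_params overrides of the perturbation defaults; see
#'   Details.
#' @param channel_shift integer `c(dy, dx)` misalignment applied to the
#'   560-nm half, to exercise registration.
#' @param layout which half carries the 451-nm channel.
#' @param seed integer RNG seed; identical config + seed gives bit-identical
#'   stacks.
#'
#' @details Perturbation defaults: cyanide multiplies the 451-nm cell signal
#' by `factor_451 = 1.6` and the 560-nm signal by `factor_560 = 0.93`
#' (raising the ORR from ~0.70 to ~0.80); glucose uses
#' `stimulus_time_s = 8`, onset delays Unif(1, 4) s, 451-nm rise rates
#' Unif(0.4, 1.6) a.u./s with the 560-nm rate a Unif(0.4, 0.8) fraction of
#' it, `plateau_multiplier = 1.10` of the pre-onset trace level, and a
#' pre-stimulus linear drift of `pre_drift_percent = -4` percent.
#' @return a `simulation_config` object.
#' @export
simulation_config <- function(n_cells = 12L,
                              fov_shape = c(140L, 240L),
                              pixel_size_um = 0.65,
                              n_frames = 3000L,
                              frame_rate_hz = 99.4,
                              illumination_mw = 4.14,
                              exposure_ms = 10,
                              base_intensity_451 = 32,
                              base_intensity_560 = 14,
                              reference_mw = 4.14,
                              reference_exposure_ms = 10,
                              nucleus_factor = 0.6,
                              mito_density = 25L,
                              mito_factor = 1.8,
                              bleach_rate_451 = 0.0019,
                              bleach_rate_560 = 0.0011,
                              bleach_cell_sdlog = 0.3,
                              background_offset = 100,
                              read_noise_sd = 2,
                              shot_noise = TRUE,
                              quantize = NULL,
                              image_jitter_sdlog = 0,
                              cell_radius_px = c(14, 18),
                              perturbation = c("none", "cyanide", "glucose_bolus"),
                              perturbation_params = list(),
                              channel_shift = c(0L, 0L),
                              layout = c("left451", "right451"),
                              seed = 1L) {
  perturbation <- match.arg(perturbation)
  layout <- match.arg(layout)
  n_cells <- as.integer(n_cells)
  n_frames <- as.integer(n_frames)
  if (n_cells < 0L) stop("n_cells must be >= 0", call. = FALSE)
  if (n_frames < 1L) stop("n_frames must be >= 1", call. = FALSE)
  if (nucleus_factor <= 0 || nucleus_factor > 1)
    stop("nucleus_factor must be in (0, 1]", call. = FALSE)
  nonneg <- c(base_intensity_451 = base_intensity_451,
              base_intensity_560 = base_intensity_560,
              bleach_rate_451 = bleach_rate_451,
              bleach_rate_560 = bleach_rate_560,
              bleach_cell_sdlog = bleach_cell_sdlog,
              background_offset = background_offset,
              read_noise_sd = read_noise_sd,
              mito_density = mito_density, mito_factor = mito_factor,
              image_jitter_sdlog = image_jitter_sdlog)
  bad <- names(nonneg)[nonneg < 0]
  if (length(bad)) stop("negative value for: ", paste(bad, collapse = ", "),
                        call. = FALSE)

  defaults <- switch(perturbation,
    none = list(),
    cyanide = list(factor_451 = 1.6, factor_560 = 0.93),
    glucose_bolus = list(stimulus_time_s = 8,
                         delay_range_s = c(1, 4),
                         rate_range_au_per_s = c(0.4, 1.6),
                         rate_560_fraction = c(0.4, 0.8),
                         plateau_multiplier = 1.10,
                         pre_drift_percent = -4))
  pp <- utils::modifyList(defaults, perturbation_params)

  structure(list(
    n_cells = n_cells, fov_shape = as.integer(fov_shape),
    pixel_size_um = pixel_size_um, n_frames = n_frames,
    frame_rate_hz = frame_rate_hz, illumination_mw = illumination_mw,
    exposure_ms = exposure_ms,
    base_intensity_451 = base_intensity_451,
    base_intensity_560 = base_intensity_560,
    reference_mw = reference_mw, reference_exposure_ms = reference_exposure_ms,
    nucleus_factor = nucleus_factor,
    mito_density = as.integer(mito_density), mito_factor = mito_factor,
    bleach_rate_451 = bleach_rate_451, bleach_rate_560 = bleach_rate_560,
    bleach_cell_sdlog = bleach_cell_sdlog,
    background_offset = background_offset, read_noise_sd = read_noise_sd,
    shot_noise = isTRUE(shot_noise), quantize = quantize,
    image_jitter_sdlog = image_jitter_sdlog,
    cell_radius_px = cell_radius_px,
    perturbation = perturbation, perturbation_params = pp,
    channel_shift = as.integer(channel_shift), layout = layout,
    seed = as.integer(seed)), class = "simulation_config")
}

#' Preset: glucose-bolus dynamics acquisition
#'
#' Five cells imaged at 99.6 Hz for 3000 frames at finer sampling
#' (0.325 um/px, larger phantoms) with a glucose stimulus at 8 s.
#' @param ... overrides passed to [simulation_config()].
#' @export
glucose_sim_config <- function(...) {
  args <- utils::modifyList(list(
    n_cells = 5L, fov_shape = c(190L, 360L), pixel_size_um = 0.325,
    n_frames = 3000L, frame_rate_hz = 99.6, cell_radius_px = c(28, 36),
    perturbation = "glucose_bolus"), list(...))
  do.call(simulation_config, args)
}

#' Preset: single-frame group-experiment acquisition (control or cyanide)
#'
#' @param cyanide simulate the cyanide-perturbed group.
#' @param ... overrides passed to [simulation_config()].
#' @export
cyanide_sim_config <- function(cyanide = TRUE, ...) {
  args <- utils::modifyList(list(
    n_cells = 8L, fov_shape = c(120L, 200L), n_frames = 1L,
    image_jitter_sdlog = 0.067,
    perturbation = if (cyanide) "cyanide" else "none"), list(...))
  do.call(simulation_config, args)
}

# --- phantom geometry -------------------------------------------------------

in_ellipse <- function(Y, X, cy, cx, ry, rx, theta = 0) {
  dy <- Y - cy; dx <- X - cx
  u <- cos(theta) * dx + sin(theta) * dy
  v <- -sin(theta) * dx + cos(theta) * dy
  (u / rx)^2 + (v / ry)^2 <= 1
}

#' Single-cell intensity phantom
#'
#' Builds one elliptical cell template pair: bright cytoplasm, a nucleus
#' dimmed by `nucleus_factor`, and `mito_density` bright mitochondrial
#' puncta (3x3 crosses, confined to the cytoplasm). Both channels share the
#' same geometry; only the base intensities differ.
#'
#' @param cyto_radii `c(ry, rx)` cytoplasm semi-axes, pixels.
#' @param nucleus_radii `c(ry, rx)` nucleus semi-axes; must be strictly
#'   smaller than the cytoplasm axes.
#' @param base_451,base_560 cytoplasm intensity per channel.
#' @param nucleus_factor,mito_density,mito_factor see [simulation_config()].
#' @param theta rotation of the ellipse (radians).
#' @return list with `mask`, `nucleus`, `mito` (logical matrices over the
#'   template bounding box) and intensity templates `t451`, `t560`.
#' @export
make_cell_phantom <- function(cyto_radii, nucleus_radii,
                              base_451 = 32, base_560 = 14,
                              nucleus_factor = 0.6,
                              mito_density = 25L, mito_factor = 1.8,
                              theta = 0) {
  if (any(nucleus_radii >= cyto_radii))
    stop("nucleus radii must be smaller than cytoplasm radii", call. = FALSE)
  ry <- cyto_radii[1]; rx <- cyto_radii[2]
  h <- 2L * ceiling(ry) + 3L; w <- 2L * ceiling(rx) + 3L
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  Y <- matrix(seq_len(h), h, w)
  X <- matrix(seq_len(w), h, w, byrow = TRUE)
  mask <- in_ellipse(Y, X, cy, cx, ry, rx, theta)
  nucleus <- in_ellipse(Y, X, cy, cx, nucleus_radii[1], nucleus_radii[2], theta)
  cyto <- mask & !nucleus
  mito <- matrix(FALSE, h, w)
  n_puncta <- min(as.integer(mito_density), sum(cyto))
  if (n_puncta > 0L) {
    seeds <- sample(which(cyto), n_puncta)
    sy <- (seeds - 1L) %% h + 1L; sx <- (seeds - 1L) %/% h + 1L
    for (k in seq_len(n_puncta)) {
      yy <- c(sy[k], sy[k] - 1L, sy[k] + 1L, sy[k], sy[k])
      xx <- c(sx[k], sx[k], sx[k], sx[k] - 1L, sx[k] + 1L)
      ok <- yy >= 1L & yy <= h & xx >= 1L & xx <= w
      mito[cbind(yy[ok], xx[ok])] <- TRUE
    }
    mito <- mito & cyto
  }
  shape <- ifelse(mask, 1, 0)
  shape[nucleus & mask] <- nucleus_factor
  shape[mito] <- mito_factor
  list(mask = mask, nucleus = nucleus & mask, mito = mito,
       t451 = shape * base_451, t560 = shape * base_560)
}

# Rejection-sampled non-overlapping placement; errors after bounded retries.
place_cells <- function(n_cells, fov_shape, radius_range, max_tries = 400L) {
  H <- fov_shape[1]; W <- fov_shape[2]
  ry <- stats::runif(n_cells, radius_range[1], radius_range[2])
  rx <- ry * stats::runif(n_cells, 0.8, 1.05)
  cy <- numeric(n_cells); cx <- numeric(n_cells)
  rmax <- pmax(ry, rx)
  for (i in seq_len(n_cells)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      y <- stats::runif(1, rmax[i] + 2, H - rmax[i] - 1)
      x <- stats::runif(1, rmax[i] + 2, W - rmax[i] - 1)
      if (i == 1L || all(sqrt((y - cy[seq_len(i - 1)])^2 +
                              (x - cx[seq_len(i - 1)])^2) >=
                         rmax[i] + rmax[seq_len(i - 1)] + 3)) {
        cy[i] <- y; cx[i] <- x; placed <- TRUE; break
      }
    }
    if (!placed)
      stop(sprintf(
        "could not place %d non-overlapping cells in a %d x %d field of view (failed at cell %d after %d tries)",
        n_cells, H, W, i, max_tries), call. = FALSE)
  }
  data.frame(cy = cy, cx = cx, ry = ry, rx = rx,
             theta = stats::runif(n_cells, 0, pi))
}

# Additive ramp profile of a delayed stimulus response: zero before
# stimulus + delay, linear rise at `rate` until `plateau_add` is reached,
# then flat. rate = 0 leaves the trace unchanged.
glucose_additive <- function(time_s, stimulus_time_s, delay_s, rate, plateau_add) {
  if (rate == 0) return(numeric(length(time_s)))
  onset <- stimulus_time_s + delay_s
  ramp_dur <- plateau_add / rate
  rate * pmin(pmax(time_s - onset, 0), ramp_dur)
}

#' Apply a glucose-bolus response to noiseless traces
#'
#' Adds a delayed piecewise-linear response to each row of a trace matrix:
#' nothing until `stimulus_time_s + delay_s`, then a rise at
#' `rate_au_per_s` until the trace reaches `plateau_multiplier` times its
#' pre-onset level, then flat.
#'
#' @param traces numeric matrix (cells x frames) or vector.
#' @param time_s frame timestamps (seconds).
#' @param stimulus_time_s stimulus time; must lie within the record.
#' @param delay_s,rate_au_per_s per-cell (recycled) onset delay and rise
#'   rate; negative values are errors.
#' @param plateau_multiplier plateau level as a multiple of the trace value
#'   at onset.
#' @return list with `traces` (modified matrix), `onset_s`, and
#'   `plateau_add` (a.u. added at plateau, per cell).
#' @export
apply_glucose_response <- function(traces, time_s, stimulus_time_s,
                                   delay_s, rate_au_per_s,
                                   plateau_multiplier = 1.10) {
  if (is.vector(traces)) traces <- matrix(traces, nrow = 1)
  n <- nrow(traces)
  delay_s <- rep_len(delay_s, n); rate_au_per_s <- rep_len(rate_au_per_s, n)
  if (any(delay_s < 0)) stop("negative delay", call. = FALSE)
  if (any(rate_au_per_s < 0)) stop("negative rise rate", call. = FALSE)
  if (stimulus_time_s < min(time_s) || stimulus_time_s > max(time_s))
    stop("stimulus_time_s lies outside the record", call. = FALSE)
  onset <- stimulus_time_s + delay_s
  plateau_add <- numeric(n)
  for (i in seq_len(n)) {
    pre_idx <- max(which(time_s <= onset[i]))
    level <- traces[i, pre_idx]
    plateau_add[i] <- (plateau_multiplier - 1) * level
    traces[i, ] <- traces[i, ] +
      glucose_additive(time_s, stimulus_time_s, delay_s[i],
                       rate_au_per_s[i], plateau_add[i])
  }
  list(traces = traces, onset_s = onset, plateau_add = plateau_add)
}

# --- main generator ---------------------------------------------------------

#' Simulate a split-frame dual-channel time lapse with ground truth
#'
#' Generates the full acquisition described by a [simulation_config()]:
#' cell phantoms are placed in the field of view, per-cell monoexponential
#' photobleaching, the configured perturbation and the camera noise model
#' are applied frame by frame, and the two channel images are composed into
#' split frames. Deterministic for a fixed config (the seed is part of the
#' config).
#'
#' @param config a [simulation_config()].
#' @return list of class `redox_sim` with:
#'   `stack` (`H x 2W x T` split-frame array), `meta` ([acquisition_meta()]),
#'   `truth` (ground truth: `label_mask`, per-pixel noiseless base images
#'   `base_451`/`base_560`, noiseless per-cell traces `true_trace_451` /
#'   `true_trace_560` (cells x frames, including the background offset, i.e.
#'   exactly what ROI means over the label mask measure), per-cell bleach
#'   rates, `true_bleach_percent`, and for glucose runs `true_delay_s`,
#'   `true_rate_drawn_au_per_s` and `true_rate_au_per_s` -- the latter is the
#'   least-squares slope of the noiseless trace over the default 2-s fit
#'   window, which differs from the drawn ramp rate by the concurrent bleach
#'   slope), and `config`.
#' @export
simulate_timelapse <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  H <- config$fov_shape[1]; W <- config$fov_shape[2]
  T_ <- config$n_frames
  n <- config$n_cells
  time_s <- (seq_len(T_) - 1) / config$frame_rate_hz
  pp <- config$perturbation_params

  scale <- (config$illumination_mw * config$exposure_ms) /
    (config$reference_mw * config$reference_exposure_ms)
  jit <- config$image_jitter_sdlog
  gain_451 <- scale * if (jit > 0) stats::rlnorm(1, -jit^2 / 2, jit) else 1
  gain_560 <- scale * if (jit > 0) stats::rlnorm(1, -jit^2 / 2, jit) else 1
  if (config$perturbation == "cyanide") {
    gain_451 <- gain_451 * pp$factor_451
    gain_560 <- gain_560 * pp$factor_560
  }

  B451 <- matrix(0, H, W); B560 <- matrix(0, H, W)
  labels <- matrix(0L, H, W)
  cells <- NULL
  if (n > 0L) {
    cells <- place_cells(n, config$fov_shape, config$cell_radius_px)
    for (i in seq_len(n)) {
      ph <- make_cell_phantom(
        cyto_radii = c(cells$ry[i], cells$rx[i]),
        nucleus_radii = 0.45 * c(cells$ry[i], cells$rx[i]),
        base_451 = config$base_intensity_451 * gain_451,
        base_560 = config$base_intensity_560 * gain_560,
        nucleus_factor = config$nucleus_factor,
        mito_density = config$mito_density,
        mito_factor = config$mito_factor,
        theta = cells$theta[i])
      y0 <- round(cells$cy[i] - (nrow(ph$mask) + 1) / 2)
      x0 <- round(cells$cx[i] - (ncol(ph$mask) + 1) / 2)
      ys <- y0 + seq_len(nrow(ph$mask)); xs <- x0 + seq_len(ncol(ph$mask))
      keep_y <- ys >= 1L & ys <= H; keep_x <- xs >= 1L & xs <= W
      sub <- ph$mask[keep_y, keep_x, drop = FALSE]
      b1 <- B451[ys[keep_y], xs[keep_x], drop = FALSE]
      b1[sub] <- ph$t451[keep_y, keep_x, drop = FALSE][sub]
      B451[ys[keep_y], xs[keep_x]] <- b1
      b2 <- B560[ys[keep_y], xs[keep_x], drop = FALSE]
      b2[sub] <- ph$t560[keep_y, keep_x, drop = FALSE][sub]
      B560[ys[keep_y], xs[keep_x]] <- b2
      lab_sub <- labels[ys[keep_y], xs[keep_x], drop = FALSE]
      lab_sub[sub] <- i
      labels[ys[keep_y], xs[keep_x]] <- lab_sub
    }
  }

  # per-cell bleach rates: lognormal multiplier (mean 1) on both channels
  mult <- if (n > 0L && config$bleach_cell_sdlog > 0)
    stats::rlnorm(n, -config$bleach_cell_sdlog^2 / 2, config$bleach_cell_sdlog)
  else rep(1, n)
  k451 <- config$bleach_rate_451 * mult
  k560 <- config$bleach_rate_560 * mult

  # pre-stimulus drift (glucose mode): linear ramp from 1 at t=0 to
  # 1 + p/100 at the stimulus, constant afterwards
  drift <- rep(1, T_)
  delay <- rate451 <- rate560 <- onset <- rep(NA_real_, n)
  if (config$perturbation == "glucose_bolus") {
    p <- pp$pre_drift_percent / 100
    st <- pp$stimulus_time_s
    if (st <= 0 || st >= max(time_s))
      stop("glucose stimulus_time_s must lie inside the record", call. = FALSE)
    drift <- 1 + p * pmin(time_s / st, 1)
    delay <- stats::runif(n, pp$delay_range_s[1], pp$delay_range_s[2])
    rate451 <- stats::runif(n, pp$rate_range_au_per_s[1], pp$rate_range_au_per_s[2])
    rate560 <- rate451 * stats::runif(n, pp$rate_560_fraction[1], pp$rate_560_fraction[2])
    onset <- st + delay
  }

  # noiseless per-cell mean traces (over the full label-mask ROI)
  idx <- which(labels > 0L)
  lab_v <- labels[idx]
  npix <- tabulate(lab_v, nbins = max(n, 1L))[seq_len(max(n, 0L))]
  mB451 <- if (n > 0L) as.vector(rowsum(B451[idx], lab_v)) / npix else numeric(0)
  mB560 <- if (n > 0L) as.vector(rowsum(B560[idx], lab_v)) / npix else numeric(0)

  decay451 <- if (n > 0L) exp(-outer(k451, time_s)) else matrix(0, 0, T_)
  decay560 <- if (n > 0L) exp(-outer(k560, time_s)) else matrix(0, 0, T_)
  # per-cell additive response, in a.u. added to every pixel of the cell
  add451 <- matrix(0, max(n, 0L), T_); add560 <- matrix(0, max(n, 0L), T_)
  plateau_add <- rep(NA_real_, max(n, 0L))
  if (config$perturbation == "glucose_bolus" && n > 0L) {
    for (i in seq_len(n)) {
      pre_idx <- max(which(time_s <= onset[i]))
      level <- mB451[i] * decay451[i, pre_idx] * drift[pre_idx] + config$background_offset
      plateau_add[i] <- (pp$plateau_multiplier - 1) * level
      add451[i, ] <- glucose_additive(time_s, pp$stimulus_time_s, delay[i],
                                      rate451[i], plateau_add[i])
      level560 <- mB560[i] * decay560[i, pre_idx] * drift[pre_idx] + config$background_offset
      add560[i, ] <- glucose_additive(time_s, pp$stimulus_time_s, delay[i],
                                      rate560[i], (pp$plateau_multiplier - 1) * level560)
    }
  }
  if (n > 0L) {
    drift_m <- matrix(drift, n, T_, byrow = TRUE)
    true451 <- mB451 * decay451 * drift_m + add451 + config$background_offset
    true560 <- mB560 * decay560 * drift_m + add560 + config$background_offset
  } else {
    true451 <- true560 <- matrix(numeric(0), 0L, T_)
  }

  quantize <- config$quantize
  if (is.null(quantize)) quantize <- config$shot_noise || config$read_noise_sd > 0

  stack <- if (quantize) array(0L, dim = c(H, 2L * W, T_))
           else array(0, dim = c(H, 2L * W, T_))
  off <- config$background_offset
  off_q <- if (quantize) round(off) else off
  npx <- H * W
  for (t in seq_len(T_)) {
    f451 <- c(1, decay451[, t] * drift[t])[labels + 1L]
    f560 <- c(1, decay560[, t] * drift[t])[labels + 1L]
    a451 <- c(0, add451[, t])[labels + 1L]
    a560 <- c(0, add560[, t])[labels + 1L]
    lam451 <- B451 * f451 + a451
    lam560 <- B560 * f560 + a560
    ch451 <- matrix(0, H, W); ch560 <- matrix(0, H, W)
    if (config$shot_noise) {
      ch451[idx] <- stats::rpois(length(idx), lam451[idx])
      ch560[idx] <- stats::rpois(length(idx), lam560[idx])
    } else {
      ch451[idx] <- lam451[idx]; ch560[idx] <- lam560[idx]
    }
    if (config$read_noise_sd > 0) {
      ch451 <- ch451 + stats::rnorm(npx, 0, config$read_noise_sd)
      ch560 <- ch560 + stats::rnorm(npx, 0, config$read_noise_sd)
    }
    ch451 <- ch451 + off; ch560 <- ch560 + off
    if (quantize) {
      ch451 <- round(ch451); ch560 <- round(ch560)
      ch451[ch451 < 0] <- 0; ch451[ch451 > 65535] <- 65535
      ch560[ch560 < 0] <- 0; ch560[ch560 > 65535] <- 65535
    }
    if (any(config$channel_shift != 0L)) {
      ch560 <- translate_img(ch560, config$channel_shift[1],
                             config$channel_shift[2], fill = off_q)
    }
    frame <- if (config$layout == "left451") cbind(ch451, ch560)
             else cbind(ch560, ch451)
    if (quantize) storage.mode(frame) <- "integer"
    stack[, , t] <- frame
  }

  # ground-truth summary metrics
  nw <- 10L
  bleach_tab <- NULL
  if (n > 0L && T_ >= 2L * nw) {
    w1_451 <- rowMeans(true451[, seq_len(nw), drop = FALSE])
    w2_451 <- rowMeans(true451[, (T_ - nw + 1L):T_, drop = FALSE])
    w1_560 <- rowMeans(true560[, seq_len(nw), drop = FALSE])
    w2_560 <- rowMeans(true560[, (T_ - nw + 1L):T_, drop = FALSE])
    orr_t <- true451 / (true451 + true560)
    w1_orr <- rowMeans(orr_t[, seq_len(nw), drop = FALSE])
    w2_orr <- rowMeans(orr_t[, (T_ - nw + 1L):T_, drop = FALSE])
    bleach_tab <- data.frame(
      cell_id = rep(seq_len(n), 3L),
      metric = rep(c("i451", "i560", "orr"), each = n),
      percent_eq2 = 100 * c((w1_451 - w2_451) / w1_451,
                            (w1_560 - w2_560) / w1_560,
                            (w1_orr - w2_orr) / w1_orr))
  }

  rate_net_451 <- rep(NA_real_, max(n, 0L))
  if (config$perturbation == "glucose_bolus" && n > 0L) {
    for (i in seq_len(n)) {
      win <- time_s >= onset[i] & time_s <= onset[i] + 2
      tt <- time_s[win]; yy <- true451[i, win]
      rate_net_451[i] <- sum((tt - mean(tt)) * (yy - mean(yy))) /
        sum((tt - mean(tt))^2)
    }
  }

  meta <- acquisition_meta(config$illumination_mw, config$exposure_ms,
                           config$frame_rate_hz, config$pixel_size_um,
                           config$layout)
  truth <- list(label_mask = labels,
                base_451 = B451, base_560 = B560,
                n_pixels = npix,
                true_trace_451 = true451, true_trace_560 = true560,
                time_s = time_s,
                bleach_rate_451 = k451, bleach_rate_560 = k560,
                true_bleach_percent = bleach_tab,
                true_delay_s = delay,
                true_onset_s = onset,
                true_rate_drawn_au_per_s = rate451,
                true_rate_drawn_560_au_per_s = rate560,
                true_rate_au_per_s = rate_net_451,
                plateau_add = plateau_add,
                cells = cells)
  structure(list(stack = stack, meta = meta, truth = truth, config = config),
            class = "redox_sim")
}

#' @export
print.redox_sim <- function(x, ...) {
  d <- dim(x$stack)
  cat(sprintf("redox_sim: %d cells, %d split frames of %d x %d, perturbation: %s\n",
              x$config$n_cells, d[3], d[1], d[2], x$config$perturbation))
  invisible(x)
}

#' Channel stack of a simulated acquisition
#'
#' Convenience accessor: splits the simulated split-frame stack into a
#' [channel_stack()] exactly as the analysis pipeline would.
#' @param sim a `redox_sim` object.
#' @param register run channel registration (needed only when the simulated
#'   `channel_shift` is nonzero).
#' @inheritParams split_stack
#' @export
sim_channel_stack <- function(sim, register = FALSE, max_shift = 10L) {
  split_stack(sim$stack, sim$meta, register = register, max_shift = max_shift)
}
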