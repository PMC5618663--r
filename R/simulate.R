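#' Acquisition noise model
#'
#' Shot + read noise approximation for an EM-CCD camera: the expected signal
#' is converted to photons with `shot_scale`, Poisson-resampled, converted
#' back, and Gaussian read noise plus a constant camera offset are added:
#' `noisy = Pois(shot_scale * signal) / shot_scale + N(0, read_sigma) + background`.
#' `shot_scale = 0` disables shot noise.
#'
#' @param shot_scale Photons per intensity unit (>= 0).
#' @param read_sigma Additive Gaussian standard deviation (>= 0).
#' @param background Constant camera offset added to every sample.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(shot_scale = 0, read_sigma = 0, background = 0) {
  check_scalar(shot_scale, "shot_scale", lower = 0)
  check_scalar(read_sigma, "read_sigma", lower = 0)
  check_scalar(background, "background")
  structure(list(shot_scale = shot_scale, read_sigma = read_sigma,
                 background = background),
            class = "noise_model")
}

# draw one noisy realisation of expected signal x (uses current RNG stream)
apply_noise <- function(x, noise) {
  out <- x
  if (noise$shot_scale > 0) {
    out <- stats::rpois(length(x), noise$shot_scale * pmax(x, 0)) /
      noise$shot_scale
  }
  if (noise$read_sigma > 0) {
    out <- out + stats::rnorm(length(x), 0, noise$read_sigma)
  }
  out + noise$background
}

#' Ground truth for a synthetic switching experiment
#'
#' Bundles the switching kinetics, the across-cycle population dynamics, the
#' noise model and the mandatory seed that together fully determine a
#' simulated experiment. The same truth and seed always regenerate identical
#' data.
#'
#' @param kinetics A [two_state_kinetics()].
#' @param popdyn A [popdyn_params()].
#' @param noise A [noise_model()]; defaults to noiseless.
#' @param seed Integer seed (mandatory; there is no silent global default).
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(kinetics, popdyn, noise = noise_model(), seed) {
  stopifnot(inherits(kinetics, "two_state_kinetics"),
            inherits(popdyn, "popdyn_params"),
            inherits(noise, "noise_model"))
  if (missing(seed)) stop("`seed` is mandatory in a ground truth", call. = FALSE)
  seed <- check_count(seed, "seed", lower = 0L)
  structure(list(kinetics = kinetics, popdyn = popdyn, noise = noise,
                 seed = seed),
            class = "ground_truth")
}

#' Default study-condition ground truth
#'
#' The reference synthetic conditions used throughout the package's tests
#' and examples, emulating a live-cell 500-cycle fatigue experiment:
#' fast species `k_A = 10/s`, slow species `k_B = 1.2/s` with residual
#' on-fraction `f_B = 0.15`, background 0.02 — both species essentially
#' complete their off-switching within the 2.5 s off half-cycle, as in the
#' high-power experiments this emulates, so the per-cycle baseline reads
#' B's residual plateau. Per-cycle interconversion `k_AB = 0.004`,
#' destruction `k_dA = 0.002`, `k_dB = 0.003`, initial amplitudes
#' `a0 = 1`, `b0 = 0.1`; shot noise at 2000 photons/unit and read noise
#' 0.01. Under these rates species A decays to ~5% of its initial amplitude
#' over 500 cycles while B rises and peaks near cycle 230 before declining
#' — the qualitative signature of interconversion plus photodestruction.
#'
#' @param seed Integer seed.
#' @param noisy If `FALSE`, return the same truth with noise disabled.
#' @return A [ground_truth()].
#' @export
default_truth <- function(seed, noisy = TRUE) {
  ground_truth(
    kinetics = two_state_kinetics(k_A = 10, k_B = 1.2, f_A = 0, f_B = 0.15,
                                  c = 0.02),
    popdyn = popdyn_params(k_AB = 0.004, k_dA = 0.002, k_dB = 0.003,
                           a0 = 1, b0 = 0.1),
    noise = if (noisy) noise_model(shot_scale = 2000, read_sigma = 0.01)
            else noise_model(),
    seed = seed)
}

# expected (noiseless) per-frame signal for one population trace.
# On-switching is complete and instantaneous by default: every on-frame sits
# at the fully recovered level a_n + b_n + c. A finite on-rate (per second)
# ramps each on-block from the level preceding it instead.
expected_signal <- function(schedule, kinetics, amplitudes, on_rate = Inf) {
  sig <- numeric(nrow(schedule))
  for (i in seq_len(nrow(amplitudes))) {
    cyc <- amplitudes$cycle[i]
    a <- amplitudes$a[i]; b <- amplitudes$b[i]
    rows_on <- which(schedule$cycle == cyc & schedule$half_cycle == "on")
    rows_off <- which(schedule$cycle == cyc & schedule$half_cycle == "off")
    full <- a + b + kinetics$c
    sig[rows_off] <- decay_model(schedule$t_half[rows_off], kinetics, a, b)
    if (is.infinite(on_rate)) {
      sig[rows_on] <- full
    } else {
      # split into contiguous on-blocks (leading, and trailing if present)
      blocks <- split(rows_on, cumsum(c(1, diff(rows_on) > 1)))
      for (blk in blocks) {
        start <- if (blk[1] == 1) kinetics$c else sig[blk[1] - 1]
        t_on <- schedule$t_half[blk] - schedule$t_half[blk][1]
        sig[blk] <- full - (full - start) * exp(-on_rate * t_on)
      }
    }
  }
  sig
}

#' Simulate a photoswitching experiment
#'
#' Generates per-frame fluorescence for one or more objects under a
#' switching protocol. Within the off half-cycle of cycle n the expected
#' signal is the two-species decay with amplitudes (a_n, b_n) given by the
#' population closed form evaluated at cycle index n - 1; each violet
#' half-cycle resets the switchable fraction to the on state. Noise is drawn
#' from the truth's seeded generator, so regeneration is byte-identical.
#'
#' @param protocol A [switching_protocol()].
#' @param truth A [ground_truth()].
#' @param n_objects Number of independent objects (colonies/cells) sharing
#'   the same population trace shape.
#' @param intensity_scale Per-object multiplicative brightness, recycled to
#'   `n_objects`.
#' @param on_rate Optional finite on-switching rate (s^-1); `Inf` (default)
#'   models complete, instantaneous on-switching.
#' @return An object of class `switch_experiment`: a list with the protocol,
#'   a tidy `traces` data frame (`frame`, `time_s`, `cycle`, `half_cycle`,
#'   `illumination`, `object_id`, `intensity`), the noiseless `clean` matrix
#'   (frames x objects), the per-cycle `amplitudes`, the normalised
#'   population `mean_trace` with its `normalization_frame_index`, and the
#'   embedded `truth`.
#' @export
simulate_switching <- function(protocol, truth, n_objects = 1L,
                               intensity_scale = 1, on_rate = Inf) {
  stopifnot(inherits(protocol, "switching_protocol"),
            inherits(truth, "ground_truth"))
  n_objects <- check_count(n_objects, "n_objects")
  intensity_scale <- rep_len(intensity_scale, n_objects)
  if (any(!is.finite(intensity_scale)) || any(intensity_scale < 0)) {
    stop("`intensity_scale` must be finite and non-negative", call. = FALSE)
  }
  schedule <- frame_schedule(protocol)
  pops <- population_closed_form(truth$popdyn, seq_len(protocol$n_cycles) - 1)
  amplitudes <- data.frame(cycle = seq_len(protocol$n_cycles),
                           a = pops$a, b = pops$b)
  base <- expected_signal(schedule, truth$kinetics, amplitudes, on_rate)
  clean <- outer(base, intensity_scale)
  noisy <- with_seed(truth$seed, {
    apply(clean, 2, apply_noise, noise = truth$noise)
  })
  noisy <- matrix(noisy, nrow = nrow(clean))
  traces <- data.frame(
    frame = rep(schedule$frame, n_objects),
    time_s = rep(schedule$time_s, n_objects),
    cycle = rep(schedule$cycle, n_objects),
    half_cycle = rep(schedule$half_cycle, n_objects),
    illumination = rep(schedule$illumination, n_objects),
    object_id = rep(seq_len(n_objects), each = nrow(schedule)),
    intensity = as.numeric(noisy),
    stringsAsFactors = FALSE)
  new_switch_experiment(protocol, traces, clean = clean,
                        amplitudes = amplitudes, truth = truth)
}

# shared constructor for simulated and extracted experiments
new_switch_experiment <- function(protocol, traces, clean = NULL,
                                  amplitudes = NULL, truth = NULL,
                                  raw_traces = NULL) {
  schedule <- frame_schedule(protocol)
  nf <- nrow(schedule)
  mat <- matrix(traces$intensity, nrow = nf)
  mean_raw <- rowMeans(mat)
  idx <- normalization_frame(protocol)
  mean_norm <- if (mean_raw[idx] != 0) mean_raw / mean_raw[idx] else mean_raw
  structure(
    list(protocol = protocol, schedule = schedule, traces = traces,
         n_objects = ncol(mat), clean = clean, amplitudes = amplitudes,
         truth = truth, mean_trace_raw = mean_raw, mean_trace = mean_norm,
         normalization_frame_index = idx),
    class = "switch_experiment")
}

#' @export
print.switch_experiment <- function(x, ...) {
  cat(sprintf(
    "Switching experiment: %d frame(s), %d cycle(s), %d object(s)%s\n",
    nrow(x$schedule), x$protocol$n_cycles, x$n_objects,
    if (!is.null(x$truth)) " [synthetic, ground truth embedded]" else ""))
  invisible(x)
}

#' Simulate a thermal (light-independent) recovery trace
#'
#' After complete off-switching the on-state fluorescence relaxes back
#' spontaneously as \eqn{F(t) = F_\infty - (F_\infty - F_0) e^{-k_{th} t}}.
#'
#' @param k_th Thermal recovery rate, s^-1 (>= 0).
#' @param F0 Fluorescence immediately after off-switching.
#' @param Finf Fully recovered fluorescence level.
#' @param duration Total duration, seconds (default 600 = 10 min).
#' @param sampling Sampling interval, seconds (default 30). Must satisfy
#'   `duration >= sampling > 0`; sampling starts at t = 0.
#' @param noise A [noise_model()].
#' @param seed Seed for the noise draws (required when noise is enabled).
#' @return A data frame (`time_s`, `intensity`) with the generating
#'   parameters attached as attribute `"metadata"`.
#' @export
simulate_recovery <- function(k_th, F0, Finf, duration = 600, sampling = 30,
                              noise = noise_model(), seed = NULL) {
  check_scalar(k_th, "k_th", lower = 0)
  check_scalar(F0, "F0")
  check_scalar(Finf, "Finf")
  check_scalar(sampling, "sampling", lower = 0, strict_lower = TRUE)
  check_scalar(duration, "duration", lower = sampling)
  t <- seq(0, duration, by = sampling)
  clean <- Finf - (Finf - F0) * exp(-k_th * t)
  y <- if (noise$shot_scale > 0 || noise$read_sigma > 0 ||
           noise$background != 0) {
    if (is.null(seed)) stop("`seed` is required for noisy traces", call. = FALSE)
    with_seed(seed, apply_noise(clean, noise))
  } else {
    clean
  }
  out <- data.frame(time_s = t, intensity = y)
  attr(out, "metadata") <- list(k_th = k_th, F0 = F0, Finf = Finf,
                                seed = seed)
  out
}

#' Simulate a pH titration table
#'
#' Sigmoidal pH dependence of the anionic-form absorbance,
#' \eqn{A(pH) = A_{max} / (1 + 10^{h (pK_a - pH)})}, with optional Gaussian
#' noise. Noiseless output is monotone non-decreasing in pH for `hill > 0`.
#'
#' @param pKa Midpoint, pH units.
#' @param A_max Saturating absorbance.
#' @param hill Slope (Hill) coefficient.
#' @param pH_grid pH values (default 3 to 11 in steps of 0.5).
#' @param noise_sigma Gaussian noise sd on the absorbance.
#' @param seed Seed, required when `noise_sigma > 0`.
#' @return Data frame (`pH`, `absorbance`).
#' @export
simulate_titration <- function(pKa, A_max = 1, hill = 1,
                               pH_grid = seq(3, 11, by = 0.5),
                               noise_sigma = 0, seed = NULL) {
  check_scalar(pKa, "pKa")
  check_scalar(A_max, "A_max")
  check_scalar(hill, "hill")
  check_scalar(noise_sigma, "noise_sigma", lower = 0)
  if (length(pH_grid) == 0) stop("`pH_grid` must be non-empty", call. = FALSE)
  A <- A_max / (1 + 10^(hill * (pKa - pH_grid)))
  if (noise_sigma > 0) {
    if (is.null(seed)) stop("`seed` is required for noisy titrations", call. = FALSE)
    A <- with_seed(seed, A + stats::rnorm(length(A), 0, noise_sigma))
  }
  data.frame(pH = pH_grid, absorbance = A)
}

#' Disk layout for synthetic colony images
#'
#' Describes circular objects (colonies) on a uniform background. Disks must
#' lie fully within the image and, unless `allow_overlap = TRUE`, must not
#' overlap.
#'
#' @param image_shape Integer (rows, cols) of the rendered frames.
#' @param centers Two-column matrix of (row, col) centres, 0-based pixels.
#' @param radii Disk radii in pixels (> 0), recycled.
#' @param intensity_scale Per-disk brightness multiplier, recycled.
#' @param background_level Constant background intensity.
#' @param allow_overlap Permit overlapping disks.
#' @return An object of class `colony_layout`.
#' @export
colony_layout <- function(image_shape, centers, radii, intensity_scale = 1,
                          background_level = 0, allow_overlap = FALSE) {
  image_shape <- c(check_count(image_shape[1], "image_shape[1]"),
                   check_count(image_shape[2], "image_shape[2]"))
  centers <- matrix(as.numeric(centers), ncol = 2)
  n <- nrow(centers)
  radii <- rep_len(as.numeric(radii), n)
  intensity_scale <- rep_len(as.numeric(intensity_scale), n)
  check_scalar(background_level, "background_level")
  if (n > 0) {
    if (any(radii <= 0)) stop("radii must be positive", call. = FALSE)
    inb <- centers[, 1] - radii >= 0 & centers[, 1] + radii <= image_shape[1] - 1 &
      centers[, 2] - radii >= 0 & centers[, 2] + radii <= image_shape[2] - 1
    if (!all(inb)) stop("all disks must lie within the image bounds", call. = FALSE)
    if (!allow_overlap && n > 1) {
      d <- as.matrix(stats::dist(centers))
      lim <- outer(radii, radii, "+")
      diag(d) <- Inf
      if (any(d <= lim)) stop("disks overlap; set allow_overlap = TRUE to permit",
                              call. = FALSE)
    }
  }
  structure(list(image_shape = image_shape, centers = centers, radii = radii,
                 intensity_scale = intensity_scale,
                 background_level = background_level),
            class = "colony_layout")
}

#' Random non-overlapping colony layout
#'
#' Draws disk centres by rejection sampling and per-disk brightness scales
#' from a log-normal distribution (colony brightness is multiplicative in
#' colony size and expression level, so log-normal scatter is the natural
#' choice).
#'
#' @param n_objects Number of disks.
#' @param image_shape Image (rows, cols).
#' @param radius_range Min/max disk radius, pixels.
#' @param meanlog,sdlog Log-normal parameters of the intensity scales.
#' @param background_level Constant background.
#' @param seed Integer seed.
#' @return A [colony_layout()].
#' @export
random_colony_layout <- function(n_objects, image_shape = c(128L, 128L),
                                 radius_range = c(4, 7), meanlog = 0,
                                 sdlog = 0.4, background_level = 0, seed) {
  n_objects <- check_count(n_objects, "n_objects")
  with_seed(seed, {
    centers <- matrix(NA_real_, 0, 2)
    radii <- numeric(0)
    tries <- 0
    while (nrow(centers) < n_objects && tries < 10000) {
      tries <- tries + 1
      r <- stats::runif(1, radius_range[1], radius_range[2])
      ctr <- c(stats::runif(1, r + 1, image_shape[1] - r - 2),
               stats::runif(1, r + 1, image_shape[2] - r - 2))
      if (nrow(centers) == 0 ||
          all(sqrt(rowSums(sweep(centers, 2, ctr)^2)) > radii + r + 2)) {
        centers <- rbind(centers, ctr)
        radii <- c(radii, r)
      }
    }
    if (nrow(centers) < n_objects) {
      stop("could not place the requested disks without overlap", call. = FALSE)
    }
    scales <- stats::rlnorm(n_objects, meanlog, sdlog)
    colony_layout(image_shape, centers, radii, intensity_scale = scales,
                  background_level = background_level)
  })
}

# binary disk mask for one object (0-based centre coordinates, row-major)
disk_mask <- function(image_shape, center, radius) {
  rows <- matrix(0:(image_shape[1] - 1), image_shape[1], image_shape[2])
  cols <- matrix(0:(image_shape[2] - 1), image_shape[1], image_shape[2],
                 byrow = TRUE)
  (rows - center[1])^2 + (cols - center[2])^2 <= radius^2
}

#' Render a switching experiment as an image stack
#'
#' Each frame is the layout background plus, for every disk, its mask scaled
#' by the disk's `intensity_scale` and that object's trace value at the
#' frame. Per-pixel noise, if any, is drawn from a seeded generator.
#'
#' @param experiment A [simulate_switching()] result (or any
#'   `switch_experiment`) with exactly one trace per layout object.
#' @param layout A [colony_layout()].
#' @param noise A [noise_model()] applied per pixel.
#' @param seed Seed for pixel noise (required when noise is enabled).
#' @return A numeric array (rows x cols x frames) with the layout attached
#'   as attribute `"layout"`.
#' @export
render_colony_stack <- function(experiment, layout, noise = noise_model(),
                                seed = NULL) {
  stopifnot(inherits(experiment, "switch_experiment"),
            inherits(layout, "colony_layout"))
  n_obj <- nrow(layout$centers)
  if (experiment$n_objects != n_obj) {
    stop(sprintf("layout has %d object(s) but the experiment has %d trace(s)",
                 n_obj, experiment$n_objects), call. = FALSE)
  }
  nf <- nrow(experiment$schedule)
  traces <- matrix(experiment$traces$intensity, nrow = nf)
  stack <- array(layout$background_level,
                 dim = c(layout$image_shape[1], layout$image_shape[2], nf))
  if (n_obj > 0) {
    masks <- lapply(seq_len(n_obj), function(i) {
      which(disk_mask(layout$image_shape, layout$centers[i, ], layout$radii[i]))
    })
    npx <- prod(layout$image_shape)
    for (f in seq_len(nf)) {
      frame <- stack[, , f]
      for (i in seq_len(n_obj)) {
        frame[masks[[i]]] <- frame[masks[[i]]] +
          layout$intensity_scale[i] * traces[f, i]
      }
      stack[, , f] <- frame
    }
  }
  if (noise$shot_scale > 0 || noise$read_sigma > 0 || noise$background != 0) {
    if (is.null(seed)) stop("`seed` is required for noisy stacks", call. = FALSE)
    stack <- with_seed(seed, {
      array(apply_noise(as.numeric(stack), noise), dim = dim(stack))
    })
  }
  attr(stack, "layout") <- layout
  stack
}

#' Write / read tidy trace CSV files
#'
#' Traces are exchanged as tidy CSV with columns `frame`, `time_s`, `cycle`,
#' `half_cycle`, `illumination`, `object_id`, `intensity` (UTF-8, comma
#' separated, header row, '.' decimal).
#'
#' @param experiment A `switch_experiment`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(experiment, path) {
  stopifnot(inherits(experiment, "switch_experiment"))
  utils::write.csv(experiment$traces, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @param protocol The protocol the traces were acquired under.
#' @return For `read_traces`, a `switch_experiment`.
#' @export
read_traces <- function(path, protocol) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "time_s", "cycle", "half_cycle", "illumination",
            "object_id", "intensity")
  if (!all(need %in% names(df))) {
    stop("trace CSV is missing required columns", call. = FALSE)
  }
  df <- df[order(df$object_id, df$frame), ]
  if (nrow(df) %% n_frames(protocol) != 0) {
    stop("trace length does not match the protocol frame count", call. = FALSE)
  }
  new_switch_experiment(protocol, df)
}

#' Write / read multi-page TIFF stacks
#'
#' Stacks are stored as grayscale multi-page TIFF. With
#' `bits_per_sample = 16` intensities are scaled by `max_value` into the
#' 16-bit range; 32-bit float storage keeps values as-is.
#'
#' @param stack Array (rows x cols x frames).
#' @param path Output path.
#' @param bits_per_sample 16 (scaled integer, default) or 32 (float).
#' @param max_value Full-scale intensity for 16-bit storage.
#' @return `path` invisibly; `read_stack_tiff` returns the array.
#' @export
write_stack_tiff <- function(stack, path, bits_per_sample = 16,
                             max_value = max(stack, 1)) {
  frames <- lapply(seq_len(dim(stack)[3]), function(f) {
    m <- stack[, , f]
    if (bits_per_sample == 16) pmin(pmax(m / max_value, 0), 1) else m
  })
  tiff::writeTIFF(frames, path, bits.per.sample = bits_per_sample,
                  reduce = TRUE)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path, max_value = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1]])[1], dim(pages[[1]])[2],
                          length(pages)))
  for (f in seq_along(pages)) {
    m <- pages[[f]]
    if (length(dim(m)) == 3) m <- m[, , 1]
    arr[, , f] <- m * max_value
  }
  arr
}
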