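#' Run the photoswitching analysis pipeline
#'
#' Orchestrates simulate -> (render/extract) -> fit-switching ->
#' fit-populations -> fatigue as a reproducible pipeline. The configuration
#' is validated up front (before any stage runs); every run writes the
#' resolved configuration, the package version and a manifest with
#' timestamps, a config hash and per-stage status next to the outputs, so
#' every artifact is regenerable from its manifest. A failing stage leaves
#' the completed artifacts in place and records the failure.
#'
#' Artifacts (all UTF-8, comma-separated, header row, '.' decimal):
#' `traces.csv`, `kinetics.json`, `amplitudes.csv`,
#' `population_params.json`, `fatigue.csv`, `ground_truth.json` (synthetic
#' runs), `resolved_config.json`, `manifest.json`.
#'
#' @param config A named list, or a path to a YAML/JSON file, with entries:
#'   \describe{
#'     \item{seed}{integer, mandatory}
#'     \item{outdir}{output directory, mandatory}
#'     \item{stages}{character subset of `simulate`, `extract`,
#'       `fit_switching`, `fit_populations`, `fatigue`}
#'     \item{protocol}{list of [switching_protocol()] arguments, or one of
#'       the presets `"hela"`/`"colony"` (default `"hela"`)}
#'     \item{n_cycles}{optional override of the preset cycle count}
#'     \item{truth}{for simulation runs: list with `kinetics`, `popdyn`,
#'       `noise` argument lists (defaults to [default_truth()])}
#'     \item{input_tiff}{for extraction from disk: a multi-page TIFF}
#'     \item{fit}{options forwarded to [fit_switching()]}
#'   }
#' @param quiet Suppress stage-level progress messages.
#' @return The run manifest (list), invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.ya?ml$", config)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  cfg <- validate_pipeline_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(cfg$outdir, "resolved_config.json")
  tr <- cfg$truth
  jsonlite::write_json(
    list(seed = cfg$seed, stages = cfg$stages,
         protocol = unclass(cfg$protocol),
         truth = list(kinetics = unclass(tr$kinetics),
                      popdyn = unclass(tr$popdyn),
                      noise = unclass(tr$noise), seed = tr$seed),
         input_tiff = cfg$input_tiff, fit = cfg$fit,
         package_version = as.character(utils::packageVersion("rsfpfit"))),
    cfg_path, auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- list(started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   config_hash = unname(tools::md5sum(cfg_path)),
                   input_hashes = if (!is.null(cfg$input_tiff))
                     as.list(tools::md5sum(cfg$input_tiff)) else list(),
                   stages = list())
  say <- function(...) if (!quiet) message(...)

  state <- list()
  for (stage in cfg$stages) {
    res <- tryCatch({
      say("[rsfpfit] stage: ", stage)
      state <- switch(stage,
        simulate = stage_simulate(cfg, state),
        extract = stage_extract(cfg, state),
        fit_switching = stage_fit_switching(cfg, state, say),
        fit_populations = stage_fit_populations(cfg, state),
        fatigue = stage_fatigue(cfg, state))
      list(status = "ok")
    }, error = function(e) list(status = "failed", error = conditionMessage(e)))
    manifest$stages[[stage]] <- res
    if (res$status == "failed") {
      say("[rsfpfit] stage ", stage, " FAILED: ", res$error)
      break
    }
  }
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

validate_pipeline_config <- function(config) {
  if (!is.list(config)) stop("config must be a list or a YAML/JSON path",
                             call. = FALSE)
  known_stages <- c("simulate", "extract", "fit_switching",
                    "fit_populations", "fatigue")
  if (is.null(config$seed)) stop("config$seed is mandatory", call. = FALSE)
  if (is.null(config$outdir)) stop("config$outdir is mandatory", call. = FALSE)
  stages <- config$stages %||% known_stages[-2]
  bad <- setdiff(stages, known_stages)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "),
                            call. = FALSE)
  proto <- config$protocol %||% "hela"
  if (is.character(proto)) {
    proto <- switch(proto, hela = protocol_hela(config$n_cycles %||% 500L),
                    colony = protocol_colony(),
                    stop("unknown protocol preset: ", proto, call. = FALSE))
  } else if (is.list(proto) && !inherits(proto, "switching_protocol")) {
    proto <- do.call(switching_protocol, proto)
  }
  if ("extract" %in% stages && !("simulate" %in% stages) &&
      is.null(config$input_tiff)) {
    stop("extraction is enabled but no input TIFF (or simulate stage) is configured",
         call. = FALSE)
  }
  if (!is.null(config$input_tiff) && !file.exists(config$input_tiff)) {
    stop("input TIFF does not exist: ", config$input_tiff, call. = FALSE)
  }
  truth <- config$truth
  if (is.null(truth)) {
    truth <- default_truth(seed = config$seed)
  } else if (!inherits(truth, "ground_truth")) {
    truth <- ground_truth(
      kinetics = do.call(two_state_kinetics, truth$kinetics),
      popdyn = do.call(popdyn_params, truth$popdyn),
      noise = do.call(noise_model, truth$noise %||% list()),
      seed = truth$seed %||% config$seed)
  }
  list(seed = check_count(config$seed, "seed", lower = 0L),
       outdir = config$outdir, stages = stages, protocol = proto,
       truth = truth, input_tiff = config$input_tiff,
       fit = config$fit %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_simulate <- function(cfg, state) {
  exp <- simulate_switching(cfg$protocol, cfg$truth)
  write_traces(exp, file.path(cfg$outdir, "traces.csv"))
  tr <- cfg$truth
  jsonlite::write_json(
    list(kinetics = unclass(tr$kinetics), popdyn = unclass(tr$popdyn),
         noise = unclass(tr$noise), seed = tr$seed),
    file.path(cfg$outdir, "ground_truth.json"), auto_unbox = TRUE,
    digits = NA)
  state$experiment <- exp
  state
}

stage_extract <- function(cfg, state) {
  if (!is.null(state$experiment)) return(state)  # traces already in memory
  stack <- read_stack_tiff(cfg$input_tiff)
  ref <- stack[, , normalization_frame(cfg$protocol)]
  objects <- segment_objects(ref, method = "otsu")
  state$experiment <- extract_traces(stack, objects, cfg$protocol)
  write_traces(state$experiment, file.path(cfg$outdir, "traces.csv"))
  state
}

stage_fit_switching <- function(cfg, state, say) {
  if (is.null(state$experiment)) stop("no experiment available; enable simulate or extract")
  fit <- do.call(fit_switching, c(list(state$experiment), cfg$fit))
  say(sprintf("[rsfpfit]   convergence %d after %d iterations, RSS %.4g",
              fit$fit$convergence, fit$fit$iterations, fit$fit$objective))
  k <- fit$kinetics
  jsonlite::write_json(
    list(k_A = k$k_A, k_B = k$k_B, f_A = k$f_A, f_B = k$f_B, c = k$c,
         objective = fit$fit$objective, convergence = fit$fit$convergence,
         weighting = fit$fit$weighting,
         note = "k_dA in population_params.json is the destruction rate of the fast state (elsewhere written kOA)"),
    file.path(cfg$outdir, "kinetics.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(fit$amplitudes, file.path(cfg$outdir, "amplitudes.csv"),
                   row.names = FALSE)
  state$switch_fit <- fit
  state
}

stage_fit_populations <- function(cfg, state) {
  if (is.null(state$switch_fit)) stop("fit_switching must run before fit_populations")
  pfit <- fit_population_dynamics(state$switch_fit)
  p <- pfit$params
  jsonlite::write_json(
    list(k_AB = p$k_AB, k_dA = p$k_dA, k_dB = p$k_dB, a0 = p$a0, b0 = p$b0,
         alpha = pfit$alpha, objective = pfit$fit$objective,
         convergence = pfit$fit$convergence),
    file.path(cfg$outdir, "population_params.json"), auto_unbox = TRUE,
    digits = NA)
  utils::write.csv(pfit$fitted,
                   file.path(cfg$outdir, "population_trajectories.csv"),
                   row.names = FALSE)
  state$popdyn_fit <- pfit
  state
}

stage_fatigue <- function(cfg, state) {
  if (is.null(state$experiment)) stop("no experiment available for fatigue metrics")
  rep <- fatigue_metrics(state$experiment)
  out <- rep$per_cycle
  utils::write.csv(out, file.path(cfg$outdir, "fatigue.csv"),
                   row.names = FALSE)
  state$fatigue <- rep
  state
}

#' Compare constructs across spectroscopy and switching results
#'
#' Builds the free-vs-fusion comparison table: percent changes of the
#' deprotonated-state extinction coefficient, scaled molecular brightness
#' and in-situ brightness readouts (computed with [percent_change()] on the
#' same convention as the reports), plus — when kinetics and population
#' parameters are supplied — off-rate ratios and the observed fold
#' stabilization of the fast species.
#'
#' @param profiles Measured-input table as in [rsgreen_profiles()].
#' @param pairs List of `c(free, fusion)` name pairs; defaults to matching
#'   each `<name>` with `<name>-Enhancer`.
#' @param reference Reference protein for the brightness scale.
#' @param kinetics Optional named list mapping construct names to
#'   `switch_fit` objects (or `two_state_kinetics`).
#' @param popdyn Optional named list mapping construct names to
#'   `popdyn_fit` objects (or [popdyn_params()]).
#' @return Data frame with one row per pair: `free`, `fusion`,
#'   `eon_change_pct`, `brightness_change_pct`, `ecoli_change_pct`,
#'   `hela_change_pct`, and (when available) `k_off_ratio`,
#'   `fold_stabilization`.
#' @export
compare_constructs <- function(profiles, pairs = NULL,
                               reference = "rsGreen1", kinetics = NULL,
                               popdyn = NULL) {
  tab <- spectro_table(profiles, reference = reference)
  if (is.null(pairs)) {
    fusions <- grep("-Enhancer$", tab$name, value = TRUE)
    pairs <- lapply(fusions, function(fu) c(sub("-Enhancer$", "", fu), fu))
  }
  if (length(pairs) < 1) stop("no construct pairs to compare", call. = FALSE)
  get_kin <- function(nm) {
    k <- kinetics[[nm]]
    if (inherits(k, "switch_fit")) k <- k$kinetics
    k
  }
  get_pop <- function(nm) {
    p <- popdyn[[nm]]
    if (inherits(p, "popdyn_fit")) p <- p$params
    p
  }
  rows <- lapply(pairs, function(pr) {
    i <- match(pr[1], tab$name); j <- match(pr[2], tab$name)
    if (is.na(i) || is.na(j)) stop("pair not found in profiles: ",
                                   paste(pr, collapse = " / "), call. = FALSE)
    row <- data.frame(
      free = pr[1], fusion = pr[2],
      eon_change_pct = percent_change(tab$eon[i], tab$eon[j]),
      brightness_change_pct = percent_change(tab$brightness[i],
                                             tab$brightness[j]),
      ecoli_change_pct = if (!is.na(tab$ecoli_brightness[i]))
        percent_change(tab$ecoli_brightness[i], tab$ecoli_brightness[j])
        else NA_real_,
      hela_change_pct = if (!is.na(tab$hela_brightness[i]))
        percent_change(tab$hela_brightness[i], tab$hela_brightness[j])
        else NA_real_,
      stringsAsFactors = FALSE)
    kf <- get_kin(pr[1]); ku <- get_kin(pr[2])
    row$k_off_ratio <- if (!is.null(kf) && !is.null(ku)) ku$k_A / kf$k_A
                       else NA_real_
    pf <- get_pop(pr[1]); pu <- get_pop(pr[2])
    row$fold_stabilization <- if (!is.null(pf) && !is.null(pu)) {
      observed_stabilization(pf, pu)$fold
    } else NA_real_
    row
  })
  do.call(rbind, rows)
}
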