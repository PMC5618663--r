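#' Fit the across-cycle population dynamics
#'
#' Fits the interconversion/photodestruction closed form
#' ([population_closed_form()]) jointly to the per-cycle amplitude
#' trajectories (a_n, b_n) by least squares over
#' `(k_AB, k_dA, k_dB, a0, b0)`, all constrained non-negative.
#' Initialisation: the total A loss rate `alpha = k_AB + k_dA` from a
#' log-linear regression on a_n (split evenly between the two rates),
#' `k_dB` from a log-linear regression on the tail of b_n, and the initial
#' amplitudes from the first cycle.
#'
#' @param amplitudes Data frame with columns `cycle`, `a`, `b` (as produced
#'   by [fit_switching()]), or a `switch_fit` object. Cycle i is mapped to
#'   population clock n = i - 1. At least 5 cycles are required.
#' @param control Optimiser settings (`rel_tol`, `max_iter`).
#' @return An object of class `popdyn_fit`: `params`
#'   ([popdyn_params()]), `alpha`, `fitted` trajectories (including the
#'   fractional share a/(a+b)), `fit` diagnostics.
#' @export
fit_population_dynamics <- function(amplitudes, control = list()) {
  if (inherits(amplitudes, "switch_fit")) amplitudes <- amplitudes$amplitudes
  stopifnot(is.data.frame(amplitudes),
            all(c("cycle", "a", "b") %in% names(amplitudes)))
  if (nrow(amplitudes) < 5) stop("at least 5 cycles are required", call. = FALSE)
  if (all(amplitudes$a == 0) && all(amplitudes$b == 0)) {
    stop("all amplitudes are zero; nothing to fit", call. = FALSE)
  }
  ctrl <- utils::modifyList(list(rel_tol = 1e-12, max_iter = 1000), control)
  n <- amplitudes$cycle - min(amplitudes$cycle)  # population clock
  a <- amplitudes$a
  b <- amplitudes$b
  scale2 <- max(a, b)^2

  # initial values
  pos <- a > max(a) * 1e-6
  alpha0 <- if (sum(pos) >= 2) {
    max(-stats::coef(stats::lm(log(a[pos]) ~ n[pos]))[[2]], 1e-8)
  } else 0.01
  tail_idx <- n >= stats::quantile(n, 2 / 3) & b > max(b) * 1e-6
  kdB0 <- if (sum(tail_idx) >= 2) {
    min(max(-stats::coef(stats::lm(log(b[tail_idx]) ~ n[tail_idx]))[[2]],
            1e-8), 1)
  } else alpha0 / 2
  par0 <- c(k_AB = alpha0 / 2, k_dA = alpha0 / 2, k_dB = kdB0,
            a0 = max(a[1], 1e-8), b0 = max(b[1], 0))

  objfn <- function(p) {
    pp <- popdyn_params(k_AB = p[1], k_dA = p[2], k_dB = p[3],
                        a0 = p[4], b0 = p[5])
    tr <- population_closed_form(pp, n)
    sum((tr$a - a)^2 + (tr$b - b)^2) / scale2
  }
  opt <- stats::nlminb(par0, objfn, lower = rep(0, 5),
                       control = list(rel.tol = ctrl$rel_tol,
                                      iter.max = ctrl$max_iter,
                                      eval.max = 4 * ctrl$max_iter))
  for (pass in 1:3) {
    nm <- stats::optim(pmax(opt$par, 0), function(p) {
      if (any(p < 0)) return(1e10)
      objfn(p)
    }, method = "Nelder-Mead", control = list(maxit = 5000, reltol = 1e-14))
    refit <- stats::nlminb(pmax(nm$par, 0), objfn, lower = rep(0, 5),
                           control = list(rel.tol = ctrl$rel_tol,
                                          iter.max = ctrl$max_iter,
                                          eval.max = 4 * ctrl$max_iter))
    improved <- opt$objective - refit$objective > abs(opt$objective) * 1e-12
    opt <- refit
    if (!improved) break
  }
  if (improved && opt$convergence != 0 && opt$objective > 1e-12) {
    warning("population-dynamics fit did not converge cleanly: ", opt$message)
  }
  pr <- unname(opt$par)
  params <- popdyn_params(k_AB = pr[1], k_dA = pr[2], k_dB = pr[3],
                          a0 = pr[4], b0 = pr[5])
  tr <- population_closed_form(params, n)
  tr$cycle <- amplitudes$cycle
  tot <- tr$a + tr$b
  tr$share_a <- ifelse(tot > 0, tr$a / tot, NA_real_)
  structure(
    list(params = params, alpha = params$k_AB + params$k_dA,
         observed = amplitudes, fitted = tr,
         fit = list(objective = opt$objective * scale2,
                    convergence = opt$convergence,
                    iterations = opt$iterations, message = opt$message,
                    control = ctrl)),
    class = "popdyn_fit")
}

#' @export
print.popdyn_fit <- function(x, ...) {
  cat("Population-dynamics fit (cycle clock):\n")
  print(x$params)
  cat(sprintf("  alpha = k_AB + k_dA = %.4g per cycle; RSS = %.4g\n",
              x$alpha, x$fit$objective))
  invisible(x)
}

#' @export
coef.popdyn_fit <- function(object, ...) {
  p <- object$params
  c(k_AB = p$k_AB, k_dA = p$k_dA, k_dB = p$k_dB, a0 = p$a0, b0 = p$b0)
}

#' @export
predict.popdyn_fit <- function(object, n = NULL, ...) {
  if (is.null(n)) return(object$fitted)
  population_closed_form(object$params, n)
}

#' @export
fitted.popdyn_fit <- function(object, ...) object$fitted

#' @export
residuals.popdyn_fit <- function(object, ...) {
  data.frame(cycle = object$observed$cycle,
             a = object$observed$a - object$fitted$a,
             b = object$observed$b - object$fitted$b)
}

#' @export
plot.popdyn_fit <- function(x, ...) {
  obs <- x$observed
  graphics::matplot(obs$cycle, cbind(obs$a, obs$b), pch = c(1, 2),
                    col = c("red", "blue"), xlab = "switching cycle",
                    ylab = "species amplitude", ...)
  graphics::matlines(x$fitted$cycle, cbind(x$fitted$a, x$fitted$b),
                     lty = 1, col = c("red", "blue"))
  graphics::legend("topright",
                   legend = c("A observed", "B observed", "A fit", "B fit"),
                   col = c("red", "blue", "red", "blue"),
                   pch = c(1, 2, NA, NA), lty = c(NA, NA, 1, 1), bty = "n")
  invisible(x)
}

#' Switching-fatigue metrics per cycle
#'
#' From the population mean trace: per-cycle on-level (maximum on-frame
#' scaled to the initial on-state fluorescence), baseline (minimum
#' off-frame as a fraction of the initial on level), on/off contrast, and
#' the number of cycles until the on-level halves (linear interpolation on
#' the elapsed-cycle axis, so a pure-A decay `a0 e^(-alpha n)` gives
#' `ln 2 / alpha`).
#'
#' @param experiment A `switch_experiment` with at least 2 cycles.
#' @return An object of class `fatigue_report`: data frame `per_cycle`
#'   (`cycle`, `on_level`, `baseline`, `contrast`) plus attributes
#'   `cycles_to_half` and `initial_on`. A zero baseline yields an infinite
#'   contrast flag (`Inf`).
#' @export
fatigue_metrics <- function(experiment) {
  stopifnot(inherits(experiment, "switch_experiment"))
  proto <- experiment$protocol
  if (proto$n_cycles < 2) stop("at least 2 cycles are required", call. = FALSE)
  sched <- experiment$schedule
  y <- experiment$mean_trace_raw
  on_max <- tapply(y[sched$half_cycle == "on"],
                   sched$cycle[sched$half_cycle == "on"], max)
  off_min <- tapply(y[sched$half_cycle == "off"],
                    sched$cycle[sched$half_cycle == "off"], min)
  init <- on_max[[1]]
  if (init == 0) stop("initial on-level is zero", call. = FALSE)
  on_level <- as.numeric(on_max) / init
  baseline <- as.numeric(off_min) / init
  contrast <- ifelse(baseline > 0, on_level / baseline, Inf)
  per_cycle <- data.frame(cycle = as.integer(names(on_max)),
                          on_level = on_level, baseline = baseline,
                          contrast = contrast)
  # first crossing of 0.5 on the elapsed-cycle axis (cycle i -> n = i - 1)
  cth <- NA_real_
  below <- which(on_level <= 0.5)
  if (length(below) > 0) {
    i <- below[1]
    if (i == 1) {
      cth <- 0
    } else {
      cth <- (i - 2) + (on_level[i - 1] - 0.5) / (on_level[i - 1] - on_level[i])
    }
  }
  structure(list(per_cycle = per_cycle, cycles_to_half = cth,
                 initial_on = init),
            class = "fatigue_report")
}

#' @export
print.fatigue_report <- function(x, ...) {
  pc <- x$per_cycle
  n <- nrow(pc)
  cat(sprintf("Fatigue report over %d cycles:\n", n))
  cat(sprintf("  on-level: 1 -> %.3f; baseline: %.4f -> %.4f (peak %.4f at cycle %d)\n",
              pc$on_level[n], pc$baseline[1], pc$baseline[n],
              max(pc$baseline), pc$cycle[which.max(pc$baseline)]))
  cat(sprintf("  cycles to half on-level: %s\n",
              if (is.na(x$cycles_to_half)) "not reached"
              else sprintf("%.1f", x$cycles_to_half)))
  invisible(x)
}

#' Expected stabilization from faster switching alone
#'
#' Faster off-switching limits the photon dose a molecule absorbs per off
#' half-cycle and should therefore reduce photodestruction proportionally.
#' The dose proxy is the integral of the on-population over the off
#' half-cycle, \eqn{D(k) = (1-f)(1 - e^{-kT})/k + f T}; the expected
#' destruction-rate ratio of free over fusion is `D(k_free)/D(k_fusion)`
#' and the expected percent stabilization is `100 (ratio - 1)`.
#'
#' @param k_free,k_fusion Off-switching rates, s^-1 (> 0).
#' @param f Residual on-fraction during off-switching (default 0).
#' @param T_off Off half-cycle duration, seconds (> 0).
#' @return List with `dose_free`, `dose_fusion`, `ratio` and
#'   `percent_stabilization`.
#' @export
expected_stabilization_from_speed <- function(k_free, k_fusion, f = 0,
                                              T_off) {
  check_scalar(k_free, "k_free", lower = 0, strict_lower = TRUE)
  check_scalar(k_fusion, "k_fusion", lower = 0, strict_lower = TRUE)
  check_scalar(f, "f", lower = 0, upper = 1, strict_upper = TRUE)
  check_scalar(T_off, "T_off", lower = 0, strict_lower = TRUE)
  dose <- function(k) (1 - f) * (1 - exp(-k * T_off)) / k + f * T_off
  d_free <- dose(k_free); d_fus <- dose(k_fusion)
  ratio <- d_free / d_fus
  list(dose_free = d_free, dose_fusion = d_fus, ratio = ratio,
       percent_stabilization = 100 * (ratio - 1))
}

#' Observed stabilization of the fast species
#'
#' The fold-reduction in the per-cycle destruction rate of the fast species
#' A upon binder fusion, `k_dA,free / k_dA,fusion`. When the switching
#' rates and off half-cycle duration are supplied, the expected
#' speed-derived stabilization and the residual intrinsic stabilization
#' (observed fold / expected ratio) are reported alongside.
#'
#' @param params_free,params_fusion [popdyn_params()] (or `popdyn_fit`
#'   objects) for the free protein and the fusion.
#' @param k_free,k_fusion,f,T_off Optional inputs forwarded to
#'   [expected_stabilization_from_speed()].
#' @return List with `fold` (Inf flag when the fusion destruction rate is
#'   0), and — when the optional inputs are given — `expected_ratio` and
#'   `intrinsic_fold`.
#' @export
observed_stabilization <- function(params_free, params_fusion,
                                   k_free = NULL, k_fusion = NULL, f = 0,
                                   T_off = NULL) {
  if (inherits(params_free, "popdyn_fit")) params_free <- params_free$params
  if (inherits(params_fusion, "popdyn_fit")) params_fusion <- params_fusion$params
  stopifnot(inherits(params_free, "popdyn_params"),
            inherits(params_fusion, "popdyn_params"))
  fold <- if (params_fusion$k_dA > 0) {
    params_free$k_dA / params_fusion$k_dA
  } else Inf
  out <- list(fold = fold)
  if (!is.null(k_free) && !is.null(k_fusion) && !is.null(T_off)) {
    exp_st <- expected_stabilization_from_speed(k_free, k_fusion, f, T_off)
    out$expected_ratio <- exp_st$ratio
    out$intrinsic_fold <- fold / exp_st$ratio
  }
  out
}
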