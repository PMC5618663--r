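# exact non-negative least squares for two columns: enumerate the active
# sets (both free / a = 0 / b = 0 / both 0) and keep the feasible minimum.
# Vectorised over many right-hand sides sharing one design matrix.
nnls2 <- function(SA, SB, Y) {
  Y <- as.matrix(Y)
  saa <- sum(SA * SA); sbb <- sum(SB * SB); sab <- sum(SA * SB)
  ya <- crossprod(SA, Y)[1, ]   # t(SA) %*% Y per column
  yb <- crossprod(SB, Y)[1, ]
  yy <- colSums(Y * Y)
  det <- saa * sbb - sab * sab
  if (det > .Machine$double.eps * saa * sbb) {
    a_un <- (sbb * ya - sab * yb) / det
    b_un <- (saa * yb - sab * ya) / det
  } else {
    a_un <- rep(-1, length(ya))  # force boundary fallback when collinear
    b_un <- rep(-1, length(ya))
  }
  a_only <- pmax(ya / saa, 0)
  b_only <- pmax(yb / sbb, 0)
  rss_un <- yy - (a_un * ya + b_un * yb)
  rss_a <- yy - 2 * a_only * ya + a_only^2 * saa
  rss_b <- yy - 2 * b_only * yb + b_only^2 * sbb
  use_un <- a_un >= 0 & b_un >= 0
  a <- ifelse(use_un, a_un, ifelse(rss_a <= rss_b, a_only, 0))
  b <- ifelse(use_un, b_un, ifelse(rss_a <= rss_b, 0, b_only))
  rss <- ifelse(use_un, rss_un, pmin(rss_a, rss_b, yy))
  list(a = a, b = b, rss = pmax(rss, 0))
}

# small-sample corrected information criterion from a least-squares fit.
# RSS is floored at the numerical-noise level so that machine-zero residuals
# of nested models compare by parameter count rather than by log of noise.
aicc_rss <- function(rss, n, k_params) {
  scale <- max(rss, .Machine$double.eps)
  p <- k_params + 1  # + residual variance
  floor_rss <- n * (1e-8 * sqrt(scale / n + 1))^2
  rss <- max(rss, floor_rss)
  n * log(rss / n) + 2 * p + 2 * p * (p + 1) / max(n - p - 1, 1)
}

# profiled objective for a single-cycle exponential fit: amplitudes (with
# non-negativity on the species amplitudes) and offset solved linearly.
single_cycle_rss <- function(t, y, ks) {
  n <- length(y)
  X <- cbind(vapply(ks, function(k) exp(-k * t), numeric(n)), 1)
  # offset column free, species amplitudes >= 0: enumerate active sets
  best <- NULL
  combos <- expand.grid(rep(list(c(TRUE, FALSE)), length(ks)))
  for (i in seq_len(nrow(combos))) {
    act <- c(unlist(combos[i, ]), TRUE)
    Xi <- X[, act, drop = FALSE]
    cf <- tryCatch(qr.coef(qr(Xi), y), error = function(e) NULL)
    if (is.null(cf) || anyNA(cf)) next
    full <- numeric(ncol(X)); full[act] <- cf
    if (any(full[seq_along(ks)] < 0)) next
    rss <- sum((y - Xi %*% cf)^2)
    if (is.null(best) || rss < best$rss) best <- list(coefs = full, rss = rss)
  }
  if (is.null(best)) best <- list(coefs = rep(0, ncol(X)), rss = sum(y^2))
  best
}

#' Fit one off-switching decay
#'
#' Fits a single off half-cycle with a mono- or bi-exponential-plus-offset
#' model, \eqn{F(t) = a e^{-k_A t} + b e^{-k_B t} + d}. Rates are optimised
#' by profiled nonlinear least squares: at each candidate rate set the
#' amplitudes (non-negative) and offset are solved by linear least squares.
#' Both model orders are always evaluated and compared by a small-sample
#' corrected information criterion, reproducing the observation that a
#' two-species decay needs at least a bi-exponential fit.
#'
#' @param t Time since the start of off-switching, seconds (>= 8 points).
#' @param y Fluorescence values.
#' @param order Model order to report, 1 or 2.
#' @return An object of class `single_cycle_fit`: `rates` (named `k`, or
#'   `k_A`/`k_B`), `amplitudes`, `offset`, `rss`, `aicc`,
#'   `comparison` (data frame over both orders), `preferred_order` and a
#'   `converged` flag. Non-convergence is flagged, never silent.
#' @export
fit_single_cycle <- function(t, y, order = 2) {
  stopifnot(order %in% c(1, 2))
  if (length(t) < 8) stop("at least 8 points are required in the off half-cycle",
                          call. = FALSE)
  if (length(t) != length(y)) stop("t and y lengths differ", call. = FALSE)
  tspan <- max(t) - min(t)
  if (tspan <= 0) stop("degenerate time axis", call. = FALSE)
  dt <- min(diff(sort(unique(t))))
  lk_lo <- log(0.01 / tspan); lk_hi <- log(20 / dt)

  # order 1: 1-D profiled search over log k
  o1 <- stats::optimize(function(lk) single_cycle_rss(t, y, exp(lk))$rss,
                        interval = c(lk_lo, lk_hi), tol = 1e-10)
  k1 <- exp(o1$minimum)
  s1 <- single_cycle_rss(t, y, k1)

  # order 2: profiled search over (log kA, u), kB = kA * plogis(u)
  init_lk <- log(max(min(k1, exp(lk_hi) / 4), exp(lk_lo) * 4))
  o2 <- stats::optim(c(init_lk + 1, 0), function(p) {
    kA <- exp(p[1]); kB <- kA * stats::plogis(p[2])
    single_cycle_rss(t, y, c(kA, kB))$rss
  }, method = "Nelder-Mead",
  control = list(maxit = 2000, reltol = 1e-12))
  kA <- exp(o2$par[1]); kB <- kA * stats::plogis(o2$par[2])
  s2 <- single_cycle_rss(t, y, c(kA, kB))

  n <- length(y)
  comparison <- data.frame(
    order = c(1, 2),
    rss = c(s1$rss, s2$rss),
    aicc = c(aicc_rss(s1$rss, n, 3), aicc_rss(s2$rss, n, 5)))
  preferred <- comparison$order[which.min(comparison$aicc)]
  if (order == 1) {
    res <- list(order = 1, rates = c(k = k1),
                amplitudes = c(a = s1$coefs[1]), offset = s1$coefs[2],
                rss = s1$rss, aicc = comparison$aicc[1])
    conv <- TRUE
  } else {
    res <- list(order = 2, rates = c(k_A = max(kA, kB), k_B = min(kA, kB)),
                amplitudes = c(a = s2$coefs[1], b = s2$coefs[2]),
                offset = s2$coefs[3], rss = s2$rss,
                aicc = comparison$aicc[2])
    conv <- o2$convergence == 0
  }
  structure(c(res, list(comparison = comparison, preferred_order = preferred,
                        converged = conv)),
            class = "single_cycle_fit")
}

#' @export
print.single_cycle_fit <- function(x, ...) {
  cat(sprintf("Single-cycle fit (order %d%s): %s, RSS = %.4g, AICc prefers order %d\n",
              x$order, if (x$converged) "" else ", NOT CONVERGED",
              paste(sprintf("%s = %.4g", names(x$rates), x$rates),
                    collapse = ", "),
              x$rss, x$preferred_order))
  invisible(x)
}

#' Globally fit repeated off-switching decays with shared kinetics
#'
#' Fits all off half-cycles of a switching experiment jointly with one
#' shared set of two-species kinetics (rates, residual on-fractions and
#' background held constant for all cycles) and free per-cycle non-negative
#' amplitudes (a_n, b_n). The problem is solved by variable projection:
#' given the nonlinear parameters, the per-cycle amplitudes are exact
#' non-negative linear least-squares solutions, so the outer optimiser only
#' searches over `(log k_A, u, logit f_B, c)` with the ordering
#' `k_B = k_A * sigmoid(u)` enforced by construction (no label switching).
#' Initialisation: a mono-exponential fit of the first cycle seeds `k_A`
#' (A dominates early) and of the last cycle seeds `k_B` (B dominates late).
#'
#' @param experiment A `switch_experiment` (simulated or extracted). For
#'   multi-object experiments the population mean trace is fitted.
#' @param order 2 (default, two species) or 1 (single species; `f` is fixed
#'   at 0 when the experiment has a single cycle, where `f` and `c` are
#'   degenerate).
#' @param fit_f_A Also fit a residual on-fraction for species A (default
#'   `FALSE`: A switches off completely).
#' @param control List of optimiser settings: `rel_tol` (default 1e-10) and
#'   `max_iter` (default 500), recorded in the result.
#' @return An object of class `switch_fit`: `kinetics`
#'   ([two_state_kinetics()]), per-cycle `amplitudes` (`cycle`, `a`, `b`),
#'   and `fit` diagnostics (`objective`, `convergence`, `iterations`,
#'   `message`, `control`). A near-degenerate rate pair
#'   (`k_B/k_A > 0.95`) triggers a degeneracy warning.
#' @seealso [fit_single_cycle()], [fit_population_dynamics()]
#' @export
fit_switching <- function(experiment, order = 2, fit_f_A = FALSE,
                          control = list()) {
  stopifnot(inherits(experiment, "switch_experiment"), order %in% c(1, 2))
  ctrl <- utils::modifyList(list(rel_tol = 1e-10, max_iter = 500), control)
  sched <- experiment$schedule
  off <- sched$half_cycle == "off"
  n_cyc <- experiment$protocol$n_cycles
  if (order == 2 && n_cyc < 2) {
    stop("a two-species global fit needs at least 2 cycles; use order = 1",
         call. = FALSE)
  }
  n_off <- experiment$protocol$off_periods
  if (n_off < 4) stop("each off half-cycle needs at least 4 frames", call. = FALSE)
  y <- experiment$mean_trace_raw
  t_off <- sched$t_half[off & sched$cycle == 1]
  Y <- matrix(y[off], nrow = n_off)   # off frames x cycles

  # initialisation from single-cycle fits of the first and last cycles
  f1 <- fit_single_cycle(t_off, Y[, 1], order = 1)
  fL <- fit_single_cycle(t_off, Y[, n_cyc], order = 1)
  kA0 <- max(unname(f1$rates["k"]), 1e-6)
  kB0 <- max(min(unname(fL$rates["k"]), 0.8 * kA0), 0.01 * kA0)
  fB0 <- min(max(min(Y[, n_cyc]) / max(max(Y[, n_cyc]), 1e-12), 0.02), 0.9)
  c0 <- max(min(Y) * 0.5, 0)

  yscale <- length(Y) * max(stats::var(as.numeric(Y)), .Machine$double.eps)
  if (order == 2) {
    par0 <- c(log(kA0), stats::qlogis(kB0 / kA0), stats::qlogis(fB0), c0)
    if (fit_f_A) par0 <- c(par0, stats::qlogis(0.01))
    lower <- replace(rep(-Inf, length(par0)), 4, 0)  # c >= 0
    objfn <- function(p) {
      if (p[4] < 0) return(1e10)
      kA <- exp(p[1]); kB <- kA * stats::plogis(p[2])
      fB <- stats::plogis(p[3]); cc <- p[4]
      fA <- if (fit_f_A) stats::plogis(p[5]) else 0
      SA <- species_decay(t_off, kA, fA)
      SB <- species_decay(t_off, kB, fB)
      sum(nnls2(SA, SB, Y - cc)$rss) / yscale
    }
  } else {
    single_cycle <- n_cyc == 1
    par0 <- c(log(kA0), stats::qlogis(max(fB0, 1e-3)), c0)
    if (single_cycle) par0 <- par0[-2]
    objfn <- function(p) {
      if (p[length(p)] < 0) return(1e10)
      k <- exp(p[1])
      f <- if (single_cycle) 0 else stats::plogis(p[2])
      cc <- p[length(p)]
      S <- species_decay(t_off, k, f)
      # one-species NNLS: project each cycle onto S
      amp <- pmax(crossprod(S, Y - cc)[1, ] / sum(S * S), 0)
      sum((Y - cc - outer(S, amp))^2) / yscale
    }
    lower <- replace(rep(-Inf, length(par0)), length(par0), 0)
  }

  # the profiled surface has long curved valleys; alternate a quasi-Newton
  # bounded pass with Nelder-Mead polish until the objective stalls
  opt <- stats::nlminb(par0, objfn, lower = lower,
                       control = list(rel.tol = ctrl$rel_tol,
                                      iter.max = ctrl$max_iter,
                                      eval.max = 4 * ctrl$max_iter))
  for (pass in 1:3) {
    nm <- stats::optim(opt$par, objfn, method = "Nelder-Mead",
                       control = list(maxit = 5000,
                                      reltol = min(ctrl$rel_tol, 1e-12)))
    refit <- stats::nlminb(nm$par, objfn, lower = lower,
                           control = list(rel.tol = ctrl$rel_tol,
                                          iter.max = ctrl$max_iter,
                                          eval.max = 4 * ctrl$max_iter))
    improved <- opt$objective - refit$objective > abs(opt$objective) * 1e-12
    opt <- refit
    if (!improved) break
  }
  stationary <- !improved  # the polish loop stalled at a stationary point
  p <- unname(opt$par)
  if (order == 2) {
    kA <- exp(p[1]); kB <- kA * stats::plogis(p[2])
    fB <- stats::plogis(p[3]); cc <- p[4]
    fA <- if (fit_f_A) stats::plogis(p[5]) else 0
    if (kB / kA > 0.95) {
      warning("k_A and k_B are nearly equal: species amplitudes are ",
              "rank-deficient (degenerate fit)")
    }
    SA <- species_decay(t_off, kA, fA)
    SB <- species_decay(t_off, kB, fB)
    sol <- nnls2(SA, SB, Y - cc)
    amplitudes <- data.frame(cycle = seq_len(n_cyc), a = sol$a, b = sol$b)
    kin <- two_state_kinetics(k_A = kA, k_B = max(kB, 1e-12), f_A = min(fA, fB),
                              f_B = fB, c = cc)
  } else {
    k <- exp(p[1])
    f <- if (n_cyc == 1) 0 else stats::plogis(p[2])
    cc <- p[length(p)]
    S <- species_decay(t_off, k, f)
    amp <- pmax(crossprod(S, Y - cc)[1, ] / sum(S * S), 0)
    amplitudes <- data.frame(cycle = seq_len(n_cyc), a = amp, b = 0)
    kin <- structure(list(k_A = k, k_B = NA_real_, f_A = f, f_B = NA_real_,
                          c = cc), class = "two_state_kinetics")
  }
  if (!stationary && opt$convergence != 0) {
    warning("global fit did not converge cleanly: ", opt$message)
  }
  structure(
    list(kinetics = kin, amplitudes = amplitudes, order = order,
         t_off = t_off, Y = Y, experiment = experiment,
         fit = list(objective = opt$objective * yscale,
                    convergence = if (stationary) 0L else opt$convergence,
                    iterations = opt$iterations, message = opt$message,
                    control = ctrl, weighting = "unweighted"),
         call = match.call()),
    class = "switch_fit")
}

#' @export
print.switch_fit <- function(x, ...) {
  cat(sprintf("Global %d-species switching fit over %d cycle(s)\n",
              x$order, nrow(x$amplitudes)))
  print(x$kinetics)
  cat(sprintf("  objective (RSS) = %.6g, convergence = %d (%s)\n",
              x$fit$objective, x$fit$convergence, x$fit$message))
  invisible(x)
}

#' @export
coef.switch_fit <- function(object, ...) {
  k <- object$kinetics
  c(k_A = k$k_A, k_B = k$k_B, f_A = k$f_A, f_B = k$f_B, c = k$c)
}

#' @export
summary.switch_fit <- function(object, ...) {
  amp <- object$amplitudes
  structure(list(kinetics = object$kinetics, order = object$order,
                 n_cycles = nrow(amp),
                 amplitude_range = rbind(a = range(amp$a), b = range(amp$b)),
                 fit = object$fit),
            class = "summary.switch_fit")
}

#' @export
print.summary.switch_fit <- function(x, ...) {
  cat(sprintf("Global %d-species switching fit, %d cycles (unweighted LS)\n",
              x$order, x$n_cycles))
  print(x$kinetics)
  cat(sprintf("  amplitude ranges: a in [%.4g, %.4g], b in [%.4g, %.4g]\n",
              x$amplitude_range[1, 1], x$amplitude_range[1, 2],
              x$amplitude_range[2, 1], x$amplitude_range[2, 2]))
  cat(sprintf("  RSS = %.6g after %d iterations (rel tol %.1g)\n",
              x$fit$objective, x$fit$iterations, x$fit$control$rel_tol))
  invisible(x)
}

#' @export
fitted.switch_fit <- function(object, ...) {
  k <- object$kinetics
  vapply(seq_len(nrow(object$amplitudes)), function(i) {
    a <- object$amplitudes$a[i]; b <- object$amplitudes$b[i]
    if (object$order == 2) {
      decay_model(object$t_off, k, a, b)
    } else {
      a * species_decay(object$t_off, k$k_A, k$f_A) + k$c
    }
  }, numeric(length(object$t_off)))
}

#' @export
residuals.switch_fit <- function(object, ...) {
  object$Y - fitted(object)
}

#' Predict off-switching decays from a global fit
#'
#' @param object A `switch_fit`.
#' @param cycles Cycle indices to evaluate (default all fitted cycles).
#' @param t Times within the off half-cycle (default the fitted frame
#'   times).
#' @param ... Unused.
#' @return Matrix of predicted fluorescence, `length(t)` x
#'   `length(cycles)`.
#' @export
predict.switch_fit <- function(object, cycles = NULL, t = NULL, ...) {
  if (is.null(cycles)) cycles <- object$amplitudes$cycle
  if (is.null(t)) t <- object$t_off
  k <- object$kinetics
  out <- vapply(cycles, function(cy) {
    i <- match(cy, object$amplitudes$cycle)
    if (is.na(i)) stop("cycle ", cy, " was not fitted", call. = FALSE)
    a <- object$amplitudes$a[i]; b <- object$amplitudes$b[i]
    if (object$order == 2) decay_model(t, k, a, b)
    else a * species_decay(t, k$k_A, k$f_A) + k$c
  }, numeric(length(t)))
  matrix(out, nrow = length(t),
         dimnames = list(NULL, paste0("cycle", cycles)))
}

#' @export
plot.switch_fit <- function(x, which = c("amplitudes", "decays"), ...) {
  which <- match.arg(which)
  if (which == "amplitudes") {
    amp <- x$amplitudes
    graphics::matplot(amp$cycle, cbind(amp$a, amp$b), type = "l", lty = 1,
                      col = c("red", "blue"), xlab = "switching cycle",
                      ylab = "species amplitude", ...)
    graphics::legend("topright", legend = c("A (fast)", "B (slow)"),
                     col = c("red", "blue"), lty = 1, bty = "n")
  } else {
    sel <- unique(round(seq(1, nrow(x$amplitudes), length.out = 3)))
    obs <- x$Y[, sel, drop = FALSE]
    fitv <- predict(x, cycles = sel)
    graphics::matplot(x$t_off, obs, pch = 1, col = seq_along(sel),
                      xlab = "time in off half-cycle (s)",
                      ylab = "fluorescence", ...)
    graphics::matlines(x$t_off, fitv, lty = 1, col = seq_along(sel))
    graphics::legend("topright", legend = paste("cycle", sel),
                     col = seq_along(sel), lty = 1, bty = "n")
  }
  invisible(x)
}

#' Simulate new experiments from a fitted switching model
#'
#' Regenerates synthetic experiments from the fitted kinetics and per-cycle
#' amplitudes (parametric bootstrap of the measurement): the expected signal
#' is rebuilt from the fit and new noise is drawn per replicate.
#'
#' @param object A `switch_fit` of order 2.
#' @param nsim Number of replicate experiments.
#' @param seed Integer seed.
#' @param noise A [noise_model()] for the replicates.
#' @param ... Unused.
#' @return A list of `switch_experiment` objects of length `nsim`.
#' @export
simulate.switch_fit <- function(object, nsim = 1, seed = 1,
                                noise = noise_model(), ...) {
  stopifnot(object$order == 2)
  proto <- object$experiment$protocol
  sched <- frame_schedule(proto)
  base <- expected_signal(sched, object$kinetics, object$amplitudes)
  lapply(seq_len(nsim), function(i) {
    noisy <- with_seed(seed + i - 1, apply_noise(base, noise))
    df <- data.frame(frame = sched$frame, time_s = sched$time_s,
                     cycle = sched$cycle, half_cycle = sched$half_cycle,
                     illumination = sched$illumination, object_id = 1L,
                     intensity = noisy, stringsAsFactors = FALSE)
    new_switch_experiment(proto, df, clean = matrix(base, ncol = 1))
  })
}

#' Fit a thermal recovery trace
#'
#' Least-squares fit of the spontaneous off-to-on relaxation
#' \eqn{F(t) = F_\infty - (F_\infty - F_0) e^{-k_{th} t}}. A decreasing
#' trace (a positive switcher, or continued off-switching) is flagged but
#' still fitted. An essentially flat trace is returned with `k_th = 0`.
#'
#' @param time Sampling times, seconds (>= 5 samples), or a data frame with
#'   columns `time_s` and `intensity` (as from [simulate_recovery()]).
#' @param intensity Fluorescence values.
#' @param horizon Time at which to report the recovered fraction (defaults
#'   to the last sample).
#' @param F_on Pre-switching on-level; when supplied the recovered fraction
#'   `(F(horizon) - F0) / (F_on - F0)` is reported.
#' @return An object of class `recovery_fit`: `k_th`, `F0`, `Finf`,
#'   `recovered_fraction` (NA without `F_on`), `increasing` flag, `ok` and
#'   the underlying fit.
#' @export
fit_thermal_recovery <- function(time, intensity = NULL, horizon = NULL,
                                 F_on = NULL) {
  if (is.data.frame(time)) {
    intensity <- time$intensity
    time <- time$time_s
  }
  if (length(time) < 5) stop("at least 5 samples are required", call. = FALSE)
  if (is.null(horizon)) horizon <- max(time)
  increasing <- utils::tail(intensity, 1) >= intensity[1]
  if (!increasing) {
    warning("trace decreases over time: not a negative-switcher recovery ",
            "(sign flagged in the result)")
  }
  span <- max(intensity) - min(intensity)
  flat <- span < 1e-10 * max(abs(intensity), 1)
  if (flat) {
    fit <- NULL
    k_th <- 0; F0 <- mean(intensity); Finf <- F0
  } else {
    df <- data.frame(t = time, y = intensity)
    start <- list(k_th = log(2) / max(stats::median(time), 1e-9),
                  F0 = intensity[1], Finf = utils::tail(intensity, 1))
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ Finf - (Finf - F0) * exp(-k_th * t), data = df,
                        start = start, lower = c(0, -Inf, -Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit)) {
      return(structure(list(k_th = NA_real_, F0 = NA_real_, Finf = NA_real_,
                            recovered_fraction = NA_real_,
                            increasing = increasing, ok = FALSE, fit = NULL),
                       class = "recovery_fit"))
    }
    cf <- stats::coef(fit)
    k_th <- unname(cf["k_th"]); F0 <- unname(cf["F0"])
    Finf <- unname(cf["Finf"])
  }
  Fh <- Finf - (Finf - F0) * exp(-k_th * horizon)
  rec <- if (!is.null(F_on) && F_on != F0) (Fh - F0) / (F_on - F0) else NA_real_
  structure(list(k_th = k_th, F0 = F0, Finf = Finf,
                 recovered_fraction = rec, horizon = horizon,
                 increasing = increasing, ok = TRUE, fit = fit),
            class = "recovery_fit")
}

#' @export
print.recovery_fit <- function(x, ...) {
  if (!x$ok) {
    cat("Thermal recovery fit FAILED\n")
    return(invisible(x))
  }
  cat(sprintf("Thermal recovery fit: k_th = %.4g /s (t1/2 = %.3g s), F0 = %.4g, Finf = %.4g%s%s\n",
              x$k_th, if (x$k_th > 0) log(2) / x$k_th else Inf, x$F0, x$Finf,
              if (!is.na(x$recovered_fraction))
                sprintf(", recovered %.1f%% at %gs", 100 * x$recovered_fraction,
                        x$horizon) else "",
              if (!x$increasing) " [decreasing trace!]" else ""))
  invisible(x)
}

#' @export
coef.recovery_fit <- function(object, ...) {
  c(k_th = object$k_th, F0 = object$F0, Finf = object$Finf)
}

#' Decompose an off-switching rate enhancement
#'
#' Splits the fold-increase in off-switching rate between a free protein and
#' its binder fusion into the part explained by increased light absorption
#' (the apparent extinction coefficient at physiological pH, which already
#' contains the pKa effect) and the remaining intrinsic change in switching
#' propensity: total ratio `r = k_fusion/k_free`, absorption factor
#' `rho_abs = eps_fusion/eps_free`, intrinsic factor `rho_int = r/rho_abs`,
#' and the fraction of the enhancement attributed to absorption,
#' `(rho_abs - 1)/(r - 1)`.
#'
#' @param k_free,k_fusion Off-switching rates of the free protein and the
#'   fusion (same illumination), s^-1.
#' @param eps_free,eps_fusion Apparent extinction coefficients at the
#'   off-switching wavelength and measurement pH.
#' @return List with `total_ratio`, `absorption_factor`,
#'   `intrinsic_factor` and `attributed_fraction` (NA with a note when the
#'   total ratio is exactly 1).
#' @export
decompose_rate_enhancement <- function(k_free, k_fusion, eps_free,
                                       eps_fusion) {
  for (nm in c("k_free", "k_fusion", "eps_free", "eps_fusion")) {
    check_scalar(get(nm), nm, lower = 0, strict_lower = TRUE)
  }
  r <- k_fusion / k_free
  rho_abs <- eps_fusion / eps_free
  rho_int <- r / rho_abs
  attributed <- if (r == 1) NA_real_ else (rho_abs - 1) / (r - 1)
  list(total_ratio = r, absorption_factor = rho_abs,
       intrinsic_factor = rho_int, attributed_fraction = attributed,
       note = if (r == 1) "no rate change: attributed fraction undefined"
              else NULL)
}
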