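#' Two-emissive-species off-switching kinetics
#'
#' Parameter container for the shared photoswitching kinetics of the fast
#' (A) and slow (B) emissive species of an RSFP. Under off-switching light
#' each species decays mono-exponentially towards its own residual on
#' fraction, so a cycle with amplitudes (a, b) follows
#' \deqn{F(t) = a[(1-f_A)e^{-k_A t} + f_A] + b[(1-f_B)e^{-k_B t} + f_B] + c.}
#'
#' @param k_A Off-switching rate of the fast species A, s^-1.
#' @param k_B Off-switching rate of the slow species B, s^-1. Must satisfy
#'   `k_A > k_B > 0` (identifiability ordering).
#' @param f_A Residual on-fraction of species A (usually 0: A switches off
#'   completely).
#' @param f_B Residual on-fraction of species B; B does not switch fully to
#'   the dark state, which is what makes the baseline rise as B accumulates.
#'   Must satisfy `0 <= f_A <= f_B < 1`.
#' @param c Constant background offset (shared across cycles), `>= 0`.
#' @return An object of class `two_state_kinetics`.
#' @export
two_state_kinetics <- function(k_A, k_B, f_A = 0, f_B = 0, c = 0) {
  check_scalar(k_A, "k_A", lower = 0, strict_lower = TRUE)
  check_scalar(k_B, "k_B", lower = 0, strict_lower = TRUE)
  if (k_A <= k_B) stop("k_A must exceed k_B (A is the fast species)", call. = FALSE)
  check_scalar(f_A, "f_A", lower = 0, upper = 1, strict_upper = TRUE)
  check_scalar(f_B, "f_B", lower = 0, upper = 1, strict_upper = TRUE)
  if (f_A > f_B) stop("f_A must not exceed f_B", call. = FALSE)
  check_scalar(c, "c", lower = 0)
  structure(list(k_A = k_A, k_B = k_B, f_A = f_A, f_B = f_B, c = c),
            class = "two_state_kinetics")
}

#' @export
print.two_state_kinetics <- function(x, ...) {
  cat(sprintf(
    "Two-species switching kinetics:\n  k_A = %.4g /s, k_B = %.4g /s, f_A = %.4g, f_B = %.4g, c = %.4g\n",
    x$k_A, x$k_B, x$f_A, x$f_B, x$c))
  invisible(x)
}

# single-species off-switching decay shape, normalised to 1 at t = 0
species_decay <- function(t, k, f) (1 - f) * exp(-k * t) + f

#' Two-species off-switching decay
#'
#' Evaluates the bi-exponential-plus-plateau decay of a single off-switching
#' half-cycle with species amplitudes `a` and `b`.
#'
#' @param t Time since the start of off-switching, seconds (vectorised).
#' @param kinetics A [two_state_kinetics()].
#' @param a,b Non-negative amplitudes of species A and B.
#' @return Fluorescence values, same length as `t`.
#' @export
#' @examples
#' k <- two_state_kinetics(k_A = 2, k_B = 0.2, f_B = 0.3)
#' decay_model(0, k, a = 1, b = 1)        # a + b + c
#' decay_model(1e6, k, a = 1, b = 1)      # plateau a*f_A + b*f_B + c
decay_model <- function(t, kinetics, a, b) {
  stopifnot(inherits(kinetics, "two_state_kinetics"))
  if (any(t < 0)) stop("`t` must be non-negative", call. = FALSE)
  check_scalar(a, "a", lower = 0)
  check_scalar(b, "b", lower = 0)
  a * species_decay(t, kinetics$k_A, kinetics$f_A) +
    b * species_decay(t, kinetics$k_B, kinetics$f_B) +
    kinetics$c
}

#' Interconversion/photodestruction parameters
#'
#' Per-cycle rates of the population dynamics coupling the two emissive
#' species across switching cycles: light-driven conversion A -> B and
#' photodestruction of each species. The cycle index is the clock, so all
#' rates are dimensionless per-cycle rates.
#'
#' @param k_AB Interconversion rate A -> B, per cycle.
#' @param k_dA Photodestruction rate of A (the fast state), per cycle.
#' @param k_dB Photodestruction rate of B, per cycle.
#' @param a0,b0 Initial amplitudes of A and B (at cycle index n = 0, i.e.
#'   the first cycle).
#' @param k_BA Back-conversion rate B -> A; the minimal model that
#'   reproduces the observed rise-then-fall of species B has none, so the
#'   default is 0. A nonzero value is honoured by the generator via
#'   numerically exact matrix exponentiation of the 2x2 rate matrix.
#' @return An object of class `popdyn_params`.
#' @export
popdyn_params <- function(k_AB, k_dA, k_dB, a0, b0, k_BA = 0) {
  for (nm in c("k_AB", "k_dA", "k_dB", "a0", "b0", "k_BA")) {
    check_scalar(get(nm), nm, lower = 0)
  }
  structure(list(k_AB = k_AB, k_dA = k_dA, k_dB = k_dB,
                 a0 = a0, b0 = b0, k_BA = k_BA),
            class = "popdyn_params")
}

#' @export
print.popdyn_params <- function(x, ...) {
  cat(sprintf(
    "Population dynamics (per-cycle rates):\n  k_AB = %.4g, k_dA = %.4g, k_dB = %.4g, a0 = %.4g, b0 = %.4g%s\n",
    x$k_AB, x$k_dA, x$k_dB, x$a0, x$b0,
    if (x$k_BA > 0) sprintf(", k_BA = %.4g", x$k_BA) else ""))
  invisible(x)
}

#' Closed-form species amplitudes across cycles
#'
#' Solves the two coupled rate equations
#' \deqn{da/dn = -(k_{AB} + k_{dA})\,a, \qquad db/dn = k_{AB}\,a - k_{dB}\,b}
#' analytically. With \eqn{\alpha = k_{AB} + k_{dA}}:
#' \deqn{a(n) = a_0 e^{-\alpha n}}
#' \deqn{b(n) = b_0 e^{-k_{dB} n} + a_0 k_{AB}
#'   \frac{e^{-k_{dB} n} - e^{-\alpha n}}{\alpha - k_{dB}},}
#' with the analytic limit \eqn{a_0 k_{AB}\, n\, e^{-\alpha n}} used when
#' \eqn{|\alpha - k_{dB}| < 10^{-9}} to avoid catastrophic cancellation.
#' If `k_BA > 0` the closed form above no longer applies and the solution is
#' obtained by eigen-decomposition of the 2x2 rate matrix instead.
#'
#' @param params A [popdyn_params()].
#' @param n Cycle index (0-based; vectorised), `n >= 0`. Need not be integer.
#' @return A data frame with columns `n`, `a`, `b`.
#' @export
population_closed_form <- function(params, n) {
  stopifnot(inherits(params, "popdyn_params"))
  if (any(n < 0)) stop("`n` must be non-negative", call. = FALSE)
  if (params$k_BA > 0) {
    return(population_matrix_exp(params, n))
  }
  alpha <- params$k_AB + params$k_dA
  a <- params$a0 * exp(-alpha * n)
  if (abs(alpha - params$k_dB) < 1e-9) {
    transfer <- params$a0 * params$k_AB * n * exp(-alpha * n)
  } else {
    transfer <- params$a0 * params$k_AB *
      (exp(-params$k_dB * n) - exp(-alpha * n)) / (alpha - params$k_dB)
  }
  b <- params$b0 * exp(-params$k_dB * n) + transfer
  data.frame(n = n, a = a, b = pmax(b, 0))
}

# general linear two-state solution via eigen-decomposition (k_BA > 0 path)
population_matrix_exp <- function(params, n) {
  M <- matrix(c(-(params$k_AB + params$k_dA), params$k_AB,
                params$k_BA, -(params$k_BA + params$k_dB)), 2, 2)
  eig <- eigen(M)
  V <- eig$vectors
  coefs <- solve(V, c(params$a0, params$b0))
  out <- vapply(n, function(ni) {
    as.numeric(V %*% (coefs * exp(eig$values * ni)))
  }, numeric(2))
  data.frame(n = n, a = pmax(Re(out[1, ]), 0), b = pmax(Re(out[2, ]), 0))
}

#' Cycle index at which the B population peaks
#'
#' For `b0 = 0`, `k_AB > 0` and distinct rates the transfer term peaks at
#' \eqn{n^* = \ln(\alpha / k_{dB}) / (\alpha - k_{dB})}.
#'
#' @param params A [popdyn_params()].
#' @return Peak cycle index (numeric), or `NA` if B never peaks
#'   (no interconversion).
#' @export
b_peak_cycle <- function(params) {
  stopifnot(inherits(params, "popdyn_params"))
  alpha <- params$k_AB + params$k_dA
  if (params$k_AB <= 0) return(NA_real_)
  if (abs(alpha - params$k_dB) < 1e-9) return(1 / alpha)
  log(alpha / params$k_dB) / (alpha - params$k_dB)
}
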