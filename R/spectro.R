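#' Fit a sigmoid pKa titration curve
#'
#' Least-squares fit of the four-parameter sigmoid
#' \deqn{A(pH) = A_{min} + (A_{max} - A_{min}) / (1 + 10^{h (pK_a - pH)})}
#' to (pH, absorbance) pairs. The pKa is the inflection point of the fitted
#' curve; the slope (Hill) coefficient is a free parameter initialised at 1.
#' Degenerate data — absorbance already saturated (or flat) over the whole
#' pH range, or an optimizer failure — yield a result flagged `ok = FALSE`
#' rather than a silently extrapolated pKa.
#'
#' @param pH Numeric vector of pH values, or a data frame with columns
#'   `pH` and `absorbance` (as produced by [simulate_titration()]).
#' @param absorbance Absorbance values (ignored when `pH` is a data frame).
#' @param span_tol Minimum relative span `(max - min)/max` of the absorbance
#'   below which the data are declared non-sigmoidal.
#' @return An object of class `pka_fit` with elements `pKa`, `hill`,
#'   `A_max`, `A_min`, `residual_norm`, `ok`, `message` and the underlying
#'   `nls` fit.
#' @export
#' @examples
#' tt <- simulate_titration(pKa = 6.2)
#' fit_pka(tt)
fit_pka <- function(pH, absorbance = NULL, span_tol = 0.1) {
  if (is.data.frame(pH)) {
    absorbance <- pH$absorbance
    pH <- pH$pH
  }
  if (length(pH) < 5) {
    stop("at least 5 titration points are required", call. = FALSE)
  }
  fail <- function(msg) {
    structure(list(pKa = NA_real_, hill = NA_real_, A_max = max(absorbance),
                   A_min = min(absorbance), residual_norm = NA_real_,
                   ok = FALSE, message = msg, fit = NULL),
              class = "pka_fit")
  }
  span <- max(absorbance) - min(absorbance)
  if (max(abs(absorbance)) == 0 || span / max(abs(absorbance)) < span_tol) {
    return(fail("absorbance is flat/saturated over the pH range; no sigmoid transition"))
  }
  mid <- min(absorbance) + span / 2
  start <- list(A_min = min(absorbance), A_max = max(absorbance),
                pKa = pH[which.min(abs(absorbance - mid))], hill = 1)
  df <- data.frame(pH = pH, A = absorbance)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      A ~ A_min + (A_max - A_min) / (1 + 10^(hill * (pKa - pH))),
      data = df, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail("nonlinear least squares failed to converge"))
  cf <- stats::coef(fit)
  if (cf[["pKa"]] < min(pH) || cf[["pKa"]] > max(pH)) {
    return(fail("fitted inflection point lies outside the titration range"))
  }
  structure(list(pKa = unname(cf["pKa"]), hill = unname(cf["hill"]),
                 A_max = unname(cf["A_max"]), A_min = unname(cf["A_min"]),
                 residual_norm = sqrt(sum(stats::resid(fit)^2)),
                 ok = TRUE, message = "converged", fit = fit),
            class = "pka_fit")
}

#' @export
print.pka_fit <- function(x, ...) {
  if (x$ok) {
    cat(sprintf("pKa titration fit: pKa = %.3f, hill = %.3f (A: %.3g-%.3g, ||r|| = %.3g)\n",
                x$pKa, x$hill, x$A_min, x$A_max, x$residual_norm))
  } else {
    cat("pKa titration fit FAILED:", x$message, "\n")
  }
  invisible(x)
}

#' @export
coef.pka_fit <- function(object, ...) {
  c(pKa = object$pKa, hill = object$hill, A_max = object$A_max,
    A_min = object$A_min)
}

#' @export
predict.pka_fit <- function(object, newdata = NULL, ...) {
  if (!object$ok) stop("cannot predict from a failed pKa fit", call. = FALSE)
  pH <- if (is.null(newdata)) stats::fitted(object$fit) else NULL
  if (!is.null(pH)) return(as.numeric(pH))
  pH <- if (is.data.frame(newdata)) newdata$pH else newdata
  object$A_min + (object$A_max - object$A_min) /
    (1 + 10^(object$hill * (object$pKa - pH)))
}

#' Extrapolate an extinction coefficient to the deprotonated chromophore
#'
#' The extinction coefficient apparent at a given pH reflects only the
#' anionic (absorbing) fraction of the chromophore. Dividing by the
#' Henderson-Hasselbalch anionic occupancy recovers the coefficient of the
#' fully deprotonated (on) form:
#' \deqn{\varepsilon_{on} = \varepsilon_{pH} (1 + 10^{pK_a - pH}).}
#'
#' @param eps74 Measured extinction coefficient at `pH`, L mol^-1 cm^-1.
#' @param pKa Chromophore pKa.
#' @param pH pH of the measurement (default physiological 7.4).
#' @return Extinction coefficient of the deprotonated state.
#' @export
#' @examples
#' extrapolate_eon(65e3, 6.2)   # ~69e3
extrapolate_eon <- function(eps74, pKa, pH = 7.4) {
  check_scalar(eps74, "eps74", lower = 0, strict_lower = TRUE)
  check_scalar(pKa, "pKa")
  check_scalar(pH, "pH")
  eps74 * (1 + 10^(pKa - pH))
}

#' Extinction coefficient by Ward's method
#'
#' The native-state extinction coefficient follows from the absorbance ratio
#' of the native protein at its excitation peak to the alkali-denatured
#' chromophore at the reference wavelength, times the known denatured
#' chromophore extinction coefficient — the unknown protein concentration
#' cancels in the ratio.
#'
#' @param A_native Absorbance of the native protein at its excitation peak.
#' @param A_denatured Absorbance of the denatured sample at the reference
#'   wavelength (> 0).
#' @param eps_reference Reference extinction coefficient, L mol^-1 cm^-1.
#' @return Apparent extinction coefficient.
#' @export
extinction_wards <- function(A_native, A_denatured, eps_reference) {
  check_scalar(A_native, "A_native", lower = 0, strict_lower = TRUE)
  if (!is.numeric(A_denatured) || length(A_denatured) != 1L ||
      !is.finite(A_denatured) || A_denatured <= 0) {
    stop("`A_denatured` must be positive", call. = FALSE)
  }
  check_scalar(eps_reference, "eps_reference", lower = 0, strict_lower = TRUE)
  eps_reference * A_native / A_denatured
}

#' Relative fluorescence quantum yield
#'
#' Quantum yield relative to a reference fluorophore measured under
#' identical conditions:
#' \deqn{\Phi = \Phi_{ref} (I / I_{ref}) (A_{ref} / A).}
#' Absorbances should be in the optically thin regime (< 0.1); larger
#' values trigger a warning, as do physically invalid results above 1.
#'
#' @param I_sample,I_reference Integrated emission of sample and reference.
#' @param A_sample,A_reference Absorbance at the excitation wavelength.
#' @param phi_reference Reference quantum yield (default 0.60, EGFP).
#' @return Quantum yield of the sample.
#' @export
relative_quantum_yield <- function(I_sample, I_reference, A_sample,
                                   A_reference, phi_reference = 0.60) {
  check_scalar(I_sample, "I_sample", lower = 0)
  check_scalar(phi_reference, "phi_reference", lower = 0, upper = 1)
  if (I_reference <= 0) stop("reference emission must be positive", call. = FALSE)
  if (A_sample <= 0 || A_reference <= 0) {
    stop("absorbances must be positive", call. = FALSE)
  }
  if (A_sample > 0.1 || A_reference > 0.1) {
    warning("absorbance above 0.1: outside the optically thin regime, ",
            "inner-filter effects may bias the quantum yield")
  }
  phi <- phi_reference * (I_sample / I_reference) * (A_reference / A_sample)
  if (phi > 1) {
    warning(sprintf("computed quantum yield %.3f exceeds 1: physically invalid",
                    phi))
  }
  phi
}

#' Scaled molecular brightness
#'
#' Molecular brightness is the product of the apparent extinction
#' coefficient and the fluorescence quantum yield, rescaled so that the
#' reference protein scores 100 and rounded half-away-from-zero to integers.
#'
#' @param profiles Data frame with columns `name`, `eps74` and `phi_fl`.
#' @param reference Name of the reference protein (must appear in
#'   `profiles`).
#' @return Named numeric vector of integer scaled brightness values.
#' @export
molecular_brightness <- function(profiles, reference = "rsGreen1") {
  stopifnot(is.data.frame(profiles),
            all(c("name", "eps74", "phi_fl") %in% names(profiles)))
  ref <- match(reference, profiles$name)
  if (is.na(ref)) stop("reference protein not found in profiles", call. = FALSE)
  ref_bright <- profiles$eps74[ref] * profiles$phi_fl[ref]
  if (ref_bright == 0) stop("reference brightness is zero", call. = FALSE)
  out <- round_half_out(100 * profiles$eps74 * profiles$phi_fl / ref_bright)
  stats::setNames(out, profiles$name)
}

#' Signed integer percent change
#'
#' `100 * (new - reference) / reference`, rounded half-away-from-zero to a
#' signed integer percent.
#'
#' @param reference Reference value (> 0), vectorised.
#' @param new New value, vectorised.
#' @return Signed integer percent(s).
#' @export
#' @examples
#' percent_change(100, 57)   # -43
percent_change <- function(reference, new) {
  if (any(!is.finite(reference)) || any(reference == 0)) {
    stop("`reference` must be finite and nonzero", call. = FALSE)
  }
  round_half_out(100 * (new - reference) / reference)
}

#' Spectroscopic property table
#'
#' Runs the full spectroscopic pipeline on a table of measured inputs
#' (pKa, quantum yield, apparent extinction coefficient): extrapolates each
#' extinction coefficient to the deprotonated state and computes scaled
#' molecular brightness. Extinction coefficients are carried in
#' L mol^-1 cm^-1 and additionally reported in units of 10^3 rounded to
#' integers for a compact report.
#'
#' @param profiles Data frame with columns `name`, `pKa`, `phi_fl`, `eps74`
#'   (see [rsgreen_profiles()] for the packaged measurement table).
#' @param reference Reference protein for the brightness scale.
#' @param pH Measurement pH used for the extrapolation.
#' @return `profiles` with added columns `eon` (exact), `eps74_1e3`,
#'   `eon_1e3` (integer-rounded, 10^3 units) and `brightness`.
#' @export
spectro_table <- function(profiles, reference = "rsGreen1", pH = 7.4) {
  stopifnot(is.data.frame(profiles),
            all(c("name", "pKa", "phi_fl", "eps74") %in% names(profiles)))
  profiles$eon <- mapply(extrapolate_eon, profiles$eps74, profiles$pKa,
                         MoreArgs = list(pH = pH))
  profiles$eps74_1e3 <- round_half_out(profiles$eps74 / 1e3)
  profiles$eon_1e3 <- round_half_out(profiles$eon / 1e3)
  profiles$brightness <- as.numeric(molecular_brightness(profiles, reference))
  profiles
}
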