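#' Define an on/off illumination schedule
#'
#' A switching protocol describes the repeated illumination cycle of a
#' negative-switching RSFP experiment: each cycle consists of a block of
#' on-switching periods (violet light) followed by a block of off-switching
#' periods (cyan light), with one camera frame recorded per period. An
#' optional trailing on-block supports the colony scheme (on/off/on within
#' a single cycle).
#'
#' @param n_cycles Number of switching cycles.
#' @param on_periods Number of on-switching periods per cycle.
#' @param off_periods Number of off-switching periods per cycle.
#' @param period_duration Duration of one period, seconds.
#' @param frame_exposure Camera exposure per frame, seconds. Defaults to the
#'   period duration; only recorded as metadata.
#' @param trailing_on_periods Extra on-switching periods appended after the
#'   off-block of each cycle (0 for the plain on/off scheme).
#' @return An object of class `switching_protocol`.
#' @seealso [protocol_hela()], [protocol_colony()] for the two standard
#'   study protocols; [frame_schedule()] for the per-frame expansion.
#' @export
switching_protocol <- function(n_cycles, on_periods, off_periods,
                               period_duration, frame_exposure = period_duration,
                               trailing_on_periods = 0L) {
  n_cycles <- check_count(n_cycles, "n_cycles")
  on_periods <- check_count(on_periods, "on_periods")
  off_periods <- check_count(off_periods, "off_periods")
  trailing_on_periods <- check_count(trailing_on_periods, "trailing_on_periods",
                                     lower = 0L)
  check_scalar(period_duration, "period_duration", lower = 0, strict_lower = TRUE)
  check_scalar(frame_exposure, "frame_exposure", lower = 0, strict_lower = TRUE)
  structure(
    list(n_cycles = n_cycles, on_periods = on_periods,
         off_periods = off_periods, period_duration = period_duration,
         frame_exposure = frame_exposure,
         trailing_on_periods = trailing_on_periods),
    class = "switching_protocol")
}

#' @export
print.switching_protocol <- function(x, ...) {
  cat(sprintf(
    "Switching protocol: %d cycle(s) of %d on + %d off%s periods of %g s (%d frames)\n",
    x$n_cycles, x$on_periods, x$off_periods,
    if (x$trailing_on_periods > 0) sprintf(" + %d trailing on", x$trailing_on_periods) else "",
    x$period_duration, n_frames(x)))
  invisible(x)
}

#' Total number of frames implied by a protocol
#' @param protocol A [switching_protocol()].
#' @return Integer frame count.
#' @export
n_frames <- function(protocol) {
  stopifnot(inherits(protocol, "switching_protocol"))
  protocol$n_cycles *
    (protocol$on_periods + protocol$off_periods + protocol$trailing_on_periods)
}

#' High-power live-cell switching protocol
#'
#' 25 periods of violet on-switching followed by 25 periods of cyan
#' off-switching, each period 100 ms, repeated for `n_cycles` cycles —
#' the repeated-switching scheme used for cultured mammalian cells.
#'
#' @param n_cycles Number of cycles (500 for the full fatigue experiment).
#' @return A [switching_protocol()].
#' @export
protocol_hela <- function(n_cycles = 500L) {
  switching_protocol(n_cycles = n_cycles, on_periods = 25L, off_periods = 25L,
                     period_duration = 0.1, frame_exposure = 0.05)
}

#' Colony-plate switching protocol
#'
#' One full cycle of 20 on-switching, 40 off-switching and again 20
#' on-switching periods, each lasting 30 s — the growth-plate scheme.
#'
#' @return A [switching_protocol()].
#' @export
protocol_colony <- function() {
  switching_protocol(n_cycles = 1L, on_periods = 20L, off_periods = 40L,
                     period_duration = 30, frame_exposure = 0.5,
                     trailing_on_periods = 20L)
}

#' Per-frame expansion of a switching protocol
#'
#' Expands a protocol into one row per recorded frame. Frames are exposed at
#' the start of each period, so the global time of frame k is
#' `(k - 1) * period_duration` and the first off-frame of every cycle sits at
#' off-time 0 (i.e. still at the fully on-switched level).
#'
#' @param protocol A [switching_protocol()].
#' @return A data frame with columns `frame`, `time_s`, `cycle`,
#'   `half_cycle` ("on"/"off"), `period` (1-based index within the
#'   half-cycle; trailing on-periods continue the on count),
#'   `t_half` (seconds since the start of the half-cycle) and
#'   `illumination` ("violet"/"cyan").
#' @export
frame_schedule <- function(protocol) {
  stopifnot(inherits(protocol, "switching_protocol"))
  per_cycle <- protocol$on_periods + protocol$off_periods +
    protocol$trailing_on_periods
  half <- c(rep("on", protocol$on_periods), rep("off", protocol$off_periods),
            rep("on", protocol$trailing_on_periods))
  period <- c(seq_len(protocol$on_periods), seq_len(protocol$off_periods),
              if (protocol$trailing_on_periods > 0)
                protocol$on_periods + seq_len(protocol$trailing_on_periods))
  t_half <- (c(seq_len(protocol$on_periods), seq_len(protocol$off_periods),
               if (protocol$trailing_on_periods > 0)
                 seq_len(protocol$trailing_on_periods)) - 1) *
    protocol$period_duration
  frame <- seq_len(protocol$n_cycles * per_cycle)
  data.frame(
    frame = frame,
    time_s = (frame - 1) * protocol$period_duration,
    cycle = rep(seq_len(protocol$n_cycles), each = per_cycle),
    half_cycle = rep(half, protocol$n_cycles),
    period = rep(period, protocol$n_cycles),
    t_half = rep(t_half, protocol$n_cycles),
    illumination = rep(ifelse(half == "on", "violet", "cyan"),
                       protocol$n_cycles),
    stringsAsFactors = FALSE)
}

#' Frame index of complete on-switching
#'
#' The last frame of the first on-illumination block: the point at which the
#' switchable population is fully in the on state for the first time. Mean
#' traces are normalised to this frame.
#'
#' @param protocol A [switching_protocol()].
#' @return Integer frame index.
#' @export
normalization_frame <- function(protocol) {
  stopifnot(inherits(protocol, "switching_protocol"))
  protocol$on_periods
}
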