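#' Stimulation waveform specification
#'
#' Parameterizes an unscaled stimulation waveform on the simulation time
#' grid. Supported modes:
#' * `MONOPHASIC_PULSE_TRAIN` — rectangular pulses of width `pw` each
#'   period;
#' * `BIPHASIC_PULSE_TRAIN` — symmetric first-then-reversed phases of
#'   width `pw` each, with an optional interphase `gap`;
#' * `BIPHASIC_FULL_DUTY` — a 50/50 square wave at `frequency` kHz with no
#'   inter-pulse interval (the kilohertz block waveform);
#' * `CUSTOM` — samples from a file or vector, normalized to unit maximum
#'   magnitude.
#'
#' The waveform itself is dimensionless with max |sample| = 1; the drive
#' delivered to a fiber is `amplitude * waveform * unit potentials`, so
#' polarity is carried by the contact weights and amplitude sign, not by
#' the waveform.
#'
#' @param mode waveform mode (see above)
#' @param pw phase width (us)
#' @param gap interphase gap (us, biphasic pulse train)
#' @param period pulse train period (us)
#' @param frequency square-wave frequency (kHz, full-duty mode)
#' @param delay onset delay (us)
#' @param dt timestep (us); must subdivide pw, gap and period to within one
#'   sample
#' @param tstop total duration (ms)
#' @param custom numeric vector or path to a single-column text file
#'   (CUSTOM mode)
#' @return an object of class `waveform_spec`
#' @export
waveform_spec <- function(mode = c("MONOPHASIC_PULSE_TRAIN",
                                   "BIPHASIC_PULSE_TRAIN",
                                   "BIPHASIC_FULL_DUTY", "CUSTOM"),
                          pw = 100, gap = 0, period = 1000,
                          frequency = 10, delay = 0, dt = 5, tstop = 5,
                          custom = NULL) {
  mode <- match.arg(mode)
  stopifnot(dt > 0, tstop > 0)
  if (mode %in% c("MONOPHASIC_PULSE_TRAIN", "BIPHASIC_PULSE_TRAIN")) {
    stopifnot(pw > 0, gap >= 0, period > 0)
    need <- if (mode == "BIPHASIC_PULSE_TRAIN") 2 * pw + gap else pw
    if (need > period) stop("pulse does not fit inside the period")
    align <- c(pw, gap, period, delay)
    off <- abs(align / dt - round(align / dt))
    if (any(off > 1 + 1e-9))
      stop("pulse edges must align with the timestep to within one sample")
  }
  if (mode == "BIPHASIC_FULL_DUTY") {
    stopifnot(frequency > 0)
    half_us <- 1000 / (2 * frequency)
    if (half_us < dt) stop("dt too coarse for the requested kHz frequency")
  }
  if (mode == "CUSTOM" && is.null(custom))
    stop("CUSTOM mode needs samples or a file path")
  structure(list(mode = mode, pw = pw, gap = gap, period = period,
                 frequency = frequency, delay = delay, dt = dt,
                 tstop = tstop, custom = custom),
            class = "waveform_spec")
}

#' Generate an unscaled waveform
#'
#' Builds the sample vector on the grid `t = 0, dt, ..., tstop` (length
#' `round(tstop * 1000 / dt) + 1`). Pulse edges follow half-open
#' `[start, start + pw)` sample windows. Any nonzero waveform is
#' normalized so its maximum magnitude is exactly one.
#'
#' @param spec a [waveform_spec()]
#' @return an object of class `waveform`: list(samples, dt (us), tstop
#'   (ms), time (us))
#' @export
make_waveform <- function(spec) {
  stopifnot(inherits(spec, "waveform_spec"))
  dt <- spec$dt
  n <- round(spec$tstop * 1000 / dt) + 1L
  t_us <- (seq_len(n) - 1L) * dt
  w <- numeric(n)
  if (spec$mode == "CUSTOM") {
    s <- spec$custom
    if (is.character(s)) s <- scan(s, quiet = TRUE)
    if (length(s) != n)
      stop(sprintf("custom waveform has %d samples; %d required", length(s), n))
    w <- s
  } else if (spec$mode == "BIPHASIC_FULL_DUTY") {
    half_us <- 1000 / (2 * spec$frequency)
    tt <- t_us - spec$delay
    on <- tt >= 0
    phase <- floor(tt[on] / half_us) %% 2
    w[on] <- ifelse(phase == 0, 1, -1)
  } else {
    tt <- t_us - spec$delay
    on <- tt >= 0
    tp <- tt[on] %% spec$period
    if (spec$mode == "MONOPHASIC_PULSE_TRAIN") {
      w[on][tp < spec$pw] <- 1
    } else {
      w[on][tp < spec$pw] <- 1
      w[on][tp >= spec$pw + spec$gap & tp < 2 * spec$pw + spec$gap] <- -1
    }
  }
  m <- max(abs(w))
  if (m == 0) stop("waveform is identically zero")
  w <- w / m
  structure(list(samples = w, dt = dt, tstop = spec$tstop, time = t_us,
                 mode = spec$mode), class = "waveform")
}

#' @exportS3Method base::print
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %s, %d samples, dt = %g us, tstop = %g ms\n",
              x$mode, length(x$samples), x$dt, x$tstop))
  invisible(x)
}

#' Quick waveform plot
#' @param x a `waveform`
#' @param ... passed to [graphics::plot()]
#' @export
plot.waveform <- function(x, ...) {
  graphics::plot(x$time / 1000, x$samples, type = "s", xlab = "time (ms)",
                 ylab = "unscaled amplitude", ...)
  invisible(x)
}
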