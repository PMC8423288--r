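#' Threshold search parameters
#'
#' @param lower,upper initial bracket (mA); the upper bound is expanded by
#'   `expansion` (up to `cap`) until the response flips
#' @param tol relative tolerance on the bracket, in (0, 0.5)
#' @param max_iter bisection iteration cap
#' @param expansion bound-expansion factor (> 1)
#' @param cap absolute amplitude cap (mA)
#' @return an object of class `search_params`
#' @export
search_params <- function(lower = 0.01, upper = 1, tol = 0.01,
                          max_iter = 50L, expansion = 2, cap = 100) {
  stopifnot(lower >= 0, lower < upper, tol > 0, tol < 0.5, expansion > 1,
            cap >= upper)
  structure(list(lower = lower, upper = upper, tol = tol,
                 max_iter = as.integer(max_iter), expansion = expansion,
                 cap = cap), class = "search_params")
}

# shared bisection on a monotone response predicate: returns the smallest
# amplitude (upper bracket) at which `responds(amp)` is TRUE
bisect_threshold <- function(responds, search) {
  lo <- search$lower
  hi <- search$upper
  history <- list()
  if (responds(lo))
    stop("response already present at the lower bound; search is ill-posed")
  while (!responds(hi)) {
    history[[length(history) + 1L]] <- c(hi, 0)
    lo <- hi
    hi <- hi * search$expansion
    if (hi > search$cap)
      return(list(threshold = NA_real_, iterations = length(history),
                  history = history, converged = FALSE))
  }
  history[[length(history) + 1L]] <- c(hi, 1)
  it <- 0L
  while ((hi - lo) / hi > search$tol && it < search$max_iter) {
    it <- it + 1L
    mid <- (lo + hi) / 2
    r <- responds(mid)
    history[[length(history) + 1L]] <- c(mid, as.numeric(r))
    if (r) hi <- mid else lo <- mid
  }
  list(threshold = hi, iterations = it, history = history, converged = TRUE)
}

#' Activation threshold by bisection
#'
#' Finds the smallest stimulus amplitude at which the fiber fires at least
#' one propagating action potential detected at a distal site. The bracket
#' is expanded geometrically until activation occurs, then bisected until
#' the relative bracket width reaches `search$tol`; the returned threshold
#' is the upper bracket (guaranteed active).
#'
#' @param fiber a `fiber_instance`
#' @param unit_potentials per-compartment 1 mA basis potentials (V)
#' @param waveform a `waveform` (finite pulse train)
#' @param search a [search_params()]
#' @param detect_site AP detection compartment; default 5 nodes in from
#'   the fiber end with the weakest drive (far from the cuff)
#' @param vthresh detection threshold (mV)
#' @return an object of class `threshold_result`
#' @export
find_activation_threshold <- function(fiber, unit_potentials, waveform,
                                      search = search_params(),
                                      detect_site = NULL, vthresh = -30) {
  if (is.null(detect_site)) detect_site <- default_detect_site(fiber,
                                                               unit_potentials)
  responds <- function(amp) {
    rec <- simulate_fiber(fiber, unit_potentials, waveform, amp,
                          record_sites = detect_site)
    detect_aps(rec, detect_site, vthresh = vthresh)$count >= 1
  }
  out <- bisect_threshold(responds, search)
  structure(list(protocol = "activation", threshold = out$threshold,
                 iterations = out$iterations, history = out$history,
                 converged = out$converged, detect_site = detect_site,
                 tol = search$tol),
            class = "threshold_result")
}

# node 5 nodes in from the end with the smallest |unit potential|
default_detect_site <- function(fiber, unit_potentials) {
  nodes <- fiber$node_index
  ends <- c(nodes[1], nodes[length(nodes)])
  far_end_first <- abs(unit_potentials[ends[1]]) <= abs(unit_potentials[ends[2]])
  k <- min(5L, length(nodes) - 1L)
  if (far_end_first) nodes[1L + k] else nodes[length(nodes) - k]
}

#' @exportS3Method base::print
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> %s: %s mA (%d bisection iters, tol %g)\n",
              x$protocol,
              if (is.na(x$threshold)) "not reached at cap"
              else format(x$threshold, digits = 4),
              x$iterations, x$tol))
  invisible(x)
}

#' Block threshold by bisection
#'
#' Finds the smallest continuous (kilohertz) stimulus amplitude that
#' prevents intracellularly evoked test action potentials from propagating
#' past the cuff. Test pulses are delivered at a proximal compartment
#' (`test_stimulus`), detection is at a distal site, and the assay window
#' opens after the kHz onset response has subsided (`assay_start`). Block
#' at amplitude A means zero test-evoked spikes are detected distally
#' inside the assay window. A zero-amplitude control must show every test
#' pulse arriving; otherwise the protocol is misconfigured.
#'
#' @param fiber a `fiber_instance`
#' @param unit_potentials 1 mA basis potentials (V) at the compartments
#' @param block_waveform a full-duty kHz `waveform`
#' @param test_stimulus intracellular test-pulse spec:
#'   `list(node, delay, dur, amp, n_pulses, interval)` (defaults: 3 pulses,
#'   10 ms apart, starting 20 ms after onset)
#' @param search a [search_params()]
#' @param detect_site distal detection compartment (default: 5 nodes from
#'   the end opposite the test stimulus)
#' @param assay_start start of the assay window (ms); onset responses
#'   before this are excluded
#' @param vthresh detection threshold (mV)
#' @return a `threshold_result` (protocol `"block"`) whose
#'   `assay_window` field reports the excluded onset interval
#' @export
find_block_threshold <- function(fiber, unit_potentials, block_waveform,
                                 test_stimulus = NULL,
                                 search = search_params(),
                                 detect_site = NULL, assay_start = 20,
                                 vthresh = -30) {
  nodes <- fiber$node_index
  if (is.null(test_stimulus))
    test_stimulus <- list(node = nodes[2], delay = assay_start, dur = 0.1,
                          amp = 10, n_pulses = 3L, interval = 10)
  test_stimulus$n_pulses <- test_stimulus$n_pulses %||% 3L
  test_stimulus$interval <- test_stimulus$interval %||% 10
  if (is.null(detect_site)) {
    # detect on the far side from the test stimulus
    k <- min(5L, length(nodes) - 1L)
    detect_site <- if (test_stimulus$node <= nodes[ceiling(length(nodes) / 2)])
      nodes[length(nodes) - k] else nodes[1L + k]
  }
  tmax_needed <- test_stimulus$delay +
    (test_stimulus$n_pulses - 1) * test_stimulus$interval + 5
  if (block_waveform$tstop < tmax_needed)
    stop("block waveform too short for the test-pulse assay")

  count_distal <- function(amp) {
    rec <- simulate_fiber(fiber, unit_potentials, block_waveform, amp,
                          istim = test_stimulus, record_sites = detect_site)
    detect_aps(rec, detect_site, vthresh = vthresh,
               t_min = assay_start - 1)$count
  }
  ctrl <- count_distal(0)
  if (ctrl < test_stimulus$n_pulses)
    stop(sprintf(
      "control run detected %d of %d test pulses; test stimulus is subthreshold or detection misconfigured",
      ctrl, test_stimulus$n_pulses))
  blocked <- function(amp) count_distal(amp) == 0
  out <- bisect_threshold(blocked, search)
  structure(list(protocol = "block", threshold = out$threshold,
                 iterations = out$iterations, history = out$history,
                 converged = out$converged, detect_site = detect_site,
                 assay_window = c(assay_start, block_waveform$tstop),
                 test_stimulus = test_stimulus, tol = search$tol),
            class = "threshold_result")
}

#' Responses to fixed stimulation amplitudes
#'
#' One simulation per amplitude; no search. Spike counts are reported at
#' the detection site.
#'
#' @param fiber a `fiber_instance`
#' @param unit_potentials 1 mA basis potentials (V)
#' @param waveform a `waveform`
#' @param amplitudes numeric vector (mA)
#' @param detect_site detection compartment (default as in
#'   [find_activation_threshold()])
#' @return list of `sim_record`s with attribute `"spike_counts"`
#' @export
run_fixed_amplitudes <- function(fiber, unit_potentials, waveform,
                                 amplitudes, detect_site = NULL) {
  stopifnot(all(is.finite(amplitudes)))
  if (is.null(detect_site)) detect_site <- default_detect_site(fiber,
                                                               unit_potentials)
  recs <- lapply(amplitudes, function(a)
    simulate_fiber(fiber, unit_potentials, waveform, a,
                   record_sites = detect_site))
  counts <- vapply(recs, function(r)
    detect_aps(r, detect_site)$count, 0L)
  attr(recs, "spike_counts") <- counts
  recs
}
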