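#' Parameters for the synthetic EMG stream generator
#'
#' The generator emulates day-long two-channel temporalis-EMG recordings
#' from sensor-equipped eyeglasses: a zero-mean noise floor, rhythmic
#' chewing bursts of band-limited (20-120 Hz) activity during eating
#' events, optional 50 Hz line interference and optional short non-eating
#' confounder bursts. Event annotations mimic a diet journal kept at one
#' minute resolution: interval edges are rounded outward to whole minutes,
#' which deliberately injects label noise at event boundaries.
#'
#' Defaults describe the emulated study conditions: 16 h of wear at 256 Hz,
#' two channels, five eating events of 10-40 min, chewing at 1.5 Hz, a
#' 10 mV noise floor (the lower context bound of the adaptive sampler) and
#' a 150 mV burst envelope peak.
#'
#' @param duration_s recording length in seconds.
#' @param sample_rate Hz.
#' @param n_channels number of EMG channels.
#' @param n_events number of eating events.
#' @param event_duration_range_s min/max event length in seconds.
#' @param chew_rate_hz chewing-burst repetition rate.
#' @param burst_amplitude_mV peak mean-rectified amplitude of a chew burst.
#' @param noise_floor_mV mean-rectified amplitude of the noise floor.
#' @param line_hum_amplitude_mV amplitude of an additive 50 Hz sinusoid
#'   (0 disables it).
#' @param n_confounders number of short non-eating bursts (knob for
#'   robustness experiments; defaults to none).
#' @param confounder_amplitude_mV envelope peak of confounder bursts.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return A `generator_params` list.
#' @export
generator_params <- function(duration_s = 16 * 3600,
                             sample_rate = 256,
                             n_channels = 2,
                             n_events = 5,
                             event_duration_range_s = c(600, 2400),
                             chew_rate_hz = 1.5,
                             burst_amplitude_mV = 150,
                             noise_floor_mV = 10,
                             line_hum_amplitude_mV = 0,
                             n_confounders = 0,
                             confounder_amplitude_mV = 60,
                             seed = 1L) {
  stopifnot(duration_s > 0, sample_rate > 0, n_channels >= 1,
            n_events >= 0, length(event_duration_range_s) == 2,
            event_duration_range_s[1] > 0,
            event_duration_range_s[1] <= event_duration_range_s[2],
            chew_rate_hz > 0, noise_floor_mV > 0,
            noise_floor_mV < burst_amplitude_mV,
            line_hum_amplitude_mV >= 0, n_confounders >= 0)
  structure(as.list(environment()), class = "generator_params")
}

#' Annotated multichannel EMG stream
#'
#' @param channels numeric matrix, samples x channels, amplitudes in mV.
#' @param sample_rate Hz.
#' @param events data frame with columns `start_s`, `end_s`; sorted,
#'   non-overlapping, within the recording.
#' @param participant_id text label.
#' @return An `annotated_signal`.
#' @export
annotated_signal <- function(channels, sample_rate, events,
                             participant_id = "P1") {
  channels <- as.matrix(channels)
  duration <- nrow(channels) / sample_rate
  events <- as.data.frame(events)
  if (nrow(events)) {
    stopifnot(all(c("start_s", "end_s") %in% names(events)))
    events <- events[, c("start_s", "end_s")]
    if (any(events$end_s <= events$start_s))
      stop("events must have positive length")
    if (is.unsorted(events$start_s, strictly = TRUE) && nrow(events) > 1)
      stop("events must be sorted by start time")
    if (nrow(events) > 1 &&
        any(events$start_s[-1] < events$end_s[-nrow(events)]))
      stop("events must not overlap")
    if (min(events$start_s) < 0 || max(events$end_s) > duration + 1e-9)
      stop("events must lie within [0, duration]")
  } else {
    events <- data.frame(start_s = numeric(0), end_s = numeric(0))
  }
  structure(list(channels = channels, sample_rate = sample_rate,
                 events = events, participant_id = participant_id,
                 duration = duration),
            class = "annotated_signal")
}

#' @export
print.annotated_signal <- function(x, ...) {
  cat("<annotated_signal> ", x$participant_id, ": ",
      ncol(x$channels), " ch x ", nrow(x$channels), " samples @ ",
      x$sample_rate, " Hz (", round(x$duration / 3600, 2), " h), ",
      nrow(x$events), " events\n", sep = "")
  invisible(x)
}

# Outward rounding of event intervals to whole minutes, clipped to the
# recording; mirrors a hand-kept journal with one-minute resolution.
.round_events_to_minutes <- function(events, duration) {
  if (!nrow(events)) return(events)
  out <- data.frame(start_s = floor(events$start_s / 60) * 60,
                    end_s = pmin(ceiling(events$end_s / 60) * 60, duration))
  out$start_s <- pmax(out$start_s, 0)
  out
}

# Place n non-overlapping intervals with >= gap_s clearance between them
# (and to the recording edges) so outward minute-rounding keeps them
# disjoint. Errors when the request cannot fit.
.place_events <- function(duration, n, dur_range, gap_s = 125) {
  if (n == 0) return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  durs <- stats::runif(n, dur_range[1], dur_range[2])
  slack <- duration - sum(durs) - gap_s * (n + 1)
  if (slack < 0)
    stop("cannot place ", n, " events of the requested length ",
         "without overlap")
  # split the slack across the n+1 gaps uniformly at random
  cuts <- sort(stats::runif(n, 0, slack))
  extra <- diff(c(0, cuts))
  starts <- gap_s + cumsum(extra) + c(0, cumsum(durs[-n] + gap_s))
  data.frame(start_s = starts, end_s = starts + durs)
}

# Band-limited (20-120 Hz) unit-mean-rectified noise of length n.
.burst_carrier <- function(n, sample_rate) {
  ny <- sample_rate / 2
  bf <- signal::butter(4, c(20 / ny, min(120 / ny, 0.99)), type = "pass")
  x <- signal::filter(bf, stats::rnorm(n + 256))[-seq_len(256)]
  x / mean(abs(x))
}

#' Generate one synthetic participant recording
#'
#' @param params a [generator_params()].
#' @param participant_id label stored in the output.
#' @return An [annotated_signal()] whose `events` are the minute-rounded
#'   annotations; the attribute `true_events` keeps the un-rounded burst
#'   intervals.
#' @examples
#' sig <- generate_participant(generator_params(duration_s = 300,
#'                                              n_events = 1,
#'                                              event_duration_range_s = c(60, 90),
#'                                              seed = 7))
#' sig
#' @export
generate_participant <- function(params, participant_id = "P1") {
  stopifnot(inherits(params, "generator_params"))
  p <- params
  set.seed(p$seed)
  n <- round(p$duration_s * p$sample_rate)
  events <- .place_events(p$duration_s, p$n_events, p$event_duration_range_s)

  # noise floor: white Gaussian scaled so mean |x| = noise_floor
  sd_noise <- p$noise_floor_mV / sqrt(2 / pi)
  ch <- matrix(stats::rnorm(n * p$n_channels, sd = sd_noise),
               nrow = n, ncol = p$n_channels)

  # per-channel gain heterogeneity (electrode placement asymmetry)
  gains <- seq(1, 0.85, length.out = p$n_channels)

  add_bursts <- function(intervals, amp) {
    for (i in seq_len(nrow(intervals))) {
      i0 <- max(1L, floor(intervals$start_s[i] * p$sample_rate) + 1L)
      i1 <- min(n, ceiling(intervals$end_s[i] * p$sample_rate))
      len <- i1 - i0 + 1L
      if (len <= 0) next
      tt <- (seq_len(len) - 1) / p$sample_rate
      env <- sin(pi * p$chew_rate_hz * tt)^2
      for (k in seq_len(p$n_channels)) {
        carrier <- .burst_carrier(len, p$sample_rate)
        ch[i0:i1, k] <<- ch[i0:i1, k] + gains[k] * amp * env * carrier
      }
    }
  }
  add_bursts(events, p$burst_amplitude_mV)

  if (p$n_confounders > 0) {
    conf <- .place_events(p$duration_s, p$n_confounders, c(5, 20), gap_s = 5)
    # keep confounders clear of eating events
    if (nrow(events)) {
      clash <- vapply(seq_len(nrow(conf)), function(i)
        any(conf$start_s[i] < events$end_s + 60 &
              conf$end_s[i] > events$start_s - 60), logical(1))
      conf <- conf[!clash, , drop = FALSE]
    }
    add_bursts(conf, p$confounder_amplitude_mV)
  }

  if (p$line_hum_amplitude_mV > 0) {
    hum <- p$line_hum_amplitude_mV *
      sin(2 * pi * 50 * (seq_len(n) - 1) / p$sample_rate)
    ch <- ch + hum
  }

  ann <- .round_events_to_minutes(events, p$duration_s)
  sig <- annotated_signal(ch, p$sample_rate, ann, participant_id)
  attr(sig, "true_events") <- events
  sig
}

#' Expand an event list to a per-sample logical mask
#'
#' @param events data frame with `start_s`, `end_s`.
#' @param n_samples stream length in samples.
#' @param sample_rate Hz.
#' @return Logical vector of length `n_samples`.
#' @export
events_to_mask <- function(events, n_samples, sample_rate) {
  mask <- logical(n_samples)
  for (i in seq_len(nrow(events))) {
    i0 <- max(1L, floor(events$start_s[i] * sample_rate) + 1L)
    i1 <- min(n_samples, ceiling(events$end_s[i] * sample_rate))
    if (i1 >= i0) mask[i0:i1] <- TRUE
  }
  mask
}

#' Write / read an annotated signal as delimited text
#'
#' The sample file is tab-separated with a header `time_s ch1_mV ch2_mV ...`
#' (UTF-8, decimal point); annotations go to a companion file
#' `<stem>_events.tsv` with columns `start_s`, `end_s`.
#'
#' @param sig an [annotated_signal()].
#' @param path path of the sample file; the events path is derived.
#' @param digits decimal digits written (default 6, i.e. 1e-6 mV).
#' @return `write_signal` returns the two paths invisibly; `read_signal`
#'   returns the reconstructed [annotated_signal()].
#' @export
write_signal <- function(sig, path, digits = 6) {
  stopifnot(inherits(sig, "annotated_signal"))
  n <- nrow(sig$channels)
  tab <- data.frame(time_s = round((seq_len(n) - 1) / sig$sample_rate, digits),
                    round(sig$channels, digits))
  names(tab) <- c("time_s", paste0("ch", seq_len(ncol(sig$channels)), "_mV"))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  epath <- .events_path(path)
  utils::write.table(sig$events, epath, sep = "\t", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(c(signal = path, events = epath))
}

.events_path <- function(path) {
  ext <- tools::file_ext(path)
  stem <- tools::file_path_sans_ext(path)
  paste0(stem, "_events", if (nzchar(ext)) paste0(".", ext) else ".tsv")
}

#' @rdname write_signal
#' @param participant_id label for the reconstructed signal.
#' @export
read_signal <- function(path, participant_id = "P1") {
  tab <- utils::read.delim(path, check.names = FALSE)
  if (!identical(names(tab)[1], "time_s") || ncol(tab) < 2)
    stop("malformed signal file: expected 'time_s' plus channel columns")
  chn <- grep("^ch[0-9]+_mV$", names(tab))
  if (length(chn) != ncol(tab) - 1)
    stop("malformed signal file: unrecognised channel columns")
  fs <- if (nrow(tab) > 1) 1 / stats::median(diff(tab$time_s)) else 256
  ev <- utils::read.delim(.events_path(path))
  if (!all(c("start_s", "end_s") %in% names(ev)))
    stop("malformed events file: expected start_s, end_s")
  annotated_signal(as.matrix(tab[, chn, drop = FALSE]), round(fs), ev,
                   participant_id)
}
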