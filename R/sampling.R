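#' Context-adaptive sampler parameters
#'
#' The sampler wakes the sensor once per decision period, takes an n-shot
#' measurement, summarises it into a context measure (mean rectified
#' amplitude, maximum over channels), maps it linearly onto a candidate
#' duty-cycle rate between `Dl` and `Dh`, and feeds that through a
#' two-state (attentive/inattentive) response model: while attentive the
#' duty never decreases, and the sampler only relaxes after the attention
#' time `tau_s` has elapsed below the duty threshold `DTH`.
#'
#' Defaults are the operating point used throughout the package: Dh=1,
#' Dl=0.1, DTH=0.6, n=4, tau=3 s, theta_l=10 mV, theta_h=180 mV, with a
#' 1 s decision period.
#'
#' @param Dl,Dh minimum/maximum duty rate, 0 < Dl <= Dh <= 1.
#' @param DTH duty threshold separating the two states, Dl <= DTH <= Dh.
#' @param theta_l,theta_h lower/upper context bounds in mV (theta_l is the
#'   noise-floor estimate).
#' @param n samples per n-shot measure.
#' @param tau_s attention time in seconds.
#' @param period_s seconds between n-shot measures (decision interval).
#' @return A `sampler_params` list.
#' @export
sampler_params <- function(Dl = 0.1, Dh = 1, DTH = 0.6,
                           theta_l = 10, theta_h = 180,
                           n = 4L, tau_s = 3, period_s = 1) {
  stopifnot(Dl > 0, Dl <= Dh, Dh <= 1, DTH >= Dl, DTH <= Dh,
            theta_l < theta_h, n >= 1, tau_s > 0, period_s > 0)
  structure(list(Dl = Dl, Dh = Dh, DTH = DTH, theta_l = theta_l,
                 theta_h = theta_h, n = as.integer(n), tau_s = tau_s,
                 period_s = period_s),
            class = "sampler_params")
}

#' Context measure of an n-shot sample block
#'
#' Per channel, the mean rectified amplitude of the n samples; the context
#' measure is the maximum over channels.
#'
#' @param shot numeric matrix, n samples x K channels (a vector is treated
#'   as one channel).
#' @return theta_t in mV (>= 0).
#' @export
context_measure <- function(shot) {
  shot <- as.matrix(shot)
  if (nrow(shot) == 0) stop("empty sample block")
  max(colMeans(abs(shot)))
}

#' Linear duty-cycle mapping
#'
#' Maps the context measure onto a candidate duty rate, anchored at
#' (theta_l -> Dl) and (theta_h -> Dh), clamped to [Dl, Dh] outside the
#' anchors.
#'
#' @param theta context measure in mV.
#' @param params a [sampler_params()].
#' @return Candidate duty rate D* in [Dl, Dh]. Vectorised over `theta`.
#' @export
map_duty <- function(theta, params) {
  stopifnot(inherits(params, "sampler_params"))
  d <- params$Dl + (params$Dh - params$Dl) /
    (params$theta_h - params$theta_l) * (theta - params$theta_l)
  pmin(pmax(d, params$Dl), params$Dh)
}

#' Initial sampler state
#'
#' @param params a [sampler_params()].
#' @return A `sampler_state`: inattentive at the minimum duty rate.
#' @export
sampler_state <- function(params) {
  structure(list(mode = "inattentive", Dt = params$Dl,
                 attention_clock = 0),
            class = "sampler_state")
}

#' One step of the attentive/inattentive response model
#'
#' Decision rules per period: when the candidate duty D* exceeds the
#' threshold DTH the model enters (or stays in) the attentive state, the
#' attention clock is reset to tau, and the duty becomes max(Dt, D*) — the
#' duty is monotonically non-decreasing while attentive. When D* is below
#' DTH and the attention time has elapsed, the model is inattentive and
#' adopts D* directly. When D* is below DTH but the attention time has not
#' yet elapsed, the current duty is held and the clock decremented by one
#' period.
#'
#' @param state a `sampler_state`.
#' @param d_star candidate duty rate from [map_duty()].
#' @param params a [sampler_params()].
#' @return List with the updated `state` and the adopted duty `Dt`.
#' @export
step_response <- function(state, d_star, params) {
  stopifnot(inherits(state, "sampler_state"),
            inherits(params, "sampler_params"))
  if (d_star > params$DTH) {
    Dt <- max(state$Dt, d_star)
    state$mode <- "attentive"
    state$attention_clock <- params$tau_s
  } else if (state$mode == "attentive" && state$attention_clock > 0) {
    Dt <- state$Dt                       # hold while the attention time runs
    state$attention_clock <- state$attention_clock - params$period_s
  } else {
    Dt <- d_star
    state$mode <- "inattentive"
    state$attention_clock <- 0
  }
  state$Dt <- Dt
  list(state = state, Dt = Dt)
}

#' Run a sampling strategy over an annotated signal
#'
#' Uniform mode keeps every sample (duty trace constantly 1). Adaptive mode
#' applies the n-shot/linear-mapping/response-model loop once per decision
#' period: the first n samples of the period form the n-shot measure (they
#' are always acquired and counted as kept), the adopted duty for the
#' period keeps `ceiling(Dt * samples_per_period)` samples at evenly spaced
#' positions. The run is fully deterministic.
#'
#' @param sig an [annotated_signal()].
#' @param params a [sampler_params()].
#' @param mode `"uniform"` or `"adaptive"`.
#' @return A `sampled_stream`: `kept_mask` (per-sample logical),
#'   `duty_trace` (per-period adopted duty), `reduction` (fraction of
#'   samples not taken), plus the parameters used.
#' @export
run_sampler <- function(sig, params, mode = c("uniform", "adaptive")) {
  mode <- match.arg(mode)
  stopifnot(inherits(sig, "annotated_signal"),
            inherits(params, "sampler_params"))
  n_samp <- nrow(sig$channels)
  spp <- round(params$period_s * sig$sample_rate)
  if (mode == "uniform") {
    n_periods <- ceiling(n_samp / spp)
    return(structure(list(kept_mask = rep(TRUE, n_samp),
                          duty_trace = rep(1, n_periods),
                          reduction = 0, mode = mode, params = params),
                     class = "sampled_stream"))
  }
  if (spp < params$n)
    stop("decision period shorter than the n-shot measure")
  n_periods <- floor(n_samp / spp)
  # context measure per period, vectorised: mean |x| of the first n samples
  starts <- (seq_len(n_periods) - 1L) * spp
  theta <- rep(0, n_periods)
  for (k in seq_len(ncol(sig$channels))) {
    shot_idx <- outer(seq_len(params$n), starts, `+`)
    ek <- colMeans(matrix(abs(sig$channels[shot_idx, k]),
                          nrow = params$n))
    theta <- pmax(theta, ek)
  }
  d_star <- map_duty(theta, params)
  duty <- numeric(n_periods)
  st <- sampler_state(params)
  for (t in seq_len(n_periods)) {
    res <- step_response(st, d_star[t], params)
    st <- res$state
    duty[t] <- res$Dt
  }
  keep_counts <- pmin(spp, ceiling(duty * spp))
  kept <- logical(n_samp)
  for (cnt in unique(keep_counts)) {
    pos <- unique(round(seq(1, spp, length.out = cnt)))
    idx <- outer(pos, starts[keep_counts == cnt], `+`)
    kept[idx] <- TRUE
  }
  # the n-shot samples are physically acquired
  kept[outer(seq_len(params$n), starts, `+`)] <- TRUE
  # any tail beyond the last full period is acquired at the final duty
  if (n_periods * spp < n_samp) {
    tail_idx <- (n_periods * spp + 1L):n_samp
    kept[tail_idx] <- TRUE        # short tail, kept conservatively
  }
  structure(list(kept_mask = kept, duty_trace = duty,
                 reduction = 1 - mean(kept), mode = mode, params = params),
            class = "sampled_stream")
}

#' @export
print.sampled_stream <- function(x, ...) {
  cat("<sampled_stream> mode=", x$mode, ", reduction=",
      round(x$reduction, 3), ", periods=", length(x$duty_trace), "\n",
      sep = "")
  invisible(x)
}

#' Apply a sampling mask to a signal
#'
#' Samples not acquired are zero-filled (the sensor was off; no
#' sample-and-hold is assumed). Annotations are unchanged.
#'
#' @param sig an [annotated_signal()].
#' @param stream a `sampled_stream` from [run_sampler()].
#' @return An [annotated_signal()] with un-kept samples set to 0 mV.
#' @export
apply_sampling <- function(sig, stream) {
  stopifnot(inherits(sig, "annotated_signal"),
            inherits(stream, "sampled_stream"))
  ch <- sig$channels
  ch[!stream$kept_mask, ] <- 0
  out <- annotated_signal(ch, sig$sample_rate, sig$events,
                          sig$participant_id)
  attr(out, "true_events") <- attr(sig, "true_events")
  out
}

#' Operation count of the context-adaptive sampling algorithm
#'
#' Per n-shot measure: the context measure costs 2n*g additions, 2
#' divisions and n-1 comparisons with one float cell (g channels); the
#' response output costs 4 additions, 1 multiplication, 1 division and four
#' float cells; the attention-time bookkeeping costs 2 comparisons and two
#' float cells. Totals scale linearly with the number of periods.
#'
#' @param params a [sampler_params()].
#' @param n_periods number of decision periods (>= 0).
#' @param g number of channels.
#' @return An [op_count()] (arithmetic scaled by `n_periods`; memory cells
#'   are the per-measure working set, not scaled).
#' @export
sampler_op_count <- function(params, n_periods, g = 2) {
  stopifnot(inherits(params, "sampler_params"), n_periods >= 0, g >= 1)
  n <- params$n
  per <- op_count(add = 2 * n * g, div = 2, comp = n - 1, float_cells = 1,
                  label = "context measure") +
    op_count(add = 4, mult = 1, div = 1, float_cells = 4,
             label = "response output") +
    op_count(comp = 2, float_cells = 2, label = "attention time")
  out <- per * n_periods
  out$int_cells <- per$int_cells
  out$float_cells <- per$float_cells
  out$label <- "context-adaptive sampling"
  out
}
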