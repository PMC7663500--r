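#' Spotting pipeline parameters
#'
#' Two eating-event spotting pipelines operate on non-overlapping sliding
#' windows of a continuous EMG stream. The FFT-based pipeline smooths the
#' frame and extracts per-channel standard deviation and peak spectral
#' magnitude. The WPD-based pipeline gates frames on their maximum
#' rectified amplitude, notch-filters 50 Hz interference, high-pass filters
#' at 20 Hz, rectifies, decomposes each channel with a depth-2 wavelet
#' packet transform and reduces the coefficients to `d` dimensions by PCA.
#' Both feed an RBF one-class SVM trained on eating frames only.
#'
#' @param kind `"wpd"` or `"fft"`.
#' @param m window length; seconds by default, raw samples when
#'   `m_unit = "samples"`.
#' @param m_unit `"s"` or `"samples"`.
#' @param d reduced feature dimension (WPD: PCA target; FFT: feature-vector
#'   length).
#' @param v support-vector budget used for cost accounting (default 1500).
#' @param gate_threshold_mV frame gate in mV (WPD kind); `NULL` defers to
#'   training, where it is set to the 95th percentile of non-event frame
#'   maxima.
#' @param sample_rate Hz.
#' @param wavelet mother wavelet of the packet decomposition (`"db2"`).
#' @param rbf_mult_convention multiplication count of the RBF kernel row in
#'   the cost table: `"worked_example"` (v(d-1), default) or `"table"`
#'   (v(d+1)).
#' @return A `spotting_params` list; `frame_len` is the window in samples.
#' @export
spotting_params <- function(kind = c("wpd", "fft"), m = 1, m_unit = c("s", "samples"),
                            d = 20L, v = 1500L, gate_threshold_mV = NULL,
                            sample_rate = 256, wavelet = "db2",
                            rbf_mult_convention = c("worked_example", "table")) {
  kind <- match.arg(kind)
  m_unit <- match.arg(m_unit)
  rbf_mult_convention <- match.arg(rbf_mult_convention)
  stopifnot(m > 0, d >= 1, v >= 1, sample_rate > 0)
  frame_len <- if (m_unit == "s") round(m * sample_rate) else round(m)
  if (frame_len < 8) stop("window too short for the filter bank")
  if (kind == "wpd" && frame_len %% 4 != 0)
    stop("WPD at depth 2 needs a frame length divisible by 4")
  structure(list(kind = kind, m_s = frame_len / sample_rate,
                 frame_len = as.integer(frame_len), d = as.integer(d),
                 l = 2L, v = as.integer(v),
                 gate_threshold_mV = gate_threshold_mV,
                 sample_rate = sample_rate, wavelet = wavelet,
                 rbf_mult_convention = rbf_mult_convention),
            class = "spotting_params")
}

# ---- filters -------------------------------------------------------------

# RBJ biquad notch at f0 with quality factor Q.
.notch_coefs <- function(f0, fs, Q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  list(b = b, a = a)
}

# IIR filter applied down the rows of a matrix (time x frames), vectorised
# across columns. Direct form I with zero initial conditions.
.iir_filter_mat <- function(b, a, X) {
  X <- as.matrix(X)
  n <- nrow(X); Y <- matrix(0, n, ncol(X))
  nb <- length(b); na <- length(a)
  for (i in seq_len(n)) {
    acc <- b[1] * X[i, ]
    jb <- min(nb, i); ja <- min(na, i)
    if (jb >= 2) for (j in 2:jb) acc <- acc + b[j] * X[i - j + 1, ]
    if (ja >= 2) for (j in 2:ja) acc <- acc - a[j] * Y[i - j + 1, ]
    Y[i, ] <- acc / a[1]
  }
  Y
}

.hp_coefs <- function(fs) {
  bf <- signal::butter(4, 20 / (fs / 2), type = "high")
  list(b = bf$b, a = bf$a)
}

#' Preprocess one frame
#'
#' WPD kind: 50 Hz notch, 20 Hz high-pass (de-trending), rectification.
#' FFT kind: first-order smoothing filter (the cost table charges one
#' addition per sample for this stage).
#'
#' @param frame numeric matrix, `frame_len` x channels (vector = 1
#'   channel).
#' @param params a [spotting_params()].
#' @return Preprocessed frame, same shape.
#' @export
preprocess <- function(frame, params) {
  stopifnot(inherits(params, "spotting_params"))
  frame <- as.matrix(frame)
  if (nrow(frame) != params$frame_len)
    stop("frame length does not match params$frame_len")
  fs <- params$sample_rate
  if (params$kind == "wpd") {
    nc <- .notch_coefs(50, fs)
    hp <- .hp_coefs(fs)
    out <- .iir_filter_mat(nc$b, nc$a, frame)
    out <- .iir_filter_mat(hp$b, hp$a, out)
    abs(out)
  } else {
    .iir_filter_mat(0.5, c(1, -0.5), frame)   # exponential smoothing
  }
}

# ---- wavelet packet decomposition ---------------------------------------

# Orthonormal Daubechies-2 analysis filters.
.db2_filters <- function() {
  s3 <- sqrt(3)
  h <- c(1 + s3, 3 + s3, 3 - s3, 1 - s3) / (4 * sqrt(2))
  g <- rev(h) * c(1, -1, 1, -1)        # g[k] = (-1)^k h[L-1-k]
  list(h = h, g = g)
}

# One periodised analysis step on the columns of X: returns approximation
# and detail halves (nrow(X)/2 each).
.wpd_step_mat <- function(X, filt) {
  n <- nrow(X)
  half <- n / 2
  A <- matrix(0, half, ncol(X)); D <- A
  for (j in seq_along(filt$h)) {
    idx <- ((2 * (seq_len(half) - 1) + (j - 1)) %% n) + 1
    A <- A + filt$h[j] * X[idx, , drop = FALSE]
    D <- D + filt$g[j] * X[idx, , drop = FALSE]
  }
  list(A = A, D = D)
}

#' Depth-2 wavelet packet decomposition of a signal frame
#'
#' Full binary filter-bank tree with the orthonormal db2 pair and periodic
#' extension; the four leaf-band coefficient vectors are concatenated
#' (total length equal to the input length), so energy is conserved
#' (Parseval).
#'
#' @param x numeric vector (length divisible by 4) or matrix with frames in
#'   columns.
#' @return Vector (or matrix, frames in columns) of concatenated leaf
#'   coefficients in band order LL, LH, HL, HH.
#' @export
wpd_leaves <- function(x) {
  X <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  if (nrow(X) %% 4 != 0) stop("length must be divisible by 4")
  filt <- .db2_filters()
  l1 <- .wpd_step_mat(X, filt)
  l2a <- .wpd_step_mat(l1$A, filt)
  l2d <- .wpd_step_mat(l1$D, filt)
  out <- rbind(l2a$A, l2a$D, l2d$A, l2d$D)
  if (is.matrix(x)) out else drop(out)
}

# ---- features ------------------------------------------------------------

.l2_normalize <- function(v) {
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) v else v / nrm
}

#' FFT-based features of a preprocessed frame
#'
#' Per channel: standard deviation and maximum FFT magnitude (frame
#' zero-padded to the next power of two). The concatenation over channels
#' is padded with zeros or truncated to length `d` and L2-normalised (an
#' all-zero frame yields the zero vector).
#'
#' @param frame preprocessed frame, `frame_len` x channels.
#' @param params a [spotting_params()].
#' @return Numeric vector of length `params$d`.
#' @export
extract_features_fft <- function(frame, params) {
  frame <- as.matrix(frame)
  if (nrow(frame) == 0) stop("zero-length frame")
  nfft <- 2^ceiling(log2(nrow(frame)))
  feats <- unlist(lapply(seq_len(ncol(frame)), function(k) {
    x <- frame[, k]
    spec <- abs(stats::fft(c(x, rep(0, nfft - length(x)))))
    c(stats::sd(x), max(spec[seq_len(nfft / 2 + 1)]))
  }))
  v <- rep(0, params$d)
  v[seq_len(min(params$d, length(feats)))] <-
    feats[seq_len(min(params$d, length(feats)))]
  .l2_normalize(v)
}

#' WPD-based features of a preprocessed frame
#'
#' Depth-2 WPD per channel, concatenated leaf coefficients over channels,
#' centred and projected with a trained PCA (c -> d); the scores are then
#' normalised with per-component centre/scale constants fitted on the
#' training event frames (amplitude information, the main discriminant of
#' chewing activity, is retained this way).
#'
#' @param frame preprocessed frame, `frame_len` x channels.
#' @param params a [spotting_params()].
#' @param projection list with `center` (length c), `rotation` (c x d,
#'   orthonormal columns), `score_center` and `score_scale` (length d) as
#'   fitted by [train_spotter()].
#' @return Numeric vector of length `params$d`.
#' @export
extract_features_wpd <- function(frame, params, projection) {
  frame <- as.matrix(frame)
  coefs <- as.vector(wpd_leaves(frame))          # channels concatenated
  if (length(projection$center) != length(coefs))
    stop("projection was trained for a different coefficient length")
  z <- drop(crossprod(projection$rotation, coefs - projection$center))
  (z - projection$score_center) / projection$score_scale
}

#' Frame gate on maximum rectified amplitude
#'
#' A frame is processed only when its maximum rectified sample reaches the
#' gate threshold (inclusive); gated-out frames are labelled non-event and
#' skip the pipeline.
#'
#' @param frame raw frame (matrix or vector), mV.
#' @param gate_threshold_mV threshold in mV.
#' @return `TRUE` when the frame should be processed.
#' @export
gate_frame <- function(frame, gate_threshold_mV) {
  max(abs(frame)) >= gate_threshold_mV
}

# ---- segmentation & labels ----------------------------------------------

# Split a stream into non-overlapping frames; returns an array
# frame_len x n_frames x channels (the tail shorter than one frame is
# discarded).
segment_frames <- function(sig, frame_len) {
  n <- nrow(sig$channels)
  n_frames <- n %/% frame_len
  arr <- array(0, dim = c(frame_len, n_frames, ncol(sig$channels)))
  for (k in seq_len(ncol(sig$channels)))
    arr[, , k] <- sig$channels[seq_len(frame_len * n_frames), k]
  arr
}

# TRUE for frames with at least half of their samples inside truth events.
frame_labels <- function(sig, frame_len) {
  n_frames <- nrow(sig$channels) %/% frame_len
  mask <- events_to_mask(sig$events, frame_len * n_frames, sig$sample_rate)
  colMeans(matrix(mask, nrow = frame_len)) >= 0.5
}

# Batched feature matrix (frames in rows) for the frames selected by `use`.
.features_mat <- function(arr, use, params, projection = NULL) {
  idx <- which(use)
  if (!length(idx))
    return(matrix(0, 0, params$d))
  K <- dim(arr)[3]
  if (params$kind == "wpd") {
    fs <- params$sample_rate
    nc <- .notch_coefs(50, fs); hp <- .hp_coefs(fs)
    coefs <- NULL
    for (k in seq_len(K)) {
      X <- arr[, idx, k, drop = FALSE]
      dim(X) <- dim(X)[1:2]
      X <- abs(.iir_filter_mat(hp$b, hp$a, .iir_filter_mat(nc$b, nc$a, X)))
      W <- wpd_leaves(X)
      coefs <- rbind(coefs, W)
    }
    if (is.null(projection)) return(t(coefs))    # raw coefficients
    proj <- crossprod(projection$rotation, coefs - projection$center)
    scale(t(proj), projection$score_center, projection$score_scale)
  } else {
    feats <- matrix(0, length(idx), params$d)
    for (k in seq_len(K)) {
      X <- arr[, idx, k, drop = FALSE]
      dim(X) <- dim(X)[1:2]
      X <- .iir_filter_mat(0.5, c(1, -0.5), X)
      nfft <- 2^ceiling(log2(nrow(X)))
      spec <- abs(stats::mvfft(rbind(X, matrix(0, nfft - nrow(X), ncol(X)))))
      cols <- (k - 1) * 2 + 1:2
      cols <- cols[cols <= params$d]
      vals <- rbind(apply(X, 2, stats::sd),
                    apply(spec[seq_len(nfft / 2 + 1), , drop = FALSE], 2, max))
      if (length(cols))
        feats[, cols] <- t(vals[seq_along(cols), , drop = FALSE])
    }
    t(apply(feats, 1, .l2_normalize))
  }
}

# ---- training ------------------------------------------------------------

#' Train a one-class spotting model with leave-one-participant-out search
#'
#' Eating frames of the training streams (one-class setting: event frames
#' only) are featurised and fitted with an RBF one-class SVM. For the WPD
#' kind a PCA projection (c -> d) is first fitted on the training event
#' frames, and the frame gate, when not supplied, is set to the 95th
#' percentile of non-event frame maxima. Hyperparameters are chosen by grid
#' search maximising the mean leave-one-participant-out F1 of the full
#' spot-and-score pipeline; the final model is refitted on all streams with
#' the winning point. Deterministic given `seed`.
#'
#' @param streams list of >= 2 [annotated_signal()]s.
#' @param params a [spotting_params()].
#' @param grid named list of hyperparameter vectors (`nu`, `gamma`).
#' @param seed integer seed.
#' @return A `trained_spotter` with the SVM, projection, gate, chosen
#'   hyperparameters, per-fold F1 scores and the recorded support-vector
#'   count (a warning is issued when it exceeds the budget `v`).
#' @export
train_spotter <- function(streams, params,
                          grid = list(nu = c(0.01, 0.05),
                                      gamma = c(1 / (8 * params$d),
                                                1 / (4 * params$d))),
                          seed = 1L) {
  stopifnot(length(streams) >= 2, inherits(params, "spotting_params"))
  set.seed(seed)
  fl <- params$frame_len
  arrs <- lapply(streams, segment_frames, frame_len = fl)
  labs <- lapply(streams, frame_labels, frame_len = fl)
  if (!any(unlist(labs))) stop("no event frames in the training data")

  gate <- params$gate_threshold_mV
  if (params$kind == "wpd" && is.null(gate)) {
    nonevent_max <- unlist(lapply(seq_along(arrs), function(i) {
      apply(abs(arrs[[i]][, !labs[[i]], , drop = FALSE]), 2, max)
    }))
    gate <- stats::quantile(nonevent_max, 0.95, names = FALSE)
  }
  params$gate_threshold_mV <- gate

  fit_fold <- function(train_idx, hp) {
    ev_feats <- NULL; proj <- NULL
    if (params$kind == "wpd") {
      raw <- do.call(rbind, lapply(train_idx, function(i)
        .features_mat(arrs[[i]], labs[[i]], params, projection = NULL)))
      pc <- stats::prcomp(raw, center = TRUE, scale. = FALSE,
                          rank. = params$d)
      scores <- pc$x[, seq_len(params$d), drop = FALSE]
      score_scale <- apply(scores, 2, stats::sd)
      score_scale[score_scale == 0] <- 1
      proj <- list(center = pc$center, rotation = pc$rotation,
                   score_center = colMeans(scores),
                   score_scale = score_scale)
      ev_feats <- do.call(rbind, lapply(train_idx, function(i)
        .features_mat(arrs[[i]], labs[[i]], params, projection = proj)))
    } else {
      ev_feats <- do.call(rbind, lapply(train_idx, function(i)
        .features_mat(arrs[[i]], labs[[i]], params)))
    }
    model <- e1071::svm(ev_feats, type = "one-classification",
                        kernel = "radial", nu = hp$nu, gamma = hp$gamma,
                        scale = FALSE)
    list(model = model, projection = proj)
  }

  hp_grid <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  fold_scores <- matrix(NA_real_, nrow(hp_grid), length(streams))
  for (g in seq_len(nrow(hp_grid))) {
    hp <- as.list(hp_grid[g, , drop = FALSE])
    for (heldout in seq_along(streams)) {
      fit <- fit_fold(setdiff(seq_along(streams), heldout), hp)
      sp <- structure(list(kind = params$kind, params = params,
                           model = fit$model, projection = fit$projection,
                           hyper = hp),
                      class = "trained_spotter")
      ev <- spot_events(streams[[heldout]], sp, params)
      pr <- sample_prf(streams[[heldout]]$events, ev,
                       nrow(streams[[heldout]]$channels),
                       streams[[heldout]]$sample_rate)
      fold_scores[g, heldout] <- pr$F1
    }
  }
  best <- which.max(rowMeans(fold_scores))
  hp <- as.list(hp_grid[best, , drop = FALSE])
  fit <- fit_fold(seq_along(streams), hp)
  svc <- nrow(fit$model$SV)
  if (svc > params$v)
    warning("trained model uses ", svc, " support vectors, above the ",
            "budget v = ", params$v, " assumed by the cost model")
  structure(list(kind = params$kind, params = params, model = fit$model,
                 projection = fit$projection, hyper = hp,
                 sv_count = svc, gate_threshold_mV = gate,
                 fold_scores = fold_scores),
            class = "trained_spotter")
}

#' @export
print.trained_spotter <- function(x, ...) {
  cat("<trained_spotter> kind=", x$kind, ", d=", x$params$d,
      ", SVs=", if (is.null(x$sv_count)) "?" else x$sv_count,
      ", nu=", x$hyper$nu, ", gamma=", signif(x$hyper$gamma, 3), "\n",
      sep = "")
  invisible(x)
}

# ---- inference -----------------------------------------------------------

#' Spot events in a stream
#'
#' Segments the stream into non-overlapping frames, gates (WPD kind),
#' classifies each processed frame with the trained one-class SVM and
#' merges maximal runs of positive frames into events. Passing the string
#' `"oracle"` as `spotter` classifies each frame by its ground-truth label
#' (pipeline identity check).
#'
#' @param sig an [annotated_signal()] (possibly after [apply_sampling()]).
#' @param spotter a `trained_spotter` or `"oracle"`.
#' @param params a [spotting_params()]; defaults to the spotter's.
#' @return Data frame of retrieved events (`start_s`, `end_s`), with
#'   attribute `n_processed` (frames that reached the pipeline).
#' @export
spot_events <- function(sig, spotter, params = NULL) {
  oracle <- identical(spotter, "oracle")
  if (is.null(params))
    params <- if (oracle) stop("oracle spotting needs explicit params")
              else spotter$params
  fl <- params$frame_len
  n_frames <- nrow(sig$channels) %/% fl
  if (n_frames == 0)
    return(structure(data.frame(start_s = numeric(0), end_s = numeric(0)),
                     n_processed = 0))
  if (oracle) {
    pos <- frame_labels(sig, fl)
    n_proc <- n_frames
  } else {
    arr <- segment_frames(sig, fl)
    use <- if (params$kind == "wpd") {
      gate <- spotter$gate_threshold_mV
      if (is.null(gate)) gate <- params$gate_threshold_mV
      apply(abs(arr), 2, max) >= gate
    } else rep(TRUE, n_frames)
    pos <- logical(n_frames)
    if (any(use)) {
      feats <- .features_mat(arr, use, params, spotter$projection)
      pos[use] <- as.logical(stats::predict(spotter$model, feats))
    }
    n_proc <- sum(use)
  }
  runs <- rle(pos)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values
  ev <- data.frame(start_s = (starts[keep] - 1) * params$m_s,
                   end_s = ends[keep] * params$m_s)
  structure(ev, n_processed = n_proc)
}

# ---- operation counts ----------------------------------------------------

#' Per-frame operation counts of a spotting pipeline
#'
#' Analytical tallies per processed frame, stage by stage, in terms of the
#' window length m (samples), the WPD coefficient count c, the feature
#' dimension d and the support-vector budget v. The RBF-kernel
#' multiplication count follows `params$rbf_mult_convention`.
#'
#' @param params a [spotting_params()].
#' @return Named list of per-function [op_count()]s plus `total`.
#' @export
spotting_op_count <- function(params) {
  stopifnot(inherits(params, "spotting_params"))
  m <- params$frame_len; d <- params$d; v <- params$v; l <- params$l
  out <- list(low_pass = op_count(add = m, float_cells = 1,
                                  label = "low-pass filtering"))
  if (params$kind == "fft") {
    out$std <- op_count(add = 3 * m - 1, mult = m, div = 2, root = 1,
                        int_cells = 1, label = "standard deviation")
    out$fft <- op_count(add = 3 * m * log2(m), mult = 2 * m * log2(m),
                        float_cells = m, label = "fast Fourier transform")
    out$max <- op_count(comp = m - 1, int_cells = 1, label = "maximum")
    out$l2_norm <- op_count(add = d - 1, mult = d, root = 1, int_cells = 1,
                            label = "L2-norm")
  } else {
    cc <- m                                   # WPD coefficients per frame
    lv <- seq_len(l)
    out$wpd <- op_count(add = sum(((m / 2^lv - 1) * 2 + 1) * 2^lv),
                        mult = sum((m / 2^lv + 1) * 4 * 2^lv),
                        float_cells = 4 + d, label = "WPD")
    out$pca <- op_count(add = d * (cc - 1), mult = d * cc,
                        float_cells = cc * d, label = "PCA")
    out$l2_norm <- op_count(add = d - 1, mult = d, root = 1, int_cells = 1,
                            label = "L2-norm")
  }
  out$kernel_svm <- kernel_svm_op_count(v, d)
  out$rbf <- rbf_op_count(v, d, params$rbf_mult_convention)
  out$total <- merge_op_counts(out)
  out$total$label <- paste0(params$kind, " pipeline / frame")
  out
}

#' Kernel-SVM and RBF-kernel operation counts
#'
#' The decision function of a one-class SVM with v support vectors costs
#' v+1 additions, 2v multiplications and one comparison; each RBF kernel
#' evaluation costs v(2d-1) additions, v exponentials, one comparison and
#' v(d-1) multiplications under the worked-example convention (v(d+1)
#' under the table convention).
#'
#' @param v support-vector count.
#' @param d feature dimension.
#' @param mult_convention,add_convention counting convention: the summary
#'   cost table (`"table"`) or the per-stage worked tally
#'   (`"worked_example"`, which prices the kernel-SVM additions as v rather
#'   than v+1 and the RBF multiplications as v(d-1) rather than v(d+1)).
#' @return An [op_count()].
#' @export
kernel_svm_op_count <- function(v, d = 20,
                                add_convention = c("table", "worked_example")) {
  add_convention <- match.arg(add_convention)
  add <- if (add_convention == "table") v + 1 else v
  op_count(add = add, mult = 2 * v, comp = 1,
           int_cells = v, float_cells = v * (d + 1), label = "kernel SVM")
}

#' @rdname kernel_svm_op_count
#' @export
rbf_op_count <- function(v, d, mult_convention = c("worked_example", "table")) {
  mult_convention <- match.arg(mult_convention)
  mult <- if (mult_convention == "worked_example") v * (d - 1) else v * (d + 1)
  op_count(add = v * (2 * d - 1), mult = mult, comp = 1, exp_ = v,
           float_cells = 1, label = "radial basis kernel")
}
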