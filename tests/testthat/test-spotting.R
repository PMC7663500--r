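test_that("preprocessing kills DC, notches 50 Hz and rectifies", {
  fs <- 256
  pw <- spotting_params("wpd", m = 4, sample_rate = fs)
  # constant frame through the 20 Hz high-pass: steady-state RMS ~ 0
  dc <- matrix(5, pw$frame_len, 2)
  out <- preprocess(dc, pw)
  steady <- out[-seq_len(fs), 1]                    # skip the transient
  expect_lt(sqrt(mean(steady^2)), 0.01 * 5)
  # pure 50 Hz sinusoid attenuated >= 20 dB by the notch
  tt <- (seq_len(pw$frame_len) - 1) / fs
  s50 <- matrix(sin(2 * pi * 50 * tt), ncol = 1)
  o50 <- preprocess(s50, pw)
  in_rms <- sqrt(mean(s50[-seq_len(fs), 1]^2))
  out_rms <- sqrt(mean(o50[-seq_len(fs), 1]^2))
  expect_lt(out_rms / in_rms, 10^(-20 / 20))
  # rectification: output is non-negative
  expect_true(all(o50 >= 0))
  expect_error(preprocess(matrix(0, 10, 1), pw), "frame length")
})

test_that("FFT features locate spectral peaks and are unit-norm", {
  fs <- 256
  pf <- spotting_params("fft", m = 1, d = 4, sample_rate = fs)
  z <- extract_features_fft(matrix(0, 256, 2), pf)
  expect_equal(z, rep(0, 4))                        # zero-vector guard
  # a unit sinusoid at bin k of an N-point transform peaks at bin k
  N <- 256
  for (k in c(8, 32)) {
    x <- sin(2 * pi * k * (seq_len(N) - 1) / N)
    spec <- abs(stats::fft(x))[seq_len(N / 2 + 1)]
    expect_equal(which.max(spec) - 1, k)
  }
  f <- extract_features_fft(matrix(rnorm(512), 256, 2), pf)
  expect_equal(sqrt(sum(f^2)), 1)
})

test_that("depth-2 WPD conserves energy and projections have length d", {
  set.seed(1)
  for (len in c(64, 256)) {
    x <- rnorm(len)
    w <- wpd_leaves(x)
    expect_length(w, len)
    expect_equal(sum(w^2), sum(x^2), tolerance = 1e-6)  # Parseval
  }
  expect_equal(wpd_leaves(rep(0, 64)), rep(0, 64))
  # matrix form agrees with the vector form
  X <- matrix(rnorm(64 * 5), 64, 5)
  W <- wpd_leaves(X)
  expect_equal(W[, 3], wpd_leaves(X[, 3]))

  pw <- spotting_params("wpd", m = 0.25, d = 10, sample_rate = 256)
  proj <- list(center = rep(0, 2 * pw$frame_len),
               rotation = diag(1, 2 * pw$frame_len)[, 1:10],
               score_center = rep(0, 10), score_scale = rep(1, 10))
  v <- extract_features_wpd(matrix(rnorm(2 * pw$frame_len),
                                   pw$frame_len, 2), pw, proj)
  expect_length(v, 10)
})

test_that("the frame gate thresholds on maximum rectified amplitude", {
  expect_false(gate_frame(matrix(c(5, -5), 2, 2), 12))
  expect_true(gate_frame(matrix(c(12, 0), 2, 1), 12))   # inclusive
  # threshold at the 95th percentile of noise maxima gates ~95% out
  sig <- generate_participant(generator_params(duration_s = 400,
                                               n_events = 0, seed = 77))
  arr <- dyndse:::segment_frames(sig, 256)
  maxima <- apply(abs(arr), 2, max)
  thr <- quantile(maxima, 0.95, names = FALSE)
  frac_gated <- mean(maxima < thr)
  expect_lt(abs(frac_gated - 0.95), 0.03)
})

test_that("run merging turns positive frame runs into events", {
  # truth event spanning frames 4..8 (1-based) of a 12 s stream, m = 1 s
  sig <- annotated_signal(matrix(0, 12 * 256, 2), 256,
                          data.frame(start_s = 3, end_s = 8))
  pw <- spotting_params("wpd", m = 1, sample_rate = 256)
  ev <- spot_events(sig, "oracle", pw)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_s, 3)
  expect_equal(ev$end_s, 8)
  # all-negative stream -> empty event list
  sig0 <- annotated_signal(matrix(0, 12 * 256, 2), 256,
                           data.frame(start_s = numeric(0),
                                      end_s = numeric(0)))
  expect_equal(nrow(spot_events(sig0, "oracle", pw)), 0)
})

test_that("oracle spotting reproduces minute-rounded annotations", {
  sig <- generate_participant(short_gen_params(61, duration_s = 600))
  pw <- spotting_params("wpd", m = 1, sample_rate = 256)
  ev <- spot_events(sig, "oracle", pw)
  pr <- sample_prf(sig$events, ev, nrow(sig$channels), sig$sample_rate)
  expect_equal(pr$F1, 1)
})

test_that("training is deterministic and separates synthetic data", {
  # long events so the minute-resolution label padding stays a small
  # fraction of the labelled span
  streams <- lapply(1:3, function(i) generate_participant(
    generator_params(duration_s = 1800, n_events = 1,
                     event_duration_range_s = c(600, 660), seed = 8000 + i),
    paste0("P", i)))
  pw <- spotting_params("wpd", m = 1, d = 8, sample_rate = 256)
  spA <- train_spotter(streams, pw, seed = 4)
  spB <- train_spotter(streams, pw, seed = 4)
  expect_identical(spA$hyper, spB$hyper)
  expect_identical(spA$fold_scores, spB$fold_scores)
  # held-out F1 on separable synthetic data
  expect_gte(max(rowMeans(spA$fold_scores)), 0.9)
  expect_lte(spA$sv_count, pw$v)
  # one-point grid selects that point
  sp1 <- train_spotter(streams, pw, grid = list(nu = 0.07, gamma = 1 / 64),
                       seed = 4)
  expect_equal(sp1$hyper$nu, 0.07)
  # no event frames -> error
  quiet <- lapply(1:2, function(i)
    generate_participant(generator_params(duration_s = 120, n_events = 0,
                                          seed = i)))
  expect_error(train_spotter(quiet, pw, seed = 1), "no event frames")
})

test_that("gated-out frames never reach feature extraction", {
  streams <- make_cohort(2, seed = 12, duration_s = 600)
  pw <- spotting_params("wpd", m = 1, d = 8, sample_rate = 256)
  sp <- train_spotter(streams, pw, grid = list(nu = 0.1, gamma = 1 / 8),
                      seed = 2)
  ev <- spot_events(streams[[1]], sp)
  arr <- dyndse:::segment_frames(streams[[1]], pw$frame_len)
  n_pass <- sum(apply(abs(arr), 2, max) >= sp$gate_threshold_mV)
  expect_equal(attr(ev, "n_processed"), n_pass)
  expect_lt(n_pass, dim(arr)[2])                    # some frames gated out
})

test_that("per-frame operation counts follow the analytical breakdown", {
  pw <- spotting_params("wpd", m = 256, m_unit = "samples", d = 20, v = 1500)
  ops <- spotting_op_count(pw)
  expect_equal(unname(ops$kernel_svm$counts["add"]), 1501)
  expect_equal(unname(ops$kernel_svm$counts["mult"]), 3000)
  expect_equal(unname(ops$kernel_svm$counts["comp"]), 1)
  # worked-example RBF multiplications v(d-1); table variant v(d+1)
  expect_equal(unname(ops$rbf$counts["mult"]), 1500 * 19)
  pwt <- spotting_params("wpd", m = 256, m_unit = "samples", d = 20,
                         v = 1500, rbf_mult_convention = "table")
  expect_equal(unname(spotting_op_count(pwt)$rbf$counts["mult"]), 1500 * 21)

  pf <- spotting_params("fft", m = 256, m_unit = "samples", d = 4, v = 1500)
  opf <- spotting_op_count(pf)
  m <- 256
  expect_equal(unname(opf$std$counts[c("add", "mult", "div", "root")]),
               c(3 * m - 1, m, 2, 1))
  expect_equal(unname(opf$fft$counts[c("add", "mult")]),
               c(3 * m * log2(m), 2 * m * log2(m)))
  expect_equal(unname(opf$max$counts["comp"]), m - 1)
  expect_equal(unname(opf$low_pass$counts["add"]), m)
})

test_that("operation counts are affine in v and d as the tables prescribe", {
  set.seed(2)
  for (i in 1:6) {
    v <- sample(10:100, 1); d <- sample(4:30, 1)
    m <- 64 * sample(1:4, 1)
    pw <- spotting_params("wpd", m = m, m_unit = "samples", d = d, v = v)
    oc <- spotting_op_count(pw)
    expect_equal(unname(oc$kernel_svm$counts["add"]), v + 1)
    expect_equal(unname(oc$rbf$counts["add"]), v * (2 * d - 1))
    expect_equal(unname(oc$rbf$counts["exp"]), v)
    expect_equal(unname(oc$pca$counts["add"]), d * (m - 1))
    expect_equal(unname(oc$pca$counts["mult"]), d * m)
    # totals are the sum of the stage rows
    stages <- oc[setdiff(names(oc), "total")]
    expect_equal(oc$total$counts, merge_op_counts(stages)$counts)
  }
})

test_that("frame segmentation covers the stream without overlap or gap", {
  sig <- generate_participant(generator_params(duration_s = 100,
                                               n_events = 0, seed = 71))
  fl <- 256
  arr <- dyndse:::segment_frames(sig, fl)
  n_frames <- dim(arr)[2]
  expect_equal(n_frames, nrow(sig$channels) %/% fl)
  flat <- as.vector(arr[, , 1])
  expect_identical(flat, sig$channels[seq_len(n_frames * fl), 1])
})
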