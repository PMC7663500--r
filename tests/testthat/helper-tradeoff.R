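# Scaled trade-off experiment: 5 synthetic participants x 2 h, LOPO-trained
# WPD spotting, evaluated under uniform sampling and a grid of context
# upper bounds theta_h.
tradeoff_one_seed <- function(master_seed, theta_grid = c(60, 120, 180, 360)) {
  sub <- function(k) (master_seed * 100003 + k) %% 2147483647
  data <- lapply(1:5, function(i) generate_participant(
    generator_params(duration_s = 7200, n_events = 2,
                     event_duration_range_s = c(600, 1200),
                     seed = sub(i)),
    paste0("P", i)))
  pw <- spotting_params("wpd", m = 1, d = 20, sample_rate = 256)
  spotters <- lapply(seq_along(data), function(h)
    train_spotter(data[-h], pw, grid = list(nu = 0.01, gamma = 1 / 160),
                  seed = sub(50 + h)))
  eval_setting <- function(mode, theta_h = 180) {
    sp_par <- sampler_params(theta_h = theta_h)
    res <- vapply(seq_along(data), function(i) {
      st <- run_sampler(data[[i]], sp_par, mode)
      masked <- if (mode == "adaptive") apply_sampling(data[[i]], st)
                else data[[i]]
      ev <- spot_events(masked, spotters[[i]], pw)
      pr <- sample_prf(data[[i]]$events, ev, nrow(data[[i]]$channels),
                       data[[i]]$sample_rate)
      c(pr$F1, st$reduction)
    }, numeric(2))
    rowMeans(res)
  }
  uni <- eval_setting("uniform")
  ada <- vapply(theta_grid, function(th) eval_setting("adaptive", th),
                numeric(2))
  list(uniform_F1 = uni[1], F1 = ada[1, ], reduction = ada[2, ],
       theta_grid = theta_grid)
}
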