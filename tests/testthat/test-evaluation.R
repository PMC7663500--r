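test_that("sample-level precision/recall matches brute-force mask counting", {
  ev <- function(...) {
    v <- c(...)
    if (is.null(v)) return(data.frame(start_s = numeric(0),
                                      end_s = numeric(0)))
    m <- matrix(v, ncol = 2, byrow = TRUE)
    data.frame(start_s = m[, 1], end_s = m[, 2])
  }
  none <- ev()
  # identical lists
  pr <- sample_prf(ev(10, 20), ev(10, 20), 256 * 30, 256)
  expect_equal(c(pr$P, pr$R, pr$F1), c(1, 1, 1))
  # disjoint lists
  pr <- sample_prf(ev(0, 10), ev(20, 30), 256 * 30, 256)
  expect_equal(c(pr$P, pr$R, pr$F1), c(0, 0, 0))
  # retrieved strictly inside truth: P = 1, R = 0.5, F1 = 2/3
  pr <- sample_prf(ev(0, 100 / 256), ev(0, 50 / 256), 256, 256)
  expect_equal(pr$P, 1)
  expect_equal(pr$R, 0.5, tolerance = 0.02)
  expect_equal(pr$F1, 2 * pr$P * pr$R / (pr$P + pr$R))
  # empty-retrieval conventions
  expect_equal(sample_prf(none, none, 100, 256)$P, 1)
  expect_equal(sample_prf(ev(0, 1), none, 512, 256)$P, 0)
  # overlap within one list is rejected
  expect_error(sample_prf(ev(0, 10, 5, 15), none, 256 * 20, 256),
               "overlap")
  # randomized agreement with an independent per-sample counting oracle
  set.seed(9)
  for (i in 1:10) {
    ns <- 2560
    t1 <- sort(runif(4, 0, 9)); r1 <- sort(runif(4, 0, 9))
    truth <- ev(t1[1], t1[2], t1[3], t1[4])
    retr <- ev(r1[1], r1[2], r1[3], r1[4])
    pr <- sample_prf(truth, retr, ns, 256)
    tm <- events_to_mask(truth, ns, 256); rm_ <- events_to_mask(retr, ns, 256)
    expect_equal(pr$P, sum(tm & rm_) / sum(rm_))
    expect_equal(pr$R, sum(tm & rm_) / sum(tm))
    if (pr$P + pr$R > 0)
      expect_equal(pr$F1, 2 * pr$P * pr$R / (pr$P + pr$R))
  }
})

test_that("normalisation divides by requirements and flags feasibility", {
  req <- requirement_set(min_precision = 0.70, min_recall = 0.80,
                         et_bound_s = 1, energy_budget_mWh = 52.03125,
                         memory_capacity_bytes = 98304)
  m <- metric_vector(P = 0.84, R = 0.80, ET = 1, EC = 52.03125, MD = 98304)
  nm <- normalize_metrics(m, req)
  expect_equal(unname(nm$benefit["P"]), 1.2)
  expect_equal(unname(nm$cost["ET"]), 1)
  expect_true(nm$feasible)
  # EC twice the budget -> normalised 2, infeasible
  m2 <- metric_vector(P = 0.84, R = 0.80, ET = 1, EC = 2 * 52.03125,
                      MD = 98304)
  nm2 <- normalize_metrics(m2, req)
  expect_equal(unname(nm2$cost["EC"]), 2)
  expect_false(nm2$feasible)
  # feasibility equals the independently re-derived conjunction
  set.seed(11)
  for (i in 1:20) {
    m3 <- random_metric_vector()
    nm3 <- normalize_metrics(m3, req)
    expect_equal(nm3$feasible,
                 m3[["P"]] >= req$min_precision &&
                   m3[["R"]] >= req$min_recall &&
                   m3[["ET"]] <= req$et_bound_s &&
                   m3[["EC"]] <= req$energy_budget_mWh &&
                   m3[["MD"]] <= req$memory_capacity_bytes)
  }
})

test_that("oracle evaluation reproduces closed-form full-duty energy", {
  data <- list(generate_participant(short_gen_params(81, duration_s = 600)),
               generate_participant(short_gen_params(82, duration_s = 600)))
  profiles <- hardware_profiles()
  sp <- design_space(list(
    functionality("algorithm", list(
      component_spec("wpd", params = list(m = 1, d = 8)))),
    functionality("sampling", list(component_spec("uniform"))),
    functionality("mcu", list(component_spec("arm_cortexm3"))),
    functionality("runtime", list(component_spec("real_time")))))
  cfg <- enumerate_configurations(sp)[[1]]
  req <- requirement_set(et_bound_s = 1, memory_capacity_bytes = 98304)
  res <- evaluate_configuration(cfg, data, "oracle", req,
                                profiles = profiles)
  expect_equal(res$metrics[["P"]], 1)
  expect_equal(res$metrics[["R"]], 1)
  # sensor term under uniform sampling: closed form at full duty
  expect_equal(unname(res$diagnostics$ec_breakdown["sensor"]),
               4.0 * 3.3 * 600 / 3600)
  # repeated evaluation is identical
  res2 <- evaluate_configuration(cfg, data, "oracle", req,
                                 profiles = profiles)
  expect_identical(res$metrics, res2$metrics)
})

test_that("adaptive sensor energy approaches the Dl closed form on noise", {
  noise <- list(generate_participant(generator_params(duration_s = 600,
                                                      n_events = 0,
                                                      seed = 5)))
  sp <- design_space(list(
    functionality("algorithm", list(
      component_spec("wpd", params = list(m = 1, d = 8)))),
    functionality("sampling", list(
      component_spec("adaptive", params = list(theta_h = 1e6)))),
    functionality("mcu", list(component_spec("arm_cortexm3"))),
    functionality("runtime", list(component_spec("real_time")))))
  cfg <- enumerate_configurations(sp)[[1]]
  req <- requirement_set(et_bound_s = 1, memory_capacity_bytes = 98304)
  res <- evaluate_configuration(cfg, noise, "oracle", req)
  sens <- hardware_profiles()$emg_sensor
  dl_form <- sensor_energy(rep(0.1, 600), sens)
  expect_equal(unname(res$diagnostics$ec_breakdown["sensor"]), dl_form,
               tolerance = 0.05)
})

test_that("exploration sweeps every configuration and re-selects the optimum", {
  data <- list(generate_participant(short_gen_params(91, duration_s = 600)),
               generate_participant(short_gen_params(92, duration_s = 600)))
  space <- design_space(list(
    functionality("algorithm", list(
      component_spec("fft", params = list(m = 1)),
      component_spec("wpd", params = list(m = 1, d = 8)))),
    functionality("sampling", list(
      component_spec("uniform"),
      component_spec("adaptive", params = list(theta_h = 180)))),
    functionality("mcu", list(component_spec("arm_cortexm3"))),
    functionality("runtime", list(component_spec("real_time")))))
  req <- requirement_set(et_bound_s = 1, memory_capacity_bytes = 98304)
  rep1 <- run_exploration(space, data, req, "oracle")
  expect_equal(nrow(rep1$table), 4)
  expect_equal(nrow(rep1$table), n_configurations(space))
  # independent re-selection oracle over the report rows
  ok <- !vapply(rep1$evaluated, is.null, logical(1))
  feas_idx <- which(vapply(rep1$evaluated[ok], function(e)
    normalize_metrics(e$metrics, req)$feasible, logical(1)))
  if (length(feas_idx)) {
    ben <- vapply(feas_idx, function(i)
      sum(rep1$evaluated[ok][[i]]$metrics[c("P", "R")]), numeric(1))
    ec <- vapply(feas_idx, function(i)
      rep1$evaluated[ok][[i]]$metrics[["EC"]], numeric(1))
    pick <- feas_idx[order(-ben, ec, feas_idx)][1]
    expect_identical(rep1$optimum$metrics,
                     rep1$evaluated[ok][[pick]]$metrics)
  } else {
    expect_null(rep1$optimum)
  }
  # repeated run is identical
  rep2 <- run_exploration(space, data, req, "oracle")
  expect_identical(rep1$table, rep2$table)
  # impossible requirements -> no feasible rows, no optimum
  req0 <- requirement_set(min_precision = 0.999999, min_recall = 0.999999,
                          et_bound_s = 1e-9,
                          energy_budget_mWh = 1e-9,
                          memory_capacity_bytes = 1)
  rep0 <- run_exploration(space, data, req0, "oracle")
  expect_false(any(rep0$table$feasible))
  expect_null(rep0$optimum)
  # report serialises to delimited text
  path <- file.path(tempdir(), "report.tsv")
  write_report(rep1, path)
  expect_equal(nrow(utils::read.delim(path)), 4)
})

test_that("adaptive sampling spreads energy across heterogeneous users", {
  data <- lapply(1:3, function(i)
    generate_participant(generator_params(duration_s = 900, n_events = i,
                                          event_duration_range_s = c(40, 60),
                                          seed = 100 + i),
                         participant_id = paste0("P", i)))
  sp <- design_space(list(
    functionality("algorithm", list(
      component_spec("wpd", params = list(m = 1, d = 8)))),
    functionality("sampling", list(
      component_spec("adaptive", params = list(theta_h = 180)))),
    functionality("mcu", list(component_spec("arm_cortexm3"))),
    functionality("runtime", list(component_spec("real_time")))))
  cfg <- enumerate_configurations(sp)[[1]]
  req <- requirement_set(et_bound_s = 1, memory_capacity_bytes = 98304)
  res <- evaluate_configuration(cfg, data, "oracle", req)
  sens_ec <- vapply(res$diagnostics$per_participant, `[[`, numeric(1),
                    "ec_sensor")
  expect_gt(stats::sd(sens_ec), 0)        # behaviour-driven spread
  # uniform sampling: equal-duration users draw identical sensor energy
  cfg_u <- cfg; cfg_u$sampling <- list(component = "uniform", params = list())
  res_u <- evaluate_configuration(cfg_u, data, "oracle", req)
  sens_u <- vapply(res_u$diagnostics$per_participant, `[[`, numeric(1),
                   "ec_sensor")
  expect_equal(stats::sd(sens_u), 0)
})
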