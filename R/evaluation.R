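#' Sample-level precision, recall and F1 of retrieved events
#'
#' Both event lists are expanded to per-sample masks over the stream.
#' Precision is the fraction of retrieved samples that fall inside truth
#' events, recall the fraction of truth samples retrieved, F1 their
#' harmonic mean. Conventions: when both lists are empty P = R = F1 = 1;
#' when only the retrieved list is empty P = R = F1 = 0.
#'
#' @param truth_events,retrieved_events data frames with `start_s`,
#'   `end_s`; each internally non-overlapping.
#' @param n_samples stream length in samples.
#' @param sample_rate Hz.
#' @return List with `P`, `R`, `F1`.
#' @export
sample_prf <- function(truth_events, retrieved_events, n_samples,
                       sample_rate) {
  .check_disjoint <- function(ev, what) {
    if (nrow(ev) > 1) {
      ev <- ev[order(ev$start_s), ]
      if (any(ev$start_s[-1] < ev$end_s[-nrow(ev)]))
        stop("overlapping intervals in the ", what, " event list")
    }
  }
  .check_disjoint(truth_events, "truth")
  .check_disjoint(retrieved_events, "retrieved")
  tm <- events_to_mask(truth_events, n_samples, sample_rate)
  rm_ <- events_to_mask(retrieved_events, n_samples, sample_rate)
  nt <- sum(tm); nr <- sum(rm_); nc <- sum(tm & rm_)
  if (nt == 0 && nr == 0) return(list(P = 1, R = 1, F1 = 1))
  P <- if (nr == 0) 0 else nc / nr
  R <- if (nt == 0) 1 else nc / nt
  F1 <- if (P + R == 0) 0 else 2 * P * R / (P + R)
  list(P = P, R = R, F1 = F1)
}

#' Normalise a metric vector against requirements
#'
#' Cost axes are divided by their bounds, benefit axes by their thresholds;
#' a configuration is feasible exactly when every normalised cost is <= 1
#' and every normalised benefit is >= 1. Latency joins the conjunction only
#' when the requirement set carries a latency tolerance.
#'
#' @param metrics a [metric_vector()].
#' @param req a [requirement_set()].
#' @return List with `benefit`, `cost` (named normalised values) and
#'   `feasible`.
#' @export
normalize_metrics <- function(metrics, req) {
  stopifnot(inherits(metrics, "metric_vector"),
            inherits(req, "requirement_set"))
  benefit <- c(P = metrics[["P"]] / req$min_precision,
               R = metrics[["R"]] / req$min_recall)
  cost <- c(ET = metrics[["ET"]] / req$et_bound_s,
            EC = metrics[["EC"]] / req$energy_budget_mWh,
            MD = metrics[["MD"]] / req$memory_capacity_bytes)
  if (!is.null(req$latency_tolerance_s))
    cost <- c(cost, CL = metrics[["CL"]] / req$latency_tolerance_s)
  list(benefit = benefit, cost = cost,
       feasible = all(cost <= 1) && all(benefit >= 1))
}

#' The four-functionality design space of the eyeglasses case study
#'
#' Spotting algorithm (FFT-based with window length m; WPD-based with m and
#' feature dimension d), data sampling (uniform; context-adaptive with
#' upper context bound theta_h), microcontroller (PSoC1 M8C,
#' TI MSP430F1611, ARM CortexM3) and runtime mode (real time; online).
#'
#' @param fft_m_s,wpd_m_s window-length grids in seconds.
#' @param wpd_d feature-dimension grid.
#' @param theta_h_mV upper-context-bound grid in mV.
#' @return A [design_space()].
#' @export
default_design_space <- function(fft_m_s = c(1, 5, 13),
                                 wpd_m_s = c(0.5, 1),
                                 wpd_d = c(15, 20),
                                 theta_h_mV = c(60, 180)) {
  design_space(list(
    functionality("algorithm", list(
      component_spec("fft", params = list(m = fft_m_s)),
      component_spec("wpd", params = list(m = wpd_m_s, d = wpd_d)))),
    functionality("sampling", list(
      component_spec("uniform"),
      component_spec("adaptive", params = list(theta_h = theta_h_mV)))),
    functionality("mcu", list(
      component_spec("psoc1_m8c"),
      component_spec("msp430f1611"),
      component_spec("arm_cortexm3"))),
    functionality("runtime", list(
      component_spec("real_time"),
      component_spec("online")))))
}

# spotting_params for the algorithm choice of a configuration
.cfg_spotting_params <- function(cfg, sample_rate = 256) {
  a <- cfg$algorithm
  if (a$component == "wpd")
    spotting_params("wpd", m = a$params$m, d = a$params$d,
                    sample_rate = sample_rate)
  else
    spotting_params("fft", m = a$params$m, sample_rate = sample_rate)
}

# key identifying the trained-model requirements of a configuration
.cfg_algo_key <- function(cfg) {
  a <- cfg$algorithm
  paste0(a$component, "_",
         paste(names(a$params), unlist(a$params), sep = "=", collapse = "_"))
}

#' Train the leave-one-participant-out spotter cache for a design space
#'
#' For every distinct algorithm+parameter combination in the space, trains
#' one spotter per participant on the remaining participants, so that
#' evaluation scores each stream with a model that never saw it.
#'
#' @param space a [design_space()] with an `algorithm` functionality.
#' @param data list of [annotated_signal()]s (>= 2 participants).
#' @param grid hyperparameter grid passed to [train_spotter()].
#' @param seed integer master seed.
#' @return Nested list: `cache[[algo_key]][[participant_index]]` is a
#'   `trained_spotter`.
#' @export
train_spotter_cache <- function(space, data,
                                grid = NULL, seed = 1L) {
  cfgs <- enumerate_configurations(space)
  keys <- unique(vapply(cfgs, .cfg_algo_key, character(1)))
  cache <- list()
  for (key in keys) {
    cfg <- cfgs[[match(key, vapply(cfgs, .cfg_algo_key, character(1)))]]
    sp <- .cfg_spotting_params(cfg, data[[1]]$sample_rate)
    g <- if (is.null(grid)) list(nu = 0.01, gamma = 1 / (8 * sp$d)) else grid
    cache[[key]] <- lapply(seq_along(data), function(heldout) {
      train_spotter(data[-heldout], sp, grid = g,
                    seed = .sub_seed(seed, match(key, keys) * 100 + heldout))
    })
  }
  cache
}

# documented counter scheme fanning a master seed into sub-seeds (< 2^31)
.sub_seed <- function(seed, counter) {
  (as.double(seed) * 100003 + counter) %% 2147483647
}

#' Evaluate one configuration on a set of participant streams
#'
#' Runs the configured sampling strategy and spotting pipeline per
#' participant, accumulates analytical operation counts and derives the
#' full metric vector: precision/recall (unweighted mean over
#' participants), execution time (per-frame in real-time mode, total in
#' online mode), energy (microcontroller + sensor + memory + radio),
#' memory demand and communication latency.
#'
#' @param cfg a `configuration` with functionalities `algorithm`,
#'   `sampling`, `mcu`, `runtime`.
#' @param data list of [annotated_signal()]s.
#' @param spotters either `"oracle"` or the entry
#'   `cache[[algo_key]]` of [train_spotter_cache()] (one spotter per
#'   participant).
#' @param req a [requirement_set()] (carried through for reporting).
#' @param profiles hardware profiles ([hardware_profiles()]).
#' @return List with `metrics` (a [metric_vector()]) and `diagnostics`
#'   (per-participant P/R/F1, sampling reduction, EC breakdown, feasibility
#'   inputs). An over-committed real-time schedule is reported through the
#'   metrics, never as an error.
#' @export
evaluate_configuration <- function(cfg, data, spotters, req,
                                   profiles = hardware_profiles()) {
  sp <- .cfg_spotting_params(cfg, data[[1]]$sample_rate)
  mcu <- profiles[[cfg$mcu$component]]
  if (is.null(mcu)) stop("unknown mcu profile: ", cfg$mcu$component)
  sensor <- profiles$emg_sensor
  radio <- profiles$ble_radio
  mode <- if (cfg$runtime$component == "real_time") "real_time" else "online"
  adaptive <- cfg$sampling$component == "adaptive"
  spar <- if (adaptive)
    sampler_params(theta_h = cfg$sampling$params$theta_h) else sampler_params()

  ops <- spotting_op_count(sp)
  frame_cyc <- cycles(ops$total, mcu)
  frame_et <- execution_time(frame_cyc, mcu)
  gate_et <- execution_time(cycles(op_count(comp = sp$frame_len), mcu), mcu)
  sampler_et_per_period <- if (adaptive)
    execution_time(cycles(sampler_op_count(spar, 1,
                                           g = ncol(data[[1]]$channels)), mcu),
                   mcu) else 0

  per <- lapply(seq_along(data), function(i) {
    sig <- data[[i]]
    stream <- run_sampler(sig, spar, if (adaptive) "adaptive" else "uniform")
    masked <- if (adaptive) apply_sampling(sig, stream) else sig
    spotter <- if (identical(spotters, "oracle")) "oracle" else spotters[[i]]
    ev <- spot_events(masked, spotter, sp)
    pr <- sample_prf(sig$events, ev, nrow(sig$channels), sig$sample_rate)
    n_frames <- nrow(sig$channels) %/% sp$frame_len
    n_proc <- attr(ev, "n_processed")
    T_s <- sig$duration
    gated_cost <- if (sp$kind == "wpd") n_frames * gate_et else 0
    active_et <- n_proc * frame_et + gated_cost +
      length(stream$duty_trace) * sampler_et_per_period
    ec_mcu <- tryCatch(mcu_energy(active_et, T_s, mcu), error = function(e) NA)
    n_events <- nrow(ev)
    blocks <- n_events                    # one block write per stored event
    list(P = pr$P, R = pr$R, F1 = pr$F1,
         reduction = stream$reduction,
         duty_trace = stream$duty_trace,
         n_frames = n_frames, n_proc = n_proc, n_events = n_events,
         active_et = active_et, T_s = T_s,
         ec_mcu = ec_mcu,
         ec_sensor = sensor_energy(stream$duty_trace, sensor,
                                   tr = spar$period_s),
         ec_mem = memory_energy(blocks, mcu, T_s),
         ec_radio = radio_energy(n_events, radio))
  })

  mean_of <- function(fld) mean(vapply(per, `[[`, numeric(1), fld))
  over_committed <- anyNA(vapply(per, `[[`, numeric(1), "ec_mcu"))
  ec_parts <- c(mcu = if (over_committed) Inf else mean_of("ec_mcu"),
                sensor = mean_of("ec_sensor"),
                memory = mean_of("ec_mem"),
                radio = mean_of("ec_radio"))
  EC <- if (over_committed) Inf else as.numeric(total_energy(ec_parts))
  ET <- if (mode == "real_time") frame_et else mean_of("active_et")
  peak <- ring_buffer_peak(frame_et, sp$m_s, per[[1]]$n_frames)
  MD <- as.numeric(memory_demand(ops[setdiff(names(ops), "total")],
                                 sp$frame_len, ncol(data[[1]]$channels),
                                 mcu, mode, n_events = 1,
                                 buffer_peak_frames = peak))
  CL <- comm_latency(frame_et, m_e_bits = 32, radio)
  metrics <- metric_vector(P = mean_of("P"), R = mean_of("R"),
                           ET = ET, EC = min(EC, .Machine$double.xmax),
                           MD = MD, CL = CL)
  list(metrics = metrics,
       diagnostics = list(per_participant = per, ec_breakdown = ec_parts,
                          over_committed = over_committed,
                          mean_reduction = mean_of("reduction"),
                          mean_F1 = mean_of("F1"),
                          buffer_peak_frames = peak))
}

#' Exhaustive exploration of a design space
#'
#' Enumerates every configuration, evaluates it on the supplied streams and
#' reports raw metrics, requirement-normalised metrics and feasibility per
#' row, plus the selected optimum (maximum benefit sum among feasible
#' configurations, ties broken by lower energy then enumeration order).
#' Per-configuration failures are recorded in the report, never abort the
#' sweep.
#'
#' @param space a [design_space()].
#' @param data list of [annotated_signal()]s.
#' @param req a [requirement_set()].
#' @param spotter_cache `"oracle"` or the result of
#'   [train_spotter_cache()].
#' @param profiles hardware profiles.
#' @return An `exploration_report`: data frame `table` (one row per
#'   configuration), list `evaluated`, and `optimum` (`NULL` when nothing
#'   is feasible).
#' @export
run_exploration <- function(space, data, req, spotter_cache = "oracle",
                            profiles = hardware_profiles()) {
  cfgs <- enumerate_configurations(space)
  evaluated <- vector("list", length(cfgs))
  rows <- vector("list", length(cfgs))
  for (i in seq_along(cfgs)) {
    cfg <- cfgs[[i]]
    res <- tryCatch({
      spotters <- if (identical(spotter_cache, "oracle")) "oracle"
                  else spotter_cache[[.cfg_algo_key(cfg)]]
      evaluate_configuration(cfg, data, spotters, req, profiles)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(config = .cfg_label(cfg), P = NA, R = NA,
                              ET = NA, EC = NA, MD = NA, CL = NA,
                              reduction = NA, feasible = FALSE,
                              error = conditionMessage(res))
      next
    }
    evaluated[[i]] <- list(configuration = cfg, metrics = res$metrics,
                           diagnostics = res$diagnostics)
    nm <- normalize_metrics(res$metrics, req)
    m <- res$metrics
    rows[[i]] <- data.frame(config = .cfg_label(cfg),
                            P = m[["P"]], R = m[["R"]], ET = m[["ET"]],
                            EC = m[["EC"]], MD = m[["MD"]], CL = m[["CL"]],
                            reduction = res$diagnostics$mean_reduction,
                            norm_P = nm$benefit[["P"]],
                            norm_R = nm$benefit[["R"]],
                            norm_ET = nm$cost[["ET"]],
                            norm_EC = nm$cost[["EC"]],
                            norm_MD = nm$cost[["MD"]],
                            feasible = nm$feasible, error = "")
  }
  table <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(c("norm_P", "norm_R", "norm_ET", "norm_EC", "norm_MD"),
                    names(r))
    for (mcol in miss) r[[mcol]] <- NA
    r[c("config", "P", "R", "ET", "EC", "MD", "CL", "reduction",
        "norm_P", "norm_R", "norm_ET", "norm_EC", "norm_MD",
        "feasible", "error")]
  }))
  ok <- !vapply(evaluated, is.null, logical(1))
  optimum <- select_optimal(evaluated[ok], req)
  structure(list(table = table, evaluated = evaluated, optimum = optimum,
                 requirements = req),
            class = "exploration_report")
}

.cfg_label <- function(cfg) {
  paste(vapply(names(cfg), function(fid) {
    ch <- cfg[[fid]]
    if (length(ch$params))
      paste0(ch$component, "(", paste(names(ch$params), unlist(ch$params),
                                      sep = "=", collapse = ","), ")")
    else ch$component
  }, character(1)), collapse = " | ")
}

#' @export
print.exploration_report <- function(x, ...) {
  cat("<exploration_report> ", nrow(x$table), " configurations, ",
      sum(x$table$feasible, na.rm = TRUE), " feasible\n", sep = "")
  if (is.null(x$optimum)) cat("no feasible configuration\n")
  else {
    cat("optimum:\n")
    print(x$optimum$configuration)
  }
  invisible(x)
}

#' Write an exploration report as delimited text
#'
#' @param report an `exploration_report`.
#' @param path output TSV path.
#' @export
write_report <- function(report, path) {
  utils::write.table(report$table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
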