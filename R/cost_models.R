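#' Machine cycles for an operation count on a microcontroller
#'
#' The machine-cycle model prices each arithmetic operation class
#' (add/subtract, multiply, divide, square root, compare, exponential) with
#' the per-operation cycle cost of the target microcontroller and sums:
#' \deqn{n^{cyc}_f = \sum_x n^{op}_{f,x} \cdot n^{cyc}_x.}
#'
#' @param counts an [op_count()].
#' @param mcu an `mcu_profile` (see [hardware_profiles()]).
#' @return Total machine cycles (numeric scalar).
#' @examples
#' mcu <- hardware_profiles()$arm_cortexm3
#' cycles(kernel_svm_op_count(v = 1500), mcu)   # ~24e4
#' @export
cycles <- function(counts, mcu) {
  stopifnot(inherits(counts, "op_count"), inherits(mcu, "mcu_profile"))
  tab <- unlist(mcu$cycles)[c("add", "mult", "div", "root", "comp", "exp")]
  if (anyNA(tab)) stop("mcu profile cycle table is incomplete")
  sum(counts$counts * tab)
}

#' Execution time of a cycle count
#'
#' Cycles divided by the microcontroller clock frequency.
#'
#' @param n_cycles machine cycles (>= 0).
#' @param mcu an `mcu_profile`.
#' @return Seconds.
#' @export
execution_time <- function(n_cycles, mcu) {
  stopifnot(n_cycles >= 0, inherits(mcu, "mcu_profile"))
  n_cycles / mcu_clock_hz(mcu)
}

#' Aggregate per-function execution times by runtime mode
#'
#' In real-time mode the constraint applies per data frame, so ET is the sum
#' of the function times within one frame (to be compared with the frame
#' length m). In online mode processing may lag behind acquisition, so ET is
#' the total over all frames (to be compared with the runtime T).
#'
#' @param frame_ets numeric vector of per-function execution times in
#'   seconds. For `online` mode, supply the concatenated times of all frames.
#' @param mode `"real_time"` or `"online"`.
#' @return ET in seconds.
#' @export
et_aggregate <- function(frame_ets, mode = c("real_time", "online")) {
  mode <- match.arg(mode)
  if (length(frame_ets) == 0) return(0)
  stopifnot(all(frame_ets >= 0))
  sum(frame_ets)
}

#' Microcontroller energy consumption
#'
#' Active energy is execution time times active power; the remainder of the
#' runtime is spent in stand-by at stand-by power. Times are converted to
#' hours internally so the result is in mWh.
#'
#' @param active_et_s total active (computing) time in seconds.
#' @param T_s total runtime in seconds.
#' @param mcu an `mcu_profile`.
#' @return Energy in mWh.
#' @export
mcu_energy <- function(active_et_s, T_s, mcu) {
  stopifnot(active_et_s >= 0, inherits(mcu, "mcu_profile"))
  T_stb_s <- T_s - active_et_s
  if (T_stb_s < 0)
    stop("active time exceeds runtime: schedule is infeasible")
  (active_et_s / 3600) * mcu_power_active_mW(mcu) +
    (T_stb_s / 3600) * mcu_power_standby_mW(mcu)
}

#' Sensor energy consumption under a duty-cycle trace
#'
#' Per simulation step of length `tr` the sensor draws its active current
#' for a fraction D_t of the step and its stand-by current for the rest:
#' \deqn{EC^s = \sum_t [I_{act} D_t + I_{stb}(1 - D_t)] \cdot V \cdot t_r.}
#'
#' @param duty_trace numeric vector of duty-cycle rates in [0, 1], one per
#'   simulation step.
#' @param sensor a `sensor_profile`.
#' @param tr step length in seconds (default 1).
#' @return Energy in mWh.
#' @export
sensor_energy <- function(duty_trace, sensor, tr = 1) {
  stopifnot(inherits(sensor, "sensor_profile"),
            all(duty_trace >= 0 & duty_trace <= 1))
  I_mA <- sensor$I_act_mA * duty_trace + sensor$I_stb_mA * (1 - duty_trace)
  sum(I_mA * sensor$V * (tr / 3600))
}

#' Non-volatile memory energy consumption
#'
#' Writing a block costs write current times voltage times write time; read
#' energy is neglected. A static stand-by term covers the rest of the
#' runtime (the shipped profiles carry a zero memory stand-by current).
#'
#' @param blocks_written number of memory blocks written.
#' @param mcu an `mcu_profile` (supplies block write current/time and the
#'   memory stand-by current `I_stb_mem_mA`).
#' @param T_s total runtime in seconds.
#' @return Energy in mWh.
#' @export
memory_energy <- function(blocks_written, mcu, T_s) {
  stopifnot(blocks_written >= 0, inherits(mcu, "mcu_profile"))
  tw_h <- mcu$t_write_ms / 1000 / 3600
  write_h <- blocks_written * tw_h
  if (T_s / 3600 < write_h)
    stop("total write time exceeds runtime")
  I_write_mA <- mcu$I_write_uA / 1000
  I_stb_mA <- if (is.null(mcu$I_stb_mem_mA)) 0 else mcu$I_stb_mem_mA
  blocks_written * I_write_mA * mcu$V * tw_h +
    I_stb_mA * mcu$V * (T_s / 3600 - write_h)
}

#' Radio transmission energy consumption
#'
#' Each packet costs the transmit current times voltage times the packet
#' preparation/transmission time.
#'
#' @param n_packets number of packets transmitted.
#' @param radio a `radio_profile`.
#' @param V radio supply voltage in volts (default system rail 3.3 V).
#' @return Energy in mWh.
#' @export
radio_energy <- function(n_packets, radio, V = 3.3) {
  stopifnot(n_packets >= 0, inherits(radio, "radio_profile"))
  n_packets * radio$I_trans_mA * V * (radio$t_trans_ms / 1000 / 3600)
}

#' Total energy consumption
#'
#' Sum of the microcontroller, sensor, memory and radio terms. The
#' breakdown is retained as an attribute for reporting.
#'
#' @param parts named numeric vector or list of energy terms in mWh.
#' @return Total in mWh with attribute `breakdown`.
#' @export
total_energy <- function(parts) {
  parts <- unlist(parts)
  stopifnot(all(parts >= 0))
  structure(sum(parts), breakdown = parts)
}

#' Energy budget implied by a battery and required runtime
#'
#' The per-runtime energy requirement is the battery capacity divided by
#' the required runtime, derated by a factor phi in (0, 1] for external
#' effects on battery life: z = BC / RT * phi.
#'
#' @param battery a `battery_profile` (capacity mWh, runtime h, derating).
#' @return Budget in mWh.
#' @examples
#' energy_requirement(hardware_profiles()$battery)  # 52.03125
#' @export
energy_requirement <- function(battery) {
  stopifnot(inherits(battery, "battery_profile"),
            battery$derating > 0, battery$derating <= 1)
  battery$capacity_mWh / battery$runtime_h * battery$derating
}

#' Peak ring-buffer occupancy for online processing
#'
#' In online mode frames are buffered while the processor catches up. A
#' frame arrives every `frame_s` seconds and takes `frame_et_s` seconds to
#' service; the queue is simulated frame by frame and the peak occupancy
#' (in frames, including the one in service) returned. When the service
#' rate keeps up (ET < frame length) the peak is 1.
#'
#' @param frame_et_s processing time per frame, seconds.
#' @param frame_s frame duration, seconds.
#' @param n_frames number of frames in the runtime.
#' @return Peak number of buffered frames.
#' @export
ring_buffer_peak <- function(frame_et_s, frame_s, n_frames) {
  stopifnot(frame_et_s >= 0, frame_s > 0, n_frames >= 0)
  if (n_frames == 0) return(0)
  # Closed-form queue: backlog after frame i is i - floor(i*frame_s/ET)
  # bounded below by 0; with deterministic arrivals/service the peak is at
  # the last arrival.
  if (frame_et_s <= frame_s) return(1)
  done_by_end <- floor((n_frames - 1) * frame_s / frame_et_s)
  n_frames - done_by_end
}

#' Memory demand of a configuration
#'
#' Upper bound MD = m_c + m_d + sum_f m_f + m_e: code memory, data memory
#' (one frame in real-time mode, the ring-buffer peak in online mode),
#' per-function working memory from the operation-count tables, and event
#' memory (two 2-byte timestamps per retrieved event).
#'
#' @param op_counts list of per-function [op_count()]s whose int/float
#'   memory cells contribute working memory.
#' @param frame_len frame length in samples.
#' @param n_channels number of signal channels.
#' @param mcu an `mcu_profile` (int cell size = resolution/8).
#' @param mode `"real_time"` or `"online"`.
#' @param n_events retrieved events held in memory.
#' @param buffer_peak_frames peak ring-buffer occupancy in frames (online
#'   mode; see [ring_buffer_peak()]).
#' @param code_bytes code memory m_c (default 8 KiB).
#' @param float_bytes float cell size (default 4).
#' @return MD in bytes, with attribute `breakdown`.
#' @export
memory_demand <- function(op_counts, frame_len, n_channels, mcu,
                          mode = c("real_time", "online"),
                          n_events = 0, buffer_peak_frames = 1,
                          code_bytes = 8192, float_bytes = 4) {
  mode <- match.arg(mode)
  stopifnot(inherits(mcu, "mcu_profile"))
  int_bytes <- mcu$resolution_bits / 8
  frame_bytes <- frame_len * n_channels * float_bytes
  m_d <- if (mode == "real_time") frame_bytes
         else frame_bytes * max(1, buffer_peak_frames)
  m_f <- sum(vapply(op_counts, function(oc)
    oc$int_cells * int_bytes + oc$float_cells * float_bytes, numeric(1)))
  m_e <- 4 * n_events
  structure(code_bytes + m_d + m_f + m_e,
            breakdown = c(code = code_bytes, data = m_d,
                          functions = m_f, events = m_e))
}

#' Communication latency of delivering retrieved event information
#'
#' The latency is the processing time plus the transmission time of the
#' event payload at the effective BLE data rate, which is the maximum
#' payload size divided by the connection interval.
#'
#' @param et_sum_s total processing time in seconds.
#' @param m_e_bits event payload size in bits.
#' @param radio a `radio_profile`.
#' @param conn_interval_ms BLE connection interval in ms (must lie on the
#'   profile's admissible grid).
#' @return Latency in seconds.
#' @export
comm_latency <- function(et_sum_s, m_e_bits, radio,
                         conn_interval_ms = radio$conn_interval_min_ms) {
  stopifnot(inherits(radio, "radio_profile"), et_sum_s >= 0, m_e_bits >= 0)
  if (conn_interval_ms < radio$conn_interval_min_ms ||
      conn_interval_ms > radio$conn_interval_max_ms)
    stop("connection interval outside the admissible BLE range")
  rate_bits_per_s <- radio$mps_bits / (conn_interval_ms / 1000)
  et_sum_s + m_e_bits / rate_bits_per_s
}
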