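#' Load a hardware profile from a YAML file
#'
#' Hardware profiles describe the electrical and timing characteristics of
#' the components a candidate device can be built from: microcontrollers
#' (per-operation machine cycles, clock, currents, memory capacities and
#' write costs), the EMG sensing front-end, the BLE radio and the battery.
#' The package ships profiles for a PSoC1 M8C, a TI MSP430F1611, an
#' ARM CortexM3, a 256 Hz EMG front-end, a BLE radio and a 925 mWh Li-Ion
#' battery; see [hardware_profiles()].
#'
#' @param path path to a YAML profile file.
#' @return A list with class `hw_profile` and a subclass of
#'   `mcu_profile`, `sensor_profile`, `radio_profile` or `battery_profile`
#'   according to the `kind` field.
#' @export
read_profile <- function(path) {
  prof <- yaml::read_yaml(path)
  if (is.null(prof$kind))
    stop("profile file lacks a 'kind' field: ", path)
  cls <- switch(prof$kind,
                mcu = "mcu_profile",
                sensor = "sensor_profile",
                radio = "radio_profile",
                battery = "battery_profile",
                stop("unknown profile kind: ", prof$kind))
  structure(prof, class = c(cls, "hw_profile"))
}

#' Shipped hardware profiles
#'
#' @param dir directory of profile YAML files; defaults to the profiles
#'   shipped with the package.
#' @return Named list of `hw_profile` objects keyed by file stem
#'   (e.g. `arm_cortexm3`, `emg_sensor`, `battery`).
#' @examples
#' p <- hardware_profiles()
#' p$arm_cortexm3$cycles$add
#' @export
hardware_profiles <- function(dir = system.file("extdata", "profiles",
                                                package = "dyndse")) {
  files <- sort(list.files(dir, pattern = "\\.ya?ml$", full.names = TRUE))
  profs <- lapply(files, read_profile)
  names(profs) <- tools::file_path_sans_ext(basename(files))
  profs
}

#' @export
print.hw_profile <- function(x, ...) {
  cat("<", class(x)[1], "> ", x$name, "\n", sep = "")
  utils::str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

# Clock frequency in Hz.
mcu_clock_hz <- function(mcu) mcu$clock_mhz * 1e6

# Active / stand-by power in mW (mA * V).
mcu_power_active_mW <- function(mcu) mcu$I_act_mA * mcu$V
mcu_power_standby_mW <- function(mcu) mcu$I_stb_mA * mcu$V

# Memory capacities in bytes (profile stores the datasheet kB figures).
mcu_ram_bytes <- function(mcu) mcu$ram_kB * 1024
mcu_flash_bytes <- function(mcu) mcu$flash_kB * 1024
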