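# Micro-controller feasibility accounting.
#
# Current figures are in micro-amperes throughout: the reference platform
# (an 80 MHz Cortex-M4 class part) draws ~10.2 mA active and ~1.6 uA in its
# deep-sleep mode, and duty-cycled operation brings the average down to
# tens of uA, which is what makes multi-year battery life possible.

#' Energy and timing model of the target micro-controller
#'
#' Defaults describe an 80 MHz Cortex-M4 (STM32L476RG class): about 9 CPU
#' cycles per FP32 multiply-accumulate, 10.2 mA active current, 1.6 uA in
#' low-power stop mode, one inference every 90 s window, powered by a
#' 2600 mAh 3.6 V lithium cell.
#'
#' @param clock_hz CPU clock (Hz)
#' @param cycles_per_macc CPU cycles per multiply-accumulate
#' @param active_current_mA current draw while computing (mA)
#' @param sleep_current_uA current draw in low-power mode (uA)
#' @param window_period_s seconds between inferences
#' @param battery_capacity_mAh battery capacity (mAh)
#' @param sensor_current_uA optional average accelerometer sampling
#'   current (uA) added to the duty-cycle average; excluded (0) by default
#' @return an `energy_model`
#' @export
energy_model <- function(clock_hz = 80e6, cycles_per_macc = 9,
                         active_current_mA = 10.2, sleep_current_uA = 1.6,
                         window_period_s = 90, battery_capacity_mAh = 2600,
                         sensor_current_uA = 0) {
  vals <- c(clock_hz, cycles_per_macc, active_current_mA, sleep_current_uA,
            window_period_s, battery_capacity_mAh)
  if (any(vals <= 0)) stop("all energy-model constants must be positive",
                           call. = FALSE)
  structure(
    list(clock_hz = clock_hz, cycles_per_macc = cycles_per_macc,
         active_current_mA = active_current_mA,
         sleep_current_uA = sleep_current_uA,
         window_period_s = window_period_s,
         battery_capacity_mAh = battery_capacity_mAh,
         sensor_current_uA = sensor_current_uA,
         hours_per_year = 8760),
    class = "energy_model"
  )
}

#' CPU cycles for a forward pass
#'
#' @param n_ops multiply-accumulate count
#' @param model an [energy_model()]
#' @return cycle count `n_ops * cycles_per_macc`
#' @export
cpu_cycles <- function(n_ops, model = energy_model()) {
  stopifnot(n_ops >= 0)
  n_ops * model$cycles_per_macc
}

#' Inference wall time
#'
#' @param cycles CPU cycle count
#' @param model an [energy_model()]
#' @return seconds, `cycles / clock_hz`
#' @export
inference_time_s <- function(cycles, model = energy_model()) {
  stopifnot(cycles >= 0)
  cycles / model$clock_hz
}

#' Duty-cycled average current
#'
#' Convex combination of active and sleep current over one window period:
#' the device computes for `active_s` seconds and sleeps for the rest.
#' The optional sensor sampling current is added on top.
#'
#' @param active_s active (computing) seconds per window period
#' @param model an [energy_model()]
#' @return average current in uA
#' @export
average_current_uA <- function(active_s, model = energy_model()) {
  if (active_s < 0 || active_s > model$window_period_s) {
    stop("active_s must lie within [0, window_period_s]", call. = FALSE)
  }
  act_uA <- model$active_current_mA * 1000
  avg <- (act_uA * active_s +
            model$sleep_current_uA * (model$window_period_s - active_s)) /
    model$window_period_s
  avg + model$sensor_current_uA
}

#' Battery lifetime
#'
#' @param avg_current_uA average current draw (uA)
#' @param model an [energy_model()]
#' @return lifetime in years at the model's battery capacity
#' @export
battery_life_years <- function(avg_current_uA, model = energy_model()) {
  if (avg_current_uA <= 0) stop("average current must be positive",
                                call. = FALSE)
  model$battery_capacity_mAh * 1000 / avg_current_uA / model$hours_per_year
}

#' Full deployment feasibility report
#'
#' Chains the accounting: parameters and MACCs of the architecture, memory
#' per precision with an SRAM-fit flag, CPU cycles, inference time,
#' duty-cycled average current and battery lifetime.
#'
#' @param spec an [architecture_spec()]
#' @param input_length input samples per axis
#' @param model an [energy_model()]
#' @param sram_limit_kb SRAM budget of the target (kB)
#' @param reference optional reference [architecture_spec()] for
#'   compression/speed-up ratios
#' @return a `deployment_report`
#' @export
deployment_report <- function(spec, input_length = 899,
                              model = energy_model(), sram_limit_kb = 128,
                              reference = NULL) {
  comp <- complexity_report(spec, input_length, reference)
  cycles <- cpu_cycles(comp$n_macc, model)
  t_inf <- inference_time_s(cycles, model)
  avg <- average_current_uA(t_inf, model)
  structure(
    list(complexity = comp,
         cycles = cycles,
         inference_time_s = t_inf,
         average_current_uA = avg,
         battery_life_years = battery_life_years(avg, model),
         fits_sram = c(FP32 = comp$memory_kb[["FP32"]] <= sram_limit_kb,
                       FP16 = comp$memory_kb[["FP16"]] <= sram_limit_kb),
         sram_limit_kb = sram_limit_kb,
         energy_model = model),
    class = "deployment_report"
  )
}

#' @export
print.deployment_report <- function(x, ...) {
  print(x$complexity)
  cat(sprintf("  cycles/inference: %.4g  (%.4g ms)\n", x$cycles,
              x$inference_time_s * 1000))
  cat(sprintf("  average current: %.3f uA -> battery life %.2f years\n",
              x$average_current_uA, x$battery_life_years))
  cat(sprintf("  fits %g kB SRAM: FP32 %s, FP16 %s\n", x$sram_limit_kb,
              x$fits_sram[["FP32"]], x$fits_sram[["FP16"]]))
  invisible(x)
}
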