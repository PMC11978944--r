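#' Multi-array probe geometry
#'
#' Describes a motorized multi-array transducer: several linear sub-arrays
#' assembled with a fixed spacing, stepped along the elevation axis by a
#' motor to tile the brain with imaging planes. Defaults follow a 15 MHz
#' four-array probe with 64 elements per array, 0.11 mm pitch and 2.1 mm
#' array spacing, stepped in 525 um increments (one quarter of the array
#' spacing) so that 4 motor stops x 4 arrays give 16 planes.
#'
#' @param n_arrays number of linear sub-arrays.
#' @param elements_per_array elements per sub-array.
#' @param pitch_mm element pitch in mm.
#' @param array_spacing_mm distance between adjacent sub-arrays in mm.
#' @param center_frequency_MHz transmit center frequency in MHz.
#' @param slice_thickness_um elevation slice thickness in um.
#' @return an object of class `probe_geometry`.
#' @export
probe_geometry <- function(n_arrays = 4L, elements_per_array = 64L,
                           pitch_mm = 0.11, array_spacing_mm = 2.1,
                           center_frequency_MHz = 15,
                           slice_thickness_um = 525) {
  stopifnot(n_arrays >= 1, array_spacing_mm > 0, pitch_mm > 0,
            elements_per_array >= 1, center_frequency_MHz > 0,
            slice_thickness_um > 0)
  structure(list(n_arrays = as.integer(n_arrays),
                 elements_per_array = as.integer(elements_per_array),
                 pitch_mm = pitch_mm, array_spacing_mm = array_spacing_mm,
                 center_frequency_MHz = center_frequency_MHz,
                 slice_thickness_um = slice_thickness_um),
            class = "probe_geometry")
}

#' Motorized scan scheme
#'
#' A scan cycle alternates a stationary acquisition period with a motor move
#' to the next position; `n_positions` stops complete one volume. Two schemes
#' are typical: a fast functional scheme (0.4 s imaging / 0.2 s move) and a
#' microbubble scheme that dwells 10 s per stop with 1.2 s moves to maximise
#' the imaging duty cycle.
#'
#' @param acquisition_s stationary imaging time per stop (s).
#' @param move_s motor travel time between stops (s).
#' @param n_positions motor stops per volume.
#' @return an object of class `motor_scheme`.
#' @export
motor_scheme <- function(acquisition_s, move_s, n_positions = 1L) {
  stopifnot(acquisition_s > 0, move_s >= 0, n_positions >= 1)
  structure(list(acquisition_s = acquisition_s, move_s = move_s,
                 n_positions = as.integer(n_positions)),
            class = "motor_scheme")
}

#' Stimulus protocol
#'
#' Block design for evoked acquisitions: a pre-stimulus baseline followed by
#' `n_repeats` ON/OFF cycles. The default is the whisker-stimulation design
#' 30 s baseline, 30 s ON, 30 s OFF repeated five times (330 s total), with
#' mechanical stimulation at 3 Hz.
#'
#' @param baseline_s pre-stimulus baseline duration (s).
#' @param on_s,off_s stimulus ON / OFF block durations (s).
#' @param n_repeats number of ON/OFF cycles.
#' @param stim_rate_Hz within-block stimulation rate (metadata only).
#' @return an object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(baseline_s = 30, on_s = 30, off_s = 30,
                              n_repeats = 5L, stim_rate_Hz = 3) {
  stopifnot(baseline_s >= 0, on_s >= 0, off_s >= 0, n_repeats >= 0)
  structure(list(baseline_s = baseline_s, on_s = on_s, off_s = off_s,
                 n_repeats = as.integer(n_repeats),
                 stim_rate_Hz = stim_rate_Hz),
            class = "stimulus_protocol")
}

#' Acquisition parameters
#'
#' Plane-wave compounding metadata: number of tilted transmits, pulse
#' repetition frequency, compounded frame rate, mechanical index and maximum
#' tilt. Beamforming itself is out of scope; these values parameterize the
#' simulators and reports. Note that 10 angles at a 4 kHz PRF implies a
#' 400 Hz compounded rate while the nominal rate is 500 Hz; the nominal rate
#' is kept as configured and the discrepancy is surfaced by
#' [geometry_report()].
#'
#' @param n_angles number of tilted plane waves per compound frame.
#' @param prf_Hz pulse repetition frequency (Hz).
#' @param compounded_rate_Hz nominal compounded frame rate (Hz).
#' @param mechanical_index transmit mechanical index.
#' @param max_tilt_deg maximum plane-wave tilt (degrees).
#' @return an object of class `acq_params`.
#' @export
acq_params <- function(n_angles = 10L, prf_Hz = 4000, compounded_rate_Hz = 500,
                       mechanical_index = 0.1, max_tilt_deg = 12) {
  stopifnot(n_angles >= 1, prf_Hz > 0, compounded_rate_Hz > 0)
  structure(list(n_angles = as.integer(n_angles), prf_Hz = prf_Hz,
                 compounded_rate_Hz = compounded_rate_Hz,
                 mechanical_index = mechanical_index,
                 max_tilt_deg = max_tilt_deg),
            class = "acq_params")
}

#' Imaging duty cycle of a motor scheme
#'
#' Fraction of wall-clock time spent acquiring, `acq / (acq + move)`. The
#' 10 s / 1.2 s microbubble scheme yields 0.893 (89% to the nearest percent).
#'
#' @param motor a [motor_scheme()].
#' @return fraction in (0, 1].
#' @export
imaging_ratio <- function(motor) {
  stopifnot(inherits(motor, "motor_scheme"))
  cycle <- motor$acquisition_s + motor$move_s
  if (cycle <= 0) stop("non-positive acquisition + move cycle")
  motor$acquisition_s / cycle
}

#' Volume cycle duration and volume rate
#'
#' One volume takes `n_positions * (acquisition_s + move_s)` seconds; the
#' volume rate is its reciprocal. The 4-stop 0.4 s / 0.2 s functional scheme
#' gives 2.4 s per volume (0.42 Hz).
#'
#' @param motor a [motor_scheme()].
#' @return list with `cycle_s` and `rate_Hz`.
#' @export
volume_cycle <- function(motor) {
  stopifnot(inherits(motor, "motor_scheme"))
  cycle <- motor$n_positions * (motor$acquisition_s + motor$move_s)
  list(cycle_s = cycle, rate_Hz = 1 / cycle)
}

#' Imaging plane positions along the motor axis
#'
#' Each of the `n_steps` motor stops shifts all arrays by
#' `array_spacing / n_steps` (525 um for a 2.1 mm spacing and 4 steps), so
#' the interleaved planes of all arrays tile the axis uniformly. Positions
#' are in mm, 0 at the first plane of the first array; `bregma_offset_mm`
#' maps them onto skull coordinates when known.
#'
#' @param probe a [probe_geometry()].
#' @param n_steps number of motor steps.
#' @param bregma_offset_mm offset added to all positions (mm).
#' @return sorted numeric vector of `n_arrays * n_steps` plane positions (mm).
#' @export
plane_positions <- function(probe, n_steps, bregma_offset_mm = 0) {
  stopifnot(inherits(probe, "probe_geometry"), n_steps >= 1)
  step <- probe$array_spacing_mm / n_steps
  pos <- as.vector(outer((seq_len(n_steps) - 1) * step,
                         (seq_len(probe$n_arrays) - 1) * probe$array_spacing_mm,
                         "+"))
  sort(pos) + bregma_offset_mm
}

#' Total duration of a stimulus protocol
#'
#' `baseline + n_repeats * (on + off)`; 330 s for the default design.
#'
#' @param protocol a [stimulus_protocol()].
#' @return duration in seconds.
#' @export
protocol_duration <- function(protocol) {
  stopifnot(inherits(protocol, "stimulus_protocol"))
  protocol$baseline_s + protocol$n_repeats * (protocol$on_s + protocol$off_s)
}

#' Cumulative imaging time per motor position
#'
#' With cycles allocated round-robin over the motor stops, a total recording
#' of `total_s` seconds yields `floor(k / n_positions) * acquisition_s`
#' seconds of imaging at every position, where `k` is the number of complete
#' cycles. A truncated final cycle contributes nothing (conservative). 1000 s
#' under the 10 s / 1.2 s 4-stop scheme gives 220 s per plane.
#'
#' @param total_s total recording duration (s).
#' @param motor a [motor_scheme()].
#' @return seconds of imaging per motor position (minimum over positions).
#' @export
cumulative_imaging_per_plane <- function(total_s, motor) {
  stopifnot(inherits(motor, "motor_scheme"), total_s > 0)
  cycle <- motor$acquisition_s + motor$move_s
  k <- floor(total_s / cycle)
  if (k < 1) {
    warning("total duration shorter than one motor cycle; no complete dwell")
    return(0)
  }
  floor(k / motor$n_positions) * motor$acquisition_s
}

#' Timing and geometry report
#'
#' Collects the derived scan quantities (duty cycles, volume rate, plane
#' tiling, protocol durations) into a printable list, flagging any
#' inconsistency between the configured compounded frame rate and the rate
#' implied by `prf / n_angles`.
#'
#' @param probe a [probe_geometry()].
#' @param motor_fus,motor_ulm motor schemes for functional and microbubble
#'   acquisitions.
#' @param protocol a [stimulus_protocol()].
#' @param acq an [acq_params()].
#' @param n_steps motor steps used for plane tiling.
#' @param ulm_total_s total microbubble recording time (s).
#' @return a list of class `geometry_report`.
#' @export
geometry_report <- function(probe = probe_geometry(),
                            motor_fus = motor_scheme(0.4, 0.2, 4L),
                            motor_ulm = motor_scheme(10, 1.2, 4L),
                            protocol = stimulus_protocol(),
                            acq = acq_params(),
                            n_steps = 4L, ulm_total_s = 1000) {
  vc <- volume_cycle(motor_fus)
  pos <- plane_positions(probe, n_steps)
  implied <- acq$prf_Hz / acq$n_angles
  structure(list(
    n_planes = length(pos),
    plane_step_um = 1000 * probe$array_spacing_mm / n_steps,
    plane_span_mm = diff(range(pos)),
    fus_volume_cycle_s = vc$cycle_s,
    fus_volume_rate_Hz = vc$rate_Hz,
    fus_imaging_ratio = imaging_ratio(motor_fus),
    ulm_imaging_ratio = imaging_ratio(motor_ulm),
    fus_protocol_s = protocol_duration(protocol),
    ulm_total_s = ulm_total_s,
    ulm_imaging_per_plane_s = cumulative_imaging_per_plane(ulm_total_s, motor_ulm),
    compounded_rate_Hz = acq$compounded_rate_Hz,
    implied_compound_rate_Hz = implied,
    rate_consistent = isTRUE(all.equal(implied, acq$compounded_rate_Hz))
  ), class = "geometry_report")
}

#' @export
print.geometry_report <- function(x, ...) {
  cat("Scan timing/geometry report\n")
  cat(sprintf("  planes: %d, step %.0f um, span %.3f mm\n",
              x$n_planes, x$plane_step_um, x$plane_span_mm))
  cat(sprintf("  fUS volume: %.2f s (%.2f Hz), imaging ratio %.0f%%\n",
              x$fus_volume_cycle_s, x$fus_volume_rate_Hz,
              100 * x$fus_imaging_ratio))
  cat(sprintf("  ULM imaging ratio %.0f%%, %.0f s per plane over %.0f s\n",
              100 * x$ulm_imaging_ratio, x$ulm_imaging_per_plane_s,
              x$ulm_total_s))
  cat(sprintf("  fUS protocol duration %.0f s\n", x$fus_protocol_s))
  cat(sprintf("  compounded rate %.0f Hz (prf/n_angles implies %.0f Hz%s)\n",
              x$compounded_rate_Hz, x$implied_compound_rate_Hz,
              if (x$rate_consistent) "" else "; inconsistent"))
  invisible(x)
}

#' @export
print.probe_geometry <- function(x, ...) {
  cat(sprintf("multi-array probe: %d x %d elements, %.2f mm pitch, %.1f MHz\n",
              x$n_arrays, x$elements_per_array, x$pitch_mm,
              x$center_frequency_MHz))
  cat(sprintf("  array spacing %.2f mm, slice thickness %.0f um\n",
              x$array_spacing_mm, x$slice_thickness_um))
  invisible(x)
}
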