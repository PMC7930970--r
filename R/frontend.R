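#' Capacitive coupling geometry
#'
#' Parallel-plate model of the skin/insulator/electrode coupling. The
#' permittivity default is treated as the absolute permittivity in F/m
#' (the plate-capacitor arithmetic only works that way), with the default
#' coupling area and distance of the in-pillow cloth electrode.
#'
#' @param epsilon Permittivity, F/m.
#' @param area_s Coupling area, m^2.
#' @param distance_d Coupling distance, m.
#' @return An object of class `coupling_spec`.
#' @export
coupling_spec <- function(epsilon = 8.85e-12, area_s = 2.00e-3,
                          distance_d = 3.08e-4) {
  if (any(c(epsilon, area_s, distance_d) <= 0)) {
    stop("all coupling parameters must be > 0", call. = FALSE)
  }
  structure(list(epsilon = epsilon, area_s = area_s,
                 distance_d = distance_d),
            class = "coupling_spec")
}

#' Bootstrapped-varistor front-end component values
#'
#' Component values of the front-end voltage follower (FVF) whose input
#' impedance is boosted by a bootstrapped varistor: series resistor `r1`,
#' bootstrap resistor `r3`, varistor high-state resistance `rh`, varistor
#' threshold voltage `v_thr`, and the op-amp input impedance.
#'
#' @param r1 Series resistance, Ohm (default 99 MOhm).
#' @param r3 Bootstrap resistance, Ohm (default 10 kOhm).
#' @param rh Varistor high-state resistance, Ohm (default 250 MOhm).
#' @param v_thr Varistor threshold voltage, V (default 8).
#' @param opamp_zin Op-amp input impedance, Ohm (default 10 TOhm).
#' @return An object of class `fvf_spec`.
#' @export
fvf_spec <- function(r1 = 99e6, r3 = 10e3, rh = 250e6, v_thr = 8,
                     opamp_zin = 10e12) {
  if (any(c(r1, r3, rh, v_thr, opamp_zin) <= 0)) {
    stop("all FVF parameters must be > 0", call. = FALSE)
  }
  structure(list(r1 = r1, r3 = r3, rh = rh, v_thr = v_thr,
                 opamp_zin = opamp_zin),
            class = "fvf_spec")
}

#' Parallel-plate coupling capacitance
#'
#' `C = epsilon * S / d`; about 57.5 pF at the default geometry.
#'
#' @param spec A [coupling_spec()].
#' @return Capacitance in farads.
#' @export
coupling_capacitance <- function(spec = coupling_spec()) {
  stopifnot(inherits(spec, "coupling_spec"))
  spec$epsilon * spec$area_s / spec$distance_d
}

#' Capacitive reactance of the coupling
#'
#' `X_C = 1 / (2 pi f C)`: about 277 MOhm at 10 Hz and half that at
#' 20 Hz for the default coupling, spanning the dominant R-wave band.
#'
#' @param C Capacitance, farads.
#' @param f Frequency, Hz.
#' @return Reactance magnitude in Ohm.
#' @export
capacitive_reactance <- function(C, f) {
  stopifnot(C > 0, f > 0)
  1 / (2 * pi * f * C)
}

#' Idealized varistor resistance
#'
#' High-state resistance `rh` below the threshold voltage, zero above it
#' (ideal clamp). The boundary `|v| == v_thr` is assigned to the clamped
#' branch (the defining inequality is open below threshold, so a
#' convention is required).
#'
#' @param v_applied Voltage across the varistor, V.
#' @param spec An [fvf_spec()].
#' @return Resistance in Ohm (vectorized over `v_applied`).
#' @export
varistor_resistance <- function(v_applied, spec = fvf_spec()) {
  stopifnot(inherits(spec, "fvf_spec"))
  ifelse(abs(v_applied) < spec$v_thr, spec$rh, 0)
}

#' Bootstrapped input impedance of the FVF
#'
#' `Z = r1 + r_bv + r1 * r_bv / r3` with `r_bv` the varistor resistance
#' at the applied voltage. Below threshold this is dominated by
#' `r1 * rh / r3` (about 2.5 TOhm at the default components); above
#' threshold it collapses to `r1`, giving the rapid static-discharge
#' path.
#'
#' @param spec An [fvf_spec()].
#' @param v_applied Voltage across the varistor, V (default 0: below
#'   threshold).
#' @return Input impedance in Ohm.
#' @export
bootstrap_input_impedance <- function(spec = fvf_spec(), v_applied = 0) {
  stopifnot(inherits(spec, "fvf_spec"))
  r_bv <- varistor_resistance(v_applied, spec)
  spec$r1 + r_bv + spec$r1 * r_bv / spec$r3
}

#' Synthesized front-end input impedance
#'
#' Parallel combination of the bootstrapped impedance with the op-amp
#' input impedance: about 2.0 TOhm for 2.475 TOhm in parallel with
#' 10 TOhm.
#'
#' @param z_bt Bootstrapped impedance, Ohm.
#' @param opamp_zin Op-amp input impedance, Ohm (may be `Inf`).
#' @return Impedance in Ohm.
#' @export
synthesized_input_impedance <- function(z_bt, opamp_zin = 10e12) {
  stopifnot(z_bt > 0, opamp_zin > 0)
  if (is.infinite(opamp_zin)) return(z_bt)
  if (is.infinite(z_bt)) return(opamp_zin)
  z_bt * opamp_zin / (z_bt + opamp_zin)
}

#' Capacitive voltage-divider gain
#'
#' The source biopotential is divided between the coupling impedance and
#' the front-end input impedance:
#' `gain = 1 / (z_cap / z_in + 1)`, so `v_in = gain * e_s`. When
#' `z_in >> z_cap` the follower sees nearly the full source voltage.
#' Impedances are treated as real magnitudes at the stated frequency.
#'
#' @param z_cap Coupling impedance magnitude, Ohm.
#' @param z_in Front-end input impedance magnitude, Ohm.
#' @param e_s Optional source amplitude, V.
#' @return The dimensionless gain in (0, 1], or `gain * e_s` when `e_s`
#'   is given.
#' @export
divider_gain <- function(z_cap, z_in, e_s = NULL) {
  stopifnot(z_cap > 0, z_in > 0)
  g <- 1 / (z_cap / z_in + 1)
  if (is.null(e_s)) g else g * e_s
}

#' Effective clamp threshold at the FVF input
#'
#' The varistor sees only the fraction `rh / (rh + r3)` of the input
#' voltage, so clamping engages when the input exceeds
#' `v_thr * (1 + r3 / rh)` — marginally above the varistor's own
#' threshold for realistic component values.
#'
#' @param spec An [fvf_spec()].
#' @return Effective threshold in volts.
#' @export
effective_clamp_threshold <- function(spec = fvf_spec()) {
  stopifnot(inherits(spec, "fvf_spec"))
  spec$v_thr * (1 + spec$r3 / spec$rh)
}

#' Front-end circuit report
#'
#' Evaluates the whole analytic front-end model at a set of frequencies:
#' coupling capacitance, capacitive reactance, bootstrapped and
#' synthesized input impedance below/above threshold, divider gain, and
#' the effective clamp threshold.
#'
#' @param coupling A [coupling_spec()].
#' @param fvf An [fvf_spec()].
#' @param freqs Frequencies (Hz) at which reactance and gain are reported.
#' @return A list of class `frontend_report`.
#' @export
frontend_report <- function(coupling = coupling_spec(), fvf = fvf_spec(),
                            freqs = c(10, 15, 20)) {
  C <- coupling_capacitance(coupling)
  z_bt_lo <- bootstrap_input_impedance(fvf, v_applied = 0)
  z_bt_hi <- bootstrap_input_impedance(fvf, v_applied = 2 * fvf$v_thr)
  z_syn <- synthesized_input_impedance(z_bt_lo, fvf$opamp_zin)
  xc <- vapply(freqs, function(f) capacitive_reactance(C, f), 0)
  structure(list(
    capacitance_F = C,
    frequencies_Hz = freqs,
    reactance_Ohm = stats::setNames(xc, paste0(freqs, "Hz")),
    z_bootstrap_below_Ohm = z_bt_lo,
    z_bootstrap_above_Ohm = z_bt_hi,
    z_synthesized_Ohm = z_syn,
    divider_gain = stats::setNames(
      vapply(xc, function(z) divider_gain(z, z_syn), 0),
      paste0(freqs, "Hz")),
    effective_clamp_threshold_V = effective_clamp_threshold(fvf)),
    class = "frontend_report")
}

#' @export
print.frontend_report <- function(x, ...) {
  cat("<frontend_report>\n")
  cat(sprintf("  coupling capacitance: %.3g pF\n", x$capacitance_F * 1e12))
  cat(sprintf("  X_C: %s\n",
              paste(sprintf("%s = %.3g MOhm", names(x$reactance_Ohm),
                            x$reactance_Ohm / 1e6), collapse = ", ")))
  cat(sprintf("  Z_in (bootstrap, below/above threshold): %.3g / %.3g TOhm\n",
              x$z_bootstrap_below_Ohm / 1e12, x$z_bootstrap_above_Ohm / 1e12))
  cat(sprintf("  Z_in (synthesized with op-amp): %.3g TOhm\n",
              x$z_synthesized_Ohm / 1e12))
  cat(sprintf("  effective clamp threshold: %.6g V\n",
              x$effective_clamp_threshold_V))
  invisible(x)
}
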