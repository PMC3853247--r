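#' Analytic drug concentration after a single subcutaneous dose
#'
#' Superposition of the two absorption routes into the central
#' compartment: a zero-order input of `fz * dose` over `[0, d2]` and a
#' lagged first-order input of the remaining `(1 - fz) * dose` starting at
#' `alag`, both eliminated first-order with `ke = cl_f / v_f`.  The
#' solution is closed-form (the `ka == ke` degeneracy uses the analytic
#' `t * ke * exp(-ke t)` limit), continuous, non-negative, and linear in
#' the dose.
#'
#' @param p A [pk_parameters()] object.
#' @param dose A [dose_event()].
#' @param t Times after dose (h), all >= 0.
#' @return Concentrations (pg/mL) at `t`.
#' @export
pk_concentration <- function(p, dose, t) {
  stopifnot(inherits(p, "pk_parameters"), inherits(dose, "dose_event"))
  if (any(!is.finite(t)) || any(t < 0)) stop("times must be finite and >= 0")
  cpp_pk_conc(as.numeric(t), dose$mass_ug, p$cl_f, p$v_f, p$d2, p$ka,
              p$alag, p$fz)
}

#' Time-varying half-maximal concentration
#'
#' `EC50(t) = ecb * (1 + ca * (1 - exp(-cb t)))`: the exponential CDF
#' shape raises EC50 from its baseline `ecb` at the time of injection
#' towards the plateau `ecb * (1 + ca)`, encoding the apparent tolerance
#' that flattens the neopterin dose-response.
#'
#' @param p A [pd_parameters()] object.
#' @param t Times after dose (h), >= 0.
#' @return EC50 values (pg/mL), monotone non-decreasing in `t`.
#' @export
ec50_at_time <- function(p, t) {
  stopifnot(inherits(p, "pd_parameters"))
  if (any(!is.finite(t)) || any(t < 0)) stop("times must be finite and >= 0")
  p$ecb * (1 + p$ca * (1 - exp(-p$cb * t)))
}

#' Sigmoid stimulation of neopterin production
#'
#' `E(C) = 1 + emax * C^gamma / (ec50^gamma + C^gamma)`, the multiplier
#' applied to the neopterin production rate; 1 with no drug, `1 + emax` at
#' saturation, `1 + emax/2` at `C = ec50`.
#'
#' @param c Drug concentration(s), pg/mL, >= 0.
#' @param emax Maximum stimulation, > 0.
#' @param ec50 Half-maximal concentration(s), pg/mL, > 0.
#' @param gamma Hill coefficient, > 0.
#' @return Unitless multiplier in `[1, 1 + emax]`.
#' @export
stimulation_effect <- function(c, emax, ec50, gamma) {
  if (any(!is.finite(c)) || any(c < 0)) stop("concentrations must be >= 0")
  stopifnot(all(ec50 > 0), gamma > 0)
  cg <- ifelse(c > 0, exp(gamma * log(c)), 0)
  eg <- exp(gamma * log(ec50))
  1 + emax * cg / (eg + cg)
}

#' Neopterin response trajectory
#'
#' Integrates the two PD states (transit compartment and neopterin) driven
#' by the analytic drug concentration through [stimulation_effect()] with
#' [ec50_at_time()], starting from the drug-free steady state
#' `A3(0) = kin/ktr`, `A4(0) = base`.  Two integrators are available: an
#' adaptive Dormand-Prince RK45 that splits the integration at the
#' absorption breakpoints (default, `rtol = 1e-8`, `atol = 1e-10`), and a
#' fixed-step RK4 on a breakpoint-aligned grid (`dt`), the variant the
#' estimation engine uses internally.
#'
#' @param pk A [pk_parameters()] object.
#' @param pd A [pd_parameters()] object.
#' @param dose A [dose_event()], or `NULL` for the drug-free system.
#' @param times Sorted non-negative output times (h).
#' @param method `"rk45"` (adaptive) or `"rk4"` (fixed step).
#' @param rtol,atol Adaptive solver tolerances.
#' @param dt Fixed-step size (h) for `method = "rk4"`.
#' @param const_conc Optional forcing-function test mode: hold the drug
#'   concentration constant at this value instead of the PK model.
#' @return Neopterin concentrations (nmol/L) at `times`.
#' @export
pd_trajectory <- function(pk, pd, dose, times, method = c("rk45", "rk4"),
                          rtol = 1e-8, atol = 1e-10, dt = 0.05,
                          const_conc = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(pk, "pk_parameters"), inherits(pd, "pd_parameters"))
  if (any(!is.finite(times)) || any(times < 0) || is.unsorted(times))
    stop("times must be finite, >= 0 and sorted")
  dose_mass <- if (is.null(dose)) 0 else {
    stopifnot(inherits(dose, "dose_event"))
    dose$mass_ug
  }
  pkv <- c(pk$cl_f, pk$v_f, pk$d2, pk$ka, pk$alag, pk$fz)
  pdv <- c(pd$base, pd$kout, pd$emax, pd$gamma, pd$ca, pd$cb, pd$ecb, pd$mtt)
  cc <- if (is.null(const_conc)) -1 else const_conc
  if (method == "rk45")
    cpp_pd_rk45(as.numeric(times), dose_mass, pkv, pdv, rtol, atol, cc)
  else
    cpp_pd_rk4(as.numeric(times), dose_mass, pkv, pdv, dt, cc)
}
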