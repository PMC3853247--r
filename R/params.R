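#' Logistic map from the unconstrained absorption-split variable to the
#' zero-order dose fraction
#'
#' The fraction of the dose delivered through the zero-order input is
#' parameterised through an unconstrained real `rf` so that estimation and
#' bootstrap resampling can move freely through negative values; the
#' fraction itself is `1 / (1 + exp(-rf))`, strictly inside (0, 1).
#'
#' @param rf Unconstrained real (finite).
#' @return The zero-order fraction, in (0, 1).
#' @examples
#' zero_order_fraction(0)      # 0.5
#' zero_order_fraction(0.185)  # about 0.546
#' @export
zero_order_fraction <- function(rf) {
  if (!is.numeric(rf) || any(!is.finite(rf)))
    stop("`rf` must be finite numeric")
  1 / (1 + exp(-rf))
}

#' Structural pharmacokinetic parameters
#'
#' One-compartment disposition with first-order elimination and a mixed
#' absorption input: a zero-order process delivering a fraction
#' `fz = zero_order_fraction(rf)` of the dose over `d2` hours starting at
#' injection, in parallel with a lagged first-order process (rate `ka`)
#' for the remaining fraction starting at `alag` hours.
#'
#' @param cl_f Apparent clearance CL/F (L/h), > 0.
#' @param v_f Apparent volume V/F (L), > 0.
#' @param d2 Duration of the zero-order absorption (h), > 0.
#' @param ka First-order absorption rate constant (1/h), > 0.
#' @param alag Lag before the first-order input starts (h), >= 0.
#' @param rf Unconstrained real governing the zero-order dose fraction.
#' @return An object of class `pk_parameters` with derived elimination
#'   rate `ke = cl_f / v_f` and zero-order fraction `fz`.
#' @export
pk_parameters <- function(cl_f, v_f, d2, ka, alag, rf) {
  stopifnot(is.finite(cl_f), cl_f > 0, is.finite(v_f), v_f > 0,
            is.finite(d2), d2 > 0, is.finite(ka), ka > 0,
            is.finite(alag), alag >= 0, is.finite(rf))
  structure(list(cl_f = cl_f, v_f = v_f, d2 = d2, ka = ka, alag = alag,
                 rf = rf, ke = cl_f / v_f, fz = zero_order_fraction(rf)),
            class = "pk_parameters")
}

#' Structural pharmacodynamic parameters
#'
#' Turnover (indirect response) model for serum neopterin with a single
#' transit compartment: production `kin` is stimulated by the drug through
#' a sigmoid Emax function whose EC50 rises over time from `ecb` towards
#' the plateau `ecb * (1 + ca)` at rate `cb`.  At baseline the system sits
#' at the drug-free steady state, which ties `kin = kout * base` and
#' `ktr = 1 / mtt`.
#'
#' @param base Baseline neopterin concentration (nmol/L), > 0.
#' @param kout First-order neopterin elimination rate (1/h), > 0.
#' @param emax Maximum stimulatory effect (unitless), > 0.
#' @param gamma Hill coefficient (unitless), > 0.
#' @param ecb Baseline EC50 (pg/mL), > 0.
#' @param ca EC50 plateau coefficient (unitless), > 0.
#' @param cb EC50 rise rate (1/h), > 0.
#' @param mtt Mean transit time (h), > 0.
#' @return An object of class `pd_parameters` with derived `kin` and `ktr`.
#' @export
pd_parameters <- function(base, kout, emax, gamma, ecb, ca, cb, mtt) {
  vals <- c(base = base, kout = kout, emax = emax, gamma = gamma,
            ecb = ecb, ca = ca, cb = cb, mtt = mtt)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all pd parameters must be finite and > 0")
  structure(list(base = base, kout = kout, emax = emax, gamma = gamma,
                 ecb = ecb, ca = ca, cb = cb, mtt = mtt,
                 kin = kout * base, ktr = 1 / mtt),
            class = "pd_parameters")
}

#' Single subcutaneous dose event
#'
#' Doses are prescribed in MIU (million international units) and converted
#' internally to mass with a configurable specific-activity factor
#' (default 5 micrograms per MIU, a typical interferon-alpha specific
#' activity of about 2e8 IU/mg).  Concentrations are in pg/mL.
#'
#' @param amount Dose in MIU, > 0.
#' @param time Administration time (h), >= 0. Only `time = 0` is used by
#'   the single-dose trial design.
#' @param miu_to_mass Conversion factor, micrograms per MIU.
#' @return An object of class `dose_event` with the dose mass in
#'   micrograms (`mass_ug`).
#' @export
dose_event <- function(amount, time = 0, miu_to_mass = 5) {
  stopifnot(is.finite(amount), amount > 0, is.finite(time), time >= 0,
            is.finite(miu_to_mass), miu_to_mass > 0)
  structure(list(amount = amount, time = time, miu_to_mass = miu_to_mass,
                 mass_ug = amount * miu_to_mass),
            class = "dose_event")
}

#' Reference population PK parameter estimates
#'
#' Typical values from the first-in-human single-ascending-dose analysis
#' of the sustained-release interferon-alpha formulation; used as defaults
#' for simulation and as literature-informed initial estimates.
#' @return A `pk_parameters` object.
#' @export
default_pk_parameters <- function() {
  pk_parameters(cl_f = 12.2, v_f = 691, d2 = 20.2, ka = 0.00653,
                alag = 85.7, rf = 0.185)
}

#' Reference population PD parameter estimates
#' @return A `pd_parameters` object.
#' @rdname default_pk_parameters
#' @export
default_pd_parameters <- function() {
  pd_parameters(base = 5.85, kout = 0.0311, emax = 16.1, gamma = 1.24,
                ecb = 2.17, ca = 405, cb = 0.0068, mtt = 14.6)
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat("PK parameters (one-compartment, mixed zero/first-order absorption)\n")
  cat(sprintf("  CL/F %.4g L/h  V/F %.4g L  D2 %.4g h  KA %.4g 1/h\n",
              x$cl_f, x$v_f, x$d2, x$ka))
  cat(sprintf("  ALAG %.4g h  RF %.4g (fz = %.4f)  ke %.5g 1/h\n",
              x$alag, x$rf, x$fz, x$ke))
  invisible(x)
}

#' @export
print.pd_parameters <- function(x, ...) {
  cat("PD parameters (turnover + transit, time-increasing EC50)\n")
  cat(sprintf("  BASE %.4g nmol/L  KOUT %.4g 1/h  EMAX %.4g  gamma %.4g\n",
              x$base, x$kout, x$emax, x$gamma))
  cat(sprintf("  ECB %.4g pg/mL  CA %.4g  CB %.4g 1/h  MTT %.4g h\n",
              x$ecb, x$ca, x$cb, x$mtt))
  cat(sprintf("  derived: Kin %.4g nmol/L/h  Ktr %.4g 1/h\n", x$kin, x$ktr))
  invisible(x)
}

# internal: parameter vectors in the fixed orders used by the C++ engine
pk_theta_vec <- function(p) c(p$cl_f, p$v_f, p$d2, p$ka, p$alag, p$rf)
pd_theta_vec <- function(p) c(p$base, p$kout, p$emax, p$gamma, p$ca, p$cb,
                              p$ecb, p$mtt)
pk_theta_names <- c("cl_f", "v_f", "d2", "ka", "alag", "rf")
pd_theta_names <- c("base", "kout", "emax", "gamma", "ca", "cb", "ecb", "mtt")
# eta order: PK {CL, V, D2, RF, KA}; PD {BASE, CB, GA, ECB, MTT}
pk_eta_names <- c("cl_f", "v_f", "d2", "rf", "ka")
pd_eta_names <- c("base", "cb", "gamma", "ecb", "mtt")
pk_eta_idx <- c(0L, 1L, 2L, 5L, 3L)   # 0-based into pk_theta_vec
pd_eta_idx <- c(0L, 5L, 3L, 6L, 7L)   # 0-based into pd_theta_vec
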