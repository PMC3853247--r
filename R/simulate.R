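#' Trial design description
#'
#' @param groups Data frame with columns `dose` (MIU) and `n` (subjects).
#' @param pk_times PK sampling grid (h), sorted, including predose 0.
#' @param pd_times PD sampling grid (h), sorted, including predose 0.
#' @param miu_to_mass Dose conversion, micrograms per MIU.
#' @param lloq_pk PK lower limit of quantification (pg/mL).
#' @param lloq_pd PD lower limit of quantification (nmol/L).
#' @return A `study_design` object.
#' @export
study_design <- function(groups, pk_times, pd_times, miu_to_mass = 5,
                         lloq_pk = 12.5, lloq_pd = 0.7) {
  stopifnot(is.data.frame(groups), all(c("dose", "n") %in% names(groups)),
            all(groups$dose > 0), all(groups$n > 0),
            !is.unsorted(pk_times), all(pk_times >= 0),
            !is.unsorted(pd_times), all(pd_times >= 0),
            miu_to_mass > 0, lloq_pk >= 0, lloq_pd >= 0)
  structure(list(groups = groups, pk_times = as.numeric(pk_times),
                 pd_times = as.numeric(pd_times), miu_to_mass = miu_to_mass,
                 lloq_pk = lloq_pk, lloq_pd = lloq_pd),
            class = "study_design")
}

#' The single-ascending-dose trial design
#'
#' Four parallel groups of 6 subjects given single subcutaneous doses of
#' 9, 18, 27 and 36 MIU; serum drug sampled predose and at 19 post-dose
#' times to 192 h; neopterin sampled predose and at 14 post-dose times to
#' 264 h.  Assay detection limits 12.5 pg/mL (drug) and 0.7 nmol/L
#' (neopterin).
#'
#' @return A [study_design()] object.
#' @export
default_study_design <- function() {
  study_design(
    groups = data.frame(dose = c(9, 18, 27, 36), n = c(6, 6, 6, 6)),
    pk_times = c(0, 0.75, 1.5, 3, 6, 8, 10, 12, 18, 24, 30, 36, 48, 60,
                 72, 96, 120, 144, 168, 192),
    pd_times = c(0, 3, 8, 12, 18, 24, 36, 48, 72, 96, 120, 144, 168, 192,
                 264))
}

#' Between-subject variability specification
#'
#' Log-normal inter-individual variability: realized parameter =
#' typical value x `exp(eta)`, `eta ~ N(0, omega^2)`, diagonal covariance.
#' Parameters not named get `omega = 0` (no variability) and are excluded
#' from the random-effect vector.
#'
#' @param omega Named numeric vector of `omega` (SD of `eta`), >= 0.
#'   Names must be parameter fields of [pk_parameters()] /
#'   [pd_parameters()].
#' @return An `iiv_spec` object (named numeric vector).
#' @export
iiv_spec <- function(omega) {
  if (length(omega) && (is.null(names(omega)) || any(names(omega) == "")))
    stop("omega must be a named vector")
  if (any(omega < 0)) stop("omega values must be >= 0")
  structure(as.numeric(omega), names = names(omega), class = "iiv_spec")
}

#' Reference variability and residual-error specifications
#'
#' `default_pk_iiv()` / `default_pd_iiv()` give the estimated
#' between-subject standard deviations of the log-scale random effects
#' (reported as approximate CV%: 26.1% on CL etc.).  `default_pk_error()`
#' is the combined additive (3.92 pg/mL) + proportional (7.8%) residual
#' model for the drug assay; `default_pd_error()` is additive-only
#' (1.14 nmol/L) for neopterin.
#'
#' @return An [iiv_spec()] or [residual_error_spec()] object.
#' @export
default_pk_iiv <- function() {
  iiv_spec(c(cl_f = 0.261, v_f = 0.238, d2 = 0.357, rf = 0.347, ka = 0.770))
}

#' @rdname default_pk_iiv
#' @export
default_pd_iiv <- function() {
  iiv_spec(c(base = 0.1385, cb = 0.5731, gamma = 0.1351, ecb = 0.2131,
             mtt = 0.1336))
}

#' Residual (intra-individual) error model
#'
#' `kind = "additive"`: `Y = IPRED + eps * sigma_add`;
#' `kind = "proportional"`: `Y = IPRED + eps * sigma_prop * IPRED`;
#' `kind = "combined"`: `Y = IPRED + eps * sqrt(sigma_add^2 +
#' (sigma_prop * IPRED)^2)` with a single standard-normal deviate `eps`
#' (the variance-correct reading of the combined form).
#'
#' @param kind One of `"additive"`, `"proportional"`, `"combined"`.
#' @param sigma_add Additive SD, observation units, >= 0.
#' @param sigma_prop Proportional SD (fraction), >= 0.
#' @return A `residual_error_spec` object.
#' @export
residual_error_spec <- function(kind = c("additive", "proportional",
                                         "combined"),
                                sigma_add = 0, sigma_prop = 0) {
  kind <- match.arg(kind)
  stopifnot(sigma_add >= 0, sigma_prop >= 0)
  if (kind == "additive") sigma_prop <- 0
  if (kind == "proportional") sigma_add <- 0
  structure(list(kind = kind, sigma_add = sigma_add,
                 sigma_prop = sigma_prop),
            class = "residual_error_spec")
}

#' @rdname default_pk_iiv
#' @export
default_pk_error <- function() {
  residual_error_spec("combined", sigma_add = 3.92, sigma_prop = 0.078)
}

#' @rdname default_pk_iiv
#' @export
default_pd_error <- function() {
  residual_error_spec("additive", sigma_add = 1.14)
}

#' Draw individual parameter sets
#'
#' Realizes per-subject parameters `P_j = TVP * exp(eta_j)` with
#' independent `eta_j ~ N(0, omega^2)` from the IIV specifications.  The
#' draw order (per subject: PK etas in `{cl_f, v_f, d2, rf, ka}` order,
#' then PD etas in `{base, cb, gamma, ecb, mtt}` order) is fixed so a
#' given seed always yields identical subjects.
#'
#' @param pk,pd Typical-value [pk_parameters()] / [pd_parameters()].
#' @param iiv_pk,iiv_pd [iiv_spec()] objects for the two models.
#' @param n Number of subjects.
#' @param seed Integer seed (required; reproducibility contract).
#' @return List of length `n`; each element has `id`, realized `pk` and
#'   `pd` parameter objects, and the generating `eta_pk` / `eta_pd`.
#' @export
draw_individual_parameters <- function(pk, pd, iiv_pk = default_pk_iiv(),
                                       iiv_pd = default_pd_iiv(), n, seed) {
  stopifnot(inherits(pk, "pk_parameters"), inherits(pd, "pd_parameters"),
            n >= 1)
  if (missing(seed)) stop("`seed` is required")
  om_pk <- expand_omega(iiv_pk, pk_eta_names)
  om_pd <- expand_omega(iiv_pd, pd_eta_names)
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    eta_pk <- setNames(rnorm(length(om_pk), 0, om_pk), pk_eta_names)
    eta_pd <- setNames(rnorm(length(om_pd), 0, om_pd), pd_eta_names)
    realize_subject(i, pk, pd, eta_pk, eta_pd)
  })
}

# internal: named omega vector in canonical eta order (0 if absent)
expand_omega <- function(iiv, eta_names) {
  bad <- setdiff(names(iiv), eta_names)
  if (length(bad))
    stop("no between-subject variability is supported on: ",
         paste(bad, collapse = ", "))
  om <- setNames(numeric(length(eta_names)), eta_names)
  om[names(iiv)] <- as.numeric(iiv)
  om
}

realize_subject <- function(id, pk, pd, eta_pk, eta_pd) {
  ipk <- pk_parameters(cl_f = pk$cl_f * exp(eta_pk[["cl_f"]]),
                       v_f  = pk$v_f  * exp(eta_pk[["v_f"]]),
                       d2   = pk$d2   * exp(eta_pk[["d2"]]),
                       ka   = pk$ka   * exp(eta_pk[["ka"]]),
                       alag = pk$alag,
                       rf   = pk$rf   * exp(eta_pk[["rf"]]))
  ipd <- pd_parameters(base  = pd$base  * exp(eta_pd[["base"]]),
                       kout  = pd$kout,
                       emax  = pd$emax,
                       gamma = pd$gamma * exp(eta_pd[["gamma"]]),
                       ecb   = pd$ecb   * exp(eta_pd[["ecb"]]),
                       ca    = pd$ca,
                       cb    = pd$cb    * exp(eta_pd[["cb"]]),
                       mtt   = pd$mtt   * exp(eta_pd[["mtt"]]))
  list(id = id, pk = ipk, pd = ipd, eta_pk = eta_pk, eta_pd = eta_pd)
}

#' Apply residual error to model predictions
#'
#' Adds one standard-normal deviate per observation, scaled by the
#' residual model's standard deviation at the prediction.  Uses the
#' caller's RNG stream: seed before calling for reproducibility.
#'
#' @param ipred Non-negative predicted values.
#' @param spec A [residual_error_spec()].
#' @return Observed values (same length as `ipred`).
#' @export
apply_residual_error <- function(ipred, spec) {
  stopifnot(inherits(spec, "residual_error_spec"), all(ipred >= 0))
  sdv <- sqrt(spec$sigma_add^2 + (spec$sigma_prop * ipred)^2)
  ipred + rnorm(length(ipred)) * sdv
}

#' Simulate a complete study
#'
#' Generates one synthetic trial: per subject a dose record at t = 0, drug
#' observations at every PK grid time and neopterin observations at every
#' PD grid time, with log-normal between-subject variability and the
#' residual-error models applied.  Predose drug concentration is simulated
#' as 0 (no endogenous drug).  Values below the assay detection limit are
#' flagged (`BLQ = 1`), never dropped, at simulation time.
#'
#' @param design A [study_design()].
#' @param pk,pd Typical-value parameter objects.
#' @param iiv_pk,iiv_pd [iiv_spec()] objects.
#' @param err_pk,err_pd [residual_error_spec()] objects.
#' @param seed Integer seed (required).
#' @return A `pop_dataset`: data frame with columns
#'   `ID, TIME, AMT, EVID, MDV, DVID, DV, BLQ, DOSE` and attributes
#'   `design`, `truth` (the generating individual parameters) and `seed`.
#' @export
simulate_study <- function(design = default_study_design(),
                           pk = default_pk_parameters(),
                           pd = default_pd_parameters(),
                           iiv_pk = default_pk_iiv(),
                           iiv_pd = default_pd_iiv(),
                           err_pk = default_pk_error(),
                           err_pd = default_pd_error(), seed) {
  stopifnot(inherits(design, "study_design"))
  if (missing(seed)) stop("`seed` is required")
  doses <- rep(design$groups$dose, design$groups$n)
  n <- length(doses)
  truth <- draw_individual_parameters(pk, pd, iiv_pk, iiv_pd, n, seed)
  pk_post <- design$pk_times[design$pk_times > 0]
  recs <- vector("list", n)
  for (i in seq_len(n)) {
    sub <- truth[[i]]
    dose <- dose_event(doses[i], 0, design$miu_to_mass)
    ipred_pk <- c(0, pk_concentration(sub$pk, dose, pk_post))
    ipred_pd <- pd_trajectory(sub$pk, sub$pd, dose, design$pd_times)
    y_pk <- apply_residual_error(ipred_pk, err_pk)
    y_pk[design$pk_times == 0] <- 0          # predose: no endogenous drug
    y_pd <- apply_residual_error(ipred_pd, err_pd)
    recs[[i]] <- data.frame(
      ID = i,
      TIME = c(0, design$pk_times, design$pd_times),
      AMT = c(doses[i], rep(NA_real_, length(y_pk) + length(y_pd))),
      EVID = c(1L, rep(0L, length(y_pk) + length(y_pd))),
      MDV = c(1L, rep(0L, length(y_pk) + length(y_pd))),
      DVID = c(NA_integer_, rep(1L, length(y_pk)), rep(2L, length(y_pd))),
      DV = c(NA_real_, y_pk, y_pd),
      BLQ = c(NA_integer_,
              as.integer(y_pk < design$lloq_pk),
              as.integer(y_pd < design$lloq_pd)),
      DOSE = doses[i])
    truth[[i]]$dose <- doses[i]
  }
  out <- do.call(rbind, recs)
  ord <- order(out$ID, out$TIME, -out$EVID, out$DVID)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, design = design, truth = truth, seed = seed,
            class = c("pop_dataset", "data.frame"))
}

#' @export
print.pop_dataset <- function(x, ...) {
  cat(sprintf("Population dataset: %d subjects, %d records (%d PK obs, %d PD obs)\n",
              length(unique(x$ID)), nrow(x),
              sum(x$EVID == 0 & x$DVID == 1, na.rm = TRUE),
              sum(x$EVID == 0 & x$DVID == 2, na.rm = TRUE)))
  print(head(as.data.frame(x), 8))
  invisible(x)
}
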