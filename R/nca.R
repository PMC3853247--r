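#' Peak concentration and its time
#'
#' @param time Strictly increasing observation times (h).
#' @param value Observed concentrations.
#' @return List with `cmax` and `tmax`; ties broken by the earliest time.
#' @export
cmax_tmax <- function(time, value) {
  if (length(time) < 1 || length(time) != length(value))
    stop("need at least one (time, value) pair of equal length")
  if (is.unsorted(time, strictly = TRUE))
    stop("times must be strictly increasing")
  i <- which.max(value)   # first maximum: earliest-time tie rule
  list(cmax = value[i], tmax = time[i])
}

#' Area under the curve to the last observation (linear trapezoid)
#'
#' Linear trapezoidal rule over the full profile, anchored at the first
#' record.  Values are pg*h/mL; divide by 1000 for ng*h/mL.
#'
#' @inheritParams cmax_tmax
#' @return AUC in the units of `value * time`.
#' @export
auc_last_trapezoid <- function(time, value) {
  if (length(time) < 2) stop("need at least two observations")
  if (is.unsorted(time, strictly = TRUE))
    stop("times must be strictly increasing")
  sum(diff(time) * (head(value, -1) + value[-1]) / 2)
}

#' Non-compartmental analysis of a simulated or loaded study
#'
#' Computes per-subject Cmax (pg/mL), Tmax (h) and AUClast (ng*h/mL) from
#' the quantifiable (non-BLQ) drug observations, anchored at t = 0.
#'
#' @param dataset A `pop_dataset`.
#' @return An `nca_result`: list with `subjects` (per-subject metrics) and
#'   `groups` (the [summarize_group()] table).
#' @export
run_nca <- function(dataset) {
  obs <- dataset[dataset$EVID == 0 & dataset$DVID == 1 & dataset$BLQ == 0, ]
  ids <- unique(dataset$ID[dataset$EVID == 1])
  subjects <- do.call(rbind, lapply(ids, function(id) {
    d <- obs[obs$ID == id, ]
    if (nrow(d) < 2) return(NULL)
    ct <- cmax_tmax(d$TIME, d$DV)
    data.frame(ID = id, DOSE = d$DOSE[1], cmax = ct$cmax, tmax = ct$tmax,
               auclast = auc_last_trapezoid(d$TIME, d$DV) / 1000)
  }))
  structure(list(subjects = subjects,
                 groups = summarize_group(subjects, subjects$DOSE)),
            class = "nca_result")
}

#' Group summary of NCA metrics
#'
#' Mean, sample SD (n - 1) and CV% (= 100 SD / mean) of Cmax and AUClast
#' plus median Tmax, per group.  Single-subject groups get SD = 0 and a
#' `degenerate` flag.
#'
#' @param results Data frame with columns `cmax`, `tmax`, `auclast`.
#' @param group Group label per row (e.g. dose).
#' @return Data frame, one row per group.
#' @export
summarize_group <- function(results, group) {
  stopifnot(nrow(results) == length(group))
  idx <- split(seq_len(nrow(results)), group)
  out <- do.call(rbind, lapply(names(idx), function(g) {
    d <- results[idx[[g]], , drop = FALSE]
    n <- nrow(d)
    s <- function(x) if (n > 1) sd(x) else 0
    data.frame(group = g, n = n,
               cmax_mean = mean(d$cmax), cmax_sd = s(d$cmax),
               cmax_cv = 100 * s(d$cmax) / mean(d$cmax),
               tmax_median = median(d$tmax),
               auclast_mean = mean(d$auclast), auclast_sd = s(d$auclast),
               auclast_cv = 100 * s(d$auclast) / mean(d$auclast),
               degenerate = n == 1)
  }))
  rownames(out) <- NULL
  out
}
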