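DATASET_COLS <- c("ID", "TIME", "AMT", "EVID", "MDV", "DVID", "DV", "BLQ",
                  "DOSE")

#' Write a population dataset as NONMEM-style CSV
#'
#' Mandatory header `ID,TIME,AMT,EVID,MDV,DVID,DV,BLQ,DOSE`; missing
#' values written as `"."`.  If the dataset carries a truth record (the
#' generating individual parameters of a simulated study), it is
#' serialized as a JSON side-car `<path>.truth.json` for recovery tests.
#'
#' @param dataset A `pop_dataset`.
#' @param path Output CSV path.
#' @param truth_sidecar Write the truth side-car when available.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path, truth_sidecar = TRUE) {
  stopifnot(all(DATASET_COLS %in% names(dataset)))
  out <- as.data.frame(dataset)[, DATASET_COLS]
  for (nm in DATASET_COLS) {
    v <- out[[nm]]
    out[[nm]] <- ifelse(is.na(v), ".", format(v, digits = 15,
                                              scientific = FALSE,
                                              trim = TRUE))
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  truth <- attr(dataset, "truth")
  if (truth_sidecar && !is.null(truth)) {
    tr <- lapply(truth, function(s)
      list(id = s$id, dose = s$dose,
           pk = as.list(coef_vector(s$pk)), pd = as.list(coef_vector(s$pd)),
           eta_pk = as.list(s$eta_pk), eta_pd = as.list(s$eta_pd)))
    jsonlite::write_json(tr, paste0(path, ".truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a population dataset from NONMEM-style CSV
#'
#' Validates the mandatory columns, parses `"."` as missing, and checks
#' basic structure (times sorted within subject, exactly one dose record
#' per subject).  A truth side-car written by [write_dataset()] is
#' re-attached when present.
#'
#' @param path CSV path.
#' @return A `pop_dataset`.
#' @export
read_dataset <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, na.strings = ".")
  missing_cols <- setdiff(DATASET_COLS, names(raw))
  if (length(missing_cols))
    stop("dataset is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- raw[, DATASET_COLS]
  for (nm in c("TIME", "AMT", "DV", "DOSE")) out[[nm]] <- as.numeric(out[[nm]])
  for (nm in c("ID", "EVID", "MDV", "DVID", "BLQ")) {
    out[[nm]] <- as.integer(out[[nm]])
  }
  for (id in unique(out$ID)) {
    d <- out[out$ID == id, ]
    if (sum(d$EVID == 1) != 1)
      stop("subject ", id, " must have exactly one dose record")
    if (is.unsorted(d$TIME))
      stop("times are not sorted within subject ", id)
  }
  side <- paste0(path, ".truth.json")
  truth <- NULL
  if (file.exists(side)) {
    tr <- jsonlite::read_json(side, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
    truth <- lapply(tr, function(s)
      list(id = s$id, dose = s$dose,
           pk = do.call(pk_parameters, s$pk[pk_theta_names]),
           pd = do.call(pd_parameters, s$pd[pd_theta_names]),
           eta_pk = unlist(s$eta_pk), eta_pd = unlist(s$eta_pd)))
  }
  structure(out, truth = truth, design = infer_design(out),
            class = c("pop_dataset", "data.frame"))
}

#' Infer the trial design from a dataset's records
#'
#' Reconstructs group sizes and the (assumed common) sampling grids from
#' the dose and observation records; assay limits and the dose conversion
#' are not stored in the CSV and take their defaults unless supplied.
#'
#' @param dataset A `pop_dataset`-shaped data frame.
#' @param miu_to_mass,lloq_pk,lloq_pd See [study_design()].
#' @return A [study_design()] object.
#' @export
infer_design <- function(dataset, miu_to_mass = 5, lloq_pk = 12.5,
                         lloq_pd = 0.7) {
  doses <- dataset$DOSE[dataset$EVID == 1]
  tab <- table(doses)
  study_design(
    groups = data.frame(dose = as.numeric(names(tab)),
                        n = as.integer(tab)),
    pk_times = sort(unique(dataset$TIME[dataset$EVID == 0 &
                                          dataset$DVID == 1])),
    pd_times = sort(unique(dataset$TIME[dataset$EVID == 0 &
                                          dataset$DVID == 2])),
    miu_to_mass = miu_to_mass, lloq_pk = lloq_pk, lloq_pd = lloq_pd)
}
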