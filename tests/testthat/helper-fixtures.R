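# shared fixture helpers

pk_eta_names_vec <- function() c("cl_f", "v_f", "d2", "rf", "ka")
pd_eta_names_vec <- function() c("base", "cb", "gamma", "ecb", "mtt")

# full-length named omega vector (zeros where not specified)
as_named_omega <- function(v, names = pk_eta_names_vec()) {
  out <- setNames(numeric(length(names)), names)
  out[names(v)] <- v
  out
}

pd_eta_names <- pd_eta_names_vec()
pk_eta_names <- pk_eta_names_vec()

# individual PK parameter table taken straight from a simulated dataset's
# truth record (bypasses the PK fit when testing the PD stage alone)
true_pk_ebes <- function(ds) {
  truth <- attr(ds, "truth")
  do.call(rbind, lapply(truth, function(s)
    data.frame(ID = s$id, cl_f = s$pk$cl_f, v_f = s$pk$v_f, d2 = s$pk$d2,
               ka = s$pk$ka, alag = s$pk$alag, rf = s$pk$rf,
               fz = s$pk$fz)))
}
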