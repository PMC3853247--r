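# small, fast trial layout for fit tests
quick_design <- function(doses = c(18, 27), n = 3) {
  d <- default_study_design()
  study_design(data.frame(dose = doses, n = rep(n, length(doses))),
               d$pk_times, d$pd_times)
}
no_iiv <- iiv_spec(setNames(numeric(0), character(0)))
tiny_err <- residual_error_spec("additive", 1e-6)

test_that("conditional_m2ll closed forms", {
  # one observation, y = ipred, additive sigma = 1, no random effects
  expect_equal(conditional_m2ll(y = 1, ipred = 1, sigma_add = 1),
               log(2 * pi))
  # eta = 0, unit omega: penalty contributes log(2*pi)
  expect_equal(conditional_m2ll(y = 1, ipred = 1, eta = 0, omega = 1,
                                sigma_add = 1), 2 * log(2 * pi))
  # interaction: variance evaluated at ipred
  expect_equal(conditional_m2ll(y = 3, ipred = 2, sigma_add = 1,
                                sigma_prop = 0.5),
               log(2 * pi * 2) + 1 / 2)
  expect_error(conditional_m2ll(y = 1, ipred = 0, sigma_add = 0), "> 0")
})

test_that("marginal OFV matches the closed-form linear-Gaussian marginal", {
  set.seed(8)
  y <- lapply(c(3, 1, 5, 2), function(n) rnorm(n, 1.3, 0.6))
  for (om in c(0.2, 0.9)) {
    m <- marginal_ofv(y, "toy", theta = c(theta = 1.1),
                      omega = c(eta1 = om), sigma = c(sigma_add = 0.4))
    expect_equal(m$ofv, toy_marginal_m2ll(y, 1.1, om, 0.4),
                 tolerance = 1e-6)
  }
  # omega = 0 limit: pure fixed-effect -2 log-likelihood
  m0 <- marginal_ofv(y, "toy", theta = c(theta = 1.1),
                     omega = c(eta1 = 0), sigma = c(sigma_add = 0.4))
  yy <- unlist(y)
  expect_equal(m0$ofv,
               sum(log(2 * pi * 0.16) + (yy - 1.1)^2 / 0.16),
               tolerance = 1e-9)
  # exchangeability: permuting subjects leaves the OFV unchanged
  mp <- marginal_ofv(y[c(3, 1, 4, 2)], "toy", theta = c(theta = 1.1),
                     omega = c(eta1 = 0.9), sigma = c(sigma_add = 0.4))
  m1 <- marginal_ofv(y, "toy", theta = c(theta = 1.1),
                     omega = c(eta1 = 0.9), sigma = c(sigma_add = 0.4))
  expect_equal(mp$ofv, m1$ofv, tolerance = 1e-10)
})

test_that("fit_pk recovers generating values from noiseless data", {
  ds <- simulate_study(quick_design(), iiv_pk = no_iiv, iiv_pd = no_iiv,
                       err_pk = tiny_err, err_pd = tiny_err, seed = 21)
  truth <- coef_vector(default_pk_parameters())
  init <- truth * c(1.2, 1.2, 1.2, 1.2, 1.2, 1)
  init["rf"] <- 0.25
  f <- fit_pk(ds, init = init,
              init_omega = setNames(numeric(5), pk_eta_names),
              init_sigma = c(sigma_add = 1e-3),
              fix = "sigma_add",
              control = fit_control(se = FALSE, iter.max = 800,
                                    eval.max = 3000, rel.tol = 1e-14))
  expect_true(all(abs(f$theta - truth) / abs(truth) < 1e-3))
})

test_that("fit_pk is robust to x2 / x0.5 starting values", {
  # well-conditioned configuration: the generating model carries IIV on
  # the parameters the data identify sharply (with IIV also on KA/RF the
  # OFV surface has a genuinely flat ridge and exact OFV agreement is
  # not a meaningful contract)
  iiv3 <- iiv_spec(c(cl_f = 0.261, v_f = 0.238, d2 = 0.357))
  ds <- simulate_study(quick_design(), iiv_pk = iiv3, seed = 22)
  ctl <- fit_control(se = FALSE)
  base <- coef_vector(default_pk_parameters())
  om3 <- c(cl_f = 0.261, v_f = 0.238, d2 = 0.357)
  f1 <- fit_pk(ds, init = replace(base * 2, "rf", 0.37),
               init_omega = om3, control = ctl)
  f2 <- fit_pk(ds, init = replace(base * 0.5, "rf", 0.0925),
               init_omega = om3, control = ctl)
  expect_lt(abs(f1$ofv - f2$ofv), 0.1)
})

test_that("compute_ebes: eta recovery, shrinkage, bookkeeping", {
  # rich low-noise data: the mode should sit close to the generating eta
  des <- quick_design(doses = 27, n = 4)
  ds <- simulate_study(des, iiv_pk = iiv_spec(c(cl_f = 0.261, v_f = 0.238)),
                       iiv_pd = no_iiv,
                       err_pk = residual_error_spec("additive", 0.05),
                       err_pd = tiny_err, seed = 23)
  truth <- attr(ds, "truth")
  fake_fit <- structure(list(model = "pk",
                             theta = coef_vector(default_pk_parameters()),
                             omega = as_named_omega(c(cl_f = 0.261,
                                                      v_f = 0.238)),
                             sigma = c(sigma_add = 0.05, sigma_prop = 0),
                             control = fit_control()),
                        class = "ifn_fit")
  eb <- compute_ebes(fake_fit, ds)
  expect_equal(nrow(eb), 4)                      # EBE count = subjects
  for (i in 1:4) {
    expect_equal(eb$eta_cl_f[i], unname(truth[[i]]$eta_pk["cl_f"]),
                 tolerance = 0.05)
    expect_equal(eb$eta_v_f[i], unname(truth[[i]]$eta_pk["v_f"]),
                 tolerance = 0.05)
  }
  # a subject with no quantifiable data is fully shrunk to eta = 0
  ds2 <- ds
  ds2$BLQ[ds2$ID == 2 & ds2$DVID == 1 & ds2$EVID == 0] <- 1L
  eb2 <- compute_ebes(fake_fit, ds2)
  expect_equal(eb2$eta_cl_f[2], 0)
  expect_equal(eb2$cl_f[2], fake_fit$theta[["cl_f"]])
})

test_that("fit_pd recovers generating values from noiseless data", {
  # four distinct doses sharpen the (emax, ca, cb, ecb) directions; the
  # PD observations are regenerated with the estimation-grade fixed-step
  # integrator so this test isolates the estimator (integrator accuracy
  # has its own oracle test)
  des <- quick_design(doses = c(9, 18, 27, 36), n = 1)
  ds <- simulate_study(des, iiv_pk = no_iiv, iiv_pd = no_iiv,
                       err_pk = tiny_err, err_pd = tiny_err, seed = 24)
  pk <- default_pk_parameters(); pd <- default_pd_parameters()
  for (id in unique(ds$ID)) {
    sel <- ds$ID == id & ds$EVID == 0 & ds$DVID == 2
    ds$DV[sel] <- pd_trajectory(pk, pd, dose_event(ds$DOSE[sel][1]),
                                ds$TIME[sel], method = "rk4", dt = 0.25)
  }
  truth <- coef_vector(pd)
  ebes <- true_pk_ebes(ds)
  init <- truth * rep(c(1.15, 0.85), 4)
  f <- fit_pd(ds, ebes, init = init,
              init_omega = setNames(numeric(5), pd_eta_names_vec()),
              init_sigma = c(sigma_add = 1e-3),
              fix = "sigma_add",
              control = fit_control(se = FALSE, h_outer = 1e-5,
                                    iter.max = 2000, eval.max = 6000,
                                    rel.tol = 1e-14, dt = 0.25))
  expect_true(all(abs(f$theta - truth) / abs(truth) < 5e-3))
})

test_that("dropping the EC50 rise term worsens the OFV on data that has it", {
  des <- quick_design(doses = c(9, 36), n = 3)
  ds <- simulate_study(des, iiv_pk = no_iiv, iiv_pd = no_iiv,
                       err_pk = tiny_err,
                       err_pd = residual_error_spec("additive", 0.5),
                       seed = 25)
  ebes <- true_pk_ebes(ds)
  om0 <- setNames(numeric(5), pd_eta_names_vec())
  ctl <- fit_control(se = FALSE)
  full <- fit_pd(ds, ebes, init_omega = om0,
                 init_sigma = c(sigma_add = 0.5), fix = "sigma_add",
                 control = ctl)
  init_red <- coef_vector(default_pd_parameters())
  init_red["ca"] <- 1e-3    # EC50 frozen at its baseline
  red <- fit_pd(ds, ebes, init = init_red, init_omega = om0,
                init_sigma = c(sigma_add = 0.5),
                fix = c("ca", "sigma_add"), control = ctl)
  expect_gt(red$ofv, full$ofv)
  expect_true(compare_models(red$ofv, full$ofv, df_diff = 1)$select_full)
})

test_that("compare_models implements the strict 3.84-per-df rule", {
  # the reference PK development step: lag time earns its df
  expect_true(compare_models(2138.416, 2130.609, 1)$select_full)
  expect_false(compare_models(100, 100 - 3.84, 1)$select_full)  # boundary
  expect_false(compare_models(100, 100, 1)$select_full)
  expect_equal(compare_models(10, 1, 2)$threshold, 7.68)
  expect_error(compare_models(1, 1, 0))
})
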