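fast_ctl <- fit_control(se = FALSE, iter.max = 60)

test_that("method constants match the qualification procedure", {
  expect_equal(formals(bootstrap_ci)$n_replicates, 1000)
  expect_equal(formals(vpc)$n_sim, 1000)
  cm <- compare_models(10, 2, 1)
  expect_equal(cm$threshold, 3.84)
})

test_that("vpc: band ordering, determinism, degenerate noise-free case", {
  des <- study_design(data.frame(dose = c(18, 36), n = c(3, 3)),
                      default_study_design()$pk_times,
                      default_study_design()$pd_times)
  ds <- simulate_study(des, seed = 41)
  pars <- list(pk = default_pk_parameters(), pd = default_pd_parameters(),
               iiv_pk = default_pk_iiv(), iiv_pd = default_pd_iiv(),
               err_pk = default_pk_error(), err_pd = default_pd_error())
  v1 <- vpc(ds, pars, n_sim = 30, seed = 42)
  v2 <- vpc(ds, pars, n_sim = 30, seed = 42)
  expect_equal(v1$bands, v2$bands)
  expect_true(all(v1$bands$lo <= v1$bands$mid & v1$bands$mid <= v1$bands$hi))
  # no IIV, no noise: all three bands collapse onto the typical profile
  none <- iiv_spec(setNames(numeric(0), character(0)))
  err0 <- residual_error_spec("additive", 0)
  pars0 <- list(pk = default_pk_parameters(), pd = default_pd_parameters(),
                iiv_pk = none, iiv_pd = none, err_pk = err0, err_pd = err0)
  v0 <- vpc(ds, pars0, n_sim = 5, seed = 43)
  expect_equal(v0$bands$lo, v0$bands$hi, tolerance = 1e-12)
  pk_rows <- v0$bands$DVID == 1 & v0$bands$DOSE == 18 & v0$bands$TIME > 0
  expect_equal(v0$bands$mid[pk_rows],
               pk_concentration(default_pk_parameters(), dose_event(18),
                                v0$bands$TIME[pk_rows]),
               tolerance = 1e-9)
})

test_that("bootstrap: degenerate single subject, stratification, CIs", {
  des1 <- study_design(data.frame(dose = 18, n = 1),
                       default_study_design()$pk_times,
                       default_study_design()$pd_times)
  ds1 <- simulate_study(des1, seed = 44)
  b1 <- bootstrap_ci(ds1, n_replicates = 3, seed = 45,
                     fit_args = list(control = fast_ctl))
  expect_equal(b1$summary$lo95, b1$summary$hi95)   # zero-width CIs
  expect_equal(b1$summary$lo95, b1$summary$median)
  expect_error(bootstrap_ci(ds1, n_replicates = 2), "seed")
})

test_that("bootstrap CIs on a simulated study cover the generating values", {
  ds <- simulate_study(seed = 46)
  b <- bootstrap_ci(ds, n_replicates = 20, seed = 47,
                    fit_args = list(control = fast_ctl))
  expect_true(b$reliable)
  truth <- coef_vector(default_pk_parameters())
  well <- c("pk.cl_f", "pk.v_f", "pk.d2", "pk.alag")
  s <- b$summary[match(well, b$summary$parameter), ]
  covered <- truth[sub("pk\\.", "", well)] >= s$lo95 &
    truth[sub("pk\\.", "", well)] <= s$hi95
  expect_gte(mean(covered), 0.75)
  # medians sit inside their own percentile CIs by construction
  expect_true(all(b$summary$median >= b$summary$lo95 &
                    b$summary$median <= b$summary$hi95))
})

test_that("gof_table: exact match on noiseless data, calibrated residuals", {
  none <- iiv_spec(setNames(numeric(0), character(0)))
  err0 <- residual_error_spec("additive", 1e-9)
  des <- study_design(data.frame(dose = c(18, 27), n = c(2, 2)),
                      default_study_design()$pk_times,
                      default_study_design()$pd_times)
  ds <- simulate_study(des, iiv_pk = none, iiv_pd = none,
                       err_pk = err0, err_pd = err0, seed = 48)
  fake <- structure(list(model = "pk",
                         theta = coef_vector(default_pk_parameters()),
                         omega = setNames(numeric(5), pk_eta_names_vec()),
                         sigma = c(sigma_add = 1, sigma_prop = 0),
                         eta = matrix(0, 0, 4),
                         control = fit_control()),
                    class = "ifn_fit")
  g <- gof_table(ds, fake)
  expect_equal(nrow(g),
               sum(ds$EVID == 0 & ds$DVID == 1 & ds$BLQ == 0))
  expect_equal(g$PRED, g$IPRED)
  expect_equal(g$DV, g$PRED, tolerance = 1e-6)
  # well-specified noisy data: residual mean within 2 SEs of zero
  ds2 <- simulate_study(des, iiv_pk = none, iiv_pd = none,
                        err_pk = residual_error_spec("additive", 2),
                        err_pd = err0, seed = 49)
  g2 <- gof_table(ds2, fake)
  se <- sd(g2$RES) / sqrt(nrow(g2))
  expect_lt(abs(mean(g2$RES)), 2 * se)
})

test_that("recovery_report: trivial identities and tolerance tiers", {
  truth <- c(cl_f = 10, base = 5, ca = 100)
  r0 <- recovery_report(truth, truth)
  expect_equal(r0$rel_error, rep(0, 3))
  expect_true(all(r0$pass))
  r2 <- recovery_report(truth, truth * 2)
  expect_equal(r2$rel_error, rep(1, 3))
  expect_false(r2$pass[r2$parameter == "cl_f"])   # hard 20% tier
  expect_true(r2$pass[r2$parameter == "ca"])      # weak tier: order of mag.
  expect_error(recovery_report(unname(truth), truth), "named")
})
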