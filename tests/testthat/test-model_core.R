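ref_pk <- default_pk_parameters()
ref_pd <- default_pd_parameters()
design <- default_study_design()

test_that("zero_order_fraction: logistic values and symmetry", {
  expect_equal(zero_order_fraction(0), 0.5)
  expect_equal(zero_order_fraction(0.185), 0.546118541, tolerance = 1e-8)
  x <- c(0.3, 1.7, 4.2)
  expect_equal(zero_order_fraction(x) + zero_order_fraction(-x),
               rep(1, 3))
  expect_true(all(diff(zero_order_fraction(seq(-5, 5, 0.5))) > 0))
  expect_error(zero_order_fraction(Inf), "finite")
  expect_error(zero_order_fraction(NA_real_), "finite")
})

test_that("pk_concentration: basic structure, dose linearity, grid Tmax", {
  d18 <- dose_event(18)
  expect_equal(pk_concentration(ref_pk, d18, 0), 0)
  t <- c(0, 1.3, 7, 19, 21, 50, 84, 90, 150)
  c1 <- pk_concentration(ref_pk, d18, t)
  c2 <- pk_concentration(ref_pk, dose_event(36), t)
  expect_equal(c2, 2 * c1, tolerance = 1e-12)   # superposition
  expect_true(all(c1 >= 0))
  expect_error(pk_concentration(ref_pk, d18, -1), ">= 0")
  # observed-median Tmax on the printed sampling grid, every dose group
  for (dose in design$groups$dose) {
    cc <- pk_concentration(ref_pk, dose_event(dose), design$pk_times)
    expect_equal(design$pk_times[which.max(cc)], 24)
  }
})

test_that("pk_concentration handles the ka == ke degeneracy analytically", {
  p <- pk_parameters(cl_f = 12.2, v_f = 691, d2 = 20.2,
                     ka = 12.2 / 691, alag = 10, rf = 0.185)
  t <- seq(0, 200, 5)
  cc <- pk_concentration(p, dose_event(18), t)
  expect_true(all(is.finite(cc)))
  # compare with ka infinitesimally away from ke
  p2 <- pk_parameters(cl_f = 12.2, v_f = 691, d2 = 20.2,
                      ka = 12.2 / 691 * (1 + 1e-7), alag = 10, rf = 0.185)
  cc2 <- pk_concentration(p2, dose_event(18), t)
  expect_equal(cc, cc2, tolerance = 1e-5)
})

test_that("analytic PK equals the RK4 ODE oracle on a dense grid", {
  t <- seq(0, 192, 0.25)
  for (dose in c(9, 36)) {
    a <- pk_concentration(ref_pk, dose_event(dose), t)
    o <- oracle_pk_rk4(ref_pk, dose * 5, t, dt = 0.01)
    rel <- abs(a - o) / pmax(abs(o), 1e-8 * max(o))
    expect_lt(max(rel[t > 0]), 1e-6)
  }
})

test_that("PK concentration is continuous at D2 and ALAG", {
  d <- dose_event(18)
  eps <- 1e-9
  for (tb in c(ref_pk$d2, ref_pk$alag)) {
    lo <- pk_concentration(ref_pk, d, tb - eps)
    hi <- pk_concentration(ref_pk, d, tb + eps)
    expect_equal(lo, hi, tolerance = 1e-6)
  }
})

test_that("ec50_at_time: baseline, plateau, direct evaluation", {
  expect_equal(ec50_at_time(ref_pd, 0), 2.17)
  expect_equal(ec50_at_time(ref_pd, 1e9), 2.17 * (1 + 405),
               tolerance = 1e-12)
  expect_equal(ec50_at_time(ref_pd, 1 / 0.0068),
               2.17 * (1 + 405 * (1 - exp(-1))), tolerance = 1e-12)
  tt <- seq(0, 500, 1)
  expect_true(all(diff(ec50_at_time(ref_pd, tt)) >= 0))
  expect_error(ec50_at_time(ref_pd, -0.1), ">= 0")
})

test_that("stimulation_effect: bounds, half-max, saturation", {
  expect_equal(stimulation_effect(0, 16.1, 2.17, 1.24), 1)
  expect_equal(stimulation_effect(2.17, 16.1, 2.17, 1.24), 1 + 16.1 / 2)
  expect_equal(stimulation_effect(1e12, 16.1, 2.17, 1.24), 1 + 16.1,
               tolerance = 1e-6)
  expect_error(stimulation_effect(-1, 16.1, 2.17, 1.24), ">= 0")
})

test_that("ec50/effect monotonicity holds over random parameter draws", {
  set.seed(42)
  for (i in 1:1000) {
    p <- pd_parameters(base = runif(1, 1, 20), kout = runif(1, 0.001, 1),
                       emax = runif(1, 0.1, 100), gamma = runif(1, 0.2, 5),
                       ecb = runif(1, 0.1, 100), ca = runif(1, 0.1, 1000),
                       cb = runif(1, 1e-4, 0.5), mtt = runif(1, 1, 100))
    tt <- sort(runif(4, 0, 400))
    expect_true(all(diff(ec50_at_time(p, tt)) >= 0))
    cc <- sort(runif(4, 0, 500))
    ee <- stimulation_effect(cc, p$emax, p$ecb, p$gamma)
    expect_true(all(diff(ee) >= 0))
    expect_true(all(ee >= 1 & ee <= 1 + p$emax))
  }
})

test_that("pd_trajectory: drug-free steady state is exactly preserved", {
  tt <- c(0, design$pd_times[-1], 264)
  a4 <- pd_trajectory(ref_pk, ref_pd, NULL, sort(unique(tt)))
  expect_lt(max(abs(a4 - ref_pd$base)), 1e-9 * ref_pd$base)
})

test_that("pd_trajectory: constant-concentration forcing reaches the
           indirect-response steady state", {
  pd0 <- pd_parameters(base = ref_pd$base, kout = ref_pd$kout,
                       emax = ref_pd$emax, gamma = ref_pd$gamma,
                       ecb = ref_pd$ecb, ca = 1e-12, cb = ref_pd$cb,
                       mtt = ref_pd$mtt)  # ca -> 0: EC50 frozen at ecb
  a4 <- pd_trajectory(ref_pk, pd0, NULL, c(0, 4000),
                      const_conc = ref_pd$ecb)
  expect_equal(a4[2], ref_pd$base * (1 + ref_pd$emax / 2),
               tolerance = 1e-6)
})

test_that("pd_trajectory matches the 4-state RK4 oracle", {
  a <- pd_trajectory(ref_pk, ref_pd, dose_event(18), design$pd_times)
  o <- oracle_pd_rk4(ref_pk, ref_pd, 18 * 5, design$pd_times, dt = 0.01)
  expect_lt(max(abs(a - o) / o), 1e-5)
  # the estimation-grade fixed-step path stays close to the oracle too
  a4 <- pd_trajectory(ref_pk, ref_pd, dose_event(18), design$pd_times,
                      method = "rk4", dt = 0.25)
  expect_lt(max(abs(a4 - o) / o), 1e-4)
})

test_that("PD saturates in dose while PK stays linear", {
  tt <- seq(0, 264, 0.5)
  auc <- function(x) sum(diff(tt) * (head(x, -1) + x[-1]) / 2)
  pk_auc <- vapply(c(9, 36), function(d)
    auc(pk_concentration(ref_pk, dose_event(d), tt)), numeric(1))
  pd_auc <- vapply(c(9, 36), function(d)
    auc(pd_trajectory(ref_pk, ref_pd, dose_event(d), tt)), numeric(1))
  expect_equal(pk_auc[2] / pk_auc[1], 4, tolerance = 1e-9)
  expect_lt(pd_auc[2] / pd_auc[1], 4)
})

test_that("parameter constructors validate their domains", {
  expect_error(pk_parameters(-1, 691, 20, 0.006, 85, 0.2))
  expect_error(pd_parameters(5.85, 0.0311, 16.1, 1.24, 2.17, 405,
                             -0.0068, 14.6))
  expect_error(dose_event(0))
  p <- pk_parameters(12.2, 691, 20.2, 0.00653, 85.7, 0.185)
  expect_equal(p$ke, 12.2 / 691)
  q <- pd_parameters(5.85, 0.0311, 16.1, 1.24, 2.17, 405, 0.0068, 14.6)
  expect_equal(q$kin, 0.0311 * 5.85)
  expect_equal(q$ktr, 1 / 14.6)
})
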