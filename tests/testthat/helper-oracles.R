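# Independent brute-force oracles.  These integrate the raw ODE system
# (depot, central, transit, neopterin) with a fixed-step classical RK4,
# segment-aligned at the absorption breakpoints so every subinterval is
# smooth.  They share no code with the package's analytic PK solution or
# its C++ integrators.

# one RK4 step of a generic 1st-order system
rk4_step <- function(f, t, y, h) {
  k1 <- f(t, y)
  k2 <- f(t + h / 2, y + h / 2 * k1)
  k3 <- f(t + h / 2, y + h / 2 * k2)
  k4 <- f(t + h, y + h * k3)
  y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

# integrate over [t0, t1] with rhs f, recording states at `record` times
# (all times assumed multiples of dt up to rounding)
rk4_span <- function(f, t0, t1, y, dt, record, store) {
  n <- max(1L, round((t1 - t0) / dt))
  h <- (t1 - t0) / n
  t <- t0
  for (i in seq_len(n)) {
    y <- rk4_step(f, t, y, h)
    t <- t0 + i * h
    hit <- which(abs(record - t) < 1e-9)
    for (k in hit) store[[k]] <- y
  }
  list(y = y, store = store)
}

# PK oracle: states (a1 depot ug, a2 central ug); zero-order input active
# on [0, d2]; (1-fz)*dose bolused into the depot at alag.
oracle_pk_rk4 <- function(pk, dose_ug, times, dt = 0.01) {
  fz <- 1 / (1 + exp(-pk$rf))
  ke <- pk$cl_f / pk$v_f
  r0 <- fz * dose_ug / pk$d2
  tmax <- max(times)
  breaks <- sort(unique(c(0, pk$d2, pk$alag, tmax)))
  breaks <- breaks[breaks <= tmax]
  if (max(breaks) < tmax) breaks <- c(breaks, tmax)
  y <- c(0, 0)
  store <- vector("list", length(times))
  for (k in which(times == 0)) store[[k]] <- y
  for (s in seq_len(length(breaks) - 1)) {
    t0 <- breaks[s]; t1 <- breaks[s + 1]
    if (abs(t0 - pk$alag) < 1e-9) y[1] <- y[1] + (1 - fz) * dose_ug
    rate <- if (t1 <= pk$d2 + 1e-9) r0 else 0
    f <- function(t, y) c(-pk$ka * y[1], pk$ka * y[1] + rate - ke * y[2])
    res <- rk4_span(f, t0, t1, y, dt, times, store)
    y <- res$y; store <- res$store
  }
  vapply(store, function(s) 1000 * s[2] / pk$v_f, numeric(1))
}

# PD oracle: full 4-state system; concentration comes from the integrated
# a2 state, not the analytic solution.
oracle_pd_rk4 <- function(pk, pd, dose_ug, times, dt = 0.01) {
  fz <- 1 / (1 + exp(-pk$rf))
  ke <- pk$cl_f / pk$v_f
  r0 <- fz * dose_ug / pk$d2
  kin <- pd$kout * pd$base
  ktr <- 1 / pd$mtt
  eff <- function(c, t) {
    if (c <= 0) return(1)
    ec50 <- pd$ecb * (1 + pd$ca * (1 - exp(-pd$cb * t)))
    1 + pd$emax * c^pd$gamma / (ec50^pd$gamma + c^pd$gamma)
  }
  tmax <- max(times)
  breaks <- sort(unique(pmin(c(0, pk$d2, pk$alag, tmax), tmax)))
  if (max(breaks) < tmax) breaks <- c(breaks, tmax)
  y <- c(0, 0, kin / ktr, pd$base)
  store <- vector("list", length(times))
  for (k in which(times == 0)) store[[k]] <- y
  for (s in seq_len(length(breaks) - 1)) {
    t0 <- breaks[s]; t1 <- breaks[s + 1]
    if (abs(t0 - pk$alag) < 1e-9) y[1] <- y[1] + (1 - fz) * dose_ug
    rate <- if (t1 <= pk$d2 + 1e-9) r0 else 0
    f <- function(t, y) {
      conc <- 1000 * y[2] / pk$v_f
      e <- eff(conc, t)
      c(-pk$ka * y[1],
        pk$ka * y[1] + rate - ke * y[2],
        kin * e - ktr * y[3],
        ktr * y[3] - pd$kout * y[4])
    }
    res <- rk4_span(f, t0, t1, y, dt, times, store)
    y <- res$y; store <- res$store
  }
  vapply(store, function(s) s[4], numeric(1))
}

# closed-form -2 log marginal likelihood of the linear toy model
# y_i = theta + eta + eps_i  (exchangeable within subject)
toy_marginal_m2ll <- function(ylist, theta, omega, sigma) {
  -2 * sum(vapply(ylist, function(y) {
    n <- length(y)
    S <- diag(sigma^2, n) + matrix(omega^2, n, n)
    -0.5 * as.numeric(n * log(2 * pi) +
                        determinant(S)$modulus +
                        t(y - theta) %*% solve(S) %*% (y - theta))
  }, numeric(1)))
}
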