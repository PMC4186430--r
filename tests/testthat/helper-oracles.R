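# Independent oracles used across the suite.  These deliberately take a
# different route than the package internals: the PK oracle integrates the
# compartmental amounts as an ODE system (the package uses the closed-form
# solution), and the turnover oracle integrates the pure-R right-hand side
# with a Runge-Kutta method (the package default is compiled lsoda).

# Plasma concentration by per-dose superposition of an amounts-based
# three-state ODE (depot, central, peripheral), solved with lsoda at tight
# tolerance.
ode_pk_oracle <- function(t_h, doses, pk) {
  k10 <- pk$cl / pk$v2
  k12 <- pk$q / pk$v2
  k21 <- pk$q / pk$v3
  cp <- numeric(length(t_h))
  for (i in seq_len(nrow(doses))) {
    route <- doses$route[i]
    f <- bioavailability(doses$amount[i], route, doses$vehicle[i], pk)
    ka <- if (route == "sc") pk$ka_sc else pk$ka_po
    amt <- f * doses$amount[i]
    y0 <- if (route == "iv") c(0, amt, 0) else c(amt, 0, 0)
    mod <- function(t, y, p) {
      list(c(-ka * y[1],
             ka * y[1] - (k10 + k12) * y[2] + k21 * y[3],
             k12 * y[2] - k21 * y[3]))
    }
    tau <- t_h - doses$time_h[i]
    on <- tau >= 0
    if (!any(on)) next
    sol <- deSolve::lsoda(y0, sort(unique(c(0, tau[on]))), mod, NULL,
                          rtol = 1e-11, atol = 1e-13)
    cp[on] <- cp[on] + sol[match(tau[on], sol[, 1]), 3] / pk$v2
  }
  cp
}

# Hand-written per-point Gaussian -2 log-likelihood (additive error).
brute_force_nll_additive <- function(obs, pred, sd) {
  total <- 0
  for (i in seq_along(obs)) {
    dens <- 1 / (sqrt(2 * pi) * sd) * exp(-(obs[i] - pred[i])^2 / (2 * sd^2))
    total <- total - 2 * log(dens)
  }
  total
}

# Hand computation of the equal-variance two-sample t statistic.
brute_force_t <- function(x, y) {
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
}

# Small event-record CSV fixture written on the fly.
write_fixture_csv <- function(path, rows) {
  header <- "ID,TIME,DV,AMT,EVID,DVID,AGE,ROUTE,VEHICLE,STUDY,ARM,LLOQ,STRAIN"
  writeLines(c(header, rows), path)
  path
}
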