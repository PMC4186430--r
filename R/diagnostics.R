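## Model diagnostics: visual predictive checks, treatment-effect summaries
## and the soluble-versus-insoluble reduction regression.

#' Visual predictive check
#'
#' Simulates `n_sim` replicate datasets under the design of the observed
#' dataset (same animals, ages and dosing histories) using the supplied
#' model parameters and residual noise, and summarises the simulated
#' observations as 5th/50th/95th percentile bands per bin.  Amyloid
#' endpoints are binned by termination age, drug concentrations by sampling
#' time.
#'
#' @param ds An [as_dataset()] object holding the observed data.
#' @param pk,pd Model parameters used for the predictions.
#' @param noise A [noise_spec()]; its residual component generates the
#'   replicate noise (`residual = NULL` gives a degenerate, noise-free VPC).
#' @param endpoint Endpoint to check.
#' @param n_sim Number of simulated replicates (the published analyses used
#'   1000).
#' @param breaks Bin breaks for the binning variable, or a single number of
#'   quantile-based bins (default 10, deciles).
#' @param seed RNG seed for the replicate noise.
#' @return An object of class `"vpc"`: a list with `bins` (per-bin
#'   percentiles), `observed` (binning variable, value and in-band flag),
#'   `endpoint` and `n_sim`.
#' @export
vpc <- function(ds, pk = pk_params(), pd = pd_params(), noise = noise_spec(),
                endpoint = "sol_ab40", n_sim = 1000, breaks = 10,
                seed = noise$seed) {
  stopifnot(inherits(ds, "abeta_dataset"))
  endpoint <- match.arg(endpoint, .endpoints)
  gb <- .build_groups(ds, pk, endpoint)
  obs <- gb$obs
  if (!nrow(obs)) stop("dataset has no usable observations for ", endpoint,
                       call. = FALSE)
  pred <- numeric(nrow(obs))
  for (g in gb$groups) {
    sol <- .pkpd_solve(g$times, g$dose_tab, pk, pd)
    i <- match(g$times, sol[, "time"])
    pred[g$obs_idx] <- switch(endpoint,
                              sol_ab40 = sol[i, "a_sol"],
                              insol_ab40 = sol[i, "a_insol"],
                              brain_conc_total = sol[i, "c_brain"],
                              plasma_conc = sol[i, "c_brain"] /
                                pk$brain_plasma_ratio)
    }
  xvar <- if (endpoint %in% c("sol_ab40", "insol_ab40")) {
    hours_to_age(obs$model_time)
  } else {
    obs$time_h
  }

  if (length(breaks) == 1) {
    qs <- stats::quantile(xvar, probs = seq(0, 1, length.out = breaks + 1))
    breaks <- unique(as.numeric(qs))
  }
  if (length(breaks) < 2) breaks <- breaks + c(-0.5, 0.5)  # single-age data
  bin <- cut(xvar, breaks = breaks, include.lowest = TRUE)

  em <- noise$residual[[endpoint]]
  sims <- withr_seed(seed, {
    matrix(.draw_noise(rep(pred, n_sim), em), nrow = nrow(obs))
  })
  bins <- do.call(rbind, lapply(levels(bin), function(b) {
    sel <- bin == b
    if (!any(sel)) return(NULL)
    v <- as.numeric(sims[sel, , drop = FALSE])
    q <- stats::quantile(v, c(0.05, 0.5, 0.95), names = FALSE)
    data.frame(bin = b, x_mid = stats::median(xvar[sel]), n = sum(sel),
               p5 = q[1], p50 = q[2], p95 = q[3])
  }))
  lo <- bins$p5[match(bin, bins$bin)]
  hi <- bins$p95[match(bin, bins$bin)]
  observed <- data.frame(x = xvar, value = obs$value,
                         in_band = obs$value >= lo & obs$value <= hi)
  structure(list(bins = bins, observed = observed, endpoint = endpoint,
                 n_sim = n_sim),
            class = "vpc")
}

#' @export
print.vpc <- function(x, ...) {
  cat(sprintf("Visual predictive check (%s, %d simulations, %d bins)\n",
              x$endpoint, x$n_sim, nrow(x$bins)))
  cat(sprintf("  observations inside the 90%% band: %.1f%%\n",
              100 * mean(x$observed$in_band)))
  invisible(x)
}

#' @export
plot.vpc <- function(x, log = "y", ...) {
  b <- x$bins[order(x$bins$x_mid), ]
  graphics::plot(x$observed$x, x$observed$value, pch = 1, col = "grey60",
                 log = log, xlab = "age (months) / time (h)",
                 ylab = x$endpoint, ...)
  graphics::polygon(c(b$x_mid, rev(b$x_mid)), c(b$p5, rev(b$p95)),
                    col = grDevices::adjustcolor("grey40", alpha.f = 0.3),
                    border = NA)
  graphics::lines(b$x_mid, b$p50, lwd = 2)
  invisible(x)
}

#' Vehicle-versus-treated effect summary
#'
#' Unpaired two-sided t-test comparison of treated against vehicle values,
#' reported as mean +/- SEM per arm, percent change and p-value, with the
#' significance level at 0.05.  The equal-variance (Student) test is the
#' default; Welch's correction is available.
#'
#' @param vehicle,treated Numeric vectors of per-animal values (each of
#'   length >= 2).
#' @param var_equal Use the equal-variance test (default) or Welch's.
#' @return An object of class `"effect_summary"` with the arm means, SEMs,
#'   `percent_change` (`100 * (treated - vehicle) / vehicle` on the means),
#'   `t_statistic`, `df`, `p_value` and `significant`.
#' @export
effect_summary <- function(vehicle, treated, var_equal = TRUE) {
  if (length(vehicle) < 2 || length(treated) < 2) {
    stop("each arm needs at least 2 values", call. = FALSE)
  }
  tt <- stats::t.test(treated, vehicle, var.equal = var_equal)
  mv <- mean(vehicle); mt <- mean(treated)
  structure(list(
    vehicle_mean = mv, vehicle_sem = stats::sd(vehicle) / sqrt(length(vehicle)),
    treated_mean = mt, treated_sem = stats::sd(treated) / sqrt(length(treated)),
    n_vehicle = length(vehicle), n_treated = length(treated),
    percent_change = 100 * (mt - mv) / mv,
    t_statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, significant = tt$p.value < 0.05,
    var_equal = var_equal
  ), class = "effect_summary")
}

#' @export
print.effect_summary <- function(x, ...) {
  cat(sprintf("vehicle %.3g +/- %.2g (n=%d), treated %.3g +/- %.2g (n=%d)\n",
              x$vehicle_mean, x$vehicle_sem, x$n_vehicle,
              x$treated_mean, x$treated_sem, x$n_treated))
  cat(sprintf("  change %+.1f%%, t = %.3g (df %.3g), p = %.3g%s\n",
              x$percent_change, x$t_statistic, x$df, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Soluble-versus-insoluble reduction regression by treatment duration
#'
#' Least-squares regression (free intercept) of the observed insoluble
#' Abeta40 reduction on the model-predicted average soluble reduction,
#' fitted separately per treatment-duration group (1-3 weeks versus 4-6
#' weeks by default).  A steeper 4-6-week slope reflects the roughly
#' 30-day insoluble turnover half-life: short treatments cannot move the
#' insoluble pool far regardless of the soluble suppression achieved.
#'
#' @param points Data frame with columns `soluble_reduction` (average
#'   percent), `insoluble_reduction` (observed percent) and
#'   `duration_weeks`.
#' @param group_breaks Breaks (weeks) defining the duration groups.
#' @return A data frame with one row per non-empty group: `group`, `n`,
#'   `slope`, `intercept`, `r_squared` and `degenerate` (TRUE when the
#'   x-values carry no variance and no slope can be estimated).
#' @export
soluble_insoluble_regression <- function(points,
                                         group_breaks = c(0, 3.5, 6.5)) {
  points <- as.data.frame(points)
  need <- c("soluble_reduction", "insoluble_reduction", "duration_weeks")
  stopifnot(all(need %in% names(points)))
  grp <- cut(points$duration_weeks, breaks = group_breaks,
             labels = c("1-3 wk", "4-6 wk")[seq_len(length(group_breaks) - 1)],
             include.lowest = TRUE)
  out <- lapply(levels(grp), function(g) {
    p <- points[!is.na(grp) & grp == g, , drop = FALSE]
    if (nrow(p) < 2) return(NULL)
    if (stats::sd(p$soluble_reduction) < 1e-12) {
      return(data.frame(group = g, n = nrow(p), slope = NA_real_,
                        intercept = NA_real_, r_squared = NA_real_,
                        degenerate = TRUE))
    }
    fit <- stats::lm(insoluble_reduction ~ soluble_reduction, data = p)
    # collinear inputs are legitimate here; silence the perfect-fit notice
    r2 <- suppressWarnings(summary(fit)$r.squared)
    data.frame(group = g, n = nrow(p), slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = r2, degenerate = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) stop("no duration group has >= 2 points", call. = FALSE)
  out
}
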