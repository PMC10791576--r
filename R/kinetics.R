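# Kinetic model fitting: single-exponential traces, hyperbolic
# concentration dependence (k_pol, K_d,app), specificity constant,
# pseudo-first-order association, and dissociation bounds.

#' Fit a single exponential to a kinetic trace
#'
#' Least-squares fit of `y = baseline + amplitude * (1 - exp(-rate * t))`
#' (rise) or `y = baseline + amplitude * exp(-rate * t)` (decay); the
#' direction is auto-detected from the trend unless given. Initialization
#' uses a log-linearization of the early points plus jittered multi-starts;
#' uncertainty comes from seeded residual-resampling bootstrap. A trace
#' statistically indistinguishable from flat returns rate 0 with a wide CI.
#'
#' @param trace data.frame with columns `time` (strictly increasing) and
#'   `signal`, e.g. a `kinetic_trace`.
#' @param direction `"auto"`, `"rise"` or `"decay"`.
#' @param n_starts Number of jittered starts.
#' @param n_boot Bootstrap replicates (0 disables the CI).
#' @param seed Seed for jitter and bootstrap.
#' @return Object of class `exp_fit`: `rate`, `amplitude`, `baseline`,
#'   `direction`, `rmse`, `ci` (95% bootstrap interval on the rate).
#' @export
fit_single_exponential <- function(trace, direction = c("auto", "rise", "decay"),
                                   n_starts = 5L, n_boot = 200L, seed = 1L) {
  direction <- match.arg(direction)
  t <- trace$time; y <- trace$signal
  if (length(t) < 5) stop("need at least 5 points")
  check_time_grid(t)
  local_rng(seed)

  third <- max(2L, floor(length(y) / 3))
  rising <- mean(y[seq_len(third)]) < mean(y[(length(y) - third + 1):length(y)])
  if (direction == "auto") direction <- if (rising) "rise" else "decay"

  # flat-trace guard: slope indistinguishable from 0
  span <- diff(range(y))
  flat <- span == 0
  if (!flat) {
    sl <- stats::lm(y ~ t)
    slope_p <- summary(sl)$coefficients[2, 4]
    flat <- slope_p > 0.05 &&
      abs(stats::coef(sl)[2]) * diff(range(t)) < 0.05 * max(abs(y), 1e-12)
  }
  if (flat) {
    return(structure(list(rate = 0, amplitude = 0, baseline = mean(y),
                          direction = direction, rmse = stats::sd(y),
                          ci = c(0, Inf), converged = TRUE, flat = TRUE),
                     class = "exp_fit"))
  }

  rate0 <- init_rate(t, y, direction)
  amp0 <- if (direction == "rise") max(y) - min(y) else y[1] - min(y)
  base0 <- if (direction == "rise") min(y) else min(y)
  model <- if (direction == "rise") {
    signal ~ baseline + amplitude * (1 - exp(-rate * time))
  } else {
    signal ~ baseline + amplitude * exp(-rate * time)
  }
  df <- data.frame(time = t, signal = y)
  fit <- NULL
  for (s in seq_len(n_starts)) {
    jit <- if (s == 1) c(1, 1, 1) else exp(stats::rnorm(3, sd = 0.3))
    st <- list(rate = rate0 * jit[1], amplitude = amp0 * jit[2],
               baseline = base0 + (jit[3] - 1) * 0.1 * abs(amp0))
    f <- tryCatch(minpack.lm::nlsLM(model, data = df, start = st,
                                    lower = c(rate = 0, amplitude = -Inf, baseline = -Inf),
                                    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10)),
                  error = function(e) NULL)
    if (!is.null(f) && (is.null(fit) || stats::deviance(f) < stats::deviance(fit))) fit <- f
  }
  if (is.null(fit)) {
    stop(sprintf("exponential fit failed to converge after %d starts (direction %s, init rate %.3g)",
                 n_starts, direction, rate0))
  }
  cf <- stats::coef(fit)
  resid <- stats::resid(fit)
  pred <- stats::fitted(fit)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    boots <- vapply(seq_len(n_boot), function(b) {
      yb <- pred + sample(resid, length(resid), replace = TRUE)
      fb <- tryCatch(minpack.lm::nlsLM(model, data = data.frame(time = t, signal = yb),
                                       start = as.list(cf),
                                       lower = c(rate = 0, amplitude = -Inf, baseline = -Inf),
                                       control = minpack.lm::nls.lm.control(maxiter = 100)),
                     error = function(e) NULL)
      if (is.null(fb)) NA_real_ else stats::coef(fb)[["rate"]]
    }, 0)
    boots <- boots[is.finite(boots)]
    if (length(boots) >= 20) ci <- unname(stats::quantile(boots, c(0.025, 0.975)))
  }
  structure(list(rate = unname(cf[["rate"]]), amplitude = unname(cf[["amplitude"]]),
                 baseline = unname(cf[["baseline"]]), direction = direction,
                 rmse = sqrt(mean(resid^2)), ci = ci, converged = TRUE,
                 flat = FALSE),
            class = "exp_fit")
}

# log-linearized rate initialization from the early part of the trace
init_rate <- function(t, y, direction) {
  n <- length(y)
  if (direction == "rise") {
    ymax <- max(y); ymin <- min(y)
    frac <- pmin(pmax((ymax - y) / max(ymax - ymin, 1e-12), 1e-6), 1)
  } else {
    ymin <- min(y); ymax <- max(y)
    frac <- pmin(pmax((y - ymin) / max(ymax - ymin, 1e-12), 1e-6), 1)
  }
  use <- frac > 0.05 & seq_len(n) <= ceiling(n * 0.8)
  if (sum(use) < 3) use <- seq_len(min(n, 5))
  sl <- stats::coef(stats::lm(log(frac[use]) ~ t[use]))[2]
  max(-unname(sl), 1 / (max(t) - min(t)))
}

#' Fit the hyperbolic concentration dependence of observed rates
#'
#' Model: `k_obs = k_pol * c / (kd_app + c)`. Weighted least squares when
#' rate uncertainties are supplied (inverse-variance weights). Warns when
#' the concentrations do not straddle the fitted half-saturation point.
#'
#' @param concs Substrate concentrations (any consistent unit).
#' @param rates Observed rates (per second).
#' @param rate_se Optional standard errors on the rates.
#' @return Object of class `hyperbolic_fit`: `k_pol`, `kd_app`, their
#'   standard errors, and `rmse`.
#' @export
fit_hyperbola <- function(concs, rates, rate_se = NULL) {
  stopifnot(length(concs) == length(rates), all(concs > 0))
  if (length(concs) < 4) warning("fewer than 4 concentrations; parameters may be weakly identified")
  w <- if (is.null(rate_se)) rep(1, length(rates)) else 1 / pmax(rate_se, 1e-12)^2
  df <- data.frame(conc = concs, rate = rates, w = w)
  half_guess <- concs[which.min(abs(rates - max(rates) / 2))]
  fit <- tryCatch(
    minpack.lm::nlsLM(rate ~ k_pol * conc / (kd_app + conc), data = df,
                      start = list(k_pol = max(rates) * 1.2, kd_app = half_guess),
                      weights = w,
                      lower = c(k_pol = 1e-12, kd_app = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-10)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) c(k_pol = NA_real_, kd_app = NA_real_))
    rmse <- sqrt(mean(stats::resid(fit)^2))
  } else {
    # near-degenerate design (e.g. all concentrations saturating): direct
    # weighted SSE minimization on log parameters, uncertainty unreported
    obj <- function(lp) sum(w * (rates - exp(lp[1]) * concs / (exp(lp[2]) + concs))^2)
    op <- stats::optim(log(c(max(rates) * 1.2, half_guess)), obj,
                       control = list(maxit = 2000, reltol = 1e-14))
    cf <- c(k_pol = exp(op$par[1]), kd_app = exp(op$par[2]))
    se <- c(k_pol = NA_real_, kd_app = NA_real_)
    rmse <- sqrt(op$value / sum(w))
  }
  if (max(concs) < cf[["kd_app"]] || min(concs) > cf[["kd_app"]]) {
    warning("parameters weakly identified: concentrations do not straddle kd_app")
  }
  structure(list(k_pol = unname(cf[["k_pol"]]), kd_app = unname(cf[["kd_app"]]),
                 k_pol_se = unname(se[["k_pol"]]), kd_app_se = unname(se[["kd_app"]]),
                 rmse = rmse),
            class = "hyperbolic_fit")
}

#' Specificity constant from a hyperbolic fit
#'
#' `k_pol / kd_app`, the specificity constant governing productive
#' nucleotide binding and incorporation, with first-order (delta-method)
#' error propagation.
#'
#' @param fit A [fit_hyperbola()] result, or a list with `k_pol`, `kd_app`
#'   (and optionally their `*_se`).
#' @return List: `value` (per concentration-unit per second) and `se`.
#' @export
specificity_constant <- function(fit) {
  v <- fit$k_pol / fit$kd_app
  se <- NA_real_
  if (!is.null(fit$k_pol_se) && !is.null(fit$kd_app_se) &&
      is.finite(fit$k_pol_se) && is.finite(fit$kd_app_se)) {
    se <- sqrt((fit$k_pol_se / fit$kd_app)^2 +
               (fit$k_pol * fit$kd_app_se / fit$kd_app^2)^2)
  }
  list(value = v, se = se)
}

#' Fit a pseudo-first-order association rate constant
#'
#' Fits each trace to a rising exponential and regresses the observed rates
#' on concentration through the origin (`k_obs = k_on * c`), inverse-variance
#' weighted when bootstrap CIs are available.
#'
#' @param traces List of rising `kinetic_trace` objects.
#' @param concs Concentration per trace (defaults to each trace's `conc`
#'   attribute).
#' @param seed Seed passed to the per-trace fits.
#' @return Object of class `association_fit`: `k_on`, per-concentration
#'   `k_obs`, and the per-trace fits.
#' @export
fit_association <- function(traces, concs = NULL, seed = 1L) {
  if (is.null(concs)) concs <- vapply(traces, function(tr) attr(tr, "conc"), 0)
  stopifnot(length(concs) == length(traces), all(concs > 0))
  fits <- lapply(seq_along(traces), function(i) {
    fit_single_exponential(traces[[i]], direction = "rise", n_boot = 0, seed = seed + i)
  })
  k_obs <- vapply(fits, function(f) f$rate, 0)
  if (length(traces) < 2) {
    warning("single concentration: k_on taken as k_obs / conc")
    k_on <- k_obs[1] / concs[1]
  } else {
    k_on <- sum(k_obs * concs) / sum(concs^2)     # through-origin LS
  }
  if (k_on <= 0) stop("fitted association slope is non-positive")
  structure(list(k_on = k_on, k_obs = k_obs, concs = concs, fits = fits),
            class = "association_fit")
}

#' Dissociation rate, or an upper bound when none is measurable
#'
#' Fits a decaying exponential over the observation window. If the fitted
#' rate's bootstrap CI includes zero (the avidite regime of persistent
#' signal) the function reports the detection-limited upper bound
#' `k_off <= log(1 / (1 - detect_frac)) / window`, i.e. the largest rate
#' whose signal loss over the window would stay below the detectable
#' fraction `detect_frac`.
#'
#' @param trace A decaying (or flat) `kinetic_trace`.
#' @param window Observation window in seconds (>= 60 to support an
#'   imaging-timescale claim; shorter windows only warn).
#' @param detect_frac Smallest fractional signal drop detectable (default
#'   0.05).
#' @param seed Bootstrap seed.
#' @return List: `k_off` (estimate or bound), `is_bound` (TRUE when only an
#'   upper bound is reported), and the underlying `fit`.
#' @export
dissociation_bound <- function(trace, window = 60, detect_frac = 0.05, seed = 1L) {
  if (window < 60) warning("window shorter than the 60 s imaging timescale")
  fit <- fit_single_exponential(trace, direction = "decay", seed = seed)
  no_decay <- fit$flat || (is.finite(fit$ci[1]) && fit$ci[1] <= 0) ||
    fit$rate <= .Machine$double.eps
  if (no_decay) {
    list(k_off = log(1 / (1 - detect_frac)) / window, is_bound = TRUE, fit = fit)
  } else {
    list(k_off = fit$rate, is_bound = FALSE, fit = fit)
  }
}
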