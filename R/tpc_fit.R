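default_tpc_bounds <- function() {
  # brackets all published parameter values with margin
  list(lower = c(e_a = 0.2, e_h = 0.3, t_h = 280),
       upper = c(e_a = 3,   e_h = 25,  t_h = 330))
}

#' Fit a Sharpe-Schoolfield thermal performance curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) with seeded random
#' multistart. Rates are internally rescaled to unit magnitude so the fit is
#' invariant to the rate's unit system; only `r_tref` and `mrp` carry the
#' unit back. Candidate fits with `e_h <= e_a` are rejected; the minimal-SSE
#' candidate is returned.
#'
#' @param rates data frame with columns `temperature_C` and `value`
#'   (replicate-level per-capita rates; >= 5 distinct temperatures).
#' @param tref reference temperature, Celsius.
#' @param multistart number of random initialisations.
#' @param seed integer seed for the initialisations.
#' @param bounds list with named `lower`/`upper` vectors for `e_a`, `e_h`,
#'   `t_h`.
#' @return object of class `tpc_fit`: `params` ([tpc_params()] with derived
#'   `topt`/`mrp`), `sse`, `sigma`, `n_obs`, `data`, `flags` (e.g. parameters
#'   pinned at bounds), and `ci` (filled by [bootstrap_cis()]).
#' @export
fit_tpc <- function(rates, tref = 20, multistart = 20, seed = NULL,
                    bounds = default_tpc_bounds()) {
  temps <- rates$temperature_C
  vals <- rates$value
  if (length(unique(temps)) < 5) {
    stop("need rates at >= 5 distinct temperatures to fit a TPC")
  }
  if (all(vals <= 0)) {
    warning("all rates are non-positive; attempting fit on raw values")
  }
  if (!is.null(seed)) set.seed(seed)

  sc <- max(abs(vals))
  if (sc == 0) stop("all rates are zero; nothing to fit")
  v <- vals / sc
  v0 <- max(mean(v[v > 0], na.rm = TRUE), 1e-3)
  lo <- bounds$lower
  hi <- bounds$upper

  starts <- lapply(seq_len(multistart), function(i) {
    ea <- stats::runif(1, lo["e_a"], min(2.5, hi["e_a"]))
    list(r = exp(stats::runif(1, log(0.05 * v0), log(20 * v0))),
         ea = ea,
         eh = min(ea + stats::runif(1, 0.2, 10), hi["e_h"]),
         th = stats::runif(1, max(285, lo["t_h"]), min(325, hi["t_h"])))
  })

  dat <- data.frame(temp = temps, v = v)
  best <- NULL
  n_conv <- 0L
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        v ~ sharpe_schoolfield(temp, r, ea, eh, th, tref),
        data = dat, start = s,
        lower = c(r = 1e-12, ea = lo["e_a"], eh = lo["e_h"], th = lo["t_h"]),
        upper = c(r = 1e6, ea = hi["e_a"], eh = hi["e_h"], th = hi["t_h"]),
        control = minpack.lm::nls.lm.control(maxiter = 300)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    cf <- stats::coef(fit)
    if (cf["eh"] <= cf["ea"]) next
    n_conv <- n_conv + 1L
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(coef = cf, sse = sse)
  }
  if (is.null(best)) stop("no multistart candidate converged to a valid fit")

  cf <- best$coef
  tol <- 1e-6
  at_bounds <- character(0)
  for (p in c("ea", "eh", "th")) {
    key <- c(ea = "e_a", eh = "e_h", th = "t_h")[[p]]
    if (cf[p] <= lo[key] + tol * max(1, abs(lo[key])) ||
        cf[p] >= hi[key] - tol * max(1, abs(hi[key]))) {
      at_bounds <- c(at_bounds, key)
    }
  }
  n <- length(vals)
  params <- tpc_params(cf[["r"]] * sc, cf[["ea"]], cf[["eh"]], cf[["th"]], tref)
  structure(list(
    params = params,
    sse = best$sse * sc^2,
    sigma = sqrt(best$sse * sc^2 / max(1, n - 4)),
    n_obs = n,
    n_starts = multistart,
    n_converged = n_conv,
    data = data.frame(temperature_C = temps, value = vals),
    bounds = bounds,
    flags = list(at_bounds = at_bounds,
                 all_nonpositive = all(vals <= 0)),
    ci = NULL
  ), class = "tpc_fit")
}

#' Case-resampling bootstrap confidence intervals for a TPC fit
#'
#' Resamples replicate rows (cases) with replacement, refits from the point
#' estimate plus one random restart, and returns percentile intervals for the
#' raw parameters and the derived optimum and peak rate. Seeded and
#' reproducible; `n_boot = 0` returns degenerate intervals at the point
#' estimates.
#'
#' @param fit a [fit_tpc()] result.
#' @param n_boot number of bootstrap resamples.
#' @param level confidence level.
#' @param seed integer seed.
#' @return the `tpc_fit` with `ci` filled: a data frame with columns
#'   `parameter`, `estimate`, `lower`, `upper`, plus attributes `level`,
#'   `n_boot`, `n_failed`.
#' @export
bootstrap_cis <- function(fit, n_boot = 999, level = 0.95, seed = NULL) {
  stopifnot(inherits(fit, "tpc_fit"))
  if (!is.null(seed)) set.seed(seed)
  p <- fit$params
  point <- c(r_tref = p$r_tref, e_a = p$e_a, e_h = p$e_h, t_h = p$t_h,
             topt = p$topt, mrp = p$mrp)
  if (n_boot == 0) {
    ci <- data.frame(parameter = names(point), estimate = unname(point),
                     lower = unname(point), upper = unname(point))
  } else {
    dat <- fit$data
    tref <- p$tref
    sc <- max(abs(dat$value))
    lo <- fit$bounds$lower
    hi <- fit$bounds$upper
    start0 <- list(r = p$r_tref / sc, ea = p$e_a, eh = p$e_h, th = p$t_h)
    draws <- matrix(NA_real_, n_boot, 6,
                    dimnames = list(NULL, names(point)))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(nrow(dat), replace = TRUE)
      bd <- data.frame(temp = dat$temperature_C[idx], v = dat$value[idx] / sc)
      cand <- list(start0,
                   list(r = start0$r * exp(stats::rnorm(1, 0, 0.5)),
                        ea = stats::runif(1, lo["e_a"], min(2.5, hi["e_a"])),
                        eh = start0$eh, th = start0$th))
      best <- NULL
      for (s in cand) {
        f <- tryCatch(
          minpack.lm::nlsLM(
            v ~ sharpe_schoolfield(temp, r, ea, eh, th, tref),
            data = bd, start = s,
            lower = c(r = 1e-12, ea = lo["e_a"], eh = lo["e_h"], th = lo["t_h"]),
            upper = c(r = 1e6, ea = hi["e_a"], eh = hi["e_h"], th = hi["t_h"]),
            control = minpack.lm::nls.lm.control(maxiter = 150)
          ),
          error = function(e) NULL
        )
        if (is.null(f)) next
        cf <- stats::coef(f)
        if (cf["eh"] <= cf["ea"]) next
        sse <- sum(stats::resid(f)^2)
        if (is.null(best) || sse < best$sse) best <- list(coef = cf, sse = sse)
      }
      if (is.null(best)) next
      cf <- best$coef
      topt <- tryCatch(topt_of(cf[["ea"]], cf[["eh"]], cf[["th"]]),
                       error = function(e) NA_real_)
      draws[b, ] <- c(cf[["r"]] * sc, cf[["ea"]], cf[["eh"]], cf[["th"]], topt,
                      if (is.na(topt)) NA_real_ else
                        sharpe_schoolfield(topt, cf[["r"]] * sc, cf[["ea"]],
                                           cf[["eh"]], cf[["th"]], p$tref))
    }
    n_failed <- sum(is.na(draws[, "e_a"]))
    if (n_failed > 0.2 * n_boot) {
      warning("more than 20% of bootstrap refits failed; intervals may be too wide")
    }
    a <- (1 - level) / 2
    qs <- apply(draws, 2, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE)
    ci <- data.frame(parameter = names(point), estimate = unname(point),
                     lower = qs[1, ], upper = qs[2, ])
    attr(ci, "n_failed") <- n_failed
  }
  rownames(ci) <- NULL
  attr(ci, "level") <- level
  attr(ci, "n_boot") <- n_boot
  fit$ci <- ci
  fit
}

#' Linear (or zero-slope constrained) model of rate versus temperature
#'
#' Ordinary least squares of rate on temperature. When the slope is not
#' significant at `alpha`, the model is refit with the slope constrained to
#' zero (intercept = sample mean) and flagged, matching the treatment of
#' temperature-independent ingestion.
#'
#' @param rates data frame with `temperature_C` and `value`.
#' @param alpha significance gate for keeping the free slope.
#' @return object of class `linear_rate_fit` with `slope`, `intercept`,
#'   `slope_se`, `r_squared`, `f_stat`, `df`, `p_value`, `constrained_zero`.
#' @export
fit_linear_rate <- function(rates, alpha = 0.05) {
  if (nrow(rates) < 3) stop("need at least 3 observations")
  m <- stats::lm(value ~ temperature_C, data = rates)
  sm <- summary(m)
  slope <- sm$coefficients["temperature_C", "Estimate"]
  p_val <- sm$coefficients["temperature_C", "Pr(>|t|)"]
  out <- list(slope = slope,
              intercept = sm$coefficients["(Intercept)", "Estimate"],
              slope_se = sm$coefficients["temperature_C", "Std. Error"],
              r_squared = sm$r.squared,
              f_stat = unname(sm$fstatistic["value"]),
              df = unname(sm$fstatistic[c("numdf", "dendf")]),
              p_value = p_val,
              constrained_zero = FALSE)
  if (is.na(p_val) || p_val >= alpha) {
    out$slope <- 0
    out$intercept <- mean(rates$value)
    out$constrained_zero <- TRUE
  }
  class(out) <- "linear_rate_fit"
  out
}

#' Fine-grid predictions from a fitted rate model
#'
#' Evaluates the model on a regular temperature grid (default 0.001 degree C
#' step, endpoints included to within one step).
#'
#' @param model a `tpc_fit`, `tpc_params`, or `linear_rate_fit`.
#' @param t_min,t_max grid limits, Celsius (`t_min < t_max`).
#' @param step grid step, Celsius.
#' @return data frame with columns `temperature_C`, `value`.
#' @export
predict_grid <- function(model, t_min, t_max, step = 0.001) {
  UseMethod("predict_grid")
}

make_grid <- function(t_min, t_max, step) {
  if (t_min >= t_max) stop("t_min must be below t_max")
  seq(t_min, t_max, by = step)
}

#' @export
predict_grid.tpc_params <- function(model, t_min, t_max, step = 0.001) {
  g <- make_grid(t_min, t_max, step)
  data.frame(temperature_C = g,
             value = sharpe_schoolfield(g, model$r_tref, model$e_a,
                                        model$e_h, model$t_h, model$tref))
}

#' @export
predict_grid.tpc_fit <- function(model, t_min, t_max, step = 0.001) {
  predict_grid(model$params, t_min, t_max, step)
}

#' @export
predict_grid.linear_rate_fit <- function(model, t_min, t_max, step = 0.001) {
  g <- make_grid(t_min, t_max, step)
  data.frame(temperature_C = g, value = model$intercept + model$slope * g)
}

#' @export
print.tpc_fit <- function(x, ...) {
  cat("Sharpe-Schoolfield fit (", x$n_obs, "observations,",
      x$n_converged, "/", x$n_starts, "starts converged )\n")
  print(x$params)
  if (length(x$flags$at_bounds)) {
    cat("  ! parameters at bounds:", paste(x$flags$at_bounds, collapse = ", "), "\n")
  }
  if (!is.null(x$ci)) {
    cat("  bootstrap", attr(x$ci, "level") * 100, "% CIs (",
        attr(x$ci, "n_boot"), "resamples ):\n")
    print(x$ci, digits = 4)
  }
  invisible(x)
}

#' @export
print.linear_rate_fit <- function(x, ...) {
  cat(sprintf("Linear rate model: value = %.4g %+.4g * T%s\n",
              x$intercept, x$slope,
              if (x$constrained_zero) "  [slope constrained to zero]" else ""))
  cat(sprintf("  slope SE %.3g, R^2 %.3f, F %.3f, p %.4g\n",
              x$slope_se, x$r_squared, x$f_stat, x$p_value))
  invisible(x)
}
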