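#' Boltzmann constant in eV per kelvin
#'
#' Fixed physical constant used throughout the Sharpe-Schoolfield model.
#' @export
boltzmann_k <- 8.62e-05

#' Sharpe-Schoolfield thermal performance curve
#'
#' Evaluates the high-temperature-inactivation form of the Sharpe-Schoolfield
#' model,
#' \deqn{rate(T) = \frac{r_{tref} \exp\left(-\frac{E_a}{k}\left(\frac{1}{T + 273.15} -
#'   \frac{1}{T_{ref} + 273.15}\right)\right)}{1 + \exp\left(\frac{E_h}{k}\left(\frac{1}{t_h} -
#'   \frac{1}{T + 273.15}\right)\right)}}
#' Temperatures are supplied in degrees Celsius and converted to kelvin only
#' inside the equation.
#'
#' @param temp temperature(s), degrees Celsius.
#' @param r_tref rate at the reference temperature `tref` (any rate unit; the
#'   output inherits it).
#' @param e_a activation energy, eV (rise below the optimum).
#' @param e_h deactivation energy, eV (fall beyond the optimum); must exceed
#'   `e_a`.
#' @param t_h temperature (kelvin) at which high-temperature enzyme
#'   inactivation halves the rate.
#' @param tref reference temperature, degrees Celsius.
#' @return numeric vector of rates, same length as `temp`.
#' @seealso [topt_of()], [tpc_params()], [reconstruct_tpc()]
#' @export
sharpe_schoolfield <- function(temp, r_tref, e_a, e_h, t_h, tref = 20) {
  t_k <- temp + 273.15
  tref_k <- tref + 273.15
  num <- r_tref * exp(-e_a / boltzmann_k * (1 / t_k - 1 / tref_k))
  den <- 1 + exp(e_h / boltzmann_k * (1 / t_h - 1 / t_k))
  num / den
}

#' Closed-form optimum temperature of a Sharpe-Schoolfield curve
#'
#' \deqn{T_{opt} = \frac{E_h t_h}{E_h + k t_h \ln(E_h/E_a - 1)}} (in kelvin),
#' returned in degrees Celsius.
#'
#' @inheritParams sharpe_schoolfield
#' @return optimum temperature, degrees Celsius.
#' @export
topt_of <- function(e_a, e_h, t_h) {
  stopifnot(is.finite(e_a), is.finite(e_h), is.finite(t_h))
  if (e_h <= e_a) stop("deactivation energy e_h must exceed activation energy e_a")
  topt_k <- e_h * t_h / (e_h + boltzmann_k * t_h * log(e_h / e_a - 1))
  topt_k - 273.15
}

#' Half-inactivation temperature from the optimum
#'
#' Inverse of [topt_of()]: given the optimum temperature and the two
#' activation energies, returns the kelvin temperature `t_h` at which the
#' rate is half-suppressed,
#' \deqn{t_h = \frac{T_{opt,K} E_h}{E_h - k T_{opt,K} \ln(E_h/E_a - 1)}}
#'
#' @param topt optimum temperature, degrees Celsius.
#' @inheritParams sharpe_schoolfield
#' @return `t_h` in kelvin.
#' @export
th_from_topt <- function(topt, e_a, e_h) {
  if (!is.finite(e_a) || e_a <= 0) stop("e_a must be positive")
  if (!is.finite(e_h) || e_h <= e_a) stop("e_h must exceed e_a (log argument otherwise invalid)")
  topt_k <- topt + 273.15
  topt_k * e_h / (e_h - boltzmann_k * topt_k * log(e_h / e_a - 1))
}

#' Construct a validated Sharpe-Schoolfield parameter set
#'
#' @inheritParams sharpe_schoolfield
#' @return an object of class `tpc_params`: a list with elements `r_tref`,
#'   `e_a`, `e_h`, `t_h`, `tref`, and derived `topt` (Celsius) and `mrp`
#'   (rate at `topt`).
#' @export
tpc_params <- function(r_tref, e_a, e_h, t_h, tref = 20) {
  if (!is.finite(e_a) || e_a <= 0) stop("e_a must be positive")
  if (!is.finite(e_h) || e_h <= e_a) stop("e_h must exceed e_a")
  if (!is.finite(t_h) || t_h <= 0) stop("t_h (kelvin) must be positive")
  topt <- topt_of(e_a, e_h, t_h)
  p <- list(
    r_tref = r_tref, e_a = e_a, e_h = e_h, t_h = t_h, tref = tref,
    topt = topt,
    mrp = sharpe_schoolfield(topt, r_tref, e_a, e_h, t_h, tref)
  )
  class(p) <- "tpc_params"
  p
}

#' Peak rate (MRP) of a Sharpe-Schoolfield parameter set
#'
#' @param params a `tpc_params` object.
#' @return the maximal rate of performance, attained at the optimum.
#' @export
mrp_of <- function(params) {
  stopifnot(inherits(params, "tpc_params"))
  sharpe_schoolfield(params$topt, params$r_tref, params$e_a, params$e_h,
                     params$t_h, params$tref)
}

#' Rebuild a full TPC parameter set from summary parameters
#'
#' Published thermal-performance summaries typically report the activation
#' energy, deactivation energy, optimum temperature and maximal rate
#' (Ea, Eh, Topt, MRP) rather than the raw model parameters. This solves for
#' `t_h` via [th_from_topt()] and scales `r_tref` so the curve attains
#' exactly `mrp` at `topt`.
#'
#' @param summary a [tpc_summary()] (or list with `e_a`, `e_h`, `topt`,
#'   `mrp`).
#' @param tref reference temperature, degrees Celsius.
#' @return a `tpc_params` object.
#' @export
reconstruct_tpc <- function(summary, tref = 20) {
  if (!is.finite(summary$mrp) || summary$mrp <= 0) stop("mrp must be positive")
  t_h <- th_from_topt(summary$topt, summary$e_a, summary$e_h)
  unit_peak <- sharpe_schoolfield(summary$topt, 1, summary$e_a, summary$e_h,
                                  t_h, tref)
  tpc_params(summary$mrp / unit_peak, summary$e_a, summary$e_h, t_h, tref)
}

#' @export
print.tpc_params <- function(x, ...) {
  cat("Sharpe-Schoolfield parameters (Tref =", x$tref, "C)\n")
  cat(sprintf("  r_tref = %.6g  Ea = %.3f eV  Eh = %.3f eV  th = %.2f K\n",
              x$r_tref, x$e_a, x$e_h, x$t_h))
  cat(sprintf("  derived: Topt = %.3f C, MRP = %.6g\n", x$topt, x$mrp))
  invisible(x)
}
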