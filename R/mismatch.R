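#' Energetic balance (gain-to-loss ratio) on a temperature grid
#'
#' Pointwise ratio of an energy-gain prediction grid to an energy-loss grid
#' on an identical temperature grid: P/Rr for a resource (net photosynthesis
#' over respiration) or I/Rc for a consumer (assimilated ingestion over
#' respiration). The ratio is masked (NA) wherever the loss is non-positive
#' or the gain is negative; the masked fraction is recorded.
#'
#' @param gain_grid,loss_grid data frames from [predict_grid()] with columns
#'   `temperature_C`, `value`, on identical grids and in matching units.
#' @param species organism label.
#' @param gain_kind,loss_kind rate-kind labels.
#' @return object of class `balance_curve`: list with `temperature_C`,
#'   `gain`, `loss`, `ratio`, `species`, `gain_kind`, `loss_kind`,
#'   `masked_fraction`.
#' @export
energetic_balance <- function(gain_grid, loss_grid, species = "",
                              gain_kind = "gain", loss_kind = "loss") {
  if (!isTRUE(all.equal(gain_grid$temperature_C, loss_grid$temperature_C))) {
    stop("gain and loss grids must share the same temperatures")
  }
  ratio <- gain_grid$value / loss_grid$value
  bad <- loss_grid$value <= 0 | gain_grid$value < 0
  ratio[bad] <- NA_real_
  structure(list(temperature_C = gain_grid$temperature_C,
                 gain = gain_grid$value, loss = loss_grid$value,
                 ratio = ratio, species = species,
                 gain_kind = gain_kind, loss_kind = loss_kind,
                 masked_fraction = mean(bad)),
            class = "balance_curve")
}

# Moving-average smoother over a window expressed in degrees C. Each point
# is averaged over a *symmetric* window that shrinks near the grid edges and
# near masked (NA) points: symmetric windows cannot invert a monotone trend
# and the gradual shrinkage leaves no discontinuity where the full window
# stops fitting. Masked points stay masked.
smooth_ma <- function(x, temps, window) {
  n <- length(x)
  if (window <= 0 || n < 3) return(x)
  step <- stats::median(diff(temps))
  h <- floor(window / step / 2)
  if (h < 1) return(x)
  na <- !is.finite(x)
  dl <- integer(n)
  run <- 0L
  for (i in seq_len(n)) {
    run <- if (na[i]) 0L else run + 1L
    dl[i] <- run
  }
  dr <- integer(n)
  run <- 0L
  for (i in rev(seq_len(n))) {
    run <- if (na[i]) 0L else run + 1L
    dr[i] <- run
  }
  half <- pmax(pmin(h, dl - 1L, dr - 1L), 0L)
  cs <- cumsum(ifelse(na, 0, x))
  i <- seq_len(n)
  lo <- i - half
  hi <- i + half
  base <- cs[pmax(lo - 1L, 1L)]
  base[lo <= 1L] <- 0
  sm <- (cs[hi] - base) / (hi - lo + 1)
  sm[na] <- NA_real_
  sm
}

# centered finite-difference derivative (one-sided at the ends), per degree C
fd_derivative <- function(x, temps) {
  n <- length(x)
  d <- rep(NA_real_, n)
  if (n >= 3) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (temps[3:n] - temps[1:(n - 2)])
  if (n >= 2) {
    d[1] <- (x[2] - x[1]) / (temps[2] - temps[1])
    d[n] <- (x[n] - x[n - 1]) / (temps[n] - temps[n - 1])
  }
  d
}

# contiguous TRUE runs -> data.frame(start, end) in temperature units
runs_to_intervals <- function(flag, temps) {
  flag[is.na(flag)] <- FALSE
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  data.frame(start = temps[starts[keep]], end = temps[ends[keep]])
}

#' Temperature of the maximal energetic balance (Tm)
#'
#' Locates the balance optimum as the lowest-temperature *local* maximum of
#' the gain-to-loss ratio. A purely monotone ratio has no interior peak, so
#' the boundary argmax is returned with `boundary = TRUE` (e.g. a consumer
#' whose balance declines over the whole assay range peaks at the grid
#' minimum). An edge maximum caused by the reconstructed loss curve
#' collapsing beyond its optimum is thereby not mistaken for the balance
#' optimum. Ties break to the lowest temperature.
#'
#' @param curve a [energetic_balance()] result.
#' @return list with `tm` (Celsius), `value` (ratio at `tm`), `boundary`
#'   (logical flag).
#' @export
find_tm <- function(curve) {
  r <- curve$ratio
  temps <- curve$temperature_C
  ok <- is.finite(r)
  if (!any(ok)) stop("ratio is masked everywhere; no Tm")
  n <- length(r)
  interior <- integer(0)
  for (i in which(ok)) {
    if (i == 1 || i == n) next
    if (!ok[i - 1] || !ok[i + 1]) next
    if (r[i] >= r[i - 1] && r[i] >= r[i + 1] &&
        (r[i] > r[i - 1] || r[i] > r[i + 1])) {
      interior <- c(interior, i)
    }
  }
  if (length(interior)) {
    i <- interior[1]
    return(list(tm = temps[i], value = r[i], boundary = FALSE))
  }
  i <- which(ok)[which.max(r[ok])]
  list(tm = temps[i], value = r[i],
       boundary = i == min(which(ok)) || i == max(which(ok)))
}

#' Crossover temperature (Tc) where the energetic balance falls to one
#'
#' The lowest grid temperature at which the gain-to-loss ratio transitions
#' from >= 1 to < 1 (a downward crossing), located by linear interpolation
#' between the bracketing grid points. Absent (NA) when no downward crossing
#' exists; a ratio that never reaches 1 is additionally flagged as an
#' always-deficit curve.
#'
#' @param curve a [energetic_balance()] result.
#' @return list with `tc` (Celsius or NA), `found`, `always_deficit`.
#' @export
find_tc <- function(curve) {
  r <- curve$ratio
  temps <- curve$temperature_C
  ok <- is.finite(r)
  if (!any(ok)) stop("ratio is masked everywhere; no Tc")
  for (i in seq_len(length(r) - 1)) {
    if (!ok[i] || !ok[i + 1]) next
    if (r[i] >= 1 && r[i + 1] < 1) {
      tc <- temps[i] + (r[i] - 1) / (r[i] - r[i + 1]) * (temps[i + 1] - temps[i])
      return(list(tc = tc, found = TRUE, always_deficit = FALSE))
    }
  }
  list(tc = NA_real_, found = FALSE, always_deficit = all(r[ok] < 1))
}

#' Intraspecific thermal mismatch interval(s)
#'
#' Maximal temperature interval(s) over which the energetic balance declines
#' with warming: where the (optionally smoothed) centered finite-difference
#' derivative of the ratio is negative. For a unimodal balance this is
#' `[Tm, grid max]`.
#'
#' @param curve a [energetic_balance()] result.
#' @param smooth_window moving-average window, degrees C, applied before
#'   differentiation (0 disables smoothing).
#' @return data frame with columns `start`, `end` (Celsius), possibly empty.
#' @export
intra_tm <- function(curve, smooth_window = 0.5) {
  sm <- smooth_ma(curve$ratio, curve$temperature_C, smooth_window)
  d <- fd_derivative(sm, curve$temperature_C)
  runs_to_intervals(d < 0 & is.finite(curve$ratio), curve$temperature_C)
}

#' Interspecific thermal mismatch regions
#'
#' Compares consumer and resource balance derivatives on a common grid.
#' Region 1 collects temperatures where the two balances trend in opposite
#' directions; region 2 where both decline. The onset is the lowest
#' temperature of any mismatch.
#'
#' @param consumer_curve,resource_curve [energetic_balance()] results on the
#'   same temperature grid.
#' @param smooth_window moving-average window, degrees C.
#' @return object of class `inter_tm_report`: list with `region1`, `region2`
#'   (interval data frames) and `onset` (Celsius, NA when no mismatch).
#' @export
inter_tm <- function(consumer_curve, resource_curve, smooth_window = 0.5) {
  if (!isTRUE(all.equal(consumer_curve$temperature_C,
                        resource_curve$temperature_C))) {
    stop("curves must share a common temperature grid")
  }
  temps <- consumer_curve$temperature_C
  dc <- fd_derivative(smooth_ma(consumer_curve$ratio, temps, smooth_window), temps)
  dr <- fd_derivative(smooth_ma(resource_curve$ratio, temps, smooth_window), temps)
  okc <- is.finite(consumer_curve$ratio) & is.finite(dc)
  okr <- is.finite(resource_curve$ratio) & is.finite(dr)
  ok <- okc & okr
  region1 <- runs_to_intervals(ok & (dc * dr < 0), temps)
  region2 <- runs_to_intervals(ok & dc < 0 & dr < 0, temps)
  onset <- suppressWarnings(min(c(region1$start, region2$start)))
  if (!is.finite(onset)) onset <- NA_real_
  structure(list(region1 = region1, region2 = region2, onset = onset),
            class = "inter_tm_report")
}

#' Consumer-resource energetic balance (CREB) curve
#'
#' The natural logarithm of the consumer's energetic balance divided by the
#' resource's, pointwise on a common grid:
#' `ln(I/Rc) - ln(P/Rr)`. Defined only where both component ratios are
#' positive.
#'
#' @param consumer_curve,resource_curve [energetic_balance()] results on the
#'   same temperature grid.
#' @return object of class `creb_curve`: list with `temperature_C`, `value`,
#'   `consumer`, `resource`.
#' @export
creb <- function(consumer_curve, resource_curve) {
  if (!isTRUE(all.equal(consumer_curve$temperature_C,
                        resource_curve$temperature_C))) {
    stop("curves must share a common temperature grid")
  }
  rc <- consumer_curve$ratio
  rr <- resource_curve$ratio
  v <- ifelse(is.finite(rc) & is.finite(rr) & rc > 0 & rr > 0,
              log(rc) - log(rr), NA_real_)
  structure(list(temperature_C = consumer_curve$temperature_C, value = v,
                 consumer = consumer_curve$species,
                 resource = resource_curve$species),
            class = "creb_curve")
}

#' Classify the temperature trend of a CREB curve
#'
#' Labels the sign pattern of the smoothed derivative of the CREB with
#' temperature: `declining`, `increasing`, `u_shaped` (negative then
#' positive), `hump_shaped` (positive then negative), or `flat`. Derivatives
#' smaller in magnitude than `eps` count as zero; `eps` defaults to 1% of
#' the CREB's range per degree C, so noise-scale wiggles do not fragment the
#' pattern.
#'
#' @param creb_curve a [creb()] result (>= 3 defined points).
#' @param eps derivative tolerance (CREB units per degree C), or NULL for the
#'   default.
#' @param smooth_window moving-average window, degrees C.
#' @return character label.
#' @export
classify_trend <- function(creb_curve, eps = NULL, smooth_window = 0.5) {
  ok <- is.finite(creb_curve$value)
  if (sum(ok) < 3) stop("need at least 3 defined CREB points")
  temps <- creb_curve$temperature_C[ok]
  v <- creb_curve$value[ok]
  if (is.null(eps)) eps <- 0.01 * diff(range(v))
  sm <- smooth_ma(v, temps, smooth_window)
  d <- fd_derivative(sm, temps)
  s <- sign(d)
  s[abs(d) < eps] <- 0
  s <- s[!is.na(s)]
  nz <- s[s != 0]
  if (!length(nz)) return("flat")
  pattern <- rle(nz)$values
  if (identical(pattern, -1)) return("declining")
  if (identical(pattern, 1)) return("increasing")
  if (identical(pattern, c(-1, 1))) return("u_shaped")
  if (identical(pattern, c(1, -1))) return("hump_shaped")
  # fragmented pattern: fall back on the interior extremum
  i_min <- which.min(sm)
  i_max <- which.max(sm)
  n <- length(sm)
  if (i_min > 1 && i_min < n && nz[1] < 0) return("u_shaped")
  if (i_max > 1 && i_max < n && nz[1] > 0) return("hump_shaped")
  if (nz[length(nz)] < 0) "declining" else "increasing"
}

#' Predicted interaction-strength trend from a CREB trend
#'
#' Maps the CREB trend label to the expected direction of per-capita
#' interaction strength with warming: a declining CREB predicts weakening
#' top-down control, an increasing CREB strengthening control; U-shaped or
#' flat CREBs predict a constant-or-increasing trend (direction
#' indeterminate), and hump-shaped ones the mirror case.
#'
#' @param trend a label from [classify_trend()].
#' @return list with `direction` (`"decreasing"`, `"increasing"`,
#'   `"constant_or_increasing"`, `"constant_or_decreasing"`) and
#'   `indeterminate` (logical).
#' @export
predict_is_trend <- function(trend) {
  switch(trend,
    declining = list(direction = "decreasing", indeterminate = FALSE),
    increasing = list(direction = "increasing", indeterminate = FALSE),
    u_shaped = list(direction = "constant_or_increasing", indeterminate = TRUE),
    flat = list(direction = "constant_or_increasing", indeterminate = TRUE),
    hump_shaped = list(direction = "constant_or_decreasing", indeterminate = TRUE),
    stop("unknown CREB trend label: ", trend)
  )
}

#' @export
print.balance_curve <- function(x, ...) {
  cat("Energetic balance:", x$species, paste0("(", x$gain_kind, "/", x$loss_kind, ")"),
      "\n  grid:", min(x$temperature_C), "-", max(x$temperature_C), "C,",
      length(x$temperature_C), "points;",
      sprintf("%.1f%% masked\n", 100 * x$masked_fraction))
  invisible(x)
}

#' @export
print.creb_curve <- function(x, ...) {
  ok <- is.finite(x$value)
  cat("CREB:", x$consumer, "over", x$resource, "\n  defined on",
      min(x$temperature_C[ok]), "-", max(x$temperature_C[ok]), "C\n")
  invisible(x)
}
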