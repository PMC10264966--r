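#' Per-capita hourly interaction strength (Dynamic Index)
#'
#' Log response ratio of resource density without versus with consumers,
#' per consumer and per hour: `IS = ln(N / D) / (y * t)`. Positive when
#' consumers depress the resource below the consumer-free controls.
#'
#' @param n resource density without consumers (mean of same-block control
#'   replicates at assay end), > 0.
#' @param d resource density with consumers present, > 0.
#' @param y consumers in the treatment vial (>= 1).
#' @param t_hours assay length in hours (> 0).
#' @return interaction strength, h^-1 per consumer.
#' @export
dynamic_index <- function(n, d, y, t_hours) {
  if (!is.finite(n) || n <= 0) stop("control density N must be positive")
  if (!is.finite(d) || d <= 0) stop("treatment density D must be positive")
  if (y < 1) stop("y must be >= 1")
  if (t_hours <= 0) stop("t must be positive")
  log(n / d) / (y * t_hours)
}

#' Interaction-strength records from a grazing-assay table
#'
#' Computes the Dynamic Index for every treatment vial of an ingestion table
#' (schema of [generate_ingestion_experiment()]), using the mean end density
#' of the same-block controls as `N`.
#'
#' @param ingestion grazing-assay data frame.
#' @param pair pair label attached to each record.
#' @return data frame `pair`, `temperature_C`, `block`, `replicate_id`,
#'   `value`, `n_controls_used`.
#' @export
is_from_ingestion <- function(ingestion, pair = "") {
  trt <- ingestion[ingestion$role == "treatment", ]
  out <- do.call(rbind, lapply(seq_len(nrow(trt)), function(i) {
    row <- trt[i, ]
    ctrl <- ingestion[ingestion$role == "control" &
                        ingestion$block == row$block &
                        ingestion$temperature_C == row$temperature_C, ]
    if (nrow(ctrl) == 0) {
      stop("no control replicates in block ", row$block, " at ",
           row$temperature_C, " C")
    }
    data.frame(pair = pair, temperature_C = row$temperature_C,
               block = row$block, replicate_id = row$replicate_id,
               value = dynamic_index(mean(ctrl$density_t150_cells_per_mL),
                                     row$density_t150_cells_per_mL,
                                     row$n_consumers, row$duration_min / 60),
               n_controls_used = nrow(ctrl))
  }))
  rownames(out) <- NULL
  out
}

#' Temperature regression of interaction strength with a species term
#'
#' Fits the full linear model `IS ~ temperature * pair` across both
#' consumer-resource pairs, reports the per-pair temperature slopes (each
#' pair's own simple regression) and the temperature-by-species interaction
#' test from a Type II ANOVA. With a single pair, only that pair's slope is
#' returned.
#'
#' @param records data frame with columns `pair`, `temperature_C`, `value`
#'   (>= 2 temperatures per pair).
#' @param exclude optional character vector of `replicate_id`s to drop
#'   (explicit outlier exclusions).
#' @return object of class `is_model`: per-pair `slopes` data frame
#'   (`pair`, `slope`, `se`, `p_value`), `interaction_F`, `interaction_df`,
#'   `interaction_p`, `sigma`, `n_obs`.
#' @export
is_regression <- function(records, exclude = NULL) {
  if (!is.null(exclude) && "replicate_id" %in% names(records)) {
    records <- records[!records$replicate_id %in% exclude, ]
  }
  pairs <- unique(records$pair)
  for (p in pairs) {
    if (length(unique(records$temperature_C[records$pair == p])) < 2) {
      stop("pair '", p, "' has fewer than 2 temperatures")
    }
  }
  slopes <- do.call(rbind, lapply(pairs, function(p) {
    m <- stats::lm(value ~ temperature_C, data = records[records$pair == p, ])
    cf <- summary(m)$coefficients
    data.frame(pair = p, slope = cf["temperature_C", "Estimate"],
               se = cf["temperature_C", "Std. Error"],
               p_value = cf["temperature_C", "Pr(>|t|)"])
  }))
  rownames(slopes) <- NULL
  interaction_F <- NA_real_
  interaction_df <- c(NA_real_, NA_real_)
  interaction_p <- NA_real_
  full <- NULL
  if (length(pairs) > 1) {
    records$pair <- factor(records$pair)
    full <- stats::lm(value ~ temperature_C * pair, data = records)
    a2 <- car::Anova(full, type = 2)
    irow <- grep(":", rownames(a2))
    interaction_F <- a2[irow, "F value"]
    interaction_df <- c(a2[irow, "Df"], a2["Residuals", "Df"])
    interaction_p <- a2[irow, "Pr(>F)"]
  }
  structure(list(slopes = slopes,
                 interaction_F = interaction_F,
                 interaction_df = interaction_df,
                 interaction_p = interaction_p,
                 sigma = if (is.null(full)) NA_real_ else summary(full)$sigma,
                 n_obs = nrow(records)),
            class = "is_model")
}

#' Concordance between a CREB-based prediction and the measured IS trend
#'
#' Compares the predicted interaction-strength direction (from
#' [predict_is_trend()]) with the sign of the fitted temperature slope for a
#' pair. A significant slope agreeing in sign gives `"agree"`; a
#' non-significant slope agrees with a constant-or-* prediction but is
#' `"inconclusive"` against a directional one.
#'
#' @param predicted a [predict_is_trend()] result (or its `direction`
#'   string).
#' @param slope,p_value fitted temperature slope of IS and its p-value.
#' @param alpha significance level.
#' @return `"agree"`, `"disagree"`, or `"inconclusive"`.
#' @export
concordance <- function(predicted, slope, p_value, alpha = 0.05) {
  direction <- if (is.list(predicted)) predicted$direction else predicted
  significant <- is.finite(p_value) && p_value < alpha
  obs_sign <- sign(slope)
  switch(direction,
    decreasing = if (!significant) "inconclusive"
                 else if (obs_sign < 0) "agree" else "disagree",
    increasing = if (!significant) "inconclusive"
                 else if (obs_sign > 0) "agree" else "disagree",
    constant_or_increasing = if (!significant || obs_sign > 0) "agree" else "disagree",
    constant_or_decreasing = if (!significant || obs_sign < 0) "agree" else "disagree",
    stop("unknown predicted direction: ", direction)
  )
}

#' @export
print.is_model <- function(x, ...) {
  cat("Interaction-strength regression (", x$n_obs, "records )\n")
  print(x$slopes, digits = 4)
  if (is.finite(x$interaction_F)) {
    cat(sprintf("  temperature x species: F(%g, %g) = %.3f, p = %.4g\n",
                x$interaction_df[1], x$interaction_df[2],
                x$interaction_F, x$interaction_p))
  }
  invisible(x)
}
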