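test_that("the energetic balance is the pointwise gain/loss ratio with masking", {
  temps <- seq(10, 14, 1)
  b <- balance_from_values(temps, gain = c(2, 2, 3, 0.5, -1),
                           loss = c(1, 2, 2, 1, 1))
  expect_equal(b$ratio[1:4], c(2, 1, 1.5, 0.5))
  expect_true(is.na(b$ratio[5])) # negative gain masked
  expect_equal(b$masked_fraction, 0.2)
  b2 <- balance_from_values(temps, gain = rep(1, 5), loss = c(1, 0, -1, 1, 1))
  expect_true(all(is.na(b2$ratio[2:3]))) # non-positive loss masked
  expect_error(energetic_balance(data.frame(temperature_C = 1:3, value = 1),
                                 data.frame(temperature_C = 2:4, value = 1)),
               "same temperatures")
})

test_that("Tm is the lowest-temperature local maximum of the ratio", {
  temps <- seq(10, 40, 0.1)
  # symmetric parabola peaking at 25
  b <- balance_from_values(temps, gain = 2 - ((temps - 25) / 10)^2,
                           loss = rep(1, length(temps)))
  res <- find_tm(b)
  expect_equal(res$tm, 25, tolerance = 1e-9)
  expect_equal(res$value, 2)
  expect_false(res$boundary)
  # monotone decline: boundary maximum at the grid minimum, flagged
  bm <- balance_from_values(temps, gain = 3 - 0.05 * temps,
                            loss = rep(1, length(temps)))
  rm_ <- find_tm(bm)
  expect_equal(rm_$tm, 10)
  expect_true(rm_$boundary)
  # two local maxima: the lower-temperature one wins even if smaller
  two <- 1 + sin((temps - 10) / 30 * 4 * pi) * c(0.5)
  bt <- balance_from_values(temps, gain = two, loss = rep(1, length(temps)))
  expect_lt(find_tm(bt)$tm, 15)
  expect_false(find_tm(bt)$boundary)
  # all masked
  bad <- balance_from_values(temps, gain = rep(1, length(temps)),
                             loss = rep(-1, length(temps)))
  expect_error(find_tm(bad), "masked everywhere")
})

test_that("Tc is the interpolated downward unity crossing, absent when none exists", {
  temps <- seq(10, 40, 0.5)
  # constructed crossing: ratio = 2 - 0.04 * T hits 1 at exactly T = 25
  b <- balance_from_values(temps, gain = 2 - 0.04 * temps,
                           loss = rep(1, length(temps)))
  res <- find_tc(b)
  expect_true(res$found)
  expect_equal(res$tc, 25, tolerance = 1e-9)
  # always above one: no crossing, not a deficit
  hi <- balance_from_values(temps, gain = rep(1.5, length(temps)),
                            loss = rep(1, length(temps)))
  rh <- find_tc(hi)
  expect_false(rh$found)
  expect_true(is.na(rh$tc))
  expect_false(rh$always_deficit)
  # always below one: flagged deficit
  lo <- balance_from_values(temps, gain = rep(0.5, length(temps)),
                            loss = rep(1, length(temps)))
  expect_true(find_tc(lo)$always_deficit)
  # upward-only crossing is not a Tc
  up <- balance_from_values(temps, gain = 0.5 + 0.04 * temps,
                            loss = rep(1, length(temps)))
  expect_false(find_tc(up)$found)
})

test_that("the intraspecific mismatch interval of a unimodal balance is [Tm, grid max]", {
  temps <- seq(10, 40, 0.01)
  b <- balance_from_values(temps, gain = exp(-((temps - 22) / 8)^2),
                           loss = rep(1, length(temps)))
  iv <- intra_tm(b, smooth_window = 0)
  expect_equal(nrow(iv), 1)
  expect_equal(iv$start, 22, tolerance = 0.02)
  expect_equal(iv$end, 40)
  # monotone increasing balance: no declining interval
  inc <- balance_from_values(temps, gain = temps, loss = rep(1, length(temps)))
  expect_equal(nrow(intra_tm(inc)), 0)
})

test_that("interspecific regions split opposite-trend from both-declining temperatures", {
  temps <- seq(10, 40, 0.01)
  loss <- rep(1, length(temps))
  cons <- balance_from_values(temps, gain = 40 - temps, loss = loss) # declining
  resr <- balance_from_values(temps, gain = exp(-((temps - 30) / 6)^2),
                              loss = loss) # peaks at 30
  rep_ <- inter_tm(cons, resr, smooth_window = 0)
  expect_equal(nrow(rep_$region1), 1)
  expect_equal(rep_$region1$start, 10, tolerance = 0.05)
  expect_equal(rep_$region1$end, 30, tolerance = 0.05)
  expect_equal(nrow(rep_$region2), 1)
  expect_equal(rep_$region2$start, 30, tolerance = 0.05)
  expect_equal(rep_$region2$end, 40)
  expect_equal(rep_$onset, 10, tolerance = 0.05)
  # parallel increasing balances: no mismatch anywhere
  inc1 <- balance_from_values(temps, gain = temps, loss = loss)
  inc2 <- balance_from_values(temps, gain = 2 * temps, loss = loss)
  none <- inter_tm(inc1, inc2, smooth_window = 0)
  expect_equal(nrow(none$region1), 0)
  expect_equal(nrow(none$region2), 0)
  expect_true(is.na(none$onset))
  expect_error(inter_tm(cons, balance_from_values(temps + 1, loss, loss)),
               "common temperature grid")
})

test_that("CREB is the log ratio difference and is antisymmetric", {
  temps <- seq(10, 20, 1)
  a <- balance_from_values(temps, gain = rep(4, 11), loss = rep(2, 11))
  b <- balance_from_values(temps, gain = rep(3, 11), loss = rep(3, 11))
  cc <- creb(a, b)
  expect_equal(cc$value, rep(log(2), 11))
  expect_equal(creb(b, a)$value, -cc$value)
  # masked where a component ratio is non-positive
  neg <- balance_from_values(temps, gain = c(rep(2, 5), rep(-1, 6)),
                             loss = rep(1, 11))
  expect_true(all(is.na(creb(neg, b)$value[6:11])))
})

test_that("trend classification labels canonical shapes", {
  temps <- seq(10, 40, 0.1)
  mk <- function(v) structure(list(temperature_C = temps, value = v,
                                   consumer = "c", resource = "r"),
                              class = "creb_curve")
  expect_equal(classify_trend(mk(5 - 0.1 * temps)), "declining")
  expect_equal(classify_trend(mk(0.1 * temps)), "increasing")
  expect_equal(classify_trend(mk(((temps - 25) / 10)^2)), "u_shaped")
  expect_equal(classify_trend(mk(-((temps - 25) / 10)^2)), "hump_shaped")
  expect_equal(classify_trend(mk(rep(1, length(temps)))), "flat")
  # noise below eps does not fragment a clean decline
  set.seed(12)
  noisy <- 5 - 0.1 * temps + rnorm(length(temps), 0, 0.001)
  expect_equal(classify_trend(mk(noisy)), "declining")
  expect_error(classify_trend(mk(rep(NA_real_, length(temps)))), "3 defined")
})

test_that("trend labels map to interaction-strength predictions", {
  expect_equal(predict_is_trend("declining"),
               list(direction = "decreasing", indeterminate = FALSE))
  expect_equal(predict_is_trend("increasing"),
               list(direction = "increasing", indeterminate = FALSE))
  expect_equal(predict_is_trend("u_shaped")$direction, "constant_or_increasing")
  expect_true(predict_is_trend("u_shaped")$indeterminate)
  expect_equal(predict_is_trend("flat")$direction, "constant_or_increasing")
  expect_equal(predict_is_trend("hump_shaped")$direction,
               "constant_or_decreasing")
  expect_error(predict_is_trend("sideways"), "unknown")
})

test_that("grid landmarks agree with a brute-force scan on reconstructed curves", {
  b <- resource_balance("chlamydomonas", step = 0.01)
  tm <- find_tm(b)
  # oracle: coarse scan for the first interior peak
  r <- b$ratio
  peaks <- which(diff(sign(diff(r))) == -2) + 1
  expect_equal(tm$tm, b$temperature_C[peaks[1]], tolerance = 0.02)
  tc <- find_tc(b)
  below <- which(r < 1 & b$temperature_C > tm$tm)
  expect_true(tc$found)
  expect_lt(abs(tc$tc - b$temperature_C[below[1]]), 0.02)
})

test_that("a unimodal gain over a monotone rising loss yields Tm below Tc", {
  # property check over random curve families
  set.seed(77)
  temps <- seq(5, 45, 0.05)
  for (i in 1:25) {
    peak <- runif(1, 15, 30)
    width <- runif(1, 4, 10)
    gain <- runif(1, 2, 5) * exp(-((temps - peak) / width)^2)
    loss <- runif(1, 0.2, 0.5) * exp(runif(1, 0.02, 0.08) * (temps - 5))
    b <- balance_from_values(temps, gain, loss)
    if (max(b$ratio) <= 1) next # no surplus anywhere: Tc undefined by design
    tm <- find_tm(b)
    tc <- find_tc(b)
    expect_false(tm$boundary)
    expect_true(tc$found)
    expect_lt(tm$tm, tc$tc)
  }
})

test_that("the smoother preserves monotonicity and leaves masked points masked", {
  temps <- seq(0, 10, 0.1)
  x <- temps^2
  x[30:35] <- NA
  sm <- smooth_ma(x, temps, 0.5)
  expect_true(all(is.na(sm[30:35])))
  ok <- which(!is.na(sm))
  segs <- split(ok, cumsum(c(1, diff(ok) != 1)))
  for (s in segs) expect_true(all(diff(sm[s]) >= -1e-12))
  # window 0 is the identity
  expect_identical(smooth_ma(x, temps, 0), x)
})
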