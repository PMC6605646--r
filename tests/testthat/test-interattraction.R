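test_that("virtual-pair superimposition recenters and truncates correctly", {
  # a trajectory pre-shifted by (+7, -3) maps back onto its unshifted twin
  tr <- tibble::tibble(t_s = 0:49 * 0.5, x_mm = sin(0:49 / 5) * 10,
                       y_mm = cos(0:49 / 5) * 10)
  shifted <- dplyr::mutate(tr, x_mm = x_mm + 7, y_mm = y_mm - 3)
  vp <- build_virtual_pair(tr, shifted, center_a = c(0, 0),
                           center_b = c(7, -3))
  expect_equal(vp$x_a, vp$x_b)
  expect_equal(vp$y_a, vp$y_b)
  expect_equal(attr(vp, "provenance"), "virtual")
  # truncation to the shorter recording
  vp2 <- build_virtual_pair(tr, tr[1:20, ])
  expect_equal(nrow(vp2), 20)
  # superimposition preserves each marginal's displacement series exactly
  expect_equal(diff(vp$x_a), diff(tr$x_mm))
  expect_equal(diff(vp$y_b), diff(tr$y_mm))
  # mismatched sampling rates are refused
  slow <- tibble::tibble(t_s = 0:49, x_mm = tr$x_mm, y_mm = tr$y_mm)
  expect_error(build_virtual_pair(tr, slow), "sampling")
})

test_that("aggregate lifetimes match hand-countable cases and a scan oracle", {
  # stationary pair within 2 mm for the whole 100-s recording
  always <- pair_from_distances(rep(2, 100), dt = 1)
  lt <- extract_aggregate_lifetimes(always)
  expect_equal(nrow(lt), 1)
  expect_equal(lt$duration_s, 100)
  expect_true(lt$censored)
  # a proximity run of exactly 1.0 s is excluded (strictly more than 1 s)
  d <- rep(20, 40); d[10:11] <- 5
  expect_equal(nrow(extract_aggregate_lifetimes(pair_from_distances(d, dt = 0.5))), 0)
  d[10:12] <- 5  # 1.5 s qualifies
  lt2 <- extract_aggregate_lifetimes(pair_from_distances(d, dt = 0.5))
  expect_equal(lt2$duration_s, 1.5)
  # alternating 5 s together / 5 s apart over 60 s: six 5-s events
  d3 <- rep(c(rep(4, 5), rep(30, 5)), 6)
  lt3 <- extract_aggregate_lifetimes(pair_from_distances(d3, dt = 1))
  expect_equal(lt3$duration_s, rep(5, 6))
  expect_false(any(lt3$censored))
  # random patterns agree with an independent frame-by-frame scan
  set.seed(8)
  for (i in 1:20) {
    d <- runif(200, 0, 20)
    dt <- sample(c(0.25, 0.48, 1), 1)
    got <- extract_aggregate_lifetimes(pair_from_distances(d, dt = dt))
    ref <- scan_lifetimes(d, dt, threshold = 10, min_duration = 1)
    expect_equal(got$duration_s, ref$durations)
    expect_equal(got$censored, ref$censored)
  }
})

test_that("contact-stop proportion counts long contacts among completed contacts", {
  # two contacts of 0.5 s and one of 3 s -> 1/3
  d <- rep(20, 60)
  d[5] <- 4; d[15] <- 4; d[30:35] <- 4
  expect_equal(contact_stop_proportion(pair_from_distances(d, dt = 0.5)), 1 / 3)
  # all contacts longer than 1 s -> 1
  d2 <- rep(20, 40); d2[5:10] <- 3; d2[20:28] <- 3
  expect_equal(contact_stop_proportion(pair_from_distances(d2, dt = 1)), 1)
  # never within 6 mm -> undefined, flagged
  expect_warning(p <- contact_stop_proportion(pair_from_distances(rep(9, 30))),
                 "no contacts")
  expect_true(is.na(p))
})

test_that("Cox hazard ratio is exact on identical samples and recovers known truth", {
  s <- gen_stop_durations(survival_params(), 300, seed = 5)
  expect_equal(cox_hazard_ratio(s, s)$hazard_ratio, 1.0)
  # exponential lifetimes with rates 1 vs 2: consistent recovery of HR 2
  fits <- lapply(21:25, function(s) {
    g <- gen_two_group_lifetimes(2, survival_params(alpha = 0, beta = 1, delta = 1),
                                 n_per_group = 5000, seed = s)
    cox_hazard_ratio(g$baseline, g$scaled)
  })
  hrs <- vapply(fits, function(f) f$hazard_ratio, numeric(1))
  expect_gt(median(hrs), 1.9)
  expect_lt(median(hrs), 2.1)
  fit <- fits[[1]]
  td <- tidy(fit)
  expect_equal(td$hazard_ratio, exp(td$estimate))
  expect_error(cox_hazard_ratio(lifetime_sample(1:10, censored = TRUE), s),
               "no observed events")
})

test_that("Cox CI covers the true hazard ratio at the nominal rate", {
  p <- survival_params(alpha = 0, beta = 1, delta = 0.5)
  cover <- vapply(1:50, function(s) {
    g <- gen_two_group_lifetimes(2, p, n_per_group = 400, seed = 500 + s)
    fit <- cox_hazard_ratio(g$baseline, g$scaled)
    fit$ci95_low <= 2 && 2 <= fit$ci95_high
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("log hazard ratios match the reference Cox implementation to 3 decimals", {
  p <- survival_params(alpha = 0.6, beta = 1.5, delta = 1e-4)
  for (s in 1:20) {
    hr <- exp(runif(1, -1, 1))
    g <- gen_two_group_lifetimes(hr, p, n_per_group = 300,
                                 censor_time = 500, seed = 900 + s)
    mine <- cox_hazard_ratio(g$baseline, g$scaled)$log_hazard_ratio
    df <- rbind(cbind(g$baseline, x = 0), cbind(g$scaled, x = 1))
    ref <- survival::coxph(survival::Surv(duration_s, !censored) ~ x,
                           data = df, ties = "breslow")
    expect_equal(mine, unname(coef(ref)), tolerance = 5e-4)
  }
})

test_that("the simulator itself exhibits interattraction under this estimator", {
  real <- list(); null <- list()
  for (s in 1:4) {
    on <- gen_pair_trajectories(3 * 3600, interattraction = TRUE, seed = 60 + s)
    off <- gen_pair_trajectories(3 * 3600, interattraction = FALSE, seed = 160 + s)
    real[[s]] <- extract_aggregate_lifetimes(on$pair)
    null[[s]] <- extract_aggregate_lifetimes(off$pair)
  }
  fit <- cox_hazard_ratio(dplyr::bind_rows(real), dplyr::bind_rows(null))
  expect_gt(fit$hazard_ratio, 1)
  expect_gt(fit$ci95_low, 1)
})
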