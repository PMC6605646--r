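test_that("mean nearest-neighbour distance matches direct expectations", {
  a4 <- arena_preset("dispersal_80mm_4c")
  open <- arena_preset("breeding_55mm")
  expect_equal(mean_nn_distance(rbind(c(20, 5), c(20, 5), c(20, 5)), a4), 0)
  expect_equal(mean_nn_distance(rbind(c(15, 5), c(27, 5)), a4), 12)
  expect_error(mean_nn_distance(rbind(c(0, 0)), a4), "two individuals")
  # translation and rotation invariance in the open arena; bounded by diameter
  set.seed(4)
  xy <- spiderling:::.runif_disc(5, 10)
  d0 <- mean_nn_distance(xy, open)
  expect_equal(mean_nn_distance(sweep(xy, 2, c(-3, 8), "+"), open), d0)
  th <- 0.7
  Rm <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(mean_nn_distance(xy %*% Rm, open), d0)
  expect_lt(d0, open$outer_diameter)
})

test_that("mean nn distance across compartments equals the lattice oracle", {
  a4 <- arena_preset("dispersal_80mm_4c")
  gg <- grid_graph(a4)
  set.seed(12)
  nodes <- sample_grid_nodes(gg, a4, 4)
  xy <- cbind(gg$nodes$x[nodes], gg$nodes$y[nodes])
  D <- matrix(Inf, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    if (i != j) D[i, j] <- grid_distance(gg, nodes[i], nodes[j])
  }
  ref <- mean(apply(D, 1, min))
  expect_equal(mean_nn_distance(xy, a4), ref, tolerance = 0.02)
})

test_that("minimal-displacement assignment equals exhaustive enumeration", {
  a4 <- arena_preset("dispersal_80mm_4c")
  # identity on identical frames
  f <- rbind(c(20, 5), c(5, 20), c(-20, 5), c(5, -20))
  asg <- min_displacement_assignment(f, f, a4)
  expect_equal(asg$to, 1:4)
  expect_equal(attr(asg, "total_mm"), 0)
  # a long swap loses to short mutual shifts
  fa <- rbind(c(15, 5), c(25, 5))
  fb <- rbind(c(25, 6), c(15, 6))
  asg2 <- min_displacement_assignment(fa, fb, a4)
  expect_equal(asg2$to, c(2, 1))
  # random frames: exactly the enumeration optimum, never beaten by any
  # permutation
  set.seed(21)
  for (i in 1:25) {
    n <- sample(2:5, 1)
    fa <- spiderling:::.runif_disc(n, 38)
    fb <- spiderling:::.runif_disc(n, 38)
    got <- min_displacement_assignment(fa, fb, a4)
    ref <- brute_force_assignment(fa, fb, a4)
    expect_equal(attr(got, "total_mm"), ref$total, tolerance = 1e-12)
    expect_equal(got$to, ref$perm)
  }
  expect_error(min_displacement_assignment(fa, fb[1:2, ], a4), "different numbers")
})

test_that("activity index counts threshold displacements per window", {
  open <- arena_preset("breeding_55mm")
  # stationary: 0; 5 mm every step: 1; alternating 5/0: 0.5
  still <- series_from_schedule(11, list(integer(0)))
  expect_equal(activity_index(still, open)$activity, 0)
  always <- series_from_schedule(11, list(1:10))
  expect_equal(activity_index(always, open)$activity, 1)
  alt <- series_from_schedule(11, list(seq(1, 10, by = 2)))
  expect_equal(activity_index(alt, open)$activity, 0.5)
  # windowing splits the series into days
  two_days <- series_from_schedule(289, list(1:144))  # move only on day 1
  ai <- activity_index(two_days, open)
  expect_equal(ai$activity[ai$window == 1], 1)
  expect_equal(ai$activity[ai$window == 2], 0)
})

test_that("unlabeled activity never exceeds labeled activity on the same frames", {
  a4 <- arena_preset("dispersal_80mm_4c")
  snaps <- gen_group_snapshots("full", days = 1, seed = 33)$labeled
  lab <- activity_index(snaps, a4)
  unl <- activity_index(snaps, a4, unlabeled = TRUE)
  per_id_mean <- mean(lab$activity)
  expect_lte(unl$activity[1], per_id_mean + 1e-9)
  # when every move is smaller than the inter-individual spacing the two agree
  spread <- series_from_schedule(13, list(c(2, 5), c(3, 7), integer(0)))
  spread$y_mm <- spread$id * 25 - 50  # far apart
  a_lab <- activity_index(spread, arena_preset("open_290mm"))
  a_unl <- activity_index(spread, arena_preset("open_290mm"), unlabeled = TRUE)
  expect_equal(a_unl$activity, mean(a_lab$activity))
})

test_that("onset detection fires at the end of the first qualifying 6-h window", {
  open <- arena_preset("breeding_55mm")
  n <- 300  # > 2 days of 10-min frames
  day_steps <- 144
  for (k in 1:3) {
    # exactly 9 qualifying movements inside window k after the Day-2 08:00 start
    win_start <- day_steps + (k - 1) * 36
    sched <- series_from_schedule(n, list(win_start + seq_len(9) * 3))
    res <- detect_onset(sched, open)
    expect_false(res$censored)
    expect_equal(res$onset_s, 86400 + k * 21600)
  }
  # eight movements per window never trigger
  sched8 <- series_from_schedule(n, list(day_steps + seq_len(8) * 4))
  expect_true(detect_onset(sched8, open)$censored)
  # monotone: adding movements can only advance the onset
  base_sched <- day_steps + 36 + seq_len(9) * 3          # window 2
  extra <- series_from_schedule(n, list(c(day_steps + c(2, 6, 9), base_sched)))
  res2 <- detect_onset(series_from_schedule(n, list(base_sched)), open)
  res3 <- detect_onset(extra, open)
  expect_lte(res3$onset_s, res2$onset_s)
  # cadence is enforced
  bad <- series_from_schedule(50, list(1:10), cadence = 300)
  expect_error(detect_onset(bad, open), "cadence")
})

test_that("group-mode onset uses one seeded random individual per step", {
  open <- arena_preset("breeding_55mm")
  sched <- series_from_schedule(300, list(144 + 1:40, integer(0)))
  r1 <- detect_onset(sched, open, group_mode = TRUE, seed = 10)
  r2 <- detect_onset(sched, open, group_mode = TRUE, seed = 10)
  expect_identical(r1, r2)
  expect_equal(r1$id, "group")
})

test_that("contact time fraction is the per-day share of frames near a conspecific", {
  # two individuals: together for the first half of day 1, apart afterwards
  n <- 288  # two days
  a <- tibble::tibble(t_s = (0:(n - 1)) * 600, id = 1, x_mm = 0, y_mm = 0)
  b <- tibble::tibble(t_s = (0:(n - 1)) * 600, id = 2,
                      x_mm = c(rep(3, 72), rep(20, n - 72)), y_mm = 0)
  ctf <- contact_time_fraction(dplyr::bind_rows(a, b))
  expect_equal(ctf$contact_fraction[ctf$id == 1 & ctf$day == 1], 0.5)
  expect_equal(ctf$contact_fraction[ctf$id == 1 & ctf$day == 2], 0)
  # permanently clustered group: 1 every day
  cl <- dplyr::bind_rows(
    tibble::tibble(t_s = (0:(n - 1)) * 600, id = 1, x_mm = 0, y_mm = 0),
    tibble::tibble(t_s = (0:(n - 1)) * 600, id = 2, x_mm = 2, y_mm = 0),
    tibble::tibble(t_s = (0:(n - 1)) * 600, id = 3, x_mm = 0, y_mm = 2)
  )
  expect_true(all(contact_time_fraction(cl)$contact_fraction == 1))
  expect_error(contact_time_fraction(a), "two individuals")
})
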