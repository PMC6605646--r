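test_that("compartment membership follows the arena partition", {
  a4 <- arena_preset("dispersal_80mm_4c")
  open <- arena_preset("breeding_55mm")
  # open arena: everything is one shared compartment
  pts <- data.frame(x = c(0, 10, -20), y = c(0, 5, 3))
  expect_equal(compartment_of(pts, open), c(0L, 0L, 0L))
  # the arena center lies in the shared central opening
  expect_equal(compartment_of(c(0, 0), a4), 0L)
  expect_equal(compartment_of(c(3, -3), a4), 0L)
  # walls lie on the axes: (30, 1) sits in the +x/+y quadrant
  expect_equal(compartment_of(c(30, 1), a4), 1L)
  expect_equal(compartment_of(c(-30, 1), a4), 2L)
  expect_equal(compartment_of(c(1, -30), a4), 4L)
  expect_error(compartment_of(c(100, 0), a4), "outside")
})

test_that("zone classification honours the wall-following and landmark radii", {
  a4 <- arena_preset("dispersal_80mm_4c")
  expect_equal(classify_zone(c(0, 0), a4), "center")
  # 1 mm from the outer wall, far from any junction
  expect_equal(classify_zone(c(39 * cos(pi / 4), 39 * sin(pi / 4)), a4), "edge")
  # 4.9 mm from the outer wall is still wall zone; 6 mm is not
  expect_equal(classify_zone(c(0, 35.2), a4), "edge")
  expect_equal(classify_zone(c(25 * cos(pi / 4), 25 * sin(pi / 4)), a4), "center")
  # an inner wall's central tip and the wall/outer-wall junction
  expect_equal(classify_zone(c(10, 0.5), a4), "inner_wall_end")
  expect_equal(classify_zone(c(39, 0.5), a4), "corner")
  # priority: a point near both corner and edge reports corner
  expect_equal(classify_zone(c(38.5, 0.5), a4), "corner")
  # near the middle of an inner wall: edge
  expect_equal(classify_zone(c(25, 1), a4), "edge")
  expect_error(classify_zone(c(0, 41), a4), "outside")
})

test_that("geodesic distance reduces to Euclidean when unobstructed", {
  a4 <- arena_preset("dispersal_80mm_4c")
  expect_equal(geodesic_distance(c(10, 5), c(10, 5), a4), 0)
  expect_equal(geodesic_distance(c(10, 1), c(13, 1), a4), 3)
  # both points deep in one compartment
  expect_equal(geodesic_distance(c(30, 1), c(1, 30), a4),
               sqrt(29^2 + 29^2))
  # crossing through the central opening is unobstructed
  expect_equal(geodesic_distance(c(30, 1), c(-30, 1), a4), 60)
  expect_error(geodesic_distance(c(45, 0), c(0, 0), a4), "outside")
})

test_that("geodesic distance is a metric dominating the Euclidean one", {
  a4 <- arena_preset("dispersal_80mm_4c")
  set.seed(31)
  pts <- spiderling:::.runif_disc(60, a4$radius - 0.5)
  i <- sample(60, 40, TRUE); j <- sample(60, 40, TRUE); k <- sample(60, 40, TRUE)
  dij <- geodesic_distance(pts[i, ], pts[j, ], a4)
  dji <- geodesic_distance(pts[j, ], pts[i, ], a4)
  djk <- geodesic_distance(pts[j, ], pts[k, ], a4)
  dik <- geodesic_distance(pts[i, ], pts[k, ], a4)
  eu <- sqrt(rowSums((pts[i, ] - pts[j, ])^2))
  expect_equal(dij, dji)                        # symmetry
  expect_true(all(dik <= dij + djk + 1e-9))     # triangle inequality
  expect_true(all(dij >= eu - 1e-12))           # dominates Euclidean
})

test_that("geodesic distances agree with an independent lattice-Dijkstra oracle", {
  a4 <- arena_preset("dispersal_80mm_4c")
  gg <- grid_graph(a4)
  set.seed(7)
  i <- sample_grid_nodes(gg, a4, 30)
  j <- sample_grid_nodes(gg, a4, 30)
  ref <- mapply(function(a, b) grid_distance(gg, a, b), i, j)
  mine <- geodesic_distance(cbind(gg$nodes$x[i], gg$nodes$y[i]),
                            cbind(gg$nodes$x[j], gg$nodes$y[j]), a4)
  expect_true(all(abs(mine - ref) / pmax(ref, 1) < 0.02))
})

test_that("random placement baseline is reproducible and matches a rejection-sampling oracle", {
  open <- arena_preset("breeding_55mm")
  b1 <- random_baseline_distance(open, 4, 300, seed = 1)
  b1b <- random_baseline_distance(open, 4, 300, seed = 1)
  expect_identical(b1$mean_nn_mm, b1b$mean_nn_mm)   # deterministic given seed
  b2 <- random_baseline_distance(open, 4, 300, seed = 2)
  # two independent seeds agree within Monte-Carlo error
  expect_lt(abs(b1$mean_nn_mm - b2$mean_nn_mm), 3 * (b1$se + b2$se))
  # independent oracle: polar-coordinate uniform sampling in the open disc,
  # plain Euclidean nearest neighbours
  set.seed(99)
  R <- open$radius
  vals <- replicate(400, {
    r <- R * sqrt(runif(4)); th <- runif(4, 0, 2 * pi)
    xy <- cbind(r * cos(th), r * sin(th))
    D <- as.matrix(dist(xy)); diag(D) <- Inf
    mean(apply(D, 1, min))
  })
  expect_lt(abs(b1$mean_nn_mm - mean(vals)),
            3 * (b1$se + sd(vals) / sqrt(length(vals))))
  expect_error(random_baseline_distance(open, 1, 10, seed = 1), ">= 2")
})

test_that("arena presets and serialization round-trip the key fields", {
  a <- arena_preset("dispersal_80mm_4c")
  j <- jsonlite::fromJSON(arena_json(a))
  expect_equal(j$outer_diameter, 80)
  expect_equal(j$n_compartments, 4)
  expect_equal(j$central_opening_diameter, 20)
  expect_equal(arena_preset("open_290mm")$outer_diameter, 290)
  expect_error(arena(outer_diameter = 80, n_compartments = 4,
                     central_opening_diameter = 90))
})
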