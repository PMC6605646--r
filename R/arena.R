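#' Circular test arena, optionally partitioned into compartments
#'
#' Constructs the geometry of a circular arena as used in spiderling
#' dispersal assays: an outer circular wall and, optionally, `n_compartments`
#' radial inner walls of zero thickness running from the boundary of a
#' central opening to the outer wall, equally spaced (for four compartments
#' the walls lie on the coordinate axes). Individuals can only move between
#' compartments through the central opening.
#'
#' @param outer_diameter Outer wall diameter in mm.
#' @param n_compartments Number of compartments; 0 means an open arena.
#' @param central_opening_diameter Diameter (mm) of the central opening left
#'   free of inner walls. Ignored when `n_compartments = 0`.
#' @param wall_zone_width Width (mm) of the zone adjacent to a wall within
#'   which an individual is considered to be wall-following (two body
#'   lengths, 5 mm).
#' @param landmark_radius Capture radius (mm, one body length) used to
#'   classify positions as sitting at an inner-wall end or at a corner.
#'
#' @return An object of class `"arena"`: a list with the supplied fields plus
#'   derived geometry (`radius`, `opening_radius`, `wall_angles`, and a
#'   `walls` matrix with one row `(x1, y1, x2, y2)` per inner wall).
#' @examples
#' a <- arena() # the 80-mm, 4-compartment dispersal arena
#' compartment_of(data.frame(x = 30, y = 1), a)
#' @export
arena <- function(outer_diameter = 80, n_compartments = 4,
                  central_opening_diameter = 20, wall_zone_width = 5,
                  landmark_radius = 2.5) {
  stopifnot(outer_diameter > 0, n_compartments >= 0,
            wall_zone_width > 0, wall_zone_width < outer_diameter / 2)
  if (n_compartments > 0) {
    stopifnot(outer_diameter > central_opening_diameter,
              central_opening_diameter > 0)
  }
  R <- outer_diameter / 2
  r0 <- if (n_compartments > 0) central_opening_diameter / 2 else 0
  angles <- if (n_compartments > 0) {
    2 * pi * (seq_len(n_compartments) - 1) / n_compartments
  } else {
    numeric(0)
  }
  walls <- cbind(
    x1 = r0 * cos(angles), y1 = r0 * sin(angles),
    x2 = R * cos(angles), y2 = R * sin(angles)
  )
  structure(
    list(
      outer_diameter = outer_diameter,
      n_compartments = n_compartments,
      central_opening_diameter = if (n_compartments > 0) central_opening_diameter else 0,
      wall_zone_width = wall_zone_width,
      landmark_radius = landmark_radius,
      radius = R,
      opening_radius = r0,
      wall_angles = angles,
      walls = walls
    ),
    class = "arena"
  )
}

#' @export
print.arena <- function(x, ...) {
  cat(sprintf("<arena> diameter %g mm, %d compartment(s)%s\n",
              x$outer_diameter, max(1L, x$n_compartments),
              if (x$n_compartments > 0) {
                sprintf(", central opening %g mm", x$central_opening_diameter)
              } else ""))
  invisible(x)
}

#' Named arena presets
#'
#' The arenas used in the dispersal study: `"dispersal_80mm_4c"` (80-mm dish
#' partitioned into four compartments with a 20-mm central opening),
#' `"breeding_55mm"` (55-mm open breeding dish), `"open_290mm"` (large open
#' PVC arena), and `"pair_44mm"` (44-mm open arena used for single/pair
#' recordings).
#'
#' @param name Preset name.
#' @return An [arena()] object.
#' @export
arena_preset <- function(name = c("dispersal_80mm_4c", "breeding_55mm",
                                  "open_290mm", "pair_44mm")) {
  name <- match.arg(name)
  switch(name,
    dispersal_80mm_4c = arena(80, 4, 20),
    breeding_55mm = arena(55, 0),
    open_290mm = arena(290, 0),
    pair_44mm = arena(44, 0)
  )
}

#' Serialize an arena to JSON
#'
#' @param x An [arena()] object.
#' @return A JSON string describing the arena.
#' @export
arena_json <- function(x) {
  stopifnot(inherits(x, "arena"))
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("arena_json() requires the 'jsonlite' package")
  }
  jsonlite::toJSON(
    x[c("outer_diameter", "n_compartments", "central_opening_diameter",
        "wall_zone_width", "landmark_radius")],
    auto_unbox = TRUE
  )
}

# --- internal geometry helpers ----------------------------------------------

.as_xy <- function(p) {
  if (is.data.frame(p)) {
    xcol <- intersect(c("x", "x_mm"), names(p))[1]
    ycol <- intersect(c("y", "y_mm"), names(p))[1]
    if (is.na(xcol) || is.na(ycol)) stop("positions need x/y (or x_mm/y_mm) columns")
    cbind(p[[xcol]], p[[ycol]])
  } else if (is.matrix(p)) {
    p[, 1:2, drop = FALSE]
  } else {
    matrix(as.numeric(p), ncol = 2)
  }
}

.check_inside <- function(xy, arena, tol = 1e-9) {
  r <- sqrt(rowSums(xy^2))
  if (any(r > arena$radius + tol)) {
    stop("position outside the arena", call. = FALSE)
  }
  invisible(r)
}

# Does the open segment p->q properly cross the inner wall w?  Touching a
# wall endpoint (e.g. grazing a wall tip) does not count as crossing, which
# is exactly what a shortest path does.
.seg_crosses <- function(px, py, qx, qy, wx1, wy1, wx2, wy2) {
  o <- function(ax, ay, bx, by, cx, cy) (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
  d1 <- o(px, py, qx, qy, wx1, wy1)
  d2 <- o(px, py, qx, qy, wx2, wy2)
  d3 <- o(wx1, wy1, wx2, wy2, px, py)
  d4 <- o(wx1, wy1, wx2, wy2, qx, qy)
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

# vectorized over segments: TRUE if the segment crosses any inner wall
.crosses_any_wall <- function(px, py, qx, qy, arena) {
  w <- arena$walls
  if (nrow(w) == 0L) return(rep(FALSE, length(px)))
  out <- rep(FALSE, length(px))
  for (k in seq_len(nrow(w))) {
    out <- out | .seg_crosses(px, py, qx, qy, w[k, 1], w[k, 2], w[k, 3], w[k, 4])
  }
  out
}

.wall_tips <- function(arena) {
  arena$walls[, c("x1", "y1"), drop = FALSE]
}

# --- exported operations -----------------------------------------------------

#' Compartment membership of positions
#'
#' Points strictly inside the central opening belong to the shared central
#' region (index 0). In an open arena every point has index 0. Otherwise
#' compartments are numbered 1..n counter-clockwise, compartment 1 spanning
#' the angular sector immediately counter-clockwise of the first inner wall
#' (for the four-compartment arena: the +x/+y quadrant).
#'
#' @param points A data frame (columns `x`, `y` or `x_mm`, `y_mm`), matrix,
#'   or length-2 numeric vector of arena-centered coordinates in mm.
#' @param arena An [arena()] object.
#' @return An integer vector of compartment indices (0 = shared central
#'   region / open arena).
#' @export
compartment_of <- function(points, arena) {
  xy <- .as_xy(points)
  r <- .check_inside(xy, arena)
  n <- arena$n_compartments
  if (n == 0L) return(rep(0L, nrow(xy)))
  idx <- ifelse(r < arena$opening_radius, 0L, {
    ang <- atan2(xy[, 2], xy[, 1]) %% (2 * pi)
    as.integer(ang %/% (2 * pi / n)) + 1L
  })
  as.integer(idx)
}

#' Behavioral zone of positions
#'
#' Classifies each position into `"corner"` (within one body length of a
#' junction between an inner wall and the outer wall), `"inner_wall_end"`
#' (within one body length of a wall's central tip), `"edge"` (within the
#' wall-following zone, 5 mm, of the outer wall or of an inner wall) or
#' `"center"`, with priority corner > inner_wall_end > edge > center.
#'
#' @inheritParams compartment_of
#' @return A character vector of zone labels.
#' @export
classify_zone <- function(points, arena) {
  xy <- .as_xy(points)
  r <- .check_inside(xy, arena)
  n <- nrow(xy)
  d_outer <- arena$radius - r
  w <- arena$walls
  d_wall <- rep(Inf, n)
  d_tip <- rep(Inf, n)
  d_corner <- rep(Inf, n)
  if (nrow(w) > 0L) {
    for (k in seq_len(nrow(w))) {
      d_wall <- pmin(d_wall, .point_seg_dist(xy, w[k, 1:2], w[k, 3:4]))
      d_tip <- pmin(d_tip, sqrt((xy[, 1] - w[k, 1])^2 + (xy[, 2] - w[k, 2])^2))
      d_corner <- pmin(d_corner, sqrt((xy[, 1] - w[k, 3])^2 + (xy[, 2] - w[k, 4])^2))
    }
  }
  lr <- arena$landmark_radius
  out <- rep("center", n)
  out[d_outer <= arena$wall_zone_width | d_wall <= arena$wall_zone_width] <- "edge"
  out[d_tip <= lr] <- "inner_wall_end"
  out[d_corner <= lr] <- "corner"
  out
}

.point_seg_dist <- function(xy, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  t <- ((xy[, 1] - a[1]) * ab[1] + (xy[, 2] - a[2]) * ab[2]) / len2
  t <- pmin(1, pmax(0, t))
  px <- a[1] + t * ab[1]
  py <- a[2] + t * ab[2]
  sqrt((xy[, 1] - px)^2 + (xy[, 2] - py)^2)
}

#' Wall-aware (geodesic) distance between positions
#'
#' Shortest-path distance within the arena's free space, treating inner
#' walls as impassable zero-thickness obstacles: a path between two
#' compartments must round the wall tips through the central opening. Equals
#' the Euclidean distance whenever the straight segment crosses no inner
#' wall. Computed on a visibility graph over the two endpoints and the wall
#' tips (tip-to-tip chords always lie inside the central opening, so at most
#' two tips appear on a shortest path).
#'
#' @param a,b Positions (data frame, matrix or length-2 vector); if both
#'   have several rows, distances are computed row-wise.
#' @param arena An [arena()] object.
#' @return A numeric vector of distances in mm.
#' @export
geodesic_distance <- function(a, b, arena) {
  A <- .as_xy(a)
  B <- .as_xy(b)
  if (nrow(A) == 1L && nrow(B) > 1L) A <- A[rep(1L, nrow(B)), , drop = FALSE]
  if (nrow(B) == 1L && nrow(A) > 1L) B <- B[rep(1L, nrow(A)), , drop = FALSE]
  stopifnot(nrow(A) == nrow(B))
  .check_inside(A, arena)
  .check_inside(B, arena)
  eu <- sqrt(rowSums((A - B)^2))
  if (arena$n_compartments == 0L) return(eu)
  blocked <- .crosses_any_wall(A[, 1], A[, 2], B[, 1], B[, 2], arena)
  if (!any(blocked)) return(eu)
  tips <- .wall_tips(arena)
  nt <- nrow(tips)
  chord <- as.matrix(stats::dist(tips))
  out <- eu
  for (i in which(blocked)) {
    pa <- A[i, ]; pb <- B[i, ]
    da <- sqrt((tips[, 1] - pa[1])^2 + (tips[, 2] - pa[2])^2)
    db <- sqrt((tips[, 1] - pb[1])^2 + (tips[, 2] - pb[2])^2)
    va <- !.crosses_any_wall(rep(pa[1], nt), rep(pa[2], nt), tips[, 1], tips[, 2], arena)
    vb <- !.crosses_any_wall(rep(pb[1], nt), rep(pb[2], nt), tips[, 1], tips[, 2], arena)
    da[!va] <- Inf
    db[!vb] <- Inf
    # at most two tips on a geodesic: direct tip or tip-to-tip chord
    best <- min(outer(da, db, "+") + chord)
    out[i] <- best
  }
  out
}

#' Random-placement baseline for the mean nearest-neighbour distance
#'
#' Monte-Carlo estimate of the mean nearest-neighbour geodesic distance
#' expected when `n_individuals` are placed at random in the arena: either
#' uniformly over the arena's free space, or by resampling observed
#' positions from independent recordings (`source`). This is the "random
#' level of aggregation" against which observed or simulated group cohesion
#' is judged.
#'
#' @param arena An [arena()] object.
#' @param n_individuals Number of individuals per placement (>= 2).
#' @param n_resamples Number of Monte-Carlo placements (500 by default).
#' @param seed Optional integer seed; the result is deterministic given it.
#' @param source Optional pool of observed positions (data frame with
#'   `x`/`y`), sampled without replacement within each resample.
#' @return A one-row tibble with columns `mean_nn_mm` (mean over resamples
#'   of the placement-level mean nearest-neighbour geodesic distance),
#'   `ci_low`/`ci_high` (2.5% and 97.5% quantiles of the placement-level
#'   values, i.e. the band of the random level), `se` (Monte-Carlo standard
#'   error of the mean), and bookkeeping columns. The resample values are
#'   attached as attribute `"resamples"`.
#' @export
random_baseline_distance <- function(arena, n_individuals, n_resamples = 500,
                                     seed = NULL, source = NULL) {
  if (n_individuals < 2) stop("n_individuals must be >= 2", call. = FALSE)
  if (!is.null(source)) {
    source <- .as_xy(source)
    if (nrow(source) < n_individuals) {
      stop("source pool smaller than n_individuals", call. = FALSE)
    }
  }
  vals <- .with_seed(seed, {
    vapply(seq_len(n_resamples), function(i) {
      pos <- if (is.null(source)) {
        .runif_disc(n_individuals, arena$radius)
      } else {
        source[sample.int(nrow(source), n_individuals), , drop = FALSE]
      }
      .mean_nn(pos, arena)
    }, numeric(1))
  })
  out <- tibble::tibble(
    mean_nn_mm = mean(vals),
    ci_low = stats::quantile(vals, 0.025, names = FALSE),
    ci_high = stats::quantile(vals, 0.975, names = FALSE),
    se = stats::sd(vals) / sqrt(n_resamples),
    n_individuals = n_individuals,
    n_resamples = n_resamples
  )
  attr(out, "resamples") <- vals
  out
}

.runif_disc <- function(n, R) {
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    m <- 2 * (n - nrow(out)) + 8
    x <- stats::runif(m, -R, R)
    y <- stats::runif(m, -R, R)
    ok <- x^2 + y^2 < R^2
    out <- rbind(out, cbind(x[ok], y[ok]))
  }
  out[seq_len(n), , drop = FALSE]
}

# mean over individuals of the geodesic distance to the nearest other
.mean_nn <- function(xy, arena) {
  n <- nrow(xy)
  idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  d <- geodesic_distance(xy[idx[, 1], , drop = FALSE],
                         xy[idx[, 2], , drop = FALSE], arena)
  D <- matrix(Inf, n, n)
  D[idx] <- d
  D[idx[, c(2, 1), drop = FALSE]] <- d
  mean(apply(D, 1, min))
}

# evaluate expr with a temporary RNG state seeded by `seed` (NULL = leave
# the global stream alone)
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
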