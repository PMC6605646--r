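#' Mean nearest-neighbour geodesic distance of one frame
#'
#' The study's aggregation/dispersal readout: for each individual, the
#' wall-aware (geodesic) distance to its closest conspecific, averaged over
#' individuals.
#'
#' @param frame Positions of all individuals in one snapshot (data frame
#'   with `x`/`y` or `x_mm`/`y_mm` columns, or a two-column matrix);
#'   at least two rows.
#' @param arena An [arena()] object.
#' @return The mean nearest-neighbour distance in mm.
#' @export
mean_nn_distance <- function(frame, arena) {
  xy <- .as_xy(frame)
  if (nrow(xy) < 2) {
    stop("need at least two individuals for a nearest-neighbour distance",
         call. = FALSE)
  }
  .mean_nn(xy, arena)
}

#' Minimal-displacement identity assignment between two frames
#'
#' Unmarked individuals cannot be identified across snapshots; following
#' the study's assumption that each spider minimized its displacement
#' between time steps, the identities are recovered as the assignment of
#' frame-A positions to frame-B positions minimizing the *total* geodesic
#' displacement. Solved exactly by depth-first branch-and-bound over
#' assignments (group sizes are at most 8); ties are broken
#' lexicographically by index.
#'
#' @param frame_a,frame_b Positions (same number of rows, at most 8).
#' @param arena An [arena()] object.
#' @return A tibble with columns `from` (index in `frame_a`), `to`
#'   (matched index in `frame_b`) and `displacement_mm`, plus attribute
#'   `"total_mm"`.
#' @export
min_displacement_assignment <- function(frame_a, frame_b, arena) {
  A <- .as_xy(frame_a)
  B <- .as_xy(frame_b)
  if (nrow(A) != nrow(B)) {
    stop("frames have different numbers of individuals", call. = FALSE)
  }
  n <- nrow(A)
  if (n > 8) stop("assignment supported for at most 8 individuals", call. = FALSE)
  cost <- matrix(0, n, n)
  for (i in seq_len(n)) {
    cost[i, ] <- geodesic_distance(A[rep(i, n), , drop = FALSE], B, arena)
  }
  best <- list(perm = seq_len(n), total = Inf)
  used <- rep(FALSE, n)
  perm <- integer(n)
  # row-wise lower bound for pruning: cheapest remaining column per row
  row_min <- apply(cost, 1, min)
  lb_tail <- rev(cumsum(rev(row_min)))
  recurse <- function(i, acc) {
    if (acc >= best$total) return()
    if (i > n) {
      best <<- list(perm = perm[seq_len(n)], total = acc)
      return()
    }
    if (acc + lb_tail[i] >= best$total) return()
    for (j in seq_len(n)) {
      if (!used[j]) {
        used[j] <<- TRUE
        perm[i] <<- j
        recurse(i + 1, acc + cost[i, j])
        used[j] <<- FALSE
      }
    }
  }
  recurse(1L, 0)
  out <- tibble::tibble(
    from = seq_len(n), to = best$perm,
    displacement_mm = cost[cbind(seq_len(n), best$perm)]
  )
  attr(out, "total_mm") <- best$total
  out
}

.series_check <- function(series) {
  stopifnot(all(c("t_s", "x_mm", "y_mm") %in% names(series)))
  if (!"id" %in% names(series)) series$id <- NA_integer_
  series
}

#' Activity index of a snapshot series
#'
#' The proportion, per time window (one day by default), of consecutive
#' snapshot pairs in which an individual displaced at least
#' `move_threshold` mm (one body length, 3 mm), the study's index of
#' mobility. For labeled series the proportion is computed per individual.
#' For unlabeled series (no `id` column, or `unlabeled = TRUE`) the
#' per-step displacements are recovered with
#' [min_displacement_assignment()], a conservative lower bound on true
#' movement, and the group mean is returned (`id = "group"`).
#'
#' @param series Snapshot tibble with columns `t_s`, `x_mm`, `y_mm` and
#'   (if labeled) `id`; one run only.
#' @param arena An [arena()] object.
#' @param move_threshold Movement threshold, mm.
#' @param window Window length in seconds (86,400 = daily).
#' @param unlabeled Force the unlabeled (assignment-based) path.
#' @return A tibble with columns `id`, `window` (1-based index), `activity`
#'   and `n_steps`.
#' @export
activity_index <- function(series, arena, move_threshold = 3,
                           window = 86400, unlabeled = FALSE) {
  series <- .series_check(series)
  labeled <- !unlabeled && !anyNA(series$id)
  times <- sort(unique(series$t_s))
  if (length(times) < 2) stop("need at least two frames", call. = FALSE)
  if (labeled) {
    series <- series[order(series$id, series$t_s), ]
    out <- lapply(split(seq_len(nrow(series)), series$id), function(ix) {
      d <- .fast_geodesic_steps(series$x_mm[ix], series$y_mm[ix], arena)
      tibble::tibble(t_s = series$t_s[ix][-1], moved = d >= move_threshold)
    })
    long <- dplyr::bind_rows(out, .id = "id")
  } else {
    moved <- logical(0)
    t_out <- numeric(0)
    for (k in seq_len(length(times) - 1)) {
      fa <- series[series$t_s == times[k], ]
      fb <- series[series$t_s == times[k + 1], ]
      asg <- min_displacement_assignment(fa, fb, arena)
      moved <- c(moved, asg$displacement_mm >= move_threshold)
      t_out <- c(t_out, rep(times[k + 1], nrow(asg)))
    }
    long <- tibble::tibble(id = "group", t_s = t_out, moved = moved)
  }
  long$window <- floor((long$t_s - min(times) - 1e-9) / window) + 1
  long %>%
    dplyr::group_by(.data$id, .data$window) %>%
    dplyr::summarise(activity = mean(.data$moved), n_steps = dplyr::n(),
                     .groups = "drop")
}

#' Onset of mobility from a 10-min snapshot series
#'
#' Detects, per individual, the end of the first 6-h window (counted from
#' `start_s`, 8:00 of Day 2 for a recording that starts at 8:00 of Day 1)
#' containing at least `min_moves` movements of `move_threshold` mm or more
#' between consecutive 10-min snapshots (9 movements = 25% of the 36 steps
#' of a 6-h window). If no window qualifies the onset is censored. In
#' `group_mode` (unmarked groups), one randomly chosen individual's
#' movement indicator is used at each time step to avoid the sampling
#' advantage of observing several spiders at once; the choice is seeded.
#'
#' @param series Labeled snapshot tibble (`t_s`, `id`, `x_mm`, `y_mm`) at a
#'   10-min cadence.
#' @param arena An [arena()] object.
#' @param window Window length, s (6 h).
#' @param min_moves Minimum number of qualifying movements per window.
#' @param move_threshold Movement threshold, mm.
#' @param start_s Time (s since the first frame) at which the first window
#'   opens.
#' @param group_mode Use the one-random-individual-per-step rule.
#' @param seed Seed for `group_mode` sampling.
#' @return A tibble with columns `id`, `onset_s` (time since the first
#'   frame of the end of the qualifying window; `NA` when censored) and
#'   `censored`.
#' @export
detect_onset <- function(series, arena, window = 21600, min_moves = 9,
                         move_threshold = 3, start_s = 86400,
                         group_mode = FALSE, seed = NULL) {
  series <- .series_check(series)
  times <- sort(unique(series$t_s))
  cad <- unique(round(diff(times), 6))
  if (length(cad) != 1 || abs(cad - 600) > 1e-6) {
    stop("detect_onset requires a strict 10-min snapshot cadence", call. = FALSE)
  }
  t0 <- times[1]
  series <- series[order(series$id, series$t_s), ]
  steps <- lapply(split(seq_len(nrow(series)), series$id), function(ix) {
    d <- .fast_geodesic_steps(series$x_mm[ix], series$y_mm[ix], arena)
    tibble::tibble(t_s = series$t_s[ix][-1], moved = d >= move_threshold)
  })
  if (group_mode) {
    ids <- names(steps)
    nstep <- nrow(steps[[1]])
    pick <- .with_seed(seed, sample.int(length(ids), nstep, replace = TRUE))
    ind <- vapply(seq_len(nstep), function(k) steps[[pick[k]]]$moved[k],
                  logical(1))
    steps <- list(group = tibble::tibble(t_s = steps[[1]]$t_s, moved = ind))
  }
  out <- lapply(names(steps), function(id) {
    st <- steps[[id]]
    st <- st[st$t_s - t0 > start_s, , drop = FALSE]
    if (nrow(st) == 0) {
      return(tibble::tibble(id = id, onset_s = NA_real_, censored = TRUE))
    }
    win <- ceiling((st$t_s - t0 - start_s) / window)
    counts <- tapply(st$moved, win, sum)
    full <- tapply(st$moved, win, length)
    qual <- which(counts >= min_moves & full == full[1])
    if (length(qual) == 0) {
      tibble::tibble(id = id, onset_s = NA_real_, censored = TRUE)
    } else {
      k <- as.integer(names(counts)[qual[1]])
      tibble::tibble(id = id, onset_s = start_s + k * window, censored = FALSE)
    }
  })
  dplyr::bind_rows(out)
}

#' Fraction of time in contact with a conspecific
#'
#' For each individual and day, the fraction of snapshots in which it was
#' within `contact_threshold` mm (leg-touch distance, 6 mm) of at least one
#' conspecific. Interindividual distance is Euclidean, as measured on the
#' photographs.
#'
#' @param series Labeled snapshot tibble with at least two individuals.
#' @param contact_threshold Contact distance, mm.
#' @return A tibble with columns `id`, `day`, `contact_fraction`.
#' @export
contact_time_fraction <- function(series, contact_threshold = 6) {
  series <- .series_check(series)
  n_id <- length(unique(series$id))
  if (n_id < 2) stop("need at least two individuals", call. = FALSE)
  t0 <- min(series$t_s)
  frames <- split(series, series$t_s)
  rows <- lapply(frames, function(fr) {
    xy <- cbind(fr$x_mm, fr$y_mm)
    D <- as.matrix(stats::dist(xy))
    diag(D) <- Inf
    tibble::tibble(id = fr$id, t_s = fr$t_s,
                   in_contact = apply(D, 1, min) <= contact_threshold)
  })
  long <- dplyr::bind_rows(rows)
  long$day <- floor((long$t_s - t0) / 86400) + 1
  long %>%
    dplyr::group_by(.data$id, .data$day) %>%
    dplyr::summarise(contact_fraction = mean(.data$in_contact),
                     .groups = "drop")
}
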