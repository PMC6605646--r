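#' Kinematic and transition parameters of the individual movement model
#'
#' Parameters of the stop-and-go movement model: constant-speed
#' wall-following along the outer and inner walls with stochastic
#' exit/U-turn/stop events, a constant-speed correlated random walk in the
#' open center, spontaneous stopping, and the social modulation of stopping
#' and leaving.
#'
#' The wall-end and corner stopping probabilities (`P_w = 0.6`,
#' `P_c = 0.4`) are the reference values of the dispersal-arena model. The
#' kinematic values (`V`, `tau_p`, `l_star`, `tau_stop_c`) and the social
#' probability tables (`stop_given_N`, `move_after_collision_given_N`) are
#' placeholder defaults -- calibrate to the supplementary movement tables of
#' the study being reproduced; every result of the simulator is a function
#' of this configuration.
#'
#' @param V Average moving speed, mm/s.
#' @param tau_p Characteristic time (s) before an exit, U-turn or stop while
#'   wall-following.
#' @param l_star Transport mean free path (mm): distance over which the
#'   central random walk decorrelates.
#' @param tau_stop_c Characteristic time (s) before a spontaneous stop far
#'   from the walls.
#' @param P_w Probability of stopping at the end of an inner wall.
#' @param P_c Probability of stopping at a corner between an inner wall and
#'   the outer wall.
#' @param stop_given_N Probability that a moving spider stops when first
#'   coming close to `N` = 1, 2, 3+ stopped conspecifics.
#' @param move_after_collision_given_N Probability that a stopped spider in
#'   an aggregate of size 1, 2, 3+ starts moving when collided by a moving
#'   conspecific.
#' @param edge_event_probs Relative probabilities of exit / U-turn / stop
#'   when a wall-following event fires (must sum to 1).
#' @param contact_radius Distance (mm) within which a moving spider
#'   perceives a stopped conspecific (leg-contact scale, 6 mm).
#' @param collision_radius Distance (mm) at which a moving spider collides
#'   with a stopped one (one body length, 2.5 mm).
#' @param aggregate_radius Single-linkage distance (mm) defining membership
#'   of an aggregate of stopped spiders (10 mm).
#' @return An object of class `"movement_params"`.
#' @export
movement_params <- function(V = 10, tau_p = 10, l_star = 20, tau_stop_c = 15,
                            P_w = 0.6, P_c = 0.4,
                            stop_given_N = c(0.3, 0.5, 0.6),
                            move_after_collision_given_N = c(0.6, 0.4, 0.25),
                            edge_event_probs = c(exit = 1 / 3, uturn = 1 / 3,
                                                 stop = 1 / 3),
                            contact_radius = 6, collision_radius = 2.5,
                            aggregate_radius = 10) {
  stopifnot(V > 0, tau_p > 0, l_star > 0, tau_stop_c > 0,
            P_w >= 0, P_w <= 1, P_c >= 0, P_c <= 1,
            all(stop_given_N >= 0 & stop_given_N <= 1),
            all(move_after_collision_given_N >= 0 &
                  move_after_collision_given_N <= 1),
            length(stop_given_N) == 3,
            length(move_after_collision_given_N) == 3,
            abs(sum(edge_event_probs) - 1) < 1e-8)
  structure(
    list(V = V, tau_p = tau_p, l_star = l_star, tau_stop_c = tau_stop_c,
         P_w = P_w, P_c = P_c, stop_given_N = stop_given_N,
         move_after_collision_given_N = move_after_collision_given_N,
         edge_event_probs = unname(edge_event_probs),
         contact_radius = contact_radius,
         collision_radius = collision_radius,
         aggregate_radius = aggregate_radius),
    class = "movement_params"
  )
}

#' Simulation configuration
#'
#' Bundles everything a simulation run needs. The default reproduces the
#' study conditions: four spiderlings in the 80-mm four-compartment arena,
#' 1-s cycles over 11 days, with both interattraction and the Day-4
#' maturational shift (`condition = "full"`). `condition = "no_social"`
#' makes every agent behave as if alone (no social stopping, no aggregate
#' scaling, no collisions); `condition = "no_shift"` disables the
#' maturational increase in mobility.
#'
#' @param arena An [arena()] object.
#' @param n_agents Number of agents (default 4, one per compartment).
#' @param timestep Simulation time step, s.
#' @param days Number of simulated days (86,400 s each, starting at the
#'   8:00 lights-on of Day 1).
#' @param condition One of `"full"`, `"no_social"`, `"no_shift"`.
#' @param survival A [survival_params()] for single individuals (Day-1 fit).
#' @param alpha_pair_aggregate Pair-aggregate dissolution parameter (the
#'   Day-1 pair fit, 0.57); divided by 2 for the per-individual value.
#' @param movement A [movement_params()].
#' @param shift_day,shift_factor Maturational shift (Day 4, 1.95-fold).
#' @param seed Master integer seed; each (run, agent) derives an
#'   independent stream from it.
#' @param n_runs Number of Monte-Carlo runs.
#' @param snapshot_every Snapshot cadence, s (10 min by default).
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(arena = arena_preset("dispersal_80mm_4c"),
                       n_agents = 4, timestep = 1, days = 11,
                       condition = c("full", "no_social", "no_shift"),
                       survival = survival_params(),
                       alpha_pair_aggregate = 0.57,
                       movement = movement_params(),
                       shift_day = 4, shift_factor = 1.95,
                       seed = 1L, n_runs = 1L, snapshot_every = 600) {
  condition <- match.arg(condition)
  stopifnot(timestep > 0, n_runs >= 1, n_agents >= 1, days > 0)
  structure(
    list(arena = arena, n_agents = n_agents, timestep = timestep,
         days = days, condition = condition, survival = survival,
         alpha_pair_aggregate = alpha_pair_aggregate, movement = movement,
         shift_day = shift_day, shift_factor = shift_factor,
         seed = as.integer(seed), n_runs = as.integer(n_runs),
         snapshot_every = snapshot_every),
    class = "sim_config"
  )
}

.cpp_pars <- function(config) {
  m <- config$movement
  s <- config$survival
  list(V = m$V, tau_p = m$tau_p, l_star = m$l_star,
       tau_stop_c = m$tau_stop_c, P_w = m$P_w, P_c = m$P_c,
       stop_given_N = m$stop_given_N,
       move_after_collision_given_N = m$move_after_collision_given_N,
       edge_event_probs = m$edge_event_probs,
       alpha_single = s$alpha, alpha_pair_aggregate = config$alpha_pair_aggregate,
       beta = s$beta, delta = s$delta,
       shift_day = config$shift_day, shift_factor = config$shift_factor,
       contact_radius = m$contact_radius,
       collision_radius = m$collision_radius,
       aggregate_radius = m$aggregate_radius)
}

# one spider at the center of each compartment (or at the arena center /
# spread on a small ring in an open arena)
.init_positions <- function(config) {
  a <- config$arena
  n <- config$n_agents
  if (a$n_compartments > 0) {
    k <- ((seq_len(n) - 1) %% a$n_compartments)
    ang <- a$wall_angles[k + 1] + pi / a$n_compartments
    rc <- (a$opening_radius + a$radius) / 2
    cbind(rc * cos(ang), rc * sin(ang))
  } else {
    if (n == 1L) return(cbind(0, 0))
    ang <- 2 * pi * (seq_len(n) - 1) / n
    rc <- a$radius / 2
    cbind(rc * cos(ang), rc * sin(ang))
  }
}

.mode_labels <- c("moving_edge", "moving_edge", "moving_center", "stopped")

#' Run the agent-based dispersal simulation
#'
#' Simulates `config$n_runs` independent runs of the stop-and-go
#' aggregation/dispersal model and returns the snapshot series. Each spider
#' starts in a moving state at the center of its compartment. Fully
#' reproducible: the same configuration (including `seed`) yields an
#' identical result, and each agent's random stream is independent of the
#' presence of other agents.
#'
#' @param config A [sim_config()].
#' @param runs Optional integer vector of run indices (defaults to
#'   `seq_len(config$n_runs)`); useful for streaming over runs.
#' @return A tibble with columns `run`, `t_s`, `id`, `x_mm`, `y_mm`,
#'   `mode` (`moving_edge`, `moving_center`, `stopped`).
#' @examples
#' cfg <- sim_config(days = 1 / 24, n_agents = 2, seed = 7,
#'                   snapshot_every = 60)
#' snaps <- simulate_spiderlings(cfg)
#' head(snaps)
#' @export
simulate_spiderlings <- function(config, runs = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(runs)) runs <- seq_len(config$n_runs)
  pars <- .cpp_pars(config)
  init <- .init_positions(config)
  social <- config$condition != "no_social"
  shift <- config$condition != "no_shift"
  out <- purrr::map(runs, function(r) {
    res <- sim_abm_cpp(
      unclass(config$arena), pars, config$n_agents, config$timestep,
      config$days * 86400, config$snapshot_every, social, shift,
      config$seed, as.integer(r), init
    )
    tibble::tibble(
      run = as.integer(r), t_s = res$t_s, id = res$id,
      x_mm = res$x_mm, y_mm = res$y_mm,
      mode = .mode_labels[res$mode + 1L]
    )
  })
  dplyr::bind_rows(out)
}

# daily summaries for a single run's snapshot tibble
.run_daily_summary <- function(snaps, arena, photo_offsets = c(3600, 21600, 36000),
                               move_threshold = 3) {
  days <- sort(unique(floor(snaps$t_s[snaps$t_s > 0] / 86400) + 1))
  days <- days[(days - 1) * 86400 + max(photo_offsets) <= max(snaps$t_s)]
  nn <- vapply(days, function(d) {
    offs <- (d - 1) * 86400 + photo_offsets
    vals <- vapply(offs, function(tt) {
      fr <- snaps[snaps$t_s == tt, ]
      if (nrow(fr) < 2) return(NA_real_)
      .mean_nn(cbind(fr$x_mm, fr$y_mm), arena)
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  act <- .daily_activity(snaps, arena, move_threshold)
  tibble::tibble(day = days, mean_nn_mm = nn,
                 activity = act$activity[match(days, act$day)])
}

# proportion of consecutive snapshot pairs with a wall-aware displacement of
# at least `threshold` mm, averaged over individuals, per day
.daily_activity <- function(snaps, arena, threshold = 3) {
  snaps <- snaps[order(snaps$id, snaps$t_s), ]
  moved <- tapply(seq_len(nrow(snaps)), snaps$id, function(ix) {
    x <- snaps$x_mm[ix]; y <- snaps$y_mm[ix]; t <- snaps$t_s[ix]
    n <- length(ix)
    d <- .fast_geodesic_steps(x, y, arena)
    tibble::tibble(t_s = t[-1], moved = d >= threshold)
  })
  long <- dplyr::bind_rows(moved, .id = "id")
  long$day <- floor((long$t_s - 1e-9) / 86400) + 1
  out <- stats::aggregate(moved ~ day, data = long, FUN = mean)
  tibble::tibble(day = out$day, activity = out$moved)
}

# geodesic step lengths along one individual's path; Euclidean unless the
# straight segment crosses an inner wall (geodesic >= Euclidean, and equal
# when unobstructed, so thresholding is exact)
.fast_geodesic_steps <- function(x, y, arena) {
  n <- length(x)
  eu <- sqrt(diff(x)^2 + diff(y)^2)
  if (arena$n_compartments == 0L) return(eu)
  cross <- .crosses_any_wall(x[-n], y[-n], x[-1], y[-1], arena)
  if (any(cross)) {
    i <- which(cross)
    eu[i] <- geodesic_distance(cbind(x[i], y[i]),
                               cbind(x[i + 1], y[i + 1]), arena)
  }
  eu
}

#' Daily summary of a simulated condition
#'
#' Runs the model under a given condition and summarises each simulated day
#' by the mean nearest-neighbour geodesic distance (averaged over the three
#' experimental photo times, 9:00/14:00/18:00) and the activity index
#' (proportion of 10-min snapshot pairs with a displacement of at least one
#' body length), with across-run 95% confidence intervals.
#'
#' @param config A [sim_config()] with `n_runs >= 2`.
#' @param photo_offsets Seconds after each day's start (8:00) at which the
#'   distance is measured.
#' @param move_threshold Movement threshold in mm for the activity index.
#' @return A tibble of class `"dispersal_summary"` with one row per day:
#'   `day`, `mean_nn_mm`, `nn_lo`, `nn_hi`, `activity`, `act_lo`, `act_hi`,
#'   `n_runs`, `condition`.
#' @export
run_condition <- function(config, photo_offsets = c(3600, 21600, 36000),
                          move_threshold = 3) {
  stopifnot(inherits(config, "sim_config"), config$n_runs >= 2)
  per_run <- purrr::map(seq_len(config$n_runs), function(r) {
    snaps <- simulate_spiderlings(config, runs = r)
    .run_daily_summary(snaps, config$arena, photo_offsets, move_threshold)
  })
  all <- dplyr::bind_rows(per_run, .id = "run")
  ci <- function(v) {
    m <- mean(v, na.rm = TRUE)
    se <- stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))
    c(m, m - 1.96 * se, m + 1.96 * se)
  }
  out <- all %>%
    dplyr::group_by(.data$day) %>%
    dplyr::summarise(
      nn = list(ci(.data$mean_nn_mm)),
      ac = list(ci(.data$activity)),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      mean_nn_mm = purrr::map_dbl(.data$nn, 1),
      nn_lo = purrr::map_dbl(.data$nn, 2),
      nn_hi = purrr::map_dbl(.data$nn, 3),
      activity = purrr::map_dbl(.data$ac, 1),
      act_lo = purrr::map_dbl(.data$ac, 2),
      act_hi = purrr::map_dbl(.data$ac, 3)
    ) %>%
    dplyr::select(-"nn", -"ac") %>%
    dplyr::mutate(n_runs = config$n_runs, condition = config$condition)
  class(out) <- c("dispersal_summary", class(out))
  out
}

#' Plot dispersal dynamics of one or more simulated conditions
#'
#' @param object A `dispersal_summary` (or several row-bound together).
#' @param baseline Optional [random_baseline_distance()] result drawn as the
#'   random level of aggregation.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dispersal_summary <- function(object, baseline = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$day, y = .data$mean_nn_mm,
                                            colour = .data$condition,
                                            fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$nn_lo, ymax = .data$nn_hi),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Day", y = "Mean nearest-neighbour distance (mm)") +
    ggplot2::theme_minimal()
  if (!is.null(baseline)) {
    p <- p +
      ggplot2::geom_hline(yintercept = baseline$mean_nn_mm, linetype = 2,
                          colour = "grey40") +
      ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                        ymin = baseline$ci_low, ymax = baseline$ci_high,
                        alpha = 0.08)
  }
  p
}
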