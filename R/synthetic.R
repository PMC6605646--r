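#' Sample stop durations from the heavy-tailed survival model
#'
#' Inverse-transform sampling of i.i.d. stop durations with survival
#' function `exp(-delta t) (1 + t/beta)^(-alpha)`: for each uniform draw
#' `u` the equation `F(t) = u` is solved by bracketed root-finding
#' (tolerance 1e-9 s; `F` is strictly decreasing so the root is unique).
#'
#' @param params A [survival_params()]; at least one of `alpha`, `delta`
#'   must be positive, otherwise the distribution is improper.
#' @param n Number of durations.
#' @param seed Optional seed; the sample is deterministic given it.
#' @return A lifetime tibble (`duration_s`, `censored = FALSE`).
#' @examples
#' gen_stop_durations(survival_params(alpha = 0.48, beta = 0.74), 5, seed = 1)
#' @export
gen_stop_durations <- function(params, n, seed = NULL) {
  stopifnot(inherits(params, "survival_params"))
  if (params$alpha == 0 && params$delta == 0) {
    stop("alpha = delta = 0: stop durations are improper (never leave)",
         call. = FALSE)
  }
  u <- .with_seed(seed, stats::runif(n))
  d <- vapply(u, function(ui) .quantile_stop(ui, params), numeric(1))
  lifetime_sample(d)
}

# solve F(t) = u for t on the log-survival scale
.quantile_stop <- function(u, params) {
  g <- function(t) {
    -params$delta * t - params$alpha * log1p(t / params$beta) - log(u)
  }
  hi <- 1
  while (g(hi) > 0) hi <- hi * 4
  stats::uniroot(g, c(0, hi), tol = 1e-9)$root
}

#' Two lifetime samples with a known hazard ratio
#'
#' Test harness for [cox_hazard_ratio()]: group `baseline` is drawn from
#' the baseline hazard; group `scaled` from the baseline hazard multiplied
#' by `true_hr`, so proportional hazards holds exactly by construction
#' (survival function `F(t)^true_hr`, sampled by inverse transform with
#' `u^(1/true_hr)`). Both groups are right-censored at `censor_time`.
#'
#' @param true_hr True hazard ratio of `scaled` relative to `baseline`,
#'   > 0.
#' @param baseline A [survival_params()] for the baseline group.
#' @param n_per_group Sample size per group.
#' @param censor_time Right-censoring time in s (`Inf` for none).
#' @param seed Optional seed.
#' @return A list with lifetime tibbles `baseline` and `scaled`.
#' @export
gen_two_group_lifetimes <- function(true_hr, baseline = survival_params(),
                                    n_per_group, censor_time = Inf,
                                    seed = NULL) {
  stopifnot(true_hr > 0, censor_time > 0)
  u <- .with_seed(seed, stats::runif(2 * n_per_group))
  d0 <- vapply(u[seq_len(n_per_group)],
               function(ui) .quantile_stop(ui, baseline), numeric(1))
  d1 <- vapply(u[n_per_group + seq_len(n_per_group)],
               function(ui) .quantile_stop(ui^(1 / true_hr), baseline),
               numeric(1))
  censor <- function(d) {
    cens <- d > censor_time
    lifetime_sample(pmin(d, censor_time), cens)
  }
  list(baseline = censor(d0), scaled = censor(d1))
}

#' Synthetic single/pair trajectories in the open interaction arena
#'
#' Generates stop-and-go trajectories of two spiderlings in a 44-mm open
#' arena sampled at the tracking frame rate (2.08 frames/s), using the same
#' agent-based stepping kernel as the dispersal simulator, so the
#' generator and the analyzers share one movement model. With
#' `interattraction = TRUE` a spider close to a stopped partner stops more
#' readily and leaves pair aggregates at the pair-scaled rate; with
#' `FALSE` both spiders follow single-spider rules throughout (the null
#' hypothesis of the virtual-pair construction). The maturational shift is
#' disabled (recordings last 24 h).
#'
#' @param duration_s Recording length in seconds.
#' @param interattraction Logical; social modulation on or off.
#' @param fps Sampling rate, frames per second.
#' @param survival Single-spider [survival_params()].
#' @param alpha_pair_aggregate Pair-aggregate dissolution parameter.
#' @param movement A [movement_params()].
#' @param arena An [arena()] (44-mm open arena by default).
#' @param seed Master seed.
#' @return A list with elements `traj_a`, `traj_b` (single-individual
#'   tibbles `t_s`, `x_mm`, `y_mm`), `pair` (the combined pair trajectory,
#'   provenance `"real"`), and `truth` (tibble of intervals during which
#'   both spiders were simultaneously stopped within the aggregation
#'   distance -- the generator's ground-truth aggregate log).
#' @export
gen_pair_trajectories <- function(duration_s = 4 * 3600,
                                  interattraction = TRUE, fps = 2.08,
                                  survival = survival_params(),
                                  alpha_pair_aggregate = 0.57,
                                  movement = movement_params(),
                                  arena = arena_preset("pair_44mm"),
                                  seed = 1L) {
  dt <- 1 / fps
  cfg <- sim_config(
    arena = arena, n_agents = 2, timestep = dt,
    days = duration_s / 86400,
    condition = if (interattraction) "full" else "no_social",
    survival = survival, alpha_pair_aggregate = alpha_pair_aggregate,
    movement = movement, shift_day = Inf, seed = seed, n_runs = 1,
    snapshot_every = dt
  )
  snaps <- simulate_spiderlings(cfg)
  traj <- split(snaps, snaps$id)
  mk <- function(tr) tibble::tibble(t_s = tr$t_s, x_mm = tr$x_mm, y_mm = tr$y_mm)
  pair <- build_virtual_pair(mk(traj[[1]]), mk(traj[[2]]), provenance = "real")
  both_stopped <- traj[[1]]$mode == "stopped" & traj[[2]]$mode == "stopped"
  close <- .pair_dist(pair) < movement$aggregate_radius
  runs <- .runs_of(both_stopped & close)
  truth <- if (nrow(runs) == 0) {
    tibble::tibble(start_s = numeric(0), end_s = numeric(0))
  } else {
    tibble::tibble(start_s = pair$t_s[runs[, "start"]],
                   end_s = pair$t_s[runs[, "end"]])
  }
  list(traj_a = mk(traj[[1]]), traj_b = mk(traj[[2]]), pair = pair,
       truth = truth)
}

#' Synthetic group snapshot series
#'
#' Ten-minute-cadence snapshots of a group of spiderlings in the dispersal
#' arena over several days, generated by the agent-based simulator under
#' the requested condition. Returned both labeled (with true identities)
#' and unlabeled (identities dropped and within-frame order scrambled
#' deterministically), to exercise the minimal-displacement identity
#' assignment exactly as unmarked experimental photographs do.
#'
#' @param condition `"full"`, `"no_social"` or `"no_shift"`.
#' @param days Number of simulated days.
#' @param n_agents Group size.
#' @param seed Master seed.
#' @param ... Further arguments passed to [sim_config()].
#' @return A list with tibbles `labeled` (columns `t_s`, `id`, `x_mm`,
#'   `y_mm`, `mode`) and `unlabeled` (no `id`).
#' @export
gen_group_snapshots <- function(condition = "full", days = 11, n_agents = 4,
                                seed = 1L, ...) {
  cfg <- sim_config(condition = condition, days = days, n_agents = n_agents,
                    seed = seed, n_runs = 1, snapshot_every = 600, ...)
  snaps <- simulate_spiderlings(cfg)
  labeled <- snaps[, c("t_s", "id", "x_mm", "y_mm", "mode")]
  unlabeled <- labeled[order(labeled$t_s, labeled$x_mm, labeled$y_mm),
                       c("t_s", "x_mm", "y_mm")]
  list(labeled = labeled, unlabeled = unlabeled)
}
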