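#' Superimpose two single-individual trajectories into a virtual pair
#'
#' Builds the trajectory-superimposition null model for interattraction:
#' the paths of two individuals recorded *alone* (ideally siblings from the
#' same cocoon) are each translated so that their arena centers coincide,
#' then overlaid as if the two spiders had shared one arena. Any
#' "aggregates" in a virtual pair arise purely by chance, so their lifetimes
#' estimate the null distribution against which real-pair lifetimes are
#' compared.
#'
#' @param traj_a,traj_b Single-individual trajectories: data frames with
#'   columns `t_s`, `x_mm`, `y_mm` sampled at a common fixed interval.
#' @param center_a,center_b Arena-center coordinates of each recording
#'   (length-2, mm); subtracted so both trajectories share the origin.
#' @param provenance `"virtual"` (default) or `"real"` (when combining the
#'   two tracks of an actual pair recording into the same structure).
#' @return A pair-trajectory tibble with columns `t_s`, `x_a`, `y_a`,
#'   `x_b`, `y_b` and attributes `provenance` and `dt_s`; truncated to the
#'   shorter of the two recordings.
#' @export
build_virtual_pair <- function(traj_a, traj_b, center_a = c(0, 0),
                               center_b = c(0, 0), provenance = "virtual") {
  for (tr in list(traj_a, traj_b)) {
    stopifnot(all(c("t_s", "x_mm", "y_mm") %in% names(tr)))
    if (nrow(tr) < 2) stop("trajectories need at least two frames", call. = FALSE)
  }
  dt_a <- diff(traj_a$t_s)
  dt_b <- diff(traj_b$t_s)
  if (max(abs(dt_a - dt_a[1])) > 1e-6 || max(abs(dt_b - dt_b[1])) > 1e-6) {
    stop("trajectories must be sampled at a fixed interval", call. = FALSE)
  }
  if (abs(dt_a[1] - dt_b[1]) > 1e-6) {
    stop("mismatched sampling rates between the two trajectories", call. = FALSE)
  }
  n <- min(nrow(traj_a), nrow(traj_b))
  out <- tibble::tibble(
    t_s = traj_a$t_s[seq_len(n)] - traj_a$t_s[1],
    x_a = traj_a$x_mm[seq_len(n)] - center_a[1],
    y_a = traj_a$y_mm[seq_len(n)] - center_a[2],
    x_b = traj_b$x_mm[seq_len(n)] - center_b[1],
    y_b = traj_b$y_mm[seq_len(n)] - center_b[2]
  )
  attr(out, "provenance") <- provenance
  attr(out, "dt_s") <- dt_a[1]
  out
}

.pair_dist <- function(pair) {
  sqrt((pair$x_a - pair$x_b)^2 + (pair$y_a - pair$y_b)^2)
}

.pair_dt <- function(pair) {
  dt <- attr(pair, "dt_s")
  if (is.null(dt)) dt <- diff(pair$t_s)[1]
  dt
}

# maximal runs of TRUE in a logical vector: (start, length) pairs
.runs_of <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  cbind(start = starts[keep], len = r$lengths[keep], end = ends[keep])
}

#' Aggregate lifetimes of a pair
#'
#' Extracts the lifetimes of aggregates from a pair trajectory: maximal
#' runs of frames during which the interindividual distance stays below
#' `dist_threshold` (10 mm) and that last strictly more than `min_duration`
#' (1 s). A run still ongoing at the end of the recording is
#' right-censored. A run of `k` frames sampled every `dt` seconds lasts
#' `k * dt`.
#'
#' @param pair A pair trajectory from [build_virtual_pair()] or
#'   [gen_pair_trajectories()].
#' @param dist_threshold Aggregation distance in mm (strictly below).
#' @param min_duration Minimum lifetime in s (strictly above).
#' @return A lifetime tibble (`duration_s`, `censored`); zero rows when the
#'   pair never aggregates.
#' @export
extract_aggregate_lifetimes <- function(pair, dist_threshold = 10,
                                        min_duration = 1) {
  d <- .pair_dist(pair)
  dt <- .pair_dt(pair)
  runs <- .runs_of(d < dist_threshold)
  if (nrow(runs) == 0) return(lifetime_sample(numeric(0)))
  dur <- runs[, "len"] * dt
  cens <- runs[, "end"] == length(d)
  keep <- dur > min_duration
  lifetime_sample(dur[keep], cens[keep])
}

#' Proportion of long contacts
#'
#' Among all completed contacts (maximal runs with interindividual distance
#' less than or equal to `contact_threshold`, 6 mm), the proportion lasting
#' strictly more than `min_duration` (1 s). This is the proxy for the
#' probability of stopping next to a conspecific: real pairs show a larger
#' proportion of long contacts than virtual pairs when interattraction
#' operates. A contact still ongoing at the end of the recording has an
#' unknown duration and is not counted.
#'
#' @inheritParams extract_aggregate_lifetimes
#' @param contact_threshold Contact distance in mm (leg-touch scale).
#' @return A single proportion in \[0, 1\], or `NA` (with a warning) when
#'   the pair never makes contact.
#' @export
contact_stop_proportion <- function(pair, contact_threshold = 6,
                                    min_duration = 1) {
  d <- .pair_dist(pair)
  dt <- .pair_dt(pair)
  runs <- .runs_of(d <= contact_threshold)
  if (nrow(runs) > 0) {
    runs <- runs[runs[, "end"] < length(d), , drop = FALSE]  # completed only
  }
  if (nrow(runs) == 0) {
    warning("no contacts between the two individuals; proportion undefined")
    return(NA_real_)
  }
  mean(runs[, "len"] * dt > min_duration)
}

#' Cox proportional-hazards comparison of real and null lifetimes
#'
#' Quantifies interattraction as the hazard ratio between the dissolution
#' rates of null-model (virtual) and real aggregates: the Cox partial
#' likelihood with a single binary covariate (virtual = 1, real = 0) is
#' maximized by Newton-Raphson, with Breslow handling of tied event times
#' and a Wald 95% CI from the observed information. A hazard ratio of 1
#' means virtual and real aggregates dissolve at the same rate; a ratio
#' above 1 means virtual aggregates dissolve faster, i.e. real aggregates
#' outlive chance (interattraction); a ratio below 1 would indicate active
#' avoidance.
#'
#' @param real Lifetime tibble (`duration_s`, `censored`) of real
#'   aggregates.
#' @param null Lifetime tibble of virtual (null-model) aggregates.
#' @return An object of class `"cox_hr"` with elements
#'   `log_hazard_ratio`, `hazard_ratio`, `se`, `ci95_low`, `ci95_high`,
#'   `n_events` (named vector, per group). Use `tidy()`/`glance()` for
#'   tibble output.
#' @export
cox_hazard_ratio <- function(real, null) {
  real <- lifetime_sample(real)
  null <- lifetime_sample(null)
  ev_real <- sum(!real$censored)
  ev_null <- sum(!null$censored)
  if (ev_real == 0 || ev_null == 0) {
    stop("no observed events in one of the groups; cannot fit", call. = FALSE)
  }
  if (ev_real < 5 || ev_null < 5) {
    warning("fewer than 5 events in a group; hazard ratio will be unstable")
  }
  time <- c(real$duration_s, null$duration_s)
  event <- c(!real$censored, !null$censored)
  x <- c(rep(0L, nrow(real)), rep(1L, nrow(null)))

  # Breslow: per distinct event time, events d_j (s_j of them in group 1)
  # and numbers at risk per group
  et <- sort(unique(time[event]))
  je <- match(time[event], et)
  d <- tabulate(je, nbins = length(et))
  s <- tabulate(je[x[event] == 1L], nbins = length(et))
  ord <- order(time)
  time_s <- time[ord]
  x_s <- x[ord]
  c1 <- c(0, cumsum(x_s))
  ntot <- length(time_s)
  k <- findInterval(et, time_s, left.open = TRUE) + 1L  # first index at risk
  n1 <- c1[ntot + 1L] - c1[k]
  n0 <- (ntot - k + 1L) - n1

  b <- 0
  for (it in 1:50) {
    eb <- exp(b)
    S0 <- n0 + n1 * eb
    p <- n1 * eb / S0
    U <- sum(s - d * p)
    I <- sum(d * p * (1 - p))
    if (I <= 0) stop("degenerate risk sets; Cox fit failed", call. = FALSE)
    step <- U / I
    step <- max(min(step, 2), -2)  # damp wild first steps
    b <- b + step
    if (abs(step) < 1e-12) break
  }
  if (abs(step) > 1e-6) {
    stop(sprintf("Cox fit did not converge (last step %.3g)", step),
         call. = FALSE)
  }
  eb <- exp(b)
  p <- n1 * eb / (n0 + n1 * eb)
  se <- 1 / sqrt(sum(d * p * (1 - p)))
  structure(
    list(log_hazard_ratio = b, hazard_ratio = exp(b), se = se,
         ci95_low = exp(b - 1.96 * se), ci95_high = exp(b + 1.96 * se),
         n_events = c(real = ev_real, null = ev_null)),
    class = "cox_hr"
  )
}

#' @export
print.cox_hr <- function(x, ...) {
  cat(sprintf(
    "<cox_hr> hazard ratio (null vs real) = %.3f [%.3f-%.3f]\n  events: %d real, %d null\n",
    x$hazard_ratio, x$ci95_low, x$ci95_high,
    x$n_events[["real"]], x$n_events[["null"]]))
  invisible(x)
}

#' @rdname cox_hazard_ratio
#' @param x A `cox_hr` object.
#' @param ... Unused.
#' @export
tidy.cox_hr <- function(x, ...) {
  tibble::tibble(
    term = "virtual_vs_real",
    estimate = x$log_hazard_ratio,
    std.error = x$se,
    hazard_ratio = x$hazard_ratio,
    conf.low = x$ci95_low,
    conf.high = x$ci95_high
  )
}

#' @rdname cox_hazard_ratio
#' @export
glance.cox_hr <- function(x, ...) {
  tibble::tibble(
    hazard_ratio = x$hazard_ratio,
    ci95_low = x$ci95_low,
    ci95_high = x$ci95_high,
    n_events_real = x$n_events[["real"]],
    n_events_null = x$n_events[["null"]]
  )
}
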