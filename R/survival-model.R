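#' Parameters of the stop/aggregate leaving-hazard model
#'
#' The duration of stops (and of aggregate lifetimes) follows a heavy-tailed
#' survival function
#' \deqn{F(t) = e^{-\delta t} (1 + t/\beta)^{-\alpha}}
#' whose leaving hazard is a power law with a low-rate cutoff,
#' \deqn{P_{leave}(t) = \delta + \alpha / (\beta + t).}
#' `alpha` sets how quickly a stopped individual resumes moving, `beta`
#' (seconds) sets how long an individual must stay stopped before its
#' accumulated staying time markedly lowers its leaving probability, and
#' `delta` (per second) is the floor the hazard plateaus to for very long
#' rests. The reference values fitted on Day-1 single spiderlings are
#' `alpha = 0.48`, `beta = 0.74` s, with `delta` held at `1e-6`/s.
#'
#' @param alpha Dimensionless hazard-shape parameter, >= 0.
#' @param beta Time constant in seconds, > 0.
#' @param delta Baseline hazard per second, >= 0.
#' @return An object of class `"survival_params"`.
#' @export
survival_params <- function(alpha = 0.48, beta = 0.74, delta = 1e-6) {
  stopifnot(is.numeric(alpha), is.numeric(beta), is.numeric(delta),
            alpha >= 0, beta > 0, delta >= 0)
  structure(list(alpha = alpha, beta = beta, delta = delta),
            class = "survival_params")
}

#' @export
print.survival_params <- function(x, ...) {
  cat(sprintf("<survival_params> alpha = %g, beta = %g s, delta = %g /s\n",
              x$alpha, x$beta, x$delta))
  invisible(x)
}

#' Survival function of stop durations
#'
#' Probability that a stop (or aggregate) initiated at time 0 is still
#' ongoing at time `t`: `exp(-delta * t) * (1 + t / beta)^(-alpha)`.
#'
#' @param t Vector of times in seconds, >= 0.
#' @param params A [survival_params()] object.
#' @return Survival probabilities in (0, 1].
#' @export
stop_survival <- function(t, params = survival_params()) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  exp(-params$delta * t) * (1 + t / params$beta)^(-params$alpha)
}

#' Leaving hazard of stopped individuals
#'
#' Instantaneous probability per second of resuming movement after a stop of
#' duration `t`: `delta + alpha / (beta + t)`. This is `-d/dt log` of
#' [stop_survival()]; it decreases with time stopped (the longer an
#' individual has rested, the less likely it is to move) and plateaus at
#' `delta`.
#'
#' @inheritParams stop_survival
#' @return Hazard values (per second).
#' @export
stop_hazard <- function(t, params = survival_params()) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  params$delta + params$alpha / (params$beta + t)
}

#' Per-individual leaving parameter as a function of group size
#'
#' Converts aggregate-level (or single-individual) leaving parameters into
#' the per-individual probability of leaving an aggregate of size `N`:
#' * `N = 1`: the single-individual `alpha` is returned unchanged;
#' * `N = 2`: the pair-aggregate dissolution parameter is divided by 2
#'   (the number of individuals), e.g. 0.57 / 2 = 0.285;
#' * `N = 3` / `N = 4`: the single-individual `alpha` is divided by 5 / 10,
#'   the scalings that reproduce the observed Day-2 aggregation level.
#'
#' The resulting per-individual parameters decrease with group size
#' (0.48 > 0.285 > 0.096 > 0.048 for the reference values), which is the
#' model's expression of interattraction.
#'
#' @param alpha For `group_size` 2 the pair-aggregate dissolution parameter;
#'   otherwise the single-individual parameter.
#' @param group_size Aggregate size, one of 1, 2, 3, 4.
#' @return The per-individual leaving parameter.
#' @export
scale_alpha_group <- function(alpha, group_size) {
  stopifnot(length(group_size) == 1L)
  if (!group_size %in% 1:4) {
    stop("group_size must be 1, 2, 3 or 4", call. = FALSE)
  }
  switch(group_size, alpha, alpha / 2, alpha / 5, alpha / 10)
}

#' Maturational (ontogenic) shift in mobility
#'
#' Applies the developmental increase in mobility: from `shift_day` onwards
#' the leaving parameter `alpha` is multiplied once by `shift_factor`
#' (1.95-fold at Day 4 for the reference calibration) and remains constant
#' afterwards; before `shift_day` it is unchanged. The shift is idempotent
#' per day: it never compounds across days.
#'
#' @param alpha Leaving parameter.
#' @param day Day index (simulation days start at 1), >= 0.
#' @param shift_day Day on and after which the shift applies.
#' @param shift_factor Multiplicative increase in `alpha`.
#' @return The (possibly shifted) `alpha`.
#' @export
apply_ontogenic_shift <- function(alpha, day, shift_day = 4, shift_factor = 1.95) {
  if (any(day < 0)) stop("day must be >= 0", call. = FALSE)
  ifelse(day >= shift_day, alpha * shift_factor, alpha)
}

#' Tidy a duration table into a lifetime sample
#'
#' Validates a table of event durations with right-censoring flags (a
#' censored duration is a stop or aggregate still ongoing when the recording
#' ended).
#'
#' @param durations Event durations in seconds (> 0), or a data frame with
#'   columns `duration_s` and (optionally) `censored`.
#' @param censored Logical vector parallel to `durations`.
#' @return A tibble with columns `duration_s` and `censored`.
#' @export
lifetime_sample <- function(durations, censored = FALSE) {
  if (is.data.frame(durations)) {
    censored <- if ("censored" %in% names(durations)) durations$censored else FALSE
    durations <- durations$duration_s
  }
  censored <- rep_len(as.logical(censored), length(durations))
  if (any(durations <= 0)) stop("durations must be > 0", call. = FALSE)
  tibble::tibble(duration_s = as.numeric(durations), censored = censored)
}

# Kaplan-Meier estimate of the survival function at the observed event
# times; censored observations contribute exposure but not events.
.km_curve <- function(sample) {
  ord <- order(sample$duration_s)
  t <- sample$duration_s[ord]
  ev <- !sample$censored[ord]
  n <- length(t)
  ut <- unique(t)
  grp <- match(t, ut)
  d <- tabulate(grp[ev], nbins = length(ut))
  cnt <- tabulate(grp, nbins = length(ut))
  at_risk <- n - c(0, cumsum(cnt)[-length(cnt)])
  S <- cumprod(1 - d / at_risk)
  keep <- d > 0
  list(time = ut[keep], surv = S[keep])
}

#' Fit the stop-survival model to a lifetime sample
#'
#' Nonlinear least-squares fit of the survival function
#' `exp(-delta t) (1 + t/beta)^(-alpha)` to the empirical (Kaplan-Meier)
#' survival curve evaluated at the observed event times. `delta` is always
#' held fixed (1e-6/s by default); `beta` may also be fixed, as done when
#' fitting pair-aggregate lifetimes with the single-individual `beta`. A
#' deterministic multi-start grid over `alpha` in \[0.05, 2\] and `beta` in
#' \[0.1, 10\] precedes Nelder-Mead/L-BFGS-B refinement to avoid local
#' minima.
#'
#' @param sample A lifetime table as returned by [lifetime_sample()] or
#'   [gen_stop_durations()] (columns `duration_s`, `censored`).
#' @param delta Fixed baseline hazard per second.
#' @param beta Optional fixed time constant; `NULL` (default) fits it.
#' @param log_scale Fit the sum of squares on log-survival rather than on
#'   the linear scale (off by default).
#' @return An object of class `"stop_survival_fit"` with elements `params`
#'   (a [survival_params()]), `objective` (residual sum of squares), `n_events`
#'   and the empirical curve. Use [tidy()][generics::tidy] / `glance()` to
#'   extract results as tibbles.
#' @export
fit_stop_survival <- function(sample, delta = 1e-6, beta = NULL,
                              log_scale = FALSE) {
  sample <- lifetime_sample(sample)
  n_events <- sum(!sample$censored)
  if (n_events < 20) {
    stop("need at least 20 uncensored events to fit", call. = FALSE)
  }
  if (length(unique(sample$duration_s[!sample$censored])) < 2) {
    stop("all event durations identical: survival curve degenerate",
         call. = FALSE)
  }
  km <- .km_curve(sample)
  emp <- if (log_scale) log(pmax(km$surv, 1e-12)) else km$surv
  sse <- function(alpha, b) {
    Fh <- exp(-delta * km$time) * (1 + km$time / b)^(-alpha)
    if (log_scale) Fh <- log(pmax(Fh, 1e-12))
    sum((Fh - emp)^2)
  }
  alpha_grid <- c(0.05, 0.1, 0.25, 0.5, 1, 2)
  if (is.null(beta)) {
    beta_grid <- c(0.1, 0.5, 1, 2, 5, 10)
    starts <- expand.grid(a = alpha_grid, b = beta_grid)
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      fit <- stats::optim(
        c(log(starts$a[i]), log(starts$b[i])),
        function(p) sse(exp(p[1]), exp(p[2])),
        method = "Nelder-Mead",
        control = list(maxit = 500, reltol = 1e-12)
      )
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    est <- survival_params(exp(best$par[1]), exp(best$par[2]), delta)
    obj <- best$value
  } else {
    best <- NULL
    for (a0 in alpha_grid) {
      fit <- stats::optim(
        log(a0), function(p) sse(exp(p), beta),
        method = "Brent", lower = log(1e-6), upper = log(50)
      )
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    est <- survival_params(exp(best$par), beta, delta)
    obj <- best$value
  }
  structure(
    list(params = est, objective = obj, n_events = n_events,
         n = nrow(sample), beta_fixed = !is.null(beta),
         km = tibble::tibble(time_s = km$time, survival = km$surv)),
    class = "stop_survival_fit"
  )
}

#' @export
print.stop_survival_fit <- function(x, ...) {
  cat(sprintf(
    "<stop_survival_fit> alpha = %.4g, beta = %.4g s%s (delta fixed at %g /s)\n  %d events, SSE = %.4g\n",
    x$params$alpha, x$params$beta,
    if (x$beta_fixed) " [fixed]" else "", x$params$delta,
    x$n_events, x$objective))
  invisible(x)
}

#' @rdname fit_stop_survival
#' @param x A `stop_survival_fit` object.
#' @param ... Unused.
#' @export
tidy.stop_survival_fit <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "beta", "delta"),
    estimate = c(x$params$alpha, x$params$beta, x$params$delta),
    fixed = c(FALSE, x$beta_fixed, TRUE)
  )
}

#' @rdname fit_stop_survival
#' @export
glance.stop_survival_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective, n = x$n, n_events = x$n_events)
}
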