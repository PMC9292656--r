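#' Define a factorial experiment plan
#'
#' @param layouts List of [layout_config()] (default: the full factorial
#'   set of 144 from [enumerate_layouts()]).
#' @param replications Replications per layout (the study design uses 30).
#' @param seed Master seed; replication `j` of every layout shares the
#'   stream seeded `seed + j` (common random numbers).
#' @return Object of class `experiment_plan`.
#' @export
experiment_plan <- function(layouts = enumerate_layouts(),
                            replications = 30L, seed = 1L) {
  if (replications < 1L) stop("replications must be >= 1", call. = FALSE)
  if (is.null(names(layouts)))
    names(layouts) <- vapply(layouts, layout_name, character(1))
  structure(list(layouts = layouts, replications = as.integer(replications),
                 seed = as.integer(seed)),
            class = "experiment_plan")
}

#' @export
print.experiment_plan <- function(x, ...) {
  cat(sprintf("<experiment_plan> %d layouts x %d replications = %d runs (seed %d)\n",
              length(x$layouts), x$replications,
              length(x$layouts) * x$replications, x$seed))
  invisible(x)
}

#' Run a factorial plan under common random numbers
#'
#' For each replication `j`, one arrival realization and one set of
#' per-donor service-time and deferral draws are generated from seed
#' `seed + j`, and every layout in the plan is simulated on that identical
#' realized input. Layouts therefore differ only through the layout
#' itself, which is what makes paired layout comparisons low-variance.
#'
#' @param plan An [experiment_plan()].
#' @param day A [day_schedule()] (default: a [baseline_day()] generated
#'   from the master seed).
#' @param behaviour,catalog,rates,costs Model parameters.
#' @return A data.frame with one row per (layout, replication) holding the
#'   flattened [kpi_report()] columns plus the six factor columns.
#' @export
run_plan <- function(plan, day = NULL,
                     behaviour = behaviour_params(),
                     catalog = process_time_catalog(),
                     rates = deferral_rates(),
                     costs = cost_model()) {
  stopifnot(inherits(plan, "experiment_plan"))
  if (is.null(day)) {
    set.seed(plan$seed)
    day <- baseline_day(behaviour)
  }
  validate_day_schedule(day)
  rows <- vector("list", length(plan$layouts) * plan$replications)
  ri <- 0L
  for (j in seq_len(plan$replications)) {
    set.seed(plan$seed + j)
    arr <- realize_arrivals(day, behaviour)
    donors <- draw_donor_attributes(arr, catalog, rates)
    for (li in seq_along(plan$layouts)) {
      lay <- plan$layouts[[li]]
      log <- run_day(lay, donors, periods = day$periods)
      rep_row <- as.data.frame(kpi_report(log, costs,
                                          day$capacity_per_period))
      rep_row$replication <- j
      rep_row$queue_policy <- lay$queue_policy
      rep_row$physician_timetable <- lay$physician_timetable
      rep_row$hb_placement <- lay$hb_placement
      rep_row$n_nurses <- lay$n_nurses
      rep_row$n_clerks <- lay$n_clerks
      rep_row$n_beds <- lay$n_beds
      ri <- ri + 1L
      rows[[ri]] <- rep_row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Validate the baseline model against a reference cycle time
#'
#' One-sample two-sided t-test of the replication means against the
#' centre-reported mean cycle time, plus the power analysis used to choose
#' the replication count: the sample critical difference
#' `delta_hat = |xbar - mu| / s`, the type-II error `beta(delta_hat)` at
#' the current `n`, and the smallest `n` bringing `beta` below
#' `beta_target`. Power is computed from the noncentral-t distribution
#' (numerically, not from a printed operating-characteristic chart, so the
#' required `n` may differ from chart-derived values).
#'
#' @param samples Numeric vector of replication means; alternatively pass
#'   summary statistics via `xbar`, `s`, `n`.
#' @param mu Reference mean (minutes).
#' @param alpha Test significance level.
#' @param beta_target Acceptable type-II error at `delta_hat`.
#' @param xbar,s,n Optional summary statistics replacing `samples`.
#' @return Object of class `validation_summary` with fields `xbar`, `s`,
#'   `n`, `mu`, `alpha`, `t`, `p_value`, `reject`, `delta_hat`, `beta`,
#'   `n_required`.
#' @export
validate_baseline <- function(samples = NULL, mu, alpha = 0.05,
                              beta_target = 0.05,
                              xbar = NULL, s = NULL, n = NULL) {
  if (!is.null(samples)) {
    if (length(samples) < 2L) stop("need at least 2 samples", call. = FALSE)
    xbar <- mean(samples); s <- stats::sd(samples); n <- length(samples)
  } else if (is.null(xbar) || is.null(s) || is.null(n)) {
    stop("supply either samples or all of xbar, s, n", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  degenerate <- s <= 0
  tstat <- if (degenerate) NA_real_ else (xbar - mu) / (s / sqrt(n))
  pval <- if (degenerate) NA_real_ else
    2 * stats::pt(-abs(tstat), df = n - 1)
  delta_hat <- if (degenerate) 0 else abs(xbar - mu) / s
  beta <- t_test_beta(delta_hat, n, alpha)
  n_required <- required_replications(delta_hat, alpha, beta_target)
  structure(list(xbar = xbar, s = s, n = n, mu = mu, alpha = alpha,
                 t = tstat, p_value = pval,
                 reject = if (degenerate) FALSE else pval < alpha,
                 delta_hat = delta_hat, beta = beta,
                 n_required = n_required, degenerate = degenerate),
            class = "validation_summary")
}

#' Type-II error of the one-sample two-sided t-test
#'
#' Probability of failing to reject when the true standardized difference
#' is `delta`, from the noncentral-t distribution with noncentrality
#' `delta * sqrt(n)`.
#'
#' @param delta Standardized difference `|mean shift| / sd`.
#' @param n Sample size (`>= 2`).
#' @param alpha Significance level.
#' @return `beta` in \[0, 1\].
#' @export
t_test_beta <- function(delta, n, alpha = 0.05) {
  if (n < 2L) return(NA_real_)
  tc <- stats::qt(1 - alpha / 2, df = n - 1)
  ncp <- delta * sqrt(n)
  stats::pt(tc, df = n - 1, ncp = ncp) - stats::pt(-tc, df = n - 1, ncp = ncp)
}

#' Smallest sample size with acceptable type-II error
#'
#' @inheritParams t_test_beta
#' @param beta_target Required `beta` bound.
#' @param n_max Search cap.
#' @return The smallest `n` with `t_test_beta(delta, n, alpha) <=
#'   beta_target`, or `NA` if none up to `n_max` (e.g. `delta = 0`).
#' @export
required_replications <- function(delta, alpha = 0.05, beta_target = 0.05,
                                  n_max = 10000L) {
  if (delta <= 0) return(NA_integer_)
  for (n in 2:n_max)
    if (t_test_beta(delta, n, alpha) <= beta_target) return(as.integer(n))
  NA_integer_
}

#' @export
print.validation_summary <- function(x, ...) {
  cat("<validation_summary>\n")
  cat(sprintf("  xbar = %.3f, s = %.3f, n = %d vs mu = %.3f\n",
              x$xbar, x$s, x$n, x$mu))
  if (x$degenerate) {
    cat("  zero sample variance: t undefined, fail to reject\n")
  } else {
    cat(sprintf("  t = %.3f, p = %.4f -> %s H0 at alpha = %g\n",
                x$t, x$p_value,
                if (x$reject) "reject" else "fail to reject", x$alpha))
  }
  cat(sprintf("  delta_hat = %.3f, beta(delta_hat) = %.3f at n = %d; n_required = %s\n",
              x$delta_hat, x$beta, x$n,
              ifelse(is.na(x$n_required), "NA", x$n_required)))
  invisible(x)
}
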