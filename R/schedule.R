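#' Construct a daily appointment schedule
#'
#' A `day_schedule` is the scheduler-facing input to the simulation: a day
#' split into contiguous periods, each carrying counts of already-booked
#' donors, pre-allocated (not yet booked) slots, the expected number of
#' walk-in donors, and a period-specific queue-penalty weight. All clock
#' times are minutes from midnight; the default day is three two-hour
#' periods from 7:30 to 13:30.
#'
#' @param periods A data.frame with one row per period and columns `k`,
#'   `start`, `end`, `n_booked`, `n_preallocated`, `n_walkin_expected`,
#'   `weight`.
#' @param capacity_per_period Nominal physician capacity per period,
#'   physician-minutes (default 450, i.e. 3.75 physician-equivalents over
#'   two hours).
#' @param consultation_time Standard consultation time `r` used by the
#'   scheduler, minutes (default 20).
#' @return An object of class `day_schedule`.
#' @export
day_schedule <- function(periods,
                         capacity_per_period = 450,
                         consultation_time = 20) {
  need <- c("k", "start", "end", "n_booked", "n_preallocated",
            "n_walkin_expected", "weight")
  if (!is.data.frame(periods) || !all(need %in% names(periods)))
    stop("periods must be a data.frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  periods <- periods[order(periods$k), need]
  day <- structure(list(periods = periods,
                        capacity_per_period = capacity_per_period,
                        consultation_time = consultation_time),
                   class = "day_schedule")
  validate_day_schedule(day)
  day
}

validate_day_schedule <- function(day) {
  p <- day$periods
  if (nrow(p) < 1L) stop("schedule needs at least one period", call. = FALSE)
  if (!all(p$k == seq_len(nrow(p))))
    stop("period indices k must be 1..K in order", call. = FALSE)
  if (any(p$start >= p$end))
    stop("each period must satisfy start < end", call. = FALSE)
  if (nrow(p) > 1L && any(p$end[-nrow(p)] != p$start[-1L]))
    stop("periods must be contiguous (end[k] == start[k+1])", call. = FALSE)
  cnt <- as.matrix(p[, c("n_booked", "n_preallocated", "n_walkin_expected")])
  if (any(cnt < 0)) stop("donor counts must be non-negative", call. = FALSE)
  if (any(p$weight <= 0)) stop("period weights must be positive", call. = FALSE)
  if (day$capacity_per_period <= 0 || day$consultation_time <= 0)
    stop("capacity and consultation time must be positive", call. = FALSE)
  invisible(day)
}

default_periods <- function() {
  data.frame(k = 1:3,
             start = c(450, 570, 690),   # 7:30, 9:30, 11:30
             end   = c(570, 690, 810),   # 9:30, 11:30, 13:30
             n_booked = 0L, n_preallocated = 0L, n_walkin_expected = 0,
             weight = c(3, 2, 1))
}

#' @export
print.day_schedule <- function(x, ...) {
  cat(sprintf("<day_schedule> K=%d periods, ct=%g min, r=%g min\n",
              nrow(x$periods), x$capacity_per_period, x$consultation_time))
  p <- x$periods
  for (i in seq_len(nrow(p)))
    cat(sprintf("  k=%d %s-%s booked=%d preallocated=%d walkins=%g w=%g\n",
                p$k[i], clock(p$start[i]), clock(p$end[i]), p$n_booked[i],
                p$n_preallocated[i], p$n_walkin_expected[i], p$weight[i]))
  cat(sprintf("  total slots: %g (expected workload %.0f min vs capacity %g min)\n",
              sum(p$n_booked + p$n_preallocated + p$n_walkin_expected),
              sum(p$n_booked + p$n_preallocated + p$n_walkin_expected) *
                x$consultation_time,
              x$capacity_per_period * nrow(p)))
  invisible(x)
}

#' Format clock minutes as HH:MM
#' @param t Minutes from midnight.
#' @return Character vector like "07:30".
#' @export
clock <- function(t) sprintf("%02d:%02d", floor(t / 60) %% 24, round(t) %% 60)

#' Donor-behaviour parameters
#'
#' @param pfill Probability a pre-allocated slot is actually booked
#'   (default 0.9).
#' @param pns No-show probability of a booked donor (default 0.05).
#' @return Object of class `behaviour_params`.
#' @export
behaviour_params <- function(pfill = 0.9, pns = 0.05) {
  if (pfill < 0 || pfill > 1 || pns < 0 || pns > 1)
    stop("pfill and pns must lie in [0, 1]", call. = FALSE)
  structure(list(pfill = pfill, pns = pns), class = "behaviour_params")
}

#' Generate a synthetic scheduler day
#'
#' Stands in for the (unpublished) output of the upstream appointment
#' scheduler. In `calibrated` mode each period's expected consultation
#' workload is matched to the nominal physician capacity:
#' `(n_booked + pfill * n_preallocated + n_walkin_expected) * r ~= ct_k`,
#' i.e. about 22.5 expected consultations per period at the defaults. The
#' composition (booked vs pre-allocated vs walk-in) is drawn at random
#' around realistic shares; `load` scales the workload of each period
#' relative to capacity, so e.g. `load = c(0.9, 1, 1.2)` produces a day
#' whose last period is overloaded.
#'
#' @param load Per-period workload as a fraction of nominal capacity
#'   (recycled to the number of periods; default 1 = calibrated).
#' @param behaviour A [behaviour_params()] (its `pfill` enters the
#'   calibration).
#' @param walkin_share,prealloc_share Expected share of walk-in donors
#'   among arrivals, and of pre-allocated slots among booked-type slots.
#' @param periods Template period table (defaults to 3 x 2h, 7:30-13:30,
#'   weights 3, 2, 1).
#' @param capacity_per_period,consultation_time See [day_schedule()].
#' @return A `day_schedule`.
#' @export
synth_day <- function(load = 1,
                      behaviour = behaviour_params(),
                      walkin_share = 0.2,
                      prealloc_share = 0.3,
                      periods = default_periods(),
                      capacity_per_period = 450,
                      consultation_time = 20) {
  K <- nrow(periods)
  load <- rep_len(load, K)
  if (any(load < 0)) stop("load must be non-negative", call. = FALSE)
  for (i in seq_len(K)) {
    target <- load[i] * capacity_per_period / consultation_time  # expected consults
    # jitter the composition so different seeds give different mixes
    ws <- max(0, min(1, walkin_share * stats::runif(1, 0.8, 1.2)))
    ps <- max(0, min(1, prealloc_share * stats::runif(1, 0.8, 1.2)))
    n_walk <- round(target * ws)
    booked_target <- target - n_walk          # booked-equivalent consults
    n_pre <- round(booked_target * ps / max(behaviour$pfill, 1e-9))
    n_booked <- max(0, round(booked_target - n_pre * behaviour$pfill))
    periods$n_booked[i] <- as.integer(n_booked)
    periods$n_preallocated[i] <- as.integer(n_pre)
    periods$n_walkin_expected[i] <- n_walk
  }
  day_schedule(periods, capacity_per_period, consultation_time)
}

#' Synthetic stand-in for the observed baseline scheduler day
#'
#' The real scheduler solution feeding the motivating centre is not
#' public, but its operating point is: the pre-feedback per-period used
#' physician capacity averaged about 368, 364 and 364 minutes of the
#' 450-minute nominal capacity, i.e. roughly 81% loading — which is what
#' yields the observed ~70% physician saturation, queue times around
#' 7 minutes and last consultation exits shortly after each period.
#' `baseline_day()` generates a synthetic day whose per-period expected
#' consultation workload is calibrated to those levels
#' (`load = c(0.82, 0.81, 0.81)`); this is the default day for
#' [run_plan()] and the packaged study scripts. Use [synth_day()]
#' directly for fully capacity-filled or custom loadings.
#'
#' @inheritParams synth_day
#' @return A [day_schedule()].
#' @export
baseline_day <- function(behaviour = behaviour_params()) {
  synth_day(load = c(0.82, 0.81, 0.81), behaviour = behaviour)
}

#' Realize stochastic donor arrivals for one day
#'
#' Each already-booked donor shows up unless a no-show is drawn
#' (probability `pns`); each pre-allocated slot first becomes booked with
#' probability `pfill` and is then subject to the same no-show draw.
#' Walk-ins arrive in deterministic count `round(n_walkin_expected)`.
#' Arrival instants are uniform within the donor's period. Uses the current
#' R random stream.
#'
#' @param day A [day_schedule()].
#' @param behaviour A [behaviour_params()].
#' @return A data.frame of arrivals sorted by arrival time with columns
#'   `donor_id` (encodes type, period and slot), `type`
#'   (`"booked"`/`"unbooked"`), `arrival` (clock minutes) and `period`.
#' @export
realize_arrivals <- function(day, behaviour = behaviour_params()) {
  validate_day_schedule(day)
  p <- day$periods
  out <- vector("list", nrow(p))
  for (i in seq_len(nrow(p))) {
    ids <- character(0); types <- character(0)
    if (p$n_booked[i] > 0) {
      show <- !bernoulli_vec(behaviour$pns, p$n_booked[i])
      idx <- which(show)
      ids <- c(ids, sprintf("B%d-%02d", p$k[i], idx))
      types <- c(types, rep("booked", length(idx)))
    }
    if (p$n_preallocated[i] > 0) {
      filled <- bernoulli_vec(behaviour$pfill, p$n_preallocated[i])
      show <- filled & !bernoulli_vec(behaviour$pns, p$n_preallocated[i])
      idx <- which(show)
      ids <- c(ids, sprintf("P%d-%02d", p$k[i], idx))
      types <- c(types, rep("booked", length(idx)))
    }
    n_walk <- round(p$n_walkin_expected[i])
    if (n_walk > 0) {
      ids <- c(ids, sprintf("U%d-%02d", p$k[i], seq_len(n_walk)))
      types <- c(types, rep("unbooked", n_walk))
    }
    arr <- stats::runif(length(ids), p$start[i], p$end[i])
    out[[i]] <- data.frame(donor_id = ids, type = types, arrival = arr,
                           period = rep(p$k[i], length(ids)),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$arrival, res$donor_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# vectorised gate sharing the package RNG conventions
bernoulli_vec <- function(p, n) if (n > 0) stats::runif(n) < p else logical(0)

#' Read or write a day schedule as YAML
#'
#' The file holds day-level `capacity_per_period` and `consultation_time`
#' (defaults 450 and 20 applied when absent) plus one record per period
#' with `k`, `start`, `end`, `n_booked`, `n_preallocated`,
#' `n_walkin_expected` and `weight`. Writing then reading returns an equal
#' schedule.
#'
#' @param path File path.
#' @param day A `day_schedule`.
#' @return `read_day_schedule()` returns a `day_schedule`;
#'   `write_day_schedule()` returns `path` invisibly.
#' @export
read_day_schedule <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$periods))
    stop("schedule file is missing the 'periods' list", call. = FALSE)
  need <- c("k", "start", "end", "n_booked", "n_preallocated",
            "n_walkin_expected", "weight")
  rows <- lapply(raw$periods, function(pr) {
    miss <- setdiff(need, names(pr))
    if (length(miss))
      stop("schedule period record is missing field(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    data.frame(k = as.integer(pr$k), start = as.numeric(pr$start),
               end = as.numeric(pr$end), n_booked = as.integer(pr$n_booked),
               n_preallocated = as.integer(pr$n_preallocated),
               n_walkin_expected = as.numeric(pr$n_walkin_expected),
               weight = as.numeric(pr$weight))
  })
  day_schedule(do.call(rbind, rows),
               capacity_per_period =
                 if (is.null(raw$capacity_per_period)) 450
                 else as.numeric(raw$capacity_per_period),
               consultation_time =
                 if (is.null(raw$consultation_time)) 20
                 else as.numeric(raw$consultation_time))
}

#' @rdname read_day_schedule
#' @export
write_day_schedule <- function(day, path) {
  validate_day_schedule(day)
  p <- day$periods
  yaml::write_yaml(list(
    capacity_per_period = day$capacity_per_period,
    consultation_time = day$consultation_time,
    periods = lapply(seq_len(nrow(p)), function(i) list(
      k = p$k[i], start = p$start[i], end = p$end[i],
      n_booked = p$n_booked[i], n_preallocated = p$n_preallocated[i],
      n_walkin_expected = p$n_walkin_expected[i], weight = p$weight[i]))),
    path)
  invisible(path)
}
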