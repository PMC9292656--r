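#' Re-calibrated standard consultation time for a layout
#'
#' When haemoglobin testing leaves the consultation room (placements
#' `"A"` and `"B"`), the physician's slot no longer contains the
#' haemoglobin measurement, so the scheduler's standard consultation time
#' should drop from 20 min to 18.33 min — the modal value of the
#' consultation-only triangular distribution, used by the upstream
#' scheduler as its nominal per-consultation time.
#'
#' @param layout A [layout_config()].
#' @return 18.33 for placements A/B, 20 for W (minutes).
#' @export
recalibrate_consultation_time <- function(layout) {
  if (layout$hb_placement %in% c("A", "B")) 18.33 else 20
}

#' Reverse the period queue-penalty weights
#'
#' Applying the original weights in inverse order penalizes queue
#' formation more in the last period and less in the first, pushing the
#' scheduler to fill the under-used first period.
#'
#' @param w Numeric weight vector of length K.
#' @return `rev(w)`.
#' @export
reverse_weights <- function(w) rev(w)

#' Feedback adjustment for a revised scheduling day
#'
#' @param consultation_time Revised standard consultation time r' in
#'   minutes (from [recalibrate_consultation_time()]).
#' @param weights Revised (typically reversed) period weights; `NULL`
#'   keeps the day's weights.
#' @return Object of class `feedback_adjustment`.
#' @export
feedback_adjustment <- function(consultation_time = 20, weights = NULL) {
  if (consultation_time <= 0)
    stop("consultation_time must be positive", call. = FALSE)
  structure(list(consultation_time = consultation_time, weights = weights),
            class = "feedback_adjustment")
}

# apportion per-period totals t_k across donor categories so that the
# column sums equal the original category totals exactly: proportional
# real-valued targets, floored, leftovers placed by largest remainder
# subject to spare row capacity
apportion_categories <- function(t_k, cat_totals) {
  K <- length(t_k); C <- length(cat_totals)
  N <- sum(t_k)
  m <- outer(t_k, cat_totals) / max(N, 1)   # K x C proportional targets
  a <- floor(m)
  # fix column sums
  for (j in seq_len(C)) {
    deficit <- cat_totals[j] - sum(a[, j])
    while (deficit > 0) {
      room <- t_k - rowSums(a)
      frac <- m[, j] - a[, j]
      frac[room <= 0] <- -Inf
      i <- which.max(frac)
      a[i, j] <- a[i, j] + 1L
      deficit <- deficit - 1L
    }
    while (deficit < 0) {
      i <- which.max(a[, j] - m[, j])
      a[i, j] <- a[i, j] - 1L
      deficit <- deficit + 1L
    }
  }
  a
}

# integer vector summing to N, proportional to target (largest remainder)
largest_remainder <- function(target, N) {
  t_int <- floor(target)
  left <- N - sum(t_int)
  if (left > 0) {
    ord <- order(target - t_int, decreasing = TRUE)
    t_int[ord[seq_len(left)]] <- t_int[ord[seq_len(left)]] + 1L
  }
  as.integer(t_int)
}

#' Rebalance a day under a feedback adjustment
#'
#' A simplified surrogate for re-running the upstream appointment
#' scheduler. Donors are re-allocated across periods in three steps:
#' (i) each period's target is its current allocation re-weighted by the
#' penalty ratio `w_old_k / w_new_k` and renormalized, so a period whose
#' queue penalty shrank attracts donors (reversing decreasing weights
#' shifts workload from the last period toward the first); (ii) targets
#' are rounded to integers conserving the daily total exactly, then
#' clipped at each period's capacity in donor units (`ct_k / r'`), excess
#' moving to the earliest period with slack; (iii) the per-period totals
#' are apportioned across booked / pre-allocated / walk-in slots so every
#' category total is conserved exactly. An adjustment that changes
#' neither weights nor consultation time is a no-op, and the operation is
#' idempotent. Only the direction of the resulting effects is meaningful;
#' the surrogate does not reproduce the true scheduler's solutions.
#'
#' @param day A [day_schedule()].
#' @param adjustment A [feedback_adjustment()].
#' @return A revised `day_schedule` carrying the new consultation time and
#'   weights. If the total workload exceeds the day's total capacity the
#'   day is returned unmodified with a warning.
#' @export
rebalance_day <- function(day, adjustment) {
  validate_day_schedule(day)
  stopifnot(inherits(adjustment, "feedback_adjustment"))
  p <- day$periods
  K <- nrow(p)
  w_new <- if (is.null(adjustment$weights)) p$weight else adjustment$weights
  if (length(w_new) != K)
    stop("adjustment weights must have one entry per period", call. = FALSE)
  if (any(w_new <= 0)) stop("weights must be positive", call. = FALSE)
  r_new <- adjustment$consultation_time
  cat_totals <- c(booked = sum(p$n_booked),
                  preallocated = sum(p$n_preallocated),
                  walkin = sum(round(p$n_walkin_expected)))
  N <- sum(cat_totals)
  cap_int <- floor(day$capacity_per_period / r_new + 1e-9)
  if (N > cap_int * K) {
    warning("total workload exceeds total capacity; day returned unmodified")
    return(day)
  }
  n_cur <- p$n_booked + p$n_preallocated + round(p$n_walkin_expected)
  ratio <- p$weight / w_new
  target <- if (sum(n_cur * ratio) > 0) N * n_cur * ratio / sum(n_cur * ratio)
            else rep(N / K, K)
  t_k <- largest_remainder(target, N)
  # clip at capacity; excess flows to the earliest period with slack
  for (i in order(t_k - cap_int, decreasing = TRUE)) {
    excess <- t_k[i] - cap_int
    if (excess <= 0) next
    t_k[i] <- cap_int
    for (j in seq_len(K)) {
      if (excess == 0) break
      slack <- cap_int - t_k[j]
      take <- min(slack, excess)
      t_k[j] <- t_k[j] + take
      excess <- excess - take
    }
  }
  a <- apportion_categories(t_k, cat_totals)
  p$n_booked <- as.integer(a[, 1])
  p$n_preallocated <- as.integer(a[, 2])
  p$n_walkin_expected <- as.numeric(a[, 3])
  p$weight <- w_new
  day_schedule(p, day$capacity_per_period, r_new)
}

#' Compare KPI results before and after feedback
#'
#' Builds the side-by-side min/avg/max table of every KPI for each layout,
#' pre- versus post-feedback. Both result sets must cover the same
#' layouts with the same replication count (and should share replication
#' seeds, so differences are attributable to the revised day alone).
#'
#' @param results_pre,results_post [run_plan()] data.frames.
#' @return data.frame with columns `layout`, `kpi`, `phase`
#'   (`pre`/`post`), `min`, `avg`, `max` — across replications of the
#'   day-level statistic.
#' @export
compare_pre_post <- function(results_pre, results_post) {
  if (!setequal(unique(results_pre$layout), unique(results_post$layout)))
    stop("pre and post results cover different layouts", call. = FALSE)
  if (nrow(results_pre) != nrow(results_post))
    stop("pre and post results have different replication counts",
         call. = FALSE)
  kpis <- anova_kpi_columns()
  one <- function(results, phase) {
    sp <- split(results, results$layout)
    do.call(rbind, lapply(sp, function(g) {
      do.call(rbind, lapply(names(kpis), function(lab) {
        x <- g[[kpis[[lab]]]]
        data.frame(layout = g$layout[1], kpi = lab, phase = phase,
                   min = min(x), avg = mean(x), max = max(x),
                   stringsAsFactors = FALSE)
      }))
    }))
  }
  out <- rbind(one(results_pre, "pre"), one(results_post, "post"))
  out <- out[order(out$layout, out$kpi, out$phase, decreasing = c(FALSE, FALSE, TRUE),
                   method = "radix"), ]
  rownames(out) <- NULL
  out
}
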