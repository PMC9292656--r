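mmx <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(c(min = NA_real_, avg = NA_real_, max = NA_real_))
  c(min = min(x), avg = mean(x), max = max(x))
}

# total busy minutes clipped to the opening window
busy_minutes <- function(busy, resource, open, close) {
  b <- busy[busy$resource == resource, , drop = FALSE]
  if (!nrow(b)) return(0)
  sum(pmax(0, pmin(b$end, close) - pmax(b$start, open)))
}

#' Cycle- and queue-time statistics of one day
#'
#' Cycle time is arrival-to-exit, refreshment included; queue time is the
#' sum of every waiting interval on the donor's path (registration,
#' haemoglobin station, consultation, bed-and-nurse, and the wait to be
#' disconnected after phlebotomy). Deferred donors are excluded from
#' cycle-time statistics (their day ends early by design); queue times
#' cover all arrivals. Empty strata yield `NA`, not zero.
#'
#' @param log An [run_day()] event log.
#' @return A data.frame with rows `cycle`, `cycle_booked`,
#'   `cycle_unbooked`, `queue`, `queue_booked`, `queue_unbooked` and
#'   columns `min`, `avg`, `max` (minutes).
#' @export
cycle_and_queue_times <- function(log) {
  d <- log$donors
  comp <- d$outcome == "completed"
  bk <- d$type == "booked"
  out <- rbind(
    cycle          = mmx(d$cycle_time[comp]),
    cycle_booked   = mmx(d$cycle_time[comp & bk]),
    cycle_unbooked = mmx(d$cycle_time[comp & !bk]),
    queue          = mmx(d$queue_time),
    queue_booked   = mmx(d$queue_time[bk]),
    queue_unbooked = mmx(d$queue_time[!bk]))
  as.data.frame(out)
}

#' Resource utilization of one day
#'
#' Busy minutes within opening hours divided by scheduled availability:
#' physicians are scheduled for the nominal capacity (450 min per period,
#' 1350 min per default day); clerks, donation-room nurses and beds are
#' present from the start of the first period to closure (360 min each);
#' the dedicated haemoglobin-station nurse (placements A/B) likewise.
#'
#' @param log An [run_day()] event log.
#' @param capacity_per_period Nominal physician-minutes per period.
#' @return Named vector of fractions: `physician`, `nurse`, `clerk`,
#'   `bed`, and `hb_nurse` (`NA` under placement W).
#' @export
utilization <- function(log, capacity_per_period = 450) {
  open <- log$periods$start[1]
  close <- log$periods$end[nrow(log$periods)]
  span <- close - open
  lay <- log$layout
  c(physician = busy_minutes(log$busy, "physician", open, close) /
      (capacity_per_period * nrow(log$periods)),
    nurse = busy_minutes(log$busy, "nurse", open, close) /
      (lay$n_nurses * span),
    clerk = busy_minutes(log$busy, "clerk", open, close) /
      (lay$n_clerks * span),
    bed = busy_minutes(log$busy, "bed", open, close) / (lay$n_beds * span),
    hb_nurse = if (lay$hb_placement == "W") NA_real_
               else busy_minutes(log$busy, "hb_nurse", open, close) / span)
}

#' Per-period used physician capacity and last consultation exit
#'
#' Used capacity of period `k` is the physician time actually delivered to
#' donors attributed to `k`; the last exit is the latest consultation end
#' among those donors. Attribution is by the donor's arrival period by
#' default (the quantity tracks the scheduler's period loading), or by the
#' period in which the consultation started.
#'
#' @param log An [run_day()] event log.
#' @param attribution `"arrival"` or `"service"`.
#' @return data.frame with columns `k`, `used_capacity` (minutes; 0 when
#'   no consultations) and `last_exit` (clock minutes; `NA` when none).
#' @export
period_capacity_and_last_exit <- function(log,
                                          attribution = c("arrival", "service")) {
  attribution <- match.arg(attribution)
  d <- log$donors
  p <- log$periods
  seen <- !is.na(d$cons_start)
  if (attribution == "arrival") {
    per <- d$period
  } else {
    per <- rep(NA_integer_, nrow(d))
    for (i in seq_len(nrow(p)))
      per[seen & d$cons_start >= p$start[i] & d$cons_start < p$end[i]] <- p$k[i]
    # consultations starting after closing belong to the last period
    per[seen & d$cons_start >= p$end[nrow(p)]] <- p$k[nrow(p)]
  }
  dur <- d$cons_end - d$cons_start
  out <- data.frame(k = p$k, used_capacity = 0, last_exit = NA_real_)
  for (i in seq_len(nrow(p))) {
    sel <- seen & per == p$k[i]
    out$used_capacity[i] <- sum(dur[sel], na.rm = TRUE)
    if (any(sel, na.rm = TRUE))
      out$last_exit[i] <- max(d$cons_end[sel], na.rm = TRUE)
  }
  out
}

#' Full KPI report for one simulated day
#'
#' Bundles every indicator tracked for the three stakeholder groups:
#' donor cycle and queue times (overall and stratified by booked/walk-in),
#' resource utilizations, per-period used physician capacity and last
#' consultation exit, layout cost, and throughput rate (the inverse of the
#' mean cycle time).
#'
#' @param log An [run_day()] event log.
#' @param costs A [cost_model()].
#' @param capacity_per_period Nominal physician-minutes per period.
#' @param attribution Passed to [period_capacity_and_last_exit()].
#' @return Object of class `kpi_report`; [as.data.frame()] flattens it to
#'   one row (`cycle_avg`, `util_physician`, `cap_used_k1`, ...).
#' @export
kpi_report <- function(log, costs = cost_model(), capacity_per_period = 450,
                       attribution = "arrival") {
  times <- cycle_and_queue_times(log)
  util <- utilization(log, capacity_per_period)
  percap <- period_capacity_and_last_exit(log, attribution)
  d <- log$donors
  comp <- d$outcome == "completed"
  mean_cycle <- if (any(comp)) mean(d$cycle_time[comp]) else NA_real_
  structure(list(
    layout = layout_name(log$layout),
    times = times,
    utilization = util,
    period = percap,
    cost = layout_cost(log$layout, costs),
    throughput = 1 / mean_cycle,
    counts = c(arrivals = nrow(d), completed = sum(comp),
               deferred_hb = sum(d$outcome == "deferred_hb"),
               deferred_consultation = sum(d$outcome == "deferred_consultation"))),
    class = "kpi_report")
}

#' @export
as.data.frame.kpi_report <- function(x, ...) {
  tm <- x$times
  flat <- list(layout = x$layout)
  for (r in rownames(tm))
    for (cc in colnames(tm))
      flat[[paste(r, cc, sep = "_")]] <- tm[r, cc]
  for (nm in names(x$utilization))
    flat[[paste0("util_", nm)]] <- unname(x$utilization[nm])
  for (i in seq_len(nrow(x$period))) {
    flat[[paste0("cap_used_k", x$period$k[i])]] <- x$period$used_capacity[i]
    flat[[paste0("last_exit_k", x$period$k[i])]] <- x$period$last_exit[i]
  }
  flat$cost <- x$cost
  flat$throughput <- x$throughput
  for (nm in names(x$counts)) flat[[paste0("n_", nm)]] <- unname(x$counts[nm])
  as.data.frame(flat, stringsAsFactors = FALSE)
}

#' @export
print.kpi_report <- function(x, ...) {
  cat(sprintf("<kpi_report> %s  (cost %g CU, throughput %.4f donors/min)\n",
              x$layout, x$cost, x$throughput))
  tm <- x$times
  for (r in rownames(tm))
    cat(sprintf("  %-15s min %6.1f  avg %6.1f  max %6.1f\n", r,
                tm[r, "min"], tm[r, "avg"], tm[r, "max"]))
  u <- x$utilization
  cat("  utilization:", paste(sprintf("%s %.2f", names(u), u), collapse = ", "),
      "\n")
  for (i in seq_len(nrow(x$period)))
    cat(sprintf("  k=%d used capacity %5.1f min, last exit %s\n",
                x$period$k[i], x$period$used_capacity[i],
                if (is.na(x$period$last_exit[i])) "-"
                else clock(x$period$last_exit[i])))
  invisible(x)
}
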