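#' Physicians on duty at a clock instant
#'
#' The nominal per-period capacity of 450 physician-minutes over a
#' two-hour period corresponds to 3.75 physician-equivalents: three
#' physicians work the whole period and a fourth works 90 minutes, placed
#' at the start of each period (timetable 1) or at its end (timetable 2).
#'
#' @param timetable 1 or 2.
#' @param t Clock time, minutes from midnight (vectorised).
#' @param periods Period table with `start`/`end` columns (defaults to the
#'   three 7:30-13:30 periods).
#' @return Integer count of physicians on duty; 0 outside all periods
#'   (consultations already in progress still finish; see [run_day()] for
#'   how the queue drains after closing).
#' @export
physicians_on_duty <- function(timetable, t, periods = default_periods()) {
  vapply(t, function(tt) {
    i <- which(tt >= periods$start & tt < periods$end)
    if (!length(i)) return(0L)
    into <- tt - periods$start[i[1]]
    if (timetable == 1L) {
      if (into < 90) 4L else 3L
    } else {
      if (into < 30) 3L else 4L
    }
  }, integer(1))
}

# capacity the engine uses for starting consultations at time t:
# on-duty count within periods, and 3 after closing so the queue drains
# (the three full-period physicians work overtime until the last donor
# has been seen).
effective_physicians <- function(timetable, t, periods) {
  if (t >= periods$end[nrow(periods)]) return(3L)
  physicians_on_duty(timetable, t, periods)
}

#' Select the next donor from a consultation queue
#'
#' FIFO serves the earliest-enqueued donor; PRTY serves the
#' earliest-enqueued booked donor whenever any booked donor is waiting,
#' falling back to FIFO among unbooked donors. Ties on the enqueue instant
#' are broken by donor id.
#'
#' @param queue A data.frame with columns `donor_id`, `type`, `enqueued`.
#' @param policy `"FIFO"` or `"PRTY"`.
#' @return The selected `donor_id`.
#' @export
select_next <- function(queue, policy = c("FIFO", "PRTY")) {
  policy <- match.arg(policy)
  if (!nrow(queue)) stop("select_next called on an empty queue", call. = FALSE)
  cand <- if (policy == "PRTY" && any(queue$type == "booked"))
    queue[queue$type == "booked", , drop = FALSE] else queue
  cand$donor_id[order(cand$enqueued, cand$donor_id)][1]
}

#' Draw per-donor service times and deferral gates
#'
#' Fixes, per donor, one draw for every activity on the pathway plus the
#' two deferral gates (haemoglobin and consultation), using the current R
#' random stream in a layout-independent order. Pre-drawing is what makes
#' common random numbers exact across layouts: the same realized arrival
#' set carries identical service times and deferral outcomes into every
#' layout.
#'
#' @param arrivals Arrival table from [realize_arrivals()].
#' @param catalog A [process_time_catalog()].
#' @param rates A [deferral_rates()].
#' @return `arrivals` with added columns `t_reg`, `t_cons`, `t_hb`,
#'   `t_pre`, `t_phleb`, `t_post`, `t_rest`, `t_refresh` (minutes) and
#'   logical `defer_hb`, `defer_cons`.
#' @export
draw_donor_attributes <- function(arrivals,
                                  catalog = process_time_catalog(),
                                  rates = deferral_rates()) {
  n <- nrow(arrivals)
  booked <- arrivals$type == "booked"
  t_reg <- numeric(n)
  if (any(booked))
    t_reg[booked] <- sample_dist(catalog$registration_booked, sum(booked))
  if (any(!booked))
    t_reg[!booked] <- sample_dist(catalog$registration_unbooked, sum(!booked))
  arrivals$t_reg     <- t_reg
  arrivals$t_cons    <- sample_dist(catalog$consultation, n)
  arrivals$t_hb      <- sample_dist(catalog$haemoglobin, n)
  arrivals$t_pre     <- sample_dist(catalog$pre_setup, n)
  arrivals$t_phleb   <- sample_dist(catalog$phlebotomy, n)
  arrivals$t_post    <- sample_dist(catalog$post_setup, n)
  arrivals$t_rest    <- sample_dist(catalog$resting, n)
  arrivals$t_refresh <- sample_dist(catalog$refreshment, n)
  arrivals$defer_hb  <- stats::runif(n) < rates$p_hb
  p_cons <- ifelse(booked, rates$p_cons_booked, rates$p_cons_unbooked)
  arrivals$defer_cons <- stats::runif(n) < p_cons
  arrivals
}

# event type codes (processing priority at exactly equal times follows
# insertion order; codes exist for readability)
EV_CAPACITY <- 0L; EV_ARRIVAL <- 1L; EV_END_REG <- 2L; EV_END_HB <- 3L
EV_END_CONS <- 4L; EV_END_PRE <- 5L; EV_END_PHLEB <- 6L; EV_END_POST <- 7L
EV_END_REST <- 8L

#' Simulate one day of centre operations
#'
#' Runs the event-driven simulation of one day under a given layout:
#' donors arrive, register with a clerk (FIFO), pass the haemoglobin
#' station before or after consultation (placements `"B"`/`"A"`, one
#' dedicated nurse) or have haemoglobin measured within the consultation
#' (`"W"`), see a physician (FIFO or booked-priority queue), then occupy a
#' bed through pre-setup, phlebotomy, post-setup and rest, and finally take
#' an unconstrained refreshment. A nurse is held only for pre-setup and
#' post-setup; the bed is held from pre-setup until the donor leaves for
#' the canteen. When a nurse frees, donors waiting to be disconnected
#' (post-setup) are served before donors waiting for a bed. The simulation
#' runs until the last donor exits, past closing if needed: after the last
#' period the three full-period physicians keep consulting until the queue
#' is empty.
#'
#' @param layout A [layout_config()].
#' @param donors Arrival table; if the service-time columns of
#'   [draw_donor_attributes()] are absent they are drawn from `catalog`
#'   and `rates` using the current random stream.
#' @param catalog,rates Used only when draws are absent from `donors`.
#' @param periods Period table (defaults to three 2-h periods).
#' @return An object of class `event_log`: list with `donors` (one row per
#'   donor: timestamps, waits, outcome), `busy` (one row per resource busy
#'   interval), `layout`, `periods`.
#' @export
run_day <- function(layout, donors,
                    catalog = process_time_catalog(),
                    rates = deferral_rates(),
                    periods = default_periods()) {
  stopifnot(inherits(layout, "layout_config"))
  if (!"t_reg" %in% names(donors))
    donors <- draw_donor_attributes(donors, catalog, rates)
  n <- nrow(donors)
  hb <- layout$hb_placement
  close_t <- periods$end[nrow(periods)]

  arrival <- donors$arrival
  type_booked <- donors$type == "booked"
  t_reg <- donors$t_reg
  t_cons_service <- if (hb == "W") donors$t_cons + donors$t_hb else donors$t_cons
  t_hb <- donors$t_hb; t_pre <- donors$t_pre; t_phleb <- donors$t_phleb
  t_post <- donors$t_post; t_rest <- donors$t_rest
  t_refresh <- donors$t_refresh
  defer_hb <- donors$defer_hb; defer_cons <- donors$defer_cons

  na <- rep(NA_real_, n)
  reg_start <- na; reg_end <- na; hb_qenter <- na; hb_start <- na; hb_end <- na
  cons_qenter <- na; cons_start <- na; cons_end <- na
  bed_qenter <- na; pre_start <- na; phleb_start <- na; phleb_end <- na
  post_start <- na; post_end <- na; rest_end <- na; exit_t <- na
  outcome <- rep(NA_character_, n)
  bed_unit <- rep(NA_integer_, n)

  clerk_free <- rep(TRUE, layout$n_clerks)
  nurse_free <- rep(TRUE, layout$n_nurses)
  hb_free <- TRUE
  bed_free <- rep(TRUE, layout$n_beds)
  phys_free <- rep(TRUE, 4L)
  phys_busy <- 0L
  clerk_of <- rep(NA_integer_, n); nurse_of <- rep(NA_integer_, n)
  phys_of <- rep(NA_integer_, n)

  reg_q <- integer(0); hb_q <- integer(0); cons_q <- integer(0)
  bed_q <- integer(0); post_q <- integer(0)

  # busy-interval store
  cap0 <- max(16L, 8L * n)
  b_res <- character(cap0); b_unit <- integer(cap0); b_start <- numeric(cap0)
  b_end <- numeric(cap0); b_donor <- integer(cap0); b_act <- character(cap0)
  b_n <- 0L
  record_busy <- function(res, unit, s, e, d, act) {
    b_n <<- b_n + 1L
    if (b_n > length(b_res)) {
      grow <- function(v) { length(v) <- 2L * length(v); v }
      b_res <<- grow(b_res); b_unit <<- grow(b_unit); b_start <<- grow(b_start)
      b_end <<- grow(b_end); b_donor <<- grow(b_donor); b_act <<- grow(b_act)
    }
    b_res[b_n] <<- res; b_unit[b_n] <<- unit; b_start[b_n] <<- s
    b_end[b_n] <<- e; b_donor[b_n] <<- d; b_act[b_n] <<- act
  }

  # event calendar
  cap_ev <- max(32L, 4L * n)
  ev_time <- numeric(cap_ev); ev_type <- integer(cap_ev)
  ev_donor <- integer(cap_ev); ev_n <- 0L
  push <- function(t, type, d = 0L) {
    ev_n <<- ev_n + 1L
    if (ev_n > length(ev_time)) {
      length(ev_time) <- 2L * length(ev_time)
      length(ev_type) <- 2L * length(ev_type)
      length(ev_donor) <- 2L * length(ev_donor)
    }
    ev_time[ev_n] <<- t; ev_type[ev_n] <<- type; ev_donor[ev_n] <<- d
  }

  for (i in seq_len(n)) push(arrival[i], EV_ARRIVAL, i)
  # capacity-change instants (dispatch hooks where capacity can rise)
  for (i in seq_len(nrow(periods))) {
    push(periods$start[i], EV_CAPACITY)
    push(periods$start[i] + if (layout$physician_timetable == 1L) 90 else 30,
         EV_CAPACITY)
  }
  push(close_t, EV_CAPACITY)

  try_reg <- function(now) {
    while (length(reg_q) && any(clerk_free)) {
      d <- reg_q[1]; reg_q <<- reg_q[-1]
      u <- which.max(clerk_free); clerk_free[u] <<- FALSE
      clerk_of[d] <<- u
      reg_start[d] <<- now; reg_end[d] <<- now + t_reg[d]
      push(reg_end[d], EV_END_REG, d)
    }
  }
  try_hb <- function(now) {
    if (hb_free && length(hb_q)) {
      d <- hb_q[1]; hb_q <<- hb_q[-1]
      hb_free <<- FALSE
      hb_start[d] <<- now; hb_end[d] <<- now + t_hb[d]
      push(hb_end[d], EV_END_HB, d)
    }
  }
  pick_cons <- function() {
    if (layout$queue_policy == "PRTY") {
      bk <- cons_q[type_booked[cons_q]]
      if (length(bk)) return(bk[1])
    }
    cons_q[1]
  }
  try_cons <- function(now) {
    while (length(cons_q) &&
           phys_busy < effective_physicians(layout$physician_timetable, now,
                                            periods)) {
      d <- pick_cons()
      cons_q <<- cons_q[cons_q != d]
      on_duty4 <- now < close_t &&
        physicians_on_duty(layout$physician_timetable, now, periods) == 4L
      u <- which(phys_free & c(TRUE, TRUE, TRUE, on_duty4))[1]
      phys_free[u] <<- FALSE; phys_busy <<- phys_busy + 1L
      phys_of[d] <<- u
      cons_start[d] <<- now; cons_end[d] <<- now + t_cons_service[d]
      push(cons_end[d], EV_END_CONS, d)
    }
  }
  try_post <- function(now) {
    while (length(post_q) && any(nurse_free)) {
      d <- post_q[1]; post_q <<- post_q[-1]
      u <- which.max(nurse_free); nurse_free[u] <<- FALSE
      nurse_of[d] <<- u
      post_start[d] <<- now; post_end[d] <<- now + t_post[d]
      push(post_end[d], EV_END_POST, d)
    }
  }
  try_pre <- function(now) {
    while (length(bed_q) && any(nurse_free) && any(bed_free)) {
      d <- bed_q[1]; bed_q <<- bed_q[-1]
      u <- which.max(nurse_free); nurse_free[u] <<- FALSE
      bu <- which.max(bed_free); bed_free[bu] <<- FALSE
      nurse_of[d] <<- u; bed_unit[d] <<- bu
      pre_start[d] <<- now
      phleb_start[d] <<- now + t_pre[d]
      push(phleb_start[d], EV_END_PRE, d)
    }
  }
  defer_exit <- function(d, now, what) {
    outcome[d] <<- what; exit_t[d] <<- now
  }
  after_registration <- function(d, now) {
    if (hb == "B") { hb_qenter[d] <<- now; hb_q <<- c(hb_q, d); try_hb(now) }
    else { cons_qenter[d] <<- now; cons_q <<- c(cons_q, d); try_cons(now) }
  }
  to_donation <- function(d, now) {
    bed_qenter[d] <<- now; bed_q <<- c(bed_q, d); try_pre(now)
  }

  while (ev_n > 0L) {
    i <- which.min(ev_time[seq_len(ev_n)])
    now <- ev_time[i]; type <- ev_type[i]; d <- ev_donor[i]
    ev_time[i] <- ev_time[ev_n]; ev_type[i] <- ev_type[ev_n]
    ev_donor[i] <- ev_donor[ev_n]; ev_n <- ev_n - 1L

    if (type == EV_ARRIVAL) {
      reg_q <- c(reg_q, d); try_reg(now)
    } else if (type == EV_END_REG) {
      u <- clerk_of[d]; clerk_free[u] <- TRUE
      record_busy("clerk", u, reg_start[d], now, d, "registration")
      after_registration(d, now)
      try_reg(now)
    } else if (type == EV_END_HB) {
      hb_free <- TRUE
      record_busy("hb_nurse", 1L, hb_start[d], now, d, "haemoglobin")
      if (defer_hb[d]) defer_exit(d, now, "deferred_hb")
      else if (hb == "B") {
        cons_qenter[d] <- now; cons_q <- c(cons_q, d); try_cons(now)
      } else to_donation(d, now)          # placement A: donation next
      try_hb(now)
    } else if (type == EV_END_CONS) {
      u <- phys_of[d]; phys_free[u] <- TRUE; phys_busy <- phys_busy - 1L
      record_busy("physician", u, cons_start[d], now, d, "consultation")
      if (hb == "W" && defer_hb[d]) defer_exit(d, now, "deferred_hb")
      else if (defer_cons[d]) defer_exit(d, now, "deferred_consultation")
      else if (hb == "A") {
        hb_qenter[d] <- now; hb_q <- c(hb_q, d); try_hb(now)
      } else to_donation(d, now)
      try_cons(now)
    } else if (type == EV_END_PRE) {
      u <- nurse_of[d]; nurse_free[u] <- TRUE
      record_busy("nurse", u, pre_start[d], now, d, "pre_setup")
      push(now + t_phleb[d], EV_END_PHLEB, d)
      try_post(now); try_pre(now)
    } else if (type == EV_END_PHLEB) {
      phleb_end[d] <- now
      post_q <- c(post_q, d)
      try_post(now)
    } else if (type == EV_END_POST) {
      u <- nurse_of[d]; nurse_free[u] <- TRUE
      record_busy("nurse", u, post_start[d], now, d, "post_setup")
      push(now + t_rest[d], EV_END_REST, d)
      try_post(now); try_pre(now)
    } else if (type == EV_END_REST) {
      rest_end[d] <- now
      bu <- bed_unit[d]; bed_free[bu] <- TRUE
      record_busy("bed", bu, pre_start[d], now, d, "donation_bed")
      outcome[d] <- "completed"
      exit_t[d] <- now + t_refresh[d]
      try_pre(now)
    } else {                              # capacity change
      try_cons(now)
    }
  }

  zero_na <- function(x) ifelse(is.na(x), 0, x)
  wait_reg <- reg_start - arrival
  wait_hb <- zero_na(hb_start - hb_qenter)
  wait_cons <- zero_na(cons_start - cons_qenter)
  wait_bed <- zero_na(pre_start - bed_qenter)
  wait_post <- zero_na(post_start - phleb_end)
  queue_time <- wait_reg + wait_hb + wait_cons + wait_bed + wait_post

  log_donors <- data.frame(
    donor_id = donors$donor_id, type = donors$type, period = donors$period,
    arrival = arrival, reg_start = reg_start, reg_end = reg_end,
    hb_start = hb_start, hb_end = hb_end,
    cons_start = cons_start, cons_end = cons_end,
    pre_start = pre_start, phleb_start = phleb_start,
    phleb_end = phleb_end, post_start = post_start, post_end = post_end,
    rest_end = rest_end, exit = exit_t,
    outcome = outcome, queue_time = queue_time,
    wait_cons = wait_cons, wait_bed = wait_bed,
    cycle_time = exit_t - arrival,
    stringsAsFactors = FALSE)

  keep <- seq_len(b_n)
  busy <- data.frame(resource = b_res[keep], unit = b_unit[keep],
                     start = b_start[keep], end = b_end[keep],
                     donor = b_donor[keep], activity = b_act[keep],
                     stringsAsFactors = FALSE)

  structure(list(donors = log_donors, busy = busy, layout = layout,
                 periods = periods),
            class = "event_log")
}

#' @export
print.event_log <- function(x, ...) {
  d <- x$donors
  cat(sprintf("<event_log> %s: %d donors (%d completed, %d deferred)\n",
              layout_name(x$layout), nrow(d),
              sum(d$outcome == "completed"),
              sum(d$outcome != "completed")))
  if (nrow(d))
    cat(sprintf("  last exit %s; mean cycle time %.1f min\n",
                clock(max(d$exit)),
                mean(d$cycle_time[d$outcome == "completed"])))
  invisible(x)
}

#' Export an event log as flat tables
#'
#' Writes two tab-separated files (`<stem>_donors.tsv`,
#' `<stem>_busy.tsv`) so KPIs can be verified outside the package.
#'
#' @param log An [run_day()] event log.
#' @param stem Output path stem.
#' @return The two paths, invisibly.
#' @export
write_event_log <- function(log, stem) {
  p1 <- paste0(stem, "_donors.tsv"); p2 <- paste0(stem, "_busy.tsv")
  utils::write.table(log$donors, p1, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(log$busy, p2, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(p1, p2))
}
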