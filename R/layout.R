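#' Centre layout configuration
#'
#' One of the 144 experimental layouts: consultation queue discipline,
#' placement of the fourth physician's 90-minute stint, placement of the
#' haemoglobin test, and resource counts.
#'
#' @param queue_policy `"FIFO"` (all donors equal) or `"PRTY"` (booked
#'   donors called before any waiting unbooked donor at the consultation
#'   queue only).
#' @param physician_timetable `1` = the fourth physician works the first
#'   90 minutes of each period, `2` = the last 90 minutes.
#' @param hb_placement `"W"` = haemoglobin measured within the
#'   consultation, `"A"` = at a separate station after it, `"B"` = before
#'   it. Under `"A"`/`"B"` the station is staffed by one additional
#'   dedicated nurse, not drawn from the donation-room pool.
#' @param n_nurses Donation-room nurses, 2 or 3.
#' @param n_clerks Registration clerks, 1 or 2.
#' @param n_beds Donation beds, 5, 6 or 7.
#' @return Object of class `layout_config`; its `name` follows the
#'   policy-timetable-hb-resourceCode convention, e.g. `"FIFO-1-W-01"`.
#' @export
layout_config <- function(queue_policy = c("FIFO", "PRTY"),
                          physician_timetable = 1L,
                          hb_placement = c("W", "A", "B"),
                          n_nurses = 2L, n_clerks = 1L, n_beds = 5L) {
  queue_policy <- match.arg(queue_policy)
  hb_placement <- match.arg(hb_placement)
  if (!physician_timetable %in% c(1L, 2L))
    stop("physician_timetable must be 1 or 2", call. = FALSE)
  if (!n_nurses %in% 2:3) stop("n_nurses must be 2 or 3", call. = FALSE)
  if (!n_clerks %in% 1:2) stop("n_clerks must be 1 or 2", call. = FALSE)
  if (!n_beds %in% 5:7) stop("n_beds must be 5, 6 or 7", call. = FALSE)
  structure(list(queue_policy = queue_policy,
                 physician_timetable = as.integer(physician_timetable),
                 hb_placement = hb_placement,
                 n_nurses = as.integer(n_nurses),
                 n_clerks = as.integer(n_clerks),
                 n_beds = as.integer(n_beds)),
            class = "layout_config")
}

# resource combinations in experiment-table order: code 01..12
resource_codes <- function() {
  data.frame(code = sprintf("%02d", 1:12),
             n_nurses = rep(2:3, each = 6),
             n_clerks = rep(rep(1:2, each = 3), 2),
             n_beds = rep(5:7, 4))
}

#' Name of a layout configuration
#' @param layout A [layout_config()].
#' @return String like `"PRTY-2-B-10"`.
#' @export
layout_name <- function(layout) {
  rc <- resource_codes()
  code <- rc$code[rc$n_nurses == layout$n_nurses &
                  rc$n_clerks == layout$n_clerks &
                  rc$n_beds == layout$n_beds]
  sprintf("%s-%d-%s-%s", layout$queue_policy, layout$physician_timetable,
          layout$hb_placement, code)
}

#' Parse a layout name back into a configuration
#' @param name String like `"FIFO-1-W-01"`.
#' @return A [layout_config()].
#' @export
parse_layout_name <- function(name) {
  parts <- strsplit(name, "-", fixed = TRUE)[[1]]
  if (length(parts) != 4L) stop("malformed layout name: ", name, call. = FALSE)
  rc <- resource_codes()
  i <- match(parts[4], rc$code)
  if (is.na(i)) stop("unknown resource code: ", parts[4], call. = FALSE)
  layout_config(parts[1], as.integer(parts[2]), parts[3],
                rc$n_nurses[i], rc$n_clerks[i], rc$n_beds[i])
}

#' @export
print.layout_config <- function(x, ...) {
  cat(sprintf("<layout_config> %s (%s queue, 4th physician %s, hb %s, %d nurses, %d clerks, %d beds)\n",
              layout_name(x), x$queue_policy,
              if (x$physician_timetable == 1L) "first 90 min" else "last 90 min",
              switch(x$hb_placement, W = "within consultation",
                     A = "after consultation", B = "before consultation"),
              x$n_nurses, x$n_clerks, x$n_beds))
  invisible(x)
}

#' Enumerate the full factorial set of layouts
#'
#' Cross product of queue policy (2) x physician timetable (2) x
#' haemoglobin placement (3) x resource combination (12) = 144 layouts, in
#' deterministic order.
#'
#' @return A list of 144 [layout_config()] objects, named by
#'   [layout_name()].
#' @export
enumerate_layouts <- function() {
  rc <- resource_codes()
  out <- list()
  for (qp in c("FIFO", "PRTY"))
    for (tt in 1:2)
      for (hb in c("W", "A", "B"))
        for (i in seq_len(nrow(rc)))
          out[[length(out) + 1L]] <-
            layout_config(qp, tt, hb, rc$n_nurses[i], rc$n_clerks[i],
                          rc$n_beds[i])
  names(out) <- vapply(out, layout_name, character(1))
  out
}

#' Deferral probabilities at the clinical gates
#'
#' Defaults reproduce total acceptance rates of 99% (booked) and 95%
#' (unbooked): walk-ins are deferred at the consultation about nine times
#' as often as booked donors, who are pre-screened when they reserve.
#'
#' @param p_cons_booked Consultation deferral probability, booked donors.
#' @param p_cons_unbooked Consultation deferral probability, walk-ins.
#' @param p_hb Haemoglobin-test deferral probability (both types).
#' @return Object of class `deferral_rates`.
#' @export
deferral_rates <- function(p_cons_booked = 5.03e-3,
                           p_cons_unbooked = 4.523e-2,
                           p_hb = 5e-3) {
  ps <- c(p_cons_booked, p_cons_unbooked, p_hb)
  if (any(ps < 0 | ps > 1)) stop("rates must lie in [0, 1]", call. = FALSE)
  structure(list(p_cons_booked = p_cons_booked,
                 p_cons_unbooked = p_cons_unbooked, p_hb = p_hb),
            class = "deferral_rates")
}

#' Overall acceptance probability by donor type
#'
#' Product of passing the haemoglobin gate and the consultation gate.
#'
#' @param rates A [deferral_rates()].
#' @return Named vector `c(booked = , unbooked = )` of acceptance
#'   probabilities.
#' @export
acceptance_rates <- function(rates = deferral_rates()) {
  c(booked = (1 - rates$p_cons_booked) * (1 - rates$p_hb),
    unbooked = (1 - rates$p_cons_unbooked) * (1 - rates$p_hb))
}

#' Variable-resource cost model
#'
#' Daily salaries/costs in non-monetary cost units (CU; about 20 euros in
#' the motivating case). Physicians and structural costs are fixed across
#' layouts and excluded.
#'
#' @param clerk,nurse,bed CU per workday for each resource unit.
#' @return Object of class `cost_model`.
#' @export
cost_model <- function(clerk = 5, nurse = 10, bed = 1) {
  if (any(c(clerk, nurse, bed) < 0)) stop("costs must be >= 0", call. = FALSE)
  structure(list(clerk = clerk, nurse = nurse, bed = bed),
            class = "cost_model")
}

#' Daily variable cost of a layout
#'
#' `n_clerks * clerk + n_nurses * nurse + n_beds * bed`, plus one extra
#' nurse salary when the haemoglobin station is separate (placements
#' `"A"`/`"B"`), since that station is staffed by a dedicated nurse.
#'
#' @param layout A [layout_config()].
#' @param costs A [cost_model()].
#' @return Cost in CU per workday.
#' @export
layout_cost <- function(layout, costs = cost_model()) {
  layout$n_clerks * costs$clerk + layout$n_nurses * costs$nurse +
    layout$n_beds * costs$bed +
    if (layout$hb_placement %in% c("A", "B")) costs$nurse else 0
}
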