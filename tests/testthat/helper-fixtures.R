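# Degenerate (point-mass) service times used by the hand-trace oracles.
# Triangular with a == b == c is a point mass in every family-invariant
# sense, so the whole catalogue can be made deterministic.
point_mass <- function(x) dist_spec("triangular", x, x, x)

degenerate_catalog <- function() {
  process_time_catalog(
    registration_booked   = point_mass(1.77),
    registration_unbooked = point_mass(1.77),
    consultation          = point_mass(18.33),
    haemoglobin           = point_mass(1.67),
    pre_setup             = point_mass(1.6),
    phlebotomy            = point_mass(13.26),
    post_setup            = point_mass(1.5),
    resting               = point_mass(5),
    refreshment           = point_mass(14.22))
}

no_deferrals <- function() deferral_rates(0, 0, 0)

# build an arrival table with fully deterministic attributes attached,
# bypassing the random stream; `hb = 0` lets a trace drop the haemoglobin
# component entirely
manual_donors <- function(arrivals, reg = 1.77, cons = 18.33, hb = 1.67,
                          pre = 1.6, phleb = 13.26, post = 1.5, rest = 5,
                          refresh = 14.22,
                          defer_hb = FALSE, defer_cons = FALSE) {
  n <- nrow(arrivals)
  arrivals$t_reg <- rep_len(reg, n)
  arrivals$t_cons <- rep_len(cons, n)
  arrivals$t_hb <- rep_len(hb, n)
  arrivals$t_pre <- rep_len(pre, n)
  arrivals$t_phleb <- rep_len(phleb, n)
  arrivals$t_post <- rep_len(post, n)
  arrivals$t_rest <- rep_len(rest, n)
  arrivals$t_refresh <- rep_len(refresh, n)
  arrivals$defer_hb <- rep_len(defer_hb, n)
  arrivals$defer_cons <- rep_len(defer_cons, n)
  arrivals
}

make_arrivals <- function(times, types = "booked", period = 1L) {
  n <- length(times)
  data.frame(donor_id = sprintf("D%02d", seq_len(n)),
             type = rep_len(types, n),
             arrival = times,
             period = rep_len(period, n),
             stringsAsFactors = FALSE)
}

# layout with arbitrary resource counts (outside the factorial levels),
# for capacity-saturation and ample-resource oracles
layout_unchecked <- function(queue_policy = "FIFO", physician_timetable = 1L,
                             hb_placement = "W", n_nurses = 99L,
                             n_clerks = 99L, n_beds = 99L) {
  structure(list(queue_policy = queue_policy,
                 physician_timetable = as.integer(physician_timetable),
                 hb_placement = hb_placement,
                 n_nurses = as.integer(n_nurses),
                 n_clerks = as.integer(n_clerks),
                 n_beds = as.integer(n_beds)),
            class = "layout_config")
}

# small explicit day: equal counts per period
explicit_day <- function(n_booked = 10L, n_preallocated = 5L, n_walkin = 4,
                         weights = c(3, 2, 1), r = 20, ct = 450) {
  p <- data.frame(k = 1:3,
                  start = c(450, 570, 690), end = c(570, 690, 810),
                  n_booked = n_booked, n_preallocated = n_preallocated,
                  n_walkin_expected = n_walkin, weight = weights)
  day_schedule(p, ct, r)
}

# independent capacity audit: at every interval boundary, count
# simultaneously busy units of a resource from the busy table
max_concurrency <- function(busy, resource) {
  b <- busy[busy$resource == resource, , drop = FALSE]
  if (!nrow(b)) return(0L)
  max(vapply(seq_len(nrow(b)), function(i) {
    t0 <- b$start[i]
    sum(b$start <= t0 & b$end > t0)
  }, integer(1)))
}
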