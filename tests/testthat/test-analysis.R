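# balanced synthetic response table over the full factorial, for
# calibration tests that need no simulation
synthetic_design <- function(replications = 5) {
  lays <- enumerate_layouts()
  fac <- do.call(rbind, lapply(lays, function(l)
    data.frame(layout = layout_name(l), queue_policy = l$queue_policy,
               physician_timetable = l$physician_timetable,
               hb_placement = l$hb_placement, n_nurses = l$n_nurses,
               n_clerks = l$n_clerks, n_beds = l$n_beds,
               stringsAsFactors = FALSE)))
  out <- fac[rep(seq_len(nrow(fac)), each = replications), ]
  out$replication <- rep(seq_len(replications), nrow(fac))
  rownames(out) <- NULL
  out
}

test_that("pure-noise responses reject at about the nominal 5% level", {
  set.seed(501)
  n_synth <- 60
  rates <- numeric(0)
  for (s in seq_len(n_synth)) {
    d <- synthetic_design(3)
    d$y <- stats::rnorm(nrow(d))
    a <- anova_kpis(d, kpis = c(noise = "y"))
    rates <- c(rates, unlist(a$p_values) < 0.05)
  }
  rate <- mean(rates)
  n <- length(rates)                   # 60 syntheses x 21 terms
  expect_lt(abs(rate - 0.05), 2.58 * sqrt(0.05 * 0.95 / n))
})

test_that("a planted factor effect is detected at the strongest tier", {
  set.seed(502)
  d <- synthetic_design(5)
  d$y <- stats::rnorm(nrow(d), sd = 2) + ifelse(d$hb_placement == "B", 10, 0)
  a <- anova_kpis(d, kpis = c(planted = "y"))
  expect_lt(a$p_values["planted", "hb_placement"], 0.001)
  expect_equal(a$tiers["planted", "hb_placement"], "0.001")
  # untouched factors stay mostly quiet
  expect_gt(a$p_values["planted", "queue_policy"], 0.001)
})

test_that("significance tiers map p-values to the three reported levels", {
  tier <- donorflow:::significance_tier
  expect_equal(tier(c(0.0002, 0.003, 0.03, 0.2)),
               c("0.001", "0.01", "0.05", "ns"))
})

test_that("unbalanced designs trigger a warning naming the SS convention", {
  set.seed(503)
  d <- synthetic_design(2)
  d <- d[-1, ]                         # drop one replication of one cell
  d$y <- stats::rnorm(nrow(d))
  expect_warning(anova_kpis(d, kpis = c(y = "y")), "sequential")
})

test_that("q-q diagnostics separate normal, heavy-tailed and constant input", {
  set.seed(504)
  qn <- qq_normality(stats::rnorm(1000))
  expect_gt(qn$correlation, 0.995)
  qc <- qq_normality(stats::rcauchy(1000))
  expect_lt(qc$correlation, qn$correlation)
  expect_lt(qc$correlation, 0.95)
  qd <- qq_normality(rep(3, 50))
  expect_true(qd$degenerate)
  expect_error(qq_normality(stats::rnorm(5)), "at least 10")
})

test_that("cost-efficiency regression recovers planted structure", {
  # exactly collinear points
  pts <- data.frame(layout = letters[1:6], cost = c(30, 31, 35, 40, 41, 47),
                    throughput = 0.001 + 0.0001 * c(30, 31, 35, 40, 41, 47))
  ce <- suppressWarnings(cost_efficiency(pts))  # lm flags the perfect fit
  expect_equal(ce$r_squared, 1)
  expect_equal(ce$slope, 1e-4)
  # planted slope with small noise, recovered within 10%
  set.seed(505)
  cost <- rep(seq(30, 47, by = 1), each = 8)
  pts2 <- data.frame(layout = paste0("l", seq_along(cost)), cost = cost,
                     throughput = 0.01 + 0.001 * cost +
                       stats::rnorm(length(cost), sd = 5e-4))
  ce2 <- cost_efficiency(pts2)
  expect_lt(abs(ce2$slope - 0.001) / 0.001, 0.10)
  # isocost winners: one per distinct cost level, the max-rate layout
  expect_equal(nrow(ce2$best_by_cost), length(unique(cost)))
  lvl <- subset(pts2, cost == 35)
  expect_equal(ce2$best_by_cost$layout[ce2$best_by_cost$cost == 35],
               lvl$layout[which.max(lvl$throughput)])
  expect_error(cost_efficiency(pts[1:2, ]), "3 distinct cost levels")
})

# minimal per-replication results table for ranking tests
fake_results <- function(spec) {
  do.call(rbind, lapply(seq_len(nrow(spec)), function(i) {
    n <- 5
    data.frame(layout = spec$layout[i],
               replication = 1:n,
               cycle_avg = spec$cycle[i] + stats::rnorm(n, sd = 1e-3),
               cycle_unbooked_avg = spec$cycle[i],
               cycle_max = spec$cycle[i] + 10,
               queue_avg = 5,
               util_physician = spec$up[i], util_nurse = spec$un[i],
               util_clerk = spec$un[i], util_bed = spec$un[i],
               cost = spec$cost[i],
               stringsAsFactors = FALSE)
  }))
}

test_that("a dominant layout is selected for all three stakeholders", {
  set.seed(506)
  spec <- data.frame(layout = c("L1", "L2", "L3"),
                     cycle = c(60, 70, 80),
                     up = c(0.6, 0.8, 0.9),
                     un = c(0.9, 0.5, 0.4),
                     cost = c(30, 40, 50))
  b <- best_layouts(fake_results(spec))
  expect_equal(b$donors, "L1")
  expect_equal(b$resources, "L1")
  expect_equal(b$management, "L1")
})

test_that("donor ranking ignores cost; management reacts to resource prices", {
  set.seed(507)
  # L2 is faster but far more expensive: donors still pick it
  spec <- data.frame(layout = c("L1", "L2"),
                     cycle = c(66, 60), up = c(0.7, 0.7),
                     un = c(0.6, 0.6), cost = c(30, 300))
  b <- best_layouts(fake_results(spec))
  expect_equal(b$donors, "L2")
  expect_equal(b$management, "L1")  # throughput per CU collapses at 300 CU
  # with beds priced at 100 CU the cheap-bed layout wins management
  lay_cheap <- layout_config("FIFO", 1, "W", 2, 1, 5)
  lay_beds <- layout_config("FIFO", 1, "W", 2, 1, 7)
  spec2 <- data.frame(layout = c("A", "B"), cycle = c(65, 64),
                      up = c(0.7, 0.7), un = c(0.6, 0.6),
                      cost = c(layout_cost(lay_cheap, cost_model(bed = 100)),
                               layout_cost(lay_beds, cost_model(bed = 100))))
  b2 <- best_layouts(fake_results(spec2))
  expect_equal(b2$management, "A")
})

test_that("best factor combinations report only significant factors", {
  set.seed(508)
  d <- synthetic_design(5)
  base <- stats::rnorm(nrow(d), sd = 0.5)
  res <- d
  # plant: placement B lowers cycle time; beds lower it slightly too
  res$cycle_avg <- 66 + base + ifelse(d$hb_placement == "B", -5, 0) -
    0.5 * (d$n_beds - 5)
  for (col in c("cycle_booked_avg", "cycle_unbooked_avg", "queue_avg",
                "queue_booked_avg", "queue_unbooked_avg", "util_nurse",
                "util_clerk", "util_bed", "util_physician",
                "cap_used_k1", "cap_used_k2", "cap_used_k3",
                "last_exit_k1", "last_exit_k2", "last_exit_k3"))
    res[[col]] <- stats::rnorm(nrow(d))
  comb <- best_factor_combinations(res)
  expect_equal(comb["cycle_time", "hb_placement"], "B")
  expect_equal(comb["cycle_time", "n_beds"], "7")
  expect_equal(comb["cycle_time", "queue_policy"], "")
})
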