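factor_cols <- function() c("queue_policy", "physician_timetable",
                            "hb_placement", "n_nurses", "n_clerks", "n_beds")

#' KPI response columns used in the factorial analysis
#'
#' Maps each analysed indicator to its per-replication column in a
#' [run_plan()] result: day-level average cycle and queue times (overall
#' and stratified), the four utilizations, and the per-period used
#' capacity and last consultation exit. Cost-efficiency is deliberately
#' not part of this set (it is a function of cycle time and cost and is
#' analysed separately by [cost_efficiency()]).
#'
#' @return Named character vector (name = KPI label, value = column).
#' @export
anova_kpi_columns <- function() {
  c(cycle_time            = "cycle_avg",
    cycle_time_booked     = "cycle_booked_avg",
    cycle_time_unbooked   = "cycle_unbooked_avg",
    queue_time            = "queue_avg",
    queue_time_booked     = "queue_booked_avg",
    queue_time_unbooked   = "queue_unbooked_avg",
    nurses_utilization    = "util_nurse",
    clerks_utilization    = "util_clerk",
    beds_utilization      = "util_bed",
    physicians_utilization = "util_physician",
    capacity_k1           = "cap_used_k1",
    capacity_k2           = "cap_used_k2",
    capacity_k3           = "cap_used_k3",
    last_donor_k1         = "last_exit_k1",
    last_donor_k2         = "last_exit_k2",
    last_donor_k3         = "last_exit_k3")
}

significance_tier <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "0.001",
                ifelse(p < 0.01, "0.01",
                       ifelse(p < 0.05, "0.05", "ns"))))
}

#' Per-KPI ANOVA over the factorial plan
#'
#' Fits, for each KPI, a linear model with the six layout factors as
#' categorical main effects plus all two-factor interactions, and reports
#' the p-value and significance tier (0.001 / 0.01 / 0.05 / ns) of every
#' term. On a balanced design (equal replications in every cell, as the
#' full factorial plan produces) the sequential sums of squares reported
#' here coincide with any other convention; on unbalanced input a warning
#' names the convention (sequential, Type I).
#'
#' @param results A [run_plan()] data.frame.
#' @param kpis Named column map, see [anova_kpi_columns()].
#' @return Object of class `anova_result`: list with `p_values` and
#'   `tiers` data.frames (rows = KPIs, columns = effects and
#'   interactions).
#' @export
anova_kpis <- function(results, kpis = anova_kpi_columns()) {
  fc <- factor_cols()
  stopifnot(all(fc %in% names(results)))
  dat <- results
  for (f in fc) dat[[f]] <- factor(dat[[f]])
  varying <- fc[vapply(dat[fc], nlevels, 1L) > 1L]
  if (length(varying) < 1L)
    stop("no layout factor varies in the supplied results", call. = FALSE)
  cells <- table(interaction(dat[varying], drop = TRUE))
  if (length(unique(as.integer(cells))) != 1L)
    warning("unbalanced design: p-values use sequential (Type I) sums of squares")
  rhs <- if (length(varying) > 1L)
    sprintf("(%s)^2", paste(varying, collapse = " + "))
  else varying
  pv <- list()
  for (lab in names(kpis)) {
    col <- kpis[[lab]]
    if (!col %in% names(dat)) next
    dat$.y <- dat[[col]]
    fit <- stats::aov(stats::as.formula(paste(".y ~", rhs)), data = dat)
    at <- summary(fit)[[1]]
    terms <- trimws(rownames(at))
    p <- at[["Pr(>F)"]]
    keep <- terms != "Residuals"
    pv[[lab]] <- stats::setNames(p[keep], terms[keep])
  }
  all_terms <- unique(unlist(lapply(pv, names)))
  pmat <- as.data.frame(do.call(rbind, lapply(pv, function(v)
    stats::setNames(v[all_terms], all_terms))))
  names(pmat) <- all_terms
  tiers <- as.data.frame(lapply(pmat, significance_tier),
                         row.names = rownames(pmat), check.names = FALSE)
  structure(list(p_values = pmat, tiers = tiers),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("<anova_result> significance tiers (rows = KPIs)\n")
  print(x$tiers)
  invisible(x)
}

#' Normal q-q diagnostic for replication samples
#'
#' Orders the sample against normal quantiles and summarizes linearity by
#' the q-q correlation coefficient (as in correlation-based normality
#' tests); values near 1 support the normality assumption behind the
#' ANOVA.
#'
#' @param samples Numeric vector, at least 10 values.
#' @return List with `sample_quantiles`, `theoretical_quantiles`,
#'   `correlation` and a `degenerate` flag (constant input).
#' @export
qq_normality <- function(samples) {
  samples <- samples[!is.na(samples)]
  if (length(samples) < 10L)
    stop("need at least 10 samples for a q-q diagnostic", call. = FALSE)
  sq <- sort(samples)
  tq <- stats::qnorm(stats::ppoints(length(sq)))
  degenerate <- stats::sd(sq) == 0
  list(sample_quantiles = sq, theoretical_quantiles = tq,
       correlation = if (degenerate) NA_real_ else stats::cor(sq, tq),
       degenerate = degenerate)
}

#' Per-layout summary of a plan result
#'
#' @param results A [run_plan()] data.frame.
#' @return One row per layout: replication count, mean and sd of the
#'   day-average cycle time, mean utilizations, cost, and throughput rate
#'   `1 / mean cycle time` (donors/min).
#' @export
layout_summary <- function(results) {
  sp <- split(results, results$layout)
  out <- do.call(rbind, lapply(sp, function(g) {
    data.frame(layout = g$layout[1],
               n = nrow(g),
               mean_cycle = mean(g$cycle_avg),
               sd_cycle = stats::sd(g$cycle_avg),
               mean_cycle_unbooked = mean(g$cycle_unbooked_avg),
               max_cycle = max(g$cycle_max),
               mean_queue = mean(g$queue_avg),
               util_physician = mean(g$util_physician),
               util_nurse = mean(g$util_nurse),
               util_clerk = mean(g$util_clerk),
               util_bed = mean(g$util_bed),
               cost = g$cost[1],
               stringsAsFactors = FALSE)
  }))
  out$throughput <- 1 / out$mean_cycle
  rownames(out) <- NULL
  out
}

#' Cost-efficiency regression and isocost best layouts
#'
#' Ordinary least squares of throughput rate (1/mean cycle time,
#' donors/min) on layout cost (CU/workday), plus, for each distinct cost
#' level, the layout with the highest throughput — the isocost view of the
#' plan.
#'
#' @param points data.frame with columns `layout`, `cost`, `throughput`
#'   (e.g. from [layout_summary()]).
#' @return List with `slope` (rate per CU), `intercept`, `r_squared`,
#'   `best_by_cost` (one row per cost level) and the fitted `model`.
#' @export
cost_efficiency <- function(points) {
  stopifnot(all(c("layout", "cost", "throughput") %in% names(points)))
  if (length(unique(points$cost)) < 3L)
    stop("cost-efficiency regression needs at least 3 distinct cost levels",
         call. = FALSE)
  fit <- stats::lm(throughput ~ cost, data = points)
  sp <- split(points, points$cost)
  best <- do.call(rbind, lapply(sp, function(g)
    g[which.max(g$throughput), c("layout", "cost", "throughput")]))
  best <- best[order(best$cost), ]
  rownames(best) <- NULL
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared,
       best_by_cost = best,
       model = fit)
}

#' Best layout per stakeholder
#'
#' Formalizes the stakeholder rankings: donors minimize the mean cycle
#' time (cost plays no role); resources maximize the mean utilization of
#' nurses, clerks and beds minus the physicians' utilization (saturate the
#' flexible resources, desaturate the bottleneck); management maximizes
#' throughput per cost unit. Selection is lexicographic on the primary
#' criterion with a two-sided tolerance of one standard error of the
#' leading layout's criterion, ties broken by lower cost and then by
#' name.
#'
#' @param results A [run_plan()] data.frame covering the layouts to rank.
#' @return List with `donors`, `resources`, `management` (layout names)
#'   and the `summary` table the ranking used.
#' @export
best_layouts <- function(results) {
  s <- layout_summary(results)
  s$resource_score <- (s$util_nurse + s$util_clerk + s$util_bed) / 3 -
    s$util_physician
  s$mgmt_score <- s$throughput / s$cost

  pick <- function(score, se, maximize = TRUE) {
    sc <- if (maximize) score else -score
    best <- max(sc)
    tol <- se[which.max(sc)]
    cand <- which(sc >= best - tol)
    cand <- cand[order(s$cost[cand], s$layout[cand])]
    s$layout[cand[1]]
  }
  se_cycle <- s$sd_cycle / sqrt(s$n)
  # SE of derived scores: carried through from the cycle-time SE where it
  # dominates; utilization spreads are comparatively tiny
  se_rate <- se_cycle / s$mean_cycle^2
  list(donors = pick(s$mean_cycle, se_cycle, maximize = FALSE),
       resources = pick(s$resource_score, rep(0, nrow(s))),
       management = pick(s$mgmt_score, se_rate / s$cost),
       summary = s)
}

kpi_direction <- function() {
  c(cycle_time = -1, cycle_time_booked = -1, cycle_time_unbooked = -1,
    queue_time = -1, queue_time_booked = -1, queue_time_unbooked = -1,
    nurses_utilization = 1, clerks_utilization = 1, beds_utilization = 1,
    physicians_utilization = -1,
    capacity_k1 = -1, capacity_k2 = -1, capacity_k3 = -1,
    last_donor_k1 = -1, last_donor_k2 = -1, last_donor_k3 = -1)
}

#' Best factor level per KPI
#'
#' For each KPI and each layout factor found significant at the 0.05 level
#' by [anova_kpis()], reports the factor level with the best marginal mean
#' (lower is better for times, physician utilization, used capacity and
#' last-exit; higher is better for nurse/clerk/bed utilization).
#' Non-significant cells are left empty, giving the best-combination table
#' of the factorial study.
#'
#' @param results A [run_plan()] data.frame.
#' @param anova An [anova_kpis()] result on the same data (computed if
#'   missing).
#' @return data.frame, rows = KPIs, columns = the six factors.
#' @export
best_factor_combinations <- function(results, anova = NULL) {
  if (is.null(anova)) anova <- anova_kpis(results)
  fc <- factor_cols()
  kpis <- anova_kpi_columns()
  dirs <- kpi_direction()
  out <- as.data.frame(matrix("", nrow = nrow(anova$p_values),
                              ncol = length(fc)),
                       row.names = rownames(anova$p_values))
  names(out) <- fc
  for (lab in rownames(anova$p_values)) {
    col <- kpis[[lab]]
    for (f in fc) {
      p <- anova$p_values[lab, f]
      if (is.na(p) || p >= 0.05) next
      marg <- tapply(results[[col]], results[[f]], mean)
      best <- names(marg)[if (dirs[[lab]] > 0) which.max(marg)
                          else which.min(marg)]
      out[lab, f] <- best
    }
  }
  out
}
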