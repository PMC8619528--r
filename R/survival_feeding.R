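# Kaplan-Meier survival from aggregated per-cage-day ledgers, median
# survival, log-rank comparison, and the per-bee feeding-rate statistic
# with its nonparametric group comparisons.

validate_ledger <- function(ledger) {
  stopifnot(all(c("group", "cage", "day", "n_at_risk", "deaths",
                  "censored") %in% names(ledger)))
  if (any(ledger$deaths + ledger$censored > ledger$n_at_risk)) {
    stop("survival ledger: deaths + censored exceed n_at_risk")
  }
  if (any(ledger$deaths > ledger$n_at_risk)) {
    stop("survival ledger: more deaths than bees at risk")
  }
  invisible(ledger)
}

# aggregate a ledger over cages into per-day risk/event counts
ledger_by_day <- function(ledger) {
  agg <- stats::aggregate(cbind(n_at_risk = ledger$n_at_risk,
                                deaths = ledger$deaths,
                                censored = ledger$censored),
                          by = list(day = ledger$day), FUN = sum)
  agg[order(agg$day), ]
}

#' Kaplan-Meier survival curve for one group
#'
#' Product-limit estimate S(t) = prod over event days d <= t of
#' (1 - deaths_d / n_risk_d), computed from an aggregated per-cage-day
#' ledger; censored bees leave the risk set after their day. The estimate is
#' invariant to how one day's deaths are split across cages.
#'
#' @param ledger a `survival_ledger` (columns group, cage, day, n_at_risk,
#'   deaths, censored).
#' @param group group (dose) to estimate; default uses all rows.
#' @return data.frame of class `survival_curve`: day, n_risk, n_event,
#'   n_censor, s_hat, starting from day 0 with s_hat = 1.
#' @export
kaplan_meier <- function(ledger, group = NULL) {
  validate_ledger(ledger)
  if (!is.null(group)) ledger <- ledger[ledger$group %in% group, , drop = FALSE]
  if (!nrow(ledger)) stop("kaplan_meier: no ledger rows for this group")
  agg <- ledger_by_day(ledger)
  s <- cumprod(1 - agg$deaths / agg$n_at_risk)
  out <- rbind(data.frame(day = 0, n_risk = agg$n_at_risk[1L], n_event = 0L,
                          n_censor = 0L, s_hat = 1),
               data.frame(day = agg$day, n_risk = agg$n_at_risk,
                          n_event = agg$deaths, n_censor = agg$censored,
                          s_hat = s))
  rownames(out) <- NULL
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Median survival time of a Kaplan-Meier curve
#'
#' Smallest event day at which the survival estimate drops to 0.5 or below;
#' `NA` when the curve never reaches 0.5.
#'
#' @param curve a `survival_curve`.
#' @return day, or `NA_real_`.
#' @export
median_survival <- function(curve) {
  hit <- which(curve$s_hat <= 0.5 & curve$n_event > 0)
  if (!length(hit)) return(NA_real_)
  curve$day[min(hit)]
}

#' Log-rank test between two groups of a survival ledger
#'
#' Standard one-degree-of-freedom log-rank statistic over the shared event
#' days, with hypergeometric variance.
#'
#' @param ledger a `survival_ledger`.
#' @param group_a,group_b the two group labels.
#' @return list: chi2, p.
#' @export
logrank <- function(ledger, group_a, group_b) {
  validate_ledger(ledger)
  la <- ledger[ledger$group %in% group_a, , drop = FALSE]
  lb <- ledger[ledger$group %in% group_b, , drop = FALSE]
  if (!nrow(la) || !nrow(lb)) stop("logrank: empty group")
  a <- ledger_by_day(la); b <- ledger_by_day(lb)
  days <- sort(union(a$day[a$deaths > 0], b$day[b$deaths > 0]))
  o_a <- e_a <- v <- 0
  for (d in days) {
    n1 <- a$n_at_risk[match(d, a$day)]; d1 <- a$deaths[match(d, a$day)]
    n2 <- b$n_at_risk[match(d, b$day)]; d2 <- b$deaths[match(d, b$day)]
    n1 <- ifelse(is.na(n1), 0, n1); d1 <- ifelse(is.na(d1), 0, d1)
    n2 <- ifelse(is.na(n2), 0, n2); d2 <- ifelse(is.na(d2), 0, d2)
    n <- n1 + n2; dd <- d1 + d2
    if (n < 2 || dd == 0) next
    o_a <- o_a + d1
    e_a <- e_a + dd * n1 / n
    v <- v + dd * (n1 / n) * (n2 / n) * (n - dd) / (n - 1)
  }
  chi2 <- if (v > 0) (o_a - e_a)^2 / v else 0
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE))
}

#' Per-bee feeding rate
#'
#' Daily syrup consumption per honeybee: the cage's measured syrup mass
#' divided by the mean of the living bees present at day t-1 and day t.
#' Rows with no living bees are skipped with a warning.
#'
#' @param ledger a `feeding_ledger` (columns group, cage, day,
#'   syrup_consumed, alive_prev, alive_now).
#' @return data.frame of class `feeding_rate`: group, cage, day,
#'   per_bee_consumption [g/bee/day].
#' @export
feeding_rate <- function(ledger) {
  stopifnot(all(c("group", "cage", "day", "syrup_consumed", "alive_prev",
                  "alive_now") %in% names(ledger)))
  if (any(ledger$syrup_consumed < 0)) stop("feeding_rate: negative syrup mass")
  if (any(ledger$alive_now > ledger$alive_prev)) {
    stop("feeding_rate: alive_now exceeds alive_prev")
  }
  mean_alive <- (ledger$alive_prev + ledger$alive_now) / 2
  dead <- mean_alive == 0
  if (any(dead)) {
    warning("feeding_rate: skipping ", sum(dead), " cage-day(s) with no living bees")
  }
  out <- data.frame(group = ledger$group[!dead], cage = ledger$cage[!dead],
                    day = ledger$day[!dead],
                    per_bee_consumption = ledger$syrup_consumed[!dead] /
                      mean_alive[!dead],
                    stringsAsFactors = FALSE)
  class(out) <- c("feeding_rate", "data.frame")
  out
}

#' Group comparisons of per-bee feeding rates
#'
#' Each exposed group vs control by a two-sided Wilcoxon rank-sum test over
#' cage-day values (default), or a Wilcoxon signed-rank test paired by day
#' after averaging cages within group (`paired_by_day = TRUE`); plus a
#' per-day Kruskal-Wallis across all groups.
#'
#' @param rates a `feeding_rate` table.
#' @param control control group label (default 0).
#' @param paired_by_day use the signed-rank pairing instead of rank-sum.
#' @return list: `vs_control` data.frame (group, n_a, n_b, p) and `per_day`
#'   data.frame (day, H, p).
#' @export
feeding_comparisons <- function(rates, control = 0, paired_by_day = FALSE) {
  groups <- setdiff(unique(rates$group), control)
  ctrl <- rates[rates$group == control, ]
  vs <- do.call(rbind, lapply(groups, function(g) {
    ex <- rates[rates$group == g, ]
    p <- if (paired_by_day) {
      days <- intersect(unique(ex$day), unique(ctrl$day))
      xa <- tapply(ex$per_bee_consumption[ex$day %in% days], ex$day[ex$day %in% days], mean)
      xb <- tapply(ctrl$per_bee_consumption[ctrl$day %in% days], ctrl$day[ctrl$day %in% days], mean)
      suppressWarnings(stats::wilcox.test(xa, xb, paired = TRUE)$p.value)
    } else {
      suppressWarnings(stats::wilcox.test(ex$per_bee_consumption,
                                          ctrl$per_bee_consumption)$p.value)
    }
    data.frame(group = g, n_a = nrow(ex), n_b = nrow(ctrl), p = p,
               stringsAsFactors = FALSE)
  }))
  per_day <- do.call(rbind, lapply(sort(unique(rates$day)), function(d) {
    sub <- rates[rates$day == d, ]
    if (length(unique(sub$group)) < 2L) return(NULL)
    kw <- stats::kruskal.test(sub$per_bee_consumption, factor(sub$group))
    data.frame(day = d, H = unname(kw$statistic), p = kw$p.value)
  }))
  list(vs_control = vs, per_day = per_day)
}
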