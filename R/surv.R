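#' Construct survival records
#'
#' One row per subject on the age scale with delayed entry: the subject is
#' under observation on (entry_age, exit_age], with `event = TRUE` meaning a
#' death at `exit_age` and `FALSE` a right-censoring there.
#'
#' @param entry_age left-truncation (delayed-entry) ages.
#' @param exit_age exit ages (death or censoring).
#' @param event logical event indicator.
#' @param group_label optional group label(s).
#' @return data.frame of class `survival_records`.
#' @export
survival_records <- function(entry_age, exit_age, event,
                             group_label = "all") {
  n <- length(exit_age)
  entry_age <- rep_len(as.numeric(entry_age), n)
  event <- rep_len(as.logical(event), n)
  group_label <- rep_len(as.character(group_label), n)
  if (any(is.na(entry_age) | is.na(exit_age) | is.na(event))) {
    stop("survival records must be complete")
  }
  if (any(entry_age < 0)) stop("entry_age must be >= 0")
  if (any(exit_age < entry_age)) stop("exit_age must be >= entry_age")
  structure(data.frame(entry_age = entry_age,
                       exit_age = as.numeric(exit_age),
                       event = event, group_label = group_label,
                       stringsAsFactors = FALSE),
            class = c("survival_records", "data.frame"))
}

new_survival_curve <- function(age, survival, n_risk, n_event, group_label,
                               start_age, end_age) {
  stopifnot(!is.unsorted(age, strictly = TRUE),
            all(survival >= -1e-12 & survival <= 1 + 1e-12),
            all(diff(survival) <= 1e-12))
  structure(data.frame(age = age, survival = pmin(pmax(survival, 0), 1),
                       n_risk = n_risk, n_event = n_event),
            group_label = group_label, start_age = start_age,
            end_age = end_age,
            class = c("survival_curve", "data.frame"))
}

#' @export
print.survival_curve <- function(x, ...) {
  cat(sprintf("survival_curve [%s]: %d event age(s) on [%g, %g]\n",
              attr(x, "group_label"), nrow(x), attr(x, "start_age"),
              attr(x, "end_age")))
  invisible(x)
}

#' Left-truncated Kaplan-Meier estimate
#'
#' Product-limit estimator on the age scale with delayed entry: the risk set
#' at age t comprises subjects with entry_age < t <= exit_age, so subjects
#' contribute only after coming under observation (avoiding immortal-time
#' bias). Ties at an age are resolved deaths before censorings. The curve is
#' reported at event ages (right-continuous step convention), with S = 1
#' before the first event. Records with `exit_age == entry_age` carry no
#' observation time and are dropped with a warning. If the risk set empties
#' while later entrants remain, the estimate beyond that age is flagged via
#' `attr(, "risk_gap")`.
#'
#' @param records a [survival_records()] data.frame (the `group_label`
#'   column is ignored here; see [logrank()] for comparisons).
#' @return a `survival_curve`: data.frame `age`, `survival`, `n_risk`,
#'   `n_event`, with `start_age`/`end_age` attributes delimiting the support.
#' @export
km_left_truncated <- function(records) {
  if (nrow(records) == 0L) stop("no survival records")
  zero <- records$exit_age == records$entry_age
  if (any(zero)) {
    warning("dropping ", sum(zero),
            " record(s) with zero observation time (exit == entry)")
    records <- records[!zero, , drop = FALSE]
    if (nrow(records) == 0L) stop("no records with positive observation time")
  }
  fit <- survival::survfit(
    survival::Surv(records$entry_age, records$exit_age, records$event) ~ 1)
  keep <- fit$n.event > 0
  curve <- new_survival_curve(
    age = fit$time[keep], survival = fit$surv[keep],
    n_risk = fit$n.risk[keep], n_event = fit$n.event[keep],
    group_label = records$group_label[1L],
    start_age = min(records$entry_age), end_age = max(records$exit_age))
  # delayed entry can empty the risk set before later entrants arrive
  gap <- any(fit$n.risk[keep] <= fit$n.event[keep] &
               fit$time[keep] < max(records$exit_age))
  attr(curve, "risk_gap") <- gap
  if (gap) warning("risk set emptied before the last exit; ",
                   "estimate beyond that age is undefined")
  curve
}

#' Evaluate a survival curve at given ages
#'
#' Right-continuous step lookup; 1 before the first event age, flat after the
#' last.
#'
#' @param curve a `survival_curve`.
#' @param t numeric ages.
#' @return survival probabilities.
#' @export
curve_survival_at <- function(curve, t) {
  idx <- findInterval(t, curve$age)
  ifelse(idx == 0L, 1, curve$survival[pmax(idx, 1L)])
}

#' Condition a survival curve on reaching an age
#'
#' Rescales the curve by S(condition_age) and restricts it to ages at or
#' above the conditioning age, so the returned curve starts at probability 1
#' there.
#'
#' @param curve a `survival_curve`.
#' @param condition_age conditioning age (default 80).
#' @return a `survival_curve` with `start_age = condition_age`.
#' @export
condition_curve <- function(curve, condition_age = 80) {
  s0 <- curve_survival_at(curve, condition_age)
  if (s0 <= 0) stop("survival is zero at age ", condition_age,
                    "; conditioning undefined")
  keep <- curve$age > condition_age
  new_survival_curve(
    age = curve$age[keep], survival = curve$survival[keep] / s0,
    n_risk = curve$n_risk[keep], n_event = curve$n_event[keep],
    group_label = attr(curve, "group_label"),
    start_age = condition_age, end_age = attr(curve, "end_age"))
}

#' Two-sample log-rank test with delayed entry
#'
#' Compares the death hazards of two groups on the age scale. At each
#' distinct event age the risk set of each group comprises its subjects with
#' entry_age < t <= exit_age (deaths before censorings at ties), the observed
#' group-A deaths are compared with their hypergeometric expectation, and the
#' variance uses the tie-corrected hypergeometric form. The statistic is the
#' usual chi-square with 1 degree of freedom. With `strata_a`/`strata_b`
#' supplied (e.g. sex), observed-minus-expected and variance accumulate
#' within strata, giving the stratified log-rank that is immune to
#' confounding by stratum composition.
#'
#' @param records_a,records_b [survival_records()] for the two groups.
#' @param strata_a,strata_b optional stratum labels aligned with the rows of
#'   the respective records.
#' @return list of class `logrank_result`: `statistic`, `df`, `p_value`,
#'   `observed`, `expected` (length-2, group A then B), `n` (group sizes).
#' @export
logrank <- function(records_a, records_b, strata_a = NULL, strata_b = NULL) {
  if (nrow(records_a) == 0L || nrow(records_b) == 0L) {
    stop("both groups must be non-empty")
  }
  if (is.null(strata_a)) strata_a <- rep("", nrow(records_a))
  if (is.null(strata_b)) strata_b <- rep("", nrow(records_b))
  stopifnot(length(strata_a) == nrow(records_a),
            length(strata_b) == nrow(records_b))
  O <- 0; E <- 0; V <- 0
  obs_b <- 0; exp_b <- 0
  any_event <- FALSE
  for (st in union(unique(strata_a), unique(strata_b))) {
    ra <- records_a[strata_a == st, , drop = FALSE]
    rb <- records_b[strata_b == st, , drop = FALSE]
    ea <- ra$entry_age; xa <- ra$exit_age; va <- ra$event
    eb <- rb$entry_age; xb <- rb$exit_age; vb <- rb$event
    times <- sort(unique(c(xa[va], xb[vb])))
    if (length(times) > 0L) any_event <- TRUE
    for (t in times) {
      nA <- sum(ea < t & t <= xa)
      nB <- sum(eb < t & t <= xb)
      n <- nA + nB
      dA <- sum(va & xa == t)
      dB <- sum(vb & xb == t)
      d <- dA + dB
      if (n == 0L || d == 0L) next
      eA <- d * nA / n
      O <- O + dA; E <- E + eA
      obs_b <- obs_b + dB; exp_b <- exp_b + (d - eA)
      if (n > 1L) {
        V <- V + d * (n - d) / (n - 1) * nA * nB / n^2
      }
    }
  }
  if (!any_event) {
    warning("no events in either group; log-rank statistic is 0")
    out <- list(statistic = 0, df = 1L, p_value = 1,
                observed = c(0, 0), expected = c(0, 0),
                n = c(nrow(records_a), nrow(records_b)))
    class(out) <- "logrank_result"
    return(out)
  }
  if (V <= 0) {
    warning("log-rank variance is zero; statistic set to 0")
    stat <- 0; p <- 1
  } else {
    stat <- (O - E)^2 / V
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  out <- list(statistic = stat, df = 1L, p_value = p,
              observed = c(O, obs_b), expected = c(E, exp_b),
              n = c(nrow(records_a), nrow(records_b)))
  class(out) <- "logrank_result"
  out
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank: chisq = %.4f on %d df, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  cat(sprintf("  observed %g vs %g, expected %.2f vs %.2f (n = %d, %d)\n",
              x$observed[1], x$observed[2], x$expected[1], x$expected[2],
              x$n[1], x$n[2]))
  invisible(x)
}

#' Restricted mean survival time
#'
#' Area under the (step) survival curve between two ages: the expected years
#' lived in the window among those under observation at its start, in years.
#' Exact step-function integration, no quadrature.
#'
#' @param curve a `survival_curve` (raw or conditioned).
#' @param from_age,to_age integration window; must lie within the curve's
#'   support (`start_age` to `end_age`).
#' @return numeric years.
#' @export
rmst <- function(curve, from_age, to_age) {
  start <- attr(curve, "start_age"); end <- attr(curve, "end_age")
  if (from_age >= to_age) stop("from_age must be below to_age")
  if (from_age < start || to_age > end) {
    stop(sprintf("window [%g, %g] outside curve support [%g, %g]",
                 from_age, to_age, start, end))
  }
  knots <- sort(unique(c(from_age,
                         curve$age[curve$age > from_age & curve$age < to_age],
                         to_age)))
  widths <- diff(knots)
  sum(curve_survival_at(curve, knots[-length(knots)]) * widths)
}

#' Write a survival curve to a delimited file
#' @param curve a `survival_curve`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  df <- as.data.frame(curve)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
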