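#' Survival exceptionality of an attained age
#'
#' The building block of the family score: u = -log S(a | base age), the
#' cumulative hazard beyond the conditioning age implied by the cohort life
#' table. Under the table's own law the score of a death is unit-exponential,
#' so it is directly comparable across sexes and birth cohorts. Living
#' individuals receive `alive_bonus` on top of u — the conditional expectation
#' of their eventual score in excess of the already-banked u under the
#' unit-exponential null — which is what makes very old living family members
#' count extra. Where tabulated survival has reached zero the score is
#' truncated at -log of the smallest strictly positive tabulated value, so
#' record ages stay finite.
#'
#' @param table a [cohort_life_table()].
#' @param age attained age(s), at or above the table's base age.
#' @param alive logical: alive at the attained age (vector or scalar).
#' @param alive_bonus additive bonus for living individuals (default 1).
#' @return data.frame with `neg_log_survival`, `bonus`, `total`.
#' @export
survival_exceptionality <- function(table, age, alive = FALSE,
                                    alive_bonus = 1) {
  base_age <- attr(table, "base_age")
  if (any(age < base_age)) {
    stop("attained age below the table's base age (", base_age, ")")
  }
  alive <- rep_len(as.logical(alive), length(age))
  s <- lookup_survival(table, age)
  floor_s <- attr(table, "min_positive")
  s <- pmax(s, if (is.na(floor_s)) .Machine$double.xmin else floor_s)
  u <- -log(s)
  bonus <- ifelse(alive, alive_bonus, 0)
  data.frame(neg_log_survival = u, bonus = bonus, total = u + bonus)
}

resolve_status <- function(birth, death, last_alive, reference_year = NULL) {
  final_end <- ifelse(is.na(death), last_alive, death)
  if (is.null(reference_year)) {
    alive <- is.na(death)
    attained <- final_end - birth
  } else {
    after <- !is.na(final_end) & final_end > reference_year
    alive <- after
    attained <- ifelse(after, reference_year - birth, final_end - birth)
  }
  data.frame(alive = alive, attained_age = as.numeric(attained))
}

#' Score one individual against a cohort life table
#'
#' Computes the individual's contribution to the family score. Without a
#' reference year, final observed status is used: the deceased contribute
#' -log S(age at death), individuals with only a last known-alive year count
#' as alive at that age and receive the alive bonus. With a reference year,
#' vital status and attained age are recomputed as of that year: an
#' individual whose death (or last-alive) year falls after it is treated as
#' alive at age `reference_year - birth_year`.
#'
#' @param ind a single-row data.frame or list with fields `person_id`, `sex`,
#'   `birth_year`, `death_year`, `last_alive_year`.
#' @param table the [cohort_life_table()] for the individual's sex and
#'   cohort band (checked when the table carries that metadata).
#' @param reference_year optional cross-sectional year.
#' @param alive_bonus additive bonus for the living (default 1).
#' @return one-row data.frame of class `individual_score`: `person_id`,
#'   `attained_age`, `alive_at_reference`, `neg_log_survival`, `bonus`,
#'   `total`.
#' @export
individual_score <- function(ind, table, reference_year = NULL,
                             alive_bonus = 1) {
  ind <- as.list(ind)
  tsex <- attr(table, "sex")
  if (nzchar(tsex) && !is.null(ind$sex) && ind$sex != tsex) {
    stop("table is for sex ", tsex, ", individual is ", ind$sex)
  }
  st <- resolve_status(ind$birth_year, ind$death_year, ind$last_alive_year,
                       reference_year)
  if (is.na(st$attained_age)) stop("individual has no usable vital year")
  if (st$attained_age < attr(table, "base_age")) {
    stop("individual not score-eligible: attained age ", st$attained_age,
         " below base age ", attr(table, "base_age"))
  }
  sc <- survival_exceptionality(table, st$attained_age, st$alive, alive_bonus)
  out <- data.frame(person_id = as.character(ind$person_id),
                    attained_age = st$attained_age,
                    alive_at_reference = st$alive,
                    neg_log_survival = sc$neg_log_survival,
                    bonus = sc$bonus, total = sc$total,
                    stringsAsFactors = FALSE)
  class(out) <- c("individual_score", "data.frame")
  out
}

# Vectorized member scoring for a whole sample. Returns one row per
# individual that is scoreable (attained age >= base age, matching table
# present); others are flagged.
score_individuals <- function(sample, tables, reference_year = NULL,
                              alive_bonus = 1) {
  ind <- sample$individuals
  base_age <- attr(tables, "base_age")
  st <- resolve_status(ind$birth_year, ind$death_year, ind$last_alive_year,
                       reference_year)
  bands <- attr(tables, "bands")
  band <- assign_cohort(ind$birth_year, bands)
  key <- paste(ind$sex, band, sep = "|")
  scoreable <- !is.na(st$attained_age) & st$attained_age >= base_age &
    key %in% names(tables)
  res <- data.frame(
    person_id = ind$person_id,
    sibship_id = if (is.null(ind$sibship_id)) NA_character_ else ind$sibship_id,
    sex = ind$sex,
    attained_age = st$attained_age,
    alive_at_reference = st$alive,
    neg_log_survival = NA_real_, bonus = NA_real_, total = NA_real_,
    scoreable = scoreable,
    stringsAsFactors = FALSE
  )
  for (k in unique(key[scoreable])) {
    sel <- which(scoreable & key == k)
    sc <- survival_exceptionality(tables[[k]], st$attained_age[sel],
                                  st$alive[sel], alive_bonus)
    res$neg_log_survival[sel] <- sc$neg_log_survival
    res$bonus[sel] <- sc$bonus
    res$total[sel] <- sc$total
  }
  res
}

#' Family Longevity Selection Score of one sibship
#'
#' The sum of member scores over the sibship's score-eligible members — for
#' each member -log S(attained age | base age) from the member's own sex- and
#' cohort-specific life table, plus the alive bonus for living members —
#' minus `size_penalty` per scored member, which centers each member's
#' contribution at its unit-exponential null expectation. With
#' `reference_year` set, status and ages are as of that year and members not
#' yet attaining the base age then are excluded from the sum.
#'
#' @param sibship_id sibship identifier.
#' @param sample a `pedigree_sample` with sibships derived.
#' @param tables a [build_life_tables()] set.
#' @param reference_year optional cross-sectional year.
#' @param alive_bonus additive bonus for the living (default 1).
#' @param size_penalty amount subtracted per scored member (default 1, the
#'   unit-exponential null expectation of a member's exceedance). This
#'   centers the score so that an unremarkable sibship of any size scores
#'   near 0, half the distribution is negative, and a fixed threshold such
#'   as 7 means "7 units of exceedance beyond expectation" regardless of
#'   family size. Set to 0 for the raw additive sum of member totals.
#' @return list of class `sibship_score`: `sibship_id`, `floss`,
#'   `n_members_scored`, `n_alive`, `member_scores`.
#' @export
sibship_floss <- function(sibship_id, sample, tables, reference_year = NULL,
                          alive_bonus = 1, size_penalty = 1) {
  stopifnot(!is.null(sample$individuals$sibship_id))
  sub <- sample
  sub$individuals <- sample$individuals[
    sample$individuals$sibship_id == sibship_id, , drop = FALSE]
  if (nrow(sub$individuals) == 0L) stop("unknown sibship ", sibship_id)
  ms <- score_individuals(sub, tables, reference_year, alive_bonus)
  ms <- ms[ms$scoreable, , drop = FALSE]
  if (nrow(ms) == 0L) stop("sibship ", sibship_id, " has no scoreable member")
  structure(list(
    sibship_id = sibship_id,
    floss = sum(ms$total) - size_penalty * nrow(ms),
    n_members_scored = nrow(ms),
    n_alive = sum(ms$alive_at_reference),
    member_scores = ms[c("person_id", "attained_age", "alive_at_reference",
                         "neg_log_survival", "bonus", "total")]
  ), class = "sibship_score")
}

#' @export
print.sibship_score <- function(x, ...) {
  cat(sprintf("sibship %s: FLoSS = %.4f over %d member(s), %d alive\n",
              x$sibship_id, x$floss, x$n_members_scored, x$n_alive))
  invisible(x)
}

#' Score every sibship in a sample
#'
#' @inheritParams sibship_floss
#' @param sample a `pedigree_sample` with sibships derived (normally after
#'   [apply_inclusion_filters()] and [apply_score_eligibility()]).
#' @return data.frame with one row per sibship having at least one scoreable
#'   member: `sibship_id`, `floss`, `n_members_scored`, `n_alive`; the
#'   member-level table is in `attr(, "member_scores")`.
#' @export
score_sibships <- function(sample, tables, reference_year = NULL,
                           alive_bonus = 1, size_penalty = 1) {
  stopifnot(!is.null(sample$individuals$sibship_id))
  ms <- score_individuals(sample, tables, reference_year, alive_bonus)
  ms <- ms[ms$scoreable, , drop = FALSE]
  if (nrow(ms) == 0L) stop("no scoreable members in sample")
  agg <- stats::aggregate(
    cbind(total = ms$total, alive = as.integer(ms$alive_at_reference)),
    by = list(sibship_id = ms$sibship_id), FUN = sum)
  cnt <- as.data.frame(table(ms$sibship_id), stringsAsFactors = FALSE)
  names(cnt) <- c("sibship_id", "n_members_scored")
  out <- merge(agg, cnt, by = "sibship_id", sort = TRUE)
  out <- data.frame(sibship_id = out$sibship_id,
                    floss = out$total -
                      size_penalty * as.integer(out$n_members_scored),
                    n_members_scored = as.integer(out$n_members_scored),
                    n_alive = as.integer(out$alive),
                    stringsAsFactors = FALSE)
  out <- out[order(out$sibship_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "member_scores") <- ms
  out
}

#' Summarize a collection of sibship scores
#'
#' @param scores data.frame from [score_sibships()] (or anything with a
#'   `floss` column), or a numeric vector of scores.
#' @param strict error when the standard deviation is zero (default TRUE),
#'   since a degenerate spread cannot standardize.
#' @return list of class `floss_summary` with `mean`, `sd`, `n_sibships`.
#' @export
summarize_floss <- function(scores, strict = TRUE) {
  x <- if (is.numeric(scores)) scores else scores$floss
  if (length(x) < 2L) stop("need at least 2 sibship scores to summarize")
  s <- stats::sd(x)
  if (strict && s <= 0) stop("degenerate score distribution: sd is zero")
  structure(list(mean = mean(x), sd = s, n_sibships = length(x)),
            class = "floss_summary")
}

#' @export
print.floss_summary <- function(x, ...) {
  cat(sprintf("FLoSS summary over %d sibships: M = %.4f, S = %.4f\n",
              x$n_sibships, x$mean, x$sd))
  invisible(x)
}

#' Standardized FLoSS
#'
#' S-FLoSS = (FLoSS - M) / S, with M and S the mean and standard deviation of
#' the score distribution being standardized against.
#'
#' @param score numeric score(s).
#' @param summary a [summarize_floss()] result (or list with `mean`, `sd`).
#' @return numeric standardized score(s).
#' @export
standardize_floss <- function(score, summary) {
  if (is.null(summary$sd) || summary$sd <= 0) {
    stop("standardization requires a positive sd")
  }
  (score - summary$mean) / summary$sd
}

#' Select sibships by score threshold
#'
#' @param scores data.frame from [score_sibships()].
#' @param threshold score threshold; the comparison is inclusive.
#' @param direction `"ge"` (scores at or above, the exceptional tail) or
#'   `"le"` (at or below, the anti-selected tail).
#' @return character vector of selected sibship ids, sorted.
#' @export
select_sibships <- function(scores, threshold, direction = c("ge", "le")) {
  direction <- match.arg(direction)
  sel <- if (direction == "ge") scores$floss >= threshold
         else scores$floss <= threshold
  sort(scores$sibship_id[sel])
}

#' Write sibship scores to a delimited file
#' @param scores data.frame from [score_sibships()].
#' @param path output path.
#' @param members also write the member-level scores alongside (suffix
#'   `_members` before the extension)?
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path, members = FALSE) {
  utils::write.csv(scores, path, row.names = FALSE, quote = FALSE)
  if (members && !is.null(attr(scores, "member_scores"))) {
    mp <- sub("(\\.[^.]*)?$", "_members\\1", path)
    utils::write.csv(attr(scores, "member_scores"), mp,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
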