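#' Study configuration
#'
#' Bundles the analysis settings: the cross-sectional study year, the age
#' threshold defining the old-age comparison groups, the score thresholds for
#' the exceptional and anti-selected tails, the birth-year floor for the
#' offspring analysis, the life-table conditioning age and alive bonus, and
#' the cohort-band layout.
#'
#' @param study_year cross-sectional year at which groups are formed
#'   (default 1980).
#' @param age_threshold minimum age, in years, to enter the comparison groups
#'   (default 80); must exceed `base_age`.
#' @param floss_threshold exceptional-family score threshold (default 7).
#' @param anti_threshold anti-selected tail threshold (default -4.5).
#' @param offspring_min_birth_year offspring born strictly after this year
#'   enter the offspring analysis (default 1900).
#' @param base_age life-table conditioning age (default 40).
#' @param alive_bonus additive score bonus for living members (default 1).
#' @param size_penalty per-member centering subtracted from sibship scores
#'   (default 1; see [sibship_floss()]).
#' @param max_birth_year inclusion cap on birth years (default 1910).
#' @param rmst_to_age upper end of the restricted-mean window starting at
#'   `age_threshold` (default 95).
#' @param bands cohort-band layout (default [cohort_bands()]).
#' @param lifetable_method passed to [build_life_tables()].
#' @param seed integer seed recorded in reports.
#' @return list of class `study_config`.
#' @export
study_config <- function(study_year = 1980, age_threshold = 80,
                         floss_threshold = 7, anti_threshold = -4.5,
                         offspring_min_birth_year = 1900, base_age = 40,
                         alive_bonus = 1, size_penalty = 1,
                         max_birth_year = 1910,
                         rmst_to_age = 95, bands = cohort_bands(),
                         lifetable_method = "product-limit", seed = 1L) {
  cfg <- list(study_year = as.integer(study_year),
              age_threshold = as.integer(age_threshold),
              floss_threshold = floss_threshold,
              anti_threshold = anti_threshold,
              offspring_min_birth_year = as.integer(offspring_min_birth_year),
              base_age = as.integer(base_age),
              alive_bonus = alive_bonus,
              size_penalty = size_penalty,
              max_birth_year = as.integer(max_birth_year),
              rmst_to_age = rmst_to_age,
              bands = bands, lifetable_method = lifetable_method,
              seed = as.integer(seed))
  if (cfg$age_threshold <= cfg$base_age) {
    stop("age_threshold must exceed base_age")
  }
  if (is.na(cfg$floss_threshold) || is.na(cfg$anti_threshold)) {
    stop("score thresholds must not be NA")
  }
  class(cfg) <- "study_config"
  cfg
}

#' Vital status and age at a cross-sectional year
#'
#' An individual is alive at the study year when the death year (or last
#' known-alive year) falls strictly after it; age is the calendar-year
#' difference. Individuals born after the year are excluded.
#'
#' @param sample a `pedigree_sample`.
#' @param year the cross-sectional year.
#' @return data.frame `person_id`, `alive`, `age` for individuals born in or
#'   before `year`.
#' @export
cross_section_status <- function(sample, year) {
  ind <- sample$individuals
  born <- ind$birth_year <= year
  end <- end_year(ind)
  data.frame(person_id = ind$person_id[born],
             alive = !is.na(end[born]) & end[born] > year,
             age = as.integer(year - ind$birth_year[born]),
             stringsAsFactors = FALSE)
}

#' Form exceptional and ordinary groups at the study year
#'
#' Individuals alive and at or above the age threshold in the study year are
#' partitioned by their sibship's score: `exceptional` when the sibship FLoSS
#' (computed as of the study year) meets the threshold, `ordinary` otherwise.
#' Everyone else is `excluded`. The scores passed in should therefore come
#' from `score_sibships(..., reference_year = config$study_year)`.
#'
#' @param sample a `pedigree_sample` with sibships derived.
#' @param scores sibship scores from [score_sibships()].
#' @param config a [study_config()].
#' @param quiet suppress the count message.
#' @return data.frame of class `group_assignment`: `person_id`, `group`,
#'   `age_at_study_year`, `alive_at_study_year`.
#' @export
build_groups_at_year <- function(sample, scores, config, quiet = FALSE) {
  stopifnot(!is.null(sample$individuals$sibship_id))
  st <- cross_section_status(sample, config$study_year)
  ind <- sample$individuals
  m <- match(ind$person_id, st$person_id)
  alive <- !is.na(m) & st$alive[ifelse(is.na(m), 1L, m)]
  age <- ifelse(is.na(m), NA_integer_, st$age[ifelse(is.na(m), 1L, m)])
  eligible <- alive & !is.na(age) & age >= config$age_threshold
  if (!any(eligible)) stop("no one alive at age ", config$age_threshold,
                           "+ in ", config$study_year)
  floss <- scores$floss[match(ind$sibship_id, scores$sibship_id)]
  group <- rep("excluded", nrow(ind))
  group[eligible] <- ifelse(
    !is.na(floss[eligible]) & floss[eligible] >= config$floss_threshold,
    "exceptional", "ordinary")
  out <- data.frame(person_id = ind$person_id, group = group,
                    age_at_study_year = age, alive_at_study_year = alive,
                    stringsAsFactors = FALSE)
  class(out) <- c("group_assignment", "data.frame")
  if (!quiet) {
    message(sprintf(
      "study year %d: %d alive aged %d+ (%d exceptional, %d ordinary)",
      config$study_year, sum(eligible), config$age_threshold,
      sum(group == "exceptional"), sum(group == "ordinary")))
  }
  out
}

#' Group offspring by parental family score
#'
#' Offspring born strictly after `config$offspring_min_birth_year` are
#' labelled `exceptional` when at least one parent belongs to a sibship with
#' FLoSS at or above the threshold, `ordinary` when both parents are scored
#' below it, and `excluded` when either parent is absent from the sample or
#' unscored (so an unscorable parent never dilutes the ordinary group).
#'
#' @param sample a `pedigree_sample` with sibships derived.
#' @param scores parental sibship scores from [score_sibships()] (normally
#'   complete-lifespan scores, no reference year).
#' @param config a [study_config()].
#' @return data.frame of class `group_assignment` over the offspring:
#'   `person_id`, `group`, plus `sex` and `birth_year` convenience columns.
#' @export
offspring_groups <- function(sample, scores, config) {
  ind <- sample$individuals
  parent_floss <- function(ids) {
    j <- match(ids, ind$person_id)
    sib <- ind$sibship_id[ifelse(is.na(j), 1L, j)]
    sib[is.na(j)] <- NA_character_
    scores$floss[match(sib, scores$sibship_id)]
  }
  is_off <- ind$birth_year > config$offspring_min_birth_year &
    (!is.na(ind$mother_id) | !is.na(ind$father_id))
  sub <- ind[is_off, , drop = FALSE]
  fm <- parent_floss(sub$mother_id)
  ff <- parent_floss(sub$father_id)
  group <- rep("excluded", nrow(sub))
  exc <- (!is.na(fm) & fm >= config$floss_threshold) |
    (!is.na(ff) & ff >= config$floss_threshold)
  ord <- !exc & !is.na(fm) & !is.na(ff) &
    fm < config$floss_threshold & ff < config$floss_threshold
  group[exc] <- "exceptional"
  group[ord] <- "ordinary"
  out <- data.frame(person_id = sub$person_id, group = group,
                    sex = sub$sex, birth_year = sub$birth_year,
                    stringsAsFactors = FALSE)
  class(out) <- c("group_assignment", "data.frame")
  out
}

# Survival records for follow-up from the study year: entry at age in the
# study year, exit at the death/last-alive age.
study_year_records <- function(sample, assignment, group, sex, config) {
  ind <- sample$individuals
  m <- match(ind$person_id, assignment$person_id)
  sel <- !is.na(m) & assignment$group[ifelse(is.na(m), 1L, m)] == group &
    ind$sex %in% sex
  ind <- ind[sel, , drop = FALSE]
  entry <- config$study_year - ind$birth_year
  exit <- end_year(ind) - ind$birth_year
  survival_records(entry, exit, !is.na(ind$death_year), group)
}

# Offspring records: observed from birth, so entry 0 (conditioning happens
# downstream at the age threshold).
offspring_records <- function(sample, assignment, group, sex) {
  ind <- sample$individuals
  m <- match(ind$person_id, assignment$person_id)
  sel <- !is.na(m) & assignment$group[ifelse(is.na(m), 1L, m)] == group &
    ind$sex %in% sex
  ind <- ind[sel, , drop = FALSE]
  exit <- end_year(ind) - ind$birth_year
  survival_records(0, exit, !is.na(ind$death_year), group)
}

compare_groups <- function(rec_exc, rec_ord, config) {
  at <- config$age_threshold
  trunc_at <- function(r) {
    r <- r[r$exit_age > at, , drop = FALSE]
    r$entry_age <- pmax(r$entry_age, at)
    r
  }
  re <- trunc_at(rec_exc); ro <- trunc_at(rec_ord)
  if (nrow(re) == 0L || nrow(ro) == 0L) {
    return(list(available = FALSE))
  }
  ce <- condition_curve(km_left_truncated(re), at)
  co <- condition_curve(km_left_truncated(ro), at)
  to_age <- min(config$rmst_to_age, attr(ce, "end_age"), attr(co, "end_age"))
  lr <- logrank(re, ro)
  list(available = TRUE,
       n_exceptional = nrow(re), n_ordinary = nrow(ro),
       curve_exceptional = ce, curve_ordinary = co,
       records_exceptional = re, records_ordinary = ro,
       logrank_statistic = lr$statistic, logrank_p = lr$p_value,
       rmst_from = at, rmst_to = to_age,
       rmst_exceptional = rmst(ce, at, to_age),
       rmst_ordinary = rmst(co, at, to_age),
       rmst_gap = rmst(ce, at, to_age) - rmst(co, at, to_age))
}

# Sex-stratified combination of per-stratum group comparisons: stratified
# log-rank, size-weighted RMST gap, and the weighted survival-difference
# curve (its minimum over the window summarises dominance) -- immune to
# confounding by stratum composition, unlike naive pooling.
stratified_compare <- function(cmps, config) {
  avail <- Filter(function(g) isTRUE(g$available), cmps)
  if (length(avail) == 0L) return(list(available = FALSE))
  w <- vapply(avail, function(g) g$n_exceptional + g$n_ordinary, numeric(1))
  w <- w / sum(w)
  re <- do.call(rbind, lapply(avail, `[[`, "records_exceptional"))
  ro <- do.call(rbind, lapply(avail, `[[`, "records_ordinary"))
  sa <- rep(names(avail),
            vapply(avail, function(g) g$n_exceptional, integer(1)))
  sb <- rep(names(avail),
            vapply(avail, function(g) g$n_ordinary, integer(1)))
  lr <- logrank(re, ro, strata_a = sa, strata_b = sb)
  at <- config$age_threshold
  to_age <- min(vapply(avail, `[[`, numeric(1), "rmst_to"))
  grid <- seq(at, to_age, by = 0.25)
  diff_curve <- rowSums(vapply(seq_along(avail), function(i) {
    g <- avail[[i]]
    w[i] * (curve_survival_at(g$curve_exceptional, grid) -
              curve_survival_at(g$curve_ordinary, grid))
  }, numeric(length(grid))))
  list(available = TRUE,
       strata = names(avail), weights = as.numeric(w),
       n_exceptional = sum(vapply(avail, `[[`, numeric(1), "n_exceptional")),
       n_ordinary = sum(vapply(avail, `[[`, numeric(1), "n_ordinary")),
       logrank_statistic = lr$statistic, logrank_p = lr$p_value,
       rmst_from = at, rmst_to = to_age,
       rmst_gap = sum(w * vapply(avail, `[[`, numeric(1), "rmst_gap")),
       min_curve_difference = min(diff_curve))
}

#' Run the full family-longevity selection study
#'
#' Orchestrates the three analyses on one pedigree sample: (1) whole-sample
#' scoring — conditional cohort life tables, sibship FLoSS, score summary and
#' threshold selection of the exceptional and anti-selected tails; (2) the
#' cross-sectional study-year comparison — individuals alive at the age
#' threshold split into exceptional and ordinary groups by as-of-year family
#' score and followed with left-truncated Kaplan-Meier curves, log-rank test
#' and restricted-mean survival; (3) the offspring comparison — offspring
#' grouped by parental family score with the same machinery, conditional on
#' reaching the age threshold. All steps are deterministic given the sample.
#'
#' @param sample a `pedigree_sample` (raw; sibships are derived and filters
#'   applied internally).
#' @param config a [study_config()].
#' @param out_dir optional output directory; when given, writes
#'   `report.json`, `sibship_scores.csv`, `group_assignments.csv`, life
#'   tables under `life_tables/` and curves under `curves/`.
#' @param quiet suppress progress messages.
#' @return list of class `study_report` with components `counts`, `floss`
#'   (summary + selections), `study_year` and `offspring` (per-sex group
#'   comparisons), and the intermediate objects (`tables`, `scores`,
#'   `groups`).
#' @export
run_study <- function(sample, config = study_config(), out_dir = NULL,
                      quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  n_raw <- n_individuals(sample)
  if (is.null(sample$individuals$sibship_id)) {
    sample <- derive_sibships(sample)
  }
  flt <- apply_inclusion_filters(sample, config$max_birth_year, quiet = quiet)
  elig <- apply_score_eligibility(flt, config$base_age, quiet = quiet)
  say("building life tables over ", n_individuals(elig),
      " score-eligible individuals")
  tables <- build_life_tables(elig, bands = config$bands,
                              base_age = config$base_age,
                              method = config$lifetable_method)

  scores_full <- score_sibships(elig, tables, reference_year = NULL,
                                alive_bonus = config$alive_bonus,
                                size_penalty = config$size_penalty)
  summ <- summarize_floss(scores_full)
  sel_exc <- select_sibships(scores_full, config$floss_threshold, "ge")
  sel_anti <- select_sibships(scores_full, config$anti_threshold, "le")

  scores_year <- score_sibships(elig, tables,
                                reference_year = config$study_year,
                                alive_bonus = config$alive_bonus,
                                size_penalty = config$size_penalty)
  groups <- build_groups_at_year(elig, scores_year, config, quiet = quiet)
  study_year <- list()
  for (sex in c("F", "M")) {
    re <- study_year_records(elig, groups, "exceptional", sex, config)
    ro <- study_year_records(elig, groups, "ordinary", sex, config)
    study_year[[sex]] <- compare_groups(re, ro, config)
  }
  study_year$stratified <- stratified_compare(study_year[c("F", "M")], config)

  off <- offspring_groups(elig, scores_full, config)
  offspring <- list()
  for (sex in c("F", "M")) {
    re <- offspring_records(elig, off, "exceptional", sex)
    ro <- offspring_records(elig, off, "ordinary", sex)
    cmp <- compare_groups(re, ro, config)
    if (cmp$available) {
      cmp$pct_exceptional_survive <- 100 *
        mean(re$exit_age >= config$age_threshold)
      cmp$pct_ordinary_survive <- 100 *
        mean(ro$exit_age >= config$age_threshold)
    }
    offspring[[sex]] <- cmp
  }
  offspring$stratified <- stratified_compare(offspring[c("F", "M")], config)
  if (offspring$stratified$available) {
    w <- offspring$stratified$weights
    offspring$stratified$pct_exceptional_survive <-
      sum(w * vapply(offspring[c("F", "M")], `[[`, numeric(1),
                     "pct_exceptional_survive"))
    offspring$stratified$pct_ordinary_survive <-
      sum(w * vapply(offspring[c("F", "M")], `[[`, numeric(1),
                     "pct_ordinary_survive"))
  }

  counts <- list(
    n_individuals_raw = n_raw,
    n_individuals_included = n_individuals(flt),
    n_individuals_score_eligible = n_individuals(elig),
    n_sibships_scored = nrow(scores_full),
    n_exceptional_sibships = length(sel_exc),
    n_anti_sibships = length(sel_anti),
    pct_exceptional_sibships = 100 * length(sel_exc) / nrow(scores_full),
    n_alive_eligible = sum(groups$group != "excluded"),
    n_exceptional_group = sum(groups$group == "exceptional"),
    n_ordinary_group = sum(groups$group == "ordinary"),
    n_exceptional_offspring = sum(off$group == "exceptional"),
    n_ordinary_offspring = sum(off$group == "ordinary")
  )
  report <- list(
    config = config[c("study_year", "age_threshold", "floss_threshold",
                      "anti_threshold", "offspring_min_birth_year",
                      "base_age", "alive_bonus", "size_penalty",
                      "max_birth_year", "rmst_to_age", "seed")],
    counts = counts,
    floss = list(mean = summ$mean, sd = summ$sd,
                 n_sibships = summ$n_sibships,
                 sfloss_of_threshold = standardize_floss(
                   config$floss_threshold, summ)),
    study_year = study_year,
    offspring = offspring,
    tables = tables, scores = scores_full, scores_at_year = scores_year,
    groups = groups, offspring_assignment = off
  )
  class(report) <- "study_report"
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  c <- x$counts
  cat("study_report\n")
  cat(sprintf("  sample: %d raw -> %d included -> %d score-eligible\n",
              c$n_individuals_raw, c$n_individuals_included,
              c$n_individuals_score_eligible))
  cat(sprintf("  FLoSS over %d sibships: M = %.3f, S = %.3f; %d exceptional (%.1f%%), %d anti\n",
              c$n_sibships_scored, x$floss$mean, x$floss$sd,
              c$n_exceptional_sibships, c$pct_exceptional_sibships,
              c$n_anti_sibships))
  cat(sprintf("  study year %d: %d alive %d+ = %d exceptional + %d ordinary\n",
              x$config$study_year, c$n_alive_eligible,
              x$config$age_threshold, c$n_exceptional_group,
              c$n_ordinary_group))
  for (sex in names(x$study_year)) {
    g <- x$study_year[[sex]]
    if (isTRUE(g$available)) {
      lab <- if (sex == "stratified") "F+M (sex-stratified)" else sex
      cat(sprintf("    %s: log-rank chisq %.2f (p %.3g), RMST(%d-%g) gap %+.2f y\n",
                  lab, g$logrank_statistic, g$logrank_p, g$rmst_from,
                  g$rmst_to, g$rmst_gap))
    }
  }
  cat(sprintf("  offspring: %d exceptional vs %d ordinary\n",
              c$n_exceptional_offspring, c$n_ordinary_offspring))
  for (sex in names(x$offspring)) {
    g <- x$offspring[[sex]]
    if (isTRUE(g$available)) {
      lab <- if (sex == "stratified") "F+M (sex-stratified)" else sex
      cat(sprintf("    %s: %.1f%% vs %.1f%% reach %d; log-rank p %.3g, RMST gap %+.2f y\n",
                  lab, g$pct_exceptional_survive, g$pct_ordinary_survive,
                  x$config$age_threshold, g$logrank_p, g$rmst_gap))
    }
  }
  invisible(x)
}

strip_curves <- function(cmp) {
  cmp[setdiff(names(cmp),
              c("curve_exceptional", "curve_ordinary",
                "records_exceptional", "records_ordinary"))]
}

#' Write a study report to disk
#'
#' Emits `report.json` (counts, score summary, test statistics), the sibship
#' score table, group assignments, per-stratum life tables and per-sex group
#' survival curves as delimited text.
#'
#' @param report a `study_report` from [run_study()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "life_tables"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "curves"), showWarnings = FALSE)
  json <- list(config = report$config, counts = report$counts,
               floss = report$floss,
               study_year = lapply(report$study_year, strip_curves),
               offspring = lapply(report$offspring, strip_curves))
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_scores(report$scores, file.path(out_dir, "sibship_scores.csv"))
  utils::write.csv(report$groups, file.path(out_dir, "group_assignments.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(report$offspring_assignment,
                   file.path(out_dir, "offspring_assignment.csv"),
                   row.names = FALSE, quote = FALSE)
  for (k in names(report$tables)) {
    fn <- paste0(gsub("[^A-Za-z0-9]+", "_", k), ".csv")
    write_life_table(report$tables[[k]],
                     file.path(out_dir, "life_tables", fn))
  }
  for (part in c("study_year", "offspring")) {
    for (sex in names(report[[part]])) {
      g <- report[[part]][[sex]]
      if (!isTRUE(g$available) || is.null(g$curve_exceptional)) next
      for (grp in c("exceptional", "ordinary")) {
        fn <- sprintf("%s_%s_%s.csv", part, sex, grp)
        write_curve(g[[paste0("curve_", grp)]],
                    file.path(out_dir, "curves", fn))
      }
    }
  }
  invisible(out_dir)
}

#' Scan study years
#'
#' Recomputes the study-year group sizes over a range of candidate years
#' (scores are re-evaluated as of each year), to locate the year with the
#' largest exceptional sample.
#'
#' @param sample a `pedigree_sample` already filtered and score-eligible,
#'   with sibships derived.
#' @param tables a [build_life_tables()] set for the sample.
#' @param years integer vector of candidate study years.
#' @param config a [study_config()] (its `study_year` is overridden).
#' @return data.frame `year`, `n_alive_eligible`, `n_exceptional`,
#'   `n_ordinary`.
#' @export
sweep_study_years <- function(sample, tables, years,
                              config = study_config()) {
  rows <- lapply(years, function(y) {
    cfg <- config
    cfg$study_year <- as.integer(y)
    sc <- score_sibships(sample, tables, reference_year = y,
                         alive_bonus = cfg$alive_bonus,
                         size_penalty = cfg$size_penalty)
    g <- tryCatch(build_groups_at_year(sample, sc, cfg, quiet = TRUE),
                  error = function(e) NULL)
    if (is.null(g)) {
      data.frame(year = y, n_alive_eligible = 0L, n_exceptional = 0L,
                 n_ordinary = 0L)
    } else {
      data.frame(year = y,
                 n_alive_eligible = sum(g$group != "excluded"),
                 n_exceptional = sum(g$group == "exceptional"),
                 n_ordinary = sum(g$group == "ordinary"))
    }
  })
  do.call(rbind, rows)
}
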