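# Independent oracles and fixture builders shared across test files.

# Brute-force product-limit with delayed entry: literal risk-set enumeration,
# independent of the survfit-based implementation path.
bf_km <- function(entry, exit, event) {
  times <- sort(unique(exit[event]))
  s <- 1
  surv <- numeric(length(times))
  for (i in seq_along(times)) {
    t <- times[i]
    n <- sum(entry < t & t <= exit)
    d <- sum(event & exit == t)
    s <- if (n > 0) s * (1 - d / n) else NA_real_
    surv[i] <- s
  }
  data.frame(age = times, survival = surv)
}

# quick individuals table with per-field defaults
ped_df <- function(person_id, sex = "F", birth_year = 1850,
                   death_year = NA, last_alive_year = NA,
                   mother_id = NA, father_id = NA, adopted = FALSE) {
  n <- length(person_id)
  data.frame(
    person_id = person_id,
    sex = rep_len(sex, n),
    birth_year = rep_len(birth_year, n),
    death_year = rep_len(death_year, n),
    last_alive_year = rep_len(last_alive_year, n),
    mother_id = rep_len(mother_id, n),
    father_id = rep_len(father_id, n),
    adopted = rep_len(adopted, n),
    stringsAsFactors = FALSE
  )
}

# closed-form conditional Gompertz table on an integer grid (the null law
# used for score calibration): S(t | base) = exp(-(a/b)(e^{bt} - e^{b base}))
gompertz_table <- function(sex = "F", a = 1e-4, b = log(2) / 8,
                           base_age = 40, max_age = 115) {
  ages <- base_age:max_age
  s <- exp(-(a / b) * (exp(b * ages) - exp(b * base_age)))
  cohort_life_table(ages, s, sex = sex, band = "null", base_age = base_age)
}

# correlation of age at death between relatives
pair_cor <- function(x, y) stats::cor(c(x, y), c(y, x))

sib_death_cor <- function(sample) {
  ind <- sample$individuals
  dead <- !is.na(ind$death_year)
  age <- ind$death_year - ind$birth_year
  xs <- c(); ys <- c()
  for (ages in split(age[dead], ind$sibship_id[dead])) {
    k <- length(ages)
    if (k < 2) next
    pr <- utils::combn(k, 2)
    xs <- c(xs, ages[pr[1, ]])
    ys <- c(ys, ages[pr[2, ]])
  }
  pair_cor(xs, ys)
}

parent_offspring_death_cor <- function(sample) {
  ind <- sample$individuals
  age <- ind$death_year - ind$birth_year
  xs <- c(); ys <- c()
  for (pcol in c("mother_id", "father_id")) {
    j <- match(ind[[pcol]], ind$person_id)
    ok <- !is.na(j) & !is.na(age) & !is.na(age[ifelse(is.na(j), 1L, j)])
    xs <- c(xs, age[ifelse(is.na(j), 1L, j)][ok])
    ys <- c(ys, age[ok])
  }
  stats::cor(xs, ys)
}

# The frailty study fixture: defaults of sim_params() are the study
# conditions; generated once per test session and reused.
.fixture <- new.env(parent = emptyenv())

frailty_fixture <- function() {
  if (is.null(.fixture$sample)) {
    .fixture$params <- sim_params()
    .fixture$sample <- simulate_pedigrees(.fixture$params, seed = 42)
    .fixture$report <- suppressWarnings(
      run_study(.fixture$sample, study_config(), quiet = TRUE))
  }
  .fixture
}
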