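# Gompertz draws: hazard h(t) = a * z * exp(b t); inverse-transform sampling,
# optionally conditional on surviving past min_age.
rgompertz <- function(n, a, b, z = 1, min_age = 0) {
  u <- stats::runif(n)
  h_min <- (a * z / b) * (exp(b * min_age) - 1)
  log1p((b / (a * z)) * (h_min - log(u))) / b
}

# zero-truncated Poisson with a given mean (> 1)
rztpois <- function(n, mean) {
  stopifnot(mean > 1)
  lambda <- stats::uniroot(function(l) l / (1 - exp(-l)) - mean,
                           c(1e-8, mean))$root
  u <- stats::runif(n, exp(-lambda), 1)
  stats::qpois(u, lambda)
}

rfrailty <- function(n, variance) {
  if (variance <= 0) rep(1, n) else {
    stats::rgamma(n, shape = 1 / variance, rate = 1 / variance)
  }
}

#' Simulation parameters for synthetic pedigrees
#'
#' Defaults describe the nineteenth-century settler-registry conditions the
#' pipeline is
#' designed for: births 1779-1910, mortality follow-up through 2013, large
#' sibships, familial clustering of lifespan through a shared gamma frailty
#' on a Gompertz hazard (log-hazard doubling time about 8 years), and weaker
#' parent-to-offspring transmission than sib-sib sharing.
#'
#' @param n_families number of founder families.
#' @param mean_sibship_size mean size of the index (parental-generation)
#'   sibships; sizes are zero-truncated Poisson.
#' @param mean_offspring mean number of children per reproducing index
#'   member (Poisson, may be zero).
#' @param birth_year_range two integers; all generated births fall inside.
#' @param followup_end administrative end of mortality follow-up.
#' @param gompertz_a baseline hazard scale at age 0 (per year), female.
#' @param gompertz_b log-hazard slope per year of age (doubling time
#'   log(2)/b).
#' @param sex_hazard_ratio male/female proportional-hazard ratio.
#' @param frailty_variance variance of the gamma family frailty (mean 1).
#' @param heritability_weight weight of mid-parent frailty in an offspring
#'   sibship's frailty; the remainder is a fresh gamma draw.
#' @param censor_rate per-year loss-to-follow-up hazard.
#' @param adopted_rate probability a sibling is flagged adopted.
#' @param missing_rate probability an individual's vital year is blanked.
#' @param seed integer seed used by [simulate_pedigrees()] when none is
#'   passed there.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(n_families = 5000,
                       mean_sibship_size = 6,
                       mean_offspring = 6,
                       birth_year_range = c(1779, 1910),
                       followup_end = 2013,
                       gompertz_a = 1e-4,
                       gompertz_b = log(2) / 8,
                       sex_hazard_ratio = 1.5,
                       frailty_variance = 0.3,
                       heritability_weight = 0.5,
                       censor_rate = 0.002,
                       adopted_rate = 0.01,
                       missing_rate = 0.005,
                       seed = 1L) {
  p <- list(n_families = as.integer(n_families),
            mean_sibship_size = mean_sibship_size,
            mean_offspring = mean_offspring,
            birth_year_range = as.integer(birth_year_range),
            followup_end = as.integer(followup_end),
            gompertz_a = gompertz_a, gompertz_b = gompertz_b,
            sex_hazard_ratio = sex_hazard_ratio,
            frailty_variance = frailty_variance,
            heritability_weight = heritability_weight,
            censor_rate = censor_rate, adopted_rate = adopted_rate,
            missing_rate = missing_rate, seed = as.integer(seed))
  if (p$n_families < 1L) stop("n_families must be at least 1")
  stopifnot(p$gompertz_a > 0, p$gompertz_b > 0, p$frailty_variance >= 0,
            p$heritability_weight >= 0, p$heritability_weight <= 1,
            p$censor_rate >= 0, p$censor_rate <= 1,
            p$adopted_rate >= 0, p$adopted_rate <= 1,
            p$missing_rate >= 0, p$missing_rate <= 1,
            length(p$birth_year_range) == 2L,
            p$birth_year_range[1] < p$birth_year_range[2])
  class(p) <- "sim_params"
  p
}

#' Simulate a two-generation pedigree sample
#'
#' Generates founder couples, their children (the index sibships, born up to
#' 1880) and grandchildren (offspring sibships, born 1881 up to the birth-year
#' cap), with lifespans from a Gompertz hazard multiplied by a gamma family
#' frailty: index siblings share their family's frailty, and each offspring
#' sibship's frailty mixes the mid-parent frailty (weight
#' `heritability_weight`) with a fresh draw, giving sib-sib lifespan
#' correlation stronger than parent-offspring correlation. Loss to follow-up
#' and the administrative end of follow-up produce last known-alive years;
#' adoption flags and missing vital years are injected at the configured
#' rates. Deterministic given the seed.
#'
#' @param params a [sim_params()] list.
#' @param seed overrides `params$seed`.
#' @return a `pedigree_sample` with sibship-truth frailties in
#'   `attr(, "truth")` (data.frame `person_id`, `generation`, `frailty`),
#'   for validation only.
#' @export
simulate_pedigrees <- function(params = sim_params(), seed = params$seed) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(seed)
  nf <- params$n_families
  yr0 <- params$birth_year_range[1]
  yr1 <- params$birth_year_range[2]
  parent_cap <- min(1880L, yr1)
  a <- params$gompertz_a; b <- params$gompertz_b
  hr <- params$sex_hazard_ratio
  v <- params$frailty_variance; w <- params$heritability_weight

  sex_a <- function(sex) ifelse(sex == "M", a * hr, a)

  # --- index sibships -------------------------------------------------------
  k <- rztpois(nf, params$mean_sibship_size)
  first_birth <- sample(seq(yr0 + 26L, parent_cap - 12L), nf, replace = TRUE)
  fam <- rep(seq_len(nf), k)
  within <- sequence(k)
  gaps <- sample(1:3, length(fam), replace = TRUE)
  gaps[within == 1L] <- 0L
  offs <- stats::ave(gaps, fam, FUN = cumsum)
  sib_birth <- pmin(first_birth[fam] + offs, parent_cap)
  sib_sex <- sample(c("F", "M"), length(fam), replace = TRUE)
  z_fam <- rfrailty(nf, v)
  sib_T <- rgompertz(length(fam), sex_a(sib_sex), b, z_fam[fam])
  sib_id <- sprintf("F%05d.S%d", fam, within)

  # --- founders (parents of the index sibships) -----------------------------
  mo_birth <- first_birth - sample(18:26, nf, replace = TRUE)
  fa_birth <- pmax(mo_birth + sample(-3:3, nf, replace = TRUE), yr0)
  last_child <- first_birth + stats::ave(offs, fam, FUN = max)[within == 1L]
  mo_T <- rgompertz(nf, a, b, rfrailty(nf, v),
                    min_age = pmax(last_child - mo_birth, 0))
  fa_T <- rgompertz(nf, a * hr, b, rfrailty(nf, v),
                    min_age = pmax(last_child - fa_birth, 0))
  mo_id <- sprintf("F%05d.MO", seq_len(nf))
  fa_id <- sprintf("F%05d.FA", seq_len(nf))

  # --- offspring of index members -------------------------------------------
  can_parent <- sib_T >= 45 & sib_birth + 21 <= yr1
  n_child <- integer(length(fam))
  n_child[can_parent] <- stats::rpois(sum(can_parent), params$mean_offspring)
  parent_idx <- rep(seq_along(fam), n_child)
  ch_within <- sequence(n_child)
  ch_gaps <- sample(1:3, length(parent_idx), replace = TRUE)
  ch_gaps[ch_within == 1L] <- 0L
  ch_off <- if (length(parent_idx)) {
    stats::ave(ch_gaps, parent_idx, FUN = cumsum)
  } else integer(0)
  couple <- match(parent_idx, unique(parent_idx))
  first_ch_off <- sample(0:8, length(unique(parent_idx)), replace = TRUE)
  ch_birth <- sib_birth[parent_idx] + 21L + first_ch_off[couple] + ch_off
  # keep offspring born inside the window and during the parent's lifetime
  keep_ch <- ch_birth > parent_cap & ch_birth <= yr1 &
    ch_birth <= sib_birth[parent_idx] + sib_T[parent_idx]
  parent_idx <- parent_idx[keep_ch]
  ch_within <- ch_within[keep_ch]
  ch_birth <- ch_birth[keep_ch]

  # spouses: one per index member that actually has kept offspring
  sp_of <- unique(parent_idx)
  sp_birth <- pmax(sib_birth[sp_of] + sample(-4:4, length(sp_of),
                                             replace = TRUE), yr0)
  sp_sex <- ifelse(sib_sex[sp_of] == "F", "M", "F")
  z_sp <- rfrailty(length(sp_of), v)
  last_ch <- tapply(ch_birth, parent_idx, max)[as.character(sp_of)]
  sp_T <- rgompertz(length(sp_of), sex_a(sp_sex), b, z_sp,
                    min_age = pmax(as.numeric(last_ch) - sp_birth, 0))
  sp_id <- sprintf("%s.SP", sib_id[sp_of])

  # spouses' own parents, so a spouse's sibship passes the parent-information
  # inclusion criterion and the spouse is scoreable like any other member
  spmo_birth <- pmax(sp_birth - sample(18:26, length(sp_of), replace = TRUE),
                     yr0)
  spfa_birth <- pmax(spmo_birth + sample(-3:3, length(sp_of), replace = TRUE),
                     yr0)
  spmo_T <- rgompertz(length(sp_of), a, b, rfrailty(length(sp_of), v),
                      min_age = pmax(sp_birth - spmo_birth, 0))
  spfa_T <- rgompertz(length(sp_of), a * hr, b, rfrailty(length(sp_of), v),
                      min_age = pmax(sp_birth - spfa_birth, 0))
  spmo_id <- sprintf("%s.MO", sp_id)
  spfa_id <- sprintf("%s.FA", sp_id)

  sp_row <- match(parent_idx, sp_of)
  z_mid <- (z_fam[fam[parent_idx]] + z_sp[sp_row]) / 2
  # one frailty per offspring sibship (= per couple)
  z_off_sib <- w * z_mid[!duplicated(parent_idx)] +
    (1 - w) * rfrailty(length(sp_of), v)
  z_off <- z_off_sib[sp_row]
  ch_sex <- sample(c("F", "M"), length(parent_idx), replace = TRUE)
  ch_T <- rgompertz(length(parent_idx), sex_a(ch_sex), b, z_off)
  ch_id <- sprintf("%s.C%d", sib_id[parent_idx], ch_within)
  ch_mo <- ifelse(sib_sex[parent_idx] == "F", sib_id[parent_idx],
                  sp_id[sp_row])
  ch_fa <- ifelse(sib_sex[parent_idx] == "M", sib_id[parent_idx],
                  sp_id[sp_row])

  # --- assemble -------------------------------------------------------------
  nsp <- length(sp_of)
  df <- data.frame(
    person_id = c(mo_id, fa_id, sib_id, sp_id, spmo_id, spfa_id, ch_id),
    sex = c(rep("F", nf), rep("M", nf), sib_sex, sp_sex,
            rep("F", nsp), rep("M", nsp), ch_sex),
    birth_year = as.integer(c(mo_birth, fa_birth, sib_birth, sp_birth,
                              spmo_birth, spfa_birth, ch_birth)),
    lifespan = c(mo_T, fa_T, sib_T, sp_T, spmo_T, spfa_T, ch_T),
    mother_id = c(rep(NA_character_, 2L * nf), mo_id[fam], spmo_id,
                  rep(NA_character_, 2L * nsp), ch_mo),
    father_id = c(rep(NA_character_, 2L * nf), fa_id[fam], spfa_id,
                  rep(NA_character_, 2L * nsp), ch_fa),
    generation = c(rep("founder", 2L * nf), rep("index", length(fam)),
                   rep("spouse", nsp), rep("founder", 2L * nsp),
                   rep("offspring", length(parent_idx))),
    frailty = c(rep(NA_real_, 2L * nf), z_fam[fam], z_sp,
                rep(NA_real_, 2L * nsp), z_off),
    stringsAsFactors = FALSE
  )

  n <- nrow(df)
  death_age <- floor(df$lifespan)
  death_year <- df$birth_year + death_age
  censor_age <- if (params$censor_rate > 0) {
    floor(stats::rexp(n, params$censor_rate))
  } else rep(Inf, n)
  censored_ltfu <- censor_age < death_age
  end_is_death <- !censored_ltfu &
    (df$birth_year + death_age) <= params$followup_end
  df$death_year <- ifelse(end_is_death, death_year, NA_integer_)
  df$last_alive_year <- ifelse(
    end_is_death, NA_integer_,
    pmin(ifelse(censored_ltfu, df$birth_year + censor_age, Inf),
         params$followup_end))
  # censoring cannot precede birth
  df$last_alive_year <- ifelse(!is.na(df$last_alive_year),
                               pmax(df$last_alive_year, df$birth_year),
                               df$last_alive_year)

  df$adopted <- df$generation %in% c("index", "offspring") &
    stats::runif(n) < params$adopted_rate
  blank <- stats::runif(n) < params$missing_rate
  df$death_year[blank] <- NA_integer_
  df$last_alive_year[blank] <- NA_integer_

  truth <- data.frame(person_id = df$person_id,
                      generation = df$generation,
                      frailty = df$frailty, stringsAsFactors = FALSE)
  out <- pedigree_sample(
    df[PEDIGREE_COLUMNS],
    provenance = sprintf("simulated Gompertz-gamma pedigree (seed %d)", seed))
  attr(out, "truth") <- truth
  out
}

#' Draw lifespans from a life table's own law
#'
#' Inverse-transform sampling through the same log-linear interpolation of
#' the tabulated survival that [lookup_survival()] uses, so
#' -log S(T | base age) of a draw is exactly -log U: unit-exponential up to
#' truncation at the table's last positive survival. Used to calibrate the
#' null distribution of the exceptionality score.
#'
#' @param table a [cohort_life_table()].
#' @param n number of draws.
#' @param seed optional seed.
#' @return numeric lifespans (continuous ages within the table's support).
#' @export
simulate_null_from_table <- function(table, n, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  a <- table$age
  s <- table$survival
  pos <- s > 0
  a <- a[pos]; s <- s[pos]
  # keep the last age of any flat run so the inverse is well defined
  keep <- !duplicated(s, fromLast = TRUE)
  a <- a[keep]; s <- s[keep]
  u <- stats::runif(n)
  if (length(a) == 1L) return(rep(a, n))
  # survival is strictly decreasing here; reverse for an increasing grid
  out <- stats::approx(x = rev(log(s)), y = rev(a), xout = log(u), rule = 2,
                       ties = "ordered")$y
  as.numeric(out)
}
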