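# table engineered so that deaths at 50/60/70 have survival 0.5,
# exp(-2.6094), 0.05 — giving member exceedances 0.6931, 2.6094, 2.9957
toy_table <- function(sex = "F") {
  cohort_life_table(c(40, 50, 60, 70), c(1, 0.5, exp(-2.6094), 0.05),
                    sex = sex, band = "toy")
}

toy_table_set <- function() {
  bands <- cohort_bands(1779, 1910)
  structure(
    list("F|1850-1859" = toy_table("F"), "M|1850-1859" = toy_table("M")),
    bands = bands, base_age = 40L, class = "life_table_set")
}

test_that("individual scores follow -log survival with an alive bonus", {
  tab <- toy_table()
  dead40 <- individual_score(list(person_id = "a", sex = "F",
                                  birth_year = 1850, death_year = 1890,
                                  last_alive_year = NA), tab)
  expect_equal(dead40$total, 0)  # S(40) = 1
  dead70 <- individual_score(list(person_id = "b", sex = "F",
                                  birth_year = 1850, death_year = 1920,
                                  last_alive_year = NA), tab)
  expect_equal(dead70$total, -log(0.05), tolerance = 1e-6)
  expect_equal(round(dead70$total, 4), 2.9957)
  alive70 <- individual_score(list(person_id = "c", sex = "F",
                                   birth_year = 1850, death_year = NA,
                                   last_alive_year = 1920), tab)
  expect_equal(alive70$total, -log(0.05) + 1, tolerance = 1e-6)
  expect_equal(alive70$bonus, 1)
  # guards
  expect_error(individual_score(list(person_id = "d", sex = "M",
                                     birth_year = 1850, death_year = 1920,
                                     last_alive_year = NA), tab), "sex")
  expect_error(individual_score(list(person_id = "e", sex = "F",
                                     birth_year = 1850, death_year = 1885,
                                     last_alive_year = NA), tab),
               "not score-eligible")
})

test_that("a reference year recomputes vital status as of that year", {
  tab <- toy_table()
  # died 1920 but alive in 1910 at age 60: scored as living then
  sc <- individual_score(list(person_id = "a", sex = "F", birth_year = 1850,
                              death_year = 1920, last_alive_year = NA),
                         tab, reference_year = 1910)
  expect_true(sc$alive_at_reference)
  expect_equal(sc$attained_age, 60)
  expect_equal(sc$total, 2.6094 + 1, tolerance = 1e-6)
  # censored before the reference year: no bonus, last-known age
  sc2 <- individual_score(list(person_id = "b", sex = "F", birth_year = 1850,
                               death_year = NA, last_alive_year = 1900),
                          tab, reference_year = 1910)
  expect_false(sc2$alive_at_reference)
  expect_equal(sc2$attained_age, 50)
})

test_that("sibship FLoSS sums member exceedances with size centering", {
  df <- ped_df(c("a", "b", "c"), birth_year = 1850,
               death_year = c(1920, 1910, 1900),  # ages 70, 60, 50
               mother_id = "m", father_id = "f")
  s <- derive_sibships(pedigree_sample(df))
  sib <- s$sibships$sibship_id[s$sibships$n_members == 3]
  raw <- sibship_floss(sib, s, toy_table_set(), size_penalty = 0)
  expect_equal(raw$floss, 6.2982, tolerance = 2e-4)  # 2.9957+2.6094+0.6931
  expect_equal(raw$n_members_scored, 3)
  expect_equal(raw$n_alive, 0)
  centered <- sibship_floss(sib, s, toy_table_set())
  expect_equal(centered$floss, raw$floss - 3)
  # member order is irrelevant
  s2 <- s
  s2$individuals <- s2$individuals[c(3, 1, 2), ]
  expect_equal(sibship_floss(sib, s2, toy_table_set())$floss, centered$floss)
  # single member dying at the base age scores exactly -size_penalty
  df1 <- ped_df("z", birth_year = 1850, death_year = 1890)
  s1 <- derive_sibships(pedigree_sample(df1))
  expect_equal(sibship_floss(s1$sibships$sibship_id, s1, toy_table_set(),
                             size_penalty = 0)$floss, 0)
})

test_that("score_sibships agrees with per-sibship scoring", {
  set.seed(9)
  n <- 40
  df <- ped_df(sprintf("p%02d", 1:n), birth_year = 1850,
               sex = sample(c("F", "M"), n, TRUE),
               death_year = 1850 + sample(41:75, n, TRUE),
               mother_id = sample(paste0("m", 1:8), n, TRUE),
               father_id = "f")
  s <- derive_sibships(pedigree_sample(df))
  all_scores <- score_sibships(s, toy_table_set())
  for (i in sample(nrow(all_scores), 5)) {
    one <- sibship_floss(all_scores$sibship_id[i], s, toy_table_set())
    expect_equal(all_scores$floss[i], one$floss)
    expect_equal(all_scores$n_members_scored[i], one$n_members_scored)
  }
})

test_that("score summary and standardization arithmetic", {
  expect_error(summarize_floss(c(0, 0, 0)), "degenerate")
  sm <- summarize_floss(c(1, 3))
  expect_equal(sm$mean, 2)
  expect_equal(sm$sd, sqrt(2))
  expect_equal(standardize_floss(sm$mean, sm), 0)
  expect_equal(standardize_floss(sm$mean + sm$sd, sm), 1)
  # standardization at the published summary statistics of the score
  pub <- list(mean = -0.234, sd = 2.9)
  expect_equal(round(standardize_floss(7, pub), 4), 2.4945)
  expect_error(summarize_floss(1), "at least 2")
})

test_that("threshold selection is inclusive and direction-aware", {
  sc <- data.frame(sibship_id = c("s1", "s2", "s3"),
                   floss = c(6.9, 7.0, 7.1))
  expect_equal(select_sibships(sc, 7, "ge"), c("s2", "s3"))
  sc2 <- data.frame(sibship_id = c("s1", "s2"), floss = c(-5, 0))
  expect_equal(select_sibships(sc2, -4.5, "le"), "s1")
  expect_equal(select_sibships(sc, -100, "ge"), c("s1", "s2", "s3"))
  expect_equal(select_sibships(sc, 100, "ge"), character(0))
})

test_that("score is non-decreasing in attained age and truncated at zero survival", {
  tab0 <- cohort_life_table(c(40, 60, 80, 90), c(1, 0.5, 0.01, 0),
                            sex = "F", band = "toy")
  u <- survival_exceptionality(tab0, seq(40, 95, by = 1))$total
  expect_true(all(diff(u) >= -1e-12))
  # beyond S = 0 the score is pinned at -log(min positive survival)
  expect_equal(survival_exceptionality(tab0, 95)$total, -log(0.01))
})

test_that("null draws from a table calibrate the score to unit exponential", {
  tab <- gompertz_table()
  T <- simulate_null_from_table(tab, 20000, seed = 77)
  expect_true(all(T >= 40 & T <= max(tab$age)))
  u <- survival_exceptionality(tab, T)$total
  expect_lt(abs(mean(u) - 1), 0.05)
  # memorylessness: expected exceedance beyond age 80 is ~1 among survivors
  past80 <- T > 80
  u80 <- survival_exceptionality(tab, 80)$total
  expect_lt(abs(mean(u[past80]) - u80 - 1), 3 / sqrt(sum(past80)))
  # single draw is within support
  expect_length(simulate_null_from_table(tab, 1, seed = 1), 1)
})

test_that("empirical survival of null draws matches the source table", {
  tab <- gompertz_table()
  T <- simulate_null_from_table(tab, 50000, seed = 88)
  emp <- vapply(tab$age, function(t) mean(T > t), numeric(1))
  expect_lt(max(abs(emp - tab$survival)), 0.01)
})

test_that("families selected by high score carry below-average frailty", {
  fx <- frailty_fixture()
  rep <- fx$report
  sel <- select_sibships(rep$scores, 7, "ge")
  ind <- rep$groups  # any person table would do; need sibship lookup
  samp <- fx$sample
  truth <- attr(samp, "truth")
  # map members of scored sibships to their true frailty
  elig_ids <- attr(rep$scores, "member_scores")$person_id
  sib_of <- attr(rep$scores, "member_scores")$sibship_id
  z <- truth$frailty[match(elig_ids, truth$person_id)]
  ok <- !is.na(z)
  expect_lt(mean(z[ok & sib_of %in% sel]), mean(z[ok]))
})
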