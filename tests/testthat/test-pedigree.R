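test_that("pedigree files round-trip and map fields faithfully", {
  df <- ped_df(c("a", "b", "c"), sex = c("F", "M", "F"),
               birth_year = c(1850, 1852, 1855),
               death_year = c(1920, 1931, NA),
               last_alive_year = c(NA, NA, 1940),
               mother_id = c("m1", "m1", NA), father_id = c("f1", "f1", NA),
               adopted = c(FALSE, FALSE, TRUE))
  path <- withr::local_tempfile(fileext = ".csv")
  write_pedigree(pedigree_sample(df), path)
  got <- read_pedigree(path)
  expect_equal(n_individuals(got), 3)
  expect_equal(sum(is.na(got$individuals$death_year)), 1)  # one censored
  expect_equal(got$individuals[names(df)], df, ignore_attr = TRUE)
  # write(read(write(x))) is stable
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_pedigree(got, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("invariant-violating rows are rejected with diagnostics", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "person_id,sex,birth_year,death_year,last_alive_year,mother_id,father_id,adopted",
    "a,F,1850,1920,,,,0",
    "b,M,1850,1840,,,,0",   # dies before birth
    "c,F,1850,,,,,0"        # no vital year at all
  ), path)
  expect_message(got <- read_pedigree(path), "rejected 2 row")
  expect_equal(n_individuals(got), 1)
  rej <- attr(got, "rejected")
  expect_setequal(rej$person_id, c("b", "c"))
  expect_match(rej$reason[rej$person_id == "b"], "before birth")
})

test_that("structural file problems are errors naming the cause", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "person_id,sex,birth_year,death_year,last_alive_year,mother_id,father_id,adopted",
    "a,F,1850,1920,,,,0",
    "a,M,1851,1921,,,,0"
  ), path)
  expect_error(read_pedigree(path), "duplicate person_id")
  writeLines(c(
    "person_id,sex,birth_year,death_year,last_alive_year,mother_id,father_id,adopted",
    "a,F,18xx,1920,,,,0"
  ), path)
  expect_error(read_pedigree(path), "unparsable birth_year.*row")
  writeLines(c("person_id,sex,birth_year", "a,F,1850"), path)
  expect_error(read_pedigree(path), "required column")
})

test_that("sibships partition the sample with full-sib keying", {
  df <- ped_df(c("a", "b", "c", "d"),
               mother_id = c("m1", "m1", "m1", NA),
               father_id = c("f1", "f1", "f2", NA),
               death_year = 1900)
  s <- derive_sibships(pedigree_sample(df))
  sib <- s$individuals$sibship_id
  expect_equal(sib[1], sib[2])      # share both parents
  expect_false(sib[2] == sib[3])    # half-sibs split
  expect_equal(nrow(s$sibships), 3)
  expect_equal(sort(s$sibships$n_members), c(1L, 1L, 2L))
  # mother-only keying merges the half-sibs
  s2 <- derive_sibships(pedigree_sample(df), key = "mother_only")
  expect_equal(length(unique(s2$individuals$sibship_id[1:3])), 1L)
})

test_that("derived sibships match brute-force grouping on random pedigrees", {
  set.seed(11)
  for (rep in 1:5) {
    n <- sample(10:40, 1)
    df <- ped_df(sprintf("p%02d", seq_len(n)),
                 mother_id = sample(c(NA, paste0("m", 1:4)), n, replace = TRUE),
                 father_id = sample(c(NA, paste0("f", 1:4)), n, replace = TRUE),
                 death_year = 1900)
    s <- derive_sibships(pedigree_sample(df))
    sib <- s$individuals$sibship_id
    # partition: every individual in exactly one sibship, sizes sum to n
    expect_equal(sum(s$sibships$n_members), n)
    expect_setequal(unique(sib), s$sibships$sibship_id)
    # same sibship iff both parents known and equal
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      same <- !is.na(df$mother_id[i]) && !is.na(df$father_id[i]) &&
        identical(df$mother_id[i], df$mother_id[j]) &&
        identical(df$father_id[i], df$father_id[j])
      expect_equal(sib[i] == sib[j], same)
    }
  }
})

make_filter_sample <- function() {
  # three sibships: k1/k2 pass everything; k3/k4 contain an 1911 birth;
  # k5's father lacks any vital year
  df <- rbind(
    ped_df(c("pm", "pf", "rm", "rf"), sex = c("F", "M", "F", "M"),
           birth_year = 1820, death_year = 1890),
    ped_df(c("qm", "qf"), sex = c("F", "M"), birth_year = 1820,
           death_year = c(1890, NA), last_alive_year = c(NA, NA)),
    ped_df(c("k1", "k2"), birth_year = c(1850, 1852), death_year = 1930,
           mother_id = "pm", father_id = "pf"),
    ped_df(c("k3", "k4"), birth_year = c(1905, 1911), death_year = 1980,
           mother_id = "rm", father_id = "rf"),
    ped_df("k5", birth_year = 1850, death_year = 1930,
           mother_id = "qm", father_id = "qf")
  )
  suppressMessages(derive_sibships(pedigree_sample(df)))
}

test_that("inclusion filters drop whole sibships per criterion", {
  s <- make_filter_sample()
  expect_message(f <- apply_inclusion_filters(s, 1910), "dropped")
  ids <- f$individuals$person_id
  expect_setequal(ids, c("k1", "k2"))        # k3 dropped with k4 (born 1911)
  expect_false(any(c("k5") %in% ids))        # father qf lacks vital year
  counts <- attr(f, "filter_counts")
  expect_equal(unname(counts["criterion1_birth_year"]), 1)
  expect_true(counts["criterion3_parent_vital"] >= 1)
  # idempotence and no surviving violation under brute-force rescan
  f2 <- suppressMessages(apply_inclusion_filters(f, 1910))
  expect_identical(f$individuals, f2$individuals)
  expect_true(all(f$individuals$birth_year <= 1910))
  expect_true(all(!is.na(f$individuals$death_year) |
                    !is.na(f$individuals$last_alive_year)))
})

test_that("score eligibility removes adoptees and pre-40 deaths, keeps age-40 deaths", {
  df <- rbind(
    ped_df(c("a", "b", "c", "d"), birth_year = 1850,
           death_year = c(1889, 1890, 1930, 1935),  # ages 39, 40, 80, 85
           mother_id = "m", father_id = "f"),
    ped_df("e", birth_year = 1850, death_year = 1930,
           mother_id = "m", father_id = "f", adopted = TRUE)
  )
  s <- derive_sibships(pedigree_sample(df))
  e <- suppressMessages(apply_score_eligibility(s, 40))
  expect_setequal(e$individuals$person_id, c("b", "c", "d"))
  expect_equal(e$sibships$n_members, 3L)
  # idempotent, and identity on a clean sample
  e2 <- suppressMessages(apply_score_eligibility(e, 40))
  expect_identical(e$individuals, e2$individuals)
})
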