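#' @keywords internal
"_PACKAGE"

PEDIGREE_COLUMNS <- c(
  "person_id", "sex", "birth_year", "death_year", "last_alive_year",
  "mother_id", "father_id", "adopted"
)

#' Construct a pedigree sample
#'
#' A pedigree sample is the central container of the package: one row per
#' individual with identifiers, sex, birth year, a death year or last
#' known-alive year, parent links and an adoption flag. Sibships (full-sib
#' groups) are attached by [derive_sibships()].
#'
#' @param individuals data.frame with columns `person_id` (character, unique),
#'   `sex` ("F"/"M"), `birth_year` (integer), `death_year`, `last_alive_year`
#'   (integer or `NA`; at least one present for an individual to be
#'   analyzable), `mother_id`, `father_id` (character or `NA`), `adopted`
#'   (logical).
#' @param sibships optional data.frame as built by [derive_sibships()].
#' @param provenance free-text source label.
#' @return An object of class `pedigree_sample`.
#' @export
pedigree_sample <- function(individuals, sibships = NULL, provenance = "") {
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  missing_cols <- setdiff(PEDIGREE_COLUMNS, names(individuals))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  individuals <- individuals[PEDIGREE_COLUMNS]
  individuals$person_id <- as.character(individuals$person_id)
  individuals$sex <- as.character(individuals$sex)
  individuals$birth_year <- as.integer(individuals$birth_year)
  individuals$death_year <- as.integer(individuals$death_year)
  individuals$last_alive_year <- as.integer(individuals$last_alive_year)
  individuals$mother_id <- as.character(individuals$mother_id)
  individuals$father_id <- as.character(individuals$father_id)
  individuals$adopted <- as.logical(individuals$adopted)
  if (anyDuplicated(individuals$person_id)) {
    stop("duplicate person_id: ",
         paste(unique(individuals$person_id[duplicated(individuals$person_id)]),
               collapse = ", "))
  }
  bad_sex <- !individuals$sex %in% c("F", "M")
  if (any(bad_sex)) stop("sex must be 'F' or 'M' (rows ",
                         paste(which(bad_sex), collapse = ", "), ")")
  bad_death <- !is.na(individuals$death_year) &
    individuals$death_year < individuals$birth_year
  bad_alive <- !is.na(individuals$last_alive_year) &
    individuals$last_alive_year < individuals$birth_year
  if (any(bad_death | bad_alive)) {
    stop("death_year/last_alive_year before birth_year (rows ",
         paste(which(bad_death | bad_alive), collapse = ", "), ")")
  }
  rownames(individuals) <- NULL
  structure(
    list(individuals = individuals, sibships = sibships,
         provenance = provenance),
    class = "pedigree_sample"
  )
}

#' @export
print.pedigree_sample <- function(x, ...) {
  cat("pedigree_sample:", nrow(x$individuals), "individuals")
  if (!is.null(x$sibships)) cat(",", nrow(x$sibships), "sibships")
  if (nzchar(x$provenance)) cat(" [", x$provenance, "]", sep = "")
  cat("\n")
  n_dead <- sum(!is.na(x$individuals$death_year))
  cat("  deaths:", n_dead, " censored:", nrow(x$individuals) - n_dead, "\n")
  invisible(x)
}

#' Number of individuals in a pedigree sample
#' @param sample a `pedigree_sample`.
#' @return integer count.
#' @export
n_individuals <- function(sample) nrow(sample$individuals)

# end-of-observation year: death year if known, else last known-alive year
end_year <- function(individuals) {
  ifelse(is.na(individuals$death_year),
         individuals$last_alive_year, individuals$death_year)
}

#' Attained age of each individual
#'
#' Age at death for the deceased, age at the last known-alive year for the
#' censored, as an integer calendar-year difference.
#'
#' @param sample a `pedigree_sample`.
#' @return integer vector aligned with `sample$individuals`.
#' @export
attained_age <- function(sample) {
  as.integer(end_year(sample$individuals) - sample$individuals$birth_year)
}

parse_year_column <- function(x, column, path) {
  x <- trimws(x)
  out <- suppressWarnings(as.integer(x))
  bad <- which(!is.na(x) & nzchar(x) & is.na(out))
  if (length(bad) > 0L) {
    stop("unparsable ", column, " in ", basename(path),
         " at data row(s) ", paste(bad, collapse = ", "),
         ": ", paste(unique(x[bad]), collapse = ", "))
  }
  out[!nzchar(ifelse(is.na(x), "", x))] <- NA_integer_
  out
}

#' Read a pedigree file
#'
#' Reads a delimited pedigree file (header row, UTF-8, empty string = absent
#' value) into a [pedigree_sample()]. Rows violating individual-level
#' invariants (no vital-status year at all, death or last-alive year before
#' birth, unknown sex code) are dropped with row-level diagnostics available
#' via `attr(, "rejected")`; structural problems (missing columns, duplicate
#' identifiers, unparsable years) are errors.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"tsv"`.
#' @param quiet suppress the rejected-row message.
#' @return a `pedigree_sample`; rejected rows (if any) in `attr(, "rejected")`
#'   as a data.frame with `row` and `reason`.
#' @export
read_pedigree <- function(path, dialect = c("csv", "tsv"), quiet = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (dialect == "csv") "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", na.strings = NULL,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", fill = FALSE)
  missing_cols <- setdiff(PEDIGREE_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("pedigree file ", basename(path), " lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  blank_to_na <- function(x) ifelse(nzchar(trimws(x)), trimws(x), NA_character_)
  df <- data.frame(
    person_id = blank_to_na(raw$person_id),
    sex = blank_to_na(raw$sex),
    birth_year = parse_year_column(raw$birth_year, "birth_year", path),
    death_year = parse_year_column(raw$death_year, "death_year", path),
    last_alive_year = parse_year_column(raw$last_alive_year,
                                        "last_alive_year", path),
    mother_id = blank_to_na(raw$mother_id),
    father_id = blank_to_na(raw$father_id),
    adopted = blank_to_na(raw$adopted),
    stringsAsFactors = FALSE
  )
  if (any(is.na(df$person_id))) {
    stop("empty person_id at data row(s) ",
         paste(which(is.na(df$person_id)), collapse = ", "))
  }
  if (anyDuplicated(df$person_id)) {
    stop("duplicate person_id in ", basename(path), ": ",
         paste(unique(df$person_id[duplicated(df$person_id)]), collapse = ", "))
  }
  adopted_chr <- tolower(ifelse(is.na(df$adopted), "0", df$adopted))
  bad_adopted <- !adopted_chr %in% c("0", "1", "true", "false")
  if (any(bad_adopted)) {
    stop("unparsable adopted flag at data row(s) ",
         paste(which(bad_adopted), collapse = ", "))
  }
  df$adopted <- adopted_chr %in% c("1", "true")

  # row-level invariant screening
  reason <- rep(NA_character_, nrow(df))
  no_vital <- is.na(df$death_year) & is.na(df$last_alive_year)
  reason[no_vital] <- "no death_year or last_alive_year"
  bad_sex <- is.na(reason) & !df$sex %in% c("F", "M")
  reason[bad_sex] <- "sex not F/M"
  no_birth <- is.na(reason) & is.na(df$birth_year)
  reason[no_birth] <- "missing birth_year"
  bad_death <- is.na(reason) & !is.na(df$death_year) &
    df$death_year < df$birth_year
  reason[bad_death] <- "death_year before birth_year"
  bad_last <- is.na(reason) & !is.na(df$last_alive_year) &
    df$last_alive_year < df$birth_year
  reason[bad_last] <- "last_alive_year before birth_year"

  rejected <- data.frame(row = which(!is.na(reason)),
                         person_id = df$person_id[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  keep <- df[is.na(reason), , drop = FALSE]
  if (nrow(rejected) > 0L && !quiet) {
    message("read_pedigree: rejected ", nrow(rejected), " row(s): ",
            paste(sprintf("row %d (%s)", rejected$row, rejected$reason),
                  collapse = "; "))
  }
  out <- pedigree_sample(keep, provenance = basename(path))
  attr(out, "rejected") <- rejected
  out
}

#' Write a pedigree file
#'
#' Emits the same schema [read_pedigree()] expects: header row, empty string
#' for absent values, sex as F/M, adopted as 0/1.
#'
#' @param sample a `pedigree_sample`.
#' @param path output file path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(sample, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  df <- sample$individuals[PEDIGREE_COLUMNS]
  df$adopted <- as.integer(df$adopted)
  out <- as.data.frame(lapply(df, function(x) {
    x <- as.character(x)
    ifelse(is.na(x), "", x)
  }), stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Group individuals into sibships
#'
#' Partitions the sample into full-sib groups keyed by the ordered pair
#' (mother_id, father_id). Individuals with any unknown parent (under the
#' chosen keying) form singleton sibships: an unknown parent is never treated
#' as evidence of shared parentage, so half-sibs and parent-missing records do
#' not coalesce. With `key = "mother_only"` grouping is by mother alone.
#'
#' @param sample a `pedigree_sample`.
#' @param key `"both_parents"` (default, full sibs) or `"mother_only"`.
#' @return the sample with a `sibships` table (`sibship_id`, `mother_id`,
#'   `father_id`, `n_members`, plus `mother_has_vital`/`father_has_vital`
#'   flags recording whether each parent resolves in the sample with a birth
#'   year and a death or last-alive year) and a `sibship_id` column on the
#'   individuals.
#' @export
derive_sibships <- function(sample, key = c("both_parents", "mother_only")) {
  key <- match.arg(key)
  ind <- sample$individuals
  ind$sibship_id <- NULL
  if (key == "both_parents") {
    known <- !is.na(ind$mother_id) & !is.na(ind$father_id)
    grp_key <- ifelse(known, paste(ind$mother_id, ind$father_id, sep = "\r"),
                      NA_character_)
  } else {
    known <- !is.na(ind$mother_id)
    grp_key <- ifelse(known, ind$mother_id, NA_character_)
  }
  # singletons get a unique key of their own
  grp_key[!known] <- paste0("\x01", ind$person_id[!known])
  fac <- factor(grp_key, levels = unique(grp_key[order(grp_key)]))
  sib_id <- sprintf("S%05d", as.integer(fac))
  ind$sibship_id <- sib_id
  first <- !duplicated(sib_id)
  sibships <- data.frame(
    sibship_id = sib_id[first],
    mother_id = ind$mother_id[first],
    father_id = ind$father_id[first],
    stringsAsFactors = FALSE
  )
  sibships <- sibships[order(sibships$sibship_id), , drop = FALSE]
  tab <- table(sib_id)
  sibships$n_members <- as.integer(tab[sibships$sibship_id])
  # snapshot parent-information availability now, while the parent records
  # are still present: filters may later remove the parents' own sibships
  has_vital <- !is.na(ind$birth_year) &
    (!is.na(ind$death_year) | !is.na(ind$last_alive_year))
  vital_of <- function(ids) {
    j <- match(ids, ind$person_id)
    !is.na(j) & has_vital[ifelse(is.na(j), 1L, j)]
  }
  sibships$mother_has_vital <- vital_of(sibships$mother_id)
  sibships$father_has_vital <- vital_of(sibships$father_id)
  rownames(sibships) <- NULL
  out <- sample
  out$individuals <- ind
  out$sibships <- sibships
  out
}

#' Member person_ids of one sibship
#' @param sample a `pedigree_sample` with sibships derived.
#' @param sibship_id sibship identifier.
#' @return character vector of person_ids.
#' @export
sibship_members <- function(sample, sibship_id) {
  stopifnot(!is.null(sample$individuals$sibship_id))
  sample$individuals$person_id[sample$individuals$sibship_id %in% sibship_id]
}

#' Apply the sample-construction inclusion filters
#'
#' Retains only sibships in which (1) every member is born in
#' `max_birth_year` or earlier; (2) every member has a birth year and a death
#' year or last known-alive year; and (3) the sibship's mother and father are
#' themselves present with birth and death (or last-alive) years. Sibships are
#' kept or dropped atomically; counts of sibships dropped per criterion are
#' reported.
#'
#' @param sample a `pedigree_sample` with sibships derived.
#' @param max_birth_year latest admissible birth year (default 1910).
#' @param quiet suppress the per-criterion message.
#' @return the filtered sample; drop counts in `attr(, "filter_counts")`.
#' @export
apply_inclusion_filters <- function(sample, max_birth_year = 1910,
                                    quiet = FALSE) {
  if (is.null(sample$sibships)) stop("derive_sibships() first")
  ind <- sample$individuals
  sib <- ind$sibship_id

  ok1 <- ind$birth_year <= max_birth_year
  ok2 <- !is.na(ind$birth_year) &
    (!is.na(ind$death_year) | !is.na(ind$last_alive_year))
  sib_ok1 <- tapply(ok1, sib, all)
  sib_ok2 <- tapply(ok2, sib, all)

  sibships <- sample$sibships
  if (is.null(sibships$mother_has_vital)) {
    stop("sibships lack parent-information flags; re-run derive_sibships()")
  }
  sib_ok3 <- sibships$mother_has_vital & sibships$father_has_vital
  names(sib_ok3) <- sibships$sibship_id

  ord <- sibships$sibship_id
  keep <- sib_ok1[ord] & sib_ok2[ord] & sib_ok3[ord]
  counts <- c(
    criterion1_birth_year = sum(!sib_ok1[ord], na.rm = TRUE),
    criterion2_member_vital = sum(sib_ok1[ord] & !sib_ok2[ord], na.rm = TRUE),
    criterion3_parent_vital = sum(sib_ok1[ord] & sib_ok2[ord] & !sib_ok3[ord],
                                  na.rm = TRUE)
  )
  if (!quiet && sum(!keep) > 0L) {
    message("apply_inclusion_filters: dropped ", sum(!keep), " sibship(s) [",
            "born after cap: ", counts[1L],
            ", member lacking vital year: ", counts[2L],
            ", parent unresolved/lacking vital year: ", counts[3L], "]")
  }
  kept_sibs <- ord[keep]
  out <- sample
  out$individuals <- ind[sib %in% kept_sibs, , drop = FALSE]
  rownames(out$individuals) <- NULL
  out$sibships <- sibships[keep, , drop = FALSE]
  rownames(out$sibships) <- NULL
  attr(out, "filter_counts") <- counts
  out
}

#' Apply score-eligibility restrictions
#'
#' Removes adopted individuals and individuals who did not attain `min_age`
#' (death or last known-alive year minus birth year strictly below `min_age`;
#' an attained age of exactly `min_age` is eligible). Sibships may shrink;
#' emptied sibships are dropped.
#'
#' @param sample a `pedigree_sample` with sibships derived.
#' @param min_age minimum attained age in years (default 40).
#' @param quiet suppress the message.
#' @return the restricted sample.
#' @export
apply_score_eligibility <- function(sample, min_age = 40, quiet = FALSE) {
  if (is.null(sample$sibships)) stop("derive_sibships() first")
  ind <- sample$individuals
  age <- end_year(ind) - ind$birth_year
  drop_adopted <- ind$adopted %in% TRUE
  drop_young <- !drop_adopted & (is.na(age) | age < min_age)
  keep <- !(drop_adopted | drop_young)
  if (!quiet && any(!keep)) {
    message("apply_score_eligibility: removed ", sum(drop_adopted),
            " adopted and ", sum(drop_young),
            " individual(s) with attained age < ", min_age)
  }
  out <- sample
  out$individuals <- ind[keep, , drop = FALSE]
  rownames(out$individuals) <- NULL
  out$sibships <- sample$sibships[
    sample$sibships$sibship_id %in% unique(out$individuals$sibship_id), ,
    drop = FALSE]
  tab <- table(out$individuals$sibship_id)
  out$sibships$n_members <- as.integer(tab[out$sibships$sibship_id])
  rownames(out$sibships) <- NULL
  out
}
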