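#' Birth-cohort band layout
#'
#' Decade-wide birth-year bands with an open pooled band for the earliest
#' births (sample sizes before 1850 are too small for stable cohort tables)
#' and a terminal band extended to absorb a short remainder, so e.g. a
#' 1779-1910 range yields pre-1850, 1850-1859, ..., 1890-1899, 1900-1910.
#'
#' @param start_year earliest birth year covered (default 1779).
#' @param end_year latest birth year covered (default 1910).
#' @param pool_before births before this year are pooled into one open band
#'   (default 1850).
#' @param width band width in years (default 10).
#' @return data.frame of class `cohort_bands` with `label`, `start_year`,
#'   `end_year`; bands are disjoint and cover `start_year:end_year`.
#' @export
cohort_bands <- function(start_year = 1779, end_year = 1910,
                         pool_before = 1850, width = 10) {
  stopifnot(start_year < pool_before, pool_before <= end_year, width >= 1)
  starts <- seq(pool_before, end_year, by = width)
  ends <- pmin(starts + width - 1L, end_year)
  # a final short band is merged into its predecessor
  if (length(starts) > 1L && (ends[length(ends)] - starts[length(starts)] + 1L) < width) {
    ends[length(ends) - 1L] <- ends[length(ends)]
    starts <- starts[-length(starts)]
    ends <- ends[-length(ends)]
  }
  bands <- data.frame(
    label = c(sprintf("pre-%d", pool_before),
              sprintf("%d-%d", starts, ends)),
    start_year = c(start_year, starts),
    end_year = c(pool_before - 1L, ends),
    stringsAsFactors = FALSE
  )
  class(bands) <- c("cohort_bands", "data.frame")
  bands
}

#' Assign a birth year to its cohort band
#'
#' @param birth_year integer vector of birth years.
#' @param bands a [cohort_bands()] layout.
#' @return character vector of band labels.
#' @export
assign_cohort <- function(birth_year, bands) {
  idx <- findInterval(birth_year, bands$start_year)
  bad <- idx < 1L | birth_year > bands$end_year[pmax(idx, 1L)] |
    is.na(birth_year)
  if (any(bad)) {
    stop("birth year(s) outside configured bands: ",
         paste(unique(birth_year[bad]), collapse = ", "))
  }
  bands$label[idx]
}

#' Construct a cohort life table object
#'
#' Survival on an integer age grid, conditional on being alive at `base_age`
#' (so S(base_age) = 1). Validity (monotone non-increasing, within [0, 1]) is
#' asserted on construction.
#'
#' @param age integer age grid starting at `base_age`.
#' @param survival survival probabilities on `age`.
#' @param sex "F" or "M" (or "" for sex-pooled tables such as external
#'   reference tables).
#' @param band band label the table applies to ("" if not cohort-specific).
#' @param base_age conditioning age (default: first age of the grid).
#' @param n number of individuals behind the estimate (informational).
#' @param method estimation method label.
#' @return object of class `cohort_life_table` (a data.frame with metadata
#'   attributes).
#' @export
cohort_life_table <- function(age, survival, sex = "", band = "",
                              base_age = min(age), n = NA_integer_,
                              method = "") {
  age <- as.integer(age)
  stopifnot(length(age) == length(survival), length(age) >= 1L)
  if (is.unsorted(age, strictly = TRUE)) stop("age grid must be increasing")
  if (age[1L] != base_age) stop("age grid must start at base_age")
  if (any(survival < -1e-12 | survival > 1 + 1e-12)) {
    stop("survival outside [0, 1]")
  }
  survival <- pmin(pmax(survival, 0), 1)
  if (abs(survival[1L] - 1) > 1e-12) {
    stop("survival at base_age must be 1")
  }
  if (any(diff(survival) > 1e-12)) stop("survival must be non-increasing")
  survival <- cummin(survival)
  pos <- survival[survival > 0]
  tab <- data.frame(age = age, survival = survival)
  structure(tab,
            sex = sex, band = band, base_age = as.integer(base_age),
            n = as.integer(n), method = method,
            min_positive = if (length(pos)) min(pos) else NA_real_,
            class = c("cohort_life_table", "data.frame"))
}

#' @export
print.cohort_life_table <- function(x, ...) {
  cat(sprintf("cohort_life_table: sex=%s band=%s ages %d-%d (base %d), n=%s\n",
              attr(x, "sex"), attr(x, "band"), min(x$age), max(x$age),
              attr(x, "base_age"), attr(x, "n")))
  invisible(x)
}

#' Build a conditional cohort life table from lifespan data
#'
#' Product-limit (Kaplan-Meier) estimate of survival past `base_age` for one
#' sex and birth-cohort band. Individuals enter the risk set at `base_age`
#' (left truncation: only those attaining it contribute) and exit at their
#' attained age — a death if the death year is known, a right-censoring at the
#' last known-alive year otherwise. Ties at an age are resolved deaths before
#' censorings (the product-limit convention). The alternative
#' `method = "empirical"` uses the deceased only and takes the empirical
#' survival of their lifespans.
#'
#' @param sample a `pedigree_sample` (normally filtered and score-eligible).
#' @param sex "F" or "M".
#' @param band band label from [cohort_bands()].
#' @param bands the band layout used to place birth years.
#' @param base_age conditioning age (default 40).
#' @param method `"product-limit"` (default) or `"empirical"`.
#' @return a [cohort_life_table()].
#' @export
build_cohort_life_table <- function(sample, sex, band,
                                    bands = cohort_bands(),
                                    base_age = 40,
                                    method = c("product-limit", "empirical")) {
  method <- match.arg(method)
  ind <- sample$individuals
  in_band <- assign_cohort(ind$birth_year, bands) == band & ind$sex == sex
  ind <- ind[in_band, , drop = FALSE]
  exit <- end_year(ind) - ind$birth_year
  event <- !is.na(ind$death_year)
  keep <- !is.na(exit) & exit > base_age
  if (!any(in_band) || !any(keep)) {
    stop("no individuals attain base age ", base_age,
         " in stratum sex=", sex, " band=", band)
  }
  exit <- exit[keep]
  event <- event[keep]
  max_age <- max(exit)
  grid <- base_age:max_age
  if (method == "product-limit") {
    fit <- survival::survfit(
      survival::Surv(rep(base_age, length(exit)), exit, event) ~ 1)
    s <- summary(fit, times = grid, extend = TRUE)$surv
  } else {
    lt <- exit[event]
    if (length(lt) == 0L) {
      s <- rep(1, length(grid))
    } else {
      s <- vapply(grid, function(t) mean(lt > t), numeric(1))
      max_age <- max(lt)
      grid <- base_age:max_age
      s <- s[seq_along(grid)]
    }
  }
  cohort_life_table(grid, s, sex = sex, band = band, base_age = base_age,
                    n = sum(keep), method = method)
}

#' Build life tables for all sex-by-band strata
#'
#' @param sample a `pedigree_sample`.
#' @param bands band layout.
#' @param base_age conditioning age (default 40).
#' @param method passed to [build_cohort_life_table()].
#' @param min_n strata with fewer attaining individuals are skipped with a
#'   warning (default 1).
#' @return object of class `life_table_set`: a list of tables keyed
#'   `"<sex>|<band>"`.
#' @export
build_life_tables <- function(sample, bands = cohort_bands(), base_age = 40,
                              method = "product-limit", min_n = 1L) {
  out <- list()
  skipped <- character(0)
  for (sex in c("F", "M")) {
    for (band in bands$label) {
      tab <- tryCatch(
        build_cohort_life_table(sample, sex, band, bands = bands,
                                base_age = base_age, method = method),
        error = function(e) NULL)
      key <- paste(sex, band, sep = "|")
      if (is.null(tab) || attr(tab, "n") < min_n) {
        skipped <- c(skipped, key)
      } else {
        out[[key]] <- tab
      }
    }
  }
  if (length(skipped) > 0L) {
    warning("empty/short life-table strata skipped: ",
            paste(skipped, collapse = ", "))
  }
  structure(out, bands = bands, base_age = as.integer(base_age),
            class = "life_table_set")
}

#' @export
print.life_table_set <- function(x, ...) {
  cat("life_table_set:", length(x), "tables, base age",
      attr(x, "base_age"), "\n")
  for (k in names(x)) {
    cat(sprintf("  %-14s n=%d, max age %d\n", k, attr(x[[k]], "n"),
                max(x[[k]]$age)))
  }
  invisible(x)
}

#' Find the life table matching an individual
#' @param tables a `life_table_set`.
#' @param sex "F" or "M".
#' @param birth_year birth year, placed with the set's band layout.
#' @return a `cohort_life_table`.
#' @export
find_life_table <- function(tables, sex, birth_year) {
  band <- assign_cohort(birth_year, attr(tables, "bands"))
  key <- paste(sex, band, sep = "|")
  tab <- tables[[key]]
  if (is.null(tab)) stop("no life table for stratum ", key)
  tab
}

#' Survival probability lookup on a life table
#'
#' Right-continuous on the integer grid; queries between grid ages use linear
#' interpolation of log-survival (linear interpolation to zero where survival
#' has reached zero). Ages beyond the grid carry the last value forward; ages
#' at or below the base age return 1.
#'
#' @param table a `cohort_life_table`.
#' @param t numeric vector of ages.
#' @return numeric vector of survival probabilities.
#' @export
lookup_survival <- function(table, t) {
  a <- table$age
  s <- table$survival
  out <- numeric(length(t))
  below <- t <= a[1L]
  out[below] <- 1
  idx <- findInterval(t, a)
  hi <- idx >= length(a)
  out[!below & hi] <- s[length(a)]
  mid <- which(!below & !hi)
  if (length(mid) > 0L) {
    i <- idx[mid]
    exact <- t[mid] == a[i]
    out[mid[exact]] <- s[i[exact]]
    ni <- mid[!exact]
    if (length(ni) > 0L) {
      i <- idx[ni]
      frac <- (t[ni] - a[i]) / (a[i + 1L] - a[i])
      s0 <- s[i]; s1 <- s[i + 1L]
      loglin <- s0 > 0 & s1 > 0
      val <- numeric(length(ni))
      val[loglin] <- exp(log(s0[loglin]) +
                           frac[loglin] * (log(s1[loglin]) - log(s0[loglin])))
      val[!loglin] <- s0[!loglin] + frac[!loglin] * (s1[!loglin] - s0[!loglin])
      out[ni] <- val
    }
  }
  out
}

#' Conditional survival from a life table
#'
#' S(t)/S(condition_age) for t >= condition_age: the survival curve rescaled
#' to probability 1 at the conditioning age.
#'
#' @param table a `cohort_life_table`.
#' @param t ages at which to evaluate.
#' @param condition_age conditioning age (default: the table's base age).
#' @return numeric vector of conditional survival probabilities.
#' @export
conditional_survival <- function(table, t,
                                 condition_age = attr(table, "base_age")) {
  if (condition_age < attr(table, "base_age")) {
    stop("condition_age below the table's base age")
  }
  s0 <- lookup_survival(table, condition_age)
  if (s0 <= 0) stop("survival is zero at condition age ", condition_age,
                    "; conditioning undefined")
  if (any(t < condition_age)) stop("t must be >= condition_age")
  lookup_survival(table, t) / s0
}

#' Read a life table file
#'
#' Delimited text with a header `age,survival` or `age,lx`; `lx` columns are
#' normalized so survival is 1 at `base_age`. Metadata may be supplied in
#' leading comment lines `# sex: F`, `# band: 1900-1910`, `# base_age: 40`.
#'
#' @param path file path.
#' @param dialect `"csv"` or `"tsv"`.
#' @param base_age conditioning age used to normalize `lx` input; overridden
#'   by a `# base_age:` header if present.
#' @return a [cohort_life_table()].
#' @export
read_life_table <- function(path, dialect = c("csv", "tsv"), base_age = 40) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (dialect == "csv") "," else "\t"
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list(sex = "", band = "", base_age = base_age)
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([a-z_]+)\\s*:\\s*(.+?)\\s*$", h))[[1]]
    if (length(m) == 3L && m[2] %in% names(meta)) meta[[m[2]]] <- m[3]
  }
  meta$base_age <- as.integer(meta$base_age)
  df <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                          sep = sep, stringsAsFactors = FALSE)
  if (!"age" %in% names(df)) stop("life table file lacks an 'age' column")
  if ("survival" %in% names(df)) {
    v <- df$survival
  } else if ("lx" %in% names(df)) {
    v <- df$lx
  } else {
    stop("life table file needs a 'survival' or 'lx' column")
  }
  keep <- df$age >= meta$base_age
  df <- df[keep, , drop = FALSE]
  v <- v[keep]
  if (nrow(df) == 0L || df$age[1L] != meta$base_age) {
    stop("life table file lacks the base_age (", meta$base_age, ") row")
  }
  if (any(diff(v) > 1e-9 * max(abs(v)))) {
    stop("survival/lx increases with age; not a valid life table")
  }
  v <- v / v[1L]
  cohort_life_table(df$age, v, sex = meta$sex, band = meta$band,
                    base_age = meta$base_age, method = "file")
}

#' Write a life table file
#'
#' Inverse of [read_life_table()]: comment-line metadata then `age,survival`.
#'
#' @param table a `cohort_life_table`.
#' @param path output file path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(table, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# sex: ", attr(table, "sex")),
    paste0("# band: ", attr(table, "band")),
    paste0("# base_age: ", attr(table, "base_age"))
  ), con)
  writeLines(paste("age", "survival", sep = sep), con)
  writeLines(paste(table$age, format(table$survival, digits = 15,
                                     scientific = FALSE, trim = TRUE),
                   sep = sep), con)
  invisible(path)
}
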