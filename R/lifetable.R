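#' Age-specific all-cause mortality table
#'
#' A life table is an ordered set of `(age, qx)` rows, where `qx` is the
#' annual probability of dying within the year of age `age`. Background
#' (other-cause) mortality in the cohort model is taken from such a table;
#' the reference analysis uses national female all-cause mortality.
#'
#' @param age Integer ages in years, strictly increasing.
#' @param qx Annual death probabilities in `[0, 1]`, one per age.
#' @return A `data.frame` of class `life_table` with columns `age` and `qx`.
#' @export
life_table <- function(age, qx) {
  if (length(age) == 0L) stop("life table must have at least one row", call. = FALSE)
  if (length(age) != length(qx))
    stop("'age' and 'qx' must have equal length", call. = FALSE)
  if (any(is.na(age)) || any(is.na(qx)))
    stop("life table must not contain missing values", call. = FALSE)
  if (any(diff(age) <= 0))
    stop("ages must be strictly increasing", call. = FALSE)
  if (any(qx < 0 | qx > 1))
    stop("each qx must lie in [0, 1]", call. = FALSE)
  structure(data.frame(age = as.numeric(age), qx = as.numeric(qx)),
            class = c("life_table", "data.frame"))
}

#' Read a life table from a delimited text file
#'
#' The file must have a header naming the two columns `age` and `qx`;
#' comma, tab and whitespace delimiters are accepted.
#'
#' @param path Path to the file.
#' @return A validated [life_table()].
#' @seealso [write_life_table()]
#' @export
read_life_table <- function(path) {
  if (!file.exists(path))
    stop(sprintf("life-table file not found: '%s'", path), call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else if (grepl("\t", first)) "\t" else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          strip.white = TRUE, stringsAsFactors = FALSE)
  if (!all(c("age", "qx") %in% names(df)))
    stop(sprintf("life-table file '%s' must have header columns 'age' and 'qx'",
                 path), call. = FALSE)
  lt <- try(life_table(df$age, df$qx), silent = TRUE)
  if (inherits(lt, "try-error"))
    stop(sprintf("invalid life table in '%s': %s", path,
                 conditionMessage(attr(lt, "condition"))), call. = FALSE)
  lt
}

#' Write a life table to a CSV file
#'
#' @param lt A [life_table()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(lt, path) {
  stopifnot(inherits(lt, "life_table"))
  utils::write.csv(as.data.frame(lt), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Monthly background mortality at a given age
#'
#' Converts the annual probability `qx` at `floor(age)` to a monthly
#' probability under constant hazard within the year:
#' `qm = 1 - (1 - qx)^(1/12)`. Ages beyond the table's last row reuse the
#' last row (the cohort model closes the horizon separately at its maximum
#' age); ages below the first row use the first row.
#'
#' @param lt A [life_table()].
#' @param age Age in years, possibly fractional; vectorised.
#' @return Monthly death probability, vectorised over `age`.
#' @export
monthly_mortality <- function(lt, age) {
  stopifnot(inherits(lt, "life_table"))
  if (nrow(lt) == 0L) stop("empty life table", call. = FALSE)
  yr <- floor(age)
  idx <- findInterval(yr, lt$age)
  idx[idx < 1L] <- 1L
  1 - (1 - lt$qx[idx])^(1 / 12)
}

#' Gompertz-Makeham mortality parameters
#'
#' Annual hazard model `mu(a) = makeham + alpha * exp(beta * a)`: a constant
#' age-independent component plus an exponentially age-increasing senescent
#' component. The defaults are calibrated so that remaining life expectancy
#' at age 57 falls in 25-27 years, emulating the all-cause mortality of
#' middle-income-country women (e.g. Chinese women around 2009).
#'
#' @param makeham Baseline annual hazard, `>= 0`.
#' @param alpha Senescent hazard level at age 0, `>= 0`.
#' @param beta Exponential slope per year of age, `> 0`.
#' @return An object of class `gompertz_params`.
#' @export
gompertz_params <- function(makeham = 2e-4, alpha = 9e-6, beta = 0.11) {
  if (makeham < 0 || alpha < 0 || beta <= 0)
    stop("require makeham >= 0, alpha >= 0, beta > 0", call. = FALSE)
  structure(list(makeham = makeham, alpha = alpha, beta = beta),
            class = "gompertz_params")
}

#' Generate a synthetic life table from a Gompertz-Makeham law
#'
#' Provides a download-free stand-in for a national all-cause mortality
#' table: `qx(a) = 1 - exp(-(makeham + alpha * exp(beta * a)))`. With the
#' default [gompertz_params()] the table emulates female mortality in a
#' middle-income country (remaining life expectancy at age 57 of about 26
#' years).
#'
#' @param gp A [gompertz_params()].
#' @param age_min,age_max Integer age span of the table (inclusive).
#' @return A [life_table()].
#' @export
synth_life_table <- function(gp = gompertz_params(), age_min = 0,
                             age_max = 100) {
  stopifnot(inherits(gp, "gompertz_params"))
  if (age_min >= age_max) stop("age_min must be < age_max", call. = FALSE)
  ages <- seq(age_min, age_max)
  hz <- gp$makeham + gp$alpha * exp(gp$beta * ages)
  life_table(ages, -expm1(-hz))
}

#' Remaining life expectancy from a life table
#'
#' Expected remaining years at `age` by monthly survival summation using
#' [monthly_mortality()], closing the horizon at `max_age` (everyone alive
#' at `max_age` is assumed to die there, matching the cohort model's
#' horizon rule).
#'
#' @param lt A [life_table()].
#' @param age Starting age in years (may be fractional).
#' @param max_age Horizon age in years.
#' @return Remaining life expectancy in years.
#' @export
life_expectancy <- function(lt, age, max_age = 100) {
  stopifnot(inherits(lt, "life_table"))
  if (age >= max_age) return(0)
  n <- ceiling((max_age - age) * 12)
  ages <- age + (seq_len(n) - 1L) / 12
  qm <- monthly_mortality(lt, ages)
  surv <- cumprod(1 - qm)
  # person-months lived: alive at the start of each month contributes 1/12
  sum(c(1, surv[-n])) / 12
}
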