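#' Actuarial life tables and general-population survival
#'
#' A life table holds the per-year death probability q(age) for males and
#' females at every integer age from 0 up to its maximum age, in the layout
#' of the U.S. Social Security Administration period tables after column
#' extraction. Cumulative survival to an age is the product of one-year
#' survival probabilities using the arithmetic male/female mean of q at
#' each age.
#'
#' @param age Integer ages, contiguous from 0.
#' @param q_male,q_female Per-year death probabilities in `[0, 1]`.
#' @param note Free-text provenance note.
#' @return An object of class `life_table` (data frame `age`, `q_male`,
#'   `q_female` with attribute `note`).
#' @export
life_table <- function(age, q_male, q_female, note = "") {
  n <- length(age)
  if (n == 0 || length(q_male) != n || length(q_female) != n)
    stop("age, q_male and q_female must have equal positive length")
  if (!identical(as.integer(age), seq(0L, n - 1L)))
    stop("ages must be contiguous integers starting at 0")
  check_q <- function(q, what) {
    bad <- which(!is.finite(q) | q < 0 | q > 1)
    if (length(bad))
      stop(sprintf("%s outside [0, 1] at row %d (age %d)",
                   what, bad[1L], age[bad[1L]]))
  }
  check_q(q_male, "q_male"); check_q(q_female, "q_female")
  structure(data.frame(age = as.integer(age), q_male = q_male,
                       q_female = q_female),
            note = note, class = c("life_table", "data.frame"))
}

#' @rdname life_table
#' @param file CSV file with header `age,q_male,q_female`.
#' @export
read_life_table <- function(file) {
  x <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("age", "q_male", "q_female")
  if (!all(need %in% names(x)))
    stop("life table must have columns age, q_male, q_female: ", file)
  life_table(x$age, x$q_male, x$q_female, note = basename(file))
}

#' @rdname life_table
#' @param q_male_col,q_female_col,age_col Column positions (or names) in an
#'   actuarial period-table CSV. The defaults match the layout of the SSA
#'   period life table (age, then male death probability / lives / life
#'   expectancy, then the same three for females): age in column 1, male q
#'   in column 2, female q in column 5.
#' @export
import_ssa_life_table <- function(file, age_col = 1, q_male_col = 2,
                                  q_female_col = 5, note = basename(file)) {
  x <- utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE)
  pick <- function(col) {
    v <- if (is.character(col)) x[[col]] else x[[as.integer(col)]]
    if (is.null(v)) stop("column ", col, " not found in ", file)
    # period tables often format numbers with thousands separators
    as.numeric(gsub(",", "", as.character(v)))
  }
  life_table(pick(age_col), pick(q_male_col), pick(q_female_col),
             note = note)
}

#' @rdname life_table
#' @param x A `life_table`.
#' @export
write_life_table <- function(x, file) {
  stopifnot(inherits(x, "life_table"))
  utils::write.csv(as.data.frame(x), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @export
print.life_table <- function(x, ...) {
  cat(sprintf("Life table, ages 0-%d", max(x$age)))
  note <- attr(x, "note")
  if (nzchar(note)) cat(" (", note, ")", sep = "")
  cat(sprintf("; survival to 64: %.3f\n",
              population_survival(x, min(64, max(x$age)))))
  invisible(x)
}

#' @rdname life_table
#' @param table A `life_table`.
#' @param age Integer age(s); survival at age 0 is 1 and ages may run to
#'   `max_age + 1`.
#' @return `population_survival()`: cumulative survival probability,
#'   \eqn{\prod_{a<\mathrm{age}} (1 - \bar q(a))} with
#'   \eqn{\bar q = (q_m + q_f)/2}.
#' @export
population_survival <- function(table, age) {
  stopifnot(inherits(table, "life_table"))
  max_age <- max(table$age)
  if (any(age < 0) || any(age > max_age + 1) || any(age != round(age)))
    stop(sprintf("age must be an integer in 0-%d", max_age + 1))
  qbar <- (table$q_male + table$q_female) / 2
  cum <- c(1, cumprod(1 - qbar))     # cum[a + 1] = survival to age a
  cum[age + 1]
}
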