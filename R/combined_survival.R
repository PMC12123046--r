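#' Combined carrier survival
#'
#' Expanded-repeat carriers face two hazards: death from Huntington's
#' disease itself (the per-CAG log-normal death model) and death from all
#' other causes, proxied by general-population life-table survival. Under
#' the assumption that the two are independent the overall carrier survival
#' is the product
#' \deqn{S(c, a) = S_{HD}(c, a) \times S_{pop}(a).}
#'
#' @param death_models Named list of death [lognormal_event_model()]s, one
#'   per CAG, names coercible to integers.
#' @param life_table A [life_table()].
#' @param band Inclusive CAG interval (default `c(40, 50)`, the range with
#'   adequate per-CAG death data) for which death models must be present.
#' @return An object of class `combined_survival`.
#' @export
combined_survival <- function(death_models, life_table, band = c(40, 50)) {
  stopifnot(inherits(life_table, "life_table"))
  band <- check_cag_range(band)
  cags <- as.integer(names(death_models))
  if (any(is.na(cags)))
    stop("death_models must be a list named by CAG length")
  ok <- vapply(death_models, function(m)
    inherits(m, "lognormal_event_model") && m$event_kind == "death",
    logical(1))
  if (!all(ok))
    stop("every element of death_models must be a death-kind ",
         "lognormal_event_model")
  missing <- setdiff(band[1]:band[2], cags)
  if (length(missing))
    stop("no death model for CAG ", paste(missing, collapse = ", "))
  structure(list(death_models = death_models, life_table = life_table,
                 band = band),
            class = "combined_survival")
}

#' @export
print.combined_survival <- function(x, ...) {
  cat(sprintf("Combined carrier survival: CAG band %d-%d, life table to age %d\n",
              x$band[1], x$band[2], max(x$life_table$age)))
  invisible(x)
}

#' @rdname combined_survival
#' @param cs A `combined_survival`.
#' @param cag A single CAG length with a death model.
#' @param age Integer age(s) within the life table.
#' @return `carrier_survival()`: probabilities
#'   `hd_survival(cag model, age) * population_survival(age)`.
#' @examples
#' cal <- hd_calibration()
#' carrier_survival(cal$survival, 42, 64)   # ~0.517, about half
#' @export
carrier_survival <- function(cs, cag, age) {
  stopifnot(inherits(cs, "combined_survival"))
  m <- cs$death_models[[as.character(cag)]]
  if (is.null(m))
    stop("no death model configured for CAG ", cag)
  hd_survival(m, age) * population_survival(cs$life_table, age)
}
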