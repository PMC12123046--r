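SERIAL_VERSION <- "1.0"

#' Serialize and restore model objects as JSON
#'
#' Decay models and event-model sets round-trip losslessly through JSON
#' documents carrying a `version` tag; loading a document with a foreign
#' version raises a migration error rather than guessing.
#'
#' @param model A [decay_model()].
#' @param file Path to write to / read from.
#' @return The file path (writers, invisibly) or the restored object
#'   (readers).
#' @export
write_decay_model <- function(model, file) {
  stopifnot(inherits(model, "decay_model"))
  doc <- list(version = SERIAL_VERSION, type = "decay_model",
              slope = model$fit$slope, intercept = model$fit$intercept,
              r_squared = model$fit$r_squared, p_value = model$fit$p_value,
              fit_range = model$fit$fit_range,
              model_range = model$model_range,
              allele_pool = model$allele_pool,
              created_by = paste0("hdfreq ", utils::packageVersion("hdfreq")))
  jsonlite::write_json(doc, file, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(file)
}

#' @rdname write_decay_model
#' @export
read_decay_model <- function(file) {
  doc <- jsonlite::read_json(file, simplifyVector = TRUE)
  check_serial_version(doc, file)
  if (!identical(doc$type, "decay_model"))
    stop("not a decay model document: ", file)
  r2 <- if (is.null(doc$r_squared)) NA_real_ else doc$r_squared
  pv <- if (is.null(doc$p_value)) NA_real_ else doc$p_value
  decay_model(decay_fit(doc$intercept, doc$slope, doc$fit_range, r2, pv),
              model_range = doc$model_range, allele_pool = doc$allele_pool)
}

#' @rdname write_decay_model
#' @param models Named list (by CAG) of [lognormal_event_model()]s.
#' @export
write_event_models <- function(models, file) {
  doc <- list(version = SERIAL_VERSION, type = "event_models",
              models = lapply(models, function(m)
                list(cag = m$cag, meanlog = m$meanlog, sdlog = m$sdlog,
                     n_obs = m$n_obs, event_kind = m$event_kind,
                     low_n = m$low_n)))
  jsonlite::write_json(doc, file, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(file)
}

#' @rdname write_decay_model
#' @export
read_event_models <- function(file) {
  doc <- jsonlite::read_json(file, simplifyVector = FALSE)
  check_serial_version(doc, file)
  if (!identical(doc$type, "event_models"))
    stop("not an event-model document: ", file)
  out <- lapply(doc$models, function(m)
    lognormal_event_model(m$meanlog, m$sdlog, cag = m$cag,
                          kind = m$event_kind,
                          n_obs = if (is.null(m$n_obs)) NA_integer_
                                  else m$n_obs,
                          low_n = isTRUE(m$low_n)))
  names(out) <- names(doc$models)
  out
}

check_serial_version <- function(doc, file) {
  if (is.null(doc$version))
    stop("missing version field in ", file)
  if (!identical(as.character(doc$version), SERIAL_VERSION))
    stop(sprintf("document version %s in %s needs migration (expected %s)",
                 doc$version, file, SERIAL_VERSION))
  invisible(TRUE)
}

#' Run the full estimation pipeline
#'
#' Composes every stage on one configuration: tabulate genotypes, fit the
#' decay law over the unexpanded and expanded ranges, extend the
#' unexpanded fit into the final model, fit onset and death models, build
#' combined survival from a life table, census a pyramid-structured
#' population and compute the clinical ascertainment rate. When cohort
#' inputs are omitted the packaged calibration supplies the corresponding
#' models, so the demo configuration runs with no external data.
#'
#' @param config A named list (or path to a YAML file holding one) with
#'   any of: `genotypes` (path or data frame), `onset_ages`, `death_ages`
#'   (paths or data frames `sample_id`, `cag`, `age_years`), `life_table`
#'   (path), `pyramid` (path; default the packaged EU 2020 fixture),
#'   `unexpanded_range`, `expanded_range`, `model_range`, `band`,
#'   `age_range`, `n_population`, `prevalence`, `band_share`,
#'   `adjusted_prevalence`, `seed`, `out_dir`. Unknown keys are rejected.
#' @return A list of class `run_report`: the fitted objects plus a
#'   `summary` list of headline numbers. When `out_dir` is set, the
#'   models and a JSON report are written there.
#' @examples
#' \donttest{
#' rep <- run_pipeline(list(n_population = 1e5, age_range = c(30, 79)))
#' rep$summary$ascertainment_rate
#' }
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("genotypes", "onset_ages", "death_ages", "life_table",
             "pyramid", "unexpanded_range", "expanded_range", "model_range",
             "band", "age_range", "n_population", "prevalence",
             "band_share", "adjusted_prevalence", "seed", "out_dir",
             "onset_sdlog", "onset_to_death_years")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  g <- function(key, default) if (is.null(config[[key]])) default
       else config[[key]]

  band <- check_cag_range(unlist(g("band", c(40, 50))))
  cal <- hd_calibration(onset_sdlog = g("onset_sdlog", 0.2),
                        onset_to_death_years = g("onset_to_death_years", 15),
                        band = band)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  # decay model: fitted from genotypes when given, else the calibration's
  fits <- NULL
  model <- cal$model
  if (!is.null(config$genotypes)) {
    decay_stage <- stage("decay", {
      geno <- if (is.character(config$genotypes))
        read_genotypes(config$genotypes) else config$genotypes
      tabs <- tabulate_alleles(geno)
      ur <- check_cag_range(unlist(g("unexpanded_range", c(18, 35))))
      er <- check_cag_range(unlist(g("expanded_range", c(42, 55))))
      fit_u <- fit_decay(tabs$unexpanded, ur)
      fit_e <- fit_decay(tabs$expanded, er)
      list(fits = list(unexpanded = fit_u, expanded = fit_e),
           model = decay_model(
             fit_u,
             model_range = check_cag_range(unlist(g("model_range",
                                                    c(17, 55)))),
             allele_pool = pool_size(tabs$unexpanded)))
    })
    fits <- decay_stage$fits
    model <- decay_stage$model
  }

  read_ages <- function(x) if (is.character(x))
    utils::read.delim(x, stringsAsFactors = FALSE) else x
  fit_set <- function(tab, kind) {
    tab <- tab[tab$cag >= band[1] & tab$cag <= band[2], ]
    out <- lapply(split(tab$age_years, tab$cag), function(a)
      fit_event_model(a, cag = as.integer(NA), kind = kind, min_n = 30))
    for (nm in names(out)) out[[nm]]$cag <- as.integer(nm)
    gaps <- setdiff(as.character(band[1]:band[2]), names(out))
    if (length(gaps))
      stop("no ", kind, " ages for CAG ", paste(gaps, collapse = ", "))
    out
  }
  onset_models <- if (is.null(config$onset_ages)) cal$onset_models
    else stage("onset", fit_set(read_ages(config$onset_ages), "onset"))
  death_models <- if (is.null(config$death_ages)) cal$death_models
    else stage("death", fit_set(read_ages(config$death_ages), "death"))

  lt <- if (is.null(config$life_table)) cal$life_table
    else stage("life_table", read_life_table(config$life_table))
  cs <- stage("survival", combined_survival(death_models, lt, band = band))

  pyramid <- stage("pyramid", if (is.null(config$pyramid)) eu_pyramid_2020()
                   else read_pyramid(config$pyramid))
  n_pop <- g("n_population", 1e5)
  age_range <- unlist(g("age_range", c(30, 79)))
  ages <- stage("ages", realize_age_structure(pyramid, n_pop, age_range))

  census <- stage("census",
                  carrier_census(model, cs, onset_models, ages, band))
  report <- stage("ascertainment",
                  ascertainment_rate(census,
                                     prevalence = g("prevalence", 12.4e-5),
                                     band_share = g("band_share", 0.9),
                                     adjusted_prevalence =
                                       g("adjusted_prevalence", 11.6e-5)))

  expanded_band <- carrier_frequency_band(model,
                                          c(36, model$model_range[2]))
  summary <- list(
    decay_slope = model$fit$slope,
    decay_intercept = model$fit$intercept,
    allele_pool = model$allele_pool,
    cag42_pct_at_birth = 100 * allele_frequency(model, 42),
    expanded_one_in_birth = expanded_band$one_in,
    carriers = census$carriers,
    symptomatic = census$symptomatic,
    asymptomatic = census$asymptomatic,
    ascertainment_rate = report$ascertainment_rate
  )
  out <- structure(list(config = config, model = model, fits = fits,
                        onset_models = onset_models,
                        death_models = death_models,
                        life_table = lt, census = census,
                        ascertainment = report, summary = summary),
                   class = "run_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_decay_model(model, file.path(config$out_dir, "decay_model.json"))
    write_event_models(onset_models,
                       file.path(config$out_dir, "onset_models.json"))
    write_event_models(death_models,
                       file.path(config$out_dir, "death_models.json"))
    jsonlite::write_json(summary,
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.run_report <- function(x, ...) {
  s <- x$summary
  cat("hdfreq pipeline report\n")
  cat(sprintf("  decay law: log10(count) = %.6f %+.5f x CAG (pool %s)\n",
              s$decay_intercept, s$decay_slope,
              format(s$allele_pool, big.mark = " ")))
  cat(sprintf("  CAG-42 allele frequency at birth: %.5f%%\n",
              s$cag42_pct_at_birth))
  cat(sprintf("  expanded-repeat carriers at birth: one in %d\n",
              s$expanded_one_in_birth))
  print(x$census)
  cat(sprintf("  clinical ascertainment rate: %.1f%%\n",
              100 * s$ascertainment_rate))
  invisible(x)
}
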