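#' Fit an uncensored log-normal event-age model
#'
#' Ages at motor onset and ages at death in Huntington's disease cohorts
#' are well described, per CAG repeat length, by log-normal distributions.
#' With fully observed (uncensored) event ages the maximum-likelihood
#' estimates have the closed form
#' \deqn{\hat\mu = \overline{\ln t}, \qquad
#'       \hat\sigma = \sqrt{\tfrac1n \sum (\ln t_i - \hat\mu)^2},}
#' i.e. the log-scale sample moments with the n-denominator variance. This
#' is identical to what an accelerated-failure-time fit
#' (`survreg(..., dist = "lognormal")`) converges to when no observation is
#' censored; censored input is not supported and is rejected explicitly.
#'
#' @param ages Numeric vector of event ages in years, all positive, at
#'   least 5 observations.
#' @param cag CAG repeat length the model applies to.
#' @param kind `"onset"` or `"death"`.
#' @param min_n Minimum sample size below which the model is flagged
#'   `low_n` (warning, not an error). Default 30, the conventional cut
#'   below which per-CAG death data are considered unreliable.
#' @param censored Must be `NULL`/all-FALSE; any censoring indicator set to
#'   TRUE raises a not-supported error.
#' @return An object of class `lognormal_event_model` with `meanlog`,
#'   `sdlog`, `n_obs`, `cag`, `event_kind`, `low_n`.
#' @examples
#' m <- fit_event_model(c(40, 50, 62.5), cag = 42, kind = "onset", min_n = 3)
#' event_median(m)   # geometric mean = 50
#' @export
fit_event_model <- function(ages, cag, kind = c("onset", "death"),
                            min_n = 30, censored = NULL) {
  kind <- match.arg(kind)
  if (!is.null(censored) && any(censored))
    stop("censored event ages are not supported: models are fitted to ",
         "fully observed ages only")
  ages <- as.numeric(ages)
  if (length(ages) < 5L)
    stop("at least 5 event ages are required")
  if (any(!is.finite(ages)) || any(ages <= 0))
    stop("event ages must be positive and finite")
  lt <- log(ages)
  meanlog <- mean(lt)
  sdlog <- sqrt(mean((lt - meanlog)^2))
  if (sdlog == 0)
    stop("degenerate sample: all event ages identical")
  low_n <- length(ages) < min_n
  if (low_n)
    warning(sprintf("only %d ages for CAG %d %s model (minimum %d): ",
                    length(ages), cag, kind, min_n),
            "estimates flagged low_n", call. = FALSE)
  lognormal_event_model(meanlog, sdlog, cag = cag, kind = kind,
                        n_obs = length(ages), low_n = low_n)
}

#' @rdname fit_event_model
#' @param meanlog,sdlog Log-normal parameters (log-years; `sdlog > 0`).
#' @param n_obs Sample size behind the parameters (NA if constructed).
#' @param low_n Low-sample-size flag.
#' @export
lognormal_event_model <- function(meanlog, sdlog, cag,
                                  kind = c("onset", "death"),
                                  n_obs = NA_integer_, low_n = FALSE) {
  kind <- match.arg(kind)
  if (!is.finite(sdlog) || sdlog <= 0)
    stop("sdlog must be positive")
  med <- exp(meanlog)
  if (!is.finite(med) || med < 1 || med > 120)
    stop("implausible event-age median ", format(med), " years")
  structure(list(cag = as.integer(cag), meanlog = meanlog, sdlog = sdlog,
                 n_obs = n_obs, event_kind = kind, low_n = low_n),
            class = "lognormal_event_model")
}

#' @export
print.lognormal_event_model <- function(x, ...) {
  cat(sprintf(
    "Log-normal %s model, CAG %d: median %.1f y (meanlog %.4f, sdlog %.4f)%s\n",
    x$event_kind, x$cag, exp(x$meanlog), x$meanlog, x$sdlog,
    if (isTRUE(x$low_n)) sprintf(" [low n = %d]", x$n_obs) else ""))
  invisible(x)
}

#' Event probabilities from a log-normal event model
#'
#' `event_cdf()` is the cumulative probability that the event (onset or
#' death) has occurred by `age`; `hd_survival()` is its complement, the
#' probability of being event-free, used as the disease-specific survival
#' factor; `event_median()` is the age at 50% event probability,
#' `exp(meanlog)`.
#'
#' @param model A [lognormal_event_model()].
#' @param age Age(s) in years, `>= 0`.
#' @return Probabilities in `[0, 1]`.
#' @export
event_cdf <- function(model, age) {
  stopifnot(inherits(model, "lognormal_event_model"))
  if (any(age < 0)) stop("age must be non-negative")
  stats::plnorm(age, meanlog = model$meanlog, sdlog = model$sdlog)
}

#' @rdname event_cdf
#' @export
hd_survival <- function(model, age) {
  1 - event_cdf(model, age)
}

#' @rdname event_cdf
#' @export
event_median <- function(model) {
  stopifnot(inherits(model, "lognormal_event_model"))
  exp(model$meanlog)
}
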