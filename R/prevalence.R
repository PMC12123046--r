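#' Prevalence anchor
#'
#' Wraps a disease prevalence (cases per person) together with its
#' "one in N" reciprocal, `N = floor(1/prevalence)`. The widely used
#' European-ancestry Huntington's disease prevalence of 12.4 per 100 000
#' corresponds to one case in 8064 people.
#'
#' @param prevalence Cases per person, strictly between 0 and 1.
#' @return A list of class `prevalence_anchor` with `prevalence` and
#'   `one_in_n`.
#' @examples
#' prevalence_anchor(12.4e-5)
#' @export
prevalence_anchor <- function(prevalence) {
  if (!is.numeric(prevalence) || length(prevalence) != 1L ||
      !is.finite(prevalence) || prevalence <= 0 || prevalence >= 1)
    stop("prevalence must be a single fraction in (0, 1)")
  structure(list(prevalence = prevalence, one_in_n = one_in(prevalence)),
            class = "prevalence_anchor")
}

#' @export
print.prevalence_anchor <- function(x, ...) {
  cat(sprintf("Prevalence %.4g per 100 000 (one in %d)\n",
              x$prevalence * 1e5, x$one_in_n))
  invisible(x)
}

#' Population size implied by a case count and a prevalence
#'
#' How many people of the general population would need to be sampled, at
#' the anchored prevalence, to ascertain `n_cases` cases. For the reference
#' cohort of 7578 subjects at one in 8064 this is 61 108 992 people.
#'
#' @param n_cases Positive case count.
#' @param anchor A [prevalence_anchor()].
#' @return `n_cases * one_in_n`, integer arithmetic.
#' @export
required_population_size <- function(n_cases, anchor) {
  stopifnot(inherits(anchor, "prevalence_anchor"))
  if (!is.numeric(n_cases) || length(n_cases) != 1L || n_cases <= 0 ||
      n_cases != round(n_cases))
    stop("n_cases must be a single positive integer")
  n_cases * anchor$one_in_n
}

#' Prevalence-anchored population allele distribution
#'
#' Scales an observed unexpanded-allele spectrum up to the chromosome count
#' of the general population implied by a prevalence anchor, and merges the
#' observed expanded alleles unchanged, yielding the bimodal spectrum the
#' population would show if every expanded-repeat carrier were ascertained.
#' The target unexpanded total is
#' `2 * required_population_size - expanded pool` (every person carries two
#' alleles and each case contributes one expanded allele).
#'
#' In `"expected"` mode the target total is distributed proportionally to
#' the observed unexpanded spectrum with largest-remainder rounding, which
#' conserves the total exactly. In `"sampled"` mode the counts are one
#' multinomial draw (a bootstrap of the observed spectrum at population
#' scale), reproducible from `seed`.
#'
#' @param expanded,unexpanded [allele_table()]s from [tabulate_alleles()].
#' @param anchor A [prevalence_anchor()].
#' @param mode `"expected"` (deterministic) or `"sampled"`.
#' @param seed Integer seed for sampled mode.
#' @return An [allele_table()] covering both ranges.
#' @export
prevalence_anchored_distribution <- function(expanded, unexpanded, anchor,
                                             mode = c("expected", "sampled"),
                                             seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(expanded, "allele_table"),
            inherits(unexpanded, "allele_table"))
  if (!nrow(expanded) || !nrow(unexpanded))
    stop("both allele tables must be non-empty")
  n_cases <- pool_size(expanded)
  pop <- required_population_size(n_cases, anchor)
  target <- 2 * pop - n_cases
  if (target <= 0)
    stop("prevalence anchor implies fewer chromosomes than observed cases")
  p <- unexpanded$count / pool_size(unexpanded)
  new_counts <- switch(mode,
    expected = largest_remainder(target * p),
    sampled = {
      if (!is.null(seed)) set.seed(seed)
      as.numeric(stats::rmultinom(1L, size = target, prob = p))
    })
  allele_table(c(unexpanded$cag, expanded$cag),
               c(new_counts, expanded$count))
}

# Largest-remainder (Hamilton) rounding: integers summing exactly to
# round(sum(x)), apportioned to x.
largest_remainder <- function(x) {
  total <- round(sum(x))
  fl <- floor(x)
  rem <- x - fl
  short <- total - sum(fl)
  if (short > 0) {
    take <- order(rem, decreasing = TRUE)[seq_len(short)]
    fl[take] <- fl[take] + 1
  }
  fl
}
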