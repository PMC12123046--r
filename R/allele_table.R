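#' Allele-count tables
#'
#' An `allele_table` stores counts of alleles (or of carriers) per integer
#' CAG repeat length. It is the common currency of the package: decay-law
#' fits consume it, the prevalence-anchored bootstrap produces it, and the
#' cohort comparison machinery compares two of them.
#'
#' @param cag Integer vector of CAG repeat lengths (positive).
#' @param count Numeric vector of non-negative counts, same length as `cag`.
#' @param unit Either `"allele"` (chromosome counts) or `"carrier"`
#'   (person counts).
#' @return An object of class `allele_table`: a data frame with columns
#'   `cag` and `count`, ordered by `cag`, plus attributes `unit` and
#'   `pool_size` (the total count).
#' @examples
#' at <- allele_table(17:20, c(120, 90, 60, 40))
#' pool_size(at)
#' @export
allele_table <- function(cag, count, unit = c("allele", "carrier")) {
  unit <- match.arg(unit)
  if (length(cag) != length(count))
    stop("`cag` and `count` must have the same length")
  if (length(cag)) {
    if (any(!is.finite(cag)) || any(cag != as.integer(cag)) || any(cag < 1))
      stop("CAG repeat lengths must be positive integers")
    if (any(!is.finite(count)) || any(count < 0))
      stop("counts must be non-negative")
    if (anyDuplicated(cag))
      stop("duplicated CAG length in allele table")
  }
  ord <- order(cag)
  x <- data.frame(cag = as.integer(cag)[ord], count = as.numeric(count)[ord])
  structure(x, unit = unit, class = c("allele_table", "data.frame"))
}

#' @rdname allele_table
#' @param x An `allele_table`.
#' @export
pool_size <- function(x) {
  stopifnot(inherits(x, "allele_table"))
  sum(x$count)
}

#' @rdname allele_table
#' @export
table_unit <- function(x) {
  stopifnot(inherits(x, "allele_table"))
  attr(x, "unit")
}

#' @export
print.allele_table <- function(x, ...) {
  cat(sprintf("Allele count table (%s unit): %d CAG bins, pool size %s\n",
              table_unit(x), nrow(x), formatC(pool_size(x), format = "fg", big.mark = " ")))
  if (nrow(x)) {
    cat(sprintf("  CAG range %d-%d\n", min(x$cag), max(x$cag)))
    print.data.frame(utils::head(as.data.frame(x), 10L), row.names = FALSE)
    if (nrow(x) > 10L) cat("  ...\n")
  }
  invisible(x)
}

# Look up the count at one CAG (0 when the bin is absent).
count_at <- function(x, cag) {
  i <- match(cag, x$cag)
  ifelse(is.na(i), 0, x$count[i])
}

#' Tabulate a per-person genotype table into allele-count tables
#'
#' Every subject carries two CAG alleles. The genotypes are split at a
#' threshold (35 by convention: unexpanded vs expanded) and counted into two
#' allele tables that partition all chromosomes, so the two pool sizes sum
#' to twice the number of subjects.
#'
#' @param genotypes A data frame with columns `allele1` and `allele2`
#'   (positive integer repeat lengths), optionally `sample_id`.
#' @param split CAG threshold: alleles `<= split` go to the first table,
#'   `> split` to the second. Default 35.
#' @return A list with elements `unexpanded` and `expanded`, both
#'   [allele_table()]s with unit `"allele"`.
#' @examples
#' g <- data.frame(allele1 = c(17, 17, 20), allele2 = c(17, 42, 44))
#' tabulate_alleles(g)$expanded
#' @export
tabulate_alleles <- function(genotypes, split = 35) {
  if (!is.data.frame(genotypes) ||
      !all(c("allele1", "allele2") %in% names(genotypes)))
    stop("`genotypes` must be a data frame with columns allele1 and allele2")
  a <- c(genotypes$allele1, genotypes$allele2)
  bad <- which(!is.finite(a) | a < 1 | a != round(a))
  if (length(bad)) {
    row <- ((bad - 1L) %% nrow(genotypes)) + 1L
    id <- if ("sample_id" %in% names(genotypes))
      genotypes$sample_id[row[1L]] else row[1L]
    stop(sprintf("invalid repeat length %s for record %s",
                 format(a[bad[1L]]), id))
  }
  a <- as.integer(a)
  mk <- function(v) {
    if (!length(v)) return(allele_table(integer(0), numeric(0)))
    tab <- table(v)
    allele_table(as.integer(names(tab)), as.numeric(tab))
  }
  list(unexpanded = mk(a[a <= split]), expanded = mk(a[a > split]))
}

#' Read and write allele-count and genotype tables
#'
#' Allele-count tables are TSV files with header `cag<TAB>count`; genotype
#' tables are TSV with header `sample_id<TAB>allele1<TAB>allele2`.
#'
#' @param file Path to a TSV file.
#' @param unit Count unit for the resulting table.
#' @return `read_allele_table()` returns an [allele_table()];
#'   `read_genotypes()` a data frame.
#' @export
read_allele_table <- function(file, unit = "allele") {
  x <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("cag", "count") %in% names(x)))
    stop("allele table file must have columns `cag` and `count`: ", file)
  allele_table(x$cag, x$count, unit = unit)
}

#' @rdname read_allele_table
#' @param x An `allele_table` to write.
#' @export
write_allele_table <- function(x, file) {
  stopifnot(inherits(x, "allele_table"))
  utils::write.table(as.data.frame(x)[, c("cag", "count")], file,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname read_allele_table
#' @export
read_genotypes <- function(file) {
  x <- utils::read.delim(file, stringsAsFactors = FALSE)
  need <- c("sample_id", "allele1", "allele2")
  if (!all(need %in% names(x)))
    stop("genotype file must have columns sample_id, allele1, allele2: ", file)
  x[need]
}
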