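#' Chi-square test of first-brood female bias against social organization
#'
#' The model predicts that the overall first-brood sex ratio should be
#' female-biased in primitively eusocial species (the sex-ratio adjustment
#' `f = 1/(2 - a)` makes the first brood female-biased whenever some
#' daughters help). The prediction is tested on a 2x2 table of species
#' counts, social organization (primitively eusocial vs not) by first-brood
#' sex-ratio bias (female bias vs none), using the Pearson chi-square
#' statistic on 1 degree of freedom without continuity correction.
#'
#' @param table a 2x2 matrix (or coercible) of non-negative counts; rows are
#'   social organization, columns bias category.
#' @return an object of class `"chisq2x2"`: `statistic`, `df`, `p.value`,
#'   `observed`, `expected`.
#' @examples
#' chi_square_2x2(halictine_sexratio_counts())   # statistic 21.496
#' @export
chi_square_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L))) stop("a 2x2 table is required", call. = FALSE)
  if (any(m < 0) || any(m != trunc(m))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(m) == 0) stop("table has no observations", call. = FALSE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("zero marginal total: expected counts undefined", call. = FALSE)
  }
  # small expected counts trigger chisq.test's approximation warning; the
  # uncorrected Pearson statistic is the documented choice here
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p.value = ht$p.value,
                 observed = m, expected = ht$expected),
            class = "chisq2x2")
}

#' @export
print.chisq2x2 <- function(x, ...) {
  cat("Pearson chi-square test of independence (no continuity correction)\n")
  cat(sprintf("  X-squared = %.3f, df = %d, p-value = %.3g\n",
              x$statistic, x$df, x$p.value))
  invisible(x)
}

#' First-brood sex-ratio counts for halictine sweat bees
#'
#' Counts of species and populations of sweat bees (Halictinae) classified
#' by social organization (primitively eusocial vs not eusocial, the latter
#' covering solitary, communal and semisocial) and by first-brood overall
#' sex ratio (female-biased vs unbiased-or-male-biased), compiled from the
#' published species survey shipped as a plain-text fixture in
#' `extdata/halictine_firstbrood_sexratio.csv`.
#'
#' @return a 2x2 integer matrix with dimnames.
#' @export
halictine_sexratio_counts <- function() {
  path <- system.file("extdata", "halictine_firstbrood_sexratio.csv",
                      package = "haplodyn", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  m <- as.matrix(df[, c("female_bias", "no_female_bias")])
  rownames(m) <- df$social_organization
  storage.mode(m) <- "integer"
  m
}

#' Sample synthetic 2x2 tables under specified bias probabilities
#'
#' Generates contingency tables by drawing, for each row, a binomial count
#' of female-biased cases out of the row total. Used for type-I-error
#' calibration and parametric-bootstrap checks of [chi_square_2x2()].
#'
#' @param row_totals integer vector of length 2: species counts per social
#'   organization.
#' @param bias_probabilities length-2 vector of probabilities that a species
#'   in each row shows female bias.
#' @param replicates number of tables.
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @return a list of 2x2 matrices (empty list when `replicates = 0`).
#' @export
sample_tables <- function(row_totals, bias_probabilities, replicates,
                          seed = NULL) {
  stopifnot(length(row_totals) == 2L, all(row_totals >= 0),
            length(bias_probabilities) == 2L,
            all(bias_probabilities >= 0), all(bias_probabilities <= 1),
            replicates >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (replicates == 0) return(list())
  lapply(seq_len(replicates), function(i) {
    fb <- stats::rbinom(2L, row_totals, bias_probabilities)
    matrix(c(fb, row_totals - fb), nrow = 2L,
           dimnames = list(NULL, c("female_bias", "no_female_bias")))
  })
}
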