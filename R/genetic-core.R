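#' One-locus, two-allele Mendelian machinery for haplodiploid and diploid
#' subsocial lifecycles
#'
#' The model assumes a single locus with a wild-type allele `A0` and an
#' allele for reproductive altruism `A1`, conditionally expressed in
#' first-brood daughters: a carrier daughter may stay at the nest and help
#' her mother produce extra second-brood offspring instead of dispersing.
#' Female genotypes are unordered pairs (`"A0A0"`, `"A0A1"`, `"A1A1"`);
#' males carry one allele under haplodiploidy (`"A0"`, `"A1"`) and two under
#' diploidy.
#'
#' @name genetic_core
NULL

.FEMALE_GENOTYPES <- c("A0A0", "A0A1", "A1A1")
.HAPLOID_MALE_GENOTYPES <- c("A0", "A1")

#' Genotype sets and allele counting
#'
#' @param ploidy `"haplodiploid"` or `"diploid"`.
#' @return `female_genotypes()` / `male_genotypes()`: character vectors of
#'   valid genotype labels; `count_a1()`: integer vector of `A1` copies
#'   carried by each genotype.
#' @export
female_genotypes <- function() .FEMALE_GENOTYPES

#' @rdname female_genotypes
#' @export
male_genotypes <- function(ploidy = c("haplodiploid", "diploid")) {
  ploidy <- match.arg(ploidy)
  if (ploidy == "haplodiploid") .HAPLOID_MALE_GENOTYPES else .FEMALE_GENOTYPES
}

#' @rdname female_genotypes
#' @param genotype character vector of genotype labels.
#' @export
count_a1 <- function(genotype) {
  vapply(genotype, function(g) {
    sum(strsplit(g, "A", fixed = TRUE)[[1]] == "1")
  }, integer(1), USE.NAMES = FALSE)
}

.alleles_of <- function(genotype) {
  a <- strsplit(genotype, "A", fixed = TRUE)[[1]]
  paste0("A", a[nzchar(a)])
}

.sort_genotype <- function(alleles) paste(sort(alleles), collapse = "")

#' Model configuration
#'
#' Bundles the four switches that define a scenario: ploidy system, dominance
#' of the altruism allele, lifecycle, and whether the first-brood sex ratio is
#' adjusted per mated pair so that the pair's dispersing first brood stays at
#' 1:1 (`f = 1/(2 - a)`, with `a` the pair's helper fraction among first-brood
#' daughters).
#'
#' @param ploidy `"haplodiploid"` or `"diploid"`.
#' @param dominance `"dominant"` or `"codominant"` expression of `A1` in
#'   heterozygous females.
#' @param lifecycle `"univoltine"` (foundress produces two broods, all
#'   offspring hers) or `"partially_bivoltine"` (dispersing first-brood
#'   offspring breed within the season, producing a second generation).
#' @param sex_adjusted logical; apply the per-pair first-brood sex-ratio
#'   adjustment `f = 1/(2 - a)`.
#' @return an object of class `"genetic_config"`.
#' @examples
#' genetic_config("haplodiploid", "dominant", "univoltine")
#' @export
genetic_config <- function(ploidy = c("haplodiploid", "diploid"),
                           dominance = c("dominant", "codominant"),
                           lifecycle = c("univoltine", "partially_bivoltine"),
                           sex_adjusted = FALSE) {
  ploidy <- match.arg(ploidy)
  dominance <- match.arg(dominance)
  lifecycle <- match.arg(lifecycle)
  stopifnot(is.logical(sex_adjusted), length(sex_adjusted) == 1L,
            !is.na(sex_adjusted))
  structure(list(ploidy = ploidy, dominance = dominance,
                 lifecycle = lifecycle, sex_adjusted = sex_adjusted),
            class = "genetic_config")
}

#' @export
print.genetic_config <- function(x, ...) {
  cat("Genetic model configuration\n")
  cat("  ploidy:      ", x$ploidy, "\n")
  cat("  dominance:   ", x$dominance, "\n")
  cat("  lifecycle:   ", x$lifecycle, "\n")
  cat("  sex adjusted:", x$sex_adjusted, "\n")
  invisible(x)
}

#' Lifecycle parameters
#'
#' @param n foundress brood size (offspring per brood), positive.
#' @param b extra second-brood offspring produced per helper, non-negative.
#' @param n2 brood size of an independently breeding first-brood female
#'   (partially bivoltine lifecycle only), positive.
#' @return an object of class `"lifecycle_params"`.
#' @export
lifecycle_params <- function(n, b, n2 = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, n > 0,
            is.numeric(b), length(b) == 1L, b >= 0)
  if (!is.null(n2)) stopifnot(is.numeric(n2), length(n2) == 1L, n2 > 0)
  structure(list(n = n, b = b, n2 = n2), class = "lifecycle_params")
}

.validate_params <- function(config, params) {
  stopifnot(inherits(config, "genetic_config"),
            inherits(params, "lifecycle_params"))
  if (config$lifecycle == "partially_bivoltine" && is.null(params$n2)) {
    stop("partially bivoltine lifecycle requires n2", call. = FALSE)
  }
  invisible(TRUE)
}

.check_female <- function(genotype) {
  if (!genotype %in% .FEMALE_GENOTYPES) {
    stop("invalid female genotype: ", genotype, call. = FALSE)
  }
}

.check_male <- function(genotype, ploidy) {
  if (!genotype %in% male_genotypes(ploidy)) {
    stop("invalid ", ploidy, " male genotype: ", genotype, call. = FALSE)
  }
}

#' Mendelian offspring distribution of a mated pair
#'
#' Enumerates offspring classes (sex by genotype) with exact rational
#' proportions. Sexes are produced at the unadjusted 1:1 ratio; any sex-ratio
#' adjustment is applied downstream by the season accounting. Under
#' haplodiploidy sons develop from unfertilized eggs and receive only a
#' maternal allele, while every daughter receives the father's entire haploid
#' genome.
#'
#' @param mother female genotype (`"A0A0"`, `"A0A1"`, `"A1A1"`).
#' @param father male genotype (one allele if haplodiploid, two if diploid).
#' @param ploidy `"haplodiploid"` or `"diploid"`.
#' @return an object of class `"offspring_dist"`: parallel vectors `sex`,
#'   `genotype` and rational `prop` summing to 1.
#' @examples
#' offspring_distribution("A0A1", "A0", "haplodiploid")
#' @export
offspring_distribution <- function(mother, father,
                                   ploidy = c("haplodiploid", "diploid")) {
  ploidy <- match.arg(ploidy)
  .check_female(mother)
  .check_male(father, ploidy)
  m_gam <- .alleles_of(mother)             # two maternal gametes, 1/2 each
  classes <- list()
  add <- function(sex, genotype, prop) {
    key <- paste(sex, genotype)
    if (is.null(classes[[key]])) {
      classes[[key]] <<- list(sex = sex, genotype = genotype, prop = prop)
    } else {
      classes[[key]]$prop <<- classes[[key]]$prop + prop
    }
  }
  if (ploidy == "haplodiploid") {
    for (mg in m_gam) {
      add("female", .sort_genotype(c(mg, father)), rational(1, 4))
      add("male", mg, rational(1, 4))
    }
  } else {
    f_gam <- .alleles_of(father)
    for (mg in m_gam) for (fg in f_gam) {
      g <- .sort_genotype(c(mg, fg))
      add("female", g, rational(1, 8))
      add("male", g, rational(1, 8))
    }
  }
  classes <- classes[order(vapply(classes, `[[`, "", "sex"),
                           vapply(classes, `[[`, "", "genotype"))]
  structure(list(sex = vapply(classes, `[[`, "", "sex"),
                 genotype = vapply(classes, `[[`, "", "genotype"),
                 prop = do.call(c, lapply(classes, `[[`, "prop"))),
            class = "offspring_dist")
}

#' @export
as.data.frame.offspring_dist <- function(x, ...) {
  data.frame(sex = x$sex, genotype = x$genotype,
             proportion = format(x$prop),
             numeric = as.numeric(x$prop),
             stringsAsFactors = FALSE)
}

#' @export
print.offspring_dist <- function(x, ...) {
  print(as.data.frame(x))
  invisible(x)
}

#' Probability that a female expresses helping
#'
#' Penetrance of the altruism allele given the opportunity to help:
#' 0 for `A0A0`, 1 for `A1A1`; heterozygotes express with probability 1 when
#' the allele is dominant and 1/2 under codominance (probabilistic
#' expression; see the methods vignette for the validation of this rule
#' against the published codominant threshold and asymptote).
#'
#' @param genotype a female genotype.
#' @param dominance `"dominant"` or `"codominant"`.
#' @return a rational probability.
#' @export
helping_penetrance <- function(genotype,
                               dominance = c("dominant", "codominant")) {
  dominance <- match.arg(dominance)
  if (!genotype %in% .FEMALE_GENOTYPES) {
    stop("helping_penetrance() requires a female genotype, got ", genotype,
         call. = FALSE)
  }
  k <- count_a1(genotype)
  if (k == 0L) return(rational(0))
  if (k == 2L) return(rational(1))
  if (dominance == "dominant") rational(1) else rational(1, 2)
}

#' Crosses carrying a single introduced altruism allele
#'
#' When one `A1` copy is introduced into an otherwise wild-type population it
#' lands in a mated pair in one of two ways under haplodiploidy: in the
#' foundress (`A0A1 x A0`) or in her mate (`A0A0 x A1`). The weights 2/3 and
#' 1/3 are the proportions of genome copies carried by females and males,
#' equivalently the sexes' reproductive values under haplodiploidy. Under
#' diploidy there is a single cross, `A0A1 x A0A0`.
#'
#' @param config a [genetic_config()].
#' @return a list of crosses, each `list(mother, father, weight)` with
#'   rational weights summing to 1.
#' @export
enumerate_introduction_crosses <- function(config) {
  stopifnot(inherits(config, "genetic_config"))
  if (config$ploidy == "haplodiploid") {
    list(list(mother = "A0A1", father = "A0", weight = rational(2, 3)),
         list(mother = "A0A0", father = "A1", weight = rational(1, 3)))
  } else {
    list(list(mother = "A0A1", father = "A0A0", weight = rational(1)))
  }
}

#' First-brood sex-ratio adjustment
#'
#' When a fraction `a` of first-brood daughters help, the dispersing first
#' brood becomes male-biased. Fisherian selection for equal investment in
#' dispersing offspring is imposed by biasing the overall first-brood sex
#' ratio toward females: the proportion of first-brood offspring that are
#' female becomes `f = 1/(2 - a)`, which makes the pair's dispersing first
#' brood exactly even (`f (1 - a) = 1 - f`).
#'
#' @param a proportion of first-brood daughters that act as helpers, in
#'   `[0, 1]`; `rational` or numeric.
#' @return `f`, the female proportion of the first brood, of the same type
#'   as `a`.
#' @examples
#' adjusted_sex_ratio(rational(1, 2))  # 2/3
#' @export
adjusted_sex_ratio <- function(a) {
  if (is_rational(a)) {
    if (a < 0 || a > 1) stop("a must lie in [0, 1]", call. = FALSE)
    return(rational(1) / (rational(2) - a))
  }
  stopifnot(is.numeric(a))
  if (any(a < 0 | a > 1)) stop("a must lie in [0, 1]", call. = FALSE)
  1 / (2 - a)
}
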