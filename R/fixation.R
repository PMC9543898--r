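#' Selection coefficient of a new altruism allele
#'
#' The relative fitness of the heterozygote carrier is `x / x_neutral`, the
#' cross-weighted season copy count of the expressed allele over the neutral
#' baseline (for the univoltine lifecycle the baseline equals the brood size
#' `n`). The selection coefficient is `s = x / x_neutral - 1`; brood size
#' cancels, so `s` depends only on `b` (and `n2` when bivoltine).
#'
#' @param config a [genetic_config()].
#' @param b amount of help (`rational` or numeric).
#' @param n2 second-generation brood size (bivoltine lifecycle only).
#' @return `s` as an exact `rational` when inputs are rational or
#'   integer-valued, else a double.
#' @examples
#' cfg <- genetic_config("haplodiploid", "dominant", "univoltine")
#' format(selection_coefficient(cfg, b = 3))   # "1/6"
#' @export
selection_coefficient <- function(config, b, n2 = NULL) {
  if (config$lifecycle == "partially_bivoltine" && is.null(n2)) {
    stop("partially bivoltine lifecycle requires n2", call. = FALSE)
  }
  s <- weighted_invasion_summary(config)
  exact <- (is_rational(b) || (is.numeric(b) && all(b == trunc(b)))) &&
    (is.null(n2) || is_rational(n2) || (is.numeric(n2) && all(n2 == trunc(n2))))
  if (exact) {
    xv <- qp_value(qp_eval(s$x, n = 1, b = b, n2 = n2))
    xn <- qp_value(qp_eval(s$x_neutral, n = 1, b = b, n2 = n2))
    return(xv / xn - 1)
  }
  n2n <- if (is.null(n2)) NA_real_ else as.numeric(n2)
  qp_eval_num(s$x, n = 1, b = as.numeric(b), n2 = n2n) /
    qp_eval_num(s$x_neutral, n = 1, b = as.numeric(b), n2 = n2n) - 1
}

#' Fixation probability under weak selection
#'
#' For a beneficial allele in a large population the fixation probability of
#' a single new copy is approximately twice the heterozygote's selective
#' advantage, `pi = 2 s`, regardless of dominance or ploidy. The
#' approximation is capped at 1 (it is a probability), and deleterious or
#' neutral alleles are assigned 0 here; the stochastic simulator measures the
#' true small neutral fixation probability instead.
#'
#' @param s selection coefficient (`rational` or numeric).
#' @return `min(2 s, 1)` for `s > 0`, else 0; rational in, rational out.
#' @examples
#' cfg <- genetic_config("haplodiploid", "dominant", "univoltine")
#' as.numeric(fixation_probability(selection_coefficient(cfg, b = 3)))  # 1/3
#' @export
fixation_probability <- function(s) {
  if (is_rational(s)) {
    if (s <= 0) return(rational(0))
    return(min(c(2 * s, rational(1))))
  }
  stopifnot(is.numeric(s))
  ifelse(s <= 0, 0, pmin(2 * s, 1))
}

#' Expected waiting time between substitutions
#'
#' The substitution rate of altruism alleles is `rho = c N mu pi`, where `c`
#' is the mean number of genome copies per individual (1.5 under
#' haplodiploidy at an even sex ratio, 2 under diploidy), `N` the population
#' size, `mu` the mutation rate and `pi` the fixation probability. Returns
#' the expected number of generations per substitution, `1/rho`. The larger
#' mutational target of a diploid population (`c = 2`) exactly cancels the
#' haplodiploid fixation advantage at `b = 3`.
#'
#' @param N population size (individuals).
#' @param mu mutation rate (mutations per site per generation).
#' @param pi fixation probability.
#' @param ploidy `"haplodiploid"` or `"diploid"`.
#' @return generations per substitution (`Inf` when `pi = 0`).
#' @examples
#' substitution_interval(1e6, 1e-9, 1 / 3, "haplodiploid")   # 2000
#' @export
substitution_interval <- function(N, mu, pi,
                                  ploidy = c("haplodiploid", "diploid")) {
  ploidy <- match.arg(ploidy)
  stopifnot(is.numeric(N), N > 0, is.numeric(mu), mu > 0)
  pi <- as.numeric(pi)
  stopifnot(pi >= 0, pi <= 1)
  cc <- if (ploidy == "haplodiploid") 1.5 else 2
  if (pi == 0) return(Inf)
  1 / (cc * N * mu * pi)
}

#' Range of help over which haplodiploidy has the fixation advantage
#'
#' The interval of `b` where the capped weak-selection fixation probability
#' is strictly larger under haplodiploidy than under diploidy. The lower end
#' is the shared invasion threshold; the upper end is where the slower
#' (diploid) curve also reaches the cap `pi = 1`, after which the two curves
#' coincide. For the univoltine dominant model this is exactly `2 < b < 6`
#' (the haplodiploid curve caps at `b = 5`, the diploid at `b = 6`).
#'
#' @param dominance allele dominance.
#' @param lifecycle lifecycle; `n2` required when partially bivoltine.
#' @param n2 second-generation brood size.
#' @return rational vector `c(lower, upper)` bounding the open interval.
#' @examples
#' format(fixation_advantage_range())   # "2" "6"
#' @export
fixation_advantage_range <- function(dominance = c("dominant", "codominant"),
                                     lifecycle = c("univoltine",
                                                   "partially_bivoltine"),
                                     n2 = NULL) {
  dominance <- match.arg(dominance)
  lifecycle <- match.arg(lifecycle)
  mk <- function(ploidy) genetic_config(ploidy, dominance, lifecycle)
  n2r <- if (is.null(n2)) NULL else as_rational(n2)
  if (lifecycle == "partially_bivoltine" && is.null(n2r)) {
    stop("partially bivoltine lifecycle requires n2", call. = FALSE)
  }
  # s is linear in b for each ploidy: s(b) = s0 + s1 b (exact rationals)
  s_line <- function(ploidy) {
    sm <- weighted_invasion_summary(mk(ploidy))
    d <- sm$x
    cb <- qp_coefs_b(d)
    xn <- qp_value(qp_eval(sm$x_neutral, n = 1, n2 = n2r))
    s0 <- qp_value(qp_eval(cb[[1L]], n = 1, n2 = n2r)) / xn - 1
    s1 <- qp_value(qp_eval(cb[[2L]], n = 1, n2 = n2r)) / xn
    list(s0 = s0, s1 = s1)
  }
  h <- s_line("haplodiploid")
  d <- s_line("diploid")
  thr <- function(l) -l$s0 / l$s1           # s = 0
  cap <- function(l) (rational(1, 2) - l$s0) / l$s1   # 2 s = 1
  lower <- max(c(thr(h), thr(d)))
  upper <- max(c(cap(h), cap(d)))
  c(lower, upper)
}
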