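#' Allele-copy accounting over a breeding season
#'
#' Counts copies of the altruism allele among dispersing offspring at the end
#' of a breeding season for a single mated pair (cross), symbolically in the
#' lifecycle parameters. The count is the pair's contribution to the next
#' generation measured in allele copies: first-brood daughters that express
#' helping are removed from the dispersing pool and instead add `b` offspring
#' each to the second brood. In the partially bivoltine lifecycle, dispersing
#' first-brood offspring breed within the season (mating with wild-type
#' partners, the rare-allele limit) and it is their second-generation
#' offspring that are counted in the autumn dispersing pool.
#'
#' With `neutral = TRUE` the allele is given no behavioral effect (penetrance
#' zero, and no sex-ratio adjustment since no helpers exist) while its copies
#' are still tracked; this is the baseline against which invasion is judged.
#'
#' @param cross a list with elements `mother` and `father` (genotypes), e.g.
#'   one element of [enumerate_introduction_crosses()].
#' @param config a [genetic_config()].
#' @param params optional [lifecycle_params()]; when supplied, numeric
#'   evaluations of all symbolic quantities are attached.
#' @param neutral logical; disable expression of the allele.
#' @return an object of class `"season_account"`: per-class rows with symbolic
#'   (`qpoly`) counts of helpers, dispersers and `A1` copies, plus season
#'   totals (`copies_total`, `dispersing_total`), the pair's helper fraction
#'   `a` and first-brood female proportion `f`.
#' @examples
#' cfg <- genetic_config("haplodiploid", "dominant", "univoltine")
#' acc <- season_account(list(mother = "A0A1", father = "A0"), cfg)
#' format(acc$copies_total)   # "(3/4)*n + (1/8)*b*n"
#' @export
season_account <- function(cross, config, params = NULL, neutral = FALSE) {
  stopifnot(inherits(config, "genetic_config"),
            is.list(cross), !is.null(cross$mother), !is.null(cross$father))
  if (!is.null(params)) .validate_params(config, params)
  bivoltine <- config$lifecycle == "partially_bivoltine"

  n <- qp_var("n"); b <- qp_var("b"); n2 <- qp_var("n2")
  dist <- offspring_distribution(cross$mother, cross$father, config$ploidy)
  fem <- dist$sex == "female"

  pen <- lapply(seq_along(dist$sex), function(i) {
    if (!fem[i] || neutral) rational(0)
    else helping_penetrance(dist$genotype[i], config$dominance)
  })

  # pair's expected helper fraction among first-brood daughters
  a <- rational(0)
  for (i in which(fem)) a <- a + (dist$prop[i] * 2) * pen[[i]]
  f <- if (config$sex_adjusted && !neutral) adjusted_sex_ratio(a)
       else rational(1, 2)

  wild_male <- if (config$ploidy == "haplodiploid") "A0" else "A0A0"

  rows <- list()
  add_row <- function(brood, sex, genotype, total, helping, dispersing,
                      copies, gen2_dispersing = NULL, gen2_copies = NULL) {
    rows[[length(rows) + 1L]] <<- list(
      brood = brood, sex = sex, genotype = genotype, total = total,
      helping = helping, dispersing = dispersing, copies = copies,
      gen2_dispersing = gen2_dispersing, gen2_copies = gen2_copies)
  }

  # expected A1 copies per offspring of a first-brood breeder mated wild-type
  gen2_copy_rate <- function(sex, genotype) {
    d <- if (sex == "female") {
      offspring_distribution(genotype, wild_male, config$ploidy)
    } else {
      offspring_distribution("A0A0", genotype, config$ploidy)
    }
    r <- rational(0)
    for (i in seq_along(d$sex)) r <- r + d$prop[i] * count_a1(d$genotype[i])
    r
  }

  helpers_total <- qp_const(0)
  for (i in seq_along(dist$sex)) {
    g <- dist$genotype[i]
    cond_p <- dist$prop[i] * 2    # proportion within the class's sex
    if (fem[i]) {
      total <- n * qp_const(f * cond_p)
      helping <- total * qp_const(pen[[i]])
      dispersing <- total - helping
      helpers_total <- helpers_total + helping
    } else {
      total <- n * qp_const((rational(1) - f) * cond_p)
      helping <- qp_const(0)
      dispersing <- total
    }
    if (bivoltine) {
      g2d <- dispersing * n2
      g2c <- g2d * qp_const(gen2_copy_rate(dist$sex[i], g))
      add_row("first", dist$sex[i], g, total, helping, dispersing,
              copies = qp_const(0), gen2_dispersing = g2d, gen2_copies = g2c)
    } else {
      add_row("first", dist$sex[i], g, total, helping, dispersing,
              copies = dispersing * count_a1(g))
    }
  }

  brood2_size <- n + b * helpers_total
  for (i in seq_along(dist$sex)) {
    total <- brood2_size * qp_const(dist$prop[i])
    add_row("second", dist$sex[i], dist$genotype[i], total,
            helping = qp_const(0), dispersing = total,
            copies = total * count_a1(dist$genotype[i]))
  }

  qsum <- function(xs) Reduce(`+`, xs, qp_const(0))
  first_rows <- Filter(function(r) r$brood == "first", rows)
  second_rows <- Filter(function(r) r$brood == "second", rows)
  if (bivoltine) {
    copies_total <- qsum(lapply(first_rows, `[[`, "gen2_copies")) +
      qsum(lapply(second_rows, `[[`, "copies"))
    dispersing_total <- qsum(lapply(first_rows, `[[`, "gen2_dispersing")) +
      qsum(lapply(second_rows, `[[`, "dispersing"))
  } else {
    copies_total <- qsum(lapply(rows, `[[`, "copies"))
    dispersing_total <- qsum(lapply(rows, `[[`, "dispersing"))
  }

  out <- structure(list(cross = cross, config = config, neutral = neutral,
                        a = a, f = f, rows = rows,
                        helpers_total = helpers_total,
                        brood2_size = brood2_size,
                        copies_total = copies_total,
                        dispersing_total = dispersing_total),
                   class = "season_account")
  if (!is.null(params)) {
    ev <- function(p) qp_eval_num(p, n = params$n, b = params$b,
                                  n2 = if (is.null(params$n2)) NA_real_
                                       else params$n2)
    out$evaluated <- list(copies_total = ev(copies_total),
                          dispersing_total = ev(dispersing_total),
                          helpers_total = ev(helpers_total))
  }
  out
}

#' @export
as.data.frame.season_account <- function(x, ...) {
  fmt <- function(p) if (is.null(p)) NA_character_ else format(p)
  do.call(rbind, lapply(x$rows, function(r) {
    data.frame(brood = r$brood, sex = r$sex, genotype = r$genotype,
               total = fmt(r$total), helping = fmt(r$helping),
               dispersing = fmt(r$dispersing), copies = fmt(r$copies),
               gen2_dispersing = fmt(r$gen2_dispersing),
               gen2_copies = fmt(r$gen2_copies),
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.season_account <- function(x, ...) {
  cat("Season account: ", x$cross$mother, " x ", x$cross$father,
      if (x$neutral) "  [neutral allele]", "\n", sep = "")
  cat("  helper fraction a = ", format(x$a),
      ",  first-brood female fraction f = ", format(x$f), "\n", sep = "")
  df <- as.data.frame(x)
  df <- df[, colSums(!is.na(df)) > 0, drop = FALSE]
  print(df, row.names = FALSE)
  cat("Season totals: copies = ", format(x$copies_total),
      ";  dispersing = ", format(x$dispersing_total), "\n", sep = "")
  invisible(x)
}

#' Cross-weighted invasion summary
#'
#' Averages the season accounts over the introduction crosses (weights 2/3
#' and 1/3 under haplodiploidy, 1 under diploidy) to obtain the expected
#' number of altruism-allele copies among dispersing offspring, `x`, and the
#' neutral baseline `x_neutral`. The allele invades when `x > x_neutral`.
#'
#' @inheritParams season_account
#' @return an object of class `"invasion_summary"` with symbolic `x`,
#'   `x_neutral`, the per-cross accounts, and the invasion threshold; when
#'   `params` is given, numeric `x`, `x_neutral` and their ratio
#'   (`relative_change`) are attached.
#' @examples
#' cfg <- genetic_config("haplodiploid", "dominant", "univoltine")
#' weighted_invasion_summary(cfg)
#' @export
weighted_invasion_summary <- function(config, params = NULL) {
  stopifnot(inherits(config, "genetic_config"))
  crosses <- enumerate_introduction_crosses(config)
  accounts <- lapply(crosses, season_account, config = config, params = params)
  accounts_neutral <- lapply(crosses, season_account, config = config,
                             params = params, neutral = TRUE)
  wmean <- function(accs) {
    out <- qp_const(0)
    for (i in seq_along(accs)) {
      out <- out + qp_const(crosses[[i]]$weight) * accs[[i]]$copies_total
    }
    out
  }
  x <- wmean(accounts)
  x_neutral <- wmean(accounts_neutral)
  out <- structure(list(config = config, crosses = crosses,
                        accounts = accounts,
                        accounts_neutral = accounts_neutral,
                        x = x, x_neutral = x_neutral,
                        threshold = .threshold_from(x, x_neutral)),
                   class = "invasion_summary")
  if (!is.null(params)) {
    n2v <- if (is.null(params$n2)) NA_real_ else params$n2
    xv <- qp_eval_num(x, n = params$n, b = params$b, n2 = n2v)
    xnv <- qp_eval_num(x_neutral, n = params$n, b = params$b, n2 = n2v)
    out$evaluated <- list(x = xv, x_neutral = xnv, relative_change = xv / xnv,
                          s = xv / xnv - 1)
  }
  out
}

#' @export
print.invasion_summary <- function(x, ...) {
  cat("Invasion summary (", x$config$ploidy, ", ", x$config$dominance, ", ",
      x$config$lifecycle,
      if (x$config$sex_adjusted) ", sex-ratio adjusted", ")\n", sep = "")
  cat("  x         =", format(x$x), "\n")
  cat("  x_neutral =", format(x$x_neutral), "\n")
  print(x$threshold)
  if (!is.null(x$evaluated)) {
    cat(sprintf("  at given parameters: x = %.6g, x_neutral = %.6g, x/x_neutral = %.6g\n",
                x$evaluated$x, x$evaluated$x_neutral,
                x$evaluated$relative_change))
  }
  invisible(x)
}

# solve x(b) = x_neutral(b) exactly; both are linear in b here
.threshold_from <- function(x, x_neutral) {
  d <- x - x_neutral
  cb <- qp_coefs_b(d)
  if (length(cb) > 2L) {
    stop("copy surplus is not linear in b; threshold solver does not apply",
         call. = FALSE)
  }
  c1 <- if (length(cb) == 2L) cb[[2L]] else qp_const(0)
  c0 <- cb[[1L]]
  if (qp_is_zero(c1)) {
    return(structure(list(b_star = NULL, no_threshold = TRUE),
                     class = "invasion_threshold"))
  }
  b_star <- qp_div_term(-c0, c1)
  structure(list(b_star = b_star, no_threshold = FALSE),
            class = "invasion_threshold")
}

#' Invasion threshold for the amount of help
#'
#' The smallest `b` at which the expressed allele's cross-weighted copy count
#' equals the neutral baseline; the allele spreads strictly above it (the
#' bound is open, equality is neutrality). Solved exactly from the symbolic
#' accounting: the threshold is a rational number for the univoltine
#' lifecycle and a rational multiple of `n2` for the partially bivoltine one.
#'
#' @param config a [genetic_config()].
#' @return an object of class `"invasion_threshold"` whose `b_star` is a
#'   `qpoly` (constant, or proportional to `n2`). Use `as.numeric(, n2 = )`
#'   to evaluate.
#' @examples
#' as.numeric(invasion_threshold(
#'   genetic_config("haplodiploid", "dominant", "univoltine",
#'                  sex_adjusted = TRUE)))  # 1.4
#' @export
invasion_threshold <- function(config) {
  weighted_invasion_summary(config)$threshold
}

#' @export
print.invasion_threshold <- function(x, ...) {
  if (x$no_threshold) cat("  no invasion threshold in b\n")
  else cat("  invasion threshold: b >", format(x$b_star), "\n")
  invisible(x)
}

#' @export
as.double.invasion_threshold <- function(x, n2 = NULL, ...) {
  if (x$no_threshold) return(NA_real_)
  if (is.null(n2)) {
    p <- x$b_star
    if (length(p$terms) && any(vapply(p$terms,
                                      function(t) t$exp[["n2"]] > 0, NA))) {
      stop("threshold is proportional to n2; supply n2 to evaluate",
           call. = FALSE)
    }
    return(qp_eval_num(p))
  }
  qp_eval_num(x$b_star, n2 = n2)
}

#' @export
#' @method as.numeric invasion_threshold
as.numeric.invasion_threshold <- as.double.invasion_threshold

#' Coefficient of `n2` in a bivoltine threshold
#'
#' @param threshold an `"invasion_threshold"` whose `b_star` is proportional
#'   to `n2`.
#' @return the rational coefficient (e.g. 7/10 for the sex-ratio-adjusted
#'   haplodiploid model).
#' @export
threshold_n2_coefficient <- function(threshold) {
  stopifnot(inherits(threshold, "invasion_threshold"), !threshold$no_threshold)
  qp_value(qp_div_term(threshold$b_star, qp_var("n2")))
}

#' Relative copy production of haplodiploidy over diploidy
#'
#' `R(b)` is the cross-weighted altruism-allele copy count under
#' haplodiploidy divided by the count under diploidy at identical parameters
#' (brood size cancels). `ratio_R()` evaluates at a given `b` (exact for
#' rational `b`); `ratio_R_formula()` returns the symbolic numerator and
#' denominator; `ratio_R_asymptote()` gives the exact large-`b` limit (the
#' ratio of the `b`-coefficients).
#'
#' @param config a [genetic_config()]; its ploidy field is ignored, both
#'   ploidies being computed internally.
#' @param b amount of help (`rational`, or numeric).
#' @param n2 second-generation brood size for the bivoltine lifecycle.
#' @return `ratio_R()`: a `rational` when `b` (and `n2`) are rational or
#'   integer-valued, otherwise a double.
#' @examples
#' cfg <- genetic_config("haplodiploid", "dominant", "univoltine")
#' as.numeric(ratio_R(cfg, b = 10))          # 14/12 = 4(4+10)/(3(6+10))
#' format(ratio_R_asymptote(cfg))            # "4/3"
#' @export
ratio_R <- function(config, b, n2 = NULL) {
  fx <- .ratio_R_parts(config)
  exact <- (is_rational(b) || (is.numeric(b) && all(b == trunc(b)))) &&
    (is.null(n2) || is_rational(n2) || (is.numeric(n2) && all(n2 == trunc(n2))))
  if (exact) {
    num <- qp_value(qp_eval(fx$x_hap, n = 1, b = b, n2 = n2))
    den <- qp_value(qp_eval(fx$x_dip, n = 1, b = b, n2 = n2))
    return(num / den)
  }
  qp_eval_num(fx$x_hap, n = 1, b = as.numeric(b),
              n2 = if (is.null(n2)) NA_real_ else as.numeric(n2)) /
    qp_eval_num(fx$x_dip, n = 1, b = as.numeric(b),
                n2 = if (is.null(n2)) NA_real_ else as.numeric(n2))
}

.ratio_R_parts <- function(config) {
  mk <- function(ploidy) {
    genetic_config(ploidy, config$dominance, config$lifecycle,
                   config$sex_adjusted)
  }
  list(x_hap = weighted_invasion_summary(mk("haplodiploid"))$x,
       x_dip = weighted_invasion_summary(mk("diploid"))$x)
}

#' @rdname ratio_R
#' @export
ratio_R_formula <- function(config) {
  fx <- .ratio_R_parts(config)
  list(numerator = qp_eval(fx$x_hap, n = 1),
       denominator = qp_eval(fx$x_dip, n = 1))
}

#' @rdname ratio_R
#' @export
ratio_R_asymptote <- function(config) {
  fx <- .ratio_R_parts(config)
  ch <- qp_coefs_b(fx$x_hap)
  cd <- qp_coefs_b(fx$x_dip)
  stopifnot(length(ch) == 2L, length(cd) == 2L)
  qp_value(qp_div_term(qp_eval(ch[[2L]], n = 1), qp_eval(cd[[2L]], n = 1)))
}

#' Naive neighbour-modulated help threshold (negative control)
#'
#' Counts total dispersing offspring of carrier pairs versus wild-type pairs,
#' ignoring the genotype composition of the dispersers, and solves for the
#' `b` at which they are equal. This is the incorrect accounting: dispersing
#' first-brood daughters are biased toward non-carriers (carriers stayed to
#' help), so simple offspring counting understates the cost of helping and
#' yields `b > 1` for the univoltine lifecycle instead of the correct
#' `b > 2`.
#'
#' @param config a [genetic_config()].
#' @return an `"invasion_threshold"` object.
#' @export
naive_dispersal_condition <- function(config) {
  crosses <- enumerate_introduction_crosses(config)
  wsum <- function(neutral) {
    out <- qp_const(0)
    for (cr in crosses) {
      acc <- season_account(cr, config, neutral = neutral)
      out <- out + qp_const(cr$weight) * acc$dispersing_total
    }
    out
  }
  .threshold_from(wsum(FALSE), wsum(TRUE))
}

#' Expected fraction of first-brood offspring (or daughters) that are
#' altruists
#'
#' Weighted over the introduction crosses. With the per-pair sex-ratio
#' adjustment the first brood is female-biased wherever helpers exist, which
#' raises the altruist fraction: 5/9 of first-brood offspring under
#' haplodiploidy versus 1/3 under diploidy (1/4 without the adjustment).
#'
#' @param config a [genetic_config()].
#' @param of `"offspring"` (altruist females among all first-brood offspring)
#'   or `"daughters"` (among first-brood daughters only).
#' @return an exact rational fraction.
#' @export
altruist_daughter_fraction <- function(config,
                                       of = c("offspring", "daughters")) {
  of <- match.arg(of)
  crosses <- enumerate_introduction_crosses(config)
  out <- rational(0)
  for (cr in crosses) {
    acc <- season_account(cr, config)
    frac <- if (of == "offspring") acc$a * acc$f else acc$a
    out <- out + cr$weight * frac
  }
  out
}
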