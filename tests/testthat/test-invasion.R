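# expected table algebra frozen from the published season accounts; every
# comparison is exact symbolic equality of rational-coefficient polynomials

row_of <- function(acc, brood, sex, genotype) {
  for (rw in acc$rows) {
    if (rw$brood == brood && rw$sex == sex && rw$genotype == genotype) {
      return(rw)
    }
  }
  stop("row not found")
}

test_that("univoltine haplodiploid season accounts reproduce every table cell", {
  n <- qn(); b <- qb()
  cfg <- cfg_hap()
  acc1 <- season_account(list(mother = "A0A1", father = "A0"), cfg)

  # cross 1, first brood
  cases1 <- list(
    list("female", "A0A0", helping = qp_const(0), dispersing = n * r(1, 4),
         copies = qp_const(0)),
    list("female", "A0A1", helping = n * r(1, 4), dispersing = qp_const(0),
         copies = qp_const(0)),
    list("male", "A0", helping = qp_const(0), dispersing = n * r(1, 4),
         copies = qp_const(0)),
    list("male", "A1", helping = qp_const(0), dispersing = n * r(1, 4),
         copies = n * r(1, 4)))
  for (cs in cases1) {
    rw <- row_of(acc1, "first", cs[[1]], cs[[2]])
    expect_true(qp_equal(rw$helping, cs$helping))
    expect_true(qp_equal(rw$dispersing, cs$dispersing))
    expect_true(qp_equal(rw$copies, cs$copies))
  }
  # cross 1, second brood: every class n/4 + nb/16, carriers' copies equal it
  disp2 <- n * r(1, 4) + n * b * r(1, 16)
  for (g in list(c("female", "A0A0", 0), c("female", "A0A1", 1),
                 c("male", "A0", 0), c("male", "A1", 1))) {
    rw <- row_of(acc1, "second", g[1], g[2])
    expect_true(qp_equal(rw$dispersing, disp2))
    expect_true(qp_equal(rw$copies, if (g[3] == "1") disp2 else qp_const(0)))
  }
  expect_true(qp_equal(acc1$dispersing_total, n * r(7, 4) + n * b * r(1, 4)))
  expect_true(qp_equal(acc1$copies_total, n * r(3, 4) + n * b * r(1, 8)))

  # cross 2: all daughters help; only second-brood daughters carry copies
  acc2 <- season_account(list(mother = "A0A0", father = "A1"), cfg)
  expect_true(qp_equal(row_of(acc2, "first", "female", "A0A1")$helping,
                       n * r(1, 2)))
  expect_true(qp_equal(row_of(acc2, "first", "male", "A0")$dispersing,
                       n * r(1, 2)))
  expect_true(qp_equal(row_of(acc2, "second", "female", "A0A1")$copies,
                       n * r(1, 2) + n * b * r(1, 4)))
  expect_true(qp_equal(acc2$copies_total, n * r(1, 2) + n * b * r(1, 4)))
  expect_true(qp_equal(acc2$dispersing_total, n * r(3, 2) + n * b * r(1, 2)))
})

test_that("partially bivoltine accounts reproduce the second-generation cells", {
  n <- qn(); b <- qb(); n2 <- qn2()
  cfg <- cfg_hap("partially_bivoltine")
  acc1 <- season_account(list(mother = "A0A1", father = "A0"), cfg)
  expect_true(qp_equal(row_of(acc1, "first", "female", "A0A0")$gen2_dispersing,
                       n * n2 * r(1, 4)))
  expect_true(qp_equal(row_of(acc1, "first", "female", "A0A0")$gen2_copies,
                       qp_const(0)))
  expect_true(qp_equal(row_of(acc1, "first", "female", "A0A1")$gen2_dispersing,
                       qp_const(0)))
  expect_true(qp_equal(row_of(acc1, "first", "male", "A1")$gen2_dispersing,
                       n * n2 * r(1, 4)))
  expect_true(qp_equal(row_of(acc1, "first", "male", "A1")$gen2_copies,
                       n * n2 * r(1, 8)))
  expect_true(qp_equal(acc1$copies_total,
                       n * n2 * r(1, 8) + n * r(1, 2) + n * b * r(1, 8)))

  acc2 <- season_account(list(mother = "A0A0", father = "A1"), cfg)
  expect_true(qp_equal(row_of(acc2, "first", "male", "A0")$gen2_dispersing,
                       n * n2 * r(1, 2)))
  expect_true(qp_equal(acc2$copies_total, n * r(1, 2) + n * b * r(1, 4)))
})

test_that("weighted copy counts and neutral baselines match the published means", {
  n <- qn(); b <- qb(); n2 <- qn2()
  su <- weighted_invasion_summary(cfg_hap())
  expect_true(qp_equal(su$x, n * r(2, 3) + n * b * r(1, 6)))
  expect_true(qp_equal(su$x_neutral, n))
  sb <- weighted_invasion_summary(cfg_hap("partially_bivoltine"))
  expect_true(qp_equal(sb$x, n * n2 * r(1, 12) + n * r(1, 2) + n * b * r(1, 6)))
  expect_true(qp_equal(sb$x_neutral, n * n2 * r(1, 4) + n * r(1, 2)))
  # diploid equals haplodiploid cross 1
  sd <- weighted_invasion_summary(cfg_dip())
  expect_true(qp_equal(sd$x, n * r(3, 4) + n * b * r(1, 8)))
  expect_true(qp_equal(sd$x_neutral, n))
  # codominance: probabilistic expression of heterozygotes
  sc <- weighted_invasion_summary(cfg_hap(dominance = "codominant"))
  expect_true(qp_equal(sc$x, n * r(5, 6) + n * b * r(1, 12)))
  # sex-ratio-adjusted haplodiploid weighted count n(11+5b)/18
  sa <- weighted_invasion_summary(cfg_hap(adjusted = TRUE))
  expect_true(qp_equal(sa$x, n * r(11, 18) + n * b * r(5, 18)))
  expect_true(qp_equal(sa$x_neutral, n))
})

test_that("invasion thresholds are the exact published rationals", {
  expect_true(qp_value(invasion_threshold(cfg_hap())$b_star) == 2)
  expect_true(qp_value(invasion_threshold(cfg_dip())$b_star) == 2)
  expect_true(qp_value(invasion_threshold(
    cfg_hap(dominance = "codominant"))$b_star) == 2)
  expect_true(qp_value(invasion_threshold(
    cfg_dip(dominance = "codominant"))$b_star) == 2)
  # bivoltine: b > n2 for both ploidies and dominances
  for (cfg in list(cfg_hap("partially_bivoltine"),
                   cfg_dip("partially_bivoltine"),
                   cfg_hap("partially_bivoltine", "codominant"),
                   cfg_dip("partially_bivoltine", "codominant"))) {
    expect_true(threshold_n2_coefficient(invasion_threshold(cfg)) == 1)
  }
  # adjusted: haplodiploid thresholds are 30% below the diploid ones
  thr_hap <- qp_value(invasion_threshold(cfg_hap(adjusted = TRUE))$b_star)
  thr_dip <- qp_value(invasion_threshold(cfg_dip(adjusted = TRUE))$b_star)
  expect_true(thr_hap == rational(7, 5))
  expect_true(thr_dip == 2)
  expect_true(thr_hap / thr_dip == rational(7, 10))
  co_hap <- threshold_n2_coefficient(
    invasion_threshold(cfg_hap("partially_bivoltine", adjusted = TRUE)))
  co_dip <- threshold_n2_coefficient(
    invasion_threshold(cfg_dip("partially_bivoltine", adjusted = TRUE)))
  expect_true(co_hap == rational(7, 10))
  expect_true(co_dip == 1)
  expect_true(co_hap / co_dip == rational(7, 10))
})

test_that("R(b) curves match the reconstructed closed forms symbolically", {
  b <- qb(); n2 <- qn2()
  # univoltine unadjusted: R = 4(4+b) / (3(6+b))
  f1 <- ratio_R_formula(cfg_hap())
  expect_true(qp_equal(f1$numerator * ((qp_const(6) + b) * 3),
                       f1$denominator * ((qp_const(4) + b) * 4)))
  # bivoltine unadjusted: R = 2(n2+6+2b) / (3(n2+4+b))
  f2 <- ratio_R_formula(cfg_hap("partially_bivoltine"))
  expect_true(qp_equal(f2$numerator * ((n2 + qp_const(4) + b) * 3),
                       f2$denominator * ((n2 + qp_const(6) + b * 2) * 2)))
  # adjusted univoltine: R = (11+5b) / (12+3b)
  f3 <- ratio_R_formula(cfg_hap(adjusted = TRUE))
  expect_true(qp_equal(f3$numerator * (qp_const(12) + b * 3),
                       f3$denominator * (qp_const(11) + b * 5)))
})

test_that("R equals 1 at shared thresholds and rises to the printed asymptotes", {
  expect_true(ratio_R(cfg_hap(), b = 2) == 1)
  expect_true(ratio_R(cfg_hap(), b = rational(7, 2)) > 1)
  expect_true(ratio_R_asymptote(cfg_hap()) == rational(4, 3))
  expect_true(ratio_R_asymptote(cfg_hap("partially_bivoltine")) ==
                rational(4, 3))
  expect_true(ratio_R_asymptote(cfg_hap(adjusted = TRUE)) == rational(5, 3))
  # bivoltine at the shared threshold b = n2
  for (n2 in c(2, 4, 10)) {
    expect_true(ratio_R(cfg_hap("partially_bivoltine"), b = n2, n2 = n2) == 1)
  }
  # bivoltine with n2 = 2 collapses to the univoltine curve
  for (b in c(1, 2, 3, 5, 10)) {
    expect_true(ratio_R(cfg_hap("partially_bivoltine"), b = b, n2 = 2) ==
                  ratio_R(cfg_hap(), b = b))
  }
  # R increases with n2 at fixed b/n2
  rs <- sapply(c(2, 4, 8, 16), function(n2) {
    as.numeric(ratio_R(cfg_hap("partially_bivoltine"), b = 2 * n2, n2 = n2))
  })
  expect_true(all(diff(rs) > 0))
})

test_that("copy counts are monotone in b and strictly costly at b = 0", {
  for (cfg in all_configs()) {
    su <- weighted_invasion_summary(cfg)
    n2v <- if (cfg$lifecycle == "partially_bivoltine") 3 else NULL
    at <- function(bv) qp_value(qp_eval(su$x, n = 1, b = bv, n2 = n2v))
    xs <- c(at(0), at(1), at(2), at(5))
    expect_true(all(diff(as.numeric(c(xs[1], xs[2], xs[3], xs[4]))) > 0))
    # helpers forgo dispersal: at b = 0 expression is strictly deleterious
    xn0 <- qp_value(qp_eval(su$x_neutral, n = 1, b = 0, n2 = n2v))
    expect_true(at(0) < xn0)
    # relative change is exactly 1 at the threshold
    thr <- su$threshold
    bstar <- qp_value(qp_eval(thr$b_star, n2 = n2v))
    expect_true(at(bstar) ==
                  qp_value(qp_eval(su$x_neutral, n = 1, b = bstar, n2 = n2v)))
  }
})

test_that("naive offspring counting understates the univoltine threshold", {
  expect_true(qp_value(naive_dispersal_condition(cfg_hap())$b_star) == 1)
  expect_true(qp_value(naive_dispersal_condition(cfg_dip())$b_star) == 1)
  # at b = 1 the carrier pair's naive output equals the wild-type pair's
  cfg <- cfg_hap()
  crosses <- enumerate_introduction_crosses(cfg)
  tot <- qp_const(0)
  for (cr in crosses) {
    acc <- season_account(cr, cfg)
    tot <- tot + qp_const(cr$weight) * acc$dispersing_total
  }
  expect_true(qp_value(qp_eval(tot, n = 1, b = 1)) == 2)  # wild pair: 2n
})

test_that("adjusted-model altruist fractions are 5/9, 1/3 and 1/4", {
  expect_true(altruist_daughter_fraction(cfg_hap(adjusted = TRUE)) ==
                rational(5, 9))
  expect_true(altruist_daughter_fraction(cfg_dip(adjusted = TRUE)) ==
                rational(1, 3))
  expect_true(altruist_daughter_fraction(cfg_dip()) == rational(1, 4))
  expect_true(altruist_daughter_fraction(cfg_hap(adjusted = TRUE)) /
                altruist_daughter_fraction(cfg_dip(adjusted = TRUE)) ==
                rational(5, 3))
})
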