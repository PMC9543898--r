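test_that("pair brood profiles follow penetrance and the per-pair adjustment", {
  cfg <- cfg_hap(adjusted = TRUE)
  pars <- lifecycle_params(n = 4, b = 3)
  # carrier-father pair: all daughters help, all-female first brood
  pf <- pair_brood_profile("A0A0", "A1", cfg, pars)
  expect_equal(pf$a, 1)
  expect_equal(pf$f, 1)
  expect_equal(sum(pf$disp_f1) + sum(pf$disp_m1), 0)
  expect_equal(sum(pf$brood2_f) + sum(pf$brood2_m), 4 * (1 + 3))
  # wild-type pair: no helpers, two even broods of n
  pw <- pair_brood_profile("A0A0", "A0", cfg, pars)
  expect_equal(pw$a, 0)
  expect_equal(pw$f, 0.5)
  expect_equal(pw$helpers, 0)
  expect_equal(sum(pw$brood2_f) + sum(pw$brood2_m), 4)
  # heterozygous-mother pair: a = 1/2, f = 2/3, n/3 helpers,
  # dispersing first brood n/3 A0A0 females + n/3 males half-carrier
  ph <- pair_brood_profile("A0A1", "A0", cfg, pars)
  expect_equal(ph$a, 0.5)
  expect_equal(ph$f, 2 / 3)
  expect_equal(ph$helpers, 4 / 3)
  expect_equal(unname(ph$disp_f1["A0A0"]), 4 / 3)
  expect_equal(unname(ph$disp_f1["A0A1"]), 0)
  expect_equal(sum(ph$disp_m1), 4 / 3)
  expect_equal(unname(ph$disp_m1["A1"]), 2 / 3)
})

test_that("monomorphic states are exact fixed points and frequencies stay normalized", {
  for (cfg in list(cfg_hap(), cfg_dip(adjusted = TRUE),
                   cfg_hap("partially_bivoltine", adjusted = TRUE))) {
    pars <- lifecycle_params(n = 4, b = 3,
                             n2 = if (cfg$lifecycle == "partially_bivoltine")
                               4 else NULL)
    for (p0 in c(0, 1)) {
      st <- pair_state_init(cfg, p0)
      st1 <- season_step(st, cfg, pars)
      expect_equal(as.numeric(st1), as.numeric(st), tolerance = 1e-14)
      expect_equal(allele_frequency(st1, cfg), p0)
    }
    # conservation along a polymorphic trajectory
    st <- pair_state_init(cfg, 0.2)
    for (i in 1:5) {
      st <- season_step(st, cfg, pars)
      expect_lt(abs(sum(st) - 1), 1e-12)
    }
  }
})

test_that("rare-allele growth equals x/x_neutral in every scenario", {
  for (cfg in all_configs()) {
    n2v <- if (cfg$lifecycle == "partially_bivoltine") 4 else NULL
    pars <- lifecycle_params(n = 4, b = 3, n2 = n2v)
    su <- weighted_invasion_summary(cfg)
    expected <- qp_eval_num(su$x, n = 1, b = 3,
                            n2 = if (is.null(n2v)) NA_real_ else n2v) /
      qp_eval_num(su$x_neutral, n = 1, b = 3,
                  n2 = if (is.null(n2v)) NA_real_ else n2v)
    g <- rare_allele_growth(cfg, pars, p0 = 1e-8)
    expect_lt(abs(g - expected), 1e-8)
  }
})

test_that("one-step growth from p0 = 1e-6 reproduces the adjusted rate to 4+ decimals", {
  g <- rare_allele_growth(cfg_hap(adjusted = TRUE), lifecycle_params(4, 3),
                          p0 = 1e-6, extrapolate = FALSE)
  expect_equal(g, (11 + 5 * 3) / 18, tolerance = 1e-5)
})

test_that("bisection thresholds from the recursion match the exact accounting", {
  expect_equal(empirical_threshold(cfg_hap(adjusted = TRUE),
                                   lifecycle_params(4, 1),
                                   bracket = c(0.5, 5)), 1.4,
               tolerance = 1e-6)
  expect_equal(empirical_threshold(cfg_dip(adjusted = TRUE),
                                   lifecycle_params(4, 1),
                                   bracket = c(0.5, 5)), 2,
               tolerance = 1e-6)
  expect_equal(empirical_threshold(
    cfg_hap("partially_bivoltine", adjusted = TRUE),
    lifecycle_params(4, 1, n2 = 4), bracket = c(0.5, 10)), 2.8,
    tolerance = 1e-6)
  expect_error(empirical_threshold(cfg_hap(), lifecycle_params(4, 1),
                                   bracket = c(3, 5)), "bracket")
})

test_that("trajectories fix above threshold, are lost below, and rank by ploidy", {
  # b = 1.5 separates the adjusted thresholds: 1.4 (haplodiploid) < 2 (diploid)
  th <- run_timecourse(cfg_hap(adjusted = TRUE), lifecycle_params(4, 1.5),
                       p0 = 1e-3, max_generations = 4000)
  td <- run_timecourse(cfg_dip(adjusted = TRUE), lifecycle_params(4, 1.5),
                       p0 = 1e-3, max_generations = 4000)
  expect_gt(max(th$p), 0.99)
  expect_identical(attr(td, "termination"), "lost")
  # at equal b the haplodiploid trajectory reaches high frequency sooner
  gen99 <- function(cfg) {
    tc <- run_timecourse(cfg, lifecycle_params(4, 3), p0 = 1e-3,
                         max_generations = 4000)
    min(tc$generation[tc$p > 0.99])
  }
  expect_lt(gen99(cfg_hap(adjusted = TRUE)), gen99(cfg_dip(adjusted = TRUE)))
})

test_that("dispersing sex ratio is even when adjusted, male-biased otherwise", {
  ta <- run_timecourse(cfg_hap(adjusted = TRUE), lifecycle_params(4, 3),
                       p0 = 1e-3, max_generations = 60)
  expect_true(all(abs(ta$disp_female_fraction[-1] - 0.5) < 1e-12))
  tu <- run_timecourse(cfg_hap(), lifecycle_params(4, 3), p0 = 1e-3,
                       max_generations = 200)
  frac <- tu$disp_female_fraction[-1]
  expect_lt(frac[length(frac)], 0.45)       # male-biased at high p
  expect_lt(frac[length(frac)], frac[1])    # and increasingly so as p rises
})
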