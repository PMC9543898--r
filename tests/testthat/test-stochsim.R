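test_that("simulated one-season copy counts match the exact accounting", {
  # oracle-equivalence sweep over randomized scenarios: for each setting the
  # cross-weighted replicate mean of A1 copies must match x within 4 SE
  set.seed(20260925)
  reps <- 20000
  for (trial in 1:20) {
    cfg <- genetic_config(
      sample(c("haplodiploid", "diploid"), 1),
      sample(c("dominant", "codominant"), 1),
      sample(c("univoltine", "partially_bivoltine"), 1),
      sample(c(TRUE, FALSE), 1))
    n2v <- if (cfg$lifecycle == "partially_bivoltine") sample(2:5, 1) else NULL
    pars <- lifecycle_params(n = sample(3:6, 1), b = sample(0:5, 1), n2 = n2v)
    su <- weighted_invasion_summary(cfg, pars)
    crosses <- enumerate_introduction_crosses(cfg)
    est <- 0; var_est <- 0
    for (cr in crosses) {
      sim <- simulate_pair_season(cr$mother, cr$father, cfg, pars,
                                  replicates = reps)
      w <- as.numeric(cr$weight)
      est <- est + w * mean(sim$a1_copies)
      var_est <- var_est + w^2 * stats::var(sim$a1_copies) / reps
    }
    expect_lt(abs(est - su$evaluated$x), 4 * sqrt(var_est) + 1e-9)
  }
})

test_that("monomorphic populations stay monomorphic and seeds reproduce runs", {
  cfg <- cfg_hap()
  pars <- lifecycle_params(4, 3)
  types <- pair_types(cfg)
  init <- structure(integer(nrow(types)), names = types$key)
  init["A0A0 x A0"] <- 50L
  out <- simulate_population(cfg, pars, N = 50, generations = 5, init = init,
                             seed = 1)
  expect_true(all(out$trajectory$p == 0))
  r1 <- simulate_population(cfg, pars, N = 100, generations = 10, seed = 33)
  r2 <- simulate_population(cfg, pars, N = 100, generations = 10, seed = 33)
  expect_identical(r1$trajectory, r2$trajectory)
})

test_that("trajectory datasets are deterministic and track the recursion mean", {
  cfg <- cfg_hap(adjusted = TRUE)
  pars <- lifecycle_params(4, 3)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  d1 <- generate_trajectory_dataset(cfg, pars, N = 300, generations = 8,
                                    replicates = 4, seed = 9, out_path = f1)
  generate_trajectory_dataset(cfg, pars, N = 300, generations = 8,
                              replicates = 4, seed = 9, out_path = f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_setequal(unique(d1$replicate), 1:4)
  # header embeds configuration and seed
  hdr <- readLines(f1, n = 3)
  expect_true(any(grepl("seed=9", hdr)))

  # large-N mean trajectory follows the deterministic recursion
  N <- 10000
  det <- run_timecourse(cfg, pars, p0 = 0.02, max_generations = 12)
  types <- pair_types(cfg)
  init <- as.integer(round(pair_state_init(cfg, 0.02) * N))
  init[1] <- init[1] + (N - sum(init))
  names(init) <- types$key
  set.seed(101)
  mat <- vapply(1:100, function(r) {
    simulate_population(cfg, pars, N, 12, init = init)$trajectory$p
  }, numeric(13))
  expect_lt(max(abs(rowMeans(mat) - det$p[1:13])), 0.01)

  # per-generation dispersing sex ratio stays near 1:1 under adjustment
  frac <- d1$disp_female_fraction[!is.na(d1$disp_female_fraction)]
  expect_lt(max(abs(frac - 0.5)), 0.05)
})

test_that("stochastic fixation frequencies agree with theory", {
  cfg <- cfg_hap()
  # neutral allele: fixation probability equals the initial copy frequency
  outN <- estimate_fixation_probability(cfg_dip(), lifecycle_params(4, 0),
                                        N = 12, replicates = 2500, seed = 7,
                                        neutral = TRUE)
  expect_lt(abs(outN$fixed_fraction - 1 / 48),
            4 * sqrt((1 / 48) * (47 / 48) / 2500))

  # b = 0: helping is strictly deleterious, fixation below neutral
  out0 <- estimate_fixation_probability(cfg, lifecycle_params(4, 0), N = 12,
                                        replicates = 2500, seed = 8)
  expect_lt(out0$fixed_fraction, 1 / 36)   # neutral value for haplodiploid
})
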