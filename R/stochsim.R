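#' Finite-population lifecycle simulator
#'
#' A stochastic, finite-population counterpart of the deterministic recursion
#' and the invasion accounting: `N` foundress pairs per spring, monogamous
#' mating, conditional helping by first-brood daughters, optional per-pair
#' sex-ratio adjustment, diapause and Wright-Fisher-style regulation (next
#' spring's `N` pairs are resampled with replacement from the diapausing
#' mated females). It serves both as the brute-force oracle validating the
#' analytic modules and as the generator of synthetic allele-trajectory and
#' fixation-outcome datasets.
#'
#' Broods are sampled at the genotype level: offspring counts are
#' binomial/multinomial with the exact Mendelian probabilities, fractional
#' expected sizes are realized by stochastic rounding (floor plus a Bernoulli
#' remainder), so all expectations match the deterministic model exactly.
#'
#' @name stochastic_population_sim
NULL

.stoch_round <- function(x) {
  fl <- floor(x)
  fl + stats::rbinom(length(x), 1L, x - fl)
}

# one multinomial draw; returns named integer vector, safe for size 0
.rmn <- function(size, probs) {
  out <- structure(integer(length(probs)), names = names(probs))
  if (size > 0) {
    out[] <- as.integer(stats::rmultinom(1L, size, probs))
  }
  out
}

# row-wise multinomials for a vector of sizes (binomial splitting)
.rmn_rows <- function(sizes, probs) {
  R <- length(sizes)
  k <- length(probs)
  out <- matrix(0L, R, k, dimnames = list(NULL, names(probs)))
  rem <- sizes
  pleft <- 1
  for (j in seq_len(k - 1L)) {
    pj <- if (pleft > 0) min(probs[j] / pleft, 1) else 0
    out[, j] <- stats::rbinom(R, rem, pj)
    rem <- rem - out[, j]
    pleft <- pleft - probs[j]
  }
  out[, k] <- rem
  out
}

# advance integer pair-type counts by one season; returns counts (attrs:
# helpers, disp) or NULL when no mated female survives (extinction);
# neutral = TRUE disables expression (no helping, no sex-ratio adjustment)
.sim_generation <- function(counts, config, params, N, mu = 0,
                            neutral = FALSE) {
  types <- pair_types(config)
  fg <- female_genotypes()
  mg <- male_genotypes(config$ploidy)
  zf <- structure(integer(length(fg)), names = fg)
  zm <- structure(integer(length(mg)), names = mg)
  F1 <- zf; M1 <- zm; F2 <- zf; M2 <- zm
  helpers_total <- 0L
  n <- params$n; b <- params$b

  for (i in seq_len(nrow(types))) {
    k <- counts[i]
    if (k == 0) next
    probs <- .offspring_probs_num(types$mother[i], types$father[i],
                                  config$ploidy, mu)
    pen <- if (neutral) c(A0A0 = 0, A0A1 = 0, A1A1 = 0)
           else .penetrance_num(config$dominance)
    a <- sum(probs$female * pen)
    f <- if (config$sex_adjusted && !neutral) 1 / (2 - a) else 0.5
    # first brood: per-pair stochastic rounding of n, aggregated over k pairs
    B1 <- k * floor(n) + stats::rbinom(1L, k, n - floor(n))
    femB1 <- stats::rbinom(1L, B1, f)
    femG <- .rmn(femB1, probs$female)
    malG <- .rmn(B1 - femB1, probs$male)
    helpG <- stats::rbinom(length(fg), femG, pen)
    names(helpG) <- fg
    H <- sum(helpG)
    helpers_total <- helpers_total + H
    F1 <- F1 + femG - helpG
    M1 <- M1 + malG
    s2 <- k * n + b * H
    B2 <- .stoch_round(s2)
    femB2 <- stats::rbinom(1L, B2, 0.5)
    F2 <- F2 + .rmn(femB2, probs$female)
    M2 <- M2 + .rmn(B2 - femB2, probs$male)
  }

  if (config$lifecycle == "univoltine") {
    pools <- list(list(F = F1, M = M1), list(F = F2, M = M2))
    disp <- c(female = sum(F1) + sum(F2), male = sum(M1) + sum(M2))
  } else {
    gen2F <- zf; gen2M <- zm
    if (sum(F1) > 0 && sum(M1) > 0) {
      n2 <- params$n2
      for (g in fg) {
        if (F1[[g]] == 0) next
        mates <- .rmn(F1[[g]], M1 / sum(M1))
        for (h in mg) {
          kk <- mates[[h]]
          if (kk == 0) next
          sz <- kk * floor(n2) + stats::rbinom(1L, kk, n2 - floor(n2))
          op <- .offspring_probs_num(g, h, config$ploidy, mu)
          femsz <- stats::rbinom(1L, sz, 0.5)
          gen2F <- gen2F + .rmn(femsz, op$female)
          gen2M <- gen2M + .rmn(sz - femsz, op$male)
        }
      }
    }
    AF <- gen2F + F2
    AM <- gen2M + M2
    pools <- list(list(F = AF, M = AM))
    disp <- c(female = sum(F1) + sum(AF), male = sum(M1) + sum(AM))
  }

  # mated diapausing females; pools with no males leave their females unmated
  pools <- Filter(function(p) sum(p$F) > 0 && sum(p$M) > 0, pools)
  W <- sum(vapply(pools, function(p) sum(p$F), 0))
  if (W == 0) return(NULL)
  pmat <- matrix(0, length(fg), length(mg), dimnames = list(fg, mg))
  for (p in pools) {
    pmat <- pmat + outer(p$F / W, p$M / sum(p$M))
  }
  pv <- numeric(nrow(types))
  for (i in seq_len(nrow(types))) {
    pv[i] <- pmat[types$mother[i], types$father[i]]
  }
  nxt <- as.integer(stats::rmultinom(1L, N, pv))
  names(nxt) <- types$key
  attr(nxt, "helpers") <- helpers_total
  attr(nxt, "disp") <- disp
  nxt
}

.counts_p <- function(counts, config) {
  types <- pair_types(config)
  sum(counts * attr(types, "copies")) / (attr(types, "slots") * sum(counts))
}

.introduction_counts <- function(config, N) {
  types <- pair_types(config)
  counts <- structure(integer(nrow(types)), names = types$key)
  wild <- paste("A0A0", if (config$ploidy == "haplodiploid") "A0" else "A0A0",
                sep = " x ")
  crosses <- enumerate_introduction_crosses(config)
  w <- vapply(crosses, function(cr) as.numeric(cr$weight), 0)
  pick <- sample.int(length(crosses), 1L, prob = w)
  ck <- paste(crosses[[pick]]$mother, crosses[[pick]]$father, sep = " x ")
  counts[wild] <- N - 1L
  counts[ck] <- counts[ck] + 1L
  counts
}

#' Simulate a finite population over breeding seasons
#'
#' @param config a [genetic_config()].
#' @param params a [lifecycle_params()].
#' @param N number of foundress pairs maintained each spring.
#' @param generations number of seasons to simulate.
#' @param init `"introduction"` (N-1 wild-type pairs plus one carrier pair,
#'   carrier sex drawn with the introduction-cross weights) or a named
#'   integer vector of pair-type counts.
#' @param mu one-way `A0 -> A1` mutation probability per transmitted copy.
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @return a list with `trajectory` (data.frame: generation, p, helpers,
#'   disp_female_fraction), `final_counts`, and `outcome` (`"fixed"`,
#'   `"lost"`, `"segregating"` or `"extinct"`).
#' @export
simulate_population <- function(config, params, N, generations,
                                init = "introduction", mu = 0, seed = NULL) {
  .validate_params(config, params)
  stopifnot(N >= 2)
  if (!is.null(seed)) set.seed(seed)
  counts <- if (is.character(init)) .introduction_counts(config, N)
            else { stopifnot(sum(init) == N); init }
  p <- .counts_p(counts, config)
  rows <- list(data.frame(generation = 0L, p = p, helpers = NA_integer_,
                          disp_female_fraction = NA_real_))
  outcome <- "segregating"
  for (gen in seq_len(generations)) {
    nxt <- .sim_generation(counts, config, params, N, mu)
    if (is.null(nxt)) { outcome <- "extinct"; break }
    counts <- nxt
    p <- .counts_p(counts, config)
    disp <- attr(nxt, "disp")
    rows[[length(rows) + 1L]] <- data.frame(
      generation = gen, p = p, helpers = attr(nxt, "helpers"),
      disp_female_fraction = disp[["female"]] / sum(disp))
    if (mu == 0 && p == 0) { outcome <- "lost"; break }
    if (mu == 0 && p == 1) { outcome <- "fixed"; break }
  }
  if (outcome == "segregating" && mu == 0) {
    if (p == 0) outcome <- "lost"
    if (p == 1) outcome <- "fixed"
  }
  list(trajectory = do.call(rbind, rows), final_counts = counts,
       outcome = outcome)
}

#' One-season brood outcomes of a single focal pair
#'
#' Vectorized over replicates: simulates one focal mated pair's season
#' (broods, conditional helping, sex-ratio adjustment; in the bivoltine
#' lifecycle its dispersing first-brood offspring breed with wild-type
#' partners, the single-copy invasion setting) and reports the realized
#' helper count, dispersing offspring and `A1` copies among dispersers.
#' The replicate mean of `a1_copies` is the Monte-Carlo estimate of the
#' season-account copy total for that cross.
#'
#' @param mother,father focal pair genotypes.
#' @param config a [genetic_config()].
#' @param params a [lifecycle_params()].
#' @param replicates number of independent season replicates.
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @param neutral logical; disable expression of the allele.
#' @return a data.frame with one row per replicate: `helpers`, `dispersing`,
#'   `a1_copies`.
#' @examples
#' cfg <- genetic_config("haplodiploid", "dominant", "univoltine")
#' sim <- simulate_pair_season("A0A1", "A0", cfg,
#'                             lifecycle_params(n = 4, b = 4),
#'                             replicates = 1000, seed = 1)
#' mean(sim$a1_copies)   # ~ 3n/4 + nb/8 = 5
#' @export
simulate_pair_season <- function(mother, father, config, params,
                                 replicates, seed = NULL, neutral = FALSE) {
  .validate_params(config, params)
  if (!is.null(seed)) set.seed(seed)
  R <- as.integer(replicates)
  stopifnot(R >= 1L)
  fg <- female_genotypes()
  mg <- male_genotypes(config$ploidy)
  probs <- .offspring_probs_num(mother, father, config$ploidy)
  pen <- if (neutral) c(A0A0 = 0, A0A1 = 0, A1A1 = 0)
         else .penetrance_num(config$dominance)
  a <- sum(probs$female * pen)
  f <- if (config$sex_adjusted && !neutral) 1 / (2 - a) else 0.5
  n <- params$n; b <- params$b
  a1f <- count_a1(fg); a1m <- count_a1(mg)

  B1 <- .stoch_round(rep(n, R))
  femB1 <- stats::rbinom(R, B1, f)
  femG <- .rmn_rows(femB1, probs$female)
  malG <- .rmn_rows(B1 - femB1, probs$male)
  helpG <- femG
  for (j in seq_along(fg)) helpG[, j] <- stats::rbinom(R, femG[, j], pen[j])
  H <- rowSums(helpG)
  dispF1 <- femG - helpG

  B2 <- .stoch_round(n + b * H)
  femB2 <- stats::rbinom(R, B2, 0.5)
  femG2 <- .rmn_rows(femB2, probs$female)
  malG2 <- .rmn_rows(B2 - femB2, probs$male)
  copies2 <- as.vector(femG2 %*% a1f + malG2 %*% a1m)

  if (config$lifecycle == "univoltine") {
    copies1 <- as.vector(dispF1 %*% a1f + malG %*% a1m)
    data.frame(helpers = H,
               dispersing = rowSums(dispF1) + rowSums(malG) + B2,
               a1_copies = copies1 + copies2)
  } else {
    # each brood-1 disperser breeds with a wild-type partner; with one
    # wild-type parent every second-generation offspring carries 0 or 1
    # copies, so per-class copy totals are exactly binomial
    wild_male <- if (config$ploidy == "haplodiploid") "A0" else "A0A0"
    rate_of <- function(sex, g) {
      op <- if (sex == "female") {
        .offspring_probs_num(g, wild_male, config$ploidy)
      } else {
        .offspring_probs_num("A0A0", g, config$ploidy)
      }
      0.5 * sum(op$female * a1f) + 0.5 * sum(op$male * a1m)
    }
    gen2_total <- integer(R)
    gen2_copies <- integer(R)
    n2 <- params$n2
    for (j in seq_along(fg)) {
      sz <- .stoch_round(dispF1[, j] * n2)
      gen2_total <- gen2_total + sz
      gen2_copies <- gen2_copies + stats::rbinom(R, sz, rate_of("female", fg[j]))
    }
    for (j in seq_along(mg)) {
      sz <- .stoch_round(malG[, j] * n2)
      gen2_total <- gen2_total + sz
      gen2_copies <- gen2_copies + stats::rbinom(R, sz, rate_of("male", mg[j]))
    }
    data.frame(helpers = H,
               dispersing = gen2_total + B2,
               a1_copies = gen2_copies + copies2)
  }
}

#' Fixation probability by brute-force replication
#'
#' Introduces a single `A1` copy (carrier pair drawn with the
#' introduction-cross weights), runs the population to absorption, and
#' reports the fraction of replicates that fixed with a Clopper-Pearson 95%
#' binomial confidence interval.
#'
#' @param config a [genetic_config()].
#' @param params a [lifecycle_params()].
#' @param N number of foundress pairs.
#' @param replicates number of independent replicates.
#' @param seed integer seed.
#' @param max_generations per-replicate cap; replicates still segregating at
#'   the cap are reported as such and excluded from the fixed fraction's
#'   numerator.
#' @param neutral logical; simulate the allele with expression disabled.
#' @return an object of class `"sim_outcome"`: counts per outcome, the
#'   fixation fraction with 95% CI, and the per-replicate generations to
#'   absorption.
#' @export
estimate_fixation_probability <- function(config, params, N, replicates,
                                          seed = NULL,
                                          max_generations = 10000,
                                          neutral = FALSE) {
  .validate_params(config, params)
  if (!is.null(seed)) set.seed(seed)
  outcomes <- character(replicates)
  gens <- integer(replicates)
  for (r in seq_len(replicates)) {
    counts <- .introduction_counts(config, N)
    out <- "segregating"
    g <- 0L
    repeat {
      g <- g + 1L
      nxt <- .sim_generation(counts, config, params, N, neutral = neutral)
      if (is.null(nxt)) { out <- "extinct"; break }
      counts <- nxt
      p <- .counts_p(counts, config)
      if (p == 0) { out <- "lost"; break }
      if (p == 1) { out <- "fixed"; break }
      if (g >= max_generations) break
    }
    outcomes[r] <- out
    gens[r] <- g
  }
  nfix <- sum(outcomes == "fixed")
  ci <- stats::binom.test(nfix, replicates)$conf.int
  structure(list(table = table(factor(outcomes,
                                      levels = c("fixed", "lost",
                                                 "segregating", "extinct"))),
                 fixed_fraction = nfix / replicates,
                 conf_int = as.numeric(ci),
                 generations = gens, N = N, replicates = replicates),
            class = "sim_outcome")
}

#' @export
print.sim_outcome <- function(x, ...) {
  cat("Stochastic fixation experiment: N =", x$N, "pairs,",
      x$replicates, "replicates\n")
  print(x$table)
  cat(sprintf("fixed fraction = %.4f  (95%% CI %.4f - %.4f)\n",
              x$fixed_fraction, x$conf_int[1], x$conf_int[2]))
  invisible(x)
}

#' Write a tidy allele-trajectory dataset
#'
#' Runs `replicates` independent population simulations and writes one tidy
#' long-format CSV (`replicate`, `generation`, `p`, `helpers`,
#' `disp_female_fraction`), preceded by `#`-prefixed header lines embedding
#' the full configuration and seed. Output is byte-identical for a given
#' seed.
#'
#' @inheritParams simulate_population
#' @param replicates number of replicate trajectories.
#' @param out_path file path for the CSV.
#' @return the combined data.frame, invisibly.
#' @export
generate_trajectory_dataset <- function(config, params, N, generations,
                                        replicates, seed, out_path,
                                        init = "introduction", mu = 0) {
  .validate_params(config, params)
  set.seed(seed)
  runs <- lapply(seq_len(replicates), function(r) {
    sim <- simulate_population(config, params, N, generations, init = init,
                               mu = mu, seed = NULL)
    cbind(replicate = r, sim$trajectory)
  })
  out <- do.call(rbind, runs)
  header <- c(
    sprintf("# haplodyn trajectory dataset"),
    sprintf("# ploidy=%s dominance=%s lifecycle=%s sex_adjusted=%s",
            config$ploidy, config$dominance, config$lifecycle,
            config$sex_adjusted),
    sprintf("# n=%g b=%g n2=%s N=%d generations=%d replicates=%d mu=%g seed=%d",
            params$n, params$b,
            if (is.null(params$n2)) "NA" else format(params$n2),
            as.integer(N), as.integer(generations), as.integer(replicates),
            mu, as.integer(seed)))
  con <- file(out_path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(out, con, row.names = FALSE)
  invisible(out)
}
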