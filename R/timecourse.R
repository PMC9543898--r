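#' Mated-pair genotype state space
#'
#' The deterministic recursion tracks frequencies of mated-pair types
#' (female genotype by male genotype): 6 types under haplodiploidy, 9 under
#' diploidy. Pairs, not gametes, are the natural state because dispersing
#' individuals carry genotype biases (carrier daughters preferentially stay
#' as helpers), so gamete fusions producing dispersers are not random even
#' though mating is.
#'
#' @param config a [genetic_config()].
#' @return a data.frame with columns `mother`, `father`, `key`.
#' @export
pair_types <- function(config) {
  stopifnot(inherits(config, "genetic_config"))
  .pair_types_cached(config$ploidy)
}

.cache <- new.env(parent = emptyenv())

.pair_types_cached <- function(ploidy) {
  key <- paste0("types_", ploidy)
  if (is.null(.cache[[key]])) {
    g <- expand.grid(mother = female_genotypes(),
                     father = male_genotypes(ploidy),
                     stringsAsFactors = FALSE)
    g$key <- paste(g$mother, g$father, sep = " x ")
    attr(g, "copies") <- count_a1(g$mother) + count_a1(g$father)
    attr(g, "slots") <- 2 + if (ploidy == "haplodiploid") 1 else 2
    .cache[[key]] <- g
  }
  .cache[[key]]
}

# numeric transmission distributions; mu is one-way A0 -> A1 per transmitted
# copy; the mutation-free distributions are cached
.offspring_probs_num <- function(mother, father, ploidy, mu = 0) {
  if (mu == 0) {
    key <- paste("probs", mother, father, ploidy)
    if (!is.null(.cache[[key]])) return(.cache[[key]])
    out <- .offspring_probs_calc(mother, father, ploidy, 0)
    .cache[[key]] <- out
    return(out)
  }
  .offspring_probs_calc(mother, father, ploidy, mu)
}

.offspring_probs_calc <- function(mother, father, ploidy, mu = 0) {
  pm <- count_a1(mother) / 2
  pm <- pm + (1 - pm) * mu
  fg <- female_genotypes()
  if (ploidy == "haplodiploid") {
    pf <- count_a1(father)
    pf <- pf + (1 - pf) * mu
    fem <- c((1 - pm) * (1 - pf), pm * (1 - pf) + (1 - pm) * pf, pm * pf)
    mal <- c(1 - pm, pm)
    names(fem) <- fg
    names(mal) <- male_genotypes("haplodiploid")
  } else {
    pf <- count_a1(father) / 2
    pf <- pf + (1 - pf) * mu
    fem <- c((1 - pm) * (1 - pf), pm * (1 - pf) + (1 - pm) * pf, pm * pf)
    names(fem) <- fg
    mal <- fem
  }
  list(female = fem, male = mal)
}

.penetrance_num <- function(dominance) {
  p <- c(A0A0 = 0, A0A1 = if (dominance == "dominant") 1 else 0.5, A1A1 = 1)
  p
}

#' Per-pair brood profile
#'
#' The expected composition of a mated pair's season output in the
#' infinite-population (deterministic) limit: helper fraction `a` among
#' first-brood daughters, adjusted female fraction `f`, helper count,
#' dispersing first-brood females and males by genotype, and the second
#' brood (size `n + b * helpers`, even sex ratio, Mendelian genotypes).
#'
#' @param mother,father pair genotypes.
#' @param config a [genetic_config()].
#' @param params a [lifecycle_params()].
#' @param neutral logical; disable expression (baseline pair).
#' @param mu one-way `A0 -> A1` mutation probability per transmitted copy.
#' @return a list with elements `a`, `f`, `helpers`, `disp_f1`, `disp_m1`,
#'   `brood2_f`, `brood2_m` (named numeric vectors of expected counts).
#' @export
pair_brood_profile <- function(mother, father, config, params,
                               neutral = FALSE, mu = 0) {
  .validate_params(config, params)
  probs <- .offspring_probs_num(mother, father, config$ploidy, mu)
  pen <- if (neutral) c(A0A0 = 0, A0A1 = 0, A1A1 = 0)
         else .penetrance_num(config$dominance)
  a <- sum(probs$female * pen)
  f <- if (config$sex_adjusted && !neutral) 1 / (2 - a) else 0.5
  n <- params$n
  helpers_g <- n * f * probs$female * pen
  H <- sum(helpers_g)
  disp_f1 <- n * f * probs$female - helpers_g
  disp_m1 <- n * (1 - f) * probs$male
  s2 <- n + params$b * H
  list(a = a, f = f, helpers = H,
       disp_f1 = disp_f1, disp_m1 = disp_m1,
       brood2_f = s2 / 2 * probs$female, brood2_m = s2 / 2 * probs$male)
}

#' One deterministic breeding season
#'
#' Advances the mated-pair frequency vector by one season. All pairs produce
#' their broods per [pair_brood_profile()]; dispersers are aggregated into
#' mating pools and next-season foundress pairs are formed by random mating
#' within each pool (product of the pool's female counts and male genotype
#' frequencies), then renormalized. Pools follow the lifecycle timing:
#' univoltine first-brood dispersers mate within the first-brood pool and
#' second-brood dispersers within the second-brood pool; in the partially
#' bivoltine lifecycle, first-brood dispersers mate and breed, and their
#' second-generation offspring join the foundress' second brood in a single
#' panmictic autumn pool.
#'
#' @param state named numeric vector of pair-type frequencies (keys from
#'   [pair_types()]), summing to 1.
#' @param config a [genetic_config()].
#' @param params a [lifecycle_params()].
#' @param mu one-way mutation probability per transmitted copy.
#' @return the next state vector, with attributes `mean_a`, `mean_f` and
#'   `disp` (dispersing female/male totals per current-generation pair).
#' @export
season_step <- function(state, config, params, mu = 0) {
  .validate_params(config, params)
  types <- pair_types(config)
  stopifnot(length(state) == nrow(types))
  if (is.null(names(state))) names(state) <- types$key
  state <- state[types$key]
  fg <- female_genotypes()
  mg <- male_genotypes(config$ploidy)

  profiles <- lapply(seq_len(nrow(types)), function(i) {
    pair_brood_profile(types$mother[i], types$father[i], config, params,
                       mu = mu)
  })

  zf <- structure(numeric(length(fg)), names = fg)
  zm <- structure(numeric(length(mg)), names = mg)
  acc <- function(field, template) {
    out <- template
    for (i in seq_along(profiles)) {
      out <- out + state[i] * profiles[[i]][[field]]
    }
    out
  }
  F1 <- acc("disp_f1", zf); M1 <- acc("disp_m1", zm)
  F2 <- acc("brood2_f", zf); M2 <- acc("brood2_m", zm)

  pool_pairs <- function(F, M, label) {
    if (sum(F) <= 0) return(NULL)
    if (sum(M) <= 0) {
      stop("extinction: ", label, " pool has females but no males",
           call. = FALSE)
    }
    outer(F, M / sum(M))
  }

  if (config$lifecycle == "univoltine") {
    mass <- matrix(0, length(fg), length(mg), dimnames = list(fg, mg))
    for (pp in list(pool_pairs(F1, M1, "first-brood"),
                    pool_pairs(F2, M2, "second-brood"))) {
      if (!is.null(pp)) mass <- mass + pp
    }
    disp <- c(female = sum(F1) + sum(F2), male = sum(M1) + sum(M2))
  } else {
    # first-brood dispersers mate and breed within the season
    gen2F <- zf; gen2M <- zm
    if (sum(F1) > 0) {
      if (sum(M1) <= 0) {
        stop("extinction: first-brood pool has females but no males",
             call. = FALSE)
      }
      mated1 <- outer(F1, M1 / sum(M1))
      n2 <- params$n2
      for (g in fg) for (h in mg) {
        w <- mated1[g, h]
        if (w > 0) {
          op <- .offspring_probs_num(g, h, config$ploidy, mu)
          gen2F <- gen2F + w * n2 * 0.5 * op$female
          gen2M <- gen2M + w * n2 * 0.5 * op$male
        }
      }
    }
    AF <- gen2F + F2
    AM <- gen2M + M2
    pp <- pool_pairs(AF, AM, "autumn")
    mass <- if (is.null(pp)) matrix(0, length(fg), length(mg),
                                    dimnames = list(fg, mg)) else pp
    disp <- c(female = sum(F1) + sum(AF), male = sum(M1) + sum(AM))
  }

  tot <- sum(mass)
  if (tot <= 0) stop("extinction: no mated females formed", call. = FALSE)
  nxt <- numeric(nrow(types))
  for (i in seq_len(nrow(types))) {
    nxt[i] <- mass[types$mother[i], types$father[i]]
  }
  nxt <- nxt / tot
  names(nxt) <- types$key
  attr(nxt, "mean_a") <- sum(state * vapply(profiles, `[[`, 0, "a"))
  attr(nxt, "mean_f") <- sum(state * vapply(profiles, `[[`, 0, "f"))
  attr(nxt, "disp") <- disp
  nxt
}

#' Copy-weighted allele frequency of a pair state
#'
#' Frequency of `A1` among genome copies of newly formed foundress pairs:
#' females contribute 2 copies, males 1 (haplodiploid) or 2 (diploid).
#'
#' @param state named pair-frequency vector.
#' @param config a [genetic_config()].
#' @return allele frequency in `[0, 1]`.
#' @export
allele_frequency <- function(state, config) {
  types <- pair_types(config)
  sum(state[types$key] * attr(types, "copies")) /
    (attr(types, "slots") * sum(state))
}

#' Initial pair states
#'
#' `pair_state_init()` forms pairs by random union at allele frequency `p0`
#' (Hardy-Weinberg genotype frequencies in each sex). `introduction_state()`
#' places carrier pairs at the single-copy introduction weights (2/3
#' heterozygous-mother, 1/3 carrier-father under haplodiploidy) scaled so the
#' copy-weighted allele frequency is `p0`; this is the state whose one-season
#' growth reproduces the invasion analysis.
#'
#' @param config a [genetic_config()].
#' @param p0 initial allele frequency in `(0, 1)`.
#' @return named pair-frequency vector.
#' @export
pair_state_init <- function(config, p0) {
  stopifnot(p0 >= 0, p0 <= 1)
  types <- pair_types(config)
  fg_freq <- c(A0A0 = (1 - p0)^2, A0A1 = 2 * p0 * (1 - p0), A1A1 = p0^2)
  mg_freq <- if (config$ploidy == "haplodiploid") {
    c(A0 = 1 - p0, A1 = p0)
  } else fg_freq
  st <- fg_freq[types$mother] * mg_freq[types$father]
  names(st) <- types$key
  st
}

#' @rdname pair_state_init
#' @export
introduction_state <- function(config, p0) {
  stopifnot(p0 > 0, p0 < 0.01)
  types <- pair_types(config)
  slots <- 2 + if (config$ploidy == "haplodiploid") 1 else 2
  delta <- slots * p0     # each carrier pair holds one A1 copy
  st <- structure(numeric(nrow(types)), names = types$key)
  for (cr in enumerate_introduction_crosses(config)) {
    st[paste(cr$mother, cr$father, sep = " x ")] <-
      as.numeric(cr$weight) * delta
  }
  wild <- paste("A0A0", if (config$ploidy == "haplodiploid") "A0" else "A0A0",
                sep = " x ")
  st[wild] <- 1 - sum(st)
  st
}

#' One-season growth factor of a rare allele
#'
#' Ratio `p1 / p0` of the copy-weighted allele frequency across one
#' deterministic season, starting from the introduction-weighted state at
#' frequency `p0`. In the rare-allele limit this equals `x / x_neutral` from
#' the invasion accounting for every scenario, which is the module's
#' validated surface.
#'
#' A finite perturbation carries a first-order density dependence: the raw
#' ratio deviates from the limit by a term proportional to `p0` (carrier
#' pairs shift pool sizes and meet other carriers). With
#' `extrapolate = TRUE` (default) the growth is Richardson-extrapolated from
#' `p0` and `p0/2`, cancelling that term so the returned value is the
#' limiting growth rate at working precision; `extrapolate = FALSE` returns
#' the raw one-step ratio.
#'
#' @param config a [genetic_config()].
#' @param params a [lifecycle_params()].
#' @param p0 initial allele frequency (small).
#' @param extrapolate logical; remove the `O(p0)` bias by extrapolation.
#' @return the growth factor `p1 / p0`.
#' @export
rare_allele_growth <- function(config, params, p0 = 1e-8,
                               extrapolate = TRUE) {
  one <- function(pp) {
    st <- introduction_state(config, pp)
    pa <- allele_frequency(st, config)
    st1 <- season_step(st, config, params)
    allele_frequency(st1, config) / pa
  }
  if (!extrapolate) return(one(p0))
  2 * one(p0 / 2) - one(p0)
}

#' Help threshold from the recursion dynamics
#'
#' Bisection on the rare-allele one-season growth factor: the returned `b*`
#' satisfies `growth(b*) = 1` to within `tol`, and agrees with the exact
#' [invasion_threshold()] for the same configuration.
#'
#' @param config a [genetic_config()].
#' @param params a [lifecycle_params()] supplying `n` (and `n2`); its `b` is
#'   ignored.
#' @param bracket numeric length-2 interval straddling the threshold.
#' @param tol bisection tolerance on `b`.
#' @param p0 rare-allele frequency used for the growth factor.
#' @return the threshold `b*`.
#' @export
empirical_threshold <- function(config, params, bracket = c(1e-3, 50),
                                tol = 1e-8, p0 = 1e-9) {
  stopifnot(length(bracket) == 2L, bracket[1] < bracket[2])
  g <- function(b) {
    rare_allele_growth(config,
                       lifecycle_params(params$n, b, params$n2), p0) - 1
  }
  lo <- bracket[1]; hi <- bracket[2]
  glo <- g(lo); ghi <- g(hi)
  if (sign(glo) == sign(ghi)) {
    stop("bracket does not straddle a sign change of the growth rate",
         call. = FALSE)
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    gm <- g(mid)
    if (sign(gm) == sign(glo)) {
      lo <- mid; glo <- gm
    } else {
      hi <- mid
    }
  }
  (lo + hi) / 2
}

#' Deterministic multi-season time course
#'
#' Iterates [season_step()] from Hardy-Weinberg pairs at frequency `p0`,
#' recording the copy-weighted allele frequency, mean helper fraction, mean
#' adjusted sex ratio and dispersing-pool female fraction each generation,
#' until fixation (`p > 1 - fixation_tol`), loss (`p < fixation_tol`),
#' stationarity (`|dp| < tol`) or `max_generations`.
#'
#' @param config a [genetic_config()].
#' @param params a [lifecycle_params()].
#' @param p0 initial allele frequency in `(0, 1)`.
#' @param max_generations iteration cap.
#' @param tol stationarity tolerance on `|dp|`.
#' @param fixation_tol absorption tolerance at the boundaries.
#' @param mu one-way mutation probability per transmitted copy.
#' @return a data.frame of class `"timecourse"` with columns `generation`,
#'   `p`, `mean_a`, `mean_f`, `disp_female_fraction`; attribute
#'   `termination` is one of `"fixed"`, `"lost"`, `"stationary"`,
#'   `"max_generations"`.
#' @examples
#' cfg <- genetic_config("haplodiploid", "dominant", "univoltine",
#'                       sex_adjusted = TRUE)
#' tc <- run_timecourse(cfg, lifecycle_params(n = 4, b = 3), p0 = 1e-3)
#' attr(tc, "termination")
#' @export
run_timecourse <- function(config, params, p0, max_generations = 10000,
                           tol = 1e-12, fixation_tol = 1e-9, mu = 0) {
  .validate_params(config, params)
  stopifnot(p0 > 0, p0 < 1)
  state <- pair_state_init(config, p0)
  p <- allele_frequency(state, config)
  rows <- list(data.frame(generation = 0L, p = p, mean_a = NA_real_,
                          mean_f = NA_real_,
                          disp_female_fraction = NA_real_))
  termination <- "max_generations"
  for (gen in seq_len(max_generations)) {
    state <- season_step(state, config, params, mu = mu)
    pnew <- allele_frequency(state, config)
    disp <- attr(state, "disp")
    rows[[gen + 1L]] <- data.frame(
      generation = gen, p = pnew,
      mean_a = attr(state, "mean_a"), mean_f = attr(state, "mean_f"),
      disp_female_fraction = disp[["female"]] / sum(disp))
    if (pnew > 1 - fixation_tol) { termination <- "fixed"; break }
    if (pnew < fixation_tol) { termination <- "lost"; break }
    if (abs(pnew - p) < tol) { termination <- "stationary"; break }
    p <- pnew
  }
  out <- do.call(rbind, rows)
  class(out) <- c("timecourse", "data.frame")
  attr(out, "termination") <- termination
  attr(out, "config") <- config
  attr(out, "params") <- params
  out
}

#' @export
plot.timecourse <- function(x, ...) {
  plot(x$generation, x$p, type = "l", xlab = "generation (breeding season)",
       ylab = "altruism allele frequency p", ylim = c(0, 1), ...)
  invisible(x)
}

#' @export
print.timecourse <- function(x, ...) {
  cat("Deterministic time course:", nrow(x) - 1L, "generations, termination:",
      attr(x, "termination"), "\n")
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4L) {
    cat("...\n")
    print.data.frame(utils::tail(as.data.frame(x), 2))
  }
  invisible(x)
}
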