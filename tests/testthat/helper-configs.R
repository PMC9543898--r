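# shorthand constructors used across test files

cfg_hap <- function(lifecycle = "univoltine", dominance = "dominant",
                    adjusted = FALSE) {
  genetic_config("haplodiploid", dominance, lifecycle, adjusted)
}

cfg_dip <- function(lifecycle = "univoltine", dominance = "dominant",
                    adjusted = FALSE) {
  genetic_config("diploid", dominance, lifecycle, adjusted)
}

all_configs <- function() {
  grid <- expand.grid(ploidy = c("haplodiploid", "diploid"),
                      dominance = c("dominant", "codominant"),
                      lifecycle = c("univoltine", "partially_bivoltine"),
                      adjusted = c(FALSE, TRUE), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    genetic_config(grid$ploidy[i], grid$dominance[i], grid$lifecycle[i],
                   grid$adjusted[i])
  })
}

# build a qpoly from coefficients: qq(c0, n = , b_n = , n_n2 = ...) where
# each name encodes a monomial; rationals given as c(num, den)
qn <- function() qp_var("n")
qb <- function() qp_var("b")
qn2 <- function() qp_var("n2")
r <- function(num, den = 1) rational(num, den)
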