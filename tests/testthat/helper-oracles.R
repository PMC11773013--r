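# Independent direct evaluations of the estimator formulas, written as
# literal transcriptions and kept separate from the package implementation.
# These serve as oracles in the equivalence tests.

oracle_chao1 <- function(x) {
  S <- length(x)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  S + f1 * (f1 - 1) / (2 * (f2 + 1))
}

oracle_ace <- function(x, cutoff = 10) {
  rare <- x[x <= cutoff]
  abund <- x[x > cutoff]
  S_rare <- length(rare)
  S_abund <- length(abund)
  if (S_rare == 0) return(S_abund)
  N_rare <- sum(rare)
  f1 <- sum(rare == 1)
  C <- 1 - f1 / N_rare
  if (C == 0) return(NA_real_)  # undefined; implementation falls back
  ss <- 0
  for (i in seq_len(cutoff)) ss <- ss + i * (i - 1) * sum(rare == i)
  g2 <- 0
  if (N_rare > 1) {
    g2 <- max((S_rare / C) * ss / (N_rare * (N_rare - 1)) - 1, 0)
  }
  max(S_abund + S_rare / C + (f1 / C) * g2, length(x))
}

oracle_pairwise <- function(set1, set2) {
  a <- length(intersect(set1, set2))
  b <- length(setdiff(set1, set2))
  cc <- length(setdiff(set2, set1))
  sor <- (b + cc) / (2 * a + b + cc)
  sim <- if (a + min(b, cc) == 0) 0 else min(b, cc) / (a + min(b, cc))
  c(total = sor, turnover = sim, nestedness = sor - sim)
}

oracle_multisite <- function(pres) {
  n <- nrow(pres)
  Si <- rowSums(pres > 0)
  ST <- sum(colSums(pres) > 0)
  smin <- 0; smax <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      bij <- sum(pres[i, ] > 0 & pres[j, ] == 0)
      bji <- sum(pres[j, ] > 0 & pres[i, ] == 0)
      smin <- smin + min(bij, bji)
      smax <- smax + max(bij, bji)
    }
  }
  sh <- sum(Si) - ST
  sim <- if (sh + smin == 0) 0 else smin / (sh + smin)
  sor <- if (2 * sh + smin + smax == 0) 0 else
    (smin + smax) / (2 * sh + smin + smax)
  c(total = sor, turnover = sim, nestedness = sor - sim)
}

# Random abundance vector with a fat tail of singletons, for oracle sweeps.
random_abundances <- function(max_s = 30) {
  s <- sample(1:max_s, 1)
  pmax(1, stats::rnbinom(s, mu = sample(c(1, 3, 20), 1), size = 0.5))
}

# Random presence matrix with every site non-empty.
random_presence <- function(max_sites = 6, max_species = 25) {
  repeat {
    n <- (2:max_sites)[sample.int(max_sites - 1, 1)]
    s <- sample(3:max_species, 1)
    m <- matrix(stats::rbinom(n * s, 1, stats::runif(1, 0.2, 0.8)),
                nrow = n,
                dimnames = list(paste0("st", 1:n), paste0("sp", 1:s)))
    if (all(rowSums(m) > 0)) return(m)
  }
}
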