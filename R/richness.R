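#' Abundance frequency counts
#'
#' Tabulates a per-species abundance vector into the frequency-of-frequencies
#' counts used by nonparametric richness estimators: `f[i]` is the number of
#' species observed exactly `i` times, `S_obs` the observed richness and `N`
#' the total number of individuals.
#'
#' @param abundances Vector of positive integer per-species abundances.
#' @return A list with elements `f` (named integer vector), `S_obs`, `N`.
#' @export
frequency_counts <- function(abundances) {
  if (length(abundances) == 0L) stop("empty abundance vector")
  if (any(is.na(abundances)) || any(abundances < 1) ||
      any(abundances != round(abundances))) {
    stop("abundances must be positive integers (no zeros or NAs)")
  }
  f <- table(abundances)
  list(f = stats::setNames(as.integer(f), names(f)),
       S_obs = length(abundances),
       N = sum(abundances))
}

f_at <- function(fc, i) {
  v <- unname(fc$f[as.character(i)])
  ifelse(is.na(v), 0L, as.integer(v))
}

new_richness_estimate <- function(estimator, estimate, se, S_obs, N,
                                  note = NULL) {
  structure(list(estimator = estimator, estimate = estimate, se = se,
                 S_obs = S_obs, N = N, note = note),
            class = "richness_estimate")
}

#' @export
print.richness_estimate <- function(x, ...) {
  se_txt <- if (is.null(x$se) || is.na(x$se)) "" else sprintf(" +/- %.1f", x$se)
  cat(sprintf("%s richness estimate: %.1f%s (S_obs = %d, N = %d)\n",
              x$estimator, x$estimate, se_txt, x$S_obs, x$N))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Bias-corrected Chao1 species richness
#'
#' Estimates total species richness from the singleton and doubleton counts
#' of an abundance sample using the bias-corrected Chao1 estimator
#' \deqn{\hat S = S_{obs} + \frac{f_1 (f_1 - 1)}{2 (f_2 + 1)}}
#' with the companion bias-corrected variance
#' \deqn{\widehat{var} = \frac{f_1(f_1-1)}{2(f_2+1)}
#'   + \frac{f_1 (2 f_1 - 1)^2}{4 (f_2+1)^2}
#'   + \frac{f_1^2 f_2 (f_1-1)^2}{4 (f_2+1)^4}.}
#' With no singletons the estimate equals the observed richness.
#'
#' @param abundances Vector of positive integer per-species abundances.
#' @return A `richness_estimate` with elements `estimate` and `se`.
#' @examples
#' chao1(c(1, 1, 1, 1, 2, 2))  # 6 + 4*3/(2*3) = 8
#' @export
chao1 <- function(abundances) {
  fc <- frequency_counts(abundances)
  f1 <- f_at(fc, 1L)
  f2 <- f_at(fc, 2L)
  est <- fc$S_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  v <- f1 * (f1 - 1) / (2 * (f2 + 1)) +
    f1 * (2 * f1 - 1)^2 / (4 * (f2 + 1)^2) +
    f1^2 * f2 * (f1 - 1)^2 / (4 * (f2 + 1)^4)
  new_richness_estimate("Chao1", est, sqrt(v), fc$S_obs, fc$N)
}

#' ACE species richness (abundance-based coverage estimator)
#'
#' Splits species into rare (abundance at most `rare_cutoff`) and abundant
#' groups, estimates sample coverage of the rare group as
#' \eqn{C = 1 - f_1 / N_{rare}}, and returns
#' \deqn{\hat S = S_{abund} + S_{rare}/C + (f_1/C)\,\hat\gamma^2,\qquad
#'   \hat\gamma^2 = \max\left\{\frac{S_{rare}}{C}
#'   \frac{\sum_{i \le cutoff} i(i-1) f_i}{N_{rare}(N_{rare}-1)} - 1,\ 0\right\}.}
#' When every rare species is a singleton the coverage estimate is zero and
#' ACE is undefined; the function falls back to [chao1()] with a warning, as
#' is conventional. The estimate is clamped below at the observed richness:
#' an extrapolative estimator below \eqn{S_{obs}} is uninterpretable.
#'
#' @param abundances Vector of positive integer per-species abundances.
#' @param rare_cutoff Abundance at and below which a species counts as rare
#'   (default 10, the conventional threshold).
#' @return A `richness_estimate`. No standard error is attached.
#' @examples
#' ace(c(1, 1, 2, 11))  # 1 + 3/0.5 = 7
#' @export
ace <- function(abundances, rare_cutoff = 10L) {
  fc <- frequency_counts(abundances)
  stopifnot(rare_cutoff >= 1)
  rare <- abundances <= rare_cutoff
  S_rare <- sum(rare)
  S_abund <- fc$S_obs - S_rare
  if (S_rare == 0L) {
    return(new_richness_estimate("ACE", as.numeric(S_abund), NA_real_,
                                 fc$S_obs, fc$N))
  }
  N_rare <- sum(abundances[rare])
  f1 <- f_at(fc, 1L)
  C <- 1 - f1 / N_rare
  if (C == 0) {
    warning("all rare species are singletons (coverage 0); falling back to Chao1")
    out <- chao1(abundances)
    out$note <- "ACE undefined (coverage 0); Chao1 reported"
    return(out)
  }
  i <- seq_len(rare_cutoff)
  fi <- vapply(i, function(k) f_at(fc, k), integer(1))
  ssum <- sum(i * (i - 1) * fi)
  gamma2 <- if (N_rare > 1) {
    max((S_rare / C) * ssum / (N_rare * (N_rare - 1)) - 1, 0)
  } else 0
  est <- S_abund + S_rare / C + (f1 / C) * gamma2
  est <- max(est, fc$S_obs)
  new_richness_estimate("ACE", est, NA_real_, fc$S_obs, fc$N)
}

#' Richness estimates per site
#'
#' Applies [chao1()] and [ace()] to each row of a sites-by-species abundance
#' matrix (as built by [community_matrix()]).
#'
#' @param comm Sites x species abundance matrix.
#' @param rare_cutoff Passed to [ace()].
#' @return A `data.frame` with one row per site: `site`, `S_obs`, `N`,
#'   `chao1`, `chao1_se`, `ace`.
#' @export
richness_by_site <- function(comm, rare_cutoff = 10L) {
  stopifnot(is.matrix(comm))
  rows <- lapply(rownames(comm), function(s) {
    x <- comm[s, ]
    x <- x[x > 0]
    c1 <- chao1(x)
    a1 <- ace(x, rare_cutoff)
    data.frame(site = s, S_obs = c1$S_obs, N = c1$N,
               chao1 = c1$estimate, chao1_se = c1$se, ace = a1$estimate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
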