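#' Pairwise beta-diversity partition (Sorensen = Simpson + nestedness)
#'
#' Partitions the Sorensen dissimilarity between two species sets into a
#' turnover component (Simpson dissimilarity, driven by species replacement)
#' and a nestedness-resultant component (driven by richness difference when
#' one assemblage is a subset of the other). With `a` shared species and
#' `b`, `c` exclusive to each site:
#' \deqn{\beta_{sor} = \frac{b + c}{2a + b + c},\quad
#'   \beta_{sim} = \frac{\min(b, c)}{a + \min(b, c)},\quad
#'   \beta_{sne} = \beta_{sor} - \beta_{sim}.}
#'
#' @param x,y Character (or other atomic) vectors: the species present at
#'   each of the two sites. Duplicates are ignored.
#' @return An object of class `"beta_partition"`: a list with `total`
#'   (Sorensen), `turnover` (Simpson) and `nestedness`, each in \[0, 1\],
#'   satisfying `total = turnover + nestedness`.
#' @examples
#' pairwise_beta(letters[1:8], letters[4:9])
#' @export
pairwise_beta <- function(x, y) {
  x <- unique(x); y <- unique(y)
  if (length(x) == 0L && length(y) == 0L) {
    stop("beta diversity undefined: both species sets are empty")
  }
  a <- length(intersect(x, y))
  b <- length(setdiff(x, y))
  c_ <- length(setdiff(y, x))
  total <- (b + c_) / (2 * a + b + c_)
  m <- min(b, c_)
  turnover <- if (a + m == 0) 0 else m / (a + m)
  new_beta_partition(total, turnover, sites = 2L)
}

new_beta_partition <- function(total, turnover, sites) {
  structure(list(total = total, turnover = turnover,
                 nestedness = total - turnover, n_sites = sites),
            class = "beta_partition")
}

#' @export
print.beta_partition <- function(x, digits = 4, ...) {
  cat(sprintf("beta-diversity partition (%d sites)\n", x$n_sites))
  cat(sprintf("  total (Sorensen):    %.*f\n", digits, x$total))
  cat(sprintf("  turnover (Simpson):  %.*f\n", digits, x$turnover))
  cat(sprintf("  nestedness:          %.*f\n", digits, x$nestedness))
  invisible(x)
}

#' Multiple-site beta-diversity partition
#'
#' Overall dissimilarity across all sites at once (not an average of pairs),
#' partitioned into turnover and nestedness. With site richness \eqn{S_i},
#' pooled richness \eqn{S_T}, and \eqn{b_{ij}} the number of species present
#' in site i but not j:
#' \deqn{\beta_{SIM} = \frac{\sum_{i<j} \min(b_{ij}, b_{ji})}
#'   {\left(\sum_i S_i - S_T\right) + \sum_{i<j} \min(b_{ij}, b_{ji})}}
#' \deqn{\beta_{SOR} = \frac{\sum_{i<j} \min + \sum_{i<j} \max}
#'   {2\left(\sum_i S_i - S_T\right) + \sum_{i<j} \min + \sum_{i<j} \max}}
#' and \eqn{\beta_{SNE} = \beta_{SOR} - \beta_{SIM}}. For exactly two sites
#' this reduces to [pairwise_beta()].
#'
#' @param comm Sites x species presence/absence matrix (counts are accepted
#'   and reduced to presence). At least two sites, each with at least one
#'   species.
#' @return A `"beta_partition"` object.
#' @examples
#' m <- rbind(A = c(1, 1, 1, 0, 0), B = c(0, 1, 1, 1, 0), C = c(0, 0, 1, 1, 1))
#' multisite_beta(m)
#' @export
multisite_beta <- function(comm) {
  stopifnot(is.matrix(comm))
  comm <- (comm > 0) + 0L
  n <- nrow(comm)
  if (n < 2L) stop("multiple-site beta diversity needs at least 2 sites")
  if (any(rowSums(comm) == 0)) stop("site(s) with zero species present")
  Si <- rowSums(comm)
  ST <- sum(colSums(comm) > 0)
  sum_min <- 0
  sum_max <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      bij <- sum(comm[i, ] == 1L & comm[j, ] == 0L)
      bji <- sum(comm[j, ] == 1L & comm[i, ] == 0L)
      sum_min <- sum_min + min(bij, bji)
      sum_max <- sum_max + max(bij, bji)
    }
  }
  shared <- sum(Si) - ST
  denom_sim <- shared + sum_min
  turnover <- if (denom_sim == 0) 0 else sum_min / denom_sim
  denom_sor <- 2 * shared + sum_min + sum_max
  total <- if (denom_sor == 0) 0 else (sum_min + sum_max) / denom_sor
  new_beta_partition(total, turnover, sites = n)
}

#' Pairwise beta-diversity table for a community matrix
#'
#' Computes [pairwise_beta()] for every pair of sites in a presence/absence
#' community matrix and returns the long-format table used in reports.
#'
#' @param comm Sites x species presence or count matrix.
#' @return A `data.frame` with columns `site_i`, `site_j`, `total`,
#'   `turnover`, `nestedness`.
#' @export
beta_pairwise_table <- function(comm) {
  stopifnot(is.matrix(comm), nrow(comm) >= 2L)
  comm <- (comm > 0) + 0L
  sites <- rownames(comm)
  if (is.null(sites)) sites <- as.character(seq_len(nrow(comm)))
  sp <- colnames(comm)
  if (is.null(sp)) sp <- as.character(seq_len(ncol(comm)))
  pairs <- utils::combn(seq_len(nrow(comm)), 2)
  rows <- apply(pairs, 2, function(ij) {
    b <- pairwise_beta(sp[comm[ij[1], ] > 0], sp[comm[ij[2], ] > 0])
    data.frame(site_i = sites[ij[1]], site_j = sites[ij[2]],
               total = b$total, turnover = b$turnover,
               nestedness = b$nestedness, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
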