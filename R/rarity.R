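#' Thresholds for the Rabinowitz rarity criteria
#'
#' The three binary criteria that cross into the eight commonness/rarity
#' categories, with the boundary conventions applied exactly as printed
#' inequalities:
#' \itemize{
#'   \item geographic range: wide when the occupied proportion of surveyed
#'     units is strictly greater than `wide_range_min_prop` (default 0.10);
#'     exactly 10 percent occupancy is narrow.
#'   \item habitat specificity: "various" when occupied habitats exceed
#'     `habitat_various_min - 1` (default: more than 1 habitat).
#'   \item population size: "large" when abundance is at least
#'     `abundance_large_min` (default 3, i.e. abundance > 2; exactly 2 is
#'     small).
#' }
#'
#' @param wide_range_min_prop Occupancy proportion above which the range is
#'   wide (strict inequality). Default 0.10.
#' @param habitat_various_min Minimum habitat count for "various". Default 2.
#' @param abundance_large_min Minimum abundance for "large". Default 3.
#' @param abundance_scope Whether the abundance criterion uses the maximum
#'   per-habitat abundance (`"max_per_habitat"`, default: "large somewhere")
#'   or the total across habitats (`"total"`).
#' @return An object of class `"rarity_thresholds"`.
#' @export
rarity_thresholds <- function(wide_range_min_prop = 0.10,
                              habitat_various_min = 2L,
                              abundance_large_min = 3L,
                              abundance_scope = c("max_per_habitat", "total")) {
  stopifnot(wide_range_min_prop > 0, wide_range_min_prop < 1,
            habitat_various_min >= 2, abundance_large_min >= 1)
  structure(list(wide_range_min_prop = wide_range_min_prop,
                 habitat_various_min = as.integer(habitat_various_min),
                 abundance_large_min = as.integer(abundance_large_min),
                 abundance_scope = match.arg(abundance_scope)),
            class = "rarity_thresholds")
}

#' Rabinowitz rarity forms
#'
#' Ordered labels of the eight categories produced by crossing geographic
#' range (wide/narrow), habitat specificity (various/single) and local
#' population size (large/small). `Common` is the fully favourable corner;
#' `Form7` (narrow + single habitat + small population) is the extreme form
#' of rarity.
#' @export
rarity_forms <- c("Common", paste0("Form", 1:7))

# (wide, various, large) -> form label, in the canonical table order.
rabinowitz_form <- function(wide, various, large) {
  idx <- 1L + (!large) + 2L * (!various) + 4L * (!wide)
  rarity_forms[idx]
}

#' Classify a species into a Rabinowitz rarity form
#'
#' Applies the three binary criteria (geographic range, habitat specificity,
#' population size) to per-species profiles and returns one of the eight
#' category labels: wide/various/large is `Common`; the seven remaining
#' combinations are rarity forms 1-7, ordered as large/small within single
#' habitat within narrow range (so `Form1` = wide + various + small, ...,
#' `Form7` = narrow + single + small).
#'
#' @param profiles A `species_profiles` data frame from [build_profiles()],
#'   or any data frame with columns `occupied_units`, `total_units`,
#'   `n_habitats` and `max_habitat_abundance` / `total_abundance`.
#' @param thresholds A [rarity_thresholds()].
#' @return Factor of form labels with levels [rarity_forms], one per row of
#'   `profiles`.
#' @examples
#' p <- data.frame(species = "x", occupied_units = 30, total_units = 100,
#'                 n_habitats = 2, max_habitat_abundance = 50,
#'                 total_abundance = 60)
#' classify_rabinowitz(p)  # Common
#' @export
classify_rabinowitz <- function(profiles, thresholds = rarity_thresholds()) {
  if (nrow(profiles) == 0L) stop("empty species profiles")
  stopifnot(all(profiles$total_units > 0), all(profiles$n_habitats >= 1))
  wide <- profiles$occupied_units / profiles$total_units >
    thresholds$wide_range_min_prop
  various <- profiles$n_habitats >= thresholds$habitat_various_min
  abundance <- switch(thresholds$abundance_scope,
                      max_per_habitat = profiles$max_habitat_abundance,
                      total = profiles$total_abundance)
  large <- abundance >= thresholds$abundance_large_min
  factor(rabinowitz_form(wide, various, large), levels = rarity_forms)
}

#' Range, habitat-specificity and population-size rarity indices
#'
#' Continuous companions to the binary Rabinowitz criteria, each normalized
#' to \[0, 1\] with higher values meaning rarer:
#' \itemize{
#'   \item `gri` (geographic range index): `1 - occupied_units/total_units`.
#'   \item `hsi` (habitat specificity index): `1 - (h - 1)/(H - 1)` for a
#'     study region with `H > 1` habitats (`h` = habitats occupied); 1 by
#'     convention when the region has a single habitat.
#'   \item `psi` (population size index):
#'     `1 - log(1 + n)/log(1 + n_max)`, a log-compressed abundance
#'     complement so that the index separates scarce species rather than the
#'     dominant tail.
#'   \item `ri` (rarity index): the mean of the three.
#' }
#' The exact functional forms are this package's own normalization; they
#' preserve the intended semantics (monotone, 0 = commonest possible,
#' 1 = rarest possible) but numeric values are specific to this
#' implementation and should be compared only within a run.
#'
#' @param profiles A `species_profiles` data frame.
#' @param n_habitats_region Number of habitats in the study region `H`
#'   (default: the maximum habitat count observed in `profiles`).
#' @param n_max Abundance of the most abundant species (default taken from
#'   `profiles`).
#' @return A `data.frame` with columns `gri`, `hsi`, `psi`, `ri`.
#' @examples
#' p <- data.frame(occupied_units = 1, total_units = 100, n_habitats = 1,
#'                 total_abundance = 1)
#' maciel_indices(p, n_habitats_region = 3, n_max = 1000)
#' @export
maciel_indices <- function(profiles,
                           n_habitats_region = max(profiles$n_habitats),
                           n_max = max(profiles$total_abundance)) {
  stopifnot(nrow(profiles) > 0, n_habitats_region >= 1)
  if (is.na(n_max) || n_max < 1) stop("n_max must be a positive abundance")
  gri <- 1 - profiles$occupied_units / profiles$total_units
  hsi <- if (n_habitats_region > 1) {
    1 - (profiles$n_habitats - 1) / (n_habitats_region - 1)
  } else {
    rep(1, nrow(profiles))
  }
  psi <- 1 - log1p(profiles$total_abundance) / log1p(n_max)
  data.frame(gri = gri, hsi = hsi, psi = psi,
             ri = (gri + hsi + psi) / 3)
}

#' Protection index
#'
#' Fraction of a species' occurrence records (plot-level presences) that fall
#' inside protected areas. 1 means the species was found exclusively within
#' PAs, 0 exclusively outside.
#'
#' @param occ_in_pa Occurrences inside protected areas.
#' @param occ_total Total occurrences (must be >= 1).
#' @return Numeric in \[0, 1\].
#' @examples
#' protection_index(3, 10)
#' @export
protection_index <- function(occ_in_pa, occ_total) {
  if (any(occ_total < 1)) stop("occ_total must be at least 1")
  if (any(occ_in_pa < 0) || any(occ_in_pa > occ_total)) {
    stop("occ_in_pa must lie in [0, occ_total]")
  }
  occ_in_pa / occ_total
}

#' Protection status from the protection index
#'
#' Species occurring exclusively within protected areas (PI = 1) are
#' `highly` protected, those occurring solely outside (PI = 0) are `poorly`
#' protected, and those found both inside and outside (0 < PI < 1) are
#' `partially` protected.
#'
#' @param pi Numeric vector of protection indices in \[0, 1\].
#' @return Factor with levels `highly`, `partially`, `poorly`.
#' @export
protection_status <- function(pi) {
  if (any(is.na(pi)) || any(pi < 0) || any(pi > 1)) {
    stop("protection index must lie in [0, 1]")
  }
  out <- ifelse(pi == 1, "highly", ifelse(pi == 0, "poorly", "partially"))
  factor(out, levels = c("highly", "partially", "poorly"))
}

#' Full per-species rarity and protection assessment
#'
#' Combines [classify_rabinowitz()], [maciel_indices()],
#' [protection_index()] and [protection_status()] into the per-species
#' assessment table.
#'
#' @param profiles A `species_profiles` data frame from [build_profiles()].
#' @param thresholds A [rarity_thresholds()].
#' @param n_habitats_region,n_max Passed to [maciel_indices()].
#' @return A `data.frame` of class `"rarity_assessment"`: `species`, `form`,
#'   `is_rare`, `gri`, `hsi`, `psi`, `ri`, `pi`, `protection`.
#' @export
assess_rarity <- function(profiles, thresholds = rarity_thresholds(),
                          n_habitats_region = max(profiles$n_habitats),
                          n_max = max(profiles$total_abundance)) {
  form <- classify_rabinowitz(profiles, thresholds)
  idx <- maciel_indices(profiles, n_habitats_region, n_max)
  pi <- protection_index(profiles$occurrences_in_pa,
                         profiles$occurrences_total)
  out <- data.frame(species = profiles$species,
                    form = form,
                    is_rare = form != "Common",
                    idx,
                    pi = pi,
                    protection = protection_status(pi),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("rarity_assessment", "data.frame")
  out
}

#' Summary counts for a rarity assessment
#'
#' Counts (and proportions) of species per rarity form and per protection
#' status. Percentages are also given rounded half-up to integers, matching
#' the usual reporting style.
#'
#' @param assessment A `rarity_assessment` data frame.
#' @return A list with data frames `by_form` and `by_protection`.
#' @export
summarize_rarity <- function(assessment) {
  n <- nrow(assessment)
  round_half_up <- function(x) floor(x + 0.5)
  tab <- function(f) {
    t <- table(f)
    data.frame(level = names(t), count = as.integer(t),
               proportion = as.numeric(t) / n,
               percent = round_half_up(100 * as.numeric(t) / n),
               stringsAsFactors = FALSE)
  }
  list(by_form = tab(assessment$form),
       by_protection = tab(assessment$protection),
       n_species = n,
       n_rare = sum(assessment$is_rare))
}
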