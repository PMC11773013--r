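#' Timber harvest policy
#'
#' Bundles the legal and sustainability screens applied to commercial timber
#' species: the minimum felling diameter (MFD) per species, a minimum legal
#' stem density of harvestable trees, the set of habitats where logging is
#' allowed, and whether harvesting requires the species to be fully common
#' (wide-ranging, habitat generalist and locally abundant).
#'
#' @param min_felling_dbh_cm Named numeric vector mapping canonical species
#'   names to their MFD in cm. Species not in the map fall back to
#'   `default_mfd_cm`.
#' @param default_mfd_cm Fallback MFD (default 40 cm).
#' @param min_harvest_density_per_ha Minimum density of harvestable stems
#'   (stems/ha) below which a species may not be logged. Default 1, the
#'   density repeatedly used as the viability benchmark for commercial-sized
#'   trees.
#' @param allowed_habitats Habitats where logging is permitted (default
#'   `"humid"`: woodland logging restricted to the humid ecoregion).
#' @param require_common Require the species' rarity form to be `Common`
#'   (default TRUE: a species exhibiting any sort of rarity - geographic,
#'   numeric or habitat specificity - may not be harvested).
#' @return An object of class `"timber_policy"`.
#' @export
timber_policy <- function(min_felling_dbh_cm = numeric(),
                          default_mfd_cm = 40,
                          min_harvest_density_per_ha = 1,
                          allowed_habitats = "humid",
                          require_common = TRUE) {
  stopifnot(is.numeric(min_felling_dbh_cm),
            all(min_felling_dbh_cm > 0),
            default_mfd_cm > 0,
            min_harvest_density_per_ha >= 0,
            length(allowed_habitats) >= 1)
  if (length(min_felling_dbh_cm) > 0 && is.null(names(min_felling_dbh_cm))) {
    stop("min_felling_dbh_cm must be a named (species -> cm) vector")
  }
  names(min_felling_dbh_cm) <- normalize_species(names(min_felling_dbh_cm))
  structure(list(min_felling_dbh_cm = min_felling_dbh_cm,
                 default_mfd_cm = default_mfd_cm,
                 min_harvest_density_per_ha = min_harvest_density_per_ha,
                 allowed_habitats = allowed_habitats,
                 require_common = isTRUE(require_common)),
            class = "timber_policy")
}

#' Minimum felling diameter for a species under a policy
#' @param species Canonical species name(s).
#' @param policy A [timber_policy()].
#' @return Numeric vector of MFDs in cm.
#' @export
mfd_for <- function(species, policy) {
  species <- normalize_species(species)
  out <- policy$min_felling_dbh_cm[species]
  out[is.na(out)] <- policy$default_mfd_cm
  unname(out)
}

#' Density of harvestable stems of one species
#'
#' Expansion-weighted stems per hectare of one species at or above its
#' minimum felling diameter, over a set of plots. Callers screening for
#' lawful harvest should pass only records from plots outside protected
#' areas in a single habitat, with `n_plots` the number of such plots.
#'
#' @param records Tree records already restricted to the stratum of
#'   interest (one habitat, outside PAs); may contain several species.
#' @param species Canonical species name.
#' @param n_plots Number of plots in the stratum.
#' @param policy A [timber_policy()].
#' @param design A [survey_design()].
#' @return Stems per hectare of trees with `dbh_cm >= mfd_for(species)`.
#' @export
harvestable_density <- function(records, species, n_plots,
                                policy = timber_policy(),
                                design = survey_design()) {
  species <- normalize_species(species)
  mfd <- mfd_for(species, policy)
  keep <- records$species == species & records$dbh_cm >= mfd
  stems_per_ha(records[keep, , drop = FALSE], n_plots, design)
}

#' Stem-form profile by DBH class
#'
#' Relative frequencies of the stem-form scores SF1 (straight, sawmill
#' ideal), SF2 (wavy, partially usable) and SF3 (crooked, unusable) within
#' half-open DBH classes. Records with no stem-form score are excluded from
#' the profile (form frequencies are conditional on scoring); DBH classes
#' with no scored stems are omitted rather than zero-filled.
#'
#' @param records Tree records.
#' @param class_edges Increasing DBH class edges in cm; classes are
#'   `[e1, e2), [e2, e3), ...` with the last edge allowed to be `Inf`.
#'   Default `c(10, 20, 30, 40, Inf)`.
#' @return A `data.frame` with columns `dbh_class`, `n`, `SF1`, `SF2`,
#'   `SF3` (relative frequencies summing to 1 per row).
#' @examples
#' rec <- data.frame(dbh_cm = c(12, 13, 15, 18),
#'                   stem_form = c("SF1", "SF1", "SF1", "SF2"))
#' stem_form_profile(rec)
#' @export
stem_form_profile <- function(records, class_edges = c(10, 20, 30, 40, Inf)) {
  if (is.unsorted(class_edges, strictly = TRUE)) {
    stop("DBH class edges must be strictly increasing")
  }
  scored <- records[!is.na(records$stem_form), , drop = FALSE]
  cls <- cut(scored$dbh_cm, breaks = class_edges, right = FALSE,
             include.lowest = FALSE, dig.lab = 4)
  keep <- !is.na(cls)
  scored <- scored[keep, , drop = FALSE]
  cls <- cls[keep]
  rows <- lapply(levels(cls), function(lv) {
    sub <- scored$stem_form[cls == lv]
    if (length(sub) == 0L) return(NULL)
    t <- table(factor(sub, levels = c("SF1", "SF2", "SF3")))
    data.frame(dbh_class = lv, n = length(sub),
               SF1 = as.numeric(t["SF1"]) / length(sub),
               SF2 = as.numeric(t["SF2"]) / length(sub),
               SF3 = as.numeric(t["SF3"]) / length(sub),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(dbh_class = character(), n = integer(),
                      SF1 = numeric(), SF2 = numeric(), SF3 = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Harvest-eligibility decision for one species in one habitat
#'
#' A timber species may be harvested in a habitat only if all of the
#' following hold: it is a legally classified timber species; it is fully
#' common under the rarity classification (when the policy requires it);
#' the habitat is one where logging is allowed; and its harvestable-stem
#' density meets the legal minimum. All failed conditions are reported as
#' machine-readable denial codes, not just the first.
#'
#' Denial codes: `NOT_TIMBER`, `RARE_FORM` (rarity form is not Common),
#' `NOT_GENERALIST` (single-habitat species; accompanies `RARE_FORM` when
#' the policy requires commonness), `HABITAT_RESTRICTED`, `LOW_DENSITY`
#' (harvestable density positive but below the legal minimum),
#' `NO_HARVESTABLE_TREES` (no stems at or above the MFD at all).
#'
#' @param species Canonical species name.
#' @param habitat Habitat label the decision applies to.
#' @param is_timber Logical: is the species legally merchantable?
#' @param form Rarity form label for the species (from
#'   [classify_rabinowitz()]).
#' @param n_habitats Number of habitats the species occupies.
#' @param density_per_ha Harvestable-stem density outside PAs in this
#'   habitat (from [harvestable_density()]).
#' @param policy A [timber_policy()].
#' @return A one-row `data.frame`: `species`, `habitat`,
#'   `harvestable_density_per_ha`, `eligible`, `reasons`
#'   (comma-separated codes; empty when eligible).
#' @export
harvest_eligibility <- function(species, habitat, is_timber, form,
                                n_habitats, density_per_ha,
                                policy = timber_policy()) {
  reasons <- character()
  if (!isTRUE(is_timber)) reasons <- c(reasons, "NOT_TIMBER")
  if (policy$require_common && form != "Common") {
    reasons <- c(reasons, "RARE_FORM")
    if (n_habitats < 2) reasons <- c(reasons, "NOT_GENERALIST")
  }
  if (!(habitat %in% policy$allowed_habitats)) {
    reasons <- c(reasons, "HABITAT_RESTRICTED")
  }
  if (density_per_ha <= 0) {
    reasons <- c(reasons, "NO_HARVESTABLE_TREES")
  } else if (density_per_ha < policy$min_harvest_density_per_ha) {
    reasons <- c(reasons, "LOW_DENSITY")
  }
  data.frame(species = normalize_species(species), habitat = habitat,
             harvestable_density_per_ha = density_per_ha,
             eligible = length(reasons) == 0L,
             reasons = paste(reasons, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Commercial availability assessment for all timber species
#'
#' Screens every species of an inventory for lawful harvest in every
#' habitat: harvestable-stem density outside protected areas, the share of
#' harvestable stems among all recorded stems of the stratum, and the
#' eligibility decision with its denial codes.
#'
#' @param records Full `tree_records` inventory.
#' @param rarity A `rarity_assessment` from [assess_rarity()] computed on
#'   the same inventory.
#' @param species_meta Species metadata table (see
#'   [read_species_metadata()]): canonical `species`, logical `is_timber`,
#'   optional `min_felling_dbh_cm` overrides merged into the policy.
#' @param profiles The `species_profiles` used for `rarity` (supplies
#'   habitat counts).
#' @param policy A [timber_policy()].
#' @param design A [survey_design()].
#' @return A `data.frame` of class `"harvest_assessment"`, one row per
#'   timber species x habitat, with density, stem share and eligibility;
#'   the per-DBH-class stem-form profile of harvestable species is attached
#'   as attribute `"stem_form_profiles"`.
#' @export
assess_harvest <- function(records, rarity, species_meta, profiles,
                           policy = timber_policy(),
                           design = survey_design()) {
  meta_mfd <- species_meta$min_felling_dbh_cm
  names(meta_mfd) <- species_meta$species
  meta_mfd <- meta_mfd[!is.na(meta_mfd)]
  # explicit policy entries win over metadata defaults
  merged <- c(policy$min_felling_dbh_cm,
              meta_mfd[setdiff(names(meta_mfd),
                               names(policy$min_felling_dbh_cm))])
  policy$min_felling_dbh_cm <- merged

  timber <- species_meta$species[species_meta$is_timber]
  habitats <- sort(unique(records$habitat))
  form_of <- stats::setNames(as.character(rarity$form), rarity$species)
  nhab_of <- stats::setNames(profiles$n_habitats, profiles$species)

  rows <- list()
  for (h in habitats) {
    stratum <- records[records$habitat == h & !records$in_pa, , drop = FALSE]
    n_plots <- length(unique(plot_uid(stratum)))
    total_stems <- nrow(stratum)
    for (sp in timber) {
      if (!(sp %in% rarity$species)) next  # timber species not observed
      dens <- if (n_plots > 0) {
        harvestable_density(stratum, sp, n_plots, policy, design)
      } else 0
      mfd <- mfd_for(sp, policy)
      n_harv <- sum(stratum$species == sp & stratum$dbh_cm >= mfd)
      row <- harvest_eligibility(sp, h, TRUE, form_of[[sp]],
                                 nhab_of[[sp]], dens, policy)
      row$harvestable_share_of_stems <-
        if (total_stems > 0) n_harv / total_stems else 0
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(species = character(), habitat = character(),
                      harvestable_density_per_ha = numeric(),
                      eligible = logical(), reasons = character(),
                      harvestable_share_of_stems = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL

  profs <- lapply(stats::setNames(timber, timber), function(sp) {
    stem_form_profile(records[records$species == sp &
                                !records$in_pa, , drop = FALSE])
  })
  attr(out, "stem_form_profiles") <- profs
  class(out) <- c("harvest_assessment", "data.frame")
  out
}
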