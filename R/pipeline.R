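#' Run the full assessment pipeline
#'
#' Orchestrates the whole analysis on one inventory: species profiles,
#' per-habitat richness (observed, bias-corrected Chao1, ACE), pairwise and
#' multiple-site beta-diversity partitions, the per-species rarity and
#' protection assessment with its summary counts, the protected/unprotected
#' compositional dissimilarity per habitat, and (when species metadata are
#' supplied) the commercial timber availability screen. The result is a
#' single classed object with `print`, `summary` and `plot` methods, and can
#' be serialized to delimited text plus a JSON manifest with
#' [write_report()].
#'
#' @param records A `tree_records` data frame (e.g. from
#'   [read_inventory()], [generate_census()] or
#'   [apply_measurement_protocol()]), or a path to an inventory file.
#' @param design A [survey_design()].
#' @param thresholds A [rarity_thresholds()].
#' @param policy A [timber_policy()]; used only when `species_meta` is
#'   given.
#' @param species_meta Optional species metadata table (canonical
#'   `species`, `is_timber`, optional `min_felling_dbh_cm`); enables the
#'   harvest screen.
#' @param unit Occupancy unit for the geographic-range criterion
#'   (`"cluster"` default).
#' @param total_units Total surveyed units for the occupancy denominator.
#'   Defaults to the units present in the records, or to the full sampling
#'   frame when the records carry a `"layout"` attribute (as synthetic
#'   censuses do).
#' @return An object of class `"woodland_assessment"`.
#' @examples
#' cen <- generate_census(community_params(n_species = 40, seed = 2))
#' res <- run_pipeline(cen$records)
#' summary(res)
#' @export
run_pipeline <- function(records,
                         design = survey_design(),
                         thresholds = rarity_thresholds(),
                         policy = timber_policy(),
                         species_meta = NULL,
                         unit = c("cluster", "plot"),
                         total_units = NULL) {
  unit <- match.arg(unit)
  if (is.character(records) && length(records) == 1L) {
    records <- read_inventory(records, design)
  }
  if (nrow(records) == 0L) stop("pipeline aborted at stage 'input': no records")
  layout <- attr(records, "layout")
  if (is.null(total_units)) {
    total_units <- if (!is.null(layout)) {
      length(unique(if (unit == "cluster") layout$cluster
                    else plot_uid(layout)))
    } else {
      length(unique(if (unit == "cluster") records$cluster
                    else plot_uid(records)))
    }
  }

  habitats_present <- sort(unique(records$habitat))
  profiles <- build_profiles(records, unit, total_units = total_units,
                             habitats = habitats_present)

  comm <- community_matrix(records, "habitat")
  richness <- richness_by_site(comm)

  pres <- (comm > 0) + 0L
  beta_pairwise <- if (nrow(comm) >= 2L) beta_pairwise_table(pres) else NULL
  beta_multisite <- if (nrow(comm) >= 2L) multisite_beta(pres) else NULL

  # compositional dissimilarity between strata inside vs outside PAs
  beta_pa <- NULL
  pa_rows <- list()
  for (h in c(habitats_present, if (length(habitats_present) > 1) "all")) {
    sub <- if (h == "all") records else
      records[records$habitat == h, , drop = FALSE]
    sp_in <- unique(sub$species[sub$in_pa])
    sp_out <- unique(sub$species[!sub$in_pa])
    if (length(sp_in) == 0L || length(sp_out) == 0L) next
    b <- pairwise_beta(sp_in, sp_out)
    pa_rows[[length(pa_rows) + 1L]] <-
      data.frame(habitat = h, total = b$total, turnover = b$turnover,
                 nestedness = b$nestedness, stringsAsFactors = FALSE)
  }
  if (length(pa_rows)) beta_pa <- do.call(rbind, pa_rows)

  rarity <- assess_rarity(profiles, thresholds,
                          n_habitats_region = length(habitats_present))
  rarity_summary <- summarize_rarity(rarity)

  harvest <- NULL
  if (!is.null(species_meta)) {
    harvest <- assess_harvest(records, rarity, species_meta, profiles,
                              policy, design)
  }

  manifest <- list(
    package = "rarewoods",
    package_version = as.character(utils::packageVersion("rarewoods")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    n_records = nrow(records),
    n_species = nrow(profiles),
    habitats = habitats_present,
    occupancy_unit = unit,
    total_units = total_units,
    design = unclass(design),
    thresholds = unclass(thresholds),
    policy = if (is.null(species_meta)) NULL else unclass(policy))

  structure(list(profiles = profiles, richness = richness,
                 beta_pairwise = beta_pairwise,
                 beta_multisite = beta_multisite,
                 beta_pa = beta_pa,
                 rarity = rarity, rarity_summary = rarity_summary,
                 harvest = harvest, manifest = manifest),
            class = "woodland_assessment")
}

#' @export
print.woodland_assessment <- function(x, ...) {
  m <- x$manifest
  cat("Woodland species assessment\n")
  cat(sprintf("  %d records, %d species, %d %ss surveyed\n",
              m$n_records, m$n_species, m$total_units, m$occupancy_unit))
  cat(sprintf("  rare species: %d of %d (%.0f%%)\n",
              x$rarity_summary$n_rare, x$rarity_summary$n_species,
              100 * x$rarity_summary$n_rare / x$rarity_summary$n_species))
  if (!is.null(x$beta_multisite)) {
    cat(sprintf("  multiple-site dissimilarity: %.2f (turnover %.2f, nestedness %.2f)\n",
                x$beta_multisite$total, x$beta_multisite$turnover,
                x$beta_multisite$nestedness))
  }
  if (!is.null(x$harvest)) {
    cat(sprintf("  harvest-eligible species x habitat combinations: %d of %d\n",
                sum(x$harvest$eligible), nrow(x$harvest)))
  }
  invisible(x)
}

#' @export
summary.woodland_assessment <- function(object, ...) {
  print(object)
  cat("\nRichness by habitat:\n")
  print(object$richness, digits = 4)
  cat("\nSpecies per rarity form:\n")
  print(object$rarity_summary$by_form)
  cat("\nSpecies per protection status:\n")
  print(object$rarity_summary$by_protection)
  if (!is.null(object$beta_pairwise)) {
    cat("\nPairwise beta-diversity partition:\n")
    print(object$beta_pairwise, digits = 3)
  }
  invisible(object)
}

#' @export
plot.woodland_assessment <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2), mar = c(6, 4, 3, 1))
  on.exit(graphics::par(old))
  bf <- x$rarity_summary$by_form
  graphics::barplot(stats::setNames(bf$count, bf$level), las = 2,
                    main = "Species per rarity form", ylab = "species", ...)
  bp <- x$rarity_summary$by_protection
  graphics::barplot(stats::setNames(bp$count, bp$level), las = 2,
                    main = "Protection status", ylab = "species", ...)
  invisible(x)
}

#' Write an assessment report bundle
#'
#' Serializes a [run_pipeline()] result to a directory of delimited text
#' tables (`richness.csv`, `beta_pairwise.csv`, `beta_multisite.csv`,
#' `beta_protected.csv`, `rarity.csv`, `summary_forms.csv`,
#' `summary_protection.csv`, `harvest.csv` when present) plus a JSON run
#' manifest recording inputs, thresholds and versions. Output is a pure
#' function of the assessment object: re-writing the same object yields
#' byte-identical files.
#'
#' @param x A `woodland_assessment`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(x, dir) {
  stopifnot(inherits(x, "woodland_assessment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE)
  }
  w(x$richness, "richness.csv")
  if (!is.null(x$beta_pairwise)) w(x$beta_pairwise, "beta_pairwise.csv")
  if (!is.null(x$beta_multisite)) {
    w(data.frame(total = x$beta_multisite$total,
                 turnover = x$beta_multisite$turnover,
                 nestedness = x$beta_multisite$nestedness),
      "beta_multisite.csv")
  }
  if (!is.null(x$beta_pa)) w(x$beta_pa, "beta_protected.csv")
  w(x$rarity, "rarity.csv")
  w(x$rarity_summary$by_form, "summary_forms.csv")
  w(x$rarity_summary$by_protection, "summary_protection.csv")
  if (!is.null(x$harvest)) w(as.data.frame(x$harvest), "harvest.csv")
  jsonlite::write_json(x$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
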