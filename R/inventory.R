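#' Survey design for nested cluster-plot inventories
#'
#' Describes the measurement protocol of a cluster-plot inventory: square
#' clusters of rectangular plots in which every stem above a full-census DBH
#' threshold is recorded over the whole plot, while small stems are recorded
#' only in one subplot covering a known fraction of the plot area. The design
#' supplies the expansion weights that put subplot-only records back on the
#' per-plot scale.
#'
#' @param plot_area_ha Area of one plot in hectares. Default 0.1 ha
#'   (a 50 x 20 m plot).
#' @param subplot_fraction Fraction of the plot covered by the small-stem
#'   subplot, in (0, 1]. Default 0.25 (one 25 x 10 m subplot).
#' @param small_tree_range_cm Half-open DBH interval `[lo, hi)` in cm measured
#'   only inside the subplot. Default `c(5, 10)`: stems with 5 <= DBH < 10 cm
#'   are subplot-only; stems >= 10 cm are censused over the full plot.
#' @param habitats Character vector of admissible habitat labels.
#' @param plots_per_cluster Number of plots per cluster (default 4).
#'
#' @return An object of class `"survey_design"`.
#' @examples
#' d <- survey_design()
#' expansion_factor(c(7, 12), d)
#' @export
survey_design <- function(plot_area_ha = 0.1,
                          subplot_fraction = 0.25,
                          small_tree_range_cm = c(5, 10),
                          habitats = c("humid", "semi-arid", "rainy"),
                          plots_per_cluster = 4L) {
  stopifnot(is.numeric(plot_area_ha), length(plot_area_ha) == 1L,
            plot_area_ha > 0)
  stopifnot(is.numeric(subplot_fraction), length(subplot_fraction) == 1L,
            subplot_fraction > 0, subplot_fraction <= 1)
  stopifnot(is.numeric(small_tree_range_cm), length(small_tree_range_cm) == 2L,
            small_tree_range_cm[1] >= 0,
            small_tree_range_cm[1] < small_tree_range_cm[2])
  stopifnot(is.character(habitats), length(habitats) >= 1L,
            !anyDuplicated(habitats))
  structure(
    list(plot_area_ha = plot_area_ha,
         subplot_fraction = subplot_fraction,
         small_tree_range_cm = small_tree_range_cm,
         habitats = habitats,
         plots_per_cluster = as.integer(plots_per_cluster)),
    class = "survey_design")
}

#' @export
print.survey_design <- function(x, ...) {
  cat("Cluster-plot survey design\n")
  cat(sprintf("  plot area:         %.3g ha\n", x$plot_area_ha))
  cat(sprintf("  subplot fraction:  %.3g (expansion factor %.3g)\n",
              x$subplot_fraction, 1 / x$subplot_fraction))
  cat(sprintf("  subplot-only DBH:  [%g, %g) cm\n",
              x$small_tree_range_cm[1], x$small_tree_range_cm[2]))
  cat(sprintf("  habitats:          %s\n", paste(x$habitats, collapse = ", ")))
  invisible(x)
}

#' Canonicalize species names
#'
#' Trims leading/trailing whitespace, collapses internal whitespace runs to a
#' single space, and case-folds to lower case, so that joins between the
#' inventory and species metadata are deterministic. No fuzzy matching is
#' attempted.
#'
#' @param x Character vector of species names.
#' @return Character vector of canonical names.
#' @examples
#' normalize_species(c("  Brachystegia   spiciformis ", "BRACHYSTEGIA boehmii"))
#' @export
normalize_species <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  tolower(x)
}

# Parse the accepted protected-area flag spellings; NA for anything else.
parse_pa_flag <- function(x) {
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("1", "true", "yes")] <- TRUE
  out[v %in% c("0", "false", "no")] <- FALSE
  out
}

# Detect the field separator of a delimited text file from its header line.
detect_sep <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a tree-record inventory file
#'
#' Reads a delimited text file (comma or tab separated, autodetected) with one
#' row per measured stem and validates every row against the survey design.
#' Required columns: `cluster`, `plot`, `habitat`, `protected_area`,
#' `species`, `dbh_cm`. Optional columns: `subplot`, `stem_form`.
#'
#' Rows that fail validation (non-numeric or sub-threshold DBH, unknown
#' habitat, unparseable protected-area flag, empty species, bad stem form)
#' are dropped with a warning naming the offending rows; the dropped rows and
#' their reasons are attached as attribute `"rejected"`. Stems at or above
#' the full-census threshold with no stem-form score are kept (field data can
#' be incomplete) and counted in a separate warning.
#'
#' @param path Path to the inventory file.
#' @param design A [survey_design()].
#' @return A `data.frame` of validated tree records with columns `cluster`,
#'   `plot`, `subplot`, `habitat`, `in_pa`, `species`, `dbh_cm`, `stem_form`,
#'   of class `c("tree_records", "data.frame")`.
#' @examples
#' path <- system.file("extdata", "mini_inventory.csv", package = "rarewoods")
#' inv <- read_inventory(path, survey_design())
#' head(inv)
#' @export
read_inventory <- function(path, design = survey_design()) {
  stopifnot(file.exists(path))
  sep <- detect_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "", fill = TRUE,
                           fileEncoding = "UTF-8",
                           colClasses = "character")
  names(raw) <- tolower(trimws(names(raw)))
  required <- c("cluster", "plot", "habitat", "protected_area",
                "species", "dbh_cm")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("inventory file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(raw)
  rec <- data.frame(
    cluster   = trimws(raw$cluster),
    plot      = trimws(raw$plot),
    subplot   = if ("subplot" %in% names(raw))
                  trimws(raw$subplot) else rep(NA_character_, n),
    habitat   = trimws(raw$habitat),
    in_pa     = parse_pa_flag(raw$protected_area),
    species   = normalize_species(raw$species),
    dbh_cm    = suppressWarnings(as.numeric(raw$dbh_cm)),
    stem_form = if ("stem_form" %in% names(raw))
                  toupper(trimws(raw$stem_form)) else rep(NA_character_, n),
    stringsAsFactors = FALSE)
  rec$subplot[!is.na(rec$subplot) & rec$subplot == ""] <- NA_character_
  rec$stem_form[!is.na(rec$stem_form) & rec$stem_form == ""] <- NA_character_
  rec$dbh_cm <- round(rec$dbh_cm, 1)

  lo <- design$small_tree_range_cm[1]
  reasons <- character(n)
  flag <- function(bad, why) {
    bad <- which(bad & !nzchar(reasons))
    reasons[bad] <<- why
  }
  flag(is.na(rec$dbh_cm), "dbh_cm is not numeric")
  flag(!is.na(rec$dbh_cm) & rec$dbh_cm < lo,
       sprintf("dbh_cm below census threshold (%g cm)", lo))
  flag(!(rec$habitat %in% design$habitats), "unknown habitat label")
  flag(is.na(rec$in_pa), "unparseable protected_area flag")
  flag(!nzchar(rec$species), "empty species name")
  flag(!is.na(rec$stem_form) & !(rec$stem_form %in% c("SF1", "SF2", "SF3")),
       "stem_form not one of SF1/SF2/SF3")

  bad <- nzchar(reasons)
  if (any(bad)) {
    rejected <- data.frame(row = which(bad), reason = reasons[bad],
                           stringsAsFactors = FALSE)
    warning(sprintf("rejected %d row(s): %s", sum(bad),
                    paste(sprintf("row %d (%s)", rejected$row,
                                  rejected$reason),
                          collapse = "; ")))
  } else {
    rejected <- data.frame(row = integer(), reason = character(),
                           stringsAsFactors = FALSE)
  }
  rec <- rec[!bad, , drop = FALSE]
  rownames(rec) <- NULL

  full_threshold <- design$small_tree_range_cm[2]
  n_missing_sf <- sum(rec$dbh_cm >= full_threshold & is.na(rec$stem_form))
  if (n_missing_sf > 0L) {
    warning(sprintf(
      "%d stem(s) at DBH >= %g cm have no stem_form score; kept with stem_form absent",
      n_missing_sf, full_threshold))
  }
  attr(rec, "rejected") <- rejected
  class(rec) <- c("tree_records", "data.frame")
  rec
}

#' Per-record expansion factor
#'
#' Design weight converting a record to its plot-scale stem count. Stems in
#' the subplot-only DBH range represent `1 / subplot_fraction` stems at plot
#' scale; all other stems represent themselves. The subplot-only interval is
#' half-open, so a stem exactly at the full-census threshold gets weight 1.
#'
#' @param dbh_cm Numeric vector of DBH values in cm (or a `tree_records`
#'   data frame, from which `dbh_cm` is taken).
#' @param design A [survey_design()].
#' @return Numeric vector of expansion factors (>= 1).
#' @examples
#' expansion_factor(c(7, 10, 55), survey_design())  # 4 1 1
#' @export
expansion_factor <- function(dbh_cm, design = survey_design()) {
  if (is.data.frame(dbh_cm)) dbh_cm <- dbh_cm$dbh_cm
  stopifnot(is.numeric(dbh_cm))
  lo <- design$small_tree_range_cm[1]
  hi <- design$small_tree_range_cm[2]
  if (any(dbh_cm < lo, na.rm = TRUE)) {
    stop(sprintf("stem(s) with DBH below the census threshold (%g cm)", lo))
  }
  ifelse(dbh_cm >= lo & dbh_cm < hi, 1 / design$subplot_fraction, 1)
}

#' Expansion-weighted stem density
#'
#' Stems per hectare over a set of surveyed plots: the sum of per-record
#' expansion factors divided by the surveyed area `n_plots * plot_area_ha`.
#' Subplot-only small stems are expanded to plot scale; full-census stems
#' count once.
#'
#' @param records A `tree_records` data frame (possibly filtered to one
#'   species, habitat or stratum). May have zero rows.
#' @param n_plots Number of plots over which the records were collected
#'   (the denominator area is `n_plots * plot_area_ha`), regardless of how
#'   many of them contained records.
#' @param design A [survey_design()].
#' @return Stem density in stems per hectare.
#' @examples
#' d <- survey_design()
#' rec <- data.frame(dbh_cm = c(7, 12, 30))
#' stems_per_ha(rec, n_plots = 10, design = d)  # (4+1+1)/1 ha = 6
#' @export
stems_per_ha <- function(records, n_plots, design = survey_design()) {
  stopifnot(is.numeric(n_plots), length(n_plots) == 1L)
  if (n_plots <= 0) stop("n_plots must be a positive integer")
  if (nrow(records) == 0L) return(0)
  sum(expansion_factor(records$dbh_cm, design)) / (n_plots * design$plot_area_ha)
}

# Plot-level unique identifier: plots are only unique within a cluster.
plot_uid <- function(records) paste(records$cluster, records$plot, sep = "\r")

#' Aggregate tree records into per-species profiles
#'
#' Summarizes an inventory into the per-species quantities that drive the
#' rarity classification and the protection index: abundance per habitat,
#' occupied spatial units (clusters by default), and plot-level occurrence
#' counts inside and outside protected areas. All counts are raw record
#' counts; no expansion weighting is applied (rarity criteria refer to
#' recorded individuals, not per-area densities).
#'
#' An "occurrence" is a plot-level presence: a species seen in a plot counts
#' once for that plot no matter how many stems were recorded there.
#'
#' @param records A `tree_records` data frame.
#' @param unit Spatial unit for geographic occupancy: `"cluster"` (default;
#'   clusters are the spatially independent sampling locations) or `"plot"`.
#' @param total_units Total number of surveyed units (the occupancy
#'   denominator). Defaults to the number of distinct units present in
#'   `records`; pass the design total explicitly when some surveyed units
#'   hold no records.
#' @param habitats Habitat labels defining the columns of the abundance
#'   table; defaults to the habitats present in `records`.
#' @return A `data.frame` of class `"species_profiles"` with one row per
#'   species and columns `species`, `total_abundance`, `n_habitats`,
#'   `max_habitat_abundance`, `occupied_units`, `total_units`,
#'   `occurrences_in_pa`, `occurrences_total`, plus the per-habitat abundance
#'   matrix as attribute `"abundance_by_habitat"`.
#' @examples
#' rec <- data.frame(cluster = "c1", plot = c("p1", "p1", "p2"),
#'                   habitat = "humid", in_pa = c(TRUE, TRUE, FALSE),
#'                   species = "sp a", dbh_cm = c(7, 12, 15))
#' build_profiles(rec)
#' @export
build_profiles <- function(records, unit = c("cluster", "plot"),
                           total_units = NULL, habitats = NULL) {
  unit <- match.arg(unit)
  if (nrow(records) == 0L) {
    out <- data.frame(species = character(), total_abundance = integer(),
                      n_habitats = integer(), max_habitat_abundance = integer(),
                      occupied_units = integer(), total_units = integer(),
                      occurrences_in_pa = integer(),
                      occurrences_total = integer(),
                      stringsAsFactors = FALSE)
    class(out) <- c("species_profiles", "data.frame")
    return(out)
  }
  if (is.null(habitats)) habitats <- sort(unique(records$habitat))
  sp <- factor(records$species, levels = sort(unique(records$species)))
  hab <- factor(records$habitat, levels = habitats)
  ab <- table(sp, hab)  # species x habitat abundance

  unit_id <- if (unit == "cluster") records$cluster else plot_uid(records)
  if (is.null(total_units)) total_units <- length(unique(unit_id))
  occupied <- tapply(unit_id, sp, function(u) length(unique(u)))
  if (any(occupied > total_units)) {
    stop("total_units is smaller than the number of occupied units")
  }

  puid <- plot_uid(records)
  pa_of_plot <- tapply(records$in_pa, puid, any)  # PA is a plot property
  first <- !duplicated(paste(as.character(sp), puid, sep = "\r"))
  occ_sp <- factor(records$species[first], levels = levels(sp))
  occ_in_pa <- as.logical(pa_of_plot[puid[first]])
  occ_total <- table(occ_sp)
  occ_pa <- table(occ_sp[occ_in_pa])

  out <- data.frame(
    species = levels(sp),
    total_abundance = as.integer(rowSums(ab)),
    n_habitats = as.integer(rowSums(ab > 0)),
    max_habitat_abundance = as.integer(apply(ab, 1, max)),
    occupied_units = as.integer(occupied[levels(sp)]),
    total_units = as.integer(total_units),
    occurrences_in_pa = as.integer(occ_pa),
    occurrences_total = as.integer(occ_total),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "abundance_by_habitat") <- unclass(ab)
  attr(out, "unit") <- unit
  class(out) <- c("species_profiles", "data.frame")
  out
}

#' Sites-by-species community matrix
#'
#' Cross-tabulates records into a sites x species count matrix, where a site
#' is defined by one or more grouping columns of the record table (default
#' the habitat; use `c("habitat", "in_pa")` for habitat-by-protection
#' strata). Use `presence = TRUE` for the 0/1 indicator matrix used by the
#' beta-diversity routines.
#'
#' @param records A `tree_records` data frame.
#' @param site_by Character vector of column names whose combination defines
#'   a site, or a vector of site labels with one element per record.
#' @param presence Return the presence/absence indicator instead of counts.
#' @return An integer matrix, sites in rows, species in columns.
#' @examples
#' rec <- data.frame(cluster = "c", plot = "p",
#'                   habitat = c("humid", "humid", "rainy"),
#'                   in_pa = FALSE, species = c("a", "b", "a"),
#'                   dbh_cm = 12)
#' community_matrix(rec)
#' @export
community_matrix <- function(records, site_by = "habitat", presence = FALSE) {
  if (is.character(site_by) && all(site_by %in% names(records))) {
    site <- do.call(paste, c(records[site_by], sep = ":"))
  } else if (length(site_by) == nrow(records)) {
    site <- as.character(site_by)
  } else {
    stop("site_by must name columns of `records` or give one site per record")
  }
  if (anyNA(site)) stop("record(s) with no site assignment")
  m <- table(factor(site), factor(records$species))
  m <- matrix(as.integer(m), nrow = nrow(m),
              dimnames = dimnames(m))
  if (presence) m <- (m > 0L) + 0L
  m
}

#' Read a species metadata table
#'
#' Reads a delimited text file with columns `species`, `is_timber`,
#' `commercial_class`, `min_felling_dbh_cm`. Species names are canonicalized
#' with [normalize_species()] so the table joins deterministically against
#' inventory records.
#'
#' @param path Path to the metadata file (comma or tab separated).
#' @return A `data.frame` with canonical `species`, logical `is_timber`,
#'   `commercial_class`, numeric `min_felling_dbh_cm` (NA where unspecified).
#' @export
read_species_metadata <- function(path) {
  stopifnot(file.exists(path))
  sep <- detect_sep(path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           fileEncoding = "UTF-8",
                           colClasses = "character")
  names(raw) <- tolower(trimws(names(raw)))
  required <- c("species", "is_timber")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("species metadata is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  out <- data.frame(
    species = normalize_species(raw$species),
    is_timber = parse_pa_flag(raw$is_timber),  # same boolean spellings
    commercial_class = if ("commercial_class" %in% names(raw))
      trimws(raw$commercial_class) else NA_character_,
    min_felling_dbh_cm = if ("min_felling_dbh_cm" %in% names(raw))
      suppressWarnings(as.numeric(raw$min_felling_dbh_cm)) else NA_real_,
    stringsAsFactors = FALSE)
  if (anyNA(out$is_timber)) {
    stop("unparseable is_timber flag in row(s): ",
         paste(which(is.na(out$is_timber)), collapse = ", "))
  }
  if (anyDuplicated(out$species)) {
    stop("duplicated species in metadata: ",
         paste(unique(out$species[duplicated(out$species)]), collapse = ", "))
  }
  out
}
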