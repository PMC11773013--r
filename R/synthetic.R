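#' Parameters for the synthetic community generator
#'
#' Describes a woodland community and sampling frame from which
#' [generate_census()] simulates inventories with known ground truth. The
#' defaults emulate the statistical structure the analysis assumes at desk
#' scale: three habitats sampled with cluster plots in roughly 72/20/8
#' proportions, plot-level protected-area membership around a quarter of
#' plots, a strongly right-skewed lognormal species-abundance distribution
#' (many singletons and doubletons, few dominants), a mix of habitat
#' specialists and generalists and of narrow and widespread ranges, a
#' small-stem-dominated truncated-Weibull DBH distribution, and stem-form
#' frequencies that deteriorate with diameter.
#'
#' @param n_species Number of species in the regional pool.
#' @param habitats Habitat labels.
#' @param clusters_per_habitat Named integer vector: clusters sampled per
#'   habitat.
#' @param plots_per_cluster Plots per cluster (default 4).
#' @param pa_fraction Named numeric vector: probability that a plot lies
#'   inside a protected area, per habitat.
#' @param abundance_log_mean,abundance_log_sd Meanlog/sdlog of the lognormal
#'   regional abundance distribution (rounded, minimum 1).
#' @param specialist_fraction Fraction of species restricted to a single
#'   habitat.
#' @param narrow_range_fraction Fraction of species with geographically
#'   narrow ranges.
#' @param narrow_range_max_units Maximum number of clusters a narrow-ranged
#'   species may occupy. Default: 10 percent of all clusters (at least 1).
#' @param dbh_weibull_shape,dbh_weibull_scale Weibull parameters of the DBH
#'   distribution in cm, left-truncated at 5 cm.
#' @param stem_form_probs Matrix of SF1/SF2/SF3 probabilities (columns) per
#'   DBH class (rows; classes `[10,20)`, `[20,30)`, `[30,40)`, `[40,Inf)`).
#'   Each row must sum to 1.
#' @param timber_fraction Fraction of species flagged as commercial timber.
#' @param mfd_cm Minimum felling diameter assigned to timber species.
#' @param seed Integer seed making the census reproducible.
#' @return An object of class `"community_params"`.
#' @export
community_params <- function(n_species = 200L,
                             habitats = c("humid", "semi-arid", "rainy"),
                             clusters_per_habitat = c(54L, 15L, 6L),
                             plots_per_cluster = 4L,
                             pa_fraction = c(0.24, 0.20, 0.27),
                             abundance_log_mean = 3.0,
                             abundance_log_sd = 2.2,
                             specialist_fraction = 0.4,
                             narrow_range_fraction = 0.33,
                             narrow_range_max_units = NULL,
                             dbh_weibull_shape = 1.3,
                             dbh_weibull_scale = 12,
                             stem_form_probs = default_stem_form_probs(),
                             timber_fraction = 0.22,
                             mfd_cm = 40,
                             seed = 1L) {
  if (is.null(names(clusters_per_habitat)))
    names(clusters_per_habitat) <- habitats
  if (is.null(names(pa_fraction))) names(pa_fraction) <- habitats
  stopifnot(n_species >= 1, length(habitats) >= 1,
            all(habitats %in% names(clusters_per_habitat)),
            all(habitats %in% names(pa_fraction)),
            all(clusters_per_habitat >= 1), plots_per_cluster >= 1,
            all(pa_fraction >= 0 & pa_fraction <= 1),
            abundance_log_sd > 0,
            specialist_fraction >= 0, specialist_fraction <= 1,
            narrow_range_fraction >= 0, narrow_range_fraction <= 1,
            dbh_weibull_shape > 0, dbh_weibull_scale > 0,
            timber_fraction >= 0, timber_fraction <= 1, mfd_cm > 0)
  total_clusters <- sum(clusters_per_habitat[habitats])
  if (is.null(narrow_range_max_units)) {
    narrow_range_max_units <- max(1L, floor(0.10 * total_clusters))
  }
  if (narrow_range_max_units > total_clusters) {
    stop("narrow_range_max_units exceeds the number of available clusters")
  }
  stopifnot(is.matrix(stem_form_probs), ncol(stem_form_probs) == 3L)
  if (any(abs(rowSums(stem_form_probs) - 1) > 1e-9)) {
    stop("each row of stem_form_probs must sum to 1")
  }
  structure(list(n_species = as.integer(n_species), habitats = habitats,
                 clusters_per_habitat = clusters_per_habitat,
                 plots_per_cluster = as.integer(plots_per_cluster),
                 pa_fraction = pa_fraction,
                 abundance_log_mean = abundance_log_mean,
                 abundance_log_sd = abundance_log_sd,
                 specialist_fraction = specialist_fraction,
                 narrow_range_fraction = narrow_range_fraction,
                 narrow_range_max_units = as.integer(narrow_range_max_units),
                 dbh_weibull_shape = dbh_weibull_shape,
                 dbh_weibull_scale = dbh_weibull_scale,
                 stem_form_probs = stem_form_probs,
                 timber_fraction = timber_fraction,
                 mfd_cm = mfd_cm,
                 seed = seed),
            class = "community_params")
}

#' Default DBH-class-conditional stem-form probabilities
#'
#' SF1/SF2/SF3 frequencies per DBH class used by the generator: straight
#' stems dominate the small classes and deteriorate with diameter, with the
#' harvestable class (>= 40 cm) holding the largest crooked-stem share.
#' @return A 4 x 3 probability matrix.
#' @export
default_stem_form_probs <- function() {
  m <- rbind("[10,20)" = c(0.74, 0.17, 0.09),
             "[20,30)" = c(0.72, 0.19, 0.09),
             "[30,40)" = c(0.69, 0.07, 0.24),
             "[40,Inf)" = c(0.47, 0.20, 0.33))
  colnames(m) <- c("SF1", "SF2", "SF3")
  m
}

# sample() without its scalar-x surprise: always samples from the vector x.
resample <- function(x, n = 1L) x[sample.int(length(x), n)]

# Truncated Weibull sampler: X | X >= lo, via inverse CDF.
rweibull_trunc <- function(n, shape, scale, lo) {
  p_lo <- stats::pweibull(lo, shape, scale)
  u <- stats::runif(n, p_lo, 1)
  stats::qweibull(u, shape, scale)
}

sf_class_index <- function(dbh) {
  findInterval(dbh, c(10, 20, 30, 40))  # 0 below 10, else class 1..4
}

#' Generate a complete synthetic census with ground truth
#'
#' Simulates a full enumeration (every stem >= 5 cm DBH recorded over whole
#' plots) of a synthetic woodland community, together with a truth table
#' giving each species' realized range occupancy, habitats, abundance,
#' density and the rarity form obtained by applying `thresholds` to the
#' realized (census) quantities. Species ranges are contiguous cluster
#' blocks within each habitat, producing spatial aggregation; stems are
#' placed uniformly over the plots of the range.
#'
#' @param params A [community_params()].
#' @param design A [survey_design()]; supplies plot area for densities.
#' @param thresholds A [rarity_thresholds()] used to derive the true rarity
#'   form from the realized census quantities.
#' @return A list of class `"synthetic_census"` with elements
#'   `records` (a `tree_records` data frame with attribute `"layout"`, the
#'   full plot table) and `truth` (one row per species: `species`,
#'   `true_range_units`, `true_n_habitats`, `true_total_abundance`,
#'   `true_max_habitat_abundance`, `true_rarity_form`, `is_timber`,
#'   `mfd_cm`, plus `true_density_<habitat>` columns in stems/ha).
#' @examples
#' cen <- generate_census(community_params(n_species = 20, seed = 7))
#' nrow(cen$truth)
#' @export
generate_census <- function(params = community_params(),
                            design = survey_design(
                              habitats = params$habitats,
                              plots_per_cluster = params$plots_per_cluster),
                            thresholds = rarity_thresholds()) {
  if (!is.null(params$seed)) set.seed(params$seed)
  H <- length(params$habitats)

  # sampling frame: clusters and plots with PA membership
  layout <- do.call(rbind, lapply(params$habitats, function(h) {
    K <- params$clusters_per_habitat[[h]]
    cl <- sprintf("%s_c%03d", h, seq_len(K))
    data.frame(cluster = rep(cl, each = params$plots_per_cluster),
               plot = rep(sprintf("p%d", seq_len(params$plots_per_cluster)),
                          times = K),
               habitat = h, stringsAsFactors = FALSE)
  }))
  layout$in_pa <- stats::runif(nrow(layout)) <
    params$pa_fraction[layout$habitat]

  sp_names <- sprintf("sp%03d", seq_len(params$n_species))
  n_spec <- round(params$specialist_fraction * params$n_species)
  is_specialist <- seq_len(params$n_species) <= n_spec
  abund <- pmax(1, round(stats::rlnorm(params$n_species,
                                       params$abundance_log_mean,
                                       params$abundance_log_sd)))
  # abundance-occupancy coupling: narrow ranges fall mostly on regionally
  # scarce species, but locally abundant narrow-ranged species stay possible
  n_narrow <- round(params$narrow_range_fraction * params$n_species)
  is_narrow <- rep(FALSE, params$n_species)
  if (n_narrow > 0) {
    w <- rank(-abund, ties.method = "average")
    is_narrow[sample.int(params$n_species, n_narrow, prob = w)] <- TRUE
  }

  clusters_of <- split(unique(layout$cluster), rep(params$habitats,
                       params$clusters_per_habitat[params$habitats]))

  rec_list <- vector("list", params$n_species)
  truth_rows <- vector("list", params$n_species)
  is_timber <- rep(FALSE, params$n_species)
  is_timber[sample.int(params$n_species,
                       round(params$timber_fraction * params$n_species))] <- TRUE

  for (s in seq_len(params$n_species)) {
    n_hab <- if (is_specialist[s] || H == 1) 1L else resample(2:H)
    habs <- resample(params$habitats, n_hab)
    # contiguous cluster block per habitat; narrow species get a small total
    if (is_narrow[s]) {
      total_range <- sample.int(params$narrow_range_max_units, 1L)
    } else {
      avail <- sum(lengths(clusters_of[habs]))
      lo <- min(avail, params$narrow_range_max_units + 1L)
      total_range <- resample(seq(lo, avail))
    }
    # split the range among habitats proportionally to their cluster counts
    sizes <- lengths(clusters_of[habs])
    take <- pmin(sizes, pmax(1L, round(total_range * sizes / sum(sizes))))
    range_clusters <- unlist(lapply(seq_along(habs), function(k) {
      K <- sizes[[k]]
      w <- take[[k]]
      start <- sample.int(K - w + 1L, 1L)
      clusters_of[[habs[k]]][start:(start + w - 1L)]
    }), use.names = FALSE)

    range_plots <- layout[layout$cluster %in% range_clusters, , drop = FALSE]
    pick <- range_plots[sample.int(nrow(range_plots), abund[s],
                                   replace = TRUE), , drop = FALSE]
    dbh <- round(rweibull_trunc(abund[s], params$dbh_weibull_shape,
                                params$dbh_weibull_scale,
                                design$small_tree_range_cm[1]), 1)
    cls <- sf_class_index(dbh)
    sf <- rep(NA_character_, abund[s])
    for (ci in seq_len(nrow(params$stem_form_probs))) {
      idx <- which(cls == ci)
      if (length(idx)) {
        sf[idx] <- sample(c("SF1", "SF2", "SF3"), length(idx),
                          replace = TRUE,
                          prob = params$stem_form_probs[ci, ])
      }
    }
    rec_list[[s]] <- data.frame(cluster = pick$cluster, plot = pick$plot,
                                subplot = NA_character_,
                                habitat = pick$habitat, in_pa = pick$in_pa,
                                species = sp_names[s], dbh_cm = dbh,
                                stem_form = sf, stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, rec_list)
  rownames(records) <- NULL

  total_clusters <- length(unique(layout$cluster))
  area_by_hab <- tapply(rep(design$plot_area_ha, nrow(layout)),
                        layout$habitat, sum)

  for (s in seq_len(params$n_species)) {
    r <- rec_list[[s]]
    occ_units <- length(unique(r$cluster))
    hab_ab <- table(factor(r$habitat, levels = params$habitats))
    n_hab_real <- sum(hab_ab > 0)
    max_hab <- max(hab_ab)
    total_ab <- nrow(r)
    crit_ab <- if (thresholds$abundance_scope == "max_per_habitat")
      max_hab else total_ab
    form <- rabinowitz_form(
      wide = occ_units / total_clusters > thresholds$wide_range_min_prop,
      various = n_hab_real >= thresholds$habitat_various_min,
      large = crit_ab >= thresholds$abundance_large_min)
    dens <- as.numeric(hab_ab) / as.numeric(area_by_hab[params$habitats])
    row <- data.frame(species = sp_names[s],
                      true_range_units = occ_units,
                      true_n_habitats = n_hab_real,
                      true_total_abundance = total_ab,
                      true_max_habitat_abundance = as.integer(max_hab),
                      true_rarity_form = form,
                      is_timber = is_timber[s],
                      mfd_cm = params$mfd_cm,
                      stringsAsFactors = FALSE)
    for (k in seq_along(params$habitats)) {
      row[[paste0("true_density_", params$habitats[k])]] <- dens[k]
    }
    truth_rows[[s]] <- row
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL

  attr(records, "layout") <- layout
  class(records) <- c("tree_records", "data.frame")
  structure(list(records = records, truth = truth, params = params),
            class = "synthetic_census")
}

#' @export
print.synthetic_census <- function(x, ...) {
  cat(sprintf("synthetic census: %d stems, %d species, %d clusters, %d plots\n",
              nrow(x$records), nrow(x$truth),
              length(unique(attr(x$records, "layout")$cluster)),
              nrow(attr(x$records, "layout"))))
  print(table(x$truth$true_rarity_form))
  invisible(x)
}

#' Apply the subplot measurement protocol to a census
#'
#' Simulates field measurement of a complete census under the cluster-plot
#' protocol: stems at or above the full-census DBH threshold are always
#' recorded, while small stems (in the subplot-only DBH range) are retained
#' independently with probability `subplot_fraction` and flagged as subplot
#' records. Independent thinning stands in for explicit within-plot
#' geometry: the analysis only ever uses the inclusion probability, which
#' the thinning reproduces exactly.
#'
#' @param census A `tree_records` data frame (a full enumeration) or a
#'   `synthetic_census`.
#' @param design A [survey_design()].
#' @param seed Optional integer seed for the thinning draw.
#' @return A `tree_records` data frame; small retained stems have
#'   `subplot == "A"`.
#' @export
apply_measurement_protocol <- function(census, design = survey_design(),
                                       seed = NULL) {
  if (inherits(census, "synthetic_census")) census <- census$records
  if (!is.null(seed)) set.seed(seed)
  lo <- design$small_tree_range_cm[1]
  hi <- design$small_tree_range_cm[2]
  small <- census$dbh_cm >= lo & census$dbh_cm < hi
  keep <- !small | (stats::runif(nrow(census)) < design$subplot_fraction)
  out <- census[keep, , drop = FALSE]
  out$subplot[small[keep]] <- "A"
  rownames(out) <- NULL
  for (a in c("layout")) attr(out, a) <- attr(census, a)
  class(out) <- c("tree_records", "data.frame")
  out
}

#' Write tree records to a delimited text file
#'
#' Writes an inventory in the format accepted by [read_inventory()]
#' (comma-separated, `protected_area` as 0/1).
#'
#' @param records A `tree_records` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_inventory <- function(records, path) {
  out <- data.frame(cluster = records$cluster, plot = records$plot,
                    subplot = ifelse(is.na(records$subplot), "",
                                     records$subplot),
                    habitat = records$habitat,
                    protected_area = as.integer(records$in_pa),
                    species = records$species,
                    dbh_cm = records$dbh_cm,
                    stem_form = ifelse(is.na(records$stem_form), "",
                                       records$stem_form),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
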