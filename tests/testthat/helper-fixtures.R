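# Small in-code fixtures shared across test files.

make_records <- function(cluster, plot, habitat = "humid", in_pa = FALSE,
                         species = "sp a", dbh_cm = 12,
                         stem_form = NA_character_, subplot = NA_character_) {
  n <- max(length(cluster), length(plot), length(species), length(dbh_cm),
           length(stem_form), length(habitat) * (length(cluster) > 0))
  if (length(cluster) == 0) n <- 0
  r <- function(x) if (n == 0) x[0] else rep_len(x, n)
  df <- data.frame(cluster = r(cluster), plot = r(plot),
                   subplot = r(subplot), habitat = r(habitat),
                   in_pa = r(in_pa), species = r(species),
                   dbh_cm = r(dbh_cm), stem_form = r(stem_form),
                   stringsAsFactors = FALSE)
  class(df) <- c("tree_records", "data.frame")
  df
}

write_temp_inventory <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Random record table over a small consistent sampling frame (habitat fixed
# per cluster, PA membership fixed per plot), for property tests.
random_records <- function(n = 50, n_clusters = 5, n_species = 6) {
  clusters <- sprintf("c%02d", 1:n_clusters)
  hab_of_cluster <- stats::setNames(
    sample(c("humid", "semi-arid", "rainy"), n_clusters, replace = TRUE),
    clusters)
  plots <- expand.grid(cluster = clusters, plot = c("p1", "p2", "p3", "p4"),
                       stringsAsFactors = FALSE)
  plots$in_pa <- sample(c(TRUE, FALSE), nrow(plots), replace = TRUE)
  pick <- plots[sample(nrow(plots), n, replace = TRUE), ]
  make_records(
    cluster = pick$cluster,
    plot = pick$plot,
    habitat = unname(hab_of_cluster[pick$cluster]),
    in_pa = pick$in_pa,
    species = sample(sprintf("sp%02d", 1:n_species), n, replace = TRUE),
    dbh_cm = round(stats::runif(n, 5, 60), 1))
}
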