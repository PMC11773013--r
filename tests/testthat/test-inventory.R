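test_that("a well-formed inventory file parses into validated records", {
  path <- write_temp_inventory(c(
    "cluster,plot,subplot,habitat,protected_area,species,dbh_cm,stem_form",
    "c1,p1,A,humid,1,Brachystegia  Spiciformis,7.2,",
    "c1,p2,,semi-arid,no,Julbernardia globiflora,15.4,SF2"))
  inv <- read_inventory(path, survey_design())
  expect_s3_class(inv, "tree_records")
  expect_equal(nrow(inv), 2L)
  expect_equal(nrow(attr(inv, "rejected")), 0L)
  expect_equal(inv$species[1], "brachystegia spiciformis")
  expect_identical(inv$in_pa, c(TRUE, FALSE))
  expect_identical(inv$subplot, c("A", NA_character_))
  expect_identical(inv$stem_form, c(NA_character_, "SF2"))
})

test_that("tab-separated files are autodetected", {
  path <- write_temp_inventory(c(
    "cluster\tplot\thabitat\tprotected_area\tspecies\tdbh_cm",
    "c1\tp1\thumid\t0\tsp a\t7.5"))
  expect_silent(inv <- read_inventory(path, survey_design()))
  expect_equal(inv$dbh_cm, 7.5)
})

test_that("invalid rows are rejected with row numbers and reasons", {
  path <- write_temp_inventory(c(
    "cluster,plot,habitat,protected_area,species,dbh_cm",
    "c1,p1,humid,1,sp a,3.0",
    "c1,p2,humid,1,sp a,12.0",
    "c1,p3,savanna,0,sp a,12.0",
    "c1,p4,humid,maybe,sp a,12.0",
    "c1,p5,humid,0,,12.0",
    "c1,p6,humid,0,sp a,notanumber"))
  expect_warning(expect_warning(inv <- read_inventory(path, survey_design()),
                                "rejected 5 row"),
                 "no stem_form")
  expect_equal(nrow(inv), 1L)
  rej <- attr(inv, "rejected")
  expect_setequal(rej$row, c(1L, 3L, 4L, 5L, 6L))
  expect_match(rej$reason[rej$row == 1L], "below census threshold")
  expect_match(rej$reason[rej$row == 3L], "habitat")
})

test_that("large stems without stem form are kept, with one counted warning", {
  path <- write_temp_inventory(c(
    "cluster,plot,habitat,protected_area,species,dbh_cm,stem_form",
    "c1,p1,humid,0,sp a,12,",
    "c1,p1,humid,0,sp a,30,",
    "c1,p1,humid,0,sp b,15,SF1",
    "c1,p1,humid,0,sp b,7.5,"))
  expect_warning(inv <- read_inventory(path, survey_design()),
                 "2 stem\\(s\\) at DBH >= 10")
  expect_equal(nrow(inv), 4L)
  expect_true(all(is.na(inv$stem_form[inv$dbh_cm < 10])))
})

test_that("a missing mandatory column is a schema error", {
  path <- write_temp_inventory(c(
    "cluster,plot,habitat,species,dbh_cm",
    "c1,p1,humid,sp a,12"))
  expect_error(read_inventory(path, survey_design()), "protected_area")
})

test_that("expansion factors follow the half-open subplot DBH interval", {
  d <- survey_design()
  expect_equal(expansion_factor(c(5, 7, 9.9, 10, 55), d), c(4, 4, 4, 1, 1))
  expect_error(expansion_factor(3, d), "below the census threshold")
  d2 <- survey_design(subplot_fraction = 0.5)
  expect_equal(expansion_factor(7, d2), 2)
})

test_that("stems_per_ha expands subplot records and divides by surveyed area", {
  d <- survey_design()
  big <- make_records("c1", "p1", dbh_cm = rep(12, 12))
  expect_equal(stems_per_ha(big, n_plots = 30, design = d), 4.0)
  small <- make_records("c1", "p1", dbh_cm = 7)
  expect_equal(stems_per_ha(small, n_plots = 1, design = d), 40.0)
  expect_equal(stems_per_ha(big[0, ], n_plots = 10, design = d), 0)
  expect_error(stems_per_ha(big, n_plots = 0, design = d), "positive")
})

test_that("stems_per_ha is linear in record multiplicity", {
  set.seed(11)
  for (i in 1:5) {
    rec <- random_records(n = 40)
    one <- stems_per_ha(rec, n_plots = 20)
    two <- stems_per_ha(rbind(rec, rec), n_plots = 20)
    expect_equal(two, 2 * one)
  }
})

test_that("profiles count occurrences at plot level and occupancy at cluster level", {
  rec <- make_records(cluster = "c1", plot = c("p1", "p1", "p2"),
                      in_pa = c(TRUE, TRUE, FALSE), dbh_cm = c(7, 12, 15))
  p <- build_profiles(rec)
  expect_equal(p$occurrences_total, 2L)   # two plots, stems collapse
  expect_equal(p$occurrences_in_pa, 1L)
  expect_equal(p$occupied_units, 1L)
  expect_equal(p$total_abundance, 3L)
  expect_equal(p$max_habitat_abundance, 3L)
})

test_that("profiles of an empty inventory form an empty table", {
  p <- build_profiles(make_records(character(), character()))
  expect_s3_class(p, "species_profiles")
  expect_equal(nrow(p), 0L)
})

test_that("profile totals conserve records and plot-species pairs", {
  set.seed(21)
  for (i in 1:5) {
    rec <- random_records(n = 80)
    p <- build_profiles(rec)
    expect_equal(sum(p$total_abundance), nrow(rec))
    pairs <- unique(paste(rec$cluster, rec$plot, rec$species))
    expect_equal(sum(p$occurrences_total), length(pairs))
    expect_true(all(p$occurrences_in_pa <= p$occurrences_total))
    expect_true(all(p$occupied_units <= p$total_units))
  }
})

test_that("explicit total_units widens the occupancy denominator", {
  rec <- make_records(cluster = c("c1", "c2"), plot = "p1", dbh_cm = 12)
  p <- build_profiles(rec, total_units = 50)
  expect_equal(p$total_units, 50L)
  expect_error(build_profiles(rec, total_units = 1), "smaller")
})

test_that("community matrices tabulate counts and reduce to presence", {
  rec <- make_records(cluster = "c", plot = "p",
                      habitat = c("h1", "h1", "h1", "h2", "h2", "h2",
                                  "h2", "h2"),
                      species = c("s1", "s1", "s2", "s3", "s3", "s3",
                                  "s3", "s3"))
  m <- community_matrix(rec)
  expect_equal(unname(rowSums(m)), c(3L, 5L))
  expect_equal(m["h1", "s1"], 2L)
  pm <- community_matrix(rec, presence = TRUE)
  expect_true(all(pm %in% 0:1))
  expect_identical(pm > 0, m > 0)
})

test_that("community matrices are invariant to record order", {
  set.seed(31)
  rec <- random_records(n = 60)
  m1 <- community_matrix(rec)
  m2 <- community_matrix(rec[sample(nrow(rec)), ])
  expect_identical(m1, m2)
})

test_that("species name normalization trims, squishes and case-folds", {
  expect_equal(normalize_species("  Brachystegia   SPICIFORMIS "),
               "brachystegia spiciformis")
  expect_equal(normalize_species(c("A b", "a  B")), c("a b", "a b"))
})

test_that("species metadata reads, normalizes and rejects duplicates", {
  path <- write_temp_inventory(c(
    "species,is_timber,commercial_class,min_felling_dbh_cm",
    "Afzelia quanzensis,yes,1,40",
    "Uapaca kirkiana,no,,"))
  meta <- read_species_metadata(path)
  expect_identical(meta$is_timber, c(TRUE, FALSE))
  expect_equal(meta$min_felling_dbh_cm, c(40, NA))
  dup <- write_temp_inventory(c("species,is_timber",
                                "sp a,yes", "SP  A,no"))
  expect_error(read_species_metadata(dup), "duplicated")
})
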