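test_that("harvestable density counts only stems at or above the species MFD", {
  pol <- timber_policy()
  rec <- make_records(cluster = "c1", plot = sprintf("p%02d", 1:8),
                      species = "afzelia quanzensis",
                      dbh_cm = c(41, 45, 50, 55, 60, 42, 47, 44))
  expect_equal(harvestable_density(rec, "Afzelia quanzensis", n_plots = 20,
                                   policy = pol), 4.0)  # 8 stems / 2 ha
  small <- make_records("c1", "p1", species = "afzelia quanzensis",
                        dbh_cm = c(35, 29.9, 20))
  expect_equal(harvestable_density(small, "afzelia quanzensis", 20, pol), 0)
  # an MFD override admits trees the 40 cm default excludes
  pol30 <- timber_policy(min_felling_dbh_cm = c("afzelia quanzensis" = 30))
  expect_equal(harvestable_density(small, "afzelia quanzensis", 20, pol30),
               1 / 2)
})

test_that("raising the MFD never increases harvestable density", {
  set.seed(61)
  rec <- random_records(n = 200, n_species = 3)
  sp <- rec$species[1]
  dens <- sapply(c(20, 30, 40, 50, 60), function(mfd) {
    pol <- timber_policy(stats::setNames(mfd, sp))
    harvestable_density(rec, sp, n_plots = 20, policy = pol)
  })
  expect_true(all(diff(dens) <= 0))
})

test_that("stem-form profiles are per-class relative frequencies", {
  rec <- make_records("c", "p", dbh_cm = c(12, 13, 15, 18),
                      stem_form = c("SF1", "SF1", "SF1", "SF2"))
  prof <- stem_form_profile(rec)
  expect_equal(nrow(prof), 1L)
  expect_equal(unlist(prof[, c("SF1", "SF2", "SF3")]),
               c(SF1 = 0.75, SF2 = 0.25, SF3 = 0))
})

test_that("empty DBH classes are omitted and unscored stems excluded", {
  rec <- make_records("c", "p", dbh_cm = c(12, 25, 45, 15),
                      stem_form = c("SF1", "SF3", "SF2", NA))
  prof <- stem_form_profile(rec)
  expect_setequal(prof$dbh_class, c("[10,20)", "[20,30)", "[40,Inf)"))
  expect_equal(prof$n[prof$dbh_class == "[10,20)"], 1L)  # the NA is dropped
  expect_true(all(abs(rowSums(prof[, c("SF1", "SF2", "SF3")]) - 1) < 1e-12))
  expect_error(stem_form_profile(rec, class_edges = c(10, 10, 20)),
               "strictly increasing")
})

test_that("profiles of a generated census recover the class-conditional probabilities", {
  set.seed(71)
  n <- 5000
  dbh <- runif(n, 10, 19.9)
  sf <- sample(c("SF1", "SF2", "SF3"), n, replace = TRUE,
               prob = c(0.74, 0.17, 0.09))
  prof <- stem_form_profile(make_records("c", "p", dbh_cm = dbh,
                                         stem_form = sf))
  # multinomial 99 % bounds at n = 5000: p_hat within ~2.58*sqrt(p(1-p)/n)
  expect_lt(abs(prof$SF1 - 0.74), 2.58 * sqrt(0.74 * 0.26 / n) + 1e-9)
  expect_lt(abs(prof$SF2 - 0.17), 2.58 * sqrt(0.17 * 0.83 / n) + 1e-9)
  expect_lt(abs(prof$SF3 - 0.09), 2.58 * sqrt(0.09 * 0.91 / n) + 1e-9)
})

test_that("eligibility requires timber, commonness, habitat and density together", {
  pol <- timber_policy()
  ok <- harvest_eligibility("b spiciformis", "humid", TRUE, "Common", 3,
                            4.0, pol)
  expect_true(ok$eligible)
  expect_equal(ok$reasons, "")

  rare <- harvest_eligibility("x", "humid", TRUE, "Form4", 2, 2.0, pol)
  expect_false(rare$eligible)
  expect_equal(rare$reasons, "RARE_FORM")

  wrong_hab <- harvest_eligibility("x", "semi-arid", TRUE, "Common", 3,
                                   3.0, pol)
  expect_equal(wrong_hab$reasons, "HABITAT_RESTRICTED")

  sparse <- harvest_eligibility("x", "humid", TRUE, "Common", 3, 0.2, pol)
  expect_equal(sparse$reasons, "LOW_DENSITY")

  none <- harvest_eligibility("x", "humid", TRUE, "Common", 3, 0, pol)
  expect_equal(none$reasons, "NO_HARVESTABLE_TREES")

  not_timber <- harvest_eligibility("x", "humid", FALSE, "Common", 3,
                                    4.0, pol)
  expect_equal(not_timber$reasons, "NOT_TIMBER")
})

test_that("all failed conditions are reported, not just the first", {
  pol <- timber_policy()
  r <- harvest_eligibility("x", "rainy", FALSE, "Form7", 1, 0.1, pol)
  codes <- strsplit(r$reasons, ",")[[1]]
  expect_setequal(codes, c("NOT_TIMBER", "RARE_FORM", "NOT_GENERALIST",
                           "HABITAT_RESTRICTED", "LOW_DENSITY"))
  # removing one failed condition does not flip eligibility...
  pol_all_hab <- timber_policy(allowed_habitats = c("humid", "semi-arid",
                                                    "rainy"))
  r2 <- harvest_eligibility("x", "rainy", FALSE, "Form7", 1, 0.1, pol_all_hab)
  expect_false(r2$eligible)
  # ...but removing the sole failed condition does
  r3 <- harvest_eligibility("x", "semi-arid", TRUE, "Common", 3, 2.0,
                            timber_policy())
  expect_identical(r3$reasons, "HABITAT_RESTRICTED")
  r4 <- harvest_eligibility("x", "semi-arid", TRUE, "Common", 3, 2.0,
                            pol_all_hab)
  expect_true(r4$eligible)
})

test_that("raising the legal minimum density never makes a species eligible", {
  set.seed(81)
  for (i in 1:30) {
    dens <- runif(1, 0, 3)
    form <- sample(rarity_forms, 1)
    hab <- sample(c("humid", "rainy"), 1)
    timber <- sample(c(TRUE, FALSE), 1)
    mins <- sort(runif(4, 0, 4))
    elig <- sapply(mins, function(m) {
      harvest_eligibility("x", hab, timber, form, 2, dens,
                          timber_policy(min_harvest_density_per_ha = m))$eligible
    })
    expect_true(all(diff(as.integer(elig)) <= 0))
  }
})

test_that("assess_harvest screens every timber species in every habitat", {
  cen <- generate_census(community_params(n_species = 40, seed = 13))
  res <- run_pipeline(cen$records)
  meta <- data.frame(species = cen$truth$species,
                     is_timber = cen$truth$is_timber,
                     commercial_class = NA_character_,
                     min_felling_dbh_cm = cen$truth$mfd_cm,
                     stringsAsFactors = FALSE)
  h <- assess_harvest(cen$records, res$rarity, meta, res$profiles)
  expect_s3_class(h, "harvest_assessment")
  n_timber_obs <- sum(meta$is_timber & meta$species %in% res$rarity$species)
  expect_equal(nrow(h), n_timber_obs * length(unique(cen$records$habitat)))
  expect_identical(h$eligible, h$reasons == "")
  expect_true(all(h$harvestable_share_of_stems >= 0 &
                    h$harvestable_share_of_stems <= 1))
  profs <- attr(h, "stem_form_profiles")
  expect_setequal(names(profs), meta$species[meta$is_timber])
})
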