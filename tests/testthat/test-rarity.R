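prof_row <- function(occupied, total, n_hab, max_ab, total_ab = max_ab) {
  data.frame(species = "x", occupied_units = occupied, total_units = total,
             n_habitats = n_hab, max_habitat_abundance = max_ab,
             total_abundance = total_ab, stringsAsFactors = FALSE)
}

test_that("the eight criteria combinations map to the canonical categories", {
  # wide = occupancy 30/100, narrow = 5/100; various = 2 habitats;
  # large = abundance 50, small = 2
  cases <- expand.grid(wide = c(TRUE, FALSE), various = c(TRUE, FALSE),
                       large = c(TRUE, FALSE))
  got <- apply(cases, 1, function(cs) {
    p <- prof_row(occupied = if (cs["wide"]) 30 else 5, total = 100,
                  n_hab = if (cs["various"]) 2 else 1,
                  max_ab = if (cs["large"]) 50 else 2)
    as.character(classify_rabinowitz(p))
  })
  want <- c("Common", "Form4", "Form2", "Form6", "Form1", "Form5",
            "Form3", "Form7")
  expect_identical(got, want)
  expect_equal(length(unique(got)), 8L)
  expect_equal(sum(got == "Common"), 1L)
})

test_that("boundary cases follow the printed inequalities", {
  # occupancy exactly 10 % is narrow
  expect_identical(as.character(classify_rabinowitz(
    prof_row(10, 100, 2, 50))), "Form4")
  expect_identical(as.character(classify_rabinowitz(
    prof_row(11, 100, 2, 50))), "Common")
  # abundance exactly 2 is small
  expect_identical(as.character(classify_rabinowitz(
    prof_row(30, 100, 2, 2))), "Form1")
  expect_identical(as.character(classify_rabinowitz(
    prof_row(30, 100, 2, 3))), "Common")
  # a single habitat is never "various"
  expect_identical(as.character(classify_rabinowitz(
    prof_row(30, 100, 1, 50))), "Form2")
})

test_that("classification is invariant to abundance within a threshold band", {
  forms <- sapply(c(3, 10, 500, 7000), function(ab) {
    as.character(classify_rabinowitz(prof_row(30, 100, 2, ab)))
  })
  expect_true(all(forms == "Common"))
})

test_that("the abundance criterion can use totals instead of per-habitat maxima", {
  p <- prof_row(30, 100, 2, max_ab = 2, total_ab = 4)
  expect_identical(as.character(classify_rabinowitz(p)), "Form1")
  th <- rarity_thresholds(abundance_scope = "total")
  expect_identical(as.character(classify_rabinowitz(p, th)), "Common")
})

test_that("classifier rejects empty or inconsistent profiles", {
  expect_error(classify_rabinowitz(prof_row(1, 100, 2, 5)[0, ]), "empty")
  expect_error(classify_rabinowitz(prof_row(1, 0, 2, 5)))
})

test_that("rarity indices match hand-computed values at the extremes", {
  common <- prof_row(100, 100, 3, 1000, total_ab = 1000)
  idx <- maciel_indices(common, n_habitats_region = 3, n_max = 1000)
  expect_equal(unlist(idx), c(gri = 0, hsi = 0, psi = 0, ri = 0))

  rare <- prof_row(1, 100, 1, 1, total_ab = 1)
  idx <- maciel_indices(rare, n_habitats_region = 3, n_max = 1000)
  expect_equal(idx$gri, 0.99)
  expect_equal(idx$hsi, 1)
  expect_equal(idx$psi, 1 - log(2) / log(1001))
  expect_equal(idx$ri, (0.99 + 1 + 1 - log(2) / log(1001)) / 3)
})

test_that("rarity indices are monotone and bounded", {
  p1 <- prof_row(10, 100, 2, 20, total_ab = 20)
  p2 <- prof_row(10, 200, 2, 20, total_ab = 20)
  expect_gt(maciel_indices(p2, 3, 1000)$gri, maciel_indices(p1, 3, 1000)$gri)
  ab <- c(1, 5, 50, 500)
  psi <- sapply(ab, function(n)
    maciel_indices(prof_row(10, 100, 2, n, total_ab = n), 3, 1000)$psi)
  expect_true(all(diff(psi) < 0))
  set.seed(41)
  for (i in 1:20) {
    p <- prof_row(sample(100, 1), 100, sample(3, 1), 1,
                  total_ab = sample(1000, 1))
    idx <- maciel_indices(p, 3, 1000)
    expect_true(all(unlist(idx) >= 0 & unlist(idx) <= 1))
  }
})

test_that("hsi degenerates to 1 for a single-habitat study region", {
  p <- prof_row(10, 100, 1, 5)
  expect_equal(maciel_indices(p, n_habitats_region = 1, n_max = 10)$hsi, 1)
})

test_that("protection index is the exact occurrence ratio with guarded bounds", {
  expect_equal(protection_index(3, 10), 0.3)
  expect_equal(protection_index(10, 10), 1)
  expect_equal(protection_index(0, 7), 0)
  expect_error(protection_index(1, 0), "at least 1")
  expect_error(protection_index(5, 3), "occ_total")
})

test_that("protection status maps PI = 1/0/interior to highly/poorly/partially", {
  expect_identical(as.character(protection_status(c(1, 0, 0.5, 0.999))),
                   c("highly", "poorly", "partially", "partially"))
  expect_error(protection_status(1.2), "\\[0, 1\\]")
  expect_error(protection_status(-0.1), "\\[0, 1\\]")
})

test_that("assess_rarity keeps its internal consistency invariants", {
  set.seed(71)
  rec <- random_records(n = 300, n_clusters = 12, n_species = 25)
  a <- assess_rarity(build_profiles(rec), n_habitats_region = 3)
  expect_identical(a$is_rare, a$form != "Common")
  expect_identical(as.character(a$protection),
                   as.character(protection_status(a$pi)))
  expect_equal(a$ri, (a$gri + a$hsi + a$psi) / 3)
  s <- summarize_rarity(a)
  expect_equal(sum(s$by_form$count), nrow(a))
  expect_equal(sum(s$by_protection$count), nrow(a))
})
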