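joint_cfg <- function(n_common = 5L, ke_cows = 150L, sa_cows = 300L,
                      ke_sires = 15L, sa_sires = 30L) {
  sim_config(countries = list(
    KE = list(n_cows = ke_cows, n_sires = ke_sires,
              n_dams = as.integer(ke_cows * 0.5), n_herds = 3L,
              years = c(2008L, 2014L), herd_window_years = 5L),
    SA = list(n_cows = sa_cows, n_sires = sa_sires,
              n_dams = as.integer(sa_cows * 0.5), n_herds = 6L,
              years = c(2008L, 2014L), herd_window_years = 5L)),
    n_common_sires = n_common)
}

test_that("a full study has the three-source gain table shape", {
  st <- simulate_study(joint_cfg(), seed = 31)
  rep <- run_study(st, seed = 31, scenarios = c(5, 10))
  expect_s3_class(rep, "comparison_report")
  gt <- rep$gains
  expect_equal(nrow(gt), 3 * 2 * 3) # traits x scenarios x sources
  expect_setequal(unique(gt$source), c("within_KE", "within_SA", "multi"))
  expect_true(all(gt$pct_pgg[gt$source == "multi"] == 100))
  expect_equal(rep$benefit$benefit + rep$benefit$pct_pgg,
               rep(100, nrow(rep$benefit)))
  expect_equal(rep$connectedness$n_common_sires, 5)
  # pooled candidate list is the undeduplicated sum of the sire lists
  expect_true(all(gt$n_candidates[gt$source == "multi"] == 15 + 30))
  expect_equal(nrow(glance(rep)), 1)
  expect_s3_class(autoplot(rep), "ggplot")
})

test_that("rerunning with the same seed reproduces the gain table exactly", {
  r1 <- run_study(simulate_study(joint_cfg(), seed = 37), seed = 37,
                  scenarios = c(5, 10))
  r2 <- run_study(simulate_study(joint_cfg(), seed = 37), seed = 37,
                  scenarios = c(5, 10))
  expect_identical(tibble::as_tibble(r1$gains), tibble::as_tibble(r2$gains))
  expect_identical(r1$manifest$config_digest, r2$manifest$config_digest)
})

test_that("artifacts land on disk with a manifest", {
  d <- withr::local_tempdir()
  st <- simulate_study(joint_cfg(ke_cows = 80L, sa_cows = 120L,
                                 ke_sires = 8L, sa_sires = 12L,
                                 n_common = 3L), seed = 41)
  run_study(st, seed = 41, out_dir = d, scenarios = 5)
  for (f in c("gains.tsv", "accuracy.tsv", "benefit.tsv", "summary.txt",
              "run_manifest.yml", "ebv_multi.tsv", "ebv_within_KE.tsv",
              "fixed_within_SA.tsv")) {
    expect_true(file.exists(file.path(d, f)), label = f)
  }
  man <- yaml::read_yaml(file.path(d, "run_manifest.yml"))
  expect_equal(man$decisions$hys_nesting,
               "country-nested (herds never span countries)")
})

test_that("disconnected countries gain nothing from pooling", {
  st <- simulate_study(joint_cfg(n_common = 0L), seed = 43)
  rep <- run_study(st, seed = 43, scenarios = 5)
  # pooled EBVs equal within-country EBVs animal by animal
  for (cc in c("KE", "SA")) {
    w <- rep$evaluations[[paste0("within_", cc)]]$solutions
    m <- rep$evaluations$multi$solutions
    j <- dplyr::inner_join(w, m, by = c("animal_id", "trait"),
                           suffix = c("_w", "_m"))
    expect_lt(max(abs(j$ebv_w - j$ebv_m)), 1e-6)
  }
  acc <- rep$accuracy
  expect_lt(max(abs(acc$within_accuracy - acc$multi_accuracy)), 1e-6)
})

test_that("pedigree merging keeps shared sires and rejects conflicts", {
  st <- simulate_study(joint_cfg(), seed = 47)
  mp <- merge_pedigrees(st$pedigree)
  n_shared <- 5
  expect_equal(nrow(mp),
               nrow(st$pedigree$KE) + nrow(st$pedigree$SA) - n_shared)
  bad <- list(
    A = tibble::tibble(animal_id = c("S1", "X"), sire_id = c(NA, "S1"),
                       dam_id = NA_character_),
    B = tibble::tibble(animal_id = c("S1", "P", "Y"),
                       sire_id = c("P", NA, "S1"),
                       dam_id = NA_character_))
  expect_error(merge_pedigrees(bad), "conflicting.*S1")
})

test_that("a sire with daughters in one country is a pedigree link only", {
  pedA <- tibble::tibble(animal_id = c("SHARED", "A1"),
                         sire_id = c(NA, "SHARED"), dam_id = NA_character_)
  pedB <- tibble::tibble(animal_id = c("SHARED", "B1", "BS", "B2"),
                         sire_id = c(NA, "SHARED", NA, "BS"),
                         dam_id = NA_character_)
  recA <- tibble::tibble(animal_id = "A1")
  recB <- tibble::tibble(animal_id = "B2") # SHARED daughter B1 unrecorded
  conn <- connectedness_summary(list(A = pedA, B = pedB),
                                list(A = recA, B = recB))
  expect_equal(conn$n_common_sires, 0)
  expect_equal(conn$pedigree_link_only, "SHARED")
})

test_that("more common sires never hurt the smaller country on average", {
  gain_for <- function(n_common, seeds) {
    mean(vapply(seeds, function(sd) {
      st <- simulate_study(joint_cfg(n_common = n_common, ke_cows = 100L,
                                     sa_cows = 250L, ke_sires = 10L,
                                     sa_sires = 25L), seed = sd)
      rep <- run_study(st, seed = sd, scenarios = 5)
      acc <- rep$accuracy[rep$accuracy$country == "KE", ]
      mean(acc$multi_accuracy - acc$within_accuracy)
    }, numeric(1)))
  }
  seeds <- 1:4
  gains <- vapply(c(0L, 4L, 10L), gain_for, numeric(1), seeds = seeds)
  expect_true(all(diff(gains) >= -1e-9))
  expect_lt(abs(gains[1]), 1e-6)
})

test_that("the reml stage estimates per-country components", {
  st <- simulate_study(joint_cfg(ke_cows = 120L, sa_cows = 120L,
                                 ke_sires = 12L, sa_sires = 12L,
                                 n_common = 3L), seed = 53)
  fits <- run_study(st, seed = 53, stages = "reml", varcomp = NULL,
                    reml_control = list(tol = 5e-3, max_iter = 30))
  expect_setequal(names(fits), c("KE", "SA"))
  for (cc in c("KE", "SA")) {
    expect_s3_class(fits[[cc]], "reml_fit")
    expect_true(all(is.finite(diag(fits[[cc]]$varcomp$G0))))
    expect_true(all(diag(fits[[cc]]$varcomp$G0) > 0))
  }
})
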