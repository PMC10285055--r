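vc1 <- function(tr = "Y", g = 1, r = 1) {
  variance_components(tr, matrix(g), matrix(r))
}

two_founders <- function() {
  as_pedigree(tibble::tibble(animal_id = c("1", "2"), sire_id = NA,
                             dam_id = NA))
}

toy_records <- function() {
  tibble::tibble(animal_id = c("1", "2"), herd = "H1", hys = "H1|2014|1",
                 age_months = 30, Y = c(10, 12))
}

toy_spec <- function(g = 1, r = 1) {
  model_spec(list(trait_spec("Y", uses_age_covariate = FALSE)),
             varcomp = vc1(g = g, r = r))
}

test_that("design counts levels and applies one constraint per nesting", {
  ped <- two_founders()
  d <- build_design(toy_records(), ped, toy_spec())
  # herd and HYS each have one level; HYS is absorbed into the herd
  expect_equal(nrow(d$eq_fixed) + nrow(d$constraints), 2)
  expect_equal(nrow(d$constraints), 1)
  expect_equal(d$constraints$effect, "hys")

  # pooled: the country factor appears with one level constrained
  recp <- tibble::tibble(animal_id = c("1", "2"),
                         country = c("KE", "ZA"),
                         herd = c("KEH1", "ZAH1"),
                         hys = c("KEH1|2014|1", "ZAH1|2014|1"),
                         age_months = 30, Y = c(10, 12))
  specp <- model_spec(list(trait_spec("Y", uses_age_covariate = FALSE)),
                      varcomp = vc1(), pooled = TRUE)
  dp <- build_design(recp, ped, specp)
  country_rows <- dp$eq_fixed[dp$eq_fixed$effect == "country", ]
  country_con <- dp$constraints[dp$constraints$effect == "country", ]
  expect_equal(nrow(country_rows) + nrow(country_con), 2)
  expect_equal(nrow(country_con), 1)
})

test_that("AFC never receives an age-covariate column", {
  ped <- two_founders()
  rec <- tibble::tibble(animal_id = c("1", "2"), herd = "H1",
                        hys = "H1|2014|1", age_months = c(30, 34),
                        MY305 = c(5000, 6000), AFC = c(30, 33))
  spec <- model_spec(c("MY305", "AFC"),
                     varcomp = variance_components(c("MY305", "AFC"),
                                                   diag(c(1, 1)),
                                                   diag(c(1, 1))))
  d <- build_design(rec, ped, spec)
  age_rows <- d$eq_fixed[d$eq_fixed$effect == "age", ]
  expect_equal(age_rows$trait, "MY305")
  expect_error(trait_spec("AFC", uses_age_covariate = TRUE), "AFC")
})

test_that("design rejects unknown animals and empty trait columns", {
  ped <- two_founders()
  rec <- toy_records()
  rec$animal_id[2] <- "GHOST"
  expect_error(build_design(rec, ped, toy_spec()), "GHOST")
  rec2 <- toy_records()
  rec2$Y <- NA_real_
  expect_error(build_design(rec2, ped, toy_spec()), "Y")
})

test_that("the two-record toy solves to mean 11 and EBVs +/-1/2", {
  # dense mixed-model arithmetic for this system: V = 2 I, mean = 11,
  # a_i = (y_i - 11) * sigma2a / (sigma2a + sigma2e) = -/+ 0.5
  ev <- run_evaluation(toy_records(), two_founders(), toy_spec(),
                       reliability_for = "all")
  expect_equal(ev$fixed$estimate[ev$fixed$effect == "herd"], 11)
  expect_equal(ev$solutions$ebv, c(-0.5, 0.5))
  # independently via the dense oracle
  orc <- dense_oracle(toy_records(), two_founders(), toy_spec())
  expect_equal(orc$ebv, c(-0.5, 0.5), tolerance = 1e-10)
})

test_that("EBVs vanish as genetic variance goes to zero", {
  ev <- run_evaluation(toy_records(), two_founders(), toy_spec(g = 1e-8),
                       reliability_for = "none")
  expect_lt(max(abs(ev$solutions$ebv)), 1e-6)
})

test_that("direct and PCG solvers agree", {
  ped <- rand_pedigree(20, seed = 31)
  rec <- rand_records(ped, c("T1", "T2"), seed = 32)
  spec <- model_spec(c("T1", "T2"), varcomp = rand_varcomp(c("T1", "T2"),
                                                           seed = 33))
  d <- build_design(rec, ped, spec)
  sys <- assemble_mme(d, build_a_inverse(ped))
  xd <- solve_mme(sys, "direct")$x
  xp <- solve_mme(sys, "pcg", tol = 1e-12)$x
  expect_lt(max(abs(xd - xp)) / max(abs(xd)), 1e-6)
  expect_error(solve_mme(sys, "pcg", tol = 1e-14, max_iter = 2L),
               "residual")
})

test_that("identity systems return their right-hand side", {
  sys <- structure(list(C = Matrix::Diagonal(4), rhs = c(1, -2, 3, 0.5),
                        n_eq = 4L), class = "mme_system")
  expect_equal(solve_mme(sys, "pcg")$x, c(1, -2, 3, 0.5))
})

test_that("multi-trait EBVs match the dense oracle on random instances", {
  for (seed in 1:5) {
    set.seed(seed)
    ped <- rand_pedigree(sample(10:16, 1), seed = 200 + seed)
    traits <- c("T1", "T2")[seq_len(sample(2, 1))]
    rec <- rand_records(ped, traits, seed = 300 + seed,
                        missing_rate = ifelse(length(traits) > 1, 0.3, 0))
    spec <- model_spec(traits, varcomp = rand_varcomp(traits, 400 + seed))
    ev <- run_evaluation(rec, ped, spec, reliability_for = "none")
    orc <- dense_oracle(rec, ped, spec)
    m <- dplyr::inner_join(ev$solutions, orc, by = c("animal_id", "trait"),
                           suffix = c("", "_oracle"))
    expect_lt(max(abs(m$ebv - m$ebv_oracle)), 1e-6)
  }
})

test_that("reliabilities match the dense oracle and behave sensibly", {
  ped <- rand_pedigree(14, seed = 51)
  rec <- rand_records(ped, "T1", seed = 52, missing_rate = 0)
  spec <- model_spec("T1", varcomp = vc1("T1", g = 2, r = 3))
  ev <- run_evaluation(rec, ped, spec, reliability_for = "all")
  orc <- dense_oracle(rec, ped, spec, pev = TRUE)
  m <- dplyr::inner_join(ev$solutions, orc, by = c("animal_id", "trait"),
                         suffix = c("", "_oracle"))
  expect_lt(max(abs(m$pev - m$pev_oracle)), 1e-8)

  # founder with no records and no offspring has zero reliability
  aug <- as_pedigree(dplyr::bind_rows(
    tibble::as_tibble(ped)[, 1:3],
    tibble::tibble(animal_id = "LONER", sire_id = NA, dam_id = NA)))
  ev2 <- run_evaluation(rec, aug, spec, reliability_for = "LONER")
  loner <- ev2$solutions[ev2$solutions$animal_id == "LONER", ]
  expect_equal(loner$reliability, 0)
  expect_equal(loner$pev, 2) # = sigma2_a
  expect_error(reliabilities(assemble_mme(build_design(rec, ped, spec),
                                          build_a_inverse(ped)),
                             animals = "NOBODY"), "NOBODY")
})

test_that("more daughters mean higher sire reliability", {
  ids <- c("SBIG", "SSMALL", sprintf("D%02d", 1:22), sprintf("C%02d", 1:22))
  ped <- as_pedigree(tibble::tibble(
    animal_id = ids,
    sire_id = c(NA, NA, rep(NA, 22), rep(c("SBIG", "SSMALL"),
                                         times = c(20, 2))),
    dam_id = c(NA, NA, rep(NA, 22), sprintf("D%02d", 1:22))))
  set.seed(8)
  rec <- tibble::tibble(animal_id = sprintf("C%02d", 1:22),
                        herd = "H1",
                        hys = sprintf("H1|201%d|1", rep(1:2, 11)),
                        age_months = 30,
                        Y = stats::rnorm(22, 10))
  ev <- run_evaluation(rec, ped, model_spec(list(
    trait_spec("Y", uses_age_covariate = FALSE)), varcomp = vc1()),
    reliability_for = c("SBIG", "SSMALL"))
  r <- ev$solutions
  expect_gt(r$reliability[r$animal_id == "SBIG"],
            r$reliability[r$animal_id == "SSMALL"])
})

test_that("reliability and EBVs ignore a constant shift of a trait", {
  ped <- rand_pedigree(16, seed = 61)
  rec <- rand_records(ped, "T1", seed = 62, missing_rate = 0)
  spec <- model_spec("T1", varcomp = vc1("T1", 2, 3))
  ev1 <- run_evaluation(rec, ped, spec, reliability_for = "all")
  rec2 <- rec
  rec2$T1 <- rec2$T1 + 1000
  ev2 <- run_evaluation(rec2, ped, spec, reliability_for = "all")
  expect_equal(ev1$solutions$ebv, ev2$solutions$ebv, tolerance = 1e-7)
  expect_equal(ev1$solutions$reliability, ev2$solutions$reliability,
               tolerance = 1e-9)
})

test_that("diagonal G0 and R0 decouple the traits", {
  ped <- rand_pedigree(18, seed = 71)
  rec <- rand_records(ped, c("T1", "T2"), seed = 72, missing_rate = 0.2)
  vc <- variance_components(c("T1", "T2"), diag(c(2, 5)), diag(c(3, 4)))
  ev <- run_evaluation(rec, ped, model_spec(c("T1", "T2"), varcomp = vc),
                       reliability_for = "none")
  for (tr in c("T1", "T2")) {
    rec1 <- rec[!is.na(rec[[tr]]), c("animal_id", "herd", "hys",
                                     "age_months", tr)]
    i <- match(tr, c("T1", "T2"))
    ev1 <- run_evaluation(rec1, ped,
                          model_spec(tr, varcomp = variance_components(
                            tr, matrix(diag(vc$G0)[i]),
                            matrix(diag(vc$R0)[i]))),
                          reliability_for = "none")
    m <- dplyr::inner_join(ev$solutions[ev$solutions$trait == tr, ],
                           ev1$solutions, by = "animal_id",
                           suffix = c("_joint", "_single"))
    expect_lt(max(abs(m$ebv_joint - m$ebv_single)), 1e-8)
  }
})

test_that("record order does not change the solution", {
  ped <- rand_pedigree(20, seed = 81)
  rec <- rand_records(ped, c("T1", "T2"), seed = 82)
  spec <- model_spec(c("T1", "T2"),
                     varcomp = rand_varcomp(c("T1", "T2"), 83))
  ev1 <- run_evaluation(rec, ped, spec, reliability_for = "none")
  ev2 <- run_evaluation(rec[rev(seq_len(nrow(rec))), ], ped, spec,
                        reliability_for = "none")
  expect_equal(ev1$solutions$ebv, ev2$solutions$ebv, tolerance = 1e-9)
})

test_that("stacked identical countries reproduce within-country EBVs", {
  ped1 <- rand_pedigree(15, seed = 91)
  rec1 <- rand_records(ped1, "T1", seed = 92, missing_rate = 0)
  spec1 <- model_spec("T1", varcomp = vc1("T1", 2, 3))
  within <- run_evaluation(rec1, ped1, spec1, reliability_for = "none")

  # same problem duplicated as a second country with prefixed ids
  clone <- function(df, pre) {
    df$animal_id <- paste0(pre, df$animal_id)
    if ("sire_id" %in% names(df)) {
      df$sire_id <- ifelse(is.na(df$sire_id), NA,
                           paste0(pre, df$sire_id))
      df$dam_id <- ifelse(is.na(df$dam_id), NA, paste0(pre, df$dam_id))
    }
    if ("herd" %in% names(df)) {
      df$herd <- paste0(pre, df$herd)
      df$hys <- paste0(pre, df$hys)
    }
    df
  }
  pedA <- clone(tibble::as_tibble(ped1)[, 1:3], "A_")
  pedB <- clone(tibble::as_tibble(ped1)[, 1:3], "B_")
  recA <- clone(rec1, "A_"); recA$country <- "A"
  recB <- clone(rec1, "B_"); recB$country <- "B"
  pooled <- run_evaluation(dplyr::bind_rows(recA, recB),
                           merge_pedigrees(list(A = pedA, B = pedB)),
                           model_spec("T1", varcomp = vc1("T1", 2, 3),
                                      pooled = TRUE),
                           reliability_for = "none")
  sol <- pooled$solutions
  for (pre in c("A_", "B_")) {
    m <- within$solutions
    m$pref_id <- paste0(pre, m$animal_id)
    j <- dplyr::inner_join(m, sol, by = c("pref_id" = "animal_id"),
                           suffix = c("_within", "_pooled"))
    expect_lt(max(abs(j$ebv_within - j$ebv_pooled)), 1e-9)
  }
})

test_that("evaluation refuses to run without variance components", {
  expect_error(assemble_mme(build_design(toy_records(), two_founders(),
                                         model_spec("Y")),
                            build_a_inverse(two_founders())),
               "variance components")
})
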