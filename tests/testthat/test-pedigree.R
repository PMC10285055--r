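test_that("reading orders parents before offspring and materialises founders", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal_id,sire_id,dam_id", "C,A,B", "A,0,0", "B,0,0"), f)
  ped <- read_pedigree(f)
  expect_s3_class(ped, "pedigree")
  expect_equal(ped$animal_id, c("A", "B", "C"))
  expect_equal(ped$order, 1:3)

  # parent-only ids become founder records
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("animal_id,sire_id,dam_id", "X,S1,D1"), f2)
  ped2 <- read_pedigree(f2)
  expect_setequal(ped2$animal_id, c("S1", "D1", "X"))
  expect_true(all(is.na(ped2$sire_id[ped2$animal_id %in% c("S1", "D1")])))
})

test_that("malformed pedigrees are rejected with the offending id", {
  expect_error(as_pedigree(tibble::tibble(animal_id = c("A", "A"),
                                          sire_id = NA, dam_id = NA)),
               "duplicate.*A")
  expect_error(as_pedigree(tibble::tibble(animal_id = c("A", "B"),
                                          sire_id = c("B", "A"),
                                          dam_id = NA)),
               "cycle.*[AB]")
  expect_error(as_pedigree(tibble::tibble(animal_id = "A",
                                          sire_id = "A", dam_id = NA)),
               "own parent")
  expect_error(as_pedigree(tibble::tibble(animal_id = c("A", "B", "C"),
                                          sire_id = c(NA, "P", NA),
                                          dam_id = c(NA, NA, "P"))),
               "both sire and dam")
})

test_that("inbreeding matches the worked sire-daughter and full-sib cases", {
  founders <- as_pedigree(tibble::tibble(animal_id = c("A", "B", "C"),
                                         sire_id = NA, dam_id = NA))
  expect_equal(unname(compute_inbreeding(founders)), c(0, 0, 0))

  # sire S mated to his own daughter D (dam of D unknown)
  sd <- as_pedigree(tibble::tibble(animal_id = c("S", "D", "X"),
                                   sire_id = c(NA, "S", "S"),
                                   dam_id = c(NA, NA, "D")))
  expect_equal(compute_inbreeding(sd)[["X"]], 0.25)

  # full sibs B, C mated
  fs <- as_pedigree(tibble::tibble(
    animal_id = c("F1", "F2", "B", "C", "X"),
    sire_id = c(NA, NA, "F1", "F1", "B"),
    dam_id = c(NA, NA, "F2", "F2", "C")))
  expect_equal(compute_inbreeding(fs)[["X"]], 0.25)
})

test_that("A-inverse matches the closed-form founder trio", {
  ped <- as_pedigree(tibble::tibble(animal_id = c("A", "B", "C"),
                                    sire_id = c(NA, NA, "A"),
                                    dam_id = c(NA, NA, "B")))
  rf <- build_a_inverse(ped)
  expect_equal(unname(as.matrix(rf$a_inverse)),
               matrix(c(1.5, 0.5, -1, 0.5, 1.5, -1, -1, -1, 2), 3, 3),
               tolerance = 1e-12)
  expect_equal(unname(as.matrix(tabular_a_matrix(ped))),
               matrix(c(1, 0, 0.5, 0, 1, 0.5, 0.5, 0.5, 1), 3, 3))
  single <- as_pedigree(tibble::tibble(animal_id = "A", sire_id = NA,
                                       dam_id = NA))
  expect_equal(as.matrix(build_a_inverse(single)$a_inverse)[1, 1], 1)
})

test_that("tabular method handles single known parents and stays PD", {
  ped <- as_pedigree(tibble::tibble(animal_id = c("A", "C"),
                                    sire_id = c(NA, "A"),
                                    dam_id = c(NA, NA)))
  A <- tabular_a_matrix(ped)
  expect_equal(A["A", "C"], 0.5)
  expect_equal(A["C", "C"], 1)
  expect_error(tabular_a_matrix(rand_pedigree(30, seed = 1),
                                dense_limit = 10), "dense")

  for (seed in 1:5) {
    ped <- rand_pedigree(sample(30:150, 1), seed = seed)
    A <- tabular_a_matrix(ped)
    expect_equal(A, t(A))
    expect_gt(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
})

test_that("sparse A-inverse inverts the tabular A on random pedigrees", {
  for (seed in 1:8) {
    n <- sample(20:120, 1)
    ped <- rand_pedigree(n, seed = 100 + seed)
    A <- tabular_a_matrix(ped)
    expect_equal(unname(compute_inbreeding(ped)), unname(diag(A) - 1),
                 tolerance = 1e-10)
    rf <- build_a_inverse(ped, use_inbreeding = TRUE)
    expect_lt(max(abs(as.matrix(rf$a_inverse) %*% A - diag(n))), 1e-8)
    expect_equal(as.matrix(rf$a_inverse), t(as.matrix(rf$a_inverse)))
  }
})

test_that("ignoring inbreeding still inverts A for non-inbred pedigrees", {
  # founders plus one generation: no inbreeding can arise
  set.seed(9)
  n_f <- 20
  ids <- c(sprintf("S%02d", 1:10), sprintf("D%02d", 1:10),
           sprintf("C%02d", 1:30))
  ped <- as_pedigree(tibble::tibble(
    animal_id = ids,
    sire_id = c(rep(NA, n_f), sprintf("S%02d", sample(10, 30, TRUE))),
    dam_id = c(rep(NA, n_f), sprintf("D%02d", sample(10, 30, TRUE)))))
  expect_equal(max(compute_inbreeding(ped)), 0)
  rf <- build_a_inverse(ped, use_inbreeding = FALSE)
  A <- tabular_a_matrix(ped)
  expect_lt(max(abs(as.matrix(rf$a_inverse) %*% A - diag(nrow(ped)))), 1e-8)
})

test_that("inbreeding is invariant to input row order", {
  ped <- rand_pedigree(60, seed = 42)
  f1 <- compute_inbreeding(ped)
  shuffled <- ped[sample(nrow(ped)), c("animal_id", "sire_id", "dam_id")]
  f2 <- compute_inbreeding(as_pedigree(shuffled))
  expect_equal(f1[sort(names(f1))], f2[sort(names(f2))])
})

test_that("adding an unrelated founder leaves existing F and A unchanged", {
  ped <- rand_pedigree(40, seed = 7)
  f1 <- compute_inbreeding(ped)
  A1 <- tabular_a_matrix(ped)
  aug <- as_pedigree(dplyr::bind_rows(
    tibble::as_tibble(ped)[, 1:3],
    tibble::tibble(animal_id = "ZZ_NEW", sire_id = NA, dam_id = NA)))
  f2 <- compute_inbreeding(aug)
  A2 <- tabular_a_matrix(aug)
  expect_equal(f2[names(f1)], f1)
  expect_equal(A2[rownames(A1), colnames(A1)], A1)
  expect_equal(f2[["ZZ_NEW"]], 0)
})

test_that("pedigree writer round-trips with an order column", {
  ped <- rand_pedigree(25, seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_pedigree(ped, f)
  back <- read_pedigree(f)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(ped))
  expect_true("order" %in% names(readr::read_csv(f, show_col_types = FALSE)))
})
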