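# Test helpers: random fixtures and an independent dense mixed-model oracle.
# The oracle goes through V = Z (A (x) G0) Z' + R and generalised least
# squares with a pseudoinverse, never through build_design/assemble_mme, so
# agreement is a genuine two-route check.

rand_pedigree <- function(n, seed, p_founder = 0.4) {
  set.seed(seed)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  sex[1:2] <- c("M", "F")
  sire <- rep(NA_character_, n)
  dam <- rep(NA_character_, n)
  ids <- sprintf("A%03d", seq_len(n))
  for (i in 3:n) {
    if (stats::runif(1) < p_founder) next
    males <- which(sex[seq_len(i - 1)] == "M")
    females <- which(sex[seq_len(i - 1)] == "F")
    if (length(males)) sire[i] <- ids[males[sample.int(length(males), 1)]]
    if (length(females)) dam[i] <- ids[females[sample.int(length(females), 1)]]
  }
  as_pedigree(tibble::tibble(animal_id = ids, sire_id = sire, dam_id = dam))
}

# random performance table over a pedigree's youngest animals
rand_records <- function(ped, traits, seed, n_herds = 2, n_hys = 3,
                         countries = NULL, missing_rate = 0.2,
                         use_age = rep(TRUE, length(traits))) {
  set.seed(seed)
  cows <- ped$animal_id[!is.na(ped$sire_id) | !is.na(ped$dam_id)]
  if (length(cows) < 4) cows <- utils::tail(ped$animal_id, 4)
  n <- length(cows)
  herd <- sprintf("H%d", sample(n_herds, n, replace = TRUE))
  if (!is.null(countries)) {
    country <- sample(countries, n, replace = TRUE)
    herd <- paste0(country, herd) # herds nested in country
  } else {
    country <- NULL
  }
  rec <- tibble::tibble(
    animal_id = cows,
    herd = herd,
    hys = paste0(herd, "|201", sample(n_hys, n, replace = TRUE), "|1"),
    age_months = round(stats::runif(n, 24, 40), 1))
  if (!is.null(country)) rec$country <- country
  for (ti in seq_along(traits)) {
    y <- stats::rnorm(n, mean = 10 * ti, sd = 2)
    y[stats::runif(n) < missing_rate] <- NA
    rec[[traits[ti]]] <- y
  }
  # every record keeps >= 1 trait
  none <- rowSums(!is.na(rec[, traits, drop = FALSE])) == 0
  rec[[traits[1]]][none] <- stats::rnorm(sum(none), 10, 2)
  rec
}

rand_varcomp <- function(traits, seed, sd_scale = 1) {
  set.seed(seed)
  Tn <- length(traits)
  rc <- function() {
    L <- matrix(stats::rnorm(Tn * Tn, sd = 0.3), Tn)
    diag(L) <- 1
    S <- crossprod(L) * sd_scale
    S
  }
  variance_components(traits, rc(), rc() * 1.5)
}

# dense fixed-effect design: full dummies per trait, no constraints; the
# age column is nested within country when countries are present (matching
# the pooled model, and spanning the same space as centred nested slopes)
.dense_X_row <- function(rec_row, levels_t, uses_age) {
  x <- numeric(levels_t$n)
  x[levels_t$herd[[rec_row$herd]]] <- 1
  x[levels_t$hys[[rec_row$hys]]] <- 1
  pooled <- !is.null(levels_t$country)
  if (pooled) x[levels_t$country[[rec_row$country]]] <- 1
  if (uses_age) {
    col <- if (pooled) levels_t$age[[rec_row$country]] else levels_t$age
    x[col] <- rec_row$age_months
  }
  x
}

# Independent dense oracle: EBVs (and PEVs) for every pedigree animal.
dense_oracle <- function(records, ped, spec, pev = FALSE) {
  ped <- as_pedigree(ped)
  traits <- spec$trait_names
  Tn <- length(traits)
  A <- tabular_a_matrix(ped)
  G0 <- spec$varcomp$G0
  R0 <- spec$varcomp$R0
  q <- nrow(ped)
  Gstar <- kronecker(A, G0) # animal-major, trait fast
  uses_age <- vapply(spec$traits, `[[`, logical(1), "uses_age_covariate")

  # stacked observations: one row per (record, observed trait)
  obs_list <- list()
  for (r in seq_len(nrow(records))) {
    for (ti in seq_len(Tn)) {
      if (!is.na(records[[traits[ti]]][r])) {
        obs_list[[length(obs_list) + 1]] <- list(r = r, ti = ti)
      }
    }
  }
  m <- length(obs_list)
  y <- vapply(obs_list, function(o) records[[traits[o$ti]]][o$r], numeric(1))

  # per-trait dense dummy blocks
  lev <- lapply(seq_len(Tn), function(ti) {
    sel <- !is.na(records[[traits[ti]]])
    hl <- sort(unique(records$herd[sel]))
    kl <- sort(unique(records$hys[sel]))
    cl <- if (spec$pooled) sort(unique(records$country[sel])) else NULL
    n_age <- if (!uses_age[ti]) 0L else if (spec$pooled) length(cl) else 1L
    n <- length(hl) + length(kl) + length(cl) + n_age
    herd <- as.list(stats::setNames(seq_along(hl), hl))
    hys <- as.list(stats::setNames(length(hl) + seq_along(kl), kl))
    country <- if (!is.null(cl)) {
      as.list(stats::setNames(length(hl) + length(kl) + seq_along(cl), cl))
    }
    age <- if (!uses_age[ti]) NULL else if (spec$pooled) {
      as.list(stats::setNames(length(hl) + length(kl) + length(cl) +
                                seq_along(cl), cl))
    } else n
    list(n = n, herd = herd, hys = hys, country = country, age = age)
  })
  offs <- cumsum(c(0, vapply(lev, `[[`, numeric(1), "n")))
  p <- offs[Tn + 1]
  X <- matrix(0, m, p)
  Z <- matrix(0, m, q * Tn)
  apos <- match(records$animal_id, ped$animal_id)
  for (k in seq_len(m)) {
    o <- obs_list[[k]]
    X[k, offs[o$ti] + seq_len(lev[[o$ti]]$n)] <-
      .dense_X_row(records[o$r, ], lev[[o$ti]], uses_age[o$ti])
    Z[k, (apos[o$r] - 1) * Tn + o$ti] <- 1
  }
  # residual covariance: records independent, traits of one record correlated
  R <- matrix(0, m, m)
  for (k1 in seq_len(m)) {
    for (k2 in seq_len(m)) {
      if (obs_list[[k1]]$r == obs_list[[k2]]$r) {
        R[k1, k2] <- R0[obs_list[[k1]]$ti, obs_list[[k2]]$ti]
      }
    }
  }
  V <- Z %*% Gstar %*% t(Z) + R
  Vi <- solve(V)
  XtVi <- t(X) %*% Vi
  b <- MASS::ginv(XtVi %*% X, tol = 1e-11) %*% XtVi %*% y
  resid <- y - X %*% b
  a <- Gstar %*% t(Z) %*% Vi %*% resid
  out <- tibble::tibble(
    animal_id = rep(ped$animal_id, each = Tn),
    trait = rep(traits, q),
    ebv = as.numeric(a))
  if (pev) {
    P <- Vi - t(XtVi) %*% MASS::ginv(XtVi %*% X, tol = 1e-11) %*% XtVi
    covmat <- Gstar - Gstar %*% t(Z) %*% P %*% Z %*% Gstar
    out$pev <- diag(covmat)
  }
  out
}
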