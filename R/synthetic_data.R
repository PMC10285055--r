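#' Configuration for the two-country herdbook simulator
#'
#' Builds (and validates) the simulation settings. Defaults describe the
#' pilot two-country Holstein-Friesian setting the package is built around:
#' 2,333 Kenyan and 25,208 South African first-lactation cows, 103 and 505
#' sires with recorded daughters, 40 sires in common, calvings spanning
#' 1979-2014 (KE) and 1997-2014 (SA). Truth variance parameters (genetic
#' SDs, heritabilities, genetic correlations), fixed-effect magnitudes and
#' phenotypic means are declared assumptions chosen to be realistic for
#' Holstein-Friesian first lactations - the source datasets are private, so
#' none of these magnitudes are data-derived.
#'
#' @param countries Named list of per-country overrides; each country may set
#'   `n_cows`, `n_sires`, `n_dams` (default `0.8 * n_cows`), `n_herds`,
#'   `years` (length-2 span), `herd_window_years` (how many consecutive
#'   years a herd records calvings - herds do not span the whole period),
#'   `mean_age`, `sd_age` (first-calving age, months), `trait_means`.
#' @param n_common_sires Sires shared by every country's sire list, the
#'   genetic connection across countries. Dams never overlap: connectedness
#'   is sire-only.
#' @param traits Trait names (order fixes all per-trait vectors).
#' @param sigma_g True genetic SDs per trait (trait units).
#' @param h2 True heritabilities per trait.
#' @param genetic_cor Genetic correlation matrix.
#' @param residual_cor Residual correlation matrix (default identity).
#' @param herd_sd_frac,hys_sd_frac Herd and herd-year-season effect SDs as
#'   fractions of the phenotypic SD.
#' @param age_slope Fixed regression on calving age per trait (ignored for
#'   traits with `uses_age = FALSE`).
#' @param uses_age Which traits carry the calving-age covariate (AFC never
#'   does).
#' @param missing_rate Per-trait probability that a record lacks the trait
#'   (a record always keeps at least its first trait).
#' @param p_move Probability a cow's production herd differs from her birth
#'   herd, which keeps the birth-herd effect separable from HYS.
#' @param sire_usage `"skewed"` (geometric-like daughters-per-sire, mimicking
#'   AI usage) or `"uniform"`.
#' @param season_rule Passed to [make_hys()].
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(countries = list(),
                       n_common_sires = 40L,
                       traits = c("MY305", "AFC", "CI1"),
                       sigma_g = c(528, 61.1948, 20.2946),
                       h2 = c(0.25, 0.15, 0.08),
                       genetic_cor = matrix(c(1, -0.2, 0.2,
                                              -0.2, 1, 0.1,
                                              0.2, 0.1, 1), 3, 3),
                       residual_cor = NULL,
                       herd_sd_frac = 0.3,
                       hys_sd_frac = 0.15,
                       age_slope = c(15, 0, 0.05),
                       uses_age = c(TRUE, FALSE, TRUE),
                       missing_rate = c(0, 0.05, 0.2),
                       p_move = 0.15,
                       sire_usage = c("skewed", "uniform"),
                       season_rule = "quarter") {
  sire_usage <- match.arg(sire_usage)
  defaults <- list(
    KE = list(n_cows = 2333L, n_sires = 103L, n_dams = NULL, n_herds = 12L,
              years = c(1979L, 2014L), herd_window_years = 10L,
              mean_age = 34, sd_age = 3.5,
              trait_means = c(4500, 34, 13.5)),
    SA = list(n_cows = 25208L, n_sires = 505L, n_dams = NULL, n_herds = 100L,
              years = c(1997L, 2014L), herd_window_years = 10L,
              mean_age = 27, sd_age = 2.5,
              trait_means = c(7000, 27, 13)))
  if (length(countries)) {
    if (is.null(names(countries)) || any(!nzchar(names(countries)))) {
      stop("`countries` must be a named list", call. = FALSE)
    }
    for (cc in names(countries)) {
      base <- defaults[[cc]] %||% defaults[[1]]
      extra <- setdiff(names(countries[[cc]]), names(base))
      if (length(extra)) {
        stop("unknown country setting(s) for ", cc, ": ",
             paste(extra, collapse = ", "), call. = FALSE)
      }
      defaults[[cc]] <- utils::modifyList(base, countries[[cc]])
    }
    defaults <- defaults[union(names(countries),
                               if (length(countries) >= 2) character(0)
                               else names(defaults))]
    if (length(countries) >= 2) defaults <- defaults[names(countries)]
  }
  countries <- defaults
  Tn <- length(traits)
  stopifnot(length(sigma_g) == Tn, length(h2) == Tn,
            length(age_slope) == Tn, length(uses_age) == Tn,
            length(missing_rate) == Tn)
  if (any(missing_rate < 0 | missing_rate >= 1)) {
    stop("missing_rate values must lie in [0, 1)", call. = FALSE)
  }
  if (any(h2 <= 0 | h2 >= 1)) stop("h2 must lie in (0, 1)", call. = FALSE)
  if (p_move < 0 || p_move > 1) stop("p_move must lie in [0, 1]",
                                     call. = FALSE)
  genetic_cor <- as.matrix(genetic_cor)
  if (is.null(residual_cor)) residual_cor <- diag(Tn)
  sigma_p <- sigma_g / sqrt(h2)
  sigma_e <- sqrt(sigma_p^2 - sigma_g^2)
  G0 <- diag(sigma_g, Tn) %*% genetic_cor %*% diag(sigma_g, Tn)
  R0 <- diag(sigma_e, Tn) %*% as.matrix(residual_cor) %*% diag(sigma_e, Tn)
  dimnames(G0) <- dimnames(R0) <- list(traits, traits)
  # PD checks via the shared validator
  vc <- variance_components(traits, G0, R0)
  for (cc in names(countries)) {
    co <- countries[[cc]]
    if (is.null(co$n_dams)) countries[[cc]]$n_dams <- round(0.8 * co$n_cows)
    co <- countries[[cc]]
    stopifnot(co$n_cows > 0, co$n_sires > 0, co$n_dams > 0, co$n_herds > 0,
              length(co$years) == 2, co$years[2] >= co$years[1],
              length(co$trait_means) == Tn)
    if (n_common_sires > co$n_sires) {
      stop("n_common_sires (", n_common_sires, ") exceeds n_sires of ",
           cc, " (", co$n_sires, ")", call. = FALSE)
    }
  }
  structure(list(countries = countries, n_common_sires = n_common_sires,
                 traits = traits, sigma_g = sigma_g, h2 = h2,
                 genetic_cor = genetic_cor, residual_cor = residual_cor,
                 G0 = G0, R0 = R0, varcomp = vc,
                 herd_sd = herd_sd_frac * sigma_p,
                 hys_sd = hys_sd_frac * sigma_p,
                 herd_sd_frac = herd_sd_frac, hys_sd_frac = hys_sd_frac,
                 age_slope = age_slope, uses_age = uses_age,
                 missing_rate = missing_rate, p_move = p_move,
                 sire_usage = sire_usage, season_rule = season_rule),
            class = "sim_config")
}

#' @export
#' @method print sim_config
print.sim_config <- function(x, ...) {
  cat("<sim_config> countries:",
      paste(sprintf("%s (%d cows, %d sires)", names(x$countries),
                    vapply(x$countries, `[[`, numeric(1), "n_cows"),
                    vapply(x$countries, `[[`, numeric(1), "n_sires")),
            collapse = ", "),
      "| common sires:", x$n_common_sires, "\n")
  invisible(x)
}

.rmvn <- function(n, Sigma) {
  L <- chol(Sigma)
  matrix(stats::rnorm(n * nrow(Sigma)), nrow = n, ncol = nrow(Sigma)) %*% L
}

#' Simulate a two-country herdbook study
#'
#' Generates founder sires (a shared subset common to every country) and
#' dams, daughter cows with first-lactation records, herd and HYS
#' assignments, and phenotypes following the animal model: country mean +
#' birth-herd effect + HYS effect + age regression (for traits carrying the
#' covariate) + true breeding value + residual. Founder TBVs are multivariate
#' normal with covariance G0; offspring TBVs are the parent average plus a
#' Mendelian-sampling deviation with covariance
#' `0.5 * (1 - (F_s + F_d)/2) * G0`. Residuals are drawn per record from R0
#' and thinned by the configured per-trait missingness.
#'
#' Identical seeds give byte-identical output.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed driving every random draw.
#' @param out_dir Optional directory; when given, per-country pedigree and
#'   performance CSVs, `truth.tsv` and a simulation manifest are written.
#' @return A `sim_study` list: `pedigree` and `performance` (named lists of
#'   tibbles per country), `truth` (TBVs, true fixed effects, residuals),
#'   `config`, `seed`.
#' @export
simulate_study <- function(cfg, seed = 1L, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(as.integer(seed))
  traits <- cfg$traits
  Tn <- length(traits)

  n_com <- cfg$n_common_sires
  common_ids <- if (n_com > 0) sprintf("SCOM%04d", seq_len(n_com)) else
    character(0)
  common_tbv <- .rmvn(n_com, cfg$G0)

  pedigree <- list()
  performance <- list()
  tbv_rows <- list()
  herd_eff_rows <- list()
  hys_eff_rows <- list()
  resid_rows <- list()

  for (cc in names(cfg$countries)) {
    co <- cfg$countries[[cc]]
    n_own <- co$n_sires - n_com
    sire_ids <- c(common_ids,
                  if (n_own > 0) sprintf("%s_S%04d", cc, seq_len(n_own)))
    dam_ids <- sprintf("%s_D%05d", cc, seq_len(co$n_dams))
    cow_ids <- sprintf("%s_C%05d", cc, seq_len(co$n_cows))

    own_tbv <- .rmvn(max(n_own, 0), cfg$G0)
    sire_tbv <- rbind(common_tbv, own_tbv)
    dam_tbv <- .rmvn(co$n_dams, cfg$G0)

    # daughters per sire: every sire gets at least one recorded daughter
    w <- if (cfg$sire_usage == "skewed") {
      exp(-5 * (seq_len(co$n_sires) - 1) / co$n_sires)
    } else {
      rep(1, co$n_sires)
    }
    sire_of <- c(sample(seq_len(co$n_sires)),
                 sample(seq_len(co$n_sires), co$n_cows - co$n_sires,
                        replace = TRUE, prob = w))[seq_len(co$n_cows)]
    dam_of <- sample(co$n_dams, co$n_cows, replace = TRUE)

    mend <- .rmvn(co$n_cows, 0.5 * cfg$G0) # founder parents: F = 0
    cow_tbv <- 0.5 * (sire_tbv[sire_of, , drop = FALSE] +
                        dam_tbv[dam_of, , drop = FALSE]) + mend

    herds <- sprintf("%s_H%03d", cc, seq_len(co$n_herds))
    dam_herd <- sample(co$n_herds, co$n_dams, replace = TRUE)
    birth_herd <- dam_herd[dam_of]
    moved <- stats::runif(co$n_cows) < cfg$p_move
    prod_herd <- birth_herd
    if (any(moved) && co$n_herds > 1) {
      prod_herd[moved] <- vapply(birth_herd[moved], function(h) {
        sample(setdiff(seq_len(co$n_herds), h), 1)
      }, integer(1))
    }

    # each herd records calvings in a contiguous window of years
    span <- co$years[1]:co$years[2]
    win <- min(co$herd_window_years, length(span))
    herd_start <- sample(length(span) - win + 1L, co$n_herds, replace = TRUE)
    year <- span[herd_start[prod_herd] + sample(win, co$n_cows,
                                                replace = TRUE) - 1L]
    month <- sample(12L, co$n_cows, replace = TRUE)
    day <- sample(28L, co$n_cows, replace = TRUE)
    calving_date <- sprintf("%04d-%02d-%02d", year, month, day)
    hys <- make_hys(herds[prod_herd], calving_date, cfg$season_rule)

    age <- pmax(18, stats::rnorm(co$n_cows, co$mean_age, co$sd_age))

    herd_eff <- matrix(stats::rnorm(co$n_herds * Tn), co$n_herds) %*%
      diag(cfg$herd_sd, Tn)
    hys_lev <- sort(unique(hys))
    hys_eff <- matrix(stats::rnorm(length(hys_lev) * Tn),
                      length(hys_lev)) %*% diag(cfg$hys_sd, Tn)
    resid <- .rmvn(co$n_cows, cfg$R0)

    Y <- matrix(NA_real_, co$n_cows, Tn, dimnames = list(NULL, traits))
    for (ti in seq_len(Tn)) {
      Y[, ti] <- co$trait_means[ti] +
        herd_eff[birth_herd, ti] +
        hys_eff[match(hys, hys_lev), ti] +
        (if (cfg$uses_age[ti]) cfg$age_slope[ti] * (age - co$mean_age)
         else 0) +
        cow_tbv[, ti] + resid[, ti]
    }
    # missingness, preserving at least the first trait of each record
    for (ti in seq_len(Tn)) {
      if (cfg$missing_rate[ti] > 0) {
        drop <- stats::runif(co$n_cows) < cfg$missing_rate[ti]
        Y[drop, ti] <- NA_real_
      }
    }
    none <- rowSums(!is.na(Y)) == 0
    if (any(none)) {
      Y[none, 1] <- co$trait_means[1] + herd_eff[birth_herd[none], 1] +
        hys_eff[match(hys[none], hys_lev), 1] +
        (if (cfg$uses_age[1]) cfg$age_slope[1] * (age[none] - co$mean_age)
         else 0) + cow_tbv[none, 1] + resid[none, 1]
    }

    pedigree[[cc]] <- as_pedigree(tibble::tibble(
      animal_id = c(sire_ids, dam_ids, cow_ids),
      sire_id = c(rep(NA_character_, co$n_sires + co$n_dams),
                  sire_ids[sire_of]),
      dam_id = c(rep(NA_character_, co$n_sires + co$n_dams),
                 dam_ids[dam_of])))
    perf <- tibble::tibble(animal_id = cow_ids,
                           country = cc,
                           herd = herds[birth_herd],
                           prod_herd = herds[prod_herd],
                           calving_date = calving_date,
                           hys = hys,
                           age_months = age)
    for (ti in seq_len(Tn)) perf[[traits[ti]]] <- Y[, ti]
    performance[[cc]] <- perf

    tbv_rows[[cc]] <- tibble::tibble(
      animal_id = rep(c(sire_ids, dam_ids, cow_ids), each = Tn),
      trait = rep(traits, co$n_sires + co$n_dams + co$n_cows),
      tbv = as.vector(t(rbind(sire_tbv, dam_tbv, cow_tbv))),
      country = cc)
    herd_eff_rows[[cc]] <- tibble::tibble(
      country = cc, herd = rep(herds, each = Tn),
      trait = rep(traits, co$n_herds),
      value = as.vector(t(herd_eff)))
    hys_eff_rows[[cc]] <- tibble::tibble(
      country = cc, hys = rep(hys_lev, each = Tn),
      trait = rep(traits, length(hys_lev)),
      value = as.vector(t(hys_eff)))
    resid_rows[[cc]] <- tibble::tibble(
      animal_id = rep(cow_ids, each = Tn),
      trait = rep(traits, co$n_cows),
      residual = as.vector(t(resid)),
      country = cc)
  }

  tbv <- dplyr::bind_rows(tbv_rows)
  # common sires appear once per country with identical TBV; keep one copy
  tbv <- dplyr::distinct(tbv, .data$animal_id, .data$trait,
                         .keep_all = TRUE)
  truth <- list(tbv = tbv,
                herd_effects = dplyr::bind_rows(herd_eff_rows),
                hys_effects = dplyr::bind_rows(hys_eff_rows),
                residuals = dplyr::bind_rows(resid_rows))
  study <- structure(list(pedigree = pedigree, performance = performance,
                          truth = truth, config = cfg, seed = seed),
                     class = "sim_study")
  if (!is.null(out_dir)) write_sim_study(study, out_dir)
  study
}

#' @export
#' @method print sim_study
print.sim_study <- function(x, ...) {
  for (cc in names(x$performance)) {
    cat(cc, ": ", nrow(x$performance[[cc]]), " records, ",
        nrow(x$pedigree[[cc]]), " pedigree animals\n", sep = "")
  }
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Emits `pedigree_<CC>.csv` and `performance_<CC>.csv` per country (the
#' standard dialects), `truth.tsv` (`animal_id,trait,tbv`) and
#' `sim_manifest.yml` recording the seed, configuration digest and the
#' declared-assumption truth parameters.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @export
write_sim_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  traits <- study$config$traits
  for (cc in names(study$performance)) {
    write_pedigree(study$pedigree[[cc]],
                   file.path(dir, paste0("pedigree_", cc, ".csv")))
    perf <- study$performance[[cc]]
    out <- perf[, c("animal_id", "country", "herd", "prod_herd",
                    "calving_date", "age_months", traits)]
    names(out)[names(out) %in% traits] <- tolower(traits)
    readr::write_csv(out, file.path(dir,
                                    paste0("performance_", cc, ".csv")),
                     na = "")
  }
  readr::write_tsv(study$truth$tbv[, c("animal_id", "trait", "tbv")],
                   file.path(dir, "truth.tsv"))
  manifest <- list(
    generator = "herdlink::simulate_study",
    version = as.character(utils::packageVersion("herdlink")),
    seed = study$seed,
    config_digest = rlang::hash(study$config),
    truth_parameters_are_declared_assumptions = TRUE,
    sigma_g = as.numeric(study$config$sigma_g),
    h2 = as.numeric(study$config$h2),
    genetic_cor = as.numeric(study$config$genetic_cor),
    season_rule = study$config$season_rule)
  yaml::write_yaml(manifest, file.path(dir, "sim_manifest.yml"))
  invisible(dir)
}

#' Diagnostics on the simulated truth
#'
#' Summarises what the generator actually realised: the covariance of the
#' founder TBVs against the configured G0, the realised heritability per
#' trait (TBV variance over TBV-plus-residual variance among recorded cows)
#' and the cross-country connectedness counts.
#'
#' @param study A [simulate_study()] result.
#' @return A list with `realized_G0`, `configured_G0`, `realized_h2` and
#'   `connectedness` (see [connectedness_summary()]).
#' @export
truth_diagnostics <- function(study) {
  stopifnot(inherits(study, "sim_study"))
  cfg <- study$config
  traits <- cfg$traits
  founder_ids <- unlist(lapply(study$pedigree, function(p)
    p$animal_id[is.na(p$sire_id) & is.na(p$dam_id)]))
  founder_ids <- unique(founder_ids)
  tb <- study$truth$tbv
  fw <- tidyr::pivot_wider(tb[tb$animal_id %in% founder_ids,
                              c("animal_id", "trait", "tbv")],
                           names_from = "trait", values_from = "tbv")
  realized_G0 <- stats::cov(as.matrix(fw[, traits]))

  rec <- dplyr::bind_rows(study$performance)
  cw <- tidyr::pivot_wider(tb[tb$animal_id %in% rec$animal_id,
                              c("animal_id", "trait", "tbv")],
                           names_from = "trait", values_from = "tbv")
  rw <- tidyr::pivot_wider(study$truth$residuals[,
                             c("animal_id", "trait", "residual")],
                           names_from = "trait", values_from = "residual")
  h2 <- vapply(traits, function(tr) {
    va <- stats::var(cw[[tr]])
    ve <- stats::var(rw[[tr]])
    va / (va + ve)
  }, numeric(1))

  list(realized_G0 = realized_G0,
       configured_G0 = cfg$G0,
       realized_h2 = h2,
       configured_h2 = cfg$h2,
       connectedness = connectedness_summary(study$pedigree,
                                             study$performance))
}
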