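#' Merge country pedigrees into one evaluation pedigree
#'
#' Union of the per-country pedigrees. Identifiers are expected to be
#' globally unique already except for deliberately shared sires (the
#' simulator prefixes country-specific animals and leaves common sires
#' unprefixed); an id recorded with conflicting parents in two files is an
#' error rather than a silent overwrite.
#'
#' @param pedigrees Named list of [pedigree][as_pedigree] tibbles.
#' @return A single merged `pedigree`.
#' @export
merge_pedigrees <- function(pedigrees) {
  all <- dplyr::bind_rows(lapply(pedigrees, function(p)
    tibble::as_tibble(p)[, c("animal_id", "sire_id", "dam_id")]))
  all <- dplyr::distinct(all)
  dup <- all$animal_id[duplicated(all$animal_id)]
  if (length(dup)) {
    stop("animal(s) with conflicting parentage across pedigrees: ",
         paste(utils::head(unique(dup), 5), collapse = ", "),
         call. = FALSE)
  }
  as_pedigree(all)
}

#' Cross-country connectedness summary
#'
#' Counts the sires that genetically connect the countries: a "common sire"
#' has recorded daughters in at least two countries. Sires present in
#' several pedigrees but with daughters in fewer than two countries are
#' flagged as pedigree-link-only.
#'
#' @param pedigrees Named list of per-country pedigrees.
#' @param records Named list of per-country performance tibbles.
#' @return A list: `n_common_sires`, `daughters` (tibble `sire_id, country,
#'   n_daughters` for common sires), `pedigree_link_only` (character ids).
#' @export
connectedness_summary <- function(pedigrees, records) {
  stopifnot(identical(sort(names(pedigrees)), sort(names(records))))
  sire_daughters <- dplyr::bind_rows(lapply(names(records), function(cc) {
    ped <- pedigrees[[cc]]
    rec <- records[[cc]]
    sires <- ped$sire_id[match(rec$animal_id, ped$animal_id)]
    sires <- sires[!is.na(sires)]
    if (!length(sires)) return(tibble::tibble(sire_id = character(0),
                                              country = character(0),
                                              n_daughters = integer(0)))
    tb <- table(sires)
    tibble::tibble(sire_id = names(tb), country = cc,
                   n_daughters = as.integer(tb))
  }))
  per_sire <- dplyr::summarise(
    dplyr::group_by(sire_daughters, .data$sire_id),
    n_countries = dplyr::n_distinct(.data$country), .groups = "drop")
  common <- per_sire$sire_id[per_sire$n_countries >= 2]
  shared_in_ped <- names(which(table(unlist(lapply(pedigrees, function(p)
    unique(stats::na.omit(p$sire_id))))) >= 2))
  link_only <- setdiff(shared_in_ped, common)
  list(n_common_sires = length(common),
       daughters = sire_daughters[sire_daughters$sire_id %in% common, ],
       pedigree_link_only = sort(link_only))
}

#' Run the full within- versus across-country study
#'
#' The experiment the package exists for: evaluate each country's data with
#' the within-country animal model, evaluate the pooled data with an
#' additional country fixed effect (an independent solve on the merged data,
#' re-using nothing from the within-country runs), then compare accuracies
#' and predicted top-k selection gains.
#'
#' @param config One of: a `sim_study` from [simulate_study()] (tibbles used
#'   directly, truth variance components as default), or a
#'   [read_config()] object whose `study` section names per-country
#'   pedigree/performance files (then `varcomp` must supply G0/R0 or
#'   request `source: reml`), or a config whose `simulate` section is used
#'   to generate the data first.
#' @param seed Seed for any simulation stage.
#' @param out_dir Optional directory for TSV artifacts and the run manifest.
#' @param scenarios Top-k scenario vector.
#' @param varcomp Optional [variance_components()] (or named list per
#'   source) overriding whatever the config supplies.
#' @param rho_mode Accuracy aggregation, see [candidate_accuracy()].
#' @param dedup_common Deduplicate common sires in the pooled candidate
#'   count (default keeps the summed sire lists).
#' @param stages `"all"`, or a single stage (`"evaluate"`, `"reml"`,
#'   `"gains"`) for the CLI.
#' @param reliability_for Passed to [run_evaluation()].
#' @param verbose Log stage progress to stderr.
#' @param reml_control Named overrides (`tol`, `max_iter`, ...) forwarded to
#'   [em_reml()] when `stages = "reml"`.
#' @return A `comparison_report`: list with `accuracy` (per country x trait:
#'   mean candidate-sire accuracy within vs pooled), `gains` (the
#'   [gain_table()]), `benefit` (per trait x k x source: `pct_pgg` and
#'   `benefit = 100 - pct_pgg`), `connectedness`, `evaluations`, `varcomp`,
#'   `manifest`.
#' @export
run_study <- function(config, seed = 1L, out_dir = NULL,
                      scenarios = c(5, 10, 25, 50, 75, 100),
                      varcomp = NULL, rho_mode = "mean_all",
                      dedup_common = FALSE, stages = "all",
                      reliability_for = "sires", verbose = FALSE,
                      reml_control = list()) {
  log_ <- function(...) if (verbose) message("[run_study] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # ---- inputs ----
  if (inherits(config, "sim_study")) {
    study <- config
  } else if (!is.null(config$study) && !is.null(config$study$countries)) {
    study <- stage("read_inputs", {
      peds <- lapply(config$study$countries, function(x)
        read_pedigree(x$pedigree))
      perfs <- lapply(config$study$countries, function(x)
        read_performance(x$performance,
                         season_rule = config$model$season_rule %||%
                           "quarter"))
      list(pedigree = peds, performance = perfs, config = NULL)
    })
  } else if (!is.null(config$simulate) || is.null(config)) {
    study <- stage("simulate",
                   simulate_study(do.call(sim_config,
                                          config$simulate %||% list()),
                                  seed = seed))
  } else {
    stop("config carries neither data files, a simulate section, nor ",
         "simulated tibbles", call. = FALSE)
  }
  countries <- names(study$performance)
  if (length(countries) < 2) {
    stop("the pooled run needs at least 2 countries; got ",
         length(countries), call. = FALSE)
  }
  if (any(scenarios <= 0)) stop("scenario k values must be positive",
                                call. = FALSE)

  # ---- variance components ----
  vc <- stage("varcomp", {
    if (!is.null(varcomp)) {
      varcomp
    } else if (inherits(config, "sim_study")) {
      config$config$varcomp
    } else if (!is.null(config$varcomp) &&
               !identical(config$varcomp$source, "reml")) {
      variance_components(unlist(config$varcomp$traits),
                          matrix(unlist(config$varcomp$G0),
                                 length(config$varcomp$traits)),
                          matrix(unlist(config$varcomp$R0),
                                 length(config$varcomp$traits)))
    } else if (!is.null(study$config)) {
      study$config$varcomp
    } else {
      NULL
    }
  })
  traits <- if (inherits(vc, "variance_components")) {
    vc$traits
  } else if (is.list(vc) && length(vc)) {
    vc[[1]]$traits
  } else if (!is.null(config$model) && !is.null(config$model$traits)) {
    unlist(config$model$traits)
  } else {
    intersect(c("MY305", "AFC", "CI1"), names(study$performance[[1]]))
  }

  if (is.null(vc) && !identical(stages, "reml")) {
    stop("no variance components available: supply them in the config, ",
         "pass `varcomp`, or run the reml stage first - evaluation ",
         "never assumes default variances", call. = FALSE)
  }
  vc_by_source <- if (is.null(vc)) NULL else
    if (inherits(vc, "variance_components")) {
      src <- c(paste0("within_", countries), "multi")
      stats::setNames(rep(list(vc), length(src)), src)
    } else vc

  if (identical(stages, "reml")) {
    fits <- stage("reml", lapply(countries, function(cc) {
      do.call(em_reml, c(list(study$performance[[cc]],
                              study$pedigree[[cc]],
                              model_spec(traits, varcomp = NULL),
                              start = if (inherits(vc,
                                "variance_components")) vc),
                         reml_control))
    }))
    names(fits) <- countries
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      for (cc in countries) {
        write_config(list(varcomp = list(
          traits = traits,
          G0 = as.list(as.data.frame(fits[[cc]]$varcomp$G0)),
          R0 = as.list(as.data.frame(fits[[cc]]$varcomp$R0)))),
          file.path(out_dir, paste0("varcomp_", cc, ".yml")))
      }
    }
    return(fits)
  }

  # ---- evaluations ----
  log_("within-country evaluations")
  within <- stage("within_evaluations", {
    res <- lapply(countries, function(cc) {
      run_evaluation(study$performance[[cc]], study$pedigree[[cc]],
                     model_spec(traits,
                                varcomp = vc_by_source[[
                                  paste0("within_", cc)]],
                                pooled = FALSE),
                     reliability_for = reliability_for,
                     model_tag = paste0("within_", cc))
    })
    names(res) <- paste0("within_", countries)
    res
  })
  log_("pooled evaluation")
  merged_ped <- stage("merge_pedigrees", merge_pedigrees(study$pedigree))
  pooled_rec <- dplyr::bind_rows(study$performance)
  multi <- stage("pooled_evaluation",
    run_evaluation(pooled_rec, merged_ped,
                   model_spec(traits, varcomp = vc_by_source$multi,
                              pooled = TRUE),
                   reliability_for = reliability_for,
                   model_tag = "multi"))
  evaluations <- c(within, list(multi = multi))
  conn <- connectedness_summary(study$pedigree, study$performance)

  if (identical(stages, "evaluate")) {
    if (!is.null(out_dir)) .write_study_artifacts(
      evaluations, NULL, conn, config, seed, out_dir, rho_mode,
      dedup_common, study)
    return(evaluations)
  }

  # ---- gains & comparison ----
  log_("gain tables")
  gains <- stage("gain_table",
    gain_table(evaluations, vc_by_source, scenarios = scenarios,
               mode = rho_mode, dedup_common = dedup_common))
  accuracy <- stage("accuracy_comparison",
    dplyr::bind_rows(lapply(countries, function(cc) {
      cands <- within[[paste0("within_", cc)]]$sires
      dplyr::bind_rows(lapply(traits, function(tr) {
        tibble::tibble(
          country = cc, trait = tr,
          within_accuracy = candidate_accuracy(
            within[[paste0("within_", cc)]], cands, tr),
          multi_accuracy = candidate_accuracy(multi, cands, tr))
      }))
    })))
  benefit <- tibble::as_tibble(gains)[, c("trait", "scenario_k", "source",
                                          "pct_pgg")]
  benefit$benefit <- 100 - benefit$pct_pgg

  manifest <- run_manifest(
    if (inherits(config, "sim_study")) config$config else config,
    seed,
    decisions = list(season_rule = "quarter",
                     pooled_candidates = if (dedup_common)
                       "deduplicated union" else "summed sire lists",
                     rho_mode = rho_mode,
                     hys_nesting = "country-nested (herds never span countries)"))

  report <- structure(list(accuracy = accuracy, gains = gains,
                           benefit = benefit, connectedness = conn,
                           evaluations = evaluations,
                           varcomp = vc_by_source,
                           manifest = manifest),
                      class = "comparison_report")
  if (!is.null(out_dir)) {
    stage("write_artifacts",
          .write_study_artifacts(evaluations, report, conn, config, seed,
                                 out_dir, rho_mode, dedup_common, study))
  }
  report
}

.write_study_artifacts <- function(evaluations, report, conn, config, seed,
                                   out_dir, rho_mode, dedup_common, study) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (tag in names(evaluations)) {
    write_evaluation(evaluations[[tag]],
                     file.path(out_dir, paste0("ebv_", tag, ".tsv")),
                     file.path(out_dir, paste0("fixed_", tag, ".tsv")))
  }
  if (!is.null(report)) {
    write_gain_table(report$gains, file.path(out_dir, "gains.tsv"))
    readr::write_tsv(report$accuracy, file.path(out_dir, "accuracy.tsv"))
    readr::write_tsv(report$benefit, file.path(out_dir, "benefit.tsv"))
    summary_path <- file.path(out_dir, "summary.txt")
    con <- file(summary_path, "w")
    on.exit(close(con))
    writeLines(utils::capture.output(print(report)), con)
    yaml::write_yaml(report$manifest,
                     file.path(out_dir, "run_manifest.yml"))
  }
  invisible(out_dir)
}

#' @export
#' @method print comparison_report
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  cat("common sires with daughters in both countries: ",
      x$connectedness$n_common_sires, "\n", sep = "")
  cat("\nMean candidate-sire accuracy (within vs pooled):\n")
  print(as.data.frame(x$accuracy), row.names = FALSE, digits = 3)
  cat("\nPredicted gain as % of the pooled evaluation (by top-k):\n")
  wide <- tidyr::pivot_wider(x$benefit[, c("trait", "scenario_k", "source",
                                           "pct_pgg")],
                             names_from = "source", values_from = "pct_pgg")
  print(as.data.frame(wide), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
#' @method tidy comparison_report
tidy.comparison_report <- function(x, ...) x$benefit

#' @importFrom generics glance
#' @export
#' @method glance comparison_report
glance.comparison_report <- function(x, ...) {
  tibble::tibble(
    n_common_sires = x$connectedness$n_common_sires,
    n_sources = length(x$evaluations),
    mean_within_accuracy = mean(x$accuracy$within_accuracy),
    mean_multi_accuracy = mean(x$accuracy$multi_accuracy))
}

#' @importFrom ggplot2 autoplot
#' @export
#' @method autoplot comparison_report
autoplot.comparison_report <- function(object, ...) {
  autoplot(object$gains, ...)
}
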