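#' Selection intensity for top-k truncation selection
#'
#' Infinite-population truncated-normal intensity: with selected proportion
#' `p = k/n`, truncation point `z` the upper-p standard-normal quantile, the
#' mean standardised superiority of the selected group is
#' `i = dnorm(z) / p`. `i = 0` when everything is kept (`k = n`).
#'
#' @param k Number of candidates retained (top-k by EBV).
#' @param n Number of candidates.
#' @return Selection intensity in genetic-standard-deviation units.
#' @examples
#' selection_intensity(5, 505)   # ~2.67
#' selection_intensity(50, 103)  # ~0.82
#' @export
selection_intensity <- function(k, n) {
  if (length(k) > 1 || length(n) > 1) {
    return(mapply(selection_intensity, k, n))
  }
  if (!is.finite(k) || !is.finite(n) || k <= 0 || n <= 0) {
    stop("k and n must be positive", call. = FALSE)
  }
  if (k > n) stop("cannot select the top ", k, " of ", n, call. = FALSE)
  p <- k / n
  if (p >= 1) return(0)
  z <- stats::qnorm(1 - p)
  stats::dnorm(z) / p
}

#' Accuracy of selection for a candidate set
#'
#' The breeders'-equation accuracy rho is taken as the arithmetic mean of the
#' candidates' EBV accuracies (square roots of reliability). `mean_top_k`
#' instead averages over the k sires actually selected on EBV.
#'
#' @param result A [run_evaluation()] result with reliabilities computed for
#'   the candidates.
#' @param candidates Character vector of candidate (sire) ids; defaults to
#'   the sires recorded in `result`.
#' @param trait Trait name.
#' @param mode `"mean_all"` (default) or `"mean_top_k"`.
#' @param k Required when `mode = "mean_top_k"`.
#' @return A single accuracy in `[0, 1]`.
#' @export
candidate_accuracy <- function(result, candidates = result$sires, trait,
                               mode = c("mean_all", "mean_top_k"), k = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(result, "herd_eval"))
  if (is.null(candidates) || !length(candidates)) {
    stop("empty candidate set", call. = FALSE)
  }
  sol <- result$solutions
  sol <- sol[sol$trait == trait & sol$animal_id %in% candidates, ,
             drop = FALSE]
  if (!nrow(sol)) stop("no candidates evaluated for trait ", trait,
                       call. = FALSE)
  if (anyNA(sol$accuracy)) {
    stop("candidates lack computed reliabilities for trait ", trait,
         "; rerun the evaluation with reliability_for covering them",
         call. = FALSE)
  }
  if (mode == "mean_top_k") {
    stopifnot(!is.null(k))
    top <- rank_sires(result, trait, candidates)[seq_len(min(k, nrow(sol)))]
    sol <- sol[sol$animal_id %in% top, , drop = FALSE]
  }
  mean(sol$accuracy)
}

#' Predicted genetic gain per generation (breeders' equation)
#'
#' `R = i * rho * sigma_g`: selection intensity times accuracy of selection
#' times the genetic standard deviation, in trait units per generation.
#'
#' @param i Selection intensity.
#' @param rho Accuracy of selection.
#' @param sigma_g Genetic standard deviation (trait units).
#' @export
predicted_gain <- function(i, rho, sigma_g) {
  stopifnot(all(i >= 0), all(rho >= 0), all(sigma_g >= 0))
  i * rho * sigma_g
}

#' Percent of multi-country gain realised by a source
#'
#' @param pgg_source Predicted gain of the within-country (or any) source.
#' @param pgg_multi Predicted gain of the multi-country evaluation.
#' @return `100 * pgg_source / pgg_multi`.
#' @export
percent_gain <- function(pgg_source, pgg_multi) {
  if (any(pgg_multi <= 0)) {
    stop("multi-country gain must be positive to express a percentage",
         call. = FALSE)
  }
  # ratio first: a source equal to the reference is exactly 100
  100 * (pgg_source / pgg_multi)
}

#' Rank sires on EBV
#'
#' Descending EBV; ties broken by ascending animal id so the ranking is
#' deterministic.
#'
#' @inheritParams candidate_accuracy
#' @return Character vector of candidate ids, best first.
#' @export
rank_sires <- function(result, trait, candidates = result$sires) {
  stopifnot(inherits(result, "herd_eval"))
  sol <- result$solutions
  sol <- sol[sol$trait == trait & sol$animal_id %in% candidates, ,
             drop = FALSE]
  sol$animal_id[order(-sol$ebv, sol$animal_id)]
}

#' Gain table across traits, top-k scenarios and evaluation sources
#'
#' Builds the within- versus across-country comparison: one row per
#' trait x scenario x source with selection intensity, mean candidate
#' accuracy, genetic SD, predicted gain `pgg = i * rho * sigma_g` (held at
#' full precision; rounding is presentation-only) and `pct_pgg`, the gain as
#' a percentage of the multi-country gain for the same trait and k.
#'
#' The multi-country candidate count defaults to the *sum* of the per-country
#' sire-list sizes without removing sires common to both lists;
#' `dedup_common = TRUE` uses the deduplicated union instead.
#'
#' @param results Named list of [run_evaluation()] results; must contain a
#'   `"multi"` element, the others are the within-country sources (e.g.
#'   `within_KE`, `within_SA`).
#' @param varcomp Named list of [variance_components()] per source (a single
#'   object is recycled); `sqrt(diag(G0))` supplies sigma_g.
#' @param scenarios Integer vector of top-k values.
#' @param candidates Optional named list of candidate id vectors per source;
#'   defaults to each evaluation's recorded sires.
#' @param mode Accuracy mode passed to [candidate_accuracy()].
#' @param dedup_common Deduplicate common sires in the pooled candidate
#'   count?
#' @return A tibble of class `gain_table` with columns `trait, scenario_k,
#'   source, n_candidates, i, rho, sigma_g, pgg, pct_pgg`.
#' @export
gain_table <- function(results, varcomp, scenarios = c(5, 10, 25, 50, 75, 100),
                       candidates = NULL, mode = "mean_all",
                       dedup_common = FALSE) {
  stopifnot(is.list(results), "multi" %in% names(results))
  if (any(scenarios <= 0)) stop("scenario k values must be positive",
                                call. = FALSE)
  sources <- names(results)
  if (inherits(varcomp, "variance_components")) {
    varcomp <- stats::setNames(rep(list(varcomp), length(sources)), sources)
  }
  missing_vc <- setdiff(sources, names(varcomp))
  if (length(missing_vc)) {
    stop("no variance components for source(s): ",
         paste(missing_vc, collapse = ", "), call. = FALSE)
  }
  if (is.null(candidates)) {
    candidates <- lapply(results, function(r) r$sires)
  }
  within_sources <- setdiff(sources, "multi")
  n_cand <- vapply(sources, function(s) length(candidates[[s]]), integer(1))
  names(n_cand) <- sources
  if (!dedup_common) {
    n_cand[["multi"]] <- sum(vapply(within_sources, function(s)
      length(candidates[[s]]), integer(1)))
  }
  traits <- unique(results$multi$solutions$trait)

  rows <- purrr::map_dfr(traits, function(tr) {
    purrr::map_dfr(scenarios, function(k) {
      purrr::map_dfr(sources, function(s) {
        n <- n_cand[[s]]
        kk <- min(k, n)
        rho <- candidate_accuracy(results[[s]], candidates[[s]], tr,
                                  mode = mode, k = kk)
        sg <- unname(sqrt(diag(varcomp[[s]]$G0))[match(tr,
                                                       varcomp[[s]]$traits)])
        ii <- selection_intensity(kk, n)
        tibble::tibble(trait = tr, scenario_k = k, source = s,
                       n_candidates = n, i = ii, rho = rho, sigma_g = sg,
                       pgg = predicted_gain(ii, rho, sg))
      })
    })
  })
  multi_ref <- rows[rows$source == "multi", c("trait", "scenario_k", "pgg")]
  names(multi_ref)[3] <- "pgg_multi"
  rows <- dplyr::left_join(rows, multi_ref, by = c("trait", "scenario_k"))
  # k >= n in the pooled list means no selection differential at all;
  # percentages of a zero gain are undefined rather than an error here
  rows$pct_pgg <- ifelse(rows$pgg_multi > 0,
                         100 * (rows$pgg / rows$pgg_multi), NA_real_)
  rows$pgg_multi <- NULL
  class(rows) <- c("gain_table", class(rows))
  rows
}

#' Write a gain table as TSV
#'
#' Emits the full-precision columns plus 2-decimal presentation companions
#' (`*_2dp`), mirroring how such tables are printed.
#'
#' @param gt A [gain_table()].
#' @param path Output path.
#' @export
write_gain_table <- function(gt, path) {
  out <- tibble::as_tibble(gt)
  for (col in c("i", "rho", "sigma_g", "pgg", "pct_pgg")) {
    out[[paste0(col, "_2dp")]] <- round(out[[col]], 2)
  }
  readr::write_tsv(out, path)
  invisible(path)
}

#' Plot predicted gain percentages by source and scenario
#'
#' @param object A `gain_table`.
#' @param ... Unused.
#' @importFrom ggplot2 autoplot
#' @export
#' @method autoplot gain_table
autoplot.gain_table <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = factor(.data$scenario_k),
                               y = .data$pct_pgg,
                               fill = .data$source)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 100, linetype = 2) +
    ggplot2::facet_wrap(~trait) +
    ggplot2::labs(x = "top-k sires selected",
                  y = "% of multi-country predicted gain") +
    ggplot2::theme_minimal()
}
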