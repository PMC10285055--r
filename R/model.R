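#' Declare a trait analysed by the animal model
#'
#' @param name Trait name; the column of the same name in the performance
#'   table holds the observations. `"MY305"`, `"AFC"` and `"CI1"` are the
#'   conventional dairy traits (305-day milk yield in kg, age at first
#'   calving in months, first calving interval in months).
#' @param uses_age_covariate Include the calving-age covariate for this
#'   trait? Defaults to `TRUE` except for `AFC`, whose observation *is* the
#'   calving age and therefore never carries the covariate.
#' @return A `trait_spec` list.
#' @export
trait_spec <- function(name, uses_age_covariate = !identical(name, "AFC")) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (identical(name, "AFC") && isTRUE(uses_age_covariate)) {
    stop("AFC cannot carry the calving-age covariate", call. = FALSE)
  }
  structure(list(name = name, uses_age_covariate = isTRUE(uses_age_covariate)),
            class = "trait_spec")
}

#' Genetic and residual covariance components
#'
#' Bundles the trait-by-trait genetic covariance matrix G0 (the covariance of
#' the random animal effects, in squared trait units) and the residual
#' covariance matrix R0. The square roots of `diag(G0)` are the genetic
#' standard deviations entering the breeders' equation.
#'
#' @param traits Character vector of trait names, fixing the row/column order.
#' @param G0,R0 Symmetric positive-definite matrices (or scalars for a single
#'   trait).
#' @return A `variance_components` object.
#' @export
variance_components <- function(traits, G0, R0) {
  t <- length(traits)
  G0 <- as.matrix(G0)
  R0 <- as.matrix(R0)
  for (nm in c("G0", "R0")) {
    M <- get(nm)
    if (!all(dim(M) == c(t, t))) {
      stop(nm, " must be ", t, "x", t, " for traits ",
           paste(traits, collapse = ", "), call. = FALSE)
    }
    if (max(abs(M - t(M))) > 1e-8 * max(1, max(abs(M)))) {
      stop(nm, " is not symmetric", call. = FALSE)
    }
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) {
      stop(nm, " is not positive definite (smallest eigenvalue ",
           signif(min(ev), 4), ")", call. = FALSE)
    }
  }
  dimnames(G0) <- dimnames(R0) <- list(traits, traits)
  structure(list(traits = traits, G0 = G0, R0 = R0),
            class = "variance_components")
}

#' @export
#' @method print variance_components
print.variance_components <- function(x, ...) {
  cat("<variance_components> traits:", paste(x$traits, collapse = ", "), "\n")
  cat("genetic SD:", paste(signif(sqrt(diag(x$G0)), 4), collapse = ", "),
      " heritability:",
      paste(signif(diag(x$G0) / (diag(x$G0) + diag(x$R0)), 3),
            collapse = ", "), "\n")
  invisible(x)
}

#' Animal-model specification
#'
#' Describes the multi-trait animal model: each trait's observation is the
#' sum of a birth-herd effect, a herd-year-season (HYS) contemporary-group
#' effect, a calving-age covariate (where applicable), the random additive
#' genetic effect of the animal and a residual. The pooled variant for data
#' merged across countries adds a fixed country effect.
#'
#' @param traits Character vector of trait names or a list of [trait_spec()]s.
#' @param varcomp A [variance_components()] object covering the same traits,
#'   or `NULL` if components will be estimated first with [em_reml()].
#'   Evaluation refuses to run without components; there are no silent
#'   default variances.
#' @param pooled Is this the across-country model with a country fixed
#'   effect?
#' @return A `model_spec` object.
#' @export
model_spec <- function(traits, varcomp = NULL, pooled = FALSE) {
  if (is.character(traits)) traits <- lapply(traits, trait_spec)
  if (inherits(traits, "trait_spec")) traits <- list(traits)
  stopifnot(all(vapply(traits, inherits, logical(1), "trait_spec")))
  nms <- vapply(traits, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate trait names", call. = FALSE)
  if (!is.null(varcomp)) {
    stopifnot(inherits(varcomp, "variance_components"))
    if (!identical(varcomp$traits, nms)) {
      stop("variance components cover traits [",
           paste(varcomp$traits, collapse = ", "),
           "] but the model declares [", paste(nms, collapse = ", "), "]",
           call. = FALSE)
    }
  }
  structure(list(traits = traits, trait_names = nms,
                 varcomp = varcomp, pooled = isTRUE(pooled)),
            class = "model_spec")
}

#' @export
#' @method print model_spec
print.model_spec <- function(x, ...) {
  cat("<model_spec> ", if (x$pooled) "pooled (country effect)" else
    "within-country", "; traits: ", paste(x$trait_names, collapse = ", "),
    "\n", sep = "")
  invisible(x)
}
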