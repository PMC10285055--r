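#' @importFrom rlang .data
NULL

# union-find for bipartite connectivity of factor levels
.uf_components <- function(a, b) {
  # a, b: integer level codes of the two factors per record
  nb <- max(b)
  n <- max(a) + nb
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (r in seq_along(a)) {
    ra <- find(a[r])
    rb <- find(b[r] + max(a))
    if (ra != rb) parent[rb] <- ra
  }
  # component id per b-level
  vapply(seq_len(nb), function(l) find(l + max(a)), integer(1))
}

#' Build the design structures for the mixed-model equations
#'
#' Turns a performance table into per-trait incidence structures for the
#' fixed effects (birth herd, HYS contemporary group, country when pooled,
#' centred calving-age covariate) and the animal effect over the whole
#' pedigree. Animals without records still receive equations; their
#' information flows through the relationship matrix only.
#'
#' The fixed part of the model is rank-deficient by construction (HYS levels
#' aggregate to herds, herds aggregate to countries). A deterministic
#' constraint set restores full rank: the last country level is fixed to
#' zero; the last herd within every country except the last is fixed to
#' zero; and within every connected component of the herd-HYS bipartite
#' record graph the last HYS level is fixed to zero. Constrained levels are
#' reported with estimate zero; estimable contrasts are unaffected by the
#' choice.
#'
#' @param records Performance tibble with columns `animal_id`, `herd`,
#'   `hys`, `age_months`, one column per trait (NA = missing) and `country`
#'   when `spec$pooled`.
#' @param ped A [pedigree][as_pedigree].
#' @param spec A [model_spec()].
#' @return An `mme_design` list used by [assemble_mme()].
#' @export
build_design <- function(records, ped, spec) {
  ped <- as_pedigree(ped)
  stopifnot(inherits(spec, "model_spec"))
  need <- c("animal_id", "herd", "hys", spec$trait_names)
  if (spec$pooled) need <- c(need, "country")
  uses_age <- vapply(spec$traits, `[[`, logical(1), "uses_age_covariate")
  if (any(uses_age)) need <- c(need, "age_months")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("performance table lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  unknown_animals <- setdiff(records$animal_id, ped$animal_id)
  if (length(unknown_animals)) {
    stop("record animal(s) absent from pedigree: ",
         paste(utils::head(unknown_animals, 5), collapse = ", "),
         call. = FALSE)
  }
  n_rec <- nrow(records)
  Tn <- length(spec$trait_names)
  obs <- vapply(spec$trait_names, function(tr) !is.na(records[[tr]]),
                logical(n_rec))
  obs <- matrix(obs, nrow = n_rec,
                dimnames = list(NULL, spec$trait_names))
  empty <- colSums(obs) == 0
  if (any(empty)) {
    stop("trait column(s) entirely missing: ",
         paste(spec$trait_names[empty], collapse = ", "), call. = FALSE)
  }
  # records observing none of the modelled traits carry no information here
  n_dropped <- sum(rowSums(obs) == 0)
  if (n_dropped > 0) {
    keep <- rowSums(obs) > 0
    records <- records[keep, , drop = FALSE]
    obs <- obs[keep, , drop = FALSE]
    n_rec <- nrow(records)
  }
  if (any(uses_age)) {
    age_needed <- rowSums(obs[, uses_age, drop = FALSE]) > 0
    bad_age <- age_needed &
      (is.na(records$age_months) | records$age_months <= 0)
    if (any(bad_age)) {
      stop(sum(bad_age), " record(s) need a positive calving age for a ",
           "trait using the age covariate", call. = FALSE)
    }
  }

  apos <- match(records$animal_id, ped$animal_id)
  n_animals <- nrow(ped)

  per_trait <- vector("list", Tn)
  names(per_trait) <- spec$trait_names
  eq_rows <- list()
  row_counter <- 0L

  for (ti in seq_len(Tn)) {
    tr <- spec$trait_names[ti]
    sel <- which(obs[, ti])
    rec <- records[sel, , drop = FALSE]
    herd_lev <- sort(unique(rec$herd))
    hys_lev <- sort(unique(rec$hys))
    hcode <- match(rec$herd, herd_lev)
    kcode <- match(rec$hys, hys_lev)

    drop_herd <- character(0)
    drop_country <- character(0)
    country_lev <- character(0)
    if (spec$pooled) {
      country_lev <- sort(unique(rec$country))
      h2c <- tapply(rec$country, rec$herd, function(x) unique(x))
      multi <- names(h2c)[lengths(h2c) > 1]
      if (length(multi)) {
        stop("herd(s) span more than one country: ",
             paste(utils::head(multi, 5), collapse = ", "), call. = FALSE)
      }
      h2c <- vapply(h2c, `[[`, character(1), 1)[herd_lev]
      drop_country <- country_lev[length(country_lev)]
      keep_c <- setdiff(country_lev, drop_country)
      drop_herd <- vapply(keep_c, function(cc) {
        hh <- herd_lev[h2c == cc]
        hh[length(hh)]
      }, character(1))
    }
    comp <- .uf_components(hcode, kcode)
    drop_hys <- vapply(split(seq_along(hys_lev), comp),
                       function(ix) hys_lev[max(ix)], character(1))

    keep_herd <- setdiff(herd_lev, drop_herd)
    keep_hys <- setdiff(hys_lev, drop_hys)
    keep_country <- setdiff(country_lev, drop_country)
    # the age regression is nested within country in the pooled model
    # (own slope per country, centred at the country mean), so a pooled run
    # restricted to one country is the same model as the within-country run.
    # A slope is only fitted where age varies within the herd x HYS cells:
    # cell-constant age lies in the span of the factor columns and the
    # slope would be unidentified (single-record cells are the usual case).
    slope_identified <- function(sel_rows) {
      age <- rec$age_months[sel_rows]
      cell <- paste(rec$herd[sel_rows], rec$hys[sel_rows])
      rss <- sum((age - stats::ave(age, cell))^2)
      tot <- sum((age - mean(age))^2)
      tot > 0 && rss > 1e-8 * tot
    }
    drop_age <- character(0)
    if (uses_age[ti]) {
      if (spec$pooled) {
        age_center <- tapply(rec$age_months, rec$country, mean)
        cs <- sort(unique(rec$country))
        ok_slope <- vapply(cs, function(cc)
          slope_identified(rec$country == cc), logical(1))
        age_levels <- if (any(ok_slope))
          paste0("slope|", cs[ok_slope]) else character(0)
        drop_age <- if (any(!ok_slope))
          paste0("slope|", cs[!ok_slope]) else character(0)
      } else {
        age_center <- mean(rec$age_months)
        if (slope_identified(rep(TRUE, nrow(rec)))) {
          age_levels <- "slope"
        } else {
          age_levels <- character(0)
          drop_age <- "slope"
        }
      }
    } else {
      age_center <- NA_real_
      age_levels <- character(0)
    }

    blocks <- list(herd = keep_herd, hys = keep_hys)
    if (spec$pooled) blocks$country <- keep_country
    if (uses_age[ti]) blocks$age <- age_levels
    eq_t <- dplyr::bind_rows(lapply(names(blocks), function(ef) {
      tibble::tibble(trait = tr, effect = ef, level = blocks[[ef]])
    }))
    eq_t$row <- row_counter + seq_len(nrow(eq_t))
    row_counter <- row_counter + nrow(eq_t)
    eq_rows[[ti]] <- eq_t

    rowidx <- function(ef, lev) {
      m <- eq_t$row[eq_t$effect == ef][match(lev, eq_t$level[eq_t$effect == ef])]
      m
    }
    cols <- matrix(NA_integer_, n_rec, 5,
                   dimnames = list(NULL,
                                   c("herd", "hys", "country", "age",
                                     "animal")))
    vals <- matrix(NA_real_, n_rec, 5)
    cols[sel, 1] <- rowidx("herd", rec$herd)
    vals[sel, 1] <- 1
    cols[sel, 2] <- rowidx("hys", rec$hys)
    vals[sel, 2] <- 1
    if (spec$pooled) {
      cols[sel, 3] <- rowidx("country", rec$country)
      vals[sel, 3] <- 1
    }
    if (uses_age[ti] && length(age_levels)) {
      if (spec$pooled) {
        cols[sel, 4] <- rowidx("age", paste0("slope|", rec$country))
        vals[sel, 4] <- rec$age_months -
          unname(age_center[rec$country])
      } else {
        cols[sel, 4] <- eq_t$row[eq_t$effect == "age"]
        vals[sel, 4] <- rec$age_months - age_center
      }
    }
    # animal rows filled after the fixed block size is known
    cols[sel, 5] <- apos[sel] # temporary: pedigree position
    vals[sel, 5] <- 1
    vals[is.na(cols)] <- NA_real_

    per_trait[[ti]] <- list(trait = tr, cols = cols, vals = vals,
                            y = records[[tr]],
                            age_center = age_center,
                            constrained = tibble::tibble(
                              trait = tr,
                              effect = c(rep("herd", length(drop_herd)),
                                         rep("hys", length(drop_hys)),
                                         rep("country", length(drop_country)),
                                         rep("age", length(drop_age))),
                              level = c(drop_herd, drop_hys,
                                        unname(drop_country), drop_age)))
  }

  n_fixed <- row_counter
  for (ti in seq_len(Tn)) {
    pc <- per_trait[[ti]]$cols
    filled <- !is.na(pc[, 5])
    per_trait[[ti]]$cols[filled, 5] <-
      n_fixed + (pc[filled, 5] - 1L) * Tn + ti
  }

  structure(list(traits = spec$trait_names,
                 spec = spec,
                 per_trait = per_trait,
                 obs = obs,
                 eq_fixed = dplyr::bind_rows(eq_rows),
                 constraints = dplyr::bind_rows(
                   lapply(per_trait, `[[`, "constrained")),
                 n_fixed = n_fixed,
                 n_eq = n_fixed + n_animals * Tn,
                 animal_ids = ped$animal_id,
                 record_animal = records$animal_id,
                 n_records = n_rec,
                 n_dropped = n_dropped),
            class = "mme_design")
}

#' Assemble Henderson's mixed-model equations
#'
#' Builds the sparse symmetric coefficient matrix
#' `W' R^-1 W + [0, 0; 0, A^-1 (x) G0^-1]` and right-hand side `W' R^-1 y`,
#' where the per-record `R^-1` is the inverse of the `R0` submatrix for that
#' record's observed-trait pattern (the standard multi-trait treatment of
#' missing traits).
#'
#' @param design An [build_design()] result.
#' @param relfac A [build_a_inverse()] result over the same pedigree.
#' @param varcomp [variance_components()]; defaults to the ones in the
#'   model spec.
#' @return An `mme_system` list with elements `C` (sparse symmetric), `rhs`,
#'   `eq_fixed`, dimensions, and the scalar accumulators (`y_Rinv_y`,
#'   `logdet_R_sum`) the REML likelihood needs.
#' @export
assemble_mme <- function(design, relfac, varcomp = design$spec$varcomp) {
  stopifnot(inherits(design, "mme_design"),
            inherits(relfac, "relationship_factors"))
  if (is.null(varcomp)) {
    stop("no variance components supplied: pass `varcomp` or run em_reml() ",
         "first - evaluation has no default variances", call. = FALSE)
  }
  stopifnot(inherits(varcomp, "variance_components"))
  if (!identical(varcomp$traits, design$traits)) {
    stop("variance components and design disagree on traits", call. = FALSE)
  }
  if (!identical(relfac$ids, design$animal_ids)) {
    stop("relationship factors and design cover different pedigrees",
         call. = FALSE)
  }
  Tn <- length(design$traits)
  G0 <- varcomp$G0
  R0 <- varcomp$R0
  G0inv <- tryCatch(solve(G0), error = function(e)
    stop("singular G0: ", conditionMessage(e), call. = FALSE))
  obs <- design$obs
  pat_key <- apply(obs, 1, function(z) paste(as.integer(z), collapse = ""))
  pats <- split(seq_len(design$n_records), pat_key)

  ci <- list(); cj <- list(); cx <- list()
  ri <- list(); rx <- list()
  y_Rinv_y <- 0
  logdet_R_sum <- 0
  k <- 0L
  for (p in names(pats)) {
    rows <- pats[[p]]
    ot <- which(strsplit(p, "")[[1]] == "1")
    Rsub <- R0[ot, ot, drop = FALSE]
    Rinv <- tryCatch(solve(Rsub), error = function(e)
      stop("singular R0 submatrix for observed-trait pattern ",
           paste(design$traits[ot], collapse = "+"), call. = FALSE))
    logdet_R_sum <- logdet_R_sum +
      length(rows) * determinant(Rsub, logarithm = TRUE)$modulus[1]
    ylist <- lapply(ot, function(ti) design$per_trait[[ti]]$y[rows])
    for (a1 in seq_along(ot)) {
      t1 <- ot[a1]
      d1 <- design$per_trait[[t1]]
      c1 <- d1$cols[rows, , drop = FALSE]
      v1 <- d1$vals[rows, , drop = FALSE]
      # rhs: sum over t2 of Rinv[t1,t2] * y_t2, against trait-1 design
      wy <- rep(0, length(rows))
      for (a2 in seq_along(ot)) {
        wy <- wy + Rinv[a1, a2] * ylist[[a2]]
        y_Rinv_y <- y_Rinv_y +
          sum(Rinv[a1, a2] * ylist[[a1]] * ylist[[a2]])
      }
      for (ca in 1:5) {
        ok <- !is.na(c1[, ca])
        if (!any(ok)) next
        k <- k + 1L
        ri[[k]] <- c1[ok, ca]
        rx[[k]] <- v1[ok, ca] * wy[ok]
      }
      for (a2 in seq_along(ot)) {
        t2 <- ot[a2]
        w <- Rinv[a1, a2]
        d2 <- design$per_trait[[t2]]
        c2 <- d2$cols[rows, , drop = FALSE]
        v2 <- d2$vals[rows, , drop = FALSE]
        for (ca in 1:5) {
          ok1 <- !is.na(c1[, ca])
          if (!any(ok1)) next
          for (cb in 1:5) {
            ok <- ok1 & !is.na(c2[, cb])
            if (!any(ok)) next
            k <- k + 1L
            ci[[k]] <- c1[ok, ca]
            cj[[k]] <- c2[ok, cb]
            cx[[k]] <- w * v1[ok, ca] * v2[ok, cb]
          }
        }
      }
    }
  }
  n_eq <- design$n_eq
  C <- Matrix::sparseMatrix(i = unlist(ci), j = unlist(cj), x = unlist(cx),
                            dims = c(n_eq, n_eq))
  akron <- Matrix::kronecker(relfac$a_inverse, G0inv)
  if (design$n_fixed > 0) {
    pad <- Matrix::Matrix(0, design$n_fixed, design$n_fixed, sparse = TRUE)
    C <- C + Matrix::bdiag(pad, akron)
  } else {
    C <- C + akron
  }
  C <- Matrix::forceSymmetric((C + Matrix::t(C)) / 2, uplo = "U")
  rhs <- as.numeric(Matrix::sparseMatrix(i = unlist(ri),
                                         j = rep(1L, length(unlist(ri))),
                                         x = unlist(rx),
                                         dims = c(n_eq, 1L)))
  structure(list(C = C, rhs = rhs,
                 design = design,
                 varcomp = varcomp,
                 relfac = relfac,
                 eq_fixed = design$eq_fixed,
                 n_fixed = design$n_fixed,
                 n_eq = n_eq,
                 n_traits = Tn,
                 y_Rinv_y = y_Rinv_y,
                 logdet_R_sum = logdet_R_sum),
            class = "mme_system")
}

#' @export
#' @method print mme_system
print.mme_system <- function(x, ...) {
  cat("<mme_system> ", x$n_eq, " equations (", x$n_fixed, " fixed), ",
      Matrix::nnzero(x$C), " nonzeros\n", sep = "")
  invisible(x)
}

# row index of an animal x trait equation
.animal_rows <- function(sys, positions, trait_index) {
  sys$n_fixed + (positions - 1L) * sys$n_traits + trait_index
}

#' Solve the mixed-model equations
#'
#' Direct sparse Cholesky (CHOLMOD) or Jacobi-preconditioned conjugate
#' gradients. Both are deterministic for fixed inputs; the direct method also
#' caches the factor so that [reliabilities()] can reuse it.
#'
#' @param sys An [assemble_mme()] system.
#' @param method `"direct"` (default) or `"pcg"`.
#' @param tol Relative residual tolerance `||Cx - rhs|| / ||rhs||`.
#' @param max_iter PCG iteration cap.
#' @return A list of class `mme_solution`: `x` (solution vector), `factor`
#'   (Cholesky factor, direct only), `diagnostics`.
#' @export
solve_mme <- function(sys, method = c("direct", "pcg"), tol = 1e-10,
                      max_iter = 10000L) {
  stopifnot(inherits(sys, "mme_system"))
  method <- match.arg(method)
  rhs <- sys$rhs
  rn <- sqrt(sum(rhs^2))
  if (rn == 0) rn <- 1
  fac <- NULL
  iters <- NA_integer_
  if (method == "direct") {
    fac <- tryCatch(Matrix::Cholesky(sys$C, LDL = FALSE),
                    error = function(e)
                      stop("sparse Cholesky failed (system singular or not ",
                           "positive definite): ", conditionMessage(e),
                           call. = FALSE))
    x <- as.numeric(Matrix::solve(fac, rhs, system = "A"))
  } else {
    M <- Matrix::diag(sys$C)
    M[M <= 0] <- 1
    x <- numeric(sys$n_eq)
    r <- rhs
    z <- r / M
    p <- z
    rz <- sum(r * z)
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      Ap <- as.numeric(sys$C %*% p)
      alpha <- rz / sum(p * Ap)
      x <- x + alpha * p
      r <- r - alpha * Ap
      if (sqrt(sum(r^2)) / rn <= tol) {
        ok <- TRUE
        iters <- it
        break
      }
      z <- r / M
      rz_new <- sum(r * z)
      p <- z + (rz_new / rz) * p
      rz <- rz_new
    }
    if (!ok) {
      stop("PCG failed to reach tol ", tol, " in ", max_iter,
           " iterations; best relative residual ",
           signif(sqrt(sum(r^2)) / rn, 4), call. = FALSE)
    }
  }
  resid <- sqrt(sum((as.numeric(sys$C %*% x) - rhs)^2)) / rn
  structure(list(x = x, factor = fac,
                 diagnostics = list(method = method,
                                    relative_residual = resid,
                                    iterations = iters,
                                    n_eq = sys$n_eq)),
            class = "mme_solution")
}

#' Prediction-error variances, reliabilities and accuracies
#'
#' Exact PEVs from the diagonal of the inverse coefficient matrix at the
#' requested animal-by-trait equations, obtained by solving against unit
#' vectors with the cached sparse Cholesky factor (chunked, so a few hundred
#' sires on a 10^5-equation system stay cheap). Reliability is
#' `r2 = 1 - pev / sigma2_a(trait)` and accuracy its square root.
#'
#' @param sys An [assemble_mme()] system.
#' @param solution A [solve_mme()] result with a direct factor; if missing or
#'   factor-less, a factorisation is done here.
#' @param animals Character vector of animal ids (defaults to all).
#' @param chunk Columns per triangular-solve batch.
#' @return Tibble `animal_id, trait, pev, reliability, accuracy`.
#' @export
reliabilities <- function(sys, solution = NULL, animals = NULL,
                          chunk = 256L) {
  stopifnot(inherits(sys, "mme_system"))
  if (is.null(animals)) animals <- sys$design$animal_ids
  posn <- match(animals, sys$design$animal_ids)
  if (anyNA(posn)) {
    stop("animal(s) without equations: ",
         paste(utils::head(animals[is.na(posn)], 5), collapse = ", "),
         call. = FALSE)
  }
  fac <- if (!is.null(solution) && !is.null(solution$factor)) {
    solution$factor
  } else {
    Matrix::Cholesky(sys$C, LDL = FALSE)
  }
  Tn <- sys$n_traits
  rows <- as.integer(vapply(seq_len(Tn), function(ti)
    .animal_rows(sys, posn, ti), numeric(length(posn))))
  # rows is animals x traits flattened: recover ordering
  rows <- matrix(rows, nrow = length(posn), ncol = Tn)
  all_rows <- as.vector(rows)
  pev <- numeric(length(all_rows))
  n_eq <- sys$n_eq
  for (start in seq(1, length(all_rows), by = chunk)) {
    ix <- start:min(start + chunk - 1L, length(all_rows))
    E <- Matrix::sparseMatrix(i = all_rows[ix], j = seq_along(ix), x = 1,
                              dims = c(n_eq, length(ix)))
    S <- Matrix::solve(fac, E, system = "A")
    pev[ix] <- S[cbind(all_rows[ix], seq_along(ix))]
  }
  sig2a <- diag(sys$varcomp$G0)
  out <- tibble::tibble(
    animal_id = rep(animals, times = Tn),
    trait = rep(sys$design$traits, each = length(animals)),
    pev = pev)
  out$reliability <- pmin(pmax(1 - out$pev /
                                 unname(sig2a[match(out$trait,
                                                    sys$varcomp$traits)]),
                               0), 1 - 1e-12)
  out$accuracy <- sqrt(out$reliability)
  out
}

#' Run a full animal-model evaluation
#'
#' Orchestrates [build_design()], [build_a_inverse()], [assemble_mme()],
#' [solve_mme()] and [reliabilities()] for one dataset (one country, or the
#' pooled two-country table with `spec$pooled = TRUE`).
#'
#' @inheritParams build_design
#' @param reliability_for `"sires"` (default; sires with recorded daughters -
#'   the selection candidates), `"all"`, `"none"`, or a character vector of
#'   animal ids. PEVs cost one triangular solve per animal-trait equation,
#'   so `"all"` is meant for desk-scale problems.
#' @param solver,tol Passed to [solve_mme()].
#' @param model_tag Label stored with the result (e.g. `"within_KE"` or
#'   `"multi"`).
#' @param relfac Optionally a precomputed [build_a_inverse()] result.
#' @param use_inbreeding Passed to [build_a_inverse()] when `relfac` is NULL.
#' @return An object of class `herd_eval` with elements `solutions` (tibble
#'   `animal_id, trait, ebv, pev, reliability, accuracy`), `fixed` (fixed
#'   effect estimates, constrained levels flagged with estimate 0), `tag`,
#'   `diagnostics`, `varcomp`, and `digest` (hash of the model setup).
#' @export
run_evaluation <- function(records, ped, spec,
                           reliability_for = "sires",
                           solver = "direct", tol = 1e-10,
                           model_tag = NULL, relfac = NULL,
                           use_inbreeding = TRUE) {
  ped <- as_pedigree(ped)
  if (is.null(relfac)) relfac <- build_a_inverse(ped, use_inbreeding)
  design <- build_design(records, ped, spec)
  sys <- assemble_mme(design, relfac)
  sol <- solve_mme(sys, method = solver, tol = max(tol, 1e-12))

  Tn <- length(design$traits)
  n_animals <- length(design$animal_ids)
  ebv <- matrix(sol$x[(design$n_fixed + 1L):design$n_eq],
                nrow = Tn, ncol = n_animals)
  solutions <- tibble::tibble(
    animal_id = rep(design$animal_ids, each = Tn),
    trait = rep(design$traits, times = n_animals),
    ebv = as.vector(ebv))

  rel_ids <- NULL
  if (is.character(reliability_for) && length(reliability_for) == 1 &&
      reliability_for %in% c("sires", "all", "none")) {
    rel_ids <- switch(reliability_for,
      sires = {
        sires <- ped$sire_id[match(design$record_animal, ped$animal_id)]
        sort(unique(stats::na.omit(sires)))
      },
      all = design$animal_ids,
      none = character(0))
  } else {
    rel_ids <- reliability_for
  }
  if (length(rel_ids)) {
    rel <- reliabilities(sys, sol, animals = rel_ids)
    solutions <- dplyr::left_join(solutions, rel,
                                  by = c("animal_id", "trait"))
  } else {
    solutions$pev <- NA_real_
    solutions$reliability <- NA_real_
    solutions$accuracy <- NA_real_
  }

  fixed <- design$eq_fixed
  fixed$estimate <- sol$x[fixed$row]
  fixed$constrained <- FALSE
  con <- design$constraints
  if (nrow(con)) {
    con$row <- NA_integer_
    con$estimate <- 0
    con$constrained <- TRUE
    fixed <- dplyr::bind_rows(fixed, con)
  }
  fixed <- dplyr::arrange(fixed, .data$trait, .data$effect, .data$level)

  structure(list(solutions = solutions,
                 fixed = fixed,
                 tag = model_tag %||%
                   if (spec$pooled) "multi" else "within",
                 sires = if (is.character(reliability_for) &&
                             identical(reliability_for, "sires"))
                   rel_ids else NULL,
                 varcomp = sys$varcomp,
                 diagnostics = sol$diagnostics,
                 digest = rlang::hash(list(spec$trait_names, spec$pooled,
                                           sys$varcomp$G0, sys$varcomp$R0)),
                 n_records = design$n_records),
            class = "herd_eval")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
#' @method print herd_eval
print.herd_eval <- function(x, ...) {
  cat("<herd_eval> tag: ", x$tag, "; ", x$n_records, " records, ",
      length(unique(x$solutions$animal_id)), " animals, traits: ",
      paste(unique(x$solutions$trait), collapse = ", "), "\n", sep = "")
  cat("solver: ", x$diagnostics$method, ", relative residual ",
      signif(x$diagnostics$relative_residual, 3), "\n", sep = "")
  invisible(x)
}

#' Tidy an evaluation into one row per animal-trait
#'
#' @param x A `herd_eval`.
#' @param ... Unused.
#' @return The solutions tibble (`animal_id, trait, ebv, pev, reliability,
#'   accuracy`).
#' @importFrom generics tidy
#' @export
#' @method tidy herd_eval
tidy.herd_eval <- function(x, ...) x$solutions

#' One-row summary of an evaluation
#'
#' @inheritParams tidy.herd_eval
#' @importFrom generics glance
#' @export
#' @method glance herd_eval
glance.herd_eval <- function(x, ...) {
  tibble::tibble(tag = x$tag,
                 n_records = x$n_records,
                 n_animals = length(unique(x$solutions$animal_id)),
                 n_traits = length(unique(x$solutions$trait)),
                 solver = x$diagnostics$method,
                 relative_residual = x$diagnostics$relative_residual)
}

#' Plot EBV distributions (and accuracies where computed) per trait
#'
#' @param object A `herd_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @importFrom ggplot2 autoplot
#' @export
#' @method autoplot herd_eval
autoplot.herd_eval <- function(object, ...) {
  df <- object$solutions
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ebv)) +
    ggplot2::geom_histogram(bins = 40, fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(~trait, scales = "free_x") +
    ggplot2::labs(x = "estimated breeding value (trait units)",
                  y = "animals",
                  title = paste0("EBV distribution (", object$tag, ")")) +
    ggplot2::theme_minimal()
}
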