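#' Estimate variance components by EM-REML
#'
#' Expectation-maximisation REML for the multi-trait animal model, so the
#' pipeline can run when no external G0/R0 are available. Each iteration
#' solves the mixed-model equations at the current components, then updates
#'
#' \deqn{G_{st} \leftarrow (\hat a_s' A^{-1} \hat a_t +
#'       tr(A^{-1} C^{aa}_{st})) / q}
#'
#' and replaces R0 by the average conditional expectation of the per-record
#' residual cross-products (with the usual `W C^{-1} W'` trace correction;
#' records with missing traits contribute through the conditional
#' distribution of their unobserved residuals). EM is monotone in the
#' restricted likelihood, which is tracked through the determinant identity
#' `log|V| + log|X'V^-1 X| = log|R| + log|A (x) G0| + log|C|` and therefore
#' costs one sparse factorisation.
#'
#' Plain EM crawls when a genetic variance is small relative to the
#' phenotypic variance, so the fixed-point iteration is accelerated with a
#' safeguarded squared-extrapolation (SQUAREM-style) step: the extrapolated
#' parameters are kept only when they are positive definite and do not
#' decrease the restricted likelihood, otherwise the plain EM step is used.
#' The reported likelihood trace is therefore still non-decreasing.
#'
#' When `start` is omitted, starting values come from a sire-family
#' method-of-moments analysis per trait (between/within sire-family mean
#' squares), which lands close enough to the optimum that the remaining EM
#' path is short.
#'
#' The trace corrections need the full inverse of the coefficient matrix, so
#' the estimator is deliberately a desk-scale tool: it refuses systems above
#' `dense_limit` equations.
#'
#' @inheritParams build_design
#' @param start A [variance_components()] starting value, or `NULL` for the
#'   method-of-moments start.
#' @param tol Convergence: maximum parameter change per EM step, relative to
#'   the current parameter magnitude.
#' @param max_iter Cap on EM steps (accelerated cycles count their inner
#'   steps). Reaching it returns the current estimate with
#'   `converged = FALSE`.
#' @param accelerate Use the safeguarded extrapolation (default) or plain
#'   EM.
#' @param dense_limit Refuse systems with more equations than this.
#' @param use_inbreeding Passed to [build_a_inverse()].
#' @return A `reml_fit` list: `varcomp` (the estimate), `trace` (tibble with
#'   per-step G0/R0 diagonals, restricted log-likelihood and delta),
#'   `converged`, `iterations`.
#' @export
em_reml <- function(records, ped, spec, start = NULL, tol = 1e-3,
                    max_iter = 200L, accelerate = TRUE,
                    dense_limit = 8000L, use_inbreeding = TRUE) {
  ped <- as_pedigree(ped)
  relfac <- build_a_inverse(ped, use_inbreeding)
  design <- build_design(records, ped, spec)
  if (design$n_eq > dense_limit) {
    stop("EM-REML needs the dense inverse of a ", design$n_eq,
         "-equation system; limit is ", dense_limit,
         " - subsample the data or raise dense_limit", call. = FALSE)
  }
  Tn <- length(design$traits)
  q <- length(design$animal_ids)
  n <- design$n_records
  ainv_trip <- Matrix::summary(methods::as(
    methods::as(relfac$a_inverse, "generalMatrix"), "TsparseMatrix"))
  obs <- design$obs
  pat_key <- apply(obs, 1, function(z) paste(as.integer(z), collapse = ""))
  pats <- split(seq_len(n), pat_key)
  arows_all <- lapply(seq_len(Tn), function(ti)
    design$n_fixed + (seq_len(q) - 1L) * Tn + ti)

  if (is.null(start)) start <- .mom_start(records, ped, design)
  stopifnot(inherits(start, "variance_components"))
  scale_ref <- pmax(diag(start$G0) + diag(start$R0), .Machine$double.eps)

  pd_repair <- function(M, warn = FALSE, label = "") {
    M <- (M + t(M)) / 2
    e <- eigen(M, symmetric = TRUE)
    floor_v <- 1e-10 * mean(pmax(abs(diag(M)), .Machine$double.eps))
    if (min(e$values) < floor_v) {
      if (warn) warning("EM update of ", label,
                        " lost positive definiteness; eigenvalues floored",
                        call. = FALSE)
      e$values <- pmax(e$values, floor_v)
      M <- e$vectors %*% diag(e$values, nrow(M)) %*% t(e$vectors)
    }
    M
  }

  # restricted log-likelihood at (G0, R0), from the sparse factorisation only
  loglik_at <- function(G0, R0) {
    vc <- variance_components(design$traits, G0, R0)
    sys <- assemble_mme(design, relfac, vc)
    fac <- Matrix::Cholesky(sys$C, LDL = FALSE)
    x <- as.numeric(Matrix::solve(fac, sys$rhs, system = "A"))
    ldC <- as.numeric(Matrix::determinant(sys$C, logarithm = TRUE)$modulus)
    ldG <- as.numeric(determinant(G0, logarithm = TRUE)$modulus)
    -0.5 * (sys$y_Rinv_y - sum(x * sys$rhs) + sys$logdet_R_sum +
              Tn * relfac$log_det_a + q * ldG + ldC)
  }

  # one EM step; returns updated components and the loglik at the INPUT
  em_step <- function(G0, R0) {
    vc <- variance_components(design$traits, G0, R0)
    sys <- assemble_mme(design, relfac, vc)
    fac <- Matrix::Cholesky(sys$C, LDL = FALSE)
    x <- as.numeric(Matrix::solve(fac, sys$rhs, system = "A"))
    Cinv <- as.matrix(Matrix::solve(fac, Matrix::Diagonal(sys$n_eq),
                                    system = "A"))
    ldC <- as.numeric(Matrix::determinant(sys$C, logarithm = TRUE)$modulus)
    ldG <- as.numeric(determinant(G0, logarithm = TRUE)$modulus)
    loglik <- -0.5 * (sys$y_Rinv_y - sum(x * sys$rhs) + sys$logdet_R_sum +
                        Tn * relfac$log_det_a + q * ldG + ldC)
    if (!is.finite(loglik)) {
      stop("EM-REML diverged (non-finite restricted likelihood)",
           call. = FALSE)
    }

    ahat <- lapply(arows_all, function(rr) x[rr])
    Gnew <- matrix(0, Tn, Tn)
    for (s in seq_len(Tn)) {
      for (t2 in s:Tn) {
        quad <- as.numeric(ahat[[s]] %*% (relfac$a_inverse %*% ahat[[t2]]))
        Cst <- Cinv[arows_all[[s]], arows_all[[t2]], drop = FALSE]
        trc <- sum(ainv_trip$x * Cst[cbind(ainv_trip$j, ainv_trip$i)])
        Gnew[s, t2] <- Gnew[t2, s] <- (quad + trc) / q
      }
    }

    S <- matrix(0, Tn, Tn)
    for (p in names(pats)) {
      rows <- pats[[p]]
      ot <- which(strsplit(p, "")[[1]] == "1")
      mt <- setdiff(seq_len(Tn), ot)
      no <- length(ot)
      ehat <- matrix(0, length(rows), no)
      Q <- array(0, c(length(rows), no, no))
      for (a1 in seq_len(no)) {
        t1 <- ot[a1]
        d1 <- design$per_trait[[t1]]
        c1 <- d1$cols[rows, , drop = FALSE]
        v1 <- d1$vals[rows, , drop = FALSE]
        fit <- rep(0, length(rows))
        for (ca in 1:5) {
          ok <- !is.na(c1[, ca])
          if (any(ok)) fit[ok] <- fit[ok] + v1[ok, ca] * x[c1[ok, ca]]
        }
        ehat[, a1] <- d1$y[rows] - fit
        for (a2 in a1:no) {
          t2 <- ot[a2]
          d2 <- design$per_trait[[t2]]
          c2 <- d2$cols[rows, , drop = FALSE]
          v2 <- d2$vals[rows, , drop = FALSE]
          qq <- rep(0, length(rows))
          for (ca in 1:5) {
            ok1 <- !is.na(c1[, ca])
            if (!any(ok1)) next
            for (cb in 1:5) {
              ok <- ok1 & !is.na(c2[, cb])
              if (!any(ok)) next
              qq[ok] <- qq[ok] + v1[ok, ca] * v2[ok, cb] *
                Cinv[cbind(c1[ok, ca], c2[ok, cb])]
            }
          }
          Q[, a1, a2] <- qq
          Q[, a2, a1] <- qq
        }
      }
      Eoo <- crossprod(ehat) + apply(Q, c(2, 3), sum)
      full <- matrix(0, Tn, Tn)
      full[ot, ot] <- Eoo
      if (length(mt)) {
        B <- R0[mt, ot, drop = FALSE] %*% solve(R0[ot, ot, drop = FALSE])
        full[mt, ot] <- B %*% Eoo
        full[ot, mt] <- t(full[mt, ot, drop = FALSE])
        full[mt, mt] <- length(rows) *
          (R0[mt, mt, drop = FALSE] - B %*% R0[ot, mt, drop = FALSE]) +
          B %*% Eoo %*% t(B)
      }
      S <- S + full
    }
    Rnew <- S / n
    list(G = pd_repair(Gnew, warn = TRUE, label = "G0"),
         R = pd_repair(Rnew, warn = TRUE, label = "R0"),
         loglik = loglik)
  }

  pack <- function(G, R) c(G[upper.tri(G, diag = TRUE)],
                           R[upper.tri(R, diag = TRUE)])
  unpack <- function(th) {
    m <- Tn * (Tn + 1) / 2
    G <- matrix(0, Tn, Tn); R <- matrix(0, Tn, Tn)
    G[upper.tri(G, diag = TRUE)] <- th[seq_len(m)]
    R[upper.tri(R, diag = TRUE)] <- th[m + seq_len(m)]
    G <- G + t(G) - diag(diag(G), Tn)
    R <- R + t(R) - diag(diag(R), Tn)
    list(G = G, R = R)
  }
  rel_delta <- function(old, new) {
    ref <- pmax(abs(old), 1e-6 * mean(scale_ref))
    max(abs(new - old) / ref)
  }

  G0 <- start$G0
  R0 <- start$R0
  trace <- list()
  push_trace <- function(step, ll, delta, G, R) {
    trace[[length(trace) + 1]] <<- tibble::tibble(
      iteration = step, loglik = ll, delta = delta,
      param = rep(c("G0", "R0"), each = Tn),
      trait = rep(design$traits, 2),
      value = c(diag(G), diag(R)))
  }
  converged <- FALSE
  steps <- 0L
  last_ll <- -Inf
  while (steps < max_iter) {
    s1 <- em_step(G0, R0)
    steps <- steps + 1L
    d1 <- rel_delta(pack(G0, R0), pack(s1$G, s1$R))
    push_trace(steps, s1$loglik, d1, s1$G, s1$R)
    if (d1 <= tol) {
      G0 <- s1$G; R0 <- s1$R
      converged <- TRUE
      break
    }
    if (!accelerate || steps >= max_iter) {
      G0 <- s1$G; R0 <- s1$R
      next
    }
    s2 <- em_step(s1$G, s1$R)
    steps <- steps + 1L
    d2 <- rel_delta(pack(s1$G, s1$R), pack(s2$G, s2$R))
    push_trace(steps, s2$loglik, d2, s2$G, s2$R)
    if (d2 <= tol) {
      G0 <- s2$G; R0 <- s2$R
      converged <- TRUE
      break
    }
    th0 <- pack(G0, R0)
    r <- pack(s1$G, s1$R) - th0
    v <- (pack(s2$G, s2$R) - pack(s1$G, s1$R)) - r
    alpha <- -sqrt(sum(r^2) / max(sum(v^2), .Machine$double.eps))
    alpha <- min(alpha, -1)
    cand <- unpack(th0 - 2 * alpha * r + alpha^2 * v)
    candG <- pd_repair(cand$G); candR <- pd_repair(cand$R)
    ll_em <- loglik_at(s2$G, s2$R)
    ll_cand <- tryCatch(loglik_at(candG, candR), error = function(e) -Inf)
    if (is.finite(ll_cand) && ll_cand >= ll_em) {
      G0 <- candG; R0 <- candR
    } else {
      G0 <- s2$G; R0 <- s2$R
    }
    last_ll <- max(ll_em, ll_cand)
  }

  structure(list(varcomp = variance_components(design$traits, G0, R0),
                 trace = dplyr::bind_rows(trace),
                 converged = converged,
                 iterations = steps,
                 start = start),
            class = "reml_fit")
}

# sire-family method-of-moments starting values (between/within mean
# squares per trait; genetic covariances start at zero)
.mom_start <- function(records, ped, design) {
  traits <- design$traits
  Tn <- length(traits)
  sires <- ped$sire_id[match(records$animal_id, ped$animal_id)]
  g_diag <- numeric(Tn)
  r_diag <- numeric(Tn)
  for (ti in seq_len(Tn)) {
    y <- records[[traits[ti]]]
    ok <- !is.na(y) & !is.na(sires)
    vy <- stats::var(y[ok])
    est <- 0.2 * vy # fallback when family structure is degenerate
    if (sum(ok) > 10) {
      yt <- y[ok]; fam <- sires[ok]
      ni <- table(fam)
      keep <- names(ni)[ni >= 2]
      if (length(keep) >= 3) {
        sel <- fam %in% keep
        yt <- yt[sel]; fam <- droplevels(factor(fam[sel]))
        N <- length(yt); s <- nlevels(fam)
        ybar <- tapply(yt, fam, mean)
        nvec <- as.numeric(table(fam))
        msb <- sum(nvec * (ybar - mean(yt))^2) / (s - 1)
        msw <- sum((yt - ybar[fam])^2) / (N - s)
        k0 <- (N - sum(nvec^2) / N) / (s - 1)
        est <- 4 * (msb - msw) / k0
      }
    }
    g_diag[ti] <- min(max(est, 0.02 * vy), 0.7 * vy)
    r_diag[ti] <- max(vy - g_diag[ti], 0.2 * vy)
  }
  variance_components(traits, diag(g_diag, Tn), diag(r_diag, Tn))
}

#' @export
#' @method print reml_fit
print.reml_fit <- function(x, ...) {
  cat("<reml_fit> ", x$iterations, " EM steps, ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  print(x$varcomp)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
#' @method tidy reml_fit
tidy.reml_fit <- function(x, ...) x$trace

#' @importFrom generics glance
#' @export
#' @method glance reml_fit
glance.reml_fit <- function(x, ...) {
  tibble::tibble(iterations = x$iterations,
                 converged = x$converged,
                 loglik = utils::tail(unique(x$trace$loglik), 1),
                 delta = utils::tail(unique(x$trace$delta), 1))
}

#' Plot the EM-REML convergence path
#'
#' @param object A `reml_fit`.
#' @param ... Unused.
#' @importFrom ggplot2 autoplot
#' @export
#' @method autoplot reml_fit
autoplot.reml_fit <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$iteration, y = .data$value,
                               colour = .data$param)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(y = "variance estimate", x = "EM step") +
    ggplot2::theme_minimal()
}
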