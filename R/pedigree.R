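#' Read a pedigree file
#'
#' Reads an animal/sire/dam CSV, validates it and returns the pedigree in
#' parent-before-offspring order. Animals that appear only as parents are
#' materialised as founder records with unknown parents, so every identifier
#' referenced anywhere in the file ends up with its own row.
#'
#' @param path Path to a CSV file with one row per animal.
#' @param dialect Named character vector mapping the roles `animal`, `sire`
#'   and `dam` to column names in the file. Defaults to
#'   `c(animal = "animal_id", sire = "sire_id", dam = "dam_id")`.
#' @param unknown Character vector of encodings treated as "parent unknown".
#' @return A [tibble][tibble::tibble] of class `pedigree` with columns
#'   `animal_id`, `sire_id`, `dam_id` (`NA` for unknown parents) and `order`,
#'   sorted so that every known parent precedes its offspring.
#' @seealso [as_pedigree()] for validating an in-memory data frame,
#'   [compute_inbreeding()], [build_a_inverse()].
#' @export
read_pedigree <- function(path,
                          dialect = c(animal = "animal_id",
                                      sire = "sire_id",
                                      dam = "dam_id"),
                          unknown = c("", "0", "NA")) {
  if (!file.exists(path)) {
    stop("pedigree file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = character(), progress = FALSE)
  missing_cols <- setdiff(unname(dialect), names(raw))
  if (length(missing_cols)) {
    stop("pedigree file ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- tibble::tibble(animal_id = raw[[dialect[["animal"]]]],
                       sire_id   = raw[[dialect[["sire"]]]],
                       dam_id    = raw[[dialect[["dam"]]]])
  as_pedigree(df, unknown = unknown)
}

#' Validate and order a pedigree data frame
#'
#' The workhorse behind [read_pedigree()]: normalises unknown-parent
#' encodings, materialises parent-only animals as founders, rejects malformed
#' pedigrees (duplicate ids, self-parenting, an id used as both sire and dam,
#' parentage cycles) and reorders rows so parents precede offspring.
#'
#' @param df Data frame with columns `animal_id`, `sire_id`, `dam_id`.
#' @inheritParams read_pedigree
#' @return A `pedigree` tibble; see [read_pedigree()].
#' @export
as_pedigree <- function(df, unknown = c("", "0", "NA")) {
  stopifnot(all(c("animal_id", "sire_id", "dam_id") %in% names(df)))
  norm <- function(x) {
    x <- trimws(as.character(x))
    x[x %in% unknown | is.na(x)] <- NA_character_
    x
  }
  animal <- norm(df$animal_id)
  sire <- norm(df$sire_id)
  dam <- norm(df$dam_id)

  if (anyNA(animal)) {
    stop("pedigree has row(s) with empty animal_id", call. = FALSE)
  }
  dup <- unique(animal[duplicated(animal)])
  if (length(dup)) {
    stop("duplicate animal_id in pedigree: ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  }
  self <- animal == sire | animal == dam
  if (any(self, na.rm = TRUE)) {
    stop("animal listed as its own parent: ",
         animal[which(self)[1]], call. = FALSE)
  }
  both <- intersect(stats::na.omit(sire), stats::na.omit(dam))
  if (length(both)) {
    stop("id(s) used as both sire and dam: ",
         paste(utils::head(both, 5), collapse = ", "), call. = FALSE)
  }

  # founders for parent-only ids
  parents_only <- setdiff(c(stats::na.omit(sire), stats::na.omit(dam)), animal)
  if (length(parents_only)) {
    animal <- c(animal, parents_only)
    sire <- c(sire, rep(NA_character_, length(parents_only)))
    dam <- c(dam, rep(NA_character_, length(parents_only)))
  }

  n <- length(animal)
  pos <- stats::setNames(seq_len(n), animal)
  sp <- unname(pos[sire])      # NA where unknown
  dp <- unname(pos[dam])

  # Kahn topological sort on the parent -> offspring DAG
  indeg <- (!is.na(sp)) + (!is.na(dp))
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(sp[i], dp[i])) {
      if (!is.na(p)) kids[[p]] <- c(kids[[p]], i)
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    i <- queue[1]
    queue <- queue[-1]
    ord <- c(ord, i)
    for (k in kids[[i]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(ord) < n) {
    stop("cycle in parentage involving animal: ",
         animal[setdiff(seq_len(n), ord)[1]], call. = FALSE)
  }

  out <- tibble::tibble(animal_id = animal[ord],
                        sire_id = sire[ord],
                        dam_id = dam[ord],
                        order = seq_len(n))
  class(out) <- c("pedigree", class(out))
  out
}

#' Write an ordered pedigree to CSV
#'
#' Emits the standard `animal_id,sire_id,dam_id,order` dialect with unknown
#' parents written as empty fields.
#'
#' @param ped A `pedigree` tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  ped <- as_pedigree(ped)
  readr::write_csv(ped, path, na = "")
  invisible(path)
}

# positions of sire/dam in the ordered pedigree; 0L where unknown
.parent_positions <- function(ped) {
  pos <- stats::setNames(seq_len(nrow(ped)), ped$animal_id)
  s <- unname(pos[ped$sire_id])
  d <- unname(pos[ped$dam_id])
  s[is.na(s)] <- 0L
  d[is.na(d)] <- 0L
  list(s = as.integer(s), d = as.integer(d))
}

#' Inbreeding coefficients by the Meuwissen-Luo algorithm
#'
#' Computes per-animal inbreeding coefficients F (the excess of the diagonal
#' of the numerator relationship matrix over 1) without ever forming A
#' densely. Unknown parents are treated as unrelated draws from a single
#' unselected base population.
#'
#' @param ped A validated, ordered `pedigree` (see [as_pedigree()]).
#' @return Named numeric vector of F coefficients in pedigree order.
#' @export
compute_inbreeding <- function(ped) {
  ped <- as_pedigree(ped)
  par <- .parent_positions(ped)
  s <- par$s
  d <- par$d
  n <- nrow(ped)
  f <- numeric(n)
  # Mendelian sampling variances with the F(unknown) = -1 convention:
  # D_i = 0.5 - 0.25 (F_s + F_d)
  fs <- function(p) if (p == 0L) -1 else f[p]
  Dv <- numeric(n)
  L <- numeric(n) # scratch, reset per animal via `touched`
  for (i in seq_len(n)) {
    Dv[i] <- 0.5 - 0.25 * (fs(s[i]) + fs(d[i]))
    if (s[i] == 0L && d[i] == 0L) {
      f[i] <- 0
      next
    }
    # ancestor set of i (including i), processed youngest-first
    anc <- i
    stack <- c(s[i], d[i])
    while (length(stack)) {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (j == 0L || j %in% anc) next
      anc <- c(anc, j)
      if (s[j] > 0L) stack <- c(stack, s[j])
      if (d[j] > 0L) stack <- c(stack, d[j])
    }
    anc <- sort.int(anc, decreasing = TRUE)
    L[anc] <- 0
    L[i] <- 1
    acc <- 0
    for (j in anc) {
      lj <- L[j]
      if (lj == 0) next
      if (s[j] > 0L) L[s[j]] <- L[s[j]] + 0.5 * lj
      if (d[j] > 0L) L[d[j]] <- L[d[j]] + 0.5 * lj
      acc <- acc + lj * lj * Dv[j]
    }
    f[i] <- acc - 1
  }
  stats::setNames(f, ped$animal_id)
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Assembles A-inverse directly from the pedigree by Henderson's rules: each
#' animal contributes at most nine entries involving itself and its known
#' parents, weighted by the inverse of its Mendelian-sampling variance. With
#' `use_inbreeding = TRUE` (default) the Mendelian-sampling variances are
#' adjusted for parental inbreeding via [compute_inbreeding()].
#'
#' @param ped A `pedigree`.
#' @param use_inbreeding Adjust Mendelian-sampling variances for parental
#'   inbreeding? Disabling mimics evaluations that ignore F.
#' @return An object of class `relationship_factors`: a list with elements
#'   `ids` (animal ids in pedigree order), `inbreeding` (named F vector),
#'   `mendelian_variance` (the per-animal D), `a_inverse` (sparse symmetric
#'   [Matrix::dsCMatrix]) and `log_det_a` (log-determinant of A, the sum of
#'   log D, used by the REML likelihood).
#' @export
build_a_inverse <- function(ped, use_inbreeding = TRUE) {
  ped <- as_pedigree(ped)
  par <- .parent_positions(ped)
  s <- par$s
  d <- par$d
  n <- nrow(ped)
  f <- if (use_inbreeding) unname(compute_inbreeding(ped)) else numeric(n)
  fpar <- function(p) ifelse(p == 0L, -1, f[pmax(p, 1L)])
  Dv <- 0.5 - 0.25 * (fpar(s) + fpar(d))
  alpha <- 1 / Dv

  idx <- seq_len(n)
  has_s <- s > 0L
  has_d <- d > 0L
  ii <- c(idx,
          idx[has_s], s[has_s],
          idx[has_d], d[has_d],
          s[has_s], d[has_d],
          s[has_s & has_d], d[has_s & has_d])
  jj <- c(idx,
          s[has_s], idx[has_s],
          d[has_d], idx[has_d],
          s[has_s], d[has_d],
          d[has_s & has_d], s[has_s & has_d])
  xx <- c(alpha,
          -alpha[has_s] / 2, -alpha[has_s] / 2,
          -alpha[has_d] / 2, -alpha[has_d] / 2,
          alpha[has_s] / 4, alpha[has_d] / 4,
          alpha[has_s & has_d] / 4, alpha[has_s & has_d] / 4)
  ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$animal_id, ped$animal_id))
  ainv <- Matrix::forceSymmetric((ainv + Matrix::t(ainv)) / 2, uplo = "U")
  structure(list(ids = ped$animal_id,
                 inbreeding = stats::setNames(f, ped$animal_id),
                 mendelian_variance = stats::setNames(Dv, ped$animal_id),
                 a_inverse = ainv,
                 log_det_a = sum(log(Dv)),
                 use_inbreeding = use_inbreeding),
            class = "relationship_factors")
}

#' @export
#' @method print relationship_factors
print.relationship_factors <- function(x, ...) {
  cat("<relationship_factors> ", length(x$ids), " animals, ",
      Matrix::nnzero(x$a_inverse), " nonzeros in A-inverse, mean F = ",
      signif(mean(x$inbreeding), 3), "\n", sep = "")
  invisible(x)
}

#' Dense numerator relationship matrix by the tabular method
#'
#' The recursive tabular construction of A, intended as a desk-scale oracle
#' for [build_a_inverse()] and [compute_inbreeding()]: `diag(A) = 1 + F` and
#' `solve(A)` must match the sparse A-inverse. Refuses pedigrees above
#' `dense_limit` animals because the result is dense.
#'
#' @param ped A `pedigree`.
#' @param dense_limit Maximum pedigree size to densify.
#' @return Dense symmetric matrix with animal ids as dimnames.
#' @export
tabular_a_matrix <- function(ped, dense_limit = 500L) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  if (n > dense_limit) {
    stop("pedigree has ", n, " animals; the tabular method is a dense ",
         "oracle for pedigrees up to ", dense_limit,
         " animals - use build_a_inverse() at scale", call. = FALSE)
  }
  par <- .parent_positions(ped)
  s <- par$s
  d <- par$d
  A <- matrix(0, n, n, dimnames = list(ped$animal_id, ped$animal_id))
  col0 <- function(p, upto) if (p == 0L) numeric(upto) else A[seq_len(upto), p]
  for (i in seq_len(n)) {
    if (i > 1) {
      above <- 0.5 * (col0(s[i], i - 1L) + col0(d[i], i - 1L))
      A[seq_len(i - 1L), i] <- above
      A[i, seq_len(i - 1L)] <- above
    }
    A[i, i] <- 1 + if (s[i] > 0L && d[i] > 0L) 0.5 * A[s[i], d[i]] else 0
  }
  A
}
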