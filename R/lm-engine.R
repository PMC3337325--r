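# Fixed-effect least squares, nested-model F ratios, and the pedigree
# mixed-model machinery used to pre-correct phenotypes.

#' Ordinary least-squares fit of a fixed-effect model
#'
#' Thin wrapper around [stats::lm()] that records what nested-model
#' F-ratio tests need: the residual sum of squares, the residual degrees
#' of freedom and the set of records actually used.  Factors use
#' treatment contrasts; rank deficiency is resolved by dropping aliased
#' columns (reported via a message).  Records with missing response,
#' factor level or covariate are dropped with a message stating the
#' count.
#'
#' @param formula Model formula.
#' @param data Data frame; if it has an `id` column the ids of the used
#'   records are stored for later identity checks.
#' @return An object of class `lc_fit`: list with `coefficients`, `rss`,
#'   `df_residual`, `residuals`, `fitted`, `n`, `rank`, `ids`, and the
#'   underlying `lm` fit.
#' @export
fit_ls <- function(formula, data) {
  data <- as.data.frame(data)
  if (nrow(data) == 0L) stop("empty data")
  vars <- all.vars(formula)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars)) {
    stop("variables not in data: ", paste(missing_vars, collapse = ", "))
  }
  keep <- stats::complete.cases(data[, vars, drop = FALSE])
  if (any(!keep)) {
    message(sum(!keep), " record(s) dropped for missing data")
  }
  data <- droplevels(data[keep, , drop = FALSE])
  if (nrow(data) == 0L) stop("no complete records")
  fit <- stats::lm(formula, data = data, singular.ok = TRUE)
  if (fit$df.residual <= 0L) stop("zero residual degrees of freedom")
  aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  if (length(aliased)) {
    message("aliased column(s) dropped: ", paste(aliased, collapse = ", "))
  }
  res <- stats::residuals(fit)
  out <- list(coefficients = stats::coef(fit),
              rss = sum(res^2),
              df_residual = fit$df.residual,
              residuals = res,
              fitted = stats::fitted(fit),
              n = nrow(data),
              rank = fit$rank,
              ids = if ("id" %in% names(data)) as.character(data$id) else NULL,
              formula = formula,
              lm = fit)
  class(out) <- "lc_fit"
  out
}

#' @export
print.lc_fit <- function(x, ...) {
  cat("least-squares fit:", deparse(x$formula), "\n")
  cat(sprintf("  n = %d, rank = %d, RSS = %.4f on %d residual df\n",
              x$n, x$rank, x$rss, x$df_residual))
  invisible(x)
}

#' @export
coef.lc_fit <- function(object, ...) object$coefficients

#' @export
residuals.lc_fit <- function(object, ...) object$residuals

#' Nested-model F ratio
#'
#' `F = ((RSS_r - RSS_f) / (df_r - df_f)) / (RSS_f / df_f)` for a reduced
#' model nested in a full model, with the P value from the F distribution.
#'
#' @param reduced,full `lc_fit` objects; `full` must nest above `reduced`
#'   (same records, strictly fewer residual df, no larger RSS).
#' @param tol Relative tolerance on the RSS monotonicity check.
#' @return An object of class `f_ratio`: list with `statistic`, `df1`,
#'   `df2`, `p.value`.
#' @export
f_ratio <- function(reduced, full, tol = 1e-8) {
  stopifnot(inherits(reduced, "lc_fit"), inherits(full, "lc_fit"))
  if (reduced$n != full$n) {
    stop("models were fitted to different numbers of records")
  }
  if (!is.null(reduced$ids) && !is.null(full$ids) &&
      !identical(sort(reduced$ids), sort(full$ids))) {
    stop("models were fitted to different record sets")
  }
  df1 <- reduced$df_residual - full$df_residual
  if (df1 <= 0L) stop("'full' must have fewer residual df than 'reduced'")
  if (full$rss > reduced$rss * (1 + tol) + tol) {
    stop("RSS of the full model exceeds that of the reduced model: ",
         "models are not nested")
  }
  fstat <- max(reduced$rss - full$rss, 0) / df1 /
    (full$rss / full$df_residual)
  out <- list(statistic = fstat, df1 = df1, df2 = full$df_residual,
              p.value = stats::pf(fstat, df1, full$df_residual,
                                  lower.tail = FALSE))
  class(out) <- "f_ratio"
  out
}

#' @export
print.f_ratio <- function(x, ...) {
  cat(sprintf("F(%d, %d) = %.4f, P = %s\n",
              x$df1, x$df2, x$statistic, format_p(x$p.value)))
  invisible(x)
}

#' Additive (numerator) relationship matrix
#'
#' Tabular-method recursion over a pedigree sorted parents-first.
#' Unknown parents are treated as unrelated, non-inbred founders.
#'
#' @param pedigree Data frame with columns `id`, `sire`, `dam` (missing
#'   parents `NA` or `"0"`).
#' @return Symmetric matrix with `dimnames` equal to the pedigree ids, in
#'   the input order.
#' @export
build_a_matrix <- function(pedigree) {
  ped <- normalize_pedigree(pedigree, require_generation = FALSE)
  ord <- pedigree_order(ped)
  ped2 <- ped[ord, , drop = FALSE]
  n <- nrow(ped2)
  si <- match(ped2$sire, ped2$id)
  di <- match(ped2$dam, ped2$id)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      prev <- seq_len(i - 1L)
      r <- numeric(i - 1L)
      if (!is.na(s)) r <- r + A[s, prev]
      if (!is.na(d)) r <- r + A[d, prev]
      A[i, prev] <- A[prev, i] <- r / 2
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  back <- match(ped$id, ped2$id)
  A <- A[back, back, drop = FALSE]
  dimnames(A) <- list(ped$id, ped$id)
  A
}

#' Inbreeding coefficients from a pedigree
#'
#' `F_i = A(sire_i, dam_i) / 2`, computed on the ancestor closure of the
#' parents only (cheap even for large pedigrees whose terminal generation
#' has no offspring).
#'
#' @inheritParams build_a_matrix
#' @return Named numeric vector of inbreeding coefficients.
#' @export
inbreeding_coefficients <- function(pedigree) {
  ped <- normalize_pedigree(pedigree, require_generation = FALSE)
  parents <- unique(stats::na.omit(c(ped$sire, ped$dam)))
  closure <- character(0)
  frontier <- parents
  while (length(frontier)) {
    closure <- union(closure, frontier)
    rows <- ped[ped$id %in% frontier, , drop = FALSE]
    frontier <- setdiff(stats::na.omit(c(rows$sire, rows$dam)), closure)
  }
  Fv <- stats::setNames(numeric(nrow(ped)), ped$id)
  if (length(closure)) {
    A <- build_a_matrix(ped[ped$id %in% closure, , drop = FALSE])
    both <- !is.na(ped$sire) & !is.na(ped$dam)
    Fv[both] <- 0.5 * A[cbind(ped$sire[both], ped$dam[both])]
  }
  Fv
}

#' Sparse inverse of the additive relationship matrix
#'
#' Henderson's rules with inbreeding: each individual contributes
#' `alpha = 1 / b` with `b = 0.5 - 0.25 (F_s + F_d)` (both parents
#' known), `0.75 - 0.25 F_p` (one parent) or `1` (founder).
#'
#' @inheritParams build_a_matrix
#' @return A sparse symmetric [Matrix::Matrix()] indexed like the
#'   pedigree.
#' @export
a_matrix_inverse <- function(pedigree) {
  ped <- normalize_pedigree(pedigree, require_generation = FALSE)
  n <- nrow(ped)
  Fv <- inbreeding_coefficients(ped)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  Fs <- ifelse(is.na(si), 0, Fv[pmax(si, 1L)])
  Fd <- ifelse(is.na(di), 0, Fv[pmax(di, 1L)])
  b <- ifelse(!is.na(si) & !is.na(di), 0.5 - 0.25 * (Fs + Fd),
              ifelse(!is.na(si), 0.75 - 0.25 * Fs,
                     ifelse(!is.na(di), 0.75 - 0.25 * Fd, 1)))
  alpha <- 1 / b
  ii <- jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }
  idx <- seq_len(n)
  add(idx, idx, alpha)
  hs <- !is.na(si)
  add(idx[hs], si[hs], -alpha[hs] / 2); add(si[hs], idx[hs], -alpha[hs] / 2)
  add(si[hs], si[hs], alpha[hs] / 4)
  hd <- !is.na(di)
  add(idx[hd], di[hd], -alpha[hd] / 2); add(di[hd], idx[hd], -alpha[hd] / 2)
  add(di[hd], di[hd], alpha[hd] / 4)
  hb <- hs & hd
  add(si[hb], di[hb], alpha[hb] / 4); add(di[hb], si[hb], alpha[hb] / 4)
  Ai <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                             dimnames = list(ped$id, ped$id))
  Matrix::forceSymmetric(Ai)
}

#' Correct phenotypes for fixed and additive infinitesimal effects
#'
#' Solves the standard mixed-model equations with animal effects
#' `u ~ N(0, A sigma2_a)` at `lambda = sigma2_e / sigma2_a =
#' (1 - h2) / h2` and returns `y - X b - Z u`, the residuals after
#' removal of both the fixed-effect and the animal solutions.  At
#' `h2 = 0` (`lambda -> Inf`) the animal solutions vanish and the result
#' equals the fixed-effects-only OLS residuals.
#'
#' @param data Data frame with `id`, the response and the fixed-effect
#'   variables of `fixed`.
#' @param pedigree Full pedigree (see [build_a_matrix()]).
#' @param h2 Heritability `sigma2_a / (sigma2_a + sigma2_e)` in `[0, 1)`.
#' @param fixed Formula for the fixed part, response included.
#' @return Named numeric vector of corrected residuals (one per used
#'   record), with the fixed-effect and animal solutions attached as
#'   attributes.
#' @export
correct_phenotypes <- function(data, pedigree, h2 = 0.4,
                               fixed = ear_size ~ batch + sex + carcass_weight) {
  if (!is.numeric(h2) || length(h2) != 1L || h2 < 0 || h2 >= 1) {
    stop("'h2' must lie in [0, 1)")
  }
  data <- as.data.frame(data)
  vars <- all.vars(fixed)
  keep <- stats::complete.cases(data[, vars, drop = FALSE])
  if (any(!keep)) message(sum(!keep), " record(s) dropped for missing data")
  data <- droplevels(data[keep, , drop = FALSE])
  mf <- stats::model.frame(fixed, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(fixed, mf)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  ids <- as.character(data$id)

  if (h2 == 0) {
    e <- as.numeric(qr.resid(qr(X), y))
    names(e) <- ids
    return(structure(e, fixed_solutions = qr.coef(qr(X), y),
                     animal_solutions = NULL, h2 = 0))
  }

  ped <- normalize_pedigree(pedigree, require_generation = FALSE)
  if (!all(ids %in% ped$id)) {
    stop("phenotyped id(s) missing from pedigree: ",
         paste(utils::head(setdiff(ids, ped$id), 5L), collapse = ", "))
  }
  lambda <- (1 - h2) / h2
  Ai <- a_matrix_inverse(ped)
  n <- length(y); q <- nrow(ped); p <- ncol(X)
  Z <- Matrix::sparseMatrix(i = seq_len(n), j = match(ids, ped$id), x = 1,
                            dims = c(n, q))
  Xs <- Matrix::Matrix(X, sparse = TRUE)
  C <- rbind(cbind(Matrix::crossprod(Xs), Matrix::crossprod(Xs, Z)),
             cbind(Matrix::crossprod(Z, Xs),
                   Matrix::crossprod(Z) + lambda * Ai))
  rhs <- c(as.numeric(Matrix::crossprod(Xs, y)),
           as.numeric(Matrix::crossprod(Z, y)))
  sol <- tryCatch(as.numeric(Matrix::solve(C, rhs)),
                  error = function(e) stop("singular mixed-model equations: ",
                                           conditionMessage(e)))
  b <- sol[seq_len(p)]
  u <- sol[-seq_len(p)]
  e <- as.numeric(y - X %*% b - Z %*% u)
  names(e) <- ids
  structure(e, fixed_solutions = stats::setNames(b, colnames(X)),
            animal_solutions = stats::setNames(u, ped$id), h2 = h2)
}
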