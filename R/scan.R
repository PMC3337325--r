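# Chromosome scan for a line-cross QTL: at every scan position the
# line-origin coefficients (c_a, c_d) are tested as a 2-df addition to a
# base fixed-effect model, by the nested-model F ratio.  The engine works
# on residualised design columns so that permutation and bootstrap
# replicates reduce to a handful of BLAS calls.

# F statistics for adding (c_a, c_d) columns to a base design whose
# orthonormal basis Q is already removed.  ey: base-model residuals of y;
# A, D: residualised ca/cd column matrices (n x P).
.f_from_resid <- function(ey, rss0, A, D, n, k) {
  saa <- colSums(A * A)
  sdd <- colSums(D * D)
  sad <- colSums(A * D)
  va <- as.numeric(crossprod(A, ey))
  vd <- as.numeric(crossprod(D, ey))
  det <- saa * sdd - sad^2
  eps <- 1e-9 * n
  ssr <- numeric(length(saa))
  full <- det > eps^2 & saa > eps & sdd > eps
  ssr[full] <- (sdd[full] * va[full]^2 - 2 * sad[full] * va[full] * vd[full] +
                  saa[full] * vd[full]^2) / det[full]
  r1 <- !full
  if (any(r1)) {
    useA <- r1 & saa >= sdd & saa > eps
    useD <- r1 & sdd > saa & sdd > eps
    ssr[useA] <- va[useA]^2 / saa[useA]
    ssr[useD] <- vd[useD]^2 / sdd[useD]
  }
  df2 <- n - k - 2L
  Fv <- (ssr / 2) / pmax(rss0 - ssr, 0) * df2
  list(F = Fv, ssr = ssr, rss0 = rss0, df2 = df2)
}

.scan_engine <- function(y, X, Ca, Cd) {
  n <- length(y)
  qrX <- qr(X)
  k <- qrX$rank
  Q <- qr.Q(qrX)[, seq_len(k), drop = FALSE]
  ey <- as.numeric(y - Q %*% crossprod(Q, y))
  rss0 <- sum(ey^2)
  A <- Ca - Q %*% crossprod(Q, Ca)
  D <- Cd - Q %*% crossprod(Q, Cd)
  out <- .f_from_resid(ey, rss0, A, D, n, k)
  out$k <- k
  out$Q <- Q
  out$ey <- ey
  out
}

# coefficients and standard errors of the last columns of an augmented
# least-squares fit (pivot-aware)
.ls_effects <- function(y, Xf) {
  q <- qr(Xf)
  r <- q$rank
  cf <- qr.coef(q, y)
  res <- qr.resid(q, y)
  s2 <- sum(res^2) / (length(y) - r)
  se <- rep(NA_real_, ncol(Xf))
  R <- qr.R(q)[seq_len(r), seq_len(r), drop = FALSE]
  se[q$pivot[seq_len(r)]] <- sqrt(pmax(diag(chol2inv(R)), 0) * s2)
  names(se) <- colnames(Xf)
  list(coef = cf, se = se, rss = sum(res^2), df = length(y) - r)
}

#' Line-cross QTL scan along a chromosome
#'
#' At each scan position, fits the base fixed-effect model with and
#' without the line-origin regression terms `(c_a, c_d)` and records the
#' 2-df nested-model F ratio.  The peak of the resulting F curve locates
#' the QTL; additive and dominance effects are estimated at the peak.
#'
#' @param formula Base model formula (response and fixed effects /
#'   covariates, e.g. `ear_size ~ batch + sex + ppard + carcass_weight`).
#' @param data Phenotype data frame with an `id` column matching the
#'   grid.
#' @param grid A [line_origin()] grid covering every phenotyped
#'   individual.
#' @return An object of class `qtl_scan` with the F curve, the peak
#'   position and F value, effect estimates `a` (additive, half the
#'   difference between the two homozygous line-origin classes) and `d`
#'   (dominance) with standard errors, and the ingredients needed by
#'   [permutation_threshold()] and [bootstrap_ci()].
#' @seealso [summary.qtl_scan()], [plot.qtl_scan()],
#'   [variance_explained()]
#' @export
scan_qtl <- function(formula, data, grid) {
  data <- as.data.frame(data)
  if (!"id" %in% names(data)) stop("'data' must have an 'id' column")
  vars <- all.vars(formula)
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("variables not in data: ", paste(miss, collapse = ", "))
  keep <- stats::complete.cases(data[, vars, drop = FALSE])
  if (any(!keep)) message(sum(!keep), " record(s) dropped for missing data")
  data <- droplevels(data[keep, , drop = FALSE])
  idx <- match(as.character(data$id), grid$ids)
  if (anyNA(idx)) {
    stop("no line-origin states for id(s): ",
         paste(utils::head(data$id[is.na(idx)], 5L), collapse = ", "))
  }
  mf <- stats::model.frame(formula, data)
  y <- as.numeric(stats::model.response(mf))
  X <- stats::model.matrix(formula, mf)
  Ca <- grid$ca[idx, , drop = FALSE]
  Cd <- grid$cd[idx, , drop = FALSE]
  eng <- .scan_engine(y, X, Ca, Cd)
  Fv <- eng$F
  ipeak <- which.max(Fv)          # ties: first = smallest position
  Xf <- cbind(X, c_a = Ca[, ipeak], c_d = Cd[, ipeak])
  eff <- .ls_effects(y, Xf)
  out <- list(positions = grid$positions,
              F = Fv,
              peak_pos = grid$positions[ipeak],
              peak_F = Fv[ipeak],
              effects = c(a = unname(eff$coef["c_a"]),
                          d = unname(eff$coef["c_d"])),
              se = c(a = unname(eff$se["c_a"]),
                     d = unname(eff$se["c_d"])),
              n = length(y), rank_base = eng$k,
              rss_base = eng$rss0,
              rss_peak = eng$rss0 - eng$ssr[ipeak],
              df_peak = eng$df2,
              formula = formula,
              ids = as.character(data$id),
              y = y, X = X, ca = Ca, cd = Cd)
  class(out) <- "qtl_scan"
  out
}

#' @export
print.qtl_scan <- function(x, ...) {
  cat("line-cross QTL scan:", deparse(x$formula), "\n")
  cat(sprintf("  %d individuals, %d positions (%.1f-%.1f cM)\n",
              x$n, length(x$positions), min(x$positions), max(x$positions)))
  cat(sprintf("  peak F(2, %d) = %.2f at %.1f cM\n",
              x$df_peak, x$peak_F, x$peak_pos))
  cat(sprintf("  a = %.2f (se %.2f), d = %.2f (se %.2f)\n",
              x$effects["a"], x$se["a"], x$effects["d"], x$se["d"]))
  invisible(x)
}

#' @export
summary.qtl_scan <- function(object, ...) {
  out <- list(scan = object,
              variance_explained = variance_explained(object),
              p_nominal = stats::pf(object$peak_F, 2, object$df_peak,
                                    lower.tail = FALSE))
  class(out) <- "summary.qtl_scan"
  out
}

#' @export
print.summary.qtl_scan <- function(x, ...) {
  print(x$scan)
  cat(sprintf("  nominal P = %s; variance explained = %.2f%%\n",
              format_p(x$p_nominal), x$variance_explained))
  invisible(x)
}

#' @export
coef.qtl_scan <- function(object, ...) object$effects

#' Plot the F curve of a QTL scan
#'
#' @param x A [scan_qtl()] object.
#' @param threshold Optional significance threshold (horizontal line).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.qtl_scan <- function(x, threshold = NULL, ...) {
  graphics::plot(x$positions, x$F, type = "l", xlab = "position (cM)",
                 ylab = "F value", ...)
  graphics::abline(v = x$peak_pos, lty = 3)
  if (!is.null(threshold)) graphics::abline(h = threshold, lty = 2)
  invisible(x)
}

#' As-data-frame method for scan curves
#' @param x A `qtl_scan` object.
#' @param ... Unused.
#' @export
as.data.frame.qtl_scan <- function(x, ...) {
  data.frame(position = x$positions, F = x$F)
}

#' Permutation significance threshold for a QTL scan
#'
#' Phenotype records (response together with their fixed-effect
#' covariates) are permuted against the line-origin states; the maximum F
#' over the scan is recorded for each permutation and the threshold is
#' the empirical `1 - alpha` quantile of those maxima.
#'
#' @param scan A [scan_qtl()] object.
#' @param n_perm Number of permutations (>= 100).
#' @param alpha Significance level(s) in `(0, 1]`.
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `lc_perm`: list with `maxima`, `threshold`
#'   (one per `alpha`), `n_perm`, `alpha`.
#' @export
permutation_threshold <- function(scan, n_perm = 1000, alpha = 0.05,
                                  seed = NULL) {
  stopifnot(inherits(scan, "qtl_scan"))
  if (n_perm < 100) stop("'n_perm' must be at least 100")
  if (any(alpha <= 0) || any(alpha > 1)) stop("'alpha' must lie in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- scan$n
  qrX <- qr(scan$X)
  k <- qrX$rank
  Q <- qr.Q(qrX)[, seq_len(k), drop = FALSE]
  ey <- as.numeric(scan$y - Q %*% crossprod(Q, scan$y))
  rss0 <- sum(ey^2)
  maxima <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    pi <- sample.int(n)
    Cab <- scan$ca[pi, , drop = FALSE]
    Cdb <- scan$cd[pi, , drop = FALSE]
    A <- Cab - Q %*% crossprod(Q, Cab)
    D <- Cdb - Q %*% crossprod(Q, Cdb)
    maxima[b] <- max(.f_from_resid(ey, rss0, A, D, n, k)$F)
  }
  thr <- stats::quantile(maxima, 1 - alpha, type = 1, names = FALSE)
  out <- list(n_perm = n_perm, maxima = maxima, alpha = alpha,
              threshold = stats::setNames(thr, paste0(alpha * 100, "%")))
  class(out) <- "lc_perm"
  out
}

#' @export
print.lc_perm <- function(x, ...) {
  cat("permutation thresholds from", x$n_perm, "permutations:\n")
  print(round(x$threshold, 3))
  invisible(x)
}

#' Bootstrap confidence interval for QTL position
#'
#' Resamples individuals with replacement, re-scans, and collects the
#' peak positions; the CI is formed by the empirical 2.5% and 97.5%
#' quantiles.  Degenerate resamples in which the base design loses rank
#' (e.g. a batch level vanishes) are skipped and counted.
#'
#' @param scan A [scan_qtl()] object.
#' @param n_boot Number of bootstrap iterations.
#' @param seed Optional integer seed.
#' @return An object of class `lc_boot`: list with `peaks`, `ci`,
#'   `histogram` (position/count at the scan step), `n_boot`, `skipped`.
#' @export
bootstrap_ci <- function(scan, n_boot = 2000, seed = NULL) {
  stopifnot(inherits(scan, "qtl_scan"))
  if (n_boot < 1) stop("'n_boot' must be positive")
  if (!is.null(seed)) set.seed(seed)
  n <- scan$n
  base_rank <- scan$rank_base
  peaks <- numeric(n_boot)
  skipped <- 0L
  b <- 0L
  while (b < n_boot) {
    idx <- sample.int(n, replace = TRUE)
    Xb <- scan$X[idx, , drop = FALSE]
    qrb <- qr(Xb)
    if (qrb$rank < base_rank) {
      skipped <- skipped + 1L
      if (skipped > 100 * n_boot) stop("too many degenerate resamples")
      next
    }
    eng <- .scan_engine(scan$y[idx], Xb,
                        scan$ca[idx, , drop = FALSE],
                        scan$cd[idx, , drop = FALSE])
    b <- b + 1L
    peaks[b] <- scan$positions[which.max(eng$F)]
  }
  if (skipped > 0L) message(skipped, " degenerate resample(s) skipped")
  ci <- stats::quantile(peaks, c(0.025, 0.975), type = 1, names = FALSE)
  counts <- table(factor(peaks, levels = scan$positions))
  out <- list(n_boot = n_boot, peaks = peaks,
              ci = stats::setNames(ci, c("2.5%", "97.5%")),
              histogram = data.frame(position = scan$positions,
                                     count = as.integer(counts)),
              skipped = skipped)
  class(out) <- "lc_boot"
  out
}

#' @export
print.lc_boot <- function(x, ...) {
  cat(sprintf("bootstrap of QTL position (%d iterations): 95%% CI %.1f-%.1f cM\n",
              x$n_boot, x$ci[1L], x$ci[2L]))
  invisible(x)
}

#' @export
confint.qtl_scan <- function(object, parm, level = 0.95, n_boot = 2000,
                             seed = NULL, ...) {
  if (level != 0.95) stop("only the 95% bootstrap interval is supported")
  bootstrap_ci(object, n_boot = n_boot, seed = seed)$ci
}

#' Percent of phenotypic variance explained by the QTL terms
#'
#' Residual-variance reduction relative to the base (fixed-effects-only)
#' model: `100 (RSS_base - RSS_qtl) / RSS_base`.
#'
#' @param x A [scan_qtl()] object, or the reduced `lc_fit`.
#' @param ... For the `lc_fit` method: `full`, the nested full fit.
#' @return Percent of variance explained.
#' @export
variance_explained <- function(x, ...) UseMethod("variance_explained")

#' @rdname variance_explained
#' @export
variance_explained.qtl_scan <- function(x, ...) {
  100 * (x$rss_base - x$rss_peak) / x$rss_base
}

#' @rdname variance_explained
#' @param full The full (QTL) model fit, nested above `x` (or equal to
#'   it, giving 0).
#' @export
variance_explained.lc_fit <- function(x, full, ...) {
  if (x$n != full$n || full$df_residual > x$df_residual ||
      full$rss > x$rss * (1 + 1e-8) + 1e-8) {
    stop("'full' must be nested above (or equal to) the reduced fit")
  }
  100 * max(x$rss - full$rss, 0) / x$rss
}
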