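# Candidate-gene dissection under a line-cross QTL.  Four nested models
# share a base of fixed effects (batch, sex, unlinked-QTL genotype) and a
# covariate (carcass weight):
#   model 1: base
#   model 2: base + c_a + c_d              (line-origin QTL terms)
#   model 3: base + candidate genotype
#   model 4: base + candidate genotype + c_a + c_d
# Standard association:      model 3 vs model 1
# Marker-assisted:           model 4 vs model 2
# F-drop (QTL F with the SNP absorbed): model 4 vs model 3, against
#                                       model 2 vs model 1.

# normalise a candidate-SNP genotype table to (id, a1, a2, g)
.snp_table <- function(snp) {
  snp <- as.data.frame(snp, stringsAsFactors = FALSE)
  if (!all(c("id", "a1", "a2") %in% names(snp))) {
    al <- setdiff(names(snp), "id")
    if (length(al) != 2L) {
      stop("snp table must have columns id, a1, a2 (or id + 2 allele columns)")
    }
    names(snp)[match(al, names(snp))] <- c("a1", "a2")
  }
  snp$id <- as.character(snp$id)
  for (col in c("a1", "a2")) {
    v <- as.character(snp[[col]])
    v[v %in% c("0", "")] <- NA
    snp[[col]] <- v
  }
  miss <- is.na(snp$a1) | is.na(snp$a2)
  snp$g <- ifelse(miss, NA,
                  paste(pmin(snp$a1, snp$a2), pmax(snp$a1, snp$a2), sep = "/"))
  snp
}

.merge_snp <- function(data, snp) {
  snp <- .snp_table(snp)
  data <- as.data.frame(data)
  data$id <- as.character(data$id)
  m <- match(data$id, snp$id)
  data$.geno <- factor(snp$g[m])
  dropped <- sum(is.na(data$.geno))
  if (dropped) message(dropped, " record(s) without genotype dropped")
  data <- droplevels(data[!is.na(data$.geno), , drop = FALSE])
  if (nlevels(data$.geno) < 2L) {
    stop("candidate SNP is monomorphic in the phenotyped records")
  }
  data
}

#' Informativeness filter for discovery-panel variants
#'
#' Keeps a variant if its minor-allele frequency in a small discovery
#' panel of diploid genotypes reaches a threshold (default 25%, the
#' classical 4-animal/8-allele discovery rule).
#'
#' @param panel Matrix or data frame of genotype strings (`"AG"`, `"A/G"`),
#'   variants in rows, panel individuals in columns.
#' @param threshold Minimum minor-allele frequency.
#' @return Named logical vector, `TRUE` = keep.
#' @export
maf_filter <- function(panel, threshold = 0.25) {
  panel <- as.matrix(panel)
  keep <- logical(nrow(panel))
  names(keep) <- rownames(panel)
  for (i in seq_len(nrow(panel))) {
    g <- panel[i, ]
    g <- g[!is.na(g) & g != ""]
    alleles <- unlist(strsplit(gsub("[/|]", "", g), ""))
    if (!length(alleles)) stop("variant ", i, " has no called genotype")
    tab <- table(alleles)
    maf <- if (length(tab) < 2L) 0 else min(tab) / sum(tab)
    keep[i] <- maf >= threshold
  }
  keep
}

#' Standard association test of a candidate SNP (model 3 vs model 1)
#'
#' F ratio for adding the candidate genotype classes to the base model.
#' In an F2 between divergent lines this test is confounded by
#' between-breed linkage disequilibrium: any breed-differentiated variant
#' under the QTL will score.
#'
#' @param data Phenotype records (with `id` and the base-model
#'   variables).
#' @param snp Candidate genotypes: data frame `id`, `a1`, `a2`.
#' @param base Base model formula (model 1).
#' @return An object of class `assoc_test` with `statistic`, `df1`,
#'   `df2`, `p.value` and the two fits.
#' @export
standard_assoc <- function(data, snp,
                           base = ear_size ~ batch + sex + ppard + carcass_weight) {
  d <- .merge_snp(data, snp)
  fit1 <- fit_ls(base, d)
  fit3 <- fit_ls(stats::update(base, . ~ . + .geno), d)
  if (fit3$rank == fit1$rank) {
    stop("candidate genotype is aliased with the base model")
  }
  fr <- f_ratio(fit1, fit3)
  structure(list(test = "standard", statistic = fr$statistic,
                 df1 = fr$df1, df2 = fr$df2, p.value = fr$p.value,
                 fit_reduced = fit1, fit_full = fit3),
            class = "assoc_test")
}

#' Marker-assisted association test (model 4 vs model 2)
#'
#' F ratio for the candidate genotype with the line-origin QTL terms
#' `(c_a, c_d)` at the QTL peak held in both models, removing the
#' between-breed LD signal: only variants in within-breed LD with the
#' causal site (or the causal site itself) remain significant.
#'
#' @inheritParams standard_assoc
#' @param states Line-origin coefficients at the QTL peak: a data frame
#'   `id`, `c_a`, `c_d` (see [states_at()]).
#' @return An `assoc_test` object.
#' @export
marker_assisted_assoc <- function(data, snp, states,
                                  base = ear_size ~ batch + sex + ppard + carcass_weight) {
  d <- .merge_snp(data, snp)
  m <- match(as.character(d$id), as.character(states$id))
  if (anyNA(m)) stop("line-origin states missing for some phenotyped ids")
  d$.ca <- states$c_a[m]
  d$.cd <- states$c_d[m]
  fit2 <- fit_ls(stats::update(base, . ~ . + .ca + .cd), d)
  fit4 <- fit_ls(stats::update(base, . ~ . + .ca + .cd + .geno), d)
  if (fit4$rank == fit2$rank) {
    # genotype fully collinear with the line-origin terms: no extra signal
    out <- list(test = "marker_assisted", statistic = 0, df1 = 0L,
                df2 = fit2$df_residual, p.value = 1,
                fit_reduced = fit2, fit_full = fit4)
    class(out) <- "assoc_test"
    return(out)
  }
  fr <- f_ratio(fit2, fit4)
  structure(list(test = "marker_assisted", statistic = fr$statistic,
                 df1 = fr$df1, df2 = fr$df2, p.value = fr$p.value,
                 fit_reduced = fit2, fit_full = fit4),
            class = "assoc_test")
}

#' @export
print.assoc_test <- function(x, ...) {
  cat(sprintf("%s association test: F(%d, %d) = %.3f, P = %s\n",
              gsub("_", "-", x$test), x$df1, x$df2, x$statistic,
              format_p(x$p.value)))
  invisible(x)
}

#' Line-origin states at one scan position
#'
#' @param grid A [line_origin()] grid.
#' @param position Position in cM; the nearest grid position is used.
#' @return Data frame `id`, `c_a`, `c_d`.
#' @export
states_at <- function(grid, position) {
  j <- which.min(abs(grid$positions - position))
  data.frame(id = grid$ids, c_a = grid$ca[, j], c_d = grid$cd[, j],
             stringsAsFactors = FALSE)
}

#' F-drop test of a candidate SNP
#'
#' Compares the QTL F statistic with and without the candidate genotype
#' as a fixed effect.  `F_qtl` is the peak of the model 2 vs model 1 F
#' curve over the scan; `F_drop` is the model 4 vs model 3 F ratio, by
#' default evaluated at the position of the model 2 vs 1 peak (the
#' like-for-like comparison), or optionally at the maximum of its own
#' curve.  A near-total drop means the SNP absorbs essentially the whole
#' line-origin QTL signal.
#'
#' @inheritParams standard_assoc
#' @param grid A [line_origin()] grid over the scan.
#' @param at `"qtl_peak"` (default) or `"curve_max"`.
#' @return An object of class `f_drop`: `F_qtl`, `F_drop`,
#'   `drop_fraction = (F_qtl - F_drop)/F_qtl`, peak position, the two F
#'   curves.
#' @export
f_drop_test <- function(data, snp, grid,
                        base = ear_size ~ batch + sex + ppard + carcass_weight,
                        at = c("qtl_peak", "curve_max")) {
  at <- match.arg(at)
  d <- .merge_snp(data, snp)
  idx <- match(as.character(d$id), grid$ids)
  if (anyNA(idx)) stop("line-origin states missing for some phenotyped ids")
  mf <- stats::model.frame(base, d)
  y <- as.numeric(stats::model.response(mf))
  X1 <- stats::model.matrix(base, mf)
  X3 <- stats::model.matrix(stats::update(base, . ~ . + .geno), d)
  Ca <- grid$ca[idx, , drop = FALSE]
  Cd <- grid$cd[idx, , drop = FALSE]
  curve_qtl <- .scan_engine(y, X1, Ca, Cd)$F
  curve_drop <- .scan_engine(y, X3, Ca, Cd)$F
  ipk <- which.max(curve_qtl)
  F_qtl <- curve_qtl[ipk]
  F_drop <- if (at == "qtl_peak") curve_drop[ipk] else max(curve_drop)
  drop_fraction <- if (F_qtl < 1e-8) {
    warning("F_qtl is essentially zero; drop fraction undefined")
    NA_real_
  } else {
    (F_qtl - F_drop) / F_qtl
  }
  structure(list(F_qtl = F_qtl, F_drop = F_drop,
                 drop_fraction = drop_fraction,
                 peak_pos = grid$positions[ipk], at = at,
                 positions = grid$positions,
                 curve_qtl = curve_qtl, curve_drop = curve_drop),
            class = "f_drop")
}

#' @export
print.f_drop <- function(x, ...) {
  cat(sprintf("F-drop test (%s): F_qtl = %.2f -> F_drop = %.2f (drop %.1f%%)\n",
              x$at, x$F_qtl, x$F_drop, 100 * x$drop_fraction))
  invisible(x)
}

#' Additive effect of a candidate SNP
#'
#' Within the model-3 layout re-parameterised on allele dosage: the
#' additive effect is half the (adjusted) difference between the two
#' homozygote classes, signed with respect to a declared reference
#' allele; a heterozygote (dominance) term is carried alongside so that
#' the additive estimate is not biased by dominance.
#'
#' @inheritParams standard_assoc
#' @param ref_allele Allele whose substitution effect is reported;
#'   default: the alphabetically first allele.
#' @return An object of class `snp_effect`: `effect`, `se`,
#'   `ref_allele`, `n`.
#' @export
estimate_snp_effects <- function(data, snp,
                                 base = ear_size ~ batch + sex + ppard + carcass_weight,
                                 ref_allele = NULL) {
  d <- .merge_snp(data, snp)
  snpt <- .snp_table(snp)
  m <- match(as.character(d$id), snpt$id)
  a1 <- snpt$a1[m]; a2 <- snpt$a2[m]
  alleles <- sort(unique(c(a1, a2)))
  if (length(alleles) != 2L) stop("effect estimation needs a biallelic SNP")
  if (is.null(ref_allele)) ref_allele <- alleles[1L]
  if (!ref_allele %in% alleles) stop("reference allele not observed")
  dose <- (a1 == ref_allele) + (a2 == ref_allele) - 1
  if (!any(dose == 1) || !any(dose == -1)) {
    warning("a homozygote class is unobserved; additive effect undefined")
    return(structure(list(effect = NA_real_, se = NA_real_,
                          ref_allele = ref_allele, n = nrow(d)),
                     class = "snp_effect"))
  }
  d$.dose <- dose
  d$.het <- as.numeric(dose == 0)
  fit <- fit_ls(stats::update(base, . ~ . + .dose + .het), d)
  sm <- summary(fit$lm)$coefficients
  structure(list(effect = unname(sm[".dose", "Estimate"]),
                 se = unname(sm[".dose", "Std. Error"]),
                 ref_allele = ref_allele, n = fit$n),
            class = "snp_effect")
}

#' @export
print.snp_effect <- function(x, ...) {
  cat(sprintf("additive effect of allele [%s]: %.2f +/- %.2f cm2 (n = %d)\n",
              x$ref_allele, x$effect, x$se, x$n))
  invisible(x)
}

#' Ratio of residual sums of squares of two candidate-gene fits
#'
#' Both fits must be model-3 fits on the same records with different
#' candidate genes; a ratio below 1 ranks the first gene closer to the
#' QTL.
#'
#' @param fit_a,fit_b `lc_fit` objects on identical record sets.
#' @return `RSS_a / RSS_b`.
#' @export
rss_ratio <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "lc_fit"), inherits(fit_b, "lc_fit"))
  if (fit_a$n != fit_b$n ||
      (!is.null(fit_a$ids) && !is.null(fit_b$ids) &&
       !identical(sort(fit_a$ids), sort(fit_b$ids)))) {
    stop("fits are on different record sets")
  }
  fit_a$rss / fit_b$rss
}

# compact significance letters for class means: sweep over classes in
# mean order, emitting every maximal run whose pairwise comparisons are
# all non-significant; runs share no letter with classes they differ from
.sig_letters <- function(means, pmat, alpha = 0.05) {
  k <- length(means)
  ord <- order(means)
  all_ns <- function(cand) {
    for (x in seq_along(cand)) {
      for (y in seq_along(cand)) {
        if (x < y && isTRUE(pmat[cand[x], cand[y]] < alpha)) return(FALSE)
      }
    }
    TRUE
  }
  ends <- integer(k)
  for (i in seq_len(k)) {
    j <- i
    while (j < k && all_ns(ord[i:(j + 1L)])) j <- j + 1L
    ends[i] <- j
  }
  letters_out <- character(k)
  r <- 0L
  for (i in seq_len(k)) {
    if (i == 1L || ends[i] > ends[i - 1L]) {   # maximal run only
      r <- r + 1L
      run <- ord[i:ends[i]]
      letters_out[run] <- paste0(letters_out[run], letters[r])
    }
  }
  letters_out
}

#' Genotype association in an outbred line (one-way ANCOVA)
#'
#' For a single outbred population segregating the SNP: analysis of
#' covariance of the phenotype on genotype class with the declared
#' covariates, an overall F test, Tukey-adjusted pairwise genotype
#' contrasts and compact significance letters.
#'
#' @param data Phenotype records of one line (`id`, response, any
#'   covariates in `base`).
#' @param snp Candidate genotypes (`id`, `a1`, `a2`).
#' @param base Base formula without the genotype (default
#'   `ear_size ~ 1`).
#' @param alpha Significance level for the letters.
#' @return An object of class `outbred_assoc`: per-genotype `n`,
#'   adjusted mean, sd and letter; overall `statistic` and `p.value`.
#' @export
outbred_assoc <- function(data, snp, base = ear_size ~ 1, alpha = 0.05) {
  d <- .merge_snp(data, snp)
  fit0 <- fit_ls(base, d)
  form <- stats::update(base, . ~ . + .geno)
  fit1 <- fit_ls(form, d)
  fr <- f_ratio(fit0, fit1)
  resp <- all.vars(base)[1L]
  used <- d[stats::complete.cases(d[, all.vars(form), drop = FALSE]), , drop = FALSE]
  classes <- levels(used$.geno)
  nn <- as.integer(table(used$.geno))
  sds <- tapply(used[[resp]], used$.geno, stats::sd)
  # population-marginal (least-squares) means: average prediction with
  # every record assigned to class g
  lsm <- vapply(classes, function(g) {
    nd <- used
    nd$.geno <- factor(g, levels = classes)
    mean(stats::predict(fit1$lm, newdata = nd))
  }, numeric(1L))
  av <- stats::aov(form, data = used)
  tk <- stats::TukeyHSD(av, ".geno")$.geno
  pmat <- matrix(1, length(classes), length(classes),
                 dimnames = list(classes, classes))
  for (rn in rownames(tk)) {
    pair <- strsplit(rn, "-", fixed = TRUE)[[1L]]
    pmat[pair[1L], pair[2L]] <- pmat[pair[2L], pair[1L]] <- tk[rn, "p adj"]
  }
  letts <- .sig_letters(lsm, pmat, alpha)
  tab <- data.frame(genotype = classes, n = nn, mean = as.numeric(lsm),
                    sd = as.numeric(sds), letter = letts,
                    stringsAsFactors = FALSE)
  structure(list(table = tab, statistic = fr$statistic, df1 = fr$df1,
                 df2 = fr$df2, p.value = fr$p.value, pairwise = tk),
            class = "outbred_assoc")
}

#' @export
print.outbred_assoc <- function(x, ...) {
  cat(sprintf("outbred-line genotype ANCOVA: F(%d, %d) = %.3f, P = %s\n",
              x$df1, x$df2, x$statistic, format_p(x$p.value)))
  tab <- x$table
  tab$mean <- sprintf("%.2f", tab$mean)
  tab$sd <- sprintf("%.2f", tab$sd)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Candidate-SNP association table
#'
#' Runs the standard test, the marker-assisted test, the F-drop test and
#' additive-effect estimation for a set of candidate SNPs, and returns
#' one row per SNP (the layout of a candidate-gene association table).
#'
#' @inheritParams f_drop_test
#' @param snps Named list of candidate genotype tables.
#' @param ref_alleles Optional named character vector of reference
#'   alleles.
#' @return Data frame with columns `snp`, `p_sa`, `p_ma`, `allele`,
#'   `effect`, `se`, `F_qtl`, `F_drop`, `drop_fraction`, `rss_model3`.
#' @export
assoc_table <- function(data, snps, grid,
                        base = ear_size ~ batch + sex + ppard + carcass_weight,
                        ref_alleles = NULL, at = "qtl_peak") {
  stopifnot(is.list(snps), !is.null(names(snps)))
  peak <- NULL
  rows <- lapply(names(snps), function(nm) {
    snp <- snps[[nm]]
    sa <- standard_assoc(data, snp, base)
    if (is.null(peak)) {
      fd0 <- f_drop_test(data, snp, grid, base, at = at)
      peak <<- fd0$peak_pos
    }
    ma <- marker_assisted_assoc(data, snp, states_at(grid, peak), base)
    fd <- f_drop_test(data, snp, grid, base, at = at)
    ref <- if (!is.null(ref_alleles) && nm %in% names(ref_alleles)) {
      ref_alleles[[nm]]
    } else NULL
    eff <- estimate_snp_effects(data, snp, base, ref_allele = ref)
    data.frame(snp = nm, p_sa = sa$p.value, p_ma = ma$p.value,
               allele = eff$ref_allele, effect = eff$effect, se = eff$se,
               F_qtl = fd$F_qtl, F_drop = fd$F_drop,
               drop_fraction = fd$drop_fraction,
               rss_model3 = sa$fit_full$rss,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
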