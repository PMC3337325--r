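# Phasing of tightly linked candidate-gene SNPs in a three-generation
# pedigree, and haplotype-copy association of the corrected phenotypes.
#
# The SNP windows are assumed recombination-free within families (spans
# far below 1 cM), so a transmitted haplotype must equal one of the
# transmitting parent's haplotypes.  Phase is resolved by enumerating
# the haplotype pairs consistent with each genotype and filtering them
# against the parents' possible haplotypes until a fixpoint; individuals
# whose phase remains ambiguous are flagged and excluded, not imputed.

.hap_collapse <- function(m) apply(m, 1L, paste, collapse = "/")

# all ordered haplotype pairs consistent with one unphased genotype
.hap_pairs <- function(a1, a2) {
  het <- which(a1 != a2)
  if (!length(het)) {
    h <- paste(a1, collapse = "/")
    return(list(c(h, h)))
  }
  combs <- as.matrix(expand.grid(rep(list(c(TRUE, FALSE)), length(het))))
  pairs <- vector("list", nrow(combs))
  for (r in seq_len(nrow(combs))) {
    h1 <- a1; h2 <- a2
    flip <- het[combs[r, ]]
    h1[flip] <- a2[flip]; h2[flip] <- a1[flip]
    pairs[[r]] <- c(paste(h1, collapse = "/"), paste(h2, collapse = "/"))
  }
  unique(lapply(pairs, sort))
}

#' Phase a tight SNP window through an F2 pedigree
#'
#' Deduces each individual's haplotype pair over an ordered set of
#' tightly linked SNPs by Mendelian transmission: a haplotype pair is
#' retained only if it can be produced, without recombination inside the
#' window, from the parents' remaining haplotype sets.  Individuals
#' whose pair is not uniquely determined (missing genotypes, residual
#' ambiguity) are flagged unresolved.
#'
#' @param pedigree Pedigree data frame (see [tracks_from_genotypes()]).
#' @param genotypes Data frame with `id` and columns `<snp>_1`,
#'   `<snp>_2` per SNP, ordered by position; `"0"`/`NA` = missing.
#' @param snps Optional character vector of SNP names (defaults to the
#'   order of the genotype columns).
#' @return An object of class `hap_phase`: data frame with `id`, `hap1`,
#'   `hap2` (allele strings like `"A/T/G"`), `resolved`, and `method`
#'   (`"genotype"` for individuals phased by homozygosity alone,
#'   `"pedigree"` for transmission-resolved ones).
#' @export
phase_f2 <- function(pedigree, genotypes, snps = NULL) {
  ped <- normalize_pedigree(pedigree)
  if (is.null(snps)) {
    snps <- sub("_1$", "", grep("_1$", names(genotypes), value = TRUE))
  }
  k <- length(snps)
  if (k < 1L) stop("no SNP columns found")
  ids <- as.character(genotypes$id)
  n <- length(ids)
  A1 <- matrix(NA_character_, n, k)
  A2 <- matrix(NA_character_, n, k)
  for (j in seq_len(k)) {
    v1 <- as.character(genotypes[[paste0(snps[j], "_1")]])
    v2 <- as.character(genotypes[[paste0(snps[j], "_2")]])
    v1[v1 %in% c("0", "")] <- NA
    v2[v2 %in% c("0", "")] <- NA
    A1[, j] <- v1; A2[, j] <- v2
  }

  prow <- match(ped$id, ids)
  srow <- match(ped$sire, ped$id)
  drow <- match(ped$dam, ped$id)

  # per-SNP Mendelian consistency of the raw genotypes
  for (j in seq_len(k)) {
    for (i in seq_len(nrow(ped))) {
      ri <- prow[i]
      if (is.na(ri) || is.na(srow[i]) || is.na(drow[i])) next
      rs <- prow[srow[i]]; rd <- prow[drow[i]]
      if (is.na(rs) || is.na(rd)) next
      x <- A1[ri, j]; y <- A2[ri, j]
      v1 <- .can_come_from(x, A1[rs, j], A2[rs, j]) &
        .can_come_from(y, A1[rd, j], A2[rd, j])
      v2 <- .can_come_from(y, A1[rs, j], A2[rs, j]) &
        .can_come_from(x, A1[rd, j], A2[rd, j])
      if (isFALSE(v1) && isFALSE(v2)) {
        stop("Mendelian inconsistency for individual ", ped$id[i],
             " at SNP ", snps[j])
      }
    }
  }

  cand <- vector("list", n)
  for (i in seq_len(n)) {
    if (anyNA(A1[i, ]) || anyNA(A2[i, ])) next  # unresolved: missing data
    cand[[i]] <- .hap_pairs(A1[i, ], A2[i, ])
  }
  deterministic <- vapply(cand, function(cp) {
    !is.null(cp) && length(cp) == 1L
  }, logical(1L))

  hapset <- function(i) {
    if (is.na(i)) return(NULL)
    ri <- prow[i]
    if (is.na(ri) || is.null(cand[[ri]]) || !length(cand[[ri]])) return(NULL)
    unique(unlist(cand[[ri]]))
  }
  repeat {
    changed <- FALSE
    for (p in seq_len(nrow(ped))) {
      ri <- prow[p]
      if (is.na(ri) || is.null(cand[[ri]]) || length(cand[[ri]]) <= 1L) next
      Hs <- hapset(srow[p])
      Hd <- hapset(drow[p])
      if (is.null(Hs) && is.null(Hd)) next
      ok <- vapply(cand[[ri]], function(pr) {
        fit1 <- (is.null(Hs) || pr[1L] %in% Hs) &&
          (is.null(Hd) || pr[2L] %in% Hd)
        fit2 <- (is.null(Hs) || pr[2L] %in% Hs) &&
          (is.null(Hd) || pr[1L] %in% Hd)
        fit1 || fit2
      }, logical(1L))
      if (!all(ok)) {
        if (!any(ok)) {
          # window inconsistency (e.g. rare within-window recombination):
          # leave unresolved rather than guessing
          cand[[ri]] <- list()
        } else {
          cand[[ri]] <- cand[[ri]][ok]
        }
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  hap1 <- hap2 <- rep(NA_character_, n)
  resolved <- logical(n)
  for (i in seq_len(n)) {
    if (!is.null(cand[[i]]) && length(cand[[i]]) == 1L) {
      hap1[i] <- cand[[i]][[1L]][1L]
      hap2[i] <- cand[[i]][[1L]][2L]
      resolved[i] <- TRUE
    }
  }
  n_un <- sum(!resolved)
  if (n_un) message(n_un, " individual(s) left unresolved and excluded")
  out <- data.frame(id = ids, hap1 = hap1, hap2 = hap2,
                    resolved = resolved,
                    method = ifelse(!resolved, NA_character_,
                                    ifelse(deterministic, "genotype",
                                           "pedigree")),
                    stringsAsFactors = FALSE)
  class(out) <- c("hap_phase", "data.frame")
  out
}

#' Haplotype copy-number matrix
#'
#' @param assignments A [phase_f2()] result (unresolved individuals are
#'   dropped).
#' @param ids Optional subset of individual ids to keep, in that order.
#' @return Integer matrix, individuals x observed haplotypes, entries in
#'   `{0, 1, 2}`; every row sums to 2.  Column means divided by two are
#'   the haplotype frequencies.
#' @export
haplotype_copy_matrix <- function(assignments, ids = NULL) {
  a <- assignments[assignments$resolved, , drop = FALSE]
  if (!is.null(ids)) {
    a <- a[a$id %in% ids, , drop = FALSE]
    a <- a[match(intersect(ids, a$id), a$id), , drop = FALSE]
  }
  if (!nrow(a)) stop("no resolved individuals")
  haps <- sort(unique(c(a$hap1, a$hap2)))
  M <- matrix(0L, nrow(a), length(haps), dimnames = list(a$id, haps))
  M[cbind(seq_len(nrow(a)), match(a$hap1, haps))] <-
    M[cbind(seq_len(nrow(a)), match(a$hap1, haps))] + 1L
  M[cbind(seq_len(nrow(a)), match(a$hap2, haps))] <-
    M[cbind(seq_len(nrow(a)), match(a$hap2, haps))] + 1L
  M
}

#' Haplotype-copy regression with Bonferroni correction
#'
#' Regresses infinitesimal-corrected phenotype residuals on the copy
#' number (0/1/2) of each haplotype separately — one simple regression
#' per haplotype — and multiplies the raw P values by the number of
#' haplotypes (capped at 1).
#'
#' @param residuals Named numeric vector of corrected residuals (names =
#'   individual ids), from [correct_phenotypes()].
#' @param copies A [haplotype_copy_matrix()].
#' @return An object of class `hap_assoc`: data frame with `haplotype`,
#'   `frequency`, `effect`, `se`, `p_raw`, `p_corrected`.
#' @export
haplotype_regression <- function(residuals, copies) {
  common <- intersect(names(residuals), rownames(copies))
  if (!length(common)) stop("no individuals shared by residuals and copies")
  y <- residuals[common]
  M <- copies[common, , drop = FALSE]
  nh <- ncol(M)
  rows <- lapply(seq_len(nh), function(j) {
    x <- M[, j]
    freq <- mean(x) / 2
    if (stats::var(x) < .Machine$double.eps) {
      warning("haplotype ", colnames(M)[j],
              " has no copy-number variation; effect undefined")
      return(data.frame(haplotype = colnames(M)[j], frequency = freq,
                        effect = NA_real_, se = NA_real_,
                        p_raw = NA_real_, p_corrected = NA_real_))
    }
    fit <- stats::lm(y ~ x)
    sm <- summary(fit)$coefficients
    p <- sm["x", "Pr(>|t|)"]
    data.frame(haplotype = colnames(M)[j], frequency = freq,
               effect = unname(sm["x", "Estimate"]),
               se = unname(sm["x", "Std. Error"]),
               p_raw = p, p_corrected = min(1, p * nh),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("hap_assoc", "data.frame")
  out
}

#' Phenotypic variance explained by all haplotypes jointly
#'
#' Joint regression of the corrected residuals on all haplotype copy
#' numbers (one column dropped to break the rows-sum-to-two aliasing);
#' percent explained is `100 * model SS / total SS`, with the overall P
#' from the joint F test.
#'
#' @inheritParams haplotype_regression
#' @return List with `percent`, `statistic`, `df1`, `df2`, `p.value`.
#' @export
haplotype_variance_explained <- function(residuals, copies) {
  common <- intersect(names(residuals), rownames(copies))
  if (!length(common)) stop("no individuals shared by residuals and copies")
  y <- residuals[common]
  M <- copies[common, , drop = FALSE]
  if (ncol(M) < 2L) stop("need at least two haplotypes")
  drop_col <- which.max(colMeans(M))     # reference haplotype
  X <- M[, -drop_col, drop = FALSE]
  fit <- stats::lm(y ~ X)
  if (any(is.na(stats::coef(fit)))) {
    stop("copy matrix is rank-deficient beyond the expected aliasing")
  }
  sst <- sum((y - mean(y))^2)
  ssr <- sst - sum(stats::residuals(fit)^2)
  sm <- summary(fit)
  fst <- sm$fstatistic
  list(percent = 100 * ssr / sst,
       statistic = unname(fst["value"]),
       df1 = unname(fst["numdf"]), df2 = unname(fst["dendf"]),
       p.value = stats::pf(fst["value"], fst["numdf"], fst["dendf"],
                           lower.tail = FALSE))
}
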