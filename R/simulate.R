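# Forward simulator of a three-generation intercross between two
# divergent founder breeds: pedigree, no-interference meiosis over a
# linkage map, multi-allelic microsatellite and biallelic SNP genotypes,
# a planted QTN with additive/dominance effects by breed origin, an
# unlinked second QTL, fixed batch/sex effects, a carcass-weight
# covariate, pedigree-correlated polygenic values and residual noise.
# Every run records the truth needed to validate the analysis stages.

#' Cross design of an F2 intercross
#'
#' Defaults mirror a classical pig resource population: 2 founder sires
#' of the first breed mated to 17 dams of the second, 9 F1 boars x 59 F1
#' sows (full-sib matings avoided) producing 1912 F2 of which 1029 are
#' phenotyped.
#'
#' @param n_f0_sires,n_f0_dams Founder counts (breeds 1 and 2).
#' @param n_f1_boars,n_f1_sows F1 parents of the F2.
#' @param n_f2 Number of F2 individuals.
#' @param n_phenotyped Size of the phenotyped F2 subset.
#' @param avoid_full_sibs Forbid brother-sister F1 matings.
#' @return A `cross_design` list.
#' @export
cross_design <- function(n_f0_sires = 2, n_f0_dams = 17, n_f1_boars = 9,
                         n_f1_sows = 59, n_f2 = 1912, n_phenotyped = 1029,
                         avoid_full_sibs = TRUE) {
  d <- list(n_f0_sires = n_f0_sires, n_f0_dams = n_f0_dams,
            n_f1_boars = n_f1_boars, n_f1_sows = n_f1_sows,
            n_f2 = n_f2, n_phenotyped = n_phenotyped,
            avoid_full_sibs = avoid_full_sibs)
  if (any(unlist(d[1:6]) < 1)) stop("all design counts must be positive")
  if (n_phenotyped > n_f2) stop("cannot phenotype more than n_f2 animals")
  class(d) <- "cross_design"
  d
}

#' The default 10-marker chromosome map of the simulated cross
#'
#' @return A [linkage_map()] spanning 115.2 cM.
#' @export
default_map <- function() {
  build_map(paste("Acr - 3.0 - SW413 - 40.0 - SWR453 - 5.4 - SSC5P3 -",
                  "12.3 - SW1904 - 10.3 - SW2003 - 2.7 - SSC5P13 - 1.6 -",
                  "SSC5P16 - 10.9 - SW1987 - 21.1 - SW986 - 7.9 - SW995"),
            chromosome = "SSC5")
}

# per-marker founder allele frequencies for microsatellite-style loci:
# 4-8 alleles, breed-divergent sparse frequency vectors
.random_dirichlet <- function(k, conc) {
  g <- stats::rgamma(k, conc)
  g / sum(g)
}

#' Breed-divergent microsatellite allele frequencies
#'
#' Draws, for each mapped marker, an allele count in `n_alleles` and two
#' sparse Dirichlet frequency vectors, one per founder breed.  Lower
#' `concentration` makes the vectors sparser and the breeds more
#' divergent (hence the markers more line-informative).
#'
#' @param map A [linkage_map()].
#' @param n_alleles Candidate allele counts.
#' @param concentration Dirichlet concentration per allele.
#' @return List (one element per marker) of lists with `alleles`,
#'   `freq1`, `freq2`.
#' @export
marker_panel <- function(map, n_alleles = 4:8, concentration = 0.5) {
  lapply(seq_len(nrow(map)), function(i) {
    k <- if (length(n_alleles) == 1L) n_alleles else sample(n_alleles, 1L)
    list(alleles = as.character(seq_len(k)),
         freq1 = .random_dirichlet(k, concentration),
         freq2 = .random_dirichlet(k, concentration))
  })
}

#' Candidate-SNP window of the simulated cross
#'
#' Three tightly linked biallelic SNPs at the QTN position (the window
#' span is far below the map resolution, so it is placed at a single map
#' coordinate and is recombination-free).  The middle SNP, `qtn`, is the
#' causal variant and is fixed for alternative alleles in the two
#' founder breeds; the flanking SNPs segregate in both breeds.
#'
#' @param pos Map position of the window in cM.
#' @return Data frame with `snp`, `pos`, `allele1`, `allele2`, `freq1`,
#'   `freq2` (frequency of `allele1` in breeds 1 and 2).
#' @export
snp_panel <- function(pos = 60.7) {
  data.frame(snp = c("cg_snp1", "qtn", "cg_snp2"),
             pos = pos,
             allele1 = c("C", "A", "G"),
             allele2 = c("T", "G", "A"),
             freq1 = c(0.75, 1.00, 0.35),
             freq2 = c(0.25, 0.00, 0.85),
             stringsAsFactors = FALSE)
}

#' Generative phenotype model of the cross
#'
#' `y = mu + batch + sex + beta * cw + ppard + qtn(a, d by line origin)
#'  + u + e`, with `u` pedigree-correlated polygenic values
#' (`u ~ N(0, A sigma2_a)`) and `e ~ N(0, sigma2_e)`.  The defaults
#' plant an additive QTN of 32.84 cm2 (second-breed origin increases the
#' trait) explaining about 19% of the phenotypic variance left after the
#' fixed effects, with a polygenic heritability of 0.4 among the
#' remainder.
#'
#' @param mu Overall mean (cm2).
#' @param batch Six batch effects (cm2).
#' @param sex Two sex effects (cm2).
#' @param beta_cw Regression on carcass weight (cm2/kg).
#' @param cw_mean,cw_sd Carcass-weight distribution (kg).
#' @param a,d Additive and dominance QTN effects (cm2); positive `a`
#'   means the second founder breed's allele increases the trait.
#' @param qtn Name of the causal SNP in the window.
#' @param ppard Genotype-class effects of the unlinked second QTL (cm2).
#' @param ppard_freq1,ppard_freq2 Frequency of the first PPARD allele in
#'   the two founder breeds.
#' @param sigma2_a,sigma2_e Polygenic and residual variances (cm4).
#' @return A `phenotype_model` list.
#' @export
phenotype_model <- function(mu = 280,
                            batch = c(0, 6, -4, 10, -8, 3),
                            sex = c(0, -10),
                            beta_cw = 1.2, cw_mean = 80, cw_sd = 10,
                            a = 32.84, d = 0, qtn = "qtn",
                            ppard = c(-12, 0, 12),
                            ppard_freq1 = 0.85, ppard_freq2 = 0.15,
                            sigma2_a = 920, sigma2_e = 1380) {
  if (sigma2_a < 0 || sigma2_e < 0) stop("variances must be non-negative")
  m <- list(mu = mu, batch = batch, sex = sex, beta_cw = beta_cw,
            cw_mean = cw_mean, cw_sd = cw_sd, a = a, d = d, qtn = qtn,
            ppard = ppard, ppard_freq1 = ppard_freq1,
            ppard_freq2 = ppard_freq2,
            sigma2_a = sigma2_a, sigma2_e = sigma2_e)
  class(m) <- "phenotype_model"
  m
}

#' Simulate meioses of one parent
#'
#' Crossovers occur independently in each inter-locus interval with
#' probability equal to the Haldane recombination fraction of the
#' interval, i.e. no interference; the starting haplotype is chosen at
#' random.
#'
#' @param parent List with `h1` and `h2`, the two haplotypes (allele
#'   vectors over the loci).
#' @param positions Locus positions in cM.
#' @param n Number of gametes.
#' @return List with `alleles` (n x loci matrix) and `source` (n x loci
#'   matrix of 1/2: which parental haplotype each allele came from).
#' @export
simulate_meiosis <- function(parent, positions, n = 1) {
  L <- length(positions)
  stopifnot(length(parent$h1) == L, length(parent$h2) == L)
  src <- matrix(0L, n, L)
  src[, 1L] <- sample(c(0L, 1L), n, replace = TRUE)
  if (L > 1L) {
    r <- haldane_d_to_r(diff(positions))
    for (j in 2L:L) {
      xo <- stats::rbinom(n, 1L, r[j - 1L])
      src[, j] <- (src[, j - 1L] + xo) %% 2L
    }
  }
  alleles <- matrix(parent$h2[rep(seq_len(L), each = n)], n, L)
  pick1 <- src == 0L
  h1m <- matrix(parent$h1[rep(seq_len(L), each = n)], n, L)
  alleles[pick1] <- h1m[pick1]
  list(alleles = alleles, source = ifelse(src == 0L, 1L, 2L))
}

# draw founder haplotypes for one breed over the extended locus set
.founder_haplo <- function(n_hap, panel, snp, ms_idx, snp_idx, breed) {
  L <- length(ms_idx) + length(snp_idx)
  H <- matrix(NA_character_, n_hap, L)
  for (j in seq_along(ms_idx)) {
    fr <- if (breed == 1L) panel[[j]]$freq1 else panel[[j]]$freq2
    H[, ms_idx[j]] <- sample(panel[[j]]$alleles, n_hap, replace = TRUE,
                             prob = fr)
  }
  for (j in seq_along(snp_idx)) {
    p1 <- if (breed == 1L) snp$freq1[j] else snp$freq2[j]
    H[, snp_idx[j]] <- ifelse(stats::runif(n_hap) < p1,
                              snp$allele1[j], snp$allele2[j])
  }
  H
}

#' Simulate the three-generation cross
#'
#' Founders are drawn from breed-specific allele frequencies (the QTN
#' fixed for alternative alleles per breed), F1 and F2 genotypes arise
#' by simulated meiosis, and the true breed origin of every transmitted
#' allele is recorded.
#'
#' @param design A [cross_design()].
#' @param map A [linkage_map()] for the scanned chromosome.
#' @param seed Optional integer seed.
#' @param panel Microsatellite frequencies ([marker_panel()]); drawn
#'   fresh when `NULL`.
#' @param snps Candidate-SNP window ([snp_panel()]).
#' @param model A [phenotype_model()] (supplies the unlinked-QTL allele
#'   frequencies; effects are used later by [simulate_phenotypes()]).
#' @param lines Founder breed labels (first = breed 1).
#' @return An object of class `sim_cross`: list with `pedigree`,
#'   `genotypes` (microsatellites, all generations), `snp_genotypes`
#'   (window SNPs, all generations), `map`, `snps`, `design`, `model`
#'   and `truth` (F2 gamete origin matrices over all loci, QTN origin
#'   counts, window haplotypes, seed).
#' @export
simulate_cross <- function(design = cross_design(), map = default_map(),
                           seed = NULL, panel = NULL, snps = snp_panel(),
                           model = phenotype_model(),
                           lines = c("W", "E")) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(panel)) panel <- marker_panel(map)

  # extended locus table: microsatellites + SNP window, in map order
  loci <- rbind(data.frame(name = map$marker, pos = map$pos, type = "ms",
                           stringsAsFactors = FALSE),
                data.frame(name = snps$snp, pos = snps$pos, type = "snp",
                           stringsAsFactors = FALSE))
  loci <- loci[order(loci$pos, loci$type != "ms"), , drop = FALSE]
  ms_idx <- match(map$marker, loci$name)
  snp_idx <- match(snps$snp, loci$name)
  pos <- loci$pos
  L <- nrow(loci)

  n_s <- design$n_f0_sires; n_d <- design$n_f0_dams
  n_f0 <- n_s + n_d
  f0_ids <- c(sprintf("F0S%02d", seq_len(n_s)), sprintf("F0D%02d", seq_len(n_d)))
  H1_f0 <- rbind(.founder_haplo(n_s, panel, snps, ms_idx, snp_idx, 1L),
                 .founder_haplo(n_d, panel, snps, ms_idx, snp_idx, 2L))
  H2_f0 <- rbind(.founder_haplo(n_s, panel, snps, ms_idx, snp_idx, 1L),
                 .founder_haplo(n_d, panel, snps, ms_idx, snp_idx, 2L))
  pfrq <- c(rep(model$ppard_freq1, n_s), rep(model$ppard_freq2, n_d))
  PP_f0 <- cbind(ifelse(stats::runif(n_f0) < pfrq, "C", "T"),
                 ifelse(stats::runif(n_f0) < pfrq, "C", "T"))

  # F1: every dam mated to one sire (round-robin); litters sized to give
  # exactly the required F1 parents, sexes assigned at random
  total_f1 <- design$n_f1_boars + design$n_f1_sows
  litter <- ceiling(total_f1 / n_d)
  f1_dam_i <- rep(n_s + seq_len(n_d), each = litter)[seq_len(total_f1)]
  f1_sire_i <- (match(f1_dam_i, n_s + seq_len(n_d)) - 1L) %% n_s + 1L
  f1_ids <- sprintf("F1_%03d", seq_len(total_f1))
  f1_sire <- f0_ids[f1_sire_i]
  f1_dam <- f0_ids[f1_dam_i]
  H1_f1 <- matrix(NA_character_, total_f1, L)   # paternal = breed-1 origin
  H2_f1 <- matrix(NA_character_, total_f1, L)   # maternal = breed-2 origin
  for (p in unique(f1_sire_i)) {
    rows <- which(f1_sire_i == p)
    g <- simulate_meiosis(list(h1 = H1_f0[p, ], h2 = H2_f0[p, ]), pos,
                          length(rows))
    H1_f1[rows, ] <- g$alleles
  }
  for (p in unique(f1_dam_i)) {
    rows <- which(f1_dam_i == p)
    g <- simulate_meiosis(list(h1 = H1_f0[p, ], h2 = H2_f0[p, ]), pos,
                          length(rows))
    H2_f1[rows, ] <- g$alleles
  }
  pick <- function(M, rows) M[cbind(rows, sample(c(1L, 2L), length(rows),
                                                 replace = TRUE))]
  PP_f1 <- cbind(pick(PP_f0, f1_sire_i), pick(PP_f0, f1_dam_i))
  boar_i <- sort(sample(total_f1, design$n_f1_boars))
  sow_i <- setdiff(seq_len(total_f1), boar_i)[seq_len(design$n_f1_sows)]

  # F2 matings: dams cycle through the sows, sires drawn per mating
  n2 <- design$n_f2
  f2_dam_i <- rep(sow_i, length.out = n2)
  f2_sire_i <- sample(boar_i, n2, replace = TRUE)
  if (design$avoid_full_sibs) {
    repeat {
      bad <- which(f1_sire_i[f2_sire_i] == f1_sire_i[f2_dam_i] &
                     f1_dam_i[f2_sire_i] == f1_dam_i[f2_dam_i])
      if (!length(bad)) break
      f2_sire_i[bad] <- sample(boar_i, length(bad), replace = TRUE)
    }
  }
  f2_ids <- sprintf("F2_%04d", seq_len(n2))

  # vectorised meiosis grouped by parent
  G_pat <- matrix(NA_character_, n2, L)
  G_mat <- matrix(NA_character_, n2, L)
  O_pat <- matrix(NA_integer_, n2, L)    # 1 = breed-1 origin
  O_mat <- matrix(NA_integer_, n2, L)
  for (p in unique(f2_sire_i)) {
    rows <- which(f2_sire_i == p)
    g <- simulate_meiosis(list(h1 = H1_f1[p, ], h2 = H2_f1[p, ]), pos,
                          length(rows))
    G_pat[rows, ] <- g$alleles
    O_pat[rows, ] <- 2L - g$source       # source 1 (h1) -> breed 1
  }
  for (p in unique(f2_dam_i)) {
    rows <- which(f2_dam_i == p)
    g <- simulate_meiosis(list(h1 = H1_f1[p, ], h2 = H2_f1[p, ]), pos,
                          length(rows))
    G_mat[rows, ] <- g$alleles
    O_mat[rows, ] <- 2L - g$source
  }
  PP_f2 <- cbind(pick(PP_f1, f2_sire_i), pick(PP_f1, f2_dam_i))

  ped <- data.frame(
    id = c(f0_ids, f1_ids, f2_ids),
    sire = c(rep(NA, n_f0), f1_sire, f1_ids[f2_sire_i]),
    dam = c(rep(NA, n_f0), f1_dam, f1_ids[f2_dam_i]),
    generation = c(rep(0L, n_f0), rep(1L, total_f1), rep(2L, n2)),
    breed = c(rep(lines[1L], n_s), rep(lines[2L], n_d),
              rep(NA, total_f1 + n2)),
    stringsAsFactors = FALSE)

  A1 <- rbind(H1_f0, H1_f1, G_pat)   # allele 1 = paternal gamete
  A2 <- rbind(H2_f0, H2_f1, G_mat)
  geno_tab <- function(idx_set, locus_names) {
    out <- data.frame(id = ped$id, stringsAsFactors = FALSE)
    for (j in seq_along(idx_set)) {
      out[[paste0(locus_names[j], "_1")]] <- A1[, idx_set[j]]
      out[[paste0(locus_names[j], "_2")]] <- A2[, idx_set[j]]
    }
    out
  }
  genotypes <- geno_tab(ms_idx, map$marker)
  snp_genotypes <- geno_tab(snp_idx, snps$snp)

  pp_all <- rbind(PP_f0, PP_f1, PP_f2)
  ppard_geno <- data.frame(id = ped$id, a1 = pp_all[, 1L], a2 = pp_all[, 2L],
                           stringsAsFactors = FALSE)

  iq <- snp_idx[match(model$qtn, snps$snp)]
  truth <- list(
    loci = loci,
    origin_paternal = O_pat, origin_maternal = O_mat,
    f2_ids = f2_ids,
    qtn_pos = pos[iq],
    qtn_n2 = (1L - O_pat[, iq]) + (1L - O_mat[, iq]),  # breed-2 allele count
    window_hap_pat = .hap_collapse(G_pat[, snp_idx, drop = FALSE]),
    window_hap_mat = .hap_collapse(G_mat[, snp_idx, drop = FALSE]),
    seed = seed)

  structure(list(pedigree = ped, genotypes = genotypes,
                 snp_genotypes = snp_genotypes, ppard = ppard_geno,
                 map = map, snps = snps, design = design, model = model,
                 lines = lines, truth = truth),
            class = "sim_cross")
}

#' @export
print.sim_cross <- function(x, ...) {
  tab <- table(x$pedigree$generation)
  cat("simulated cross:", paste0("F", names(tab), "=", tab, collapse = ", "),
      "\n  ", nrow(x$map), "microsatellites +", nrow(x$snps),
      "window SNPs on", attr(x$map, "chromosome") %||% "chromosome", "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Simulate phenotypes for the F2 of a simulated cross
#'
#' Applies the generative phenotype model: batch (uniform over 6
#' levels), sex (balanced Bernoulli), carcass-weight covariate, the
#' unlinked-QTL genotype effect, the QTN effect by breed origin,
#' pedigree-exact polygenic values (parent average plus Mendelian
#' sampling scaled by parental inbreeding) and Gaussian residuals.
#' A random subset of the F2 is phenotyped.
#'
#' @param cross A [simulate_cross()] result.
#' @param model A [phenotype_model()]; defaults to the one stored in the
#'   cross.
#' @param seed Optional integer seed.
#' @return Data frame `id`, `ear_size`, `batch`, `sex`,
#'   `carcass_weight`, `ppard` for the phenotyped subset, with the truth
#'   (all F2 components) in `attr(, "truth")`.
#' @export
simulate_phenotypes <- function(cross, model = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(model)) model <- cross$model
  ped <- cross$pedigree
  f2 <- cross$truth$f2_ids
  n2 <- length(f2)

  batch <- sample(seq_along(model$batch), n2, replace = TRUE)
  sex <- sample(seq_along(model$sex), n2, replace = TRUE)
  cw <- stats::rnorm(n2, model$cw_mean, model$cw_sd)

  pg <- cross$ppard
  m <- match(f2, pg$id)
  ppard_class <- (pg$a1[m] == "C") + (pg$a2[m] == "C") + 1L  # 1..3 = TT,CT,CC

  qtn_n2 <- cross$truth$qtn_n2
  qtn_val <- model$a * (qtn_n2 - 1) + model$d * (qtn_n2 == 1L)

  # polygenic values: recursive parent-average + Mendelian sampling
  u <- stats::setNames(numeric(nrow(ped)), ped$id)
  if (model$sigma2_a > 0) {
    Fv <- inbreeding_coefficients(ped)
    ord <- pedigree_order(ped)
    for (i in ord) {
      s <- ped$sire[i]; d <- ped$dam[i]
      if (is.na(s) && is.na(d)) {
        u[i] <- stats::rnorm(1L, 0, sqrt(model$sigma2_a))
      } else {
        pa <- mean(c(u[s], u[d]), na.rm = TRUE)
        Fs <- if (is.na(s)) 0 else Fv[s]
        Fd <- if (is.na(d)) 0 else Fv[d]
        msv <- model$sigma2_a * (0.5 - 0.25 * (Fs + Fd))
        u[i] <- pa + stats::rnorm(1L, 0, sqrt(msv))
      }
    }
  }
  e <- stats::rnorm(n2, 0, sqrt(model$sigma2_e))
  y <- model$mu + model$batch[batch] + model$sex[sex] +
    model$beta_cw * cw + model$ppard[ppard_class] + qtn_val + u[f2] + e

  keep <- sort(sample(n2, cross$design$n_phenotyped))
  out <- data.frame(id = f2, ear_size = y,
                    batch = factor(batch, levels = seq_along(model$batch)),
                    sex = factor(sex, levels = seq_along(model$sex)),
                    carcass_weight = cw,
                    ppard = factor(ppard_class, levels = 1:3),
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  attr(out, "truth") <- list(u = u[f2], e = e, qtn_val = qtn_val,
                             qtn_n2 = qtn_n2, batch = batch, sex = sex,
                             phenotyped = f2[keep], model = model)
  out
}

#' True line-origin tracks of a simulated cross
#'
#' Packages the simulator's recorded gamete origins at the
#' microsatellite markers as an `origin_tracks` object, for oracle
#' comparisons with [tracks_from_genotypes()].
#'
#' @param cross A [simulate_cross()] result.
#' @return An `origin_tracks` object (fully informative at every
#'   marker).
#' @export
true_tracks <- function(cross) {
  ms_idx <- match(cross$map$marker, cross$truth$loci$name)
  pat <- cross$truth$origin_paternal[, ms_idx, drop = FALSE]
  mat <- cross$truth$origin_maternal[, ms_idx, drop = FALSE]
  dimnames(pat) <- dimnames(mat) <- list(cross$truth$f2_ids,
                                         cross$map$marker)
  structure(list(ids = cross$truth$f2_ids, map = cross$map,
                 lines = cross$lines,
                 paternal = pat, maternal = mat),
            class = "origin_tracks")
}

#' Mendelian consistency check
#'
#' Verifies that every genotyped offspring could have received one
#' allele from each parent at every marker.
#'
#' @param pedigree Pedigree data frame.
#' @param genotypes Genotype table (`id` + `<marker>_1`/`_2` columns).
#' @return Data frame of violations (`id`, `marker`); zero rows when
#'   consistent.
#' @export
check_mendelian <- function(pedigree, genotypes) {
  ped <- normalize_pedigree(pedigree, require_generation = FALSE)
  markers <- sub("_1$", "", grep("_1$", names(genotypes), value = TRUE))
  gid <- as.character(genotypes$id)
  bad_id <- character(0); bad_mk <- character(0)
  has_par <- !is.na(ped$sire) & !is.na(ped$dam)
  ci <- match(ped$id, gid); si <- match(ped$sire, gid); di <- match(ped$dam, gid)
  for (mk in markers) {
    a1 <- as.character(genotypes[[paste0(mk, "_1")]])
    a2 <- as.character(genotypes[[paste0(mk, "_2")]])
    a1[a1 %in% c("0", "")] <- NA; a2[a2 %in% c("0", "")] <- NA
    rows <- which(has_par & !is.na(ci) & !is.na(si) & !is.na(di))
    x <- a1[ci[rows]]; y <- a2[ci[rows]]
    v1 <- .can_come_from(x, a1[si[rows]], a2[si[rows]]) &
      .can_come_from(y, a1[di[rows]], a2[di[rows]])
    v2 <- .can_come_from(y, a1[si[rows]], a2[si[rows]]) &
      .can_come_from(x, a1[di[rows]], a2[di[rows]])
    viol <- !is.na(v1) & !is.na(v2) & !v1 & !v2
    if (any(viol)) {
      bad_id <- c(bad_id, ped$id[rows[viol]])
      bad_mk <- c(bad_mk, rep(mk, sum(viol)))
    }
  }
  data.frame(id = bad_id, marker = bad_mk, stringsAsFactors = FALSE)
}

#' Simulate an outbred commercial line segregating the candidate SNP
#'
#' A single population with genotype classes drawn from given
#' frequencies and phenotypes from class means plus Gaussian noise (the
#' design of a synthetic-line confirmation study).
#'
#' @param n Number of animals.
#' @param freqs Genotype-class frequencies (hom1, het, hom2).
#' @param means Class means (cm2).
#' @param sd Within-class standard deviation (cm2).
#' @param alleles The two SNP alleles.
#' @param seed Optional integer seed.
#' @return List with `data` (`id`, `ear_size`) and `snp`
#'   (`id`, `a1`, `a2`).
#' @export
simulate_outbred <- function(n = 173, freqs = c(0.52, 0.44, 0.04),
                             means = c(258.57, 292.60, 323.50), sd = 42,
                             alleles = c("A", "G"), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cls <- sample(1:3, n, replace = TRUE, prob = freqs)
  ids <- sprintf("OB_%03d", seq_len(n))
  a1 <- c(alleles[1L], alleles[1L], alleles[2L])[cls]
  a2 <- c(alleles[1L], alleles[2L], alleles[2L])[cls]
  list(data = data.frame(id = ids,
                         ear_size = means[cls] + stats::rnorm(n, 0, sd),
                         stringsAsFactors = FALSE),
       snp = data.frame(id = ids, a1 = a1, a2 = a2,
                        stringsAsFactors = FALSE))
}

#' Generate a complete synthetic dataset for one scenario
#'
#' Scenarios: `"study_like"` (full cross, planted QTN, candidate-SNP
#' window), `"qtn_genotyped"` (identical cross; the causal SNP is the
#' designated candidate), `"null"` (no QTN, no polygenic variance,
#' 400 F2 all phenotyped) and `"outbred_line"` (a single commercial
#' line).  When `dir` is given, all tables are written as TSV plus a
#' truth JSON.
#'
#' @param scenario Scenario label.
#' @param seed Integer seed (all randomness flows from it).
#' @param dir Optional output directory.
#' @return Invisibly, a list with the simulated objects (and `files`
#'   when written).
#' @export
make_fixture <- function(scenario = c("study_like", "qtn_genotyped",
                                      "null", "outbred_line"),
                         seed = 1, dir = NULL) {
  scenario <- match.arg(scenario)
  set.seed(seed)
  if (scenario == "outbred_line") {
    ob <- simulate_outbred()
    out <- list(scenario = scenario, seed = seed, data = ob$data,
                snp = ob$snp)
  } else {
    design <- cross_design()
    model <- phenotype_model()
    if (scenario == "null") {
      design <- cross_design(n_f2 = 400, n_phenotyped = 400)
      model <- phenotype_model(a = 0, d = 0, sigma2_a = 0)
    }
    cross <- simulate_cross(design, model = model)
    phen <- simulate_phenotypes(cross)
    out <- list(scenario = scenario, seed = seed, cross = cross,
                phenotypes = phen, qtn_snp = "qtn")
  }
  if (!is.null(dir)) {
    out$files <- write_fixture(out, dir)
  }
  invisible(out)
}
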