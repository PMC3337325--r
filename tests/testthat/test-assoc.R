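sc <- small_cross(23, n_f2 = 500)
tracks <- tracks_from_genotypes(sc$cross$pedigree, sc$cross$genotypes,
                                sc$cross$map)
grid <- line_origin(tracks, step = 2)
qtn <- snp_from(sc$cross$snp_genotypes, "qtn")
lnk <- snp_from(sc$cross$snp_genotypes, "cg_snp1")

test_that("the discovery-panel MAF filter applies the 25% boundary exactly", {
  panel <- rbind(v1 = c("AA", "AA", "AG", "AG"),   # maf 2/8 = 0.25: keep
                 v2 = c("AA", "AA", "AA", "AG"),   # maf 1/8: drop
                 v3 = c("A/G", "A/G", "G/G", "G/G"))
  keep <- maf_filter(panel)
  expect_true(keep[["v1"]])
  expect_false(keep[["v2"]])
  expect_true(keep[["v3"]])
  expect_error(maf_filter(rbind(v = c(NA, NA, NA, NA))), "no called")
})

test_that("the MAF filter equals brute-force allele counting on random panels", {
  set.seed(31)
  for (rep in 1:30) {
    g <- replicate(4, paste0(sample(c("A", "C"), 1), sample(c("A", "C"), 1)))
    panel <- rbind(v = g)
    counts <- table(factor(unlist(strsplit(g, "")), levels = c("A", "C")))
    maf <- min(counts) / 8
    expect_identical(unname(maf_filter(panel)), maf >= 0.25)
  }
})

test_that("the standard test detects a planted QTN and rejects aliased input", {
  sa <- standard_assoc(sc$phen, qtn, base_formula)
  expect_lt(sa$p.value, 1e-10)
  expect_equal(sa$df1, 2L)
  # a 'SNP' that duplicates a design factor adds no rank
  fake <- data.frame(id = sc$phen$id,
                     a1 = as.character(sc$phen$sex),
                     a2 = as.character(sc$phen$sex))
  expect_error(standard_assoc(sc$phen, fake, base_formula), "aliased")
  mono <- data.frame(id = sc$phen$id, a1 = "A", a2 = "A")
  expect_error(standard_assoc(sc$phen, mono, base_formula), "monomorphic")
})

test_that("null SNPs give uniform P values in both association tests", {
  set.seed(77)
  ids <- sc$phen$id
  pk <- states_at(grid, 60.7)
  p_sa <- p_ma <- numeric(120)
  for (r in 1:120) {
    al <- sample(c("A", "G"), 2 * length(ids), TRUE, prob = c(0.6, 0.4))
    nullsnp <- data.frame(id = ids, a1 = al[seq_along(ids)],
                          a2 = al[-seq_along(ids)])
    p_sa[r] <- standard_assoc(sc$phen, nullsnp, base_formula)$p.value
    p_ma[r] <- marker_assisted_assoc(sc$phen, nullsnp, pk, base_formula)$p.value
  }
  expect_gt(ks.test(p_sa, "punif")$p.value, 0.001)
  expect_gt(ks.test(p_ma, "punif")$p.value, 0.001)
})

test_that("marker-assisted testing separates the causal SNP from a distant diagnostic one", {
  # a fully breed-diagnostic variant far from the QTL carries line-origin
  # information but no causal signal at the peak
  sca <- scan_qtl(base_formula, sc$phen, grid)
  pk <- states_at(grid, sca$peak_pos)
  ma_qtn <- marker_assisted_assoc(sc$phen, qtn, pk, base_formula)
  # diagnostic SNP: allele equals the true origin at 0 cM (far marker)
  tt <- true_tracks(sc$cross)
  ids <- sc$phen$id
  i <- match(ids, tt$ids)
  diag_snp <- data.frame(id = ids,
                         a1 = ifelse(tt$paternal[i, 1] == 1, "W", "E"),
                         a2 = ifelse(tt$maternal[i, 1] == 1, "W", "E"))
  ma_diag <- marker_assisted_assoc(sc$phen, diag_snp, pk, base_formula)
  expect_lt(ma_qtn$p.value, ma_diag$p.value)
})

test_that("perfect collinearity with the line-origin terms yields P = 1", {
  # states built directly from the SNP itself: dosage and heterozygosity
  ids <- sc$phen$id
  m <- match(ids, qtn$id)
  nA <- (qtn$a1[m] == "A") + (qtn$a2[m] == "A")
  st <- data.frame(id = ids, c_a = nA - 1, c_d = as.numeric(nA == 1))
  ma <- marker_assisted_assoc(sc$phen, qtn, st, base_formula)
  expect_equal(ma$p.value, 1)
  expect_equal(ma$statistic, 0)
})

test_that("the F-drop test collapses for the causal SNP but not for independents", {
  fd <- f_drop_test(sc$phen, qtn, grid, base_formula)
  expect_gt(fd$drop_fraction, 0.9)
  expect_equal(fd$F_qtl, max(fd$curve_qtl))
  # an unlinked null SNP leaves the QTL F essentially unchanged
  set.seed(5)
  ids <- sc$phen$id
  al <- sample(c("A", "G"), 2 * length(ids), TRUE)
  nullsnp <- data.frame(id = ids, a1 = al[seq_along(ids)],
                        a2 = al[-seq_along(ids)])
  fd0 <- f_drop_test(sc$phen, nullsnp, grid, base_formula)
  expect_lt(abs(fd0$drop_fraction), 0.2)
  # affine phenotype transforms leave the drop fraction unchanged
  phen2 <- sc$phen
  phen2$ear_size <- 3 * phen2$ear_size - 40
  fd2 <- f_drop_test(phen2, qtn, grid, base_formula)
  expect_equal(fd2$drop_fraction, fd$drop_fraction, tolerance = 1e-9)
  # the curve-max variant is also available
  fdm <- f_drop_test(sc$phen, qtn, grid, base_formula, at = "curve_max")
  expect_gte(fdm$F_drop, fd$F_drop)
})

test_that("additive effects are signed by the reference allele and recovered", {
  effA <- estimate_snp_effects(sc$phen, qtn, base_formula, ref_allele = "A")
  effG <- estimate_snp_effects(sc$phen, qtn, base_formula, ref_allele = "G")
  expect_equal(effA$effect, -effG$effect, tolerance = 1e-10)
  expect_equal(effA$se, effG$se, tolerance = 1e-10)
  # truth: allele A (first-breed origin) lowers the trait by a = 32.84
  expect_lt(abs(effA$effect - (-32.84)), 3 * effA$se)
  # equal class means give a zero effect
  d0 <- data.frame(id = sprintf("x%03d", 1:300),
                   ear_size = rep(c(10, 20, 10), 100),
                   stringsAsFactors = FALSE)
  s0 <- data.frame(id = d0$id, a1 = rep(c("A", "A", "G"), 100),
                   a2 = rep(c("A", "G", "G"), 100))
  e0 <- suppressWarnings(estimate_snp_effects(d0, s0, ear_size ~ 1))
  expect_equal(e0$effect, 0, tolerance = 1e-10)
  # a missing homozygote class is flagged
  s1 <- s0[s0$a1 == "A", ]
  expect_warning(e1 <- estimate_snp_effects(d0, s1, ear_size ~ 1),
                 "homozygote")
  expect_true(is.na(e1$effect))
})

test_that("RSS ratios are reciprocal, unity on identical fits, and rank genes", {
  f_qtn <- standard_assoc(sc$phen, qtn, base_formula)$fit_full
  f_lnk <- standard_assoc(sc$phen, lnk, base_formula)$fit_full
  expect_equal(rss_ratio(f_qtn, f_qtn), 1)
  expect_equal(rss_ratio(f_qtn, f_lnk) * rss_ratio(f_lnk, f_qtn), 1,
               tolerance = 1e-12)
  # the causal gene leaves less residual variance than a linked proxy
  expect_lt(rss_ratio(f_qtn, f_lnk), 1)
  other <- fit_ls(ear_size ~ 1, sc$phen[1:100, ])
  expect_error(rss_ratio(f_qtn, other), "different record sets")
})

test_that("outbred-line ANCOVA separates ordered class means with distinct letters", {
  ob <- simulate_outbred(n = 600, freqs = c(0.4, 0.4, 0.2), sd = 30,
                         seed = 12)
  res <- outbred_assoc(ob$data, ob$snp, ear_size ~ 1)
  expect_lt(res$p.value, 1e-6)
  expect_equal(sum(res$table$n), 600L)
  expect_identical(res$table$letter[order(res$table$mean)],
                   c("a", "b", "c"))
  # under the null the overall P is not degenerate
  ob0 <- simulate_outbred(n = 150, means = c(250, 250, 250), seed = 3)
  res0 <- outbred_assoc(ob0$data, ob0$snp, ear_size ~ 1)
  expect_gt(res0$p.value, 0.001)
})

test_that("the association table ranks the causal SNP first", {
  tab <- assoc_table(sc$phen,
                     list(qtn = qtn, cg_snp1 = lnk,
                          cg_snp2 = snp_from(sc$cross$snp_genotypes, "cg_snp2")),
                     grid, base_formula)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$snp[which.min(tab$rss_model3)], "qtn")
  expect_equal(tab$snp[which.max(tab$drop_fraction)], "qtn")
  expect_true(all(tab$p_sa > 0 & tab$p_sa <= 1))
})
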