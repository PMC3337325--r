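test_that("least-squares fits report RSS and degrees of freedom", {
  d <- data.frame(y = c(1, 2, 3, 4))
  fit <- fit_ls(y ~ 1, d)
  expect_equal(fit$rss, 5)
  expect_equal(fit$df_residual, 3L)
  # a regressor orthogonal to y's variation leaves RSS unchanged
  d$w <- c(1, -1, -1, 1)                  # orthogonal to 1 and to y - mean(y)
  expect_equal(fit_ls(y ~ w, d)$rss, fit$rss)
  expect_error(fit_ls(y ~ 1, d[0, , drop = FALSE]), "empty")
  expect_error(fit_ls(y ~ factor(seq_along(y)), d), "zero residual")
})

test_that("fits drop incomplete records with a message and aliased columns", {
  d <- data.frame(y = c(1, 2, 3, 4, 5), x = c(1, 2, NA, 4, 5))
  expect_message(fit <- fit_ls(y ~ x, d), "1 record")
  expect_equal(fit$n, 4L)
  d2 <- data.frame(y = rnorm(6), a = c(1, 1, 2, 2, 3, 3), x = c(0, 0, 1, 1, 2, 2))
  d2$a <- factor(d2$a)
  expect_message(fit2 <- fit_ls(y ~ a + x, d2), "aliased")
})

test_that("the nested-model F ratio matches hand computation", {
  d <- data.frame(y = c(1, 2, 3, 4), g = factor(c(0, 0, 1, 1)))
  red <- fit_ls(y ~ 1, d)
  ful <- fit_ls(y ~ g, d)
  expect_equal(ful$rss, 1)
  fr <- f_ratio(red, ful)
  expect_equal(fr$statistic, 8)
  expect_equal(fr$df1, 1L)
  expect_equal(fr$df2, 2L)
  expect_equal(fr$p.value, pf(8, 1, 2, lower.tail = FALSE))
  # equal RSS in a genuinely larger model gives F = 0, P = 1
  d$w <- c(1, -1, -1, 1)
  fr0 <- f_ratio(red, fit_ls(y ~ w, d))
  expect_equal(fr0$statistic, 0)
  expect_equal(fr0$p.value, 1)
  expect_error(f_ratio(red, red), "fewer residual df")
  expect_error(f_ratio(ful, red), "fewer residual df|not nested")
})

test_that("F ratios are invariant to affine response transforms and reordering", {
  set.seed(21)
  d <- data.frame(y = rnorm(40), g = factor(sample(1:3, 40, TRUE)),
                  x = rnorm(40))
  f1 <- f_ratio(fit_ls(y ~ x, d), fit_ls(y ~ x + g, d))
  d2 <- d; d2$y <- 2 * d$y + 7
  f2 <- f_ratio(fit_ls(y ~ x, d2), fit_ls(y ~ x + g, d2))
  expect_equal(f2$statistic, f1$statistic, tolerance = 1e-10)
  d3 <- d[sample(nrow(d)), ]
  f3 <- f_ratio(fit_ls(y ~ x, d3), fit_ls(y ~ x + g, d3))
  expect_equal(f3$statistic, f1$statistic, tolerance = 1e-10)
  # residuals scale with the response
  expect_equal(residuals(fit_ls(y ~ x, d2)),
               2 * residuals(fit_ls(y ~ x, d)), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("null F-ratio P values are uniform", {
  set.seed(8)
  n <- 30
  p <- replicate(1500, {
    y <- rnorm(n)
    g <- factor(sample(1:2, n, TRUE))
    x <- cbind(1, model.matrix(~g)[, -1, drop = FALSE])
    rss0 <- sum(qr.resid(qr(matrix(1, n, 1)), y)^2)
    rss1 <- sum(qr.resid(qr(x), y)^2)
    fstat <- (rss0 - rss1) / (rss1 / (n - 2))
    pf(fstat, 1, n - 2, lower.tail = FALSE)
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.001)
})

test_that("the tabular A-matrix reproduces textbook relationships", {
  ped <- data.frame(id = c("a", "b"), sire = NA, dam = NA)
  expect_equal(unname(build_a_matrix(ped)), diag(2))
  # full sibs of unrelated non-inbred parents
  ped <- data.frame(id = c("s", "d", "o1", "o2"),
                    sire = c(NA, NA, "s", "s"),
                    dam = c(NA, NA, "d", "d"))
  A <- build_a_matrix(ped)
  expect_equal(A["o1", "o2"], 0.5)
  expect_equal(A["o1", "o1"], 1)
  expect_equal(A["o1", "s"], 0.5)
  # offspring of a parent-offspring mating is inbred F = 0.25
  ped <- data.frame(id = c("s", "d", "o", "x"),
                    sire = c(NA, NA, "s", "s"),
                    dam = c(NA, NA, "d", "o"))
  A <- build_a_matrix(ped)
  expect_equal(A["x", "x"], 1.25)
  expect_equal(inbreeding_coefficients(ped)[["x"]], 0.25)
  # cycles are rejected
  bad <- data.frame(id = c("a", "b"), sire = c("b", "a"), dam = NA)
  expect_error(build_a_matrix(bad), "cycle")
})

random_pedigree <- function(seed, n = 40) {
  set.seed(seed)
  ped <- data.frame(id = paste0("i", 1:n), sire = NA_character_,
                    dam = NA_character_, stringsAsFactors = FALSE)
  for (i in 11:n) {
    ped$sire[i] <- paste0("i", sample(i - 10, 1))
    ped$dam[i] <- paste0("i", sample(i - 10, 1))
    if (ped$dam[i] == ped$sire[i]) ped$dam[i] <- NA  # no selfing
  }
  ped
}

test_that("A-matrix properties hold on random pedigrees and A-inverse matches", {
  for (seed in 1:5) {
    ped <- random_pedigree(seed)
    A <- build_a_matrix(ped)
    expect_equal(A, t(A))
    expect_true(all(diag(A) >= 1))
    ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev > -1e-8))
    Ai <- as.matrix(a_matrix_inverse(ped))
    expect_equal(unname(Ai %*% A), diag(nrow(A)), tolerance = 1e-8)
  }
})

test_that("mixed-model correction reduces to OLS as lambda grows", {
  sc <- small_cross(2, n_f2 = 150)
  phen <- sc$phen
  ols <- correct_phenotypes(phen, sc$cross$pedigree, h2 = 0,
                            fixed = ear_size ~ batch + sex + carcass_weight)
  mm <- correct_phenotypes(phen, sc$cross$pedigree, h2 = 1e-9,
                           fixed = ear_size ~ batch + sex + carcass_weight)
  expect_lt(max(abs(ols - mm)), 1e-6)
  expect_error(correct_phenotypes(phen, sc$cross$pedigree, h2 = 1), "0, 1")
})

test_that("unrelated individuals are shrunk by a uniform factor", {
  set.seed(4)
  n <- 80
  ped <- data.frame(id = paste0("i", 1:n), sire = NA, dam = NA)
  d <- data.frame(id = ped$id, ear_size = rnorm(n, 100, 10))
  h2 <- 0.5
  cor_res <- correct_phenotypes(d, ped, h2 = h2, fixed = ear_size ~ 1)
  ols_res <- correct_phenotypes(d, ped, h2 = 0, fixed = ear_size ~ 1)
  # with A = I and one record each: u = e_ols/(1 + lambda), so the
  # corrected residual is e_ols * lambda / (1 + lambda)... up to the
  # re-estimated intercept, which is unchanged here
  lambda <- (1 - h2) / h2
  expect_equal(as.numeric(cor_res), as.numeric(ols_res) * lambda / (1 + lambda),
               tolerance = 1e-8)
})

test_that("infinitesimal correction improves agreement with true breeding values", {
  sc <- small_cross(9, n_f2 = 400)
  truth <- attr(sc$phen, "truth")
  u_true <- truth$u[match(sc$phen$id, names(truth$u))]
  raw <- correct_phenotypes(sc$phen, sc$cross$pedigree, h2 = 0,
                            fixed = ear_size ~ batch + sex + carcass_weight)
  cor_res <- correct_phenotypes(sc$phen, sc$cross$pedigree, h2 = 0.4,
                                fixed = ear_size ~ batch + sex + carcass_weight)
  # corrected residuals should contain less of the polygenic signal
  expect_lt(abs(cor(cor_res, u_true)), abs(cor(raw, u_true)))
})
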