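toy_map <- linkage_map(c("m1", "m2", "m3"), c(0, 20, 50))

test_that("gamete origin probability handles the degenerate and symmetric cases", {
  tr <- data.frame(pos = c(0, 20), origin = c("W", "E"))
  # at an informative marker the origin is certain
  expect_equal(gamete_origin_probability(tr, toy_map, 0), 1)
  expect_equal(gamete_origin_probability(tr, toy_map, 20), 0)
  # midpoint of recombinant flanks: symmetry
  expect_equal(gamete_origin_probability(tr, toy_map, 10), 0.5)
  # 5 cM from the W flank of a 20 cM recombinant interval
  r5 <- haldane_d_to_r(5); r15 <- haldane_d_to_r(15); r20 <- haldane_d_to_r(20)
  expect_equal(gamete_origin_probability(tr, toy_map, 5),
               (1 - r5) * r15 / r20)
  expect_equal(gamete_origin_probability(tr, toy_map, 5), 0.7488,
               tolerance = 1e-4)
  expect_error(gamete_origin_probability(tr[0, ], toy_map, 5), "empty")
  expect_error(gamete_origin_probability(tr, toy_map, 60), "span")
})

test_that("flanking-marker conditioning equals brute-force crossover enumeration", {
  map <- toy_map
  configs <- expand.grid(o1 = 0:1, o2 = 0:1, o3 = 0:1)
  positions <- c(0, 3.7, 10, 20, 31.4, 50)
  for (i in seq_len(nrow(configs))) {
    o <- as.integer(configs[i, ])
    tr <- data.frame(pos = map$pos, origin = ifelse(o == 1, "W", "E"))
    for (p in positions) {
      # the implementation conditions on the nearest flanks only; with
      # no interference that equals conditioning on all markers jointly,
      # which is what the enumeration oracle computes
      expect_equal(gamete_origin_probability(tr, map, p),
                   oracle_origin_prob(map$pos, o, p),
                   tolerance = 1e-9,
                   info = sprintf("config %d, position %.1f", i, p))
    }
  }
})

test_that("a single informative marker decays monotonically toward 1/2", {
  map <- linkage_map(c("a", "b"), c(0, 100))
  tr <- data.frame(pos = 0, origin = "W")
  p <- vapply(seq(0, 100, by = 5),
              function(x) gamete_origin_probability(tr, map, x), numeric(1))
  expect_equal(p[1L], 1)
  expect_true(all(diff(p) < 0))
  expect_true(all(p > 0.5))
})

test_that("line-origin states multiply gamete probabilities and close to 1", {
  tr_w <- data.frame(pos = 20, origin = "W")
  st <- line_origin_state_f2(tr_w, tr_w, toy_map, 20)
  expect_equal(c(st$p_ww, st$p_we, st$p_ee), c(1, 0, 0))
  expect_equal(st$c_a, 1)
  expect_equal(st$c_d, 0)
  # both gametes at probability 1/2
  tr_mid <- data.frame(pos = c(0, 20), origin = c("W", "E"))
  st <- line_origin_state_f2(tr_mid, tr_mid, toy_map, 10)
  expect_equal(st$p_we, 0.5)
  expect_equal(st$c_a, 0)
  expect_equal(st$c_d, 0.5)
  # product rule: paternal gamete certain (informative marker at the
  # query position), maternal at the recombinant-flank probability
  map2 <- linkage_map(c("m1", "mq", "m2"), c(0, 5, 20))
  tr_pat <- data.frame(pos = 5, origin = "W")
  pm <- gamete_origin_probability(tr_mid, map2, 5)
  st <- line_origin_state_f2(tr_mid, tr_pat, map2, 5)
  expect_equal(st$p_ww, pm)
  expect_equal(st$c_a, pm)
  expect_equal(st$c_d, 1 - pm)
  expect_equal(st$p_ee, 0)
})

test_that("line-origin states satisfy closure and coefficient bounds on random tracks", {
  set.seed(11)
  map <- linkage_map(letters[1:5], c(0, 7, 19, 40, 66))
  for (rep in 1:50) {
    keep_m <- sort(sample(5, sample(1:5, 1)))
    keep_p <- sort(sample(5, sample(1:5, 1)))
    trm <- data.frame(pos = map$pos[keep_m],
                      origin = sample(c("W", "E"), length(keep_m), TRUE))
    trp <- data.frame(pos = map$pos[keep_p],
                      origin = sample(c("W", "E"), length(keep_p), TRUE))
    p <- runif(1, 0, 66)
    st <- line_origin_state_f2(trm, trp, map, p)
    expect_equal(st$p_ww + st$p_we + st$p_ee, 1, tolerance = 1e-9)
    expect_true(st$c_a >= -1 && st$c_a <= 1)
    expect_true(st$c_d >= 0 && st$c_d <= 1)
  }
})

test_that("the grid evaluator agrees with the single-track evaluator", {
  set.seed(3)
  map <- linkage_map(letters[1:4], c(0, 12, 30, 55))
  O <- matrix(sample(c(0, 1, NA), 4 * 20, TRUE), 20, 4)
  O[1, ] <- NA                              # fully uninformative row
  tracks <- structure(list(ids = sprintf("i%02d", 1:20), map = map,
                           lines = c("W", "E"), paternal = O, maternal = O),
                      class = "origin_tracks")
  grid <- line_origin(tracks, step = 2.5)
  for (i in c(1, 2, 7, 20)) {
    keep <- !is.na(O[i, ])
    for (j in seq_along(grid$positions)) {
      expected <- if (!any(keep)) 0.5 else {
        tr <- data.frame(pos = map$pos[keep],
                         origin = ifelse(O[i, keep] == 1, "W", "E"))
        gamete_origin_probability(tr, map, grid$positions[j])
      }
      expect_equal(grid$p_ww[i, j], expected^2, tolerance = 1e-12)
    }
  }
})

test_that("empirical origin frequencies match computed probabilities", {
  set.seed(99)
  map <- linkage_map(c("L", "R"), c(0, 30))
  n <- 100000
  parent <- list(h1 = c("1", "1"), h2 = c("2", "2"))  # phase-known parent
  g <- simulate_meiosis(parent, map$pos, n)
  # condition on gametes carrying h1 (origin W) at the left marker and
  # h2 (origin E) at the right marker; compare the crossover model's
  # origin probability at 10 cM against the empirical h1 frequency
  tr <- data.frame(pos = c(0, 30), origin = c("W", "E"))
  p_theory <- gamete_origin_probability(tr, map, 10)
  # simulate the full three-point process to observe the middle locus
  map3 <- c(0, 10, 30)
  parent3 <- list(h1 = c("1", "1", "1"), h2 = c("2", "2", "2"))
  g3 <- simulate_meiosis(parent3, map3, n)
  sel <- g3$source[, 1] == 1L & g3$source[, 3] == 2L
  p_emp <- mean(g3$source[sel, 2] == 1L)
  se <- sqrt(p_theory * (1 - p_theory) / sum(sel))
  expect_lt(abs(p_emp - p_theory), 3 * se)
})

test_that("origin tracks are reconstructed exactly where markers are informative", {
  sc <- small_cross(5, n_f2 = 250)
  tracks <- tracks_from_genotypes(sc$cross$pedigree, sc$cross$genotypes,
                                  sc$cross$map)
  truth <- true_tracks(sc$cross)
  for (side in c("paternal", "maternal")) {
    got <- tracks[[side]]
    keep <- !is.na(got)
    expect_gt(mean(keep), 0.4)            # divergent markers are informative
    expect_true(all(got[keep] == truth[[side]][keep]))
  }
})

test_that("breed-diagnostic and monomorphic markers behave as expected", {
  # hand-built family: founders fixed for different alleles at m1,
  # monomorphic at m2; X is origin-homozygous at m1, Y heterozygous
  ped <- data.frame(id = c("S", "D", "F1a", "F1b", "X", "Y"),
                    sire = c(NA, NA, "S", "S", "F1a", "F1a"),
                    dam = c(NA, NA, "D", "D", "F1b", "F1b"),
                    generation = c(0, 0, 1, 1, 2, 2),
                    breed = c("W", "E", NA, NA, NA, NA))
  geno <- data.frame(id = c("S", "D", "F1a", "F1b", "X", "Y"),
                     m1_1 = c("1", "2", "1", "1", "1", "1"),
                     m1_2 = c("1", "2", "2", "2", "1", "2"),
                     m2_1 = c("3", "3", "3", "3", "3", "3"),
                     m2_2 = c("3", "3", "3", "3", "3", "3"),
                     stringsAsFactors = FALSE)
  map <- linkage_map(c("m1", "m2"), c(0, 10))
  tracks <- tracks_from_genotypes(ped, geno, map)
  # homozygote: both transmitted alleles trace to the first breed
  expect_equal(unname(tracks$paternal["X", "m1"]), 1)
  expect_equal(unname(tracks$maternal["X", "m1"]), 1)
  # heterozygote with both parents heterozygous: the transmitting parent
  # of each allele is ambiguous, so the per-gamete origin is dropped
  expect_true(is.na(tracks$paternal["Y", "m1"]))
  # monomorphic marker: uninformative everywhere
  expect_true(all(is.na(tracks$paternal[, "m2"])))
  expect_true(all(is.na(tracks$maternal[, "m2"])))
})

test_that("Mendelian inconsistencies are reported with individual and marker", {
  ped <- data.frame(id = c("S", "D", "F1a", "F1b", "X"),
                    sire = c(NA, NA, "S", "S", "F1a"),
                    dam = c(NA, NA, "D", "D", "F1b"),
                    generation = c(0, 0, 1, 1, 2),
                    breed = c("W", "E", NA, NA, NA))
  geno <- data.frame(id = c("S", "D", "F1a", "F1b", "X"),
                     m1_1 = c("1", "2", "1", "1", "5"),
                     m1_2 = c("1", "2", "2", "2", "5"),
                     m2_1 = c("3", "3", "3", "3", "3"),
                     m2_2 = c("3", "3", "3", "3", "3"),
                     stringsAsFactors = FALSE)
  map <- linkage_map(c("m1", "m2"), c(0, 10))
  expect_error(tracks_from_genotypes(ped, geno, map), "X@m1")
})
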