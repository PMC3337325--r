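# Independent oracles and small fixtures shared by the tests.

# Brute-force gamete-origin probability: enumerate every crossover
# indicator pattern over the intervals between consecutive points
# (informative markers plus the query position), weight by per-interval
# Haldane recombination fractions, and condition on the observed marker
# origins.  Origins coded 1 = first line, 0 = second.
oracle_origin_prob <- function(tpos, origins, p) {
  pts <- sort(unique(c(tpos, p)))
  K <- length(pts) - 1L
  r <- haldane_d_to_r(diff(pts))
  obs_idx <- match(tpos, pts)
  p_idx <- match(p, pts)
  tot <- 0
  hit <- 0
  for (start in 0:1) {
    for (mask in 0:(2^K - 1L)) {
      xo <- as.integer(intToBits(mask))[seq_len(K)]
      states <- (start + cumsum(c(0L, xo))) %% 2L
      prob <- 0.5 * prod(ifelse(xo == 1L, r, 1 - r))
      if (all(states[obs_idx] == origins)) {
        tot <- tot + prob
        if (states[p_idx] == 1L) hit <- hit + prob
      }
    }
  }
  hit / tot
}

# a reduced cross for fast end-to-end tests
small_cross <- function(seed = 1, n_f2 = 300, n_phen = n_f2, ...) {
  set.seed(seed)
  design <- cross_design(n_f2 = n_f2, n_phenotyped = n_phen)
  cross <- simulate_cross(design, ...)
  phen <- simulate_phenotypes(cross)
  list(cross = cross, phen = phen)
}

snp_from <- function(tab, nm) {
  data.frame(id = tab$id, a1 = tab[[paste0(nm, "_1")]],
             a2 = tab[[paste0(nm, "_2")]], stringsAsFactors = FALSE)
}

base_formula <- ear_size ~ batch + sex + ppard + carcass_weight
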