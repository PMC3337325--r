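# Breed-line-origin probabilities for F2 gametes and individuals.
#
# A gamete transmitted by an F1 parent is a mosaic of the two founder
# breeds.  At markers where Mendelian logic resolves the transmitted
# allele's grand-parental origin, the origin is observed; between such
# informative markers the origin probability is obtained by conditioning
# on the nearest informative flank on each side, assuming no crossover
# interference (Haldane model).

# transmission probability helper: P(no switch) = 1 - r, P(switch) = r
.tr <- function(r, same) ifelse(same, 1 - r, r)

# Origin probabilities for one informativeness pattern.
# o: ng x m matrix of 1 (first line) / 0 (second line), no NA;
# tpos: the m informative positions; positions: scan positions.
# Returns ng x P matrix of P(origin == first line).
.origin_prob <- function(o, tpos, positions) {
  o <- as.matrix(o)
  ng <- nrow(o)
  m <- length(tpos)
  P <- length(positions)
  out <- matrix(NA_real_, ng, P)
  iL <- findInterval(positions, tpos)
  for (j in seq_len(P)) {
    i <- iL[j]
    if (i == 0L) {                       # left of first informative marker
      r <- haldane_d_to_r(tpos[1L] - positions[j])
      out[, j] <- .tr(r, o[, 1L] == 1)
    } else if (i == m) {                 # right of (or at) the last one
      r <- haldane_d_to_r(positions[j] - tpos[m])
      out[, j] <- .tr(r, o[, m] == 1)
    } else {
      dL <- positions[j] - tpos[i]
      dR <- tpos[i + 1L] - positions[j]
      rL <- haldane_d_to_r(dL)
      rR <- haldane_d_to_r(dR)
      rLR <- haldane_d_to_r(dL + dR)
      oL <- o[, i]
      oR <- o[, i + 1L]
      out[, j] <- .tr(rL, oL == 1) * .tr(rR, oR == 1) /
        .tr(rLR, oL == oR)
    }
  }
  out
}

# Vectorised origin probabilities for a whole gamete-origin matrix
# (n x M, entries 1/0/NA, NA = uninformative in that family).  For every
# row the nearest informative flank indices are precomputed by running
# scans, so each scan position costs a few vector operations.  Rows with
# no informative marker at all fall back to 1/2 everywhere.
.origin_prob_matrix <- function(O, mpos, positions) {
  n <- nrow(O)
  M <- ncol(O)
  P <- length(positions)
  inf <- !is.na(O)
  Lidx <- matrix(0L, n, M)        # last informative index <= k (0: none)
  Ridx <- matrix(M + 1L, n, M)    # first informative index >= k (M+1: none)
  for (k in seq_len(M)) {
    Lidx[, k] <- ifelse(inf[, k], k, if (k > 1L) Lidx[, k - 1L] else 0L)
  }
  for (k in rev(seq_len(M))) {
    Ridx[, k] <- ifelse(inf[, k], k,
                        if (k < M) Ridx[, k + 1L] else M + 1L)
  }
  out <- matrix(0.5, n, P)
  iv <- findInterval(positions, mpos)
  rows <- seq_len(n)
  for (j in seq_len(P)) {
    k <- iv[j]
    lf <- if (k >= 1L) Lidx[, k] else rep(0L, n)
    rf <- if (k < M) Ridx[, k + 1L] else rep(M + 1L, n)
    # a position sitting exactly on an informative marker has lf == that
    # marker with distance 0, which the flank formula handles exactly
    hasL <- lf >= 1L
    hasR <- rf <= M
    pW <- rep(0.5, n)
    both <- hasL & hasR
    if (any(both)) {
      dL <- positions[j] - mpos[lf[both]]
      dR <- mpos[rf[both]] - positions[j]
      rL <- haldane_d_to_r(dL)
      rR <- haldane_d_to_r(dR)
      rLR <- haldane_d_to_r(dL + dR)
      oL <- O[cbind(rows[both], lf[both])]
      oR <- O[cbind(rows[both], rf[both])]
      pW[both] <- .tr(rL, oL == 1) * .tr(rR, oR == 1) / .tr(rLR, oL == oR)
    }
    onlyL <- hasL & !hasR
    if (any(onlyL)) {
      r1 <- haldane_d_to_r(positions[j] - mpos[lf[onlyL]])
      pW[onlyL] <- .tr(r1, O[cbind(rows[onlyL], lf[onlyL])] == 1)
    }
    onlyR <- hasR & !hasL
    if (any(onlyR)) {
      r1 <- haldane_d_to_r(mpos[rf[onlyR]] - positions[j])
      pW[onlyR] <- .tr(r1, O[cbind(rows[onlyR], rf[onlyR])] == 1)
    }
    out[, j] <- pW
  }
  out
}

#' Probability that a transmitted allele originates from the first founder line
#'
#' Conditions on the nearest informative flanking markers of one gamete's
#' origin track, assuming no interference (Haldane).  Outside the
#' outermost informative markers, the single nearest marker is used.
#'
#' @param track Data frame with columns `pos` (cM) and `origin` (founder
#'   line labels), the informative markers of one transmitted gamete.
#' @param map A [linkage_map()]; the position must lie within its span.
#' @param position Scan position in cM.
#' @param lines Length-2 character vector of founder line labels; the
#'   returned probability refers to the first.
#' @return Probability in `[0, 1]` that the allele at `position` descends
#'   from `lines[1]`.
#' @export
gamete_origin_probability <- function(track, map, position,
                                      lines = c("W", "E")) {
  if (is.null(track) || nrow(track) < 1L) {
    stop("empty origin track: no informative marker")
  }
  span <- map_span(map)
  if (position < span[1L] || position > span[2L]) {
    stop("position ", position, " cM lies outside the map span")
  }
  if (!all(track$origin %in% lines)) {
    stop("track origins must be founder line labels: ",
         paste(lines, collapse = "/"))
  }
  ord <- order(track$pos)
  o <- matrix(as.numeric(track$origin[ord] == lines[1L]), nrow = 1L)
  drop(.origin_prob(o, track$pos[ord], position))
}

#' Line-origin genotype state of one F2 individual at a position
#'
#' Combines the two gametic origin probabilities (independent given the
#' parental marker data) into the three breed-origin genotype
#' probabilities and the additive/dominance regression coefficients.
#'
#' @param maternal_track,paternal_track Origin tracks as in
#'   [gamete_origin_probability()].
#' @param map A [linkage_map()].
#' @param position Scan position in cM.
#' @param lines Founder line labels, first = "high" line of `c_a`.
#' @return An object of class `line_origin_state`: list with `position`,
#'   `p_ww`, `p_we`, `p_ee` (both alleles from line 1 / one each / both
#'   from line 2), `c_a = p_ww - p_ee` and `c_d = p_we`.
#' @export
line_origin_state_f2 <- function(maternal_track, paternal_track, map,
                                 position, lines = c("W", "E")) {
  pm <- gamete_origin_probability(maternal_track, map, position, lines)
  pp <- gamete_origin_probability(paternal_track, map, position, lines)
  p_ww <- pm * pp
  p_ee <- (1 - pm) * (1 - pp)
  p_we <- 1 - p_ww - p_ee
  state <- list(position = position, p_ww = p_ww, p_we = p_we,
                p_ee = p_ee, c_a = p_ww - p_ee, c_d = p_we)
  class(state) <- "line_origin_state"
  state
}

#' @export
print.line_origin_state <- function(x, ...) {
  cat(sprintf(
    "line-origin state at %.2f cM: P(11)=%.4f P(12)=%.4f P(22)=%.4f  c_a=%.4f c_d=%.4f\n",
    x$position, x$p_ww, x$p_we, x$p_ee, x$c_a, x$c_d))
  invisible(x)
}

# allele x of a child can have been transmitted by a parent with allele
# pair (p1, p2); missing parent alleles are wildcards
.can_come_from <- function(x, p1, p2) {
  ifelse(is.na(x), NA,
         is.na(p1) | is.na(p2) |
           (!is.na(p1) & x == p1) | (!is.na(p2) & x == p2))
}

#' Resolve gamete breed-origin tracks from pedigree and marker genotypes
#'
#' For every F2 individual, determines at each marker (i) which allele was
#' transmitted by the sire and which by the dam, and (ii) from which
#' founder breed the transmitting F1 parent inherited that allele.
#' Markers whose alleles do not distinguish breed origin in a family
#' (heterozygosity of the wrong parent, shared alleles, missing data) are
#' left uninformative for that gamete.
#'
#' @param pedigree Data frame with columns `id`, `sire`, `dam`,
#'   `generation` (0 = founders, 1 = F1, 2 = F2) and `breed` (founder
#'   line label for generation 0, `NA` otherwise).  Missing parents are
#'   `NA` or `"0"`.
#' @param genotypes Data frame with column `id` and two columns
#'   `<marker>_1`, `<marker>_2` per mapped marker; `"0"` or `NA` denotes a
#'   missing allele.
#' @param map A [linkage_map()].
#' @param lines Length-2 vector of founder breed labels.
#' @return An object of class `origin_tracks`: list with `ids` (F2 ids),
#'   `map`, `lines`, and `paternal`/`maternal` numeric matrices
#'   (individuals x markers) coded 1 = `lines[1]`, 0 = `lines[2]`,
#'   `NA` = uninformative.
#' @export
tracks_from_genotypes <- function(pedigree, genotypes, map,
                                  lines = c("W", "E")) {
  ped <- normalize_pedigree(pedigree)
  founders <- ped$id[ped$generation == 0L]
  if (!all(ped$breed[ped$generation == 0L] %in% lines)) {
    stop("all founders must carry a breed label in: ",
         paste(lines, collapse = "/"))
  }
  f1 <- ped[ped$generation == 1L, , drop = FALSE]
  f2 <- ped[ped$generation == 2L, , drop = FALSE]
  if (nrow(f2) == 0L) stop("pedigree contains no generation-2 individuals")
  gid <- as.character(genotypes$id)
  geno_row <- function(ids) match(ids, gid)
  breed_of <- stats::setNames(ped$breed, ped$id)

  M <- nrow(map)
  n2 <- nrow(f2)
  pat <- matrix(NA_real_, n2, M, dimnames = list(f2$id, map$marker))
  mat <- matrix(NA_real_, n2, M, dimnames = list(f2$id, map$marker))
  errors <- character(0)

  for (k in seq_len(M)) {
    mk <- map$marker[k]
    a1 <- genotypes[[paste0(mk, "_1")]]
    a2 <- genotypes[[paste0(mk, "_2")]]
    if (is.null(a1) || is.null(a2)) {
      stop("genotype columns for marker '", mk, "' not found")
    }
    a1 <- as.character(a1); a1[a1 %in% c("0", "")] <- NA
    a2 <- as.character(a2); a2[a2 %in% c("0", "")] <- NA

    # --- phase F1 individuals against their founder parents ------------
    i1 <- geno_row(f1$id)
    isire <- geno_row(f1$sire)
    idam <- geno_row(f1$dam)
    x <- a1[i1]; y <- a2[i1]
    v1 <- .can_come_from(x, a1[isire], a2[isire]) &
      .can_come_from(y, a1[idam], a2[idam])
    v2 <- .can_come_from(y, a1[isire], a2[isire]) &
      .can_come_from(x, a1[idam], a2[idam])
    hom <- !is.na(x) & !is.na(y) & x == y
    bad <- which(!is.na(v1) & !is.na(v2) & !v1 & !v2)
    if (length(bad)) {
      errors <- c(errors, paste0(f1$id[bad], "@", mk))
    }
    f1_pat <- ifelse(hom & (v1 | v2), x,
                     ifelse(!hom & v1 & !v2, x,
                            ifelse(!hom & v2 & !v1, y, NA)))
    f1_mat <- ifelse(hom & (v1 | v2), x,
                     ifelse(!hom & v1 & !v2, y,
                            ifelse(!hom & v2 & !v1, x, NA)))
    f1_pat_breed <- breed_of[f1$sire]      # origin carried by f1_pat
    f1_mat_breed <- breed_of[f1$dam]

    # --- assign F2 alleles to parental gametes --------------------------
    i2 <- geno_row(f2$id)
    si <- match(f2$sire, f1$id)
    di <- match(f2$dam, f1$id)
    if (anyNA(si) || anyNA(di)) {
      stop("every F2 parent must be a generation-1 individual")
    }
    X <- a1[i2]; Y <- a2[i2]
    S1 <- a1[geno_row(f2$sire)]; S2 <- a2[geno_row(f2$sire)]
    D1 <- a1[geno_row(f2$dam)]; D2 <- a2[geno_row(f2$dam)]
    w1 <- .can_come_from(X, S1, S2) & .can_come_from(Y, D1, D2)
    w2 <- .can_come_from(Y, S1, S2) & .can_come_from(X, D1, D2)
    hom2 <- !is.na(X) & !is.na(Y) & X == Y
    bad2 <- which(!is.na(w1) & !is.na(w2) & !w1 & !w2)
    if (length(bad2)) {
      errors <- c(errors, paste0(f2$id[bad2], "@", mk))
    }
    patA <- ifelse(hom2 & (w1 | w2), X,
                   ifelse(!hom2 & w1 & !w2, X,
                          ifelse(!hom2 & w2 & !w1, Y, NA)))
    matA <- ifelse(hom2 & (w1 | w2), X,
                   ifelse(!hom2 & w1 & !w2, Y,
                          ifelse(!hom2 & w2 & !w1, X, NA)))

    # --- translate transmitted alleles into breed origins ---------------
    orig_from <- function(tA, pPat, pMat, bPat, bMat, who) {
      ok <- !is.na(tA) & !is.na(pPat) & !is.na(pMat) & pPat != pMat
      o <- rep(NA_character_, length(tA))
      o[ok & tA == pPat] <- bPat[ok & tA == pPat]
      o[ok & tA == pMat] <- bMat[ok & tA == pMat]
      mism <- ok & tA != pPat & tA != pMat
      if (any(mism)) {
        errors <<- c(errors, paste0(who[mism], "@", mk))
      }
      o
    }
    op <- orig_from(patA, f1_pat[si], f1_mat[si],
                    f1_pat_breed[si], f1_mat_breed[si], f2$id)
    om <- orig_from(matA, f1_pat[di], f1_mat[di],
                    f1_pat_breed[di], f1_mat_breed[di], f2$id)
    pat[, k] <- ifelse(is.na(op), NA, as.numeric(op == lines[1L]))
    mat[, k] <- ifelse(is.na(om), NA, as.numeric(om == lines[1L]))
  }

  if (length(errors)) {
    stop("Mendelian inconsistency at (individual@marker): ",
         paste(utils::head(unique(errors), 10L), collapse = ", "),
         if (length(unique(errors)) > 10L) " ...")
  }
  structure(list(ids = f2$id, map = map, lines = lines,
                 paternal = pat, maternal = mat),
            class = "origin_tracks")
}

#' @export
print.origin_tracks <- function(x, ...) {
  info <- mean(!is.na(x$paternal)) + mean(!is.na(x$maternal))
  cat("origin tracks for", length(x$ids), "F2 individuals,",
      nrow(x$map), "markers;",
      sprintf("%.1f%% of gamete-marker cells informative\n", 50 * info))
  invisible(x)
}

#' Extract one gamete's origin track as a data frame
#'
#' @param tracks An [tracks_from_genotypes()] result.
#' @param id F2 individual id.
#' @param gamete `"paternal"` or `"maternal"`.
#' @return Data frame with columns `marker`, `pos`, `origin` at the
#'   informative markers of that gamete.
#' @export
origin_track <- function(tracks, id, gamete = c("paternal", "maternal")) {
  gamete <- match.arg(gamete)
  i <- match(id, tracks$ids)
  if (is.na(i)) stop("unknown F2 id: ", id)
  o <- tracks[[gamete]][i, ]
  keep <- !is.na(o)
  data.frame(marker = tracks$map$marker[keep], pos = tracks$map$pos[keep],
             origin = ifelse(o[keep] == 1, tracks$lines[1L],
                             tracks$lines[2L]),
             stringsAsFactors = FALSE)
}

#' Line-origin coefficients on a scan grid
#'
#' Evaluates, for every individual and every scan position, the
#' breed-origin genotype probabilities and the additive (`c_a`) and
#' dominance (`c_d`) regression coefficients.  Gametes with no
#' informative marker fall back to probability 1/2 at all positions.
#'
#' @param tracks An [tracks_from_genotypes()] result (or a compatible
#'   list from the simulator's truth).
#' @param step Scan step in cM (ignored when `positions` is given).
#' @param positions Optional explicit scan positions in cM.
#' @return An object of class `line_origin_grid`: list with `ids`,
#'   `positions`, and individuals x positions matrices `ca`, `cd`,
#'   `p_ww`, `p_we`, `p_ee`.
#' @export
line_origin <- function(tracks, step = 1, positions = NULL) {
  if (is.null(positions)) positions <- scan_positions(tracks$map, step)
  pp <- .origin_prob_matrix(tracks$paternal, tracks$map$pos, positions)
  pm <- .origin_prob_matrix(tracks$maternal, tracks$map$pos, positions)
  p_ww <- pm * pp
  p_ee <- (1 - pm) * (1 - pp)
  p_we <- 1 - p_ww - p_ee
  structure(list(ids = tracks$ids, positions = positions,
                 lines = tracks$lines,
                 ca = p_ww - p_ee, cd = p_we,
                 p_ww = p_ww, p_we = p_we, p_ee = p_ee),
            class = "line_origin_grid")
}

#' @export
print.line_origin_grid <- function(x, ...) {
  cat("line-origin grid:", length(x$ids), "individuals x",
      length(x$positions), "positions (",
      sprintf("%.1f-%.1f cM )\n", min(x$positions), max(x$positions)))
  invisible(x)
}
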