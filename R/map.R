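#' Haldane map function
#'
#' Convert a map distance in centiMorgans to a recombination fraction under
#' the Haldane (no-interference) model, `r = (1 - exp(-2 d / 100)) / 2`, or
#' back.
#'
#' @param d Map distance in cM (non-negative, possibly a vector).
#' @param r Recombination fraction in `[0, 0.5)`.
#' @return `haldane_d_to_r()` returns the recombination fraction in
#'   `[0, 0.5)`; `haldane_r_to_d()` the distance in cM.
#' @examples
#' haldane_d_to_r(10)           # 0.0906
#' haldane_r_to_d(0.25)         # 34.66 cM
#' @export
haldane_d_to_r <- function(d) {
  if (!is.numeric(d) || anyNA(d) || any(d < 0)) {
    stop("map distance must be a non-negative number (cM)")
  }
  0.5 * (1 - exp(-2 * d / 100))
}

#' @rdname haldane_d_to_r
#' @export
haldane_r_to_d <- function(r) {
  if (!is.numeric(r) || anyNA(r) || any(r < 0) || any(r >= 0.5)) {
    stop("recombination fraction must lie in [0, 0.5)")
  }
  -50 * log(1 - 2 * r)
}

#' Construct a linkage map
#'
#' A linkage map is an ordered set of markers with cumulative positions in
#' cM, measured from the first mapped marker (position 0).
#'
#' @param markers Character vector of unique marker identifiers, in map
#'   order.
#' @param positions Numeric vector of cM positions, non-decreasing, same
#'   length as `markers`.
#' @param chromosome Optional chromosome label.
#' @return An object of class `linkage_map`: a data frame with columns
#'   `marker` and `pos`.
#' @seealso [build_map()] to build a map from inter-marker distances.
#' @export
linkage_map <- function(markers, positions, chromosome = NA_character_) {
  markers <- as.character(markers)
  positions <- as.numeric(positions)
  if (length(markers) < 2L) stop("a linkage map needs at least 2 markers")
  if (length(markers) != length(positions)) {
    stop("'markers' and 'positions' must have the same length")
  }
  if (anyDuplicated(markers)) {
    stop("duplicate marker name: ",
         paste(unique(markers[duplicated(markers)]), collapse = ", "))
  }
  if (anyNA(positions) || is.unsorted(positions)) {
    stop("positions must be non-decreasing and free of NA")
  }
  map <- data.frame(marker = markers, pos = positions,
                    stringsAsFactors = FALSE)
  attr(map, "chromosome") <- chromosome
  class(map) <- c("linkage_map", "data.frame")
  map
}

#' Build a linkage map from an alternating marker/distance description
#'
#' Accepts either a single string of the form
#' `"M1 - 3.0 - M2 - 40.0 - M3"` (markers separated by inter-marker
#' distances in cM) or a vector/list alternating marker names and
#' distances.  Positions are the cumulative sums of the distances, with the
#' first marker at 0 cM.
#'
#' @param segments Character scalar, or vector/list alternating names and
#'   distances (odd entries names, even entries distances).
#' @param chromosome Optional chromosome label.
#' @return A [linkage_map()] object.
#' @examples
#' build_map("A - 10 - B - 5.5 - C")
#' @export
build_map <- function(segments, chromosome = NA_character_) {
  if (is.character(segments) && length(segments) == 1L &&
      grepl("-", segments)) {
    # split on spaced hyphens first so that negative numbers survive to
    # be rejected with a clear message; fall back to bare hyphens for
    # compact strings like "A-0-B"
    parts <- strsplit(segments, " - ", fixed = TRUE)[[1L]]
    if (length(parts) == 1L) parts <- strsplit(segments, "-", fixed = TRUE)[[1L]]
    segments <- trimws(parts)
  } else {
    segments <- trimws(as.character(unlist(segments)))
  }
  n <- length(segments)
  if (n < 3L || n %% 2L == 0L) {
    stop("'segments' must alternate marker names and distances, ",
         "starting and ending with a marker")
  }
  markers <- segments[seq(1L, n, by = 2L)]
  dists <- suppressWarnings(as.numeric(segments[seq(2L, n, by = 2L)]))
  if (anyNA(dists)) stop("inter-marker distances must be numeric")
  if (any(dists < 0)) stop("negative inter-marker distance")
  linkage_map(markers, cumsum(c(0, dists)), chromosome)
}

#' @export
print.linkage_map <- function(x, ...) {
  chrom <- attr(x, "chromosome")
  cat("Linkage map", if (!is.na(chrom)) paste0("(", chrom, ")"),
      "with", nrow(x), "markers spanning",
      sprintf("%.1f cM\n", max(x$pos) - min(x$pos)))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

map_span <- function(map) range(map$pos)

#' Scan positions along a map
#'
#' Equally spaced positions at a fixed step, always including both ends of
#' the map.
#'
#' @param map A [linkage_map()].
#' @param step Step in cM (> 0).
#' @return Numeric vector of cM positions.
#' @export
scan_positions <- function(map, step = 1) {
  if (!is.numeric(step) || length(step) != 1L || step <= 0) {
    stop("'step' must be a positive number of cM")
  }
  span <- map_span(map)
  pos <- seq(span[1L], span[2L], by = step)
  if (pos[length(pos)] < span[2L]) pos <- c(pos, span[2L])
  pos
}
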