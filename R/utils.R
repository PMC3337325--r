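# shared pedigree plumbing

# Canonical pedigree columns: id, sire, dam, generation, breed.
# "0" / "" parents become NA; parents must be NA or themselves listed.
normalize_pedigree <- function(pedigree, require_generation = TRUE) {
  ped <- as.data.frame(pedigree, stringsAsFactors = FALSE)
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(ped))) {
    stop("pedigree must have columns: ", paste(need, collapse = ", "))
  }
  ped$id <- as.character(ped$id)
  for (col in c("sire", "dam")) {
    v <- as.character(ped[[col]])
    v[v %in% c("0", "")] <- NA
    ped[[col]] <- v
  }
  if (anyDuplicated(ped$id)) {
    stop("duplicated pedigree id: ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  }
  unknown <- setdiff(c(ped$sire, ped$dam), c(ped$id, NA))
  if (length(unknown)) {
    stop("parent id not in pedigree: ", paste(unknown, collapse = ", "))
  }
  if (require_generation) {
    if (!"generation" %in% names(ped)) {
      stop("pedigree must have a 'generation' column (0/1/2)")
    }
    ped$generation <- as.integer(ped$generation)
    if (!"breed" %in% names(ped)) ped$breed <- NA_character_
    ped$breed <- as.character(ped$breed)
  }
  ped
}

# topological order, parents before offspring; detects cycles
pedigree_order <- function(ped) {
  n <- nrow(ped)
  placed <- logical(n)
  si <- match(ped$sire, ped$id)
  di <- match(ped$dam, ped$id)
  ord <- integer(0)
  while (length(ord) < n) {
    ready <- which(!placed &
                     (is.na(si) | placed[pmax(si, 1L)] | is.na(ped$sire)) &
                     (is.na(di) | placed[pmax(di, 1L)] | is.na(ped$dam)))
    ready <- ready[(is.na(si[ready]) | placed[si[ready]]) &
                     (is.na(di[ready]) | placed[di[ready]])]
    if (!length(ready)) stop("pedigree cycle detected")
    placed[ready] <- TRUE
    ord <- c(ord, ready)
  }
  ord
}

# format a P value the way association tables print them
format_p <- function(p) {
  ifelse(is.na(p), "NA",
         ifelse(p >= 0.001, sprintf("%.3g", p),
                sprintf("%.2E", p)))
}
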