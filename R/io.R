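# Delimited-text readers/writers for the pipeline's table formats, a
# PLINK .ped/.map reader for biallelic SNP sets, fixture export, and the
# end-to-end pipeline driver.
#
# Native dialects (all TSV with header):
#   map:        chromosome, marker, position_cM
#   pedigree:   id, sire, dam, generation, breed
#   genotypes:  id, <marker>_1, <marker>_2, ...   ("0"/NA = missing)
#   phenotypes: id, ear_size, batch, sex, carcass_weight[, ppard]

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE)
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Read a linkage map file
#'
#' @param path TSV with header `chromosome, marker, position_cM`.
#' @return A [linkage_map()].
#' @export
read_map <- function(path) {
  x <- .read_tsv(path)
  need <- c("chromosome", "marker", "position_cM")
  if (!all(need %in% names(x))) {
    stop(path, ": expected columns ", paste(need, collapse = ", "))
  }
  if (length(unique(x$chromosome)) > 1L) {
    stop(path, ": a map file must describe a single chromosome")
  }
  linkage_map(x$marker, as.numeric(x$position_cM), x$chromosome[1L])
}

#' @rdname read_map
#' @param map A [linkage_map()] to write.
#' @export
write_map <- function(map, path) {
  .write_tsv(data.frame(chromosome = attr(map, "chromosome"),
                        marker = map$marker, position_cM = map$pos), path)
}

#' Read a pedigree file
#'
#' @param path TSV with header `id, sire, dam, generation, breed`.
#' @return Normalised pedigree data frame.
#' @export
read_pedigree <- function(path) {
  normalize_pedigree(.read_tsv(path))
}

#' Read a genotype table
#'
#' @param path TSV with header `id` plus `<marker>_1`/`<marker>_2`
#'   columns.
#' @return Data frame with `NA` for missing alleles.
#' @export
read_genotypes <- function(path) {
  x <- .read_tsv(path)
  if (!"id" %in% names(x)) stop(path, ": missing 'id' column")
  for (col in setdiff(names(x), "id")) {
    x[[col]][x[[col]] %in% c("0", "", "NA")] <- NA
  }
  x
}

#' Read a phenotype table
#'
#' @param path TSV with header `id, ear_size, batch, sex,
#'   carcass_weight` and optionally `ppard`.
#' @return Data frame with typed columns (factors for batch/sex/ppard).
#' @export
read_phenotypes <- function(path) {
  x <- .read_tsv(path)
  need <- c("id", "ear_size", "batch", "sex", "carcass_weight")
  if (!all(need %in% names(x))) {
    stop(path, ": expected columns ", paste(need, collapse = ", "))
  }
  x$ear_size <- as.numeric(x$ear_size)
  x$carcass_weight <- as.numeric(x$carcass_weight)
  x$batch <- factor(x$batch)
  x$sex <- factor(x$sex)
  if ("ppard" %in% names(x)) x$ppard <- factor(x$ppard)
  x
}

#' Cross-file referential integrity checks
#'
#' Every phenotyped and genotyped id must be in the pedigree and every
#' genotyped marker on the map.
#'
#' @param pedigree,genotypes,phenotypes,map The parsed tables (any may
#'   be `NULL` to skip its checks).
#' @return Invisibly `TRUE`; stops with the offending ids/markers
#'   otherwise.
#' @export
validate_tables <- function(pedigree, genotypes = NULL, phenotypes = NULL,
                            map = NULL) {
  if (!is.null(phenotypes)) {
    bad <- setdiff(as.character(phenotypes$id), pedigree$id)
    if (length(bad)) {
      stop("phenotyped id(s) not in pedigree: ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
  }
  if (!is.null(genotypes)) {
    bad <- setdiff(as.character(genotypes$id), pedigree$id)
    if (length(bad)) {
      stop("genotyped id(s) not in pedigree: ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
    if (!is.null(map)) {
      mk <- unique(sub("_[12]$", "", setdiff(names(genotypes), "id")))
      bad <- setdiff(mk, map$marker)
      if (length(bad)) {
        stop("genotyped marker(s) not on map: ",
             paste(bad, collapse = ", "))
      }
    }
  }
  invisible(TRUE)
}

#' Read PLINK-style .ped/.map files
#'
#' Whitespace-delimited PLINK text dialect: the `.map` file has columns
#' chromosome, marker, cM position, bp position; the `.ped` file has
#' family id, individual id, father, mother, sex, phenotype, then two
#' allele columns per marker ("0" = missing).
#'
#' @param ped_path,map_path Paths to the two files.
#' @return List with `genotypes` (native layout) and `map` (a
#'   [linkage_map()]).
#' @export
read_plink <- function(ped_path, map_path) {
  mp <- utils::read.table(map_path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(mp) < 3L) stop(map_path, ": expected >= 3 columns")
  map <- linkage_map(mp[[2L]], as.numeric(mp[[3L]]), mp[[1L]][1L])
  pd <- utils::read.table(ped_path, stringsAsFactors = FALSE,
                          colClasses = "character")
  n_mark <- nrow(mp)
  if (ncol(pd) != 6L + 2L * n_mark) {
    stop(ped_path, ": expected ", 6L + 2L * n_mark, " columns for ",
         n_mark, " markers, found ", ncol(pd))
  }
  out <- data.frame(id = pd[[2L]], stringsAsFactors = FALSE)
  for (j in seq_len(n_mark)) {
    a1 <- pd[[5L + 2L * j]]
    a2 <- pd[[6L + 2L * j]]
    a1[a1 == "0"] <- NA; a2[a2 == "0"] <- NA
    out[[paste0(map$marker[j], "_1")]] <- a1
    out[[paste0(map$marker[j], "_2")]] <- a2
  }
  list(genotypes = out, map = map)
}

#' Write a simulated fixture to disk
#'
#' @param fixture A [make_fixture()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of written file paths.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  files <- c()
  if (fixture$scenario == "outbred_line") {
    files["phenotypes"] <- .write_tsv(fixture$data, p("phenotypes.tsv"))
    files["snp"] <- .write_tsv(fixture$snp, p("snp.tsv"))
    truth <- list(scenario = fixture$scenario, seed = fixture$seed)
  } else {
    cross <- fixture$cross
    files["map"] <- write_map(cross$map, p("map.tsv"))
    files["pedigree"] <- .write_tsv(cross$pedigree, p("pedigree.tsv"))
    files["genotypes"] <- .write_tsv(cross$genotypes, p("genotypes.tsv"))
    files["snps"] <- .write_tsv(cross$snp_genotypes, p("snps.tsv"))
    ph <- fixture$phenotypes
    pg <- cross$ppard
    m <- match(ph$id, pg$id)
    ph$ppard <- factor((pg$a1[m] == "C") + (pg$a2[m] == "C") + 1L,
                       levels = 1:3)
    files["phenotypes"] <- .write_tsv(ph, p("phenotypes.tsv"))
    truth <- list(scenario = fixture$scenario, seed = fixture$seed,
                  qtn_pos = cross$truth$qtn_pos,
                  qtn_snp = fixture$qtn_snp,
                  model = unclass(cross$model),
                  design = unclass(cross$design))
  }
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  files["truth"] <- p("truth.json")
  files
}

#' Run the full mapping-and-dissection pipeline
#'
#' Reads (or simulates) a dataset, computes origin tracks and the
#' line-origin grid, scans the chromosome, calibrates the significance
#' threshold by permutation and the QTL location by bootstrap, builds
#' the candidate-SNP association table, and runs the haplotype-copy
#' association on infinitesimal-corrected residuals.  All outputs are
#' written to `config$out_dir` as TSV/JSON and are deterministic given
#' the inputs, the configuration and the seed.
#'
#' @param config Named list (or path to a JSON/YAML file) with entries:
#'   `scenario` (to simulate) or `map`/`pedigree`/`genotypes`/`snps`/
#'   `phenotypes` paths; `step` (cM, default 1), `n_perm` (default
#'   1000), `n_boot` (default 2000), `alpha` (default 0.05), `h2`
#'   (default 0.4), `seed`, `out_dir`.
#' @return Invisibly, a list with the fitted objects and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("[.]ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("reading YAML configs requires the 'yaml' package")
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  cfg <- utils::modifyList(
    list(step = 1, n_perm = 1000, n_boot = 2000, alpha = 0.05, h2 = 0.4,
         seed = 1, out_dir = "linecross_out", scenario = NULL),
    config)
  set.seed(cfg$seed)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(sprintf("seed: %d", cfg$seed))

  if (!is.null(cfg$scenario)) {
    fx <- make_fixture(cfg$scenario, seed = cfg$seed)
    map <- fx$cross$map
    ped <- fx$cross$pedigree
    geno <- fx$cross$genotypes
    snps_tab <- fx$cross$snp_genotypes
    phen <- fx$phenotypes
    pg <- fx$cross$ppard
    phen$ppard <- factor((pg$a1[match(phen$id, pg$id)] == "C") +
                           (pg$a2[match(phen$id, pg$id)] == "C") + 1L,
                         levels = 1:3)
    snp_names <- fx$cross$snps$snp
  } else {
    map <- read_map(cfg$map)
    ped <- read_pedigree(cfg$pedigree)
    geno <- read_genotypes(cfg$genotypes)
    snps_tab <- read_genotypes(cfg$snps)
    phen <- read_phenotypes(cfg$phenotypes)
    validate_tables(ped, geno, phen, map)
    snp_names <- unique(sub("_[12]$", "", setdiff(names(snps_tab), "id")))
  }
  base <- if ("ppard" %in% names(phen)) {
    ear_size ~ batch + sex + ppard + carcass_weight
  } else {
    ear_size ~ batch + sex + carcass_weight
  }

  tracks <- tracks_from_genotypes(ped, geno, map)
  grid <- line_origin(tracks, step = cfg$step)
  scan <- scan_qtl(base, phen, grid)
  perm <- permutation_threshold(scan, n_perm = cfg$n_perm,
                                alpha = cfg$alpha, seed = cfg$seed + 1L)
  boot <- bootstrap_ci(scan, n_boot = cfg$n_boot, seed = cfg$seed + 2L)

  snp_list <- lapply(snp_names, function(nm) {
    data.frame(id = snps_tab$id, a1 = snps_tab[[paste0(nm, "_1")]],
               a2 = snps_tab[[paste0(nm, "_2")]], stringsAsFactors = FALSE)
  })
  names(snp_list) <- snp_names
  tab1 <- assoc_table(phen, snp_list, grid, base)
  tab1 <- tab1[order(tab1$p_ma), , drop = FALSE]

  corr <- correct_phenotypes(phen, ped, h2 = cfg$h2,
                             fixed = ear_size ~ batch + sex + carcass_weight)
  phase <- phase_f2(ped[ped$generation <= 2L, , drop = FALSE], snps_tab)
  copies <- haplotype_copy_matrix(phase, ids = names(corr))
  tab2 <- haplotype_regression(corr, copies)
  hve <- haplotype_variance_explained(corr, copies)

  out <- list(
    scan = .write_tsv(as.data.frame(scan), file.path(cfg$out_dir, "scan.tsv")),
    table1 = .write_tsv(tab1, file.path(cfg$out_dir, "table1.tsv")),
    table2 = .write_tsv(as.data.frame(tab2),
                        file.path(cfg$out_dir, "table2.tsv")),
    bootstrap = .write_tsv(boot$histogram,
                           file.path(cfg$out_dir, "bootstrap_hist.tsv")))
  summary_json <- list(
    seed = cfg$seed,
    peak_position_cM = scan$peak_pos,
    peak_F = scan$peak_F,
    variance_explained_pct = variance_explained(scan),
    additive_effect = unname(scan$effects["a"]),
    dominance_effect = unname(scan$effects["d"]),
    permutation_threshold = as.list(perm$threshold),
    bootstrap_ci_cM = as.list(boot$ci),
    haplotype_variance_pct = hve$percent,
    haplotype_overall_p = hve$p.value)
  jsonlite::write_json(summary_json, file.path(cfg$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  out$summary <- file.path(cfg$out_dir, "summary.json")

  cfg_path <- file.path(cfg$out_dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, pretty = TRUE)
  log_lines <- c(log_lines,
                 sprintf("config_md5: %s", unname(tools::md5sum(cfg_path))),
                 sprintf("peak: %.2f cM, F = %.2f", scan$peak_pos,
                         scan$peak_F))
  writeLines(log_lines, file.path(cfg$out_dir, "run.log"))
  invisible(list(scan = scan, permutation = perm, bootstrap = boot,
                 assoc = tab1, haplotypes = tab2, hap_variance = hve,
                 files = out, config = cfg))
}
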