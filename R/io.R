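# Readers/writers for the plain-text dialects used throughout: pedigree CSV
# (animal,sire,dam; 0 = unknown), PLINK-raw-like genotype TSV (IID + one
# 0/1/2 column per SNP) with a map TSV (chrom, snp_id, pos_bp), OTU counts
# TSV (first column sample id), taxonomy TSV, phenotype CSV.

#' Read / write a pedigree CSV
#'
#' Columns `animal,sire,dam`, unknown parents coded 0.  Records are
#' topologically reordered on read if offspring precede parents (with a
#' message).
#'
#' @param path file path.
#' @return a [pedigree].
#' @export
read_pedigree <- function(path) {
  df <- data.table::fread(path, colClasses = "character", data.table = FALSE)
  if (!all(c("animal", "sire", "dam") %in% names(df)))
    stop(path, ": expected columns animal,sire,dam")
  ped <- pedigree(df$animal, df$sire, df$dam)
  if (!identical(ped$animal, df$animal))
    message("pedigree reordered so that parents precede offspring")
  extra <- setdiff(names(df), c("animal", "sire", "dam"))
  for (cc in extra) ped[[cc]] <- df[[cc]][match(ped$animal, df$animal)]
  ped
}

#' @rdname read_pedigree
#' @param ped a [pedigree].
#' @export
write_pedigree <- function(ped, path) {
  data.table::fwrite(as.data.frame(unclass(ped)), path)
  invisible(path)
}

#' Read / write genotypes (raw-like TSV + map TSV)
#'
#' The genotype table has an `IID` column of individual ids followed by one
#' 0/1/2 column per SNP (NA = missing); the map has columns
#' `chrom,snp_id,pos_bp`.
#'
#' @param geno_path,map_path file paths.
#' @return a [genotype_set].
#' @export
read_genotypes <- function(geno_path, map_path) {
  g <- data.table::fread(geno_path, data.table = FALSE)
  if (names(g)[1] != "IID") stop(geno_path, ": first column must be IID")
  map <- data.table::fread(map_path, data.table = FALSE)
  if (!all(c("chrom", "snp_id", "pos_bp") %in% names(map)))
    stop(map_path, ": expected columns chrom,snp_id,pos_bp")
  M <- as.matrix(g[, -1, drop = FALSE])
  if (anyDuplicated(g$IID)) stop(geno_path, ": duplicated individual ids")
  rownames(M) <- g$IID
  bad <- which(!(M %in% c(0, 1, 2) | is.na(M)))
  if (length(bad))
    stop(geno_path, ": non-0/1/2 genotype value near row ",
         ((bad[1] - 1) %% nrow(M)) + 1)
  if (!identical(colnames(M), map$snp_id))
    stop("genotype columns do not match the map's snp_id order")
  genotype_set(M, map)
}

#' @rdname read_genotypes
#' @param genotypes a [genotype_set].
#' @export
write_genotypes <- function(genotypes, geno_path, map_path) {
  df <- data.frame(IID = rownames(genotypes$allele_counts),
                   genotypes$allele_counts, check.names = FALSE)
  data.table::fwrite(df, geno_path, sep = "\t")
  data.table::fwrite(genotypes$snp_map, map_path, sep = "\t")
  invisible(geno_path)
}

#' Read / write an OTU count table (+ taxonomy)
#'
#' Counts TSV: first column `sample_id`, one integer column per OTU.
#' Taxonomy TSV: `otu_id` plus rank columns.
#'
#' @param counts_path,taxonomy_path file paths (taxonomy optional).
#' @return an [otu_table].
#' @export
read_otu_table <- function(counts_path, taxonomy_path = NULL) {
  df <- data.table::fread(counts_path, data.table = FALSE)
  if (names(df)[1] != "sample_id")
    stop(counts_path, ": first column must be sample_id")
  M <- as.matrix(df[, -1, drop = FALSE])
  if (any(M != round(M)))
    stop(counts_path, ": non-integer count near row ",
         which(rowSums(M != round(M)) > 0)[1])
  rownames(M) <- df$sample_id
  tax <- if (!is.null(taxonomy_path))
    data.table::fread(taxonomy_path, data.table = FALSE) else NULL
  otu_table(M, tax)
}

#' @rdname read_otu_table
#' @param table an [otu_table].
#' @export
write_otu_table <- function(table, counts_path, taxonomy_path = NULL) {
  df <- data.frame(sample_id = rownames(table$counts), table$counts,
                   check.names = FALSE)
  data.table::fwrite(df, counts_path, sep = "\t")
  if (!is.null(taxonomy_path))
    data.table::fwrite(table$taxonomy, taxonomy_path, sep = "\t")
  invisible(counts_path)
}

#' Read / write phenotypes
#'
#' CSV with an `animal` column, fixed-effect factor columns, the DIM
#' covariate and trait columns.  Optionally checks every animal against a
#' pedigree.
#'
#' @param path file path.
#' @param ped optional [pedigree] for id reconciliation.
#' @param factors columns to read as factors (default the simulator's).
#' @return data.frame.
#' @export
read_phenotypes <- function(path, ped = NULL,
                            factors = c("year", "parity", "litter_size",
                                        "run", "order")) {
  df <- data.table::fread(path, data.table = FALSE)
  if (!"animal" %in% names(df)) stop(path, ": expected an animal column")
  df$animal <- as.character(df$animal)
  for (f in intersect(factors, names(df))) df[[f]] <- factor(df[[f]])
  if (!is.null(ped)) {
    unknown <- setdiff(df$animal, ped$animal)
    if (length(unknown))
      stop("phenotyped animal(s) absent from pedigree: ",
           paste(utils::head(unknown, 5), collapse = ", "))
  }
  df
}

#' @rdname read_phenotypes
#' @param phenotypes data.frame with an `animal` column.
#' @export
write_phenotypes <- function(phenotypes, path) {
  data.table::fwrite(phenotypes, path)
  invisible(path)
}

#' Genotype quality control
#'
#' Fixed filter order, frequencies recomputed after each step:
#' (1) drop SNPs with call rate below `snp_call_rate`;
#' (2) drop individuals with call rate below `ind_call_rate`;
#' (3) drop SNPs with minor allele frequency below `maf_min`.
#' Remaining missing entries are mean-imputed (`2 p_i`) so relationship
#' matrices can be built.
#'
#' @param genotypes a [genotype_set] (may contain NAs).
#' @param snp_call_rate minimum SNP call rate (default 0.90).
#' @param ind_call_rate minimum individual call rate (default 0.95).
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @return list with `genotypes` (clean [genotype_set], no missing values)
#'   and `report` (counts removed at each step).
#' @export
qc_genotypes <- function(genotypes, snp_call_rate = 0.90,
                         ind_call_rate = 0.95, maf_min = 0.05) {
  stopifnot(inherits(genotypes, "genotype_set"))
  M <- genotypes$allele_counts
  map <- genotypes$snp_map
  cr_snp <- colMeans(!is.na(M))
  keep_snp <- cr_snp >= snp_call_rate
  n_snp_cr <- sum(!keep_snp)
  M <- M[, keep_snp, drop = FALSE]; map <- map[keep_snp, , drop = FALSE]
  cr_ind <- rowMeans(!is.na(M))
  keep_ind <- cr_ind >= ind_call_rate
  n_ind_cr <- sum(!keep_ind)
  M <- M[keep_ind, , drop = FALSE]
  p <- colMeans(M, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep_maf <- maf >= maf_min & !is.na(maf)
  n_snp_maf <- sum(!keep_maf)
  M <- M[, keep_maf, drop = FALSE]; map <- map[keep_maf, , drop = FALSE]
  if (!ncol(M) || !nrow(M))
    stop("no SNPs or individuals survive quality control")
  p <- colMeans(M, na.rm = TRUE) / 2
  if (anyNA(M)) {
    for (j in which(colSums(is.na(M)) > 0)) {
      M[is.na(M[, j]), j] <- 2 * p[j]
    }
  }
  list(genotypes = genotype_set(M, map, allele_freqs = p),
       report = data.frame(step = c("snp_call_rate", "ind_call_rate", "maf"),
                           removed = c(n_snp_cr, n_ind_cr, n_snp_maf)))
}

#' Run the full analysis pipeline on a simulated or loaded dataset
#'
#' Orchestrates the stages in the order of the underlying study design:
#' genotype QC, compositional preprocessing, relationship matrices,
#' per-OTU 3-trait variance components (heritabilities), the permutation
#' significance threshold, genus enrichment, per-pair 4-trait genetic
#' correlations, and single-trait ssGBLUP GWAS with QTL regions.  Every
#' output is written as TSV into `out_dir` together with a run log; the
#' whole run is a pure function of the configuration seed.
#'
#' @param dataset a `sim_dataset` (from [simulate_dataset()]) or a list
#'   with the same elements built from files.
#' @param out_dir output directory (created if needed).
#' @param otu_subset OTU ids to analyse (default: all OTU surviving the
#'   abundance filter; cap with `max_otus`).
#' @param max_otus cap on the number of OTU put through the variance
#'   -component stage (default 20; the stage is linear in this number).
#' @param traits dairy traits for heritability and the rg stage (default:
#'   every trait after the two leading selection-criterion traits).
#' @param n_perm permutations for the empirical threshold (default 200).
#' @param run_gwas_stage fit the ssGBLUP GWAS for the first dairy trait and
#'   the first analysed OTU (default TRUE).
#' @param threshold_fraction,occurrence compositional settings.
#' @param alpha G-blending weight (default 0.05).
#' @param seed seed for the permutation stage (default: config seed + 10).
#' @return list with all stage outputs (invisible); files in `out_dir`.
#' @export
run_pipeline <- function(dataset, out_dir, otu_subset = NULL, max_otus = 20L,
                         traits = NULL, n_perm = 200L, run_gwas_stage = TRUE,
                         threshold_fraction = 5e-5, occurrence = 0.90,
                         alpha = 0.05, seed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  logf <- function(...) cat(format(Sys.time(), "%H:%M:%S "), sprintf(...),
                            "\n", sep = "", file = log_path, append = TRUE)
  cat("", file = log_path)
  if (is.null(seed)) seed <- dataset$config$seed + 10L
  logf("pipeline start, seed %d", seed)

  ped <- dataset$pedigree
  phen <- dataset$phenotypes
  trait_names <- dataset$config$trait_specs$name
  lead <- trait_names[seq_len(min(2L, length(trait_names)))]
  if (is.null(traits)) traits <- setdiff(trait_names, lead)

  # --- genotype QC
  qc <- NULL
  if (!is.null(dataset$genotypes)) {
    qc <- qc_genotypes(dataset$genotypes)
    logf("QC: removed %s", paste(qc$report$removed, collapse = "/"))
    data.table::fwrite(qc$report, file.path(out_dir, "qc_report.tsv"), sep = "\t")
  }

  # --- compositional preprocessing
  filtered <- filter_low_abundance(dataset$otu_counts, threshold_fraction)
  logf("abundance filter: %d of %d OTU retained", ncol(filtered$counts),
       ncol(dataset$otu_counts$counts))
  clr_std <- preprocess_otu(dataset$otu_counts, threshold_fraction)
  core <- core_microbiome(filtered, occurrence)
  writeLines(core, file.path(out_dir, "core_microbiome.txt"))
  logf("core microbiome: %d OTU at %.0f%% occurrence", length(core),
       100 * occurrence)

  # --- relationship matrix
  A <- build_A(ped)

  # --- per-OTU heritability (3-trait models: lead traits + OTU)
  if (is.null(otu_subset)) otu_subset <- colnames(clr_std)
  otu_subset <- utils::head(intersect(otu_subset, colnames(clr_std)), max_otus)
  h2_rows <- lapply(otu_subset, function(otu) {
    fr <- build_model_frame(phen, c(lead, otu),
                            fixed_effects = .default_fe_spec(phen, c(lead, otu)),
                            ped = ped, responses = clr_std)
    vc <- reml_ai(fr, A, em_rounds = 30L, max_iter = 50L, tol = 1e-8)
    h <- heritability(vc, otu)
    data.frame(otu_id = otu, h2 = h$h2, se = h$se, converged = vc$converged)
  })
  h2_table <- do.call(rbind, h2_rows)
  data.table::fwrite(h2_table, file.path(out_dir, "otu_heritability.tsv"), sep = "\t")
  logf("heritability: %d OTU fitted, mean h2 %.3f", nrow(h2_table),
       mean(h2_table$h2))

  # --- dairy-trait heritability
  trait_h2 <- lapply(traits, function(tr) {
    fr <- build_model_frame(phen, c(lead, tr),
                            fixed_effects = .default_fe_spec(phen, c(lead, tr)),
                            ped = ped)
    vc <- reml_ai(fr, A, em_rounds = 30L, max_iter = 50L, tol = 1e-8)
    h <- heritability(vc, tr)
    data.frame(trait = tr, h2 = h$h2, se = h$se, converged = vc$converged)
  })
  trait_h2 <- do.call(rbind, trait_h2)
  data.table::fwrite(trait_h2, file.path(out_dir, "trait_heritability.tsv"), sep = "\t")

  # --- permutation threshold (first analysed OTU)
  fr0 <- build_model_frame(phen, c(lead, otu_subset[1]),
                           fixed_effects = .default_fe_spec(phen, c(lead, otu_subset[1])),
                           ped = ped, responses = clr_std)
  perm <- permute_and_refit(fr0$Y[, 3L], fr0, A, n_perm = n_perm, seed = seed)
  logf("permutation threshold (%d perms): h2 > %.4f", n_perm, perm$threshold)
  sig_otus <- h2_table$otu_id[h2_table$h2 > perm$threshold]
  data.table::fwrite(data.frame(n_perm = n_perm, threshold = perm$threshold,
                                n_significant = length(sig_otus)),
                     file.path(out_dir, "permutation_threshold.tsv"), sep = "\t")

  # --- genus enrichment
  enrich <- genus_enrichment(filtered$taxonomy, sig_otus, h2_table$otu_id)
  data.table::fwrite(enrich, file.path(out_dir, "genus_enrichment.tsv"), sep = "\t")

  # --- genetic correlations (4-trait models per heritable OTU x trait)
  tasks <- build_rg_tasks(sig_otus, traits)
  rg_table <- NULL
  if (nrow(tasks)) {
    rg_rows <- lapply(seq_len(nrow(tasks)), function(i) {
      otu <- tasks$otu_id[i]; tr <- tasks$trait[i]
      fr <- build_model_frame(phen, c(lead, otu, tr),
                              fixed_effects = .default_fe_spec(phen, c(lead, otu, tr)),
                              ped = ped, responses = clr_std)
      vc <- reml_ai(fr, A, em_rounds = 30L, max_iter = 50L, tol = 1e-8)
      rg <- tryCatch(genetic_correlation(vc, otu, tr), error = function(e)
        list(rg = NA_real_, se = NA_real_, significant = FALSE))
      data.frame(otu_id = otu, trait = tr, rg = rg$rg, se = rg$se,
                 significant = isTRUE(rg$significant))
    })
    rg_table <- do.call(rbind, rg_rows)
    data.table::fwrite(rg_table, file.path(out_dir, "genetic_correlations.tsv"),
                       sep = "\t")
    logf("rg stage: %d estimates (%d OTU x %d traits)", nrow(rg_table),
         length(sig_otus), length(traits))
  }

  # --- ssGBLUP GWAS (first dairy trait; first analysed OTU)
  gwas_out <- NULL
  if (run_gwas_stage && !is.null(qc)) {
    gset <- qc$genotypes
    gids <- intersect(rownames(gset$allele_counts), ped$animal)
    gset$allele_counts <- gset$allele_counts[gids, , drop = FALSE]
    gset$allele_freqs <- colMeans(gset$allele_counts) / 2
    blocks <- partition_A(A, gids)
    G <- blend_G(compute_G_raw(gset), blocks$A22, alpha = alpha)
    H <- build_H(blocks, G)
    tr <- traits[1]
    fr <- build_model_frame(phen, c(lead, tr),
                            fixed_effects = .default_fe_spec(phen, c(lead, tr)),
                            ped = ped)
    vc <- reml_ai(fr, A, em_rounds = 30L, max_iter = 50L, tol = 1e-8)
    i3 <- 3L
    fr1 <- build_model_frame(phen, tr,
                             fixed_effects = .default_fe_spec(phen, tr), ped = ped)
    gwas_out <- run_gwas(fr1$Y[, 1L], fr1$X[[1L]], fr1$ids, H, gset, G,
                         sigma_g2 = vc$P[i3, i3], sigma_e2 = vc$R[i3, i3])
    data.table::fwrite(gwas_out$gwas, file.path(out_dir, paste0("gwas_", tr, ".tsv")),
                       sep = "\t")
    if (nrow(gwas_out$regions))
      data.table::fwrite(gwas_out$regions,
                         file.path(out_dir, paste0("qtl_regions_", tr, ".tsv")),
                         sep = "\t")
    logf("GWAS %s: %d significant SNPs, %d region(s)", tr,
         sum(gwas_out$gwas$significant), nrow(gwas_out$regions))
  }
  logf("pipeline done")
  invisible(list(qc = qc, clr = clr_std, core = core, A = A,
                 h2_table = h2_table, trait_h2 = trait_h2, perm = perm,
                 significant_otus = sig_otus, enrichment = enrich,
                 rg_table = rg_table, gwas = gwas_out))
}

# Fixed-effect spec used by the pipeline: every factor present in the
# phenotype table applies to OTU responses; run/order (sequencing and
# sampling-order effects) are omitted for dairy traits.
.default_fe_spec <- function(phen, traits) {
  all_fac <- intersect(c("year", "parity", "litter_size", "run", "order"),
                       names(phen))
  dairy_fac <- setdiff(all_fac, c("run", "order"))
  specs <- lapply(traits, function(tr)
    if (grepl("^OTU", tr)) all_fac else dairy_fac)
  stats::setNames(specs, traits)
}

#' Write a simulated dataset to plain-text files
#'
#' Writes pedigree CSV, genotype + map TSV, OTU count and taxonomy TSV,
#' phenotype CSV, and a YAML summary of the simulation truth (heritabilities,
#' variance components, QTL table) into a directory.
#'
#' @param dataset a `sim_dataset` from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pedigree(dataset$pedigree, file.path(dir, "pedigree.csv"))
  if (!is.null(dataset$genotypes))
    write_genotypes(dataset$genotypes, file.path(dir, "genotypes.tsv"),
                    file.path(dir, "snp_map.tsv"))
  if (!is.null(dataset$otu_counts))
    write_otu_table(dataset$otu_counts, file.path(dir, "otu_counts.tsv"),
                    file.path(dir, "taxonomy.tsv"))
  write_phenotypes(dataset$phenotypes, file.path(dir, "phenotypes.csv"))
  truth <- dataset$truth
  yaml::write_yaml(list(
    h2 = as.list(round(truth$h2, 6)),
    sigma = as.list(round(truth$sigma, 6)),
    qtl = if (is.null(truth$qtl)) NULL else
      lapply(seq_len(nrow(truth$qtl)), function(i) as.list(truth$qtl[i, ])),
    seed = dataset$config$seed), file.path(dir, "truth.yaml"))
  invisible(dir)
}

#' Load a dataset from plain-text files for the pipeline
#'
#' Counterpart of [write_dataset()]: reads the tables written there (or any
#' files in the same dialects) and reconciles ids across them.
#'
#' @param dir directory containing `pedigree.csv`, `phenotypes.csv` and
#'   optionally `genotypes.tsv`/`snp_map.tsv`, `otu_counts.tsv`,
#'   `taxonomy.tsv`.
#' @param config a [sim_config] attached to the result (trait names are
#'   taken from its `trait_specs`); default [sim_config()] with trait specs
#'   inferred from the phenotype columns is not attempted — pass the config
#'   used to create the files where possible.
#' @return list shaped like a `sim_dataset` (without `truth`).
#' @export
read_dataset <- function(dir, config = NULL) {
  ped <- read_pedigree(file.path(dir, "pedigree.csv"))
  phen <- read_phenotypes(file.path(dir, "phenotypes.csv"), ped = ped)
  gset <- NULL
  if (file.exists(file.path(dir, "genotypes.tsv")))
    gset <- read_genotypes(file.path(dir, "genotypes.tsv"),
                           file.path(dir, "snp_map.tsv"))
  otu <- NULL
  if (file.exists(file.path(dir, "otu_counts.tsv")))
    otu <- read_otu_table(file.path(dir, "otu_counts.tsv"),
                          if (file.exists(file.path(dir, "taxonomy.tsv")))
                            file.path(dir, "taxonomy.tsv") else NULL)
  structure(list(pedigree = ped, genotypes = gset, otu_counts = otu,
                 phenotypes = phen, truth = NULL, config = config),
            class = "sim_dataset")
}

#' Read a pipeline configuration file
#'
#' YAML (or JSON, which YAML parses) configuration naming the input files
#' and stage settings; missing settings fall back to the documented
#' defaults (QC call rates 0.90/0.95, MAF 0.05, abundance threshold
#' 0.005%, occurrence 0.90, alpha 0.05, FDR 0.10/0.30, window 20).
#'
#' @param path configuration file.
#' @return list with `data_dir`, `out_dir`, `settings`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$data_dir) || is.null(cfg$out_dir))
    stop(path, ": config needs data_dir and out_dir")
  defaults <- list(snp_call_rate = 0.90, ind_call_rate = 0.95,
                   maf_min = 0.05, threshold_fraction = 5e-5,
                   occurrence = 0.90, alpha = 0.05, n_perm = 200L,
                   max_otus = 20L, seed = 1L)
  settings <- utils::modifyList(defaults, cfg$settings %||% list())
  list(data_dir = cfg$data_dir, out_dir = cfg$out_dir, settings = settings)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
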