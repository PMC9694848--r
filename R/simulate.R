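#' Configuration for the hologenome simulator
#'
#' Collects every knob of the synthetic-data generator.  The defaults emulate
#' the study population the package's models were designed for: a dairy-ewe
#' flock of five discrete generations with a final phenotyped cohort of 795
#' ewes (pedigree of ~4,500 animals), a post-QC medium-density SNP panel of
#' 35,492 markers on 26 autosomes, ~2,000 OTU with ~37.5% zero cells and
#' compositional count structure, OTU latent heritabilities in [0, 0.3]
#' (mean 0.04) and dairy traits with heritabilities 0.2-0.7.
#'
#' @param seed integer seed; every simulator output is a pure function of
#'   the configuration including this seed.
#' @param n_founders founder animals (generation 0).
#' @param n_generations discrete non-founder generations (default 5).
#' @param cohort_size animals born per generation.
#' @param n_offspring_per_mating offspring per mating pair (default 2).
#' @param n_sires sires used per generation (default 30, an AI-like
#'   structure; the real flock's family structure is not public, so this is
#'   an explicit assumption).
#' @param n_snps,n_chromosomes,chr_length_bp,maf_range SNP panel layout:
#'   marker count, autosome count, per-autosome length (bp) and the uniform
#'   range founder allele frequencies are drawn from.
#' @param n_otus number of OTU.
#' @param target_zero_fraction realized zero-cell fraction the sparsity
#'   offset is calibrated to (default 0.375).
#' @param sparsity_cell_fraction fraction of latent cells eligible for the
#'   calibrated sparsity offset (default 0.5).
#' @param otu_log_mean_sd SD of per-OTU baseline log-abundances (controls
#'   how uneven the community is; default 1.5).
#' @param otu_h2 per-OTU latent heritability: scalar, vector of length
#'   `n_otus`, or `NULL` to draw `min(Exp(mean 0.04), 0.30)` per OTU.
#' @param depth_range sequencing depth range (reads per sample), drawn
#'   uniformly per sample.
#' @param trait_specs data.frame with columns `name`, `h2`, `mean`, `sd`
#'   describing the dairy traits; the default five traits carry the study's
#'   descriptive statistics (LSCS, CV milk, milk yield, fat and protein
#'   content).  The first trait is the selection criterion when
#'   `selection = "truncation"`.
#' @param genetic_correlations optional symmetric PSD correlation matrix
#'   with dimnames naming latent variables (trait names and/or OTU ids);
#'   unnamed latents are simulated independently.
#' @param qtl_list optional data.frame with columns `chrom`, `pos_bp`,
#'   `target` (latent name), `var_fraction` (share of the target's genetic
#'   variance); each QTL is attached to the simulated SNP nearest the
#'   requested position so GWAS can rediscover it.
#' @param fixed_effect_levels named integer vector of factor level counts;
#'   default `c(year = 5, parity = 3, litter_size = 2, run = 6, order = 8)`.
#'   `run` and `order` (sequencing run, rumen-sampling order) act on OTU
#'   only; the others act on every latent variable.
#' @param fe_sd size of fixed-effect level values, as a fraction of each
#'   latent's genetic-plus-residual SD (default 0.25).
#' @param dim_range days-in-milk covariate range (default `c(28, 133)`).
#' @param phenotyped which animals carry records: `"last_generation"`
#'   (default), `"all_nonfounders"` or `"all"`.
#' @param selection `"none"` (random mating, default) or `"truncation"`
#'   (parents of each generation are the top `selected_fraction` by the
#'   first trait's phenotype, within sex).
#' @param selected_fraction truncation-selection proportion (default 0.3).
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_founders = 500L, n_generations = 5L,
                       cohort_size = 795L, n_offspring_per_mating = 2L,
                       n_sires = 30L,
                       n_snps = 35492L, n_chromosomes = 26L,
                       chr_length_bp = 1e8, maf_range = c(0.05, 0.5),
                       n_otus = 2000L, target_zero_fraction = 0.375,
                       sparsity_cell_fraction = 0.5,
                       otu_log_mean_sd = 1.5, otu_h2 = NULL,
                       depth_range = c(5000L, 25000L),
                       trait_specs = default_trait_specs(),
                       genetic_correlations = NULL,
                       qtl_list = NULL,
                       fixed_effect_levels = c(year = 5L, parity = 3L,
                                               litter_size = 2L, run = 6L,
                                               order = 8L),
                       fe_sd = 0.25, dim_range = c(28L, 133L),
                       phenotyped = c("last_generation", "all_nonfounders", "all"),
                       selection = c("none", "truncation"),
                       selected_fraction = 0.3) {
  phenotyped <- match.arg(phenotyped)
  selection <- match.arg(selection)
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (n_founders < 2L || n_generations < 1L)
    stop("need n_founders >= 2 and n_generations >= 1")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (target_zero_fraction < 0 || target_zero_fraction >= 1)
    stop("target_zero_fraction must lie in [0, 1)")
  if (any(depth_range <= 0)) stop("depths must be positive")
  stopifnot(is.data.frame(trait_specs),
            all(c("name", "h2", "mean", "sd") %in% names(trait_specs)))
  if (any(trait_specs$h2 < 0 | trait_specs$h2 >= 1))
    stop("trait h2 must lie in [0, 1)")
  if (!is.null(otu_h2)) {
    if (!length(otu_h2) %in% c(1L, n_otus)) stop("otu_h2 length mismatch")
    if (any(otu_h2 < 0 | otu_h2 >= 1)) stop("otu_h2 must lie in [0, 1)")
  }
  if (!is.null(genetic_correlations)) {
    gc <- as.matrix(genetic_correlations)
    if (is.null(rownames(gc)) || !identical(rownames(gc), colnames(gc)))
      stop("genetic_correlations needs matching dimnames")
    if (max(abs(gc - t(gc))) > 1e-8) stop("genetic_correlations must be symmetric")
    if (min(eigen(gc, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stop("genetic_correlations must be positive semi-definite")
  }
  if (!is.null(qtl_list)) {
    stopifnot(is.data.frame(qtl_list),
              all(c("chrom", "pos_bp", "target", "var_fraction") %in% names(qtl_list)))
    if (any(qtl_list$var_fraction < 0 | qtl_list$var_fraction > 1))
      stop("QTL variance fractions must lie in [0, 1]")
    if (selection == "truncation")
      stop("planted QTL are not supported under truncation selection")
  }
  cfg <- list(seed = as.integer(seed), n_founders = as.integer(n_founders),
              n_generations = as.integer(n_generations),
              cohort_size = as.integer(cohort_size),
              n_offspring_per_mating = as.integer(n_offspring_per_mating),
              n_sires = as.integer(n_sires),
              n_snps = as.integer(n_snps), n_chromosomes = as.integer(n_chromosomes),
              chr_length_bp = chr_length_bp, maf_range = maf_range,
              n_otus = as.integer(n_otus),
              target_zero_fraction = target_zero_fraction,
              sparsity_cell_fraction = sparsity_cell_fraction,
              otu_log_mean_sd = otu_log_mean_sd, otu_h2 = otu_h2,
              depth_range = depth_range, trait_specs = trait_specs,
              genetic_correlations = genetic_correlations, qtl_list = qtl_list,
              fixed_effect_levels = fixed_effect_levels, fe_sd = fe_sd,
              dim_range = dim_range, phenotyped = phenotyped,
              selection = selection, selected_fraction = selected_fraction)
  class(cfg) <- "sim_config"
  cfg
}

#' Default dairy-trait specifications
#'
#' Five traits with the study population's descriptive statistics: lactation
#' somatic cell score and the coefficient of variation of milk yield (the
#' two selection-criterion traits that lead every multi-trait model), milk
#' yield, fat content and protein content.
#'
#' @return data.frame with columns `name`, `h2`, `mean`, `sd`.
#' @export
default_trait_specs <- function() {
  data.frame(
    name = c("LSCS", "CVmilk", "MilkYield", "FatContent", "ProteinContent"),
    h2   = c(0.37, 0.22, 0.28, 0.59, 0.57),
    mean = c(3.29, 53.93, 1946, 7.37, 5.71),
    sd   = c(1.50, 12.18, 589, 1.14, 0.52))
}

.otu_ids <- function(n) sprintf("OTU%04d", seq_len(n))

#' Simulate a multi-generation pedigree
#'
#' Discrete generations: `n_founders` unrelated founders (generation 0,
#' unknown parents), then `n_generations` cohorts of `cohort_size` animals.
#' Each generation draws `n_sires` sires and dams (without replacement where
#' possible) from the previous generation and mates them at random without
#' selfing; parents always precede offspring in the output.
#'
#' @param config a [sim_config].
#' @return [pedigree] with extra columns `generation` and `sex`.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  .grow_pedigree(config, select_on = NULL)
}

# Generation-wise pedigree builder.  select_on: NULL for random mating, or a
# function(ids) -> numeric scores used for within-sex truncation selection.
.grow_pedigree <- function(config, select_on = NULL, score_env = NULL) {
  id_fmt <- function(gen, i) sprintf("G%d_%04d", gen, i)
  n0 <- config$n_founders
  animal <- id_fmt(0L, seq_len(n0))
  sire <- dam <- rep("0", n0)
  generation <- rep(0L, n0)
  sex <- sample(rep_len(c("M", "F"), n0))
  prev <- data.frame(animal = animal, sex = sex, stringsAsFactors = FALSE)
  for (g in seq_len(config$n_generations)) {
    males <- prev$animal[prev$sex == "M"]
    females <- prev$animal[prev$sex == "F"]
    if (!length(males) || !length(females))
      stop("generation ", g - 1L, " has a single sex; increase cohort size")
    if (!is.null(select_on)) {
      keep <- function(ids) {
        sc <- select_on(ids, score_env)
        n_keep <- max(2L, ceiling(config$selected_fraction * length(ids)))
        ids[order(sc, decreasing = TRUE)[seq_len(min(n_keep, length(ids)))]]
      }
      males <- keep(males); females <- keep(females)
    }
    sires_pool <- if (length(males) > config$n_sires)
      sample(males, config$n_sires) else males
    n_mat <- ceiling(config$cohort_size / config$n_offspring_per_mating)
    dams_mat <- sample(females, n_mat, replace = n_mat > length(females))
    sires_mat <- sample(sires_pool, n_mat, replace = TRUE)
    off_s <- rep(sires_mat, each = config$n_offspring_per_mating)[seq_len(config$cohort_size)]
    off_d <- rep(dams_mat, each = config$n_offspring_per_mating)[seq_len(config$cohort_size)]
    ids <- id_fmt(g, seq_len(config$cohort_size))
    animal <- c(animal, ids); sire <- c(sire, off_s); dam <- c(dam, off_d)
    generation <- c(generation, rep(g, config$cohort_size))
    new_sex <- sample(rep_len(c("M", "F"), config$cohort_size))
    sex <- c(sex, new_sex)
    prev <- data.frame(animal = ids, sex = new_sex, stringsAsFactors = FALSE)
    if (!is.null(select_on)) score_env$new_generation(ids, off_s, off_d)
  }
  ped <- pedigree(animal, sire, dam)   # input already ordered; kept as-is
  ped$generation <- generation[match(ped$animal, animal)]
  ped$sex <- sex[match(ped$animal, animal)]
  ped
}

#' Genotype container
#'
#' @param allele_counts individuals x SNP matrix of 0/1/2 allele counts
#'   (NA = missing), with individual row names and SNP column names.
#' @param snp_map data.frame with columns `chrom`, `snp_id`, `pos_bp`,
#'   positions ascending within chromosome.
#' @param allele_freqs optional per-SNP counted-allele frequencies; default
#'   observed `colMeans/2` (missing entries ignored).
#' @return object of class `genotype_set`.
#' @export
genotype_set <- function(allele_counts, snp_map, allele_freqs = NULL) {
  allele_counts <- as.matrix(allele_counts)
  if (is.null(rownames(allele_counts))) stop("allele_counts needs row names")
  stopifnot(all(c("chrom", "snp_id", "pos_bp") %in% names(snp_map)),
            nrow(snp_map) == ncol(allele_counts))
  ok <- allele_counts %in% c(0L, 1L, 2L) | is.na(allele_counts)
  if (!all(ok)) stop("allele counts must be 0/1/2 or NA")
  for (ch in unique(snp_map$chrom)) {
    pos <- snp_map$pos_bp[snp_map$chrom == ch]
    if (is.unsorted(pos)) stop("positions must ascend within chromosome ", ch)
  }
  colnames(allele_counts) <- snp_map$snp_id
  if (is.null(allele_freqs))
    allele_freqs <- colMeans(allele_counts, na.rm = TRUE) / 2
  structure(list(allele_counts = allele_counts,
                 snp_map = as.data.frame(snp_map),
                 allele_freqs = allele_freqs),
            class = "genotype_set")
}

#' @export
print.genotype_set <- function(x, ...) {
  cat(sprintf("genotype_set: %d individuals x %d SNPs on %d chromosome(s), %.2f%% missing\n",
              nrow(x$allele_counts), ncol(x$allele_counts),
              length(unique(x$snp_map$chrom)),
              100 * mean(is.na(x$allele_counts))))
  invisible(x)
}

#' Gene-drop genotypes down a pedigree
#'
#' Founder allele counts are drawn per SNP as Binomial(2, p) with
#' p ~ Uniform(`maf_range`); every descendant receives one allele per parent,
#' sampled independently per SNP (unlinked Mendelian dropping, so no LD is
#' simulated between markers).  SNPs are laid out in ascending position over
#' `n_chromosomes` autosomes.
#'
#' @param ped ordered [pedigree].
#' @param config a [sim_config].
#' @return [genotype_set] covering every pedigree animal.
#' @export
simulate_genotypes <- function(ped, config) {
  stopifnot(inherits(ped, "pedigree"), inherits(config, "sim_config"))
  par <- .check_pedigree_ordered(ped)
  set.seed(config$seed + 1L)
  m <- config$n_snps; n <- nrow(ped)
  p0 <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  M <- matrix(0L, n, m, dimnames = list(ped$animal, NULL))
  for (i in seq_len(n)) {
    s <- par$sire[i]; d <- par$dam[i]
    if (s == 0L && d == 0L) {
      M[i, ] <- stats::rbinom(m, 2L, p0)
    } else {
      gs <- if (s > 0L) M[s, ] else stats::rbinom(m, 2L, p0)
      gd <- if (d > 0L) M[d, ] else stats::rbinom(m, 2L, p0)
      M[i, ] <- stats::rbinom(m, 1L, gs / 2) + stats::rbinom(m, 1L, gd / 2)
    }
  }
  chrom <- sort(rep_len(seq_len(config$n_chromosomes), m))
  pos <- unlist(lapply(split(seq_len(m), chrom), function(ix)
    sort(sample.int(config$chr_length_bp, length(ix)))), use.names = FALSE)
  map <- data.frame(chrom = chrom, snp_id = sprintf("snp%05d", seq_len(m)),
                    pos_bp = pos)
  gs <- genotype_set(M, map)
  attr(gs, "founder_p") <- p0
  gs
}

# Draw per-OTU latent heritabilities (exponential, mean 0.04, capped at 0.30).
.draw_otu_h2 <- function(config) {
  if (!is.null(config$otu_h2)) return(rep_len(config$otu_h2, config$n_otus))
  pmin(stats::rexp(config$n_otus, rate = 1 / 0.04), 0.30)
}

# Latent-variable bookkeeping shared by the random-mating and selection paths.
.latent_layout <- function(config) {
  traits <- config$trait_specs
  otu_ids <- .otu_ids(config$n_otus)
  name <- c(traits$name, otu_ids)
  list(name = name,
       is_otu = c(rep(FALSE, nrow(traits)), rep(TRUE, config$n_otus)),
       n = length(name))
}

#' Simulate latent genetic values, fixed effects and phenotypes
#'
#' For every latent variable (dairy trait or OTU log-abundance) the
#' phenotype of a recorded animal is
#' `mean + fixed effects + QTL term + polygenic breeding value + residual`.
#' Breeding values are generated by the gene-flow recursion
#' `a_i = (a_sire + a_dam)/2 + m_i` with Mendelian-sampling variance `P/2`
#' (parental inbreeding, which is negligible at the default population
#' sizes, is ignored in the Mendelian term), giving covariance `A x P`
#' across animals and latents.  Latents named in
#' `config$genetic_correlations` are drawn jointly with that correlation on
#' their polygenic parts; all others are independent.  Each planted QTL
#' contributes `beta * (g - 2p)` with `beta` sized so the QTL explains the
#' requested fraction of the target's genetic variance, and the polygenic
#' variance of the target is scaled down to keep the total genetic variance
#' at `h2 * sigma^2`.
#'
#' @param genotypes [genotype_set] covering the pedigree (required when
#'   `config$qtl_list` is non-empty, otherwise optional).
#' @param ped [pedigree] from [simulate_pedigree()].
#' @param config a [sim_config].
#' @return list with `samples` (data.frame of recorded animals and their
#'   fixed-effect levels incl. the DIM covariate), `traits` (records x
#'   dairy-trait phenotype matrix), `otu_latent` (records x OTU latent
#'   log-abundance matrix) and `truth` (h2, genetic/residual SDs, breeding
#'   values, QTL table, realized variance partition).
#' @export
simulate_latent_traits <- function(genotypes, ped, config) {
  stopifnot(inherits(ped, "pedigree"), inherits(config, "sim_config"))
  par <- .check_pedigree_ordered(ped)
  set.seed(config$seed + 2L)
  lay <- .latent_layout(config)
  n_lat <- lay$n; n_ped <- nrow(ped)
  h2 <- c(config$trait_specs$h2, .draw_otu_h2(config))
  sigma <- c(config$trait_specs$sd, rep(1, config$n_otus))     # sd of g + e
  mu <- c(config$trait_specs$mean,
          stats::rnorm(config$n_otus, 0, config$otu_log_mean_sd))
  names(h2) <- names(sigma) <- names(mu) <- lay$name

  # --- QTL: pick carrier SNPs, size effects, reduce polygenic share
  qtl <- NULL
  qtl_frac <- stats::setNames(rep(0, n_lat), lay$name)
  if (!is.null(config$qtl_list) && nrow(config$qtl_list)) {
    if (is.null(genotypes)) stop("QTL requested but no genotypes supplied")
    qtl <- config$qtl_list
    qtl$snp_id <- NA_character_; qtl$beta <- NA_real_; qtl$p <- NA_real_
    for (k in seq_len(nrow(qtl))) {
      tgt <- qtl$target[k]
      if (!tgt %in% lay$name) stop("unknown QTL target: ", tgt)
      on_chr <- which(genotypes$snp_map$chrom == qtl$chrom[k])
      if (!length(on_chr)) stop("no SNPs on chromosome ", qtl$chrom[k])
      j <- on_chr[which.min(abs(genotypes$snp_map$pos_bp[on_chr] - qtl$pos_bp[k]))]
      pj <- genotypes$allele_freqs[j]
      if (pj <= 0 || pj >= 1) stop("QTL SNP is monomorphic; pick another position")
      sg2 <- h2[tgt] * sigma[tgt]^2
      qtl$snp_id[k] <- genotypes$snp_map$snp_id[j]
      qtl$p[k] <- pj
      qtl$beta[k] <- sqrt(qtl$var_fraction[k] * sg2 / (2 * pj * (1 - pj)))
      qtl_frac[tgt] <- qtl_frac[tgt] + qtl$var_fraction[k]
    }
    if (any(qtl_frac > 1)) stop("QTL variance fractions exceed 1 for a target")
  }

  # --- polygenic breeding values via gene-flow recursion
  sd_g <- sigma * sqrt(h2)
  poly_sd <- sd_g * sqrt(pmax(0, 1 - qtl_frac))
  corr_names <- if (is.null(config$genetic_correlations)) character(0) else
    intersect(rownames(config$genetic_correlations), lay$name)
  draw_block <- function(n_rows, scale) {
    # scale: 1 founders, sqrt(1/2) Mendelian draws
    Zm <- matrix(stats::rnorm(n_rows * n_lat), n_rows, n_lat)
    if (length(corr_names) > 1L) {
      Cm <- config$genetic_correlations[corr_names, corr_names]
      Zm[, match(corr_names, lay$name)] <-
        Zm[, match(corr_names, lay$name), drop = FALSE] %*% chol(Cm)
    }
    sweep(Zm, 2L, poly_sd * scale, "*")
  }
  founder <- par$sire == 0L & par$dam == 0L
  BV <- matrix(0, n_ped, n_lat, dimnames = list(ped$animal, lay$name))
  draws <- matrix(0, n_ped, n_lat)
  draws[founder, ] <- draw_block(sum(founder), 1)
  draws[!founder, ] <- draw_block(sum(!founder), sqrt(0.5))
  for (i in seq_len(n_ped)) {
    s <- par$sire[i]; d <- par$dam[i]
    if (s == 0L && d == 0L) BV[i, ] <- draws[i, ]
    else BV[i, ] <- (BV[max(s, 1L), ] * (s > 0) + BV[max(d, 1L), ] * (d > 0)) / 2 +
      draws[i, ]
  }
  if (!is.null(qtl)) {
    for (k in seq_len(nrow(qtl))) {
      g <- genotypes$allele_counts[ped$animal, qtl$snp_id[k]]
      BV[, qtl$target[k]] <- BV[, qtl$target[k]] + qtl$beta[k] * (g - 2 * qtl$p[k])
    }
  }

  # --- recorded animals, fixed effects, residuals
  rec <- switch(config$phenotyped,
                last_generation = ped$animal[ped$generation == max(ped$generation)],
                all_nonfounders = ped$animal[ped$generation > 0L],
                all = ped$animal)
  n_rec <- length(rec)
  fe <- .draw_fixed_effects(config, lay, sigma, n_rec)
  resid <- sweep(matrix(stats::rnorm(n_rec * n_lat), n_rec, n_lat),
                 2L, sigma * sqrt(1 - h2), "*")
  values <- sweep(BV[rec, , drop = FALSE] + fe$contrib + resid, 2L, mu, "+")

  traits <- values[, !lay$is_otu, drop = FALSE]
  otu_latent <- values[, lay$is_otu, drop = FALSE]
  samples <- cbind(data.frame(animal = rec, stringsAsFactors = FALSE), fe$design)
  truth <- list(h2 = h2, sigma = sigma, mean = mu, sd_genetic = sd_g,
                sd_residual = sigma * sqrt(1 - h2),
                breeding_values = BV, qtl = qtl,
                fixed_effects = fe$effects,
                realized_h2 = apply(BV[rec, , drop = FALSE], 2L, stats::var) /
                  (apply(BV[rec, , drop = FALSE], 2L, stats::var) +
                     apply(resid, 2L, stats::var)))
  list(samples = samples, traits = traits, otu_latent = otu_latent, truth = truth)
}

# Factor-level assignments and level effects.  run/order act on OTU only.
.draw_fixed_effects <- function(config, lay, sigma, n_rec) {
  lv <- config$fixed_effect_levels
  design <- data.frame(row.names = seq_len(n_rec))
  contrib <- matrix(0, n_rec, lay$n)
  effects <- list()
  otu_only <- c("run", "order")
  for (f in names(lv)) {
    assign_f <- sample.int(lv[[f]], n_rec, replace = TRUE)
    eff <- matrix(stats::rnorm(lv[[f]] * lay$n), lv[[f]], lay$n)
    eff <- sweep(eff, 2L, config$fe_sd * sigma, "*")
    if (f %in% otu_only) eff[, !lay$is_otu] <- 0
    design[[f]] <- factor(assign_f)
    contrib <- contrib + eff[assign_f, , drop = FALSE]
    effects[[f]] <- eff
  }
  dim_val <- sample(seq(config$dim_range[1], config$dim_range[2]), n_rec,
                    replace = TRUE)
  slope <- config$fe_sd * sigma / stats::sd(dim_val)
  contrib <- contrib + outer(dim_val - mean(dim_val), slope)
  design$dim <- dim_val
  effects$dim_slope <- slope
  list(design = design, contrib = contrib, effects = effects)
}

#' Render OTU counts from latent log-abundances
#'
#' Each sample's composition is `exp(latent)/sum(exp(latent))`; counts are
#' drawn multinomially at a depth uniform in `depth_range`.  Zero inflation:
#' a constant offset is subtracted from a fixed random subset of latent
#' cells (fraction `sparsity_cell_fraction`), with the offset calibrated by
#' bisection so the expected zero fraction matches
#' `target_zero_fraction`.
#'
#' @param latent records x OTU matrix of latent log-abundances (row names =
#'   sample/animal ids).
#' @param config a [sim_config].
#' @return [otu_table] with simulated taxonomy; attributes `depths` and
#'   `sparsity_offset` record the drawn depths and calibrated offset.
#' @export
render_otu_counts <- function(latent, config) {
  stopifnot(inherits(config, "sim_config"))
  latent <- as.matrix(latent)
  if (any(!is.finite(latent))) stop("latent values must be finite")
  if (any(config$depth_range <= 0)) stop("depths must be positive")
  set.seed(config$seed + 3L)
  n <- nrow(latent); D <- ncol(latent)
  depth_vals <- seq.int(config$depth_range[1], config$depth_range[2])
  depths <- depth_vals[sample.int(length(depth_vals), n, replace = TRUE)]
  offset_cells <- matrix(stats::runif(n * D) < config$sparsity_cell_fraction, n, D)
  expected_zero <- function(c_off) {
    lat <- latent - c_off * offset_cells
    lat <- lat - apply(lat, 1L, max)
    pi_ <- exp(lat); pi_ <- pi_ / rowSums(pi_)
    mean(exp(-depths * pi_))       # Poisson approx of multinomial zero prob
  }
  c_off <- 0
  if (config$target_zero_fraction > 0 &&
      expected_zero(0) < config$target_zero_fraction) {
    lo <- 0; hi <- 40
    for (it in 1:60) {
      c_off <- (lo + hi) / 2
      if (expected_zero(c_off) < config$target_zero_fraction) lo <- c_off else hi <- c_off
    }
  }
  lat <- latent - c_off * offset_cells
  lat <- lat - apply(lat, 1L, max)
  pi_ <- exp(lat); pi_ <- pi_ / rowSums(pi_)
  counts <- t(vapply(seq_len(n),
                     function(i) stats::rmultinom(1L, depths[i], pi_[i, ])[, 1L],
                     integer(D)))
  dimnames(counts) <- list(rownames(latent),
                           if (is.null(colnames(latent))) .otu_ids(D) else colnames(latent))
  out <- otu_table(counts, simulate_taxonomy(colnames(counts), config$seed + 4L))
  attr(out, "depths") <- depths
  attr(out, "sparsity_offset") <- c_off
  out
}

#' Simulate a taxonomy table
#'
#' Assigns OTU to a pool of rumen bacterial genera with frequencies close to
#' those observed in ewe rumen communities (Prevotella-dominated), carrying
#' the genus -> family -> phylum mapping.
#'
#' @param otu_ids character vector of OTU ids.
#' @param seed integer seed.
#' @return data.frame with columns `otu_id`, `domain`..`genus`.
#' @export
simulate_taxonomy <- function(otu_ids, seed = 1L) {
  set.seed(seed)
  pool <- data.frame(
    genus = c("Prevotella", "Christensenellaceae_R-7_group", "Ruminococcus",
              "Rikenellaceae_RC9_gut_group", "F082_unknown_genus",
              "Prevotellaceae_UCG-001", "Muribaculaceae_unknown_genus",
              "Acetitomaculum", "Treponema", "Ruminococcaceae_unknown_genus",
              "NK4A214_group", "Lachnospiraceae_NK4A136_group", "Butyrivibrio",
              "Succiniclasticum", "Fibrobacter", "unknown"),
    family = c("Prevotellaceae", "Christensenellaceae", "Ruminococcaceae",
               "Rikenellaceae", "F082", "Prevotellaceae", "Muribaculaceae",
               "Lachnospiraceae", "Spirochaetaceae", "Ruminococcaceae",
               "Oscillospiraceae", "Lachnospiraceae", "Lachnospiraceae",
               "Acidaminococcaceae", "Fibrobacteraceae", "unknown"),
    phylum = c("Bacteroidota", "Firmicutes", "Firmicutes", "Bacteroidota",
               "Bacteroidota", "Bacteroidota", "Bacteroidota", "Firmicutes",
               "Spirochaetota", "Firmicutes", "Firmicutes", "Firmicutes",
               "Firmicutes", "Firmicutes", "Fibrobacterota", "unknown"),
    prob = c(0.22, 0.08, 0.06, 0.05, 0.04, 0.03, 0.03, 0.02, 0.02, 0.02,
             0.04, 0.05, 0.03, 0.02, 0.02, 0.27))
  pick <- sample.int(nrow(pool), length(otu_ids), replace = TRUE, prob = pool$prob)
  data.frame(otu_id = otu_ids, domain = "Bacteria",
             phylum = pool$phylum[pick], class = "unknown", order = "unknown",
             family = pool$family[pick], genus = pool$genus[pick])
}

#' Simulate a complete hologenome dataset
#'
#' Orchestrates [simulate_pedigree()], [simulate_genotypes()],
#' [simulate_latent_traits()] and [render_otu_counts()] into a single
#' reproducible dataset.  With `selection = "truncation"` the pedigree and
#' trait phenotypes are built generation by generation so that parents can
#' be truncation-selected on the first trait's phenotype (a divergent-line
#' stand-in used to probe the multi-trait model's accounting for selection);
#' OTU latents are then drawn conditionally on the realized pedigree.
#'
#' @param config a [sim_config].
#' @param genotypes simulate genotypes (default TRUE; skip for pure
#'   variance-component studies to save time).
#' @return list of class `sim_dataset` with elements `pedigree`,
#'   `genotypes` (or NULL), `otu_counts` (or NULL when `n_otus = 0`),
#'   `phenotypes` (samples + trait columns), `truth`, `config`.
#' @export
simulate_dataset <- function(config, genotypes = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (config$selection == "truncation")
    return(.simulate_dataset_selected(config, genotypes))
  ped <- simulate_pedigree(config)
  gset <- if (genotypes) simulate_genotypes(ped, config) else NULL
  lat <- simulate_latent_traits(gset, ped, config)
  otu <- if (config$n_otus > 0L) render_otu_counts(lat$otu_latent, config) else NULL
  phenotypes <- cbind(lat$samples, as.data.frame(lat$traits))
  structure(list(pedigree = ped, genotypes = gset, otu_counts = otu,
                 phenotypes = phenotypes, truth = lat$truth, config = config),
            class = "sim_dataset")
}

# Truncation-selection path: phenotypes must exist before the next
# generation's parents are chosen, so traits are simulated alongside the
# pedigree.  Restricted to trait latents (no QTL).
.simulate_dataset_selected <- function(config, genotypes = TRUE) {
  set.seed(config$seed)
  specs <- config$trait_specs
  n_tr <- nrow(specs)
  sd_g <- specs$sd * sqrt(specs$h2)
  sd_e <- specs$sd * sqrt(1 - specs$h2)
  corr_names <- if (is.null(config$genetic_correlations)) character(0) else
    intersect(rownames(config$genetic_correlations), specs$name)
  cholC <- if (length(corr_names) > 1L)
    chol(config$genetic_correlations[corr_names, corr_names]) else NULL
  draw_bv <- function(n_rows, scale) {
    Zm <- matrix(stats::rnorm(n_rows * n_tr), n_rows, n_tr)
    if (!is.null(cholC)) {
      ix <- match(corr_names, specs$name)
      Zm[, ix] <- Zm[, ix, drop = FALSE] %*% cholC
    }
    sweep(Zm, 2L, sd_g * scale, "*")
  }
  env <- new.env()
  env$bv <- draw_bv(config$n_founders, 1)
  env$ph <- env$bv + sweep(matrix(stats::rnorm(config$n_founders * n_tr),
                                  config$n_founders, n_tr), 2L, sd_e, "*")
  rownames(env$bv) <- rownames(env$ph) <- sprintf("G0_%04d", seq_len(config$n_founders))
  env$new_generation <- function(ids, sires, dams) {
    mend <- draw_bv(length(ids), sqrt(0.5))
    bv_new <- (env$bv[sires, , drop = FALSE] + env$bv[dams, , drop = FALSE]) / 2 + mend
    ph_new <- bv_new + sweep(matrix(stats::rnorm(length(ids) * n_tr),
                                    length(ids), n_tr), 2L, sd_e, "*")
    rownames(bv_new) <- rownames(ph_new) <- ids
    env$bv <- rbind(env$bv, bv_new)
    env$ph <- rbind(env$ph, ph_new)
  }
  score <- function(ids, e) e$ph[ids, 1L]
  ped <- .grow_pedigree(config, select_on = score, score_env = env)

  rec <- switch(config$phenotyped,
                last_generation = ped$animal[ped$generation == max(ped$generation)],
                all_nonfounders = ped$animal[ped$generation > 0L],
                all = ped$animal)
  lay <- list(name = specs$name, is_otu = rep(FALSE, n_tr), n = n_tr)
  fe <- .draw_fixed_effects(config, lay, specs$sd, length(rec))
  traits <- sweep(env$ph[rec, , drop = FALSE] + fe$contrib, 2L, specs$mean, "+")
  colnames(traits) <- specs$name
  gset <- if (genotypes) simulate_genotypes(ped, config) else NULL
  otu <- NULL
  if (config$n_otus > 0L) {
    cfg_otu <- config
    cfg_otu$trait_specs <- specs[0, ]
    lat <- simulate_latent_traits(gset, ped, cfg_otu)
    otu <- render_otu_counts(lat$otu_latent[rec, , drop = FALSE], config)
  }
  bv_full <- env$bv[ped$animal, , drop = FALSE]
  colnames(bv_full) <- specs$name
  truth <- list(h2 = stats::setNames(specs$h2, specs$name),
                sigma = stats::setNames(specs$sd, specs$name),
                breeding_values = bv_full, qtl = NULL,
                fixed_effects = fe$effects)
  phenotypes <- cbind(data.frame(animal = rec, stringsAsFactors = FALSE),
                      fe$design, as.data.frame(traits))
  structure(list(pedigree = ped, genotypes = gset, otu_counts = otu,
                 phenotypes = phenotypes, truth = truth, config = config),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("sim_dataset: %d pedigree animals, %d recorded, %s SNPs, %s OTU\n",
              nrow(x$pedigree), nrow(x$phenotypes),
              if (is.null(x$genotypes)) "no" else ncol(x$genotypes$allele_counts),
              if (is.null(x$otu_counts)) "no" else ncol(x$otu_counts$counts)))
  invisible(x)
}
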