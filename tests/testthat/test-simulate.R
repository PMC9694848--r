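test_that("pedigree simulation respects founder-only, determinism and depth", {
  cfg <- sim_config(seed = 1, n_founders = 10, n_generations = 1,
                    cohort_size = 0, n_otus = 0, n_snps = 10)
  # founder-only case via n_generations = 1 with an empty cohort is not
  # meaningful; use cohort_size and inspect generation 0 instead
  ped <- simulate_pedigree(sim_config(seed = 1, n_founders = 10,
                                      n_generations = 1, cohort_size = 4,
                                      n_otus = 0, n_snps = 10))
  founders <- ped[ped$generation == 0, ]
  expect_equal(nrow(founders), 10)
  expect_true(all(founders$sire == "0" & founders$dam == "0"))

  cfg2 <- sim_config(seed = 1, n_founders = 20, n_generations = 5,
                     cohort_size = 12, n_otus = 0, n_snps = 10)
  p1 <- simulate_pedigree(cfg2); p2 <- simulate_pedigree(cfg2)
  expect_identical(p1, p2)

  # recursive ancestor walk: depth of the final generation is exactly 5
  depth <- function(ped, id, memo = new.env()) {
    if (!is.null(memo[[id]])) return(memo[[id]])
    row <- ped[ped$animal == id, ]
    d <- if (row$sire == "0" && row$dam == "0") 0L else
      1L + max(depth(ped, row$sire, memo), depth(ped, row$dam, memo))
    memo[[id]] <- d
    d
  }
  last <- p1$animal[p1$generation == 5]
  expect_equal(mean(sapply(last, function(id) depth(p1, id))), 5)
})

test_that("gene dropping obeys Mendelian constraints and founder frequencies", {
  ds <- small_sim(seed = 2, n_otus = 0, n_snps = 100)
  M <- ds$genotypes$allele_counts
  ped <- ds$pedigree
  offs <- ped[ped$sire != "0", ]
  for (i in sample(nrow(offs), 20)) {
    gs <- M[offs$sire[i], ]; gd <- M[offs$dam[i], ]; gc <- M[offs$animal[i], ]
    expect_true(all(gc[gs == 0 & gd == 0] == 0))   # (0,0) -> always 0
    expect_true(all(gc[gs == 2 & gd == 2] == 2))   # fixation is absorbing
    expect_true(all(gc >= (gs == 2) + (gd == 2)))
    expect_true(all(gc <= 2 - (gs == 0) - (gd == 0)))
  }

  # realized founder frequency tracks the drawn p (binomial tolerance)
  cfg <- sim_config(seed = 3, n_founders = 200, n_generations = 1,
                    cohort_size = 5, n_snps = 10000, n_otus = 0)
  ped2 <- simulate_pedigree(cfg)
  gs2 <- simulate_genotypes(ped2, cfg)
  founders <- ped2$animal[ped2$generation == 0]
  p_hat <- colMeans(gs2$allele_counts[founders, ]) / 2
  p_drawn <- attr(gs2, "founder_p")
  expect_lt(mean(abs(p_hat - p_drawn)), 0.02)
  # map positions ascend within chromosome
  expect_true(all(tapply(gs2$snp_map$pos_bp, gs2$snp_map$chrom,
                         function(x) !is.unsorted(x))))
})

test_that("latent traits realize the configured variance partition", {
  # h2 = 0: no genetic variance at all
  cfg0 <- sim_config(seed = 4, n_founders = 20, n_generations = 2,
                     cohort_size = 40, n_otus = 5, otu_h2 = 0, n_snps = 10,
                     trait_specs = data.frame(name = "T1", h2 = 0, mean = 0, sd = 1))
  ds0 <- simulate_dataset(cfg0, genotypes = FALSE)
  expect_equal(max(abs(ds0$truth$breeding_values)), 0)

  # h2 = 0.3 recovered as Var(BV)/(Var(BV) + Var(E)) over replicates
  ratios <- sapply(1:20, function(s) {
    cfg <- sim_config(seed = 100 + s, n_founders = 100, n_generations = 2,
                      cohort_size = 250, n_otus = 0, n_snps = 10,
                      trait_specs = data.frame(name = "T1", h2 = 0.3,
                                               mean = 0, sd = 1),
                      phenotyped = "all_nonfounders")
    ds <- simulate_dataset(cfg, genotypes = FALSE)
    ds$truth$realized_h2["T1"]
  })
  expect_lt(abs(mean(ratios) - 0.30), 0.03)
})

test_that("a planted QTL is recovered by regression on its allele count", {
  cfg <- sim_config(seed = 5, n_founders = 100, n_generations = 2,
                    cohort_size = 400, n_snps = 300, n_otus = 0,
                    trait_specs = data.frame(name = "T1", h2 = 0.5, mean = 0, sd = 1),
                    qtl_list = data.frame(chrom = 3, pos_bp = 5e7,
                                          target = "T1", var_fraction = 0.10),
                    phenotyped = "last_generation")
  ds <- simulate_dataset(cfg)
  q <- ds$truth$qtl
  g <- ds$genotypes$allele_counts[ds$phenotypes$animal, q$snp_id]
  fit <- summary(lm(ds$phenotypes$T1 ~ g))$coefficients
  expect_lt(abs(fit["g", "Estimate"] - q$beta), 2 * fit["g", "Std. Error"])
  # realized QTL variance share close to requested
  expect_lt(abs(2 * q$p * (1 - q$p) * q$beta^2 / (0.5 * 1) - 0.10), 0.02)
})

test_that("OTU count rendering hits depth, sparsity and determinism contracts", {
  ds <- small_sim(seed = 6, cohort_size = 100, n_otus = 300)
  counts <- ds$otu_counts$counts
  expect_equal(unname(rowSums(counts)), attr(ds$otu_counts, "depths"))
  expect_lt(abs(mean(counts == 0) - 0.375), 0.05)
  ds2 <- small_sim(seed = 6, cohort_size = 100, n_otus = 300)
  expect_identical(counts, ds2$otu_counts$counts)

  # equal latent values at huge depth: near-equal counts per OTU
  cfg <- sim_config(seed = 7, n_otus = 10, target_zero_fraction = 0,
                    depth_range = c(2e6, 2e6), n_snps = 10)
  lat <- matrix(0, 5, 10, dimnames = list(paste0("s", 1:5), NULL))
  tab <- render_otu_counts(lat, cfg)
  expect_lt(max(abs(tab$counts / 2e5 - 1)), 0.02)
  expect_error(render_otu_counts(lat,
                 sim_config(seed = 1, depth_range = c(-5, 10), n_snps = 10)),
               "positive")
})

test_that("taxonomy generation covers all OTU with a Prevotella-dominated pool", {
  tax <- simulate_taxonomy(sprintf("OTU%04d", 1:500), seed = 1)
  expect_equal(nrow(tax), 500)
  expect_true(all(c("phylum", "family", "genus") %in% names(tax)))
  frac_prev <- mean(tax$genus == "Prevotella")
  expect_gt(frac_prev, 0.15); expect_lt(frac_prev, 0.30)
})
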