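# shared small all-genotyped instance
make_gblup_instance <- function(n = 80, m = 250, sg2 = 0.4, se2 = 0.6,
                                seed = 31) {
  set.seed(seed)
  M <- matrix(rbinom(n * m, 2, rep(runif(m, 0.1, 0.5), each = n)), n, m,
              byrow = FALSE)
  M <- matrix(as.integer(M), n, m,
              dimnames = list(sprintf("id%03d", 1:n), sprintf("s%04d", 1:m)))
  p <- colMeans(M) / 2
  keep <- p > 0 & p < 1
  M <- M[, keep]; p <- p[keep]
  Z <- sweep(M, 2, 2 * p, "-")
  sumpq <- sum(p * (1 - p))
  G <- tcrossprod(Z) / (2 * sumpq)
  dimnames(G) <- list(rownames(M), rownames(M))
  beta <- rnorm(ncol(Z), 0, sqrt(sg2 / (2 * sumpq)))
  y <- drop(1.5 + Z %*% beta + rnorm(n, 0, sqrt(se2)))
  list(M = M, Z = Z, p = p, sumpq = sumpq, G = G, y = y,
       X = matrix(1, n, 1), ids = rownames(M), sg2 = sg2, se2 = se2)
}

test_that("ssGBLUP collapses to pedigree BLUP when H = A and shrinks to zero", {
  ds <- small_sim(seed = 32, n_otus = 0, n_snps = 20, n_founders = 20,
                  cohort_size = 50)
  A <- build_A(ds$pedigree)
  fr <- build_model_frame(ds$phenotypes, "MilkYield", fixed_effects = "year",
                          ped = ds$pedigree)
  fit <- fit_ssgblup(fr$Y[, 1], fr$X[[1]], fr$ids, A, 2e4, 3e5)
  mm <- solve_mme(fr, A, P = matrix(2e4), R = matrix(3e5))
  expect_lt(max(abs(fit$g_hat[rownames(A)] - mm$u[rownames(A), 1])), 1e-8)
  expect_lt(max(abs(fit$b - mm$b)), 1e-8)

  fit0 <- fit_ssgblup(fr$Y[, 1], fr$X[[1]], fr$ids, A, 1e-8, 3e5)
  expect_lt(max(abs(fit0$g_hat)), 1e-4)

  # PEV never exceeds the prior variance
  expect_true(all(diag(fit$C_u2u2) <= diag(A) * 2e4 + 1e-6))
  expect_true(all(diag(fit$C_u2u2) >= -1e-8))
})

test_that("back-solved effects satisfy the GBLUP/SNP-BLUP projection identities", {
  gi <- make_gblup_instance()
  fit <- fit_ssgblup(gi$y, gi$X, gi$ids, gi$G, gi$sg2, gi$se2)
  a_hat <- backsolve_snp_effects(fit$g2_hat, gi$Z, gi$G, gi$sumpq)
  expect_lt(max(abs(gi$Z %*% a_hat - fit$g2_hat)), 1e-8)
  # direct ridge SNP-BLUP with lambda = sigma_e2 * 2 sum(pq) / sigma_g2
  lam <- gi$se2 * 2 * gi$sumpq / gi$sg2
  a_ridge <- solve(crossprod(gi$Z) + diag(lam, ncol(gi$Z)),
                   crossprod(gi$Z, gi$y - fit$b[1]))
  expect_lt(max(abs(a_hat - a_ridge)), 1e-6)
  expect_equal(unname(backsolve_snp_effects(rep(0, length(gi$ids)), gi$Z,
                                            gi$G, gi$sumpq)),
               rep(0, ncol(gi$Z)))
})

test_that("SNP sampling variances collapse and flag degenerate cases", {
  gi <- make_gblup_instance(n = 40, m = 60)
  # no information: C = G sigma_g2 -> all variances zero
  s0 <- snp_sampling_sd(gi$Z, gi$G, gi$G * gi$sg2, gi$sg2, gi$sumpq)
  expect_lt(max(s0$sd), 1e-8)
  expect_true(all(!s0$testable))
  # a zero centered column is untestable
  Z2 <- cbind(gi$Z, null_snp = 0)
  fit <- fit_ssgblup(gi$y, gi$X, gi$ids, gi$G, gi$sg2, gi$se2)
  s1 <- snp_sampling_sd(Z2, gi$G, fit$C_u2u2, gi$sg2, gi$sumpq)
  expect_false(s1$testable[s1$snp_id == "null_snp"])
})

test_that("p-values follow the two-sided normal formula", {
  expect_equal(snp_pvalues(0, 1), 1)
  expect_equal(snp_pvalues(1.959964, 1), 0.05, tolerance = 1e-6)
  a <- c(-0.3, 0, 0.7, 2); s <- c(0.1, 1, 0.5, 1)
  expect_equal(snp_pvalues(a, s),
               vapply(1:4, function(i) snp_pvalues(a[i], s[i]), 1))
  expect_true(is.na(snp_pvalues(1, 0)))
})

test_that("BH adjustment matches hand enumeration and dominates p", {
  expect_equal(fdr_adjust(rep(0.07, 6))$q, rep(0.07, 6))
  out <- fdr_adjust(c(0.01, 0.02, 0.03, 0.8))
  expect_equal(out$q, c(0.04, 0.04, 0.04, 0.8))
  set.seed(33)
  p <- runif(200)^2
  expect_true(all(fdr_adjust(p)$q >= p))
  expect_error(fdr_adjust(c(0.5, 1.2)), "lie in")
})

test_that("QTL grouping follows the lead/distance/peak-fraction rule", {
  empty <- group_qtl_regions(data.frame(snp_id = "s1", chrom = 1,
                                        pos_bp = 1e6, p = 0.5,
                                        significant = FALSE))
  expect_equal(nrow(empty), 0L)

  tab <- data.frame(
    snp_id = c("lead", "near_in", "near_out", "far"),
    chrom = 1,
    pos_bp = c(10e6, 10.5e6, 10.8e6, 30e6),
    p = 10^(-c(6, 5, 3.5, 5.5)),
    significant = c(TRUE, TRUE, FALSE, TRUE))
  reg <- group_qtl_regions(tab, distance_limit = 1e6)
  expect_equal(nrow(reg), 2L)
  expect_equal(reg$lead_snp, c("lead", "far"))     # ordered by lead logp
  expect_setequal(strsplit(reg$snp_ids[1], ",")[[1]], c("lead", "near_in"))
  expect_equal(reg$snp_ids[2], "far")
  # singleton region
  one <- group_qtl_regions(tab[4, ])
  expect_equal(one$lead_snp, "far")
  expect_equal(one$n_snps, 1L)
})

test_that("LD r2 matches squared correlation and its invariances", {
  set.seed(34)
  g <- rbinom(5000, 2, 0.3)
  expect_equal(ld_r2(g, g), 1)
  expect_equal(ld_r2(g, 2 - g), 1)
  g2 <- rbinom(5000, 2, 0.4)
  expect_lt(ld_r2(g, g2), 0.01)
  expect_error(ld_r2(g, rep(1, 5000)), "monomorphic")
})

test_that("window variance reproduces the single-locus formula", {
  gi <- make_gblup_instance(n = 600, m = 60, seed = 35)
  map <- data.frame(chrom = rep(1:2, each = 30), pos_bp = rep(1:30 * 1e6, 2))
  eff <- setNames(rep(0, ncol(gi$Z)), colnames(gi$Z))
  expect_equal(window_variance_explained(eff, gi$Z, map, 1),
               rep(0, ncol(gi$Z)))
  # single causal SNP: window % = Var(z * a) / sigma_p2 * 100 ~ 2pq a^2
  j <- 15; a <- 0.5
  eff[j] <- a
  wv <- window_variance_explained(eff, gi$Z, map, sigma_p2 = 1, window = 20)
  expected <- 100 * 2 * gi$p[j] * (1 - gi$p[j]) * a^2
  expect_lt(abs(wv[j] - expected) / expected, 0.15)
  # region variance >= max member window variance (orthogonal extra signal)
  reg <- data.frame(snp_ids = paste(colnames(gi$Z)[c(14, 15, 16)], collapse = ","))
  rv <- region_variance_explained(reg, eff, gi$Z, map, sigma_p2 = 1)
  expect_gte(rv, max(wv[14:16]) - 1e-8)
})

test_that("allele substitution recovers a planted effect and flags degeneracies", {
  set.seed(36)
  n <- 300
  ids <- sprintf("a%03d", 1:n)
  A <- diag(n); dimnames(A) <- list(ids, ids)
  snp <- rbinom(n, 2, 0.35)
  y <- 0.5 * snp + rnorm(n)
  X <- matrix(1, n, 1)
  est <- allele_substitution(y, snp, X, ids, A, sigma_g2 = 0.3, sigma_e2 = 0.7)
  expect_lt(abs(est$estimate - 0.5), 2 * est$se)
  est_flip <- allele_substitution(y, 2 - snp, X, ids, A, 0.3, 0.7)
  expect_equal(est_flip$estimate, -est$estimate, tolerance = 1e-10)
  expect_error(allele_substitution(y, rep(2, n), X, ids, A), "monomorphic")
  expect_error(allele_substitution(y, snp, cbind(X, snp), ids, A), "aliased")
})
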