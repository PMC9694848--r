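test_that("model frames code factors, check ranks and police the DIM range", {
  dat <- data.frame(animal = sprintf("a%02d", 1:30),
                    year = factor(rep(1:3, 10)),
                    dup = factor(rep(1:3, 10)),
                    dim = seq(30, 120, length.out = 30),
                    y = rnorm(30))
  fr <- build_model_frame(dat, "y", fixed_effects = "year")
  expect_equal(ncol(fr$X$y), 4L)           # intercept + 2 dummies + dim
  fr2 <- build_model_frame(dat, "y", fixed_effects = "year", covariates = NULL)
  expect_equal(ncol(fr2$X$y), 3L)
  expect_error(build_model_frame(dat, "y", fixed_effects = c("year", "dup")),
               "aliased")
  dat$dim[1] <- 200
  expect_warning(build_model_frame(dat, "y", fixed_effects = "year"),
                 "DIM")
  dat$animal[1] <- "stranger"
  expect_error(suppressWarnings(
    build_model_frame(dat, "y", fixed_effects = "year",
                      ped = pedigree(sprintf("a%02d", 1:30), rep(0, 30), rep(0, 30)))),
    "stranger")
})

test_that("MME solutions satisfy the equations, the ridge identity and the GLS limit", {
  set.seed(10)
  n <- 40
  dat <- data.frame(animal = sprintf("a%02d", 1:n),
                    year = factor(rep(1:4, n / 4)), y = rnorm(n))
  fr <- build_model_frame(dat, "y", fixed_effects = "year", covariates = NULL)
  K <- diag(n); dimnames(K) <- list(fr$ids, fr$ids)
  mm <- solve_mme(fr, K, P = matrix(0.5), R = matrix(1))
  expect_lt(mm$residual_norm, 1e-8)
  # ridge oracle with penalty sigma_e2 / sigma_g2 = 2
  X <- fr$X$y; y <- fr$Y[, 1]
  Cfull <- rbind(cbind(crossprod(X), t(X)), cbind(X, diag(n) * 3))
  sol <- solve(Cfull, c(crossprod(X, y), y))
  expect_lt(max(abs(mm$u[fr$ids, 1] - sol[-(1:ncol(X))])), 1e-10)

  # vanishing genetic variance: fixed effects -> GLS (here OLS) estimates
  mm0 <- solve_mme(fr, K, P = matrix(1e-10), R = matrix(1))
  expect_lt(max(abs(mm0$b - qr.solve(X, y))), 1e-5)
  expect_lt(max(abs(mm0$u)), 1e-8)
})

test_that("EM-REML increases the likelihood monotonically and matches a dense oracle", {
  ds <- small_sim(seed = 11, n_otus = 0, n_snps = 10, n_founders = 20,
                  cohort_size = 50, phenotyped = "all_nonfounders")
  fr <- build_model_frame(ds$phenotypes, c("LSCS", "CVmilk"),
                          fixed_effects = "year", ped = ds$pedigree)
  A <- build_A(ds$pedigree)
  em <- reml_em(fr, A, n_rounds = 40)
  path <- attr(em, "loglik_path")
  expect_false(is.unsorted(path))
  expect_false(em$converged)
  expect_equal(em$n_iterations, 40L)
  # symmetric PSD at the end
  expect_gt(min(eigen(em$P, only.values = TRUE)$values), -1e-10)
  expect_gt(min(eigen(em$R, only.values = TRUE)$values), -1e-10)
  # package likelihood equals the dense-matrix REML formula
  ll_pkg <- reml_loglik(fr, A, em$P, em$R)
  ll_ora <- oracle_reml_loglik(fr, A, em$P, em$R)
  expect_equal(ll_pkg, ll_ora, tolerance = 1e-8)
})

test_that("AI-REML refines the EM start and is invariant to record order", {
  ds <- small_sim(seed = 12, n_otus = 0, n_snps = 10, n_founders = 30,
                  cohort_size = 80, phenotyped = "all_nonfounders")
  fr <- build_model_frame(ds$phenotypes, c("LSCS", "CVmilk"),
                          fixed_effects = "year", ped = ds$pedigree)
  A <- build_A(ds$pedigree)
  em <- reml_em(fr, A, n_rounds = 30)
  vc <- reml_ai(fr, A, warm_start = em, tol = 1e-10)
  expect_true(vc$converged)
  expect_gte(vc$loglik, em$loglik - 1e-8)
  expect_true(all(vc$se >= 0))

  perm <- sample(nrow(ds$phenotypes))
  fr_p <- build_model_frame(ds$phenotypes[perm, ], c("LSCS", "CVmilk"),
                            fixed_effects = "year", ped = ds$pedigree)
  vc_p <- reml_ai(fr_p, A, tol = 1e-10)
  expect_equal(vc$P, vc_p$P, tolerance = 1e-6)
  expect_equal(vc$R, vc_p$R, tolerance = 1e-6)
})

test_that("a fully confounded single-trait model is reported unidentifiable", {
  set.seed(13)
  n <- 60
  dat <- data.frame(animal = sprintf("a%02d", 1:n), y = rnorm(n))
  fr <- build_model_frame(dat, "y", covariates = NULL)
  K <- diag(n); dimnames(K) <- list(fr$ids, fr$ids)
  vc <- reml_ai(fr, K, em_rounds = 10, max_iter = 20)
  expect_false(vc$converged)
  expect_match(vc$note, "unidentifiable")
})

test_that("AI-REML matches closed-form ANOVA-REML on a balanced half-sib design", {
  hs <- half_sib_data(s = 40, m = 20, h2 = 0.4, seed = 14)
  fr <- build_model_frame(hs$data, "y", covariates = NULL, ped = hs$ped)
  A <- build_A(hs$ped)
  vc <- reml_ai(fr, A, em_rounds = 50, max_iter = 200, tol = 1e-12)
  expect_true(vc$converged)
  # one-way ANOVA on sire families; REML = ANOVA for balanced designs
  sire <- rep(seq_len(hs$s), each = hs$m)
  ybar <- tapply(hs$data$y, sire, mean)
  MSB <- hs$m * sum((ybar - mean(hs$data$y))^2) / (hs$s - 1)
  MSW <- sum((hs$data$y - ybar[sire])^2) / (hs$s * (hs$m - 1))
  sigma_b <- (MSB - MSW) / hs$m
  sg2_anova <- 4 * sigma_b            # a(i,j) = 1/4 within paternal half sibs
  se2_anova <- MSW - 3 * sigma_b
  expect_equal(vc$P[1, 1], sg2_anova, tolerance = 1e-4)
  expect_equal(vc$R[1, 1], se2_anova, tolerance = 1e-4)
})

test_that("heritability and genetic correlation follow their definitions", {
  vc <- structure(list(P = diag(c(1, 2)), R = diag(c(1, 2)),
                       cov_params = NULL, traits = c("t1", "t2")),
                  class = "variance_components")
  expect_equal(heritability(vc, 1)$h2, 0.5)
  expect_equal(genetic_correlation(vc, 1, 2)$rg, 0)
  vc$P <- tcrossprod(c(1, 2))          # rank-1, positive loadings
  expect_equal(genetic_correlation(vc, 1, 2)$rg, 1)
  vc$P <- diag(c(0, 1))
  expect_error(genetic_correlation(vc, 1, 2), "zero genetic variance")
  expect_equal(heritability(vc, 1)$h2, 0)
})

test_that("delta-method SE of h2 agrees with a parametric bootstrap", {
  ds <- small_sim(seed = 15, n_otus = 0, n_snps = 10, n_founders = 60,
                  cohort_size = 150, phenotyped = "all_nonfounders",
                  trait_specs = data.frame(name = "T1", h2 = 0.35,
                                           mean = 0, sd = 1))
  fr <- build_model_frame(ds$phenotypes, "T1", fixed_effects = "year",
                          ped = ds$pedigree)
  A <- build_A(ds$pedigree)
  vc <- reml_ai(fr, A, em_rounds = 40, tol = 1e-10)
  h <- heritability(vc, 1)
  K <- unclass(A)[fr$ids, fr$ids]
  L <- t(chol(vc$P[1, 1] * K + vc$R[1, 1] * diag(nrow(K))))
  mu <- fr$X[[1]] %*% qr.solve(fr$X[[1]], fr$Y[, 1])
  su <- rumenQG:::.reml_setup(fr, A)
  set.seed(15)
  boot <- replicate(200, {
    su$Ystar[, 1] <- crossprod(su$U, mu + L %*% rnorm(nrow(K)))
    f <- rumenQG:::.reml_fit_rotated(su, em_rounds = 25, max_iter = 40)
    f$P[1, 1] / (f$P[1, 1] + f$R[1, 1])
  })
  expect_lt(abs(sd(boot) - h$se) / h$se, 0.25)
})

test_that("modelling the selection trait jointly reduces bias in h2 of a correlated trait", {
  C <- diag(3); C[1, 3] <- C[3, 1] <- 0.8
  dimnames(C) <- list(c("T1", "T2", "T3"), c("T1", "T2", "T3"))
  h2_hat <- sapply(1:20, function(s) {
    cfg <- sim_config(seed = 300 + s, n_founders = 60, n_generations = 3,
                      cohort_size = 120, n_otus = 0, n_snps = 10,
                      trait_specs = data.frame(name = c("T1", "T2", "T3"),
                                               h2 = c(0.6, 0.3, 0.3),
                                               mean = 0, sd = 1),
                      genetic_correlations = C, phenotyped = "all",
                      selection = "truncation", selected_fraction = 0.2)
    ds <- simulate_dataset(cfg, genotypes = FALSE)
    A <- build_A(ds$pedigree)
    fr1 <- build_model_frame(ds$phenotypes, "T3", fixed_effects = "year",
                             ped = ds$pedigree)
    v1 <- reml_ai(fr1, A, em_rounds = 25, max_iter = 40, tol = 1e-8)
    fr3 <- build_model_frame(ds$phenotypes, c("T1", "T2", "T3"),
                             fixed_effects = "year", ped = ds$pedigree)
    v3 <- reml_ai(fr3, A, em_rounds = 25, max_iter = 40, tol = 1e-8)
    c(alone = heritability(v1, 1)$h2, joint = heritability(v3, "T3")$h2)
  })
  bias_alone <- mean(h2_hat["alone", ]) - 0.3
  bias_joint <- mean(h2_hat["joint", ]) - 0.3
  expect_lte(abs(bias_joint), abs(bias_alone))
})

test_that("the rg task grid emits one row per OTU x trait pair", {
  tasks <- build_rg_tasks(c("OTU1", "OTU2", "OTU3"), c("fat", "protein"))
  expect_equal(nrow(tasks), 6L)
  expect_equal(anyDuplicated(tasks), 0L)
  expect_equal(nrow(build_rg_tasks(character(0), "fat")), 0L)
})

test_that("fixed-effect screening flags effects that act on enough responses", {
  set.seed(77)
  n <- 120
  dat <- data.frame(year = factor(rep(1:4, n / 4)),
                    noisefac = factor(sample(1:3, n, replace = TRUE)))
  yr_eff <- c(-1, 0, 1, 2)[as.integer(dat$year)]
  Y <- cbind(sapply(1:15, function(j) yr_eff + rnorm(n)),   # year matters
             sapply(1:5, function(j) rnorm(n)))             # pure noise
  colnames(Y) <- sprintf("r%02d", 1:20)
  sc <- screen_fixed_effects(dat, Y, c("year", "noisefac"))
  expect_true(sc$summary$include[sc$summary$effect == "year"])
  expect_gt(sc$summary$fraction_significant[1], 0.5)
  expect_lt(sc$summary$fraction_significant[2], 0.3)
  # oracle: one response's p-value from a direct anova
  p_direct <- anova(lm(Y[, 1] ~ year + noisefac, data = dat))["year", "Pr(>F)"]
  expect_equal(unname(sc$per_response["r01", "year"]), p_direct)
})
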