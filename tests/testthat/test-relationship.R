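test_that("A matrix reproduces textbook relationships and inbreeding", {
  ped0 <- pedigree(animal = letters[1:4], sire = rep(0, 4), dam = rep(0, 4))
  expect_equal(unclass(build_A(ped0))[, ], diag(4), ignore_attr = TRUE)

  ped <- toy_pedigree()
  A <- build_A(ped)
  expect_equal(A["f1", "o1"], 0.5)       # sire-offspring
  expect_equal(A["o1", "o2"], 0.5)       # full sibs, non-inbred parents
  expect_equal(A["o1", "o3"], 0)         # unrelated families
  expect_equal(A["x1", "x1"], 1.25)      # full-sib mating: F = 0.25
  expect_lt(max(abs(A - t(A))), 1e-12)
  expect_true(all(diag(A) >= 1 & diag(A) <= 2))
})

test_that("A matrix matches Monte-Carlo gene-dropping IBD on a 3-generation pedigree", {
  ped <- pedigree(
    animal = c("a", "b", "c", "d", "e", "f", "g", "h", "i", "j", "k", "l"),
    sire   = c(0, 0, 0, 0, "a", "a", "c", "c", "e", "e", "g", "i"),
    dam    = c(0, 0, 0, 0, "b", "b", "d", "d", "f", "h", "h", "j"))
  A <- build_A(ped)
  set.seed(99)
  A_mc <- oracle_gene_drop_A(ped, n_loci = 60000L)
  expect_lt(max(abs(A - A_mc[rownames(A), colnames(A)])), 0.02)
})

test_that("A construction is invariant to founder ordering", {
  ped1 <- toy_pedigree()
  perm <- c("f4", "f2", "f1", "f3")
  ped2 <- pedigree(animal = c(perm, "o1", "o2", "o3", "o4", "x1"),
                   sire = c(rep(0, 4), "f1", "f1", "f3", "f3", "o1"),
                   dam = c(rep(0, 4), "f2", "f2", "f4", "f4", "o2"))
  A1 <- build_A(ped1); A2 <- build_A(ped2)
  ids <- rownames(A1)
  expect_equal(unclass(A1)[ids, ids], unclass(A2)[ids, ids], tolerance = 1e-12)
})

test_that("partition blocks reassemble A exactly and permute consistently", {
  ds <- small_sim(seed = 4, n_otus = 0, n_snps = 20)
  A <- build_A(ds$pedigree)
  gids <- sample(ds$pedigree$animal, 20)
  bl <- partition_A(A, gids)
  re <- rbind(cbind(bl$A11, bl$A12), cbind(bl$A21, bl$A22))
  ids <- c(bl$ids1, bl$ids2)
  expect_identical(re, unclass(A)[ids, ids])
  # permuting the genotyped id list must not change the blocks
  bl2 <- partition_A(A, rev(gids))
  expect_identical(bl$A22, bl2$A22)
  expect_identical(unclass(extract_A22(A, gids))[, ], bl$A22)
  # all genotyped: A22 = A
  expect_equal(unclass(extract_A22(A, ds$pedigree$animal))[, ],
               unclass(A)[, ], ignore_attr = TRUE)
  expect_error(partition_A(A, "nobody"), "not in A")
})

test_that("VanRaden G matches single-SNP arithmetic and a dense oracle", {
  M1 <- matrix(c(0, 1, 2), 3, 1, dimnames = list(c("i1", "i2", "i3"), "s1"))
  G1 <- compute_G_raw(M1)
  expect_equal(diag(G1), c(i1 = 2, i2 = 0, i3 = 2))
  expect_equal(G1["i1", "i3"], -2)

  set.seed(5)
  M <- matrix(rbinom(50 * 500, 2, 0.3), 50, 500,
              dimnames = list(sprintf("i%02d", 1:50), sprintf("s%03d", 1:500)))
  G <- compute_G_raw(M)
  p <- colMeans(M) / 2
  Zo <- M - matrix(2 * p, 50, 500, byrow = TRUE)
  Go <- (Zo %*% t(Zo)) / (2 * sum(p * (1 - p)))
  expect_lt(max(abs(unclass(G)[, ] - Go)), 1e-10)

  # duplicated individuals are genomically identical
  Md <- rbind(M, dup = M[1, ])
  Gd <- compute_G_raw(Md)
  expect_equal(Gd["dup", "i01"], Gd["dup", "dup"])
  expect_equal(Gd["i01", "i01"], Gd["dup", "dup"])

  Mm <- M; Mm[, 1] <- 2
  expect_error(compute_G_raw(Mm), "monomorphic")
})

test_that("G blending solves the two-moment system and keeps G_blended PD", {
  ds <- small_sim(seed = 6, n_otus = 0, n_snps = 300)
  A <- build_A(ds$pedigree)
  gids <- ds$pedigree$animal[ds$pedigree$generation == 2]
  bl <- partition_A(A, gids)
  gset <- ds$genotypes
  M <- gset$allele_counts[bl$ids2, ]
  M <- M[, apply(M, 2, sd) > 0]          # QC: drop SNPs fixed by drift
  G_raw <- compute_G_raw(M)
  G <- blend_G(G_raw, bl$A22, alpha = 0.05)
  # independent 2x2 solve
  off <- upper.tri(G_raw)
  ab <- solve(matrix(c(1, 1, mean(diag(G_raw)), mean(G_raw[off])), 2),
              c(mean(diag(bl$A22)), mean(bl$A22[off])))
  tuned <- ab[1] + ab[2] * unclass(G_raw)[, ]
  expect_equal(mean(diag(tuned)), mean(diag(bl$A22)))
  expect_equal(unclass(G)[, ], 0.95 * tuned + 0.05 * bl$A22, tolerance = 1e-10)
  expect_equal(attr(G, "a"), ab[1], tolerance = 1e-10)
  expect_equal(attr(G, "b"), ab[2], tolerance = 1e-10)
  expect_gt(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values), 0)

  # fixed point: G_raw already matching both moments -> a = 0, b = 1
  Gfix <- blend_G(bl$A22, bl$A22, alpha = 0.05)
  expect_equal(attr(Gfix, "a"), 0, tolerance = 1e-10)
  expect_equal(attr(Gfix, "b"), 1, tolerance = 1e-10)
  expect_equal(unclass(Gfix)[, ], bl$A22, tolerance = 1e-10)
  # alpha = 0 with A22 = G_raw returns G_raw exactly
  G0 <- blend_G(G_raw, G_raw, alpha = 0)
  expect_equal(unclass(G0)[, ], unclass(G_raw)[, ], tolerance = 1e-10)
  expect_error(blend_G(matrix(1, 5, 5), diag(5)), "singular")
})

test_that("H collapses to A when G = A22 and satisfies the inverse identity", {
  ds <- small_sim(seed = 7, n_otus = 0, n_snps = 50, n_founders = 10,
                  cohort_size = 10)
  A <- build_A(ds$pedigree)
  gids <- utils::tail(ds$pedigree$animal, 10)
  bl <- partition_A(A, gids)
  H0 <- build_H(bl, bl$A22)
  ids <- rownames(A)
  expect_lt(max(abs(unclass(H0)[ids, ids] - unclass(A)[ids, ids])), 1e-10)

  Mg <- ds$genotypes$allele_counts[gids, ]
  Mg <- Mg[, apply(Mg, 2, sd) > 0]       # QC: drop SNPs fixed by drift
  G <- unclass(blend_G(compute_G_raw(Mg), bl$A22, alpha = 0.05))[, ]
  H <- build_H(bl, G)
  expect_lt(max(abs(unclass(H) - t(unclass(H)))), 1e-10)
  expect_equal(unclass(H)[gids, gids], G, tolerance = 1e-12)
  # classical inverse identity
  Hinv <- solve(unclass(H)[ids, ids])
  corr <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  corr[gids, gids] <- solve(G) - solve(bl$A22)
  expect_lt(max(abs(Hinv - (solve(unclass(A)[ids, ids]) + corr))), 1e-8)

  # all animals genotyped: H = G
  bl_all <- partition_A(A, ds$pedigree$animal)
  Gall <- unclass(A)[, ]
  expect_equal(unclass(build_H(bl_all, Gall))[, ], Gall, ignore_attr = TRUE)
  expect_error(build_H(bl, diag(3)), "dimension")
})
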