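# Independent oracle implementations used to cross-check the package.
# Deliberately written as plain per-element loops, sharing no code with R/.

# Bayesian-multiplicative zero replacement (geometric prior) followed by
# CLR, one sample at a time.
oracle_gbm_clr <- function(counts, s = sqrt(ncol(counts)), t_prior = NULL) {
  D <- ncol(counts)
  if (is.null(t_prior)) {
    t_prior <- numeric(D)
    for (j in seq_len(D)) {
      pj <- counts[, j] / rowSums(counts)
      pj <- pj[pj > 0]
      t_prior[j] <- if (length(pj)) exp(mean(log(pj))) else NA
    }
    t_prior[is.na(t_prior)] <- min(t_prior, na.rm = TRUE)
    t_prior <- t_prior / sum(t_prior)
  }
  out <- matrix(NA_real_, nrow(counts), D)
  for (k in seq_len(nrow(counts))) {
    ck <- counts[k, ]; nk <- sum(ck)
    x <- numeric(D)
    zmass <- 0
    for (j in seq_len(D)) if (ck[j] == 0) zmass <- zmass + t_prior[j] * s / (nk + s)
    for (j in seq_len(D)) {
      x[j] <- if (ck[j] == 0) t_prior[j] * s / (nk + s)
              else (ck[j] / nk) * (1 - zmass)
    }
    gm <- exp(mean(log(x)))
    for (j in seq_len(D)) out[k, j] <- log(x[j] / gm)
  }
  out
}

# Two-sided Fisher exact p by explicit hypergeometric enumeration:
# sum of P(tables) with probability <= observed (with relative slack).
oracle_fisher_2sided <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Monte-Carlo gene dropping: estimate additive relationships by IBD sharing.
oracle_gene_drop_A <- function(ped, n_loci = 50000L) {
  idx <- setNames(seq_len(nrow(ped)), ped$animal)
  si <- ifelse(ped$sire == "0", 0L, idx[ped$sire])
  di <- ifelse(ped$dam == "0", 0L, idx[ped$dam])
  n <- nrow(ped)
  a1 <- matrix(0L, n, n_loci); a2 <- matrix(0L, n, n_loci)
  next_allele <- 1L
  for (i in seq_len(n)) {
    if (si[i] == 0L) { a1[i, ] <- next_allele; next_allele <- next_allele + 1L }
    else {
      pick <- runif(n_loci) < 0.5
      a1[i, ] <- ifelse(pick, a1[si[i], ], a2[si[i], ])
    }
    if (di[i] == 0L) { a2[i, ] <- next_allele; next_allele <- next_allele + 1L }
    else {
      pick <- runif(n_loci) < 0.5
      a2[i, ] <- ifelse(pick, a1[di[i], ], a2[di[i], ])
    }
  }
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) for (j in seq_len(i)) {
    if (i == j) {
      A[i, i] <- 1 + mean(a1[i, ] == a2[i, ])
    } else {
      kin <- (mean(a1[i, ] == a1[j, ]) + mean(a1[i, ] == a2[j, ]) +
                mean(a2[i, ] == a1[j, ]) + mean(a2[i, ] == a2[j, ])) / 4
      A[i, j] <- A[j, i] <- 2 * kin
    }
  }
  A
}

# Dense REML log-likelihood for the multi-trait animal model (trait-major).
oracle_reml_loglik <- function(frame, A, P, R) {
  K <- as.matrix(A)[frame$ids, frame$ids]
  n <- nrow(frame$Y); t_ <- length(frame$traits)
  V <- kronecker(as.matrix(P), K) + kronecker(as.matrix(R), diag(n))
  p_tot <- sum(vapply(frame$X, ncol, 1L))
  X <- matrix(0, n * t_, p_tot)
  col0 <- 0L
  for (a in seq_len(t_)) {
    X[(a - 1L) * n + seq_len(n), col0 + seq_len(ncol(frame$X[[a]]))] <- frame$X[[a]]
    col0 <- col0 + ncol(frame$X[[a]])
  }
  y <- as.vector(frame$Y)
  Vi <- solve(V)
  B <- t(X) %*% Vi %*% X
  beta <- solve(B, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  -0.5 * (as.numeric(determinant(V)$modulus) +
            as.numeric(determinant(B)$modulus) + sum(r * (Vi %*% r)))
}
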