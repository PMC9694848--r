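# Symmetric solve with Moore-Penrose fallback for PSD matrices that are
# singular by construction (e.g. an unblended G from centered allele counts).
.sym_solve <- function(M, B, tol = 1e-10) {
  out <- tryCatch(solve(M, B), error = function(e) NULL)
  if (!is.null(out) && rcond(M) > tol) return(out)
  eg <- eigen((M + t(M)) / 2, symmetric = TRUE)
  keep <- eg$values > tol * max(abs(eg$values))
  eg$vectors[, keep, drop = FALSE] %*%
    ((1 / eg$values[keep]) * crossprod(eg$vectors[, keep, drop = FALSE], B))
}

#' Fit a single-trait ssGBLUP animal model
#'
#' Solves `y = Xb + Wg + e` with `g ~ N(0, H sigma_g^2)` and
#' `e ~ N(0, I sigma_e^2)` for fixed effects, breeding values of every
#' animal in `H`, and the prediction-error covariance block of the
#' genotyped animals needed for back-solved SNP-effect variances.  The
#' system is solved in variance-matrix form (GLS on
#' `V = W H W' sigma_g^2 + I sigma_e^2`), which is algebraically identical
#' to Henderson's equations but also tolerates a singular `H` (as arises
#' with an unblended genomic matrix).
#'
#' @param y response vector (one record per row of `X`).
#' @param X fixed-effect design matrix.
#' @param ids animal id per record (must index rows of `H`).
#' @param H relationship matrix (A, G or H) with id dimnames.
#' @param sigma_g2,sigma_e2 genetic and residual variances (from the
#'   variance-component stage).
#' @param genotyped_ids ids forming the "2" (genotyped) block; default all
#'   animals in `H`.
#' @return list with `b`, `g_hat` (named, all animals of H), `g2_hat`
#'   (genotyped subset), `C_u2u2` (PEV block, genotyped animals),
#'   `sigma_g2`, `sigma_e2`.
#' @export
fit_ssgblup <- function(y, X, ids, H, sigma_g2, sigma_e2,
                        genotyped_ids = rownames(H)) {
  H <- as.matrix(H)
  n <- length(y)
  stopifnot(nrow(X) == n, length(ids) == n)
  all_ids <- rownames(H)
  miss <- setdiff(c(ids, genotyped_ids), all_ids)
  if (length(miss)) stop("ids missing from H: ", paste(utils::head(miss, 5), collapse = ", "))
  if (sigma_g2 < 0 || sigma_e2 <= 0) stop("variances must be positive")
  ri <- match(ids, all_ids)
  HW <- H[, ri, drop = FALSE]                 # q x n  (H W')
  V <- sigma_g2 * HW[ri, , drop = FALSE]
  diag(V) <- diag(V) + sigma_e2
  Vch <- tryCatch(chol(V), error = function(e) stop("singular phenotypic covariance"))
  Vinv_X <- backsolve(Vch, forwardsolve(t(Vch), X))
  Vinv_y <- backsolve(Vch, forwardsolve(t(Vch), y))
  XtVX <- crossprod(X, Vinv_X)
  b <- solve(XtVX, crossprod(X, Vinv_y))
  r <- y - X %*% b
  Vinv_r <- backsolve(Vch, forwardsolve(t(Vch), r))
  g_hat <- sigma_g2 * HW %*% Vinv_r
  # PEV = sigma_g2 H - Cov(g_hat): with Pv = Vinv - Vinv X (X'Vinv X)^-1 X'Vinv
  g2 <- match(genotyped_ids, all_ids)
  HW2 <- HW[g2, , drop = FALSE]               # rows: genotyped animals
  VinvHW2 <- backsolve(Vch, forwardsolve(t(Vch), t(HW2)))
  XtVinvHW2 <- crossprod(Vinv_X, t(HW2))      # p x n2
  covg <- sigma_g2^2 * (HW2 %*% VinvHW2 -
                          t(XtVinvHW2) %*% solve(XtVX, XtVinvHW2))
  C_u2u2 <- sigma_g2 * H[g2, g2, drop = FALSE] - covg
  C_u2u2 <- (C_u2u2 + t(C_u2u2)) / 2
  list(b = stats::setNames(drop(b), colnames(X)),
       g_hat = stats::setNames(drop(g_hat), all_ids),
       g2_hat = stats::setNames(drop(g_hat)[g2], all_ids[g2]),
       C_u2u2 = C_u2u2, sigma_g2 = sigma_g2, sigma_e2 = sigma_e2)
}

#' Back-solve SNP effects from genomic breeding values
#'
#' `a_hat = (1 - alpha) * b * Z' G^{-1} g2_hat / (2 sum p_i q_i)`, the
#' projection of the genotyped animals' breeding values onto SNP effects
#' under the genomic model that generated `G`.  `b` and `alpha` are the
#' blending constants of [blend_G()] (`b = 1`, `alpha = 0` for a raw G).
#'
#' @param g2_hat breeding values of the genotyped animals (named).
#' @param Z centered allele-count matrix (individuals x SNPs), same
#'   individual order as `g2_hat`.
#' @param G the genomic relationship used in `H` (blended or raw).
#' @param sumpq `sum p_i q_i` over the SNPs in `Z`.
#' @param b,alpha blending slope and A22 weight used to build `G`.
#' @return named vector of SNP effects.
#' @export
backsolve_snp_effects <- function(g2_hat, Z, G, sumpq, b = 1, alpha = 0) {
  Z <- as.matrix(Z)
  if (nrow(Z) != length(g2_hat)) stop("Z rows must match g2_hat")
  Ginv_g <- .sym_solve(as.matrix(G), cbind(as.numeric(g2_hat)))
  a_hat <- (1 - alpha) * b / (2 * sumpq) * crossprod(Z, Ginv_g)
  stats::setNames(drop(a_hat), colnames(Z))
}

#' Sampling standard deviations of back-solved SNP effects
#'
#' Per-SNP sampling variance
#' `Var(a_i) = k^2 (1-alpha)^2 b^2 z_i' G^{-1} (G sigma_g^2 - C_u2u2) G^{-1} z_i`
#' with `k = 1/(2 sum p_i q_i)`; computed variances below zero (possible
#' with a blended G) are floored at zero and flagged untestable, as are
#' SNPs with a zero centered column.
#'
#' @inheritParams backsolve_snp_effects
#' @param C_u2u2 prediction-error covariance of the genotyped animals'
#'   breeding values (from [fit_ssgblup()]).
#' @param sigma_g2 additive-genetic variance of the trait.
#' @return data.frame with `sd` and logical `testable` per SNP.
#' @export
snp_sampling_sd <- function(Z, G, C_u2u2, sigma_g2, sumpq, b = 1, alpha = 0) {
  Z <- as.matrix(Z); G <- as.matrix(G)
  if (!all(dim(C_u2u2) == dim(G))) stop("C_u2u2 and G are not conformable")
  k <- 1 / (2 * sumpq)
  M <- sigma_g2 * G - C_u2u2
  GinvZ <- .sym_solve(G, Z)
  quad <- colSums(GinvZ * (M %*% GinvZ))
  v <- k^2 * (1 - alpha)^2 * b^2 * quad
  flagged <- v < 0
  v[flagged] <- 0
  zero_col <- colSums(abs(Z)) == 0
  data.frame(snp_id = colnames(Z), sd = sqrt(v),
             testable = !flagged & !zero_col & sqrt(v) > 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-sided normal p-values for SNP effects
#'
#' `p_i = 2 (1 - Phi(|a_i / sd(a_i)|))`; SNPs with zero sampling SD are
#' returned as `NA` (skipped, flagged untestable upstream).
#'
#' @param a_hat SNP effects.
#' @param sd sampling standard deviations.
#' @return numeric vector of p-values.
#' @export
snp_pvalues <- function(a_hat, sd) {
  if (length(a_hat) != length(sd)) stop("length mismatch")
  p <- rep(NA_real_, length(a_hat))
  ok <- is.finite(sd) & sd > 0
  p[ok] <- 2 * stats::pnorm(-abs(a_hat[ok] / sd[ok]))
  p
}

#' Benjamini-Hochberg q-values with genome-wide and suggestive flags
#'
#' Step-up FDR adjustment applied within trait; flags at the q < 0.10
#' (significant) and q < 0.30 (suggestive) thresholds.
#'
#' @param p p-values (NAs allowed, excluded from the adjustment).
#' @param fdr_significant,fdr_suggestive flag thresholds.
#' @return data.frame with `q`, `significant`, `suggestive`.
#' @export
fdr_adjust <- function(p, fdr_significant = 0.10, fdr_suggestive = 0.30) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  data.frame(q = q,
             significant = !is.na(q) & q < fdr_significant,
             suggestive = !is.na(q) & q < fdr_suggestive)
}

#' Group significant SNPs into QTL regions
#'
#' Iteratively, per chromosome: the most significant remaining SNP becomes
#' a region lead; every remaining significant SNP within `distance_limit`
#' of the lead whose -log10(p) reaches the upper third of the peak (i.e. at
#' least `(1 - peak_fraction)` times the lead's -log10(p)) joins the
#' region; the members are removed and the rule repeats.  Singleton regions
#' are allowed.
#'
#' @param gwas_table data.frame with columns `snp_id`, `chrom`, `pos_bp`,
#'   `p`, `significant`.
#' @param distance_limit maximum distance (bp) of a member from its lead;
#'   default 1 Mbp.
#' @param peak_fraction fraction of the peak height defining membership
#'   (default 1/3: members need -log10 p >= 2/3 of the lead's).
#' @return data.frame with one row per region: `region_id`, `chrom`,
#'   `lead_snp`, `lead_pos_bp`, `lead_logp`, `start_bp`, `end_bp`,
#'   `n_snps`, `snp_ids` (comma-separated).
#' @export
group_qtl_regions <- function(gwas_table, distance_limit = 1e6,
                              peak_fraction = 1 / 3) {
  need <- c("snp_id", "chrom", "pos_bp", "p", "significant")
  stopifnot(all(need %in% names(gwas_table)))
  sig <- gwas_table[gwas_table$significant & !is.na(gwas_table$p), , drop = FALSE]
  if (!nrow(sig))
    return(data.frame(region_id = integer(0), chrom = integer(0),
                      lead_snp = character(0), lead_pos_bp = numeric(0),
                      lead_logp = numeric(0), start_bp = numeric(0),
                      end_bp = numeric(0), n_snps = integer(0),
                      snp_ids = character(0)))
  sig$logp <- -log10(pmax(sig$p, .Machine$double.xmin))
  regions <- list()
  for (ch in unique(sig$chrom)) {
    rem <- sig[sig$chrom == ch, , drop = FALSE]
    rem <- rem[order(rem$pos_bp), , drop = FALSE]
    while (nrow(rem)) {
      lead <- which.max(rem$logp)
      memb <- abs(rem$pos_bp - rem$pos_bp[lead]) <= distance_limit &
        rem$logp >= (1 - peak_fraction) * rem$logp[lead]
      mm <- rem[memb, , drop = FALSE]
      regions[[length(regions) + 1L]] <- data.frame(
        chrom = ch, lead_snp = rem$snp_id[lead],
        lead_pos_bp = rem$pos_bp[lead], lead_logp = rem$logp[lead],
        start_bp = min(mm$pos_bp), end_bp = max(mm$pos_bp),
        n_snps = nrow(mm), snp_ids = paste(mm$snp_id, collapse = ","),
        stringsAsFactors = FALSE)
      rem <- rem[!memb, , drop = FALSE]
    }
  }
  out <- do.call(rbind, regions)
  out <- out[order(-out$lead_logp), , drop = FALSE]
  out <- cbind(region_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Linkage disequilibrium between two SNPs
#'
#' Squared Pearson correlation of 0/1/2 allele counts.
#'
#' @param g_i,g_j genotype vectors (allele counts).
#' @return `r^2` scalar.
#' @export
ld_r2 <- function(g_i, g_j) {
  if (stats::sd(g_i) == 0 || stats::sd(g_j) == 0)
    stop("LD undefined for a monomorphic SNP")
  stats::cor(g_i, g_j)^2
}

#' Phenotypic variance explained by SNP windows
#'
#' For every SNP, the window of `window` adjacent SNPs on the same
#' chromosome centered on it (truncated at chromosome edges) defines a
#' genomic score `Z_w a_w`; the variance of that score across individuals,
#' as a percentage of the phenotypic variance, is the window variance
#' explained.
#'
#' @param effects named vector of back-solved SNP effects (map order).
#' @param Z centered allele-count matrix (individuals x SNPs, map order).
#' @param snp_map data.frame with `chrom` and `pos_bp` per SNP (map order).
#' @param sigma_p2 phenotypic variance of the trait.
#' @param window window size in SNPs (default 20).
#' @return numeric vector, percentage per SNP.
#' @export
window_variance_explained <- function(effects, Z, snp_map, sigma_p2,
                                      window = 20L) {
  if (window < 1L) stop("window must be >= 1")
  m <- length(effects)
  stopifnot(ncol(Z) == m, nrow(snp_map) == m)
  out <- numeric(m)
  half_lo <- floor((window - 1) / 2)
  half_hi <- window - 1L - half_lo
  for (ch in unique(snp_map$chrom)) {
    ix <- which(snp_map$chrom == ch)
    for (r in seq_along(ix)) {
      lo <- max(1L, r - half_lo); hi <- min(length(ix), r + half_hi)
      w <- ix[lo:hi]
      score <- Z[, w, drop = FALSE] %*% effects[w]
      out[ix[r]] <- 100 * stats::var(drop(score)) / sigma_p2
    }
  }
  out
}

#' Variance explained by a QTL region
#'
#' Variance (across individuals) of the genomic score over the union of the
#' region members' windows, as a percentage of phenotypic variance.
#'
#' @param region one row of the [group_qtl_regions()] output.
#' @inheritParams window_variance_explained
#' @return percentage scalar.
#' @export
region_variance_explained <- function(region, effects, Z, snp_map, sigma_p2,
                                      window = 20L) {
  members <- strsplit(region$snp_ids, ",")[[1]]
  ix_m <- match(members, names(effects))
  if (anyNA(ix_m)) stop("region member SNPs not found among effects")
  half_lo <- floor((window - 1) / 2)
  half_hi <- window - 1L - half_lo
  w_all <- integer(0)
  for (ix in ix_m) {
    ch_ix <- which(snp_map$chrom == snp_map$chrom[ix])
    r <- match(ix, ch_ix)
    lo <- max(1L, r - half_lo); hi <- min(length(ch_ix), r + half_hi)
    w_all <- union(w_all, ch_ix[lo:hi])
  }
  score <- Z[, sort(w_all), drop = FALSE] %*% effects[sort(w_all)]
  100 * stats::var(drop(score)) / sigma_p2
}

#' Allele substitution effect of a single SNP
#'
#' Fits `y = mu + SNP * beta + fixed effects + animal + e` with the SNP's
#' allele count (0/1/2) as a fixed covariate and a polygenic animal effect
#' with covariance proportional to `A`, by GLS on
#' `V = W A_pp W' sigma_g2 + I sigma_e2`.  With the default unit variances
#' this is the substitution-effect model in its standard form; supplying
#' estimated components generalises it.
#'
#' @param y response vector.
#' @param snp allele counts (0/1/2) aligned with `y`.
#' @param X fixed-effect design (including intercept).
#' @param ids animal ids per record.
#' @param A relationship matrix with id dimnames.
#' @param sigma_g2,sigma_e2 variance components (default 1, 1).
#' @return list with `estimate`, `se`, `z`, `p`, `sign`.
#' @export
allele_substitution <- function(y, snp, X, ids, A, sigma_g2 = 1, sigma_e2 = 1) {
  if (stats::sd(snp) == 0) stop("SNP is monomorphic in the phenotyped set")
  Xa <- cbind(snp = snp, X)
  if (qr(Xa)$rank < ncol(Xa))
    stop("SNP covariate is aliased with a fixed-effect column")
  K <- as.matrix(A)[ids, ids]
  V <- sigma_g2 * K
  diag(V) <- diag(V) + sigma_e2
  Vch <- chol(V)
  VinvX <- backsolve(Vch, forwardsolve(t(Vch), Xa))
  Vinvy <- backsolve(Vch, forwardsolve(t(Vch), y))
  XtVX <- crossprod(Xa, VinvX)
  bhat <- solve(XtVX, crossprod(Xa, Vinvy))
  covb <- solve(XtVX)
  est <- bhat[1L]; se <- sqrt(covb[1L, 1L])
  z <- est / se
  list(estimate = unname(est), se = unname(se), z = unname(z),
       p = 2 * stats::pnorm(-abs(z)), sign = sign(unname(est)))
}

#' Run a complete single-trait ssGBLUP GWAS
#'
#' Convenience wrapper: fits the ssGBLUP model, back-solves SNP effects,
#' computes sampling SDs, p- and q-values, window variances and QTL
#' regions.
#'
#' @inheritParams fit_ssgblup
#' @param genotypes [genotype_set] for the genotyped animals (rows must be
#'   named by animal id; all must appear in `H`).
#' @param G the blended genomic matrix used when `H` was built.
#' @param sigma_p2 phenotypic variance (default `sigma_g2 + sigma_e2`).
#' @param window,distance_limit,peak_fraction,fdr_significant,fdr_suggestive
#'   see the respective stage functions.
#' @return list with `gwas` (per-SNP table), `regions`, `fit`.
#' @export
run_gwas <- function(y, X, ids, H, genotypes, G, sigma_g2, sigma_e2,
                     sigma_p2 = sigma_g2 + sigma_e2, window = 20L,
                     distance_limit = 1e6, peak_fraction = 1 / 3,
                     fdr_significant = 0.10, fdr_suggestive = 0.30) {
  gids <- rownames(genotypes$allele_counts)
  fit <- fit_ssgblup(y, X, ids, H, sigma_g2, sigma_e2, genotyped_ids = gids)
  p_frq <- genotypes$allele_freqs
  Z <- sweep(genotypes$allele_counts, 2L, 2 * p_frq, "-")
  sumpq <- sum(p_frq * (1 - p_frq))
  bb <- attr(G, "b"); aa <- attr(G, "alpha")
  if (is.null(bb)) bb <- 1
  if (is.null(aa)) aa <- 0
  a_hat <- backsolve_snp_effects(fit$g2_hat, Z, G, sumpq, b = bb, alpha = aa)
  sds <- snp_sampling_sd(Z, G, fit$C_u2u2, sigma_g2, sumpq, b = bb, alpha = aa)
  p <- snp_pvalues(a_hat, sds$sd)
  p[!sds$testable] <- NA_real_
  fdr <- fdr_adjust(p, fdr_significant, fdr_suggestive)
  tab <- data.frame(snp_id = genotypes$snp_map$snp_id,
                    chrom = genotypes$snp_map$chrom,
                    pos_bp = genotypes$snp_map$pos_bp,
                    effect = unname(a_hat), sd = sds$sd, p = p, q = fdr$q,
                    significant = fdr$significant, suggestive = fdr$suggestive,
                    stringsAsFactors = FALSE)
  tab$var_window_pct <- window_variance_explained(a_hat, Z, genotypes$snp_map,
                                                  sigma_p2, window)
  regions <- group_qtl_regions(tab, distance_limit, peak_fraction)
  if (nrow(regions)) {
    regions$var_region_pct <- vapply(seq_len(nrow(regions)), function(i)
      region_variance_explained(regions[i, ], a_hat, Z, genotypes$snp_map,
                                sigma_p2, window), numeric(1))
  }
  list(gwas = tab, regions = regions, fit = fit)
}
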