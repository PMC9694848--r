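#' Pedigree object
#'
#' Ordered animal/sire/dam records.  Unknown parents are coded `0` (or
#' `NA`, normalised to `0`).  Records are topologically sorted so that
#' parents always precede offspring; a cycle (an animal that is its own
#' ancestor) is an error.
#'
#' @param animal,sire,dam vectors of ids (character or integer); `sire`/`dam`
#'   may contain `0`/`NA` for unknown parents.
#' @return object of class `pedigree`: data.frame with columns
#'   `animal`, `sire`, `dam` (character, `"0"` = unknown), parents first.
#' @export
pedigree <- function(animal, sire, dam) {
  norm <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x == "" | x == "0"] <- "0"
    x
  }
  animal <- norm(animal); sire <- norm(sire); dam <- norm(dam)
  if (any(animal == "0")) stop("animal id 0/NA is reserved for unknown parents")
  if (anyDuplicated(animal))
    stop("duplicated animal id(s): ",
         paste(unique(animal[duplicated(animal)]), collapse = ", "))
  known <- unique(c(sire, dam)); known <- known[known != "0"]
  phantom <- setdiff(known, animal)
  if (length(phantom))
    stop("parent(s) without own record: ", paste(utils::head(phantom, 5), collapse = ", "))
  ped <- data.frame(animal = animal, sire = sire, dam = dam,
                    stringsAsFactors = FALSE)
  ped <- .topo_sort_pedigree(ped)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Kahn-style topological sort; errors on cycles.
.topo_sort_pedigree <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$animal)
  si <- ifelse(ped$sire == "0", 0L, idx[ped$sire])
  di <- ifelse(ped$dam == "0", 0L, idx[ped$dam])
  placed <- logical(n)
  order_out <- integer(n)
  k <- 0L
  repeat {
    ready <- !placed & (si == 0L | placed[pmax(si, 1L)]) &
                       (di == 0L | placed[pmax(di, 1L)])
    if (!any(ready)) break
    ids <- which(ready)
    order_out[k + seq_along(ids)] <- ids
    k <- k + length(ids)
    placed[ids] <- TRUE
  }
  if (k < n)
    stop("pedigree contains a cycle involving: ",
         paste(utils::head(ped$animal[!placed], 5), collapse = ", "))
  out <- ped[order_out, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.pedigree <- function(x, ...) {
  founders <- sum(x$sire == "0" & x$dam == "0")
  cat(sprintf("pedigree: %d animals (%d founders)\n", nrow(x), founders))
  invisible(x)
}

.check_pedigree_ordered <- function(ped) {
  idx <- stats::setNames(seq_len(nrow(ped)), ped$animal)
  si <- ifelse(ped$sire == "0", 0L, idx[ped$sire])
  di <- ifelse(ped$dam == "0", 0L, idx[ped$dam])
  if (any(si >= seq_len(nrow(ped))) || any(di >= seq_len(nrow(ped))))
    stop("pedigree is not ordered (a parent follows its offspring)")
  invisible(list(sire = si, dam = di))
}

#' Numerator relationship matrix A
#'
#' Builds the additive (numerator) relationship matrix from an ordered
#' pedigree by the recursive tabular method, including inbreeding:
#' `a(i,i) = 1 + F_i` with `F_i = a(sire, dam)/2`, and
#' `a(i,j) = (a(j, sire_i) + a(j, dam_i))/2` for `j < i`.
#'
#' @param ped a [pedigree].
#' @return `relationship_matrix` of kind `"A"` indexed by animal id.
#' @export
build_A <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  par <- .check_pedigree_ordered(ped)
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    s <- par$sire[i]; d <- par$dam[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      rel <- numeric(i - 1L)
      if (s > 0L) rel <- rel + A[j, s]
      if (d > 0L) rel <- rel + A[j, d]
      rel <- rel / 2
      A[j, i] <- rel
      A[i, j] <- rel
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) A[s, d] / 2 else 0
  }
  relationship_matrix(A, kind = "A")
}

#' Relationship matrix container
#'
#' @param values symmetric numeric matrix with id dimnames.
#' @param kind one of `"A"`, `"A22"`, `"G_raw"`, `"G_blended"`, `"H"`.
#' @return `relationship_matrix` object (matrix with `kind` attribute).
#' @export
relationship_matrix <- function(values, kind = c("A", "A22", "G_raw", "G_blended", "H")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("relationship matrix must be square")
  if (max(abs(values - t(values))) > 1e-8)
    stop("relationship matrix must be symmetric")
  values <- (values + t(values)) / 2
  structure(values, kind = kind, class = c("relationship_matrix", "matrix", "array"))
}

#' @export
print.relationship_matrix <- function(x, ...) {
  cat(sprintf("%s relationship matrix, %d x %d, mean diag %.3f\n",
              attr(x, "kind"), nrow(x), ncol(x), mean(diag(x))))
  invisible(x)
}

#' Partition A by genotyping status
#'
#' Splits `A` into the blocks `A11` (non-genotyped), `A12`, `A21` and `A22`
#' (genotyped) used by the single-step H-matrix construction.
#'
#' @param A a relationship matrix of kind `"A"` with id dimnames.
#' @param genotyped_ids ids of genotyped animals (subset of rownames of A).
#' @return list with elements `A11`, `A12`, `A21`, `A22`, `ids1`, `ids2`.
#' @export
partition_A <- function(A, genotyped_ids) {
  ids <- rownames(A)
  unknown <- setdiff(genotyped_ids, ids)
  if (length(unknown))
    stop("genotyped id(s) not in A: ", paste(utils::head(unknown, 5), collapse = ", "))
  ids2 <- ids[ids %in% genotyped_ids]   # keep A's ordering
  ids1 <- setdiff(ids, ids2)
  list(A11 = A[ids1, ids1, drop = FALSE], A12 = A[ids1, ids2, drop = FALSE],
       A21 = A[ids2, ids1, drop = FALSE], A22 = A[ids2, ids2, drop = FALSE],
       ids1 = ids1, ids2 = ids2)
}

#' Pedigree relationships among genotyped animals
#'
#' @inheritParams partition_A
#' @return `relationship_matrix` of kind `"A22"`.
#' @export
extract_A22 <- function(A, genotyped_ids) {
  blocks <- partition_A(A, genotyped_ids)
  relationship_matrix(blocks$A22, kind = "A22")
}

#' Raw genomic relationship matrix (VanRaden)
#'
#' `G = Z Z' / (2 * sum(p_i * (1 - p_i)))` where `Z` holds allele counts
#' centered by twice the allele frequency.
#'
#' @param genotypes a [genotype_set] or a complete 0/1/2 matrix
#'   (individuals x SNPs) with row names.
#' @param allele_freqs optional per-SNP frequencies of the counted allele
#'   used for centering; default: observed frequencies `mean(count)/2`.
#' @return `relationship_matrix` of kind `"G_raw"`.
#' @export
compute_G_raw <- function(genotypes, allele_freqs = NULL) {
  M <- if (inherits(genotypes, "genotype_set")) genotypes$allele_counts else as.matrix(genotypes)
  if (anyNA(M)) stop("missing genotypes: run qc_genotypes() (mean imputation) first")
  p <- if (is.null(allele_freqs)) colMeans(M) / 2 else allele_freqs
  if (length(p) != ncol(M)) stop("allele_freqs length mismatch")
  mono <- p <= 0 | p >= 1
  if (any(mono))
    stop(sum(mono), " monomorphic SNP(s) (p in {0,1}); remove them in QC ",
         "before building G")
  Z <- sweep(M, 2L, 2 * p, "-")
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(Z) / denom
  relationship_matrix(G, kind = "G_raw")
}

#' Blend G to the pedigree base and add a stabilising share of A22
#'
#' Rescales the raw genomic matrix so its average diagonal and average
#' off-diagonal match those of `A22` (intercept `a` and slope `b` solved
#' from the 2x2 linear system), then returns
#' `(1 - alpha) * (a + b * G_raw) + alpha * A22` with a small `alpha`
#' (default 0.05) guaranteeing invertibility.
#'
#' @param G_raw raw genomic relationship matrix.
#' @param A22 pedigree relationships among the genotyped animals.
#' @param alpha weight on `A22`; default 0.05.
#' @return `relationship_matrix` of kind `"G_blended"` with attributes
#'   `a`, `b`, `alpha` recording the tuning.
#' @export
blend_G <- function(G_raw, A22, alpha = 0.05) {
  G_raw <- as.matrix(G_raw); A22 <- as.matrix(A22)
  if (!all(dim(G_raw) == dim(A22))) stop("G_raw and A22 are not conformable")
  n <- nrow(G_raw)
  off <- upper.tri(G_raw)
  # mean(diag(a + b G)) = mean(diag(A22)); mean(offdiag(a + b G)) = mean(offdiag(A22))
  M <- rbind(c(1, mean(diag(G_raw))), c(1, mean(G_raw[off])))
  rhs <- c(mean(diag(A22)), mean(A22[off]))
  if (abs(det(M)) < 1e-12)
    stop("tuning system singular: G_raw has equal average diagonal and ",
         "off-diagonal (constant matrix?)")
  ab <- solve(M, rhs)
  G <- (1 - alpha) * (ab[1] + ab[2] * G_raw) + alpha * A22
  if (alpha > 0) {
    ev_min <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
    if (ev_min <= 0)
      warning("blended G is not positive definite (min eigenvalue ",
              signif(ev_min, 3), "); check A22")
  }
  out <- relationship_matrix(G, kind = "G_blended")
  attr(out, "a") <- unname(ab[1]); attr(out, "b") <- unname(ab[2])
  attr(out, "alpha") <- alpha
  out
}

#' Joint pedigree-genomic relationship matrix H
#'
#' Single-step H matrix projecting genomic relationships from the genotyped
#' animals (block 2) to their non-genotyped relatives (block 1):
#' \deqn{H = \begin{pmatrix}
#'   A_{11} - A_{12}A_{22}^{-1}A_{21} + A_{12}A_{22}^{-1} G A_{22}^{-1}A_{21}
#'     & A_{12}A_{22}^{-1}G \\
#'   G A_{22}^{-1}A_{21} & G \end{pmatrix}}
#' The genotyped block of H equals `G` exactly; if `G = A22`, `H = A`.
#'
#' @param A_blocks block partition from [partition_A()].
#' @param G blended genomic relationship matrix for the genotyped animals,
#'   ordered like `A_blocks$ids2`.
#' @return `relationship_matrix` of kind `"H"` indexed `c(ids1, ids2)`.
#' @export
build_H <- function(A_blocks, G) {
  G <- as.matrix(G)
  n2 <- length(A_blocks$ids2)
  if (!all(dim(G) == n2))
    stop("G dimension (", nrow(G), ") does not match genotyped block (", n2, ")")
  if (length(A_blocks$ids1) == 0L)
    return(relationship_matrix(structure(G, dimnames = list(A_blocks$ids2, A_blocks$ids2)),
                               kind = "H"))
  A22inv <- solve(A_blocks$A22)
  P12 <- A_blocks$A12 %*% A22inv            # A12 A22^-1
  H11 <- A_blocks$A11 - P12 %*% A_blocks$A21 + P12 %*% G %*% t(P12)
  H12 <- P12 %*% G
  H <- rbind(cbind(H11, H12), cbind(t(H12), G))
  ids <- c(A_blocks$ids1, A_blocks$ids2)
  dimnames(H) <- list(ids, ids)
  relationship_matrix(H, kind = "H")
}
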