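#' OTU count table with taxonomy
#'
#' Container for a samples x OTU matrix of sequence counts plus a taxonomy
#' table mapping each OTU to the ranks domain..genus.  Abundance analyses in
#' this package treat each sample's counts as compositional: the sequencing
#' depth is an artefact of the technology, so only ratios between OTU carry
#' information.
#'
#' @param counts non-negative integer matrix, samples in rows, OTU in
#'   columns; must carry unique row (sample) and column (OTU) names.
#' @param taxonomy data.frame with a column `otu_id` plus any of the rank
#'   columns `domain`, `phylum`, `class`, `order`, `family`, `genus`
#'   (missing ranks are filled with `"unknown"`); must cover every OTU in
#'   `counts`.
#' @return an object of class `otu_table`: list with elements `counts`,
#'   `taxonomy`, `sample_ids`, `otu_ids`.
#' @export
otu_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample (row) and OTU (column) names")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("sample and OTU ids must be unique")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  ranks <- c("domain", "phylum", "class", "order", "family", "genus")
  if (is.null(taxonomy)) {
    taxonomy <- data.frame(otu_id = colnames(counts))
  }
  taxonomy <- as.data.frame(taxonomy)
  if (!"otu_id" %in% names(taxonomy)) stop("taxonomy needs an otu_id column")
  missing_tax <- setdiff(colnames(counts), taxonomy$otu_id)
  if (length(missing_tax))
    stop("taxonomy does not cover OTU: ", paste(utils::head(missing_tax, 5), collapse = ", "))
  for (r in ranks) if (!r %in% names(taxonomy)) taxonomy[[r]] <- "unknown"
  taxonomy <- taxonomy[match(colnames(counts), taxonomy$otu_id), c("otu_id", ranks)]
  rownames(taxonomy) <- NULL
  structure(list(counts = counts, taxonomy = taxonomy,
                 sample_ids = rownames(counts), otu_ids = colnames(counts)),
            class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTU, %.1f%% zero cells\n",
              nrow(x$counts), ncol(x$counts), 100 * mean(x$counts == 0)))
  invisible(x)
}

#' Remove OTU below a relative-abundance threshold
#'
#' Drops every OTU whose total count across all samples is less than
#' `threshold_fraction` of the grand total (the cluster-abundance filter,
#' default 0.005 %).  Samples are never dropped.
#'
#' @param table an [otu_table].
#' @param threshold_fraction fraction of the grand total below which an OTU
#'   is removed; in `[0, 1)`.  The default `5e-5` is 0.005 %.
#' @return filtered [otu_table].
#' @export
filter_low_abundance <- function(table, threshold_fraction = 5e-5) {
  stopifnot(inherits(table, "otu_table"))
  if (!is.numeric(threshold_fraction) || threshold_fraction < 0 ||
      threshold_fraction >= 1)
    stop("threshold_fraction must lie in [0, 1)")
  if (ncol(table$counts) == 0L || sum(table$counts) == 0)
    stop("empty OTU table")
  totals <- colSums(table$counts)
  keep <- totals / sum(totals) >= threshold_fraction
  if (!any(keep))
    stop("threshold removes every OTU")
  otu_table(table$counts[, keep, drop = FALSE],
            table$taxonomy[keep, , drop = FALSE])
}

#' Bayesian-multiplicative zero imputation
#'
#' Replaces zero counts with small positive proportions using the
#' Bayesian-multiplicative replacement with a geometric (data-driven) prior:
#' for sample \eqn{k} with row total \eqn{n_k}, a zero part \eqn{j} is
#' replaced by \eqn{t_j s/(n_k+s)} and the non-zero parts are shrunk by the
#' complementary multiplicative factor, which leaves all pairwise ratios
#' among observed parts untouched.  Rows are closed to sum to one.
#'
#' The prior expectation \eqn{t_j} of part \eqn{j} is the closed geometric
#' mean of its observed (non-zero) proportions across samples
#' (`prior = "geometric"`); with `prior = "uniform"` each part gets
#' \eqn{1/D}.  The prior strength is \eqn{s = \sqrt{D}} by default
#' (\eqn{D} = number of parts), exposed via `s`.
#'
#' @param table an [otu_table] or a non-negative count matrix.
#' @param s Dirichlet prior strength; default `sqrt(ncol)`.
#' @param prior `"geometric"` (default) or `"uniform"` prior expectations.
#' @return strictly positive matrix of proportions (rows sum to 1), same
#'   dimnames as the input counts.
#' @export
impute_zeros <- function(table, s = NULL, prior = c("geometric", "uniform")) {
  prior <- match.arg(prior)
  counts <- if (inherits(table, "otu_table")) table$counts else as.matrix(table)
  if (any(counts < 0)) stop("counts must be non-negative")
  rs <- rowSums(counts)
  if (any(rs == 0))
    stop("all-zero sample(s): ", paste(rownames(counts)[rs == 0], collapse = ", "))
  D <- ncol(counts)
  if (is.null(s)) s <- sqrt(D)
  prop <- counts / rs
  if (prior == "uniform" || nrow(counts) == 1L) {
    t_prior <- rep(1 / D, D)
  } else {
    # per-part geometric mean of observed proportions, closed to sum 1;
    # parts never observed fall back to the smallest prior mass present
    t_prior <- apply(prop, 2L, function(p) {
      p <- p[p > 0]
      if (!length(p)) NA_real_ else exp(mean(log(p)))
    })
    if (anyNA(t_prior)) t_prior[is.na(t_prior)] <- min(t_prior, na.rm = TRUE)
    t_prior <- t_prior / sum(t_prior)
  }
  repl <- outer(s / (rs + s), t_prior)        # t_j * s / (n_k + s)
  zero <- counts == 0
  zmass <- rowSums(repl * zero)
  if (any(zmass >= 1))
    stop("zero-replacement mass >= 1 for sample(s): ",
         paste(rownames(counts)[zmass >= 1], collapse = ", "))
  out <- prop * (1 - zmass)                    # multiplicative adjustment
  out[zero] <- repl[zero]
  dimnames(out) <- dimnames(counts)
  out
}

#' Centered log-ratio transform
#'
#' `clr(x)[k, j] = log(x[k, j]) - mean(log(x[k, ]))`; each row of the result
#' sums to zero.  Input must be strictly positive (impute zeros first).
#'
#' @param x strictly positive matrix (samples x parts).
#' @return object of class `clr_matrix`: the transformed matrix with
#'   attribute `standardised = FALSE`.
#' @export
clr <- function(x) {
  x <- as.matrix(x)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("clr requires strictly positive entries; impute zeros first")
  lx <- log(x)
  out <- lx - rowMeans(lx)
  structure(out, standardised = FALSE, class = c("clr_matrix", "matrix", "array"))
}

#' Scale CLR columns to unit variance
#'
#' Divides every column by its sample standard deviation so that each OTU's
#' CLR abundance has variance 1.  Columns are not recentered: the animal
#' model's fixed effects absorb the means.
#'
#' @param x a `clr_matrix` (or plain matrix) with at least two rows.
#' @return `clr_matrix` with attribute `standardised = TRUE`.
#' @export
standardise_columns <- function(x) {
  x <- unclass(x)
  if (nrow(x) < 2L) stop("need at least two samples to standardise")
  v <- apply(x, 2L, stats::var)
  bad <- v <= 0 | !is.finite(v)
  if (any(bad))
    stop("zero-variance column(s): ", paste(colnames(x)[bad], collapse = ", "))
  out <- sweep(x, 2L, sqrt(v), "/")
  structure(out, standardised = TRUE, class = c("clr_matrix", "matrix", "array"))
}

#' Preprocess an OTU table for genetic analysis
#'
#' Runs the full compositional chain in fixed order: abundance filter,
#' Bayesian-multiplicative zero imputation, CLR transform, per-OTU
#' standardisation.
#'
#' @inheritParams filter_low_abundance
#' @inheritParams impute_zeros
#' @param standardise scale each OTU column to unit variance (default TRUE).
#' @return standardised `clr_matrix` (samples x retained OTU).
#' @export
preprocess_otu <- function(table, threshold_fraction = 5e-5, s = NULL,
                           prior = "geometric", standardise = TRUE) {
  filtered <- filter_low_abundance(table, threshold_fraction)
  z <- clr(impute_zeros(filtered, s = s, prior = prior))
  if (standardise) z <- standardise_columns(z)
  z
}

#' Core microbiome
#'
#' OTU detected (non-zero count) in at least `occurrence` of the samples.
#' The sample threshold is `ceiling(occurrence * n_samples)`, so with 10
#' samples and `occurrence = 0.9` an OTU must be present in 9 of them.
#'
#' @param table an [otu_table].
#' @param occurrence required occurrence proportion in `(0, 1]`; default 0.90.
#' @return character vector of core OTU ids.
#' @export
core_microbiome <- function(table, occurrence = 0.90) {
  stopifnot(inherits(table, "otu_table"))
  if (!is.numeric(occurrence) || occurrence <= 0 || occurrence > 1)
    stop("occurrence must lie in (0, 1]")
  need <- ceiling(occurrence * nrow(table$counts))
  present <- colSums(table$counts > 0)
  colnames(table$counts)[present >= need]
}
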