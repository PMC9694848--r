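#' Permutation null distribution of an OTU's heritability
#'
#' Empirical null for "no host-genetic control": the OTU's abundances are
#' shuffled across individuals (which breaks the link between abundance and
#' the relationship matrix while leaving the fixed-effect columns and the
#' two leading selection-criterion traits untouched), the multi-trait model
#' is refitted, and the heritability of the shuffled OTU is recorded for
#' each permutation.
#'
#' @param otu_values numeric vector of (CLR) abundances, aligned with the
#'   rows of `frame_template`.
#' @param frame_template a [model_frame] whose *last* trait is the OTU slot
#'   to be permuted (e.g. the 3-trait frame LSCS, CV milk, OTU).
#' @param A relationship matrix covering the frame's animals.
#' @param n_perm number of permutations (>= 20).
#' @param seed integer seed; permutation `i` uses a reproducible shuffle.
#' @param include_identity if TRUE the first "permutation" is the identity
#'   (useful for checking the unpermuted fit is reproduced).
#' @param em_rounds,max_iter REML control handed to [reml_ai()] (reduced
#'   defaults keep thousands of refits affordable).
#' @return object of class `permutation_result`: list with `h2_estimates`,
#'   `threshold` (at 5%), `n_perm`, `n_unconverged`, `error_rate`, `seed`.
#' @export
permute_and_refit <- function(otu_values, frame_template, A, n_perm = 200L,
                              seed = 1L, include_identity = FALSE,
                              em_rounds = 30L, max_iter = 50L) {
  stopifnot(inherits(frame_template, "model_frame"))
  if (n_perm < 20L) stop("n_perm must be at least 20")
  n <- nrow(frame_template$Y)
  if (length(otu_values) != n) stop("otu_values length must match the frame")
  slot <- length(frame_template$traits)
  su <- .reml_setup(frame_template, A)       # rotation reused across refits
  set.seed(seed)
  h2s <- rep(NA_real_, n_perm)
  n_uncv <- 0L
  for (i in seq_len(n_perm)) {
    perm <- if (include_identity && i == 1L) seq_len(n) else sample.int(n)
    yperm <- otu_values[perm]
    su$Ystar[, slot] <- crossprod(su$U, yperm)
    fit <- tryCatch(.reml_fit_rotated(su, em_rounds = em_rounds,
                                      max_iter = max_iter),
                    error = function(e) NULL)
    if (is.null(fit)) { n_uncv <- n_uncv + 1L; next }
    if (!fit$converged) n_uncv <- n_uncv + 1L
    h2s[i] <- fit$P[slot, slot] / (fit$P[slot, slot] + fit$R[slot, slot])
  }
  if (n_uncv > 0.05 * n_perm)
    warning(n_uncv, " of ", n_perm, " permutation refits did not converge")
  h2s_ok <- h2s[!is.na(h2s)]
  structure(list(h2_estimates = h2s_ok,
                 threshold = if (length(h2s_ok) >= 20L)
                   empirical_threshold(h2s_ok, 0.05) else NA_real_,
                 n_perm = n_perm, n_unconverged = n_uncv,
                 error_rate = 0.05, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation_result: %d permutations (%d unconverged), 5%% threshold h2 = %.4f\n",
              x$n_perm, x$n_unconverged, x$threshold))
  invisible(x)
}

#' Empirical significance threshold from a permutation null
#'
#' Sorts the estimates in increasing order and returns the lower value of
#' the upper `error_rate` fraction: with 1-based ascending ranks the
#' threshold is element `n - floor(error_rate * n) + 1`, the smallest
#' member of the top tail (ties resolved by taking that sorted element).
#'
#' @param h2_estimates numeric vector of null heritability estimates.
#' @param error_rate tail probability in (0, 1); default 0.05.
#' @return the threshold value (an element of `h2_estimates`).
#' @export
empirical_threshold <- function(h2_estimates, error_rate = 0.05) {
  if (!length(h2_estimates)) stop("empty estimate vector")
  if (!is.numeric(error_rate) || error_rate <= 0 || error_rate >= 1)
    stop("error_rate must lie in (0, 1)")
  n <- length(h2_estimates)
  m <- floor(error_rate * n)
  if (m < 1L)
    stop("too few estimates (", n, ") to resolve the upper ",
         100 * error_rate, "% tail")
  sort(h2_estimates)[n - m + 1L]
}

#' Genus over/under-representation among significant OTU
#'
#' For each genus, a 2x2 table counts membership in the significant group
#' against genus membership, and a two-sided Fisher exact test (sum of all
#' table probabilities not exceeding the observed one) gives the p-value.
#'
#' @param taxonomy data.frame with columns `otu_id` and `genus` (e.g. from
#'   an [otu_table]).
#' @param significant_otu_ids OTU declared heritable (subset of
#'   `all_otu_ids`).
#' @param all_otu_ids the full OTU universe.
#' @param p_cutoff significance level for the flag (default 0.05).
#' @return data.frame (class `enrichment_table`) with one row per genus:
#'   counts `n_sig`/`n_nonsig`, the group percentages, odds ratio, `p`,
#'   `significant`.
#' @export
genus_enrichment <- function(taxonomy, significant_otu_ids, all_otu_ids,
                             p_cutoff = 0.05) {
  bad <- setdiff(significant_otu_ids, all_otu_ids)
  if (length(bad))
    stop("significant OTU not in the universe: ",
         paste(utils::head(bad, 5), collapse = ", "))
  tax <- taxonomy[match(all_otu_ids, taxonomy$otu_id), ]
  if (anyNA(tax$otu_id)) stop("taxonomy does not cover all OTU")
  sig <- all_otu_ids %in% significant_otu_ids
  genera <- sort(unique(tax$genus))
  rows <- lapply(genera, function(g) {
    in_g <- tax$genus == g
    tab <- matrix(c(sum(in_g & sig), sum(!in_g & sig),
                    sum(in_g & !sig), sum(!in_g & !sig)), 2L, 2L)
    ft <- stats::fisher.test(tab)
    data.frame(genus = g,
               n_sig = tab[1, 1], n_nonsig = tab[1, 2],
               pct_sig = 100 * tab[1, 1] / max(sum(sig), 1L),
               pct_all = 100 * sum(in_g) / length(all_otu_ids),
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               significant = ft$p.value < p_cutoff)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("enrichment_table", "data.frame")
  out
}
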