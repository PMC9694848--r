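# Shared fixture builders (all generated in code; no data files).

toy_otu_table <- function(counts = NULL) {
  if (is.null(counts)) {
    counts <- matrix(c(10, 0, 30,
                       5, 15, 20,
                       0, 25, 35), 3, 3, byrow = TRUE)
  }
  dimnames(counts) <- list(paste0("s", seq_len(nrow(counts))),
                           paste0("OTU", seq_len(ncol(counts))))
  otu_table(counts, data.frame(otu_id = colnames(counts),
                               genus = rep_len(c("Prevotella", "Ruminococcus"),
                                               ncol(counts))))
}

random_otu_table <- function(n = 12, D = 30, seed = 1) {
  set.seed(seed)
  counts <- matrix(rpois(n * D, lambda = rep(exp(rnorm(D, 2, 1.2)), each = n)),
                   n, D)
  counts[sample(length(counts), round(0.3 * length(counts)))] <- 0
  counts[rowSums(counts) == 0, 1] <- 1
  dimnames(counts) <- list(sprintf("s%02d", 1:n), sprintf("OTU%03d", 1:D))
  otu_table(counts)
}

# small pedigree: 4 founders, two full-sib pairs, one inbred mating
toy_pedigree <- function() {
  pedigree(animal = c("f1", "f2", "f3", "f4", "o1", "o2", "o3", "o4", "x1"),
           sire   = c(0, 0, 0, 0, "f1", "f1", "f3", "f3", "o1"),
           dam    = c(0, 0, 0, 0, "f2", "f2", "f4", "f4", "o2"))
}

small_sim <- function(seed = 1, ...) {
  args <- list(seed = seed, n_founders = 30, n_generations = 2,
               cohort_size = 60, n_snps = 150, n_otus = 40,
               trait_specs = default_trait_specs()[1:3, ],
               phenotyped = "last_generation")
  args[names(list(...))] <- list(...)
  simulate_dataset(do.call(sim_config, args))
}

# balanced paternal half-sib design: s sires, each with m offspring from
# unrelated unknown dams; offspring phenotyped, intercept-only model
half_sib_data <- function(s = 40, m = 20, h2 = 0.4, seed = 1) {
  set.seed(seed)
  sires <- sprintf("S%03d", 1:s)
  off <- sprintf("O%04d", 1:(s * m))
  ped <- pedigree(animal = c(sires, off),
                  sire = c(rep("0", s), rep(sires, each = m)),
                  dam = rep("0", s + s * m))
  sg2 <- h2; se2 <- 1 - h2
  u_s <- rnorm(s, 0, sqrt(sg2 / 4))           # sire transmitting ability
  y <- rep(u_s, each = m) + rnorm(s * m, 0, sqrt(sg2 * 3 / 4 + se2))
  dat <- data.frame(animal = off, y = y)
  list(ped = ped, data = dat, sg2 = sg2, se2 = se2, m = m, s = s)
}
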