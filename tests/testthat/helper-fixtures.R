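# Shared fixture builders. Everything is generated in code; no binary data.

# small structured cohort: one strongly circumstance-specific locus (SPEC1,
# planted in NN.FF) on top of a uniform background panel
small_catalog <- function(n_background = 8L, base_rate = 0.3,
                          spec_rate = 2.0, spec_circ = "NN.FF") {
  gen <- data.frame(locus = paste0("BG", seq_len(n_background)),
                    chrom = "chrI",
                    start = 1000L + 2000L * seq_len(n_background),
                    end = 1999L + 2000L * seq_len(n_background),
                    type = "SNV", circumstance = "*", rate = base_rate,
                    stringsAsFactors = FALSE)
  spec <- data.frame(locus = "SPEC1", chrom = "chrII", start = 5000L,
                     end = 5999L, type = "SNV",
                     circumstance = c("*", spec_circ),
                     rate = c(base_rate / 5, spec_rate),
                     stringsAsFactors = FALSE)
  rbind(gen, spec)
}

small_cohort <- function(seed = 1L, replicates = 10L, ...) {
  generate_cohort(cohort_config(seed = seed,
                                replicates_per_circumstance = replicates,
                                extinction_probability = 0,
                                locus_catalog = small_catalog(...)))
}

# exact Euclidean configuration and its distance matrix, for NMDS recovery
perfect_config <- function(n = 5L, seed = 7L) {
  withr::with_seed(seed, {
    xy <- matrix(stats::runif(n * 2), n, 2)
    rownames(xy) <- paste0("p", seq_len(n))
    list(points = xy, D = as.matrix(stats::dist(xy)))
  })
}

# brute-force Bray-Curtis for a pair of count vectors (independent oracle)
bc_pair_oracle <- function(u, v) {
  1 - 2 * sum(pmin(u, v)) / (sum(u) + sum(v))
}
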