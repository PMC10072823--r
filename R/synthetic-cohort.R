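#' Default locus catalog for synthetic cohorts
#'
#' The catalog states where mutations can land and at what per-clone rate in
#' each evolutionary circumstance. Rows with `circumstance == "*"` give the
#' baseline rate for a locus; rows naming a specific circumstance override
#' it there. The default catalog echoes the headline structure of the study
#' design it emulates: chromosome XII and IV aneuploidies concentrated in the
#' NN background (mostly nonfermentable medium), chromosome IX gains in
#' nuclear-D derivatives, a strong HPF1 CNV hotspot in ND evolved on
#' fermentable medium, an MNN4 CNV hotspot in YD on nonfermentable medium,
#' and a panel of generic SNV target genes mutated at a background rate in
#' every circumstance.
#'
#' @param genotypes,media the design to cover (used only for validation of
#'   circumstance overrides).
#' @return data.frame with columns locus, chrom, start, end, type
#'   (SNV/CNV/ANEUPLOIDY), circumstance ("*" or a circumstance label), rate
#'   (expected mutations per clone).
#' @export
default_locus_catalog <- function(genotypes = default_genotypes(),
                                  media = c("FF", "NF")) {
  gene <- function(locus, chrom, start, rate, circumstance = "*",
                   type = "SNV", len = 1000L) {
    data.frame(locus = locus, chrom = chrom, start = start,
               end = start + len - 1L, type = type,
               circumstance = circumstance, rate = rate,
               stringsAsFactors = FALSE)
  }
  chrom_entry <- function(chrom, size, rate, circumstance = "*") {
    gene(chrom, chrom, 1L, rate, circumstance, type = "ANEUPLOIDY", len = size)
  }
  # a long tail of rarely hit genes: most annotations accumulate only a few
  # mutations cohort-wide, so different circumstances sample largely
  # disjoint locus sets and profile dissimilarity stays high
  generic <- paste0("GEN", seq_len(150))
  rows <- list(
    # whole-chromosome gains/losses
    chrom_entry("chrXII", 1078177L, 0.02),
    chrom_entry("chrXII", 1078177L, 0.40, "NN.NF"),
    chrom_entry("chrXII", 1078177L, 0.08, "NN.FF"),
    chrom_entry("chrIV",  1531933L, 0.01),
    chrom_entry("chrIV",  1531933L, 0.15, "NN.NF"),
    chrom_entry("chrIX",   439888L, 0.01),
    chrom_entry("chrIX",   439888L, 0.10, "DN.FF"),
    chrom_entry("chrIX",   439888L, 0.10, "DD.NF"),
    chrom_entry("chrIX",   439888L, 0.10, "DY.NF"),
    # CNV hotspots
    gene("HPF1", "chrXV", 171070L, 0.005, type = "CNV", len = 1800L),
    gene("HPF1", "chrXV", 171070L, 0.85, "ND.FF", type = "CNV", len = 1800L),
    gene("MNN4", "chrXI", 582621L, 0.005, type = "CNV", len = 1600L),
    gene("MNN4", "chrXI", 582621L, 0.60, "YD.NF", type = "CNV", len = 1600L),
    # SNV targets with circumstance bias
    gene("RIM20", "chrXV", 567434L, 0.02),
    gene("RIM20", "chrXV", 567434L, 0.20, "YY.NF"),
    gene("TSA2", "chrIV", 1316922L, 0.02),
    gene("TSA2", "chrIV", 1316922L, 0.15, "NN.NF")
  )
  # generic SNV background spread across chromosomes
  circ_all <- circumstance_table(genotypes, media)$circumstance
  rows <- c(rows, lapply(seq_along(generic), function(i) {
    g <- gene(generic[i], paste0("chrI", strrep("I", i %% 3)),
              10000L + 5000L * i, 0.004)
    # each background gene is preferentially available to one circumstance
    # (round-robin), recreating the observed largely disjoint profiles
    # (mean pairwise Bray-Curtis ~0.9 at full design scale)
    biased <- g
    biased$circumstance <- circ_all[1L + (i - 1L) %% length(circ_all)]
    biased$rate <- 0.20
    rbind(g, biased)
  }))
  cat <- do.call(rbind, rows)
  circ <- circumstance_table(genotypes, media)$circumstance
  bad <- setdiff(setdiff(cat$circumstance, "*"), circ)
  if (length(bad))
    stop("catalog references unknown circumstances: ", paste(bad, collapse = ", "))
  cat
}

#' Configuration of a synthetic evolution cohort
#'
#' Bundles every parameter of the emulated design: the background set, the
#' mitonuclear genotypes, the media, the replication level, the locus
#' catalog with per-circumstance mutation rates, the mutation-type mix used
#' when a locus does not fix its own type, and the extinction model.
#' Defaults instantiate the study design the package emulates: 7 genotypes
#' from backgrounds N, D, Y; 2 carbon sources; 96 replicate populations per
#' circumstance (1,344 populations); extinction probability 230/1344.
#'
#' @param seed mandatory integer seed; the whole cohort is deterministic
#'   given the seed.
#' @param backgrounds allowed single-character background identifiers.
#' @param genotypes mitonuclear genotype labels (nuclear first).
#' @param media medium codes.
#' @param replicates_per_circumstance populations launched per circumstance.
#' @param locus_catalog see [default_locus_catalog()].
#' @param mutation_type_mix named proportions (SNV, CNV, ANEUPLOIDY) used for
#'   catalog rows with type NA; must sum to 1.
#' @param extinction_probability per-population Bernoulli probability of
#'   extinction before clone isolation.
#' @param extinction_count if non-NULL, exactly this many populations
#'   (sampled uniformly) are removed instead of Bernoulli draws.
#' @return an object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(seed,
                          backgrounds = c("N", "D", "Y"),
                          genotypes = default_genotypes(),
                          media = c("FF", "NF"),
                          replicates_per_circumstance = 96L,
                          locus_catalog = default_locus_catalog(genotypes, media),
                          mutation_type_mix = c(SNV = 0.900, CNV = 0.066,
                                                ANEUPLOIDY = 0.034),
                          extinction_probability = 230 / 1344,
                          extinction_count = NULL) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("a single integer seed is mandatory")
  if (is.null(locus_catalog) || nrow(locus_catalog) == 0L)
    stop("locus_catalog must not be empty")
  req <- c("locus", "chrom", "start", "end", "type", "circumstance", "rate")
  if (!all(req %in% names(locus_catalog)))
    stop("locus_catalog lacks columns: ",
         paste(setdiff(req, names(locus_catalog)), collapse = ", "))
  if (any(locus_catalog$rate < 0)) stop("locus rates must be >= 0")
  if (replicates_per_circumstance < 1L)
    stop("replicates_per_circumstance must be >= 1")
  if (abs(sum(mutation_type_mix) - 1) > 1e-8)
    stop("mutation_type_mix proportions must sum to 1")
  nuc <- genotype_nuclear(genotypes); mit <- genotype_mito(genotypes)
  if (!all(c(nuc, mit) %in% backgrounds))
    stop("genotype labels use backgrounds outside the configured set")
  if (!is.null(extinction_count)) {
    total <- length(genotypes) * length(media) * replicates_per_circumstance
    if (extinction_count < 0L || extinction_count > total)
      stop("extinction_count out of range")
  } else if (extinction_probability < 0 || extinction_probability >= 1) {
    stop("extinction_probability must be in [0, 1)")
  }
  structure(list(seed = as.integer(seed), backgrounds = backgrounds,
                 genotypes = genotypes, media = media,
                 replicates_per_circumstance = as.integer(replicates_per_circumstance),
                 locus_catalog = locus_catalog,
                 mutation_type_mix = mutation_type_mix,
                 extinction_probability = extinction_probability,
                 extinction_count = extinction_count),
            class = "cohort_config")
}

# rate matrix loci x circumstances from the long catalog ("*" base, overrides)
.catalog_rates <- function(catalog, circumstances) {
  loci <- unique(catalog$locus)
  rates <- matrix(0, length(loci), length(circumstances),
                  dimnames = list(loci, circumstances))
  base <- catalog[catalog$circumstance == "*", ]
  for (i in seq_len(nrow(base)))
    rates[base$locus[i], ] <- base$rate[i]
  spec <- catalog[catalog$circumstance != "*", ]
  for (i in seq_len(nrow(spec)))
    rates[spec$locus[i], spec$circumstance[i]] <- spec$rate[i]
  rates
}

#' Generate a synthetic evolution cohort with ground truth
#'
#' Simulates the outcome of the replicated evolution experiment: populations
#' are launched for every circumstance, a subset goes extinct, and one clone
#' is isolated from each survivor. Per-clone mutation counts at each catalog
#' locus are Poisson with the circumstance-specific catalog rate; each event
#' becomes a mutation call (SNV with random distinct ref/alt bases, CNV with
#' a copy-ratio of 2 or 0.5, or whole-chromosome aneuploidy).
#'
#' @param config a [cohort_config()].
#' @return list of class `cohort` with elements
#'   * `metadata`: one row per surviving clone (clone_id, genotype, nuclear,
#'     mito, medium, circumstance),
#'   * `calls`: mutation-call table (clone_id, type, chromosome, start, end,
#'     ref_allele, alt_allele, copy_ratio, annotation),
#'   * `truth`: planted ground truth (the same calls, the rate matrix, the
#'     config) for recovery tests.
#' @examples
#' cfg <- cohort_config(seed = 1, replicates_per_circumstance = 4)
#' coh <- generate_cohort(cfg)
#' head(coh$metadata)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, {
    circ <- circumstance_table(config$genotypes, config$media)
    pops <- circ[rep(seq_len(nrow(circ)),
                     each = config$replicates_per_circumstance), ]
    pops$replicate <- rep(seq_len(config$replicates_per_circumstance),
                          times = nrow(circ))
    n <- nrow(pops)
    extinct <- if (!is.null(config$extinction_count)) {
      seq_len(n) %in% sample.int(n, config$extinction_count)
    } else {
      runif(n) < config$extinction_probability
    }
    clones <- pops[!extinct, , drop = FALSE]
    clones$clone_id <- sprintf("%s.r%03d", clones$circumstance, clones$replicate)
    metadata <- clones[, c("clone_id", "genotype", "nuclear", "mito",
                           "medium", "circumstance")]
    rownames(metadata) <- NULL

    rates <- .catalog_rates(config$locus_catalog, circ$circumstance)
    locus_info <- config$locus_catalog[!duplicated(config$locus_catalog$locus), ]
    rownames(locus_info) <- locus_info$locus

    calls <- vector("list", nrow(metadata))
    bases <- c("A", "C", "G", "T")
    for (i in seq_len(nrow(metadata))) {
      cc <- metadata$circumstance[i]
      counts <- rpois(nrow(rates), rates[, cc])
      if (sum(counts) == 0L) next
      loci <- rep(rownames(rates), counts)
      info <- locus_info[loci, , drop = FALSE]
      type <- info$type
      missing_type <- is.na(type)
      if (any(missing_type))
        type[missing_type] <- sample(names(config$mutation_type_mix),
                                     sum(missing_type), replace = TRUE,
                                     prob = config$mutation_type_mix)
      ref <- rep(NA_character_, length(loci))
      alt <- rep(NA_character_, length(loci))
      start <- info$start; end <- info$end
      ratio <- rep(NA_real_, length(loci))
      for (j in seq_along(loci)) {
        if (type[j] == "SNV") {
          pos <- info$start[j] + sample.int(info$end[j] - info$start[j] + 1L, 1L) - 1L
          start[j] <- end[j] <- pos
          ref[j] <- sample(bases, 1L)
          alt[j] <- sample(setdiff(bases, ref[j]), 1L)
          ratio[j] <- NA_real_
        } else if (type[j] == "CNV") {
          ratio[j] <- if (runif(1) < 0.8) 2 else 0.5
        } else {
          ratio[j] <- if (runif(1) < 0.9) 1.5 else 0.5
        }
      }
      calls[[i]] <- data.frame(clone_id = metadata$clone_id[i], type = type,
                               chromosome = info$chrom, start = start, end = end,
                               ref_allele = ref, alt_allele = alt,
                               copy_ratio = ratio, annotation = loci,
                               stringsAsFactors = FALSE)
    }
    calls <- if (all(vapply(calls, is.null, logical(1)))) {
      data.frame(clone_id = character(), type = character(),
                 chromosome = character(), start = integer(), end = integer(),
                 ref_allele = character(), alt_allele = character(),
                 copy_ratio = numeric(), annotation = character())
    } else do.call(rbind, calls[!vapply(calls, is.null, logical(1))])
    rownames(calls) <- NULL
    calls$artifact_flag <- FALSE

    structure(list(metadata = metadata, calls = calls,
                   truth = list(calls = calls, rates = rates, config = config)),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat("Synthetic evolution cohort:", nrow(x$metadata), "clones,",
      nrow(x$calls), "mutation calls over",
      length(unique(x$metadata$circumstance)), "circumstances\n")
  invisible(x)
}
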