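#' Toy genome model for depth and pileup simulation
#'
#' A compact genome stands in for the 12-Mb yeast genome so per-position
#' tables stay desk-sized: a handful of nuclear chromosomes plus a
#' mitochondrial chromosome of which a configurable fraction is coding.
#' A fixed `ref_seed` makes the reference base at every position reproducible
#' across pileups drawn from the same model, so ancestor and evolved-clone
#' pileups share coordinates and reference alleles.
#'
#' @param nuclear_sizes named integer vector of nuclear chromosome sizes (bp).
#' @param mito_size mitochondrial chromosome size (bp).
#' @param mito_coding_fraction fraction of the mitochondrial chromosome that
#'   is coding; coding positions form a single leading interval.
#' @param mito_chrom mitochondrial chromosome name.
#' @param ref_seed seed fixing the simulated reference sequence.
#' @return list of class `genome_model` with `chrom_sizes` (nuclear + mito),
#'   `mito_chrom`, `mito_coding` (interval data.frame) and `ref_seed`.
#' @export
toy_genome_model <- function(nuclear_sizes = c(chrI = 8000L, chrII = 8000L,
                                               chrIII = 8000L, chrIV = 8000L),
                             mito_size = 2000L,
                             mito_coding_fraction = 0.6,
                             mito_chrom = "chrM",
                             ref_seed = 42L) {
  stopifnot(all(nuclear_sizes > 0), mito_size > 0,
            mito_coding_fraction > 0, mito_coding_fraction <= 1)
  sizes <- c(nuclear_sizes, setNames(as.integer(mito_size), mito_chrom))
  coding_len <- max(1L, floor(mito_size * mito_coding_fraction))
  structure(list(
    chrom_sizes = sizes,
    mito_chrom = mito_chrom,
    mito_coding = data.frame(chrom = mito_chrom, start = 1L,
                             end = coding_len, stringsAsFactors = FALSE),
    ref_seed = as.integer(ref_seed)
  ), class = "genome_model")
}

.check_no_overlap <- function(iv) {
  if (is.null(iv) || nrow(iv) < 2L) return(invisible(TRUE))
  for (ch in unique(iv$chrom)) {
    x <- iv[iv$chrom == ch, , drop = FALSE]
    x <- x[order(x$start), , drop = FALSE]
    if (nrow(x) > 1L && any(x$start[-1L] <= x$end[-nrow(x)]))
      stop("overlapping CNV intervals on ", ch)
  }
  invisible(TRUE)
}

#' Simulate a per-position depth-of-coverage table
#'
#' Expected depth at a position is `mean_depth` times the local copy ratio;
#' whole-chromosome ratios come from `karyotype`, sub-chromosomal ones from
#' `cnvs`. Gaussian noise proportional to the local mean is added and depths
#' are truncated at zero. If `mtdna_fraction_target` is given, the
#' mitochondrial chromosome is rescaled so that the expected ratio of
#' depth summed over mitochondrial coding positions to depth summed over the
#' whole genome equals the target.
#'
#' @param genome_model a [toy_genome_model()].
#' @param karyotype named numeric vector of per-chromosome copy ratios
#'   (missing chromosomes default to 1); all ratios must be > 0.
#' @param cnvs data.frame (chrom, start, end, ratio) of planted CNVs; must
#'   not overlap.
#' @param mtdna_fraction_target target mitochondrial-coding depth fraction,
#'   or NULL to leave the mitochondrial ratio as configured.
#' @param mean_depth genome baseline mean depth (> 0).
#' @param noise_sd Gaussian noise standard deviation as a proportion of the
#'   local expected depth.
#' @param seed integer seed.
#' @return data.frame (chrom, pos, depth), 1-based positions, one row per
#'   genomic position.
#' @export
generate_depth_profile <- function(genome_model, karyotype = NULL, cnvs = NULL,
                                   mtdna_fraction_target = NULL,
                                   mean_depth = 30, noise_sd = 0.05, seed = 1L) {
  stopifnot(inherits(genome_model, "genome_model"), mean_depth > 0,
            noise_sd >= 0)
  if (!is.null(karyotype) && any(karyotype <= 0))
    stop("karyotype copy ratios must be > 0")
  .check_no_overlap(cnvs)
  sizes <- genome_model$chrom_sizes
  ratio_of <- setNames(rep(1, length(sizes)), names(sizes))
  if (!is.null(karyotype)) ratio_of[names(karyotype)] <- karyotype

  if (!is.null(mtdna_fraction_target)) {
    f <- mtdna_fraction_target
    mito <- genome_model$mito_chrom
    lc <- sum(genome_model$mito_coding$end - genome_model$mito_coding$start + 1L)
    lm_ <- sizes[[mito]]
    ln <- sum(sizes[setdiff(names(sizes), mito)] *
                ratio_of[setdiff(names(sizes), mito)])
    if (f <= 0 || f >= lc / lm_)
      stop("mtdna_fraction_target infeasible: must be < coding/mito length ratio ",
           signif(lc / lm_, 4))
    ratio_of[[mito]] <- f * ln / (lc - f * lm_)
  }

  withr::with_seed(seed, {
    out <- lapply(names(sizes), function(ch) {
      n <- sizes[[ch]]
      ratio <- rep(ratio_of[[ch]], n)
      if (!is.null(cnvs)) {
        cv <- cnvs[cnvs$chrom == ch, , drop = FALSE]
        for (i in seq_len(nrow(cv)))
          ratio[cv$start[i]:cv$end[i]] <- ratio[cv$start[i]:cv$end[i]] * cv$ratio[i]
      }
      mu <- mean_depth * ratio
      depth <- if (noise_sd == 0) mu else pmax(0, rnorm(n, mu, noise_sd * mu))
      data.frame(chrom = ch, pos = seq_len(n), depth = round(depth),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Simulate a pileup base-count table
#'
#' Reference bases are drawn once per genome model (via its `ref_seed`), so
#' repeated calls for the same model share references. Each position receives
#' `depth` reads; a planted SNV contributes alternative reads at its allele
#' fraction, and every non-variant read is miscalled at `error_rate`, spread
#' uniformly over the three non-reference bases.
#'
#' @param genome_model a [toy_genome_model()].
#' @param snvs data.frame (chrom, pos, alt, af) of planted variants; `alt`
#'   optional (random non-reference base when absent); duplicate positions
#'   are an error.
#' @param depth reads per position.
#' @param error_rate per-base miscall probability.
#' @param seed integer seed for the read sampling.
#' @param chroms restrict output to these chromosomes (default all).
#' @return data.frame (chrom, pos, ref, A, C, G, T).
#' @export
generate_pileup <- function(genome_model, snvs = NULL, depth = 30,
                            error_rate = 0.001, seed = 1L, chroms = NULL) {
  stopifnot(inherits(genome_model, "genome_model"), depth > 0,
            error_rate >= 0, error_rate <= 1)
  sizes <- genome_model$chrom_sizes
  if (!is.null(chroms)) sizes <- sizes[chroms]
  if (!is.null(snvs)) {
    if (any(snvs$af < 0 | snvs$af > 1)) stop("allele_fraction must be in [0,1]")
    if (anyDuplicated(snvs[, c("chrom", "pos")]))
      stop("duplicate SNV positions")
  }
  bases <- c("A", "C", "G", "T")
  tab <- do.call(rbind, lapply(names(sizes), function(ch) {
    data.frame(chrom = ch, pos = seq_len(sizes[[ch]]), stringsAsFactors = FALSE)
  }))
  # reference sequence fixed by the model, independent of the read seed
  tab$ref <- withr::with_seed(genome_model$ref_seed, {
    all_sizes <- genome_model$chrom_sizes
    refs <- lapply(names(all_sizes), function(ch)
      sample(bases, all_sizes[[ch]], replace = TRUE))
    names(refs) <- names(all_sizes)
    unlist(lapply(names(sizes), function(ch) refs[[ch]]), use.names = FALSE)
  })

  withr::with_seed(seed, {
    n <- nrow(tab)
    counts <- matrix(0L, n, 4L, dimnames = list(NULL, bases))
    af <- rep(0, n); alt_base <- rep(NA_character_, n)
    if (!is.null(snvs)) {
      key <- paste(tab$chrom, tab$pos)
      idx <- match(paste(snvs$chrom, snvs$pos), key)
      if (anyNA(idx)) stop("planted SNV outside the genome model")
      af[idx] <- snvs$af
      alt_base[idx] <- if ("alt" %in% names(snvs)) snvs$alt else NA
      need <- idx[is.na(alt_base[idx])]
      if (length(need))
        alt_base[need] <- vapply(need, function(i)
          sample(setdiff(bases, tab$ref[i]), 1L), character(1))
      if (any(alt_base[idx] == tab$ref[idx], na.rm = TRUE))
        stop("planted alt equals the reference base")
    }
    for (i in seq_len(n)) {
      p <- setNames(rep(0, 4L), bases)
      others <- setdiff(bases, tab$ref[i])
      p[tab$ref[i]] <- (1 - af[i]) * (1 - error_rate)
      p[others] <- p[others] + (1 - af[i]) * error_rate / 3
      if (af[i] > 0) p[alt_base[i]] <- p[alt_base[i]] + af[i]
      counts[i, ] <- if (error_rate == 0 && (af[i] %in% c(0, 1))) {
        as.integer(round(depth * p))
      } else {
        as.integer(rmultinom(1L, depth, p))
      }
    }
    cbind(tab, as.data.frame(counts))
  })
}
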