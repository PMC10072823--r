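#' Fraction of sequenced bases mapping to mitochondrial coding regions
#'
#' Sums quality-filtered depth of coverage over mitochondrial coding
#' positions and divides by the same sum over the whole genome. The input
#' depth table is assumed to be pre-filtered at base quality > 20 (the
#' samtools-depth default workflow); no further filtering is applied here.
#' Under uniform depth the statistic reduces to the coding-length fraction,
#' and it is invariant to uniform depth scaling.
#'
#' @param depth depth table (chrom, pos, depth).
#' @param mito_coding interval data.frame (chrom, start, end) of
#'   mitochondrial coding regions, 1-based inclusive.
#' @return proportion between 0 and 1.
#' @export
mtdna_fraction <- function(depth, mito_coding) {
  stopifnot(all(c("chrom", "pos", "depth") %in% names(depth)),
            all(c("chrom", "start", "end") %in% names(mito_coding)))
  total <- sum(as.numeric(depth$depth))
  if (total <= 0) stop("total genome depth is zero; fraction undefined")
  in_coding <- rep(FALSE, nrow(depth))
  for (i in seq_len(nrow(mito_coding))) {
    in_coding <- in_coding |
      (depth$chrom == mito_coding$chrom[i] &
         depth$pos >= mito_coding$start[i] & depth$pos <= mito_coding$end[i])
  }
  sum(as.numeric(depth$depth[in_coding])) / total
}

# median depth per fixed-size window, one row per (chrom, window)
.window_depth <- function(depth, window_bp, stat = median) {
  dt <- data.table::as.data.table(depth)
  dt[, win := (pos - 1L) %/% window_bp]
  w <- dt[, .(wdepth = stat(depth)), by = .(chrom, win)]
  as.data.frame(w)
}

#' Call whole-chromosome aneuploidies from depth of coverage
#'
#' Each chromosome's copy ratio is its median windowed depth divided by the
#' median windowed depth over all other chromosomes. A gain (loss) is called
#' when the ratio exceeds `min_ratio_gain` (falls below `max_ratio_loss`)
#' and a Wilcoxon rank-sum test of that chromosome's window depths against
#' all other windows is significant at `alpha` after Bonferroni correction
#' over chromosomes.
#'
#' @param depth depth table (chrom, pos, depth).
#' @param min_ratio_gain,max_ratio_loss copy-ratio thresholds (defaults 1.35
#'   and 0.65).
#' @param alpha familywise significance level.
#' @param window_bp window size for median summarisation (default 1000).
#' @return data.frame (chromosome, copy_ratio, direction, p_value) with one
#'   row per called chromosome; zero rows when the genome is euploid.
#' @export
call_aneuploidies <- function(depth, min_ratio_gain = 1.35,
                              max_ratio_loss = 0.65, alpha = 0.05,
                              window_bp = 1000L) {
  chroms <- unique(depth$chrom)
  if (length(chroms) < 2L) stop("need at least 2 chromosomes")
  sizes <- tapply(depth$pos, depth$chrom, max)
  short <- names(sizes)[sizes < window_bp]
  if (length(short)) {
    warning("skipping chromosomes shorter than one window: ",
            paste(short, collapse = ", "))
    depth <- depth[!depth$chrom %in% short, , drop = FALSE]
    chroms <- setdiff(chroms, short)
  }
  w <- .window_depth(depth, window_bp)
  res <- lapply(chroms, function(ch) {
    own <- w$wdepth[w$chrom == ch]
    rest <- w$wdepth[w$chrom != ch]
    ratio <- median(own) / median(rest)
    p <- suppressWarnings(wilcox.test(own, rest)$p.value)
    if (!is.finite(p)) p <- 1  # fully tied windows: no evidence of a shift
    data.frame(chromosome = ch, copy_ratio = ratio,
               direction = if (ratio >= 1) "gain" else "loss",
               p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$p_value <- pmin(1, res$p_value * length(chroms))  # Bonferroni
  keep <- (res$copy_ratio >= min_ratio_gain | res$copy_ratio <= max_ratio_loss) &
    res$p_value < alpha
  res[keep, , drop = FALSE]
}

#' Call sub-chromosomal copy-number variants from windowed depth
#'
#' Depth is averaged in fixed windows and normalised by the enclosing
#' chromosome's median depth, which removes whole-chromosome (aneuploid)
#' shifts so only focal events remain. Maximal runs of consecutive windows
#' beyond a threshold in the same direction, spanning at least `min_len_bp`,
#' are merged into calls whose copy ratio is the mean normalised depth over
#' the run.
#'
#' @param depth depth table (chrom, pos, depth).
#' @param window_bp window size in bp (default 50).
#' @param gain_threshold,loss_threshold normalised-depth thresholds
#'   (defaults 1.5 and 0.5).
#' @param min_len_bp minimum merged-call span (default 150, below the
#'   smallest event size the design aims to recover).
#' @return data.frame (chromosome, start, end, copy_ratio, n_windows,
#'   artifact_flag); `artifact_flag` is initialised FALSE and only set by
#'   [resolve_cnv_artifacts()].
#' @export
call_cnv_segments <- function(depth, window_bp = 50L, gain_threshold = 1.5,
                              loss_threshold = 0.5, min_len_bp = 150L) {
  stopifnot(window_bp >= 1L)
  out <- list()
  for (ch in unique(depth$chrom)) {
    d <- depth[depth$chrom == ch, , drop = FALSE]
    baseline <- median(d$depth)
    if (baseline <= 0) next
    win <- (d$pos - 1L) %/% window_bp
    win <- factor(win, levels = sort(unique(win)))  # keep genomic order
    wmean <- as.vector(tapply(d$depth, win, mean)) / baseline
    wstart <- as.vector(tapply(d$pos, win, min))
    wend <- as.vector(tapply(d$pos, win, max))
    state <- ifelse(wmean >= gain_threshold, 1L,
                    ifelse(wmean <= loss_threshold, -1L, 0L))
    r <- rle(state)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values != 0L)) {
      s <- wstart[starts[k]]; e <- wend[ends[k]]
      if (e - s + 1L < min_len_bp) next
      out[[length(out) + 1L]] <- data.frame(
        chromosome = ch, start = s, end = e,
        copy_ratio = mean(wmean[starts[k]:ends[k]]),
        n_windows = ends[k] - starts[k] + 1L,
        artifact_flag = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chromosome = character(), start = integer(),
                      end = integer(), copy_ratio = numeric(),
                      n_windows = integer(), artifact_flag = logical()))
  do.call(rbind, out)
}

#' Flag recurrent CNV candidates that reflect shared coverage bias
#'
#' A locus that shows the same relative depth in every sample is a mapping
#' or coverage artifact, not a clone-specific CNV. For each recurrent
#' candidate locus, per-sample mean depth at the locus is regressed on
#' per-sample genome-wide mean depth across *all* samples; a sample keeps
#' its call only when its standardised residual exceeds `residual_cutoff`
#' (the locus is unusually deep or shallow in that sample specifically).
#' All other candidate calls at the locus are flagged as artifacts.
#'
#' @param calls data.frame of candidate CNV calls with a `sample_id` column
#'   plus the [call_cnv_segments()] columns.
#' @param depths named list of depth tables, one per sample (names are
#'   sample ids); must cover every sample with and without candidate calls.
#' @param residual_cutoff absolute standardised-residual threshold
#'   (default 2).
#' @param min_samples minimum number of samples required for the regression
#'   (default 8); with fewer, calls pass through unflagged with a warning.
#' @return `calls` with `artifact_flag` updated.
#' @export
resolve_cnv_artifacts <- function(calls, depths, residual_cutoff = 2,
                                  min_samples = 8L) {
  if (!nrow(calls)) return(calls)
  stopifnot("sample_id" %in% names(calls))
  if (length(depths) < min_samples) {
    warning("fewer than ", min_samples,
            " samples; candidate CNVs passed through unflagged")
    return(calls)
  }
  gmean <- vapply(depths, function(d) mean(d$depth), numeric(1))
  # cluster candidate intervals into recurrent loci by overlap (per chromosome)
  calls$locus_id <- NA_integer_
  next_id <- 1L
  for (ch in unique(calls$chromosome)) {
    idx <- which(calls$chromosome == ch)
    o <- idx[order(calls$start[idx])]
    cur_end <- -Inf; cur_id <- NA_integer_
    for (i in o) {
      if (calls$start[i] > cur_end) {
        cur_id <- next_id; next_id <- next_id + 1L
        cur_end <- calls$end[i]
      } else cur_end <- max(cur_end, calls$end[i])
      calls$locus_id[i] <- cur_id
    }
  }
  for (id in unique(calls$locus_id)) {
    rows <- which(calls$locus_id == id)
    ch <- calls$chromosome[rows[1L]]
    s <- min(calls$start[rows]); e <- max(calls$end[rows])
    lmean <- vapply(depths, function(d) {
      sel <- d$chrom == ch & d$pos >= s & d$pos <= e
      if (!any(sel)) NA_real_ else mean(d$depth[sel])
    }, numeric(1))
    ok <- !is.na(lmean)
    if (sum(ok) < min_samples) {
      warning("locus ", ch, ":", s, "-", e, " covered by fewer than ",
              min_samples, " samples; calls unflagged")
      next
    }
    fit <- lm(lmean[ok] ~ gmean[ok])
    rs <- rstandard(fit)
    rs[!is.finite(rs)] <- 0  # zero-residual (perfect) fits: nothing stands out
    # an (almost) perfect fit means pure shared bias; float noise must not
    # masquerade as a clone-specific deviation
    sigma <- suppressWarnings(summary(fit)$sigma)
    if (!is.finite(sigma) || sigma < 1e-8 * max(1, mean(lmean[ok]))) rs[] <- 0
    names(rs) <- names(depths)[ok]
    keep_samples <- names(rs)[abs(rs) > residual_cutoff]
    calls$artifact_flag[rows] <- !(calls$sample_id[rows] %in% keep_samples)
  }
  calls$locus_id <- NULL
  calls
}

.pileup_alt_stats <- function(p) {
  bases <- c("A", "C", "G", "T")
  cnt <- as.matrix(p[, bases])
  depth <- rowSums(cnt)
  ref_idx <- match(p$ref, bases)
  ref_cnt <- cnt[cbind(seq_len(nrow(cnt)), ref_idx)]
  alt_cnt_mat <- cnt
  alt_cnt_mat[cbind(seq_len(nrow(cnt)), ref_idx)] <- -1L
  alt_idx <- max.col(alt_cnt_mat, ties.method = "first")
  alt_cnt <- cnt[cbind(seq_len(nrow(cnt)), alt_idx)]
  list(depth = depth, ref_count = ref_cnt, alt = bases[alt_idx],
       alt_count = alt_cnt,
       alt_fraction = ifelse(depth > 0, alt_cnt / depth, 0))
}

#' Call clonal SNVs from a pileup with ancestral subtraction
#'
#' A site is called when the evolved clone's most frequent non-reference
#' base reaches `min_alt_fraction` at depth at least `min_depth`, while the
#' same base stays at or below `max_ancestor_alt_fraction` in the ancestor
#' pileup (removing ancestral variants and systematic miscalls). The default
#' alternative-fraction threshold of 0.8 encodes the clonal/haploid
#' assumption for isolates streaked to single colonies.
#'
#' @param sample,ancestor pileup tables (chrom, pos, ref, A, C, G, T) on
#'   identical coordinates.
#' @param min_depth minimum total read depth at the site.
#' @param min_alt_fraction minimum alternative-allele fraction in the clone.
#' @param max_ancestor_alt_fraction maximum fraction of the same base in the
#'   ancestor.
#' @return data.frame (chromosome, position, ref, alt, depth, alt_fraction,
#'   ancestor_alt_fraction).
#' @export
call_snvs <- function(sample, ancestor, min_depth = 10L,
                      min_alt_fraction = 0.8,
                      max_ancestor_alt_fraction = 0.05) {
  if (nrow(sample) != nrow(ancestor) ||
      !all(sample$chrom == ancestor$chrom & sample$pos == ancestor$pos))
    stop("sample and ancestor pileups must share coordinates")
  if (!all(sample$ref == ancestor$ref))
    stop("sample and ancestor pileups disagree on reference bases")
  st <- .pileup_alt_stats(sample)
  bases <- c("A", "C", "G", "T")
  anc_cnt <- as.matrix(ancestor[, bases])
  anc_depth <- rowSums(anc_cnt)
  anc_alt <- anc_cnt[cbind(seq_len(nrow(sample)), match(st$alt, bases))]
  anc_fraction <- ifelse(anc_depth > 0, anc_alt / anc_depth, 0)
  keep <- st$depth >= min_depth & st$alt_fraction >= min_alt_fraction &
    anc_fraction <= max_ancestor_alt_fraction & st$alt_count > 0
  data.frame(chromosome = sample$chrom[keep], position = sample$pos[keep],
             ref = sample$ref[keep], alt = st$alt[keep],
             depth = st$depth[keep], alt_fraction = st$alt_fraction[keep],
             ancestor_alt_fraction = anc_fraction[keep],
             stringsAsFactors = FALSE)
}

#' Annotate calls against a feature interval set
#'
#' Each call receives the label of an overlapping feature; calls with no
#' overlap get the nearest feature on the same chromosome within
#' `proximity_bp`, else a positional label `intergenic:<chrom>:<bin>`.
#' Aneuploidies are always labelled by their chromosome.
#'
#' @param calls data.frame with columns type, chromosome, start, end (plus
#'   any others, preserved).
#' @param features interval set (chrom, start, end, label), e.g. from
#'   [read_intervals()].
#' @param proximity_bp nearest-feature search distance (default 500).
#' @param bin_bp width of intergenic positional bins (default 10000).
#' @return `calls` with an `annotation` column filled in.
#' @export
annotate_calls <- function(calls, features, proximity_bp = 500L,
                           bin_bp = 10000L) {
  if (!nrow(calls)) { calls$annotation <- character(0); return(calls) }
  ann <- character(nrow(calls))
  missing_chroms <- character(0)
  for (i in seq_len(nrow(calls))) {
    if (calls$type[i] == "ANEUPLOIDY") { ann[i] <- calls$chromosome[i]; next }
    f <- features[features$chrom == calls$chromosome[i], , drop = FALSE]
    if (!nrow(f)) {
      missing_chroms <- c(missing_chroms, calls$chromosome[i])
      ann[i] <- calls$chromosome[i]
      next
    }
    hit <- f$start <= calls$end[i] & f$end >= calls$start[i]
    if (any(hit)) { ann[i] <- f$label[which(hit)[1L]]; next }
    gap <- pmax(f$start - calls$end[i], calls$start[i] - f$end, 0L)
    j <- which.min(gap)
    ann[i] <- if (gap[j] <= proximity_bp) f$label[j] else
      sprintf("intergenic:%s:%d", calls$chromosome[i],
              (calls$start[i] - 1L) %/% bin_bp)
  }
  if (length(missing_chroms))
    warning("no features on chromosome(s) ",
            paste(unique(missing_chroms), collapse = ", "),
            "; calls labelled by chromosome")
  calls$annotation <- ann
  calls
}
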