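#' Build mutational profiles per evolutionary circumstance
#'
#' Counts mutation calls per (circumstance, annotation) cell, giving equal
#' weight to every mutation type — an aneuploidy spanning a megabase and a
#' single-nucleotide variant each contribute one count, so profile distance
#' reflects which loci were hit, not how large the events were. Calls
#' flagged as artifacts are excluded.
#'
#' @param calls mutation-call table with clone_id and annotation columns
#'   (artifact_flag honoured when present).
#' @param metadata clone metadata with clone_id and circumstance columns
#'   (plus nuclear, mito, medium, carried as an attribute for downstream
#'   partitioning).
#' @return integer matrix (circumstances x annotations) of class
#'   `profile_matrix`, with the circumstance metadata in
#'   `attr(, "circumstances")`.
#' @export
build_profiles <- function(calls, metadata) {
  stopifnot(all(c("clone_id", "annotation") %in% names(calls)),
            all(c("clone_id", "circumstance") %in% names(metadata)))
  if ("artifact_flag" %in% names(calls))
    calls <- calls[!calls$artifact_flag, , drop = FALSE]
  idx <- match(calls$clone_id, metadata$clone_id)
  if (anyNA(idx))
    stop("calls reference unknown clone_id: ",
         paste(unique(calls$clone_id[is.na(idx)]), collapse = ", "))
  circ_levels <- unique(metadata$circumstance)
  circ <- factor(metadata$circumstance[idx], levels = circ_levels)
  ann <- factor(calls$annotation)
  m <- table(circ, ann)
  out <- matrix(as.integer(m), nrow = nrow(m), dimnames = dimnames(m))
  names(dimnames(out)) <- NULL
  circ_meta <- metadata[!duplicated(metadata$circumstance),
                        intersect(c("circumstance", "genotype", "nuclear",
                                    "mito", "medium"), names(metadata)),
                        drop = FALSE]
  rownames(circ_meta) <- NULL
  attr(out, "circumstances") <- circ_meta
  class(out) <- c("profile_matrix", class(out))
  out
}

#' Bray-Curtis dissimilarity between mutational profiles
#'
#' For count vectors u, v: `BC(u, v) = 1 - 2 * sum(pmin(u, v)) /
#' (sum(u) + sum(v))`, a compositional distance in \[0, 1\] that is 0 for
#' identical profiles and 1 for profiles with disjoint support. A pair of
#' all-zero rows has an undefined dissimilarity and is reported as NA with
#' a warning.
#'
#' @param profiles matrix (rows = circumstances, columns = annotations) of
#'   non-negative counts.
#' @return symmetric matrix with zero diagonal, entries in \[0, 1\].
#' @examples
#' bray_curtis_matrix(rbind(a = c(3, 1, 0), b = c(1, 1, 2)))["a", "b"]  # 0.5
#' @export
bray_curtis_matrix <- function(profiles) {
  m <- as.matrix(unclass(profiles))
  if (nrow(m) < 2L) stop("need at least 2 profiles")
  if (any(m < 0)) stop("profile counts must be non-negative")
  n <- nrow(m)
  rs <- rowSums(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  warned <- FALSE
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    denom <- rs[i] + rs[j]
    if (denom == 0) {
      out[i, j] <- out[j, i] <- NA_real_
      warned <- TRUE
    } else {
      bc <- 1 - 2 * sum(pmin(m[i, ], m[j, ])) / denom
      out[i, j] <- out[j, i] <- bc
    }
  }
  if (warned) warning("pair(s) of all-zero profiles: dissimilarity undefined (NA)")
  out
}

#' Nonmetric multidimensional scaling of a dissimilarity matrix
#'
#' Rank-based (nonmetric) MDS minimising Kruskal stress-1, restarted from
#' many initial configurations and keeping the best. The first start is the
#' classical metric (principal-coordinates) configuration; the remaining
#' `n_init - 1` are random. The monotone-regression engine is
#' [vegan::monoMDS()] (global model, primary tie treatment); multi-start
#' control and seeding live here. The full-scale default of 10,000 starts
#' matches exhaustive published practice; reduce `n_init` for interactive
#' use.
#'
#' @param D square symmetric dissimilarity matrix (or `dist`).
#' @param dims embedding dimension (must be < number of points).
#' @param n_init number of initial configurations.
#' @param max_iter maximum iterations per start.
#' @param tol stress tolerance declaring convergence.
#' @param seed integer seed; results are deterministic given the seed.
#' @return list of class `nmds_result`: coordinates (points x dims), stress
#'   (Kruskal stress-1 of the retained solution), all_stress (every start's
#'   final stress), n_init_used, converged.
#' @export
nmds_embed <- function(D, dims = 2L, n_init = 10000L, max_iter = 3000L,
                       tol = 1e-9, seed = 1L) {
  m <- as.matrix(D)
  n <- nrow(m)
  if (dims >= n) stop("dims must be smaller than the number of points")
  if (anyNA(m)) stop("dissimilarity matrix contains NA")
  d <- stats::as.dist(m)
  withr::with_seed(seed, {
    run <- function(y) {
      fit <- vegan::monoMDS(d, y = y, k = dims, model = "global",
                            maxit = max_iter, smin = tol, sfgrmin = 1e-12,
                            sratmax = 1 - 1e-12)
      list(points = fit$points, stress = fit$stress,
           # icause 1 = stopped at maxit; 2-4 = a convergence criterion fired
           converged = fit$icause != 1L)
    }
    metric_start <- tryCatch({
      y <- stats::cmdscale(d, k = dims)
      if (ncol(y) < dims) cbind(y, matrix(0, n, dims - ncol(y))) else y
    }, error = function(e) matrix(runif(n * dims, -1, 1), n, dims))
    best <- run(metric_start)
    all_stress <- best$stress
    for (i in seq_len(max(0L, n_init - 1L))) {
      cand <- run(matrix(runif(n * dims, -1, 1), n, dims))
      all_stress <- c(all_stress, cand$stress)
      if (cand$stress < best$stress) best <- cand
    }
    rownames(best$points) <- rownames(m)
    colnames(best$points) <- paste0("NMDS", seq_len(dims))
    structure(list(coordinates = best$points, stress = best$stress,
                   all_stress = all_stress, n_init_used = n_init,
                   converged = best$converged),
              class = "nmds_result")
  })
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS embedding: %d points, stress-1 = %.4g over %d starts\n",
              nrow(x$coordinates), x$stress, x$n_init_used))
  invisible(x)
}

#' Partition a dissimilarity matrix by match/mismatch structure
#'
#' Every unordered pair of circumstances is classified by whether the two
#' members share the environment, the nuclear background, and the
#' mitochondrial background (three booleans, eight classes), and the
#' pairwise dissimilarities are submitted to a three-way factorial ANOVA
#' with all interactions, testing whether each kind of match shapes the
#' divergence of mutational profiles.
#'
#' @param D dissimilarity matrix with circumstance row names.
#' @param circ_meta data.frame (circumstance, nuclear, mito, medium), e.g.
#'   `attr(profiles, "circumstances")`.
#' @return list with `pairs` (one row per pair: the booleans and the
#'   dissimilarity) and `anova` (the three-way [factorial_anova()] table).
#' @export
partition_dissimilarity <- function(D, circ_meta) {
  m <- as.matrix(D)
  stopifnot(!is.null(rownames(m)))
  idx <- match(rownames(m), circ_meta$circumstance)
  if (anyNA(idx)) stop("circumstance metadata does not cover all rows of D")
  meta <- circ_meta[idx, ]
  n <- nrow(m)
  pr <- which(upper.tri(m), arr.ind = TRUE)
  pairs <- data.frame(
    circ1 = rownames(m)[pr[, 1L]], circ2 = rownames(m)[pr[, 2L]],
    env_match = meta$medium[pr[, 1L]] == meta$medium[pr[, 2L]],
    nuclear_match = meta$nuclear[pr[, 1L]] == meta$nuclear[pr[, 2L]],
    mito_match = meta$mito[pr[, 1L]] == meta$mito[pr[, 2L]],
    dissimilarity = m[pr], stringsAsFactors = FALSE)
  ok <- !is.na(pairs$dissimilarity)
  an <- factorial_anova(pairs$dissimilarity[ok],
                        list(env_match = pairs$env_match[ok],
                             nuclear_match = pairs$nuclear_match[ok],
                             mito_match = pairs$mito_match[ok]))
  list(pairs = pairs, anova = an)
}

# chi-squared statistic of independence for a 2 x k table, no continuity
# correction (matches chisq.test(correct = FALSE))
.chi2_independence <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  list(stat = sum((tab - e)^2 / e), df = (nrow(tab) - 1L) * (ncol(tab) - 1L),
       min_expected = min(e))
}

#' Mutual information of a contingency table, in dits
#'
#' MI computed from the empirical joint frequencies, using base-10
#' logarithms (1 dit = log2(10) bits). Zero cells contribute zero. MI is 0
#' exactly when the table is a product of its margins and is invariant to
#' row/column permutation.
#'
#' @param tab non-negative count matrix.
#' @return mutual information in dits (>= 0).
#' @examples
#' mutual_information_dits(diag(c(10, 10)))  # log10(2)
#' @export
mutual_information_dits <- function(tab) {
  n <- sum(tab)
  if (n == 0) return(0)
  p <- tab / n
  pr <- rowSums(p); pc <- colSums(p)
  e <- outer(pr, pc)
  nz <- p > 0
  sum(p[nz] * log10(p[nz] / e[nz]))
}

.call_categories <- function(calls, metadata,
                             factor = c("medium", "mitonuclear", "nuclear",
                                        "mito", "medium_x_background")) {
  factor <- match.arg(factor)
  idx <- match(calls$clone_id, metadata$clone_id)
  if (anyNA(idx)) stop("calls reference unknown clone_id")
  switch(factor,
         medium = metadata$medium[idx],
         mitonuclear = metadata$genotype[idx],
         nuclear = metadata$nuclear[idx],
         mito = metadata$mito[idx],
         medium_x_background = paste(metadata$genotype[idx],
                                     metadata$medium[idx], sep = "."))
}

#' Score locus specificity by joint chi-squared and mutual information
#'
#' For each annotation, all mutation calls are cross-tabulated as inside
#' versus outside the locus against the levels of the chosen factor (carbon
#' source, mitonuclear background, nuclear or mitochondrial background
#' alone, or their conjunction). The 2 x k table yields a chi-squared test
#' of independence (no continuity correction) and a mutual information in
#' dits. An annotation is called *specific* when its Benjamini-Hochberg
#' q-value is at most `fdr_alpha` AND its MI lies at least `mi_sd_mult`
#' standard deviations above the mean MI across all tested annotations
#' (roughly the 95th percentile at the default of 2) — the dual threshold
#' guards against large-count loci that are statistically but not
#' informationally distinctive.
#'
#' @param calls mutation-call table (clone_id, annotation; artifact_flag
#'   honoured).
#' @param metadata clone metadata.
#' @param factor which partition of the calls to test.
#' @param fdr_alpha FDR level (default 0.05).
#' @param mi_sd_mult MI threshold in SD units above the mean (default 2).
#' @param monte_carlo use a Monte-Carlo chi-squared p-value
#'   (`chisq.test(simulate.p.value = TRUE)`) instead of the asymptotic one.
#' @param b Monte-Carlo replicates.
#' @return data.frame (annotation, chi2_stat, p_value, q_value, mi_dits,
#'   specific), one row per annotation with at least one call. A
#'   small-sample warning is raised when any expected cell count is < 1.
#' @export
locus_specificity <- function(calls, metadata, factor = "mitonuclear",
                              fdr_alpha = 0.05, mi_sd_mult = 2,
                              monte_carlo = FALSE, b = 2000L) {
  if ("artifact_flag" %in% names(calls))
    calls <- calls[!calls$artifact_flag, , drop = FALSE]
  if (!nrow(calls)) stop("no calls to test")
  category <- .call_categories(calls, metadata, factor)
  cat_f <- base::factor(category)
  if (nlevels(cat_f) < 2L) stop("need at least 2 categories")
  ann_f <- base::factor(calls$annotation)
  counts_in <- table(ann_f, cat_f)          # annotations x categories
  totals <- as.vector(table(cat_f))
  res <- lapply(seq_len(nrow(counts_in)), function(i) {
    in_k <- as.vector(counts_in[i, ])
    tab <- rbind(inside = in_k, outside = totals - in_k)
    ch <- .chi2_independence(tab)
    p <- if (monte_carlo) {
      suppressWarnings(chisq.test(tab, simulate.p.value = TRUE, B = b)$p.value)
    } else pchisq(ch$stat, ch$df, lower.tail = FALSE)
    data.frame(annotation = rownames(counts_in)[i], chi2_stat = ch$stat,
               p_value = p, mi_dits = mutual_information_dits(tab),
               min_expected = ch$min_expected, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (any(res$min_expected < 1))
    warning("expected cell counts < 1 for some annotations; ",
            "consider monte_carlo = TRUE")
  res$min_expected <- NULL
  res$q_value <- p.adjust(res$p_value, method = "BH")
  mi_cut <- mean(res$mi_dits) + mi_sd_mult * sd(res$mi_dits)
  if (is.na(mi_cut)) mi_cut <- Inf  # a single annotation: SD undefined
  res$specific <- res$q_value <= fdr_alpha & res$mi_dits >= mi_cut
  res[, c("annotation", "chi2_stat", "p_value", "q_value", "mi_dits",
          "specific")]
}

#' Chi-squared goodness-of-fit test of a count distribution
#'
#' Tests observed counts per category against expected proportions (uniform
#' by default), the test used to flag uneven distribution of mutation
#' counts across mitonuclear backgrounds and carbon sources.
#'
#' @param counts named or unnamed vector of category counts (>= 2).
#' @param expected expected proportions (default uniform); must be positive.
#' @return list (chi2, df, p).
#' @export
count_distribution_test <- function(counts, expected = NULL) {
  k <- length(counts)
  if (k < 2L) stop("need at least 2 categories")
  if (is.null(expected)) expected <- rep(1 / k, k)
  if (length(expected) != k) stop("expected length mismatch")
  expected <- expected / sum(expected)
  e <- sum(counts) * expected
  if (any(e == 0)) stop("expected count of 0 in a cell")
  stat <- sum((counts - e)^2 / e)
  list(chi2 = stat, df = k - 1L, p = pchisq(stat, k - 1L, lower.tail = FALSE))
}

# collapse a ref>alt substitution to its pyrimidine-context class
.spectrum_class <- function(ref, alt) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip <- ref %in% c("A", "G")
  ref2 <- ifelse(flip, comp[ref], ref)
  alt2 <- ifelse(flip, comp[alt], alt)
  paste0(ref2, ">", alt2)
}

#' Compare nucleotide-level mutation spectra between clone groups
#'
#' SNVs are collapsed to the six pyrimidine-context substitution classes
#' (C>A, C>G, C>T, T>A, T>C, T>G) and a chi-squared test of independence
#' between groups is performed on the group x class table. Groups with no
#' SNVs are excluded with a warning.
#'
#' @param snv_calls table with clone_id, ref_allele, alt_allele (SNVs only;
#'   other types are ignored).
#' @param clone_groups data.frame (clone_id, group).
#' @return list (spectrum: group x class count matrix, chi2, df, p).
#' @export
mutation_spectrum_test <- function(snv_calls, clone_groups) {
  if ("type" %in% names(snv_calls))
    snv_calls <- snv_calls[snv_calls$type == "SNV", , drop = FALSE]
  snv_calls <- snv_calls[!is.na(snv_calls$ref_allele), , drop = FALSE]
  grp <- clone_groups$group[match(snv_calls$clone_id, clone_groups$clone_id)]
  if (anyNA(grp)) stop("SNVs reference clones without a group")
  cls <- .spectrum_class(snv_calls$ref_allele, snv_calls$alt_allele)
  classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  tab <- table(factor(grp, levels = sort(unique(clone_groups$group))),
               factor(cls, levels = classes))
  empty <- rowSums(tab) == 0
  if (any(empty)) {
    warning("group(s) with 0 SNVs excluded: ",
            paste(rownames(tab)[empty], collapse = ", "))
    tab <- tab[!empty, , drop = FALSE]
  }
  if (nrow(tab) < 2L) stop("need at least 2 non-empty groups")
  use <- colSums(tab) > 0
  ch <- .chi2_independence(as.matrix(tab[, use, drop = FALSE]))
  list(spectrum = as.matrix(tab), chi2 = ch$stat, df = ch$df,
       p = pchisq(ch$stat, ch$df, lower.tail = FALSE))
}

#' Associate mutant annotations with phenotype measurements
#'
#' Within each circumstance, clones carrying at least one (non-artifact)
#' call at an annotation are compared with clones carrying none by a
#' Wilcoxon rank-sum test on the phenotype; tests run only where both
#' groups reach `min_mutant_clones`. P-values are Benjamini-Hochberg
#' adjusted over all performed tests. The effect size is the difference of
#' group medians (mutant minus non-mutant).
#'
#' @param calls mutation-call table.
#' @param phenotypes data.frame (clone_id, value).
#' @param metadata clone metadata (clone_id, circumstance).
#' @param min_mutant_clones minimum clones required in each group.
#' @return data.frame (annotation, circumstance, n_mutant, n_other,
#'   effect, p, q).
#' @export
phenotype_association <- function(calls, phenotypes, metadata,
                                  min_mutant_clones = 5L) {
  if ("artifact_flag" %in% names(calls))
    calls <- calls[!calls$artifact_flag, , drop = FALSE]
  ph <- phenotypes$value[match(metadata$clone_id, phenotypes$clone_id)]
  rows <- list()
  for (cc in unique(metadata$circumstance)) {
    in_cc <- metadata$circumstance == cc & !is.na(ph)
    clones_cc <- metadata$clone_id[in_cc]
    calls_cc <- calls[calls$clone_id %in% clones_cc, , drop = FALSE]
    for (a in unique(calls_cc$annotation)) {
      mut <- clones_cc %in% calls_cc$clone_id[calls_cc$annotation == a]
      n1 <- sum(mut); n0 <- sum(!mut)
      if (n1 < min_mutant_clones || n0 < min_mutant_clones) next
      y1 <- ph[in_cc][mut]; y0 <- ph[in_cc][!mut]
      p <- suppressWarnings(wilcox.test(y1, y0)$p.value)
      rows[[length(rows) + 1L]] <- data.frame(
        annotation = a, circumstance = cc, n_mutant = n1, n_other = n0,
        effect = median(y1) - median(y0), p = p, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(annotation = character(), circumstance = character(),
                      n_mutant = integer(), n_other = integer(),
                      effect = numeric(), p = numeric(), q = numeric()))
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
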