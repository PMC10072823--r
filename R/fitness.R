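#' Estimate a selection coefficient from a competition time series
#'
#' Ordinary least squares of `log(count_mutant / count_reference)` on
#' elapsed generations; the slope is the per-generation selection
#' coefficient s (dimensionless), comparable across media with different
#' growth rates. Days on which either population has a zero count receive a
#' symmetric pseudocount on both populations (default 0.5) so the log ratio
#' stays defined.
#'
#' @param series data.frame (day, count_mutant, count_reference); at least
#'   3 usable timepoints (a 3-day assay with its day-0 mix gives 4).
#' @param generations_per_day generations elapsed per day (> 0; default
#'   5.2, matching a serial-passage regime of roughly 300 generations over
#'   58 days).
#' @param pseudocount added to both counts on days where either is zero.
#' @return list of class `fitness_effect`: s, se, r2, n_days, plus any
#'   identifier columns (assay_id, genotype, locus, medium) found on the
#'   series.
#' @examples
#' ser <- generate_competition_series(s_true = log(2), days = 3,
#'   generations_per_day = 1, count_depth = Inf)
#' estimate_fitness(ser, generations_per_day = 1)$s  # log(2)
#' @export
estimate_fitness <- function(series, generations_per_day = 5.2,
                             pseudocount = 0.5) {
  stopifnot(generations_per_day > 0,
            all(c("day", "count_mutant", "count_reference") %in% names(series)))
  cm <- series$count_mutant; cr <- series$count_reference
  if (any(cm < 0 | cr < 0)) stop("counts must be non-negative")
  dead <- cm == 0 & cr == 0
  cm <- cm[!dead]; cr <- cr[!dead]; day <- series$day[!dead]
  if (length(day) < 3L)
    stop(structure(class = c("insufficient_series", "error", "condition"),
                   list(message = "fewer than 3 usable timepoints",
                        call = sys.call())))
  zero <- cm == 0 | cr == 0
  cm[zero] <- cm[zero] + pseudocount
  cr[zero] <- cr[zero] + pseudocount
  y <- log(cm / cr)
  x <- day * generations_per_day
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # perfect fits warn; se is then 0
  se <- sm$coefficients["x", "Std. Error"]
  out <- list(s = unname(coef(fit)[["x"]]),
              se = if (is.finite(se)) se else 0,
              r2 = if (is.null(sm$r.squared)) NA_real_ else sm$r.squared,
              n_days = length(day))
  for (col in c("assay_id", "genotype", "locus", "medium"))
    if (col %in% names(series)) out[[col]] <- series[[col]][1L]
  class(out) <- "fitness_effect"
  out
}

#' @export
print.fitness_effect <- function(x, ...) {
  cat(sprintf("s = %.4g per generation (se %.3g, R2 %.3f, %d days)\n",
              x$s, x$se, x$r2, x$n_days))
  invisible(x)
}

#' Tabulate fitness effects and test mitonuclear interaction per locus
#'
#' Builds the mean selection-coefficient matrix (locus x genotype, per
#' medium) and, for each locus and medium with replicated assays over at
#' least two nuclear and two mitochondrial backgrounds, runs a two-way
#' [factorial_anova()] of s on nuclear x mitochondrial background — the
#' test of whether a knockout's cost depends on the mitonuclear genotype
#' and its interaction.
#'
#' @param effects data.frame with columns s, genotype (two-character
#'   label), locus, medium (one row per assay replicate).
#' @return list with `matrix` (data.frame locus x genotype mean s, split by
#'   medium) and `anova` (named list of anova tables per locus/medium
#'   tested; loci with a single genotype are skipped).
#' @export
fitness_matrix <- function(effects) {
  stopifnot(all(c("s", "genotype", "locus", "medium") %in% names(effects)))
  effects$nuclear <- genotype_nuclear(effects$genotype)
  effects$mito <- genotype_mito(effects$genotype)
  agg <- stats::aggregate(s ~ locus + genotype + medium, data = effects, FUN = mean)
  mats <- lapply(split(agg, agg$medium), function(a) {
    stats::xtabs(s ~ locus + genotype, data = a) |> as.matrix()
  })
  anovas <- list()
  for (key in unique(paste(effects$locus, effects$medium, sep = "|"))) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1L]]
    e <- effects[effects$locus == parts[1L] & effects$medium == parts[2L], ]
    if (length(unique(e$genotype)) < 2L) next
    if (length(unique(e$nuclear)) < 2L || length(unique(e$mito)) < 2L) next
    anovas[[key]] <- tryCatch(
      factorial_anova(e$s, list(nuclear = e$nuclear, mito = e$mito)),
      error = function(err) NULL)
  }
  list(matrix = mats, anova = anovas[!vapply(anovas, is.null, logical(1))])
}

#' Concordance between fitness preference and mutation frequency
#'
#' Tests whether loci preferred by selection (larger fitness effects) are
#' also the loci hit most often during evolution: Spearman rank correlation
#' between the two vectors, plus the p-value that the linear-regression
#' slope of mutation frequency on fitness effect is zero. Concordance is
#' declared when `rho > rho_threshold` and the slope p-value is below 0.05.
#'
#' @param fitness numeric vector of per-locus fitness effects.
#' @param frequency numeric vector of per-locus mutation frequencies,
#'   aligned with `fitness`.
#' @param rho_threshold Spearman threshold (default 0.7).
#' @return list of class `concordance_result`: rho, slope_p, concordant.
#'   A constant input vector makes rho undefined (NA, with a warning).
#' @export
rank_concordance <- function(fitness, frequency, rho_threshold = 0.7) {
  stopifnot(length(fitness) == length(frequency), length(fitness) >= 3L)
  if (sd(fitness) == 0 || sd(frequency) == 0) {
    warning("constant vector: Spearman rho undefined")
    return(structure(list(rho = NA_real_, slope_p = NA_real_,
                          concordant = NA), class = "concordance_result"))
  }
  rho <- suppressWarnings(
    cor.test(fitness, frequency, method = "spearman")$estimate)
  slope_p <- suppressWarnings(
    summary(lm(frequency ~ fitness)))$coefficients[2L, 4L]
  structure(list(rho = unname(rho), slope_p = slope_p,
                 concordant = unname(rho) > rho_threshold & slope_p < 0.05),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f, slope p = %.3g -> %s\n", x$rho,
              x$slope_p,
              if (isTRUE(x$concordant)) "concordant" else "not concordant"))
  invisible(x)
}
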