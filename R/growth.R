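#' Fit a colony growth curve to the modified Gompertz model
#'
#' Least-squares fit of the Zwietering modified Gompertz form (see
#' [gompertz()]) on the raw size scale. Starting values come from
#' data-driven heuristics (A from the maximum size, mu from the steepest
#' finite-difference slope, lambda from the time of first rise) and the fit
#' is restarted from a small deterministic grid of perturbed starts; the
#' lowest residual sum of squares wins.
#'
#' @param time,size numeric vectors (hours, colony size); at least 5 points,
#'   strictly increasing times, non-negative sizes.
#' @param log_transform fit on log(size + 1) instead of the raw scale.
#' @param on_degenerate `"error"` (default) raises a `degenerate_curve`
#'   condition for flat or monotone-decreasing curves; `"flag"` returns a
#'   non-converged fit instead.
#' @return list of class `gompertz_fit`: A, mu, lam, rss, converged.
#' @examples
#' t <- seq(0, 48, 2)
#' y <- gompertz(t, 1.2, 0.25, 3)
#' unlist(fit_gompertz(t, y)[c("A", "mu", "lam")])
#' @export
fit_gompertz <- function(time, size, log_transform = FALSE,
                         on_degenerate = c("error", "flag")) {
  on_degenerate <- match.arg(on_degenerate)
  stopifnot(length(time) == length(size), length(time) >= 5L,
            all(diff(time) > 0), all(size >= 0))
  y <- if (log_transform) log1p(size) else size
  degenerate <- function(msg) {
    if (on_degenerate == "error")
      stop(structure(class = c("degenerate_curve", "error", "condition"),
                     list(message = msg, call = sys.call(-1))))
    structure(list(A = NA_real_, mu = NA_real_, lam = NA_real_,
                   rss = NA_real_, converged = FALSE),
              class = "gompertz_fit")
  }
  rng <- max(y) - min(y)
  slopes <- diff(y) / diff(time)
  if (rng <= .Machine$double.eps || max(slopes) <= 0)
    return(degenerate("flat or monotone-decreasing curve"))

  a0 <- max(y)
  mu0 <- max(slopes)
  risen <- which(y >= min(y) + 0.1 * rng)
  lam0 <- max(0, time[risen[1L]] - (y[risen[1L]] - min(y)) / mu0)

  # deterministic multi-start grid around the heuristics
  grid <- expand.grid(fa = c(1, 1.2), fm = c(1, 0.5, 2), fl = c(1, 0.25),
                      KEEP.OUT.ATTRS = FALSE)
  best <- NULL
  dat <- data.frame(t = time, y = y)
  for (g in seq_len(nrow(grid))) {
    st <- list(A = a0 * grid$fa[g], mu = mu0 * grid$fm[g],
               lam = max(0, lam0 * grid$fl[g]))
    fit <- tryCatch(
      nls(y ~ A * exp(-exp(mu * exp(1) / A * (lam - t) + 1)),
          data = dat, start = st, algorithm = "port",
          lower = c(A = 1e-9, mu = 1e-9, lam = 0),
          control = list(maxiter = 200, warnOnly = FALSE)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss)
      best <- c(as.list(coef(fit)), list(rss = rss))
  }
  if (is.null(best)) return(degenerate("optimizer failed from all starts"))
  structure(list(A = best$A, mu = best$mu, lam = best$lam, rss = best$rss,
                 converged = TRUE), class = "gompertz_fit")
}

#' @export
print.gompertz_fit <- function(x, ...) {
  cat(sprintf("Gompertz fit: A=%.4g mu=%.4g lam=%.4g rss=%.3g (%s)\n",
              x$A, x$mu, x$lam, x$rss,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' Fit all growth curves of a plate and aggregate per clone
#'
#' Fits every curve with [fit_gompertz()] (non-converged fits are excluded
#' and counted) and reports the per-clone median of mu and A over replicate
#' curves, supporting the heavily replicated technical designs (8-42
#' replicates per strain) of robotic colony phenotyping.
#'
#' @param curves data.frame (curve_id, clone_id, time_h, size).
#' @param metadata optional clone metadata merged onto the result by
#'   clone_id.
#' @param ... passed to [fit_gompertz()] (`on_degenerate` is forced to
#'   `"flag"` so single bad curves never abort a plate).
#' @return data.frame (clone_id, mu, A, n_replicates, n_converged, missing);
#'   `missing` is TRUE when no replicate converged.
#' @export
fit_plate <- function(curves, metadata = NULL, ...) {
  stopifnot(all(c("curve_id", "clone_id", "time_h", "size") %in% names(curves)))
  fits <- lapply(split(curves, curves$curve_id), function(cv) {
    f <- fit_gompertz(cv$time_h[order(cv$time_h)], cv$size[order(cv$time_h)],
                      on_degenerate = "flag", ...)
    data.frame(clone_id = cv$clone_id[1L], converged = f$converged,
               mu = f$mu, A = f$A, stringsAsFactors = FALSE)
  })
  fits <- do.call(rbind, fits)
  agg <- lapply(split(fits, fits$clone_id), function(fc) {
    ok <- fc$converged
    data.frame(clone_id = fc$clone_id[1L],
               mu = if (any(ok)) median(fc$mu[ok]) else NA_real_,
               A = if (any(ok)) median(fc$A[ok]) else NA_real_,
               n_replicates = nrow(fc), n_converged = sum(ok),
               missing = !any(ok), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  if (!is.null(metadata)) out <- merge(out, metadata, by = "clone_id")
  out
}

# terms of a full-factorial formula as character vectors of factor names
.term_factors <- function(tt) {
  labs <- attr(tt, "term.labels")
  lapply(strsplit(labs, ":", fixed = TRUE), sort)
}

#' Factorial ANOVA with Type II sums of squares
#'
#' Fixed-effects factorial ANOVA for two or three crossed factors with all
#' interactions. Sums of squares are Type II (each term is adjusted for all
#' terms that do not contain it), the appropriate choice for the unbalanced
#' replicate counts that survive an evolution experiment; on balanced
#' designs Type II coincides with the sequential decomposition. Terms made
#' inestimable by empty cells are dropped with a warning.
#'
#' @param values numeric response vector.
#' @param factors named list of 2 or 3 vectors (coerced to factor), same
#'   length as `values`.
#' @param include_interactions include all interaction terms (default TRUE).
#' @return data.frame of class `anova_table` (term, sum_sq, df, F, p) with a
#'   final Residuals row.
#' @examples
#' set.seed(1)
#' d <- expand.grid(a = c("x", "y"), b = c("u", "v"))[rep(1:4, 5), ]
#' factorial_anova(rnorm(20), list(a = d$a, b = d$b))
#' @export
factorial_anova <- function(values, factors, include_interactions = TRUE) {
  stopifnot(is.list(factors), length(factors) %in% c(2L, 3L))
  if (is.null(names(factors)) || any(!nzchar(names(factors))))
    names(factors) <- paste0("f", seq_along(factors))
  dat <- data.frame(.y = values, lapply(factors, factor))
  if (any(vapply(dat[-1L], nlevels, integer(1)) < 2L))
    stop("every factor needs at least 2 levels")
  fnames <- names(factors)
  full_rhs <- if (include_interactions)
    paste(fnames, collapse = " * ") else paste(fnames, collapse = " + ")
  full_formula <- stats::as.formula(paste(".y ~", full_rhs))
  full <- lm(full_formula, data = dat)
  tt <- terms(full)
  tfac <- .term_factors(tt)
  labs <- attr(tt, "term.labels")

  rss_full <- sum(resid(full)^2)
  df_res <- df.residual(full)
  mse <- rss_full / df_res

  fit_rss <- function(term_labels) {
    f <- if (length(term_labels))
      reformulate(term_labels, response = ".y") else .y ~ 1
    m <- lm(f, data = dat)
    c(sum(resid(m)^2), df.residual(m))
  }

  rows <- list()
  for (i in seq_along(labs)) {
    contains_i <- vapply(tfac, function(s)
      all(tfac[[i]] %in% s) && length(s) > length(tfac[[i]]), logical(1))
    with_term <- labs[!contains_i]
    without_term <- setdiff(with_term, labs[i])
    r1 <- fit_rss(with_term)
    r0 <- fit_rss(without_term)
    ss <- r0[1L] - r1[1L]
    df <- r0[2L] - r1[2L]
    if (df <= 0) {
      warning("term ", labs[i], " inestimable (empty cells); dropped")
      next
    }
    f_stat <- (ss / df) / mse
    rows[[length(rows) + 1L]] <- data.frame(
      term = labs[i], sum_sq = ss, df = df, F = f_stat,
      p = pf(f_stat, df, df_res, lower.tail = FALSE),
      stringsAsFactors = FALSE)
  }
  out <- rbind(do.call(rbind, rows),
               data.frame(term = "Residuals", sum_sq = rss_full, df = df_res,
                          F = NA_real_, p = NA_real_, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Tukey HSD pairwise comparisons
#'
#' All pairwise mean differences between groups with studentized-range
#' adjusted p-values. Comparisons involving singleton groups are reported
#' but their p-values are set to NA (a single observation gives no
#' within-group variance contribution to compare against).
#'
#' @param values numeric response vector.
#' @param groups group labels (coerced to factor, >= 2 groups).
#' @param alpha significance level for the `significant` flag.
#' @return data.frame (group1, group2, diff, lwr, upr, p_adj, significant).
#' @export
tukey_posthoc <- function(values, groups, alpha = 0.05) {
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  fit <- aov(values ~ g)
  tk <- TukeyHSD(fit)$g
  parts <- strsplit(rownames(tk), "-", fixed = TRUE)
  out <- data.frame(group1 = vapply(parts, `[`, "", 1L),
                    group2 = vapply(parts, `[`, "", 2L),
                    diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
                    p_adj = tk[, "p adj"], stringsAsFactors = FALSE)
  n_by <- table(g)
  singleton <- names(n_by)[n_by < 2L]
  und <- out$group1 %in% singleton | out$group2 %in% singleton
  out$p_adj[und] <- NA_real_
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  rownames(out) <- NULL
  out
}
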