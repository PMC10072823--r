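#' Modified Gompertz growth model
#'
#' The Zwietering reparameterisation of the Gompertz curve, written in terms
#' of biologically meaningful parameters: carrying capacity `A` (size
#' units), maximum specific growth rate `mu` (size units per hour, the slope
#' at the inflection point), and lag time `lam` (hours):
#' \deqn{y(t) = A \exp(-\exp(\mu e / A (\lambda - t) + 1))}
#'
#' @param t time (hours).
#' @param A carrying capacity (> 0).
#' @param mu maximum specific growth rate (> 0).
#' @param lam lag time (>= 0).
#' @return colony size at time `t`.
#' @export
gompertz <- function(t, A, mu, lam) {
  A * exp(-exp(mu * exp(1) / A * (lam - t) + 1))
}

#' Simulate replicate colony growth curves
#'
#' Curves follow the modified Gompertz form with additive Gaussian noise
#' (truncated at zero), emulating robot-imaged colony-size time series.
#' The default of 4 replicates matches typical biological replication in
#' high-throughput colony phenotyping.
#'
#' @param params named vector (A, mu, lam) of true parameters.
#' @param noise_sd additive Gaussian noise SD (size units).
#' @param timepoints measurement times in hours (at least 5).
#' @param n_replicates number of replicate curves.
#' @param seed integer seed.
#' @param curve_prefix prefix for curve identifiers.
#' @return data.frame (curve_id, time_h, size).
#' @export
generate_growth_curves <- function(params = c(A = 1.2, mu = 0.25, lam = 3),
                                   noise_sd = 0.02,
                                   timepoints = seq(0, 48, by = 2),
                                   n_replicates = 4L, seed = 1L,
                                   curve_prefix = "curve") {
  stopifnot(params[["A"]] > 0, params[["mu"]] > 0, params[["lam"]] >= 0,
            length(timepoints) >= 5L, n_replicates >= 1L)
  mu_t <- gompertz(timepoints, params[["A"]], params[["mu"]], params[["lam"]])
  withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      size <- if (noise_sd == 0) mu_t else
        pmax(0, mu_t + rnorm(length(mu_t), 0, noise_sd))
      data.frame(curve_id = sprintf("%s_%02d", curve_prefix, r),
                 time_h = timepoints, size = size, stringsAsFactors = FALSE)
    }))
  })
}

#' Simulate a head-to-head competition time series
#'
#' A fluorescent mutant and its reference ancestor are mixed and sampled
#' daily. The log abundance ratio drifts by `s_true * generations_per_day`
#' per day; daily counts are a multinomial sample of `count_depth` cytometry
#' events. `count_depth = Inf` disables sampling noise (expected counts are
#' emitted, scaled to one million events).
#'
#' @param s_true true per-generation selection coefficient of the mutant.
#' @param days number of days after mixing (>= 2; day 0 is included, so a
#'   3-day assay yields 4 timepoints).
#' @param generations_per_day generations elapsed per day (default 5.2, the
#'   serial-passage regime of roughly 300 generations over 58 days).
#' @param initial_ratio mutant/reference abundance ratio at day 0 (> 0).
#' @param count_depth cytometry events recorded per day.
#' @param seed integer seed.
#' @param assay_id identifier copied into the output.
#' @return data.frame (assay_id, day, count_mutant, count_reference).
#' @export
generate_competition_series <- function(s_true = 0.1, days = 3L,
                                        generations_per_day = 5.2,
                                        initial_ratio = 1,
                                        count_depth = 10000L, seed = 1L,
                                        assay_id = "assay1") {
  if (days < 2L) stop("days must be >= 2")
  if (initial_ratio <= 0) stop("initial_ratio must be > 0")
  if (count_depth <= 0) stop("count_depth must be > 0")
  day <- 0:days
  ratio <- initial_ratio * exp(s_true * generations_per_day * day)
  p_mut <- ratio / (1 + ratio)
  withr::with_seed(seed, {
    if (is.infinite(count_depth)) {
      cm <- p_mut * 1e6
      cr <- (1 - p_mut) * 1e6
    } else {
      draws <- vapply(p_mut, function(p)
        as.numeric(rmultinom(1L, count_depth, c(p, 1 - p))), numeric(2))
      cm <- draws[1L, ]; cr <- draws[2L, ]
    }
    data.frame(assay_id = assay_id, day = day,
               count_mutant = cm, count_reference = cr,
               stringsAsFactors = FALSE)
  })
}
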