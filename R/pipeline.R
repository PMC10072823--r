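#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end chain: cohort acquisition (synthetic
#' generation or user-supplied call/metadata tables), profile construction,
#' Bray-Curtis dissimilarity, NMDS ordination, match/mismatch partitioning
#' with three-way ANOVA, locus-specificity scoring per factor, and
#' count-distribution tests per mutation type. Every stage is wrapped so a
#' failure aborts with a stage-tagged error while earlier outputs remain on
#' disk; a JSON provenance manifest records package version, parameters,
#' seeds and MD5 checksums of every written table.
#'
#' @param config named list (see [read_config()]); recognised keys:
#'   `run_mode` ("synthetic" or "user-data"), `seed` (mandatory in
#'   synthetic mode), `replicates_per_circumstance`,
#'   `extinction_probability`, `extinction_count`, `nmds_n_init`,
#'   `nmds_dims`, `fdr_alpha`, `specificity_factors`, and in user-data mode
#'   `calls_path` / `metadata_path`.
#' @param out_dir output directory (created if absent).
#' @return invisible list with every in-memory result plus the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(stage, ...) {
    line <- sprintf("[%s] [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    stage, paste0(...))
    cat(line, "\n", file = log_path, append = TRUE)
    message(line)
  }
  stage <- function(name, expr) {
    logf(name, "start")
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  get_opt <- function(key, default) {
    if (!is.null(config[[key]])) config[[key]] else default
  }
  written <- character(0)
  emit <- function(table, name) {
    p <- file.path(out_dir, name)
    write_tsv_table(table, p)
    written <<- c(written, p)
    p
  }
  mode <- get_opt("run_mode", "synthetic")

  acquired <- stage("acquire", {
    if (identical(mode, "synthetic")) {
      if (is.null(config$seed)) stop("seed is mandatory in synthetic mode")
      logf("acquire", "synthetic cohort, seed = ", config$seed)
      cfg <- cohort_config(
        seed = config$seed,
        replicates_per_circumstance = get_opt("replicates_per_circumstance", 96L),
        extinction_probability = get_opt("extinction_probability", 230 / 1344),
        extinction_count = config$extinction_count)
      coh <- generate_cohort(cfg)
      emit(coh$metadata, "clone_metadata.tsv")
      emit(coh$calls, "mutation_calls.tsv")
      emit(data.frame(locus = rownames(coh$truth$rates), coh$truth$rates,
                      check.names = FALSE), "truth_locus_rates.tsv")
      coh
    } else {
      for (key in c("calls_path", "metadata_path"))
        if (is.null(config[[key]]) || !file.exists(config[[key]]))
          stop("user-data mode requires an existing ", key)
      list(metadata = read_tsv_table(config$metadata_path),
           calls = read_tsv_table(config$calls_path), truth = NULL)
    }
  })

  profiles <- stage("profiles", {
    p <- build_profiles(acquired$calls, acquired$metadata)
    emit(data.frame(circumstance = rownames(p), unclass(p),
                    check.names = FALSE), "profile_matrix.tsv")
    p
  })

  bc <- stage("dissimilarity", {
    d <- bray_curtis_matrix(profiles)
    emit(data.frame(circumstance = rownames(d), d, check.names = FALSE),
         "dissimilarity.tsv")
    d
  })

  nmds <- stage("nmds", {
    fit <- nmds_embed(bc, dims = get_opt("nmds_dims", 2L),
                      n_init = get_opt("nmds_n_init", 200L),
                      seed = get_opt("seed", 1L))
    emit(data.frame(circumstance = rownames(fit$coordinates),
                    fit$coordinates, stress = fit$stress),
         "nmds_coordinates.tsv")
    fit
  })

  partition <- stage("partition", {
    pt <- partition_dissimilarity(bc, attr(profiles, "circumstances"))
    emit(pt$pairs, "dissimilarity_pairs.tsv")
    emit(pt$anova, "partition_anova.tsv")
    pt
  })

  spec_factors <- get_opt("specificity_factors", c("medium", "mitonuclear"))
  specificity <- stage("specificity", {
    res <- lapply(spec_factors, function(f) {
      s <- locus_specificity(acquired$calls, acquired$metadata, factor = f,
                             fdr_alpha = get_opt("fdr_alpha", 0.05))
      emit(s, paste0("specificity_", f, ".tsv"))
      s
    })
    names(res) <- spec_factors
    res
  })

  count_tests <- stage("count_tests", {
    calls <- acquired$calls
    if ("artifact_flag" %in% names(calls))
      calls <- calls[!calls$artifact_flag, , drop = FALSE]
    cat14 <- .call_categories(calls, acquired$metadata, "medium_x_background")
    res <- lapply(split(seq_len(nrow(calls)), calls$type), function(ix) {
      counts <- table(factor(cat14[ix], levels = sort(unique(cat14))))
      ct <- count_distribution_test(as.vector(counts))
      data.frame(n = sum(counts), chi2 = ct$chi2, df = ct$df, p = ct$p)
    })
    tab <- cbind(type = names(res), do.call(rbind, res))
    rownames(tab) <- NULL
    emit(tab, "count_distribution_tests.tsv")
    tab
  })

  manifest <- stage("manifest", {
    mf <- list(package = "mitoconverge",
               version = as.character(packageVersion("mitoconverge")),
               run_mode = mode,
               parameters = config[setdiff(names(config), NULL)],
               outputs = lapply(stats::setNames(nm = basename(written)),
                                function(b)
                                  unname(tools::md5sum(file.path(out_dir, b)))))
    jsonlite::write_json(mf, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    mf
  })
  logf("done", length(written), " tables written to ", out_dir)

  invisible(list(cohort = acquired, profiles = profiles, dissimilarity = bc,
                 nmds = nmds, partition = partition,
                 specificity = specificity, count_tests = count_tests,
                 manifest = manifest))
}
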