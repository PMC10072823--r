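test_that("profiles count each call once and conserve the total", {
  meta <- data.frame(clone_id = c("c1", "c2", "c3"),
                     circumstance = c("NN.FF", "NN.FF", "DD.NF"),
                     nuclear = c("N", "N", "D"), mito = c("N", "N", "D"),
                     medium = c("FF", "FF", "NF"))
  calls <- data.frame(clone_id = c("c1", "c1", "c2", "c3"),
                      annotation = c("g1", "g1", "g2", "g1"),
                      artifact_flag = c(FALSE, FALSE, FALSE, TRUE))
  p <- build_profiles(calls, meta)
  expect_equal(p["NN.FF", "g1"], 2)
  expect_equal(p["NN.FF", "g2"], 1)
  expect_equal(sum(p), 3)  # the artifact-flagged call is excluded
  expect_error(build_profiles(data.frame(clone_id = "zz", annotation = "g1"),
                              meta), "unknown clone_id")

  # equal weights: a CNV and an SNV at the same locus are 1 count each
  coh <- small_cohort(seed = 2)
  p2 <- build_profiles(coh$calls, coh$metadata)
  expect_equal(sum(p2), nrow(coh$calls))
})

test_that("Bray-Curtis matches the direct formula and its bounds", {
  m <- rbind(u = c(3, 1, 0), v = c(1, 1, 2))
  expect_equal(bray_curtis_matrix(m)["u", "v"], 0.5)
  same <- rbind(a = c(2, 5), b = c(2, 5))
  expect_equal(bray_curtis_matrix(same)["a", "b"], 0)
  disjoint <- rbind(a = c(2, 0), b = c(0, 7))
  expect_equal(bray_curtis_matrix(disjoint)["a", "b"], 1)

  # property: random matrices agree with the pairwise oracle and vegan
  withr::with_seed(99, {
    for (rep in 1:20) {
      mm <- matrix(rpois(5 * 8, 3), 5, 8,
                   dimnames = list(paste0("r", 1:5), NULL))
      mm[1, ] <- mm[1, ] + 1  # avoid all-zero rows
      d <- bray_curtis_matrix(mm)
      expect_true(isSymmetric(d))
      expect_true(all(diag(d) == 0))
      expect_true(all(d >= 0 & d <= 1))
      for (i in 1:4) for (j in (i + 1):5)
        expect_equal(d[i, j], bc_pair_oracle(mm[i, ], mm[j, ]), tolerance = 1e-12)
      expect_equal(as.matrix(vegan::vegdist(mm, method = "bray")), d,
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  })

  zz <- rbind(a = c(0, 0), b = c(0, 0))
  expect_warning(dz <- bray_curtis_matrix(zz), "all-zero")
  expect_true(is.na(dz["a", "b"]))
})

test_that("mutual information is exact on canonical tables", {
  expect_equal(mutual_information_dits(diag(c(10, 10))), log10(2),
               tolerance = 1e-12)
  # product table: MI exactly 0
  prod_tab <- outer(c(3, 7), c(2, 5, 3))
  expect_equal(mutual_information_dits(prod_tab), 0, tolerance = 1e-12)
  # invariance to row/column permutation
  withr::with_seed(5, {
    tab <- matrix(rpois(8, 5), 2, 4)
    expect_equal(mutual_information_dits(tab),
                 mutual_information_dits(tab[2:1, c(3, 1, 4, 2)]),
                 tolerance = 1e-12)
  })
  expect_gte(mutual_information_dits(matrix(rpois(8, 2), 2, 4)), 0)
})

test_that("NMDS recovers perfect configurations and keeps the best start", {
  pc <- perfect_config(n = 6)
  fit <- nmds_embed(pc$D, dims = 2, n_init = 20, seed = 3)
  expect_lt(fit$stress, 1e-6)
  expect_true(all(fit$stress <= fit$all_stress))
  # determinism
  fit2 <- nmds_embed(pc$D, dims = 2, n_init = 20, seed = 3)
  expect_identical(fit$coordinates, fit2$coordinates)
  # a different seed may find a different (but no better-kept) path
  expect_error(nmds_embed(pc$D, dims = 6), "smaller")
})

test_that("partitioning yields 91 pairs with the right match structure", {
  coh <- small_cohort(seed = 4, replicates = 6)
  p <- build_profiles(coh$calls, coh$metadata)
  d <- bray_curtis_matrix(p)
  pt <- suppressWarnings(partition_dissimilarity(d, attr(p, "circumstances")))
  expect_equal(nrow(pt$pairs), 14 * 13 / 2)
  # same genotype, different medium: exactly 7 pairs
  expect_equal(sum(pt$pairs$nuclear_match & pt$pairs$mito_match &
                     !pt$pairs$env_match), 7)
  # no pair can match on everything (it would be the same circumstance)
  expect_equal(sum(pt$pairs$nuclear_match & pt$pairs$mito_match &
                     pt$pairs$env_match), 0)
  expect_s3_class(pt$anova, "anova_table")
})

test_that("a planted nuclear effect dominates the partition ANOVA", {
  # profiles built directly: circumstances sharing a nucleus share targets
  circ <- circumstance_table()
  loci <- paste0("L", 1:12)
  prof <- matrix(0L, nrow(circ), 12,
                 dimnames = list(circ$circumstance, loci))
  withr::with_seed(8, {
    for (i in seq_len(nrow(circ))) {
      nuc_block <- match(circ$nuclear[i], c("N", "D", "Y"))
      idx <- (nuc_block - 1) * 4 + 1:4
      prof[i, idx] <- rpois(4, 40)            # strong nuclear signature
      prof[i, -idx] <- rpois(8, 2)            # background noise
    }
  })
  d <- bray_curtis_matrix(prof)
  pt <- suppressWarnings(
    partition_dissimilarity(d, circ[, c("circumstance", "nuclear", "mito",
                                        "medium")]))
  an <- pt$anova
  expect_lt(an$p[an$term == "nuclear_match"], 1e-6)
  expect_gt(an$p[an$term == "mito_match"], 0.01)
})

test_that("locus specificity equals the chisq.test oracle and flags correctly", {
  coh <- small_cohort(seed = 6, replicates = 12)
  res <- suppressWarnings(
    locus_specificity(coh$calls, coh$metadata, factor = "mitonuclear"))
  # oracle: chisq.test(correct = FALSE) on each reconstructed table
  cat_lab <- coh$metadata$genotype[match(coh$calls$clone_id,
                                         coh$metadata$clone_id)]
  for (a in res$annotation) {
    inside <- table(factor(cat_lab[coh$calls$annotation == a],
                           levels = sort(unique(cat_lab))))
    total <- table(factor(cat_lab, levels = sort(unique(cat_lab))))
    tab <- rbind(inside, as.vector(total) - as.vector(inside))
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    row <- res[res$annotation == a, ]
    expect_equal(row$chi2_stat, unname(ct$statistic), tolerance = 1e-10)
    expect_equal(row$p_value, ct$p.value, tolerance = 1e-10)
  }
  # the planted NN.FF-specific locus is the flagged one
  expect_true(res$specific[res$annotation == "SPEC1"])
  expect_false(any(res$specific[res$annotation != "SPEC1"]))

  # a locus proportional to category totals carries zero information
  meta <- data.frame(clone_id = paste0("c", 1:8),
                     genotype = rep(c("NN", "DD"), each = 4),
                     nuclear = rep(c("N", "D"), each = 4),
                     mito = rep(c("N", "D"), each = 4),
                     medium = "FF",
                     circumstance = rep(c("NN.FF", "DD.FF"), each = 4))
  calls <- data.frame(clone_id = rep(paste0("c", 1:8), each = 2),
                      annotation = rep(c("gA", "gB"), 8))
  resp <- locus_specificity(calls, meta, factor = "mitonuclear")
  expect_equal(resp$mi_dits, c(0, 0), tolerance = 1e-12)
  expect_false(any(resp$specific))
})

test_that("count distribution test flags extreme skew only", {
  even <- count_distribution_test(rep(25, 4))
  expect_equal(even$chi2, 0)
  expect_gt(even$p, 0.99)
  skew <- count_distribution_test(c(92, 86, rep(9, 12)))
  expect_lt(skew$p, 0.05)
  # oracle agreement with chisq.test
  x <- c(30, 12, 8, 50)
  expect_equal(count_distribution_test(x)$chi2,
               unname(suppressWarnings(chisq.test(x)$statistic)),
               tolerance = 1e-12)
  expect_error(count_distribution_test(5), "2 categories")
})

test_that("mutation spectra collapse to pyrimidine classes and compare", {
  groups <- data.frame(clone_id = c("c1", "c2"), group = c("g1", "g2"))
  # G>A is the reverse complement of C>T: same class
  calls <- data.frame(clone_id = c("c1", "c2"), type = "SNV",
                      ref_allele = c("C", "G"), alt_allele = c("T", "A"))
  st <- mutation_spectrum_test(calls, groups)
  expect_equal(unname(st$spectrum[, "C>T"]), c(1, 1))
  expect_equal(st$chi2, 0)

  # planted C>T excess in one group is detected
  withr::with_seed(10, {
    base <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
    mk <- function(clone, n, probs) {
      cls <- sample(base, n, replace = TRUE, prob = probs)
      ref <- substr(cls, 1, 1); alt <- substr(cls, 3, 3)
      data.frame(clone_id = clone, type = "SNV", ref_allele = ref,
                 alt_allele = alt)
    }
    calls2 <- rbind(mk("c1", 300, rep(1 / 6, 6)),
                    mk("c2", 300, c(.05, .05, .7, .05, .1, .05)))
    st2 <- mutation_spectrum_test(calls2, groups)
    expect_lt(st2$p, 1e-6)
  })

  # empty group excluded with warning
  calls3 <- data.frame(clone_id = "c1", type = "SNV",
                       ref_allele = c("C", "C"), alt_allele = c("T", "A"))
  groups3 <- data.frame(clone_id = c("c1", "c2", "c3"),
                        group = c("g1", "g2", "g3"))
  calls3b <- rbind(calls3,
                   data.frame(clone_id = "c2", type = "SNV",
                              ref_allele = "T", alt_allele = "C"))
  expect_warning(mutation_spectrum_test(calls3b, groups3), "0 SNVs")
})

test_that("phenotype association detects planted shifts and skips small groups", {
  withr::with_seed(21, {
    n <- 40
    meta <- data.frame(clone_id = paste0("c", 1:n), genotype = "NN",
                       nuclear = "N", mito = "N", medium = "FF",
                       circumstance = "NN.FF")
    mutant <- 1:20
    calls <- data.frame(clone_id = paste0("c", mutant), annotation = "gMUT")
    ph <- data.frame(clone_id = meta$clone_id,
                     value = rnorm(n) + ifelse(1:n %in% mutant, 2, 0))
    res <- phenotype_association(calls, ph, meta)
    expect_equal(res$annotation, "gMUT")
    expect_lte(res$q, 0.05)
    expect_gt(res$effect, 1)
    # too few mutants: skipped
    res2 <- phenotype_association(calls[1:2, ], ph, meta)
    expect_equal(nrow(res2), 0)
  })
})
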