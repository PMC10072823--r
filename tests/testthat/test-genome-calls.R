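test_that("mtdna_fraction matches direct summation and its invariants", {
  # 100 mito-coding + 900 nuclear positions, all depth 10 -> length ratio
  depth <- data.frame(chrom = c(rep("chrM", 100), rep("chrI", 900)),
                      pos = c(1:100, 1:900), depth = 10)
  coding <- data.frame(chrom = "chrM", start = 1, end = 100)
  expect_equal(mtdna_fraction(depth, coding), 0.1)

  # scale invariance
  depth2 <- depth; depth2$depth <- depth2$depth * 7
  expect_equal(mtdna_fraction(depth2, coding), 0.1)

  # mito depth 20, nuclear 10: 20*100 / (20*100 + 10*900) = 2000/11000
  depth3 <- depth
  depth3$depth[depth3$chrom == "chrM"] <- 20
  expect_equal(mtdna_fraction(depth3, coding), 2000 / 11000)

  depth0 <- depth; depth0$depth <- 0
  expect_error(mtdna_fraction(depth0, coding), "zero")
})

test_that("aneuploidy caller recovers planted chromosomes and nothing else", {
  gm <- toy_genome_model()
  # euploid genome: no calls
  flat <- generate_depth_profile(gm, noise_sd = 0.05, seed = 1)
  expect_equal(nrow(call_aneuploidies(flat)), 0)

  # gain at 1.5
  gain <- generate_depth_profile(gm, karyotype = c(chrII = 1.5),
                                 noise_sd = 0.05, seed = 2)
  calls <- call_aneuploidies(gain)
  expect_equal(calls$chromosome, "chrII")
  expect_equal(calls$direction, "gain")
  expect_gt(calls$copy_ratio, 1.4); expect_lt(calls$copy_ratio, 1.6)

  # loss at 0.5
  loss <- generate_depth_profile(gm, karyotype = c(chrIV = 0.5),
                                 noise_sd = 0.05, seed = 3)
  calls <- call_aneuploidies(loss)
  expect_equal(calls$chromosome, "chrIV")
  expect_equal(calls$direction, "loss")

  # chromosome shorter than one window is skipped with a warning
  tiny <- rbind(flat, data.frame(chrom = "chrTiny", pos = 1:100, depth = 30))
  expect_warning(call_aneuploidies(tiny), "shorter")
  expect_error(call_aneuploidies(flat[flat$chrom == "chrI", ]), "2 chromosomes")
})

test_that("CNV caller finds planted segments and honours the length filter", {
  gm <- toy_genome_model()
  flat <- generate_depth_profile(gm, noise_sd = 0, seed = 1)
  expect_equal(nrow(call_cnv_segments(flat)), 0)

  cnv <- data.frame(chrom = "chrI", start = 3001, end = 3300, ratio = 2)
  dp <- generate_depth_profile(gm, cnvs = cnv, noise_sd = 0.03, seed = 2)
  calls <- call_cnv_segments(dp, window_bp = 50)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$chromosome, "chrI")
  # boundaries within one window of the planted interval
  expect_lte(abs(calls$start - 3001), 50)
  expect_lte(abs(calls$end - 3300), 50)
  expect_lt(abs(calls$copy_ratio - 2), 0.2)

  # 100-bp blip below min_len_bp = 150 is suppressed
  blip <- data.frame(chrom = "chrI", start = 5001, end = 5100, ratio = 2)
  dpb <- generate_depth_profile(gm, cnvs = blip, noise_sd = 0, seed = 3)
  expect_equal(nrow(call_cnv_segments(dpb, window_bp = 50,
                                      min_len_bp = 150)), 0)
})

test_that("artifact resolution separates shared bias from clone CNVs", {
  gm <- toy_genome_model(nuclear_sizes = c(chrI = 4000L, chrII = 4000L),
                         mito_size = 500L)
  region <- data.frame(chrom = "chrI", start = 1001, end = 1400, ratio = 2)
  # 20 samples; sample s01 carries a real CNV, all others are flat
  depths <- lapply(1:20, function(i) {
    generate_depth_profile(gm, cnvs = if (i == 1) region else NULL,
                           noise_sd = 0.02, seed = 100 + i)
  })
  names(depths) <- sprintf("s%02d", 1:20)
  # everyone is a "candidate" at the locus (e.g. from a lenient first pass)
  cand <- do.call(rbind, lapply(names(depths), function(sid)
    data.frame(sample_id = sid, chromosome = "chrI", start = 1001L,
               end = 1400L, copy_ratio = 2, n_windows = 8L,
               artifact_flag = FALSE)))
  res <- resolve_cnv_artifacts(cand, depths, residual_cutoff = 2)
  expect_false(res$artifact_flag[res$sample_id == "s01"])
  expect_true(all(res$artifact_flag[res$sample_id != "s01"]))

  # a locus with *identical* relative depth everywhere (pure mappability
  # bias, zero residuals): every candidate flagged
  depths0 <- lapply(1:20, function(i)
    generate_depth_profile(gm, noise_sd = 0, seed = i))
  names(depths0) <- names(depths)
  cand2 <- cand; cand2$start <- 3001L; cand2$end <- 3400L
  res2 <- resolve_cnv_artifacts(cand2, depths0, residual_cutoff = 2)
  expect_true(all(res2$artifact_flag))

  # residual_cutoff -> Inf flags everything
  res3 <- resolve_cnv_artifacts(cand, depths, residual_cutoff = Inf)
  expect_true(all(res3$artifact_flag))

  # too few samples: passed through unflagged with a warning
  expect_warning(res4 <- resolve_cnv_artifacts(cand[1:3, ], depths[1:3]),
                 "fewer than")
  expect_false(any(res4$artifact_flag))
})

test_that("SNV caller equals brute-force filter evaluation", {
  gm <- toy_genome_model(nuclear_sizes = c(chrI = 1500L), mito_size = 200L)
  ref900 <- generate_pileup(gm, depth = 1, error_rate = 0, seed = 1,
                            chroms = "chrI")$ref[900]
  alt900 <- setdiff(c("A", "C", "G", "T"), ref900)[1]
  snvs <- data.frame(chrom = "chrI", pos = c(100, 400, 900),
                     af = c(1, 0.3, 0.95), alt = c(NA, NA, alt900))
  # pos 900 is an ancestral variant (same alt base): must be subtracted
  anc_snv <- data.frame(chrom = "chrI", pos = 900, af = 1, alt = alt900)
  smp <- generate_pileup(gm, snvs = snvs, depth = 30, error_rate = 0.005,
                         seed = 1, chroms = "chrI")
  anc <- generate_pileup(gm, snvs = anc_snv, depth = 28, error_rate = 0.005,
                         seed = 2, chroms = "chrI")
  calls <- call_snvs(smp, anc, min_depth = 10, min_alt_fraction = 0.8,
                     max_ancestor_alt_fraction = 0.05)

  # independent brute-force oracle over all sites
  bases <- c("A", "C", "G", "T")
  expected <- integer(0)
  for (i in seq_len(nrow(smp))) {
    cnt <- as.numeric(smp[i, bases]); names(cnt) <- bases
    dp <- sum(cnt)
    alt <- names(which.max(cnt[setdiff(bases, smp$ref[i])]))
    af <- cnt[[alt]] / dp
    anc_cnt <- as.numeric(anc[i, bases]); names(anc_cnt) <- bases
    anc_af <- anc_cnt[[alt]] / sum(anc_cnt)
    if (dp >= 10 && af >= 0.8 && anc_af <= 0.05 && cnt[[alt]] > 0)
      expected <- c(expected, smp$pos[i])
  }
  expect_identical(calls$position, expected)
  expect_true(100 %in% calls$position)   # clean clonal SNV called
  expect_false(400 %in% calls$position)  # sub-threshold fraction dropped
  expect_false(900 %in% calls$position)  # ancestral variant subtracted
  expect_error(call_snvs(smp[-1, ], anc), "coordinates")
})

test_that("annotation assigns labels by overlap, proximity, then bins", {
  features <- data.frame(chrom = "chrI", start = c(1000, 5000),
                         end = c(2000, 6000), label = c("g1", "g2"))
  calls <- data.frame(
    type = c("SNV", "SNV", "SNV", "ANEUPLOIDY", "SNV"),
    chromosome = c("chrI", "chrI", "chrI", "chrXII", "chrI"),
    start = c(1500, 900, 30000, 1, 4900),
    end = c(1500, 900, 30000, 1078177, 4900))
  ann <- annotate_calls(calls, features, proximity_bp = 500)
  expect_equal(ann$annotation[1], "g1")        # inside g1
  expect_equal(ann$annotation[2], "g1")        # 100 bp upstream, within 500
  expect_match(ann$annotation[3], "^intergenic:chrI:")
  expect_equal(ann$annotation[4], "chrXII")    # aneuploidy labelled by chrom
  expect_equal(ann$annotation[5], "g2")        # nearest within window

  far <- data.frame(type = "SNV", chromosome = "chrZ", start = 10, end = 10)
  expect_warning(annz <- annotate_calls(far, features), "no features")
  expect_equal(annz$annotation, "chrZ")
})
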