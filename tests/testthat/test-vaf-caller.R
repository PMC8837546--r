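test_that("BAF_som applies the purity/ploidy correction and floor rule", {
  # pure tumour: no correction
  expect_equal(compute_baf_som(0.75, 1, 2, 0), 0.75)
  # rho 0.5, diploid, logR 0: subtract (1-rho)/2
  expect_equal(compute_baf_som(0.75, 0.5, 2, 0), 0.5)
  # boundary: raw exactly 0.05 is kept (floor engages strictly below)
  expect_equal(compute_baf_som(0.5, 0.1, 2, 0), 0.05)
  # raw below 0.05: conservatively raised back to BAF_seg
  expect_equal(compute_baf_som(0.5, 0.05, 2, 0), 0.5)
  # 2+1 segment at rho 0.9: equals the clonal major-allele VAF
  rho <- 0.9
  baf_seg <- ((1 - rho) + rho * 2) / (2 * (1 - rho) + rho * 3)
  got <- compute_baf_som(baf_seg, rho, 3, 0)
  expect_equal(got, rho * 2 / (2 * (1 - rho) + rho * 3),
               tolerance = 1e-12)
  # input contract and degenerate denominator
  expect_error(compute_baf_som(0.49, 0.5, 2, 0), "0.5")
  # monotone in purity down to the floor
  vals <- vapply(c(0.9, 0.7, 0.5, 0.3), compute_baf_som,
                 numeric(1L), baf_seg = 0.8, psi_t = 2, logr_seg = 0)
  expect_true(all(diff(vals) < 0))
})

test_that("power filter keys on the minimal attainable p-value", {
  expect_false(power_filter(5L, betabinom_model(0.9, 100)))
  expect_equal(oracle_bb_upper_tail(5L, 5L, 0.9, 100), 0.59,
               tolerance = 0.02)
  expect_true(power_filter(60L, betabinom_model(0.5, 500)))
  # BAF_som ~ 1: never powered even at depth 500
  expect_false(power_filter(500L, betabinom_model(1 - 1e-9, 300)))
})

test_that("flanking-SNP guard detects segment outliers", {
  set.seed(21)
  omega <- 300
  # well-behaved flanks drawn from the segment model
  hs <- data.frame(pos = c(100L, 300L, 500L, 700L),
                   major_count = c(39L, 40L, 41L, 40L),
                   minor_count = c(21L, 20L, 19L, 20L),
                   logr = c(0.0, 0.01, -0.01, 0.02))
  g <- neighbour_guard(400L, hs, baf_seg = 0.66, omega = omega)
  expect_identical(g$status, "pass")
  # a flank with an extreme BAF fails the single-SNP threshold
  hs2 <- hs; hs2$major_count[2] <- 60L; hs2$minor_count[2] <- 0L
  expect_identical(neighbour_guard(400L, hs2, 0.66, omega)$status,
                   "fail")
  # missing flank on one side: untestable, not fail
  expect_identical(neighbour_guard(50L, hs, 0.66, omega)$status,
                   "untestable")
  # logR outlier trips the Gaussian/MAD check
  hs3 <- rbind(hs, data.frame(pos = c(350L, 420L),
                              major_count = 40L, minor_count = 20L,
                              logr = c(1.4, 1.5)))
  expect_identical(neighbour_guard(400L, hs3, 0.66, omega)$status,
                   "fail")
})

test_that("the site filter cascade removes and flags by construction", {
  fx <- cascade_fixture()
  out <- apply_site_filters(fx$snvs, fx$segments, fx$resources)
  # exactly 6 of 10 survive: germline overlap, common SV, SNP density and
  # LOH each remove one
  expect_identical(sum(out$status == "testable"), 6L)
  expect_identical(out$filter[out$pos == 200L], "germline-overlap")
  expect_identical(out$filter[out$pos == 400L], "common-sv")
  expect_identical(out$filter[out$pos == 600L], "snp-density")
  expect_identical(out$filter[out$pos == 1500L], "loh")
  # flags never remove
  expect_true(out$flag_tcr_bcr[out$pos == 100L])
  expect_identical(out$status[out$pos == 100L], "testable")
  expect_true(out$flag_indel_proximity[out$pos == 900L])
  expect_identical(out$status[out$pos == 900L], "testable")
  # SNP-density needs two SNPs within 25 bp: single close SNP passes
  expect_identical(out$status[out$pos == 500L], "testable")
})

test_that("male X outside the pseudoautosomal regions is not tested", {
  snvs <- data.frame(chrom = c("chrX", "chrX"), pos = c(100L, 5000L),
                     ref = "C", alt = "T", alt_count = 10L, depth = 30L)
  segments <- data.frame(chrom = "chrX", start = 1L, end = 10000L,
                         major = 1L, minor = 1L, baf_seg = 0.5,
                         logr_seg = 0)
  par <- data.frame(chrom = "chrX", start = 1L, end = 1000L)
  out <- apply_site_filters(snvs, segments, list(), sex = "male",
                            par_regions = par)
  expect_identical(out$status, c("testable", "removed"))
  expect_identical(out$filter[2], "male-x-nonpar")
  # females untouched
  outf <- apply_site_filters(snvs, segments, list(), sex = "female")
  expect_true(all(outf$status == "testable"))
})

test_that("call_sample recovers planted clonal parallel events", {
  g <- generate_reference(c(chr1 = 2e5, chr2 = 2e5), gc_fraction = 0.45,
                          seed = 10L)
  spec <- numeric(96L); spec[c(33, 40, 45, 70)] <- c(0.4, 0.3, 0.2, 0.1)
  co <- generate_catalog(g, spec, burden = 3000L, n_parallel = 12L,
                         seed = 11L)
  lay <- segment_layout(g, n_segments = 2L,
                        states = list(c(2L, 1L), c(2L, 2L)))
  b <- simulate_observations(co, g, lay, rho = 0.9, mean_depth = 80,
                             omega_true = 300, seed = 12L)
  res <- call_sample(b, omega = 300)
  expect_false(res$excluded)
  calls <- res$calls
  key <- paste(calls$chrom, calls$pos)
  truth <- paste(co$manifest$parallel$chrom, co$manifest$parallel$pos)
  hits <- key[!is.na(calls$verdict) &
                calls$verdict == "parallel-candidate"]
  expect_gte(sum(hits %in% truth) / max(length(hits), 1L), 0.9)
  expect_gte(sum(truth %in% hits) / length(truth), 0.9)
  # filter-trail completeness: every SNV lands in exactly one bucket
  buckets <- ifelse(calls$status == "removed", "removed", calls$verdict)
  expect_false(any(is.na(buckets)))
  expect_identical(length(buckets), nrow(b$snvs))
  # candidates satisfy the verdict invariant
  cand <- calls[calls$verdict == "parallel-candidate" &
                  !is.na(calls$verdict), ]
  expect_true(all(cand$q <= 0.1 & cand$powered & cand$guard == "pass"))
})

test_that("a purity-inflated sample is excluded by the QQ-slope check", {
  g <- generate_reference(c(chr1 = 2e5), gc_fraction = 0.45, seed = 20L)
  spec <- numeric(96L); spec[33] <- 1
  co <- generate_catalog(g, spec, burden = 1500L, seed = 21L)
  lay <- segment_layout(g, n_segments = 2L, states = list(c(1L, 1L)))
  b <- simulate_observations(co, g, lay, rho = 0.9, mean_depth = 80,
                             omega_true = 300, seed = 22L)
  b$rho <- 0.55  # claim far less purity than the data carry
  res <- call_sample(b, omega = 300)
  expect_true(res$excluded)
  expect_identical(res$exclusion_reason, "qq-slope-above-1")
  expect_false(any(res$calls$verdict == "parallel-candidate", na.rm = TRUE))
})

test_that("an all-LOH genome yields zero tested sites", {
  g <- generate_reference(c(chr1 = 1e5), gc_fraction = 0.45, seed = 30L)
  spec <- numeric(96L); spec[33] <- 1
  co <- generate_catalog(g, spec, burden = 300L, seed = 31L)
  lay <- segment_layout(g, n_segments = 1L, states = list(c(2L, 0L)))
  b <- simulate_observations(co, g, lay, rho = 0.9, mean_depth = 60,
                             omega_true = 300, seed = 32L)
  res <- call_sample(b, omega = 300)
  expect_true(all(res$calls$status == "removed"))
  # everything falls to the LOH rule (or an earlier positional filter)
  expect_true(all(res$calls$filter %in% c("loh", "snp-density",
                                          "germline-overlap")))
  expect_gt(sum(res$calls$filter == "loh"), 0L)
  expect_identical(sum(!is.na(res$calls$p)), 0L)
})

test_that("simulator-zero samples are excluded when a summary is given", {
  g <- generate_reference(c(chr1 = 1e5), gc_fraction = 0.45, seed = 40L)
  spec <- numeric(96L); spec[33] <- 1
  co <- generate_catalog(g, spec, burden = 500L, n_parallel = 2L,
                         seed = 41L)
  lay <- segment_layout(g, n_segments = 1L, states = list(c(2L, 1L)))
  b <- simulate_observations(co, g, lay, rho = 0.9, mean_depth = 80,
                             omega_true = 300, seed = 42L)
  zero_summary <- list(list(mean_biallelic = 0), list(mean_biallelic = 0))
  res <- call_sample(b, omega = 300, simulator_summary = zero_summary)
  expect_true(res$excluded)
  expect_identical(res$exclusion_reason, "simulators-zero-biallelic")
  ok_summary <- list(list(mean_biallelic = 0.4),
                     list(mean_biallelic = 0))
  res2 <- call_sample(b, omega = 300, simulator_summary = ok_summary)
  expect_false(res2$excluded)
})

test_that("divergent candidates face the germline and depth rules", {
  rec <- data.frame(p_germline1 = c(-3, -3, -3, NA),
                    p_germline2 = c(-4, -0.5, -4, -4),
                    normal_depth = c(25L, 25L, 18L, 25L))
  expect_identical(filter_divergent_candidates(rec),
                   c("pass", "fail", "fail", "unevaluable"))
  # missing annotation columns entirely
  expect_identical(filter_divergent_candidates(data.frame(x = 1)),
                   "unevaluable")
})
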