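test_that("reference generation is deterministic and hits the GC target", {
  g1 <- generate_reference(c(chr1 = 5e4), gc_fraction = 0.5, seed = 9L)
  g2 <- generate_reference(c(chr1 = 5e4), gc_fraction = 0.5, seed = 9L)
  expect_identical(as.character(g1$sequences[[1]]),
                   as.character(g2$sequences[[1]]))
  s <- strsplit(as.character(g1$sequences[[1]]), "")[[1]]
  gc <- mean(s %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / 5e4))
  # context abundance covers callable length minus interval edges
  expect_identical(sum(g1$class_abundance), 50000L - 2L)
  # masked windows are excluded from contexts
  gm <- generate_reference(c(chr1 = 5e4), gc_fraction = 0.5, seed = 9L,
                           masked = data.frame(chrom = "chr1",
                                               start = 1000L,
                                               end = 2000L))
  expect_lt(sum(gm$class_abundance), sum(g1$class_abundance))
  pos <- gm$contexts$chr1$positions
  expect_false(any(pos >= 1000L & pos <= 2000L))
})

test_that("catalog generation books the planted events", {
  g <- generate_reference(c(chr1 = 1e5), gc_fraction = 0.45, seed = 13L)
  spec <- numeric(96L); spec[c(33, 70)] <- c(0.7, 0.3)
  co <- generate_catalog(g, spec, burden = 500L, n_parallel = 5L,
                         n_divergent = 3L, seed = 14L)
  expect_identical(nrow(co$manifest$parallel), 5L)
  expect_identical(nrow(co$manifest$divergent), 3L)
  expect_identical(co$manifest$n_single, 492L)
  expect_identical(nrow(co$catalog), 500L)
  # no locus reused, divergent alternates distinct
  expect_false(any(duplicated(paste(co$catalog$chrom, co$catalog$pos))))
  dv <- co$manifest$divergent
  expect_true(all(dv$alt != dv$alt2 & dv$alt2 != dv$ref))
  # empty plan books nothing
  co0 <- generate_catalog(g, spec, burden = 50L, seed = 15L)
  expect_identical(nrow(co0$manifest$parallel), 0L)
  # catalog spectrum tracks the request
  sp <- compute_spectrum(co$catalog, g, normalise = TRUE)
  expect_gte(cosine_similarity(sp, spec), 0.95)
})

test_that("expected VAFs follow the purity and multiplicity arithmetic", {
  # rho 1, 1+1 segment: parallel VAF 1, single VAF 0.5
  expect_equal(1 * 2 / (2 * 0 + 1 * 2), 1)
  g <- generate_reference(c(chr1 = 1e5), gc_fraction = 0.45, seed = 16L)
  spec <- numeric(96L); spec[33] <- 1
  co <- generate_catalog(g, spec, burden = 400L, n_parallel = 20L,
                         seed = 17L)
  lay <- segment_layout(g, n_segments = 1L, states = list(c(2L, 1L)))
  rho <- 0.6
  b <- simulate_observations(co, g, lay, rho = rho, mean_depth = 100,
                             omega_true = 1e7, seed = 18L)
  # single SNV on one copy in 2+1: VAF = 0.6 / (0.8 + 1.8) = 0.2308
  singles <- b$truth$role == "single"
  vaf_single <- mean(b$snvs$alt_count[singles] / b$snvs$depth[singles])
  expect_equal(vaf_single, rho / (2 * (1 - rho) + rho * 3),
               tolerance = 0.02)
  # parallel on all 3 copies: VAF = 1.8 / 2.6
  par <- b$truth$role == "parallel"
  vaf_par <- mean(b$snvs$alt_count[par] / b$snvs$depth[par])
  expect_equal(vaf_par, rho * 3 / (2 * (1 - rho) + rho * 3),
               tolerance = 0.05)
  # mean depth near the requested genome average (single-state layout)
  expect_lt(abs(mean(b$snvs$depth) - 100),
            3 * sqrt(100 / nrow(b$snvs)) + 1)
  # segment summaries reflect the generated data
  expect_equal(b$segments$baf_seg,
               ((1 - rho) + rho * 2) / (2 * (1 - rho) + rho * 3),
               tolerance = 0.02)
})

test_that("observation bundles are reproducible given the seed", {
  g <- generate_reference(c(chr1 = 5e4), gc_fraction = 0.45, seed = 19L)
  spec <- numeric(96L); spec[33] <- 1
  co <- generate_catalog(g, spec, burden = 100L, seed = 20L)
  lay <- segment_layout(g, n_segments = 1L, states = list(c(2L, 1L)))
  b1 <- simulate_observations(co, g, lay, seed = 21L)
  b2 <- simulate_observations(co, g, lay, seed = 21L)
  expect_identical(b1$snvs, b2$snvs)
  expect_identical(b1$het_snps, b2$het_snps)
})

test_that("phased evidence reflects the planted allele configuration", {
  g <- generate_reference(c(chr1 = 1e5), gc_fraction = 0.45, seed = 22L)
  spec <- numeric(96L); spec[33] <- 1
  co <- generate_catalog(g, spec, burden = 200L, n_parallel = 8L,
                         seed = 23L)
  lay <- segment_layout(g, n_segments = 1L, states = list(c(1L, 1L)))
  b <- simulate_observations(co, g, lay, rho = 1, mean_depth = 60,
                             omega_true = 300, het_snp_density = 1 / 300,
                             seed = 24L)
  ev <- simulate_phased_pairs(b, pairs_per_site = 20L, error_rate = 0,
                              seed = 25L)
  par_keys <- paste(co$manifest$parallel$chrom, co$manifest$parallel$pos)
  ev_key <- paste(ev$snv_chrom, ev$snv_pos)
  par_ev <- ev[ev_key %in% par_keys, ]
  # noise-free parallel truth at full purity: every pair reports the
  # variant from both SNP alleles and no reference-only pairs remain
  if (nrow(par_ev)) {
    expect_true(all(par_ev$n_ra > 0L))
    expect_true(all(par_ev$n_aa > 0L))
    expect_true(all(par_ev$n_rr + par_ev$n_ar == 0L))
  }
  sing_ev <- ev[!(ev_key %in% par_keys), ]
  expect_true(all(sing_ev$n_aa == 0L))
  # error-free single-allele truth never calls parallel
  calls <- phase_snvs(sing_ev)
  expect_false(any(calls$verdict == "parallel"))
})

test_that("sequencing errors rarely fake parallel evidence", {
  g <- generate_reference(c(chr1 = 4e5), gc_fraction = 0.45, seed = 26L)
  spec <- numeric(96L); spec[33] <- 1
  co <- generate_catalog(g, spec, burden = 2500L, seed = 27L)
  lay <- segment_layout(g, n_segments = 1L, states = list(c(1L, 1L)))
  b <- simulate_observations(co, g, lay, rho = 0.95, mean_depth = 60,
                             omega_true = 300, het_snp_density = 1 / 250,
                             seed = 28L)
  ev <- simulate_phased_pairs(b, pairs_per_site = 20L, error_rate = 0.01,
                              seed = 29L)
  calls <- phase_snvs(ev)
  # the >= 2 Alt-Alt read rule keeps the false-positive rate < 1e-3
  expect_lt(mean(calls$verdict == "parallel"), 1e-3)
})
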