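test_that("burden model solves the mode and sd constraints exactly", {
  m <- burden_model(10000L)
  # gamma mode (beta - 1)/r equals the observed burden
  expect_equal((m$shape - 1) / m$rate, 10000, tolerance = 1e-9)
  # gamma sd sqrt(beta)/r equals cv * n
  expect_equal(sqrt(m$shape) / m$rate, 0.05 * 10000, tolerance = 1e-9)
  expect_error(burden_model(100, cv = 0), "cv")
  expect_identical(sample_total_burden(burden_model(0L)), 0L)
})

test_that("sampled burdens match gamma-Poisson moments", {
  set.seed(101)
  m <- burden_model(10000L)
  draws <- replicate(20000L, sample_total_burden(m))
  # mean of the mixture: E[lambda] = beta/r = n + sigma^2/n-ish
  mean_expect <- m$shape / m$rate
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - mean_expect), 3 * se)
  # spread: Var = E[lambda] + Var(lambda)
  var_expect <- m$shape / m$rate + m$shape / m$rate^2
  expect_equal(stats::var(draws), var_expect, tolerance = 0.1)
  # empirical mode near the observed burden (coarse binning)
  h <- hist(draws, breaks = 60, plot = FALSE)
  expect_lt(abs(h$mids[which.max(h$counts)] - 10000),
            2 * 0.05 * 10000)
})

test_that("chromosome allocation follows the Dirichlet-multinomial", {
  expect_error(allocate_to_chromosomes(5L, integer(0)), "empty")
  one <- allocate_to_chromosomes(7L, c(chr1 = 3L))
  expect_identical(unname(one), 7L)
  set.seed(7)
  draws <- replicate(20000L,
                     allocate_to_chromosomes(50L, c(a = 100L, b = 1L)))
  # conservation holds in every draw
  expect_true(all(colSums(draws) == 50L))
  fr <- draws["a", ] / 50
  # Dirichlet-multinomial mean fraction = alpha_a / alpha_0 = 101/103
  se <- stats::sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 101 / 103), 3 * se)
})

test_that("per-chromosome spectra have the Dirichlet means", {
  overall <- numeric(96L); overall[c(1, 33)] <- c(600, 400)
  psi <- (overall + 1) * (2 / 3) / 1000
  set.seed(5)
  # chromosome with no observed mutations: mean is psi/sum(psi)
  draws <- replicate(4000L, sample_chromosome_spectrum(numeric(96L),
                                                       overall, 1000L))
  expect_equal(rowMeans(draws)[1], psi[1] / sum(psi), tolerance = 0.02)
  expect_equal(sum(sample_chromosome_spectrum(numeric(96L), overall,
                                              1000L)), 1,
               tolerance = 1e-12)
  # dominant observed channel converges to count/(count + sum(other mu))
  chrom <- numeric(96L); chrom[1] <- 500
  draws2 <- replicate(4000L, sample_chromosome_spectrum(chrom, overall,
                                                        1000L))
  expect_equal(rowMeans(draws2)[1], (500 + psi[1]) / (500 + sum(psi)),
               tolerance = 0.01)
  expect_error(sample_chromosome_spectrum(-chrom, overall, 1000L),
               "negative")
})

test_that("a single mutation can never violate infinite sites", {
  g <- single_channel_genome(50L)
  cat1 <- single_channel_catalog(1L, 50L)
  res <- run_uniform_permutation(cat1, g, replicates = 200L, seed = 3L)
  expect_true(all(res$tallies$parallel + res$tallies$divergent +
                    res$tallies$back + res$tallies$forward == 0L |
                    res$tallies$n_t_sim > 1L))
  # burden 1 replicates specifically
  ones <- res$tallies[res$tallies$n_t_sim <= 1L, ]
  if (nrow(ones)) expect_true(all(ones$n_colliding == 0L))
})

test_that("every replicate conserves its sampled burden", {
  g <- two_channel_genome(100L, 100L)
  cpos <- aca_positions(60L)
  cat <- mutation_records("chr1", cpos, "C", "T")
  res <- run_uniform_permutation(cat, g, replicates = 40L, seed = 11L)
  # all accepted hits across replicates equal all sampled burdens
  expect_equal(sum(res$hit_spectrum), sum(res$tallies$n_t_sim))
})

test_that("uniform permutation matches the brute-force collision oracle", {
  n_loci <- 2000L
  g <- single_channel_genome(n_loci)
  cat <- single_channel_catalog(200L, n_loci)
  reps <- 400L
  res <- run_uniform_permutation(cat, g, replicates = reps, seed = 23L)
  set.seed(99)
  # oracle: per replicate draw the same gamma-Poisson burden, scatter
  # over allelic sites directly
  bm <- burden_model(200L)
  oracle <- vapply(seq_len(reps), function(r) {
    n <- sample_total_burden(bm)
    oracle_collisions(n, n_loci, 1L)
  }, numeric(1L))
  se <- sqrt(stats::var(res$tallies$n_colliding) / reps +
               stats::var(oracle) / reps)
  expect_lt(abs(mean(res$tallies$n_colliding) - mean(oracle)), 3 * se)
  # single-channel second hits land on the other allele: all parallel
  expect_true(all(res$tallies$divergent == 0L |
                    res$tallies$parallel >= 0L))
  expect_equal(mean(res$tallies$n_colliding),
               2 * mean(res$tallies$parallel), tolerance = 0.05)
})

test_that("simulated spectra are indistinguishable from the catalog's", {
  g <- two_channel_genome(150L, 150L)
  cpos <- aca_positions(150L)
  tpos <- 7L * (seq_len(150L) - 1L) + 4L  # central T of GGTTTGG units
  cat <- rbind(mutation_records("chr1", cpos[1:100], "C", "T"),
               mutation_records("chr2", tpos[1:50], "T", "C"))
  res <- run_uniform_permutation(cat, g, replicates = 150L, seed = 2L)
  catalog_spec <- compute_spectrum(cat, g)
  expect_gte(cosine_similarity(res$hit_spectrum,
                               as.numeric(catalog_spec)), 0.999)
})

test_that("biallelic counts scale as burden squared and inverse loci", {
  # burden scaling at fixed locus count
  n_loci <- 1500L
  g <- single_channel_genome(n_loci)
  means <- vapply(c(100L, 200L), function(k) {
    res <- run_uniform_permutation(single_channel_catalog(k, n_loci), g,
                                   replicates = 250L, seed = 31L)
    mean(res$tallies$parallel + res$tallies$divergent)
  }, numeric(1L))
  # doubling the burden quadruples collisions (generous MC tolerance)
  expect_gt(means[2] / means[1], 3.0)
  expect_lt(means[2] / means[1], 5.2)
})

test_that("representative pools respect histology, cosine and drivers", {
  g <- two_channel_genome(80L, 80L)
  cpos <- aca_positions(80L)
  tpos <- 7L * (seq_len(80L) - 1L) + 4L
  target <- mutation_records("chr1", cpos[1:30], "C", "T")
  same <- mutation_records("chr1", cpos[31:60], "C", "T",
                           sample_id = "d1")
  same$is_driver <- c(TRUE, rep(FALSE, 29))
  disjoint_spec <- mutation_records("chr2", tpos[1:30], "T", "C",
                                    sample_id = "d2")
  other_hist <- mutation_records("chr1", cpos[61:80], "C", "T",
                                 sample_id = "d3")
  cohort <- list(
    list(catalog = same, histology = "melanoma", sample_id = "d1"),
    list(catalog = disjoint_spec, histology = "melanoma",
         sample_id = "d2"),
    list(catalog = other_hist, histology = "lung", sample_id = "d3"))
  pool <- select_representative_pool(target, "melanoma", cohort, g)
  expect_identical(pool$donors, "d1")
  # driver record excluded from the pool
  expect_false(any(pool$records$is_driver))
  expect_identical(pool$n_pool, 29L)
  # 29 >= 0.5 * 30: eligible
  expect_true(pool$eligible)
  # a pool below half the burden is ineligible
  small <- select_representative_pool(
    mutation_records("chr1", cpos[1:80], "C", "T"), "melanoma",
    cohort[1], g)
  expect_false(small$eligible)
})

test_that("neighbour resampling pairs positions across alleles", {
  g <- single_channel_genome(60L)
  pos <- aca_positions(60L)
  # pool positionally disjoint from the target: no violations ever
  target <- mutation_records("chr1", pos[1:10], "C", "T")
  pool_rec <- mutation_records("chr1", pos[21:40], "C", "T",
                               sample_id = "d")
  pool_rec$donor <- "d"
  pool <- structure(list(records = pool_rec, eligible = TRUE,
                         n_pool = 20L, target_burden = 10L),
                    class = "cohort_pool")
  res <- run_neighbour_resampling(target, pool, replicates = 100L,
                                  seed = 5L)
  expect_true(all(res$tallies$parallel == 0L))
  expect_true(all(res$tallies$divergent == 0L))
  # back/forward are structurally impossible
  expect_true(all(res$tallies$back == 0L & res$tallies$forward == 0L))
})

test_that("two-record resampling reproduces the enumerated parallel rate", {
  g <- single_channel_genome(10L)
  pos <- aca_positions(10L)
  # target {p, q}; pool {p:C>T, r:C>T}; allele A keeps 1, allele B draws 1
  target <- mutation_records("chr1", pos[c(1, 2)], "C", "T")
  pool_rec <- mutation_records("chr1", pos[c(1, 3)], "C", "T",
                               sample_id = "d")
  pool_rec$donor <- "d"
  pool <- structure(list(records = pool_rec, eligible = TRUE, n_pool = 2L,
                         target_burden = 2L), class = "cohort_pool")
  res <- run_neighbour_resampling(target, pool, replicates = 2000L,
                                  seed = 13L)
  # exhaustive enumeration: A is {p} or {q} (1/2 each), B is {p} or {r}
  # (1/2 each); a parallel event needs A = {p} and B = {p}: rate 1/4
  rate <- mean(res$tallies$parallel)
  expect_lt(abs(rate - 0.25), 3 * sqrt(0.25 * 0.75 / 2000))
})

test_that("driver records never enter allele B", {
  g <- single_channel_genome(30L)
  pos <- aca_positions(30L)
  target <- mutation_records("chr1", pos[1:10], "C", "T")
  donor_cat <- mutation_records("chr1", pos[1:20], "C", "T",
                                sample_id = "d")
  donor_cat$is_driver <- c(TRUE, rep(FALSE, 19))
  pool <- select_representative_pool(
    target, "x", list(list(catalog = donor_cat, histology = "x",
                           sample_id = "d")), g)
  expect_false(pos[1] %in% pool$records$pos[pool$records$is_driver])
  res <- run_neighbour_resampling(target, pool, replicates = 50L,
                                  seed = 1L)
  expect_s3_class(res$tallies, "data.frame")
})

test_that("tally summaries match independent computations", {
  fake <- structure(list(
    tallies = data.frame(replicate = 1:4, n_t_sim = 10L,
                         parallel = c(0L, 1L, 2L, 3L),
                         divergent = 0L, back = 0L, forward = 0L,
                         n_colliding = c(0L, 2L, 4L, 6L)),
    spec_parallel = matrix(0, 4, 96), spec_divergent = matrix(0, 4, 96)),
    class = "violation_tallies")
  s <- summarize_tallies(fake)
  expect_equal(s$per_class$parallel[["mean"]], 1.5)
  expect_equal(s$per_class$parallel[["se"]],
               stats::sd(c(0, 1, 2, 3)) / 2)
  # sort-based percentile oracle (inverse ecdf)
  x <- c(0L, 1L, 2L, 3L)
  expect_equal(s$per_class$parallel[["q975"]],
               sort(x)[ceiling(0.975 * 4)])
  expect_equal(s$frac_replicates_with_violation, 0.75)
  zero <- fake
  zero$tallies$parallel <- 0L; zero$tallies$n_colliding <- 0L
  sz <- summarize_tallies(zero)
  expect_equal(sz$per_class$parallel[["mean"]], 0)
  expect_equal(sz$frac_replicates_with_violation, 0)
})
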