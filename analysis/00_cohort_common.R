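# Shared helpers for the numbered analysis steps: rebuild the synthetic
# cohort deterministically from the truth manifest written by
# 01_synthesize_cohort.R (the manifest seeds regenerate every bundle
# bit-exactly, so no binary intermediates are stored).

suppressPackageStartupMessages(library(biallelic))

cohort_dir <- "results/cohort"

cohort_spectra <- list(
  skin = local({ s <- numeric(96L); s[33:48] <- 1; s / sum(s) }),
  lung = local({ s <- numeric(96L)
                 s[c(1:16, 33:48, 65:80)] <- rep(c(3, 2, 1), each = 16)
                 s / sum(s) }))

load_cohort <- function() {
  manifest <- jsonlite::read_json(
    file.path(cohort_dir, "truth_manifest.json"), simplifyVector = TRUE)
  config <- jsonlite::read_json(
    file.path(cohort_dir, "generator_config.json"),
    simplifyVector = TRUE)
  genome <- generate_reference(c(chr1 = 3e5, chr2 = 3e5),
                               gc_fraction = 0.45, seed = config$seed)
  list(manifest = manifest, config = config, genome = genome)
}

rebuild_sample <- function(cohort, sample_id) {
  info <- cohort$manifest[[sample_id]]
  co <- generate_catalog(cohort$genome, cohort_spectra[[info$type]],
                         burden = info$burden,
                         n_parallel = info$n_parallel,
                         n_divergent = info$n_divergent,
                         seed = info$catalog_seed, sample_id = sample_id)
  lay <- segment_layout(cohort$genome, n_segments = 2L,
                        states = list(c(2L, 1L), c(2L, 2L)))
  bundle <- simulate_observations(co, cohort$genome, lay,
                                  rho = cohort$config$rho,
                                  mean_depth = cohort$config$mean_depth,
                                  omega_true = cohort$config$omega_true,
                                  seed = info$obs_seed)
  list(catalog = co$catalog, manifest = co$manifest, bundle = bundle,
       histology = info$type)
}
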