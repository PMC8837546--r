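#!/usr/bin/env Rscript

# Build a small synthetic tumour cohort: a shared reference genome and,
# per "tumour type", a handful of samples with type-specific trinucleotide
# spectra, planted biallelic events and read-count observations. Writes
# the cohort (FASTA/VCF/TSV/JSON) under results/cohort/ for the downstream
# steps.

suppressPackageStartupMessages(library(biallelic))

seed <- 2026L
out <- "results/cohort"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genome <- generate_reference(c(chr1 = 3e5, chr2 = 3e5),
                             gc_fraction = 0.45, seed = seed,
                             fasta = file.path(out, "reference.fa"))
write_bed(genome$callable, file.path(out, "callable.bed"))

# two caricatured mutational processes: a UV-like C>T-dominant spectrum
# and a more even substitution mix
spectra <- list(
  skin = local({ s <- numeric(96L); s[33:48] <- 1; s / sum(s) }),
  lung = local({ s <- numeric(96L)
                 s[c(1:16, 33:48, 65:80)] <- rep(c(3, 2, 1), each = 16)
                 s / sum(s) }))

plan <- expand.grid(type = names(spectra), rep = 1:3,
                    stringsAsFactors = FALSE)
plan$sample <- sprintf("%s_%02d", plan$type, plan$rep)
plan$burden <- c(8000L, 6000L, 7000L, 3000L, 2500L, 3500L)[
  seq_len(nrow(plan))]
plan$n_parallel <- ifelse(plan$type == "skin", 12L, 4L)

manifest <- list()
for (i in seq_len(nrow(plan))) {
  sm <- plan$sample[i]
  co <- generate_catalog(genome, spectra[[plan$type[i]]],
                         burden = plan$burden[i],
                         n_parallel = plan$n_parallel[i],
                         n_divergent = 2L,
                         seed = seed + i, sample_id = sm)
  lay <- segment_layout(genome, n_segments = 2L,
                        states = list(c(2L, 1L), c(2L, 2L)))
  bundle <- simulate_observations(co, genome, lay, rho = 0.9,
                                  mean_depth = 80, omega_true = 300,
                                  seed = seed + 100L + i)
  write_catalog_vcf(co$catalog, file.path(out, paste0(sm, ".vcf")))
  utils::write.table(bundle$segments,
                     file.path(out, paste0(sm, "_segments.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$het_snps,
                     file.path(out, paste0(sm, "_hetsnps.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  # bundles are regenerated downstream from the manifest seeds
  manifest[[sm]] <- list(type = plan$type[i], burden = plan$burden[i],
                         n_parallel = plan$n_parallel[i],
                         n_divergent = 2L,
                         catalog_seed = seed + i,
                         obs_seed = seed + 100L + i,
                         truth_parallel = co$manifest$parallel,
                         truth_divergent = co$manifest$divergent)
  message(sm, ": ", plan$burden[i], " mutations, ",
          plan$n_parallel[i], " planted parallel events")
}
jsonlite::write_json(manifest, file.path(out, "truth_manifest.json"),
                     auto_unbox = TRUE, digits = NA)
jsonlite::write_json(list(seed = seed, rho = 0.9, mean_depth = 80,
                          omega_true = 300),
                     file.path(out, "generator_config.json"),
                     auto_unbox = TRUE)
message("cohort written to ", out)
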