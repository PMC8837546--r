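#!/usr/bin/env Rscript

# Closed-form estimation: compare simulated violation counts with the
# birthday-problem expectation, fit the per-type coefficient C_type by
# rescaling a representative catalog over a burden grid, and derive the
# effective genome size from the two simulators' expectations.

source("analysis/00_cohort_common.R")

out <- "results/estimators"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
seed <- 5050L
replicates <- 200L

cohort <- load_cohort()
sim_summary <- utils::read.delim(
  "results/simulations/simulation_summary.tsv")
n_callable <- sum(vapply(cohort$genome$contexts,
                         function(p) length(p$positions), 0L))

# birthday expectations per sample (diploid callable sites)
bd <- do.call(rbind, lapply(seq_len(nrow(sim_summary)), function(i) {
  b <- birthday_expectation(sim_summary$burden[i], 2L * n_callable)
  data.frame(sample = sim_summary$sample[i], exact = b$exact,
             approx = b$approx,
             uniform_sim = sim_summary$uniform_mean_biallelic[i])
}))
utils::write.table(bd, file.path(out, "birthday_comparison.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

# C_type per tumour type: neighbour-style burden scaling of one
# representative sample per type
ct_rows <- list()
for (tp in unique(sim_summary$type)) {
  rep_sample <- sim_summary$sample[sim_summary$type == tp][1L]
  s <- rebuild_sample(cohort, rep_sample)
  burdens <- round(nrow(s$catalog) * c(0.4, 0.7, 1))
  means <- vapply(seq_along(burdens), function(j) {
    sub <- s$catalog[sample.int(nrow(s$catalog), burdens[j]), ]
    res <- run_uniform_permutation(sub, cohort$genome,
                                   replicates = replicates,
                                   seed = seed + j)
    mean(res$tallies$parallel + res$tallies$divergent)
  }, numeric(1L))
  fit <- fit_c_type(burdens, means, 2L * n_callable)
  ct_rows[[tp]] <- data.frame(type = tp, sample = rep_sample,
                              c_type = fit$c_type,
                              residual_scale = fit$residual_scale)
  message(tp, ": C_type = ", round(fit$c_type, 3))
}
utils::write.table(do.call(rbind, ct_rows),
                   file.path(out, "c_type.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

# effective genome size from the simulator pair, per eligible sample
eligible <- sim_summary[sim_summary$neighbour_eligible &
                          !is.na(sim_summary$neighbour_mean_biallelic) &
                          sim_summary$neighbour_mean_biallelic > 0, ]
neff <- do.call(rbind, lapply(seq_len(nrow(eligible)), function(i) {
  e <- effective_genome_size(eligible$uniform_mean_biallelic[i],
                             eligible$neighbour_mean_biallelic[i],
                             n_callable)
  data.frame(sample = eligible$sample[i], type = eligible$type[i],
             n_eff = e$n_eff, estimator = e$estimator)
}))
if (!is.null(neff) && nrow(neff)) {
  utils::write.table(neff, file.path(out, "effective_genome_size.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  agg <- stats::aggregate(n_eff ~ type, neff, stats::median)
  print(agg)
}
message("estimator outputs written to ", out)
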