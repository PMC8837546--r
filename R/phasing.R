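# Read-backed phasing of heterozygous SNP - somatic SNV pairs.
#
# When a germline heterozygous SNP lies within read-pair range (700 bp) of
# a somatic SNV, the reads connecting them reveal which parental allele
# carries the variant. A parallel mutation places the variant on both
# alleles, so both Ref-Alt and Alt-Alt read pairs (SNP allele x SNV allele)
# are observed.

#' Quality-filter a phased read pair
#'
#' Accepts a read pair for phasing evidence when: mapping quality >= 20 on
#' both reads, base quality >= 25 at both phased positions, no hard or
#' soft clipping, properly paired, not a duplicate, no vendor-fail flag,
#' no indel in the pair, and fewer than 2 mismatches in any single read and
#' fewer than 3 in the whole pair (mismatch counts exclude the phased
#' positions themselves).
#'
#' @param obs Data frame (one row per pair) with columns `mq1`, `mq2`,
#'   `bq_snp`, `bq_snv`, `clipped`, `proper_pair`, `duplicate`,
#'   `vendor_fail`, `has_indel`, `mismatches1`, `mismatches2`.
#' @return Logical vector: pair accepted.
#' @export
filter_read_pair <- function(obs) {
  obs$mq1 >= 20 & obs$mq2 >= 20 &
    obs$bq_snp >= 25 & obs$bq_snv >= 25 &
    !obs$clipped & obs$proper_pair & !obs$duplicate & !obs$vendor_fail &
    !obs$has_indel &
    obs$mismatches1 < 2 & obs$mismatches2 < 2 &
    (obs$mismatches1 + obs$mismatches2) < 3
}

#' Call a parallel mutation from phased read-pair counts
#'
#' A SNP-SNV pair evidences a parallel mutation when at least 2 Ref-Alt and
#' at least 2 Alt-Alt read pairs are seen, each representing more than 10%
#' of the total phased reads, and the SNP itself is not a BAF outlier on
#' its segment (two-sided beta-binomial p > 0.001) -- the latter guards
#' against a post-gain mutation of the in-cis SNP allele masquerading as
#' biallelic.
#'
#' @param n_rr,n_ra,n_ar,n_aa Phased pair counts (SNP allele x SNV allele:
#'   Ref-Ref, Ref-Alt, Alt-Ref, Alt-Alt), from accepted pairs only.
#' @param snp_two_sided_p Two-sided beta-binomial p-value of the SNP
#'   against its segment BAF.
#' @param min_reads,min_fraction,snp_outlier_p Call thresholds.
#' @return Verdict: `"parallel"`, `"single"` or `"uninformative"`.
#' @export
call_parallel_phasing <- function(n_rr, n_ra, n_ar, n_aa,
                                  snp_two_sided_p,
                                  min_reads = 2L, min_fraction = 0.1,
                                  snp_outlier_p = 0.001) {
  total <- n_rr + n_ra + n_ar + n_aa
  if (total == 0) return("uninformative")
  ok <- n_ra >= min_reads && n_aa >= min_reads &&
    n_ra / total > min_fraction && n_aa / total > min_fraction &&
    snp_two_sided_p > snp_outlier_p
  if (ok) "parallel" else "single"
}

#' Phase a table of SNP-SNV evidence
#'
#' Each SNP-SNV pair is evaluated independently; an SNV with several
#' informative SNPs is called parallel if any of its pairs is.
#'
#' @param evidence Data frame with columns `snv_chrom`, `snv_pos`,
#'   `snp_pos`, `n_rr`, `n_ra`, `n_ar`, `n_aa`, `snp_p` (SNP two-sided
#'   beta-binomial p-value), and optionally `sample`.
#' @param ... Thresholds passed to [call_parallel_phasing()].
#' @return Data frame, one row per SNV, with `verdict` and supporting
#'   counts of its best pair.
#' @export
phase_snvs <- function(evidence, ...) {
  need <- c("snv_chrom", "snv_pos", "snp_pos",
            "n_rr", "n_ra", "n_ar", "n_aa", "snp_p")
  stopifnot(all(need %in% names(evidence)))
  evidence$verdict <- vapply(seq_len(nrow(evidence)), function(i) {
    call_parallel_phasing(evidence$n_rr[i], evidence$n_ra[i],
                          evidence$n_ar[i], evidence$n_aa[i],
                          evidence$snp_p[i], ...)
  }, character(1L))
  keysnv <- paste(evidence$snv_chrom, evidence$snv_pos, sep = ":")
  out <- lapply(split(seq_len(nrow(evidence)), keysnv), function(idx) {
    sub <- evidence[idx, , drop = FALSE]
    v <- if (any(sub$verdict == "parallel")) "parallel"
    else if (any(sub$verdict == "single")) "single"
    else "uninformative"
    best <- sub[order(sub$verdict != "parallel",
                      -(sub$n_ra + sub$n_aa)), , drop = FALSE][1, ]
    data.frame(snv_chrom = best$snv_chrom, snv_pos = best$snv_pos,
               verdict = v, n_rr = best$n_rr, n_ra = best$n_ra,
               n_ar = best$n_ar, n_aa = best$n_aa,
               n_pairs = nrow(sub), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$snv_chrom, out$snv_pos), , drop = FALSE]
}

#' Precision and recall of VAF calls against phasing
#'
#' Precision is the fraction of VAF-inferred parallel mutations, restricted
#' to phaseable SNVs, confirmed by phasing; recall is the fraction of
#' phasing-confirmed parallel mutations recovered through their allele
#' frequencies. Phaseable SNVs are those whose SNP shows >= 2 reads of each
#' allele and whose SNV is reported by >= 4 reads.
#'
#' @param vaf_keys Character keys (`chrom:pos`) of VAF parallel candidates.
#' @param phasing_keys Keys of phasing-confirmed parallel mutations.
#' @param phaseable_keys Keys of all phaseable SNVs.
#' @return List with `precision` and `recall` (NA when a denominator is
#'   empty, never 0 by convention).
#' @export
evaluate_precision_recall <- function(vaf_keys, phasing_keys,
                                      phaseable_keys) {
  vaf_ph <- intersect(vaf_keys, phaseable_keys)
  confirmed <- intersect(vaf_keys, phasing_keys)
  precision <- if (length(vaf_ph) == 0L) NA_real_ else
    length(confirmed) / length(vaf_ph)
  recall <- if (length(phasing_keys) == 0L) NA_real_ else
    length(confirmed) / length(phasing_keys)
  list(precision = precision, recall = recall,
       n_vaf_phaseable = length(vaf_ph),
       n_phasing = length(phasing_keys),
       n_confirmed = length(confirmed))
}

#' Extrapolate the total parallel burden from phaseable SNVs
#'
#' The parallel rate observed at phaseable SNVs is extrapolated to all
#' tested SNVs under a beta-binomial model:
#' n_viol ~ Bin(n_tested, P ~ Beta(n_par + 0.001, n_single + 0.001)).
#'
#' @param n_tested Number of SNVs passing all VAF-caller filters.
#' @param n_phas_par Phasing-confirmed parallel mutations.
#' @param n_phas_single Phaseable SNVs without parallel evidence.
#' @return List with `mean` (posterior predictive mean) and `lower`/`upper`
#'   (2.5 and 97.5 percentiles of the predictive distribution).
#' @export
extrapolate_total_parallel <- function(n_tested, n_phas_par,
                                       n_phas_single) {
  if (n_phas_par + n_phas_single < 1) {
    stop("no phaseable observations to extrapolate from")
  }
  a <- n_phas_par + 0.001
  b <- n_phas_single + 0.001
  mean_est <- n_tested * a / (a + b)
  # beta-binomial predictive pmf over 0..n_tested
  k <- 0:n_tested
  lp <- betabinom_lpmf(k, n_tested, a, b)
  cdf <- cumsum(exp(lp))
  cdf <- cdf / cdf[length(cdf)]
  lower <- k[which(cdf >= 0.025)[1]]
  upper <- k[which(cdf >= 0.975)[1]]
  list(mean = mean_est, lower = lower, upper = upper)
}
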