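# VAF-based detection of biallelic parallel mutations.
#
# A parallel mutation sits on all copies of both parental alleles, so its
# variant allele frequency exceeds the maximum expected for a variant
# confined to the major allele. That maximum is the segment's mean phased
# BAF corrected for the major-allele contribution of admixed normal cells
# (purity rho, tumour ploidy psi_t, segment logR); candidate SNVs are then
# tested one-sided under the sample-calibrated beta-binomial and passed
# through a cascade of quality filters.

#' Purity- and copy-number-corrected somatic BAF ceiling
#'
#' BAF_som = BAF_seg - (1 - rho) / ((2 (1 - rho) + rho psi_t) * 2^logR_seg):
#' the expected allele fraction of a clonal variant on all copies of the
#' major allele. If the corrected value falls below 0.05 it is
#' conservatively raised back to BAF_seg.
#'
#' @param baf_seg Segment mean phased BAF, in \[0.5, 1\].
#' @param rho Tumour purity in (0, 1\].
#' @param psi_t Tumour ploidy (> 0).
#' @param logr_seg Segment logR.
#' @return BAF_som.
#' @export
compute_baf_som <- function(baf_seg, rho, psi_t, logr_seg) {
  stopifnot(rho > 0, rho <= 1, psi_t > 0)
  if (any(baf_seg < 0.5 | baf_seg > 1)) {
    stop("baf_seg must lie in [0.5, 1] (haplotype-flipped input contract)")
  }
  denom <- (2 * (1 - rho) + rho * psi_t) * 2^logr_seg
  if (any(denom <= 0)) stop("non-positive denominator in BAF_som")
  raw <- baf_seg - (1 - rho) / denom
  # strict floor with float tolerance: raw exactly at 0.05 is kept
  ifelse(raw < 0.05 - 1e-12, baf_seg, raw)
}

#' Statistical power filter for one-sided VAF tests
#'
#' A site is powered when its minimal attainable one-sided p-value --- the
#' upper tail at v = n --- falls below `threshold`; sites with low read
#' counts or BAF_som near 1 can never reach significance and are excluded
#' before multiple-testing correction.
#'
#' @param n Total read count at the site.
#' @param model `betabinom_model` with mean BAF_som.
#' @param threshold Maximal minimal p (default 0.001).
#' @return Logical: site is powered.
#' @export
power_filter <- function(n, model, threshold = 0.001) {
  stopifnot(n >= 1)
  betabinom_tail(n, n, model) < threshold
}

#' Outlier guard on heterozygous SNPs flanking a candidate
#'
#' The nearest heterozygous SNP on each side of a candidate (within its
#' copy-number segment) must look like the rest of the segment, otherwise
#' a missed copy-number change may explain the allele-frequency excess.
#' BAF check: each flank's two-sided beta-binomial p > `p_single` and
#' their Fisher-combined p > `p_combined`. logR check: identical
#' thresholds with two-tailed Gaussian p-values against the segment median
#' logR and a MAD-based (consistency-adjusted) standard deviation.
#'
#' @param snv_pos Candidate position.
#' @param het_snps Data frame of the segment's heterozygous SNPs with
#'   columns `pos`, `major_count`, `minor_count`, `logr`.
#' @param baf_seg Segment mean phased BAF.
#' @param omega Calibrated concentration.
#' @param p_single,p_combined Guard thresholds.
#' @return List with `status` (`"pass"`, `"fail"` or `"untestable"`) and
#'   per-check diagnostics.
#' @export
neighbour_guard <- function(snv_pos, het_snps, baf_seg, omega,
                            p_single = 0.001, p_combined = 0.01) {
  left <- het_snps[het_snps$pos < snv_pos, , drop = FALSE]
  right <- het_snps[het_snps$pos > snv_pos, , drop = FALSE]
  if (nrow(left) == 0L || nrow(right) == 0L) {
    return(list(status = "untestable", reason = "missing flank"))
  }
  flanks <- rbind(left[which.max(left$pos), , drop = FALSE],
                  right[which.min(right$pos), , drop = FALSE])
  model <- betabinom_model(baf_seg, omega)
  p_baf <- vapply(seq_len(2L), function(i) {
    betabinom_two_sided(flanks$major_count[i],
                        flanks$major_count[i] + flanks$minor_count[i],
                        model)
  }, numeric(1L))
  med <- stats::median(het_snps$logr)
  sd_r <- stats::mad(het_snps$logr)  # 1.4826 * MAD, consistency-adjusted
  p_logr <- if (sd_r > 0) {
    2 * stats::pnorm(-abs((flanks$logr - med) / sd_r))
  } else {
    ifelse(flanks$logr == med, 1, .Machine$double.xmin)
  }
  p_baf <- pmax(p_baf, .Machine$double.xmin)
  p_logr <- pmax(p_logr, .Machine$double.xmin)
  baf_ok <- all(p_baf > p_single) && fisher_combine(p_baf) > p_combined
  logr_ok <- all(p_logr > p_single) && fisher_combine(p_logr) > p_combined
  list(status = if (baf_ok && logr_ok) "pass" else "fail",
       p_baf = p_baf, p_logr = p_logr,
       fisher_baf = fisher_combine(p_baf),
       fisher_logr = fisher_combine(p_logr))
}

# left-most containing segment index per position (1-based inclusive)
assign_segment <- function(chrom, pos, segments) {
  vapply(seq_along(pos), function(i) {
    hit <- which(segments$chrom == chrom[i] &
                   segments$start <= pos[i] & segments$end >= pos[i])
    if (length(hit)) hit[1L] else NA_integer_
  }, integer(1L))
}

in_intervals <- function(chrom, pos, intervals) {
  if (is.null(intervals) || nrow(intervals) == 0L) {
    return(rep(FALSE, length(pos)))
  }
  vapply(seq_along(pos), function(i) {
    any(intervals$chrom == chrom[i] & intervals$start <= pos[i] &
          intervals$end >= pos[i])
  }, logical(1L))
}

#' Apply the positional filter cascade to candidate SNVs
#'
#' Removing filters: (i) overlap with a known heterozygous germline SNP;
#' (ii) region of common structural variation; (iv) two or more
#' heterozygous SNPs within 25 bp; (v) loss-of-heterozygosity segments are
#' not tested (in males only the pseudoautosomal regions of X are
#' considered). Non-removing flags: T/B-cell receptor loci, proximity to an
#' indel (window -10 to +25 bp around the variant) and the liftover status
#' carried on input.
#'
#' @param snvs Data frame with `chrom`, `pos` (and optionally
#'   `liftover_ok`).
#' @param segments Segment table with `chrom`, `start`, `end`, `minor`.
#' @param resources List with elements `germline_snps` (`chrom`, `pos`),
#'   `common_sv` (`chrom`, `start`, `end`), `het_snp_positions`
#'   (`chrom`, `pos`), `indels` (`chrom`, `pos`), `tcr_bcr`
#'   (`chrom`, `start`, `end`); any may be `NULL`.
#' @param sex `"female"` or `"male"`.
#' @param par_regions X pseudoautosomal intervals (`chrom`, `start`,
#'   `end`); only used for males.
#' @param x_chrom Name of the X chromosome in this assembly.
#' @return `snvs` with columns `segment`, `status`
#'   (`"testable"`/`"removed"`), `filter` (removal id or `NA`) and flag
#'   columns `flag_tcr_bcr`, `flag_indel_proximity`, `flag_liftover_fail`.
#' @export
apply_site_filters <- function(snvs, segments, resources, sex = "female",
                               par_regions = NULL, x_chrom = "chrX") {
  n <- nrow(snvs)
  status <- rep("testable", n)
  filter_id <- rep(NA_character_, n)
  mark <- function(sel, id) {
    sel <- sel & status == "testable"
    status[sel] <<- "removed"
    filter_id[sel] <<- id
  }
  gl <- resources$germline_snps
  if (!is.null(gl) && nrow(gl)) {
    hit <- paste(snvs$chrom, snvs$pos) %in% paste(gl$chrom, gl$pos)
    mark(hit, "germline-overlap")
  }
  sv <- resources$common_sv
  mark(in_intervals(snvs$chrom, snvs$pos, sv), "common-sv")
  hs <- resources$het_snp_positions
  if (!is.null(hs) && nrow(hs)) {
    dense <- vapply(seq_len(n), function(i) {
      sum(hs$chrom == snvs$chrom[i] &
            abs(hs$pos - snvs$pos[i]) <= 25) >= 2L
    }, logical(1L))
    mark(dense, "snp-density")
  }
  seg <- assign_segment_all(snvs, segments)
  no_seg <- is.na(seg)
  mark(no_seg, "no-segment")
  loh <- !no_seg & segments$minor[seg] == 0
  mark(loh, "loh")
  if (identical(sex, "male")) {
    on_x <- snvs$chrom == x_chrom
    in_par <- in_intervals(snvs$chrom, snvs$pos, par_regions)
    mark(on_x & !in_par, "male-x-nonpar")
  }
  snvs$segment <- seg
  snvs$status <- status
  snvs$filter <- filter_id
  snvs$flag_tcr_bcr <- in_intervals(snvs$chrom, snvs$pos,
                                    resources$tcr_bcr)
  ind <- resources$indels
  snvs$flag_indel_proximity <- if (!is.null(ind) && nrow(ind)) {
    vapply(seq_len(n), function(i) {
      any(ind$chrom == snvs$chrom[i] &
            ind$pos >= snvs$pos[i] - 10 & ind$pos <= snvs$pos[i] + 25)
    }, logical(1L))
  } else rep(FALSE, n)
  snvs$flag_liftover_fail <- if ("liftover_ok" %in% names(snvs)) {
    !snvs$liftover_ok
  } else rep(FALSE, n)
  snvs
}

assign_segment_all <- function(snvs, segments) {
  seg <- rep(NA_integer_, nrow(snvs))
  for (ch in unique(snvs$chrom)) {
    sel <- snvs$chrom == ch
    seg[sel] <- assign_segment(snvs$chrom[sel], snvs$pos[sel], segments)
  }
  seg
}

#' Call biallelic parallel mutations from allele frequencies in one sample
#'
#' Pipeline: calibrate omega on heterozygous SNPs (unless supplied), derive
#' each segment's BAF_som, apply the positional filter cascade, drop
#' unpowered sites, compute one-sided beta-binomial p-values, adjust by
#' Benjamini-Hochberg over the tested sites, and subject q <= `q_max`
#' candidates to the flanking-SNP outlier guard. Sample-level QC: the
#' robust QQ slope of the tested p-values must not exceed 1 (otherwise
#' purity may be under-estimated and the whole sample is excluded), and, if
#' a simulator summary is supplied, samples in which both simulators yield
#' zero biallelic mutations are excluded.
#'
#' @param bundle List describing the sample: `rho`, `psi_t`, `segments`
#'   (with `baf_seg`, `logr_seg`, `minor`, coordinates), `het_snps` (with
#'   `pos`, `major_count`, `minor_count`, `logr`, `segment`), `snvs`
#'   (with `chrom`, `pos`, `ref`, `alt`, `alt_count`, `depth`), `sex` and
#'   `resources` (see [apply_site_filters()]).
#' @param omega Calibrated concentration; `NULL` to calibrate from
#'   `het_snps`.
#' @param q_max BH significance level (default 0.1).
#' @param power_p Power-filter threshold (default 0.001).
#' @param guard_p,guard_fisher_p Flanking-guard thresholds.
#' @param simulator_summary Optional list of two [summarize_tallies()]
#'   results (uniform and neighbour models).
#' @return List of class `vaf_calls`: `calls` (per-SNV table with `status`,
#'   `p`, `q`, `powered`, `guard`, `verdict`, filter trail and flags),
#'   `omega`, `qq_slope`, `excluded`, `exclusion_reason`.
#' @export
call_sample <- function(bundle, omega = NULL, q_max = 0.1,
                        power_p = 0.001, guard_p = 0.001,
                        guard_fisher_p = 0.01,
                        simulator_summary = NULL) {
  stopifnot(!is.null(bundle$rho), !is.null(bundle$psi_t))
  segments <- bundle$segments
  if (is.null(omega)) {
    omega <- calibrate_omega(bundle$het_snps, segments)$omega
  }
  segments$baf_som <- compute_baf_som(segments$baf_seg, bundle$rho,
                                      bundle$psi_t, segments$logr_seg)
  calls <- apply_site_filters(bundle$snvs, segments, bundle$resources,
                              sex = if (is.null(bundle$sex)) "female"
                              else bundle$sex,
                              par_regions = bundle$resources$par_regions)
  n <- nrow(calls)
  calls$p <- NA_real_; calls$q <- NA_real_
  calls$powered <- NA; calls$guard <- NA_character_
  calls$verdict <- ifelse(calls$status == "removed", "untested",
                          NA_character_)
  testable <- which(calls$status == "testable")
  models <- vector("list", nrow(segments))
  for (i in testable) {
    s <- calls$segment[i]
    if (is.null(models[[s]])) {
      models[[s]] <- betabinom_model(min(segments$baf_som[s],
                                         1 - 1e-9), omega)
    }
    dep <- calls$depth[i]
    if (dep < 1) { calls$verdict[i] <- "untested"; next }
    calls$powered[i] <- power_filter(dep, models[[s]], power_p)
    if (calls$powered[i]) {
      calls$p[i] <- betabinom_tail(calls$alt_count[i], dep, models[[s]])
    } else {
      calls$verdict[i] <- "untested"
    }
  }
  tested <- which(!is.na(calls$p))
  if (length(tested)) {
    calls$q[tested] <- bh_adjust(calls$p[tested])
  }
  slope <- if (length(tested) >= 10L) {
    tryCatch(qq_slope(calls$p[tested]), error = function(e) NA_real_)
  } else NA_real_
  for (i in tested) {
    if (calls$q[i] > q_max) { calls$verdict[i] <- "not-significant"; next }
    s <- calls$segment[i]
    hs <- bundle$het_snps[bundle$het_snps$segment == s, , drop = FALSE]
    g <- neighbour_guard(calls$pos[i], hs, segments$baf_seg[s], omega,
                         p_single = guard_p, p_combined = guard_fisher_p)
    calls$guard[i] <- g$status
    calls$verdict[i] <- if (g$status == "pass") "parallel-candidate"
    else "untested"
  }
  excluded <- FALSE; reason <- NA_character_
  if (!is.na(slope) && slope > 1) {
    excluded <- TRUE
    reason <- "qq-slope-above-1"
  }
  if (!excluded && !is.null(simulator_summary)) {
    zeros <- vapply(simulator_summary, function(s) {
      s$mean_biallelic == 0
    }, logical(1L))
    if (length(zeros) && all(zeros)) {
      excluded <- TRUE
      reason <- "simulators-zero-biallelic"
    }
  }
  if (excluded) {
    calls$verdict[calls$verdict == "parallel-candidate"] <- "untested"
  }
  structure(list(calls = calls, omega = omega, qq_slope = slope,
                 excluded = excluded, exclusion_reason = reason,
                 baf_som = segments$baf_som),
            class = "vaf_calls")
}

#' Germline and depth filter for divergent candidates
#'
#' A multi-allelic candidate passes when the germline posterior
#' (log10 scale) is below -1 for both alternate alleles and the matched
#' normal shows at least 19 high-quality reads.
#'
#' @param records Data frame with columns `p_germline1`, `p_germline2`,
#'   `normal_depth`.
#' @param max_p_germline,min_depth Rule thresholds.
#' @return Character vector: `"pass"`, `"fail"` or `"unevaluable"` (missing
#'   annotations).
#' @export
filter_divergent_candidates <- function(records, max_p_germline = -1,
                                        min_depth = 19L) {
  need <- c("p_germline1", "p_germline2", "normal_depth")
  if (!all(need %in% names(records))) {
    return(rep("unevaluable", nrow(records)))
  }
  ifelse(is.na(records$p_germline1) | is.na(records$p_germline2) |
           is.na(records$normal_depth), "unevaluable",
         ifelse(records$p_germline1 < max_p_germline &
                  records$p_germline2 < max_p_germline &
                  records$normal_depth >= min_depth, "pass", "fail"))
}
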