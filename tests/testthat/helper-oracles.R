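# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately use different arithmetic than the implementation.

# Beta-binomial pmf by forward recurrence (independent of the
# lchoose/lbeta route used in the package):
#   pmf(k+1)/pmf(k) = (n-k)/(k+1) * (a+k)/(b+n-k-1)
oracle_bb_pmf <- function(n, a, b) {
  j <- 0:(n - 1)
  pmf <- numeric(n + 1L)
  pmf[1L] <- exp(sum(log(b + j) - log(a + b + j)))
  for (k in 0:(n - 1L)) {
    pmf[k + 2L] <- pmf[k + 1L] * (n - k) / (k + 1) *
      (a + k) / (b + n - k - 1)
  }
  pmf
}

oracle_bb_upper_tail <- function(v, n, m, omega) {
  pmf <- oracle_bb_pmf(n, m * omega, (1 - m) * omega)
  sum(pmf[(v + 1L):(n + 1L)])
}

# hand step-up BH
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# toy genome: n_loci copies of a context unit; "GGACA" yields one A[C>A]A
# class locus per unit, spacer contexts carry no spectrum mass
single_channel_genome <- function(n_loci, unit = "GGACA") {
  seqs <- c(chr1 = paste(rep(unit, n_loci), collapse = ""))
  context_genome(seqs)
}

# two chromosomes, each a run of a single context class:
# chr1 A[C>.]A loci, chr2 T[T>.]T loci
two_channel_genome <- function(n_loci1, n_loci2) {
  seqs <- c(chr1 = paste(rep("GGACA", n_loci1), collapse = ""),
            chr2 = paste(rep("GGTTTGG", n_loci2), collapse = ""))
  context_genome(seqs)
}

# positions of the central C in each "GGACA" unit of chr1
aca_positions <- function(n_loci) 5L * (seq_len(n_loci) - 1L) + 4L

# catalog of k C>T mutations at distinct ACA loci on chr1
single_channel_catalog <- function(k, n_loci) {
  mutation_records("chr1", aca_positions(n_loci)[seq_len(k)], "C", "T")
}

# brute-force collision counter: scatter n hits over the 2*n_loci allelic
# copies of identical loci (without replacement, mirroring the fact that a
# mutated single-channel site leaves the mutable set) and count mutations
# at loci hit on both alleles
oracle_collisions <- function(n, n_loci, reps) {
  vapply(seq_len(reps), function(r) {
    idx <- sample.int(2L * n_loci, n)
    locus <- (idx + 1L) %/% 2L
    cnt <- tabulate(locus, nbins = n_loci)
    as.numeric(sum(cnt[cnt >= 2L]))
  }, numeric(1L))
}

# toy fixture: 10 SNVs on one chromosome, each removing filter tripped
# once and both flags set once; 6 survive by construction
cascade_fixture <- function() {
  segments <- data.frame(chrom = "chr1",
                         start = c(1L, 1001L), end = c(1000L, 2000L),
                         major = c(2L, 1L), minor = c(1L, 0L),
                         baf_seg = c(0.65, 0.95),
                         logr_seg = c(0, -0.5))
  snvs <- data.frame(chrom = "chr1",
                     pos = c(100L, 200L, 300L, 400L, 500L, 600L, 700L,
                             800L, 900L, 1500L),
                     ref = "C", alt = "T",
                     alt_count = 30L, depth = 60L, liftover_ok = TRUE)
  resources <- list(
    germline_snps = data.frame(chrom = "chr1", pos = 200L),
    common_sv = data.frame(chrom = "chr1", start = 390L, end = 410L),
    het_snp_positions = data.frame(chrom = "chr1",
                                   pos = c(590L, 615L, 50L, 960L)),
    indels = data.frame(chrom = "chr1", pos = 910L),
    tcr_bcr = data.frame(chrom = "chr1", start = 95L, end = 105L),
    par_regions = NULL)
  list(segments = segments, snvs = snvs, resources = resources)
}

# heterozygous-SNP table at one segment with known concentration
calibration_fixture <- function(n_snps, depth, omega_true,
                                baf = 0.5, seed = 1L) {
  set.seed(seed)
  dep <- pmax(stats::rpois(n_snps, depth), 1L)
  p <- stats::rbeta(n_snps, baf * omega_true, (1 - baf) * omega_true)
  v <- stats::rbinom(n_snps, dep, p)
  # flip so the reported major count reflects the phased major allele
  list(het_snps = data.frame(major_count = v, minor_count = dep - v,
                             segment = 1L),
       segments = data.frame(baf_seg = baf))
}
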