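# Synthetic tumour cohorts with known biallelic truth.
#
# The generator inverts the detection model: it builds a random reference,
# scatters a mutation catalog according to a requested trinucleotide
# spectrum, plants parallel/divergent events, and draws SNP/SNV read
# counts from the purity- and copy-number-aware beta-binomial model, so
# every pipeline stage can be benchmarked against a truth manifest.

# beta-binomial draws; m clamped away from {0,1} so a "certain" allele
# still tolerates the Beta draw
rbetabinom <- function(n_draws, size, m, omega) {
  m <- pmin(pmax(m, 1e-9), 1 - 1e-9)
  p <- stats::rbeta(n_draws, m * omega, (1 - m) * omega)
  stats::rbinom(n_draws, size, p)
}

#' Generate a random reference genome
#'
#' Bases are i.i.d. at the requested GC content; callable intervals cover
#' each chromosome except optional masked windows.
#'
#' @param chrom_lengths Named integer vector of chromosome lengths
#'   (>= 1000).
#' @param gc_fraction Genome GC content in (0, 1).
#' @param seed RNG seed (deterministic output per seed).
#' @param masked Optional data frame (`chrom`, `start`, `end`) of
#'   non-callable windows.
#' @param fasta Optional path: write the sequences as FASTA.
#' @return A `context_genome`.
#' @export
generate_reference <- function(chrom_lengths, gc_fraction = 0.4,
                               seed = 1L, masked = NULL, fasta = NULL) {
  stopifnot(all(chrom_lengths >= 1000L), !is.null(names(chrom_lengths)))
  set.seed(seed)
  probs <- c((1 - gc_fraction) / 2, gc_fraction / 2,
             gc_fraction / 2, (1 - gc_fraction) / 2)
  seqs <- vapply(chrom_lengths, function(len) {
    paste(sample(BASES, len, replace = TRUE, prob = probs), collapse = "")
  }, character(1L))
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- names(chrom_lengths)
  callable <- data.frame(chrom = names(chrom_lengths), start = 1L,
                         end = as.integer(unname(chrom_lengths)),
                         stringsAsFactors = FALSE)
  if (!is.null(masked) && nrow(masked)) {
    pieces <- list()
    for (ch in names(chrom_lengths)) {
      keep <- IRanges::IRanges(1L, chrom_lengths[[ch]])
      msk <- masked[masked$chrom == ch, , drop = FALSE]
      if (nrow(msk)) {
        keep <- IRanges::setdiff(keep,
                                 IRanges::IRanges(msk$start, msk$end))
      }
      if (length(keep)) {
        pieces[[ch]] <- data.frame(chrom = ch,
                                   start = IRanges::start(keep),
                                   end = IRanges::end(keep))
      }
    }
    callable <- do.call(rbind, pieces)
  }
  if (!is.null(fasta)) Biostrings::writeXStringSet(ss, fasta)
  context_genome(ss, callable)
}

#' Generate a mutation catalog with planted biallelic events
#'
#' Single SNVs are drawn per the requested spectrum at uniform callable
#' positions (one mutation per locus). Parallel events are planted as the
#' same substitution on both parental alleles -- emitted as one ordinary
#' record, their biallelic nature living only in the truth manifest and
#' later in read counts. Divergent events carry two distinct alternates.
#'
#' @param genome A `context_genome`.
#' @param spectrum Numeric vector of 96 channel probabilities (or a
#'   `trinuc_spectrum`).
#' @param burden Total number of catalog records (singles + planted).
#' @param n_parallel,n_divergent Planted biallelic events.
#' @param seed RNG seed.
#' @param sample_id Sample label.
#' @return List with `catalog` (`mutation_records`) and `manifest` (truth:
#'   `parallel`, `divergent` data frames, `n_single`, generator
#'   parameters).
#' @export
generate_catalog <- function(genome, spectrum, burden,
                             n_parallel = 0L, n_divergent = 0L,
                             seed = 1L, sample_id = "synthetic") {
  stopifnot(burden >= n_parallel + n_divergent)
  set.seed(seed)
  p <- as.numeric(spectrum)
  stopifnot(length(p) == 96L, sum(p) > 0)
  p <- p / sum(p)
  chroms <- names(genome$contexts)
  # flatten callable positions over chromosomes
  all_pos <- do.call(rbind, lapply(chroms, function(ch) {
    ctx <- genome$contexts[[ch]]
    data.frame(chrom = ch, pos = ctx$positions, class = ctx$class,
               pyr = ctx$pyrimidine, stringsAsFactors = FALSE)
  }))
  chan <- sample.int(96L, burden, replace = TRUE, prob = p)
  cls <- class_of_channel()[chan]
  need <- table(cls)
  rows <- integer(burden)
  for (c2 in as.integer(names(need))) {
    avail <- which(all_pos$class == c2)
    k <- need[[as.character(c2)]]
    if (length(avail) < k) {
      stop("insufficient context loci for class ",
           context_class_labels()[c2])
    }
    rows[cls == c2] <- sample(avail, k)
  }
  pyr <- all_pos$pyr[rows]
  sub <- (chan - 1L) %/% 16L
  alt_pyr <- vapply(chan, function(ch2) {
    s <- (ch2 - 1L) %/% 16L
    SUB_ALTS[[PYRIMIDINES[s %/% 3L + 1L]]][s %% 3L + 1L]
  }, character(1L))
  ref_pyr <- PYRIMIDINES[sub %/% 3L + 1L]
  ref <- ifelse(pyr, ref_pyr, unname(COMPLEMENT[ref_pyr]))
  alt <- ifelse(pyr, alt_pyr, unname(COMPLEMENT[alt_pyr]))
  roles <- rep("single", burden)
  if (n_parallel + n_divergent > 0) {
    planted <- sample.int(burden, n_parallel + n_divergent)
    roles[planted[seq_len(n_parallel)]] <- "parallel"
    if (n_divergent > 0) {
      roles[planted[n_parallel + seq_len(n_divergent)]] <- "divergent"
    }
  }
  alt2 <- rep(NA_character_, burden)
  div <- which(roles == "divergent")
  for (i in div) {
    others <- setdiff(BASES, c(ref[i], alt[i]))
    alt2[i] <- sample(others, 1L)
  }
  catalog <- mutation_records(all_pos$chrom[rows], all_pos$pos[rows],
                              ref, alt, alt2 = alt2, vtype = "SNV",
                              is_driver = FALSE, sample_id = sample_id)
  catalog$role <- roles
  ord <- order(catalog$chrom, catalog$pos)
  catalog <- catalog[ord, , drop = FALSE]
  rownames(catalog) <- NULL
  manifest <- list(
    parallel = catalog[catalog$role == "parallel",
                       c("chrom", "pos", "ref", "alt"), drop = FALSE],
    divergent = catalog[catalog$role == "divergent",
                        c("chrom", "pos", "ref", "alt", "alt2"),
                        drop = FALSE],
    n_single = sum(roles == "single"),
    params = list(burden = burden, n_parallel = n_parallel,
                  n_divergent = n_divergent, seed = seed,
                  sample_id = sample_id))
  list(catalog = catalog, manifest = manifest)
}

#' Default segment layout over a genome
#'
#' Contiguous, non-overlapping segments covering each chromosome, with
#' (major, minor) copy states cycled from `states`.
#'
#' @param genome A `context_genome`.
#' @param n_segments Segments per chromosome.
#' @param states List of c(major, minor) states to cycle through.
#' @return Data frame `chrom`, `start`, `end`, `major`, `minor`.
#' @export
segment_layout <- function(genome, n_segments = 2L,
                           states = list(c(2L, 1L))) {
  pieces <- list()
  k <- 0L
  for (ch in names(genome$chrom_lengths)) {
    len <- genome$chrom_lengths[[ch]]
    bounds <- round(seq(0, len, length.out = n_segments + 1L))
    for (i in seq_len(n_segments)) {
      k <- k + 1L
      st <- states[[(k - 1L) %% length(states) + 1L]]
      pieces[[k]] <- data.frame(chrom = ch, start = bounds[i] + 1L,
                                end = bounds[i + 1L],
                                major = st[1L], minor = st[2L])
    }
  }
  do.call(rbind, pieces)
}

#' Simulate read-count observations for a synthetic sample
#'
#' Heterozygous SNPs are placed at the requested density with beta-binomial
#' major-allele counts at the segment's expected BAF; catalog SNVs receive
#' beta-binomial alt counts at the multiplicity-determined expected VAF
#' rho k / (2 (1 - rho) + rho (major + minor)). Planted parallel events get
#' multiplicity major + minor (clonal early event on all copies of both
#' alleles); planted divergent events get the major-allele copies for their
#' first alternate and the minor copies for the second; single SNVs default
#' to multiplicity 1 (`single_multiplicity`). Depths are Poisson around a
#' copy-number-scaled mean. Segment BAF/logR summaries are computed from
#' the generated SNPs, and resource tables (germline SNPs, empty common-SV
#' and indel sets) are emitted alongside.
#'
#' @param cat_out Result of [generate_catalog()].
#' @param genome A `context_genome`.
#' @param layout Segment table from [segment_layout()].
#' @param rho Tumour purity in (0, 1\].
#' @param mean_depth Genome-average sequencing depth (>= 10).
#' @param omega_true Concentration used to over-disperse counts.
#' @param het_snp_density Expected heterozygous SNPs per base
#'   (e.g. 1/1500).
#' @param seed RNG seed.
#' @param single_multiplicity Copies carrying a non-planted SNV (capped at
#'   the segment major copy number).
#' @param late_parallel If `TRUE`, parallel events get multiplicity 2
#'   (one copy of each allele) instead of all copies, to exercise the
#'   VAF caller's documented blind spot.
#' @return A sample bundle (see [call_sample()]) with an added `truth`
#'   element carrying the manifest and per-SNV multiplicities.
#' @export
simulate_observations <- function(cat_out, genome, layout, rho = 0.9,
                                  mean_depth = 80, omega_true = 300,
                                  het_snp_density = 1 / 1500, seed = 1L,
                                  single_multiplicity = 1L,
                                  late_parallel = FALSE) {
  stopifnot(rho > 0, rho <= 1, mean_depth >= 10)
  set.seed(seed)
  catalog <- cat_out$catalog
  seg <- layout
  seg_len <- seg$end - seg$start + 1L
  n_tot <- seg$major + seg$minor
  psi_t <- sum(n_tot * seg_len) / sum(seg_len)
  denom <- 2 * (1 - rho) + rho * n_tot
  lambda <- mean_depth * denom / (2 * (1 - rho) + rho * psi_t)
  baf_true <- ((1 - rho) + rho * seg$major) / denom

  # heterozygous SNPs, avoiding catalog positions
  snps <- list()
  for (s in seq_len(nrow(seg))) {
    n_snp <- stats::rpois(1L, het_snp_density * seg_len[s])
    if (n_snp == 0L) next
    pos <- sort(sample(seq.int(seg$start[s], seg$end[s]), n_snp))
    pos <- setdiff(pos, catalog$pos[catalog$chrom == seg$chrom[s]])
    if (!length(pos)) next
    depth <- pmax(stats::rpois(length(pos), lambda[s]), 1L)
    major <- rbetabinom(length(pos), depth, baf_true[s], omega_true)
    snps[[length(snps) + 1L]] <- data.frame(
      chrom = seg$chrom[s], pos = pos, major_count = major,
      minor_count = depth - major,
      logr = log2(pmax(depth, 0.5) / mean_depth), segment = s,
      stringsAsFactors = FALSE)
  }
  het_snps <- do.call(rbind, snps)
  seg$baf_seg <- vapply(seq_len(nrow(seg)), function(s) {
    hs <- het_snps[het_snps$segment == s, , drop = FALSE]
    if (nrow(hs) == 0L) return(max(0.5, baf_true[s]))
    b <- mean(hs$major_count / (hs$major_count + hs$minor_count))
    min(max(b, 0.5), 1)
  }, numeric(1L))
  seg$logr_seg <- vapply(seq_len(nrow(seg)), function(s) {
    hs <- het_snps[het_snps$segment == s, , drop = FALSE]
    if (nrow(hs) == 0L) return(log2(lambda[s] / mean_depth))
    mean(hs$logr)
  }, numeric(1L))

  # SNV observations
  sseg <- assign_segment_all(catalog, seg)
  if (any(is.na(sseg))) stop("catalog position outside the segment layout")
  mult <- ifelse(catalog$role == "parallel",
                 if (late_parallel) 2L else n_tot[sseg],
                 pmin(single_multiplicity, seg$major[sseg]))
  mult[catalog$role == "divergent"] <- seg$major[sseg][
    catalog$role == "divergent"]
  vaf <- rho * mult / denom[sseg]
  depth <- pmax(stats::rpois(nrow(catalog), lambda[sseg]), 1L)
  alt_count <- rbetabinom(nrow(catalog), depth, vaf, omega_true)
  snvs <- data.frame(chrom = catalog$chrom, pos = catalog$pos,
                     ref = catalog$ref, alt = catalog$alt,
                     alt_count = alt_count, depth = depth,
                     liftover_ok = TRUE, stringsAsFactors = FALSE)
  resources <- list(
    germline_snps = het_snps[, c("chrom", "pos")],
    het_snp_positions = het_snps[, c("chrom", "pos")],
    common_sv = NULL, indels = NULL, tcr_bcr = NULL, par_regions = NULL)
  list(rho = rho, psi_t = psi_t, sex = "female", segments = seg,
       het_snps = het_snps, snvs = snvs, resources = resources,
       truth = list(manifest = cat_out$manifest, multiplicity = mult,
                    role = catalog$role,
                    params = list(rho = rho, mean_depth = mean_depth,
                                  omega_true = omega_true, seed = seed)))
}

#' Simulate phased read-pair evidence for a sample
#'
#' For each catalog SNV with a heterozygous SNP within `max_dist`, read
#' pairs are drawn from the allele configuration implied by the truth:
#' parallel events emit both Ref-Alt and Alt-Alt pairs; single-allele
#' events emit Ref-Alt (or Alt-Ref) only, plus normal-cell background.
#' A symmetric per-read error rate flips the observed allele at each
#' phased position independently.
#'
#' @param bundle Result of [simulate_observations()].
#' @param pairs_per_site Phased pairs drawn per SNP-SNV pair.
#' @param error_rate Per-position allele mis-read probability.
#' @param seed RNG seed.
#' @param max_dist Maximal SNP-SNV distance (default 700).
#' @return Data frame of phased evidence (`snv_chrom`, `snv_pos`,
#'   `snp_chrom`, `snp_pos`, `n_rr`, `n_ra`, `n_ar`, `n_aa`, `snp_p`,
#'   `truth_role`). Sites without a SNP in range are omitted.
#' @export
simulate_phased_pairs <- function(bundle, pairs_per_site = 20L,
                                  error_rate = 0, seed = 1L,
                                  max_dist = 700L) {
  set.seed(seed)
  seg <- bundle$segments
  hs <- bundle$het_snps
  out <- list()
  for (i in seq_len(nrow(bundle$snvs))) {
    ch <- bundle$snvs$chrom[i]; p <- bundle$snvs$pos[i]
    cand <- hs[hs$chrom == ch & abs(hs$pos - p) <= max_dist, ,
               drop = FALSE]
    if (nrow(cand) == 0L) next
    snp <- cand[which.min(abs(cand$pos - p)), , drop = FALSE]
    s <- snp$segment
    rho <- bundle$rho
    mj <- seg$major[s]; mn <- seg$minor[s]
    role <- bundle$truth$role[i]
    mult <- bundle$truth$multiplicity[i]
    # copy masses per (SNP allele, SNV allele); SNP ref on the major
    # haplotype by convention
    if (role == "parallel") {
      mj_mut <- if (mult >= mj + mn) mj else 1L
      mn_mut <- if (mult >= mj + mn) mn else 1L
    } else {
      mj_mut <- min(mult, mj); mn_mut <- 0L
    }
    w_ra <- rho * mj_mut
    w_rr <- (1 - rho) + rho * (mj - mj_mut)
    w_aa <- rho * mn_mut
    w_ar <- (1 - rho) + rho * (mn - mn_mut)
    probs <- c(w_rr, w_ra, w_ar, w_aa)
    probs <- probs / sum(probs)
    cat4 <- stats::rmultinom(1L, pairs_per_site, probs)[, 1L]
    if (error_rate > 0) {
      # expand, flip each axis independently, re-tally
      snp_alt <- rep(c(FALSE, FALSE, TRUE, TRUE), cat4[c(1, 2, 3, 4)])
      snv_alt <- rep(c(FALSE, TRUE, FALSE, TRUE), cat4[c(1, 2, 3, 4)])
      flip1 <- stats::runif(length(snp_alt)) < error_rate
      flip2 <- stats::runif(length(snv_alt)) < error_rate
      snp_alt <- xor(snp_alt, flip1); snv_alt <- xor(snv_alt, flip2)
      cat4 <- c(sum(!snp_alt & !snv_alt), sum(!snp_alt & snv_alt),
                sum(snp_alt & !snv_alt), sum(snp_alt & snv_alt))
    }
    model <- betabinom_model(seg$baf_seg[s],
                             bundle$truth$params$omega_true)
    snp_p <- betabinom_two_sided(snp$major_count,
                                 snp$major_count + snp$minor_count,
                                 model)
    out[[length(out) + 1L]] <- data.frame(
      snv_chrom = ch, snv_pos = p, snp_chrom = ch, snp_pos = snp$pos,
      n_rr = cat4[1L], n_ra = cat4[2L], n_ar = cat4[3L], n_aa = cat4[4L],
      snp_p = snp_p, truth_role = role, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(snv_chrom = character(0), snv_pos = integer(0),
                      snp_chrom = character(0), snp_pos = integer(0),
                      n_rr = integer(0), n_ra = integer(0),
                      n_ar = integer(0), n_aa = integer(0),
                      snp_p = numeric(0), truth_role = character(0)))
  }
  do.call(rbind, out)
}
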