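# Simulators of infinite sites violations.
#
# Two complementary models estimate how often independent somatic mutations
# collide at the same genomic position in a tumour:
#  * uniform permutation: the observed burden is re-scattered uniformly over
#    the callable trinucleotide contexts of both parental alleles, keeping
#    the observed mutation spectrum (hierarchical burden -> chromosome ->
#    spectrum resampling);
#  * neighbour resampling: one allele keeps half of the observed (non-driver)
#    mutations, the other half is drawn from pooled mutations of
#    representative same-histology tumours, preserving positional hotspots.

#' Gamma-Poisson burden model
#'
#' The simulated total burden is drawn as n ~ Poisson(lambda) with
#' lambda ~ Gamma(shape beta, rate r) whose mode equals the observed burden
#' and whose standard deviation is `cv` times the observed burden. Solving
#' mode = (beta - 1)/r = n and sd^2 = beta/r^2 = (cv n)^2 exactly gives
#' r = (n + sqrt(n^2 + 4 sigma^2)) / (2 sigma^2) and beta = 1 + n r.
#'
#' @param n_t_obs Observed total mutation count.
#' @param cv Relative standard deviation of the Gamma component
#'   (default 0.05).
#' @return List of class `burden_model` with `n_t_obs`, `cv`, `rate`,
#'   `shape`.
#' @export
burden_model <- function(n_t_obs, cv = 0.05) {
  stopifnot(n_t_obs >= 0)
  if (cv <= 0) stop("cv must be positive")
  sigma <- cv * n_t_obs
  if (n_t_obs == 0) {
    r <- NA_real_; beta <- NA_real_
  } else {
    r <- (n_t_obs + sqrt(n_t_obs^2 + 4 * sigma^2)) / (2 * sigma^2)
    beta <- 1 + n_t_obs * r
  }
  structure(list(n_t_obs = n_t_obs, cv = cv, rate = r, shape = beta),
            class = "burden_model")
}

#' Draw a simulated total mutation burden
#'
#' @param model A [burden_model()].
#' @return Integer burden; 0 deterministically when the observed burden
#'   is 0.
#' @export
sample_total_burden <- function(model) {
  stopifnot(inherits(model, "burden_model"))
  if (model$n_t_obs == 0) return(0L)
  lambda <- stats::rgamma(1L, shape = model$shape, rate = model$rate)
  stats::rpois(1L, lambda)
}

#' Allocate a burden across chromosomes (Dirichlet-multinomial)
#'
#' @param n_t_sim Total simulated burden.
#' @param n_obs Named vector of observed per-chromosome counts; the
#'   Dirichlet parameter is `n_obs + 1`.
#' @return Named integer vector of per-chromosome counts summing to
#'   `n_t_sim`.
#' @export
allocate_to_chromosomes <- function(n_t_sim, n_obs) {
  if (length(n_obs) == 0L) stop("empty chromosome list")
  stopifnot(n_t_sim >= 0, all(n_obs >= 0))
  alpha <- n_obs + 1
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  counts <- as.integer(stats::rmultinom(1L, n_t_sim, prob = g / sum(g)))
  names(counts) <- names(n_obs)
  counts
}

PSEUDOCOUNT_SCALE <- 2 / 3

#' Draw a per-chromosome mutation spectrum
#'
#' pi_i ~ Dirichlet(mu_i) with mu_i = chromosome channel counts + psi, where
#' psi = (overall channel counts + 1) * 2/3 / n_t_obs is a weak pseudocount
#' anchored on the sample's overall spectrum.
#'
#' @param chrom_counts 96 observed channel counts on the chromosome.
#' @param overall_counts 96 observed channel counts in the whole sample.
#' @param n_t_obs Observed total burden (> 0).
#' @return Numeric vector of 96 channel probabilities summing to 1.
#' @export
sample_chromosome_spectrum <- function(chrom_counts, overall_counts,
                                       n_t_obs) {
  stopifnot(length(chrom_counts) == 96L, length(overall_counts) == 96L,
            n_t_obs > 0)
  if (any(chrom_counts < 0) || any(overall_counts < 0)) {
    stop("negative channel counts")
  }
  psi <- (overall_counts + 1) * PSEUDOCOUNT_SCALE / n_t_obs
  mu <- chrom_counts + psi
  g <- stats::rgamma(96L, shape = mu, rate = 1)
  g / sum(g)
}

# deterministic child seed for replicate r of a run (kept below 2^31)
child_seed <- function(seed, r) {
  as.integer((as.numeric(seed) %% 2147483647) * 48271 %% 2147483647 +
               r * 7919) %% 2147483646L + 1L
}

# empty tally accumulator
empty_tally <- function() {
  list(parallel = 0L, divergent = 0L, back = 0L, forward = 0L,
       n_colliding = 0L,
       spec_parallel = numeric(96L), spec_divergent = numeric(96L))
}

# Sequentially scatter n_i mutations over both alleles of one chromosome's
# callable contexts, overlay-aware. Proposals are uniform over allelic
# positions; a proposal at current context class c is accepted with
# probability proportional to (sum of pi over the class's channels) / f_c,
# i.e. per-position mutation-type mass relative to reference context
# abundance. Clean proposals (away from any prior hit) are processed in
# vectorised bulk; proposals at or next to previously mutated positions go
# through an exact sequential path that evaluates the current (possibly
# mutated) trinucleotide. Within one batch, position duplicates are handled
# exactly in proposal order; a proposal merely flanking a hit accepted
# earlier in the same batch sees the batch-start overlay (the distortion is
# O(hit density) and vanishes at genomic scales).
simulate_chromosome_hits <- function(ctx, seq_chars, pi, n_i, tally,
                                     hit_spectrum, max_attempts = NULL) {
  ncall <- length(ctx$positions)
  if (is.null(max_attempts)) max_attempts <- 1e6 * max(n_i, 1L)
  f <- ctx$f
  class_channels <- CLASS_CHANNELS
  pi_class <- .rowSums(pi[as.vector(class_channels)], 32L, 3L)
  w <- ifelse(f > 0, pi_class / f, 0)
  wmax <- max(w)
  if (wmax == 0) stop("no callable context carries spectrum mass")
  A <- w / wmax
  # conditional channel probabilities within each class
  cond <- matrix(pi[as.vector(t(class_channels))], nrow = 32L,
                 byrow = TRUE)
  cond <- cond / pmax(rowSums(cond), .Machine$double.eps)
  cum2 <- cond[, 1]; cum3 <- cond[, 1] + cond[, 2]
  # mean acceptance probability over positions
  pbar <- sum((f / ncall) * A)

  chrom_len <- length(seq_chars)
  # per-allele overlay of current bases (NA = reference) and per-locus
  # hit counts; single-binding local vectors are modified in place
  mb1 <- rep(NA_character_, chrom_len)
  mb2 <- rep(NA_character_, chrom_len)
  nhit <- integer(chrom_len)
  hp <- integer(0)       # accepted positions, for batch marking/tallies
  hall <- integer(0)
  acc <- 0L
  attempts <- 0

  overlay_base <- function(p, a) {
    b <- if (a == 1L) mb1[p] else mb2[p]
    if (is.na(b)) seq_chars[p] else b
  }

  record_hit <- function(p, a, base, channel) {
    cura <- overlay_base(p, 1L); curb <- overlay_base(p, 2L)
    # a locus whose prior hits were all reverted by back mutation is in
    # the reference state again: a new hit there is a fresh first hit
    # under the current-allelic-state semantics, not a violation event
    if (nhit[p] > 0L && (cura != seq_chars[p] || curb != seq_chars[p])) {
      cls <- classify_violation(list(ref = seq_chars[p],
                                     alleles = c(cura, curb)),
                                a, base)
      tally[[cls]] <<- tally[[cls]] + 1L
      if (cls == "parallel") {
        tally$spec_parallel[channel] <<- tally$spec_parallel[channel] + 1
      } else if (cls == "divergent") {
        tally$spec_divergent[channel] <<- tally$spec_divergent[channel] + 1
      }
    }
    if (a == 1L) mb1[p] <<- base else mb2[p] <<- base
    nhit[p] <<- nhit[p] + 1L
    hp <<- c(hp, p); hall <<- c(hall, a)
    hit_spectrum[channel] <<- hit_spectrum[channel] + 1
    acc <<- acc + 1L
  }

  while (acc < n_i) {
    need <- n_i - acc
    K <- min(max(128L, ceiling(need / max(pbar, 1e-9) * 1.3)), 2000000L)
    attempts <- attempts + K
    if (attempts > max_attempts) {
      stop("rejection sampling exhausted its attempt budget on a ",
           "chromosome; spectrum mass may sit on absent contexts")
    }
    ii <- sample.int(ncall, K, replace = TRUE)
    al <- sample.int(2L, K, replace = TRUE)
    pos <- ctx$positions[ii]
    cls <- ctx$class[ii]

    # proposals needing the sequential path: at or next to a mutated
    # position from earlier batches, or at a position proposed more than
    # once within this batch
    if (length(hp)) {
      special <- nhit[pos] > 0L
      near1 <- !is.na(mb1[pmax(pos - 1L, 1L)]) |
        !is.na(mb1[pmin(pos + 1L, chrom_len)])
      near2 <- !is.na(mb2[pmax(pos - 1L, 1L)]) |
        !is.na(mb2[pmin(pos + 1L, chrom_len)])
      special <- special | ifelse(al == 1L, near1, near2)
    } else {
      special <- logical(K)
    }
    special <- special | (pos %in% pos[duplicated(pos)])

    # clean acceptance draws (vectorised); specials drawn in the slow path
    accept_clean <- !special & (stats::runif(K) < A[cls])

    take_clean <- function(idx) {
      # bulk-record non-interacting accepted proposals
      kcls <- cls[idx]
      u2 <- stats::runif(length(idx))
      jsel <- 1L + (u2 > cum2[kcls]) + (u2 > cum3[kcls])
      chan <- class_channels[cbind(kcls, jsel)]
      alt_pyr2 <- ALT_PYR[chan]
      pyr2 <- ctx$pyrimidine[ii[idx]]
      base <- ifelse(pyr2, alt_pyr2, unname(COMPLEMENT[alt_pyr2]))
      p2 <- pos[idx]; a2 <- al[idx]
      one <- a2 == 1L
      if (any(one)) mb1[p2[one]] <<- base[one]
      if (any(!one)) mb2[p2[!one]] <<- base[!one]
      nhit[p2] <<- nhit[p2] + 1L
      hp <<- c(hp, p2); hall <<- c(hall, a2)
      hit_spectrum <<- hit_spectrum + tabulate(chan, nbins = 96L)
      acc <<- acc + length(idx)
    }

    take_special <- function(k) {
      p <- pos[k]; a <- al[k]
      # current trinucleotide on this allele, overlay-aware
      b5 <- overlay_base(p - 1L, a)
      bc <- overlay_base(p, a)
      b3 <- overlay_base(p + 1L, a)
      if (bc %in% PYRIMIDINES) {
        c2 <- context_class_index(b5, bc, b3)
        pyr_here <- TRUE
      } else {
        c2 <- context_class_index(unname(COMPLEMENT[b3]),
                                  unname(COMPLEMENT[bc]),
                                  unname(COMPLEMENT[b5]))
        pyr_here <- FALSE
      }
      if (is.na(c2)) return(invisible())       # N in context
      if (stats::runif(1L) >= A[c2]) return(invisible())
      u2 <- stats::runif(1L)
      jsel <- 1L + (u2 > cum2[c2]) + (u2 > cum3[c2])
      chan <- class_channels[c2, jsel]
      alt_pyr2 <- ALT_PYR[chan]
      base <- if (pyr_here) alt_pyr2 else unname(COMPLEMENT[alt_pyr2])
      record_hit(p, a, base, chan)
      invisible()
    }

    # consume the batch in proposal order: cleans in the gaps between
    # specials are bulk-processed (they cannot collide with anything),
    # specials go one at a time against the current overlay
    sp_idx <- which(special)
    if (length(sp_idx) == 0L) {
      keep <- which(accept_clean)
      if (length(keep) > need) keep <- keep[seq_len(need)]
      if (length(keep)) take_clean(keep)
    } else {
      bounds <- c(sp_idx, K + 1L)
      ptr <- 1L
      for (s in bounds) {
        if (acc >= n_i) break
        if (s > ptr) {
          gap <- ptr:(s - 1L)
          gap <- gap[accept_clean[gap]]
          rem <- n_i - acc
          if (length(gap) > rem) gap <- gap[seq_len(rem)]
          if (length(gap)) take_clean(gap)
          if (acc >= n_i) break
        }
        if (s <= K) take_special(s)
        ptr <- s + 1L
      }
    }
  }

  if (length(hp)) {
    cnt <- nhit[unique(hp)]
    tally$n_colliding <- tally$n_colliding +
      as.integer(sum(cnt[cnt >= 2L]))
  }
  list(tally = tally, hit_spectrum = hit_spectrum)
}

#' Run the uniform permutation simulator
#'
#' Per replicate: draw a total burden from the gamma-Poisson model,
#' allocate it over chromosomes (Dirichlet-multinomial anchored on the
#' observed per-chromosome counts), draw a per-chromosome spectrum
#' (Dirichlet with overall-spectrum pseudocounts), and scatter the
#' mutations one at a time uniformly over both parental copies of the
#' callable contexts, accepting against the current (overlay-aware)
#' trinucleotide. Repeat hits at a locus are classified as parallel,
#' divergent, back or forward mutations.
#'
#' @param catalog `mutation_records` of observed SNVs.
#' @param genome A `context_genome` with callable contexts for every
#'   chromosome carrying catalog mass.
#' @param replicates Number of simulation replicates (study default 1000).
#' @param seed Run seed; each replicate derives a deterministic child seed.
#' @param cv Relative burden standard deviation (default 0.05).
#' @return Object of class `violation_tallies`: list with `tallies`
#'   (one row per replicate: n_t_sim, parallel, divergent, back, forward,
#'   n_colliding), matrices `spec_parallel`/`spec_divergent`
#'   (replicates x 96) and `hit_spectrum` (pooled 96-channel spectrum of
#'   all simulated mutations).
#' @export
run_uniform_permutation <- function(catalog, genome, replicates = 1000L,
                                    seed = 1L, cv = 0.05) {
  stopifnot(inherits(genome, "context_genome"), nrow(catalog) > 0L)
  snvs <- catalog[catalog$vtype == "SNV", , drop = FALSE]
  if (nrow(snvs) == 0L) stop("catalog holds no SNVs")
  chroms <- names(genome$contexts)
  if (!all(unique(snvs$chrom) %in% chroms)) {
    stop("catalog chromosome without callable contexts: ",
         paste(setdiff(unique(snvs$chrom), chroms), collapse = ", "))
  }
  n_t_obs <- nrow(snvs)
  n_obs <- vapply(chroms, function(ch) sum(snvs$chrom == ch), 0L)
  chan <- vapply(seq_len(n_t_obs), function(i) {
    extract_channel(genome, snvs$chrom[i], snvs$pos[i],
                    snvs$ref[i], snvs$alt[i])
  }, integer(1L))
  overall_counts <- tabulate(chan, nbins = 96L)
  chrom_counts <- lapply(chroms, function(ch) {
    tabulate(chan[snvs$chrom == ch], nbins = 96L)
  })
  names(chrom_counts) <- chroms
  seq_chars <- lapply(chroms, function(ch) {
    strsplit(as.character(genome$sequences[[ch]]), "", fixed = TRUE)[[1]]
  })
  names(seq_chars) <- chroms

  model <- burden_model(n_t_obs, cv)
  spec_par <- matrix(0, replicates, 96L)
  spec_div <- matrix(0, replicates, 96L)
  hit_spectrum <- numeric(96L)
  v_n <- integer(replicates); v_par <- integer(replicates)
  v_div <- integer(replicates); v_back <- integer(replicates)
  v_fwd <- integer(replicates); v_col <- integer(replicates)
  for (r in seq_len(replicates)) {
    set.seed(child_seed(seed, r))
    n_t_sim <- sample_total_burden(model)
    alloc <- allocate_to_chromosomes(n_t_sim, n_obs)
    tally <- empty_tally()
    for (ch in chroms) {
      n_i <- alloc[[ch]]
      if (n_i == 0L) next
      pi <- sample_chromosome_spectrum(chrom_counts[[ch]], overall_counts,
                                       n_t_obs)
      out <- simulate_chromosome_hits(genome$contexts[[ch]],
                                      seq_chars[[ch]], pi, n_i, tally,
                                      hit_spectrum)
      tally <- out$tally
      hit_spectrum <- out$hit_spectrum
    }
    v_n[r] <- n_t_sim
    v_par[r] <- tally$parallel; v_div[r] <- tally$divergent
    v_back[r] <- tally$back; v_fwd[r] <- tally$forward
    v_col[r] <- tally$n_colliding
    spec_par[r, ] <- tally$spec_parallel
    spec_div[r, ] <- tally$spec_divergent
  }
  res <- data.frame(replicate = seq_len(replicates), n_t_sim = v_n,
                    parallel = v_par, divergent = v_div, back = v_back,
                    forward = v_fwd, n_colliding = v_col)
  structure(list(tallies = res, spec_parallel = spec_par,
                 spec_divergent = spec_div, hit_spectrum = hit_spectrum,
                 model = "uniform_permutation"),
            class = "violation_tallies")
}

#' Select the representative mutation pool for neighbour resampling
#'
#' Donors qualify when they share the target's histology and their mutation
#' spectrum has cosine similarity of at least `min_cosine` with the
#' target's. The pool unions their non-driver records (the target never
#' contributes to its own pool). A target is eligible for neighbour
#' resampling when the pool holds at least `pool_factor` times its total
#' burden.
#'
#' @param target_catalog `mutation_records` of the target tumour.
#' @param target_histology Histology label of the target.
#' @param cohort List of donors, each a list with elements `catalog`,
#'   `histology` and `sample_id`.
#' @param genome `context_genome` used to compute spectra (SNV records).
#' @param min_cosine Spectrum similarity threshold (default 0.9).
#' @param pool_factor Eligibility factor on the target burden (default 0.5).
#' @return List of class `cohort_pool` with `records`, `eligible`,
#'   `n_pool`, `target_burden` and the donor ids used.
#' @export
select_representative_pool <- function(target_catalog, target_histology,
                                       cohort, genome, min_cosine = 0.9,
                                       pool_factor = 0.5) {
  tspec <- compute_spectrum(
    target_catalog[target_catalog$vtype == "SNV", , drop = FALSE], genome)
  used <- character(0)
  recs <- list()
  for (donor in cohort) {
    if (!identical(donor$histology, target_histology)) next
    dspec <- compute_spectrum(
      donor$catalog[donor$catalog$vtype == "SNV", , drop = FALSE], genome)
    if (sum(as.numeric(dspec)) == 0) next
    if (cosine_similarity(tspec, dspec) < min_cosine) next
    keep <- donor$catalog[!donor$catalog$is_driver, , drop = FALSE]
    if (nrow(keep)) {
      keep$donor <- donor$sample_id
      recs[[length(recs) + 1L]] <- keep
    }
    used <- c(used, donor$sample_id)
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    cbind(target_catalog[0, , drop = FALSE], donor = character(0))
  target_burden <- nrow(target_catalog)
  structure(list(records = records,
                 eligible = nrow(records) >= pool_factor * target_burden,
                 n_pool = nrow(records), target_burden = target_burden,
                 donors = used), class = "cohort_pool")
}

#' Run the neighbour resampling simulator
#'
#' Per replicate one "allele" keeps a random half of the target's
#' non-driver records and the other half is drawn without replacement from
#' the representative pool. Any same-position pair across the two alleles
#' is a violation: same alternate allele, parallel; different, divergent
#' (for indels, identical inserted/deleted sequence means parallel). Back
#' and forward mutations cannot arise under this model. Duplicate positions
#' drawn within one allele are discarded and redrawn, since only
#' cross-allele events are defined.
#'
#' @param target_catalog `mutation_records` of the target tumour.
#' @param pool A `cohort_pool` from [select_representative_pool()];
#'   must be eligible.
#' @param replicates Number of replicates.
#' @param seed Run seed.
#' @param vtype `"SNV"` or `"indel"`: which record type to resample.
#' @param genome Optional `context_genome` used to attach channel spectra
#'   to SNV violations.
#' @return A `violation_tallies` object (back/forward always zero).
#' @export
run_neighbour_resampling <- function(target_catalog, pool,
                                     replicates = 1000L, seed = 1L,
                                     vtype = "SNV", genome = NULL) {
  stopifnot(inherits(pool, "cohort_pool"))
  if (!pool$eligible) {
    stop("target is ineligible: representative pool smaller than the ",
         "eligibility factor times the target burden")
  }
  tgt <- target_catalog[target_catalog$vtype == vtype &
                          !target_catalog$is_driver, , drop = FALSE]
  pl <- pool$records[pool$records$vtype == vtype, , drop = FALSE]
  if (nrow(tgt) == 0L) stop("target catalog holds no records of this type")
  n <- nrow(tgt)
  n_a <- ceiling(n / 2); n_b <- floor(n / 2)
  if (nrow(pl) < n_b) {
    stop("pool smaller than the number of records to resample")
  }
  key <- function(df) paste(df$chrom, df$pos, sep = ":")
  same_mut <- function(a, b) a$ref == b$ref & a$alt == b$alt
  res <- data.frame(replicate = seq_len(replicates), n_t_sim = n,
                    parallel = 0L, divergent = 0L, back = 0L,
                    forward = 0L, n_colliding = 0L)
  spec_par <- matrix(0, replicates, 96L)
  spec_div <- matrix(0, replicates, 96L)
  for (r in seq_len(replicates)) {
    set.seed(child_seed(seed, r))
    a_idx <- sample.int(n, n_a)
    A <- tgt[a_idx, , drop = FALSE]
    b_idx <- sample.int(nrow(pl), n_b)
    B <- pl[b_idx, , drop = FALSE]
    # same-allele duplicate positions: discard and redraw
    guard <- 0L
    repeat {
      dup <- duplicated(key(B))
      if (!any(dup)) break
      guard <- guard + 1L
      if (guard > 1000L) stop("could not draw a duplicate-free allele set")
      remaining <- setdiff(seq_len(nrow(pl)), b_idx)
      if (length(remaining) < sum(dup)) break
      extra <- sample(remaining, sum(dup))
      b_idx <- c(b_idx[!seq_len(nrow(B)) %in% which(dup)], extra)
      B <- pl[b_idx, , drop = FALSE]
    }
    hits <- match(key(B), key(A))
    paired <- which(!is.na(hits))
    if (length(paired)) {
      a_rec <- A[hits[paired], , drop = FALSE]
      b_rec <- B[paired, , drop = FALSE]
      par <- same_mut(a_rec, b_rec)
      res$parallel[r] <- sum(par)
      res$divergent[r] <- sum(!par)
      res$n_colliding[r] <- 2L * length(paired)
      if (!is.null(genome) && vtype == "SNV") {
        for (i in seq_len(nrow(b_rec))) {
          chv <- extract_channel(genome, b_rec$chrom[i], b_rec$pos[i],
                                 b_rec$ref[i], b_rec$alt[i])
          if (par[i]) spec_par[r, chv] <- spec_par[r, chv] + 1
          else spec_div[r, chv] <- spec_div[r, chv] + 1
        }
      }
    }
  }
  structure(list(tallies = res, spec_parallel = spec_par,
                 spec_divergent = spec_div, hit_spectrum = NULL,
                 model = "neighbour_resampling"),
            class = "violation_tallies")
}

#' Summarise violation tallies across replicates
#'
#' @param tallies A `violation_tallies` object.
#' @return List with per-class mean, Monte-Carlo standard error and
#'   2.5/97.5 percentiles, pooled parallel/divergent spectra, and the
#'   fraction of replicates with at least one (biallelic or any)
#'   violation.
#' @export
summarize_tallies <- function(tallies) {
  stopifnot(inherits(tallies, "violation_tallies"))
  df <- tallies$tallies
  if (nrow(df) == 0L) stop("no replicates to summarise")
  classes <- c("parallel", "divergent", "back", "forward", "n_colliding")
  summ <- lapply(classes, function(cl) {
    x <- df[[cl]]
    c(mean = mean(x), se = stats::sd(x) / sqrt(length(x)),
      q025 = unname(stats::quantile(x, 0.025, type = 1)),
      q975 = unname(stats::quantile(x, 0.975, type = 1)))
  })
  names(summ) <- classes
  biallelic <- df$parallel + df$divergent
  total <- biallelic + df$back + df$forward
  list(per_class = summ,
       mean_biallelic = mean(biallelic),
       se_biallelic = stats::sd(biallelic) / sqrt(nrow(df)),
       frac_replicates_with_violation = mean(total >= 1),
       frac_replicates_with_biallelic = mean(biallelic >= 1),
       pooled_spec_parallel = colSums(tallies$spec_parallel),
       pooled_spec_divergent = colSums(tallies$spec_divergent),
       replicates = nrow(df))
}
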