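BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")
PYRIMIDINES <- c("C", "T")

# Alternate bases per pyrimidine, in channel order: C>A, C>G, C>T then
# T>A, T>C, T>G. The 96 channels are substitution-major, then 5' flank
# (A,C,G,T), then 3' flank (A,C,G,T): frozen serialisation order.
SUB_ALTS <- list(C = c("A", "G", "T"), T = c("A", "C", "G"))

#' The 96 trinucleotide substitution channels
#'
#' Channels are keyed on the pyrimidine-normalised strand and ordered
#' substitution-major (C>A, C>G, C>T, T>A, T>C, T>G), then by 5' flank
#' (A, C, G, T), then 3' flank (A, C, G, T). This order is frozen and used
#' for all spectrum serialisation.
#'
#' @return Character vector of 96 labels such as `"A[C>T]G"`.
#' @export
channel_labels <- function() {
  labs <- character(96L)
  k <- 0L
  for (ref in PYRIMIDINES) {
    for (alt in SUB_ALTS[[ref]]) {
      for (five in BASES) {
        for (three in BASES) {
          k <- k + 1L
          labs[k] <- paste0(five, "[", ref, ">", alt, "]", three)
        }
      }
    }
  }
  labs
}

# 32 pyrimidine-centred context classes: (centre C then T) x 5' x 3',
# same flank order as the channels. Class index 1..32.
context_class_labels <- function() {
  labs <- character(32L)
  k <- 0L
  for (ref in PYRIMIDINES) {
    for (five in BASES) {
      for (three in BASES) {
        k <- k + 1L
        labs[k] <- paste0(five, ref, three)
      }
    }
  }
  labs
}

#' Map a substitution in context to its channel index
#'
#' @param five,three Flanking bases on the pyrimidine-normalised strand.
#' @param ref Central pyrimidine (`"C"` or `"T"`).
#' @param alt Alternate base, distinct from `ref`.
#' @return Integer channel index in 1..96.
#' @keywords internal
channel_index <- function(five, ref, alt, three) {
  sub_idx <- integer(length(ref))
  for (i in seq_along(ref)) {
    a <- match(alt[i], SUB_ALTS[[ref[i]]])
    if (is.na(a)) stop("invalid substitution ", ref[i], ">", alt[i])
    sub_idx[i] <- (match(ref[i], PYRIMIDINES) - 1L) * 3L + a
  }
  (sub_idx - 1L) * 16L +
    (match(five, BASES) - 1L) * 4L +
    match(three, BASES)
}

# context class index (1..32) for a pyrimidine-strand trinucleotide
context_class_index <- function(five, ref, three) {
  (match(ref, PYRIMIDINES) - 1L) * 16L +
    (match(five, BASES) - 1L) * 4L +
    match(three, BASES)
}

# channels belonging to context class c: centre pyrimidine has 3 alts
channels_of_class <- function(class_idx) {
  pyr <- (class_idx - 1L) %/% 16L          # 0 = C, 1 = T
  flank <- (class_idx - 1L) %% 16L
  (pyr * 3L + 0:2) * 16L + flank + 1L
}

# class of each channel (length-96 integer vector)
class_of_channel <- function() {
  sub <- (seq_len(96L) - 1L) %/% 16L       # 0..5
  flank <- (seq_len(96L) - 1L) %% 16L
  pyr <- sub %/% 3L
  pyr * 16L + flank + 1L
}

# frozen lookup tables used by the samplers
CLASS_CHANNELS <- t(vapply(1:32, channels_of_class, integer(3L)))
ALT_PYR <- vapply(seq_len(96L), function(ch) {
  sub <- (ch - 1L) %/% 16L
  SUB_ALTS[[PYRIMIDINES[sub %/% 3L + 1L]]][sub %% 3L + 1L]
}, character(1L))

#' Normalise a strand-specific trinucleotide substitution to channel space
#'
#' Purine-centred substitutions are reverse-complemented so that every
#' substitution is expressed with a central pyrimidine.
#'
#' @param triplet Character vector of reference trinucleotides.
#' @param alt Alternate central base on the same strand as `triplet`.
#' @return Integer channel indices (1..96).
#' @export
normalize_substitution <- function(triplet, alt) {
  stopifnot(all(nchar(triplet) == 3L))
  five <- substr(triplet, 1L, 1L)
  ref <- substr(triplet, 2L, 2L)
  three <- substr(triplet, 3L, 3L)
  if (any(!ref %in% BASES) || any(!alt %in% BASES) ||
      any(!five %in% BASES) || any(!three %in% BASES)) {
    stop("uncallable context: non-ACGT base in trinucleotide or alt")
  }
  if (any(ref == alt)) stop("ref and alt must differ")
  flip <- ref %in% c("A", "G")
  f2 <- ifelse(flip, COMPLEMENT[three], five)
  r2 <- ifelse(flip, COMPLEMENT[ref], ref)
  a2 <- ifelse(flip, COMPLEMENT[alt], alt)
  t2 <- ifelse(flip, COMPLEMENT[five], three)
  channel_index(unname(f2), unname(r2), unname(a2), unname(t2))
}

#' Construct a trinucleotide spectrum
#'
#' @param counts Numeric vector of length 96 (channel order of
#'   [channel_labels()]); non-negative.
#' @param normalised Logical; if `TRUE`, `counts` are rescaled to sum to 1.
#' @return An object of class `trinuc_spectrum`: a named numeric vector of
#'   length 96 with attribute `normalised`.
#' @export
trinuc_spectrum <- function(counts, normalised = FALSE) {
  stopifnot(length(counts) == 96L, all(counts >= 0))
  x <- as.numeric(counts)
  if (normalised) {
    tot <- sum(x)
    if (tot <= 0) stop("cannot normalise a spectrum with zero total mass")
    x <- x / tot
  }
  names(x) <- channel_labels()
  structure(x, normalised = normalised, class = "trinuc_spectrum")
}

#' Cosine similarity between two spectra
#'
#' Scale-invariant: `cos(a, b) = <a,b> / (|a||b|)`, in \[0, 1\] for
#' non-negative spectra.
#'
#' @param a,b Numeric vectors (e.g. `trinuc_spectrum` objects) of equal
#'   length; both must be non-zero.
#' @return Cosine similarity in \[0, 1\].
#' @export
cosine_similarity <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for zero vector")
  min(1, sum(a * b) / (na * nb))
}

#' Expected spectrum of parallel mutations under independent hits
#'
#' If single mutations fall in channel j with probability p_j and the
#' callable genome holds f_j sites of that channel's context class, two
#' independent hits collide within the class at a rate proportional to
#' p_j^2 / f_j. Parallel mutations are therefore expected to carry (after
#' normalisation) the square of the single-mutation spectrum corrected for
#' context abundance. Used as an analytic cross-check of simulator output.
#'
#' @param spectrum Normalised `trinuc_spectrum` of single mutations.
#' @param genome A `context_genome` (for channel context abundances), or a
#'   numeric vector of 96 per-channel abundances.
#' @param abundance_correct If `FALSE`, returns the normalised raw square
#'   p_j^2 (no 1/f_j correction).
#' @return Normalised `trinuc_spectrum` of predicted parallel mutations.
#' @export
predicted_parallel_spectrum <- function(spectrum, genome,
                                        abundance_correct = TRUE) {
  p <- as.numeric(spectrum)
  stopifnot(length(p) == 96L)
  if (abundance_correct) {
    f <- if (inherits(genome, "context_genome")) {
      genome$channel_abundance
    } else {
      as.numeric(genome)
    }
    stopifnot(length(f) == 96L)
    if (any(p > 0 & f == 0)) {
      stop("spectrum has mass on a channel with zero context abundance")
    }
    q <- ifelse(f > 0, p^2 / f, 0)
  } else {
    q <- p^2
  }
  trinuc_spectrum(q, normalised = TRUE)
}

#' Classify a repeat hit at a mutated locus
#'
#' Given the current allelic state of a diploid locus with at least one
#' prior somatic hit, classify a new hit into one of the four violation
#' classes: a hit on the other (so far unmutated) allele producing the same
#' base is *parallel*; a different base, *divergent*; a hit on an already
#' mutated allele restoring the reference is *back*; producing yet another
#' base, *forward*. Classification is against the current allelic state, so
#' loci with more than two hits are handled sequentially.
#'
#' @param site List with elements `ref` (reference base) and `alleles`,
#'   a length-2 character vector of current bases on alleles A and B.
#' @param allele Integer 1 or 2: allele receiving the new hit.
#' @param new_base Resulting base of the new hit.
#' @return One of `"parallel"`, `"divergent"`, `"back"`, `"forward"`.
#' @export
classify_violation <- function(site, allele, new_base) {
  cur <- site$alleles
  if (all(cur == site$ref)) stop("locus has no prior hit")
  if (new_base == cur[allele]) {
    stop("no-op mutation: new base equals current base on that allele")
  }
  other <- cur[3L - allele]
  if (cur[allele] != site$ref) {
    # second hit on an already-mutated allele
    if (new_base == site$ref) "back" else "forward"
  } else {
    # hit on the so-far unmutated allele
    if (new_base == other) "parallel" else "divergent"
  }
}
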