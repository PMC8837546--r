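#' Build a context genome from sequences and callable intervals
#'
#' A `context_genome` bundles the reference sequences, the callable
#' intervals and, per chromosome, the callable interior positions together
#' with their pyrimidine-normalised trinucleotide context class. It carries
#' everything the simulators and spectrum operations need: the per-class
#' context abundances f (how many callable sites of each of the 32
#' pyrimidine-centred trinucleotides exist) and, derived from those, the
#' per-channel abundances.
#'
#' Positions whose trinucleotide contains an N (or that sit on the first or
#' last base of a chromosome) are excluded from the callable abundance and
#' from sampling.
#'
#' @param sequences Named `Biostrings::DNAStringSet` (or named character
#'   vector) of chromosome sequences.
#' @param callable Data frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive). Defaults to whole chromosomes.
#' @return An object of class `context_genome`.
#' @export
context_genome <- function(sequences, callable = NULL) {
  if (is.character(sequences)) {
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  chroms <- names(sequences)
  if (is.null(chroms) || any(chroms == "")) stop("sequences must be named")
  lens <- Biostrings::width(sequences)
  names(lens) <- chroms
  if (is.null(callable)) {
    callable <- data.frame(chrom = chroms, start = 1L, end = unname(lens),
                           stringsAsFactors = FALSE)
  }
  stopifnot(all(c("chrom", "start", "end") %in% names(callable)))
  if (!all(callable$chrom %in% chroms)) {
    stop("callable intervals on unknown chromosome: ",
         paste(setdiff(callable$chrom, chroms), collapse = ", "))
  }
  per_chrom <- list()
  for (ch in chroms) {
    iv <- callable[callable$chrom == ch, , drop = FALSE]
    if (nrow(iv) == 0L) next
    ir <- IRanges::reduce(IRanges::IRanges(iv$start, iv$end))
    # interior positions only: need both flanks on-chromosome
    ir <- IRanges::restrict(ir, start = 2L, end = lens[[ch]] - 1L)
    pos <- as.integer(unlist(lapply(seq_along(ir), function(i) {
      seq.int(IRanges::start(ir)[i], IRanges::end(ir)[i])
    })))
    if (length(pos) == 0L) next
    s <- strsplit(as.character(sequences[[ch]]), "", fixed = TRUE)[[1]]
    five <- s[pos - 1L]; cen <- s[pos]; three <- s[pos + 1L]
    ok <- five %in% BASES & cen %in% BASES & three %in% BASES
    pos <- pos[ok]; five <- five[ok]; cen <- cen[ok]; three <- three[ok]
    pyr <- cen %in% PYRIMIDINES
    cls <- integer(length(pos))
    if (any(pyr)) {
      cls[pyr] <- context_class_index(five[pyr], cen[pyr], three[pyr])
    }
    if (any(!pyr)) {
      cls[!pyr] <- context_class_index(unname(COMPLEMENT[three[!pyr]]),
                                       unname(COMPLEMENT[cen[!pyr]]),
                                       unname(COMPLEMENT[five[!pyr]]))
    }
    per_chrom[[ch]] <- list(positions = pos, class = cls, pyrimidine = pyr,
                            f = tabulate(cls, nbins = 32L))
  }
  f_total <- Reduce(`+`, lapply(per_chrom, `[[`, "f"), integer(32L))
  g <- list(sequences = sequences, callable = callable,
            chrom_lengths = lens, contexts = per_chrom,
            class_abundance = f_total,
            channel_abundance = f_total[class_of_channel()])
  class(g) <- "context_genome"
  g
}

#' @export
print.context_genome <- function(x, ...) {
  cat("context_genome:", length(x$sequences), "chromosome(s),",
      sum(vapply(x$contexts, function(p) length(p$positions), 0L)),
      "callable context positions\n")
  invisible(x)
}

# base at (chrom, pos) from the reference
genome_base <- function(genome, chrom, pos) {
  as.character(Biostrings::subseq(genome$sequences[[chrom]], pos, pos))
}

#' Trinucleotide channel of a single substitution
#'
#' Looks up the reference trinucleotide around `pos`, checks that the
#' reference base matches, and returns the pyrimidine-normalised channel.
#'
#' @param genome A `context_genome`.
#' @param chrom Chromosome name.
#' @param pos 1-based position (must have both flanks on-chromosome).
#' @param ref,alt Reference and alternate single bases.
#' @return Integer channel index in 1..96.
#' @export
extract_channel <- function(genome, chrom, pos, ref, alt) {
  len <- genome$chrom_lengths[[chrom]]
  if (is.null(len)) stop("unknown chromosome: ", chrom)
  if (pos < 2L || pos > len - 1L) {
    stop("position ", pos, " on ", chrom, " lacks a flanking base")
  }
  tri <- as.character(Biostrings::subseq(genome$sequences[[chrom]],
                                         pos - 1L, pos + 1L))
  obs_ref <- substr(tri, 2L, 2L)
  if (obs_ref != ref) {
    stop("reference mismatch at ", chrom, ":", pos,
         " (genome has ", obs_ref, ", record says ", ref, ")")
  }
  normalize_substitution(tri, alt)
}

#' Compute the 96-channel mutation spectrum of a catalog
#'
#' @param mutations Data frame of SNV records with columns `chrom`, `pos`,
#'   `ref`, `alt` (see [mutation_records()]).
#' @param genome A `context_genome` resolving every record's context.
#' @param normalise Return channel probabilities instead of counts.
#' @return A `trinuc_spectrum`.
#' @export
compute_spectrum <- function(mutations, genome, normalise = FALSE) {
  if (nrow(mutations) == 0L) {
    if (normalise) stop("cannot normalise the spectrum of an empty catalog")
    return(trinuc_spectrum(numeric(96L)))
  }
  ch <- vapply(seq_len(nrow(mutations)), function(i) {
    extract_channel(genome, mutations$chrom[i], mutations$pos[i],
                    mutations$ref[i], mutations$alt[i])
  }, integer(1L))
  trinuc_spectrum(tabulate(ch, nbins = 96L), normalised = normalise)
}

#' Construct a somatic mutation catalog
#'
#' Validates and assembles a data frame of mutation records. SNVs carry
#' single-base `ref`/`alt`; divergent candidates carry two distinct
#' alternates in `alt2`.
#'
#' @param chrom,pos,ref,alt Per-record fields; `pos` is 1-based.
#' @param alt2 Optional second alternate allele (divergent candidates);
#'   `NA` otherwise.
#' @param vtype `"SNV"` or `"indel"` per record.
#' @param is_driver Logical driver annotation.
#' @param sample_id Sample label.
#' @return Data frame of class `mutation_records`.
#' @export
mutation_records <- function(chrom, pos, ref, alt, alt2 = NA_character_,
                             vtype = "SNV", is_driver = FALSE,
                             sample_id = "sample") {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = as.character(ref), alt = as.character(alt),
                   alt2 = as.character(alt2), vtype = vtype,
                   is_driver = is_driver, sample_id = sample_id,
                   stringsAsFactors = FALSE)
  if (any(df$ref == df$alt)) stop("ref must differ from alt")
  snv <- df$vtype == "SNV"
  if (any(snv & (!df$ref %in% BASES | !df$alt %in% BASES))) {
    stop("SNV ref and alt must be single A/C/G/T bases")
  }
  has2 <- !is.na(df$alt2)
  if (any(has2 & (df$alt2 == df$alt | df$alt2 == df$ref))) {
    stop("second alternate must differ from ref and from the first alt")
  }
  class(df) <- c("mutation_records", "data.frame")
  df
}
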