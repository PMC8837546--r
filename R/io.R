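# Readers and writers for the standard interchange formats: VCF catalogs,
# Battenberg-style segment TSVs, BED resources, spectrum TSVs and call
# tables. BED input is 0-based half-open and converted to the package's
# 1-based inclusive convention on load.

#' Read a somatic mutation catalog from VCF
#'
#' Multi-allelic records (two ALT alleles) become divergent-candidate
#' records; records with FILTER other than PASS/"." are loaded with
#' `filter_pass = FALSE`, not dropped.
#'
#' @param path VCF 4.x file.
#' @param sample_id Sample label attached to the records.
#' @return A `mutation_records` data frame (column `filter_pass` added).
#' @export
read_catalog_vcf <- function(path, sample_id = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) stop("empty VCF: ", path)
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  if (any(n_alt > 2L)) stop("records with more than two ALT alleles")
  alt1 <- vapply(alts, `[`, character(1L), 1L)
  alt2 <- ifelse(n_alt == 2L, vapply(alts, function(a) a[length(a)],
                                     character(1L)), NA_character_)
  vtype <- ifelse(nchar(fix$REF) == 1L & nchar(alt1) == 1L &
                    (is.na(alt2) | nchar(alt2) == 1L), "SNV", "indel")
  rec <- mutation_records(fix$CHROM, as.integer(fix$POS), fix$REF, alt1,
                          alt2 = alt2, vtype = vtype,
                          sample_id = if (is.null(sample_id))
                            basename(path) else sample_id)
  rec$filter_pass <- is.na(fix$FILTER) | fix$FILTER %in% c("PASS", ".")
  rec
}

#' Write a mutation catalog as a minimal VCF 4.2
#'
#' @param records A `mutation_records` data frame.
#' @param path Output file.
#' @export
write_catalog_vcf <- function(records, path) {
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=biallelic-", utils::packageVersion("biallelic")),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  alt <- ifelse(is.na(records$alt2), records$alt,
                paste(records$alt, records$alt2, sep = ","))
  body <- paste(records$chrom, records$pos, ".", records$ref, alt, ".",
                "PASS", ".", sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read allele-specific copy-number segments
#'
#' Tab-separated with columns `chrom`, `start`, `end`, `major`, `minor`,
#' `baf_seg`, `logr_seg` (1-based inclusive coordinates). Overlapping
#' segments are rejected.
#'
#' @param path TSV file.
#' @return Segment data frame.
#' @export
read_segments_tsv <- function(path) {
  seg <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "major", "minor", "baf_seg",
            "logr_seg")
  if (!all(need %in% names(seg))) {
    stop("segment file lacks columns: ",
         paste(setdiff(need, names(seg)), collapse = ", "))
  }
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1L && any(s$start[-1L] <= s$end[-nrow(s)])) {
      stop("overlapping segments on ", ch)
    }
  }
  seg
}

#' Read a BED file (0-based half-open) into 1-based inclusive intervals
#'
#' @param path BED file (first three columns used).
#' @return Data frame `chrom`, `start`, `end` (1-based inclusive).
#' @export
read_bed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 3L) stop("BED file needs at least 3 columns: ", path)
  data.frame(chrom = as.character(bed[[1L]]),
             start = as.integer(bed[[2L]]) + 1L,
             end = as.integer(bed[[3L]]), stringsAsFactors = FALSE)
}

#' Write intervals as BED (converting back to 0-based half-open)
#'
#' @param intervals Data frame `chrom`, `start`, `end` (1-based inclusive).
#' @param path Output file.
#' @export
write_bed <- function(intervals, path) {
  writeLines(paste(intervals$chrom, intervals$start - 1L, intervals$end,
                   sep = "\t"), path)
  invisible(path)
}

#' Write a 96-channel spectrum as labelled TSV
#'
#' @param spectrum A `trinuc_spectrum` (or 96-vector).
#' @param path Output file.
#' @export
write_spectrum_tsv <- function(spectrum, path) {
  utils::write.table(data.frame(channel = channel_labels(),
                                value = as.numeric(spectrum)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a spectrum TSV written by [write_spectrum_tsv()]
#'
#' @param path TSV file with columns `channel`, `value` in frozen channel
#'   order.
#' @return A `trinuc_spectrum`.
#' @export
read_spectrum_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!identical(df$channel, channel_labels())) {
    stop("spectrum file channels not in the frozen serialisation order")
  }
  trinuc_spectrum(df$value)
}

#' Write a VAF call table with provenance header
#'
#' @param result A `vaf_calls` object.
#' @param path Output TSV.
#' @param config Optional configuration list echoed (as JSON) into the
#'   header for provenance.
#' @export
write_calls <- function(result, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# omega=", format(result$omega),
                    " qq_slope=", format(result$qq_slope),
                    " excluded=", result$excluded), con)
  if (!is.null(config)) {
    writeLines(paste0("# config=",
                      jsonlite::toJSON(unclass(config),
                                       auto_unbox = TRUE)),
               con)
  }
  utils::write.table(result$calls, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a call table written by [write_calls()]
#'
#' @param path TSV file.
#' @return The calls data frame (header metadata in attributes).
#' @export
read_calls <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  df <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                          stringsAsFactors = FALSE)
  attr(df, "meta") <- meta
  df
}

#' Run configuration with the study's default thresholds
#'
#' Collects the tunable constants of the pipeline: BH level 0.1, guard
#' p 0.001 with Fisher 0.01, phasing fractions 0.1, omega bounds
#' \[50, 1000\], pool cosine 0.9 and eligibility factor 0.5, 1000
#' replicates, burden cv 0.05.
#'
#' @param ... Overrides of the defaults.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(seed = 1L, replicates = 1000L, cv = 0.05, q_max = 0.1,
              power_p = 0.001, guard_p = 0.001, guard_fisher_p = 0.01,
              phasing_min_reads = 2L, phasing_min_fraction = 0.1,
              snp_outlier_p = 0.001, omega_bounds = c(50, 1000),
              min_cosine = 0.9, pool_factor = 0.5)
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown)) stop("unknown config fields: ",
                              paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
  }
  stopifnot(cfg$q_max > 0, cfg$q_max <= 1, cfg$omega_bounds[1] > 0)
  class(cfg) <- "run_config"
  cfg
}
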