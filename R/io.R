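# File formats. All coordinates in files are 1-based inclusive.

#' Read sequences from FASTA or one-sequence-per-line text
#'
#' @param path file path. FASTA is detected by a leading \code{>}.
#' @return named character vector (line-format input gets seq1, seq2, ...).
#' @export
readSequences <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) && startsWith(first, ">")) {
    # read as raw text so RNA-style U survives until normalization
    ss <- Biostrings::readBStringSet(path)
    out <- as.character(ss)
    names(out) <- sub("\\s.*$", "", names(ss))
    return(vapply(out, normalizeSequence, ""))
  }
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  out <- vapply(lines, normalizeSequence, "", USE.NAMES = FALSE)
  names(out) <- paste0("seq", seq_along(out))
  out
}

#' Write sequences to FASTA
#'
#' @param sequences named character vector.
#' @param path output path.
#' @export
writeSequences <- function(sequences, path) {
  ss <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Write / read an InfoModel (TSV weights + JSON sidecar)
#'
#' The TSV has a header row of position offsets and four base rows of
#' weights in bits, written with 17 significant digits so that a
#' write-read-write round trip is byte-identical. The JSON sidecar
#' (\code{<path>.json}) carries name, site kind, offsets, training-set size,
#' \code{rSequence} and pseudocount.
#'
#' @param model an \code{\linkS4class{InfoModel}}.
#' @param path TSV path; the sidecar goes to \code{paste0(path, ".json")}.
#' @return \code{writeInfoModel}: the path, invisibly;
#'   \code{readInfoModel}: an \code{\linkS4class{InfoModel}}.
#' @export
writeInfoModel <- function(model, path) {
  stopifnot(is(model, "InfoModel"))
  fmt <- function(x) sprintf("%.17g", x)
  lines <- c(
    paste(c("base", colnames(model@weights)), collapse = "\t"),
    vapply(DNA_BASES4, function(b)
      paste(c(b, fmt(model@weights[b, ])), collapse = "\t"), ""))
  writeLines(lines, path)
  meta <- list(name = model@name, site_kind = model@siteKind,
               offset_start = model@offsetStart,
               offset_end = model@offsetEnd, n_sites = model@nSites,
               r_sequence = model@rSequence,
               r_sequence_sd = model@rSequenceSD,
               pseudocount = model@pseudocount,
               correction_applied = model@correctionApplied,
               floor_bits = model@floorBits)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeInfoModel
#' @export
readInfoModel <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, row.names = 1)
  weights <- as.matrix(tab)
  if (!identical(rownames(weights), DNA_BASES4))
    stop("model file must have base rows A, C, G, T")
  metaPath <- paste0(path, ".json")
  if (!file.exists(metaPath))
    stop("missing model sidecar: ", metaPath)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  colnames(weights) <- as.character(meta$offset_start:meta$offset_end)
  # frequencies recovered from the weights (floor rows treated as absent)
  freqs <- 2^(weights - 2)
  freqs[weights <= meta$floor_bits] <- 0
  freqs <- sweep(freqs, 2, colSums(freqs), "/")
  new("InfoModel", name = meta$name, siteKind = meta$site_kind,
      offsetStart = as.integer(meta$offset_start),
      offsetEnd = as.integer(meta$offset_end),
      weights = weights, freqs = freqs,
      nSites = as.integer(meta$n_sites),
      rSequence = meta$r_sequence, rSequenceSD = meta$r_sequence_sd,
      pseudocount = meta$pseudocount,
      correctionApplied = meta$correction_applied,
      floorBits = meta$floor_bits)
}

#' Read variants from a TSV table
#'
#' Columns: \code{seq_id}, \code{pos}, \code{ref}, \code{alt} (header
#' required). Empty ref = insertion after \code{pos}; empty alt = deletion.
#'
#' @param path TSV path.
#' @return list of \code{\linkS4class{VariantRecord}}s.
#' @export
readVariantTable <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", na.strings = NULL)
  need <- c("seq_id", "pos", "ref", "alt")
  if (!all(need %in% names(tab)))
    stop("variant TSV needs columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i)
    variantRecord(tab$seq_id[i], as.integer(tab$pos[i]),
                  normalizeSequence(tab$ref[i]),
                  normalizeSequence(tab$alt[i])))
}

#' Read variants from a minimal VCF
#'
#' Reads the CHROM, POS, ID, REF and ALT columns of a VCF v4 file (INFO and
#' genotypes ignored); multi-allelic rows are split into one record per
#' alternate allele. VCF indel conventions (shared anchor base) are kept
#' as-is: records are ref/alt replacements at POS.
#'
#' @param path VCF path (uncompressed).
#' @return list of \code{\linkS4class{VariantRecord}}s.
#' @export
readVcfVariants <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 5L) stop("malformed VCF row: ", ln)
    for (alt in strsplit(f[5], ",", fixed = TRUE)[[1]]) {
      if (alt %in% c(".", "*")) next
      out[[length(out) + 1L]] <- variantRecord(
        f[1], as.integer(f[2]), normalizeSequence(f[4]),
        normalizeSequence(alt), "genomic",
        sprintf("%s:%s%s>%s", f[1], f[2], f[4], alt))
    }
  }
  out
}

#' Read an exon table (for c./IVS variant resolution)
#'
#' TSV with columns \code{exon}, \code{start}, \code{end}, \code{strand}
#' (1-based inclusive genomic coordinates).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readExonTable <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  checkExonTable(tab)
}

#' Read a length / distance distribution as a gap-surprisal model
#'
#' Two-column TSV: upper bin edge (nt) and probability; probabilities must
#' sum to 1 (tolerance 1e-9).
#'
#' @param path TSV path.
#' @param kind \code{"exon_length"} or \code{"regulatory_distance"}.
#' @return a \code{\linkS4class{GapSurprisalModel}}.
#' @export
readLengthDistribution <- function(path, kind = "exon_length") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  if (ncol(tab) < 2L)
    stop("distribution TSV needs two columns: edge, probability")
  gapSurprisalModel(tab[[1]], tab[[2]], kind = kind)
}

#' Write site deltas as TSV or JSON
#'
#' Emits the reporting fields a variant interpretation should always carry:
#' model name, coordinates (1-based), strand, \eqn{R_{i,initial}},
#' \eqn{R_{i,final}}, \eqn{\Delta R_i}, minimum fold change, residual
#' percent, category and severity bin.
#'
#' @param deltas data.frame from \code{\link{analyzeVariant}}.
#' @param path output path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @export
writeSiteDeltas <- function(deltas, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(deltas, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(deltas, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
  }
  invisible(path)
}

RUN_CONFIG_DEFAULTS <- list(
  r_i_min = 1.6, significance_bits = 1.0, window_nt = 54L,
  skip_threshold_bits = 7.0, bps_search_nt = 100L, bps_hard_max_nt = 400L,
  distance_cutoff_nt = 400L, slack_bits = 1.0, strand = "+", seed = 1L,
  output_format = "tsv")

#' Read a YAML run configuration
#'
#' Unknown keys are rejected; missing keys take the documented defaults
#' (r_i_min 1.6 bits, significance 1.0 bit, window 54 nt, skip threshold
#' 7.0 bits, branch-point search 100 / hard max 400 nt, distance cutoff
#' 400 nt, slack 1.0 bit, annotated strand only).
#'
#' @param path YAML file, or \code{NULL} for pure defaults.
#' @return named list of configuration values.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- RUN_CONFIG_DEFAULTS
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown config keys: ", paste(unknown, collapse = ", "))
    cfg[names(user)] <- user
  }
  num <- c("r_i_min", "significance_bits", "skip_threshold_bits",
           "slack_bits")
  for (k in num)
    if (!is.finite(cfg[[k]])) stop("config value must be finite: ", k)
  cfg$window_nt <- as.integer(cfg$window_nt)
  cfg
}
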