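# Lane deconvolution: split the reads of one barcoded Illumina lane into
# per-sample FASTQ files, removing barcodes and trimming adapter
# contamination at the first occurrence of a short adapter tag (default
# AGATCG, the first 6-mer of the common GBS adapter).

#' Read a barcode-to-sample map
#'
#' Two-column tab-separated text: barcode, sample. Barcodes must be
#' non-empty strings over A/C/G/T and unique; malformed lines are reported
#' with their line number.
#'
#' @param path Path to the barcode file.
#' @return List of class `barcode_map` with fields `barcode` and `sample`.
#' @export
read_barcode_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2)
  if (length(bad)) {
    stop("malformed barcode file line ", bad[1], ": ", lines[bad[1]])
  }
  barcode_map(vapply(parts, `[`, character(1), 1),
              vapply(parts, `[`, character(1), 2))
}

#' Construct a barcode map
#' @param barcode Character vector of barcodes (A/C/G/T).
#' @param sample Character vector of sample identifiers, same length.
#' @return List of class `barcode_map`.
#' @export
barcode_map <- function(barcode, sample) {
  barcode <- toupper(as.character(barcode))
  sample <- as.character(sample)
  stopifnot(length(barcode) == length(sample), length(barcode) > 0)
  if (any(!grepl("^[ACGT]+$", barcode))) {
    stop("barcodes must be non-empty strings over A/C/G/T")
  }
  if (anyDuplicated(barcode)) {
    stop("duplicated barcode: ",
         paste(unique(barcode[duplicated(barcode)]), collapse = ", "))
  }
  structure(list(barcode = barcode, sample = sample),
            class = "barcode_map")
}

#' Assign reads to samples by exact barcode prefix match
#'
#' A read is assigned to the sample whose barcode exactly matches the read
#' prefix; when one barcode is a prefix of another, the longest matching
#' barcode wins. Reads matching no barcode yield `NA` (unassigned — a value,
#' not an error).
#'
#' @param read_sequence Character vector of read sequences.
#' @param barcodes A [barcode_map()].
#' @return Character vector of sample identifiers (`NA` = unassigned).
#' @export
assign_read <- function(read_sequence, barcodes) {
  stopifnot(inherits(barcodes, "barcode_map"))
  out <- rep(NA_character_, length(read_sequence))
  ord <- order(nchar(barcodes$barcode))   # longest checked last wins? no:
  # iterate shortest -> longest so that later (longer) matches overwrite
  for (i in ord) {
    hit <- startsWith(read_sequence, barcodes$barcode[i])
    out[hit] <- barcodes$sample[i]
  }
  out
}

# barcode length actually matched per read (for removal)
matched_barcode_length <- function(read_sequence, barcodes) {
  len <- integer(length(read_sequence))
  for (i in order(nchar(barcodes$barcode))) {
    hit <- startsWith(read_sequence, barcodes$barcode[i])
    len[hit] <- nchar(barcodes$barcode[i])
  }
  len
}

#' Trim reads at the first occurrence of an adapter tag
#'
#' If the tag occurs in a read, sequence (and qualities, in lockstep) are
#' truncated to end immediately before its first occurrence; otherwise the
#' read is unchanged. Trimming is idempotent, never lengthens a read, and
#' always returns a prefix of the input. A read beginning with the tag
#' becomes empty (callers discard such reads).
#'
#' @param read Character vector of read sequences.
#' @param tag Adapter tag (single string, length >= 4); default `"AGATCG"`,
#'   the first 6-mer of the standard GBS adapter.
#' @param quality Optional character vector of quality strings.
#' @return List with `sequence`, `quality` (or `NULL`) and logical
#'   `trimmed`.
#' @export
trim_adapter <- function(read, tag = "AGATCG", quality = NULL) {
  stopifnot(length(tag) == 1, nchar(tag) >= 4)
  hit <- regexpr(tag, read, fixed = TRUE)
  trimmed <- hit >= 1
  keep_len <- ifelse(trimmed, hit - 1L, nchar(read))
  list(sequence = substr(read, 1L, keep_len),
       quality = if (is.null(quality)) NULL else
         substr(quality, 1L, keep_len),
       trimmed = trimmed)
}

#' Demultiplex one sequencing lane into per-sample FASTQ files
#'
#' Each read is assigned by exact barcode prefix (longest match wins), the
#' barcode is removed, and the remainder is adapter-trimmed. Unassigned
#' reads, and reads shorter than `min_read_length` after trimming, are
#' routed to a rejects file. The report satisfies the partition property:
#' assigned + unassigned + discarded = total reads.
#'
#' @param fastq_in Input FASTQ path (plain or gzip).
#' @param barcodes A [barcode_map()] or path to a barcode file.
#' @param out_dir Output directory (created if needed).
#' @param tag Adapter tag passed to [trim_adapter()].
#' @param min_read_length Minimum post-trim length to keep a read; default 1
#'   (i.e. only empty reads are discarded).
#' @return List of class `demux_report`: per-sample data frame (`sample`,
#'   `n_reads`, `n_trimmed`, `n_discarded`), totals, and output paths. Also
#'   written as `demux_report.tsv` in `out_dir`.
#' @export
demultiplex_lane <- function(fastq_in, barcodes, out_dir,
                             tag = "AGATCG", min_read_length = 1) {
  if (is.character(barcodes)) barcodes <- read_barcode_map(barcodes)
  stopifnot(inherits(barcodes, "barcode_map"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reads <- Biostrings::readDNAStringSet(fastq_in, format = "fastq",
                                        with.qualities = TRUE)
  seqs <- as.character(reads)
  quals <- as.character(S4Vectors::mcols(reads)$qualities)
  ids <- names(reads)
  total <- length(seqs)

  assigned <- assign_read(seqs, barcodes)
  bclen <- matched_barcode_length(seqs, barcodes)
  body <- substr(seqs, bclen + 1L, nchar(seqs))
  bqual <- substr(quals, bclen + 1L, nchar(quals))
  tr <- trim_adapter(body, tag = tag, quality = bqual)

  is_unassigned <- is.na(assigned)
  discard <- !is_unassigned & nchar(tr$sequence) < min_read_length

  samples <- unique(barcodes$sample)
  paths <- file.path(out_dir, paste0(samples, ".fastq"))
  names(paths) <- samples
  n_reads <- integer(length(samples))
  n_trim <- integer(length(samples))
  n_disc <- integer(length(samples))
  for (i in seq_along(samples)) {
    mine <- !is_unassigned & assigned == samples[i]
    keep <- mine & !discard
    n_reads[i] <- sum(keep)
    n_trim[i] <- sum(tr$trimmed[keep])
    n_disc[i] <- sum(mine & discard)
    write_fastq(ids[keep], tr$sequence[keep], tr$quality[keep], paths[i])
  }
  rejects_path <- file.path(out_dir, "rejected.fastq")
  rej <- is_unassigned | discard
  write_fastq(ids[rej], seqs[rej], quals[rej], rejects_path)

  per_sample <- data.frame(sample = samples, n_reads = n_reads,
                           n_trimmed = n_trim, n_discarded = n_disc,
                           stringsAsFactors = FALSE)
  report <- structure(list(
    per_sample = per_sample,
    total_reads = total,
    n_assigned = sum(n_reads),
    n_unassigned = sum(is_unassigned),
    n_discarded = sum(discard),
    n_trimmed = sum(tr$trimmed[!is_unassigned & !discard]),
    trimmed_fraction = if (total > 0) {
      sum(tr$trimmed[!is_unassigned]) / sum(!is_unassigned)
    } else NA_real_,
    paths = paths, rejects_path = rejects_path), class = "demux_report")
  write.table(per_sample, file.path(out_dir, "demux_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  report
}

#' @export
print.demux_report <- function(x, ...) {
  cat(sprintf(paste0("demux_report: %d reads; %d assigned, %d unassigned, ",
                     "%d discarded; trimmed fraction %.3f\n"),
              x$total_reads, x$n_assigned, x$n_unassigned, x$n_discarded,
              x$trimmed_fraction))
  invisible(x)
}

write_fastq <- function(ids, seqs, quals, path) {
  if (length(ids) == 0) {
    file.create(path)
    return(invisible(path))
  }
  out <- character(4L * length(ids))
  out[c(TRUE, FALSE, FALSE, FALSE)] <- paste0("@", ids)
  out[c(FALSE, TRUE, FALSE, FALSE)] <- seqs
  out[c(FALSE, FALSE, TRUE, FALSE)] <- "+"
  out[c(FALSE, FALSE, FALSE, TRUE)] <- quals
  writeLines(out, path)
  invisible(path)
}
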