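#' Read a FASTQ file of raw small RNA reads
#'
#' Reads Sanger (phred+33) FASTQ and returns the read sequences as an
#' uppercase character vector named by read id. Qualities are not used by the
#' pipeline (quality-based trimming is out of scope) and are discarded.
#'
#' @param path Path to an uncompressed or gzipped FASTQ file.
#' @return Named character vector of uppercase DNA sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write reads to FASTQ
#'
#' Writes a fixed maximal quality ("I", phred 40) for every base; the
#' simulator does not model quality scores.
#'
#' @param sequences Character vector of DNA sequences, optionally named.
#' @param path Output path.
#' @export
write_fastq <- function(sequences, path) {
  ids <- names(sequences)
  if (is.null(ids)) ids <- sprintf("read%d", seq_along(sequences))
  x <- Biostrings::DNAStringSet(sequences)
  names(x) <- ids
  qual <- Biostrings::BStringSet(vapply(nchar(sequences), function(n)
    paste(rep("I", n), collapse = ""), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read / write FASTA
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] returning plain named
#' character vectors with T-normalized (DNA alphabet) sequences.
#'
#' @param path File path.
#' @return Named character vector.
#' @export
read_fasta <- function(path) {
  # read as raw text so RNA (U) records survive, then T-normalize
  x <- Biostrings::readBStringSet(path, format = "fasta")
  out <- gsub("U", "T", toupper(as.character(x)))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_fasta
#' @param sequences Named character vector of sequences.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(gsub("U", "T", toupper(sequences)))
  names(x) <- names(sequences)
  Biostrings::writeXStringSet(x, path, format = "fasta")
  invisible(path)
}

#' Clip 3' adapter sequences from reads
#'
#' Finds, for each read, the leftmost exact occurrence of the adapter: either
#' the full adapter internally, or a prefix of the adapter (of at least
#' `min_overlap` bases) running to the 3' end of the read. The read is
#' truncated to the bases preceding that occurrence. Matching is exact; no
#' mismatches are tolerated.
#'
#' @param reads Character vector of read sequences (uppercase DNA).
#' @param adapter Adapter sequence, length >= `min_overlap`.
#' @param min_overlap Minimum adapter prefix length that must be seen at the
#'   read 3' end, default 6.
#' @return A list with `sequence` (clipped reads; unchanged where no adapter
#'   was found) and `found` (logical vector).
#' @export
clip_adapter <- function(reads, adapter, min_overlap = 6L) {
  if (any(!nzchar(reads))) stop("empty read sequence")
  if (!nzchar(adapter)) stop("empty adapter sequence")
  adapter <- toupper(adapter)
  la <- nchar(adapter)
  if (la < min_overlap || min_overlap < 1L)
    stop("adapter length must be >= min_overlap >= 1")
  n <- length(reads)
  len <- nchar(reads)
  # position (1-based) of leftmost full internal adapter occurrence
  pos_full <- regexpr(adapter, reads, fixed = TRUE)
  cut <- ifelse(pos_full > 0L, as.integer(pos_full), NA_integer_)
  # longest adapter prefix terminating the read (checked longest-first so the
  # leftmost, i.e. largest-overlap, suffix wins)
  best_ov <- integer(n)
  ov_hi <- min(la - 1L, max(len))
  for (ov in (if (ov_hi >= min_overlap) seq.int(ov_hi, min_overlap) else integer(0))) {
    pre <- substr(adapter, 1L, ov)
    hit <- best_ov == 0L & len >= ov &
      substr(reads, len - ov + 1L, len) == pre
    best_ov[hit] <- ov
  }
  cut_suffix <- ifelse(best_ov > 0L, len - best_ov + 1L, NA_integer_)
  cut <- pmin(cut, cut_suffix, na.rm = TRUE)
  found <- !is.na(cut)
  out <- reads
  out[found] <- substr(reads[found], 1L, cut[found] - 1L)
  list(sequence = out, found = found)
}

#' Collapse reads into unique sequences with multiplicities
#'
#' @param reads Character vector of read sequences (a multiset).
#' @param total_raw Number of reads that entered the processing cascade;
#'   defaults to `length(reads)`.
#' @param provenance Character vector describing filters already applied.
#' @return A `collapsed_library`: list with `entries` (named integer vector,
#'   names are unique sequences), `total_raw`, `provenance`.
#' @export
collapse_reads <- function(reads, total_raw = length(reads),
                           provenance = character()) {
  if (length(reads) == 0L) {
    entries <- integer(0)
  } else {
    tab <- table(reads)
    entries <- as.integer(tab)
    names(entries) <- names(tab)
  }
  structure(
    list(entries = entries, total_raw = as.integer(total_raw),
         provenance = c(provenance, "collapse")),
    class = "collapsed_library")
}

#' @export
print.collapsed_library <- function(x, ...) {
  cat(sprintf("collapsed_library: %d unique sequences, %d reads (of %d raw)\n",
              length(x$entries), sum(x$entries), x$total_raw))
  cat("provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' Total reads represented by a collapsed library
#' @param lib A `collapsed_library`.
#' @export
library_reads <- function(lib) sum(lib$entries)

#' Length filter: retain sequences strictly longer than a cutoff
#'
#' Mirrors the analysis convention that only reads of more than `min_len`
#' nucleotides (default 15) carry on to mapping; the short GC-rich inserts
#' peaking at 7 nt are removed here.
#'
#' @param x Character vector of reads, or a `collapsed_library`.
#' @param min_len Retain length > `min_len` (strict). Default 15.
#' @return Same type as `x`, filtered; a library's provenance records the rule.
#' @export
length_filter <- function(x, min_len = 15L) {
  stopifnot(min_len >= 0L)
  if (inherits(x, "collapsed_library")) {
    keep <- nchar(names(x$entries)) > min_len
    x$entries <- x$entries[keep]
    x$provenance <- c(x$provenance, sprintf("length>%d", min_len))
    x
  } else {
    x[nchar(x) > min_len]
  }
}

#' Abundance filter: drop rare unique sequences
#'
#' Removes unique sequences seen fewer than `min_count` times (default 3,
#' i.e. sequences represented by fewer than 3 reads are discarded). Returns
#' the filtered library plus a summary of how many unique sequences survive
#' and what fraction of reads they account for.
#'
#' @param lib A `collapsed_library`.
#' @param min_count Keep entries with count >= `min_count`. Default 3.
#' @return List with `library` (filtered `collapsed_library`),
#'   `retained_unique`, and `retained_read_fraction` (fraction of the reads
#'   entering this filter).
#' @export
abundance_filter <- function(lib, min_count = 3L) {
  stopifnot(inherits(lib, "collapsed_library"), min_count >= 1L)
  total_in <- sum(lib$entries)
  keep <- lib$entries >= min_count
  out <- lib
  out$entries <- lib$entries[keep]
  out$provenance <- c(lib$provenance, sprintf("count>=%d", min_count))
  list(library = out,
       retained_unique = sum(keep),
       retained_read_fraction =
         if (total_in > 0) sum(lib$entries[keep]) / total_in else NA_real_)
}

#' Read-weighted length histogram of a collapsed library
#'
#' @param lib A `collapsed_library`.
#' @return List with `histogram` (named integer vector, length -> read count)
#'   and `mean_length` (read-weighted mean).
#' @export
length_histogram <- function(lib) {
  stopifnot(inherits(lib, "collapsed_library"))
  if (length(lib$entries) == 0L)
    return(list(histogram = integer(0), mean_length = NA_real_))
  len <- nchar(names(lib$entries))
  h <- tapply(lib$entries, len, sum)
  hist <- as.integer(h)
  names(hist) <- names(h)
  list(histogram = hist,
       mean_length = sum(len * lib$entries) / sum(lib$entries))
}

#' Serialize / deserialize a collapsed library
#'
#' The on-disk forms are a FASTA with headers `tag<k>_x<count>` and a
#' two-column TSV (sequence, count).
#'
#' @param lib A `collapsed_library`.
#' @param path Output path.
#' @export
write_collapsed_fasta <- function(lib, path) {
  seqs <- names(lib$entries)
  names(seqs) <- sprintf("tag%d_x%d", seq_along(seqs), lib$entries)
  write_fasta(seqs, path)
}

#' @rdname write_collapsed_fasta
#' @export
write_collapsed_tsv <- function(lib, path) {
  utils::write.table(
    data.frame(sequence = names(lib$entries), count = unname(lib$entries)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_collapsed_fasta
#' @export
read_collapsed_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c("character", "integer"))
  entries <- d$count
  names(entries) <- d$sequence
  structure(list(entries = entries, total_raw = sum(entries),
                 provenance = "loaded"),
            class = "collapsed_library")
}

#' Run the read-processing cascade
#'
#' clip adapter -> length filter (> `min_len`) -> collapse -> abundance
#' filter (>= `min_count`), recording the count of reads/unique sequences at
#' every step, mirroring how a deep-sequencing small RNA library is reduced
#' to a workable tag list.
#'
#' @param reads Raw read sequences (character vector).
#' @param adapter Adapter sequence.
#' @param min_len Strict length cutoff after clipping (default 15).
#' @param min_count Minimum tag multiplicity (default 3).
#' @param min_overlap Minimum adapter overlap for clipping (default 6).
#' @return List with `library` (final `collapsed_library`) and `cascade`, a
#'   named list: `raw`, `gt_min_len` (reads > min_len), `unique`
#'   (unique sequences among them), `unique_filtered` (unique sequences with
#'   >= min_count reads), `retained_read_fraction`.
#' @export
read_cascade <- function(reads, adapter, min_len = 15L, min_count = 3L,
                         min_overlap = 6L) {
  clip <- clip_adapter(reads, adapter, min_overlap)
  kept <- length_filter(clip$sequence, min_len)
  lib <- collapse_reads(kept, total_raw = length(reads),
                        provenance = c("clip", sprintf("length>%d", min_len)))
  ab <- abundance_filter(lib, min_count)
  list(library = ab$library,
       cascade = list(
         raw = length(reads),
         gt_min_len = length(kept),
         unique = length(lib$entries),
         unique_filtered = ab$retained_unique,
         retained_read_fraction = ab$retained_read_fraction))
}
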