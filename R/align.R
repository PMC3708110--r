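#' Map collapsed tags onto reference sequences
#'
#' Places each unique tag on every reference sequence, allowing up to
#' `max_mismatch` substitutions (no indels), and keeps only the best
#' stratum: all placements at the minimum mismatch count observed for that
#' tag across all targets. Genome-kind targets are searched on both strands;
#' a minus-strand placement means the reverse complement of the tag matches
#' the forward reference at the reported interval. Tags containing N are not
#' placed.
#'
#' @param tags Character vector of tag sequences, or a `collapsed_library`.
#' @param targets Named list of reference sets; each element is a named
#'   character vector (or DNAStringSet) of sequences. Element names give the
#'   `target_kind` (e.g. `mature`, `hairpin`, `genome`).
#' @param max_mismatch Maximum substitutions, 0-2. May be a single value or
#'   a named vector keyed by target kind.
#' @param both_strands Kinds searched on both strands (default `"genome"`).
#' @return data.frame of placements: `tag`, `target_kind`, `target_id`,
#'   `start` (0-based), `end` (exclusive), `strand`, `mismatches`. Unplaced
#'   tags are absent.
#' @export
map_tags <- function(tags, targets, max_mismatch = 1L,
                     both_strands = "genome") {
  if (inherits(tags, "collapsed_library")) tags <- names(tags$entries)
  tags <- unique(tags)
  tags <- tags[!grepl("N", tags, fixed = TRUE)]
  if (length(max_mismatch) == 1L && is.null(names(max_mismatch)))
    max_mismatch <- stats::setNames(rep(max_mismatch, length(targets)),
                                    names(targets))
  stopifnot(all(max_mismatch %in% 0:2))

  rows <- vector("list", 0L)
  for (kind in names(targets)) {
    refs <- targets[[kind]]
    if (!inherits(refs, "DNAStringSet"))
      refs <- Biostrings::DNAStringSet(normalize_dna(refs))
    mm <- unname(max_mismatch[[kind]])
    strands <- if (kind %in% both_strands) c("+", "-") else "+"
    widths <- Biostrings::width(refs)
    for (strand in strands) {
      for (ti in seq_along(tags)) {
        tg <- tags[ti]
        pat <- if (strand == "+") tg else
          as.character(Biostrings::reverseComplement(Biostrings::DNAString(tg)))
        pat_d <- Biostrings::DNAString(pat)
        fit <- which(nchar(pat) <= widths)
        if (!length(fit)) next
        refs_fit <- refs[fit]
        m <- Biostrings::vmatchPattern(pat, refs_fit, max.mismatch = mm,
                                       with.indels = FALSE)
        nh <- S4Vectors::elementNROWS(m)
        for (k in which(nh > 0L)) {
          ri <- fit[k]
          st <- BiocGenerics::start(m[[k]])
          nmm <- Biostrings::neditStartingAt(pat_d, refs[[ri]],
                                             starting.at = st,
                                             with.indels = FALSE)
          keep <- nmm <= mm
          if (!any(keep)) next
          rows[[length(rows) + 1L]] <- data.frame(
            tag = tg, target_kind = kind, target_id = names(refs)[ri],
            start = st[keep] - 1L, end = st[keep] - 1L + nchar(pat),
            strand = strand, mismatches = as.integer(nmm[keep]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) return(empty_placements())
  out <- do.call(rbind, rows)
  # best stratum per tag
  best <- tapply(out$mismatches, out$tag, min)
  out <- out[out$mismatches == best[out$tag], , drop = FALSE]
  out <- out[order(out$tag, out$target_kind, out$target_id, out$start,
                   out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_placements <- function() {
  data.frame(tag = character(), target_kind = character(),
             target_id = character(), start = integer(), end = integer(),
             strand = character(), mismatches = integer(),
             stringsAsFactors = FALSE)
}

#' Brute-force placement oracle
#'
#' Exhaustive sliding-window comparison of a tag against one reference,
#' written in plain R without any alignment library, used in tests to
#' certify [map_tags()]. Returns all placements with at most `max_mismatch`
#' substitutions (not only the best stratum).
#'
#' @param tag Tag sequence.
#' @param reference Reference sequence (<= 100 kb).
#' @param max_mismatch Maximum substitutions.
#' @param both_strands Search the reverse complement too.
#' @return data.frame with `start` (0-based), `end`, `strand`, `mismatches`.
#' @export
brute_force_map <- function(tag, reference, max_mismatch = 0L,
                            both_strands = FALSE) {
  stopifnot(nchar(reference) <= 100000L)
  ref <- utf8ToInt(reference)
  comp <- function(s) chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                                   collapse = ""))
  out <- list()
  strands <- if (both_strands) c("+", "-") else "+"
  for (strand in strands) {
    pat <- if (strand == "+") tag else comp(tag)
    p <- utf8ToInt(pat)
    k <- length(p)
    if (k > length(ref) || grepl("N", pat, fixed = TRUE)) next
    for (s0 in 0:(length(ref) - k)) {
      mm <- sum(ref[(s0 + 1):(s0 + k)] != p)
      if (mm <= max_mismatch)
        out[[length(out) + 1L]] <- data.frame(
          start = s0, end = s0 + k, strand = strand,
          mismatches = as.integer(mm), stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Export placements as BED6 (+ mismatch column)
#'
#' @param placements data.frame from [map_tags()] (genome placements).
#' @param path Output path.
#' @export
placements_to_bed <- function(placements, path) {
  d <- data.frame(chrom = placements$target_id, start = placements$start,
                  end = placements$end, name = placements$tag,
                  score = placements$mismatches, strand = placements$strand)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Export placements as minimal single-end SAM
#'
#' Writes `@SQ` header lines from the reference set and one alignment line
#' per placement with the NM tag carrying the mismatch count.
#'
#' @param placements Genome placements from [map_tags()].
#' @param references Named character vector or DNAStringSet of references.
#' @param path Output path.
#' @param counts Optional named counts per tag (written into the read name).
#' @export
placements_to_sam <- function(placements, references, path, counts = NULL) {
  if (inherits(references, "DNAStringSet")) {
    lens <- Biostrings::width(references)
    rn <- names(references)
  } else {
    lens <- nchar(references)
    rn <- names(references)
  }
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", rn, lens))
  revcomp <- function(s) chartr("ACGT", "TGCA",
                                paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  body <- vapply(seq_len(nrow(placements)), function(i) {
    p <- placements[i, ]
    flag <- if (p$strand == "-") 16L else 0L
    seqf <- if (p$strand == "-") revcomp(p$tag) else p$tag
    qname <- if (!is.null(counts)) sprintf("%s_x%d", p$tag, counts[[p$tag]]) else p$tag
    sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
            qname, flag, p$target_id, p$start + 1L, nchar(p$tag), seqf,
            p$mismatches)
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}
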