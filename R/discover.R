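#' Merge genome placements of unannotated tags into expressed intervals
#'
#' Strand-specific single-linkage merge of placements that overlap or lie
#' within `merge_gap` of one another. Read support sums the full count of
#' every placement in the interval; the dominant tag is the highest-count
#' tag (ties by lexicographic tag).
#'
#' @param placements Genome placements (data.frame from [map_tags()]).
#' @param counts Named reads-per-tag vector.
#' @param merge_gap Maximum gap merged, default 15 (so that mature and star
#'   products of one precursor, separated by the loop, coalesce into one
#'   locus).
#' @return data.frame: `chrom`, `start`, `end`, `strand`, `read_support`,
#'   `dominant_tag`, `dominant_length`.
#' @export
call_intervals <- function(placements, counts, merge_gap = 15L) {
  gp <- placements[placements$target_kind == "genome", , drop = FALSE]
  if (!nrow(gp))
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      strand = character(), read_support = numeric(),
                      dominant_tag = character(), dominant_length = integer(),
                      stringsAsFactors = FALSE))
  gr <- GenomicRanges::GRanges(gp$target_id,
                               IRanges::IRanges(gp$start + 1L, gp$end),
                               strand = gp$strand)
  red <- GenomicRanges::reduce(gr, min.gapwidth = merge_gap + 1L,
                               ignore.strand = FALSE)
  ov <- GenomicRanges::findOverlaps(gr, red)
  grp <- S4Vectors::subjectHits(ov)[order(S4Vectors::queryHits(ov))]
  out <- lapply(seq_along(red), function(k) {
    rows <- gp[grp == k, , drop = FALSE]
    cnt <- as.numeric(counts[rows$tag])
    best <- order(-cnt, rows$tag)[1]
    data.frame(chrom = as.character(GenomicRanges::seqnames(red))[k],
               start = BiocGenerics::start(red)[k] - 1L,
               end = BiocGenerics::end(red)[k],
               strand = as.character(GenomicRanges::strand(red))[k],
               read_support = sum(cnt),
               dominant_tag = rows$tag[best],
               dominant_length = nchar(rows$tag[best]),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Default novel-miRNA filter parameters
#'
#' `min_reads`: expression evidence, read support must exceed it (>100).
#' `len_range`: dominant tag length window, the optimum miRNA size 21-23.
#' `mfe_max`: hairpin stability, MFE must be at or below -25 kcal/mol.
#' `pairing_min`: fraction of mature bases paired into the stem (0.75).
#' `flank`: nucleotides of genomic context added each side before folding.
#' @export
default_discovery_params <- function() {
  list(min_reads = 100, len_range = c(21L, 23L), mfe_max = -25,
       pairing_min = 0.75, flank = 60L, frame_lens = c(70L, 90L, 110L),
       frame_step = 10L)
}

#' Fold the best hairpin frame around an expressed interval
#'
#' Extracts the interval plus `flank` nucleotides each side (strand-aware)
#' and folds sliding frames of several lengths (`frame_lens`) that fully
#' contain the dominant tag. The best frame is the one whose fold has a
#' single hairpin loop and the lowest energy; when no frame yields a single
#' hairpin loop the minimum-energy frame is kept (and the candidate will
#' fail the single-hairpin criterion). Trying several frame lengths lets a
#' genuine stem-loop be judged on a window matching its own extent rather
#' than being charged for incidental structure in surrounding sequence.
#'
#' @param interval One row of [call_intervals()] output.
#' @param genome DNAStringSet.
#' @param params See [default_discovery_params()].
#' @return List: `fold` (`hairpin_fold`), `frame_start` (0-based genomic,
#'   forward coordinates), `mature_offset` (0-based offset of the dominant
#'   tag within the folded frame).
#' @export
fold_candidate_frame <- function(interval, genome, params = default_discovery_params()) {
  chrlen <- length(genome[[interval$chrom]])
  lo <- max(0L, interval$start - params$flank)
  hi <- min(chrlen, interval$end + params$flank)
  region <- genome_sequence(genome, interval$chrom, lo, hi, "+")
  # dominant tag position in forward coordinates of the region
  tag_fw <- if (interval$strand == "+") interval$dominant_tag else
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(interval$dominant_tag)))
  tpos <- regexpr(tag_fw, region, fixed = TRUE)
  if (tpos < 1L) {
    # dominant tag may carry a mismatch; anchor on the interval instead
    tpos <- interval$start - lo + 1L
  }
  tlen <- nchar(interval$dominant_tag)
  best <- NULL
  better <- function(a, b) {   # TRUE if a beats b
    if (is.null(b)) return(TRUE)
    a1 <- a$fold$n_hairpin_loops == 1L
    b1 <- b$fold$n_hairpin_loops == 1L
    if (a1 != b1) return(a1)
    a$fold$mfe < b$fold$mfe
  }
  for (flen in unique(pmin(params$frame_lens, nchar(region)))) {
    starts <- unique(pmax(1L, pmin(
      seq(tpos + tlen - flen, tpos, by = params$frame_step),
      nchar(region) - flen + 1L)))
    starts <- starts[starts + flen - 1L <= nchar(region) &
                     starts <= tpos & starts + flen >= tpos + tlen]
    if (!length(starts))
      starts <- max(1L, min(tpos, nchar(region) - flen + 1L))
    for (s in starts) {
      frame <- substr(region, s, s + flen - 1L)
      fseq <- if (interval$strand == "+") frame else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(frame)))
      f <- fold_hairpin(fseq)
      cand <- list(fold = f, frame_start = lo + s - 1L,
                   mature_offset = if (interval$strand == "+") tpos - s else
                     (s + flen - 1L) - (tpos + tlen - 1L))
      if (better(cand, best)) best <- cand
    }
  }
  best
}

#' Apply the novel-miRNA candidate filters
#'
#' Pass requires all of: read support above `min_reads`; dominant tag length
#' inside `len_range`; no overlap with annotated ncRNAs; frame MFE at or
#' below `mfe_max`; exactly one hairpin loop; mature pairing fraction at
#' least `pairing_min` with the mature wholly on one arm.
#'
#' @param interval One row of [call_intervals()] output.
#' @param frame Result of [fold_candidate_frame()].
#' @param annotations GRanges of ncRNA annotations (or NULL).
#' @param params See [default_discovery_params()].
#' @return One-row data.frame with per-criterion logicals and `pass`.
#' @export
filter_candidate <- function(interval, frame, annotations = NULL,
                             params = default_discovery_params()) {
  m0 <- frame$mature_offset
  m1 <- m0 + interval$dominant_length
  n <- nchar(frame$fold$sequence)
  m0 <- max(0L, m0); m1 <- min(n, m1)
  ok_support <- interval$read_support > params$min_reads
  ok_len <- interval$dominant_length >= params$len_range[1] &&
    interval$dominant_length <= params$len_range[2]
  ok_unannotated <- TRUE
  if (!is.null(annotations) && length(annotations)) {
    iv <- GenomicRanges::GRanges(interval$chrom,
                                 IRanges::IRanges(interval$start + 1L, interval$end),
                                 strand = interval$strand)
    ok_unannotated <- !any(suppressWarnings(
      IRanges::overlapsAny(iv, annotations, ignore.strand = FALSE)))
  }
  ok_mfe <- frame$fold$mfe <= params$mfe_max
  ok_single_hairpin <- frame$fold$n_hairpin_loops == 1L
  pf <- if (m1 > m0) pairing_fraction(frame$fold, m0, m1) else 0
  ok_pairing <- pf >= params$pairing_min &&
    (m1 > m0 && on_single_arm(frame$fold, m0, m1))
  data.frame(read_support = interval$read_support,
             dominant_length = interval$dominant_length,
             mfe = frame$fold$mfe, n_hairpin_loops = frame$fold$n_hairpin_loops,
             pairing_fraction = pf,
             ok_support = ok_support, ok_len = ok_len,
             ok_unannotated = ok_unannotated, ok_mfe = ok_mfe,
             ok_single_hairpin = ok_single_hairpin, ok_pairing = ok_pairing,
             pass = ok_support && ok_len && ok_unannotated && ok_mfe &&
               ok_single_hairpin && ok_pairing,
             stringsAsFactors = FALSE)
}

#' Count star-strand support for a candidate hairpin
#'
#' Counts reads whose 5' end lies on the arm opposite the dominant (mature)
#' tag at the position expected for the star strand of a Dicer duplex with
#' 2-nt 3' overhangs, within a tolerance of `tol` nucleotides. Candidates
#' with any such read are tier `star_supported`; otherwise
#' `structure_only`.
#'
#' @param frame Result of [fold_candidate_frame()].
#' @param interval One row of [call_intervals()] output.
#' @param placements Genome placements of all unannotated tags.
#' @param counts Named reads-per-tag vector.
#' @param tol Tolerance around the expected star 5' end, default 2.
#' @return List: `star_reads`, `tier`.
#' @export
detect_star_support <- function(frame, interval, placements, counts, tol = 2L) {
  fold <- frame$fold
  m0 <- frame$mature_offset            # 0-based in folded frame
  m1 <- m0 + interval$dominant_length
  n <- nchar(fold$sequence)
  pr <- fold$pairs
  # expected star 5' end: partner of the mature base 2 nt inside its 3' end
  anchor <- NA_integer_
  for (k in seq(min(m1, n), max(m0 + 1L, 1L))) {
    if (k >= 1 && k <= n && pr[k] > 0) { anchor <- k; break }
  }
  if (is.na(anchor)) return(list(star_reads = 0, tier = "structure_only"))
  exp_star5_frame <- pr[anchor] - (m1 - anchor) + 2L   # 2-nt 3' overhang
  # convert to genomic forward coordinate of the star 5' end
  flen <- n
  gp <- placements[placements$target_kind == "genome" &
                     placements$target_id == interval$chrom &
                     placements$strand == interval$strand, , drop = FALSE]
  if (interval$strand == "+") {
    exp_g5 <- frame$frame_start + (exp_star5_frame - 1L)
    read5 <- gp$start
    mature_lo <- frame$frame_start + m0
  } else {
    exp_g5 <- frame$frame_start + flen - exp_star5_frame
    read5 <- gp$end - 1L
    mature_lo <- frame$frame_start + flen - m1
  }
  mature_hi <- mature_lo + (m1 - m0)
  sel <- abs(read5 - exp_g5) <= tol &
    !(gp$start < mature_hi & gp$end > mature_lo)
  star_reads <- sum(as.numeric(counts[gp$tag[sel]]))
  list(star_reads = star_reads,
       tier = if (star_reads > 0) "star_supported" else "structure_only")
}

#' Full candidate evaluation over expressed intervals
#'
#' @param intervals Output of [call_intervals()].
#' @param genome DNAStringSet.
#' @param placements Genome placements of unannotated tags.
#' @param counts Named reads-per-tag vector.
#' @param annotations GRanges or NULL.
#' @param params See [default_discovery_params()].
#' @return data.frame: interval columns + filter columns + `star_reads`,
#'   `tier`, `seed`, `sequence` (dominant tag), `dot_bracket`, `mfe`.
#' @export
evaluate_candidates <- function(intervals, genome, placements, counts,
                                annotations = NULL,
                                params = default_discovery_params()) {
  rows <- lapply(seq_len(nrow(intervals)), function(i) {
    iv <- intervals[i, ]
    frame <- fold_candidate_frame(iv, genome, params)
    flt <- filter_candidate(iv, frame, annotations, params)
    star <- detect_star_support(frame, iv, placements, counts)
    cbind(iv[, c("chrom", "start", "end", "strand", "dominant_tag")], flt,
          data.frame(star_reads = star$star_reads, tier = star$tier,
                     seed = if (nchar(iv$dominant_tag) >= 8)
                       seed_of(iv$dominant_tag) else NA_character_,
                     dot_bracket = frame$fold$dot_bracket,
                     stringsAsFactors = FALSE))
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Detect orthologs of foreign mature miRNAs among unmatched tags
#'
#' Tags that fail to match any native mature are compared (5'-anchored,
#' substitution only) to a foreign mature set. A tag is called an ortholog
#' of a foreign miRNA when its length differs by at most 2 nt and the
#' overlap carries at most `max_mismatch` substitutions, none of them in
#' the seed (positions 2-8).
#'
#' @param tags Character vector of tag sequences.
#' @param native Character vector of native mature sequences.
#' @param foreign Named character vector of foreign mature sequences.
#' @param max_mismatch Default 2.
#' @return data.frame: `tag`, `ortholog_of`, `mismatches`.
#' @export
find_orthologs <- function(tags, native, foreign, max_mismatch = 2L) {
  native <- normalize_dna(native)
  foreign_n <- normalize_dna(foreign)
  hamming5 <- function(a, b) {
    n <- min(nchar(a), nchar(b))
    av <- utf8ToInt(substr(a, 1, n)); bv <- utf8ToInt(substr(b, 1, n))
    list(mm = sum(av != bv), seed_mm = sum(av[2:8] != bv[2:8]))
  }
  matches_set <- function(tg, set, mm_allow) {
    for (s in set) {
      if (abs(nchar(tg) - nchar(s)) > 2L) next
      h <- hamming5(tg, s)
      if (h$mm <= mm_allow && h$seed_mm == 0L) return(TRUE)
    }
    FALSE
  }
  out <- list()
  for (tg in tags) {
    if (nchar(tg) < 16L) next
    if (matches_set(tg, native, max_mismatch)) next
    best <- NULL
    for (fi in seq_along(foreign_n)) {
      s <- foreign_n[fi]
      if (abs(nchar(tg) - nchar(s)) > 2L) next
      h <- hamming5(tg, s)
      if (h$mm <= max_mismatch && h$seed_mm == 0L &&
          (is.null(best) || h$mm < best$mm))
        best <- list(name = names(foreign_n)[fi], mm = h$mm)
    }
    if (!is.null(best))
      out[[length(out) + 1L]] <- data.frame(
        tag = tg, ortholog_of = best$name, mismatches = best$mm,
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(tag = character(), ortholog_of = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Group miRNAs into seed families
#'
#' Sequences sharing an identical seed (positions 2-8) form one family.
#' A family containing known members is named after the lexicographically
#' earliest known member; otherwise it receives the id `FAM-<seed>`.
#'
#' @param sequences Named character vector of candidate sequences.
#' @param known Named character vector of known mature sequences.
#' @return data.frame: `name`, `sequence`, `seed`, `family`, `known`.
#' @export
assign_families <- function(sequences, known = character()) {
  all_seq <- c(known, sequences)
  is_known <- c(rep(TRUE, length(known)), rep(FALSE, length(sequences)))
  seeds <- seed_of(all_seq)
  fam <- vapply(seeds, function(sd) {
    members <- which(seeds == sd & is_known)
    if (length(members)) sort(names(all_seq)[members])[1]
    else paste0("FAM-", sd)
  }, character(1))
  data.frame(name = names(all_seq), sequence = unname(normalize_dna(all_seq)),
             seed = unname(seeds), family = unname(fam), known = is_known,
             row.names = NULL, stringsAsFactors = FALSE)
}
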