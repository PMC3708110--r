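#' Default ncRNA class precedence
#'
#' When a tag's best-stratum placements overlap annotations of several
#' classes, the class earliest in this ordered list wins. miRNA outranks
#' everything so that tags from miRNA loci nested in other transcripts are
#' still counted as miRNA.
#' @export
default_precedence <- function() {
  c("miRNA", "snoRNA", "tRNA", "snRNA", "rRNA", "mt_rRNA", "mt_tRNA", "miscRNA")
}

#' Classify placed tags into ncRNA classes
#'
#' Each tag is assigned once, by its unique sequence, to a single (class,
#' ncRNA id): among the tag's best-stratum genome placements that overlap an
#' annotation (strand-aware), the class earliest in `precedence` is chosen;
#' ties within a class are broken by lowest mismatch count, then
#' lexicographic annotation id. Tags whose placements touch no annotation
#' are `unannotated` (the input to novel-miRNA discovery); tags with no
#' placements at all are `unmapped`.
#'
#' @param placements Genome placements from [map_tags()] (kind `genome`).
#' @param annotations GRanges with `id` and `class` columns.
#' @param tags All tag sequences considered (so unmapped tags are reported);
#'   defaults to the tags present in `placements`.
#' @param precedence Ordered character vector of classes.
#' @return data.frame: `tag`, `class` (annotation class, `unannotated`, or
#'   `unmapped`), `ncrna_id` (NA when not annotated).
#' @export
classify_tags <- function(placements, annotations,
                          tags = unique(placements$tag),
                          precedence = default_precedence()) {
  gp <- placements[placements$target_kind == "genome", , drop = FALSE]
  res <- data.frame(tag = tags, class = "unmapped",
                    ncrna_id = NA_character_, stringsAsFactors = FALSE)
  if (nrow(gp)) {
    pl_gr <- GenomicRanges::GRanges(
      gp$target_id,
      IRanges::IRanges(gp$start + 1L, gp$end),
      strand = gp$strand)
    ov <- GenomicRanges::findOverlaps(pl_gr, annotations, ignore.strand = FALSE)
    hit <- data.frame(
      tag = gp$tag[S4Vectors::queryHits(ov)],
      mismatches = gp$mismatches[S4Vectors::queryHits(ov)],
      class = annotations$class[S4Vectors::subjectHits(ov)],
      id = annotations$id[S4Vectors::subjectHits(ov)],
      stringsAsFactors = FALSE)
    res$class[res$tag %in% gp$tag] <- "unannotated"
    if (nrow(hit)) {
      hit$rank <- match(hit$class, precedence)
      hit <- hit[order(hit$tag, hit$rank, hit$mismatches, hit$id), , drop = FALSE]
      hit <- hit[!duplicated(hit$tag), , drop = FALSE]
      m <- match(hit$tag, res$tag)
      res$class[m] <- hit$class
      res$ncrna_id[m] <- hit$id
    }
  }
  res
}

#' Summarize library composition by ncRNA class
#'
#' Read-weighted and distinct-feature tallies of classified tags: for every
#' class, how many distinct ncRNAs contributed reads, how many reads they
#' account for, and the fraction of all annotated reads. Unannotated and
#' unmapped tags are excluded from the fractions (they are reported
#' separately in the pipeline summary).
#'
#' @param classified data.frame from [classify_tags()].
#' @param counts Named integer vector: reads per tag sequence.
#' @return data.frame: `class`, `n_features`, `reads`, `read_fraction`,
#'   sorted by decreasing reads.
#' @export
summarize_classes <- function(classified, counts) {
  ann <- classified[!classified$class %in% c("unannotated", "unmapped"), ,
                    drop = FALSE]
  if (!nrow(ann))
    return(data.frame(class = character(), n_features = integer(),
                      reads = integer(), read_fraction = numeric(),
                      stringsAsFactors = FALSE))
  ann$reads <- as.numeric(counts[ann$tag])
  reads <- tapply(ann$reads, ann$class, sum)
  nfeat <- tapply(ann$ncrna_id, ann$class, function(x) length(unique(x)))
  out <- data.frame(class = names(reads),
                    n_features = as.integer(nfeat[names(reads)]),
                    reads = as.numeric(reads),
                    read_fraction = as.numeric(reads) / sum(reads),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$reads), , drop = FALSE]
  rownames(out) <- NULL
  out
}
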