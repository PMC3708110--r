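#' Profile small RNA fragments derived from snoRNA / tRNA hosts
#'
#' Takes genome placements of tags classified to snoRNA or tRNA loci and
#' expresses each as a fragment of its host: offsets within the host (5'->3'
#' in host orientation), an arm call, and read counts. The arm rule is
#' positional: `five_prime` when the fragment starts within the first
#' quarter of the host, `three_prime` when it ends within the last quarter,
#' otherwise `internal`; a fragment covering the whole host is `internal`
#' and flagged `full_length`. Multi-copy tRNA genes are aggregated by
#' family (name minus the copy suffix, e.g. `tRNA-Gly-GCC`): a tag matching
#' several copies contributes its full count once to the family.
#'
#' @param placements Genome placements from [map_tags()].
#' @param classified data.frame from [classify_tags()].
#' @param annotations GRanges with `id`, `class`.
#' @param counts Named reads-per-tag vector.
#' @param trna Optional tRNA table (data.frame with `name`, `family`) used
#'   for family aggregation.
#' @return data.frame of fragment records: `host_id`, `host_class`,
#'   `fragment`, `host_start`, `host_end`, `arm`, `full_length`, `length`,
#'   `count`.
#' @export
profile_host_fragments <- function(placements, classified, annotations,
                                   counts, trna = NULL) {
  sel <- classified[classified$class %in% c("snoRNA", "tRNA"), , drop = FALSE]
  empty <- data.frame(host_id = character(), host_class = character(),
                      fragment = character(), host_start = integer(),
                      host_end = integer(), arm = character(),
                      full_length = logical(), length = integer(),
                      count = numeric(), stringsAsFactors = FALSE)
  if (!nrow(sel)) return(empty)
  ann_idx <- match(sel$ncrna_id, annotations$id)
  gp <- placements[placements$target_kind == "genome", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(sel))) {
    aid <- sel$ncrna_id[i]
    a <- ann_idx[i]
    h_start <- BiocGenerics::start(annotations)[a] - 1L
    h_end <- BiocGenerics::end(annotations)[a]
    h_strand <- as.character(GenomicRanges::strand(annotations))[a]
    h_chrom <- as.character(GenomicRanges::seqnames(annotations))[a]
    h_len <- h_end - h_start
    pl <- gp[gp$tag == sel$tag[i] & gp$target_id == h_chrom &
               gp$strand == h_strand &
               gp$start < h_end & gp$end > h_start, , drop = FALSE]
    if (!nrow(pl)) next
    pl <- pl[1, ]   # one record per (host, fragment)
    if (h_strand == "+") {
      f0 <- pl$start - h_start; f1 <- pl$end - h_start
    } else {
      f0 <- h_end - pl$end; f1 <- h_end - pl$start
    }
    full <- f0 <= 0L && f1 >= h_len
    arm <- if (full) "internal"
      else if (f0 < 0.25 * h_len) "five_prime"
      else if (f1 > 0.75 * h_len) "three_prime"
      else "internal"
    host_key <- aid
    host_class <- sel$class[i]
    if (host_class == "tRNA" && !is.null(trna)) {
      fam <- trna$family[match(aid, trna$name)]
      if (!is.na(fam)) host_key <- fam
    }
    out[[length(out) + 1L]] <- data.frame(
      host_id = host_key, host_class = host_class, fragment = sel$tag[i],
      host_start = f0, host_end = f1, arm = arm, full_length = full,
      length = nchar(sel$tag[i]), count = as.numeric(counts[[sel$tag[i]]]),
      stringsAsFactors = FALSE)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  # a tag matching several copies of a tRNA family counts once per family
  res <- res[!duplicated(res[, c("host_id", "fragment")]), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Dominant fragment of one host
#'
#' Highest-count fragment; ties broken by longer fragment, then
#' lexicographic sequence.
#'
#' @param fragments data.frame from [profile_host_fragments()].
#' @param host_id Host (or tRNA family) id.
#' @return One-row data.frame.
#' @export
dominant_fragment <- function(fragments, host_id) {
  f <- fragments[fragments$host_id == host_id, , drop = FALSE]
  if (!nrow(f)) stop("no fragments recorded for host '", host_id, "'")
  f[order(-f$count, -f$length, f$fragment), , drop = FALSE][1, ]
}

#' Per-member summary of a snoRNA cluster
#'
#' @param fragments data.frame from [profile_host_fragments()].
#' @param members Ordered character vector of host ids in the cluster.
#' @return data.frame with one row per member (zeros when unobserved):
#'   `host_id`, `total_reads`, `n_fragments`, `dominant_fragment`, `arms`.
#' @export
cluster_report <- function(fragments, members) {
  rows <- lapply(members, function(m) {
    f <- fragments[fragments$host_id == m, , drop = FALSE]
    if (!nrow(f))
      return(data.frame(host_id = m, total_reads = 0, n_fragments = 0L,
                        dominant_fragment = NA_character_, arms = "",
                        stringsAsFactors = FALSE))
    dom <- dominant_fragment(fragments, m)
    data.frame(host_id = m, total_reads = sum(f$count),
               n_fragments = nrow(f),
               dominant_fragment = dom$fragment,
               arms = paste(sort(unique(f$arm)), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
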