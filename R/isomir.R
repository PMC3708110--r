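#' Assign hairpin-placed tags to mature/star arms as isomiRs
#'
#' A tag placed on a precursor belongs to an arm when its 5' end lies within
#' `offset_window` nucleotides of that arm's annotated 5' boundary (nearest
#' boundary wins on ties). Offsets are signed relative to the annotated
#' mature interval: `offset5` is negative when the tag is shorter at the 5'
#' end (starts downstream of the mature 5' boundary) and `offset3` negative
#' when shorter at the 3' end; class `sub`/`mature`/`super` follows the sign.
#'
#' @param placements Placements on hairpins from [map_tags()] (kind
#'   `hairpin`).
#' @param catalog A `ref_catalog` (arm intervals from its `hairpins` table).
#' @param counts Named integer vector of reads per tag.
#' @param offset_window Maximum |5' offset| for arm membership, default 5.
#' @return data.frame of isomiR records: `mature_name`, `hairpin`, `tag`,
#'   `arm` (`mature`/`star`), `offset5`, `offset3`, `class5`, `class3`,
#'   `count`. The mature arm is the arm carrying the catalog mature; when
#'   both arms carry catalog matures each is its own `mature` record.
#' @export
assign_isomirs <- function(placements, catalog, counts,
                           offset_window = 5L) {
  hp <- placements[placements$target_kind == "hairpin", , drop = FALSE]
  out <- list()
  hptab <- catalog$hairpins
  for (i in seq_len(nrow(hp))) {
    p <- hp[i, ]
    j <- match(p$target_id, hptab$id)
    if (is.na(j)) next
    arms <- list()
    if (!is.na(hptab$mature5_start[j]))
      arms[["5p"]] <- c(hptab$mature5_start[j], hptab$mature5_end[j])
    if (!is.na(hptab$mature3_start[j]))
      arms[["3p"]] <- c(hptab$mature3_start[j], hptab$mature3_end[j])
    if (!length(arms)) next
    d5 <- vapply(arms, function(a) abs(p$start - a[1]), numeric(1))
    if (min(d5) > offset_window) next
    arm_key <- names(arms)[which.min(d5)]
    a <- arms[[arm_key]]
    nm5 <- hptab$mature5_name[j]; nm3 <- hptab$mature3_name[j]
    arm_name <- if (arm_key == "5p") nm5 else nm3
    # an arm without a named catalog mature is the star arm of the other
    if (is.na(arm_name)) {
      host_mature <- if (arm_key == "5p") nm3 else nm5
      arm_role <- "star"
      mature_name <- host_mature
    } else {
      arm_role <- "mature"
      mature_name <- arm_name
    }
    offset5 <- a[1] - p$start
    offset3 <- p$end - a[2]
    cls <- function(x) if (x == 0) "mature" else if (x < 0) "sub" else "super"
    out[[length(out) + 1L]] <- data.frame(
      mature_name = mature_name, hairpin = p$target_id, tag = p$tag,
      arm = arm_role, offset5 = offset5, offset3 = offset3,
      class5 = cls(offset5), class3 = cls(offset3),
      count = as.numeric(counts[[p$tag]]), stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(mature_name = character(), hairpin = character(),
                      tag = character(), arm = character(),
                      offset5 = integer(), offset3 = integer(),
                      class5 = character(), class3 = character(),
                      count = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  # a tag placed identically on several merged precursors of one mature
  # counts once per mature
  res <- res[!duplicated(res[, c("mature_name", "tag", "arm")]), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Arm profile: mature vs star read totals per miRNA
#'
#' @param isomirs data.frame from [assign_isomirs()].
#' @return data.frame: `mature_name`, `mature_count`, `star_count`,
#'   `star_fraction`.
#' @export
arm_profiles <- function(isomirs) {
  if (!nrow(isomirs))
    return(data.frame(mature_name = character(), mature_count = numeric(),
                      star_count = numeric(), star_fraction = numeric()))
  mats <- unique(isomirs$mature_name)
  m <- vapply(mats, function(x)
    sum(isomirs$count[isomirs$mature_name == x & isomirs$arm == "mature"]),
    numeric(1))
  s <- vapply(mats, function(x)
    sum(isomirs$count[isomirs$mature_name == x & isomirs$arm == "star"]),
    numeric(1))
  data.frame(mature_name = mats, mature_count = m, star_count = s,
             star_fraction = ifelse(m + s > 0, s / (m + s), NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Star-arm read fraction
#'
#' @param mature_count,star_count Read totals on the two arms.
#' @return `star_count / (mature_count + star_count)`.
#' @export
arm_ratio <- function(mature_count, star_count) {
  if (mature_count + star_count <= 0) stop("no reads on either arm")
  star_count / (mature_count + star_count)
}

#' Positional nucleotide variant profile of a mature miRNA
#'
#' Builds a read-weighted base-count matrix over the mature positions from
#' the tags assigned to that miRNA (mature arm, 5' offset 0 so positions
#' align; substitution-only alignment). Positions where the reference base
#' is A additionally report the G fraction, the signature of A-to-I editing.
#'
#' @param isomirs data.frame from [assign_isomirs()] for one mature.
#' @param reference Mature reference sequence (DNA alphabet).
#' @return List: `base_counts` (4 x L matrix, rows ACGT), `a_to_g`
#'   (data.frame `position`, `g_fraction` for reference-A positions).
#' @export
variant_profile <- function(isomirs, reference) {
  reference <- normalize_dna(reference)
  L <- nchar(reference)
  bases <- c("A", "C", "G", "T")
  mat <- matrix(0, 4, L, dimnames = list(bases, NULL))
  rec <- isomirs[isomirs$arm == "mature" & isomirs$offset5 == 0, , drop = FALSE]
  for (i in seq_len(nrow(rec))) {
    tg <- rec$tag[i]
    n <- min(nchar(tg), L)
    bs <- strsplit(substr(tg, 1, n), "")[[1]]
    for (pos in seq_len(n)) {
      if (bs[pos] %in% bases)
        mat[bs[pos], pos] <- mat[bs[pos], pos] + rec$count[i]
    }
  }
  refb <- strsplit(reference, "")[[1]]
  apos <- which(refb == "A")
  tot <- colSums(mat)
  g_frac <- ifelse(tot[apos] > 0, mat["G", apos] / tot[apos], NA_real_)
  list(base_counts = mat,
       a_to_g = data.frame(position = apos, g_fraction = g_frac,
                           row.names = NULL))
}
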