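#' Default pipeline configuration
#'
#' All numeric thresholds of the analysis in one place: adapter and its
#' minimum overlap; the strict length cutoff (> 15 nt); the abundance
#' cutoff (>= 3 reads); per-stage mismatch budgets; the isomiR arm window
#' (5 nt); interval merge gap; the novel-miRNA filter parameters; the RPM
#' denominator mode; and the class precedence.
#'
#' @param adapter 3' adapter sequence.
#' @param ... Overrides for any field.
#' @return A `run_config` list.
#' @export
default_config <- function(adapter = "TCGTATGCCGTCTTCTGCTTG", ...) {
  cfg <- list(adapter = adapter, min_overlap = 6L, min_len = 15L,
              min_count = 3L,
              max_mismatch = c(mature = 1L, hairpin = 1L, genome = 1L),
              offset_window = 5L, merge_gap = 15L,
              discovery = default_discovery_params(),
              denominator_mode = "mirna_mapped",
              precedence = default_precedence(),
              max_candidate_intervals = 50L)
  over <- list(...)
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Run the full small RNA analysis pipeline
#'
#' Executes the fixed stage order: adapter clip -> length filter ->
#' collapse -> abundance filter -> map -> annotate -> isomiR / fragments /
#' discovery -> quantify. Deterministic: the same reads, catalog and config
#' always give the same summary.
#'
#' @param reads Raw read sequences (character vector) or a FASTQ path.
#' @param catalog A `ref_catalog` (see [load_references()] /
#'   [manifest_catalog()]).
#' @param config A `run_config`, see [default_config()].
#' @param foreign Optional named character vector of foreign mature miRNAs
#'   for ortholog detection.
#' @return A `pipeline_result` list: `cascade`, `library`
#'   (`collapsed_library`), `placements`, `classified`, `class_summary`,
#'   `isomirs`, `arm_profiles`, `expression` (RPM table), `length_profile`,
#'   `fragments`, `intervals`, `candidates`, `orthologs`, `families`.
#' @export
run_pipeline <- function(reads, catalog, config = default_config(),
                         foreign = NULL) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_fastq(reads)

  casc <- read_cascade(reads, config$adapter, config$min_len,
                       config$min_count, config$min_overlap)
  lib <- casc$library
  counts <- lib$entries

  mature_refs <- stats::setNames(catalog$mature$sequence, catalog$mature$name)
  hairpin_refs <- stats::setNames(catalog$hairpins$sequence, catalog$hairpins$id)
  targets <- list(mature = mature_refs, hairpin = hairpin_refs)
  if (!is.null(catalog$genome)) targets$genome <- catalog$genome
  placements <- map_tags(lib, targets, max_mismatch = config$max_mismatch)

  classified <- classify_tags(placements, catalog$annotations,
                              tags = names(counts),
                              precedence = config$precedence)
  class_summary <- summarize_classes(classified, counts)

  isomirs <- assign_isomirs(placements, catalog, counts,
                            offset_window = config$offset_window)
  arms <- arm_profiles(isomirs)
  mir_counts <- mirna_counts(isomirs)
  expression <- if (length(mir_counts))
    rpm_table(mir_counts, config$denominator_mode,
              all_mapped_total = sum(class_summary$reads)) else NULL

  fragments <- profile_host_fragments(placements, classified,
                                      catalog$annotations, counts,
                                      trna = catalog$trna)

  un_tags <- classified$tag[classified$class == "unannotated"]
  un_pl <- placements[placements$tag %in% un_tags &
                        placements$target_kind == "genome", , drop = FALSE]
  intervals <- call_intervals(un_pl, counts, merge_gap = config$merge_gap)
  candidates <- NULL
  if (nrow(intervals)) {
    ord <- order(-intervals$read_support)
    use <- intervals[utils::head(ord, config$max_candidate_intervals), ,
                     drop = FALSE]
    candidates <- evaluate_candidates(use, catalog$genome, un_pl, counts,
                                      annotations = catalog$annotations,
                                      params = config$discovery)
  }

  orthologs <- NULL
  if (!is.null(foreign) && length(un_tags))
    orthologs <- find_orthologs(un_tags, catalog$mature$sequence, foreign)

  fam_input <- character(0)
  if (!is.null(candidates) && any(candidates$pass)) {
    pass <- candidates[candidates$pass, , drop = FALSE]
    fam_input <- stats::setNames(pass$dominant_tag,
                                 sprintf("cand-%s:%d", pass$chrom, pass$start))
  }
  families <- assign_families(
    fam_input, stats::setNames(catalog$mature$sequence, catalog$mature$name))

  structure(list(
    cascade = casc$cascade, library = lib, placements = placements,
    classified = classified, class_summary = class_summary,
    isomirs = isomirs, arm_profiles = arms, expression = expression,
    length_profile = length_histogram(lib), fragments = fragments,
    intervals = intervals, candidates = candidates, orthologs = orthologs,
    families = families, config = config), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  c0 <- x$cascade
  cat("small RNA pipeline result\n")
  cat(sprintf("  cascade: %d raw -> %d >%dnt -> %d unique -> %d at >=%d reads (%.1f%% of reads)\n",
              c0$raw, c0$gt_min_len, x$config$min_len, c0$unique,
              c0$unique_filtered, x$config$min_count,
              100 * c0$retained_read_fraction))
  if (nrow(x$class_summary)) {
    mi <- x$class_summary[x$class_summary$class == "miRNA", ]
    if (nrow(mi))
      cat(sprintf("  miRNA reads: %.0f (%.1f%% of annotated)\n",
                  mi$reads, 100 * mi$read_fraction))
  }
  if (!is.null(x$expression) && nrow(x$expression))
    cat(sprintf("  top miRNA: %s (%.1f RPM)\n",
                x$expression$name[1], x$expression$rpm[1]))
  if (!is.null(x$candidates))
    cat(sprintf("  novel candidates passing: %d of %d intervals\n",
                sum(x$candidates$pass), nrow(x$intervals)))
  invisible(x)
}

#' Write pipeline reports to a directory
#'
#' Emits TSVs for the collapsed library, class summary, expression table,
#' isomiRs, fragments and candidates, a BED of candidate loci, and a JSON
#' machine-readable summary.
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory.
#' @export
write_reports <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(d, f) if (!is.null(d) && nrow(d))
    utils::write.table(d, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  write_collapsed_tsv(result$library, file.path(dir, "library.tsv"))
  wtsv(result$class_summary, "class_summary.tsv")
  wtsv(result$expression, "expression.tsv")
  wtsv(result$isomirs, "isomirs.tsv")
  wtsv(result$arm_profiles, "arm_profiles.tsv")
  wtsv(result$fragments, "fragments.tsv")
  wtsv(result$candidates, "candidates.tsv")
  if (!is.null(result$candidates) && any(result$candidates$pass)) {
    p <- result$candidates[result$candidates$pass, ]
    write_bed6(data.frame(chrom = p$chrom, start = p$start, end = p$end,
                          name = sprintf("novel-cand-%d", seq_len(nrow(p))),
                          score = round(p$read_support), strand = p$strand),
               file.path(dir, "candidates.bed"))
  }
  summary <- list(
    schema_version = 1L,
    cascade = result$cascade,
    classes = result$class_summary,
    n_mirna_detected = if (is.null(result$expression)) 0L else
      nrow(result$expression),
    top_mirna = if (is.null(result$expression)) NA else
      result$expression$name[1],
    n_candidates_pass = if (is.null(result$candidates)) 0L else
      sum(result$candidates$pass))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
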