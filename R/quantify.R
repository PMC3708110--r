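#' Reads-per-million expression table
#'
#' Normalizes per-miRNA read counts to reads per million mapped. The default
#' denominator is the total of reads mapped to miRNAs (`mirna_mapped`), the
#' convention under which the most abundant miRNA's RPM times the library
#' total reproduces its read count; `all_mapped` divides by all
#' ncRNA-mapped reads instead.
#'
#' @param counts Named numeric vector: reads per (merged) mature miRNA.
#' @param denominator_mode `"mirna_mapped"` (default) or `"all_mapped"`.
#' @param all_mapped_total Required when `denominator_mode = "all_mapped"`.
#' @return data.frame sorted by decreasing RPM: `name`, `total_reads`,
#'   `rpm` (full precision) and `rpm_1dp` (reported rounding, 1 decimal).
#' @export
rpm_table <- function(counts, denominator_mode = c("mirna_mapped", "all_mapped"),
                      all_mapped_total = NULL) {
  denominator_mode <- match.arg(denominator_mode)
  denom <- switch(denominator_mode,
                  mirna_mapped = sum(counts),
                  all_mapped = all_mapped_total)
  if (is.null(denom) || !is.finite(denom) || denom <= 0)
    stop("RPM denominator must be a positive count")
  rpm <- as.numeric(counts) / denom * 1e6
  out <- data.frame(name = names(counts), total_reads = as.numeric(counts),
                    rpm = rpm, rpm_1dp = round(rpm, 1),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$rpm, out$name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Implied per-million denominator of a printed expression table
#'
#' Given printed (total reads, RPM) pairs, each row constrains the library
#' denominator to the interval consistent with the RPM's printed rounding
#' (1 decimal). Returns the midpoint of the intersection of all row
#' intervals -- the denominator under which re-computed RPMs reproduce every
#' printed value -- together with the row-wise point estimates and their
#' coefficient of variation.
#'
#' @param total_reads,rpm Numeric vectors of equal length.
#' @param digits Printed precision of the RPM column (default 1 decimal).
#' @return List: `denominator`, `row_estimates`, `cv` (sd/mean of row
#'   estimates), `feasible` (TRUE when the row intervals intersect).
#' @export
implied_denominator <- function(total_reads, rpm, digits = 1L) {
  stopifnot(length(total_reads) == length(rpm), all(rpm > 0))
  est <- total_reads / rpm * 1e6
  half <- 0.5 * 10^(-digits)
  lo <- max(total_reads / (rpm + half) * 1e6)
  hi <- min(total_reads / (rpm - half) * 1e6)
  feasible <- lo <= hi
  den <- if (feasible) (lo + hi) / 2 else stats::median(est)
  list(denominator = den, row_estimates = est,
       cv = stats::sd(est) / mean(est), feasible = feasible)
}

#' Fraction of the mapped library contributed by one feature
#'
#' @param count Reads for the feature.
#' @param mapped_total Total mapped reads.
#' @return Percentage (0-100).
#' @export
library_fraction <- function(count, mapped_total) {
  stopifnot(mapped_total > 0)
  100 * count / mapped_total
}

#' qPCR relative expression (2^-dCt)
#'
#' Relative expression of a target against a reference gene from threshold
#' cycles: `2^-(ct_target - ct_reference)`.
#'
#' @param ct_target,ct_reference Threshold cycle values (finite).
#' @return Fold level relative to the reference.
#' @export
relative_expression <- function(ct_target, ct_reference) {
  if (!all(is.finite(ct_target)) || !all(is.finite(ct_reference)))
    stop("threshold cycle values must be finite")
  2^-(ct_target - ct_reference)
}

#' Per-miRNA read totals from isomiR records
#'
#' Sums mature-arm isomiR counts per (merged) mature name: the per-miRNA
#' expression measure feeding [rpm_table()].
#'
#' @param isomirs data.frame from [assign_isomirs()].
#' @param include_star Count star-arm reads too (default FALSE).
#' @return Named numeric vector.
#' @export
mirna_counts <- function(isomirs, include_star = FALSE) {
  rec <- if (include_star) isomirs else
    isomirs[isomirs$arm == "mature", , drop = FALSE]
  if (!nrow(rec)) return(stats::setNames(numeric(0), character(0)))
  tot <- tapply(rec$count, rec$mature_name, sum)
  stats::setNames(as.numeric(tot), names(tot))
}

#' Relative expression for a qPCR measurement table
#'
#' Applies [relative_expression()] row-wise to a table of threshold cycles
#' (columns `target`, `ct_target`, `ct_reference`, optional `replicate`),
#' as read from a plain CSV.
#'
#' @param x data.frame or path to a CSV file.
#' @return The table with `dct` and `fold` (2^-dCt) columns appended.
#' @export
qpcr_table <- function(x) {
  d <- if (is.character(x)) utils::read.csv(x, stringsAsFactors = FALSE) else x
  stopifnot(all(c("target", "ct_target", "ct_reference") %in% names(d)))
  d$dct <- d$ct_target - d$ct_reference
  d$fold <- relative_expression(d$ct_target, d$ct_reference)
  d
}
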