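#' Normalize RNA/DNA sequences to the DNA alphabet
#'
#' U is replaced by T and the sequence upper-cased. All internal work uses
#' the DNA alphabet; miRNA FASTA output converts back to U.
#'
#' @param x Character vector.
#' @export
normalize_dna <- function(x) gsub("U", "T", toupper(x))

#' Seed sequence of a mature miRNA
#'
#' Positions 2-8 (1-based) of the mature sequence: the 7-mer that drives
#' target recognition and defines family membership.
#'
#' @param sequence Mature miRNA sequence(s), length >= 8.
#' @return Character vector of 7-mers (DNA alphabet).
#' @export
seed_of <- function(sequence) {
  s <- normalize_dna(sequence)
  if (any(nchar(s) < 8L)) stop("mature sequence shorter than 8 nt has no seed")
  substr(s, 2L, 8L)
}

#' Load and index the reference universe
#'
#' Builds a catalog from a mature miRNA FASTA, a precursor (hairpin) FASTA,
#' a GFF3 of ncRNA annotations, a genome FASTA and a BED of tRNA genes.
#' Mature miRNAs with identical sequence hosted by several precursors are
#' merged into a single entry whose name joins the precursor-qualified names
#' with "//" in lexicographic order. Coordinates are converted internally to
#' 0-based half-open; GFF3 input is 1-based inclusive and BED 0-based
#' half-open.
#'
#' @param mature_fasta FASTA of mature miRNAs (names `<precursor>` or
#'   `<precursor> <arm>`); sequences may use U or T.
#' @param hairpin_fasta FASTA of precursor hairpins (same ids as the
#'   precursor part of mature names).
#' @param annotation_gff GFF3 with ncRNA features; the feature `type` column
#'   (or a `class=` attribute) gives the ncRNA class.
#' @param genome_fasta Genome FASTA.
#' @param trna_bed Optional BED6 of tRNA genes; the name field is expected to
#'   carry the isotype/anticodon (e.g. `tRNA-Gly-GCC-1`).
#' @param mature_intervals Optional data.frame (`hairpin`, `arm` in
#'   `c("5p","3p")`, `start`, `end`, 0-based half-open within the hairpin)
#'   giving mature/star positions; when absent, intervals are located by
#'   exact search of each mature inside its hairpin.
#' @return A `ref_catalog` list: `mature` (data.frame), `hairpins`
#'   (data.frame), `annotations` (GRanges with `id`, `class`), `genome`
#'   (DNAStringSet), `trna` (data.frame or NULL).
#' @export
load_references <- function(mature_fasta, hairpin_fasta, annotation_gff = NULL,
                            genome_fasta = NULL, trna_bed = NULL,
                            mature_intervals = NULL) {
  mat_raw <- if (is.character(mature_fasta) && length(mature_fasta) == 1L &&
                 file.exists(mature_fasta)) read_fasta(mature_fasta) else mature_fasta
  hp_raw <- if (is.character(hairpin_fasta) && length(hairpin_fasta) == 1L &&
                file.exists(hairpin_fasta)) read_fasta(hairpin_fasta) else hairpin_fasta
  genome <- NULL
  if (!is.null(genome_fasta)) {
    genome <- if (inherits(genome_fasta, "DNAStringSet")) genome_fasta
    else Biostrings::readDNAStringSet(genome_fasta)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }

  mat_seq <- normalize_dna(mat_raw)
  hp_seq <- normalize_dna(hp_raw)

  # merge identical mature sequences across precursors
  prec_of <- sub("\\s.*$", "", names(mat_seq))
  merged <- split(prec_of, mat_seq)
  mature <- data.frame(
    sequence = names(merged),
    name = vapply(merged, function(p) paste(sort(unique(p)), collapse = "//"),
                  character(1)),
    stringsAsFactors = FALSE)
  mature$merged_names <- mature$name
  mature$seed <- seed_of(mature$sequence)
  mature$hosts <- vapply(merged, function(p) paste(sort(unique(p)), collapse = ","),
                         character(1))
  rownames(mature) <- NULL
  mature <- mature[order(mature$name), , drop = FALSE]

  # locate matures inside their host precursors (asserting containment)
  hairpins <- data.frame(id = names(hp_seq), sequence = unname(hp_seq),
                         stringsAsFactors = FALSE)
  loc <- locate_matures(mature, hairpins, mature_intervals)
  mature <- loc$mature
  hairpins <- loc$hairpins

  ann <- NULL
  if (!is.null(annotation_gff)) ann <- read_ncrna_gff(annotation_gff, genome)

  trna <- NULL
  if (!is.null(trna_bed)) {
    trna <- if (is.data.frame(trna_bed)) trna_bed else read_bed6(trna_bed)
    trna$family <- sub("-[0-9]+$", "", trna$name)
  }

  structure(list(mature = mature, hairpins = hairpins, annotations = ann,
                 genome = genome, trna = trna),
            class = "ref_catalog")
}

#' @export
print.ref_catalog <- function(x, ...) {
  cat(sprintf("ref_catalog: %d mature miRNAs, %d hairpins, %d annotations, %s genome\n",
              nrow(x$mature), nrow(x$hairpins),
              if (is.null(x$annotations)) 0L else length(x$annotations),
              if (is.null(x$genome)) "no" else
                sprintf("%d-seq (%d bp)", length(x$genome),
                        sum(Biostrings::width(x$genome)))))
  invisible(x)
}

# Locate every mature inside each host precursor; error if absent.
locate_matures <- function(mature, hairpins, mature_intervals = NULL) {
  hp_idx <- stats::setNames(seq_len(nrow(hairpins)), hairpins$id)
  m5s <- m5e <- m3s <- m3e <- rep(NA_integer_, nrow(hairpins))
  m5name <- m3name <- rep(NA_character_, nrow(hairpins))
  for (i in seq_len(nrow(mature))) {
    hosts <- strsplit(mature$hosts[i], ",")[[1]]
    for (h in hosts) {
      j <- hp_idx[[h]]
      if (is.null(j) || is.na(j)) stop("mature '", mature$name[i],
                                       "' names unknown precursor '", h, "'")
      if (!is.null(mature_intervals)) {
        mi <- mature_intervals[mature_intervals$hairpin == h, , drop = FALSE]
      } else mi <- NULL
      pos <- regexpr(mature$sequence[i], hairpins$sequence[j], fixed = TRUE)
      if (pos < 1L) stop("mature '", mature$name[i],
                         "' not found in precursor '", h, "'")
      start0 <- as.integer(pos) - 1L
      end0 <- start0 + nchar(mature$sequence[i])
      hplen <- nchar(hairpins$sequence[j])
      arm <- if ((start0 + end0) / 2 < hplen / 2) "5p" else "3p"
      if (!is.null(mi) && nrow(mi) > 0L) {
        k <- which(mi$start == start0)
        if (length(k) == 1L) arm <- mi$arm[k]
      }
      if (arm == "5p") { m5s[j] <- start0; m5e[j] <- end0; m5name[j] <- mature$name[i] }
      else { m3s[j] <- start0; m3e[j] <- end0; m3name[j] <- mature$name[i] }
    }
  }
  # fill annotated star/mature intervals provided explicitly but not occupied
  if (!is.null(mature_intervals)) {
    for (r in seq_len(nrow(mature_intervals))) {
      h <- mature_intervals$hairpin[r]
      j <- hp_idx[[h]]
      if (is.null(j) || is.na(j)) next
      if (mature_intervals$arm[r] == "5p" && is.na(m5s[j])) {
        m5s[j] <- mature_intervals$start[r]; m5e[j] <- mature_intervals$end[r]
      } else if (mature_intervals$arm[r] == "3p" && is.na(m3s[j])) {
        m3s[j] <- mature_intervals$start[r]; m3e[j] <- mature_intervals$end[r]
      }
    }
  }
  hairpins$mature5_start <- m5s; hairpins$mature5_end <- m5e
  hairpins$mature3_start <- m3s; hairpins$mature3_end <- m3e
  hairpins$mature5_name <- m5name; hairpins$mature3_name <- m3name
  list(mature = mature, hairpins = hairpins)
}

#' Read an ncRNA GFF3 into a classed GRanges
#'
#' Features are bucketed into the closed class set `miRNA, snoRNA, snRNA,
#' rRNA, tRNA, mt_rRNA, mt_tRNA, miscRNA`; unknown classes raise a warning
#' and fall into `miscRNA`. Coordinates outside the chromosome raise an
#' error naming the record (when a genome is supplied).
#'
#' @param path GFF3 path (or a GRanges already carrying `id` and `class`).
#' @param genome Optional DNAStringSet used to validate coordinates.
#' @return GRanges with metadata columns `id` and `class`.
#' @export
read_ncrna_gff <- function(path, genome = NULL) {
  classes <- c("miRNA", "snoRNA", "snRNA", "rRNA", "tRNA",
               "mt_rRNA", "mt_tRNA", "miscRNA")
  if (inherits(path, "GRanges")) {
    gr <- path
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    mc <- S4Vectors::mcols(gr)
    cls <- if (!is.null(mc$class)) as.character(mc$class) else as.character(mc$type)
    id <- if (!is.null(mc$ID)) as.character(mc$ID)
      else if (!is.null(mc$Name)) as.character(mc$Name)
      else sprintf("feature%d", seq_along(gr))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(id = id, class = cls)
  }
  bad <- !(gr$class %in% classes)
  if (any(bad)) {
    warning("unknown ncRNA class(es) ", paste(unique(gr$class[bad]), collapse = ", "),
            " bucketed as miscRNA")
    gr$class[bad] <- "miscRNA"
  }
  if (!is.null(genome)) {
    lens <- stats::setNames(Biostrings::width(genome), names(genome))
    chr <- as.character(GenomicRanges::seqnames(gr))
    over <- which(chr %in% names(lens) & GenomicRanges::end(gr) > lens[chr])
    if (length(over))
      stop("annotation '", gr$id[over[1]], "' extends beyond chromosome ",
           chr[over[1]])
  }
  gr
}

#' Read a BED6 file
#' @param path BED path.
#' @return data.frame with chrom, start (0-based), end, name, score, strand.
#' @export
read_bed6 <- function(path) {
  d <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(d)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  d
}

#' Write intervals as BED6
#' @param d data.frame with chrom, start, end, name, score, strand.
#' @param path Output path.
#' @export
write_bed6 <- function(d, path) {
  utils::write.table(d[, c("chrom", "start", "end", "name", "score", "strand")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extract the sequence of a genomic interval
#'
#' 0-based half-open coordinates; minus-strand loci are reverse-complemented.
#'
#' @param genome DNAStringSet.
#' @param chrom,start,end,strand Locus.
#' @export
genome_sequence <- function(genome, chrom, start, end, strand = "+") {
  s <- Biostrings::subseq(genome[[chrom]], start + 1L, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}
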