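

# run expr under a private RNG stream seeded with `seed`, restoring the
# caller's stream afterwards
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

rand_dna <- function(len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
}

revcomp <- function(s)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

# dinucleotide shuffle (Altschul-Erickson style via simple repeated swaps
# preserving dinucleotide composition approximately)
dinuc_shuffle <- function(s) {
  b <- strsplit(s, "")[[1]]
  n <- length(b)
  for (it in seq_len(10 * n)) {
    idx <- sort(sample(2:(n - 1), 2))
    i <- idx[1]; j <- idx[2]
    if (i + 1 >= j) next
    # swap-reverse segment keeps many adjacencies
    b[(i):(j)] <- rev(b[(i):(j)])
  }
  paste(b, collapse = "")
}

#' Build the default synthetic study manifest
#'
#' Constructs a toy genome, reference catalog and sampling design emulating
#' the statistical structure of a deep-sequenced endothelial small RNA
#' library: 25 known miRNAs with a strongly skewed abundance distribution
#' (the heaviest carrying ~34% of miRNA reads), per-miRNA isomiR offset
#' distributions with the dominant miRNA's top isomiR one nucleotide short
#' at the 3' end, small star-arm fractions (one miRNA with a prominent
#' ~7.6% star fraction), a positional A-to-G substitution planted at 3% in
#' one miRNA, a 5-member snoRNA cluster whose dominant member sheds a ~28 nt
#' fragment, a 9-copy tRNA family shedding 5' fragments, 3 novel miRNA
#' hairpins, 5 dinucleotide-shuffled decoy loci, and one locus matching a
#' foreign ("human-only") mature miRNA. Hairpins are rejection-sampled until
#' they fold into a single stem-loop at or below -25 kcal/mol under the
#' built-in folder.
#'
#' @param seed Integer seed governing every random choice in construction.
#' @return An `srn_manifest` list; see fields in the source. Includes the
#'   genome (DNAStringSet), annotations (GRanges), mature/hairpin tables,
#'   and the template sampling table (`templates`) with per-template
#'   probabilities.
#' @export
default_manifest <- function(seed = 1L) {
  with_seed(seed, build_manifest_impl(seed))
}

build_manifest_impl <- function(seed) {
  adapter <- "TCGTATGCCGTCTTCTGCTTG"
  stopifnot(!adapter_self_overlaps(adapter, 4L))
  read_length <- 36L
  error_rate <- 0.002

  n_mirna <- 25L
  # relative within-miRNA weights follow a strongly skewed, empirically
  # typical endothelial profile: heaviest ~33.9% of miRNA-mapped reads
  rel <- c(2318344, 1073705, 1014272, 387336, 340689, 258546, 148228,
           112865, 104682, 66479, 61833, 61224, 60052, 55008, 48329,
           45707, 45449, 34754, 33677, 30576, 27688, 27177, 25142, 25078)
  rel <- c(rel, 6846785 - sum(rel))     # tail member aggregates the rest
  rel <- rel / sum(rel)

  # class weights over the whole library (reads, before mapping)
  class_w <- c(miRNA = 0.700, snoRNA = 0.055, tRNA = 0.032, rRNA = 0.007,
               snRNA = 0.004, miscRNA = 0.0038,
               novel = 0.012, decoy = 0.010, foreign = 0.004,
               junk = 0.1822)
  class_w["junk"] <- 1 - sum(class_w[names(class_w) != "junk"])

  # --- mature miRNAs and hairpins -------------------------------------
  fam_seed <- NULL
  matures <- character(n_mirna)
  seeds_used <- character(0)
  for (i in seq_len(n_mirna)) {
    repeat {
      m <- rand_dna(22L, gc = 0.52)
      if (i %in% c(20L, 21L)) {          # planted seed family (2284/2285-like)
        if (is.null(fam_seed)) fam_seed <- substr(m, 2, 8)
        else m <- paste0(substr(m, 1, 1), fam_seed, substr(m, 9, 22))
      }
      if (i == 8L) substr(m, 12, 12) <- "A"   # editing site host
      sd <- substr(m, 2, 8)
      clash <- sd %in% seeds_used && !(i == 21L && sd == fam_seed)
      if (!clash) { seeds_used <- c(seeds_used, sd); matures[i] <- m; break }
    }
  }
  mir_names <- sprintf("smir-%d", seq_len(n_mirna))

  # star arm: reverse complement of the mature with three G.U wobbles at
  # internal positions, as in natural precursors; the wobbles still pair in
  # the fold but put the two arms >1 substitution apart so neither arm maps
  # onto the reverse strand of the other
  wobble_star <- function(mature) {
    b <- strsplit(revcomp(mature), "")[[1]]
    cand <- which(b %in% c("A", "C"))
    cand <- cand[cand > 3L & cand < length(b) - 2L]
    pick <- cand[unique(round(seq(1, length(cand), length.out = 3)))]
    b[pick] <- ifelse(b[pick] == "A", "G", "T")
    paste(b, collapse = "")
  }
  build_hairpin <- function(mature) {
    for (try in 1:60) {
      f5 <- rand_dna(6L); f3 <- rand_dna(6L)
      loop <- paste0(rand_dna(3L, gc = 0.2), "TTCG", rand_dna(3L, gc = 0.2))
      hp <- paste0(f5, mature, loop, wobble_star(mature), f3)
      fold <- fold_hairpin(hp)
      m0 <- 6L; m1 <- 6L + 22L
      if (fold$n_hairpin_loops == 1L && fold$mfe <= -25 &&
          pairing_fraction(fold, m0, m1) >= 0.75 &&
          on_single_arm(fold, m0, m1)) {
        # star with 2-nt 3' overhangs: starts 2 nt into the 3' arm
        star_start <- nchar(f5) + 22L + nchar(loop) + 2L
        return(list(sequence = hp, mature_start = m0, mature_end = m1,
                    star_start = star_start, star_end = star_start + 22L,
                    mfe = fold$mfe))
      }
    }
    stop("failed to construct a folding hairpin after 60 attempts")
  }
  hp <- lapply(matures, build_hairpin)
  # one mature hosted by two distinct precursors (merged "a//b" naming)
  dup_idx <- n_mirna
  hp2 <- build_hairpin(matures[dup_idx])
  hairpin_ids <- c(sprintf("smir-%d", seq_len(n_mirna - 1L)),
                   sprintf("smir-%da", n_mirna))
  hairpin_ids <- c(hairpin_ids, sprintf("smir-%db", n_mirna))
  hp <- c(hp, list(hp2))
  mir_names[dup_idx] <- sprintf("smir-%da//smir-%db", n_mirna, n_mirna)

  # --- snoRNA cluster --------------------------------------------------
  sno_n <- 5L
  sno_seqs <- vapply(seq_len(sno_n), function(i) rand_dna(75L, gc = 0.48),
                     character(1))
  sno_ids <- sprintf("SNOsim-%d", seq_len(sno_n))
  sno_rel <- c(0.06, 0.08, 0.62, 0.14, 0.10)   # member 3 dominant (U78-like)
  # fragments: each member sheds a 3'-arm (major) and 5'-arm (minor) product
  sno_frag <- lapply(seq_len(sno_n), function(i) {
    L <- nchar(sno_seqs[i])
    list(three = list(start = L - 28L, end = L, w = 0.7),
         five = list(start = 0L, end = 29L, w = 0.3))
  })

  # --- tRNA family -----------------------------------------------------
  trna_gly <- rand_dna(72L, gc = 0.55)
  trna_other <- c(rand_dna(72L, gc = 0.55), rand_dna(72L, gc = 0.55))
  trna_rel <- c(gly30 = 0.55, gly28 = 0.25, t2 = 0.12, t3 = 0.08)

  # --- other annotated hosts ------------------------------------------
  rrna_host <- rand_dna(160L, gc = 0.55)
  snrna_host <- rand_dna(120L, gc = 0.45)
  misc_host <- rand_dna(140L, gc = 0.5)

  # --- novel hairpins, decoys, foreign locus --------------------------
  novel_mat <- character(3L)
  for (i in 1:3) {
    repeat {
      m <- rand_dna(22L, gc = 0.52)
      if (i <= 2L) m <- paste0(substr(m, 1, 1), fam_seed, substr(m, 9, 22))
      if (!(substr(m, 2, 8) %in% seeds_used) || i <= 2L) break
    }
    novel_mat[i] <- m
  }
  novel_hp <- lapply(novel_mat, build_hairpin)
  decoy_seqs <- vapply(1:5, function(i) dinuc_shuffle(rand_dna(22L, gc = 0.52)),
                       character(1))
  foreign_mat <- rand_dna(22L, gc = 0.5)
  foreign_name <- "hsa-sim-miR-F1"

  # --- genome assembly -------------------------------------------------
  spacer <- function(n) rand_dna(n, gc = 0.42)
  place <- function(parts) {
    # parts: list of list(id=, seq=, keep=TRUE/FALSE); returns chrom string +
    # locus table
    loci <- list(); cur <- 0L; segs <- character(0)
    for (p in parts) {
      sp <- spacer(80L + sample(0:60, 1))
      segs <- c(segs, sp); cur <- cur + nchar(sp)
      if (!is.null(p$id))
        loci[[length(loci) + 1L]] <- data.frame(
          id = p$id, start = cur, end = cur + nchar(p$seq),
          stringsAsFactors = FALSE)
      segs <- c(segs, p$seq); cur <- cur + nchar(p$seq)
    }
    segs <- c(segs, spacer(100L))
    list(seq = paste(segs, collapse = ""), loci = do.call(rbind, loci))
  }

  chr1 <- place(lapply(seq_along(hp), function(i)
    list(id = hairpin_ids[i], seq = hp[[i]]$sequence)))
  parts2 <- c(
    lapply(seq_len(sno_n), function(i) list(id = sno_ids[i], seq = sno_seqs[i])),
    lapply(1:9, function(i) list(id = sprintf("tRNA-Gly-GCC-%d", i),
                                 seq = trna_gly)),
    list(list(id = "tRNA-Asp-GTC-1", seq = trna_other[1]),
         list(id = "tRNA-Glu-CTC-1", seq = trna_other[2]),
         list(id = "rRNAsim-1", seq = rrna_host),
         list(id = "snRNAsim-1", seq = snrna_host),
         list(id = "miscsim-1", seq = misc_host)))
  chr2 <- place(parts2)
  parts3 <- c(
    lapply(1:3, function(i) list(id = sprintf("novel-%d", i),
                                 seq = novel_hp[[i]]$sequence)),
    lapply(1:5, function(i) list(id = sprintf("decoy-%d", i),
                                 seq = decoy_seqs[i])),
    list(list(id = "foreign-locus", seq = foreign_mat)))
  chr3 <- place(parts3)

  genome <- Biostrings::DNAStringSet(c(chr1 = chr1$seq, chr2 = chr2$seq,
                                       chr3 = chr3$seq))

  locus_of <- function(tab, id) tab[tab$id == id, , drop = FALSE]

  # --- annotations -----------------------------------------------------
  ann_rows <- list()
  add_ann <- function(chrom, tab, id, class) {
    l <- locus_of(tab, id)
    ann_rows[[length(ann_rows) + 1L]] <<- data.frame(
      chrom = chrom, start = l$start, end = l$end, id = id, class = class,
      strand = "+", stringsAsFactors = FALSE)
  }
  for (i in seq_along(hairpin_ids)) add_ann("chr1", chr1$loci, hairpin_ids[i], "miRNA")
  for (i in seq_len(sno_n)) add_ann("chr2", chr2$loci, sno_ids[i], "snoRNA")
  for (i in 1:9) add_ann("chr2", chr2$loci, sprintf("tRNA-Gly-GCC-%d", i), "tRNA")
  add_ann("chr2", chr2$loci, "tRNA-Asp-GTC-1", "tRNA")
  add_ann("chr2", chr2$loci, "tRNA-Glu-CTC-1", "tRNA")
  add_ann("chr2", chr2$loci, "rRNAsim-1", "rRNA")
  add_ann("chr2", chr2$loci, "snRNAsim-1", "snRNA")
  add_ann("chr2", chr2$loci, "miscsim-1", "miscRNA")
  ann <- do.call(rbind, ann_rows)
  annotations <- GenomicRanges::GRanges(
    ann$chrom, IRanges::IRanges(ann$start + 1L, ann$end), strand = ann$strand,
    id = ann$id, class = ann$class)

  trna_tab <- ann[grepl("^tRNA-", ann$id), , drop = FALSE]
  trna_tab <- data.frame(chrom = trna_tab$chrom, start = trna_tab$start,
                         end = trna_tab$end, name = trna_tab$id, score = 0L,
                         strand = trna_tab$strand,
                         family = sub("-[0-9]+$", "", trna_tab$id),
                         stringsAsFactors = FALSE)

  # --- isomiR distributions -------------------------------------------
  iso_default <- list(o5 = c(0, 0, 0, 0, -1, 1),
                      o3 = c(0, -1, 1, -2, 0, 0),
                      p = c(0.55, 0.20, 0.10, 0.05, 0.05, 0.05))
  iso_by_mirna <- rep(list(iso_default), n_mirna)
  iso_by_mirna[[1]] <- list(o5 = c(0, 0, 0, 0, -1),
                            o3 = c(-1, 0, -2, 1, 0),
                            p = c(0.45, 0.30, 0.12, 0.08, 0.05))
  iso_by_mirna[[3]] <- list(o5 = c(-1, 0, 0, 0),
                            o3 = c(0, 0, -1, 1),
                            p = c(0.45, 0.35, 0.15, 0.05))
  star_frac <- rep(0.01, n_mirna)
  star_frac[1] <- 27 / (2318344 + 27)
  star_frac[3] <- 83798 / (1014272 + 83798)

  editing <- list(mirna = 8L, position = 12L, fraction = 0.03)

  # --- template table --------------------------------------------------
  tmpl <- list()
  add_tmpl <- function(group, feature, seq, prob, meta = NA_character_) {
    tmpl[[length(tmpl) + 1L]] <<- data.frame(
      group = group, feature = feature, sequence = seq, prob = prob,
      meta = meta, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_mirna)) {
    h <- hp[[i]]
    d <- iso_by_mirna[[i]]
    w_mat <- class_w[["miRNA"]] * rel[i] * (1 - star_frac[i])
    for (k in seq_along(d$p)) {
      s0 <- h$mature_start - d$o5[k]   # offset5 = mature_start - tag_start
      s1 <- h$mature_end + d$o3[k]
      seqk <- substr(h$sequence, s0 + 1L, s1)
      add_tmpl("miRNA", mir_names[i], seqk, w_mat * d$p[k],
               meta = sprintf("o5=%d;o3=%d", d$o5[k], d$o3[k]))
    }
    star_seq <- substr(h$sequence, h$star_start + 1L, h$star_end)
    add_tmpl("miRNA_star", mir_names[i], star_seq,
             class_w[["miRNA"]] * rel[i] * star_frac[i])
  }
  for (i in seq_len(sno_n)) {
    fr <- sno_frag[[i]]
    add_tmpl("snoRNA", sno_ids[i],
             substr(sno_seqs[i], fr$three$start + 1L, fr$three$end),
             class_w[["snoRNA"]] * sno_rel[i] * fr$three$w, meta = "arm=3p")
    add_tmpl("snoRNA", sno_ids[i],
             substr(sno_seqs[i], fr$five$start + 1L, fr$five$end),
             class_w[["snoRNA"]] * sno_rel[i] * fr$five$w, meta = "arm=5p")
  }
  add_tmpl("tRNA", "tRNA-Gly-GCC", substr(trna_gly, 1, 30),
           class_w[["tRNA"]] * trna_rel[["gly30"]], meta = "arm=5p")
  add_tmpl("tRNA", "tRNA-Gly-GCC", substr(trna_gly, 1, 28),
           class_w[["tRNA"]] * trna_rel[["gly28"]], meta = "arm=5p")
  add_tmpl("tRNA", "tRNA-Asp-GTC", substr(trna_other[1], 1, 30),
           class_w[["tRNA"]] * trna_rel[["t2"]], meta = "arm=5p")
  add_tmpl("tRNA", "tRNA-Glu-CTC", substr(trna_other[2], 1, 30),
           class_w[["tRNA"]] * trna_rel[["t3"]], meta = "arm=5p")
  add_tmpl("rRNA", "rRNAsim-1", substr(rrna_host, 61, 82), class_w[["rRNA"]])
  add_tmpl("snRNA", "snRNAsim-1", substr(snrna_host, 41, 62), class_w[["snRNA"]])
  add_tmpl("miscRNA", "miscsim-1", substr(misc_host, 51, 72), class_w[["miscRNA"]])
  for (i in 1:3) {
    h <- novel_hp[[i]]
    w <- class_w[["novel"]] / 3
    add_tmpl("novel", sprintf("novel-%d", i),
             substr(h$sequence, h$mature_start + 1L, h$mature_end), w * 0.80)
    add_tmpl("novel", sprintf("novel-%d", i),
             substr(h$sequence, h$mature_start + 1L, h$mature_end - 1L), w * 0.10)
    add_tmpl("novel_star", sprintf("novel-%d", i),
             substr(h$sequence, h$star_start + 1L, h$star_end), w * 0.10)
  }
  for (i in 1:5)
    add_tmpl("decoy", sprintf("decoy-%d", i), decoy_seqs[i],
             class_w[["decoy"]] / 5)
  add_tmpl("foreign", foreign_name, foreign_mat, class_w[["foreign"]])
  templates <- do.call(rbind, tmpl)
  # scale template probs so that, together with junk, everything sums to 1
  templates$prob <- templates$prob / sum(templates$prob) * (1 - class_w[["junk"]])

  mature_tab <- data.frame(name = mir_names, sequence = matures,
                           stringsAsFactors = FALSE)
  hairpin_tab <- data.frame(
    id = hairpin_ids,
    sequence = vapply(hp, `[[`, character(1), "sequence"),
    mature_start = vapply(hp, `[[`, integer(1), "mature_start"),
    mature_end = vapply(hp, `[[`, integer(1), "mature_end"),
    star_start = vapply(hp, `[[`, integer(1), "star_start"),
    star_end = vapply(hp, `[[`, integer(1), "star_end"),
    stringsAsFactors = FALSE)
  novel_tab <- data.frame(
    id = sprintf("novel-%d", 1:3), mature = novel_mat,
    sequence = vapply(novel_hp, `[[`, character(1), "sequence"),
    chrom = "chr3",
    start = vapply(1:3, function(i)
      locus_of(chr3$loci, sprintf("novel-%d", i))$start, numeric(1)),
    end = vapply(1:3, function(i)
      locus_of(chr3$loci, sprintf("novel-%d", i))$end, numeric(1)),
    stringsAsFactors = FALSE)
  decoy_tab <- data.frame(
    id = sprintf("decoy-%d", 1:5), sequence = decoy_seqs, chrom = "chr3",
    start = vapply(1:5, function(i)
      locus_of(chr3$loci, sprintf("decoy-%d", i))$start, numeric(1)),
    end = vapply(1:5, function(i)
      locus_of(chr3$loci, sprintf("decoy-%d", i))$end, numeric(1)),
    stringsAsFactors = FALSE)

  structure(list(
    seed = seed, adapter = adapter, read_length = read_length,
    error_rate = error_rate, class_weights = class_w,
    mirna = mature_tab, mirna_rel = rel, hairpins = hairpin_tab,
    iso_by_mirna = stats::setNames(iso_by_mirna, mir_names),
    star_fractions = stats::setNames(star_frac, mir_names),
    editing = editing,
    sno_ids = sno_ids, sno_sequences = sno_seqs, sno_rel = sno_rel,
    trna = trna_tab, genome = genome, annotations = annotations,
    novel = novel_tab, decoys = decoy_tab,
    foreign = stats::setNames(foreign_mat, foreign_name),
    family_seed = fam_seed,
    templates = templates), class = "srn_manifest")
}

# TRUE if the adapter equals a shift of itself over >= k overlapping
# positions (a periodic adapter would make exact clipping ambiguous)
adapter_self_overlaps <- function(adapter, k = 4L) {
  n <- nchar(adapter)
  for (sh in seq_len(n - k)) {
    if (substr(adapter, 1L, n - sh) == substr(adapter, sh + 1L, n))
      return(TRUE)
  }
  FALSE
}

#' @export
print.srn_manifest <- function(x, ...) {
  cat(sprintf(paste0("srn_manifest (seed %d): %d miRNAs, %d hairpins, ",
                     "%d-member snoRNA cluster, %d templates, genome %d bp\n"),
              x$seed, nrow(x$mirna), nrow(x$hairpins), length(x$sno_ids),
              nrow(x$templates), sum(Biostrings::width(x$genome))))
  invisible(x)
}

#' Reference catalog of a synthetic manifest
#'
#' @param manifest An `srn_manifest`.
#' @return A `ref_catalog` built from the manifest's matures, hairpins,
#'   annotations, genome and tRNA table.
#' @export
manifest_catalog <- function(manifest) {
  # expand merged names: one FASTA record per hosting precursor
  recs <- list()
  for (i in seq_len(nrow(manifest$mirna))) {
    hosts <- strsplit(manifest$mirna$name[i], "//", fixed = TRUE)[[1]]
    for (h in hosts) recs[[h]] <- manifest$mirna$sequence[i]
  }
  mature_fa <- unlist(recs)
  hp_fa <- stats::setNames(manifest$hairpins$sequence, manifest$hairpins$id)
  mi <- rbind(
    data.frame(hairpin = manifest$hairpins$id, arm = "5p",
               start = manifest$hairpins$mature_start,
               end = manifest$hairpins$mature_end, stringsAsFactors = FALSE),
    data.frame(hairpin = manifest$hairpins$id, arm = "3p",
               start = manifest$hairpins$star_start,
               end = manifest$hairpins$star_end, stringsAsFactors = FALSE))
  load_references(mature_fa, hp_fa, manifest$annotations, manifest$genome,
                  manifest$trna, mature_intervals = mi)
}

#' Simulate a small RNA sequencing library from a manifest
#'
#' Draws reads from the manifest's template distribution, applies the
#' planted A-to-G editing, adds per-base substitution errors to the insert,
#' appends the adapter (reads are a fixed `read_length`, padded with A past
#' the adapter for very short inserts), and returns the reads together with
#' a realized ground truth: per-template sampled counts and the expected
#' read-processing cascade computed by direct accounting of the sampled
#' inserts.
#'
#' @param manifest An `srn_manifest`.
#' @param n_reads Number of reads.
#' @param seed Integer seed for the sampling stream.
#' @return List: `reads` (character), `truth` (list with `template_counts`,
#'   `insert_lengths`, `cascade` = list(raw, gt_min_len, unique,
#'   unique_filtered, retained_read_fraction), `mirna_expected` named reads
#'   per miRNA sampled on the mature arm).
#' @export
simulate_reads <- function(manifest, n_reads, seed = manifest$seed) {
  with_seed(seed + 1000003L, {
    tm <- manifest$templates
    p_junk <- unname(manifest$class_weights[["junk"]])
    probs <- c(tm$prob, p_junk)
    draw <- sample.int(length(probs), n_reads, replace = TRUE, prob = probs)
    is_junk <- draw > nrow(tm)
    inserts <- character(n_reads)
    inserts[!is_junk] <- tm$sequence[draw[!is_junk]]
    n_junk <- sum(is_junk)
    if (n_junk) {
      junk_pool <- vapply(1:40, function(i) rand_dna(7L, gc = 0.8),
                          character(1))
      inserts[is_junk] <- sample(junk_pool, n_junk, replace = TRUE)
    }

    # planted A-to-G editing on the edited miRNA's transcript position
    ed <- manifest$editing
    ed_name <- manifest$mirna$name[ed$mirna]
    ed_rows <- which(tm$group == "miRNA" & tm$feature == ed_name)
    ed_sel <- which(!is_junk & draw %in% ed_rows)
    if (length(ed_sel)) {
      # position of the edit inside each template (offset5 shifts it)
      o5 <- as.integer(sub("^o5=(-?[0-9]+);.*$", "\\1", tm$meta[draw[ed_sel]]))
      pos_in_tag <- ed$position + o5
      cover <- pos_in_tag >= 1L & pos_in_tag <= nchar(inserts[ed_sel])
      flip <- stats::runif(length(ed_sel)) < ed$fraction
      mod <- ed_sel[cover & flip]
      pos_mod <- pos_in_tag[cover & flip]
      if (length(mod))
        substr(inserts[mod], pos_mod, pos_mod) <- "G"
    }

    # sequencing errors: per-base substitutions within the insert
    L <- nchar(inserts)
    nerr <- stats::rbinom(n_reads, L, manifest$error_rate)
    for (i in which(nerr > 0L)) {
      pos <- sample.int(L[i], nerr[i])
      b <- strsplit(inserts[i], "")[[1]]
      for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1L)
      inserts[i] <- paste(b, collapse = "")
    }

    reads <- substr(paste0(inserts, manifest$adapter,
                           strrep("A", manifest$read_length)),
                    1L, manifest$read_length)
    names(reads) <- sprintf("sim%d", seq_len(n_reads))

    # realized truth by direct accounting of the sampled inserts
    keep <- L > 15L
    tab <- table(inserts[keep])
    template_counts <- tabulate(draw, nbins = nrow(tm) + 1L)[seq_len(nrow(tm))]
    mature_rows <- tm$group == "miRNA"
    mirna_expected <- tapply(template_counts[mature_rows],
                             tm$feature[mature_rows], sum)
    truth <- list(
      template_counts = stats::setNames(template_counts,
                                        paste(tm$feature, tm$meta, sep = "|")),
      insert_lengths = L,
      cascade = list(raw = n_reads,
                     gt_min_len = sum(keep),
                     unique = length(tab),
                     unique_filtered = sum(tab >= 3L),
                     retained_read_fraction = sum(tab[tab >= 3L]) / sum(tab)),
      mirna_expected = stats::setNames(as.numeric(mirna_expected),
                                       names(mirna_expected)))
    list(reads = reads, truth = truth)
  })
}

#' Write a manifest's reference files to a directory
#'
#' Emits `genome.fa`, `mature.fa` (U alphabet), `hairpin.fa`,
#' `annotations.gff3`, `trna.bed` and `manifest.json` (design parameters;
#' sequences included so the manifest round-trips).
#'
#' @param manifest An `srn_manifest`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference_files <- function(manifest, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(manifest$genome, file.path(dir, "genome.fa"))
  # one record per hosting precursor; merged naming is rebuilt at load
  recs <- list()
  for (i in seq_len(nrow(manifest$mirna))) {
    hosts <- strsplit(manifest$mirna$name[i], "//", fixed = TRUE)[[1]]
    for (h in hosts) recs[[h]] <- gsub("T", "U", manifest$mirna$sequence[i])
  }
  writeLines(paste0(">", names(recs), "\n", unlist(recs)),
             file.path(dir, "mature.fa"))
  write_fasta(stats::setNames(manifest$hairpins$sequence,
                              manifest$hairpins$id),
              file.path(dir, "hairpin.fa"))
  gr <- manifest$annotations
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   src = "srnatlas", type = gr$class,
                   start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
                   score = ".", strand = as.character(GenomicRanges::strand(gr)),
                   phase = ".", attr = sprintf("ID=%s;class=%s", gr$id, gr$class))
  writeLines(c("##gff-version 3",
               do.call(sprintf, c(list("%s\t%s\t%s\t%d\t%d\t%s\t%s\t%s\t%s"),
                                  df))),
             file.path(dir, "annotations.gff3"))
  write_bed6(manifest$trna, file.path(dir, "trna.bed"))
  design <- manifest[c("seed", "adapter", "read_length", "error_rate",
                       "class_weights", "mirna_rel", "star_fractions",
                       "editing", "sno_rel", "family_seed")]
  jsonlite::write_json(design, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
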