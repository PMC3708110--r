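test_that("interval calling merges by strand and gap", {
  pl <- rbind(
    data.frame(tag = "t1", target_kind = "genome", target_id = "chr1",
               start = 100L, end = 122L, strand = "+", mismatches = 0L),
    data.frame(tag = "t2", target_kind = "genome", target_id = "chr1",
               start = 112L, end = 134L, strand = "+", mismatches = 0L),
    data.frame(tag = "t3", target_kind = "genome", target_id = "chr1",
               start = 112L, end = 134L, strand = "-", mismatches = 0L))
  iv <- call_intervals(pl, c(t1 = 10, t2 = 30, t3 = 5))
  expect_equal(nrow(iv), 2L)            # same-strand overlap merges; strands split
  plus <- iv[iv$strand == "+", ]
  expect_equal(plus$start, 100L)
  expect_equal(plus$end, 134L)
  expect_equal(plus$read_support, 40)
  expect_equal(plus$dominant_tag, "t2")

  # gap larger than merge_gap stays split
  pl2 <- pl[1:2, ]; pl2$start[2] <- 150L; pl2$end[2] <- 172L
  expect_equal(nrow(call_intervals(pl2, c(t1 = 1, t2 = 1), merge_gap = 10L)),
               2L)
})

test_that("candidate filters enforce each criterion independently", {
  man <- shared_manifest()
  cat <- shared_catalog()
  nv <- man$novel[1, ]
  frame_iv <- function(support, len = 22L) {
    tag <- substr(nv$sequence,
                  man$hairpins$mature_start[1] + 1L,
                  man$hairpins$mature_start[1] + len)
    # dominant tag of the planted novel hairpin at its genomic locus
    tag <- substr(genome_sequence(cat$genome, nv$chrom, nv$start, nv$end),
                  7L, 6L + len)
    data.frame(chrom = nv$chrom, start = nv$start + 6L,
               end = nv$start + 6L + len, strand = "+",
               read_support = support, dominant_tag = tag,
               dominant_length = len, stringsAsFactors = FALSE)
  }
  iv <- frame_iv(150)
  fr <- fold_candidate_frame(iv, cat$genome)
  ok <- filter_candidate(iv, fr, cat$annotations)
  expect_true(ok$pass)
  expect_true(ok$ok_mfe && ok$ok_single_hairpin && ok$ok_pairing)

  # insufficient read support fails only that criterion
  low <- filter_candidate(frame_iv(50), fr, cat$annotations)
  expect_false(low$pass)
  expect_false(low$ok_support)
  expect_true(low$ok_len && low$ok_mfe)

  # sno-like length fails the size criterion
  iv28 <- frame_iv(150); iv28$dominant_length <- 28L
  len28 <- filter_candidate(iv28, fr, cat$annotations)
  expect_false(len28$pass)
  expect_false(len28$ok_len)

  # an annotated locus fails the overlap criterion
  ann_iv <- iv
  ann_iv$chrom <- "chr1"
  l1 <- cat$hairpins$id[1]
  gr1 <- cat$annotations[cat$annotations$id == l1]
  ann_iv$start <- BiocGenerics::start(gr1)[1] + 5L
  ann_iv$end <- ann_iv$start + 22L
  fr1 <- fold_candidate_frame(ann_iv, cat$genome)
  annh <- filter_candidate(ann_iv, fr1, cat$annotations)
  expect_false(annh$ok_unannotated)
})

test_that("weakening thresholds never turns a pass into a fail (monotone)", {
  run <- shared_run()
  cat <- shared_catalog()
  iv <- run$res$intervals
  iv <- iv[order(-iv$read_support), ][seq_len(min(6, nrow(iv))), ]
  base <- default_discovery_params()
  weaker <- base
  weaker$min_reads <- 10; weaker$mfe_max <- -10
  weaker$pairing_min <- 0.5; weaker$len_range <- c(18L, 26L)
  for (i in seq_len(nrow(iv))) {
    fr <- fold_candidate_frame(iv[i, ], cat$genome, base)
    p1 <- filter_candidate(iv[i, ], fr, cat$annotations, base)
    p2 <- filter_candidate(iv[i, ], fr, cat$annotations, weaker)
    if (p1$pass) expect_true(p2$pass)
  }
})

test_that("star support distinguishes two-arm from one-arm candidates", {
  run <- shared_run()
  res <- run$res
  man <- run$man
  cand <- res$candidates
  for (i in 1:3) {
    nv <- man$novel[i, ]
    row <- cand[cand$chrom == nv$chrom & cand$start < nv$end &
                  cand$end > nv$start, ]
    expect_equal(nrow(row), 1L)
    expect_equal(row$tier, "star_supported")  # star reads are planted
    expect_gt(row$star_reads, 0)
  }
  # decoys have no opposite-arm reads
  for (i in 1:5) {
    dc <- man$decoys[i, ]
    row <- cand[cand$chrom == dc$chrom & cand$start < dc$end &
                  cand$end > dc$start, ]
    if (nrow(row)) expect_equal(row$star_reads, 0)
  }
})

test_that("ortholog detection matches foreign matures and spares native ones", {
  native <- c("TAGCTTATCAGACTGATGTTGA")
  foreign <- c(hsa1 = "ACCCGTAGATCCGAACTTGTGA")
  # exact foreign match
  hit <- find_orthologs("ACCCGTAGATCCGAACTTGTGA", native, foreign)
  expect_equal(hit$ortholog_of, "hsa1")
  expect_equal(hit$mismatches, 0L)
  # native tag excluded
  expect_equal(nrow(find_orthologs(native, native, foreign)), 0L)
  # seed mismatch disqualifies
  seedmut <- "AGCCGTAGATCCGAACTTGTGA"   # position 2 differs
  expect_equal(nrow(find_orthologs(seedmut, native, foreign)), 0L)
  # 3'-end mismatches within budget still match
  tailmut <- "ACCCGTAGATCCGAACTTGTCT"
  expect_equal(find_orthologs(tailmut, native, foreign)$mismatches, 2L)
})

test_that("the planted foreign-only mature is recovered as an ortholog", {
  run <- shared_run()
  ort <- run$res$orthologs
  expect_true(!is.null(ort) && nrow(ort) >= 1L)
  expect_true(names(run$man$foreign) %in% ort$ortholog_of)
  best <- ort[ort$mismatches == 0, ]
  expect_equal(best$tag[1], unname(run$man$foreign))
})

test_that("seed families group candidates with known members", {
  known <- c(kA = "TAGCTTATCAGACTGATGTTGA",
             kB = "TAGGTTATCAGACTGATGTTGA")   # seed differs at one base
  cands <- c(c1 = "AAGCTTATCAGACTGATGAAAA",   # same seed as kA
             c2 = "CAGCTTATCAGACTGATGCCCC",   # same seed as kA
             c3 = "GCCGGTATCGGACTGATGTTGA")   # novel seed
  fam <- assign_families(cands, known)
  expect_equal(fam$family[fam$name == "c1"], "kA")
  expect_equal(fam$family[fam$name == "c2"], "kA")
  expect_equal(fam$family[fam$name == "kA"], "kA")
  expect_match(fam$family[fam$name == "c3"], "^FAM-")
  # seeds differing at one base split families
  expect_false(fam$family[fam$name == "kB"] == fam$family[fam$name == "kA"])
})

test_that("the planted seed family is recovered as one 4-member group", {
  man <- shared_manifest()
  known <- stats::setNames(man$mirna$sequence, man$mirna$name)
  novel <- stats::setNames(man$novel$mature, man$novel$id)
  fam <- assign_families(novel, known)
  members <- fam$name[fam$seed == man$family_seed]
  expect_equal(length(members), 4L)   # two known + two novel share the seed
  expect_equal(length(unique(fam$family[fam$seed == man$family_seed])), 1L)
})
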