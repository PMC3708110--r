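adapter <- "TCGTATGCCGTCTTCTGCTTG"

test_that("adapter clipping recovers the insert in the exact-concatenation case", {
  insert <- "ACGTACGTACGTACGTACGTAC"
  r <- clip_adapter(paste0(insert, adapter), adapter)
  expect_true(r$found)
  expect_equal(r$sequence, insert)

  # partial adapter at the 3' end, down to min_overlap
  r2 <- clip_adapter(paste0(insert, substr(adapter, 1, 7)), adapter,
                     min_overlap = 6L)
  expect_true(r2$found)
  expect_equal(r2$sequence, insert)

  # a 7-nt GC-rich insert is clipped to 7 nt (removed later by the length
  # filter, not here)
  r3 <- clip_adapter(paste0("GCCGGGC", adapter), adapter)
  expect_equal(nchar(r3$sequence), 7L)
})

test_that("reads without the adapter are left unchanged", {
  r <- clip_adapter("AAAACCCCGGGGTTTT", adapter)
  expect_false(r$found)
  expect_equal(r$sequence, "AAAACCCCGGGGTTTT")
})

test_that("clipping rejects degenerate inputs", {
  expect_error(clip_adapter("", adapter))
  expect_error(clip_adapter("ACGT", ""))
  expect_error(clip_adapter("ACGT", "ACG", min_overlap = 5L))
})

test_that("clipping is idempotent when the adapter is absent from inserts", {
  set.seed(101)
  inserts <- random_dna(50, 22)
  inserts <- inserts[!grepl(substr(adapter, 1, 6), paste0(inserts, "x"))]
  reads <- paste0(inserts, adapter)
  once <- clip_adapter(reads, adapter)
  twice <- clip_adapter(once$sequence, adapter)
  expect_false(any(twice$found))
  expect_equal(twice$sequence, once$sequence)
})

test_that("length filter retains strictly longer sequences only", {
  reads <- c(strrep("A", 15), strrep("C", 15), strrep("G", 16))
  expect_equal(length_filter(reads, 15L), strrep("G", 16))
  expect_equal(length_filter(character(0), 15L), character(0))
  expect_equal(length_filter(reads, 0L), reads)

  lib <- collapse_reads(reads)
  flib <- length_filter(lib, 15L)
  expect_equal(names(flib$entries), strrep("G", 16))
  expect_match(tail(flib$provenance, 1), "length>15")
})

test_that("collapsing counts exact multiplicities, order-independently", {
  lib <- collapse_reads(c("AAAC", "AAAC", "GGGT"))
  expect_equal(lib$entries[["AAAC"]], 2L)
  expect_equal(lib$entries[["GGGT"]], 1L)

  expect_equal(length(collapse_reads(character(0))$entries), 0L)

  lib10 <- collapse_reads(rep("ACGTACGT", 10))
  expect_equal(unname(lib10$entries), 10L)

  set.seed(7)
  reads <- sample(random_dna(20, 20), 200, replace = TRUE)
  a <- collapse_reads(reads)
  b <- collapse_reads(sample(reads))
  expect_equal(a$entries[order(names(a$entries))],
               b$entries[order(names(b$entries))])

  # collapse then expansion is a multiset identity
  expanded <- rep(names(a$entries), a$entries)
  expect_equal(sort(expanded), sort(reads))
})

test_that("abundance filter keeps >= min_count with the documented boundary", {
  lib <- collapse_reads(c(rep("AAAA", 2), rep("CCCC", 3), rep("GGGG", 100)))
  f <- abundance_filter(lib, 3L)
  expect_setequal(names(f$library$entries), c("CCCC", "GGGG"))
  expect_equal(f$retained_unique, 2L)
  expect_equal(f$retained_read_fraction, 103 / 105)

  # min_count = 1 is the identity
  f1 <- abundance_filter(lib, 1L)
  expect_equal(f1$library$entries, lib$entries)

  # retained fraction from a known count spectrum, against a direct sum
  set.seed(13)
  counts <- sample(1:20, 50, replace = TRUE)
  reads <- rep(random_dna(50, 18), counts)
  libs <- collapse_reads(reads)
  for (k in c(2L, 3L, 5L)) {
    fk <- abundance_filter(libs, k)
    expect_equal(fk$retained_read_fraction,
                 sum(counts[counts >= k]) / sum(counts))
  }

  # retained fraction is non-increasing in the cutoff
  fr <- vapply(1:10, function(k)
    abundance_filter(libs, k)$retained_read_fraction, numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("length histogram is read-weighted with the correct mean", {
  lib <- collapse_reads(c(rep(strrep("A", 22), 3), strrep("C", 28)))
  h <- length_histogram(lib)
  expect_equal(h$histogram, c(`22` = 3L, `28` = 1L))
  expect_equal(h$mean_length, 23.5)

  one <- length_histogram(collapse_reads("ACGTACGTAC"))
  expect_equal(one$mean_length, 10)
})

test_that("the read cascade is reproducible and monotone", {
  set.seed(23)
  inserts <- c(rep(random_dna(5, 22), c(50, 30, 10, 2, 1)),
               rep(random_dna(2, 7), c(20, 5)))
  reads <- paste0(sample(inserts), adapter)
  cas <- read_cascade(reads, adapter)
  expect_equal(cas$cascade$raw, length(reads))
  expect_equal(cas$cascade$gt_min_len, 93L)      # 22-mers only
  expect_equal(cas$cascade$unique, 5L)
  expect_equal(cas$cascade$unique_filtered, 3L)  # the 1- and 2-read tags drop
  expect_true(cas$cascade$unique_filtered <= cas$cascade$unique)
  expect_true(cas$cascade$gt_min_len <= cas$cascade$raw)
})

test_that("collapsed libraries round-trip through TSV and FASTA", {
  lib <- collapse_reads(c("AAAC", "AAAC", "GGGT"))
  tsv <- tempfile(fileext = ".tsv")
  write_collapsed_tsv(lib, tsv)
  back <- read_collapsed_tsv(tsv)
  expect_equal(back$entries[order(names(back$entries))],
               lib$entries[order(names(lib$entries))])

  fa <- tempfile(fileext = ".fa")
  write_collapsed_fasta(lib, fa)
  seqs <- read_fasta(fa)
  expect_equal(sort(unname(seqs)), sort(names(lib$entries)))
  expect_match(names(seqs)[1], "^tag[0-9]+_x[0-9]+$")
})

test_that("FASTQ round-trips through write and read", {
  seqs <- stats::setNames(c("ACGTACGT", "GGGTTTAA"), c("r1", "r2"))
  fq <- tempfile(fileext = ".fastq")
  write_fastq(seqs, fq)
  back <- read_fastq(fq)
  expect_equal(back, seqs)
})
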