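test_that("a tag equal to a mature sequence places exactly with 0 mismatches", {
  refs <- list(mature = c(m1 = "TAGCTTATCAGACTGATGTTGA"))
  pl <- map_tags("TAGCTTATCAGACTGATGTTGA", refs, max_mismatch = 1L)
  expect_equal(nrow(pl), 1L)
  expect_equal(pl$start, 0L)
  expect_equal(pl$end, 22L)
  expect_equal(pl$mismatches, 0L)
})

test_that("mismatch budget controls placement of a 1-substitution tag", {
  refs <- list(mature = c(m1 = "TAGCTTATCAGACTGATGTTGA"))
  tag <- "TAGCTTATCAGACAGATGTTGA"   # one substitution
  expect_equal(map_tags(tag, refs, max_mismatch = 1L)$mismatches, 1L)
  expect_equal(nrow(map_tags(tag, refs, max_mismatch = 0L)), 0L)
})

test_that("a tag planted at two genome loci yields both placements", {
  set.seed(31)
  tag <- random_dna(1, 22)
  g <- paste0(random_dna(1, 100), tag, random_dna(1, 100), tag,
              random_dna(1, 50))
  pl <- map_tags(tag, list(genome = c(chr1 = g)), max_mismatch = 0L)
  pl <- pl[pl$strand == "+", ]
  expect_equal(nrow(pl), 2L)
  expect_equal(pl$start, c(100L, 222L))
})

test_that("reverse-complement palindromes place on both strands at one locus", {
  half <- "ACGGTTCACGA"
  tag <- paste0(half, as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(half))))
  expect_equal(
    tag,
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(tag))))
  g <- paste0(strrep("A", 30), tag, strrep("T", 30))
  pl <- map_tags(tag, list(genome = c(chr1 = g)), max_mismatch = 0L)
  expect_setequal(pl$strand, c("+", "-"))
  expect_equal(unique(pl$start), 30L)
})

test_that("tags containing N are never placed", {
  refs <- list(mature = c(m1 = "TAGCTTATCAGACTGATGTTGA"))
  expect_equal(nrow(map_tags("TAGCTTATCAGACTGATGTNGA", refs, 2L)), 0L)
})

test_that("map_tags agrees with the brute-force oracle on random cases", {
  set.seed(41)
  for (i in 1:60) {
    ref <- random_dna(1, sample(100:400, 1))
    mm <- sample(0:2, 1)
    tag <- if (runif(1) < 0.5) {
      # embedded tag with up to mm substitutions
      start <- sample(1:(nchar(ref) - 22), 1)
      t0 <- substr(ref, start, start + 21)
      b <- strsplit(t0, "")[[1]]
      nmut <- sample(0:mm, 1)
      if (nmut > 0) {
        pos <- sample(22, nmut)
        b[pos] <- vapply(b[pos], function(x)
          sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
      }
      paste(b, collapse = "")
    } else random_dna(1, sample(16:28, 1))
    oracle <- brute_force_map(tag, ref, mm, both_strands = TRUE)
    got <- map_tags(tag, list(genome = c(chr1 = ref)), max_mismatch = mm)
    if (nrow(oracle) == 0L) {
      expect_equal(nrow(got), 0L)
    } else {
      best <- min(oracle$mismatches)
      ob <- oracle[oracle$mismatches == best, ]
      ob <- ob[order(ob$start, ob$strand), ]
      gb <- got[order(got$start, got$strand), ]
      expect_equal(gb$start, ob$start)
      expect_equal(gb$strand, ob$strand)
      expect_equal(gb$mismatches, ob$mismatches)
    }
  }
})

test_that("a tag longer than the reference is unplaced by both routes", {
  expect_equal(nrow(brute_force_map(strrep("A", 30), strrep("A", 20))), 0L)
  expect_equal(nrow(map_tags(strrep("ACGT", 8),
                             list(genome = c(chr1 = "ACGTACGT")), 0L)), 0L)
})

test_that("placement results are invariant to tag input order", {
  set.seed(43)
  g <- paste(random_dna(1, 500), collapse = "")
  tags <- c(substr(g, 51, 72), substr(g, 201, 222), substr(g, 401, 422))
  a <- map_tags(tags, list(genome = c(chr1 = g)), 1L)
  b <- map_tags(rev(tags), list(genome = c(chr1 = g)), 1L)
  key <- function(d) with(d, sort(paste(tag, start, strand, mismatches)))
  expect_equal(key(a), key(b))
})

test_that("best-stratum reporting drops suboptimal placements", {
  tag <- "ACGTACGTACGTACGTAC"
  b <- strsplit(tag, "")[[1]]; b[9] <- "T"
  near <- paste(b, collapse = "")
  g <- paste0(strrep("T", 20), tag, strrep("C", 20), near, strrep("T", 20))
  pl <- map_tags(tag, list(genome = c(chr1 = g)), max_mismatch = 1L)
  pl <- pl[pl$strand == "+", ]
  expect_equal(nrow(pl), 1L)    # only the exact hit survives
  expect_equal(pl$mismatches, 0L)
})

test_that("SAM and BED exports are well-formed", {
  refs <- c(chr1 = "AAAATAGCTTATCAGACTGATGTTGAAAAA")
  pl <- map_tags("TAGCTTATCAGACTGATGTTGA", list(genome = refs), 0L)
  pl <- pl[pl$strand == "+", ]
  sam <- tempfile(fileext = ".sam")
  placements_to_sam(pl, refs, sam)
  lines <- readLines(sam)
  expect_match(lines[2], "@SQ\tSN:chr1\tLN:30")
  body <- lines[!startsWith(lines, "@")]
  expect_match(body[1], "NM:i:0")
  f <- strsplit(body[1], "\t")[[1]]
  expect_equal(as.integer(f[4]), 5L)   # 1-based POS

  bed <- tempfile(fileext = ".bed")
  placements_to_bed(pl, bed)
  b <- read.table(bed, sep = "\t")
  expect_equal(b$V2, 4L)               # 0-based start
  expect_equal(b$V3, 26L)
})
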