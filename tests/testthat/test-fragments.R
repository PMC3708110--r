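mk_frag_fixture <- function() {
  # one 80-nt snoRNA host on chr1:[100,180)
  ann <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 180),
                                strand = "+", id = "snoX", class = "snoRNA")
  pl <- function(tag, start) data.frame(
    tag = tag, target_kind = "genome", target_id = "chr1", start = start,
    end = start + nchar(tag), strand = "+", mismatches = 0L,
    stringsAsFactors = FALSE)
  list(ann = ann, pl = pl)
}

test_that("fragment arms follow the quartile rule", {
  fx <- mk_frag_fixture()
  cl <- data.frame(tag = c("f5", "f3", "fi", "full"),
                   class = "snoRNA", ncrna_id = "snoX",
                   stringsAsFactors = FALSE)
  # names double as sequences for clarity; lengths carried by placements
  pl <- rbind(fx$pl(strrep("A", 28), 100L),    # host offset [0,28): 5'
              fx$pl(strrep("C", 28), 152L),    # [52,80): 3'
              fx$pl(strrep("G", 20), 130L),    # [30,50): internal
              fx$pl(strrep("T", 80), 100L))    # whole host
  cl$tag <- pl$tag
  counts <- stats::setNames(c(10, 20, 5, 2), pl$tag)
  fr <- profile_host_fragments(pl, cl, fx$ann, counts)
  expect_equal(fr$arm[fr$host_start == 0 & fr$length == 28], "five_prime")
  expect_equal(fr$arm[fr$host_start == 52], "three_prime")
  expect_equal(fr$arm[fr$host_start == 30], "internal")
  full <- fr[fr$length == 80, ]
  expect_equal(full$arm, "internal")
  expect_true(full$full_length)
})

test_that("arm assignment is invariant under symmetric host padding", {
  # same fragment, host padded by 10 nt on each side
  ann_pad <- GenomicRanges::GRanges("chr1", IRanges::IRanges(91, 190),
                                    strand = "+", id = "snoX",
                                    class = "snoRNA")
  fx <- mk_frag_fixture()
  cl <- data.frame(tag = strrep("A", 25), class = "snoRNA",
                   ncrna_id = "snoX", stringsAsFactors = FALSE)
  pl <- fx$pl(strrep("A", 25), 100L)
  counts <- stats::setNames(10, strrep("A", 25))
  a <- profile_host_fragments(pl, cl, fx$ann, counts)
  b <- profile_host_fragments(pl, cl, ann_pad, counts)
  expect_equal(a$arm, "five_prime")
  expect_equal(b$arm, "five_prime")
})

test_that("dominant fragment selection applies the documented tie-breaks", {
  fr <- data.frame(
    host_id = "h", host_class = "snoRNA",
    fragment = c("AAA", "CCCC", "GGGG"),
    host_start = 0L, host_end = 4L, arm = "five_prime",
    full_length = FALSE, length = c(3L, 4L, 4L),
    count = c(101948, 230, 230), stringsAsFactors = FALSE)
  expect_equal(dominant_fragment(fr, "h")$fragment, "AAA")   # by count
  fr2 <- fr; fr2$count <- c(5, 10, 10)
  expect_equal(dominant_fragment(fr2, "h")$fragment, "CCCC") # longer, then lex
  expect_error(dominant_fragment(fr, "nope"), "no fragments")
})

test_that("cluster report keeps zero-count members and matches single summaries", {
  fr <- data.frame(
    host_id = c("s1", "s1", "s3"), host_class = "snoRNA",
    fragment = c("AC", "GT", "CA"), host_start = 0L, host_end = 2L,
    arm = "five_prime", full_length = FALSE, length = 2L,
    count = c(7, 3, 9), stringsAsFactors = FALSE)
  rep <- cluster_report(fr, c("s1", "s2", "s3"))
  expect_equal(nrow(rep), 3L)
  expect_equal(rep$total_reads, c(10, 0, 9))
  expect_equal(rep$dominant_fragment[1], "AC")
  expect_true(is.na(rep$dominant_fragment[2]))
  # single-member cluster equals the host summary
  one <- cluster_report(fr, "s3")
  expect_equal(one$total_reads, sum(fr$count[fr$host_id == "s3"]))
})

test_that("multi-copy tRNA tags aggregate once per family", {
  run <- shared_run()
  fr <- run$res$fragments
  gly <- fr[fr$host_id == "tRNA-Gly-GCC", ]
  expect_gt(nrow(gly), 0L)
  # family total equals the tag counts once, not once per gene copy
  expect_equal(sum(gly$count),
               sum(run$res$library$entries[unique(gly$fragment)]))
  expect_true(all(gly$arm == "five_prime"))
})

test_that("the planted snoRNA cluster is recovered with its dominant member", {
  run <- shared_run()
  man <- run$man
  rep <- cluster_report(run$res$fragments, man$sno_ids)
  expect_equal(nrow(rep), length(man$sno_ids))
  expect_true(all(rep$total_reads > 0))          # reads on every member
  expect_equal(rep$host_id[which.max(rep$total_reads)], man$sno_ids[3])
  # both arms observed for the dominant member
  expect_match(rep$arms[rep$host_id == man$sno_ids[3]], "five_prime")
  expect_match(rep$arms[rep$host_id == man$sno_ids[3]], "three_prime")
  # conservation: per-host fragment counts do not exceed reads on the host
  fr <- run$res$fragments
  for (h in man$sno_ids) {
    sub <- fr[fr$host_id == h, ]
    expect_lte(sum(sub$count),
               sum(run$res$library$entries[unique(sub$fragment)]) + 1e-9)
  }
})
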