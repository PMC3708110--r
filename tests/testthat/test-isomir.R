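# a minimal catalog with one hairpin: 6 nt flank + 22 nt mature + 10 nt loop
# + star arm + 6 nt flank, mature at [6, 28), star at [40, 62)
mk_iso_catalog <- function() {
  man <- shared_manifest()
  shared_catalog()
}

hp_pl <- function(tag, start, hairpin, mm = 0L) {
  data.frame(tag = tag, target_kind = "hairpin", target_id = hairpin,
             start = start, end = start + nchar(tag), strand = "+",
             mismatches = mm, stringsAsFactors = FALSE)
}

test_that("isomiR offsets and classes follow the sign convention", {
  cat <- mk_iso_catalog()
  hp <- cat$hairpins[1, ]
  m0 <- hp$mature5_start; m1 <- hp$mature5_end
  mature <- substr(hp$sequence, m0 + 1, m1)

  # exact mature: offsets (0,0), classes mature/mature
  counts <- stats::setNames(10, mature)
  rec <- assign_isomirs(hp_pl(mature, m0, hp$id), cat, counts)
  expect_equal(rec$offset5, 0L); expect_equal(rec$offset3, 0L)
  expect_equal(rec$class5, "mature"); expect_equal(rec$class3, "mature")
  expect_equal(rec$arm, "mature")

  # one base shorter at the 3' end: offset3 = -1, class sub
  sub3 <- substr(hp$sequence, m0 + 1, m1 - 1)
  rec3 <- assign_isomirs(hp_pl(sub3, m0, hp$id),
                         cat, stats::setNames(5, sub3))
  expect_equal(rec3$offset5, 0L); expect_equal(rec3$offset3, -1L)
  expect_equal(rec3$class3, "sub")

  # shifted one base at the 5' start: offset5 = -1 (shorter), class sub
  sub5 <- substr(hp$sequence, m0 + 2, m1)
  rec5 <- assign_isomirs(hp_pl(sub5, m0 + 1L, hp$id),
                         cat, stats::setNames(5, sub5))
  expect_equal(rec5$offset5, -1L); expect_equal(rec5$class5, "sub")

  # one base longer at the 5' end: offset5 = +1, class super
  sup5 <- substr(hp$sequence, m0, m1)
  rec6 <- assign_isomirs(hp_pl(sup5, m0 - 1L, hp$id),
                         cat, stats::setNames(5, sup5))
  expect_equal(rec6$offset5, 1L); expect_equal(rec6$class5, "super")
})

test_that("offset classification is antisymmetric in the offset sign", {
  cls <- function(x) if (x == 0) "mature" else if (x < 0) "sub" else "super"
  for (o in -5:5) {
    a <- cls(o); b <- cls(-o)
    if (o == 0) expect_equal(a, b) else expect_true(setdiff(c("sub", "super"),
                                                            a) == b)
  }
})

test_that("tags outside the arm window and star-arm tags are handled", {
  cat <- mk_iso_catalog()
  hp <- cat$hairpins[1, ]
  # a tag starting in the loop, > window from both arms: unassigned
  loop_tag <- substr(hp$sequence, hp$mature5_end + 4, hp$mature5_end + 20)
  rec <- assign_isomirs(hp_pl(loop_tag, hp$mature5_end + 3L, hp$id),
                        cat, stats::setNames(5, loop_tag))
  expect_equal(nrow(rec), 0L)

  # a star-arm tag is assigned to the mature with arm = star
  star <- substr(hp$sequence, hp$mature3_start + 1, hp$mature3_end)
  rec2 <- assign_isomirs(hp_pl(star, hp$mature3_start, hp$id),
                         cat, stats::setNames(7, star))
  expect_equal(rec2$arm, "star")
  expect_equal(rec2$mature_name, hp$mature5_name)
})

test_that("arm ratio reproduces the published extreme and moderate cases", {
  # miR-21-like processing specificity: 27 star vs 2,318,344 mature reads
  expect_equal(arm_ratio(2318344, 27), 27 / 2318371, tolerance = 1e-12)
  expect_equal(round(arm_ratio(2318344, 27), 10), round(1.1646e-5, 10),
               tolerance = 1e-4)
  # miR-126-like: clearly detectable star strand
  expect_equal(round(arm_ratio(1014272, 83798), 4), 0.0763)
  # degenerate cases
  expect_equal(arm_ratio(0, 5), 1)
  expect_error(arm_ratio(0, 0))
})

test_that("isomiR counts are conserved per mature on synthetic data", {
  run <- shared_run()
  iso <- run$res$isomirs
  for (nm in unique(iso$mature_name)[1:5]) {
    sub <- iso[iso$mature_name == nm, ]
    expect_equal(sum(sub$count),
                 sum(run$res$library$entries[sub$tag]))
  }
})

test_that("variant profile reports A-to-G fractions at reference-A positions", {
  ref <- "AAGACTGACTGACTGACTGACT"
  iso <- data.frame(
    mature_name = "m", hairpin = "h",
    tag = c(ref, sub("^AAG", "AGG", ref)),
    arm = "mature", offset5 = 0L, offset3 = 0L,
    class5 = "mature", class3 = "mature",
    count = c(97, 3), stringsAsFactors = FALSE)
  vp <- variant_profile(iso, ref)
  expect_equal(vp$a_to_g$g_fraction[vp$a_to_g$position == 2], 0.03)
  expect_equal(vp$a_to_g$g_fraction[vp$a_to_g$position == 1], 0)

  # identical reads: no variants anywhere
  vp0 <- variant_profile(iso[1, ], ref)
  expect_true(all(vp0$a_to_g$g_fraction == 0))
})

test_that("planted editing fraction is recovered within sampling error", {
  run <- shared_run(n = 30000L)
  man <- run$man
  ed <- man$editing
  nm <- man$mirna$name[ed$mirna]
  iso <- run$res$isomirs[run$res$isomirs$mature_name == nm, ]
  vp <- variant_profile(iso, man$mirna$sequence[ed$mirna])
  g <- vp$a_to_g$g_fraction[vp$a_to_g$position == ed$position]
  n_reads <- sum(iso$count[iso$arm == "mature" & iso$offset5 == 0])
  tol <- 4 * sqrt(ed$fraction * (1 - ed$fraction) / n_reads)
  expect_gt(g, ed$fraction - tol)
  expect_lt(g, ed$fraction + tol)
})
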