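test_that("planted tags are found with the right identity, offset and strand", {
  set.seed(61)
  tag <- random_tags(1)
  ref <- plant_tag(random_dna(200), tag, 80L)
  hit <- match_tag(tag, ref, ref_id = "g1")
  expect_identical(hit$identity[1], 26L)
  expect_identical(hit$offset[1], 80L)
  expect_identical(hit$strand[1], "sense")
  expect_true(all(hit$anchor_ok))
  # antisense planting: the reverse complement at a known position
  ref2 <- plant_tag(random_dna(200), reverse_complement(tag), 60L)
  hit2 <- match_tag(tag, ref2)
  expect_identical(hit2$strand[1], "antisense")
  expect_identical(hit2$offset[1], 60L)
  expect_identical(hit2$identity[1], 26L)
})

test_that("the 22-of-26 identity boundary is sharp", {
  set.seed(62)
  for (i in 1:10) {
    tag <- random_tags(1)
    for (m in 0:4) {
      ref <- plant_tag(random_dna(120), mutate_tag(tag, m), 40L)
      hit <- match_tag(tag, ref)
      expect_identical(hit$identity[1], 26L - m)
      expect_gte(hit$identity[1], 22L)
    }
    ref5 <- plant_tag(random_dna(120), mutate_tag(tag, 5), 40L)
    expect_identical(nrow(match_tag(tag, ref5)), 0L)
  }
})

test_that("a broken anchor is rejected at any identity", {
  set.seed(63)
  tag <- random_tags(1)
  ref <- plant_tag(random_dna(120), tag, 40L)
  # mutate one anchor base of the planted site: identity would be 25
  substr(ref, 41, 41) <- "T"  # C -> T at the anchor start
  expect_identical(nrow(match_tag(tag, ref)), 0L)
  # an N in the reference never counts as a match
  refN <- plant_tag(random_dna(120), tag, 40L)
  substr(refN, 50, 53) <- "NNNN"
  hit <- match_tag(tag, refN)
  expect_identical(hit$identity[1], 22L)
})

test_that("strand classification reports sense, antisense, both and none", {
  set.seed(64)
  tags <- random_tags(4)
  refs <- c(
    s  = plant_tag(random_dna(150), tags[1], 50L),
    a  = plant_tag(random_dna(150), reverse_complement(tags[2]), 50L),
    b  = plant_tag(plant_tag(random_dna(150), tags[3], 20L),
                   reverse_complement(tags[3]), 100L)
  )
  m <- match_tags(tags, refs)
  cls <- classify_strand(m, tags)
  expect_identical(unname(cls[tags[1]]), "sense")
  expect_identical(unname(cls[tags[2]]), "antisense")
  expect_identical(unname(cls[tags[3]]), "both")
  expect_identical(unname(cls[tags[4]]), "none")
})

test_that("multi-site genes list all their tags and shared tags appear under each reference", {
  set.seed(65)
  tags <- random_tags(3)
  refs <- c(
    two_sites = plant_tag(plant_tag(random_dna(200), tags[1], 30L),
                          tags[2], 120L),
    other     = plant_tag(random_dna(200), tags[1], 80L)
  )
  m <- match_tags(tags, refs)
  rep <- multi_site_report(m)
  expect_setequal(rep$two_sites, tags[1:2])
  expect_identical(rep$other, tags[1])
  expect_identical(multi_site_report(supersage:::.empty_matches()),
                   setNames(list(), character(0)))
})

test_that("anchored scanning equals the exhaustive every-offset oracle", {
  set.seed(66)
  for (i in 1:30) {
    tag <- random_tags(1)
    ref <- random_dna(150)
    # plant a mutated copy (0-4 substitutions) or its reverse
    # complement at a random position; sometimes leave the reference
    # unplanted entirely
    if (i %% 5 != 0) {
      planted <- mutate_tag(tag, sample(0:4, 1))
      if (i %% 2 == 0) planted <- reverse_complement(planted)
      ref <- plant_tag(ref, planted, sample(0:(150 - 26), 1))
    }
    got <- match_tag(tag, ref)
    want <- brute_force_match(tag, ref)
    expect_equal(got, want, ignore_attr = TRUE)
    expect_true(all(got$identity >= 22L))
    expect_true(all(got$anchor_ok))
  }
})

test_that("match_tags agrees with per-pair match_tag and reads FASTA references", {
  set.seed(67)
  tags <- random_tags(3)
  refs <- c(r1 = plant_tag(random_dna(120), tags[1], 30L),
            r2 = plant_tag(random_dna(120), tags[2], 60L))
  combined <- match_tags(tags, refs)
  for (tg in tags) {
    per_pair <- do.call(rbind, lapply(names(refs), function(id) {
      match_tag(tg, refs[[id]], ref_id = id)
    }))
    got <- combined[combined$tag == tg, ]
    expect_equal(got[order(got$ref_id), ],
                 per_pair[order(per_pair$ref_id), ], ignore_attr = TRUE)
  }
  fa <- tempfile(fileext = ".fasta")
  write_reference(refs, fa)
  expect_equal(match_tags(tags, fa), combined, ignore_attr = TRUE)
})
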