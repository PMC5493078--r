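small_cfg <- function(seed = 3L) {
  sim_config(seed = seed, n_tags_per_category = 5L, n_null = 200L,
             n_antisense = 2L)
}

test_that("all generators are deterministic under a fixed seed", {
  cfg <- small_cfg()
  r1 <- generate_reference(cfg)
  r2 <- generate_reference(cfg)
  expect_identical(r1, r2)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1, s2)
  d1 <- generate_ditag_reads(s1$truth, cfg, n_reads = 200)
  d2 <- generate_ditag_reads(s1$truth, cfg, n_reads = 200)
  expect_identical(d1, d2)
  # a different seed changes the data
  expect_false(identical(generate_reference(small_cfg(4L)), r1))
})

test_that("references carry valid canonical tags and multi-site second tags", {
  cfg <- small_cfg()
  refs <- generate_reference(cfg)
  expect_length(refs$sequences, cfg$n_refs)
  expect_true(all(is_supertag(refs$canonical)))
  expect_true(all(nchar(refs$sequences) == cfg$ref_length))
  # every canonical tag is literally present in its reference
  for (id in names(refs$canonical)) {
    expect_true(grepl(refs$canonical[[id]], refs$sequences[[id]],
                      fixed = TRUE))
  }
  # multi-site references expose a second extractable anchored tag
  multi <- names(which(refs$multi_site))
  expect_gte(length(multi), 1L)
  for (id in multi) {
    sec <- refs$secondary[[id]]
    expect_true(is_supertag(sec))
    m <- match_tags(c(refs$canonical[[id]], sec), refs$sequences[id])
    expect_setequal(multi_site_report(m)[[id]],
                    c(refs$canonical[[id]], sec))
  }
})

test_that("multinomial counts conserve totals and respect structural zeros", {
  cfg <- small_cfg()
  sim <- simulate_experiment(cfg)
  ut <- sim$counts
  expect_equal(unname(colSums(ut[, LIB_IDS])),
               unname(library_totals(ut)))
  # exclusive tags are never observed outside their library
  for (lib in LIB_IDS) {
    excl <- sim$truth$tag[sim$truth$category == paste0("excl_", lib)]
    rows <- ut[ut$tag %in% excl, , drop = FALSE]
    other <- setdiff(LIB_IDS, lib)
    expect_true(all(rows[, other] == 0L))
    expect_true(all(rows[, lib] > 0L))
  }
  # zero-rate input is rejected
  bad <- sim$truth
  bad[, paste0("rate_", LIB_IDS)] <- 0
  expect_error(generate_counts(bad, cfg), "zero")
})

test_that("sampled abundances sit within binomial error of the planted rates", {
  cfg <- small_cfg()
  sim <- simulate_experiment(cfg)
  rates <- as.matrix(sim$truth[, paste0("rate_", LIB_IDS)])
  prob <- sweep(rates, 2, colSums(rates), "/")
  counts <- as.matrix(sim$counts[match(sim$truth$tag, sim$counts$tag),
                                 LIB_IDS])
  counts[is.na(counts)] <- 0L
  ok <- 0L; n <- 0L
  for (j in seq_along(LIB_IDS)) {
    N <- library_totals(sim$counts)[j]
    pos <- which(prob[, j] > 0)
    se <- sqrt(prob[pos, j] * (1 - prob[pos, j]) / N)
    dev <- abs(counts[pos, j] / N - prob[pos, j])
    ok <- ok + sum(dev <= 3 * se)
    n <- n + length(pos)
  }
  expect_gte(ok / n, 0.99)
})

test_that("antisense planted tags are classified antisense against their hosts", {
  cfg <- small_cfg()
  sim <- simulate_experiment(cfg)
  anti <- sim$truth[sim$truth$antisense, ]
  expect_identical(nrow(anti), cfg$n_antisense)
  m <- match_tags(anti$tag, sim$refs$sequences)
  cls <- classify_strand(m, anti$tag)
  expect_true(all(cls == "antisense"))
})

test_that("truth tables round-trip through TSV losslessly", {
  cfg <- small_cfg()
  sim <- simulate_experiment(cfg)
  path <- tempfile(fileext = ".tsv")
  write_truth(sim$truth, path)
  back <- read_truth(path)
  expect_identical(back, sim$truth)
})

test_that("recovery scoring handles the degenerate cases", {
  cfg <- small_cfg()
  sim <- simulate_experiment(cfg)
  no_calls <- data.frame(tag = character(0), category = character(0))
  sc <- score_recovery(no_calls, sim$truth)
  expect_identical(sc$sensitivity, 0)
  expect_identical(sc$fpr, 0)
  # a perfect oracle caller scores sensitivity 1
  planted <- sim$truth[sim$truth$category != "null", ]
  perfect <- data.frame(
    tag = planted$tag,
    category = sub("^excl_", "EXCL_", sub("^over_", "OVER_",
                                          planted$category)))
  sc2 <- score_recovery(perfect, sim$truth)
  expect_identical(sc2$sensitivity, 1)
  expect_identical(sc2$fpr, 0)
})
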