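# Seeded synthetic-data generator: reference sequences with anchored
# tag sites, a truth table of planted expression categories, multinomial
# tag-count libraries and clean ditag reads, so that every stage of the
# pipeline can be exercised without external data.

#' Configuration of a synthetic SuperSAGE experiment
#'
#' Defaults emulate the design of the lentil cold-acclimation
#' experiment at desk scale: the four library totals are the published
#' sequencing depths divided by 50 (about 60k-107k tags per library),
#' the planted effect fold between pooled sides is 10, and planted
#' tags are abundant enough that their summed counts clear the
#' abundance filter (>= 50) by a wide margin. Over-represented tags
#' are planted with a skewed major/minor pattern inside the favoured
#' pooled pair (see the vignette: a symmetric high/high pattern has CV
#' bounded by 2/sqrt(3) and could never pass the CV > 1.5 prefilter).
#'
#' @param n_tags_per_category Planted tags in each of the eight
#'   differential categories (4 exclusive, 4 over-represented).
#' @param n_null Null tags with identical expected expression in all
#'   four libraries.
#' @param n_antisense Antisense-planted differential tags (their
#'   reverse complement is inserted into a host reference).
#' @param n_refs Number of reference sequences; defaults to one per
#'   sense-planted tag plus the antisense hosts.
#' @param ref_length Reference length in nt (>= 60).
#' @param multi_site_frac Fraction of references given a second
#'   anchored tag site (multi-tag genes).
#' @param effect_fold Planted pooled-rate ratio of over-represented
#'   tags.
#' @param excl_tpm Planted rate (TPM) of exclusive tags in their
#'   single library.
#' @param over_tpm_major,over_tpm_minor Planted rates of
#'   over-represented tags in the two libraries of the favoured pooled
#'   pair; the opposite pair receives the pooled favoured rate divided
#'   by `effect_fold`.
#' @param null_meanlog,null_sdlog Log-normal parameters of null-tag
#'   rates.
#' @param library_totals Named totals of the four libraries (each
#'   >= 10^4).
#' @param seed Mandatory integer seed; all generators derive their
#'   streams from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_tags_per_category = 25L,
                       n_null = 2000L,
                       n_antisense = 4L,
                       n_refs = NULL,
                       ref_length = 300L,
                       multi_site_frac = 0.1,
                       effect_fold = 10,
                       excl_tpm = 2000,
                       over_tpm_major = 3000,
                       over_tpm_minor = 150,
                       null_meanlog = log(300),
                       null_sdlog = 1,
                       library_totals = round(c(NAS = 4220553, NAT = 4011993,
                                                AS = 5357611, AT = 2990512) / 50),
                       seed = 1L) {
  if (is.null(seed)) stop("seed is mandatory", call. = FALSE)
  n_sense <- 8L * as.integer(n_tags_per_category)
  if (is.null(n_refs)) n_refs <- n_sense + as.integer(n_antisense)
  stopifnot(ref_length >= 60L, n_refs >= n_sense + n_antisense,
            effect_fold > 1, excl_tpm > 0,
            over_tpm_major > 0, over_tpm_minor > 0)
  library_totals <- library_totals[LIB_IDS]
  if (any(is.na(library_totals)) || any(library_totals < 1e4)) {
    stop("library totals must be named NAS/NAT/AS/AT and >= 10^4",
         call. = FALSE)
  }
  structure(list(
    n_tags_per_category = as.integer(n_tags_per_category),
    n_null = as.integer(n_null),
    n_antisense = as.integer(n_antisense),
    n_refs = as.integer(n_refs),
    ref_length = as.integer(ref_length),
    multi_site_frac = multi_site_frac,
    effect_fold = effect_fold,
    excl_tpm = excl_tpm,
    over_tpm_major = over_tpm_major,
    over_tpm_minor = over_tpm_minor,
    null_meanlog = null_meanlog,
    null_sdlog = null_sdlog,
    library_totals = library_totals,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# 3'-most CATG occurrence with a full 26-nt window, or NA.
.canonical_site <- function(seq) {
  pos <- gregexpr(TAG_ANCHOR, seq, fixed = TRUE)[[1L]]
  if (pos[1L] == -1L) return(NA_integer_)
  pos <- pos[pos + TAG_LENGTH - 1L <= nchar(seq)]
  if (length(pos) == 0L) return(NA_integer_)
  max(pos)
}

#' Generate reference sequences with anchored tag sites
#'
#' Random sequences, each guaranteed at least one CATG site with a
#' full 26-nt window; the canonical tag of a reference is the window
#' at its 3'-most such site (most SuperSAGE tags derive from the 3'
#' end of transcripts). A `multi_site_frac` fraction of references
#' carries a second upstream site whose window is a second extractable
#' tag. Deterministic under the configuration seed.
#'
#' @param cfg A [sim_config()].
#' @return List with `sequences` (named character), `canonical` (named
#'   character, one tag per reference), `secondary` (named character,
#'   upstream tags of multi-site references) and `multi_site`
#'   (logical).
#' @export
generate_reference <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed, {
    n <- cfg$n_refs
    L <- cfg$ref_length
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
            collapse = "")
    }, character(1L))
    # guarantee a 3' site with a full window, 10 nt in from the end
    anchor_at <- L - TAG_LENGTH - 9L
    substr(seqs, anchor_at, anchor_at + 3L) <- TAG_ANCHOR
    n_multi <- ceiling(cfg$multi_site_frac * n)
    multi <- seq_len(n) <= n_multi
    if (n_multi > 0L) {
      substr(seqs[multi], 20L, 23L) <- TAG_ANCHOR
    }
    names(seqs) <- sprintf("ref_%04d", seq_len(n))
    canonical <- vapply(seqs, function(s) {
      p <- .canonical_site(s)
      substr(s, p, p + TAG_LENGTH - 1L)
    }, character(1L))
    if (anyDuplicated(canonical)) {
      stop("canonical tag collision; increase ref_length or change seed",
           call. = FALSE)
    }
    secondary <- vapply(seqs[multi], function(s) {
      substr(s, 20L, 20L + TAG_LENGTH - 1L)
    }, character(1L))
    list(sequences = seqs, canonical = canonical,
         secondary = secondary, multi_site = setNames(multi, names(seqs)))
  })
}

# Planted per-library rates (TPM) for one over-represented tag.
.over_rates <- function(category, major_first, cfg) {
  pair <- switch(category,
                 over_N = c("NAS", "NAT"), over_A = c("AS", "AT"),
                 over_T = c("NAT", "AT"), over_S = c("NAS", "AS"))
  low_pair <- setdiff(LIB_IDS, pair)
  major <- if (major_first) pair[1L] else pair[2L]
  minor <- setdiff(pair, major)
  nt <- cfg$library_totals
  pooled_high <- (cfg$over_tpm_major * nt[major] +
                    cfg$over_tpm_minor * nt[minor]) / sum(nt[pair])
  rates <- setNames(numeric(4L), LIB_IDS)
  rates[major] <- cfg$over_tpm_major
  rates[minor] <- cfg$over_tpm_minor
  rates[low_pair] <- pooled_high / cfg$effect_fold
  rates
}

# Truth table: planted categories, rates, antisense flags.
.make_truth <- function(refs, cfg) {
  .with_seed(cfg$seed + 1L, {
    n_cat <- cfg$n_tags_per_category
    cats <- c("excl_NAS", "excl_NAT", "excl_AS", "excl_AT",
              "over_N", "over_A", "over_T", "over_S")
    n_sense <- 8L * n_cat
    sense_refs <- names(refs$sequences)[seq_len(n_sense)]
    sense_tags <- unname(refs$canonical[sense_refs])
    category <- rep(cats, each = n_cat)

    anti_refs <- names(refs$sequences)[n_sense + seq_len(cfg$n_antisense)]
    anti_tags <- random_tags(cfg$n_antisense)
    anti_cat <- rep_len(c("over_A", "over_T"), cfg$n_antisense)

    planted_tags <- c(sense_tags, anti_tags)
    null_tags <- setdiff(random_tags(cfg$n_null), planted_tags)
    while (length(null_tags) < cfg$n_null) {
      null_tags <- setdiff(unique(c(null_tags,
                                    random_tags(cfg$n_null - length(null_tags)))),
                           planted_tags)
    }

    truth <- data.frame(
      tag = c(sense_tags, anti_tags, null_tags),
      origin_ref = c(sense_refs, anti_refs,
                     rep(NA_character_, cfg$n_null)),
      category = c(category, anti_cat, rep("null", cfg$n_null)),
      antisense = c(rep(FALSE, n_sense), rep(TRUE, cfg$n_antisense),
                    rep(FALSE, cfg$n_null)),
      planted_mismatches = 0L,
      stringsAsFactors = FALSE
    )
    rates <- matrix(0, nrow(truth), 4L,
                    dimnames = list(NULL, LIB_IDS))
    major_flip <- FALSE
    for (i in seq_len(nrow(truth))) {
      cat_i <- truth$category[i]
      if (startsWith(cat_i, "excl_")) {
        rates[i, sub("excl_", "", cat_i)] <- cfg$excl_tpm
      } else if (startsWith(cat_i, "over_")) {
        rates[i, ] <- .over_rates(cat_i, major_flip, cfg)
        major_flip <- !major_flip
      }
    }
    null_idx <- truth$category == "null"
    null_rate <- rlnorm(sum(null_idx), cfg$null_meanlog, cfg$null_sdlog)
    rates[null_idx, ] <- matrix(null_rate, sum(null_idx), 4L)
    colnames(rates) <- paste0("rate_", LIB_IDS)
    cbind(truth, as.data.frame(rates))
  })
}

#' Draw multinomial tag counts from a truth table
#'
#' Per library, counts are drawn multinomially over all truth tags
#' with probabilities proportional to the planted rates, with the
#' configured total as the fixed library size (so column sums equal
#' the totals exactly). Tags with a zero rate in a library have a
#' structural zero there: exclusive tags are never observed outside
#' their library. Tags with all-zero sampled counts are dropped from
#' the returned table (they were never sequenced). Deterministic
#' under the configuration seed.
#'
#' @param truth Truth data.frame from [simulate_experiment()] (columns
#'   `tag` and `rate_NAS` .. `rate_AT`).
#' @param cfg A [sim_config()].
#' @return A [unitag_table()].
#' @export
generate_counts <- function(truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  rates <- as.matrix(truth[, paste0("rate_", LIB_IDS)])
  if (any(colSums(rates) == 0)) {
    stop("rates sum to zero in at least one library", call. = FALSE)
  }
  .with_seed(cfg$seed + 2L, {
    counts <- vapply(seq_along(LIB_IDS), function(j) {
      as.vector(rmultinom(1L, cfg$library_totals[j], rates[, j]))
    }, integer(nrow(truth)))
    colnames(counts) <- LIB_IDS
    keep <- rowSums(counts) > 0L
    df <- data.frame(tag = truth$tag[keep], counts[keep, , drop = FALSE],
                     stringsAsFactors = FALSE)
    unitag_table(df, setNames(as.numeric(cfg$library_totals), LIB_IDS))
  })
}

#' Generate clean ditag reads from a truth table
#'
#' Random tag pairs, drawn with probability proportional to each
#' tag's mean planted rate, are joined tail-to-tail (first tag
#' followed by the reverse complement of the second), giving 52-nt
#' CATG...CATG ditags. Deterministic under the configuration seed.
#'
#' @param truth Truth data.frame.
#' @param cfg A [sim_config()].
#' @param n_reads Number of ditag reads.
#' @return Data.frame with columns `read_id`, `sequence`,
#'   `tag_forward`, `tag_reverse` (the two generating tags).
#' @export
generate_ditag_reads <- function(truth, cfg, n_reads = 10000L) {
  stopifnot(inherits(cfg, "sim_config"), n_reads >= 1L)
  rates <- as.matrix(truth[, paste0("rate_", LIB_IDS)])
  w <- rowMeans(rates)
  if (sum(w) == 0) stop("rates sum to zero", call. = FALSE)
  .with_seed(cfg$seed + 3L, {
    i <- sample.int(nrow(truth), n_reads, replace = TRUE, prob = w)
    j <- sample.int(nrow(truth), n_reads, replace = TRUE, prob = w)
    t1 <- truth$tag[i]
    t2 <- truth$tag[j]
    data.frame(read_id = sprintf("ditag_%06d", seq_len(n_reads)),
               sequence = paste0(t1, reverse_complement(t2)),
               tag_forward = t1, tag_reverse = t2,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a complete synthetic experiment
#'
#' Generates references, the planted truth table and the multinomial
#' count table in one call.
#'
#' @param cfg A [sim_config()].
#' @return List with elements `refs` (see [generate_reference()]),
#'   `truth` (data.frame) and `counts` (a [unitag_table()]).
#' @export
simulate_experiment <- function(cfg = sim_config()) {
  refs <- generate_reference(cfg)
  # plant the reverse complement of each antisense tag into its host
  truth <- .make_truth(refs, cfg)
  anti <- truth[truth$antisense, , drop = FALSE]
  for (i in seq_len(nrow(anti))) {
    host <- anti$origin_ref[i]
    ins <- reverse_complement(anti$tag[i])
    s <- refs$sequences[[host]]
    substr(s, 30L, 30L + TAG_LENGTH - 1L) <- ins
    refs$sequences[[host]] <- s
  }
  counts <- generate_counts(truth, cfg)
  list(refs = refs, truth = truth, counts = counts)
}

#' Score recovery of planted differential tags
#'
#' Sensitivity is the fraction of planted differential tags that
#' received the matching call (`excl_X` -> `EXCL_X`, `over_X` ->
#' `OVER_X`); the false-positive rate is the fraction of null tags
#' appearing in any call.
#'
#' @param calls Data.frame from [call_differential_tags()].
#' @param truth Truth data.frame.
#' @return List with `sensitivity`, `fpr`, `n_planted`, `n_null` and a
#'   `per_category` data.frame.
#' @export
score_recovery <- function(calls, truth) {
  planted <- truth[truth$category != "null", , drop = FALSE]
  expected <- sub("^excl_", "EXCL_", sub("^over_", "OVER_",
                                         planted$category))
  hit <- vapply(seq_len(nrow(planted)), function(i) {
    any(calls$tag == planted$tag[i] & calls$category == expected[i])
  }, logical(1L))
  nulls <- truth$tag[truth$category == "null"]
  n_fp <- length(intersect(unique(calls$tag), nulls))
  per_cat <- aggregate(hit, by = list(category = planted$category), FUN = mean)
  names(per_cat)[2L] <- "sensitivity"
  list(sensitivity = if (nrow(planted)) mean(hit) else 0,
       fpr = if (length(nulls)) n_fp / length(nulls) else 0,
       n_planted = nrow(planted), n_null = length(nulls),
       per_category = per_cat)
}

#' Write / read a truth table (lossless round trip)
#'
#' Rates are serialized with 17 significant digits so that the
#' numeric columns survive the text round trip bit-for-bit.
#'
#' @param truth Truth data.frame.
#' @param path TSV file.
#' @export
write_truth <- function(truth, path) {
  out <- truth
  for (cc in paste0("rate_", LIB_IDS)) {
    out[[cc]] <- sprintf("%.17g", out[[cc]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname write_truth
#' @return `read_truth()`: the truth data.frame.
#' @export
read_truth <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "character",
                                  "logical", "integer",
                                  rep("numeric", 4L)))
  df
}
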