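# Differential-tag procedure: CV and abundance prefilter, fold change
# with zero substitution, Audic-Claverie significance, and
# classification into exclusive (one library) and over-represented
# (pooled axis) sets.

#' Thresholds of the differential-tag search
#'
#' Defaults are the published filter cascade: coefficient of variation
#' of the four normalized values above 1.5; summed raw count of at
#' least 50; fold change of at least 4.0 (the exclusive search accepts
#' FC = 4.0 exactly, the over-represented search requires FC strictly
#' above 4.0, following the wording of the two searches); p-value
#' below 0.001; and normalized zeros replaced by 0.5 before fold
#' changes are formed.
#'
#' @param cv_min CV threshold (tags with CV strictly above pass).
#' @param count_min Minimum absolute tag count.
#' @param fc_min Fold-change threshold.
#' @param p_max Significance level (tags with p strictly below pass).
#' @param zero_sub TPM value substituted for zero when forming fold
#'   changes.
#' @param sd_type `"sample"` (divisor n-1, default) or `"population"`
#'   (divisor n) standard deviation for the CV. Either choice lets a
#'   single-library tag pass `cv_min = 1.5`.
#' @param count_rule `"total"` (default): `count_min` applies to the
#'   sum of the four raw counts; `"max"`: to the largest per-library
#'   count.
#' @return A list of class `sage_thresholds`.
#' @export
sage_thresholds <- function(cv_min = 1.5, count_min = 50L, fc_min = 4.0,
                            p_max = 0.001, zero_sub = 0.5,
                            sd_type = c("sample", "population"),
                            count_rule = c("total", "max")) {
  stopifnot(cv_min > 0, count_min > 0, fc_min > 0, p_max > 0, zero_sub > 0)
  structure(list(cv_min = cv_min, count_min = as.integer(count_min),
                 fc_min = fc_min, p_max = p_max, zero_sub = zero_sub,
                 sd_type = match.arg(sd_type),
                 count_rule = match.arg(count_rule)),
            class = "sage_thresholds")
}

#' Fold change with zero substitution
#'
#' Any zero operand is replaced by `zero_sub` before the ratio is
#' formed; the fold change is reported as max/min (always at least 1),
#' with direction carried separately by the caller.
#'
#' @param tpm_a,tpm_b Non-negative normalized values (recycled).
#' @param zero_sub Replacement for zeros (default 0.5).
#' @return Numeric fold change(s) >= 1.
#' @examples
#' fold_change(2, 0)  # 4: forced by the 0 -> 0.5 substitution
#' @export
fold_change <- function(tpm_a, tpm_b, zero_sub = 0.5) {
  if (any(tpm_a < 0) || any(tpm_b < 0)) {
    stop("normalized values must be non-negative", call. = FALSE)
  }
  stopifnot(zero_sub > 0)
  a <- ifelse(tpm_a == 0, zero_sub, tpm_a)
  b <- ifelse(tpm_b == 0, zero_sub, tpm_b)
  pmax(a, b) / pmin(a, b)
}

#' Per-tag summary statistics
#'
#' Normalized values of one tag in the four libraries together with
#' their mean, standard deviation, coefficient of variation and the
#' summed raw count. A tag seen in a single library has CV exactly 2
#' under the sample (n-1) standard deviation, whatever its abundance.
#'
#' @param counts Numeric vector of four raw counts (named or in
#'   NAS, NAT, AS, AT order); at least one must be positive.
#' @param totals Named vector of the four library totals.
#' @param sd_type `"sample"` (default) or `"population"`.
#' @return A list with elements `tpm` (named length-4), `mean`, `sd`,
#'   `cv` and `total_count`.
#' @export
tag_stats <- function(counts, totals, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  counts <- .as_lib_vector(counts, "counts")
  totals <- .as_lib_vector(totals, "totals")
  if (sum(counts) == 0) stop("all-zero count row", call. = FALSE)
  tpm <- normalize_tpm(counts, totals)
  m <- mean(tpm)
  s <- if (sd_type == "sample") sd(tpm) else sqrt(mean((tpm - m)^2))
  list(tpm = tpm, mean = m, sd = s, cv = s / m,
       total_count = sum(counts))
}

.as_lib_vector <- function(x, what) {
  if (length(x) != 4L) stop(what, " must have length 4", call. = FALSE)
  if (!is.null(names(x))) {
    if (!all(LIB_IDS %in% names(x))) {
      stop(what, " must be named NAS, NAT, AS, AT", call. = FALSE)
    }
    x <- x[LIB_IDS]
  } else {
    names(x) <- LIB_IDS
  }
  x
}

# Vectorized tag statistics for a whole unitag table.
.tag_stats_table <- function(x, sd_type = "sample") {
  stopifnot(inherits(x, "unitag_table"))
  tpm <- tpm_matrix(x)
  m <- rowMeans(tpm)
  dev2 <- rowSums((tpm - m)^2)
  s <- if (sd_type == "sample") sqrt(dev2 / 3) else sqrt(dev2 / 4)
  counts <- as.matrix(x[, LIB_IDS])
  out <- data.frame(tag = x$tag, counts,
                    tpm, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(out) <- c("tag", paste0("count_", LIB_IDS), paste0("tpm_", LIB_IDS))
  out$mean_tpm <- m
  out$sd_tpm <- s
  out$cv <- s / m
  out$total_count <- rowSums(counts)
  rownames(out) <- NULL
  out
}

#' Prefilter tags by dispersion and abundance
#'
#' Retains tags whose coefficient of variation over the four
#' normalized values is strictly above `cv_min` and whose absolute
#' count reaches `count_min` (boundary inclusive: a summed count of
#' exactly 50 passes the default).
#'
#' @param x A [unitag_table()].
#' @param thresholds A [sage_thresholds()] object.
#' @return A data.frame of per-tag statistics (counts, TPMs, mean, sd,
#'   CV, total count) restricted to retained tags.
#' @export
prefilter_tags <- function(x, thresholds = sage_thresholds()) {
  stats <- .tag_stats_table(x, thresholds$sd_type)
  abundance <- if (thresholds$count_rule == "total") {
    stats$total_count
  } else {
    do.call(pmax, stats[paste0("count_", LIB_IDS)])
  }
  keep <- stats$cv > thresholds$cv_min & abundance >= thresholds$count_min
  out <- stats[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a tag as exclusive to one library
#'
#' A tag observed in exactly one of the four libraries is tested
#' against the pooled remaining three: fold change is the observed TPM
#' over the zero substitute, and significance is the two-sided
#' Audic-Claverie test of 0 counts in the pooled absent libraries
#' versus the observed count. A call is emitted when FC >= `fc_min`
#' (boundary inclusive) and p < `p_max`. The caller is responsible for
#' applying [prefilter_tags()] first.
#'
#' @param counts Four raw counts (named or in canonical order).
#' @param totals The four library totals.
#' @param thresholds A [sage_thresholds()] object.
#' @return `NULL`, or a list with `category` (e.g. `"EXCL_AT"`),
#'   `library`, `fold_change`, `p_value`.
#' @export
classify_exclusive <- function(counts, totals,
                               thresholds = sage_thresholds()) {
  counts <- .as_lib_vector(counts, "counts")
  totals <- .as_lib_vector(totals, "totals")
  pos <- which(counts > 0)
  if (length(pos) != 1L) return(NULL)
  lib <- LIB_IDS[pos]
  tpm_obs <- normalize_tpm(counts[pos], totals[pos])
  fc <- unname(tpm_obs / thresholds$zero_sub)
  p <- audic_claverie_p(0, counts[pos], sum(totals[-pos]), totals[pos],
                        sided = "two")
  if (fc >= thresholds$fc_min && p < thresholds$p_max) {
    list(category = paste0("EXCL_", lib), library = lib,
         fold_change = fc, p_value = unname(p))
  } else {
    NULL
  }
}

# Pooled library pairs per comparison axis.
.axis_pools <- function(axis) {
  switch(axis,
         treatment = list(N = c("NAS", "NAT"), A = c("AS", "AT")),
         genotype  = list(S = c("NAS", "AS"), T = c("NAT", "AT")),
         stop("axis must be 'treatment' or 'genotype'", call. = FALSE))
}

#' Classify a tag as over-represented on a pooled axis
#'
#' Counts and totals are pooled on the chosen axis (treatment:
#' acclimated AS+AT versus non-acclimated NAS+NAT; genotype: tolerant
#' NAT+AT versus susceptible NAS+AS). Pooled TPMs are compared by
#' [fold_change()] (with zero substitution) and the pooled counts by
#' the two-sided Audic-Claverie test. A call for the side with the
#' larger pooled TPM is emitted when FC is strictly above `fc_min` and
#' p < `p_max`. The caller applies [prefilter_tags()] first.
#'
#' @inheritParams classify_exclusive
#' @param axis `"treatment"` or `"genotype"`.
#' @return `NULL`, or a list with `category` (e.g. `"OVER_A"`),
#'   `axis`, `fold_change`, `p_value`.
#' @export
classify_overrepresented <- function(counts, totals,
                                     thresholds = sage_thresholds(),
                                     axis = c("treatment", "genotype")) {
  axis <- match.arg(axis)
  counts <- .as_lib_vector(counts, "counts")
  totals <- .as_lib_vector(totals, "totals")
  pools <- .axis_pools(axis)
  c1 <- sum(counts[pools[[1L]]]); t1 <- sum(totals[pools[[1L]]])
  c2 <- sum(counts[pools[[2L]]]); t2 <- sum(totals[pools[[2L]]])
  tpm1 <- c1 / t1 * 1e6
  tpm2 <- c2 / t2 * 1e6
  if (tpm1 == tpm2) return(NULL)
  fc <- fold_change(tpm1, tpm2, thresholds$zero_sub)
  side <- names(pools)[if (tpm1 > tpm2) 1L else 2L]
  p <- audic_claverie_p(c1, c2, t1, t2, sided = "two")
  if (fc > thresholds$fc_min && p < thresholds$p_max) {
    list(category = paste0("OVER_", side), axis = axis,
         fold_change = unname(fc), p_value = unname(p))
  } else {
    NULL
  }
}

#' Run the full differential-tag search on a unitag table
#'
#' Applies the CV/abundance prefilter, then the exclusive search
#' (tags seen in a single library) and, for tags supported in more
#' than one library, the over-represented search on both pooled axes.
#' A tag may receive calls on both axes (it is then reported twice,
#' one row per call). A Benjamini-Hochberg adjusted p-value over all
#' performed tests is attached for information only; no multiple-
#' testing correction enters the call criteria.
#'
#' @param x A [unitag_table()].
#' @param thresholds A [sage_thresholds()] object.
#' @return A data.frame of calls with columns `tag`, `category`,
#'   `axis`, per-library counts and TPMs, `cv`, `total_count`,
#'   `fold_change`, `p_value`, `p_adj`.
#' @export
call_differential_tags <- function(x, thresholds = sage_thresholds()) {
  stats <- prefilter_tags(x, thresholds)
  totals <- attr(x, "totals")
  count_cols <- paste0("count_", LIB_IDS)
  rows <- vector("list", nrow(stats) * 2L)
  n_rows <- 0L
  add <- function(i, category, axis, fc, p) {
    n_rows <<- n_rows + 1L
    rows[[n_rows]] <<- data.frame(
      tag = stats$tag[i], category = category, axis = axis,
      stats[i, c(count_cols, paste0("tpm_", LIB_IDS))],
      cv = stats$cv[i], total_count = stats$total_count[i],
      fold_change = fc, p_value = p,
      stringsAsFactors = FALSE, check.names = FALSE)
  }
  for (i in seq_len(nrow(stats))) {
    counts <- setNames(as.numeric(stats[i, count_cols]), LIB_IDS)
    excl <- classify_exclusive(counts, totals, thresholds)
    if (!is.null(excl)) {
      add(i, excl$category, "exclusive", excl$fold_change, excl$p_value)
      next
    }
    for (ax in c("treatment", "genotype")) {
      ov <- classify_overrepresented(counts, totals, thresholds, ax)
      if (!is.null(ov)) {
        add(i, ov$category, ax, ov$fold_change, ov$p_value)
      }
    }
  }
  if (n_rows == 0L) {
    out <- data.frame(tag = character(0), category = character(0),
                      axis = character(0), stringsAsFactors = FALSE)
    for (cc in c(count_cols, paste0("tpm_", LIB_IDS))) out[[cc]] <- numeric(0)
    out$cv <- numeric(0); out$total_count <- numeric(0)
    out$fold_change <- numeric(0); out$p_value <- numeric(0)
    out$p_adj <- numeric(0)
    return(out)
  }
  out <- do.call(rbind, rows[seq_len(n_rows)])
  out$p_adj <- p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Write differential calls as TSV
#'
#' @param calls Data.frame from [call_differential_tags()].
#' @param path Output file.
#' @export
write_calls <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
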