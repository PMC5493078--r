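# Reporting: library-support partition of unitags, call/identification
# summaries, and grouped normalized-value sums.

# All 15 non-empty subsets of the four libraries, canonical order.
.venn_classes <- function() {
  unlist(lapply(1:4, function(k) {
    apply(utils::combn(LIB_IDS, k), 2L, paste, collapse = "+")
  }))
}

#' Partition unitags by library support
#'
#' Assigns every unitag to exactly one of the 15 non-empty subsets of
#' {NAS, NAT, AS, AT} according to which libraries have a positive
#' count. Classes are disjoint and exhaustive, so the class counts sum
#' to the number of unitags.
#'
#' @param x A [unitag_table()].
#' @return Named integer vector over the 15 support classes (names
#'   like `"NAS"`, `"NAT+AT"`, `"NAS+NAT+AS+AT"`).
#' @export
venn_partition <- function(x) {
  stopifnot(inherits(x, "unitag_table"))
  m <- as.matrix(x[, LIB_IDS]) > 0
  labels <- apply(m, 1L, function(row) {
    paste(LIB_IDS[row], collapse = "+")
  })
  classes <- .venn_classes()
  out <- table(factor(labels, levels = classes))
  setNames(as.integer(out), classes)
}

#' Summarize differential calls and reference identification
#'
#' One row per call category with the number of significant tags and
#' the number of those with an accepted reference match.
#'
#' @param calls Data.frame from [call_differential_tags()].
#' @param matches Optional data.frame of accepted matches from
#'   [match_tags()]; when `NULL`, the matched column is all zero.
#' @return Data.frame with columns `category`, `n_significant`,
#'   `n_matched` (matched never exceeds significant).
#' @export
summarize_calls <- function(calls, matches = NULL) {
  categories <- c("EXCL_AS", "EXCL_AT", "EXCL_NAS", "EXCL_NAT",
                  "OVER_N", "OVER_A", "OVER_T", "OVER_S")
  matched_tags <- if (is.null(matches) || nrow(matches) == 0L) {
    character(0)
  } else {
    unique(matches$tag)
  }
  n_sig <- integer(length(categories))
  n_mat <- integer(length(categories))
  for (i in seq_along(categories)) {
    tags <- unique(calls$tag[calls$category == categories[i]])
    n_sig[i] <- length(tags)
    n_mat[i] <- sum(tags %in% matched_tags)
  }
  data.frame(category = categories, n_significant = n_sig,
             n_matched = n_mat, stringsAsFactors = FALSE)
}

#' Column sum of a normalized tag-group profile
#'
#' Sums the normalized (TPM) values of one library column over a tag
#' group, optionally restricted to antisense-flagged rows, rounded
#' half-up to 2 decimals, matching the "Total" and "Total antisense"
#' rows of printed group tables.
#'
#' @param profile Data.frame with the four library columns `NAS`,
#'   `NAT`, `AS`, `AT` and, if `antisense_only` is used, a logical
#'   `antisense` column.
#' @param column One of `"NAS"`, `"NAT"`, `"AS"`, `"AT"`.
#' @param antisense_only Sum only antisense-flagged rows.
#' @return The rounded column total (0 for an empty group).
#' @export
group_sum <- function(profile, column, antisense_only = FALSE) {
  if (!column %in% LIB_IDS) {
    stop("unknown column: ", column, call. = FALSE)
  }
  if (!column %in% names(profile)) {
    stop("profile lacks column ", column, call. = FALSE)
  }
  rows <- if (antisense_only) {
    if (!"antisense" %in% names(profile)) {
      stop("profile lacks an antisense column", call. = FALSE)
    }
    as.logical(profile$antisense)
  } else {
    rep(TRUE, nrow(profile))
  }
  round_half_up(sum(profile[[column]][rows]), 2L)
}

#' Normalized profile of the glycine-rich (CORA-family) tag group
#'
#' Bundled example dataset: tags-per-million values of twelve
#' SuperSAGE tags identifying glycine-rich / cold- and
#' drought-regulated (CORA) and dormancy-associated protein sequences
#' across the four lentil bulk libraries, three of them antisense.
#' Blank cells of the source table are zero observations. The group is
#' collectively overexpressed in the acclimated tolerant bulk; its
#' column totals are reproduced by [group_sum()].
#'
#' @return Data.frame with columns `label`, `tag`, `antisense`,
#'   `NAS`, `NAT`, `AS`, `AT`.
#' @export
glycine_rich_profile <- function() {
  path <- system.file("extdata", "glycine_rich_cora_tpm.tsv",
                      package = "supersage", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c("character", "character", "logical",
                            rep("numeric", 4L)))
}

#' Write a plain-text run report
#'
#' Human-readable summary of a pipeline run: library totals, unitag
#' counts, the support partition, the filter funnel and the call
#' summary.
#'
#' @param x A [unitag_table()].
#' @param calls Data.frame from [call_differential_tags()].
#' @param matches Optional match data.frame.
#' @param path Output file.
#' @param thresholds The [sage_thresholds()] used.
#' @export
write_report <- function(x, calls, matches = NULL, path,
                         thresholds = sage_thresholds()) {
  totals <- attr(x, "totals")
  venn <- venn_partition(x)
  summ <- summarize_calls(calls, matches)
  pre <- prefilter_tags(x, thresholds)
  lines <- c(
    "SuperSAGE differential-tag report",
    "",
    sprintf("Library totals: %s",
            paste(sprintf("%s=%s", names(totals),
                          format(totals, big.mark = ",", trim = TRUE)),
                  collapse = "  ")),
    sprintf("Unitags: %d", nrow(x)),
    sprintf("Tags passing CV > %.2f and count >= %d: %d",
            thresholds$cv_min, thresholds$count_min, nrow(pre)),
    sprintf("Differential calls: %d (%d distinct tags)",
            nrow(calls), length(unique(calls$tag))),
    "",
    "Library-support partition:",
    sprintf("  %-16s %d", names(venn), venn),
    "",
    "Calls per category (significant / with reference match):",
    sprintf("  %-9s %4d / %4d", summ$category, summ$n_significant,
            summ$n_matched)
  )
  writeLines(lines, path)
  invisible(path)
}
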