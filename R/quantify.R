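# Unitag quantification: aggregation of identical tag sequences per
# library and tags-per-million normalization.

#' Construct a unitag count table
#'
#' A unitag table holds one row per distinct tag sequence with raw
#' counts in the four libraries, plus the library totals (the count of
#' all sequenced tags in each library, which may exceed the column
#' sums when the table is a filtered subset).
#'
#' @param counts A data.frame with columns `tag`, `NAS`, `NAT`, `AS`,
#'   `AT`; counts are non-negative integers, tags unique, every row
#'   has at least one positive count.
#' @param totals Named numeric vector of library totals (names
#'   `NAS`, `NAT`, `AS`, `AT`), each at least 1 and at least the
#'   corresponding column sum.
#' @return An object of class `unitag_table` (a data.frame with a
#'   `totals` attribute).
#' @seealso [count_unitags()], [read_count_matrix()]
#' @export
unitag_table <- function(counts, totals) {
  stopifnot(is.data.frame(counts))
  need <- c("tag", LIB_IDS)
  if (!all(need %in% names(counts))) {
    stop("counts must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  counts <- counts[, need]
  if (anyDuplicated(counts$tag)) stop("duplicated tag sequences", call. = FALSE)
  m <- as.matrix(counts[, LIB_IDS])
  if (any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(m) == 0)) {
    stop("every unitag must have at least one positive count", call. = FALSE)
  }
  if (!all(LIB_IDS %in% names(totals))) {
    stop("totals must be named NAS, NAT, AS, AT", call. = FALSE)
  }
  totals <- totals[LIB_IDS]
  if (any(totals < 1)) stop("library totals must be >= 1", call. = FALSE)
  if (any(colSums(m) > totals)) {
    stop("column sums exceed library totals", call. = FALSE)
  }
  rownames(counts) <- NULL
  structure(counts, totals = totals,
            class = c("unitag_table", "data.frame"))
}

#' @export
print.unitag_table <- function(x, ...) {
  totals <- attr(x, "totals")
  cat("Unitag table:", nrow(x), "unitags over 4 libraries\n")
  cat("Library totals:",
      paste(sprintf("%s=%s", names(totals),
                    format(totals, big.mark = ",")), collapse = "  "),
      "\n")
  NextMethod()
}

#' Library totals of a unitag table
#'
#' @param x A `unitag_table`.
#' @return Named numeric vector of the four library totals.
#' @export
library_totals <- function(x) {
  stopifnot(inherits(x, "unitag_table"))
  attr(x, "totals")
}

#' Aggregate extracted tags into a unitag count table
#'
#' Counts the multiplicity of every distinct tag sequence per library.
#' Library totals are the numbers of input tags (all extracted tags,
#' including tags that later fail abundance filters).
#'
#' @param tag_lists Named list of four character vectors of Supertags,
#'   names `NAS`, `NAT`, `AS`, `AT`. Every library must contain at
#'   least one tag (a library total of zero is meaningless).
#' @return A [unitag_table()].
#' @export
count_unitags <- function(tag_lists) {
  if (!is.list(tag_lists) || !all(LIB_IDS %in% names(tag_lists))) {
    stop("tag_lists must be a named list with elements NAS, NAT, AS, AT",
         call. = FALSE)
  }
  tag_lists <- tag_lists[LIB_IDS]
  lens <- lengths(tag_lists)
  if (any(lens == 0L)) {
    stop("empty library: ", paste(LIB_IDS[lens == 0L], collapse = ", "),
         call. = FALSE)
  }
  for (l in LIB_IDS) .check_supertag(tag_lists[[l]])
  all_tags <- sort(unique(unlist(tag_lists, use.names = FALSE)))
  counts <- vapply(tag_lists, function(tags) {
    tabulate(factor(tags, levels = all_tags), nbins = length(all_tags))
  }, integer(length(all_tags)))
  df <- data.frame(tag = all_tags, counts, stringsAsFactors = FALSE)
  unitag_table(df, setNames(as.numeric(lens), LIB_IDS))
}

#' Tags-per-million normalization
#'
#' TPM = count / total x 10^6, at full precision. Values are rounded
#' only at presentation ([round_half_up()] to 2 decimals reproduces
#' printed table values, e.g. a singleton in a library of 5,357,611
#' tags prints as 0.19).
#'
#' @param count Non-negative integer count(s), each at most `total`.
#' @param total Positive library total (recycled).
#' @return Numeric TPM value(s), zero exactly when the count is zero.
#' @seealso [denormalize_tpm()], [round_half_up()]
#' @export
normalize_tpm <- function(count, total) {
  if (any(total < 1)) stop("library total must be >= 1", call. = FALSE)
  if (any(count < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(count > total)) stop("count exceeds library total", call. = FALSE)
  count / total * 1e6
}

#' Recover a raw count from a (possibly rounded) TPM value
#'
#' Inverse of [normalize_tpm()] up to presentation rounding:
#' round(tpm x total / 10^6) to the nearest integer (halves up). For
#' any TPM printed to 2 decimals from a true count, this returns that
#' count whenever the library total is below about 10^7.
#'
#' @param tpm Non-negative TPM value(s).
#' @param total Positive library total (recycled).
#' @return Integer count(s).
#' @export
denormalize_tpm <- function(tpm, total) {
  if (any(tpm < 0)) stop("tpm must be non-negative", call. = FALSE)
  if (any(total < 1)) stop("library total must be >= 1", call. = FALSE)
  as.integer(floor(tpm * total / 1e6 + 0.5))
}

#' Half-up decimal rounding
#'
#' Rounds halves away from zero (for non-negative input, upward),
#' matching the presentation convention of the printed expression
#' tables; `round_half_up(0.125, 2)` is 0.13 where base `round()`
#' would give 0.12.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2).
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Full-precision TPM matrix of a unitag table
#'
#' @param x A `unitag_table`.
#' @return Numeric matrix (rows = tags, columns = libraries) of
#'   unrounded TPM values.
#' @export
tpm_matrix <- function(x) {
  stopifnot(inherits(x, "unitag_table"))
  totals <- attr(x, "totals")
  m <- as.matrix(x[, LIB_IDS])
  out <- sweep(m, 2L, as.numeric(totals), "/") * 1e6
  rownames(out) <- x$tag
  out
}

#' Write a unitag count matrix as TSV
#'
#' The dialect is a `#totals` header line carrying the four library
#' totals in column order, then a tab-separated table with header
#' `tag NAS NAT AS AT`.
#'
#' @param x A `unitag_table`.
#' @param path Output file.
#' @export
write_count_matrix <- function(x, path) {
  stopifnot(inherits(x, "unitag_table"))
  totals <- attr(x, "totals")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#totals", format(totals, scientific = FALSE,
                                       trim = TRUE)),
                   collapse = "\t"), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a unitag count matrix written by [write_count_matrix()]
#'
#' @param path Input TSV file.
#' @return A [unitag_table()].
#' @export
read_count_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "#totals")) {
    stop("missing #totals header line in ", path, call. = FALSE)
  }
  totals <- as.numeric(strsplit(first, "\t", fixed = TRUE)[[1L]][-1L])
  df <- read.delim(path, skip = 1L, stringsAsFactors = FALSE,
                   colClasses = c("character", rep("integer", 4L)))
  unitag_table(df, setNames(totals, LIB_IDS))
}
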