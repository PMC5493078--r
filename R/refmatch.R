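# Anchored tag-to-reference matching.
#
# A tag identifies a reference when at least 22 of its 26 nt match an
# anchored window of the reference and the 4-nt CATG anchor matches
# exactly. Matching is ungapped; both strands are scanned, the reverse
# strand via the reverse complement of the reference with offsets
# mapped back to forward coordinates. Scanning only CATG occurrences
# is exhaustive: an accepted match requires an exact anchor, which is
# itself a CATG occurrence.

.empty_matches <- function() {
  data.frame(tag = character(0), ref_id = character(0),
             offset = integer(0), strand = character(0),
             identity = integer(0), anchor_ok = logical(0),
             stringsAsFactors = FALSE)
}

# Scan one strand of a reference; `seq` is already oriented, offsets
# are mapped back to the forward strand via `len_fwd`.
.scan_strand <- function(tag, seq, ref_id, strand, len_fwd) {
  pos <- gregexpr(TAG_ANCHOR, seq, fixed = TRUE)[[1L]]
  if (pos[1L] == -1L) return(.empty_matches())
  pos <- pos[pos + TAG_LENGTH - 1L <= nchar(seq)]
  if (length(pos) == 0L) return(.empty_matches())
  tagc <- strsplit(tag, "", fixed = TRUE)[[1L]]
  identity <- integer(length(pos))
  for (j in seq_along(pos)) {
    wc <- strsplit(substr(seq, pos[j], pos[j] + TAG_LENGTH - 1L),
                   "", fixed = TRUE)[[1L]]
    identity[j] <- sum(wc == tagc & wc != "N")
  }
  offset <- if (strand == "sense") {
    pos - 1L
  } else {
    len_fwd - (pos - 1L) - TAG_LENGTH
  }
  data.frame(tag = tag, ref_id = ref_id, offset = as.integer(offset),
             strand = strand, identity = identity,
             anchor_ok = TRUE,  # window starts with CATG = tag anchor
             stringsAsFactors = FALSE)
}

#' Match one tag against one reference sequence
#'
#' Compares the tag position-wise to every fully contained 26-nt
#' window starting at a CATG occurrence, on both strands. An N in the
#' reference never counts as a match. Windows with identity of at
#' least `min_identity` (anchor included, and matching exactly) are
#' returned best first; ties are broken by smaller forward-strand
#' offset, then sense before antisense.
#'
#' @param tag A single Supertag.
#' @param ref A single reference sequence (A, C, G, T, N).
#' @param ref_id Identifier carried into the result.
#' @param min_identity Minimum matching positions out of 26
#'   (default 22).
#' @return A data.frame with columns `tag`, `ref_id`, `offset`
#'   (0-based forward-strand start of the window, half-open
#'   `[offset, offset + 26)`), `strand` (`"sense"` or `"antisense"`),
#'   `identity` and `anchor_ok`; zero rows when nothing qualifies.
#' @export
match_tag <- function(tag, ref, ref_id = "ref", min_identity = 22L) {
  .check_supertag(tag)
  .check_dna(ref, "reference")
  stopifnot(length(ref) == 1L)
  len <- nchar(ref)
  res <- rbind(
    .scan_strand(tag, ref, ref_id, "sense", len),
    .scan_strand(tag, reverse_complement(ref), ref_id, "antisense", len)
  )
  res <- res[res$identity >= min_identity & res$anchor_ok, , drop = FALSE]
  if (nrow(res) == 0L) return(.empty_matches())
  res <- res[order(-res$identity, res$offset, res$strand != "sense"), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

# Enumerate all anchored, fully contained 26-nt windows of a
# reference set on both strands, as a character matrix (one row per
# window) plus window coordinates. Built once per reference set so
# matching many tags is a vectorized comparison.
.reference_windows <- function(refs) {
  rows <- vector("list", 2L * length(refs))
  k <- 0L
  for (id in names(refs)) {
    s_fwd <- refs[[id]]
    len <- nchar(s_fwd)
    for (strand in c("sense", "antisense")) {
      s <- if (strand == "sense") s_fwd else reverse_complement(s_fwd)
      pos <- gregexpr(TAG_ANCHOR, s, fixed = TRUE)[[1L]]
      if (pos[1L] == -1L) next
      pos <- pos[pos + TAG_LENGTH - 1L <= len]
      if (length(pos) == 0L) next
      offset <- if (strand == "sense") pos - 1L else len - (pos - 1L) - TAG_LENGTH
      k <- k + 1L
      rows[[k]] <- data.frame(ref_id = id, offset = as.integer(offset),
                              strand = strand,
                              window = substring(s, pos, pos + TAG_LENGTH - 1L),
                              stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows[seq_len(k)])
  if (is.null(tab) || nrow(tab) == 0L) return(NULL)
  chars <- matrix(unlist(strsplit(tab$window, "", fixed = TRUE),
                         use.names = FALSE),
                  nrow = nrow(tab), byrow = TRUE)
  list(table = tab, chars = chars, not_n = chars != "N")
}

#' Match a set of tags against a reference set
#'
#' Same acceptance rules as [match_tag()], applied to every tag /
#' reference pair; the anchored windows of the reference set are
#' indexed once, so large tag sets match quickly.
#'
#' @param tags Character vector of Supertags.
#' @param refs Named character vector of reference sequences, or a
#'   path to a FASTA file (read via [read_reference()]).
#' @param min_identity Minimum identity, as in [match_tag()].
#' @return Combined data.frame of accepted matches for all tag /
#'   reference pairs, ordered by tag then match quality.
#' @export
match_tags <- function(tags, refs, min_identity = 22L) {
  if (length(tags) == 0L) return(.empty_matches())
  tags <- unique(tags)
  .check_supertag(tags)
  if (is.character(refs) && length(refs) == 1L && file.exists(refs)) {
    refs <- read_reference(refs)
  }
  if (is.null(names(refs)) || any(!nzchar(names(refs)))) {
    stop("references must be named", call. = FALSE)
  }
  idx <- .reference_windows(refs)
  if (is.null(idx)) return(.empty_matches())
  out <- vector("list", length(tags))
  for (i in seq_along(tags)) {
    tagc <- strsplit(tags[i], "", fixed = TRUE)[[1L]]
    eq <- idx$chars == matrix(tagc, nrow(idx$chars), TAG_LENGTH,
                              byrow = TRUE)
    identity <- as.integer(rowSums(eq & idx$not_n))
    hit <- identity >= min_identity
    if (!any(hit)) next
    res <- idx$table[hit, c("ref_id", "offset", "strand"), drop = FALSE]
    res <- data.frame(tag = tags[i], res, identity = identity[hit],
                      anchor_ok = TRUE, stringsAsFactors = FALSE)
    out[[i]] <- res[order(-res$identity, res$offset,
                          res$strand != "sense"), , drop = FALSE]
  }
  res <- do.call(rbind, out)
  if (is.null(res) || nrow(res) == 0L) return(.empty_matches())
  rownames(res) <- NULL
  res
}

#' Strand classification of matched tags
#'
#' A tag is `"antisense"` when its best accepted match (highest
#' identity; ties broken as in [match_tag()]) lies on the reverse
#' strand, `"sense"` when on the forward strand, and `"both"` when
#' equal-identity best matches exist on both strands (reported, never
#' silently resolved). Tags without accepted matches are `"none"`.
#'
#' @param matches Data.frame of accepted matches from [match_tags()].
#' @param tags Optional character vector of tags to report on
#'   (defaults to the tags present in `matches`).
#' @return Named character vector (`sense`, `antisense`, `both` or
#'   `none` per tag).
#' @export
classify_strand <- function(matches, tags = NULL) {
  if (is.null(tags)) tags <- unique(matches$tag)
  out <- setNames(rep("none", length(tags)), tags)
  for (tg in tags) {
    sub <- matches[matches$tag == tg, , drop = FALSE]
    if (nrow(sub) == 0L) next
    best <- max(sub$identity)
    strands <- unique(sub$strand[sub$identity == best])
    out[tg] <- if (length(strands) == 2L) "both" else strands
  }
  out
}

#' Group accepted matches by reference
#'
#' Exposes multi-tag genes: references carrying two or more NlaIII
#' sites can be identified by several distinct tags.
#'
#' @param matches Data.frame of accepted matches from [match_tags()].
#' @return Named list mapping each matched `ref_id` to the character
#'   vector of distinct tags matching it; empty list when there are
#'   no matches.
#' @export
multi_site_report <- function(matches) {
  if (nrow(matches) == 0L) return(setNames(list(), character(0)))
  lapply(split(matches$tag, matches$ref_id), unique)
}

#' Read a reference FASTA file
#'
#' @param path FASTA file (optionally gzip-compressed).
#' @return Named character vector of reference sequences.
#' @export
read_reference <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write reference sequences as FASTA
#'
#' @param refs Named character vector of sequences.
#' @param path Output file.
#' @export
write_reference <- function(refs, path) {
  stopifnot(!is.null(names(refs)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(refs), path)
  invisible(path)
}
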