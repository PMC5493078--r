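# Supertag extraction from ditag or single-tag reads.
#
# Ditags are two 26-nt tags ligated at their non-anchor ends, so a
# clean ditag reads CATG + 22 nt + 22 nt(rc) + CATG over 52 nt. The
# forward tag is read off the 5'-most CATG; the reverse tag is the
# reverse complement of the last 26 nt, accepted only when it starts
# with the anchor itself.

#' Extract 26-nt Supertags from reads
#'
#' Recovers up to two tags per read. The forward tag is the 26-nt
#' window starting at the 5'-most CATG occurrence, emitted when at
#' least 26 nt remain from that anchor and the window is free of N.
#' The reverse tag is the reverse complement of the final 26 nt of the
#' read, emitted when it begins with CATG (CATG is its own reverse
#' complement), is free of N, and its window does not start at the
#' same position as the forward tag (a single-tag read yields the tag
#' once, not twice). Reads from which nothing can be extracted yield
#' an empty element; their number is attached as attribute
#' `n_unextractable`.
#'
#' @param reads Character vector of read sequences over {A,C,G,T,N}.
#' @return A list (one element per read) of character vectors holding
#'   0, 1 or 2 Supertags, with attribute `n_unextractable`.
#' @examples
#' extract_tags("AAATTTGGG")  # no anchor: empty
#' @seealso [extract_tags_flat()], [read_reads()]
#' @export
extract_tags <- function(reads) {
  .check_dna(reads, "read")
  if (any(nchar(reads) < 1L)) stop("empty read sequence", call. = FALSE)
  n <- length(reads)
  len <- nchar(reads)

  # forward: 5'-most anchor
  fpos <- as.integer(regexpr(TAG_ANCHOR, reads, fixed = TRUE))
  fwd <- rep(NA_character_, n)
  ok <- fpos > 0L & (len - fpos + 1L) >= TAG_LENGTH
  fwd[ok] <- substr(reads[ok], fpos[ok], fpos[ok] + TAG_LENGTH - 1L)
  fwd[!is.na(fwd) & grepl("N", fwd, fixed = TRUE)] <- NA_character_

  # reverse: rc of the 3'-terminal 26-nt window
  rstart <- len - TAG_LENGTH + 1L
  rtag <- rep(NA_character_, n)
  long <- len >= TAG_LENGTH
  if (any(long)) {
    rwin <- substr(reads[long], rstart[long], len[long])
    rtag[long] <- reverse_complement(rwin)
  }
  drop <- !is.na(rtag) &
    (substr(rtag, 1L, 4L) != TAG_ANCHOR | grepl("N", rtag, fixed = TRUE))
  rtag[drop] <- NA_character_
  # deduplicate a window coinciding with the forward anchor
  rtag[!is.na(rtag) & !is.na(fwd) & rstart == fpos] <- NA_character_

  out <- mapply(function(a, b) {
    tags <- c(a, b)
    tags[!is.na(tags)]
  }, fwd, rtag, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  names(out) <- names(reads)
  attr(out, "n_unextractable") <- sum(lengths(out) == 0L)
  out
}

#' Extract tags from reads as one flat vector
#'
#' Convenience wrapper around [extract_tags()] that concatenates the
#' per-read tag lists, preserving read order (forward tag before
#' reverse tag within a read).
#'
#' @inheritParams extract_tags
#' @return Character vector of Supertags.
#' @export
extract_tags_flat <- function(reads) {
  unlist(extract_tags(reads), use.names = FALSE)
}

#' Read sequences from a FASTA or FASTQ file
#'
#' Thin wrapper over Biostrings, accepting plain or gzip-compressed
#' files. The format is guessed from the file extension unless given.
#' FASTQ quality strings are read but discarded: no quality filtering
#' is applied anywhere in the pipeline.
#'
#' @param path Path to a FASTA or FASTQ file (optionally .gz).
#' @param format `"auto"` (default), `"fasta"` or `"fastq"`.
#' @return Named character vector of sequences.
#' @export
read_reads <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    base <- sub("\\.gz$", "", path)
    format <- if (grepl("\\.(fq|fastq)$", base, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  x <- Biostrings::readDNAStringSet(path, format = format)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write tag sequences, one per line
#'
#' @param tags Character vector of Supertags.
#' @param path Output file.
#' @export
write_tags <- function(tags, path) {
  .check_supertag(tags)
  writeLines(tags, path)
  invisible(path)
}

#' Read tag sequences written by [write_tags()]
#'
#' @param path Input file, one tag per line.
#' @return Character vector of Supertags.
#' @export
read_tags <- function(path) {
  tags <- readLines(path)
  tags <- tags[nzchar(tags)]
  .check_supertag(tags)
  tags
}
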