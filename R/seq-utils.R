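# Nucleotide string helpers shared by extraction, matching and simulation.

.check_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) == 0L) {
    stop(what, " must be a non-empty character vector", call. = FALSE)
  }
  if (anyNA(seq)) stop(what, " contains NA", call. = FALSE)
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop(what, " contains characters outside {A,C,G,T,N}: ",
         paste(utils::head(seq[bad], 3L), collapse = ", "), call. = FALSE)
  }
  invisible(seq)
}

.check_supertag <- function(tag) {
  .check_dna(tag, "tag")
  ok <- nchar(tag) == TAG_LENGTH &
    substr(tag, 1L, 4L) == TAG_ANCHOR &
    !grepl("N", tag, fixed = TRUE)
  if (!all(ok)) {
    stop("not a valid Supertag (26 nt, CATG prefix, no N): ",
         paste(utils::head(tag[!ok], 3L), collapse = ", "), call. = FALSE)
  }
  invisible(tag)
}

#' Watson-Crick reverse complement
#'
#' Standard reverse complement over the alphabet A, C, G, T, N
#' (N maps to N). The operation is an involution, and the NlaIII
#' anchor CATG is its own reverse complement.
#'
#' @param seq Character vector of nucleotide sequences.
#' @return Character vector of the same length with each sequence
#'   reverse-complemented. Names are preserved.
#' @examples
#' reverse_complement("AACCG")  # "CGGTT"
#' reverse_complement("CATG")   # palindromic
#' @export
reverse_complement <- function(seq) {
  .check_dna(seq)
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
  names(out) <- names(seq)
  out
}

#' Test whether sequences are valid Supertags
#'
#' A Supertag is exactly 26 nt long, begins with the CATG anchor and
#' contains no ambiguous (N) bases.
#'
#' @param seq Character vector.
#' @return Logical vector.
#' @export
is_supertag <- function(seq) {
  if (!is.character(seq)) return(rep(FALSE, length(seq)))
  !is.na(seq) &
    !grepl("[^ACGTN]", seq) &
    nchar(seq) == TAG_LENGTH &
    substr(seq, 1L, 4L) == TAG_ANCHOR &
    !grepl("N", seq, fixed = TRUE)
}

#' Introduce substitutions outside the tag anchor
#'
#' Mutates `n_sub` distinct positions of a 26-nt tag to a different
#' base, drawing positions from outside the 4-nt CATG anchor (so the
#' result is still a valid Supertag). Used to plant controlled
#' mismatches for reference-matching tests and simulations. Uses the
#' current RNG state; seed upstream for reproducibility.
#'
#' @param tag A single Supertag.
#' @param n_sub Number of substitutions, 0 to 22.
#' @return The mutated tag.
#' @export
mutate_tag <- function(tag, n_sub) {
  .check_supertag(tag)
  n_sub <- as.integer(n_sub)
  stopifnot(length(tag) == 1L, n_sub >= 0L, n_sub <= TAG_LENGTH - 4L)
  if (n_sub == 0L) return(tag)
  chars <- strsplit(tag, "", fixed = TRUE)[[1L]]
  pos <- sample(5:TAG_LENGTH, n_sub)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Random Supertag sequences
#'
#' Draws tags as CATG followed by 22 uniformly random bases, without
#' duplicates. Uses the current RNG state.
#'
#' @param n Number of tags.
#' @return Character vector of `n` distinct Supertags.
#' @export
random_tags <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 0L)
  if (n == 0L) return(character(0L))
  draw <- function(k) {
    suffix <- matrix(sample(c("A", "C", "G", "T"), k * (TAG_LENGTH - 4L),
                            replace = TRUE),
                     nrow = k)
    paste0(TAG_ANCHOR, apply(suffix, 1L, paste, collapse = ""))
  }
  tags <- unique(draw(n))
  while (length(tags) < n) {
    tags <- unique(c(tags, draw(n - length(tags))))
  }
  tags[seq_len(n)]
}

# Evaluate `code` under `seed`, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}
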