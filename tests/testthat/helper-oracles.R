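# Independent oracles used across the suite.

# Exhaustive ungapped matcher: scores EVERY offset of the reference
# (not only CATG-anchored ones) on both strands, then applies the
# identity and anchor criteria. Used to prove the anchored scan of
# match_tag() exhaustive.
brute_force_match <- function(tag, ref, ref_id = "ref", min_identity = 22L) {
  tagc <- strsplit(tag, "", fixed = TRUE)[[1L]]
  len <- nchar(ref)
  rows <- list()
  for (strand in c("sense", "antisense")) {
    s <- if (strand == "sense") ref else reverse_complement(ref)
    for (p in seq_len(nchar(s) - 25L)) {
      wc <- strsplit(substr(s, p, p + 25L), "", fixed = TRUE)[[1L]]
      identity <- sum(wc == tagc & wc != "N")
      anchor_ok <- all(wc[1:4] == tagc[1:4])
      if (identity >= min_identity && anchor_ok) {
        offset <- if (strand == "sense") p - 1L else len - (p - 1L) - 26L
        rows[[length(rows) + 1L]] <- data.frame(
          tag = tag, ref_id = ref_id, offset = as.integer(offset),
          strand = strand, identity = as.integer(identity),
          anchor_ok = TRUE, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) return(supersage:::.empty_matches())
  out <- do.call(rbind, rows)
  out <- out[order(-out$identity, out$offset, out$strand != "sense"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# Exact-rational tail probabilities of the Audic-Claverie posterior
# for equal library sizes, computed with arbitrary-precision rational
# arithmetic (python fractions; p(k|x) = C(x+k,k) / 2^(x+k+1)), then
# correctly rounded to double. Returns a data.frame over the full
# (x, y) grid with exact lower and upper tails.
ac_exact_grid <- function(xmax = 60L, ymax = 60L) {
  script <- c(
    "from fractions import Fraction",
    sprintf("xmax, ymax = %d, %d", xmax, ymax),
    "for x in range(xmax + 1):",
    "    term = Fraction(1, 2 ** (x + 1))",
    "    cum = Fraction(0)",
    "    lows = []",
    "    for k in range(ymax + 1):",
    "        if k > 0:",
    "            term = term * (x + k) / (2 * k)",
    "        cum += term",
    "        lows.append(cum)",
    "    for y in range(ymax + 1):",
    "        lo = lows[y]",
    "        up = 1 - (lows[y - 1] if y > 0 else Fraction(0))",
    "        print(x, y, repr(float(lo)), repr(float(up)))"
  )
  f <- tempfile(fileext = ".py")
  writeLines(script, f)
  out <- system2("python", f, stdout = TRUE)
  read.table(text = out, col.names = c("x", "y", "lower", "upper"))
}

# Reference sequence with a tag planted at a CATG-anchored site.
# `offset` is 0-based; the tag overwrites ref[offset+1 .. offset+26].
plant_tag <- function(ref, tag, offset) {
  stopifnot(offset + 26L <= nchar(ref))
  substr(ref, offset + 1L, offset + 26L) <- tag
  ref
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
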