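# Audic-Claverie exact test for digital tag counts.
#
# Given x occurrences of a tag in a library of n1 total tags, the
# posterior probability of seeing y occurrences in a second library of
# n2 tags is
#
#   p(y | x) = (n2/n1)^y * (x+y)! / (x! y! (1 + n2/n1)^(x+y+1)),
#
# a negative-binomial distribution in y with size x+1 and success
# probability n1/(n1+n2). Tail sums of this pmf give the significance
# of an observed count difference.

.ac_logpmf <- function(x, k, r) {
  lgamma(x + k + 1) - lgamma(x + 1) - lgamma(k + 1) +
    k * log(r) - (x + k + 1) * log1p(r)
}

.logsumexp <- function(lp) {
  m <- max(lp)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(lp - m)))
}

# Lower tail: sum_{k <= y} p(k | x).
.ac_lower <- function(x, y, r) {
  min(1, exp(.logsumexp(.ac_logpmf(x, 0:y, r))))
}

# Upper tail: sum_{k >= y} p(k | x), summed directly past the mode
# until terms are negligible (avoids cancellation in 1 - lower).
.ac_upper <- function(x, y, r) {
  mode_k <- floor(x * r)
  kmax <- max(y, mode_k) + 64
  repeat {
    lp <- .ac_logpmf(x, y:kmax, r)
    ls <- .logsumexp(lp)
    if (kmax > mode_k && lp[length(lp)] < ls + log(1e-18)) {
      return(min(1, exp(ls)))
    }
    kmax <- kmax * 2 + 64
  }
}

#' Audic-Claverie significance of a count difference
#'
#' Exact test comparing the count of one tag between two libraries of
#' possibly different depths, based on the posterior probability
#' p(y|x) for digital count data (see the package vignette for the
#' formula). The one-sided p-value is the smaller of the lower and
#' upper tail sums at the observed `y`; the two-sided p-value doubles
#' it, capped at 1. Computation is in log space via log-gamma; the
#' infinite upper tail is summed directly until convergence, so no
#' cancellation-prone complementation is involved.
#'
#' @param x,y Observed counts in library 1 and library 2
#'   (non-negative integers; vectors are recycled).
#' @param n1,n2 Total tag counts of the two libraries (positive).
#' @param sided `"two"` (default) or `"one"`.
#' @return p-value(s) in \[0, 1\].
#' @examples
#' audic_claverie_p(0, 5, 1e6, 1e6, sided = "one")  # 2^-5 = 0.03125
#' @export
audic_claverie_p <- function(x, y, n1, n2, sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (any(x < 0) || any(y < 0) || any(x != round(x)) || any(y != round(y))) {
    stop("x and y must be non-negative integers", call. = FALSE)
  }
  if (any(n1 < 1) || any(n2 < 1)) {
    stop("library totals must be >= 1", call. = FALSE)
  }
  n <- max(length(x), length(y), length(n1), length(n2))
  x <- rep_len(x, n); y <- rep_len(y, n)
  n1 <- rep_len(n1, n); n2 <- rep_len(n2, n)
  p <- vapply(seq_len(n), function(i) {
    r <- n2[i] / n1[i]
    one <- min(.ac_lower(x[i], y[i], r), .ac_upper(x[i], y[i], r))
    if (sided == "one") one else min(1, 2 * one)
  }, numeric(1L))
  p
}
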