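#' Randomness indices of a digit-generation sequence
#'
#' Three classical indices of how non-random a subject's 100-digit sequence
#' is. All are proportions in [0, 1]; higher means more structured (less
#' random) output.
#'
#' `counting_bias()` (CB) is the fraction of adjacent pairs that count up or
#' down by one, |s[i+1] - s[i]| = 1 (non-modular: 9 -> 0 is not counting),
#' over the length-1 adjacent pairs. A uniform random sequence gives about
#' 0.18 (18 of the 100 equiprobable ordered digit pairs differ by 1).
#'
#' `interval_bias()` (IB) is the fraction of adjacent signed inter-digit
#' differences that repeat, d[i+1] = d[i] with d[i] = s[i+1] - s[i], over the
#' length-2 difference pairs.
#'
#' `rng_index()` is the digram-concentration (Evans) index: from the 10x10
#' table of first-order pair counts n_ij with row marginals n_i,
#' RNG = sum(n_ij log n_ij) / sum(n_i log n_i) over occupied cells. It is 0
#' when every occupied digram occurs once and 1 when each row's mass sits in
#' a single cell. When all row marginals are 1 (denominator 0) the index is
#' defined as 0.
#'
#' @param s A digit sequence: integer vector with values in 0-9, length >= 2
#'   (>= 3 for `interval_bias`).
#' @return A single number in [0, 1].
#' @export
#' @examples
#' counting_bias(as.integer(strsplit("0123456789", "")[[1]]))  # 1
#' rng_index(rep(5L, 10))                                      # 1
counting_bias <- function(s) {
  s <- check_digits(s, 2L)
  d <- diff(s)
  mean(abs(d) == 1L)
}

#' @rdname counting_bias
#' @export
interval_bias <- function(s) {
  s <- check_digits(s, 3L)
  d <- diff(s)
  mean(d[-1L] == d[-length(d)])
}

#' @rdname counting_bias
#' @export
rng_index <- function(s) {
  s <- check_digits(s, 2L)
  pairs <- paste(s[-length(s)], s[-1L])
  nij <- as.numeric(table(pairs))
  ni <- as.numeric(table(s[-length(s)]))
  den <- sum(ni * log(ni))
  if (den == 0) return(0)       # all-singleton rows: index defined as 0
  sum(nij * log(nij)) / den
}

#' @rdname counting_bias
#' @return `randomness_indices()` returns a named numeric vector with
#'   elements `cb`, `ib`, `rng`.
#' @export
randomness_indices <- function(s) {
  c(cb = counting_bias(s), ib = interval_bias(s), rng = rng_index(s))
}

check_digits <- function(s, min_len) {
  s <- as.integer(unclass(s))
  if (length(s) < min_len) {
    stop("digit sequence must have length >= ", min_len, call. = FALSE)
  }
  if (anyNA(s) || any(s < 0L | s > 9L)) {
    stop("digit sequence must contain only values 0-9", call. = FALSE)
  }
  s
}
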