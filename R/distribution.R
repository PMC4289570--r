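# Fine-grained distributions over integer letter change -30..+30.
#
# A fine_grain_distribution is a probability vector p with one entry per
# integer letter change on the grid, named "-30".."30". Values outside the
# grid carry zero mass by construction.

letter_grid <- function() LETTER_MIN:LETTER_MAX

#' Fine-grained letter-change distribution
#'
#' Validates and wraps a probability vector over the 61 integer letter
#' changes \code{-30..+30}.
#'
#' @param probs Numeric vector of length 61 (or named by letter change);
#'   non-negative, summing to 1 within \code{1e-9}.
#' @return A named numeric vector of class \code{fine_grain_distribution}.
#' @export
fine_grain_distribution <- function(probs) {
  grid <- letter_grid()
  if (length(probs) != length(grid))
    stop("expected ", length(grid), " probabilities, one per integer change")
  if (any(probs < 0)) stop("probabilities must be non-negative")
  if (abs(sum(probs) - 1) > 1e-9) stop("probabilities must sum to 1")
  structure(setNames(as.numeric(probs), as.character(grid)),
            class = "fine_grain_distribution")
}

#' Expand range probabilities uniformly over the letters they contain
#'
#' Each range's probability is split equally over the integer letter values
#' inside it (e.g. 9 values in \code{[-4,+4]}, 11 in \code{[+20,+30]}),
#' giving a fine-grained distribution consistent with the range masses.
#'
#' @param q Numeric probability vector, one entry per row of \code{scheme}.
#' @param scheme A [category_scheme()].
#' @return A [fine_grain_distribution()].
#' @export
expand_uniform <- function(q, scheme) {
  stopifnot(length(q) == nrow(scheme))
  grid <- letter_grid()
  p <- numeric(length(grid))
  for (j in seq_len(nrow(scheme))) {
    idx <- which(grid >= scheme$lower[j] & grid <= scheme$upper[j])
    p[idx] <- q[j] / length(idx)
  }
  fine_grain_distribution(p)
}

#' Moments of a fine-grained distribution
#'
#' Mean and population standard deviation (letters) of the letter-change
#' distribution: \code{mean = sum(i * p_i)} and
#' \code{sd = sqrt(sum(p_i * (i - mean)^2))} over \code{i = -30..+30}.
#'
#' @param p A [fine_grain_distribution()] (or plain length-61 vector).
#' @return A length-1 numeric.
#' @export
distribution_mean <- function(p) {
  sum(letter_grid() * as.numeric(p))
}

#' @rdname distribution_mean
#' @export
distribution_sd <- function(p) {
  m <- distribution_mean(p)
  sqrt(sum(as.numeric(p) * (letter_grid() - m)^2))
}

#' Probability of a letter-change range
#'
#' Sums \code{p_i} over \code{lower <= i <= upper} (inclusive bounds).
#'
#' @param p A [fine_grain_distribution()] (or plain length-61 vector).
#' @param lower,upper Inclusive integer letter bounds.
#' @return A probability.
#' @export
aggregate_range <- function(p, lower, upper) {
  grid <- letter_grid()
  sum(as.numeric(p)[grid >= lower & grid <= upper])
}
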