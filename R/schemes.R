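#' @useDynLib mnitc, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats optim quantile rgamma runif sd var setNames
#' @importFrom utils read.csv write.csv head
NULL

# Letter-change grid shared by all schemes: integer changes from baseline.
LETTER_MIN <- -30L
LETTER_MAX <- 30L

#' Construct a category scheme for BCVA letter change
#'
#' A category scheme is an ordered partition of the integer letter-change grid
#' \code{-30..+30} into labelled, contiguous, non-overlapping ranges with
#' inclusive integer bounds. Rows are ordered from the greatest gain (row 1)
#' to the greatest loss (last row), matching the convention of trial report
#' tables.
#'
#' @param name Scheme label.
#' @param categories A data frame with columns \code{label}, \code{lower},
#'   \code{upper} (inclusive integer letter bounds), in any row order.
#' @return An object of class \code{category_scheme}: a data frame with
#'   columns \code{label}, \code{lower}, \code{upper} ordered gain-first, plus
#'   a \code{name} attribute.
#' @seealso [ranibizumab_scheme()], [geneva_scheme()], [common_refinement()]
#' @export
category_scheme <- function(name, categories) {
  stopifnot(is.data.frame(categories),
            all(c("label", "lower", "upper") %in% names(categories)))
  cat <- data.frame(label = as.character(categories$label),
                    lower = as.integer(categories$lower),
                    upper = as.integer(categories$upper),
                    stringsAsFactors = FALSE)
  cat <- cat[order(cat$lower, decreasing = TRUE), , drop = FALSE]
  rownames(cat) <- NULL
  if (any(cat$lower > cat$upper))
    stop("each category must have lower <= upper")
  # contiguity and coverage of the full grid
  if (cat$upper[1L] != LETTER_MAX || cat$lower[nrow(cat)] != LETTER_MIN)
    stop("categories must cover ", LETTER_MIN, "..", LETTER_MAX)
  if (nrow(cat) > 1L) {
    gaps <- cat$lower[-nrow(cat)] - cat$upper[-1L]
    if (any(gaps != 1L))
      stop("categories must be contiguous and non-overlapping")
  }
  structure(cat, name = name, class = c("category_scheme", "data.frame"))
}

#' @export
print.category_scheme <- function(x, ...) {
  cat("Category scheme:", attr(x, "name"), "(", nrow(x), "categories )\n")
  print(as.data.frame(x), ...)
  invisible(x)
}

scheme_name <- function(scheme) attr(scheme, "name")

category_sizes <- function(scheme) scheme$upper - scheme$lower + 1L

# Symmetric 5-category scheme from two positive cut-points a < b:
# gain >= b, gain in [a, b-1], |change| < a, loss in [a, b-1], loss >= b.
scheme_from_cuts <- function(name, a, b) {
  stopifnot(a > 0, b > a, b <= LETTER_MAX)
  category_scheme(name, data.frame(
    label = c(sprintf("Gain >=%d letters", b),
              sprintf("Gain >=%d and <%d letters", a, b),
              sprintf("Loss <%d letters and gain <%d letters", a, a),
              sprintf("Loss >=%d and <%d letters", a, b),
              sprintf("Loss >=%d letters", b)),
    lower = c(b, a, -(a - 1L), -(b - 1L), LETTER_MIN),
    upper = c(LETTER_MAX, b - 1L, a - 1L, -a, -b)))
}

#' Built-in category schemes
#'
#' \code{ranibizumab_scheme()} uses cut-points at +/-10 and +/-20 letters
#' (the 5 response classes used in the ranibizumab sham-controlled trials);
#' \code{geneva_scheme()} uses cut-points at +/-5 and +/-15 letters (the
#' classes published for the dexamethasone implant trials).
#'
#' @return A [category_scheme()] with 5 categories.
#' @export
ranibizumab_scheme <- function() scheme_from_cuts("ranibizumab", 10L, 20L)

#' @rdname ranibizumab_scheme
#' @export
geneva_scheme <- function() scheme_from_cuts("geneva", 5L, 15L)

#' Common refinement of two category schemes
#'
#' Returns the coarsest scheme refining both inputs: its boundaries are the
#' union of the two schemes' boundaries, so every input category is a union
#' of output ranges. For the two built-in schemes this yields the 9 ranges
#' with cuts at +/-5, +/-10, +/-15 and +/-20 letters.
#'
#' @param schemeA,schemeB [category_scheme()] objects.
#' @return A [category_scheme()], gain-first like its inputs.
#' @export
common_refinement <- function(schemeA, schemeB) {
  lowers <- sort(unique(c(schemeA$lower, schemeB$lower)))
  uppers <- c(lowers[-1L] - 1L, LETTER_MAX)
  lab <- function(l, u) {
    # reuse an input label when the range coincides with an input category
    for (s in list(schemeA, schemeB)) {
      hit <- which(s$lower == l & s$upper == u)
      if (length(hit)) return(s$label[hit[1L]])
    }
    sprintf("%+d..%+d letters", l, u)
  }
  category_scheme(
    paste0("refinement(", scheme_name(schemeA), ",", scheme_name(schemeB), ")"),
    data.frame(label = mapply(lab, lowers, uppers),
               lower = lowers, upper = uppers))
}

#' The 9-range common refinement of the built-in schemes
#'
#' Convenience accessor for
#' \code{common_refinement(ranibizumab_scheme(), geneva_scheme())}: the nine
#' ranges \code{[+20,+30], [+15,+19], [+10,+14], [+5,+9], [-4,+4], [-9,-5],
#' [-14,-10], [-19,-15], [-30,-20]} (gain-first order).
#'
#' @return A [category_scheme()] with 9 ranges.
#' @export
refinement_scheme <- function() {
  common_refinement(ranibizumab_scheme(), geneva_scheme())
}

# TRUE if every category of `coarse` is a union of categories of `fine`.
refines <- function(fine, coarse) {
  all(coarse$lower %in% fine$lower) && all(coarse$upper %in% fine$upper)
}

#' Re-express range probabilities on a coarser scheme
#'
#' Sums a probability vector indexed by the rows of \code{from} onto the rows
#' of \code{to}; \code{from} must refine \code{to}.
#'
#' @param q Numeric vector, one probability per row of \code{from}.
#' @param from,to [category_scheme()] objects.
#' @return Numeric vector, one probability per row of \code{to}, named by its
#'   labels.
#' @export
project_q <- function(q, from, to) {
  stopifnot(length(q) == nrow(from))
  if (!refines(from, to))
    stop("scheme '", scheme_name(from), "' does not refine '",
         scheme_name(to), "'")
  out <- vapply(seq_len(nrow(to)), function(j) {
    sum(q[from$lower >= to$lower[j] & from$upper <= to$upper[j]])
  }, numeric(1))
  setNames(out, to$label)
}

# Probability of an arbitrary letter range [lower, upper] that is exactly
# tiled by rows of `scheme`; errors if the range cuts across a category.
range_prob_from_q <- function(q, scheme, lower, upper) {
  inside <- scheme$lower >= lower & scheme$upper <= upper
  crossed <- !inside & scheme$upper >= lower & scheme$lower <= upper
  if (any(crossed))
    stop("range [", lower, ",", upper, "] is not aligned with scheme '",
         scheme_name(scheme), "' boundaries")
  sum(q[inside])
}
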