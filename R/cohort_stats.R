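#' Cross-tabulate fragment-size class against copy-number detectability
#'
#' Builds the 2x2 contingency table with rows = size class (biphasic /
#' monophasic) and columns = copy-number aberrations detected (yes / no):
#' `a` biphasic-detected, `b` biphasic-undetected, `c`
#' monophasic-detected, `d` monophasic-undetected.
#'
#' @param size_classes character vector, "biphasic"/"monophasic" per
#'   sample (or `size_profile_call` list).
#' @param detected logical vector: copy-number aberrations detected
#'   (i.e. profile unbalanced) per sample.
#' @return object of class `contingency_2x2`: list with counts a, b, c,
#'   d and n.
#' @export
tally_cohort <- function(size_classes, detected) {
  if (is.list(size_classes))
    size_classes <- vapply(size_classes, `[[`, "", "class")
  if (length(size_classes) != length(detected))
    stop("one size class and one detection flag per sample required")
  if (length(size_classes) == 0) stop("empty cohort")
  if (!all(size_classes %in% c("biphasic", "monophasic")))
    stop("size classes must be 'biphasic' or 'monophasic'")
  bi <- size_classes == "biphasic"
  structure(list(a = sum(bi & detected), b = sum(bi & !detected),
                 c = sum(!bi & detected), d = sum(!bi & !detected),
                 n = length(detected)), class = "contingency_2x2")
}

#' @rdname tally_cohort
#' @param a,b,c,d cell counts (non-negative integers).
#' @export
contingency_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (sum(counts) == 0) stop("table must contain at least one observation")
  structure(list(a = a, b = b, c = c, d = d, n = sum(counts)),
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("biphasic", "monophasic"),
                              c("detected", "not detected")))
  print(m)
  invisible(x)
}

#' Row percentages of a 2x2 table
#'
#' Detection rate within each size class, as percentages rounded to one
#' decimal: `100 a / (a + b)` for biphasic rows and `100 c / (c + d)`
#' for monophasic rows.
#'
#' @param table a `contingency_2x2`.
#' @return named numeric vector `c(biphasic = ..., monophasic = ...)`.
#' @export
row_percentages <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  if (table$a + table$b == 0 || table$c + table$d == 0)
    stop("zero row total")
  round(c(biphasic = 100 * table$a / (table$a + table$b),
          monophasic = 100 * table$c / (table$c + table$d)), 1)
}

#' Pearson chi-squared test for a 2x2 table
#'
#' `chi2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, df = 1, p from the
#' chi-squared survival function.  No continuity correction by default;
#' `correction = TRUE` applies Yates' correction
#' (`|ad - bc| - n/2`, floored at 0).
#'
#' @param table a `contingency_2x2`.
#' @param correction apply Yates' continuity correction.
#' @return list with `statistic`, `df` (= 1), `p_value`, `correction`.
#' @export
chi_square_2x2 <- function(table, correction = FALSE) {
  stopifnot(inherits(table, "contingency_2x2"))
  a <- table$a; b <- table$b; c <- table$c; d <- table$d; n <- table$n
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0))
    stop("chi-squared test undefined: a row or column margin is zero")
  num <- abs(a * d - b * c)
  if (correction) num <- max(num - n / 2, 0)
  stat <- n * num^2 / prod(margins)
  list(statistic = stat, df = 1L,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       correction = correction)
}
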