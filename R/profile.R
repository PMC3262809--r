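#' Construct a single-gene expression profile
#'
#' Bundles one gene's control-group and case-group expression values into the
#' object scanned by [dn_scan()] and [detect()].  The scan statistic reads the
#' combined sequence as control block followed by case block; a change point
#' is a position after which the distribution differs from the control
#' distribution.
#'
#' For microarray data the case samples carrying differential expression are
#' unknown, so the case group is sorted ascending (`sort_case = TRUE`), which
#' moves any over-expressed subset to the right end of the sequence.  For
#' data that is already a change-point sequence -- e.g. simulated genes where
#' the shifted samples form the trailing block -- the case order is kept
#' (`sort_case = FALSE`, the [generate_gene()] convention).
#'
#' @param control numeric vector of control-group values (at least 2, finite).
#' @param case numeric vector of case-group values (at least 2, finite).
#' @param gene_id identifier carried through to results.
#' @param sort_case sort the case group ascending before scanning?
#' @return An object of class `wcps_profile` with elements `gene_id`,
#'   `control`, `case` (scan order), `case_original` (input order), `sorted`,
#'   `n1`, `n2`, `n`.
#' @examples
#' p <- expression_profile(rnorm(25), c(rnorm(20), rnorm(5) + 2))
#' detect(p, alpha = 0.01)
#' @export
expression_profile <- function(control, case, gene_id = "gene",
                               sort_case = FALSE) {
  control <- as.numeric(control)
  case <- as.numeric(case)
  if (length(control) < 2 || length(case) < 2)
    stop("need at least 2 control and 2 case values", call. = FALSE)
  if (!all(is.finite(control)) || !all(is.finite(case)))
    stop("all expression values must be finite", call. = FALSE)
  structure(
    list(gene_id = as.character(gene_id)[1],
         control = control,
         case = if (sort_case) sort(case) else case,
         case_original = case,
         sorted = isTRUE(sort_case),
         n1 = length(control), n2 = length(case),
         n = length(control) + length(case)),
    class = "wcps_profile")
}

#' @export
print.wcps_profile <- function(x, ...) {
  cat(sprintf("<wcps_profile> %s: n1 = %d control, n2 = %d case%s\n",
              x$gene_id, x$n1, x$n2,
              if (x$sorted) " (sorted ascending)" else ""))
  invisible(x)
}

#' Empirical distribution of the control group
#'
#' Builds the right-continuous empirical CDF \eqn{F_1} of a sample together
#' with its generalized inverse \eqn{F_1^{-1}(y) = \inf\{x : F_1(x) \ge y\}},
#' the quantile map used when the scan discrepancy is evaluated on a fixed
#' grid of probabilities \eqn{y}.
#'
#' @param values numeric vector, at least 2 finite values.
#' @param y_step step of the probability grid on which the inverse is
#'   tabulated; defaults to \eqn{1/(4 n)}.  The inverse itself can be
#'   evaluated at any `y` in (0, 1].
#' @return An object of class `wcps_ecdf`: list with `cdf` (function),
#'   `inverse` (function), `support` (sorted values), `n`, `y_grid`.
#' @examples
#' F1 <- build_empirical_distribution(c(1, 2, 3, 4))
#' F1$cdf(2.5)      # 0.5
#' F1$inverse(0.5)  # 2
#' @export
build_empirical_distribution <- function(values, y_step = NULL) {
  values <- as.numeric(values)
  if (length(values) < 2)
    stop("need at least 2 values", call. = FALSE)
  if (!all(is.finite(values)))
    stop("all values must be finite", call. = FALSE)
  sorted <- sort(values)
  n <- length(sorted)
  if (is.null(y_step)) y_step <- 1 / (4 * n)
  if (!is.numeric(y_step) || y_step <= 0 || y_step > 1)
    stop("'y_step' must be in (0, 1]", call. = FALSE)
  structure(
    list(cdf = stats::ecdf(sorted),
         # generalized (type-1) inverse: guarantees inverse(cdf(x)) <= x
         inverse = function(y) {
           if (any(y <= 0 | y > 1)) stop("y must be in (0, 1]", call. = FALSE)
           sorted[ceiling(y * n - 1e-9)]
         },
         support = sorted,
         n = n,
         y_grid = seq(y_step, 1, by = y_step)),
    class = "wcps_ecdf")
}

#' @export
print.wcps_ecdf <- function(x, ...) {
  cat(sprintf("<wcps_ecdf> empirical CDF on %d values in [%g, %g]\n",
              x$n, x$support[1], x$support[x$n]))
  invisible(x)
}
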