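# Comparator statistics for the ROC study.  Each maps a wcps_profile to a
# single score oriented so that larger means stronger evidence of
# differential expression; degenerate scales are guarded rather than
# erroring so that whole-matrix scans never abort on a flat gene.

.guard_scale <- function(s, what) {
  if (!is.finite(s) || s <= 0) {
    warning(sprintf("%s scale is zero; falling back to a small constant", what),
            call. = FALSE)
    s <- 1e-8
  }
  s
}

#' Two-sample t statistic
#'
#' Classical pooled-variance two-sample t comparing case against control.
#' The absolute value is returned so that the score ranks two-sided evidence
#' (the signed statistic is available as attribute `"sign"`).  A gene with
#' zero pooled variance scores 0 with a warning.
#'
#' @param profile a [expression_profile()].
#' @return A single non-negative score.
#' @export
score_t <- function(profile) {
  x <- profile$control; y <- profile$case_original
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  if (!is.finite(sp2) || sp2 <= 0) {
    warning("zero pooled variance; t score set to 0", call. = FALSE)
    return(structure(0, sign = 0))
  }
  tt <- (mean(y) - mean(x)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  structure(abs(tt), sign = sign(tt))
}

#' COPA score (cancer outlier profile analysis)
#'
#' Median-centres and MAD-scales the gene over all samples and returns the
#' `r`-th percentile of the scaled case values.
#'
#' @inheritParams score_t
#' @param r percentile of the scaled case values (default 0.75).
#' @export
score_copa <- function(profile, r = 0.75) {
  all <- c(profile$control, profile$case_original)
  med <- stats::median(all)
  s <- .guard_scale(stats::mad(all), "MAD")
  unname(stats::quantile((profile$case_original - med) / s, r))
}

#' Outlier sum (OS)
#'
#' After median/MAD standardization over all samples, sums the standardized
#' case values that exceed the 75th percentile plus one IQR of the combined
#' standardized values.
#' @inheritParams score_t
#' @export
score_os <- function(profile) {
  all <- c(profile$control, profile$case_original)
  med <- stats::median(all)
  s <- .guard_scale(stats::mad(all), "MAD")
  z <- (all - med) / s
  thr <- stats::quantile(z, 0.75) + stats::IQR(z)
  zc <- z[(profile$n1 + 1):length(z)]
  sum(zc[zc > thr])
}

#' Outlier-robust t statistic (ORT)
#'
#' Sums case values above the control-group outlier threshold
#' (q75 + IQR of controls), centred at the control median and scaled by the
#' pooled median absolute residual of both groups.
#' @inheritParams score_t
#' @export
score_ort <- function(profile) {
  x <- profile$control; y <- profile$case_original
  medx <- stats::median(x); medy <- stats::median(y)
  s <- .guard_scale(
    stats::median(abs(c(x - medx, y - medy))) * 1.4826, "median residual")
  thr <- stats::quantile(x, 0.75) + stats::IQR(x)
  out <- y[y > thr]
  if (!length(out)) return(0)
  sum((out - medx) / s)
}

# mean/sd of the sum of the top-k of n2 standard normal order statistics,
# cached per n2 (fixed internal seed: deterministic across sessions)
.most_env <- new.env(parent = emptyenv())
.most_constants <- function(n2, nsim = 5000) {
  key <- as.character(n2)
  if (!is.null(.most_env[[key]])) return(.most_env[[key]])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(20120129)
  sums <- matrix(0, nsim, n2)
  for (i in seq_len(nsim))
    sums[i, ] <- cumsum(sort(stats::rnorm(n2), decreasing = TRUE))
  out <- list(mean = colMeans(sums), sd = apply(sums, 2, stats::sd))
  .most_env[[key]] <- out
  out
}

#' Maximum ordered-subset t statistic (MOST)
#'
#' Standardizes the gene by the all-sample median and MAD, orders the case
#' values descending, and for every subset size `k` compares the cumulative
#' sum of the top `k` values against its null mean and standard deviation
#' under standard normal order statistics; the score is the maximum
#' standardized cumulative sum over `k`.
#' @inheritParams score_t
#' @export
score_most <- function(profile) {
  all <- c(profile$control, profile$case_original)
  med <- stats::median(all)
  s <- .guard_scale(stats::mad(all), "MAD")
  zc <- sort((profile$case_original - med) / s, decreasing = TRUE)
  k <- .most_constants(length(zc))
  max((cumsum(zc) - k$mean) / k$sd)
}

#' @rdname score_ort
#' @details `score_tri_ort()` and `score_tri_most()` are registry aliases
#'   for the trigonometric refinements of ORT/MOST; this implementation
#'   falls back to the base statistics.
#' @export
score_tri_ort <- function(profile) score_ort(profile)

#' @rdname score_most
#' @export
score_tri_most <- function(profile) score_most(profile)

#' Likelihood ratio score (LRS)
#'
#' Normal two-component likelihood ratio: under the alternative the top `j`
#' ordered case values share a shifted mean while the remaining samples keep
#' the baseline mean, with a common variance; the score maximizes twice the
#' log likelihood ratio over `j`.
#' @inheritParams score_t
#' @export
score_lrs <- function(profile) {
  x <- profile$control; y <- sort(profile$case_original, decreasing = TRUE)
  n <- length(x) + length(y)
  ll <- function(rss) -n / 2 * log(rss / n)
  rss0 <- sum((c(x, y) - mean(c(x, y)))^2)
  if (rss0 <= 0) return(0)
  best <- 0
  for (j in seq_len(length(y))) {
    top <- y[seq_len(j)]; rest <- c(x, y[-seq_len(j)])
    rss1 <- sum((top - mean(top))^2) + sum((rest - mean(rest))^2)
    if (rss1 <= 0) next
    best <- max(best, 2 * (ll(rss1) - ll(rss0)))
  }
  best
}

#' @rdname score_t
#' @details `score_npcps()` and `score_wcps()` expose the change-point scan
#'   maxima under the shared scoring interface.
#' @export
score_npcps <- function(profile) {
  max(.dn_by_tail(profile$control, profile$case))
}

#' @rdname score_t
#' @export
score_wcps <- function(profile) {
  D <- .dn_by_tail(profile$control, profile$case)
  max(D * (1 + 3 / (seq_along(D) + 6)))
}

#' Registry of scoring methods
#'
#' Named list of all single-gene scoring functions, keyed by the names used
#' in the ROC tables.  Used by [run_roc_table()] and the command line.
#'
#' @return Named list of functions `profile -> score`.
#' @examples
#' names(dge_methods())
#' @export
dge_methods <- function() {
  list(wcps = score_wcps, npcps = score_npcps, lrs = score_lrs,
       tri_most = score_tri_most, tri_ort = score_tri_ort,
       copa = score_copa, os = score_os, t = score_t,
       ort = score_ort, most = score_most)
}

#' Score one gene with a registered method
#'
#' @inheritParams score_t
#' @param method a name from [dge_methods()].
#' @return A `data.frame` row: `gene_id`, `method`, `score`.
#' @export
score_gene <- function(profile, method = "wcps") {
  reg <- dge_methods()
  if (!method %in% names(reg))
    stop(sprintf("unknown method '%s'; available: %s", method,
                 paste(names(reg), collapse = ", ")), call. = FALSE)
  data.frame(gene_id = profile$gene_id, method = method,
             score = as.numeric(reg[[method]](profile)))
}
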