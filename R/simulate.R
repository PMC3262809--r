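# Monte Carlo harness: the study design draws both groups from a common
# base distribution (standard normal or skew-normal) and, for a DGE gene,
# adds a shift mu to exactly k case samples.  The shifted samples form the
# trailing block of the case group, so the combined sequence has its true
# change point at position n - k (fraction (n - k)/n), matching the
# sequence model of the scan.

#' Skew-normal deviates
#'
#' Standard skew-normal SN(0, 1, shape) via the half-normal representation
#' \eqn{Z = \delta |U_0| + \sqrt{1-\delta^2} U_1},
#' \eqn{\delta = shape/\sqrt{1+shape^2}}.
#'
#' @param n number of draws.
#' @param shape skewness (slant) parameter; 0 recovers the standard normal.
#' @export
rskewnorm <- function(n, shape = 4) {
  delta <- shape / sqrt(1 + shape^2)
  delta * abs(stats::rnorm(n)) + sqrt(1 - delta^2) * stats::rnorm(n)
}

#' Simulate one gene of the Monte Carlo design
#'
#' @param n1,n2 control and case group sizes.
#' @param k number of case samples carrying DGE (0 for a null gene;
#'   `0 <= k <= n2`).
#' @param mu expression shift added to the k affected samples (may be
#'   negative for under-expression).
#' @param distribution base distribution of all samples.
#' @param shape skew-normal shape parameter (ignored for `"normal"`).
#' @param gene_id identifier.
#' @return A sequence-order [expression_profile()] (the affected samples are
#'   the trailing block of the case group; true change fraction
#'   \eqn{(n-k)/n}).  Uses the current RNG state; seed via `set.seed()`.
#' @examples
#' set.seed(1)
#' generate_gene(25, 25, k = 9, mu = 2)
#' @export
generate_gene <- function(n1, n2, k = 0, mu = 0,
                          distribution = c("normal", "skew_normal"),
                          shape = 4, gene_id = "gene") {
  distribution <- match.arg(distribution)
  if (k < 0 || k > n2) stop("need 0 <= k <= n2", call. = FALSE)
  draw <- switch(distribution,
                 normal = stats::rnorm,
                 skew_normal = function(m) rskewnorm(m, shape))
  control <- draw(n1)
  case <- draw(n2)
  if (k > 0) case[(n2 - k + 1):n2] <- case[(n2 - k + 1):n2] + mu
  expression_profile(control, case, gene_id, sort_case = FALSE)
}

# scan maxima and argmax fractions for both modes from a single scan
.cp_stats <- function(profile) {
  D <- .dn_by_tail(profile$control, profile$case)
  w <- 1 + 3 / (seq_along(D) + 6)
  Dw <- D * w
  n <- profile$n
  iw <- which.max(Dw); inp <- which.max(D)
  c(stat_wcps = Dw[iw], stat_npcps = D[inp],
    cp_wcps = (n - iw) / n, cp_npcps = (n - inp) / n)
}

#' Monte Carlo change-point estimate and miss-rate table
#'
#' For each DGE subset size `k` on a grid, simulates `reps` genes with shift
#' `mu`, runs both the weighted and unweighted scans, and tabulates the mean
#' estimated change-point fraction and the miss rate (fraction of DGE genes
#' whose scan maximum does not exceed \eqn{C(\alpha)}).  The summary
#' attributes give the mean absolute error of the change-point estimate and
#' the mean miss rate across the grid, for both modes.
#'
#' @param n1,n2 group sizes.
#' @param mu expression shift.
#' @param k_grid vector of DGE subset sizes (each `0 < k <= n2`).
#' @param reps Monte Carlo replicates per k.
#' @param alpha significance level of the decision threshold (default 0.01).
#' @inheritParams generate_gene
#' @param seed optional RNG seed.
#' @return A `data.frame` with one row per k: `k`, `actual_cp`, `cp_wcps`,
#'   `cp_npcps` (means over all replicates), `cp_wcps_det`, `cp_npcps_det`
#'   (means over detected replicates only), `miss_wcps`, `miss_npcps`;
#'   attributes `mae_wcps`, `mae_npcps`, `mean_miss_wcps`,
#'   `mean_miss_npcps`.
#' @examples
#' run_cp_table(10, 10, mu = 2, k_grid = c(2, 5), reps = 50, seed = 1)
#' @export
run_cp_table <- function(n1, n2, mu = 2, k_grid, reps = 1000, alpha = 0.01,
                         distribution = c("normal", "skew_normal"),
                         shape = 4, seed = NULL) {
  distribution <- match.arg(distribution)
  if (!is.null(seed)) set.seed(seed)
  if (any(k_grid <= 0 | k_grid > n2)) stop("k_grid must be in (0, n2]", call. = FALSE)
  crit <- critical_value(alpha)
  n <- n1 + n2
  rows <- lapply(k_grid, function(k) {
    s <- vapply(seq_len(reps), function(i)
      .cp_stats(generate_gene(n1, n2, k, mu, distribution, shape)),
      numeric(4))
    detw <- s["stat_wcps", ] > crit
    detn <- s["stat_npcps", ] > crit
    data.frame(k = k, actual_cp = (n - k) / n,
               cp_wcps = mean(s["cp_wcps", ]),
               cp_npcps = mean(s["cp_npcps", ]),
               cp_wcps_det = if (any(detw)) mean(s["cp_wcps", detw]) else NA_real_,
               cp_npcps_det = if (any(detn)) mean(s["cp_npcps", detn]) else NA_real_,
               miss_wcps = mean(!detw), miss_npcps = mean(!detn))
  })
  out <- do.call(rbind, rows)
  structure(out,
            mae_wcps = mean(abs(out$cp_wcps - out$actual_cp)),
            mae_npcps = mean(abs(out$cp_npcps - out$actual_cp)),
            mean_miss_wcps = mean(out$miss_wcps),
            mean_miss_npcps = mean(out$miss_npcps),
            alpha = alpha, critical_value = crit, mu = mu,
            n1 = n1, n2 = n2, reps = reps, distribution = distribution)
}

#' Monte Carlo ROC/AUC comparison table
#'
#' For every simulation cell (a combination of group sizes, shift and DGE
#' subset size), generates a labelled mixture of DGE and null genes, scores
#' every gene with every requested method, and computes the area under the
#' ROC curve of each method against the ground-truth labels.
#'
#' @param cells data frame with columns `n1`, `n2`, `mu`, `k` (one row per
#'   cell); a total-size column `n` with `n1 = n2 = n/2` is also accepted.
#' @param methods names from [dge_methods()].
#' @param n_genes genes per cell.
#' @param dge_fraction fraction of genes carrying DGE (default 0.10; AUC is
#'   prevalence-insensitive in expectation).
#' @inheritParams run_cp_table
#' @return Data frame with one row per cell and one AUC column per method;
#'   attribute `mean_auc` holds the per-method mean across cells.
#' @export
run_roc_table <- function(cells, methods = c("wcps", "npcps"),
                          n_genes = 1000, dge_fraction = 0.1,
                          distribution = c("normal", "skew_normal"),
                          shape = 4, seed = NULL) {
  distribution <- match.arg(distribution)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(cells$n) && is.null(cells$n1)) {
    cells$n1 <- cells$n %/% 2
    cells$n2 <- cells$n - cells$n1
  }
  stopifnot(all(c("n1", "n2", "mu", "k") %in% names(cells)))
  reg <- dge_methods()
  bad <- setdiff(methods, names(reg))
  if (length(bad))
    stop(sprintf("unknown method(s) %s; available: %s",
                 paste(bad, collapse = ", "),
                 paste(names(reg), collapse = ", ")), call. = FALSE)
  n_dge <- round(n_genes * dge_fraction)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cc <- cells[i, ]
    labels <- c(rep(TRUE, n_dge), rep(FALSE, n_genes - n_dge))
    profs <- lapply(seq_len(n_genes), function(j)
      generate_gene(cc$n1, cc$n2, if (labels[j]) cc$k else 0,
                    if (labels[j]) cc$mu else 0, distribution, shape,
                    gene_id = sprintf("g%05d", j)))
    aucs <- vapply(methods, function(m) {
      sc <- vapply(profs, reg[[m]], numeric(1))
      auc(roc_curve(sc, labels))
    }, numeric(1))
    cbind(data.frame(n = cc$n1 + cc$n2, n1 = cc$n1, n2 = cc$n2,
                     mu = cc$mu, k = cc$k), as.list(aucs))
  })
  out <- do.call(rbind, rows)
  structure(out, mean_auc = colMeans(out[, methods, drop = FALSE]),
            n_genes = n_genes, dge_fraction = dge_fraction,
            distribution = distribution)
}
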