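#' Generate a synthetic microarray-shaped fixture
#'
#' Writes a matrix/labels/ground-truth TSV triple whose statistical
#' structure matches [generate_gene()]: all samples drawn from the base
#' distribution, with each DGE block adding a shift to `k` case samples
#' (chosen at random per gene; membership is recorded in the truth file).
#' Presets mimic the shapes of the two breast-cancer datasets analysed with
#' the method: `"dataset1"` is 5293 genes by 49 samples (25 control, 24
#' case) and `"dataset2"` is 12576 genes by 42 samples (24 control from two
#' subgroups, 18 case).  All fixture data is synthetic.
#'
#' @param dir output directory (created if needed).
#' @param n_genes,n1,n2 dimensions (ignored when `preset` is given).
#' @param dge_spec data frame with columns `n_genes`, `k`, `mu` describing
#'   blocks of DGE genes; remaining genes are null.
#' @param preset `"dataset1"` or `"dataset2"` for the dataset-shaped
#'   fixtures (a default `dge_spec` is supplied).
#' @param distribution,shape base distribution, as in [generate_gene()].
#' @param seed RNG seed.
#' @return Invisibly, the paths of the files written (`matrix`, `labels`,
#'   `truth`).
#' @export
generate_fixture <- function(dir, n_genes = 500, n1 = 25, n2 = 24,
                             dge_spec = NULL, preset = NULL,
                             distribution = c("normal", "skew_normal"),
                             shape = 4, seed = 1) {
  distribution <- match.arg(distribution)
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("dataset1", "dataset2"))
    if (preset == "dataset1") { n_genes <- 5293; n1 <- 25; n2 <- 24 }
    else                      { n_genes <- 12576; n1 <- 24; n2 <- 18 }
    if (is.null(dge_spec))
      dge_spec <- data.frame(n_genes = round(n_genes * c(0.2, 0.1, 0.05)),
                             k = pmin(n2 - 1, c(4, 8, 12)),
                             mu = c(2, 2, 3))
  }
  if (is.null(dge_spec))
    dge_spec <- data.frame(n_genes = integer(), k = integer(), mu = numeric())
  if (nrow(dge_spec) && any(dge_spec$k >= n2 | dge_spec$k < 1))
    stop("dge_spec k must be in [1, n2)", call. = FALSE)
  if (sum(dge_spec$n_genes) > n_genes)
    stop("dge_spec assigns more genes than n_genes", call. = FALSE)
  set.seed(seed)
  draw <- switch(distribution, normal = stats::rnorm,
                 skew_normal = function(m) rskewnorm(m, shape))
  n <- n1 + n2
  vals <- matrix(draw(n_genes * n), n_genes, n)
  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  truth <- data.frame(gene = gene_ids, k = 0L, mu = 0,
                      samples = "", stringsAsFactors = FALSE)
  case_cols <- (n1 + 1):n
  row <- 1
  for (b in seq_len(nrow(dge_spec))) {
    for (g in seq_len(dge_spec$n_genes[b])) {
      idx <- sample(case_cols, dge_spec$k[b])
      vals[row, idx] <- vals[row, idx] + dge_spec$mu[b]
      truth$k[row] <- dge_spec$k[b]
      truth$mu[row] <- dge_spec$mu[b]
      truth$samples[row] <- paste(sort(idx - n1), collapse = ",")
      row <- row + 1
    }
  }
  sample_ids <- c(sprintf("ctrl%02d", seq_len(n1)), sprintf("case%02d", seq_len(n2)))
  dimnames(vals) <- list(gene_ids, sample_ids)
  em <- structure(list(values = vals,
                       groups = factor(rep(c("control", "case"), c(n1, n2)),
                                       levels = c("control", "case")),
                       n1 = n1, n2 = n2),
                  class = "expression_matrix")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(matrix = file.path(dir, "matrix.tsv"),
                labels = file.path(dir, "labels.tsv"),
                truth = file.path(dir, "truth.tsv"))
  write_expression(em, paths$matrix, paths$labels)
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
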