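# Gene-by-sample expression matrix pipeline.  Interchange format is plain
# TSV: matrix files have probe/gene identifiers in the first column and
# sample identifiers in the header; label files map sample id -> group
# ("control" or "case").

#' Read an expression matrix and its sample labels
#'
#' @param matrix_file tab-delimited file, first column identifiers, header
#'   row of sample ids.
#' @param labels_file two-column tab-delimited file (optional header
#'   `sample<TAB>group`) mapping every sample id to `control` or `case`.
#' @return Object of class `expression_matrix`: list with `values` (numeric
#'   matrix, samples ordered control block then case block), `groups`
#'   (factor aligned with columns), `n1`, `n2`.
#' @export
read_expression <- function(matrix_file, labels_file) {
  hdr <- strsplit(readLines(matrix_file, n = 1), "\t", fixed = TRUE)[[1]][-1]
  if (anyDuplicated(hdr))
    stop(sprintf("duplicate sample id '%s'", hdr[duplicated(hdr)][1]),
         call. = FALSE)
  raw <- utils::read.delim(matrix_file, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 3) stop("matrix file needs >= 2 sample columns", call. = FALSE)
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids))
    stop(sprintf("duplicate row identifier '%s'", ids[duplicated(ids)][1]),
         call. = FALSE)
  vals <- as.matrix(raw[, -1, drop = FALSE])
  if (anyDuplicated(colnames(vals)))
    stop(sprintf("duplicate sample id '%s'",
                 colnames(vals)[duplicated(colnames(vals))][1]), call. = FALSE)
  if (!is.numeric(vals)) {
    bad <- which(!vapply(raw[-1], is.numeric, logical(1)))[1]
    stop(sprintf("non-numeric values in column '%s'",
                 colnames(vals)[bad]), call. = FALSE)
  }
  rownames(vals) <- ids

  lab <- utils::read.delim(labels_file, header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(lab) < 2) stop("labels file needs two columns", call. = FALSE)
  if (tolower(lab[1, 1]) == "sample") lab <- lab[-1, , drop = FALSE]
  groups <- tolower(trimws(lab[[2]]))
  names(groups) <- trimws(lab[[1]])
  if (!all(groups %in% c("control", "case")))
    stop("group labels must be 'control' or 'case'", call. = FALSE)
  missing_lab <- setdiff(colnames(vals), names(groups))
  if (length(missing_lab))
    stop(sprintf("sample '%s' has no group label", missing_lab[1]), call. = FALSE)
  unknown <- setdiff(names(groups), colnames(vals))
  if (length(unknown))
    stop(sprintf("label file names unknown sample '%s'", unknown[1]),
         call. = FALSE)
  groups <- groups[colnames(vals)]
  ord <- order(groups != "control")        # control block first
  vals <- vals[, ord, drop = FALSE]
  groups <- factor(groups[ord], levels = c("control", "case"))
  if (sum(groups == "control") < 2 || sum(groups == "case") < 2)
    stop("need at least 2 samples per group", call. = FALSE)
  structure(list(values = vals, groups = groups,
                 n1 = sum(groups == "control"), n2 = sum(groups == "case")),
            class = "expression_matrix")
}

#' Write an expression matrix and labels to TSV
#' @param em an `expression_matrix`.
#' @param matrix_file,labels_file output paths.
#' @export
write_expression <- function(em, matrix_file, labels_file) {
  stopifnot(inherits(em, "expression_matrix"))
  df <- data.frame(id = rownames(em$values), em$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, matrix_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample = colnames(em$values), group = as.character(em$groups)),
    labels_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(em)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples (%d control, %d case)\n",
              nrow(x$values), ncol(x$values), x$n1, x$n2))
  invisible(x)
}

.profile_from_row <- function(em, i, sort_case = TRUE) {
  expression_profile(em$values[i, em$groups == "control"],
                     em$values[i, em$groups == "case"],
                     gene_id = rownames(em$values)[i], sort_case = sort_case)
}

#' Collapse multiple probes per gene
#'
#' Maps probe identifiers to gene symbols and, when several probes hit the
#' same gene, keeps the probe with the largest scan statistic (weighted for
#' `mode = "wcps"`).  Probes absent from the map are dropped, mirroring the
#' removal of obsolete probes.
#'
#' @param em an `expression_matrix` keyed by probe ids.
#' @param map a named character vector `probe -> gene`, or a data frame with
#'   columns `probe` and `gene`.
#' @param mode statistic used to pick the representative probe.
#' @return An `expression_matrix` keyed by gene, one row per gene.
#' @export
collapse_probes <- function(em, map, mode = c("wcps", "npcps")) {
  stopifnot(inherits(em, "expression_matrix"))
  mode <- match.arg(mode)
  if (is.data.frame(map)) {
    stopifnot(all(c("probe", "gene") %in% names(map)))
    map <- stats::setNames(as.character(map$gene), as.character(map$probe))
  }
  probes <- intersect(rownames(em$values), names(map))
  if (!length(probes)) stop("no probe maps to a gene", call. = FALSE)
  score <- vapply(probes, function(p) {
    pr <- .profile_from_row(em, which(rownames(em$values) == p))
    if (mode == "wcps") score_wcps(pr) else score_npcps(pr)
  }, numeric(1))
  keep <- vapply(split(probes, map[probes]),
                 function(ps) ps[which.max(score[ps])], character(1))
  vals <- em$values[keep, , drop = FALSE]
  rownames(vals) <- names(keep)
  vals <- vals[order(rownames(vals)), , drop = FALSE]
  structure(list(values = vals, groups = em$groups, n1 = em$n1, n2 = em$n2),
            class = "expression_matrix")
}

#' Rank all genes of a matrix by the change-point statistic
#'
#' Runs [detect()] on every gene (case group sorted ascending, both
#' orientations scanned) and returns the genes in descending order of the
#' statistic, ties broken by gene id.
#'
#' @param em an `expression_matrix`.
#' @param mode `"wcps"` or `"npcps"`.
#' @param alpha significance level reported in the `significant` column.
#' @return A `data.frame` with columns `gene`, `statistic`, `cp_fraction`,
#'   `cp_value`, `direction`, `significant`, `sig_0.05`, `sig_0.01`, and the
#'   per-gene [detect()] results in attribute `results` (keyed by gene).
#' @export
rank_genes <- function(em, mode = c("wcps", "npcps"), alpha = 0.05) {
  stopifnot(inherits(em, "expression_matrix"))
  mode <- match.arg(mode)
  c05 <- critical_value(0.05); c01 <- critical_value(0.01)
  res <- lapply(seq_len(nrow(em$values)), function(i)
    detect(.profile_from_row(em, i), alpha = alpha, mode = mode))
  names(res) <- rownames(em$values)
  out <- data.frame(
    gene = names(res),
    statistic = vapply(res, `[[`, numeric(1), "statistic"),
    cp_fraction = vapply(res, `[[`, numeric(1), "cp_fraction"),
    cp_value = vapply(res, `[[`, numeric(1), "cp_value"),
    direction = vapply(res, `[[`, character(1), "direction"),
    significant = vapply(res, `[[`, logical(1), "significant"),
    row.names = NULL, stringsAsFactors = FALSE)
  out$sig_0.05 <- out$statistic > c05
  out$sig_0.01 <- out$statistic > c01
  out <- out[order(-out$statistic, out$gene), ]
  rownames(out) <- NULL
  structure(out, results = res, mode = mode, alpha = alpha)
}

#' Binary DGE matrix and its marginals
#'
#' For every gene significant at `alpha`, flags the case samples lying
#' beyond the change-point expression value in the detected direction
#' ([flag_dge_samples()]); non-significant genes contribute all-zero rows.
#' The marginals reproduce the study's summary figures: the per-sample
#' counts of DGE genes and the histogram of genes by DGE-subset size.
#'
#' @param em the `expression_matrix` that produced `ranked`.
#' @param ranked a [rank_genes()] result.
#' @param alpha flagging level (default 0.05, i.e. C = 1.358).
#' @return Object of class `dge_matrix`: list with `flags` (genes x case
#'   samples 0/1 matrix), `sample_counts` (DGE genes per case sample),
#'   `subset_size_hist` (named vector; genes by DGE subset size, including
#'   size 0).
#' @export
build_dge_matrix <- function(em, ranked, alpha = 0.05) {
  stopifnot(inherits(em, "expression_matrix"))
  res <- attr(ranked, "results")
  if (is.null(res)) stop("'ranked' must come from rank_genes()", call. = FALSE)
  crit <- critical_value(alpha)
  case_ids <- colnames(em$values)[em$groups == "case"]
  flags <- matrix(0L, nrow(em$values), em$n2,
                  dimnames = list(rownames(em$values), case_ids))
  for (g in rownames(em$values)) {
    r <- res[[g]]
    if (r$statistic > crit && r$direction != "none") {
      pr <- .profile_from_row(em, which(rownames(em$values) == g))
      r$significant <- TRUE
      flags[g, ] <- flag_dge_samples(pr, r)
    }
  }
  sizes <- rowSums(flags)
  hist <- table(factor(sizes, levels = 0:em$n2))
  structure(list(flags = flags,
                 sample_counts = colSums(flags),
                 subset_size_hist = hist,
                 alpha = alpha, critical_value = crit),
            class = "dge_matrix")
}

#' @export
print.dge_matrix <- function(x, ...) {
  cat(sprintf("<dge_matrix> %d genes x %d case samples; %d genes with >= 1 flagged sample\n",
              nrow(x$flags), ncol(x$flags), sum(rowSums(x$flags) > 0)))
  invisible(x)
}
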