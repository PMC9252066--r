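#' Percent-of-maximum expression per gene
#'
#' Scales each gene's row to percent of its own maximum across samples
#' (scale-invariant: multiplying a row by a positive constant leaves the
#' percentages unchanged). Genes whose row is all zero cannot be scaled
#' and are flagged.
#'
#' @param mat tibble with a `gene` identifier column and one numeric column
#'   per sample; values must be non-negative.
#' @param gene_col name of the identifier column (default `"gene"`).
#' @return tibble of the same shape with percent values and an added
#'   logical `not_assessable` column marking all-zero rows (their percent
#'   cells are `NA`).
#' @export
#' @examples
#' percent_of_max(tibble::tibble(gene = "g", s1 = 10, s2 = 50, s3 = 100))
percent_of_max <- function(mat, gene_col = "gene") {
  check_that(gene_col %in% names(mat), paste0("no column '", gene_col, "'"))
  vals <- dplyr::select(mat, -dplyr::all_of(gene_col))
  check_that(all(vapply(vals, is.numeric, logical(1))),
             "sample columns must be numeric")
  m <- as.matrix(vals)
  check_that(all(m >= 0, na.rm = TRUE), "expression values must be >= 0")
  rmax <- apply(m, 1, max, na.rm = TRUE)
  flagged <- rmax <= 0
  pct <- 100 * m / ifelse(flagged, NA_real_, rmax)
  out <- dplyr::bind_cols(mat[gene_col], as_tibble(pct))
  out$not_assessable <- flagged
  out
}

#' Mean expression per sample group
#'
#' Arithmetic mean over all gene-by-sample cells belonging to each group.
#'
#' @param mat tibble as in [percent_of_max()].
#' @param grouping tibble with columns `sample`, `group` assigning every
#'   sample column to exactly one group.
#' @param gene_col identifier column name.
#' @return tibble with `group`, `mean_expression`, `n_cells`.
#' @export
condition_average <- function(mat, grouping, gene_col = "gene") {
  samples <- setdiff(names(mat), gene_col)
  check_that(all(samples %in% grouping$sample),
             "every sample column must be assigned to a group")
  check_that(!anyDuplicated(grouping$sample),
             "samples must belong to exactly one group")
  long <- tidyr::pivot_longer(mat, -dplyr::all_of(gene_col),
                              names_to = "sample", values_to = "value")
  joined <- dplyr::inner_join(long, grouping, by = "sample")
  groups_seen <- unique(grouping$group[grouping$sample %in% samples])
  check_that(length(groups_seen) > 0 && all(table(joined$group) > 0),
             "empty group")
  joined %>%
    dplyr::group_by(.data$group) %>%
    dplyr::summarise(mean_expression = mean(.data$value),
                     n_cells = dplyr::n())
}

#' Count highly expressed genes per tissue
#'
#' A gene counts as highly expressed in a tissue when its percent-of-max
#' value exceeds the threshold (strictly) in at least one of the tissue's
#' samples.
#'
#' @param pct_mat percent matrix from [percent_of_max()].
#' @param grouping tibble with `sample`, `group` (tissue) assignments.
#' @param threshold percent cutoff (default 60).
#' @param gene_col identifier column name.
#' @return tibble with `group` and `n_high` per tissue.
#' @export
high_expression_count <- function(pct_mat, grouping, threshold = 60,
                                  gene_col = "gene") {
  pct_mat <- dplyr::select(pct_mat, -dplyr::any_of("not_assessable"))
  long <- tidyr::pivot_longer(pct_mat, -dplyr::all_of(gene_col),
                              names_to = "sample", values_to = "pct")
  long %>%
    dplyr::inner_join(grouping, by = "sample") %>%
    dplyr::group_by(.data$group, gene = .data[[gene_col]]) %>%
    dplyr::summarise(high = any(.data$pct > threshold, na.rm = TRUE),
                     .groups = "drop") %>%
    dplyr::group_by(.data$group) %>%
    dplyr::summarise(n_high = sum(.data$high))
}

#' Hierarchical clustering of expression rows
#'
#' Agglomerative clustering with Manhattan (city-block) distance and
#' average (UPGMA-style) linkage via [stats::hclust()], the combination
#' used for the published expression heatmaps.
#'
#' @param mat tibble as in [percent_of_max()]; at least two rows.
#' @param gene_col identifier column name.
#' @param metric distance metric (default `"manhattan"`).
#' @param linkage linkage method (default `"average"`).
#' @return an object of class `"expr_hclust"`: list with `$hclust` (the
#'   stats object), `$order` (leaf order as gene IDs) and `$merges`.
#' @export
#' @examples
#' m <- tibble::tibble(gene = c("a", "b", "c"),
#'                     s1 = c(0, 0, 10), s2 = c(0, 1, 10))
#' hcluster_rows(m)$order
hcluster_rows <- function(mat, gene_col = "gene", metric = "manhattan",
                          linkage = "average") {
  vals <- as.matrix(dplyr::select(mat, -dplyr::all_of(gene_col)))
  check_that(nrow(vals) >= 2, "need at least two rows to cluster")
  check_that(!anyNA(vals), "clustering input must be complete")
  rownames(vals) <- mat[[gene_col]]
  hc <- stats::hclust(stats::dist(vals, method = metric), method = linkage)
  structure(
    list(hclust = hc, order = mat[[gene_col]][hc$order], merges = hc$merge),
    class = "expr_hclust"
  )
}

#' @export
print.expr_hclust <- function(x, ...) {
  cat("<expr_hclust> leaf order:", paste(x$order, collapse = ", "), "\n")
  invisible(x)
}

#' qPCR fold changes by the 2^-ddCt method
#'
#' Per gene: dCt = Cq(target) - Cq(reference) for each replicate; ddCt of
#' each treated replicate is its dCt minus the mean control dCt; the fold
#' change per treated replicate is `2^-ddCt`. The mean and standard error
#' are computed on the per-replicate fold changes.
#'
#' @param cq tibble with columns `gene`, `condition`
#'   (`"control"`/`"treated"`), `replicate`, `cq_target`, `cq_reference`.
#' @return an object of class `"ddct_fc"`: tibble with one row per gene
#'   (`gene`, `fold_change`, `se`, `n`), with `tidy()`, `glance()` and
#'   `autoplot()` methods.
#' @export
#' @examples
#' cq <- tibble::tibble(
#'   gene = "g", condition = c("control", "treated"), replicate = 1,
#'   cq_target = c(25, 23), cq_reference = c(20, 20)
#' )
#' ddct_fold_change(cq) # fold change 4
ddct_fold_change <- function(cq) {
  need <- c("gene", "condition", "replicate", "cq_target", "cq_reference")
  check_that(all(need %in% names(cq)),
             paste0("cq table needs columns: ", paste(need, collapse = ", ")))
  check_that(!anyNA(cq$cq_reference), "missing reference Cq")
  check_that(all(cq$condition %in% c("control", "treated")),
             "condition must be 'control' or 'treated'")
  out <- cq %>%
    dplyr::mutate(dct = .data$cq_target - .data$cq_reference) %>%
    dplyr::group_by(.data$gene) %>%
    dplyr::group_modify(function(df, key) {
      ctrl <- df$dct[df$condition == "control"]
      trt <- df$dct[df$condition == "treated"]
      check_that(length(ctrl) >= 1 && length(trt) >= 1,
                 "each gene needs control and treated replicates")
      fc <- 2^(-(trt - mean(ctrl)))
      tibble(
        fold_change = mean(fc),
        se = if (length(fc) > 1) sd(fc) / sqrt(length(fc)) else 0,
        n = length(fc)
      )
    }) %>%
    dplyr::ungroup()
  class(out) <- c("ddct_fc", class(out))
  out
}

#' @rdname ddct_fold_change
#' @param x,object a `"ddct_fc"`.
#' @param ... unused.
#' @method tidy ddct_fc
#' @export
tidy.ddct_fc <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @rdname ddct_fold_change
#' @method glance ddct_fc
#' @export
glance.ddct_fc <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_up = sum(x$fold_change > 1),
    n_down = sum(x$fold_change < 1),
    max_fold_change = max(x$fold_change)
  )
}

#' @rdname ddct_fold_change
#' @method autoplot ddct_fc
#' @export
autoplot.ddct_fc <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$fold_change)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$fold_change - .data$se,
                   ymax = .data$fold_change + .data$se),
      width = 0.2
    ) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "fold change (2^-ddCt)",
                  title = "qPCR relative expression") +
    ggplot2::theme_minimal()
}
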