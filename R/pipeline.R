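#' Run the gene-family characterization pipeline on annotation tables
#'
#' Orchestrates the desk-scale stages that operate on a curated gene table
#' and (optionally) a duplicate-pair table: inventory counts, duplicate
#' classification with selection and dating, physicochemical aggregates,
#' and — when promoter sequences or expression inputs are supplied — the
#' promoter and expression summaries. Stages without inputs are skipped.
#'
#' @param genes gene table (tibble from [read_gene_table()]).
#' @param dup_pairs optional tibble with `locus_a`, `locus_b`, `ka`, `ks`.
#' @param promoters optional tibble `gene_id`, `sequence`.
#' @param expression optional list with `$matrix` and `$grouping` as in
#'   [simulate_expression()].
#' @param cq optional Cq table for [ddct_fold_change()].
#' @param config a [pipeline_config()].
#' @return an object of class `"aldh_run"`: list with `$counts`,
#'   `$physico`, and whichever of `$duplication`, `$elements`, `$percent`,
#'   `$high_expression`, `$fold_changes` had inputs, plus `$config`.
#' @export
#' @examples
#' genes <- read_gene_table(aldh_example("table1.tsv"))
#' run <- run_pipeline(genes)
#' run$counts
run_pipeline <- function(genes, dup_pairs = NULL, promoters = NULL,
                         expression = NULL, cq = NULL,
                         config = pipeline_config()) {
  check_that(nrow(genes) > 0, "empty gene table")
  out <- list(config = config)
  out$counts <- gene_table_counts(genes)
  out$physico <- summarize_physico(genes)
  if (!is.null(dup_pairs)) {
    out$duplication <- annotate_duplications(dup_pairs, genes, config)
    out$counts$n_tandem <- sum(out$duplication$pairs$dup_class == "tandem")
    out$counts$n_segmental <- sum(out$duplication$pairs$dup_class == "segmental")
  }
  if (!is.null(promoters)) {
    occ <- purrr::map_dfr(seq_len(nrow(promoters)), function(i) {
      scan_elements(promoters$sequence[[i]], gene_id = promoters$gene_id[[i]])
    })
    out$elements <- summarize_elements(occ, promoters$gene_id)
  }
  if (!is.null(expression)) {
    out$percent <- percent_of_max(expression$matrix)
    out$high_expression <- high_expression_count(
      out$percent, expression$grouping,
      threshold = config$high_expression_threshold
    )
  }
  if (!is.null(cq)) {
    out$fold_changes <- ddct_fold_change(cq)
  }
  structure(out, class = "aldh_run")
}

#' @export
print.aldh_run <- function(x, ...) {
  cat("<aldh_run>\n counts:\n")
  print(x$counts)
  cat(" stages:", paste(setdiff(names(x), c("config", "counts")),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Write pipeline reports as TSV files
#'
#' Emits one TSV per computed stage with stable column orders; numeric
#' formatting follows each stage's reporting rules (duplication statistics
#' truncated as in [render_duplication_table()]). Re-running on identical
#' inputs produces byte-identical files.
#'
#' @param run an `"aldh_run"` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @param gene_names optional locus-ID-to-name map for the duplication
#'   table.
#' @return tibble of written files (stage, path), invisibly.
#' @export
render_tables <- function(run, dir, gene_names = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- list()
  emit <- function(stage, df) {
    path <- file.path(dir, paste0(stage, ".tsv"))
    readr::write_tsv(df, path, progress = FALSE)
    written[[length(written) + 1L]] <<- tibble(stage = stage, path = path)
  }
  emit("counts", run$counts)
  emit("physico", run$physico)
  if (!is.null(run$duplication)) {
    emit("duplication", render_duplication_table(run$duplication, gene_names))
  }
  if (!is.null(run$elements)) {
    emit("elements_per_element", run$elements$per_element)
    emit("elements_per_gene", run$elements$per_gene)
  }
  if (!is.null(run$high_expression)) emit("high_expression", run$high_expression)
  if (!is.null(run$fold_changes)) emit("fold_changes", tidy(run$fold_changes))
  invisible(dplyr::bind_rows(written))
}
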