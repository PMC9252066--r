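#' Classify a duplicate gene pair as tandem or segmental
#'
#' Tandem: both loci on the same chromosome with an inter-gene gap (end of
#' the upstream gene to start of the downstream gene; 0 when the spans
#' overlap) no larger than the tandem window (100 kb by default).
#' Everything else is segmental. With `strict_segmental = TRUE`, non-tandem
#' pairs below the 90% identity threshold are labelled `"unclassified"`
#' instead (the published duplicate table is reproduced with the default,
#' non-strict rule).
#'
#' @param genes gene table with `locus_id`, `chromosome`, `start`, `end`.
#' @param locus_a,locus_b locus IDs of the pair (vectorized).
#' @param config a [pipeline_config()].
#' @param protein_identity optional percent identity per pair, only used by
#'   the strict rule.
#' @param strict_segmental apply the 90% rule (default `FALSE`).
#' @return character vector: `"tandem"`, `"segmental"` or
#'   `"unclassified"`.
#' @export
#' @examples
#' genes <- read_gene_table(aldh_example("table1.tsv"))
#' classify_pair(genes, "Sobic.003G203500", "Sobic.003G203600")
classify_pair <- function(genes, locus_a, locus_b, config = pipeline_config(),
                          protein_identity = NULL, strict_segmental = FALSE) {
  check_that(length(locus_a) == length(locus_b), "pair vectors differ in length")
  check_that(!any(locus_a == locus_b), "a locus cannot be paired with itself")
  span <- genes %>%
    dplyr::distinct(.data$locus_id, .data$chromosome) %>%
    dplyr::left_join(
      dplyr::summarise(dplyr::group_by(genes, .data$locus_id),
                       start = min(.data$start), end = max(.data$end)),
      by = "locus_id"
    )
  look <- function(ids, col) {
    idx <- match(ids, span$locus_id)
    check_that(!anyNA(idx), paste0("locus not in gene table: ",
                                   paste(ids[is.na(idx)], collapse = ", ")))
    span[[col]][idx]
  }
  same_chr <- look(locus_a, "chromosome") == look(locus_b, "chromosome")
  gap <- pmax(0, pmax(look(locus_a, "start"), look(locus_b, "start")) -
                pmin(look(locus_a, "end"), look(locus_b, "end")))
  out <- ifelse(same_chr & gap <= config$tandem_window, "tandem", "segmental")
  if (strict_segmental) {
    check_that(!is.null(protein_identity),
               "strict segmental rule needs protein_identity")
    out[out == "segmental" &
          protein_identity <= config$segmental_identity_threshold] <- "unclassified"
  }
  out
}

#' Annotate duplicate gene pairs with class, selection and age
#'
#' Takes a pair table that already carries `ka` and `ks` (from [kaks()] or
#' an external source such as the published duplicate table), classifies
#' each pair from coordinates, computes the Ka/Ks ratio, the selection
#' regime, and the divergence time.
#'
#' @param pairs tibble with `locus_a`, `locus_b`, `ka`, `ks`.
#' @param genes gene table with coordinates for every locus in `pairs`.
#' @param config a [pipeline_config()]; `config$substitution_rate` dates
#'   the pairs.
#' @return an object of class `"dup_analysis"`: list with `$pairs` (the
#'   annotated tibble with `dup_class`, `ratio`, `regime`, `time_mya`),
#'   `$rate` and `$config`. `tidy()`, `glance()` and `autoplot()` methods
#'   are available; [render_duplication_table()] prints it like the
#'   published table.
#' @export
#' @examples
#' genes <- read_gene_table(aldh_example("table1.tsv"))
#' tab2 <- readr::read_tsv(aldh_example("table2.tsv"), show_col_types = FALSE)
#' dup <- annotate_duplications(
#'   dplyr::select(tab2, locus_a, locus_b, ka, ks), genes,
#'   pipeline_config(substitution_rate = 1.5e-8)
#' )
#' tidy(dup)
annotate_duplications <- function(pairs, genes, config = pipeline_config()) {
  check_that(all(c("locus_a", "locus_b", "ka", "ks") %in% names(pairs)),
             "pairs needs columns locus_a, locus_b, ka, ks")
  ann <- pairs %>%
    dplyr::mutate(
      dup_class = classify_pair(genes, .data$locus_a, .data$locus_b, config),
      ratio = purrr::map2_dbl(.data$ka, .data$ks, compute_ratio),
      regime = selection_regime(.data$ratio),
      time_mya = divergence_time(.data$ks, rate = config$substitution_rate)
    )
  structure(list(pairs = ann, rate = config$substitution_rate, config = config),
            class = "dup_analysis")
}

#' @export
print.dup_analysis <- function(x, ...) {
  cat(sprintf("<dup_analysis> %d pairs (%s), rate %.3g subs/site/year\n",
              nrow(x$pairs),
              paste(names(table(x$pairs$dup_class)),
                    table(x$pairs$dup_class), sep = ": ", collapse = ", "),
              x$rate))
  print(tidy(x))
  invisible(x)
}

#' @rdname annotate_duplications
#' @param x a `"dup_analysis"`.
#' @param ... unused.
#' @method tidy dup_analysis
#' @export
tidy.dup_analysis <- function(x, ...) x$pairs

#' @rdname annotate_duplications
#' @method glance dup_analysis
#' @export
glance.dup_analysis <- function(x, ...) {
  tibble(
    n_pairs = nrow(x$pairs),
    n_tandem = sum(x$pairs$dup_class == "tandem"),
    n_segmental = sum(x$pairs$dup_class == "segmental"),
    median_ratio = stats::median(x$pairs$ratio, na.rm = TRUE),
    n_purifying = sum(x$pairs$regime == "purifying"),
    rate = x$rate
  )
}

#' @rdname annotate_duplications
#' @param object a `"dup_analysis"`.
#' @method autoplot dup_analysis
#' @export
autoplot.dup_analysis <- function(object, ...) {
  df <- dplyr::filter(object$pairs, !is.na(.data$ratio))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ks, y = .data$ka,
                                   colour = .data$dup_class)) +
    ggplot2::geom_abline(slope = 1, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(size = 3) +
    ggplot2::labs(x = "Ks (syn subs/site)", y = "Ka (nonsyn subs/site)",
                  colour = "duplication",
                  title = "Duplicate pairs: Ka vs Ks",
                  subtitle = "dashed line: Ka/Ks = 1 (neutrality)") +
    ggplot2::theme_minimal()
}

#' Render a duplicate-pair table with the published formatting
#'
#' Ka, Ks and Ka/Ks are truncated to 4 decimals and times to 2; the 0/0
#' pair renders its ratio as the infinity glyph and its time as
#' `"Not determinable"`.
#'
#' @param dup a `"dup_analysis"`.
#' @param gene_names optional named character vector mapping locus IDs to
#'   display names.
#' @return a tibble with display columns `locus_1`, `locus_2`, `ka`, `ks`,
#'   `ka_ks`, `time_mya`, `dup_type`.
#' @export
render_duplication_table <- function(dup, gene_names = NULL) {
  p <- dup$pairs
  disp <- function(ids) {
    if (is.null(gene_names)) ids else unname(gene_names[ids])
  }
  zero_zero <- p$ka == 0 & p$ks == 0
  fmt <- function(x, digits) {
    s <- sprintf(paste0("%.", digits, "f"), trunc_dec(x, digits))
    s <- sub("0+$", "", s)
    sub("\\.$", "", s)
  }
  tibble(
    locus_1 = disp(p$locus_a),
    locus_2 = disp(p$locus_b),
    ka = fmt(p$ka, 4),
    ks = fmt(p$ks, 4),
    ka_ks = dplyr::case_when(
      zero_zero ~ "∞",
      is.na(p$ratio) ~ "NA",
      TRUE ~ sprintf("%.4f", trunc_dec(p$ratio, 4))
    ),
    time_mya = ifelse(zero_zero, "Not determinable",
                      sprintf("%.2f", trunc_dec(p$time_mya, 2))),
    dup_type = paste0(toupper(substr(p$dup_class, 1, 1)),
                      substring(p$dup_class, 2))
  )
}
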