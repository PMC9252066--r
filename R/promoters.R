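#' Extract the upstream promoter window of a locus
#'
#' For a `+`-strand gene the promoter is the `length` bases immediately 5'
#' of `start` (positions `start - length` to `start - 1`, 1-based
#' inclusive); for a `-`-strand gene it is the reverse complement of the
#' `length` bases just 3' of `end`. The window is truncated, with a
#' warning, when it runs off the chromosome end.
#'
#' @param chromosome_seq chromosome (or scaffold) sequence as a string.
#' @param start,end 1-based inclusive gene coordinates on the chromosome.
#' @param strand `"+"` or `"-"`.
#' @param length promoter length in bp (default 1000).
#' @return promoter sequence, 5' to 3' relative to the gene.
#' @export
#' @examples
#' extract_upstream(strrep("ACGT", 500), start = 1001, end = 1200, length = 100)
extract_upstream <- function(chromosome_seq, start, end, strand = "+",
                             length = 1000) {
  n <- nchar(chromosome_seq)
  check_that(start >= 1 && end <= n && start <= end,
             "locus coordinates fall outside the chromosome")
  check_that(strand %in% c("+", "-"), "strand must be '+' or '-'")
  if (strand == "+") {
    lo <- start - length
    if (lo < 1) {
      warn(sprintf("promoter truncated to %d bp at the chromosome start",
                   max(start - 1, 0)))
      lo <- 1
    }
    if (start == 1) return("")
    substr(chromosome_seq, lo, start - 1)
  } else {
    hi <- end + length
    if (hi > n) {
      warn(sprintf("promoter truncated to %d bp at the chromosome end",
                   max(n - end, 0)))
      hi <- n
    }
    if (end == n) return("")
    window <- substr(chromosome_seq, end + 1, hi)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(window)))
  }
}

#' Read the bundled cis-regulatory element catalog
#'
#' PlantCARE-style named consensi shipped as editable configuration; the
#' consensus strings approximate the PlantCARE entries and should be
#' verified against the database before use on real promoters.
#'
#' @param path catalog TSV with columns `name`, `consensus` (IUPAC DNA),
#'   `category`.
#' @return tibble catalog.
#' @export
#' @examples
#' head(read_motif_catalog())
read_motif_catalog <- function(path = aldh_example("plantcare_catalog.tsv")) {
  cat <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  check_that(all(c("name", "consensus", "category") %in% names(cat)),
             "catalog needs columns name, consensus, category")
  check_that(!anyDuplicated(cat$name), "catalog element names must be unique")
  check_that(!any(grepl("[^ACGTRYSWKMBDHVN]", toupper(cat$consensus))),
             "consensus strings must be IUPAC DNA")
  cat
}

#' Scan a promoter for catalog elements on both strands
#'
#' IUPAC-aware exact matching (via [Biostrings::matchPattern()] with a
#' literal subject, so `N` in the promoter matches nothing). Reverse-strand
#' hits are found by scanning the reverse complement of each consensus and
#' are reported on forward promoter coordinates. All (overlapping) matches
#' are kept.
#'
#' @param promoter promoter sequence over A/C/G/T/N.
#' @param catalog tibble from [read_motif_catalog()].
#' @param gene_id optional label stored with the occurrences.
#' @return tibble with `gene_id`, `element`, `strand`, `start`, `end`
#'   (1-based, forward promoter coordinates).
#' @export
#' @examples
#' scan_elements("TTACGTGTT", read_motif_catalog())
scan_elements <- function(promoter, catalog = read_motif_catalog(),
                          gene_id = NA_character_) {
  check_that(nrow(catalog) > 0, "catalog must be non-empty")
  empty <- tibble(gene_id = character(), element = character(),
                  strand = character(), start = integer(), end = integer())
  if (is.na(promoter) || nchar(promoter) == 0) return(empty)
  subj <- Biostrings::DNAString(toupper(promoter))
  hits <- purrr::pmap(list(catalog$name, catalog$consensus), function(nm, cons) {
    fwd <- Biostrings::matchPattern(Biostrings::DNAString(toupper(cons)), subj,
                                    fixed = "subject")
    rc <- Biostrings::matchPattern(
      Biostrings::reverseComplement(Biostrings::DNAString(toupper(cons))), subj,
      fixed = "subject")
    dplyr::bind_rows(
      tibble(gene_id = gene_id, element = nm, strand = "+",
             start = BiocGenerics::start(fwd), end = BiocGenerics::end(fwd)),
      tibble(gene_id = gene_id, element = nm, strand = "-",
             start = BiocGenerics::start(rc), end = BiocGenerics::end(rc))
    )
  })
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0) return(empty)
  dplyr::arrange(out, .data$element, .data$start, .data$strand)
}

#' Summarize element occurrences across a gene set
#'
#' Two views of the occurrence table: per element, the number of genes with
#' at least one occurrence; per gene, the total occurrence count and the
#' number of distinct element types.
#'
#' @param occurrences tibble from [scan_elements()] (rows for all genes).
#' @param gene_ids character vector of all genes scanned (genes without
#'   occurrences are reported as zeros).
#' @param catalog catalog tibble; elements without occurrences are reported
#'   as zeros.
#' @return an object of class `"element_summary"`: list with
#'   `$per_element` (`element`, `category`, `n_genes`, `n_occurrences`) and
#'   `$per_gene` (`gene_id`, `total`, `types`); `tidy()` returns the
#'   per-element view, `glance()` overall counts, `autoplot()` the
#'   per-element bar chart.
#' @export
summarize_elements <- function(occurrences, gene_ids,
                               catalog = read_motif_catalog()) {
  per_element <- catalog %>%
    dplyr::select("name", "category") %>%
    dplyr::rename(element = "name") %>%
    dplyr::left_join(
      occurrences %>%
        dplyr::group_by(.data$element) %>%
        dplyr::summarise(n_genes = dplyr::n_distinct(.data$gene_id),
                         n_occurrences = dplyr::n()),
      by = "element"
    ) %>%
    tidyr::replace_na(list(n_genes = 0L, n_occurrences = 0L))
  per_gene <- tibble(gene_id = gene_ids) %>%
    dplyr::left_join(
      occurrences %>%
        dplyr::group_by(.data$gene_id) %>%
        dplyr::summarise(total = dplyr::n(),
                         types = dplyr::n_distinct(.data$element)),
      by = "gene_id"
    ) %>%
    tidyr::replace_na(list(total = 0L, types = 0L))
  structure(list(per_element = per_element, per_gene = per_gene),
            class = "element_summary")
}

#' @export
print.element_summary <- function(x, ...) {
  cat(sprintf("<element_summary> %d elements x %d genes\n",
              nrow(x$per_element), nrow(x$per_gene)))
  print(x$per_element)
  invisible(x)
}

#' @rdname summarize_elements
#' @param x,object an `"element_summary"`.
#' @param ... unused.
#' @method tidy element_summary
#' @export
tidy.element_summary <- function(x, ...) x$per_element

#' @rdname summarize_elements
#' @method glance element_summary
#' @export
glance.element_summary <- function(x, ...) {
  tibble(
    n_elements_seen = sum(x$per_element$n_genes > 0),
    n_occurrences = sum(x$per_element$n_occurrences),
    n_genes = nrow(x$per_gene),
    max_per_gene = max(c(0L, x$per_gene$total)),
    mean_types_per_gene = mean(x$per_gene$types)
  )
}

#' @rdname summarize_elements
#' @method autoplot element_summary
#' @export
autoplot.element_summary <- function(object, ...) {
  df <- dplyr::mutate(object$per_element,
                      element = stats::reorder(.data$element, .data$n_genes))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$element, y = .data$n_genes,
                                   fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "genes with ≥ 1 occurrence",
                  title = "Cis-regulatory elements across promoters") +
    ggplot2::theme_minimal()
}
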