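#' Read a labelled ALDH reference panel from FASTA
#'
#' Panel headers carry the family/subfamily labels as pipe-separated tokens:
#' `>id|family|subfamily`, e.g. `>AtALDH2B4|2|B`.
#'
#' @param path FASTA path.
#' @return a tibble with columns `id`, `family` (integer), `subfamily`
#'   (single uppercase letter) and `sequence`.
#' @export
read_reference_panel <- function(path) {
  fa <- read_fasta(path, alphabet = "aa")
  parts <- strsplit(fa$id, "|", fixed = TRUE)
  check_that(all(lengths(parts) == 3),
             "panel headers must be id|family|subfamily")
  tibble(
    id = vapply(parts, `[[`, "", 1),
    family = as.integer(vapply(parts, `[[`, "", 2)),
    subfamily = vapply(parts, `[[`, "", 3),
    sequence = fa$sequence
  )
}

#' Assign AGNC families and subfamilies by best-hit global identity
#'
#' Each query is globally aligned against every reference; the best hit is
#' the reference with the highest percent identity (ties broken by lowest
#' family number, then lexicographic reference ID). The AGNC thresholds are
#' strict: identity > 60% inherits family and subfamily of the best
#' reference; 40% < identity <= 60% inherits the family with the next
#' unused subfamily letter in that family; identity <= 40% founds a novel
#' family.
#'
#' @param queries tibble with columns `id`, `sequence` (e.g. from
#'   [read_fasta()]).
#' @param panel reference tibble with columns `id`, `family`, `subfamily`,
#'   `sequence` (e.g. from [read_reference_panel()]).
#' @param config an [pipeline_config()] list supplying the 40/60 thresholds.
#' @param ... passed to [global_align()] (scoring parameters).
#' @return a tibble with one row per query: `query_id`, `best_reference`,
#'   `identity`, `family` (integer; novel families get fresh numbers above
#'   the panel's maximum), `subfamily`, `novel` (logical).
#' @export
#' @examples
#' panel <- tibble::tibble(id = "ref1", family = 2L, subfamily = "B",
#'                         sequence = "MSTAGKVIKCKAAVLWEEKKPFSIEE")
#' assign_family(tibble::tibble(id = "q", sequence = panel$sequence), panel)
assign_family <- function(queries, panel, config = pipeline_config(), ...) {
  check_that(nrow(panel) > 0, "reference panel must be non-empty")
  check_that(all(c("id", "sequence") %in% names(queries)),
             "queries must have columns 'id' and 'sequence'")
  fam_thr <- config$family_identity_threshold
  sub_thr <- config$subfamily_identity_threshold

  used_letters <- split(panel$subfamily, panel$family)
  next_novel <- max(panel$family) + 1L
  out <- vector("list", nrow(queries))
  for (i in seq_len(nrow(queries))) {
    ids <- vapply(seq_len(nrow(panel)), function(j) {
      percent_identity(global_align(queries$sequence[[i]], panel$sequence[[j]], ...))
    }, numeric(1))
    ord <- order(-ids, panel$family, panel$id)
    best <- ord[[1]]
    identity <- ids[[best]]
    if (identity > sub_thr) {
      fam <- panel$family[[best]]
      sub <- panel$subfamily[[best]]
      novel <- FALSE
    } else if (identity > fam_thr) {
      fam <- panel$family[[best]]
      taken <- used_letters[[as.character(fam)]]
      sub <- setdiff(LETTERS, taken)[[1]]
      used_letters[[as.character(fam)]] <- c(taken, sub)
      novel <- FALSE
    } else {
      fam <- next_novel
      next_novel <- next_novel + 1L
      sub <- "A"
      novel <- TRUE
    }
    out[[i]] <- tibble(
      query_id = queries$id[[i]],
      best_reference = panel$id[[best]],
      identity = identity,
      family = as.integer(fam),
      subfamily = sub,
      novel = novel
    )
  }
  dplyr::bind_rows(out)
}

#' Construct AGNC gene symbols
#'
#' Builds symbols of the form `<prefix><root><family><subfamily><gene
#' number><variant letter>`: within each (family, subfamily) genes are
#' numbered 1..n by chromosomal position (chromosome, then start
#' coordinate), and a gene's transcripts are lettered a, b, c... in
#' lexicographic transcript-ID order. Genes with a single transcript carry
#' no variant letter. Novel families are symbolled `<prefix><root>novelK`
#' with a running index K.
#'
#' @param assignments tibble mapping `locus_id` to `family`, `subfamily`
#'   and optionally `novel` (one row per locus).
#' @param loci tibble with `locus_id`, `chromosome`, `start`.
#' @param variants tibble with `locus_id`, `transcript_id` (one row per
#'   transcript).
#' @param prefix species prefix (default `"Sb"`).
#' @param root gene root symbol (default `"ALDH"`).
#' @return `variants` with added columns `gene_number`, `variant_letter`
#'   and `symbol`; symbols are guaranteed unique.
#' @export
build_symbols <- function(assignments, loci, variants,
                          prefix = "Sb", root = "ALDH") {
  check_that(!anyDuplicated(assignments$locus_id),
             "assignments must have one row per locus")
  if (!"novel" %in% names(assignments)) assignments$novel <- FALSE
  gene <- assignments %>%
    dplyr::inner_join(loci, by = "locus_id") %>%
    dplyr::arrange(.data$family, .data$subfamily, .data$chromosome, .data$start) %>%
    dplyr::group_by(.data$family, .data$subfamily) %>%
    dplyr::mutate(gene_number = dplyr::row_number()) %>%
    dplyr::ungroup()
  check_that(nrow(gene) == nrow(assignments),
             "every assigned locus needs coordinates in `loci`")

  novel_idx <- cumsum(gene$novel)
  gene$stem <- ifelse(
    gene$novel,
    paste0(prefix, root, "novel", novel_idx),
    paste0(prefix, root, gene$family, gene$subfamily, gene$gene_number)
  )

  if (max(table(variants$locus_id)) > 26) {
    abort("more than 26 transcript variants for one locus")
  }
  out <- variants %>%
    dplyr::inner_join(dplyr::select(gene, "locus_id", "gene_number", "stem"),
                      by = "locus_id") %>%
    dplyr::arrange(.data$locus_id, .data$transcript_id) %>%
    dplyr::group_by(.data$locus_id) %>%
    dplyr::mutate(
      variant_letter = if (dplyr::n() == 1) "" else letters[dplyr::row_number()],
      symbol = paste0(.data$stem, .data$variant_letter)
    ) %>%
    dplyr::ungroup() %>%
    dplyr::select(-"stem")
  check_that(!anyDuplicated(out$symbol), "constructed symbols must be unique")
  out
}
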