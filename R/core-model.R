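#' Read a FASTA file into a tibble
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that uppercases the
#' sequences, keeps record order, and validates identifiers and characters.
#'
#' @param path path to a FASTA file (wrapped or unwrapped records).
#' @param alphabet `"aa"` for protein or `"dna"` for nucleotide validation.
#'   Protein sequences may use the 20 standard residues plus `B`, `Z`, `X`
#'   and `*`; nucleotide sequences `A`, `C`, `G`, `T`, `N`.
#' @return a tibble with columns `id` and `sequence`, one row per record.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "acgt"), fa)
#' read_fasta(fa, alphabet = "dna")
read_fasta <- function(path, alphabet = c("aa", "dna")) {
  alphabet <- match.arg(alphabet)
  check_that(file.exists(path), paste0("file not found: ", path))
  if (file.size(path) == 0) {
    return(tibble(id = character(), sequence = character()))
  }
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  check_that(all(nzchar(ids)), "FASTA records must have non-empty headers")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(paste0("duplicate FASTA ID(s): ", paste(unique(dup), collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  allowed <- if (alphabet == "aa") c(AA20, "B", "Z", "X", "*") else c(DNA4, "N")
  bad_rx <- paste0("[^", paste(gsub("\\*", "\\\\*", allowed), collapse = ""), "]")
  for (i in seq_along(seqs)) {
    hit <- regexpr(bad_rx, seqs[[i]])
    if (hit > 0) {
      abort(sprintf("illegal character '%s' at position %d of record '%s'",
                    substr(seqs[[i]], hit, hit), hit, ids[[i]]))
    }
  }
  tibble(id = ids, sequence = unname(seqs))
}

#' Write a tibble of sequences to FASTA
#'
#' @param x tibble with columns `id` and `sequence`.
#' @param path output path.
#' @param width line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60) {
  check_that(all(c("id", "sequence") %in% names(x)),
             "x must have columns 'id' and 'sequence'")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(x))) {
    writeLines(paste0(">", x$id[[i]]), con)
    s <- x$sequence[[i]]
    starts <- seq(1, max(nchar(s), 1), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Parse the chromosome number from a locus identifier
#'
#' Phytozome sorghum locus IDs encode the chromosome in the three digits
#' following the `Sobic.` prefix (`Sobic.004G250900` is on chromosome 4).
#' An explicit chromosome label such as `"Chr02"` always takes precedence.
#'
#' @param locus_id character vector of locus IDs.
#' @param chromosome optional explicit chromosome labels (e.g. `"Chr02"`,
#'   `"2"`); non-missing entries override ID parsing.
#' @return integer vector of chromosome numbers.
#' @export
#' @examples
#' chromosome_of(c("Sobic.004G250900", "Sobic.010G113000"))
#' chromosome_of("geneX", chromosome = "Chr02")
chromosome_of <- function(locus_id, chromosome = NULL) {
  out <- rep(NA_integer_, length(locus_id))
  if (!is.null(chromosome)) {
    chromosome <- rep_len(as.character(chromosome), length(locus_id))
    expl <- !is.na(chromosome) & nzchar(chromosome)
    out[expl] <- as.integer(sub("(?i)^chr0*", "", chromosome[expl], perl = TRUE))
  }
  need <- which(is.na(out))
  if (length(need) > 0) {
    caps <- regmatches(locus_id[need],
                       regexec("^[A-Za-z]+\\.(\\d{3})G", locus_id[need]))
    out[need] <- vapply(caps, function(g) {
      if (length(g) == 2) as.integer(g[[2]]) else NA_integer_
    }, integer(1))
  }
  if (anyNA(out)) {
    abort(paste0("cannot determine chromosome for locus ID(s): ",
                 paste(locus_id[is.na(out)], collapse = ", ")))
  }
  out
}

#' Read a gene/transcript annotation table
#'
#' Reads a TSV laid out like the published gene inventory: one row per
#' transcript with its parent locus, 1-based inclusive genomic coordinates,
#' transcript/CDS/protein lengths, conserved-domain span, active-site flags,
#' and physicochemical columns. The chromosome is parsed from the locus ID
#' unless an explicit `chromosome` column is present.
#'
#' Validation enforces `start <= end`, CDS length divisible by 3, and the
#' coding identity `protein_aa == cds_nt / 3 - 1` (terminal stop codon
#' excluded). With `strict = TRUE` any violation is an error; otherwise
#' non-structural violations are collected as warnings.
#'
#' @param path TSV path with header columns `family`, `locus_id`,
#'   `transcript_id`, `name`, `start`, `end`, `transcript_nt`, `cds_nt`,
#'   `protein_aa`, `domain_start`, `domain_end`, `ps00687`, `ps00070`,
#'   `mw_kda`, `pi` (optional: `chromosome`, `strand`, `localization`).
#' @param strict escalate validation warnings to errors (default `TRUE`,
#'   appropriate for curated fixtures).
#' @return a tibble with one row per transcript and a derived integer
#'   `chromosome` column.
#' @export
#' @examples
#' tab <- read_gene_table(aldh_example("table1.tsv"))
#' dplyr::count(tab, family)
read_gene_table <- function(path, strict = TRUE) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("family", "locus_id", "transcript_id", "name", "start", "end",
                "transcript_nt", "cds_nt", "protein_aa")
  missing <- setdiff(required, names(tab))
  check_that(length(missing) == 0,
             paste0("gene table lacks column(s): ", paste(missing, collapse = ", ")))
  if (!"strand" %in% names(tab)) tab$strand <- "+"
  tab$strand[is.na(tab$strand)] <- "+"
  tab$chromosome <- chromosome_of(
    tab$locus_id,
    chromosome = if ("chromosome" %in% names(tab)) tab$chromosome else NULL
  )
  check_that(all(tab$start <= tab$end), "start must be <= end for every row")
  check_that(!anyDuplicated(tab$transcript_id),
             "transcript_id values must be unique")
  bad_cds <- tab$transcript_id[tab$cds_nt %% 3 != 0]
  if (length(bad_cds) > 0) {
    abort(paste0("CDS length not divisible by 3 for: ",
                 paste(bad_cds, collapse = ", ")))
  }
  bad_len <- tab$transcript_id[tab$protein_aa != tab$cds_nt / 3 - 1]
  if (length(bad_len) > 0) {
    msg <- paste0("protein length != CDS/3 - 1 for: ",
                  paste(bad_len, collapse = ", "))
    if (strict) abort(msg) else warn(msg)
  }
  if (all(c("domain_start", "domain_end") %in% names(tab))) {
    bad_dom <- !is.na(tab$domain_start) &
      (tab$domain_start < 1 | tab$domain_end > tab$protein_aa |
         tab$domain_start > tab$domain_end)
    if (any(bad_dom)) {
      msg <- paste0("domain span outside [1, protein length] for: ",
                    paste(tab$transcript_id[bad_dom], collapse = ", "))
      if (strict) abort(msg) else warn(msg)
    }
  }
  dplyr::relocate(tab, "family", "locus_id", "transcript_id", "name",
                  "chromosome", "start", "end", "strand")
}

#' Write a gene table back to TSV
#'
#' Inverse of [read_gene_table()]; a write-then-read round trip reproduces
#' the records.
#'
#' @param x gene-table tibble.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Path to a bundled example/fixture file
#'
#' @param file file name under the package's `extdata` (e.g. `"table1.tsv"`,
#'   `"table2.tsv"`, `"fig4_scenarios.tsv"`, `"prosite_patterns.cfg"`,
#'   `"plantcare_catalog.tsv"`). With no argument, lists available files.
#' @return a file path, or a character vector of file names.
#' @export
#' @examples
#' aldh_example()
aldh_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "aldhfam")))
  }
  path <- system.file("extdata", file, package = "aldhfam", mustWork = TRUE)
  path
}

#' Summary counts for a gene table
#'
#' @param genes gene-table tibble from [read_gene_table()].
#' @return a one-row tibble: number of loci, transcripts, families, and
#'   occupied chromosomes.
#' @export
#' @examples
#' gene_table_counts(read_gene_table(aldh_example("table1.tsv")))
gene_table_counts <- function(genes) {
  tibble(
    n_genes = dplyr::n_distinct(genes$locus_id),
    n_transcripts = nrow(genes),
    n_families = dplyr::n_distinct(genes$family),
    n_chromosomes = dplyr::n_distinct(genes$chromosome)
  )
}
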