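# Nei-Gojobori (1986) synonymous/nonsynonymous machinery with
# Jukes-Cantor multiple-hit correction. Stop handling: mutational
# neighbours that would create a stop codon are excluded from both the
# numerator and the per-position denominator in site counting, and
# substitution pathways passing through a stop are dropped from the
# pathway average.

GENETIC_CODE <- Biostrings::GENETIC_CODE

translate_codon <- function(codon) {
  aa <- GENETIC_CODE[[codon]]
  if (is.null(aa)) abort(paste0("not a valid codon: ", codon))
  aa
}

is_stop <- function(codon) translate_codon(codon) == "*"

#' Synonymous and nonsynonymous site counts of a codon (NG86)
#'
#' For each of the three positions, the synonymous fraction is the number
#' of the possible single-nucleotide changes that preserve the amino acid,
#' divided by the number of changes that do not create a stop codon.
#' Each position contributes one site, so the two counts always sum to 3.
#'
#' @param codon three unambiguous nucleotides, not a stop codon.
#' @return named numeric vector `c(syn = , nonsyn = )`.
#' @export
#' @examples
#' ng86_sites("TTT") # c(syn = 1/3, nonsyn = 8/3)
ng86_sites <- function(codon) {
  codon <- toupper(codon)
  check_that(nchar(codon) == 3 && !grepl("[^ACGT]", codon),
             "codon must be 3 unambiguous nucleotides")
  check_that(!is_stop(codon), "stop codons carry no sites")
  aa <- translate_codon(codon)
  syn <- 0
  for (pos in 1:3) {
    n_syn <- 0L
    n_valid <- 0L
    for (nt in setdiff(DNA4, substr(codon, pos, pos))) {
      mut <- codon
      substr(mut, pos, pos) <- nt
      if (is_stop(mut)) next
      n_valid <- n_valid + 1L
      if (translate_codon(mut) == aa) n_syn <- n_syn + 1L
    }
    if (n_valid > 0) syn <- syn + n_syn / n_valid
  }
  c(syn = syn, nonsyn = 3 - syn)
}

#' Synonymous and nonsynonymous differences between two codons (NG86)
#'
#' Differences are averaged over all minimal substitution pathways (1, 2 or
#' 6 orderings for 1, 2 or 3 differing positions); pathways passing through
#' a stop codon are excluded from the average. If every pathway is
#' stop-excluded (vanishingly rare at the divergences seen in practice),
#' all pathways are used with stop intermediates classified as
#' nonsynonymous steps.
#'
#' @param codon_a,codon_b two non-stop codons.
#' @return named numeric vector `c(syn = , nonsyn = )`; the two entries sum
#'   to the number of differing positions whenever no pathway is excluded.
#' @export
#' @examples
#' ng86_differences("TTT", "GTA") # c(syn = 0.5, nonsyn = 1.5)
ng86_differences <- function(codon_a, codon_b) {
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  for (cd in c(codon_a, codon_b)) {
    check_that(nchar(cd) == 3 && !grepl("[^ACGT]", cd),
               "codons must be 3 unambiguous nucleotides")
    check_that(!is_stop(cd), "stop codons are not allowed")
  }
  diff_pos <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  if (length(diff_pos) == 0) return(c(syn = 0, nonsyn = 0))

  paths <- pathway_counts(codon_a, codon_b, diff_pos)
  valid <- paths[!paths$through_stop, , drop = FALSE]
  use <- if (nrow(valid) > 0) valid else paths
  c(syn = mean(use$syn), nonsyn = mean(use$nonsyn))
}

# enumerate all orderings of the differing positions; count step classes
pathway_counts <- function(codon_a, codon_b, diff_pos) {
  orderings <- perms(diff_pos)
  res <- lapply(orderings, function(ord) {
    cur <- codon_a
    syn <- 0L; nonsyn <- 0L; through_stop <- FALSE
    for (pos in ord) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(codon_b, pos, pos)
      if (is_stop(nxt)) through_stop <- TRUE
      aa_cur <- translate_codon(cur); aa_nxt <- translate_codon(nxt)
      if (aa_cur == aa_nxt && aa_nxt != "*") syn <- syn + 1L else nonsyn <- nonsyn + 1L
      cur <- nxt
    }
    data.frame(syn = syn, nonsyn = nonsyn, through_stop = through_stop)
  })
  do.call(rbind, res)
}

perms <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in perms(x[-i])) out[[length(out) + 1L]] <- c(x[[i]], rest)
  }
  out
}

#' Jukes-Cantor correction of a proportion of differences
#'
#' `d = -(3/4) * ln(1 - 4p/3)`; monotone increasing on `[0, 3/4)` with
#' `JC(0) = 0`. Proportions at or beyond saturation (`p >= 3/4`) give `NA`.
#'
#' @param p proportion of observed differences per site.
#' @return corrected distance, or `NA` when saturated.
#' @export
#' @examples
#' jc_correct(0.5) # 0.8239 to 4 dp
jc_correct <- function(p) {
  check_that(all(p >= 0, na.rm = TRUE), "p must be >= 0")
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

# Back-thread a protein alignment onto the two CDS, dropping gap columns.
# Returns a data.frame of paired codons.
codon_alignment <- function(cds_a, cds_b, aligned_a, aligned_b) {
  cds_a <- toupper(cds_a); cds_b <- toupper(cds_b)
  check_that(nchar(cds_a) %% 3 == 0 && nchar(cds_b) %% 3 == 0,
             "CDS lengths must be divisible by 3")
  ca <- strsplit(aligned_a, "")[[1]]
  cb <- strsplit(aligned_b, "")[[1]]
  check_that(length(ca) == length(cb), "aligned strings differ in length")
  codons_of <- function(cds) {
    n <- nchar(cds) %/% 3
    substring(cds, 3 * seq_len(n) - 2, 3 * seq_len(n))
  }
  cod_a <- codons_of(cds_a)
  cod_b <- codons_of(cds_b)
  # strip terminal stop codons if present
  if (length(cod_a) > 0 && is_stop(cod_a[[length(cod_a)]])) cod_a <- cod_a[-length(cod_a)]
  if (length(cod_b) > 0 && is_stop(cod_b[[length(cod_b)]])) cod_b <- cod_b[-length(cod_b)]
  check_that(sum(ca != "-") == length(cod_a) && sum(cb != "-") == length(cod_b),
             "CDS length does not match the aligned protein")
  ia <- 0L; ib <- 0L
  pairs <- list()
  for (k in seq_along(ca)) {
    if (ca[[k]] != "-") ia <- ia + 1L
    if (cb[[k]] != "-") ib <- ib + 1L
    if (ca[[k]] != "-" && cb[[k]] != "-") {
      pairs[[length(pairs) + 1L]] <- c(cod_a[[ia]], cod_b[[ib]])
    }
  }
  data.frame(
    codon_a = vapply(pairs, `[[`, "", 1),
    codon_b = vapply(pairs, `[[`, "", 2)
  )
}

#' Ka and Ks by Nei-Gojobori (1986) with Jukes-Cantor correction
#'
#' The protein alignment is back-threaded onto the two CDS (gap columns
#' dropped) to give a codon alignment. Synonymous (S) and nonsynonymous (N)
#' site totals are averaged over the two sequences; observed differences
#' are pathway-averaged per codon pair; `pS = Sd/S` and `pN = Nd/N` are
#' Jukes-Cantor corrected to Ks and Ka.
#'
#' @param cds_a,cds_b in-frame coding sequences (terminal stop codon
#'   allowed and ignored) translating to the aligned proteins.
#' @param alignment a `"protein_alignment"` from [global_align()], or
#'   `NULL` to align the translations internally.
#' @return a one-row tibble: `ka`, `ks`, `ratio` (NA when `ks` is 0 or
#'   undefined), `n_codons`, `syn_sites`, `nonsyn_sites`, `syn_diffs`,
#'   `nonsyn_diffs`. Saturated rates (`p >= 3/4`) are `NA`.
#' @export
#' @examples
#' kaks("ATGGCTGCT", "ATGGCAGCT") # one synonymous difference
kaks <- function(cds_a, cds_b, alignment = NULL) {
  if (is.null(alignment)) {
    prot <- function(cds) {
      as.character(Biostrings::translate(Biostrings::DNAString(toupper(cds)),
                                         no.init.codon = TRUE))
    }
    pa <- sub("\\*$", "", prot(cds_a))
    pb <- sub("\\*$", "", prot(cds_b))
    alignment <- global_align(pa, pb)
  }
  codons <- codon_alignment(cds_a, cds_b, alignment$aligned_a, alignment$aligned_b)
  check_that(nrow(codons) > 0, "no aligned codon columns")
  check_that(!any(vapply(codons$codon_a, is_stop, logical(1))) &&
               !any(vapply(codons$codon_b, is_stop, logical(1))),
             "internal stop codon in codon alignment")

  sites_a <- vapply(codons$codon_a, ng86_sites, numeric(2))
  sites_b <- vapply(codons$codon_b, ng86_sites, numeric(2))
  S <- (sum(sites_a["syn", ]) + sum(sites_b["syn", ])) / 2
  N <- (sum(sites_a["nonsyn", ]) + sum(sites_b["nonsyn", ])) / 2
  diffs <- mapply(function(a, b) ng86_differences(a, b),
                  codons$codon_a, codons$codon_b)
  Sd <- sum(diffs["syn", ])
  Nd <- sum(diffs["nonsyn", ])
  ks <- if (S > 0) jc_correct(Sd / S) else NA_real_
  ka <- if (N > 0) jc_correct(Nd / N) else NA_real_
  tibble(
    ka = ka, ks = ks,
    ratio = compute_ratio(ka, ks),
    n_codons = nrow(codons),
    syn_sites = S, nonsyn_sites = N,
    syn_diffs = Sd, nonsyn_diffs = Nd
  )
}

#' Ka/Ks ratio with the 0/0 convention
#'
#' @param ka,ks non-negative rates (NA allowed for saturated estimates).
#' @return `ka/ks` when `ks > 0`; `NA` otherwise (including the 0/0 case,
#'   rendered as the infinity glyph in reports).
#' @export
#' @examples
#' compute_ratio(0.1664, 2.5295)
compute_ratio <- function(ka, ks) {
  check_that(all(c(ka, ks) >= 0, na.rm = TRUE), "ka and ks must be >= 0")
  if (is.na(ka) || is.na(ks) || ks == 0) return(NA_real_)
  ka / ks
}

#' Duplication date from Ks
#'
#' `T = Ks / (2 * lambda)` expressed in million years (Mya). The workflow's
#' printed default rate is 6.1e-9 substitutions/site/year; the dates in the
#' published duplicate table are consistent with 1.5e-8 instead, so the
#' rate is always an explicit argument.
#'
#' @param ks synonymous substitutions per synonymous site (NA gives NA).
#' @param rate neutral substitution rate lambda per site per year.
#' @return time in Mya.
#' @export
#' @examples
#' divergence_time(0.7719, rate = 1.5e-8) # 25.73 Mya
divergence_time <- function(ks, rate = 6.1e-9) {
  check_that(rate > 0, "rate must be > 0")
  check_that(all(ks >= 0, na.rm = TRUE), "ks must be >= 0")
  ks / (2 * rate) * 1e-6
}

#' Selection regime from a Ka/Ks ratio
#'
#' @param ratio Ka/Ks value, or NA for the undefined case.
#' @param tol tolerance for calling equality with 1 (default 1e-9).
#' @return one of `"positive"`, `"purifying"`, `"neutral"`,
#'   `"undetermined"`.
#' @export
#' @examples
#' selection_regime(0.0657)
selection_regime <- function(ratio, tol = 1e-9) {
  vapply(ratio, function(r) {
    if (is.na(r)) return("undetermined")
    if (abs(r - 1) <= tol) return("neutral")
    if (r > 1) "positive" else "purifying"
  }, character(1))
}
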