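# Seeded synthetic-data generators with ground-truth manifests. Every
# generator is a pure function of its arguments and seed (withr::with_seed
# isolates the RNG), so regeneration with the same seed is byte-identical.

random_protein <- function(length) {
  paste(sample(AA20, length, replace = TRUE), collapse = "")
}

# substitute exactly k positions, each to a different residue
mutate_protein <- function(seq, k) {
  chars <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(chars), k)
  for (p in pos) {
    chars[[p]] <- sample(setdiff(AA20, chars[[p]]), 1)
  }
  paste(chars, collapse = "")
}

#' Simulate a labelled reference panel with planted-identity queries
#'
#' Generates one random ancestor protein per family; the panel entry for a
#' family is the ancestor itself (subfamily "A"). Each query is derived
#' from its family ancestor by substitution-only mutation at exactly the
#' number of positions giving the requested ungapped identity, so the
#' realized identity is exact by construction (well within the ±3%
#' calibration band).
#'
#' @param n_families number of families.
#' @param members_per_family queries generated per family per identity
#'   level.
#' @param identity_levels planted percent identities (each in (5, 100\]).
#' @param protein_length ancestor length in aa (>= 100).
#' @param seed integer RNG seed.
#' @return list with `$panel` (reference tibble for [assign_family()]),
#'   `$queries` (tibble `id`, `sequence`) and `$manifest` (tibble with the
#'   planted family, identity level and the expected assignment tier).
#' @export
#' @examples
#' sim <- simulate_family_panel(2, 1, c(85, 25), seed = 1)
#' sim$manifest
simulate_family_panel <- function(n_families = 3, members_per_family = 2,
                                  identity_levels = c(85, 50, 25),
                                  protein_length = 150, seed = 1L) {
  check_that(all(identity_levels > 5 & identity_levels <= 100),
             "identity levels must lie in (5, 100]")
  check_that(protein_length >= 100, "protein_length must be >= 100")
  withr::with_seed(seed, {
    panel <- tibble(
      id = sprintf("REF%d", seq_len(n_families)),
      family = seq_len(n_families),
      subfamily = "A",
      sequence = vapply(seq_len(n_families), function(i) {
        random_protein(protein_length)
      }, character(1))
    )
    rows <- list()
    for (fam in seq_len(n_families)) {
      for (lvl in identity_levels) {
        for (m in seq_len(members_per_family)) {
          k <- round((1 - lvl / 100) * protein_length)
          q <- mutate_protein(panel$sequence[[fam]], k)
          realized <- 100 * (protein_length - k) / protein_length
          rows[[length(rows) + 1L]] <- tibble(
            id = sprintf("Q_f%d_i%d_m%d", fam, round(lvl), m),
            sequence = q,
            family = fam,
            planted_identity = lvl,
            realized_identity = realized,
            expected_tier = if (lvl > 60) "subfamily"
                            else if (lvl > 40) "family" else "novel"
          )
        }
      }
    }
    truth <- dplyr::bind_rows(rows)
    list(
      panel = panel,
      queries = dplyr::select(truth, "id", "sequence"),
      manifest = dplyr::select(truth, -"sequence")
    )
  })
}

# codons whose third position is fully degenerate (any base keeps the aa)
FOURFOLD_PREFIXES <- c("GC", "GG", "CC", "AC", "GT", "CT", "TC", "CG")

random_cds <- function(n_codons) {
  sense <- setdiff(names(GENETIC_CODE)[GENETIC_CODE != "*"], c("TAA", "TAG", "TGA"))
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

#' Simulate duplicate CDS pairs with planted substitution counts
#'
#' Each pair derives from a random stop-free ancestor CDS: synonymous
#' changes are planted at third positions of fourfold-degenerate codons,
#' nonsynonymous changes at first/second positions (rejecting any change
#' that creates a stop or preserves the amino acid). The genomic layout
#' places `tandem` pairs on a shared chromosome within the 100-kb window
#' and the rest on distinct chromosomes.
#'
#' @param n_pairs number of duplicate pairs.
#' @param n_codons codons per CDS (>= 50).
#' @param syn_subs,nonsyn_subs substitutions planted per pair (recycled).
#' @param n_tandem how many pairs are laid out as tandem duplicates.
#' @param seed integer RNG seed.
#' @return list with `$cds` (tibble `id`, `sequence`), `$genes` (coordinate
#'   tibble usable by [classify_pair()]), `$pairs` (tibble `locus_a`,
#'   `locus_b`) and `$manifest` (planted counts, per-site proportions and
#'   true duplication class).
#' @export
simulate_duplication_set <- function(n_pairs = 3, n_codons = 300,
                                     syn_subs = 10, nonsyn_subs = 10,
                                     n_tandem = 1, seed = 1L) {
  check_that(n_codons >= 50, "n_codons must be >= 50")
  check_that(n_tandem <= n_pairs, "n_tandem cannot exceed n_pairs")
  syn_subs <- rep_len(syn_subs, n_pairs)
  nonsyn_subs <- rep_len(nonsyn_subs, n_pairs)
  withr::with_seed(seed, {
    cds <- list(); genes <- list(); pairs <- list(); manifest <- list()
    for (p in seq_len(n_pairs)) {
      anc <- random_cds(n_codons)
      codons <- substring(anc, 3 * seq_len(n_codons) - 2, 3 * seq_len(n_codons))
      fourfold <- which(substr(codons, 1, 2) %in% FOURFOLD_PREFIXES)
      check_that(length(fourfold) >= syn_subs[[p]],
                 "synonymous substitution budget exceeds available sites")
      der <- codons
      syn_at <- sample(fourfold, syn_subs[[p]])
      for (i in syn_at) {
        third <- substr(der[[i]], 3, 3)
        substr(der[[i]], 3, 3) <- sample(setdiff(DNA4, third), 1)
      }
      non_at <- sample(setdiff(seq_len(n_codons), syn_at), nonsyn_subs[[p]])
      for (i in non_at) {
        repeat {
          cand <- der[[i]]
          pos <- sample(1:2, 1)
          substr(cand, pos, pos) <- sample(setdiff(DNA4, substr(cand, pos, pos)), 1)
          if (!is_stop(cand) &&
              translate_codon(cand) != translate_codon(der[[i]])) {
            der[[i]] <- cand
            break
          }
        }
      }
      id_a <- sprintf("SIMDUP%d_a", p)
      id_b <- sprintf("SIMDUP%d_b", p)
      cds[[p]] <- tibble(id = c(id_a, id_b),
                         sequence = c(anc, paste(der, collapse = "")))
      tandem <- p <= n_tandem
      if (tandem) {
        chr <- 1L
        start_a <- 1e6 + p * 3e5
        start_b <- start_a + nchar(anc) + 3e4   # 30-kb gap, within window
        chr_b <- chr
      } else {
        chr <- p + 1L
        start_a <- 1e6
        start_b <- 1e6
        chr_b <- chr + n_pairs
      }
      genes[[p]] <- tibble(
        locus_id = c(id_a, id_b),
        chromosome = c(chr, chr_b),
        start = c(start_a, start_b),
        end = c(start_a, start_b) + nchar(anc) - 1
      )
      pairs[[p]] <- tibble(locus_a = id_a, locus_b = id_b)
      manifest[[p]] <- tibble(
        locus_a = id_a, locus_b = id_b,
        syn_subs = syn_subs[[p]], nonsyn_subs = nonsyn_subs[[p]],
        true_class = ifelse(tandem, "tandem", "segmental"),
        n_codons = n_codons
      )
    }
    list(
      cds = dplyr::bind_rows(cds),
      genes = dplyr::bind_rows(genes),
      pairs = dplyr::bind_rows(pairs),
      manifest = dplyr::bind_rows(manifest)
    )
  })
}

#' Simulate promoters with planted motif occurrences
#'
#' Backgrounds are rejection-sampled until free of any catalog match on
#' either strand; motifs are then planted at non-overlapping positions
#' (ambiguity codes instantiated at random) and the promoter is re-scanned
#' to confirm the realized occurrence table equals the plan exactly.
#'
#' @param plant tibble with columns `gene_id`, `element`, `n` (occurrences
#'   to plant) and optionally `strand` (`"+"` default).
#' @param catalog motif catalog (default bundled).
#' @param length promoter length in bp (default 1000).
#' @param seed integer RNG seed.
#' @param max_tries rejection-sampling cap per promoter.
#' @return list with `$promoters` (tibble `gene_id`, `sequence`) and
#'   `$manifest` (the realized plant table with positions and strands).
#' @export
simulate_promoters <- function(plant, catalog = read_motif_catalog(),
                               length = 1000, seed = 1L, max_tries = 200) {
  check_that(all(c("gene_id", "element", "n") %in% names(plant)),
             "plant needs columns gene_id, element, n")
  if (!"strand" %in% names(plant)) plant$strand <- "+"
  check_that(all(plant$element %in% catalog$name),
             "planted elements must exist in the catalog")
  iupac <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                D = c("A", "G", "T"), H = c("A", "C", "T"),
                V = c("A", "C", "G"), N = DNA4)
  instantiate <- function(cons) {
    paste(vapply(strsplit(toupper(cons), "")[[1]], function(ch) {
      opts <- iupac[[ch]]
      if (length(opts) == 1) opts else sample(opts, 1)
    }, character(1)), collapse = "")
  }
  revcomp <- function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  withr::with_seed(seed, {
    out_seq <- list(); out_man <- list()
    for (g in unique(plant$gene_id)) {
      want <- dplyr::filter(plant, .data$gene_id == g, .data$n > 0)
      done <- FALSE
      for (try in seq_len(max_tries)) {
        # catalog-free background: start random, then scrub residual matches
        # by point-mutating inside each match until the scan comes back empty
        cand <- paste(sample(DNA4, length, replace = TRUE), collapse = "")
        bg <- NULL
        for (bgtry in seq_len(max_tries)) {
          occ0 <- scan_elements(cand, catalog, gene_id = g)
          if (nrow(occ0) == 0) {
            bg <- cand
            break
          }
          chars0 <- strsplit(cand, "")[[1]]
          for (r in seq_len(nrow(occ0))) {
            at <- sample(occ0$start[[r]]:occ0$end[[r]], 1)
            chars0[[at]] <- sample(setdiff(DNA4, chars0[[at]]), 1)
          }
          cand <- paste(chars0, collapse = "")
        }
        check_that(!is.null(bg), "could not sample a catalog-free background")
        inserts <- want[rep(seq_len(nrow(want)), want$n), , drop = FALSE]
        widths <- nchar(catalog$consensus[match(inserts$element, catalog$name)])
        # non-overlapping placement, greedy with resampling
        taken <- integer(0)
        pos <- integer(nrow(inserts))
        ok <- TRUE
        if (nrow(inserts) > 0) {
          check_that(sum(widths) <= length,
                     "requested plants exceed promoter capacity")
          for (i in seq_len(nrow(inserts))) {
            placed <- FALSE
            for (ptry in 1:200) {
              s <- sample.int(length - widths[[i]] + 1, 1)
              span <- s:(s + widths[[i]] - 1)
              if (!any(span %in% taken)) {
                taken <- c(taken, span)
                pos[[i]] <- s
                placed <- TRUE
                break
              }
            }
            if (!placed) { ok <- FALSE; break }
          }
        }
        if (!ok) next
        seqchars <- strsplit(bg, "")[[1]]
        for (i in seq_len(nrow(inserts))) {
          cons <- catalog$consensus[[match(inserts$element[[i]], catalog$name)]]
          word <- instantiate(cons)
          if (inserts$strand[[i]] == "-") word <- revcomp(word)
          seqchars[pos[[i]]:(pos[[i]] + nchar(word) - 1)] <- strsplit(word, "")[[1]]
        }
        prom <- paste(seqchars, collapse = "")
        occ <- scan_elements(prom, catalog, gene_id = g)
        # a palindromic consensus hits both strands at one site; count sites
        realized <- occ %>%
          dplyr::distinct(.data$element, .data$start, .data$end) %>%
          dplyr::group_by(.data$element) %>%
          dplyr::summarise(k = dplyr::n()) %>%
          dplyr::arrange(.data$element)
        wanted <- inserts %>%
          dplyr::group_by(.data$element) %>%
          dplyr::summarise(k = dplyr::n()) %>%
          dplyr::arrange(.data$element)
        if (identical(realized$element, wanted$element) &&
            identical(realized$k, wanted$k)) {
          out_seq[[g]] <- tibble(gene_id = g, sequence = prom)
          out_man[[g]] <- if (nrow(inserts) > 0) {
            dplyr::mutate(inserts, position = pos)
          } else {
            tibble(gene_id = character(), element = character(),
                   n = integer(), strand = character(), position = integer())
          }
          done <- TRUE
          break
        }
      }
      check_that(done, paste0("could not realize the requested plants for ", g))
    }
    list(promoters = dplyr::bind_rows(out_seq),
         manifest = dplyr::bind_rows(out_man))
  })
}

#' Simulate an expression matrix and a matching Cq table
#'
#' The matrix is `gene effect x group mean` with multiplicative lognormal
#' noise. The Cq table plants per-gene fold changes: control dCt values are
#' drawn around a baseline, treated dCt values subtract log2(fold change),
#' and Gaussian cycle noise of `noise_sd` is added to the target Cq (so
#' `noise_sd` is the standard deviation of dCt in cycles).
#'
#' @param n_genes genes in the matrix.
#' @param group_means named numeric vector of group mean levels; each group
#'   gets `n_per_group` sample columns.
#' @param n_per_group samples per group.
#' @param fold_changes named (by gene id) or unnamed vector of planted qPCR
#'   fold changes (recycled over genes).
#' @param noise_sd lognormal sdlog for the matrix and Cq cycle noise sd.
#' @param n_replicates qPCR replicates per condition (default 3).
#' @param seed integer RNG seed.
#' @return list with `$matrix` (tibble, `gene` + sample columns),
#'   `$grouping` (sample-to-group tibble), `$cq` (Cq tibble for
#'   [ddct_fold_change()]) and `$manifest`.
#' @export
simulate_expression <- function(n_genes = 6,
                                group_means = c(control = 100, stress = 400),
                                n_per_group = 3,
                                fold_changes = c(0.25, 1, 4),
                                noise_sd = 0.1,
                                n_replicates = 3,
                                seed = 1L) {
  check_that(noise_sd >= 0, "noise_sd must be >= 0")
  withr::with_seed(seed, {
    genes <- sprintf("SIMG%02d", seq_len(n_genes))
    effects <- stats::runif(n_genes, 0.5, 2)
    samples <- unlist(lapply(names(group_means), function(g) {
      sprintf("%s_s%d", g, seq_len(n_per_group))
    }))
    grouping <- tibble(
      sample = samples,
      group = rep(names(group_means), each = n_per_group)
    )
    mat <- matrix(0, n_genes, length(samples),
                  dimnames = list(genes, samples))
    for (j in seq_along(samples)) {
      mu <- group_means[[grouping$group[[j]]]]
      noise <- if (noise_sd > 0) stats::rlnorm(n_genes, 0, noise_sd) else 1
      mat[, j] <- mu * effects * noise
    }
    fc <- rep_len(fold_changes, n_genes)
    cq <- purrr::map_dfr(seq_len(n_genes), function(i) {
      base_dct <- stats::runif(1, 2, 6)
      ref <- 20
      mk <- function(cond, dct) {
        tibble(
          gene = genes[[i]], condition = cond,
          replicate = seq_len(n_replicates),
          cq_target = ref + dct +
            (if (noise_sd > 0) stats::rnorm(n_replicates, 0, noise_sd) else 0),
          cq_reference = ref
        )
      }
      dplyr::bind_rows(mk("control", base_dct),
                       mk("treated", base_dct - log2(fc[[i]])))
    })
    list(
      matrix = dplyr::bind_cols(tibble(gene = genes), as_tibble(mat)),
      grouping = grouping,
      cq = cq,
      manifest = tibble(gene = genes, effect = effects, fold_change = fc)
    )
  })
}
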