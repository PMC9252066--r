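test_that("global alignment recovers textbook cases and the brute-force optimum", {
  m <- simple_aa_matrix(match = 1, mismatch = 0)

  # identity: ungapped, score = sum of diagonal entries
  aln <- global_align("ACD", "ACD", substitution_matrix = m,
                      gap_open = 0, gap_extend = 1)
  expect_equal(aln$aligned_a, "ACD")
  expect_equal(aln$aligned_b, "ACD")
  expect_equal(aln$score, 3)

  # classic one-gap case: ACD / A-D, score 1 under match=1/mismatch=0/gap=-1
  aln <- global_align("ACD", "AD", substitution_matrix = m,
                      gap_open = 0, gap_extend = 1)
  expect_equal(aln$aligned_a, "ACD")
  expect_equal(aln$aligned_b, "A-D")
  expect_equal(aln$score, oracle_align_score("ACD", "AD"))

  # single mismatch column
  aln <- global_align("A", "G", substitution_matrix = m,
                      gap_open = 0, gap_extend = 1)
  expect_equal(nchar(aln$aligned_a), 1)

  expect_error(global_align("", "A"), "non-empty")
})

test_that("alignment score equals the brute-force optimum on random tiny pairs", {
  withr::local_seed(11)
  m <- simple_aa_matrix(match = 1, mismatch = 0)
  for (rep in 1:25) {
    a <- random_protein_seq(sample(1:6, 1), alphabet = c("A", "C", "D", "G"))
    b <- random_protein_seq(sample(1:6, 1), alphabet = c("A", "C", "D", "G"))
    got <- global_align(a, b, substitution_matrix = m,
                        gap_open = 0, gap_extend = 1)$score
    expect_equal(got, oracle_align_score(a, b, 1, 0, -1), info = paste(a, b))
  }
})

test_that("percent identity counts identical columns over the gapped length", {
  expect_equal(percent_identity(strrep("K", 10), strrep("K", 10)), 100)
  expect_equal(percent_identity("ACD", "A-D"), 100 * 2 / 3)
  expect_equal(percent_identity("AAAA", "GGGG"), 0)
  expect_equal(percent_identity("AC-D", "AC-D"), 75)  # shared gap not identical
  expect_equal(percent_identity("ACD-", "-ACD", denominator = "shorter"),
               100 * 0 / 3)
})

test_that("identity and score are symmetric under argument swap", {
  withr::local_seed(5)
  for (rep in 1:10) {
    a <- random_protein_seq(sample(10:30, 1), alphabet = AA_LETTERS)
    b <- random_protein_seq(sample(10:30, 1), alphabet = AA_LETTERS)
    ab <- global_align(a, b)
    ba <- global_align(b, a)
    expect_equal(ab$score, ba$score)
    expect_equal(percent_identity(ab), percent_identity(ba))
  }
})

test_that("AGNC tiers follow the strict 40/60 thresholds", {
  withr::local_seed(3)
  panel <- tibble::tibble(
    id = c("refA", "refB"),
    family = c(2L, 3L),
    subfamily = c("B", "H"),
    sequence = c(random_protein_seq(150, AA_LETTERS),
                 random_protein_seq(150, AA_LETTERS))
  )
  sim <- simulate_family_panel(1, 1, c(85, 50, 25), protein_length = 150,
                               seed = 9)
  res <- assign_family(sim$queries, sim$panel)
  man <- sim$manifest
  expect_equal(res$family[man$expected_tier == "subfamily"],
               man$family[man$expected_tier == "subfamily"])
  expect_equal(res$subfamily[man$expected_tier == "subfamily"],
               rep("A", sum(man$expected_tier == "subfamily")))
  # mid-tier inherits the family but founds a new subfamily letter
  mid <- res[man$expected_tier == "family", ]
  expect_equal(mid$family, man$family[man$expected_tier == "family"])
  expect_false(any(mid$subfamily == "A"))
  expect_true(all(res$novel[man$expected_tier == "novel"]))

  expect_error(assign_family(sim$queries, panel[0, ]), "non-empty")
})

test_that("symbol construction numbers genes by position and letters variants", {
  tab <- read_gene_table(aldh_example("table1.tsv"))
  loci <- tab |>
    dplyr::group_by(locus_id, chromosome) |>
    dplyr::summarise(start = min(start), .groups = "drop")
  # derive the per-locus family/subfamily labels from the published names
  assignments <- tab |>
    dplyr::distinct(locus_id, family) |>
    dplyr::mutate(subfamily = vapply(locus_id, function(l) {
      nm <- tab$name[tab$locus_id == l][1]
      sub("^SbALDH[0-9]+([A-Z]).*$", "\\1", nm)
    }, character(1)))
  variants <- dplyr::select(tab, locus_id, transcript_id)
  sym <- build_symbols(assignments, loci, variants)
  got <- sym$symbol[match(tab$transcript_id, sym$transcript_id)]
  expect_equal(got, tab$name)
})

test_that("symbol construction edge rules: no letter for single transcripts, >26 errors", {
  assignments <- tibble::tibble(locus_id = "L1", family = 22L, subfamily = "A")
  loci <- tibble::tibble(locus_id = "L1", chromosome = 1L, start = 100)
  one <- build_symbols(assignments, loci,
                       tibble::tibble(locus_id = "L1", transcript_id = "L1.1"))
  expect_equal(one$symbol, "SbALDH22A1")

  many <- tibble::tibble(locus_id = "L1",
                         transcript_id = sprintf("L1.%02d", 1:27))
  expect_error(build_symbols(assignments, loci, many), "26")
})
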