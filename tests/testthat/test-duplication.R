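genes_tab <- read_gene_table(aldh_example("table1.tsv"))
tab2 <- readr::read_tsv(aldh_example("table2.tsv"), show_col_types = FALSE)

test_that("tandem classification uses the same-chromosome 100-kb gap rule", {
  # published tandem pair: ~29.6-kb gap on chromosome 3
  expect_equal(classify_pair(genes_tab, "Sobic.003G203500", "Sobic.003G203600"),
               "tandem")
  # different chromosomes
  expect_equal(classify_pair(genes_tab, "Sobic.003G356000", "Sobic.009G160100"),
               "segmental")
  # same chromosome but beyond the window
  toy <- tibble::tibble(
    locus_id = c("g1", "g2"), chromosome = c(1L, 1L),
    start = c(1e6, 1e6 + 155e3), end = c(1e6 + 5e3, 1e6 + 160e3)
  )
  expect_equal(classify_pair(toy, "g1", "g2"), "segmental")
  # overlap counts as gap zero
  toy$start[2] <- 1e6 + 2e3
  expect_equal(classify_pair(toy, "g1", "g2"), "tandem")

  expect_error(classify_pair(toy, "g1", "g1"), "itself")
  expect_error(classify_pair(toy, "g1", "missing"), "not in gene table")
})

test_that("strict segmental mode downgrades low-identity non-tandem pairs", {
  toy <- tibble::tibble(
    locus_id = c("g1", "g2"), chromosome = c(1L, 2L),
    start = c(1, 1), end = c(10, 10)
  )
  expect_equal(
    classify_pair(toy, "g1", "g2", protein_identity = 95,
                  strict_segmental = TRUE),
    "segmental"
  )
  expect_equal(
    classify_pair(toy, "g1", "g2", protein_identity = 50,
                  strict_segmental = TRUE),
    "unclassified"
  )
})

test_that("the published pair table reproduces under the implied rate", {
  cfg <- pipeline_config(substitution_rate = 1.5e-8)
  dup <- annotate_duplications(
    dplyr::select(tab2, locus_a, locus_b, ka, ks), genes_tab, cfg
  )
  got <- tidy(dup)
  expect_equal(sum(got$dup_class == "tandem"), 1)
  expect_equal(sum(got$dup_class == "segmental"), 5)
  expect_equal(got$dup_class[got$locus_a == "Sobic.003G203500"], "tandem")

  expect_equal(trunc_dec(got$ratio[-1], 4),
               c(0.0657, 0.2953, 0.1465, 0.1451, 0.1318))
  expect_true(is.na(got$ratio[1]))
  expect_equal(trunc_dec(got$time_mya[-1], 2),
               c(84.31, 25.73, 52.16, 36.37, 35.35))
  expect_equal(got$regime, c("undetermined", rep("purifying", 5)))

  g <- glance(dup)
  expect_equal(g$n_tandem, 1L)
  expect_equal(g$n_segmental, 5L)
  expect_equal(g$n_purifying, 5L)
})

test_that("the rendered duplicate table matches the published formatting", {
  cfg <- pipeline_config(substitution_rate = 1.5e-8)
  dup <- annotate_duplications(
    dplyr::select(tab2, locus_a, locus_b, ka, ks), genes_tab, cfg
  )
  names_map <- stats::setNames(
    c(tab2$gene_a, tab2$gene_b), c(tab2$locus_a, tab2$locus_b)
  )
  out <- render_duplication_table(dup, names_map)
  expect_equal(out$ka, c("0", "0.1664", "0.228", "0.2294", "0.1584", "0.1399"))
  expect_equal(out$ks, c("0", "2.5295", "0.7719", "1.5649", "1.0913", "1.0607"))
  expect_equal(out$ka_ks[1], "∞")
  expect_equal(out$ka_ks[-1],
               c("0.0657", "0.2953", "0.1465", "0.1451", "0.1318"))
  expect_equal(out$time_mya[1], "Not determinable")
  expect_equal(out$time_mya[-1],
               c("84.31", "25.73", "52.16", "36.37", "35.35"))
  expect_equal(out$dup_type, tab2$dup_type)
  expect_equal(out$locus_1, tab2$gene_a)
})

test_that("synthetic duplicates recover class and planted rates", {
  sim <- simulate_duplication_set(n_pairs = 4, n_codons = 300, syn_subs = 10,
                                  nonsyn_subs = 10, n_tandem = 2, seed = 14)
  cls <- classify_pair(sim$genes, sim$pairs$locus_a, sim$pairs$locus_b)
  expect_equal(cls, sim$manifest$true_class)

  res <- kaks(sim$cds$sequence[[1]], sim$cds$sequence[[2]])
  # 10 planted synonymous and 10 nonsynonymous substitutions over 300 codons
  expect_equal(res$syn_diffs + res$nonsyn_diffs, 20)
  expect_gt(res$ka, 0)
  expect_gt(res$ks, 0)

  # same seed regenerates identical sequences
  sim2 <- simulate_duplication_set(n_pairs = 4, n_codons = 300, syn_subs = 10,
                                   nonsyn_subs = 10, n_tandem = 2, seed = 14)
  expect_identical(sim$cds, sim2$cds)
})

test_that("autoplot on a duplication analysis returns a ggplot", {
  cfg <- pipeline_config(substitution_rate = 1.5e-8)
  dup <- annotate_duplications(
    dplyr::select(tab2, locus_a, locus_b, ka, ks), genes_tab, cfg
  )
  expect_s3_class(autoplot(dup), "ggplot")
})
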