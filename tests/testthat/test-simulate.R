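test_that("generators are pure functions of their seed", {
  a <- simulate_family_panel(2, 1, c(85, 25), seed = 42)
  b <- simulate_family_panel(2, 1, c(85, 25), seed = 42)
  expect_identical(a, b)
  c <- simulate_family_panel(2, 1, c(85, 25), seed = 43)
  expect_false(identical(a$queries$sequence, c$queries$sequence))

  d1 <- simulate_duplication_set(2, 100, 5, 5, 1, seed = 7)
  d2 <- simulate_duplication_set(2, 100, 5, 5, 1, seed = 7)
  expect_identical(d1, d2)

  p1 <- simulate_promoters(
    tibble::tibble(gene_id = "g", element = "ABRE", n = 2),
    length = 300, seed = 11
  )
  p2 <- simulate_promoters(
    tibble::tibble(gene_id = "g", element = "ABRE", n = 2),
    length = 300, seed = 11
  )
  expect_identical(p1, p2)
})

test_that("family-panel queries carry exact planted ungapped identity", {
  sim <- simulate_family_panel(3, 2, c(85, 50, 25), protein_length = 200,
                               seed = 3)
  expect_equal(nrow(sim$queries), 3 * 2 * 3)
  expect_equal(sim$manifest$realized_identity, sim$manifest$planted_identity,
               tolerance = 0.5 / 200)
  # hamming identity of each query to its family ancestor equals the plan
  for (i in seq_len(nrow(sim$manifest))) {
    anc <- sim$panel$sequence[[sim$manifest$family[[i]]]]
    q <- sim$queries$sequence[[i]]
    same <- sum(strsplit(anc, "")[[1]] == strsplit(q, "")[[1]])
    expect_equal(100 * same / nchar(anc), sim$manifest$realized_identity[[i]])
  }
  expect_error(simulate_family_panel(1, 1, c(3), seed = 1), "identity levels")
})

test_that("duplication generator plants counted substitutions and layouts", {
  sim <- simulate_duplication_set(n_pairs = 3, n_codons = 120, syn_subs = 6,
                                  nonsyn_subs = 4, n_tandem = 1, seed = 8)
  expect_equal(sim$manifest$true_class, c("tandem", "segmental", "segmental"))
  for (p in 1:3) {
    a <- sim$cds$sequence[[2 * p - 1]]
    b <- sim$cds$sequence[[2 * p]]
    diffs <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_equal(diffs, 6 + 4)
    # ancestor and derived translate without internal stops
    for (s in c(a, b)) {
      prot <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
      expect_false(grepl("\\*", substr(prot, 1, nchar(prot) - 1)))
    }
  }
  expect_error(
    simulate_duplication_set(1, 50, syn_subs = 60, nonsyn_subs = 0, seed = 1),
    "budget"
  )
})

test_that("promoter generator manifest matches a rescan of its output", {
  plan <- tibble::tibble(gene_id = c("g1", "g1", "g2"),
                         element = c("ABRE", "MBS", "LTR"),
                         n = c(2, 1, 3),
                         strand = c("+", "-", "+"))
  sim <- simulate_promoters(plan, length = 400, seed = 19)
  expect_equal(nrow(sim$promoters), 2)
  expect_equal(nchar(sim$promoters$sequence), c(400, 400))
  man <- sim$manifest
  for (i in seq_len(nrow(man))) {
    prom <- sim$promoters$sequence[sim$promoters$gene_id == man$gene_id[[i]]][[1]]
    occ <- scan_elements(prom, gene_id = man$gene_id[[i]])
    hit <- occ[occ$element == man$element[[i]] & occ$start == man$position[[i]], ]
    expect_gte(nrow(hit), 1)
  }
  # zero-plant gene yields a motif-free promoter
  none <- simulate_promoters(
    tibble::tibble(gene_id = "g0", element = "ABRE", n = 0),
    length = 300, seed = 23
  )
  expect_equal(nrow(scan_elements(none$promoters$sequence[[1]])), 0)

  expect_error(
    simulate_promoters(
      tibble::tibble(gene_id = "g", element = "ABRE", n = 100),
      length = 120, seed = 1
    ),
    "capacity"
  )
})

test_that("expression generator plants group structure and fold changes", {
  sim <- simulate_expression(n_genes = 4,
                             group_means = c(control = 100, stress = 300),
                             n_per_group = 3, fold_changes = 2,
                             noise_sd = 0, seed = 31)
  expect_equal(dim(sim$matrix), c(4, 7))
  avg <- condition_average(sim$matrix, sim$grouping)
  expect_equal(
    avg$mean_expression[avg$group == "stress"] /
      avg$mean_expression[avg$group == "control"],
    3
  )
  res <- ddct_fold_change(sim$cq)
  expect_equal(res$fold_change, rep(2, 4))
})
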