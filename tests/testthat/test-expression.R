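test_that("percent-of-max scales rows, flags all-zero genes, ignores scale", {
  m <- tibble::tibble(gene = c("a", "b", "c"),
                      s1 = c(10, 5, 0), s2 = c(50, 5, 0), s3 = c(100, 5, 0))
  p <- percent_of_max(m)
  expect_equal(unlist(p[1, c("s1", "s2", "s3")], use.names = FALSE),
               c(10, 50, 100))
  expect_equal(unlist(p[2, c("s1", "s2", "s3")], use.names = FALSE),
               c(100, 100, 100))
  expect_true(p$not_assessable[3])
  expect_true(all(is.na(p[3, c("s1", "s2", "s3")])))

  scaled <- dplyr::mutate(m, dplyr::across(s1:s3, ~ .x * 7.5))
  expect_equal(percent_of_max(scaled)[, c("s1", "s2", "s3")],
               p[, c("s1", "s2", "s3")])

  expect_error(percent_of_max(dplyr::mutate(m, s1 = -s1)), ">= 0")
})

test_that("condition averages pool all cells in a group", {
  m <- tibble::tibble(gene = c("g1", "g2"), s1 = c(1, 3), s2 = c(2, 4))
  grouping <- tibble::tibble(sample = c("s1", "s2"), group = "seedling")
  avg <- condition_average(m, grouping)
  expect_equal(avg$mean_expression, 2.5)
  expect_equal(avg$n_cells, 4L)

  one <- condition_average(
    tibble::tibble(gene = "g", s1 = 42),
    tibble::tibble(sample = "s1", group = "solo")
  )
  expect_equal(one$mean_expression, 42)

  expect_error(
    condition_average(m, tibble::tibble(sample = "s1", group = "x")),
    "assigned"
  )

  # identical values give that value for every grouping
  flat <- tibble::tibble(gene = c("a", "b"), s1 = 5, s2 = 5)
  g2 <- tibble::tibble(sample = c("s1", "s2"), group = c("u", "v"))
  expect_equal(condition_average(flat, g2)$mean_expression, c(5, 5))
})

test_that("high-expression counting applies the strict 60% rule per tissue", {
  pct <- tibble::tibble(gene = c("g1", "g2", "g3"),
                        root = c(70, 61, 59), leaf = c(10, 100, 60))
  grouping <- tibble::tibble(sample = c("root", "leaf"),
                             group = c("root", "leaf"))
  counts <- high_expression_count(pct, grouping, threshold = 60)
  expect_equal(counts$n_high[counts$group == "root"], 2L)
  expect_equal(counts$n_high[counts$group == "leaf"], 1L)  # 60 is not > 60

  expect_equal(
    high_expression_count(pct, grouping, threshold = 100)$n_high,
    c(0L, 0L)
  )
})

test_that("manhattan/average clustering merges the closest rows first", {
  m <- tibble::tibble(gene = c("r1", "r2", "r3"),
                      s1 = c(0, 0, 10), s2 = c(0, 1, 10))
  hc <- hcluster_rows(m)
  # first merge joins rows 1 and 2 (distance 1 vs 19/20)
  expect_equal(sort(hc$hclust$merge[1, ]), c(-2, -1))
  expect_equal(hc$hclust$height[1], 1)

  dup <- tibble::tibble(gene = c("x", "y"), s1 = c(3, 3), s2 = c(4, 4))
  expect_equal(hcluster_rows(dup)$hclust$height, 0)

  # permuting rows leaves the topology intact (same merge heights)
  perm <- m[c(3, 1, 2), ]
  expect_equal(hcluster_rows(perm)$hclust$height, hc$hclust$height)

  expect_error(hcluster_rows(m[1, ]), "two rows")
})

test_that("ddCt fold changes follow 2^-ddCt with SE over replicates", {
  cq <- tibble::tibble(
    gene = "g", condition = c("control", "treated"), replicate = 1L,
    cq_target = c(25, 23), cq_reference = c(20, 20)
  )
  expect_equal(ddct_fold_change(cq)$fold_change, 4)

  flat <- tibble::tibble(
    gene = "g", condition = rep(c("control", "treated"), each = 3),
    replicate = rep(1:3, 2), cq_target = 24, cq_reference = 20
  )
  res <- ddct_fold_change(flat)
  expect_equal(res$fold_change, 1)
  expect_equal(res$se, 0)

  up <- tibble::tibble(
    gene = "g", condition = rep(c("control", "treated"), each = 3),
    replicate = rep(1:3, 2),
    cq_target = c(24, 24, 24, 23, 23, 23), cq_reference = 20
  )
  res <- ddct_fold_change(up)
  expect_equal(res$fold_change, 2)
  expect_equal(res$se, 0)
  expect_equal(res$n, 3L)

  expect_error(
    ddct_fold_change(dplyr::mutate(up, cq_reference = NA_real_)),
    "reference"
  )
})

test_that("ddCt is invariant to a constant shift of one condition's Cq values", {
  cq <- tibble::tibble(
    gene = "g", condition = rep(c("control", "treated"), each = 3),
    replicate = rep(1:3, 2),
    cq_target = c(25.1, 24.9, 25.0, 22.8, 23.1, 23.0),
    cq_reference = c(20.0, 20.1, 19.9, 20.2, 20.0, 19.9)
  )
  base <- ddct_fold_change(cq)$fold_change
  shifted <- dplyr::mutate(
    cq,
    cq_target = cq_target + ifelse(condition == "treated", 3.7, 0),
    cq_reference = cq_reference + ifelse(condition == "treated", 3.7, 0)
  )
  expect_equal(ddct_fold_change(shifted)$fold_change, base)
})

test_that("planted fold changes are recovered from simulated Cq tables", {
  noiseless <- simulate_expression(n_genes = 3, fold_changes = c(0.25, 1, 4),
                                   noise_sd = 0, seed = 5)
  res <- ddct_fold_change(noiseless$cq)
  man <- noiseless$manifest
  expect_equal(res$fold_change[match(man$gene, res$gene)], man$fold_change)

  # planted two-group structure separates at the top split when noiseless
  top <- simulate_expression(n_genes = 4,
                             group_means = c(low = 10, high = 1000),
                             noise_sd = 0, seed = 6)
  expect_s3_class(hcluster_rows(top$matrix), "expr_hclust")

  # determinism
  again <- simulate_expression(n_genes = 3, fold_changes = c(0.25, 1, 4),
                               noise_sd = 0, seed = 5)
  expect_identical(noiseless$matrix, again$matrix)
  expect_identical(noiseless$cq, again$cq)
})
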