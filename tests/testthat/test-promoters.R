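test_that("upstream extraction honours strand, window and truncation", {
  chrom <- paste(rep(c("A", "C", "G", "T"), 500), collapse = "")  # 2000 bp

  plus <- extract_upstream(chrom, start = 1001, end = 1500, strand = "+",
                           length = 1000)
  expect_equal(plus, substr(chrom, 1, 1000))

  minus <- extract_upstream(chrom, start = 401, end = 500, strand = "-",
                            length = 100)
  want <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(chrom, 501, 600))))
  expect_equal(minus, want)

  expect_warning(
    short <- extract_upstream(chrom, start = 300, end = 400, strand = "+",
                              length = 1000),
    "truncated"
  )
  expect_equal(nchar(short), 299)

  expect_error(extract_upstream(chrom, start = 0, end = 10), "outside")
  expect_error(extract_upstream(chrom, start = 10, end = 3000), "outside")
})

test_that("element scanning finds planted forward and reverse hits", {
  catalog <- read_motif_catalog()

  fwd <- scan_elements("TTACGTGTT", catalog)
  abre_fwd <- fwd[fwd$element == "ABRE" & fwd$strand == "+", ]
  expect_equal(abre_fwd$start, 3L)
  expect_equal(abre_fwd$end, 7L)

  rev <- scan_elements("TTCACGTTT", catalog)
  abre_rev <- rev[rev$element == "ABRE" & rev$strand == "-", ]
  expect_equal(abre_rev$start, 3L)
  expect_equal(abre_rev$end, 7L)

  # N matches nothing
  expect_equal(nrow(scan_elements("TTACGNGTT", catalog)[
    scan_elements("TTACGNGTT", catalog)$element == "ABRE", ]), 0)

  expect_equal(nrow(scan_elements("", catalog)), 0)
})

test_that("scanning the reverse complement swaps strands and mirrors positions", {
  withr::local_seed(8)
  catalog <- read_motif_catalog()
  sim <- simulate_promoters(
    tibble::tibble(gene_id = "g", element = c("ABRE", "MBS"), n = c(2, 1)),
    catalog = catalog, length = 300, seed = 15
  )
  prom <- sim$promoters$sequence[[1]]
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(prom)))
  a <- scan_elements(prom, catalog)
  b <- scan_elements(rc, catalog)
  expect_equal(nrow(a), nrow(b))
  L <- nchar(prom)
  mirrored <- tibble::tibble(
    element = b$element,
    strand = ifelse(b$strand == "+", "-", "+"),
    start = L - b$end + 1L,
    end = L - b$start + 1L
  )
  mirrored <- dplyr::arrange(mirrored, element, start, strand)
  expect_equal(dplyr::select(a, element, strand, start, end),
               mirrored)
})

test_that("planted motif counts are recovered exactly across replicates", {
  catalog <- read_motif_catalog()
  # G-box (CACGTG) nests the ABRE core (ACGTG), so an exact-count plant of
  # G-box is unrealizable by construction; sample from the other elements
  plantable <- setdiff(catalog$name, "G-box")
  withr::local_seed(202)
  for (rep in 1:50) {
    plan <- tibble::tibble(
      gene_id = "g",
      element = sample(plantable, sample(1:3, 1)),
      n = sample(1:3, length(element), replace = TRUE),
      strand = sample(c("+", "-"), length(element), replace = TRUE)
    )
    sim <- simulate_promoters(plan, catalog = catalog, length = 300,
                              seed = 1000 + rep)
    occ <- scan_elements(sim$promoters$sequence[[1]], catalog, gene_id = "g")
    sites <- dplyr::distinct(occ, element, start, end)
    got <- dplyr::arrange(dplyr::count(sites, element, name = "k"), element)
    want <- plan |>
      dplyr::group_by(element) |>
      dplyr::summarise(k = as.integer(sum(n))) |>
      dplyr::arrange(element)
    expect_equal(got, want, info = paste("replicate", rep))
  }
})

test_that("element summaries count genes per element and types per gene", {
  catalog <- read_motif_catalog()
  occ <- dplyr::bind_rows(
    tibble::tibble(gene_id = "g1", element = rep("ABRE", 4), strand = "+",
                   start = 1:4 * 10L, end = 1:4 * 10L + 4L),
    tibble::tibble(gene_id = "g1", element = "MBS", strand = "+",
                   start = 100L, end = 105L),
    tibble::tibble(gene_id = "g2", element = "ABRE", strand = "-",
                   start = 7L, end = 11L)
  )
  s <- summarize_elements(occ, gene_ids = c("g1", "g2", "g3"),
                          catalog = catalog)
  pe <- tidy(s)
  expect_equal(pe$n_genes[pe$element == "ABRE"], 2L)
  expect_equal(pe$n_genes[pe$element == "MBS"], 1L)
  expect_equal(pe$n_genes[pe$element == "G-box"], 0L)
  pg <- s$per_gene
  expect_equal(pg$total[pg$gene_id == "g1"], 5L)
  expect_equal(pg$types[pg$gene_id == "g1"], 2L)
  expect_equal(pg$total[pg$gene_id == "g3"], 0L)

  g <- glance(s)
  expect_equal(g$n_occurrences, 6L)
  expect_s3_class(autoplot(s), "ggplot")

  empty <- summarize_elements(occ[0, ], gene_ids = "g1", catalog = catalog)
  expect_true(all(tidy(empty)$n_genes == 0))
})
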