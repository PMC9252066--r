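#' Cluster two species' family members into orthogroups
#'
#' Reciprocal best hits across species seed the clusters; each remaining
#' gene joins the cluster of its best cross-species hit when the identity
#' reaches the threshold, and otherwise forms a singleton. Deterministic
#' under a fixed input order.
#'
#' @param genes_a,genes_b tibbles with `id` and `sequence` for species A
#'   and B.
#' @param identity_fn function of two sequences returning percent identity;
#'   defaults to gap-inclusive identity of [global_align()].
#' @param threshold minimum identity for joining a cluster (default 60).
#' @return a tibble with one row per gene: `id`, `species` (`"A"`/`"B"`),
#'   `cluster` (integer).
#' @export
build_orthogroups <- function(genes_a, genes_b,
                              identity_fn = function(x, y) {
                                percent_identity(global_align(x, y))
                              },
                              threshold = 60) {
  check_that(nrow(genes_a) + nrow(genes_b) > 0, "no genes supplied")
  na <- nrow(genes_a); nb <- nrow(genes_b)
  id_mat <- matrix(0, nrow = max(na, 1), ncol = max(nb, 1))
  if (na > 0 && nb > 0) {
    for (i in seq_len(na)) {
      for (j in seq_len(nb)) {
        id_mat[i, j] <- identity_fn(genes_a$sequence[[i]], genes_b$sequence[[j]])
      }
    }
  }
  cluster_a <- rep(NA_integer_, na)
  cluster_b <- rep(NA_integer_, nb)
  next_cluster <- 0L
  if (na > 0 && nb > 0) {
    best_b_for_a <- apply(id_mat, 1, which.max)
    best_a_for_b <- apply(id_mat, 2, which.max)
    for (i in seq_len(na)) {
      j <- best_b_for_a[[i]]
      if (best_a_for_b[[j]] == i && id_mat[i, j] >= threshold) {
        next_cluster <- next_cluster + 1L
        cluster_a[[i]] <- next_cluster
        cluster_b[[j]] <- next_cluster
      }
    }
    for (i in which(is.na(cluster_a))) {
      j <- best_b_for_a[[i]]
      if (!is.na(cluster_b[[j]]) && id_mat[i, j] >= threshold) {
        cluster_a[[i]] <- cluster_b[[j]]
      }
    }
    for (j in which(is.na(cluster_b))) {
      i <- best_a_for_b[[j]]
      if (!is.na(cluster_a[[i]]) && id_mat[i, j] >= threshold) {
        cluster_b[[j]] <- cluster_a[[i]]
      }
    }
  }
  for (i in which(is.na(cluster_a))) {
    next_cluster <- next_cluster + 1L
    cluster_a[[i]] <- next_cluster
  }
  for (j in which(is.na(cluster_b))) {
    next_cluster <- next_cluster + 1L
    cluster_b[[j]] <- next_cluster
  }
  dplyr::bind_rows(
    tibble(id = genes_a$id, species = "A", cluster = cluster_a),
    tibble(id = genes_b$id, species = "B", cluster = cluster_b)
  )
}

#' Ancestral (MRCA) copy number of an orthogroup set
#'
#' The most-recent-common-ancestor copy number is the number of
#' orthogroups: each cluster descends from one ancestral gene.
#'
#' @param ortho tibble from [build_orthogroups()], or any tibble with a
#'   `cluster` column.
#' @return integer ancestral count.
#' @export
mrca_count <- function(ortho) {
  dplyr::n_distinct(ortho$cluster)
}

#' Per-lineage gains and losses relative to the MRCA
#'
#' For each species, losses are the clusters containing none of its genes
#' and gains are its extant genes beyond one per occupied cluster, so the
#' accounting identity `extant = ancestral - losses + gains` always holds.
#'
#' @param ortho tibble with columns `species` (`"A"`/`"B"`) and `cluster`;
#'   one row per gene.
#' @param extant_a,extant_b optional extant counts; default to the numbers
#'   of genes in `ortho`, and an inconsistent explicit count is an error.
#' @return a one-row tibble: `ancestral`, `extant_a`, `extant_b`,
#'   `gains_a`, `losses_a`, `gains_b`, `losses_b`.
#' @export
#' @examples
#' scen <- read_fig4_scenarios()
#' gains_losses(expand_scenario(scen, "sorghum_maize_ALDH2"))
gains_losses <- function(ortho, extant_a = NULL, extant_b = NULL) {
  n_a <- sum(ortho$species == "A")
  n_b <- sum(ortho$species == "B")
  if (is.null(extant_a)) extant_a <- n_a
  if (is.null(extant_b)) extant_b <- n_b
  check_that(extant_a == n_a && extant_b == n_b,
             "extant counts must equal genes per species in the orthogroup set")
  ancestral <- mrca_count(ortho)
  occupied_a <- dplyr::n_distinct(ortho$cluster[ortho$species == "A"])
  occupied_b <- dplyr::n_distinct(ortho$cluster[ortho$species == "B"])
  tibble(
    ancestral = ancestral,
    extant_a = extant_a, extant_b = extant_b,
    gains_a = extant_a - occupied_a,
    losses_a = ancestral - occupied_a,
    gains_b = extant_b - occupied_b,
    losses_b = ancestral - occupied_b
  )
}

#' Read the bundled two-species expansion scenarios
#'
#' Encodes the published sorghum/maize and sorghum/rice family scenarios as
#' per-cluster membership counts.
#'
#' @param path TSV path (default: bundled fixture).
#' @return tibble with `scenario`, `family`, `species_a`, `species_b`,
#'   `cluster`, `n_a`, `n_b`.
#' @export
read_fig4_scenarios <- function(path = aldh_example("fig4_scenarios.tsv")) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Expand a cluster-count scenario into a per-gene orthogroup tibble
#'
#' @param scenarios tibble from [read_fig4_scenarios()].
#' @param which scenario name to expand.
#' @return per-gene tibble with `species` and `cluster`, suitable for
#'   [gains_losses()].
#' @export
expand_scenario <- function(scenarios, which) {
  sc <- dplyr::filter(scenarios, .data$scenario == which)
  check_that(nrow(sc) > 0, paste0("unknown scenario: ", which))
  rows <- purrr::pmap(list(sc$cluster, sc$n_a, sc$n_b), function(cl, a, b) {
    tibble(
      id = c(sprintf("A_c%d_g%d", cl, seq_len(a)),
             sprintf("B_c%d_g%d", cl, seq_len(b))),
      species = c(rep("A", a), rep("B", b)),
      cluster = cl
    )
  })
  dplyr::bind_rows(rows)
}

#' Expansion summary for every bundled scenario
#'
#' @param scenarios tibble from [read_fig4_scenarios()].
#' @return tibble with one row per scenario joining [gains_losses()]
#'   output to the scenario labels.
#' @export
#' @examples
#' summarize_expansion(read_fig4_scenarios())
summarize_expansion <- function(scenarios = read_fig4_scenarios()) {
  purrr::map_dfr(unique(scenarios$scenario), function(s) {
    sc <- dplyr::filter(scenarios, .data$scenario == s)
    dplyr::bind_cols(
      tibble(scenario = s, family = sc$family[[1]],
             species_a = sc$species_a[[1]], species_b = sc$species_b[[1]]),
      gains_losses(expand_scenario(scenarios, s))
    )
  })
}

#' Neighbor-joining tree from a distance matrix
#'
#' Validates the matrix (symmetric, non-negative, zero diagonal, at least
#' three taxa) and delegates the agglomeration to [ape::nj()].
#'
#' @param distance_matrix symmetric numeric matrix.
#' @param labels optional taxon labels (default: matrix dimnames or T1..Tn).
#' @return an [ape::ape-package] `"phylo"` tree; use [ape::write.tree()]
#'   for Newick output.
#' @export
#' @examples
#' d <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3)
#' nj_tree(d, c("a", "b", "c"))
nj_tree <- function(distance_matrix, labels = NULL) {
  m <- as.matrix(distance_matrix)
  check_that(nrow(m) == ncol(m) && isTRUE(all.equal(m, t(m), tolerance = 1e-8)),
             "distance matrix must be symmetric")
  check_that(all(diag(m) == 0), "distance matrix must have a zero diagonal")
  check_that(all(m >= 0), "distances must be non-negative")
  check_that(nrow(m) >= 3, "neighbor joining needs at least 3 taxa")
  if (is.null(labels)) {
    labels <- rownames(m) %||% paste0("T", seq_len(nrow(m)))
  }
  dimnames(m) <- list(labels, labels)
  ape::nj(stats::as.dist(m))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
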