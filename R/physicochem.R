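# Average residue masses (Da) and water mass used for protein MW.
RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.0153

# Bjellqvist pKa values (the set used by ProtParam): terminal and
# side-chain ionizable groups.
PKA_SETS <- list(
  bjellqvist = list(
    n_term = 7.5, c_term = 3.55,
    acidic = c(D = 4.05, E = 4.45, C = 9.0, Y = 10.0),
    basic = c(H = 5.98, K = 10.0, R = 12.0)
  )
)

#' Protein molecular weight
#'
#' Sum of average residue masses plus one water, reported in kDa. MW is
#' additive over concatenation up to one water mass.
#'
#' @param sequence non-empty string over the 20 standard amino acids.
#' @param mass_table named vector of residue masses in Da.
#' @return molecular weight in kDa.
#' @export
#' @examples
#' protein_mw("G") # 0.07507 kDa
protein_mw <- function(sequence, mass_table = RESIDUE_MASS) {
  check_that(is.character(sequence) && length(sequence) == 1 && nzchar(sequence),
             "sequence must be a non-empty string")
  chars <- strsplit(toupper(sequence), "")[[1]]
  unknown <- setdiff(chars, names(mass_table))
  check_that(length(unknown) == 0,
             paste0("unknown residue(s): ", paste(unknown, collapse = ", ")))
  (sum(mass_table[chars]) + WATER_MASS) / 1000
}

# Net charge of a protein at a given pH under a pKa set.
net_charge <- function(counts, pH, pka) {
  pos_pka <- c(pka$n_term, unname(pka$basic[names(pka$basic)]))
  pos_n <- c(1, unname(counts[names(pka$basic)]))
  neg_pka <- c(pka$c_term, unname(pka$acidic[names(pka$acidic)]))
  neg_n <- c(1, unname(counts[names(pka$acidic)]))
  sum(pos_n * 10^pos_pka / (10^pos_pka + 10^pH)) -
    sum(neg_n * 10^pH / (10^neg_pka + 10^pH))
}

#' Theoretical isoelectric point by bisection
#'
#' Finds the pH of zero net charge on \[0, 14\]. The charge function is
#' strictly decreasing in pH, so bisection converges to the unique root;
#' iteration stops when |charge| < 1e-4.
#'
#' @param sequence non-empty amino-acid string.
#' @param pka_set name of a bundled pKa set (currently `"bjellqvist"`, the
#'   values used by ProtParam) or a list with elements `n_term`, `c_term`,
#'   `acidic`, `basic`.
#' @return isoelectric point (pH units).
#' @export
#' @examples
#' protein_pi("KKKK") > protein_pi("DDDD")
protein_pi <- function(sequence, pka_set = "bjellqvist") {
  check_that(is.character(sequence) && length(sequence) == 1 && nzchar(sequence),
             "sequence must be a non-empty string")
  pka <- if (is.list(pka_set)) pka_set else PKA_SETS[[pka_set]]
  check_that(!is.null(pka), "unknown pKa set")
  chars <- strsplit(toupper(sequence), "")[[1]]
  counts <- table(factor(chars, levels = names(RESIDUE_MASS)))
  counts <- setNames(as.numeric(counts), names(RESIDUE_MASS))
  lo <- 0; hi <- 14
  for (i in 1:100) {
    mid <- (lo + hi) / 2
    q <- net_charge(counts, mid, pka)
    if (abs(q) < 1e-4) break
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Aggregate physicochemical statistics of a protein inventory
#'
#' Min, max and mean of protein length, molecular weight and isoelectric
#' point, with means rounded half-up at the reporting precision (0 decimals
#' for length, 2 otherwise).
#'
#' @param records tibble with numeric columns `protein_aa`, `mw_kda`, `pi`
#'   (e.g. a gene table).
#' @return tibble with columns `stat` (`"min"`, `"max"`, `"mean"`),
#'   `protein_aa`, `mw_kda`, `pi`.
#' @export
#' @examples
#' summarize_physico(read_gene_table(aldh_example("table1.tsv")))
summarize_physico <- function(records) {
  need <- c("protein_aa", "mw_kda", "pi")
  check_that(all(need %in% names(records)),
             paste0("records needs columns: ", paste(need, collapse = ", ")))
  check_that(nrow(records) > 0, "no records")
  agg <- function(x, digits) {
    c(min = min(x), max = max(x), mean = round_half_up(mean(x), digits))
  }
  len <- agg(records$protein_aa, 0)
  mw <- agg(records$mw_kda, 2)
  pi <- agg(records$pi, 2)
  tibble(
    stat = c("min", "max", "mean"),
    protein_aa = unname(len), mw_kda = unname(mw), pi = unname(pi)
  )
}
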