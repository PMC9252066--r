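# Independent oracles used by the property and acceptance tests. Each is a
# deliberately naive implementation kept separate from the package code
# paths it checks.

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# ---- PROSITE brute force -------------------------------------------------

# Does `s` match the element list exactly, consuming all of it?
oracle_prosite_full_match <- function(elements, s) {
  chars <- strsplit(s, "")[[1]]
  match_elem_char <- function(el, ch) {
    if (ch == "X") return(el$type == "wildcard")
    if (ch %in% c("B", "Z")) return(el$type == "set" && ch %in% el$residues)
    switch(el$type,
           wildcard = TRUE,
           fixed = ch == el$residues,
           set = ch %in% el$residues,
           forbidden = !(ch %in% el$residues))
  }
  rec <- function(ei, si) {
    if (ei > length(elements)) return(si == length(chars) + 1)
    el <- elements[[ei]]
    for (take in el$min:el$max) {
      if (si + take - 1 > length(chars)) break
      ok <- take == 0 ||
        all(vapply(chars[si:(si + take - 1)], function(ch) {
          match_elem_char(el, ch)
        }, logical(1)))
      if (ok && rec(ei + 1, si + take)) return(TRUE)
    }
    FALSE
  }
  rec(1, 1)
}

# All start positions where some substring starting there matches.
oracle_prosite_starts <- function(pattern, protein) {
  if (nchar(protein) == 0) return(integer(0))
  chars <- strsplit(protein, "")[[1]]
  starts <- if (pattern$n_anchor) 1L else seq_along(chars)
  found <- integer(0)
  for (s in starts) {
    ends <- if (pattern$c_anchor) length(chars) else s:length(chars)
    for (e in ends) {
      if (e < s) next
      if (oracle_prosite_full_match(pattern$elements,
                                    paste(chars[s:e], collapse = ""))) {
        found <- c(found, s)
        break
      }
    }
  }
  found
}

# random pattern of <= max_elements elements over a small alphabet
random_prosite_pattern <- function(max_elements = 6) {
  n <- sample(1:max_elements, 1)
  els <- vapply(seq_len(n), function(i) {
    kind <- sample(c("fixed", "set", "forbidden", "x"), 1,
                   prob = c(0.4, 0.25, 0.15, 0.2))
    base <- switch(kind,
                   fixed = sample(c("A", "C", "G", "L", "K"), 1),
                   set = paste0("[", paste(sample(c("A", "C", "G", "L", "K"),
                                                  sample(2:3, 1)),
                                           collapse = ""), "]"),
                   forbidden = paste0("{", sample(c("A", "C", "G"), 1), "}"),
                   x = "x")
    rep_suffix <- sample(c("", "(2)", "(1,3)"), 1, prob = c(0.7, 0.15, 0.15))
    paste0(base, rep_suffix)
  }, character(1))
  paste(els, collapse = "-")
}

random_protein_seq <- function(len, alphabet = c("A", "C", "G", "L", "K")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# ---- brute-force global alignment ---------------------------------------

# Maximum global alignment score over all alignments under linear gap
# penalty (per-gap-column cost) and a match/mismatch scoring function.
oracle_align_score <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i > length(ca) && j > length(cb)) return(0)
    best <- -Inf
    if (i <= length(ca) && j <= length(cb)) {
      s <- if (ca[[i]] == cb[[j]]) match else mismatch
      best <- max(best, s + rec(i + 1, j + 1))
    }
    if (i <= length(ca)) best <- max(best, gap + rec(i + 1, j))
    if (j <= length(cb)) best <- max(best, gap + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

simple_aa_matrix <- function(match = 1, mismatch = 0) {
  letters20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  m <- matrix(mismatch, 20, 20, dimnames = list(letters20, letters20))
  diag(m) <- match
  m
}

# ---- NG86 oracle ---------------------------------------------------------

# translation via seqinr, an independent codon-table source
oracle_translate <- function(codon) {
  seqinr::translate(strsplit(codon, "")[[1]])
}

oracle_ng86_sites <- function(codon) {
  nts <- c("A", "C", "G", "T")
  aa0 <- oracle_translate(codon)
  syn <- 0
  for (pos in 1:3) {
    muts <- character(0)
    for (nt in nts[nts != substr(codon, pos, pos)]) {
      m <- codon
      substr(m, pos, pos) <- nt
      muts <- c(muts, m)
    }
    aas <- vapply(muts, oracle_translate, character(1))
    keep <- aas != "*"
    if (sum(keep) > 0) syn <- syn + sum(aas[keep] == aa0) / sum(keep)
  }
  c(syn = syn, nonsyn = 3 - syn)
}

oracle_ng86_diffs <- function(a, b) {
  pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  if (length(pos) == 0) return(c(syn = 0, nonsyn = 0))
  ords <- combinat_perms(pos)
  tallies <- lapply(ords, function(ord) {
    cur <- a; sy <- 0; ns <- 0; stopflag <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      if (oracle_translate(nxt) == "*") stopflag <- TRUE
      if (oracle_translate(nxt) == oracle_translate(cur) &&
          oracle_translate(nxt) != "*") sy <- sy + 1 else ns <- ns + 1
      cur <- nxt
    }
    list(sy = sy, ns = ns, stopflag = stopflag)
  })
  ok <- Filter(function(t) !t$stopflag, tallies)
  use <- if (length(ok) > 0) ok else tallies
  c(syn = mean(vapply(use, `[[`, 0, "sy")),
    nonsyn = mean(vapply(use, `[[`, 0, "ns")))
}

combinat_perms <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (r in combinat_perms(x[-i])) out[[length(out) + 1]] <- c(x[[i]], r)
  }
  out
}

oracle_kaks <- function(cds_a, cds_b) {
  n <- nchar(cds_a) / 3
  cod_a <- substring(cds_a, 3 * seq_len(n) - 2, 3 * seq_len(n))
  cod_b <- substring(cds_b, 3 * seq_len(n) - 2, 3 * seq_len(n))
  Sa <- sum(vapply(cod_a, function(c) oracle_ng86_sites(c)[["syn"]], 0))
  Sb <- sum(vapply(cod_b, function(c) oracle_ng86_sites(c)[["syn"]], 0))
  S <- (Sa + Sb) / 2
  N <- 3 * n - S
  d <- mapply(function(x, y) oracle_ng86_diffs(x, y), cod_a, cod_b)
  ps <- sum(d["syn", ]) / S
  pn <- sum(d["nonsyn", ]) / N
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  c(ka = jc(pn), ks = jc(ps))
}

# ---- pI grid oracle ------------------------------------------------------

oracle_pi <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  nD <- sum(chars == "D"); nE <- sum(chars == "E"); nC <- sum(chars == "C")
  nY <- sum(chars == "Y"); nH <- sum(chars == "H"); nK <- sum(chars == "K")
  nR <- sum(chars == "R")
  charge <- function(pH) {
    pos <- function(pka, n) n * 10^pka / (10^pka + 10^pH)
    neg <- function(pka, n) n * 10^pH / (10^pka + 10^pH)
    pos(7.5, 1) + pos(5.98, nH) + pos(10.0, nK) + pos(12.0, nR) -
      neg(3.55, 1) - neg(4.05, nD) - neg(4.45, nE) - neg(9.0, nC) -
      neg(10.0, nY)
  }
  grid <- seq(0, 14, length.out = 1e6 + 1)
  q <- charge(grid)
  grid[which.min(abs(q))]
}
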