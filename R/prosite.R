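#' Parse a PROSITE-syntax pattern
#'
#' Supports the classical PROSITE grammar: elements separated by `-`;
#' `[ABC]` allowed sets; `{ABC}` forbidden sets; `x` wildcard; `(n)` or
#' `(n,m)` repetition suffixes; `<` / `>` terminal anchors. A trailing `.`
#' is tolerated.
#'
#' @param text pattern string, e.g. `"[FY]-x(2)-{P}"`.
#' @param accession optional accession stored with the pattern.
#' @return an object of class `"prosite_pattern"`: a list with `accession`,
#'   `n_anchor`, `c_anchor`, and `elements`, each element a list with
#'   `type` (`"fixed"`, `"set"`, `"forbidden"`, `"wildcard"`), `residues`,
#'   `min` and `max` repetition counts.
#' @export
#' @examples
#' parse_pattern("[FY]-x(2)-{P}")
parse_pattern <- function(text, accession = NA_character_) {
  check_that(is.character(text) && length(text) == 1 && nzchar(text),
             "pattern text must be a non-empty string")
  raw <- gsub("\\s", "", text)
  raw <- sub("\\.$", "", raw)
  n_anchor <- startsWith(raw, "<")
  if (n_anchor) raw <- substring(raw, 2)
  c_anchor <- endsWith(raw, ">")
  if (c_anchor) raw <- substring(raw, 1, nchar(raw) - 1)
  check_that(nzchar(raw), "pattern must contain at least one element")

  parse_err <- function(offset, why) {
    abort(sprintf("PROSITE parse error at offset %d: %s", offset, why))
  }
  tokens <- strsplit(raw, "-", fixed = TRUE)[[1]]
  if (any(!nzchar(tokens))) parse_err(regexpr("--|^-|-$", raw), "empty element")

  offset <- 1L
  elements <- vector("list", length(tokens))
  for (k in seq_along(tokens)) {
    tok <- tokens[[k]]
    rep_min <- 1L; rep_max <- 1L
    rep_at <- regexpr("\\(", tok)
    if (rep_at > 0) {
      if (!grepl("\\)$", tok)) parse_err(offset + rep_at - 1L, "unclosed repetition")
      inner <- sub("^.*\\(", "", sub("\\)$", "", tok))
      parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
      if (!(length(parts) %in% 1:2) || any(!grepl("^\\d+$", parts))) {
        parse_err(offset + rep_at - 1L, "malformed repetition count")
      }
      rep_min <- as.integer(parts[[1]])
      rep_max <- as.integer(parts[[length(parts)]])
      if (rep_min > rep_max) parse_err(offset + rep_at - 1L, "repetition min > max")
      tok <- substring(tok, 1, rep_at - 1L)
    }
    if (tok == "x" || tok == "X") {
      el <- list(type = "wildcard", residues = character(0))
    } else if (grepl("^\\[[A-Z]+\\]$", tok)) {
      el <- list(type = "set", residues = strsplit(gsub("\\[|\\]", "", tok), "")[[1]])
    } else if (grepl("^\\{[A-Z]+\\}$", tok)) {
      el <- list(type = "forbidden", residues = strsplit(gsub("[{}]", "", tok), "")[[1]])
    } else if (grepl("^[A-WYZ]$", tok)) {
      el <- list(type = "fixed", residues = tok)
    } else {
      parse_err(offset, paste0("unrecognized element '", tok, "'"))
    }
    if (el$type %in% c("set", "forbidden") && length(el$residues) == 0) {
      parse_err(offset, "empty residue set")
    }
    el$min <- rep_min
    el$max <- rep_max
    elements[[k]] <- el
    offset <- offset + nchar(tokens[[k]]) + 1L
  }
  structure(
    list(accession = accession, text = text, n_anchor = n_anchor,
         c_anchor = c_anchor, elements = elements),
    class = "prosite_pattern"
  )
}

#' @export
print.prosite_pattern <- function(x, ...) {
  cat(sprintf("<prosite_pattern %s> %s (%d elements)\n",
              ifelse(is.na(x$accession), "", x$accession),
              x$text, length(x$elements)))
  invisible(x)
}

# Does protein character `ch` satisfy one repetition of element `el`?
# Conservative ambiguity handling: X matches only wildcards; B/Z match only
# explicit set membership.
prosite_char_match <- function(el, ch) {
  if (ch == "X") return(el$type == "wildcard")
  if (ch %in% c("B", "Z")) {
    return(el$type == "set" && ch %in% el$residues)
  }
  switch(el$type,
         wildcard = TRUE,
         fixed = ch == el$residues,
         set = ch %in% el$residues,
         forbidden = !(ch %in% el$residues))
}

# Greedy-with-backtracking matcher: returns the match end (0-based length
# consumed) of the leftmost-greedy match starting at `pos`, or -1L.
prosite_match_from <- function(chars, pos, elements, idx, c_anchor) {
  if (idx > length(elements)) {
    if (c_anchor && pos != length(chars) + 1L) return(-1L)
    return(pos - 1L)
  }
  el <- elements[[idx]]
  avail <- length(chars) - pos + 1L
  hi <- min(el$max, avail)
  if (hi < el$min) return(-1L)
  # longest repetition count consistent with the element, tried first
  ok_upto <- 0L
  while (ok_upto < hi && prosite_char_match(el, chars[[pos + ok_upto]])) {
    ok_upto <- ok_upto + 1L
  }
  if (ok_upto < el$min) return(-1L)
  for (take in seq(ok_upto, el$min)) {
    res <- prosite_match_from(chars, pos + take, elements, idx + 1L, c_anchor)
    if (res >= 0L) return(res)
  }
  -1L
}

#' Scan a protein with a PROSITE pattern
#'
#' Reports the greedy (maximal-repetition, with backtracking) match at every
#' start position where the pattern matches; overlapping matches are kept
#' and results are ordered by start.
#'
#' @param pattern a `"prosite_pattern"` from [parse_pattern()], or a pattern
#'   string.
#' @param protein amino-acid string (20-letter alphabet; `X` matches
#'   wildcards only, `B`/`Z` only explicit set membership).
#' @return a tibble with columns `accession`, `start`, `end`,
#'   `matched_subsequence` (1-based inclusive positions). Empty protein
#'   gives zero rows.
#' @export
#' @examples
#' scan_prosite("G-x-G", "AGAGA")
scan_prosite <- function(pattern, protein) {
  if (is.character(pattern)) pattern <- parse_pattern(pattern)
  check_that(inherits(pattern, "prosite_pattern"), "pattern must be a prosite_pattern")
  empty <- tibble(accession = character(), start = integer(),
                  end = integer(), matched_subsequence = character())
  if (is.na(protein) || nchar(protein) == 0) return(empty)
  chars <- strsplit(toupper(protein), "")[[1]]
  starts <- if (pattern$n_anchor) 1L else seq_along(chars)
  hits <- list()
  for (s in starts) {
    e <- prosite_match_from(chars, s, pattern$elements, 1L, pattern$c_anchor)
    if (e >= 0L && e >= s) {
      hits[[length(hits) + 1L]] <- tibble(
        accession = pattern$accession,
        start = s, end = e,
        matched_subsequence = paste(chars[s:e], collapse = "")
      )
    }
  }
  if (length(hits) == 0) return(empty)
  dplyr::bind_rows(hits)
}

#' Read a PROSITE pattern catalog from a key=value config file
#'
#' @param path config file; lines of the form `ACCESSION=pattern`, `#`
#'   comments and blank lines ignored.
#' @return named list of `"prosite_pattern"` objects keyed by accession.
#' @export
#' @examples
#' cat <- read_pattern_catalog(aldh_example("prosite_patterns.cfg"))
#' names(cat)
read_pattern_catalog <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  check_that(all(grepl("=", lines, fixed = TRUE)),
             "catalog lines must be ACCESSION=pattern")
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  check_that(!anyDuplicated(keys), "duplicate accessions in pattern catalog")
  setNames(lapply(seq_along(keys), function(i) parse_pattern(vals[[i]], keys[[i]])),
           keys)
}

#' Flag the ALDH glutamic-acid and cysteine active sites
#'
#' Presence/absence semantics: a site is "present" when the corresponding
#' PROSITE pattern matches at least once anywhere in the protein.
#'
#' @param protein amino-acid string.
#' @param catalog named list of patterns containing keys `PS00687`
#'   (glutamic-acid active site) and `PS00070` (cysteine active site);
#'   default is the bundled catalog.
#' @return a one-row tibble with logical columns `glutamic_site` and
#'   `cysteine_site`.
#' @export
#' @examples
#' detect_active_sites("")
detect_active_sites <- function(protein,
                                catalog = read_pattern_catalog(
                                  aldh_example("prosite_patterns.cfg"))) {
  check_that(all(c("PS00687", "PS00070") %in% names(catalog)),
             "catalog must contain patterns keyed PS00687 and PS00070")
  tibble(
    glutamic_site = nrow(scan_prosite(catalog[["PS00687"]], protein)) > 0,
    cysteine_site = nrow(scan_prosite(catalog[["PS00070"]], protein)) > 0
  )
}
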