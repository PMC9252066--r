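#' Pipeline configuration
#'
#' Collects the thresholds and constants that drive every analysis stage.
#' Defaults follow the published workflow: AGNC family/subfamily identity
#' thresholds of 40%/60% (strict `>` comparisons, so equality falls to the
#' lower tier), a 100-kb window for tandem duplication, a 90% identity
#' threshold used only by the optional strict segmental rule, a neutral
#' substitution rate of 6.1e-9 substitutions/site/year for dating, 1-kb
#' promoters, and a 60% high-expression cutoff.
#'
#' @param family_identity_threshold percent identity above which a query
#'   joins an existing family (default 40).
#' @param subfamily_identity_threshold percent identity above which a query
#'   inherits the subfamily of its best reference (default 60).
#' @param tandem_window maximum inter-gene gap in bp for a tandem call
#'   (default 1e5).
#' @param segmental_identity_threshold percent identity for the optional
#'   strict segmental rule (default 90).
#' @param substitution_rate neutral substitution rate lambda in
#'   substitutions/site/year used in T = Ks / (2 * lambda) (default 6.1e-9).
#' @param promoter_length upstream window in bp (default 1000).
#' @param high_expression_threshold percent-of-max cutoff defining "highly
#'   expressed" (default 60).
#' @param random_seed integer seed recorded for provenance.
#' @return a list with class `"aldh_config"`.
#' @export
#' @examples
#' cfg <- pipeline_config()
#' cfg$tandem_window
pipeline_config <- function(family_identity_threshold = 40,
                            subfamily_identity_threshold = 60,
                            tandem_window = 1e5,
                            segmental_identity_threshold = 90,
                            substitution_rate = 6.1e-9,
                            promoter_length = 1000,
                            high_expression_threshold = 60,
                            random_seed = 1L) {
  thr <- c(family_identity_threshold, subfamily_identity_threshold,
           segmental_identity_threshold, high_expression_threshold)
  check_that(all(thr > 0 & thr <= 100), "thresholds must lie in (0, 100]")
  check_that(substitution_rate > 0, "substitution_rate must be > 0")
  check_that(promoter_length > 0, "promoter_length must be > 0")
  check_that(tandem_window > 0, "tandem_window must be > 0")
  structure(
    list(
      family_identity_threshold = family_identity_threshold,
      subfamily_identity_threshold = subfamily_identity_threshold,
      tandem_window = tandem_window,
      segmental_identity_threshold = segmental_identity_threshold,
      substitution_rate = substitution_rate,
      promoter_length = promoter_length,
      high_expression_threshold = high_expression_threshold,
      random_seed = as.integer(random_seed)
    ),
    class = "aldh_config"
  )
}

#' @export
print.aldh_config <- function(x, ...) {
  cat("<aldh_config>\n")
  for (nm in names(x)) cat(sprintf("  %-30s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
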