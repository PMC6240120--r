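# Access to the bundled reference selection summaries.

#' Published selection summaries used for cross-checks
#'
#' Selection probabilities (P) and 2 log_e Bayes factors (BF) as printed in
#' the summary tables of a community-wide European plant-frugivore
#' colour-cue analysis: the colour-reward model (four nutrient responses on
#' x, y, z, a across 44 plant species) and the fruit-choice structural
#' equation model (eight responses across 165 observations of 43 bird
#' species). `BF_bound` marks entries printed as a resolution bound
#' ("> 15"). Used to reconcile the package's Bayes-factor arithmetic with
#' independently produced numbers.
#'
#' @return Data frame with columns `model`, `response`, `term`, `P`, `BF`,
#'   `BF_bound`.
#' @export
published_selection_summaries <- function() {
  path <- system.file("extdata", "published_selection_summaries.csv",
                      package = "frugicue", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
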