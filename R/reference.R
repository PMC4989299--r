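#' Reference group means of Achilles tendon QUS measurements
#'
#' Published group means of the 11 QUS measurements for symptomatic and
#' asymptomatic Achilles tendons, shipped with the package as plain CSV.
#' They serve two purposes: plausible default parameters for the synthetic
#' phantom generator, and inputs to the percent-difference computation
#' between groups (see [percent_difference()]).  No reliability value is
#' derived from them.
#'
#' @return data.frame with columns `view`, `feature`, `all_mean`,
#'   `symptomatic_mean`, `asymptomatic_mean`.
#' @export
reference_group_means <- function() {
  path <- system.file("extdata", "achilles_reference_means.csv",
                      package = "tendonqus")
  if (path == "") stop("reference data not found; package not installed?")
  read.csv(path, stringsAsFactors = FALSE)
}
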