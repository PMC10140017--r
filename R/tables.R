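#' Reference values of the three in vitro aneurysm cases
#'
#' Published geometric, flow-condition and image-quality values for the
#' three silicone aneurysm models (two carotid-ophthalmic, IA1/IA2, and
#' one middle-cerebral, IA3) that define the study conditions emulated by
#' the synthetic module: sac morphometrics, time-averaged flow rates,
#' fluid properties and per-model SNR/VNR.
#'
#' @return list of data frames `morphometrics`, `quality`, `flow`, each
#'   with a `quantity` column and one column per case (IA1-IA3).
#' @examples
#' ref <- study_reference_values()
#' ref$flow
#' @export
study_reference_values <- function() {
  rd <- function(f) {
    utils::read.csv(system.file("extdata", f, package = "anewall"),
                    check.names = FALSE)
  }
  list(morphometrics = rd("table1_morphometrics.csv"),
       quality = rd("table3_quality.csv"),
       flow = rd("flow_conditions.csv"))
}

# convenience: one named value from a reference table
ref_value <- function(tab, quantity, case) {
  tab[tab$quantity == quantity, case]
}
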