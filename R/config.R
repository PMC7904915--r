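#' Read enzyme specs from a YAML/JSON config
#'
#' Loads named enzyme definitions (fields `mode`, `cleaves`,
#' `blocks_on_3S`, `min_substrate_dp`) and merges them over the shipped
#' defaults, so a config may override a single field of a known enzyme or
#' define a new one.  The shipped defaults live at
#' `system.file("extdata", "enzymes.yaml", package = "hepseq")`.
#'
#' @param path YAML (or JSON) file path.
#' @return named list of [enzyme_spec()]s.
#' @export
read_enzyme_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  specs <- heparinases()
  for (nm in names(raw)) {
    d <- raw[[nm]]
    allowed <- c("mode", "cleaves", "blocks_on_3S", "min_substrate_dp")
    unknown <- setdiff(names(d), allowed)
    if (length(unknown))
      hepseq_error(paste0("enzyme '", nm, "': unknown field(s) ",
                          paste(unknown, collapse = ", ")),
                   "hepseq_bad_config")
    base <- if (nm %in% names(specs)) specs[[nm]] else
      list(mode = "endo", cleaves = c("2S-uronate", "unsulfated-uronate"),
           blocks_on_3S = TRUE, min_substrate_dp = NULL)
    mode <- if (is.null(d$mode)) base$mode else d$mode
    specs[[nm]] <- enzyme_spec(
      nm, mode = mode,
      cleaves = if (is.null(d$cleaves)) base$cleaves else unlist(d$cleaves),
      blocks_on_3S = if (is.null(d$blocks_on_3S)) base$blocks_on_3S
                     else d$blocks_on_3S,
      min_substrate_dp = if (is.null(d$min_substrate_dp)) {
        if (is.null(base$min_substrate_dp))
          (if (mode == "exo") 4L else 3L) else base$min_substrate_dp
      } else d$min_substrate_dp)
  }
  specs
}

#' Static reference metadata
#'
#' Ships, as plain data with no computation attached, the measured
#' biochemical reference values for the PL15_2 family enzymes (optima,
#' masses, isoelectric points, specific activities) and for the five
#' reference tetrasaccharide substrates (specific activities and
#' single-timepoint conversion efficiencies).  The conversion efficiencies
#' are not reproducible by any single-rate first-order model scaled by the
#' activities, so they are provided for reference only and never fitted.
#'
#' @param name `"pl15_2_properties"` or `"tetrasaccharide_activities"`.
#' @return data.frame.
#' @export
reference_metadata <- function(name = c("pl15_2_properties",
                                        "tetrasaccharide_activities")) {
  name <- match.arg(name)
  read.csv(system.file("extdata", paste0(name, ".csv"), package = "hepseq"),
           stringsAsFactors = FALSE, check.names = FALSE)
}
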