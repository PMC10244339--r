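#' Load a coastal-to-ocean dissolved-iron compilation
#'
#' Reads (or validates) a table of surface dissolved-iron observations
#' against distance offshore and classifies each record as coastal or
#' oceanic by a distance cutoff. Coastal waters, fed by rivers, sediments
#' and atmospheric deposition, carry dFe up to hundreds of nM; open-ocean
#' surface waters sit uniformly below ~1 nM.
#'
#' @param x CSV path or data.frame with columns `distance_km`, `dfe_nM`,
#'   `source_label`.
#' @param coastal_cutoff_km records at or beyond this distance are
#'   classified `oceanic` (default 50 km, the distance band where
#'   offshore transect data take over from coastal site surveys).
#' @return data.frame of class `gradient_table`: `distance_km`, `dfe`
#'   (mol L-1), `dfe_nM`, `source_label`, `environment`
#'   (`coastal`/`oceanic`).
#' @examples
#' load_gradient(kelpfe_example_gradient())
#' @export
load_gradient <- function(x, coastal_cutoff_km = 50) {
  df <- if (is.character(x)) {
    utils::read.csv(x, stringsAsFactors = FALSE)
  } else {
    as.data.frame(x)
  }
  required <- c("distance_km", "dfe_nM", "source_label")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("gradient table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0) {
    warning("gradient table is empty", call. = FALSE)
  }
  problems <- character(0)
  bad <- which(!is.na(df$distance_km) & df$distance_km < 0)
  if (length(bad) > 0) {
    problems <- c(problems, paste0("negative distance_km (rows ",
                                   paste(bad, collapse = ", "), ")"))
  }
  bad <- which(!is.na(df$dfe_nM) & df$dfe_nM < 0)
  if (length(bad) > 0) {
    problems <- c(problems, paste0("negative dfe_nM (rows ",
                                   paste(bad, collapse = ", "), ")"))
  }
  if (length(problems) > 0) {
    stop("invalid gradient table:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  out <- data.frame(
    distance_km = df$distance_km,
    dfe = df$dfe_nM * 1e-9,
    dfe_nM = df$dfe_nM,
    source_label = df$source_label,
    environment = ifelse(df$distance_km < coastal_cutoff_km,
                         "coastal", "oceanic")
  )
  class(out) <- c("gradient_table", "data.frame")
  out
}

#' Path to the bundled illustrative gradient compilation
#'
#' A small synthetic stand-in for a literature compilation of surface
#' dFe against distance offshore: values span the published extremes
#' (hundreds of nM in river-fed bays near shore, down to < 0.33 nM in
#' Southern Ocean surface waters) but the individual rows are
#' illustrative, not digitised observations. Replace with your own
#' compilation for real analyses.
#'
#' @return file path.
#' @export
kelpfe_example_gradient <- function() {
  system.file("extdata", "dfe_gradient_synthetic.csv",
              package = "kelpfe", mustWork = TRUE)
}

#' Fold difference between required and available inorganic iron
#'
#' How many times higher the Fe' requirement of a kelp is than the Fe'
#' available in the water: `required / available`. Homogeneous of degree
#' zero (units cancel), so both arguments just need the same units.
#'
#' @param required_fe_prime Fe' required to sustain healthy growth,
#'   mol L-1 (or suffixed string).
#' @param available_fe_prime Fe' available in the environment, mol L-1.
#' @return dimensionless fold (vectorised).
#' @examples
#' fold_limitation("45.2nM", "1.49pM")  # ~3e4
#' @export
fold_limitation <- function(required_fe_prime, available_fe_prime) {
  required_fe_prime <- parse_conc(required_fe_prime)
  available_fe_prime <- parse_conc(available_fe_prime)
  if (any(available_fe_prime <= 0)) {
    stop("available_fe_prime must be > 0", call. = FALSE)
  }
  if (any(required_fe_prime < 0)) {
    stop("required_fe_prime must be >= 0", call. = FALSE)
  }
  required_fe_prime / available_fe_prime
}
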