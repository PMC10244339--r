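#' Growth rate from surface areas
#'
#' Growth of a kelp disc over the incubation, `(SA_F - SA_I) / d` in
#' cm2 d-1. Negative values are meaningful (tissue loss and
#' fragmentation under iron limitation).
#'
#' @param sa_initial,sa_final surface area at the start and end of the
#'   experiment, cm2.
#' @param days experiment duration, days (default the 14-day run).
#' @return growth rate, cm2 d-1.
#' @examples
#' growth_rate(19.6, 25.2)
#' @export
growth_rate <- function(sa_initial, sa_final, days = 14) {
  if (any(days <= 0)) stop("days must be > 0", call. = FALSE)
  (sa_final - sa_initial) / days
}

#' Net DOC flux normalised to biomass
#'
#' Rate of change in dissolved organic carbon between the initial and
#' final incubation samples, scaled to flask volume, incubation period
#' and dry biomass. Positive rates are net DOC release by the alga;
#' negative rates are net uptake in the system (e.g. bacterial
#' consumption outpacing release).
#'
#' @param doc_initial,doc_final DOC at the start and end, umol C L-1.
#' @param volume flask volume, L.
#' @param hours incubation period, h.
#' @param dry_mass seaweed dry mass, g.
#' @return net DOC flux, umol C gDW-1 h-1.
#' @examples
#' doc_flux(100, 110, volume = 0.25, hours = 24, dry_mass = 0.5)
#' @export
doc_flux <- function(doc_initial, doc_final, volume, hours, dry_mass) {
  if (any(volume <= 0) || any(hours <= 0) || any(dry_mass <= 0)) {
    stop("volume, hours and dry_mass must be > 0", call. = FALSE)
  }
  (doc_final - doc_initial) * volume / (dry_mass * hours)
}

#' Oxygen flux (net photosynthesis or respiration)
#'
#' Oxygen change in the flask scaled to volume, time and wet biomass,
#' with the sign convention of the assays: in the light phase the result
#' is net photosynthesis (O2 produced, positive when O2 rises); in the
#' dark phase it is respiration (O2 consumed, positive when O2 falls).
#'
#' @param o2_initial,o2_final dissolved O2 at the start and end,
#'   umol O2 L-1.
#' @param volume flask volume, L.
#' @param hours incubation period, h.
#' @param wet_mass seaweed wet mass, g.
#' @param phase `"light"` or `"dark"`.
#' @return O2 flux, umol O2 gWW-1 h-1.
#' @examples
#' o2_flux(200, 260, 0.25, 3, 1.0, phase = "light")
#' o2_flux(260, 200, 0.25, 12, 1.0, phase = "dark")
#' @export
o2_flux <- function(o2_initial, o2_final, volume, hours, wet_mass,
                    phase = c("light", "dark")) {
  if (length(phase) != 1 && !identical(phase, c("light", "dark"))) {
    phase <- phase[1]
  }
  phase <- match.arg(phase)
  if (any(volume <= 0) || any(hours <= 0) || any(wet_mass <= 0)) {
    stop("volume, hours and wet_mass must be > 0", call. = FALSE)
  }
  delta <- if (phase == "light") o2_final - o2_initial else o2_initial - o2_final
  delta * volume / (wet_mass * hours)
}

#' Soluble tissue nitrate content
#'
#' Tissue nitrate (+ nitrite) recovered by two sequential boiling-water
#' extractions of a fresh tissue piece, standardised to wet weight:
#' `(N1 + N2) * V / WW`.
#'
#' @param n1,n2 N(NO3- + NO2-) concentration in the supernatant after the
#'   first and second extraction, uM.
#' @param wet_mass wet weight of the extracted tissue piece, g.
#' @param extract_volume liquid volume in each boiling tube, L
#'   (default 0.02 L).
#' @return soluble nitrate content, umol gWW-1.
#' @examples
#' soluble_nitrate(10, 2, wet_mass = 0.2)
#' @export
soluble_nitrate <- function(n1, n2, wet_mass, extract_volume = 0.02) {
  if (any(wet_mass <= 0)) stop("wet_mass must be > 0", call. = FALSE)
  if (any(n1 < 0) || any(n2 < 0)) {
    stop("extract concentrations must be >= 0", call. = FALSE)
  }
  (n1 + n2) * extract_volume / wet_mass
}

#' Maximum photochemical efficiency of PSII
#'
#' Fv/Fm = (Fm - Fo)/Fm from dark-acclimated fluorescence, where Fo and
#' Fm are the minimum and maximum fluorescence.
#'
#' @param f_o,f_m minimum and maximum fluorescence (relative units).
#' @return Fv/Fm, dimensionless in [0, 1].
#' @examples
#' fv_fm(0.2, 0.8)
#' @export
fv_fm <- function(f_o, f_m) {
  if (any(f_m <= 0)) stop("f_m must be > 0", call. = FALSE)
  if (any(f_o < 0) || any(f_o > f_m)) {
    stop("need f_m >= f_o >= 0", call. = FALSE)
  }
  (f_m - f_o) / f_m
}

#' Atomic carbon-to-nitrogen ratio of tissue
#'
#' C:N on atomic weights (C = 12.011, N = 14.007) from percent dry-weight
#' contents; invariant to common rescaling of the two percentages.
#'
#' @param pct_c,pct_n tissue carbon and nitrogen, percent of dry weight.
#' @return atomic C:N ratio.
#' @examples
#' cn_atomic_ratio(30, 3)
#' @export
cn_atomic_ratio <- function(pct_c, pct_n) {
  if (any(pct_n <= 0)) stop("pct_n must be > 0", call. = FALSE)
  if (any(pct_c < 0)) stop("pct_c must be >= 0", call. = FALSE)
  (pct_c / 12.011) / (pct_n / 14.007)
}

#' Spectrophotometric pigment coefficients for brown algae
#'
#' Coefficient sets for chlorophyll a and chlorophyll c from extract
#' absorbances, following the standard spectrophotometric method for
#' brown algae (DMSO extraction followed by 90% acetone). Each entry maps
#' wavelength (nm, as names) to the linear coefficient applied to that
#' absorbance; the combination yields pigment concentration in g L-1 of
#' extract for a 1-cm light path. The defaults are configuration data:
#' override them to use a different calibration.
#'
#' @return nested list: `$dmso` and `$acetone`, each with `$chl_a` and
#'   `$chl_c` named numeric vectors.
#' @examples
#' seely_coefficients()$dmso$chl_a
#' @export
seely_coefficients <- function() {
  list(
    dmso = list(
      chl_a = c("665" = 1 / 72.8),
      chl_c = c("631" = 1 / 61.8, "582" = 1 / 61.8,
                "665" = -0.297 / 61.8)
    ),
    acetone = list(
      chl_a = c("664" = 1 / 73.6),
      chl_c = c("631" = 1 / 62.2, "581" = 1 / 62.2,
                "664" = -0.3 / 62.2)
    )
  )
}

#' Total chlorophyll (a + c) content from extract absorbances
#'
#' Applies the configured linear combinations to the measured extract
#' absorbances per solvent, sums chlorophyll a and c over solvents, and
#' normalises to the wet mass of the extracted tissue piece. All
#' combinations pass through the origin, so the estimate is linear in the
#' absorbances.
#'
#' @param absorbances nested list mirroring the coefficient structure:
#'   one entry per solvent, each a named numeric vector of
#'   wavelength -> absorbance. Every wavelength referenced by the
#'   coefficients of that solvent must be present.
#' @param extract_volumes named numeric, litres of extract per solvent
#'   (default 4 mL DMSO, 4 mL acetone).
#' @param tissue_mass wet mass of the extracted tissue piece, g.
#' @param coefficients coefficient sets as from [seely_coefficients()].
#' @return total chlorophyll, mg gWW-1.
#' @examples
#' abs <- list(dmso = c("665" = 0.5, "631" = 0.2, "582" = 0.05),
#'             acetone = c("664" = 0, "631" = 0, "581" = 0))
#' total_chlorophyll(abs, tissue_mass = 0.1)
#' @export
total_chlorophyll <- function(absorbances,
                              extract_volumes = c(dmso = 0.004,
                                                  acetone = 0.004),
                              tissue_mass = 0.1,
                              coefficients = seely_coefficients()) {
  if (any(tissue_mass <= 0)) stop("tissue_mass must be > 0", call. = FALSE)
  total_g <- 0
  for (solvent in names(absorbances)) {
    if (!solvent %in% names(coefficients)) next
    abs_s <- absorbances[[solvent]]
    conc_gl <- 0
    for (pig in names(coefficients[[solvent]])) {
      cf <- coefficients[[solvent]][[pig]]
      missing_wl <- setdiff(names(cf), names(abs_s))
      if (length(missing_wl) > 0) {
        stop("missing ", solvent, " absorbance at ",
             paste(missing_wl, collapse = ", "), " nm", call. = FALSE)
      }
      conc_gl <- conc_gl + sum(cf * abs_s[names(cf)])
    }
    vol <- extract_volumes[[solvent]]
    if (is.null(vol) || vol <= 0) {
      stop("extract volume for ", solvent, " must be > 0", call. = FALSE)
    }
    total_g <- total_g + conc_gl * vol
  }
  # g of pigment -> mg, per g wet tissue
  total_g * 1000 / tissue_mass
}

# Column order of the replicate table (one row per kelp disc).
replicate_columns <- c(
  "treatment_fe_prime", "replicate_id", "is_control",
  "sa_initial_cm2", "sa_final_cm2", "days",
  "wet_mass_g", "dry_mass_g",
  "doc_initial_umol_l", "doc_final_umol_l", "doc_hours",
  "flask_volume_l",
  "o2_light_initial_umol_l", "o2_light_final_umol_l", "o2_light_hours",
  "o2_dark_initial_umol_l", "o2_dark_final_umol_l", "o2_dark_hours",
  "f_o", "f_m", "pct_c", "pct_n",
  "n1_um", "n2_um", "extract_volume_l", "no3_tissue_mass_g",
  "pigment_tissue_mass_g", "dmso_volume_l", "acetone_volume_l",
  "abs_dmso_665", "abs_dmso_631", "abs_dmso_582", "abs_dmso_480",
  "abs_acetone_664", "abs_acetone_631", "abs_acetone_581",
  "abs_acetone_470"
)

#' Read a replicate table from CSV
#'
#' One row per kelp disc; see [generate_replicates()] for the full column
#' schema. Empty cells are read as `NA` and propagate as absent derived
#' metrics, never as silent zeros. Validation problems are reported with
#' row numbers, aggregated into a single error.
#'
#' @param path CSV file path.
#' @return validated replicate data.frame.
#' @export
read_replicates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_replicates(df)
}

#' Validate a replicate table
#'
#' @param df replicate data.frame.
#' @return the data.frame, invisibly validated (errors aggregate row
#'   numbers).
#' @export
validate_replicates <- function(df) {
  required <- c("treatment_fe_prime", "replicate_id", "is_control")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("replicate table lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.logical(df$is_control)) {
    df$is_control <- as.logical(df$is_control)
  }
  problems <- character(0)
  check_pos <- function(col) {
    if (!col %in% names(df)) return(invisible(NULL))
    bad <- which(!is.na(df[[col]]) & df[[col]] <= 0 & !df$is_control)
    if (length(bad) > 0) {
      problems <<- c(problems, paste0(
        col, " must be > 0 (rows ", paste(bad, collapse = ", "), ")"))
    }
  }
  for (col in c("sa_initial_cm2", "wet_mass_g", "dry_mass_g",
                "flask_volume_l", "days", "doc_hours",
                "o2_light_hours", "o2_dark_hours")) {
    check_pos(col)
  }
  if (all(c("f_o", "f_m") %in% names(df))) {
    bad <- which(!is.na(df$f_o) & !is.na(df$f_m) & df$f_o > df$f_m)
    if (length(bad) > 0) {
      problems <- c(problems, paste0(
        "f_o exceeds f_m (rows ", paste(bad, collapse = ", "), ")"))
    }
  }
  bad <- which(!is.na(df$treatment_fe_prime) & df$treatment_fe_prime < 0)
  if (length(bad) > 0) {
    problems <- c(problems, paste0(
      "treatment_fe_prime must be >= 0 (rows ",
      paste(bad, collapse = ", "), ")"))
  }
  if (length(problems) > 0) {
    stop("invalid replicate table:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  df
}

#' Derive physiological rates for every replicate
#'
#' Maps each raw replicate row to the derived physiological metrics:
#' growth, net DOC flux, net photosynthesis, respiration, Fv/Fm, atomic
#' C:N, soluble tissue nitrate and total chlorophyll. No-seaweed control
#' rows yield `NA` for tissue-based metrics. Missing raw fields propagate
#' as `NA` in the affected metric only.
#'
#' @param replicates replicate data.frame (see [read_replicates()]).
#' @param coefficients pigment coefficients, see [seely_coefficients()].
#' @return data.frame with one row per replicate: `treatment_fe_prime`,
#'   `replicate_id`, `is_control`, `growth`, `doc_flux`,
#'   `net_photosynthesis`, `respiration`, `fv_fm`, `cn_ratio`,
#'   `soluble_no3`, `total_chl`.
#' @examples
#' reps <- generate_replicates(synthetic_config(seed = 1))
#' head(replicate_rates(reps))
#' @export
replicate_rates <- function(replicates,
                            coefficients = seely_coefficients()) {
  df <- validate_replicates(replicates)
  n <- nrow(df)
  get <- function(col) if (col %in% names(df)) df[[col]] else rep(NA_real_, n)
  safe <- function(expr) {
    tryCatch(expr, error = function(e) NA_real_)
  }
  out <- data.frame(
    treatment_fe_prime = df$treatment_fe_prime,
    replicate_id = df$replicate_id,
    is_control = df$is_control,
    growth = NA_real_, doc_flux = NA_real_,
    net_photosynthesis = NA_real_, respiration = NA_real_,
    fv_fm = NA_real_, cn_ratio = NA_real_,
    soluble_no3 = NA_real_, total_chl = NA_real_
  )
  for (i in seq_len(n)) {
    live <- !isTRUE(df$is_control[i])
    if (live) {
      out$growth[i] <- safe(growth_rate(
        get("sa_initial_cm2")[i], get("sa_final_cm2")[i], get("days")[i]))
      out$doc_flux[i] <- safe(doc_flux(
        get("doc_initial_umol_l")[i], get("doc_final_umol_l")[i],
        get("flask_volume_l")[i], get("doc_hours")[i],
        get("dry_mass_g")[i]))
      out$net_photosynthesis[i] <- safe(o2_flux(
        get("o2_light_initial_umol_l")[i], get("o2_light_final_umol_l")[i],
        get("flask_volume_l")[i], get("o2_light_hours")[i],
        get("wet_mass_g")[i], phase = "light"))
      out$respiration[i] <- safe(o2_flux(
        get("o2_dark_initial_umol_l")[i], get("o2_dark_final_umol_l")[i],
        get("flask_volume_l")[i], get("o2_dark_hours")[i],
        get("wet_mass_g")[i], phase = "dark"))
      out$fv_fm[i] <- safe(fv_fm(get("f_o")[i], get("f_m")[i]))
      out$cn_ratio[i] <- safe(cn_atomic_ratio(
        get("pct_c")[i], get("pct_n")[i]))
      out$soluble_no3[i] <- safe(soluble_nitrate(
        get("n1_um")[i], get("n2_um")[i], get("no3_tissue_mass_g")[i],
        get("extract_volume_l")[i]))
      out$total_chl[i] <- safe(total_chlorophyll(
        list(
          dmso = c("665" = get("abs_dmso_665")[i],
                   "631" = get("abs_dmso_631")[i],
                   "582" = get("abs_dmso_582")[i],
                   "480" = get("abs_dmso_480")[i]),
          acetone = c("664" = get("abs_acetone_664")[i],
                      "631" = get("abs_acetone_631")[i],
                      "581" = get("abs_acetone_581")[i],
                      "470" = get("abs_acetone_470")[i])
        ),
        extract_volumes = c(dmso = get("dmso_volume_l")[i],
                            acetone = get("acetone_volume_l")[i]),
        tissue_mass = get("pigment_tissue_mass_g")[i],
        coefficients = coefficients))
    }
  }
  out
}
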