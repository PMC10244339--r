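#' Configuration for a full analysis run
#'
#' Bundles the chemistry constants, medium description, significance
#' level and seed that a full pipeline run needs, so every report can
#' carry the fully resolved configuration for provenance.
#'
#' @param constants an [fe_edta_constants()].
#' @param medium a [buffer_medium()].
#' @param alpha significance level for the treatment statistics.
#' @param seed integer seed for any randomness downstream.
#' @param responses derived metrics to test across treatments.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(constants = fe_edta_constants(),
                            medium = buffer_medium(),
                            alpha = 0.05,
                            seed = 1L,
                            responses = c("doc_flux",
                                          "net_photosynthesis",
                                          "respiration", "fv_fm",
                                          "cn_ratio", "soluble_no3",
                                          "total_chl")) {
  stopifnot(inherits(constants, "fe_edta_constants"),
            inherits(medium, "buffer_medium"))
  if (alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(constants = constants, medium = medium, alpha = alpha,
         seed = as.integer(seed), responses = responses,
         schema_version = "1"),
    class = "pipeline_config"
  )
}

#' Run the full analysis over a replicate table
#'
#' One deterministic pass over the experiment: speciation table for the
#' seven standard iron additions, per-replicate physiological rates,
#' Michaelis-Menten fit of growth against Fe', treatment statistics
#' (transform selection, one-way ANOVA, Tukey HSD, compact letters) for
#' each configured response, and - when a gradient table is supplied -
#' the fold difference between the saturating Fe' requirement and
#' offshore availability.
#'
#' @param replicates replicate table (see [read_replicates()] /
#'   [generate_replicates()]); malformed tables abort with an aggregated
#'   row-level report.
#' @param config a [pipeline_config()].
#' @param gradient optional gradient table or CSV path for
#'   [load_gradient()].
#' @param required_fe_prime Fe' requirement used in the gradient
#'   comparison, mol L-1 (default 45.2 nM, the lowest level at which
#'   replicates stay healthy).
#' @return list of class `kelpfe_report`: `config`, `speciation`,
#'   `rates`, `mm_fit`, `anova` (one [fe_anova()] per response),
#'   `gradient` (folds per oceanic record, or `NULL`).
#' @examples
#' reps <- generate_replicates(synthetic_config(seed = 2))
#' rep <- run_pipeline(reps)
#' names(rep)
#' @export
run_pipeline <- function(replicates, config = pipeline_config(),
                         gradient = NULL,
                         required_fe_prime = 45.2e-9) {
  stopifnot(inherits(config, "pipeline_config"))
  replicates <- validate_replicates(replicates)
  set.seed(config$seed)

  speciation <- treatment_speciation(medium = config$medium,
                                     constants = config$constants)
  rates <- replicate_rates(replicates)
  live <- rates[!rates$is_control, ]

  mm <- suppressWarnings(
    fit_michaelis_menten(live$treatment_fe_prime, live$growth))

  anovas <- list()
  for (resp in config$responses) {
    if (!resp %in% names(live)) next
    ok <- is.finite(live[[resp]])
    if (sum(ok) < 4) next
    anovas[[resp]] <- tryCatch(
      fe_anova(live[[resp]][ok],
               format_conc(live$treatment_fe_prime[ok]),
               alpha = config$alpha),
      error = function(e) NULL)
  }

  grad <- NULL
  if (!is.null(gradient)) {
    gt <- load_gradient(gradient)
    oceanic <- gt[gt$environment == "oceanic" & gt$dfe > 0, ]
    fe_avail <- ocean_dfe_to_fe_prime(pmin(oceanic$dfe, 1e-9))
    grad <- data.frame(
      distance_km = oceanic$distance_km,
      dfe_nM = oceanic$dfe_nM,
      fe_prime_pM = as.numeric(fe_avail) * 1e12,
      fold_limitation = fold_limitation(required_fe_prime,
                                        as.numeric(fe_avail))
    )
  }

  out <- list(config = config, speciation = speciation, rates = rates,
              mm_fit = mm, anova = anovas, gradient = grad)
  class(out) <- "kelpfe_report"
  out
}

#' @export
print.kelpfe_report <- function(x, ...) {
  cat("kelpfe analysis report\n")
  cat("  replicates:", nrow(x$rates), "rows (",
      sum(x$rates$is_control), "controls )\n")
  cat("  treatments:",
      paste(format_conc(x$speciation$fe_prime), collapse = ", "), "\n")
  if (isTRUE(x$mm_fit$converged)) {
    cat(sprintf("  growth fit: Vmax = %.3g, Km = %s, adj R2 = %.3f\n",
                x$mm_fit$vmax, format_conc(x$mm_fit$km),
                x$mm_fit$adj_r2))
  }
  for (resp in names(x$anova)) {
    a <- x$anova[[resp]]
    cat(sprintf("  %s: F(%d, %d) = %.3f, p = %.4g [%s]\n", resp,
                a$df_between, a$df_within, a$f_value, a$p_value,
                a$transform_used))
  }
  if (!is.null(x$gradient)) {
    cat(sprintf("  offshore limitation: %.0f- to %.0f-fold\n",
                min(x$gradient$fold_limitation),
                max(x$gradient$fold_limitation)))
  }
  invisible(x)
}
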