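#' Parse a suffixed concentration string to mol per litre
#'
#' Experimental descriptions mix micromolar iron additions with nanomolar
#' and picomolar results; every kelpfe function works in mol per litre and
#' this helper converts on input. Plain numbers (numeric or digit-only
#' strings) are taken to be mol per litre already.
#'
#' @param x character vector such as `"100uM"`, `"45.2nM"`, `"0.11pM"`,
#'   `"1e-7M"`; whitespace between number and unit is allowed. Recognised
#'   suffixes: `M`, `mM`, `uM` (also `µM`/`μM`), `nM`, `pM`, `fM`.
#' @return numeric vector, mol per litre.
#' @examples
#' parse_conc(c("100uM", "45.2nM", "700pM"))
#' @export
parse_conc <- function(x) {
  if (is.numeric(x)) {
    return(as.numeric(x))
  }
  scales <- c(
    M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12, fM = 1e-15
  )
  out <- vapply(as.character(x), function(s) {
    s <- gsub("[µμ]", "u", trimws(s))
    m <- regmatches(s, regexec("^([-+0-9.eE]+)\\s*([a-zA-Z]*)$", s))[[1]]
    if (length(m) == 0) {
      stop("cannot parse concentration: '", s, "'", call. = FALSE)
    }
    val <- suppressWarnings(as.numeric(m[2]))
    if (is.na(val)) {
      stop("cannot parse concentration: '", s, "'", call. = FALSE)
    }
    unit <- m[3]
    if (unit == "") {
      return(val)
    }
    if (!unit %in% names(scales)) {
      stop("unknown concentration unit: '", unit, "'", call. = FALSE)
    }
    val * scales[[unit]]
  }, numeric(1), USE.NAMES = FALSE)
  out
}

#' Format mol-per-litre values with a sensible SI suffix
#'
#' @param x numeric, mol per litre.
#' @param digits significant digits.
#' @return character vector.
#' @export
format_conc <- function(x, digits = 3) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    av <- abs(v)
    if (av == 0) return("0 M")
    if (av >= 1e-3) return(paste0(signif(v * 1e3, digits), " mM"))
    if (av >= 1e-6) return(paste0(signif(v * 1e6, digits), " uM"))
    if (av >= 1e-9) return(paste0(signif(v * 1e9, digits), " nM"))
    paste0(signif(v * 1e12, digits), " pM")
  }, character(1))
}
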