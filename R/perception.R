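# Oral psychophysics helpers: capsaicin dilution-series design, threshold
# categories, and PROP taster classification on the 0-100 labelled
# magnitude scale (LMS).

#' Build a serial-dilution series
#'
#' Consecutive 1:`factor` dilutions of a stock: swab `n_steps` holds the
#' stock, swab 1 the most dilute solution, so
#' `concentration[k] = stock / factor^(n_steps - k)`. The default design
#' is ten 1:2 dilutions of a 2.243 ug/mL capsaicin stock, giving the
#' 0.004-2.243 ug/mL range.
#'
#' @param stock Stock concentration (ug/mL), positive.
#' @param factor Dilution ratio per step (> 1).
#' @param n_steps Number of swabs (>= 2).
#' @return List of class `dilution_series`: `stock`, `factor`, `n_steps`,
#'   `concentrations` (ordered, index 1 = most dilute).
#' @export
build_series <- function(stock = 2.243, factor = 2, n_steps = 10) {
  if (stock <= 0) stop("stock must be positive")
  if (factor <= 1) stop("dilution factor must exceed 1")
  if (n_steps < 2) stop("need at least 2 steps")
  k <- seq_len(n_steps)
  structure(list(stock = stock, factor = factor, n_steps = n_steps,
                 concentrations = stock / factor^(n_steps - k)),
            class = "dilution_series")
}

#' Concentration at one swab of a dilution series
#'
#' @param series A [build_series()] result.
#' @param swab Swab index (1 = most dilute).
#' @param digits Optional rounding for display; default reports full
#'   precision.
#' @return Concentration in the stock's units.
#' @export
swab_concentration <- function(series, swab, digits = NULL) {
  stopifnot(inherits(series, "dilution_series"))
  if (any(swab < 1 | swab > series$n_steps))
    stop("swab index out of range 1..", series$n_steps)
  x <- series$concentrations[swab]
  if (!is.null(digits)) round(x, digits) else x
}

#' @export
print.dilution_series <- function(x, ...) {
  cat(sprintf("<dilution_series> %d swabs, 1:%g dilutions of %g stock\n",
              x$n_steps, x$factor, x$stock))
  print(data.frame(swab = seq_len(x$n_steps),
                   concentration = signif(x$concentrations, 4)))
  invisible(x)
}

#' Classify a PROP intensity score as taster / non-taster
#'
#' Taster iff LMS score >= 50 (closed lower bound).
#'
#' @param lms_score Score(s) on the 0-100 labelled magnitude scale.
#' @return Character vector: `"taster"` or `"non_taster"`.
#' @export
classify_prop <- function(lms_score) {
  if (any(!is.na(lms_score) & (lms_score < 0 | lms_score > 100)))
    stop("LMS score must lie in [0, 100]")
  ifelse(is.na(lms_score), NA_character_,
         ifelse(lms_score >= 50, "taster", "non_taster"))
}

#' Convert molar to mass concentration
#'
#' `mg/mL = mM * (g/mol) / 1000`; e.g. a 50 mM solution of a 170.23 g/mol
#' compound is 8.51 mg/mL.
#'
#' @param molarity_mM Molar concentration (mM), positive.
#' @param molar_mass Molar mass (g/mol), positive.
#' @return Mass concentration in mg/mL.
#' @export
molar_to_mass_conc <- function(molarity_mM, molar_mass) {
  if (any(molarity_mM <= 0) || any(molar_mass <= 0))
    stop("inputs must be positive")
  molarity_mM * molar_mass / 1000
}
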