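# Binding-affinity unit conversions: Gibbs free energy of binding (kcal/mol),
# inhibition constant Ki (molar) and half-maximal inhibitory concentration
# IC50 (molar).

#' Physical constants used by the affinity conversions
#'
#' Gas constant `R` in cal/(mol K) and absolute temperature `T` in kelvin.
#' The conversion itself uses the composite factor 1.3633 kcal/mol per log10
#' unit of Ki (see [ki_to_delta_g()]); `R` and `T` are retained for
#' documentation. Note that `R * T * ln(10) / 1000` evaluates to about
#' 1.3641, slightly different from the composite factor in common use; the
#' composite factor is the one that reproduces the conventional potency
#' cut-offs of -9.54 kcal/mol (Ki = 0.1 uM) and -8.18 kcal/mol (Ki = 1 uM)
#' at two-decimal precision, so it is used throughout.
#'
#' @format A named list with elements `R_cal` (1.987 cal/(mol K)), `T_kelvin`
#'   (298.15 K) and `kcal_per_log10_ki` (1.3633 kcal/mol).
#' @export
affinity_constants <- list(
  R_cal = 1.987,
  T_kelvin = 298.15,
  kcal_per_log10_ki = 1.3633
)

#' Convert an inhibition constant to binding free energy
#'
#' Applies the standard thermodynamic relation Delta G = -RT ln(Ki),
#' expressed through the composite factor
#' `Delta G ~= 1.3633 * log10(Ki)` kcal/mol with Ki in molar units. More
#' negative values mean tighter binding: Ki = 0.1 uM maps to -9.54 kcal/mol
#' (the usual activity cut-off) and Ki = 1 uM to -8.18 kcal/mol (the hERG
#' safety threshold), both at two decimals.
#'
#' @param ki inhibition constant(s) in molar. Must be positive and finite.
#' @return binding free energy in kcal/mol, same length as `ki`.
#' @seealso [delta_g_to_ki()], [ic50_to_ki()]
#' @examples
#' ki_to_delta_g(1e-7)  # -9.54 kcal/mol at 2 d.p.
#' ki_to_delta_g(1e-6)  # -8.18 kcal/mol at 2 d.p.
#' @export
ki_to_delta_g <- function(ki) {
  if (!is.numeric(ki) || length(ki) == 0L || !all(is.finite(ki)) || any(ki <= 0)) {
    stop_domain("ki must be positive finite molar concentration(s)")
  }
  affinity_constants$kcal_per_log10_ki * log10(ki)
}

#' Convert binding free energy back to an inhibition constant
#'
#' Inverse of [ki_to_delta_g()]: `Ki = 10^(Delta G / 1.3633)` molar.
#'
#' @param delta_g binding free energy in kcal/mol; finite.
#' @return inhibition constant in molar, same length as `delta_g`.
#' @examples
#' delta_g_to_ki(0)       # 1 M
#' delta_g_to_ki(-9.5431) # ~1e-7 M
#' @export
delta_g_to_ki <- function(delta_g) {
  if (!is.numeric(delta_g) || length(delta_g) == 0L || !all(is.finite(delta_g))) {
    stop_domain("delta_g must be finite kcal/mol value(s)")
  }
  10^(delta_g / affinity_constants$kcal_per_log10_ki)
}

#' Approximate an inhibition constant from an IC50
#'
#' Uses the flat competitive/uncompetitive-inhibition approximation
#' `Ki = IC50 / 2`, with both quantities in molar. No inhibition-mode switch
#' or substrate-concentration correction is applied.
#'
#' @param ic50 half-maximal inhibitory concentration(s) in molar; positive.
#' @return inhibition constant in molar.
#' @examples
#' ic50_to_ki(2e-7)  # 1e-7 M
#' @export
ic50_to_ki <- function(ic50) {
  if (!is.numeric(ic50) || length(ic50) == 0L || !all(is.finite(ic50)) || any(ic50 <= 0)) {
    stop_domain("ic50 must be positive finite molar concentration(s)")
  }
  ic50 / 2
}

# Multipliers to molar for the unit strings accepted in dataset files.
.molar_units <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9)

#' Normalize a concentration to molar units
#'
#' @param value numeric concentration(s).
#' @param unit unit string(s): one of `"M"`, `"mM"`, `"uM"`, `"nM"`
#'   (recycled if length 1).
#' @return concentration(s) in molar.
#' @export
to_molar <- function(value, unit = "M") {
  if (!is.numeric(value)) stop_domain("value must be numeric")
  unit <- rep_len(as.character(unit), length(value))
  bad <- !(unit %in% names(.molar_units))
  if (any(bad)) {
    stop_data("unknown concentration unit(s): ",
              paste(unique(unit[bad]), collapse = ", "))
  }
  value * unname(.molar_units[unit])
}
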