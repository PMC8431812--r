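# Entropy-enthalpy compensation arithmetic: the hydrogen-bond-swap
# enthalpy, the hydration-shell entropy released by hydrophobic collapse,
# and the Gibbs predicate that combines them.

# 1 kcal = 4184 J, exact by definition of the thermochemical calorie.
JOULES_PER_KCAL <- 4184

#' Thermodynamic parameter table
#'
#' Bond-energy magnitudes (kcal/mol) and molar entropies (J/mol/K) used
#' by the compensation bookkeeping.  The three peptide hydrogen-bond
#' energies are literature magnitudes; \code{e_water_water} is a
#' calibrated default chosen so that the default swap enthalpy is exactly
#' 2.70 kcal/mol -- it is exposed and documented as calibrated, not
#' sourced.
#'
#' @param e_nh_oc Backbone N-H...O=C hydrogen bond, magnitude (default
#'   3.47).
#' @param e_nh_water N-H...water hydrogen bond (default 7.65).
#' @param e_co_water C=O...water hydrogen bond (default 4.7).
#' @param e_water_water Water-water hydrogen bond formed between the two
#'   released waters (default 6.18, calibrated).
#' @param s_liquid_water Standard molar entropy of bulk liquid water,
#'   J/mol/K (default 70).
#' @param s_ordered_water Molar entropy of hydration-shell (solid-like)
#'   water (default 45).
#' @param temperature Kelvin (default 298).
#' @return List of class \code{thermo_params}.
#' @export
thermo_params <- function(e_nh_oc = 3.47, e_nh_water = 7.65,
                          e_co_water = 4.7, e_water_water = 6.18,
                          s_liquid_water = 70, s_ordered_water = 45,
                          temperature = 298) {
  p <- list(e_nh_oc = e_nh_oc, e_nh_water = e_nh_water,
            e_co_water = e_co_water, e_water_water = e_water_water,
            s_liquid_water = s_liquid_water,
            s_ordered_water = s_ordered_water,
            temperature = temperature)
  if (any(!vapply(p, is.numeric, logical(1))) ||
      any(!is.finite(unlist(p)))) {
    stop("all thermodynamic parameters must be finite numbers",
         call. = FALSE)
  }
  if (any(unlist(p[1:6]) < 0)) {
    stop("energies and entropies are magnitudes and must be >= 0",
         call. = FALSE)
  }
  if (s_liquid_water <= s_ordered_water) {
    stop("s_liquid_water must exceed s_ordered_water", call. = FALSE)
  }
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  structure(p, class = "thermo_params")
}

#' @export
print.thermo_params <- function(x, ...) {
  cat("<thermo_params>\n")
  cat(sprintf("  H-bond magnitudes (kcal/mol): N-H...O=C %.2f, N-H...w %.2f, C=O...w %.2f, w...w %.2f (calibrated)\n",
              x$e_nh_oc, x$e_nh_water, x$e_co_water, x$e_water_water))
  cat(sprintf("  molar entropy (J/mol/K): liquid %.0f, hydration shell %.0f;  T = %.0f K\n",
              x$s_liquid_water, x$s_ordered_water, x$temperature))
  invisible(x)
}

#' Enthalpy of swapping peptide-water for peptide-peptide hydrogen bonds
#'
#' To form one backbone N-H...O=C bond in water, the chain breaks one
#' N-H...water and one C=O...water bond, and the two released waters form
#' one water-water bond:
#' \deqn{\Delta H = E_{NH,w} + E_{CO,w} - E_{NH,OC} - E_{w,w}}
#' Positive at the defaults (2.70 kcal/mol): the swap is enthalpically
#' uphill and needs an entropic compensation to proceed.
#'
#' @param p \code{\link{thermo_params}}.
#' @return Enthalpy change, kcal/mol.
#' @examples
#' hbond_swap_enthalpy()  # 2.70
#' @export
hbond_swap_enthalpy <- function(p = thermo_params()) {
  stopifnot(inherits(p, "thermo_params"))
  p$e_nh_water + p$e_co_water - p$e_nh_oc - p$e_water_water
}

#' Entropy released by expelling ordered hydration-shell water
#'
#' Each water molecule expelled from the solid-like hydration shell into
#' bulk liquid gains the difference of the two molar entropies.
#'
#' @param n_waters Number of expelled waters (default 12, the
#'   hand-estimate for a lateral leucine-leucine collapse).
#' @param p \code{\link{thermo_params}}.
#' @return Entropy change, J/mol/K.
#' @examples
#' collapse_entropy_gain(12)  # 300
#' @export
collapse_entropy_gain <- function(n_waters = 12, p = thermo_params()) {
  stopifnot(inherits(p, "thermo_params"))
  if (!is.numeric(n_waters) || length(n_waters) != 1L || n_waters < 0) {
    stop("n_waters must be a single nonnegative number", call. = FALSE)
  }
  n_waters * (p$s_liquid_water - p$s_ordered_water)
}

#' Gibbs compensation predicate
#'
#' Combines an enthalpy change (kcal/mol) and an entropy change (J/mol/K)
#' into \eqn{\Delta G = \Delta H - T \Delta S} at the parameter table's
#' temperature, converting the entropy with 4184 J/kcal.
#'
#' @param delta_h Enthalpy change, kcal/mol.
#' @param delta_s_joules Entropy change, J/mol/K.
#' @param p \code{\link{thermo_params}}.
#' @return List of class \code{compensation_result}: \code{delta_h}
#'   (kcal/mol), \code{delta_s} (kcal/mol/K), \code{delta_g} (kcal/mol),
#'   \code{spontaneous} (\code{delta_g < 0}).
#' @examples
#' compensation(hbond_swap_enthalpy(), collapse_entropy_gain(12))
#' @export
compensation <- function(delta_h, delta_s_joules, p = thermo_params()) {
  stopifnot(inherits(p, "thermo_params"))
  if (!is.finite(delta_h) || !is.finite(delta_s_joules)) {
    stop("delta_h and delta_s_joules must be finite", call. = FALSE)
  }
  ds <- delta_s_joules / JOULES_PER_KCAL
  dg <- delta_h - p$temperature * ds
  structure(list(delta_h = delta_h, delta_s = ds, delta_g = dg,
                 spontaneous = dg < 0, temperature = p$temperature),
            class = "compensation_result")
}

#' @export
print.compensation_result <- function(x, ...) {
  cat("<compensation>\n")
  cat(sprintf("  dH = %+.3f kcal/mol\n", x$delta_h))
  cat(sprintf("  dS = %+.5f kcal/mol/K  (-T dS = %+.3f kcal/mol at %g K)\n",
              x$delta_s, -x$temperature * x$delta_s, x$temperature))
  cat(sprintf("  dG = %+.3f kcal/mol  -> %s\n", x$delta_g,
              if (x$spontaneous) "spontaneous" else "not spontaneous"))
  invisible(x)
}
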