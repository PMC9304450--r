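# Embedded reference values for the Fbln4-SMKO mouse ATAA study design:
# the ten-mouse cohort table, the RCR outlet parameters, the published
# biomarker ranges, and the summary HGO parameters used as generator truth.

#' Reference cohort of ten Fbln4-SMKO mice
#'
#' Per-mouse ascending-aorta elastic modulus (MPa), unloaded wall thickness
#' (mm), lifespan (months, right-censored at 25 for mice euthanized at that
#' age) and aortic tortuosity index at six months. Two mice lacked
#' mechanical/geometry data; their modulus and thickness are \code{NA} here
#' and are imputed with the mean of the other eight
#' (\code{\link{impute_elastic_modulus}}).
#'
#' @return data.frame with columns \code{subject_id}, \code{sex},
#'   \code{elastic_modulus_mpa}, \code{wall_thickness_mm},
#'   \code{lifespan_months}, \code{censored}, \code{ati}.
#' @export
mouse_cohort <- function() {
  data.frame(
    subject_id = c("15469_3", "15398_3", "15392_1", "15392_2", "15466_1",
                   "15398_1", "15466_3", "15474_2", "15474_3", "15389_1"),
    sex = c("F", "M", "M", "M", "F", "M", "F", "F", "F", "M"),
    elastic_modulus_mpa = c(NA, 0.47, 2.23, 1.16, 0.88, 1.22, 1.59, 0.93,
                            0.64, NA),
    wall_thickness_mm = c(NA, 0.142, 0.129, 0.122, 0.125, 0.140, 0.122,
                          0.180, 0.162, NA),
    lifespan_months = c(12.4, 13.3, 17.8, 18.2, 21.9, 22.4, 25, 25, 25, 25),
    censored = c(0, 0, 0, 0, 0, 0, 1, 1, 1, 1),
    ati = c(35.4, 52.0, 45.3, 59.5, 53.6, 37.9, 39.9, 38.8, 22.8, 28.7),
    stringsAsFactors = FALSE)
}

#' Mean-of-available imputation for the elastic modulus
#'
#' Mice without mechanical data receive the mean elastic modulus of the
#' mice that have one (1.14 MPa for the reference cohort).
#'
#' @param cohort a cohort data.frame with \code{elastic_modulus_mpa}.
#' @return the cohort with \code{NA} moduli replaced; the imputation value
#'   is attached as attribute \code{"imputed_value"}.
#' @export
impute_elastic_modulus <- function(cohort = mouse_cohort()) {
  v <- cohort$elastic_modulus_mpa
  m <- mean(v, na.rm = TRUE)
  cohort$elastic_modulus_mpa[is.na(v)] <- m
  attr(cohort, "imputed_value") <- m
  cohort
}

#' Three-element Windkessel parameters for the four aortic outlets
#'
#' Proximal resistance (Pa.s/mm^3), compliance (mm^3/Pa) and distal
#' resistance (Pa.s/mm^3) for the left subclavian artery, left common
#' carotid, brachiocephalic trunk, and the distal outlet.
#'
#' @return named list of \code{\link{windkessel_params}}.
#' @export
windkessel_outlets <- function() {
  list(
    left_subclavian = windkessel_params(19.58, 5.5e-4, 286.2,
                                        "left subclavian artery"),
    left_common_carotid = windkessel_params(44.70, 3.23e-4, 488.0,
                                            "left common carotid"),
    brachiocephalic = windkessel_params(21.55, 3.54e-4, 443.2,
                                        "brachiocephalic trunk"),
    outlet = windkessel_params(10.30, 5.41e-4, 443.2, "outlet"))
}

#' Published biomarker ranges for the reference cohort
#'
#' Observed min/max of each biomarker across the ten mice at six months
#' (and of the two-to-six-month absolute changes), used to calibrate the
#' cohort generator. Units: mmHg (P_max), kPa (vMs_max), Pa (TAWSS), mm
#' (D_max), months (LS); OSI, Re, Wo, ATI dimensionless.
#'
#' @return data.frame with columns \code{abbrev}, \code{lo}, \code{hi}.
#' @export
biomarker_ranges <- function() {
  data.frame(
    abbrev = c("P_max", "vMs_max", "Re_max", "OSI_min", "OSI_mean",
               "TAWSS_mean", "TAWSS_max", "TAWSS_min", "Wo", "ATI", "D_max",
               "delta_P_max", "delta_vMs_max", "delta_Re_max",
               "delta_OSI_min", "delta_OSI_mean", "delta_TAWSS_mean",
               "delta_TAWSS_max", "delta_Wo", "delta_D_max", "LS"),
    lo = c(110, 320, 143, 3.3e-8, 0.17, 0.9, 6.1, 0.005, 1.1, 22.8, 1.20,
           0, 10, 18, 1e-9, 0.012, 0.09, 0.064, 0.07, 0.01, 12.37),
    hi = c(172, 770, 227, 1.2e-5, 0.38, 3.42, 11, 0.33, 2.3, 59.5, 3.30,
           67.5, 210, 75, 2e-6, 0.063, 4.3, 2.3, 1.2, 0.73, 25),
    stringsAsFactors = FALSE)
}

#' Summary HGO parameters for the reference cohort
#'
#' Cohort-mean fitted HGO parameters of the ascending aorta (n = 8),
#' used as the default ground truth of the biaxial generator.
#'
#' @return an \code{\link{hgo_params}} object (c = 1.77 MPa, k1 = 0.43 MPa,
#'   k2 = 2.01, kappa = 0.17, gamma = 44.95 degrees).
#' @export
hgo_reference_params <- function() {
  hgo_params(1.77, 0.43, 2.01, 0.17, 44.95, degrees = TRUE)
}
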