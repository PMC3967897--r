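#' Derive leaf functional traits from laboratory quantities
#'
#' From fresh mass, dry mass, leaf area and mass-based nutrient contents the
#' derived traits are:
#' \describe{
#'   \item{sla}{specific leaf area, `leaf_area_mm2 / dry_mass_mg` (mm^2/mg)}
#'   \item{ldmc}{leaf dry matter content, `1000 * dry_mass_mg / fresh_mass_mg`
#'     (mg/g)}
#'   \item{lnc_area, lpc_area}{N and P content per unit leaf area,
#'     `lnc_mg_g / sla` and `lpc_mg_g / sla`; with these units the quotient
#'     (mg/g)/(mm^2/mg) equals g/m^2 numerically}
#'   \item{np_ratio}{`lnc_mg_g / lpc_mg_g`, dimensionless}
#'   \item{limitation}{nutrient-limitation class from the N:P ratio, see
#'     [classify_limitation()]}
#' }
#'
#' @param traits data frame with columns `plant_id`, `fresh_mass_mg`,
#'   `dry_mass_mg`, `leaf_area_mm2`, `lnc_mg_g`, `lpc_mg_g` and optionally
#'   `lcc_mg_g`. Masses and areas must be positive and
#'   `dry_mass_mg <= fresh_mass_mg`.
#' @return The input data frame with the derived columns appended.
#' @export
derive_traits <- function(traits) {
  need <- c("plant_id", "fresh_mass_mg", "dry_mass_mg", "leaf_area_mm2",
            "lnc_mg_g", "lpc_mg_g")
  missing_cols <- setdiff(need, names(traits))
  if (length(missing_cols) > 0L)
    stop("trait table lacks column(s): ", paste(missing_cols, collapse = ", "))
  num <- setdiff(need, "plant_id")
  for (cl in num)
    if (any(!is.finite(traits[[cl]]) | traits[[cl]] <= 0))
      stop("non-positive or non-finite ", cl, " for plant(s) ",
           paste(traits$plant_id[!is.finite(traits[[cl]]) | traits[[cl]] <= 0],
                 collapse = ", "))
  if (any(traits$dry_mass_mg > traits$fresh_mass_mg))
    stop("dry mass exceeds fresh mass for plant(s) ",
         paste(traits$plant_id[traits$dry_mass_mg > traits$fresh_mass_mg],
               collapse = ", "))
  traits$sla <- traits$leaf_area_mm2 / traits$dry_mass_mg
  traits$ldmc <- 1000 * traits$dry_mass_mg / traits$fresh_mass_mg
  traits$lnc_area <- traits$lnc_mg_g / traits$sla
  traits$lpc_area <- traits$lpc_mg_g / traits$sla
  traits$np_ratio <- traits$lnc_mg_g / traits$lpc_mg_g
  traits$limitation <- classify_limitation(traits$np_ratio)
  traits
}

#' Classify nutrient limitation from the leaf N:P ratio
#'
#' Plants from N-limited ecosystems show `N:P < 14`, plants from P-limited
#' ecosystems `N:P > 16`; ratios in `[14, 16]` indicate that both nutrients
#' are about equally limiting. The boundary values belong to the colimited
#' class, since the limited classes are defined by strict inequalities.
#'
#' @param np_ratio positive numeric vector of N:P ratios.
#' @return Factor with levels `N_limited`, `colimited`, `P_limited`.
#' @export
classify_limitation <- function(np_ratio) {
  if (any(!is.finite(np_ratio) | np_ratio <= 0))
    stop("N:P ratio must be positive and finite")
  cls <- ifelse(np_ratio < 14, "N_limited",
                ifelse(np_ratio > 16, "P_limited", "colimited"))
  factor(cls, levels = c("N_limited", "colimited", "P_limited"))
}

#' Base-10 log transform of trait values
#'
#' Trait distributions are right-skewed; regression is run on
#' `log10(trait)`. The base only rescales regression coefficients by a
#' constant and affects neither r-squared nor band selection.
#'
#' @param values positive numeric vector.
#' @param plant_id optional identifiers used in error messages.
#' @return `log10(values)`.
#' @export
log_traits <- function(values, plant_id = NULL) {
  bad <- !is.finite(values) | values <= 0
  if (any(bad)) {
    who <- if (is.null(plant_id)) paste("element", which(bad)) else plant_id[bad]
    stop("log transform requires positive values; offending plant(s): ",
         paste(utils::head(who, 5L), collapse = ", "))
  }
  log10(values)
}
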