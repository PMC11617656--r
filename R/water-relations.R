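#' Solute potential from osmolality
#'
#' Van't Hoff relation used with vapor-pressure osmometry:
#' psi_solute = -osmolality x 8.3144598e-6 x T, giving MPa from osmolality
#' in mmol kg^-1 and temperature in K.
#'
#' @param osmolality mmol kg^-1 (>= 0)
#' @param temp chamber temperature, K (> 0); default 305.0 K
#' @return solute potential, MPa (<= 0)
#' @export
solutePotential <- function(osmolality, temp = 305.0) {
  if (any(temp <= 0, na.rm = TRUE))
    stop("physical-domain error: temperature must be positive (K)")
  if (any(osmolality < 0, na.rm = TRUE))
    stop("validation error: osmolality must be non-negative")
  -osmolality * .VANT_HOFF_MPA * temp
}

#' Pressure (turgor) potential
#'
#' psi_pressure = psi - psi_solute. Positive values indicate turgid cells;
#' negative values indicate estimated turgor loss.
#'
#' @param psi_pd tissue water potential (predawn shoot psi used as the
#'   inner-bark estimate), MPa
#' @param psi_solute solute potential, MPa (<= 0)
#' @return pressure potential, MPa
#' @export
pressurePotential <- function(psi_pd, psi_solute) {
  if (any(psi_solute > 0, na.rm = TRUE))
    stop("psi_solute must be non-positive")
  psi_pd - psi_solute
}

#' Per-tree inner-bark water state
#'
#' Computes solute and pressure potentials for every tree with osmometry,
#' and classifies trees into turgid (psi_pressure > 0) vs turgor-lost
#' groups. Trees lacking a chamber temperature use `defaultTemp`.
#'
#' @param cohort a [DefenseCohort-class]
#' @param defaultTemp chamber temperature (K) substituted where missing
#' @return data.frame: tree_id, psi_pd, osmolality, chamber_temp,
#'   psi_solute, psi_pressure, turgid
#' @export
waterState <- function(cohort, defaultTemp = 305.0) {
  td <- treeData(cohort)
  temp <- ifelse(is.na(td$chamber_temp), defaultTemp, td$chamber_temp)
  psiS <- solutePotential(td$osmolality, temp)
  psiP <- pressurePotential(td$psi_pd, psiS)
  data.frame(tree_id = td$tree_id, psi_pd = td$psi_pd,
             osmolality = td$osmolality, chamber_temp = temp,
             psi_solute = psiS, psi_pressure = psiP,
             turgid = psiP > 0, stringsAsFactors = FALSE)
}
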