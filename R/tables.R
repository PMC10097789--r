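fabrifem_extdata <- function(file) {
  path <- system.file("extdata", file, package = "fabrifem")
  if (path == "") path <- file.path("inst", "extdata", file) # pre-install fallback
  path
}

#' Material constants of the trabecular stiffness power law
#'
#' Returns the bundled tissue-level constants of the Zysset-Curnier law
#' (E0, nu0, G0 and exponents k, l) together with the density thresholds and
#' special-phase properties used by the material-assignment rules: BV/TV below
#' `rho_lo` or above `rho_hi` switches to isotropic behaviour, dense bone is
#' treated as cortical with the bundled modulus, and tendon/cartilage layers
#' get a soft isotropic material.
#'
#' @param E0,nu0,G0,k,l optional overrides of the bundled constants
#'   (MPa, -, MPa, -, -).
#' @param rho_lo,rho_hi,rho_cortical optional overrides of the BV/TV
#'   thresholds.
#' @param E_cortical,nu_cortical,E_tendon,nu_tendon optional overrides of the
#'   special-phase isotropic properties (MPa, -).
#' @return object of class `material_card`.
#' @export
material_card <- function(E0 = NULL, nu0 = NULL, G0 = NULL, k = NULL, l = NULL,
                          rho_lo = 0.1, rho_hi = 0.9, rho_cortical = 0.95,
                          E_cortical = 22500, nu_cortical = 0.3,
                          E_tendon = 5, nu_tendon = 0.3) {
  tab <- utils::read.csv(fabrifem_extdata("material_constants.csv"))
  val <- function(nm) tab$value[tab$constant == nm]
  card <- list(
    E0 = if (is.null(E0)) val("E0_MPa") else E0,
    nu0 = if (is.null(nu0)) val("nu0") else nu0,
    G0 = if (is.null(G0)) val("G0_MPa") else G0,
    k = if (is.null(k)) val("k") else k,
    l = if (is.null(l)) val("l") else l,
    rho_lo = rho_lo, rho_hi = rho_hi, rho_cortical = rho_cortical,
    E_cortical = E_cortical, nu_cortical = nu_cortical,
    E_tendon = E_tendon, nu_tendon = nu_tendon
  )
  stopifnot(card$E0 > 0, card$G0 > 0, card$nu0 > 0, card$nu0 < 0.5,
            card$k > 0, card$l > 0, card$rho_lo < card$rho_hi)
  structure(card, class = "material_card")
}

#' Bundled muscle and joint-reaction load cases
#'
#' Two reference load sets for a right proximal femur at 30% (config 1, single
#' -leg stance) and 60% (config 2, toe-off) of the gait cycle: 15 muscle
#' contraction forces (unit direction + magnitude, femur coordinate frame with
#' the head centre at the origin) plus the hip joint reaction resolved at the
#' joint centre. Directions are printed to 3 decimals; two transcribed entries
#' whose components were inconsistent with unit length are renormalized (flag
#' `renormalized` in the bundled CSV).
#'
#' @param config 1 or 2.
#' @return object of class `load_case`: `muscles` (data.frame), `reaction`
#'   (direction, magnitude), `distribution` (rod spec: joint centre +
#'   joint-surface node set name).
#' @export
load_case <- function(config = 1) {
  stopifnot(config %in% c(1, 2))
  mus <- utils::read.csv(fabrifem_extdata("muscle_forces.csv"))
  mus <- mus[mus$config == config, c("muscle", "nx", "ny", "nz", "magnitude_N")]
  rownames(mus) <- NULL
  rea <- utils::read.csv(fabrifem_extdata("joint_reactions.csv"))
  rea <- rea[rea$config == config, ]
  nrm <- sqrt(mus$nx^2 + mus$ny^2 + mus$nz^2)
  if (any(abs(nrm - 1) > 5e-3)) stop("muscle direction norms deviate from 1 beyond print rounding")
  if (any(mus$magnitude_N < 0)) stop("negative muscle magnitude")
  structure(list(
    config = config,
    muscles = mus,
    reaction = list(direction = c(rea$nx, rea$ny, rea$nz), magnitude_N = rea$magnitude_N),
    distribution = list(joint_center_mm = c(0, 0, 0), surface_set = "joint_surface")
  ), class = "load_case")
}

#' Frost mechanostat thresholds
#'
#' The bundled minimum-effective-strain table: MESr (disuse/resorption range),
#' MESm (modeling threshold), MESp (microdamage) and Fx (fracture), each as a
#' strain (microstrain), stress (MPa) and strain-energy-density (MPa) entry.
#' SED entries other than Fx equal E*eps^2/2 at the cortical tissue modulus
#' E = 22500 MPa; the Fx SED entry is stored as printed and is not derivable
#' that way.
#'
#' @return object of class `frost_thresholds` (a data.frame).
#' @export
frost_thresholds <- function() {
  tab <- utils::read.csv(fabrifem_extdata("frost_thresholds.csv"))
  structure(tab, class = c("frost_thresholds", "data.frame"))
}

#' All bundled fixtures at once
#'
#' @return list with `card` ([material_card()]), `config1` and `config2`
#'   ([load_case()]) and `frost` ([frost_thresholds()]).
#' @export
builtin_tables <- function() {
  list(card = material_card(), config1 = load_case(1), config2 = load_case(2),
       frost = frost_thresholds())
}
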