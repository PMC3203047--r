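# Hille-style pore-diameter estimation from single-channel conductance.
#
# The pore is modelled as an electrolyte-filled cylinder of length l whose
# interior conductivity is reduced relative to the bulk by a fixed factor
# (rho_pore = rho_bulk * factor). Two variants are offered:
#   cylinder             1/g = rho_pore * l / (pi r^2)
#   cylinder_plus_access 1/g = rho_pore * l / (pi r^2) + rho_bulk / (2 r)
# The second adds the access (convergence) resistance of the two pore
# mouths, evaluated with the unreduced bulk resistivity. The cylinder case
# inverts in closed form, d = 2 sqrt(g rho_pore l / pi); the access case is
# solved numerically for the radius.

#' Parameters for the Hille pore-size estimate
#'
#' @param conductance_pS single-channel (or conductance-class) conductance
#'   g (pS).
#' @param length_min_nm,length_max_nm assumed range of the channel length l
#'   (nm); default 1-5 nm.
#' @param rho_bulk_ohm_cm bulk electrolyte resistivity (ohm cm); the default
#'   247.5 corresponds to 250 mM KCl.
#' @param pore_conductivity_factor factor by which conductivity inside the
#'   pore is lower than in bulk (default 5); the in-pore resistivity is
#'   `rho_bulk * factor`.
#' @param variant `"cylinder"` or `"cylinder_plus_access"`.
#' @return An object of class `"hille_params"`.
#' @export
hille_params <- function(conductance_pS, length_min_nm = 1,
                         length_max_nm = 5, rho_bulk_ohm_cm = 247.5,
                         pore_conductivity_factor = 5,
                         variant = c("cylinder", "cylinder_plus_access")) {
  variant <- match.arg(variant)
  check_scalar_number(conductance_pS, "conductance_pS", positive = TRUE)
  check_scalar_number(length_min_nm, "length_min_nm", positive = TRUE)
  check_scalar_number(length_max_nm, "length_max_nm", positive = TRUE)
  check_scalar_number(rho_bulk_ohm_cm, "rho_bulk_ohm_cm", positive = TRUE)
  check_scalar_number(pore_conductivity_factor, "pore_conductivity_factor",
                      positive = TRUE)
  if (length_min_nm > length_max_nm)
    stop_invalid("'length_min_nm' must be <= 'length_max_nm'")
  structure(list(conductance_pS = conductance_pS,
                 length_min_nm = length_min_nm,
                 length_max_nm = length_max_nm,
                 rho_bulk_ohm_cm = rho_bulk_ohm_cm,
                 pore_conductivity_factor = pore_conductivity_factor,
                 variant = variant),
            class = "hille_params")
}

# Pore diameter (angstrom) at a single length l (nm) for given parameters.
hille_diameter_at_length_A <- function(params, length_nm) {
  g_S <- params$conductance_pS * 1e-12
  rho_bulk <- params$rho_bulk_ohm_cm * 0.01            # ohm m
  rho_pore <- rho_bulk * params$pore_conductivity_factor
  l <- length_nm * 1e-9                                 # m
  if (params$variant == "cylinder") {
    d <- 2 * sqrt(g_S * rho_pore * l / pi)
    return(d * 1e10)
  }
  # cylinder_plus_access: bisection on the radius to 1e-4 angstrom
  f <- function(r) rho_pore * l / (pi * r^2) + rho_bulk / (2 * r) - 1 / g_S
  lo <- 1e-13
  hi <- 1e-13
  while (f(hi) > 0) hi <- hi * 2
  if (f(lo) < 0) stop_invalid("no positive root for the pore radius")
  while (hi - lo > 0.5e-14) {   # 1e-4 angstrom on the diameter
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) * 1e10              # diameter = 2 r
}

#' Hille pore-diameter estimate
#'
#' Converts a channel conductance into a pore-diameter range over the
#' assumed channel-length range, for the chosen resistance model (see
#' [hille_params()]). The diameter is monotone increasing in both the
#' length and the conductance; under the plain cylinder variant it scales
#' exactly as `sqrt(g)` and `sqrt(l)`.
#'
#' @param params a [hille_params()].
#' @return An object of class `"pore_estimate"`: `diameter_min_A` (at
#'   `length_min_nm`), `diameter_max_A` (at `length_max_nm`), both in
#'   angstrom, plus the input `params`.
#' @export
hille_pore_diameter <- function(params) {
  if (!inherits(params, "hille_params"))
    stop_invalid("'params' must be a hille_params")
  d_lo <- hille_diameter_at_length_A(params, params$length_min_nm)
  d_hi <- hille_diameter_at_length_A(params, params$length_max_nm)
  structure(list(diameter_min_A = min(d_lo, d_hi),
                 diameter_max_A = max(d_lo, d_hi),
                 params = params),
            class = "pore_estimate")
}

#' @export
print.pore_estimate <- function(x, ...) {
  cat(sprintf(
    "pore_estimate (%s): d = %.1f-%.1f A for g = %g pS, l = %g-%g nm\n",
    x$params$variant, x$diameter_min_A, x$diameter_max_A,
    x$params$conductance_pS, x$params$length_min_nm, x$params$length_max_nm))
  invisible(x)
}
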