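# Electrolyte-gated FET electrostatics: the chain from bound molecular
# charge to drain-source current. The gate stack is three capacitances in
# series (graphene EDL, reference-electrode EDL, graphene quantum
# capacitance); tethered DNA charge is screened exponentially over the Debye
# length; a charge-neutrality-point shift reports probe surface density; and
# the transconductance converts per-molecule gate-charge into current.

ELEMENTARY_CHARGE <- 1.602176634e-19  # C
VACUUM_PERMITTIVITY <- 8.8541878128e-12  # F/m
AVOGADRO <- 6.02214076e23

#' Electrolyte-gated FET stack parameters
#'
#' @param graphene_area_um2 electrolyte-exposed graphene area in um^2
#' @param quantum_cap_uF_cm2 graphene quantum capacitance per unit area in
#'   uF/cm^2 (~2 for CVD graphene near the neutrality point)
#' @param transconductance_uA_V transconductance dI_ds/dV_g in uA/V
#'   (negative on the electron branch of an n-doping response)
#' @param baseline_uA baseline drain-source current in uA (> 0)
#' @param pt_area_um2 wetted reference-electrode area in um^2; `Inf` (the
#'   default) drops its EDL from the series stack, appropriate when the
#'   electrode is orders of magnitude larger than the graphene
#' @return an object of class `fet_stack`
#' @export
fet_stack <- function(graphene_area_um2 = 4e3, quantum_cap_uF_cm2 = 2,
                      transconductance_uA_V = -28.0, baseline_uA = 31.25,
                      pt_area_um2 = Inf) {
  if (!is.finite(graphene_area_um2) || graphene_area_um2 <= 0)
    stop("graphene area must be strictly positive")
  if (!is.finite(quantum_cap_uF_cm2) || quantum_cap_uF_cm2 <= 0)
    stop("quantum capacitance per area must be strictly positive")
  if (!is.finite(baseline_uA) || baseline_uA <= 0)
    stop("baseline current must be strictly positive")
  structure(
    list(graphene_area = graphene_area_um2 * 1e-12,       # m^2
         pt_area = pt_area_um2 * 1e-12,                   # m^2 (may be Inf)
         quantum_cap_per_area = quantum_cap_uF_cm2 * 1e-2, # F/m^2
         transconductance = transconductance_uA_V,         # uA/V
         baseline = baseline_uA),                          # uA
    class = "fet_stack")
}

#' Surface-tethered oligonucleotide probe
#'
#' The effective height of the charge centroid above the surface is
#' `n_bases * base_rise_nm * length_fraction`; the default fraction 1/2
#' places it at half the contour length of a vertically tethered single
#' strand.
#'
#' @param n_bases number of bases (>= 1)
#' @param charge_per_base elementary charges per base (1 for the
#'   phosphate backbone)
#' @param base_rise_nm axial rise per base in nm (0.34 for B-form stacking)
#' @param length_fraction fraction of contour length at which the effective
#'   charge sits, in (0, 1]
#' @param diffusion_um2_s free-solution diffusion coefficient in um^2/s
#' @return an object of class `oligo_probe`
#' @export
oligo_probe <- function(n_bases = 18, charge_per_base = 1,
                        base_rise_nm = 0.34, length_fraction = 0.5,
                        diffusion_um2_s = 100) {
  if (n_bases < 1) stop("n_bases must be >= 1")
  if (length_fraction <= 0 || length_fraction > 1)
    stop("length_fraction must be in (0, 1]")
  structure(
    list(n_bases = n_bases, charge_per_base = charge_per_base,
         base_rise = base_rise_nm * 1e-9,                 # m
         length_fraction = length_fraction,
         diffusion = diffusion_um2_s * 1e-12),            # m^2/s
    class = "oligo_probe")
}

#' Electrical double-layer capacitance of a plane electrode
#'
#' Parallel-plate capacitance with the Debye length as dielectric
#' thickness: C = A eps_r eps_0 / lambda_D. The Debye length may be given
#' explicitly (e.g. a rounded literature value) or computed from an
#' [electrolyte()] at full precision.
#'
#' @param area_um2 wetted electrode area in um^2
#' @param el an [electrolyte()]; ignored when `lambda_d_nm` is given
#' @param lambda_d_nm optional explicit Debye length in nm
#' @param rel_permittivity relative permittivity used with `lambda_d_nm`
#' @return capacitance in nF
#' @export
edl_capacitance <- function(area_um2, el = NULL, lambda_d_nm = NULL,
                            rel_permittivity = 80) {
  if (!is.finite(area_um2) || area_um2 <= 0)
    stop("area must be strictly positive")
  if (is.null(lambda_d_nm)) {
    stopifnot(inherits(el, "electrolyte"))
    lambda_d_nm <- debye_length(el)
    rel_permittivity <- el$rel_permittivity
  }
  if (lambda_d_nm <= 0) stop("Debye length must be strictly positive")
  area_um2 * 1e-12 * rel_permittivity * VACUUM_PERMITTIVITY /
    (lambda_d_nm * 1e-9) * 1e9
}

#' Series gate capacitance of the electrolyte-gated stack
#'
#' C_G = (1/C_Gr + 1/C_Pt + 1/C_Q)^-1. Any term passed as `Inf` drops out
#' of the series sum (the usual treatment of a macroscopic reference
#' electrode). The result is bounded above by the smallest finite term.
#'
#' @param c_gr_nF graphene EDL capacitance in nF
#' @param c_q_nF graphene quantum capacitance in nF
#' @param c_pt_nF reference-electrode EDL capacitance in nF, or `Inf`
#' @return gate capacitance in nF
#' @export
gate_capacitance <- function(c_gr_nF, c_q_nF, c_pt_nF = Inf) {
  terms <- c(c_gr_nF, c_q_nF, c_pt_nF)
  if (any(is.na(terms)) || any(terms <= 0))
    stop("capacitances must be strictly positive (Inf allowed)")
  1 / sum(1 / terms)
}

#' Graphene quantum capacitance of the exposed channel
#'
#' @param fet a [fet_stack()]
#' @return C_Q = c_q * A_gr in nF
#' @export
quantum_capacitance <- function(fet) {
  stopifnot(inherits(fet, "fet_stack"))
  fet$quantum_cap_per_area * fet$graphene_area * 1e9
}

#' Debye-screened effective charge of a tethered oligonucleotide
#'
#' q = n q_e exp(-r / lambda_D) with r the effective height of the charge
#' centroid. Monotone increasing in both the Debye length and the base
#' count; the unscreened limit is the full backbone charge n q_e.
#'
#' @param probe an [oligo_probe()]
#' @param el an [electrolyte()]; ignored when `lambda_d_nm` is given
#' @param lambda_d_nm optional explicit Debye length in nm
#' @return effective charge in coulombs
#' @export
effective_charge <- function(probe, el = NULL, lambda_d_nm = NULL) {
  stopifnot(inherits(probe, "oligo_probe"))
  if (is.null(lambda_d_nm)) lambda_d_nm <- debye_length(el)
  r_nm <- probe$n_bases * probe$base_rise * 1e9 * probe$length_fraction
  probe$n_bases * probe$charge_per_base * ELEMENTARY_CHARGE *
    exp(-r_nm / lambda_d_nm)
}

#' Probe surface density from a charge-neutrality-point shift
#'
#' n = dV_CNP * C_G / (q_mol * A); the gate capacitance referred to the
#' molecular charge at the surface converts the observed voltage shift into
#' a charge areal density.
#'
#' @param dv_cnp_mV neutrality-point shift in mV
#' @param c_g_nF gate capacitance in nF
#' @param q_mol_C per-molecule effective charge in C (> 0)
#' @param area_um2 graphene area in um^2 (> 0)
#' @return surface density in um^-2
#' @export
surface_density_from_cnp_shift <- function(dv_cnp_mV, c_g_nF, q_mol_C,
                                           area_um2) {
  if (q_mol_C <= 0 || area_um2 <= 0)
    stop("molecular charge and area must be strictly positive")
  (dv_cnp_mV * 1e-3) * (c_g_nF * 1e-9) / (q_mol_C * area_um2)
}

#' Per-molecule current transduction factor
#'
#' Q = g_m q / C_G: the drain-source current change contributed by one
#' bound target molecule. Shares the sign of the transconductance, so an
#' n-doping response with negative g_m gives a negative Q and a current
#' that falls as binding proceeds.
#'
#' @param fet a [fet_stack()], or a bare transconductance in uA/V
#' @param q_mol_C per-molecule effective charge in C
#' @param c_g_nF gate capacitance in nF (> 0)
#' @return current per bound molecule in uA
#' @export
transduction_factor <- function(fet, q_mol_C, c_g_nF) {
  gm <- if (inherits(fet, "fet_stack")) fet$transconductance else fet
  if (!is.finite(c_g_nF) || c_g_nF <= 0)
    stop("gate capacitance must be strictly positive")
  gm * q_mol_C / (c_g_nF * 1e-9)
}

#' Convert a current change to a bound-receptor count, and back
#'
#' N = dI / Q and dI = N Q are exact mutual inverses; the count is positive
#' whenever the current change and the transduction factor share sign.
#'
#' @param delta_i_uA current change(s) in uA
#' @param q_factor_uA per-molecule transduction factor in uA (nonzero)
#' @return receptor count (`current_to_bound`) or current in uA
#'   (`bound_to_current`)
#' @export
current_to_bound <- function(delta_i_uA, q_factor_uA) {
  if (q_factor_uA == 0) stop("transduction factor must be nonzero")
  delta_i_uA / q_factor_uA
}

#' @rdname current_to_bound
#' @param n_bound bound-receptor count(s)
#' @export
bound_to_current <- function(n_bound, q_factor_uA) {
  if (q_factor_uA == 0) stop("transduction factor must be nonzero")
  n_bound * q_factor_uA
}

#' Receptor ceiling from the equilibrium response
#'
#' N_max = ((c + K_D) / c) * N_eq inverts the Langmuir isotherm: given the
#' equilibrium occupancy at concentration c, the total receptor count
#' follows. Always >= N_eq, with equality only in the K_D -> 0 limit.
#'
#' @param c_avg_M concentration seen by the surface, in M (> 0)
#' @param k_d_M dissociation constant in M (>= 0)
#' @param n_r_eq equilibrium bound count at `c_avg_M`
#' @return maximum (total) receptor count
#' @export
n_r_max <- function(c_avg_M, k_d_M, n_r_eq) {
  if (!is.finite(c_avg_M) || c_avg_M <= 0)
    stop("concentration must be strictly positive")
  (c_avg_M + k_d_M) / c_avg_M * n_r_eq
}

#' Half-cylinder wetted area of a wire electrode
#'
#' Convenience for sensitivity checks on the reference-electrode term:
#' A = l d pi / 2 for a wire of length l and diameter d half-immersed.
#'
#' @param length_mm wire length in mm
#' @param diameter_mm wire diameter in mm
#' @return area in um^2
#' @export
wire_half_area <- function(length_mm, diameter_mm) {
  length_mm * diameter_mm * pi / 2 * 1e6
}
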