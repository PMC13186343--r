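#' Force-field parameter set
#'
#' Container for every potential constant of the sticker-spacer model:
#' harmonic chain bonds E = Kb (R - R0)^2, cosine bending E = kappa (1 - cos
#' theta) (theta = deviation from a straight chain), truncated Lennard-Jones
#' cohesion of depth \code{Ens}, and the shifted-harmonic specific well of
#' depth \code{Es} between complementary stickers, formed/broken with
#' probabilities \code{p_on} / \code{p_off}.
#'
#' Defaults are the model's standard values: Kb = 3 kcal/mol/A^2, R0 = 10 A,
#' kappa = 2 kcal/mol, sigma = 10 A, Rmax = 2.5 sigma, R0_stick = 1.122
#' sigma, Rcut_stick = R0_stick + 1.5 A, p_on = p_off = 1.
#'
#' @param Kb bond spring constant (kcal/mol/A^2)
#' @param R0_bond equilibrium bond length (A)
#' @param kappa bending stiffness (kcal/mol)
#' @param sigma bead diameter (A)
#' @param Ens non-specific LJ well depth (kcal/mol)
#' @param Rmax LJ cutoff (A)
#' @param Es specific well depth (kcal/mol)
#' @param R0_stick sticker-bond rest length (A)
#' @param Rcut_stick sticker-bond cutoff (A)
#' @param p_on,p_off bond formation / breakage probabilities in [0, 1]
#' @return an \code{ssp_params} list
#' @export
forcefield_params <- function(Kb = 3, R0_bond = 10, kappa = 2, sigma = 10,
                              Ens = 0.3 * kT_kcal(310), Rmax = 2.5 * sigma,
                              Es = 6 * kT_kcal(310),
                              R0_stick = 1.122 * sigma,
                              Rcut_stick = 1.122 * sigma + 1.5,
                              p_on = 1, p_off = 1) {
  p <- list(Kb = Kb, R0_bond = R0_bond, kappa = kappa, sigma = sigma,
            Ens = Ens, Rmax = Rmax, Es = Es, R0_stick = R0_stick,
            Rcut_stick = Rcut_stick, p_on = p_on, p_off = p_off)
  if (p$Rcut_stick <= p$R0_stick) stop("Rcut_stick must exceed R0_stick")
  if (p$Rmax <= p$sigma) stop("Rmax must exceed sigma")
  if (any(c(p$Kb, p$kappa, p$Ens, p$Es) < 0)) stop("well depths and stiffnesses must be >= 0")
  if (p$p_on < 0 || p$p_on > 1 || p$p_off < 0 || p$p_off > 1)
    stop("p_on and p_off must lie in [0, 1]")
  structure(p, class = "ssp_params")
}

#' Default force field with energies given in units of kT
#'
#' @param T temperature (K) at which kT-valued energies are converted
#' @param Es_kT specific energy in kT
#' @param Ens_kT non-specific energy in kT
#' @param ... further overrides passed to [forcefield_params()]
#' @export
default_forcefield <- function(T = 310, Es_kT = 6, Ens_kT = 0.3, ...) {
  forcefield_params(Es = Es_kT * kT_kcal(T), Ens = Ens_kT * kT_kcal(T), ...)
}

#' Harmonic bond energy and force
#'
#' E = Kb (R - R0)^2 (note: no factor 1/2), scalar force -dE/dR.
#'
#' @param R bond length(s), A
#' @param Kb spring constant (kcal/mol/A^2)
#' @param R0_bond equilibrium length (A)
#' @return list with \code{energy} and \code{force} (kcal/mol, kcal/mol/A)
#' @export
harmonic_bond <- function(R, Kb = 3, R0_bond = 10) {
  stopifnot(all(R > 0))
  list(energy = Kb * (R - R0_bond)^2, force = -2 * Kb * (R - R0_bond))
}

#' Cosine bending energy
#'
#' E = kappa (1 - cos theta) where theta is the deviation from a straight
#' chain (a collinear triplet has theta = 0 and zero energy; equivalently
#' E = kappa (1 + cos theta_interior) on the interior angle).
#'
#' @param theta deviation angle(s) from collinearity, radians, in [0, pi]
#' @param kappa bending stiffness (kcal/mol)
#' @return list with \code{energy} and \code{torque} = -dE/dtheta magnitude
#' @export
cosine_angle <- function(theta, kappa = 2) {
  stopifnot(all(theta >= 0), all(theta <= pi + 1e-12))
  list(energy = kappa * (1 - cos(theta)), torque = kappa * abs(sin(theta)))
}

#' Truncated Lennard-Jones pair energy and force
#'
#' E = 4 Ens [(sigma/r)^12 - (sigma/r)^6] for r <= Rmax, zero beyond the
#' cutoff (truncated, unshifted).
#'
#' @param r separation(s), A
#' @param Ens well depth (kcal/mol)
#' @param sigma bead diameter (A)
#' @param Rmax cutoff (A)
#' @return list with \code{energy} and scalar \code{force} = -dE/dr
#' @export
lj_pair <- function(r, Ens, sigma = 10, Rmax = 2.5 * sigma) {
  if (any(r < 1e-9)) stop("bead overlap: r is numerically zero")
  sr6 <- (sigma / r)^6
  e <- 4 * Ens * (sr6^2 - sr6)
  f <- 24 * Ens * (2 * sr6^2 - sr6) / r
  e[r > Rmax] <- 0
  f[r > Rmax] <- 0
  list(energy = e, force = f)
}

#' Shifted-harmonic specific (sticker) bond
#'
#' E(R) = Es/(R0 - Rcut)^2 * [(R - R0)^2 - (Rcut - R0)^2] for R < Rcut and 0
#' beyond; the well bottom at R0 has depth -Es and the potential rises to
#' exactly zero at Rcut.
#'
#' @param R inter-sticker distance(s), A
#' @param Es well depth (kcal/mol)
#' @param R0_stick rest length (A)
#' @param Rcut_stick cutoff (A)
#' @return list with \code{energy} and scalar \code{force} = -dE/dR
#' @export
sticker_bond <- function(R, Es, R0_stick = 11.22, Rcut_stick = 12.72) {
  stopifnot(all(R > 0))
  k <- Es / (R0_stick - Rcut_stick)^2
  shift <- (Rcut_stick - R0_stick)^2
  e <- k * ((R - R0_stick)^2 - shift)
  f <- -2 * k * (R - R0_stick)
  e[R >= Rcut_stick] <- 0
  f[R >= Rcut_stick] <- 0
  list(energy = e, force = f)
}

#' Total potential energy and forces of a configuration
#'
#' Sums permanent harmonic bonds and active sticker bonds (E_bond), the
#' bending term (E_angle) and truncated LJ over all non-excluded pairs
#' (E_pair). Directly bonded pairs -- permanent 1-2 neighbours and currently
#' bonded sticker pairs -- feel no LJ; second (1-3) and further neighbours
#' interact at full strength. Forces are exact negative gradients.
#'
#' @param state an \code{ssp_state}
#' @param topology combined \code{ssp_topology} (from [pack_system()])
#' @param params \code{ssp_params}
#' @return list: \code{forces} (N x 3, kcal/mol/A) and the energy breakdown
#'   \code{E_bond}, \code{E_pair}, \code{E_angle}, \code{E_potential}
#' @export
total_energy_forces <- function(state, topology, params) {
  res <- energy_forces_cpp(state$pos, state$pairing, state$box,
                           topo_for_engine(topology), unclass(params))
  res[c("forces", "E_bond", "E_pair", "E_angle", "E_potential")]
}

# engine-facing view of a topology (integer types + comp matrix)
topo_for_engine <- function(topology) {
  if (is.null(topology$type)) {
    labels <- sort(unique(topology$role[topology$role != "spacer"]))
    topology$type <- role_types(topology$role, labels)
    topology$type_labels <- labels
    topology$comp <- comp_matrix(labels, NULL)
  }
  list(bonds = matrix(as.integer(topology$bonds), ncol = 2),
       angles = matrix(as.integer(topology$angles), ncol = 3),
       type = as.integer(topology$type),
       chain = as.integer(topology$chain),
       comp = topology$comp)
}

#' Candidate non-bonded pairs within a cutoff
#'
#' Enumerates all bead pairs within \code{cutoff} under the minimum-image
#' convention, using the engine's cell/Verlet machinery (with an automatic
#' all-pairs fallback when the box is too small for spatial binning).
#'
#' @param state an \code{ssp_state} (or an N x 3 position matrix)
#' @param cutoff pair cutoff (A)
#' @param box box edges, required when \code{state} is a bare matrix
#' @param skin extra Verlet margin (A); candidates are pruned back to
#'   \code{cutoff} before returning
#' @return two-column integer matrix of bead index pairs (i < j)
#' @export
build_neighbor_list <- function(state, cutoff, box = NULL, skin = 0) {
  if (is.matrix(state)) {
    pos <- state
  } else {
    pos <- state$pos
    box <- state$box
  }
  neighbor_pairs_cpp(pos, as.numeric(box), cutoff, skin)
}
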