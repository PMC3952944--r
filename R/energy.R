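#' Energy models
#'
#' Potential energy of a conformation is evaluated through a pluggable model
#' contract: any object of class \code{energy_model} with an
#' \code{\link{evaluate_energy}} method.  The package ships a coarse-grained
#' five-term model (\code{\link{energy_amw}}) in the Lennard-Jones + H-bond +
#' contact + burial + water family, plus deliberately simple toy models used
#' to test the planner in isolation from force-field fidelity.
#'
#' @name energy_models
NULL

#' Boltzmann constant in kcal/(mol K)
#' @export
KB_KCAL <- 0.0019872

new_energy_model <- function(name, class, ...) {
  structure(list(name = name, ...), class = c(class, "energy_model"))
}

#' @export
print.energy_model <- function(x, ...) {
  cat("energy_model:", x$name, "\n"); invisible(x)
}

#' Evaluate the potential energy of a conformation
#'
#' @param model An \code{energy_model}.
#' @param conf A \code{conformation} (all non-terminal dihedrals defined).
#' @param geo Geometry used to realize coordinates.
#' @return An \code{energy_breakdown}: list with \code{total} (kcal/mol) and
#'   a named numeric vector \code{terms} summing to \code{total}.
#' @export
evaluate_energy <- function(model, conf, geo = geometry_params()) {
  UseMethod("evaluate_energy")
}

energy_breakdown <- function(terms) {
  total <- sum(terms)
  if (!all(is.finite(terms))) stop("non-finite energy term")
  structure(list(total = total, terms = terms), class = "energy_breakdown")
}

#' Constant-zero toy energy
#'
#' Accepts every Metropolis move; isolates planner geometry from energetics.
#' @return An \code{energy_model}.
#' @export
energy_zero <- function() new_energy_model("zero", "energy_zero")

#' @export
evaluate_energy.energy_zero <- function(model, conf, geo = geometry_params()) {
  energy_breakdown(c(toy = 0))
}

# internal: total energy with an optional precomputed coordinate matrix,
# letting the planner reuse the forward-kinematics result it needs anyway
energy_total_xyz <- function(model, conf, xyz, geo) {
  UseMethod("energy_total_xyz")
}

#' @noRd
#' @export
energy_total_xyz.default <- function(model, conf, xyz, geo) {
  evaluate_energy(model, conf, geo)$total
}

#' @noRd
#' @export
energy_total_xyz.energy_zero <- function(model, conf, xyz, geo) 0

#' @noRd
#' @export
energy_total_xyz.energy_goal_funnel <- function(model, conf, xyz, geo) {
  model$scale * lrmsd(xyz, model$goal_xyz)
}

#' @noRd
#' @export
energy_total_xyz.energy_barrier <- function(model, conf, xyz, geo) {
  dr <- delta_r(xyz, model$start_xyz, model$goal_xyz)
  model$scale * lrmsd(xyz, model$goal_xyz) +
    model$height * exp(-dr^2 / (2 * model$width^2))
}

#' Goal-funnel toy energy
#'
#' \code{scale * lrmsd(conf, goal)}: zero exactly at the goal (up to rigid
#' motion) and monotone in the progress coordinate.  Used to give planner
#' tests a smooth, fully-understood landscape.
#'
#' @param goal Goal \code{conformation} or 4n x 3 coordinate matrix.
#' @param scale kcal/mol per Angstrom of lRMSD (default 1).
#' @param geo Geometry used when \code{goal} is a conformation.
#' @return An \code{energy_model}.
#' @export
energy_goal_funnel <- function(goal, scale = 1, geo = geometry_params()) {
  gxyz <- if (inherits(goal, "conformation")) forward_kinematics(goal, geo) else goal
  new_energy_model("goal_funnel", "energy_goal_funnel",
                   goal_xyz = gxyz, scale = scale)
}

#' @export
evaluate_energy.energy_goal_funnel <- function(model, conf,
                                               geo = geometry_params()) {
  xyz <- forward_kinematics(conf, geo)
  if (nrow(xyz) != nrow(model$goal_xyz)) stop("chain length mismatch")
  energy_breakdown(c(toy = model$scale * lrmsd(xyz, model$goal_xyz)))
}

#' Goal funnel with a Gaussian barrier on the delta-R coordinate
#'
#' Adds to the goal funnel a bump of \code{height} kcal/mol centred at
#' delta-R = 0 between the two reference states (start and goal), emulating
#' a transition-state barrier separating two basins.
#'
#' @param start,goal End-state \code{conformation}s or coordinate matrices.
#' @param height Barrier height in kcal/mol.
#' @param width Gaussian width (Angstrom on the delta-R axis).
#' @param scale Funnel slope, kcal/mol per Angstrom.
#' @param geo Geometry used for conformations.
#' @return An \code{energy_model}.
#' @export
energy_barrier <- function(start, goal, height, width = 1.5, scale = 1,
                           geo = geometry_params()) {
  sxyz <- if (inherits(start, "conformation")) forward_kinematics(start, geo) else start
  gxyz <- if (inherits(goal, "conformation")) forward_kinematics(goal, geo) else goal
  new_energy_model("goal_funnel_barrier", "energy_barrier",
                   start_xyz = sxyz, goal_xyz = gxyz,
                   height = height, width = width, scale = scale)
}

#' @export
evaluate_energy.energy_barrier <- function(model, conf,
                                           geo = geometry_params()) {
  xyz <- forward_kinematics(conf, geo)
  dr <- delta_r(xyz, model$start_xyz, model$goal_xyz)
  funnel <- model$scale * lrmsd(xyz, model$goal_xyz)
  bump <- model$height * exp(-dr^2 / (2 * model$width^2))
  energy_breakdown(c(toy = funnel + bump))
}

#' Prohibitive-energy toy model
#'
#' Every conformation sits at a constant, practically infinite energy, so
#' any move proposed from a finite-energy parent fails the Metropolis test;
#' used to exercise expansion-exhaustion paths.
#' @return An \code{energy_model}.
#' @export
energy_reject_all <- function() {
  new_energy_model("reject_all", "energy_reject_all")
}

#' @export
evaluate_energy.energy_reject_all <- function(model, conf,
                                              geo = geometry_params()) {
  energy_breakdown(c(toy = 1e12))
}

#' @noRd
#' @export
energy_total_xyz.energy_reject_all <- function(model, conf, xyz, geo) 1e12

# ---- coarse-grained five-term model ---------------------------------------

# 12-6 Lennard-Jones with a constant soft-core cap below pen_frac * sigma and
# cubic switching to zero between r_switch and r_cut.
lj_pair_energy <- function(r, sigma, eps, pen_frac = 0.8,
                           r_switch = 7, r_cut = 8) {
  lj <- function(x) 4 * eps * ((sigma / x)^12 - (sigma / x)^6)
  r_pen <- pen_frac * sigma
  e <- ifelse(r < r_pen, lj(r_pen), lj(pmax(r, r_pen)))
  # smoothstep switch: 1 below r_switch, 0 above r_cut
  t <- pmin(pmax((r - r_switch) / (r_cut - r_switch), 0), 1)
  s <- 1 - t^2 * (3 - 2 * t)
  e * s
}

sigmoid_count <- function(r, r0, w) 1 / (1 + exp((r - r0) / w))

#' Coarse-grained five-term backbone energy
#'
#' A linear combination of non-local terms over the four modeled backbone
#' heavy atoms: 12-6 Lennard-Jones with a soft core allowing van der Waals
#' penetration, a distance-and-angle backbone H-bond well on N...O pairs,
#' and smoothed sigmoid contact, burial, and water-mediated terms over CA
#' distances.  Term weights and parameters are simplified documented
#' defaults and fully pluggable; planner behaviour in this package is never
#' conditioned on reproducing any published parameterization.
#'
#' @param lj_sigma,lj_eps Named per-atom-type (N, CA, C, O) Lennard-Jones
#'   parameters (Angstrom; kcal/mol); combined by Lorentz-Berthelot rules.
#' @param pen_frac Soft-core penetration fraction: below
#'   \code{pen_frac * sigma_ij} the pair energy is capped at its value at
#'   that separation.
#' @param r_switch,r_cut Switching window for the Lennard-Jones term.
#' @param hb_eps,hb_r0,hb_sw H-bond well depth (kcal/mol), optimum N...O
#'   distance and Gaussian width (Angstrom).
#' @param contact_eps,contact_r0,contact_w Contact term weight and sigmoid
#'   midpoint/width over CA pairs at sequence separation >= 4.
#' @param burial_eps,burial_target Burial term weight and target CA
#'   neighbour count.
#' @param water_eps,water_r0,water_sw Water-mediated term weight, optimum CA
#'   distance and Gaussian width.
#' @return An \code{energy_model} whose breakdown has the five named terms
#'   \code{lj}, \code{hbond}, \code{contact}, \code{burial}, \code{water}.
#' @export
energy_amw <- function(lj_sigma = c(N = 3.25, CA = 3.40, C = 3.40, O = 2.96),
                       lj_eps = c(N = 0.17, CA = 0.086, C = 0.086, O = 0.21),
                       pen_frac = 0.8, r_switch = 7, r_cut = 8,
                       hb_eps = 1.5, hb_r0 = 2.9, hb_sw = 0.3,
                       contact_eps = 0.1, contact_r0 = 8, contact_w = 0.5,
                       burial_eps = 0.02, burial_target = 4,
                       water_eps = 0.05, water_r0 = 6.5, water_sw = 1.0) {
  new_energy_model("amw5", "energy_amw",
                   lj_sigma = lj_sigma, lj_eps = lj_eps, pen_frac = pen_frac,
                   r_switch = r_switch, r_cut = r_cut,
                   hb_eps = hb_eps, hb_r0 = hb_r0, hb_sw = hb_sw,
                   contact_eps = contact_eps, contact_r0 = contact_r0,
                   contact_w = contact_w, burial_eps = burial_eps,
                   burial_target = burial_target, water_eps = water_eps,
                   water_r0 = water_r0, water_sw = water_sw)
}

#' @export
evaluate_energy.energy_amw <- function(model, conf, geo = geometry_params()) {
  xyz <- forward_kinematics(conf, geo)
  n <- nrow(xyz) / 4
  atom <- rep(c("N", "CA", "C", "O"), n)
  res <- rep(seq_len(n), each = 4)

  # Lennard-Jones over atom pairs at residue separation >= 2
  e_lj <- 0
  pr <- which(outer(res, res, function(a, b) b - a) >= 2, arr.ind = TRUE)
  if (nrow(pr)) {
    d <- sqrt(rowSums((xyz[pr[, 1], , drop = FALSE] -
                       xyz[pr[, 2], , drop = FALSE])^2))
    si <- (model$lj_sigma[atom[pr[, 1]]] + model$lj_sigma[atom[pr[, 2]]]) / 2
    ei <- sqrt(model$lj_eps[atom[pr[, 1]]] * model$lj_eps[atom[pr[, 2]]])
    e_lj <- sum(lj_pair_energy(d, si, ei, model$pen_frac,
                               model$r_switch, model$r_cut))
  }

  # backbone H-bond: N(i)...O(j) at |i-j| >= 3, distance well x angular factor
  e_hb <- 0
  iN <- which(atom == "N"); iO <- which(atom == "O"); iC <- which(atom == "C")
  for (a in iN) for (b in iO) {
    if (abs(res[a] - res[b]) < 3) next
    v <- xyz[a, ] - xyz[b, ]
    r <- sqrt(sum(v^2))
    if (r > model$hb_r0 + 4 * model$hb_sw) next
    cvec <- xyz[iC[res[b]], ] - xyz[b, ]           # O -> C of same residue
    ct <- sum(v * cvec) / (r * sqrt(sum(cvec^2)))  # cos(C=O...N angle) * -1
    wang <- if (ct < 0) ct^2 else 0                # favour linear C=O...N
    e_hb <- e_hb - model$hb_eps *
      exp(-(r - model$hb_r0)^2 / (2 * model$hb_sw^2)) * wang
  }

  # CA-based terms
  ca <- xyz[atom == "CA", , drop = FALSE]
  dca <- as.matrix(stats::dist(ca))
  sep <- abs(outer(seq_len(n), seq_len(n), `-`))
  far <- sep >= 4 & upper.tri(dca)
  e_contact <- -model$contact_eps *
    sum(sigmoid_count(dca[far], model$contact_r0, model$contact_w))
  e_water <- -model$water_eps *
    sum(exp(-(dca[far] - model$water_r0)^2 / (2 * model$water_sw^2)))
  nb <- rowSums(sigmoid_count(dca, 7.0, 0.5) * (sep >= 2))
  e_burial <- model$burial_eps * mean((nb - model$burial_target)^2)

  energy_breakdown(c(lj = unname(e_lj), hbond = e_hb, contact = e_contact,
                     burial = e_burial, water = e_water))
}
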