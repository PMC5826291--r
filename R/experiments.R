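# End-to-end desk-scale experiment: assemble a grafted pore, run Langevin
# dynamics, and reduce the trajectory to density summaries.

#' Grafted-pore density experiment
#'
#' Assembles a pore grafted with `seq`, minimizes, runs Langevin dynamics
#' and returns central and pore-average densities plus the radial profile.
#' This is the desk-scale analogue of the production density pipeline:
#' small pores, reduced chain counts, truncated constructs.
#'
#' @param seq a [nup_sequence()]
#' @param diameter pore diameter, nm
#' @param spacing grafting distance, nm (larger than the production 5.7 nm
#'   reduces the chain count to desk scale)
#' @param n_steps integration steps
#' @param seed RNG seed (controls assembly and dynamics)
#' @param box simulation box, nm
#' @param timestep,friction integrator parameters
#' @param central_r radius of the central region, nm
#' @param ff a [force_field()]
#' @return one-row tibble: `central_density`, `pore_density` (mg/ml),
#'   `central_number`, `pore_number` (beads/nm^3 scaled like mg/ml at unit
#'   mass), `n_chains`, `n_beads`, plus the `profile` list-column
#' @export
grafted_pore_density <- function(seq, diameter = 16, spacing = 10,
                                 n_steps = 100000, seed = 1,
                                 box = c(40, 40, 70), timestep = 0.015,
                                 friction = 0.05, central_r = 4,
                                 ff = force_field()) {
  geom <- pore_geometry(diameter, box = box)
  an <- build_anchors(geom, spacing)
  sys <- assemble_system(geom, an, seq, seed = seed)
  sys <- minimize_system(sys, ff, max_iter = 200, force_tol = 100)
  cfg <- simulation_config(n_steps = n_steps, timestep = timestep,
                           friction = friction, stride = max(1000, n_steps %/% 100),
                           equil_fraction = 0.5, ramp_fraction = 0.05,
                           seed = seed + 500)
  tr <- run_dynamics(sys, cfg, ff)
  g <- accumulate_grid(tr)
  gN <- accumulate_grid(tr, masses = rep(1, nrow(sys$beads)))
  tibble(
    central_density = central_density(g, r_max = central_r),
    pore_density = pore_mean_density(g, diameter),
    central_number = central_density(gN, r_max = central_r),
    pore_number = pore_mean_density(gN, diameter),
    n_chains = nrow(an$sites),
    n_beads = nrow(sys$beads),
    profile = list(radial_profile(g, "pore")$profile)
  )
}
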