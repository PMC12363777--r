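# Cellular Potts core: Hamiltonian evaluation, Metropolis dynamics,
# crowding pressure.

#' Energy change of a single pixel-copy attempt
#'
#' Computes the exact change in total effective energy if the owner of
#' `target_px` were overwritten by the owner of `source_px`, evaluated
#' incrementally: contact energies over the target pixel's 8-neighbourhood,
#' volume and surface constraint terms of the two affected cells, the
#' chemotaxis term \eqn{-\mu (c_{target} - c_{source})} of the invading
#' cell on the EGF field, and adhesion-spring changes from the COM shift.
#'
#' @param state A `cornea_state`.
#' @param config A `cornea_config` (energy parameters).
#' @param source_px,target_px Integer `c(x, y)` lattice coordinates in the
#'   0-based convention used throughout (x in `0..width-1`, y in
#'   `0..height-1`, y = 0 at the stromal bottom); must be 8-neighbours with
#'   different, non-frozen owners.
#' @return The energy change (a scalar).
#' @export
delta_hamiltonian <- function(state, config, source_px, target_px) {
  stopifnot(inherits(state, "cornea_state"))
  fp <- flatten_params(config)
  cpp_delta_h(state_for_cpp(state), fp$potts, fp$rules, config$egf,
              as.integer(source_px), as.integer(target_px))
}

#' Run Metropolis pixel-copy dynamics only
#'
#' Performs `n_mcs` Monte Carlo Steps of pure pixel-copy dynamics (no
#' growth, differentiation, mitosis, sloughing or field updates). In each
#' MCS, N copy attempts are made (N = number of non-frozen lattice sites),
#' each picking a random eligible target pixel and a random 8-neighbour as
#' source; the copy is accepted when it lowers the energy, and with
#' Boltzmann probability `exp(-dH/T)` otherwise. One MCS corresponds to
#' 6 minutes of biological time.
#'
#' @param state A `cornea_state`.
#' @param config A `cornea_config`.
#' @param n_mcs Number of Monte Carlo Steps.
#' @param seed Integer seed for the run's RNG stream.
#' @return A list: updated `state`, `attempts`, `accepts`.
#' @export
metropolis_mcs <- function(state, config, n_mcs = 1L, seed = 1L) {
  res <- engine_call(state, config, n_mcs = n_mcs, seed = seed,
                     sample_every = 0L,
                     enable = enable_flags(metropolis = TRUE))
  list(state = res$state, attempts = res$attempts, accepts = res$accepts)
}

#' Crowding pressure of a growth-competent cell
#'
#' The effective pressure inside a cell is its volume-constraint response:
#' `P = max(0, lambda_v * (target_volume - volume))`. Cells prevented by
#' crowding from reaching their target volume report high pressure;
#' overshoot is clamped to zero so it does not stimulate growth.
#'
#' @param volume Current volume (pixels).
#' @param target_volume Target volume (pixels).
#' @param lambda_volume Volume-constraint stiffness of the cell's type.
#' @return Pressure (non-negative scalar, vectorized).
#' @export
#' @examples
#' compute_pressure(25, 30, 2)   # 10
#' compute_pressure(32, 30, 2)   # 0: overshoot does not push growth
compute_pressure <- function(volume, target_volume, lambda_volume) {
  pmax(0, lambda_volume * (target_volume - volume))
}

#' Count fragmented cells
#'
#' Cell connectivity is not enforced by the dynamics; this diagnostic
#' reports how many cells currently own a non-8-connected pixel set.
#'
#' @param state A `cornea_state`.
#' @return Integer count.
#' @export
count_fragmented <- function(state) cpp_count_fragmented(state$owner)
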