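# Reaction-diffusion scalar fields (EGF and toxicant).

#' Per-pixel diffusion coefficient map
#'
#' The diffusion coefficient of a field varies with the owning cell type:
#' a barrier value in superficial cells (tight junctions) and in the
#' central basement membrane, zero in the limbal membrane (impermeable) and
#' in the wall columns, and the global coefficient everywhere else.
#'
#' @param state A `cornea_state`.
#' @param field_params Field parameter list (e.g. `config$egf`), with
#'   `d_global`, `d_super`, `d_memb`, `d_limb`.
#' @return Numeric matrix of per-pixel coefficients (voxel^2/MCS).
#' @export
diffusion_coefficient_map <- function(state, field_params) {
  type_of_id <- integer(state$next_id)
  type_of_id[state$cells$id + 1L] <- state$cells$type
  cpp_diffusion_map(state$owner, type_of_id,
                    field_params$d_global, field_params$d_super,
                    field_params$d_memb, field_params$d_limb)
}

#' Advance a scalar field by whole Monte Carlo Steps
#'
#' Integrates diffusion with spatially varying coefficient (harmonic-mean
#' face fluxes), first-order decay, Dirichlet clamps and the lattice
#' boundary conditions (zero concentration at top and bottom rows under
#' `boundary = "paper"`, no-flux everywhere under `"noflux"`). The solver
#' is operator-split implicit and unconditionally stable for any
#' coefficient; concentrations never become negative.
#'
#' With pure decay (`D = 0`) one MCS multiplies the field by
#' `(1 + kd/(2 n_sub))^(-2 n_sub)`, within `kd^2/(4 n_sub)` of the
#' continuous factor `exp(-kd)`.
#'
#' @param conc Concentration matrix (width x height).
#' @param state A `cornea_state` supplying the owner grid.
#' @param field_params Field parameter list (`config$egf` or `config$tox`).
#' @param n_mcs Number of MCS to advance (default 1).
#' @return Updated concentration matrix.
#' @export
step_field <- function(conc, state, field_params, n_mcs = 1L) {
  dmap <- diffusion_coefficient_map(state, field_params)
  clamp <- matrix(FALSE, nrow = nrow(conc), ncol = ncol(conc))
  if (isTRUE(field_params$clamp_tear)) {
    tear_ids <- state$cells$id[state$cells$type == TYPES[["TEAR"]]]
    clamp[state$owner %in% tear_ids] <- TRUE
  }
  cpp_step_field(conc, dmap, field_params$decay, as.integer(n_mcs),
                 as.integer(field_params$n_sub), clamp,
                 field_params$clamp_value,
                 identical(field_params$boundary, "paper"))
}

#' Mean field concentration over a cell
#'
#' Arithmetic mean of a concentration field over the pixels owned by one
#' cell; this is the quantity driving the EGF-dependent growth response.
#'
#' @param conc Concentration matrix.
#' @param state A `cornea_state`.
#' @param cell_id Id of a live cell.
#' @return Scalar mean concentration.
#' @export
average_over_cell <- function(conc, state, cell_id) {
  if (!cell_id %in% state$cells$id) stop("cell ", cell_id, " is not alive")
  mean(conc[state$owner == cell_id])
}
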