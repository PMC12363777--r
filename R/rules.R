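# Biological rule engine: growth, mitosis, differentiation, sloughing.

#' EGF-dependent growth activation
#'
#' Hill response of proliferation to the cell's mean EGF concentration:
#' `EGF^4 / (km^4 + EGF^4)`. Half-maximal at `km`, saturating to 1.
#'
#' @param egf_avg Mean EGF concentration over the cell (non-negative).
#' @param km Half-saturation constant (same units as the field).
#' @param n Hill exponent (default 4).
#' @return Growth fraction in `[0, 1]` (vectorized).
#' @export
#' @examples
#' growth_egf(0, 0.3)      # 0
#' growth_egf(0.3, 0.3)    # 0.5
growth_egf <- function(egf_avg, km, n = 4L) {
  if (any(egf_avg < 0)) stop("EGF concentration must be non-negative")
  r <- (egf_avg / km)^n
  r / (1 + r)
}

#' Density-dependent growth inhibition
#'
#' Inverted Hill response to crowding pressure:
#' `km^4 / (km^4 + P^4)`; equals 1 for an unconstrained cell and falls
#' monotonically as pressure builds.
#'
#' @param pressure Crowding pressure (see [compute_pressure()]).
#' @param km Half-inhibition pressure.
#' @param n Hill exponent (default 4).
#' @return Growth fraction in `[0, 1]` (vectorized).
#' @export
#' @examples
#' growth_density(0, 8)    # 1
#' growth_density(8, 8)    # 0.5
growth_density <- function(pressure, km, n = 4L) {
  if (any(pressure < 0)) stop("pressure must be non-negative")
  r <- (pressure / km)^n
  1 / (1 + r)
}

#' Apply one MCS of growth to all stem and basal cells
#'
#' Each growth-competent cell's target volume advances by
#' `delta * G_density(P) * G_EGF(EGF)`, where `delta` is the intrinsic
#' maximal growth rate (25 px per 80 MCS, i.e. a minimum doubling interval
#' of 8 hours). Other cell types are unchanged.
#'
#' @param state A `cornea_state`.
#' @param config A `cornea_config`.
#' @return Updated `cornea_state`.
#' @export
apply_growth <- function(state, config) {
  engine_call(state, config, n_mcs = 1L, seed = 0L, sample_every = 0L,
              enable = enable_flags(growth = TRUE))$state
}

#' Attempt mitosis of one cell
#'
#' A stem or basal cell that has reached double its initial volume (50
#' pixels) splits along a cleavage line through its centre of mass: stem
#' cells divide with the plane normal along x so daughters separate
#' centripetally; basal cells use a uniformly random orientation. Daughter
#' volumes are within one pixel of half the parent's; target volumes reset
#' to the actual daughter volumes; both inherit the parent's type. Below
#' the threshold the call is a no-op.
#'
#' @param state A `cornea_state`.
#' @param config A `cornea_config`.
#' @param cell_id Id of the candidate cell.
#' @param seed RNG seed for the cleavage orientation.
#' @return List with the updated `state` and `daughters` (two ids, or NULL
#'   if no division occurred).
#' @export
attempt_mitosis <- function(state, config, cell_id, seed = 1L) {
  fp <- flatten_params(config)
  res <- cpp_divide(state_for_cpp(state), fp$potts, fp$rules,
                    as.integer(cell_id), as.integer(seed))
  res$state$cells <- as.data.frame(res$state$cells)
  res$state$config <- config
  if (is.null(state$tox)) res$state$tox <- NULL
  class(res$state) <- "cornea_state"
  res
}

#' Apply the contact-driven differentiation rules once
#'
#' Transitions applied simultaneously from a snapshot of the contact
#' relation (8-neighbourhood): a stem cell with no limbal-membrane contact
#' becomes basal; a basal cell whose membrane contact area has diminished
#' to at most `omega_contact_basal` boundary pixels becomes a wing cell; a
#' wing cell becomes superficial when its neighbour set contains tear film
#' and wing cells but no basal, stem, or central-membrane contact (the
#' apical position). Transitions are deterministic, immediate, and only
#' ever run forward (stem to basal to wing to superficial).
#'
#' @param state A `cornea_state`.
#' @param config A `cornea_config`.
#' @return Updated `cornea_state`.
#' @export
differentiate <- function(state, config) {
  engine_call(state, config, n_mcs = 1L, seed = 0L, sample_every = 0L,
              enable = enable_flags(differentiation = TRUE))$state
}

#' Apply one MCS of probabilistic sloughing
#'
#' Every superficial cell currently in contact with the tear film
#' independently draws `u ~ U(0,1)` and is shed when
#' `u < 1/(3 * day_to_mcs)` (1/720 per MCS, i.e. a mean tear-exposed
#' lifetime of 3 days). Shed cells are removed and their pixels converted
#' to tear film.
#'
#' @param state A `cornea_state`.
#' @param config A `cornea_config`.
#' @param seed RNG seed.
#' @return Updated `cornea_state`.
#' @export
slough <- function(state, config, seed = 1L) {
  engine_call(state, config, n_mcs = 1L, seed = seed, sample_every = 0L,
              enable = enable_flags(slough = TRUE))$state
}
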