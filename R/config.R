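# Simulation configuration: defaults, validation, YAML round-trip.
#
# Printed model constants (lattice 200x90 voxels of 4 um^2, 6 min/MCS,
# D_global = 186 voxel^2/MCS, kd = 0.5/MCS, barrier D = 20 in superficial
# cells and central membrane, 0 in limbal membrane, omega_contact = 5 px,
# 25/50 px division volumes, 240 MCS/day, slough probability 1/720) are
# fixed defaults here. Energies and Hill constants are calibrated values
# (tagged "calibrated" below): they are chosen so the emergent tissue shows
# stable ~50 um stratification, uniform thickness, 7/14-day peripheral and
# limbal turnover and depth-graded chemical injury, and are not taken from
# any printed table.

default_contact_energies <- function() {
  J <- matrix(25, nrow = 11, ncol = 11, dimnames = list(TYPE_NAMES, TYPE_NAMES))
  set <- function(a, b, v) {
    J[a, b] <<- v
    J[b, a] <<- v
  }
  epi <- EPITHELIAL
  # all pairwise energies below are calibrated against the emergent tissue
  # (stable stratification, flat apical monolayer, no fragmentation); low J
  # means strong adhesion
  for (a in epi) for (b in epi) set(a, b, 7)          # baseline cell-cell adhesion
  set("STEM", "STEM", 5)                              # niche cohesion
  set("BASAL", "BASAL", 7)
  set("WING", "WING", 6)
  set("SUPER", "SUPER", 4)                            # cohesive apical sheet
  set("SUPER", "WING", 8)    # mild repulsion: superficial cells sort upward
  set("SUPER", "BASAL", 12)
  # tear interfaces: the apical surface wets the tear; deeper types avoid it
  set("STEM", "TEAR", 14)
  set("BASAL", "TEAR", 8)
  set("WING", "TEAR", 30)    # wings hide behind the superficial sheet
  set("SUPER", "TEAR", 12)   # finite tension keeps the surface smooth
  for (a in epi) set(a, "AIR", 40)                    # strong air avoidance
  set("TEAR", "AIR", 4)
  # basement-membrane adhesion hierarchy: stem/basal cells wet the membrane,
  # suprabasal types are expelled from it
  set("STEM", "LIMB", 1)
  set("STEM", "MEMB", 2)
  set("BASAL", "LIMB", 2)
  set("BASAL", "MEMB", 1)
  for (a in c("WING", "SUPER")) {
    set(a, "LIMB", 30)
    set(a, "MEMB", 30)
  }
  for (a in epi) set(a, "DMG", 14)   # weak adhesion on damaged membrane
  for (a in epi) set(a, "STROMA", 30)
  set("STEM", "WALL", 30)
  set("BASAL", "WALL", 30)
  set("WING", "WALL", 15)
  set("SUPER", "WALL", 15)
  set("TEAR", "LIMB", 12)
  set("TEAR", "MEMB", 12)
  set("TEAR", "DMG", 12)
  set("TEAR", "STROMA", 20)
  set("TEAR", "WALL", 15)
  set("AIR", "WALL", 0)
  set("AIR", "TEAR", 4)
  J
}

#' Build a simulation configuration
#'
#' Returns the full nested configuration with the model's standard constants
#' as defaults; any element can be overridden through `...` using the same
#' nesting, e.g. `cornea_config(potts = list(temperature = 15))`. Unknown
#' keys are rejected.
#'
#' Sections: `geometry` (lattice and tissue layout, voxel = 2 um),
#' `potts` (contact-energy table `J`, constraint stiffnesses, temperature,
#' chemotaxis coefficients, adhesion springs), `rules` (growth Hill
#' constants, division volumes, differentiation contact threshold, slough
#' probability), `egf` and `tox` (reaction-diffusion fields), `run`
#' (sampling cadence, replicate seeds).
#'
#' @param ... Named nested overrides merged over the defaults.
#' @return A list of class `cornea_config`.
#' @export
#' @examples
#' cfg <- cornea_config()
#' cfg$egf$d_global          # 186 voxel^2/MCS
#' cfg2 <- cornea_config(potts = list(temperature = 15))
cornea_config <- function(...) {
  lam_v <- setNames(numeric(11), TYPE_NAMES)
  lam_v[EPITHELIAL] <- 2                              # calibrated
  lam_s <- setNames(numeric(11), TYPE_NAMES)
  lam_s[EPITHELIAL] <- 0.5                            # calibrated
  lam_s[c("STEM", "BASAL")] <- 0.8
  sfac <- setNames(rep(4, 11), TYPE_NAMES)
  sfac[c("STEM", "BASAL")] <- 6.5   # calibrated: flat cells wetting the membrane
  mu <- setNames(numeric(11), TYPE_NAMES)
  # calibrated: basal cells chemotax up EGF gradients; this drives the
  # centripetal colonization front and post-injury wound closure
  mu["BASAL"] <- 600

  cfg <- list(
    geometry = list(
      width = 200L, height = 90L, pixel_um = 2,
      limbal_width = 40L,          # 80 um limbal zone; peripheral = the rest
      stroma_rows = 45L,
      tear_thickness = 4L,         # 8 um, within the 5-10 um tear film range
      stem_width = 5L, stem_height = 5L
    ),
    potts = list(
      J = default_contact_energies(),
      lambda_volume = lam_v,
      lambda_surface = lam_s,
      surface_factor = sfac,
      chemotaxis_mu = mu,
      temperature = 6,                                # calibrated
      lambda_link = 0,             # adhesion springs inert by default
      link_rest = 0
    ),
    rules = list(
      km_egf = 0.088,                                 # calibrated
      km_egf_stem = 0.128,   # calibrated: stem cells cycle more slowly
      km_density = 8,                                 # calibrated
      hill_n = 4L,
      delta_max = 25 / 80,         # 8 h minimum doubling: 25 px per 80 MCS
      init_volume = 25L,
      mitosis_volume = 50L,
      omega_contact_basal = 5L,
      day_to_mcs = 240L,
      slough_prob = 1 / (3 * 240)
    ),
    egf = list(
      d_global = 186, d_super = 20, d_memb = 20, d_limb = 0,
      decay = 0.5, n_sub = 10L, clamp_tear = TRUE, clamp_value = 1,
      boundary = "paper"
    ),
    tox = list(
      d_global = 30, d_super = 20, d_memb = 20, d_limb = 0,  # calibrated
      decay = 0.05, n_sub = 10L, clamp_tear = FALSE, clamp_value = 0,
      boundary = "paper",
      kill_threshold = 0.14                           # calibrated
    ),
    run = list(
      sample_every = 10L,
      seed = 1L,
      replicates = 3L
    )
  )
  overrides <- list(...)
  if (length(overrides)) cfg <- merge_config(cfg, overrides, path = "")
  cfg <- normalize_config(cfg)
  validate_config(cfg)
  class(cfg) <- "cornea_config"
  cfg
}

# Recursive merge that refuses keys absent from the defaults.
merge_config <- function(base, override, path) {
  if (is.null(names(override)) || any(!nzchar(names(override))))
    stop("configuration overrides must be fully named (at '", path, "')")
  for (k in names(override)) {
    if (!k %in% names(base))
      stop("unknown configuration key: '", paste0(path, k), "'")
    bv <- base[[k]]
    ov <- override[[k]]
    if (is.list(bv) && !is.data.frame(bv)) {
      if (!is.list(ov))
        stop("configuration key '", paste0(path, k), "' must be a list")
      base[[k]] <- merge_config(bv, ov, paste0(path, k, "$"))
    } else {
      base[[k]] <- ov
    }
  }
  base
}

normalize_config <- function(cfg) {
  g <- cfg$geometry
  for (k in c("width", "height", "limbal_width", "stroma_rows",
              "tear_thickness", "stem_width", "stem_height"))
    cfg$geometry[[k]] <- as.integer(g[[k]])
  for (k in c("hill_n", "init_volume", "mitosis_volume", "omega_contact_basal",
              "day_to_mcs"))
    cfg$rules[[k]] <- as.integer(cfg$rules[[k]])
  cfg$egf$n_sub <- as.integer(cfg$egf$n_sub)
  cfg$tox$n_sub <- as.integer(cfg$tox$n_sub)
  cfg$run$sample_every <- as.integer(cfg$run$sample_every)
  cfg$run$seed <- as.integer(cfg$run$seed)
  cfg$run$replicates <- as.integer(cfg$run$replicates)
  J <- as.matrix(cfg$potts$J)
  if (!identical(dim(J), c(11L, 11L)))
    stop("contact-energy table J must be 11 x 11")
  dimnames(J) <- list(TYPE_NAMES, TYPE_NAMES)
  storage.mode(J) <- "double"
  cfg$potts$J <- J
  for (k in c("lambda_volume", "lambda_surface", "chemotaxis_mu",
              "surface_factor")) {
    v <- as.numeric(cfg$potts[[k]])
    if (length(v) == 1 && k == "surface_factor") v <- rep(v, 11)
    if (length(v) != 11) stop("potts$", k, " must have one entry per type")
    cfg$potts[[k]] <- setNames(v, TYPE_NAMES)
  }
  cfg
}

validate_config <- function(cfg) {
  g <- cfg$geometry
  p <- cfg$potts
  r <- cfg$rules
  if (g$width < 20 || g$height < 20)
    stop("lattice must be at least 20 x 20 voxels")
  if (g$limbal_width <= 0 || g$limbal_width >= g$width)
    stop("limbal zone width must lie inside the lattice: limbal + peripheral ",
         "widths must equal the lattice width")
  if (g$stroma_rows + 1 + g$stem_height + g$tear_thickness + 2 > g$height)
    stop("geometry does not fit the lattice height")
  if (!isTRUE(all.equal(p$J, t(p$J))))
    stop("contact-energy table J must be symmetric")
  if (p$temperature <= 0) stop("temperature must be positive")
  if (any(p$lambda_volume < 0) || any(p$lambda_surface < 0))
    stop("constraint stiffnesses must be non-negative")
  if (r$hill_n != 4L) stop("both growth Hill functions use exponent 4")
  if (r$mitosis_volume != 2L * r$init_volume)
    stop("mitosis volume must be twice the initial volume")
  if (r$slough_prob <= 0 || r$slough_prob >= 1)
    stop("slough probability must lie in (0, 1)")
  for (f in c("egf", "tox")) {
    fd <- cfg[[f]]
    if (any(unlist(fd[c("d_global", "d_super", "d_memb", "d_limb")]) < 0))
      stop("diffusion coefficients must be non-negative")
    if (fd$decay < 0) stop("decay rate must be non-negative")
    if (!fd$boundary %in% c("paper", "noflux"))
      stop("field boundary must be 'paper' or 'noflux'")
  }
  if (cfg$tox$kill_threshold <= 0) stop("kill threshold must be positive")
  invisible(TRUE)
}

#' Read a configuration from a YAML file
#'
#' The file holds overrides over [cornea_config()] defaults using the same
#' nesting; the contact-energy table may be adjusted through a
#' `j_overrides` list of `{a, b, value}` entries. Unknown keys are rejected
#' with an error listing the offending key.
#'
#' @param path Path to a YAML file.
#' @return A validated `cornea_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  jov <- raw$j_overrides
  raw$j_overrides <- NULL
  cfg <- do.call(cornea_config, raw)
  if (!is.null(jov)) {
    for (ov in jov) {
      if (!all(c("a", "b", "value") %in% names(ov)))
        stop("each j_overrides entry needs fields a, b, value")
      if (!ov$a %in% TYPE_NAMES || !ov$b %in% TYPE_NAMES)
        stop("unknown cell type in j_overrides: ", ov$a, "/", ov$b)
      cfg$potts$J[ov$a, ov$b] <- ov$value
      cfg$potts$J[ov$b, ov$a] <- ov$value
    }
    validate_config(cfg)
  }
  cfg
}

#' Write a configuration to YAML
#'
#' The full normalized configuration is written (the contact table as a
#' `j_overrides` list), so `write_config()` followed by [load_config()]
#' reproduces the configuration exactly.
#'
#' @param cfg A `cornea_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "cornea_config"))
  out <- unclass(cfg)
  J <- out$potts$J
  out$potts$J <- NULL
  jov <- list()
  for (a in seq_len(11)) for (b in a:11) {
    jov[[length(jov) + 1]] <- list(a = TYPE_NAMES[a], b = TYPE_NAMES[b],
                                   value = unname(J[a, b]))
  }
  out$potts$lambda_volume <- as.list(out$potts$lambda_volume)
  out$potts$lambda_surface <- as.list(out$potts$lambda_surface)
  out$potts$chemotaxis_mu <- as.list(out$potts$chemotaxis_mu)
  out$potts$surface_factor <- as.list(out$potts$surface_factor)
  out$j_overrides <- jov
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @export
print.cornea_config <- function(x, ...) {
  g <- x$geometry
  cat("Cellular Potts configuration\n")
  cat(sprintf("  lattice: %d x %d voxels (%g um/voxel), limbal zone %d px\n",
              g$width, g$height, g$pixel_um, g$limbal_width))
  cat(sprintf("  temperature %g, lambda_v %g, EGF: D = %g (barrier %g), kd = %g\n",
              x$potts$temperature, x$potts$lambda_volume[["BASAL"]],
              x$egf$d_global, x$egf$d_super, x$egf$decay))
  cat(sprintf("  growth: km_EGF = %g, km_density = %g, delta = %g px/MCS\n",
              x$rules$km_egf, x$rules$km_density, x$rules$delta_max))
  invisible(x)
}

# A short stable hash of the configuration for run metadata (FNV-1a over
# the serialized object).
config_hash <- function(cfg) {
  raw <- as.integer(serialize(cfg, NULL, version = 2))
  h <- 17
  for (b in raw) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
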