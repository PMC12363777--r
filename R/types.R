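# Cell-type codes, kept in sync with src/engine.h.

#' Cell-type codes used on the lattice
#'
#' Integer codes identifying the agent types of the model: the four
#' epithelial types (`STEM` limbal epithelial stem cells, `BASAL`, `WING`,
#' `SUPER`ficial cells), the tear film, the two basement-membrane segments
#' (`LIMB` limbal, `MEMB` central), the stroma, lateral wall cells, damaged
#' membrane (`DMG`) and the air medium (`AIR`, owner id 0).
#'
#' @return Named integer vector mapping type names to lattice codes.
#' @export
#' @examples
#' cornea_types()
cornea_types <- function() {
  c(AIR = 0L, STEM = 1L, BASAL = 2L, WING = 3L, SUPER = 4L, TEAR = 5L,
    LIMB = 6L, MEMB = 7L, STROMA = 8L, WALL = 9L, DMG = 10L)
}

TYPES <- c(AIR = 0L, STEM = 1L, BASAL = 2L, WING = 3L, SUPER = 4L, TEAR = 5L,
           LIMB = 6L, MEMB = 7L, STROMA = 8L, WALL = 9L, DMG = 10L)
TYPE_NAMES <- names(TYPES)
EPITHELIAL <- c("STEM", "BASAL", "WING", "SUPER")

#' Convert between type codes and names
#'
#' @param code Integer lattice type code(s).
#' @param name Type name(s), e.g. `"BASAL"`.
#' @return `type_name()` gives names for codes; `type_code()` the reverse.
#' @export
type_name <- function(code) TYPE_NAMES[code + 1L]

#' @rdname type_name
#' @export
type_code <- function(name) unname(TYPES[name])

#' Rendering palette for lattice snapshots
#'
#' Colors follow the conventional rendering of the simulated tissue:
#' lilac-purple stroma, pink limbal and magenta central basement membrane,
#' rose-red stem cells, peach-orange basal, blue wing, cyan superficial
#' cells, bright-green tear film and black air.
#'
#' @return Named character vector of hex colors, one per cell type.
#' @export
cornea_palette <- function() {
  c(AIR = "#000000", STEM = "#D9405E", BASAL = "#FFB347", WING = "#3B5BDB",
    SUPER = "#00E5E5", TEAR = "#17D517", LIMB = "#FFB6C1", MEMB = "#E417E4",
    STROMA = "#B695C0", WALL = "#555555", DMG = "#7A1212")
}
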