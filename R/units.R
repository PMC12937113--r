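#' Unit conversion constants
#'
#' All internal quantities are in Hartree atomic units. Geometry files (XYZ)
#' are in Angstrom and converted on read.
#'
#' @name units
#' @keywords internal
NULL

#' Angstrom to Bohr conversion factor
#' @export
ANGSTROM_TO_BOHR <- 1.8897261254578281

#' Hartree to electronvolt conversion factor
#' @export
HARTREE_TO_EV <- 27.211386245988

`%||%` <- function(a, b) if (is.null(a)) b else a
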