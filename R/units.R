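#' Unit conversion helpers
#'
#' The package stores lengths in the units the laboratory reports them in
#' (thicknesses in micrometres, diffusivities in cm^2/s) and converts to a
#' single internal convention at solver boundaries: lengths in cm,
#' diffusivities in cm^2/h, time in h, amounts in micrograms, volumes in mL
#' (= cm^3), concentrations in ug/mL. These converters are exact and
#' round-trip to machine precision.
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
um_to_cm <- function(x) x / 1e4

#' @rdname units
#' @export
cm_to_um <- function(x) x * 1e4

#' @rdname units
#' @export
cm2s_to_cm2h <- function(x) x * 3600

#' @rdname units
#' @export
cm2h_to_cm2s <- function(x) x / 3600

#' @rdname units
#' @export
mg_to_ug <- function(x) x * 1e3

#' @rdname units
#' @export
ug_to_mg <- function(x) x / 1e3

#' @rdname units
#' @export
ul_min_mg_to_l_h <- function(x) x * 60 / 1e6
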