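#' Unit conversions
#'
#' All geometry is stored in millimetres, moduli and pressures in
#' kilopascals. Conversions between clinical (mmHg, micrometre) and
#' model (kPa, mm) units are centralized here.
#'
#' @param p Pressure values.
#' @name units
NULL

KPA_PER_MMHG <- 0.133322

#' @rdname units
#' @export
mmHg_to_kPa <- function(p) p * KPA_PER_MMHG

#' @rdname units
#' @export
kPa_to_mmHg <- function(p) p / KPA_PER_MMHG

#' @rdname units
#' @param x Lengths in micrometres (um) or millimetres (mm).
#' @export
um_to_mm <- function(x) x / 1000

#' @rdname units
#' @export
mm_to_um <- function(x) x * 1000
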