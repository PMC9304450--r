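# Unit conventions: stresses MPa (wall) / Pa (WSS, pressure traces), lengths
# mm, time s, flow mm^3/s, viscosity Pa.s internally; mmHg and cP at I/O.

#' Unit conversion helpers
#'
#' Internal units are Pa/MPa, mm, s; clinical I/O units are mmHg (pressure)
#' and cP (viscosity). 1 mmHg = 133.322 Pa; 1 cP = 1e-3 Pa.s.
#'
#' @param x numeric vector to convert.
#' @return converted numeric vector.
#' @name units
NULL

#' @rdname units
#' @export
mmhg_to_pa <- function(x) x * 133.322

#' @rdname units
#' @export
pa_to_mmhg <- function(x) x / 133.322

#' @rdname units
#' @export
cp_to_pas <- function(x) x * 1e-3

#' @rdname units
#' @export
pas_to_cp <- function(x) x * 1e3
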