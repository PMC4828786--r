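#' Unit conversion helpers
#'
#' The package works internally in a consistent mm--MPa--N system
#' (lengths mm, stresses/pressures MPa, forces N, volumes mm^3, energies
#' N*mm = mJ).  User-facing interfaces accept and emit the units customary
#' on the bench: pressures in mmHg, volumes in ml, lengths in mm.
#'
#' Conversions: 1 mmHg = 133.322 Pa = 133.322e-6 MPa; 1 atm = 760 mmHg;
#' 1 ml = 1000 mm^3.
#'
#' @param x numeric vector to convert.
#' @return numeric vector in the target unit.
#' @examples
#' mmHg_to_MPa(760)      # one atmosphere in MPa
#' ml_to_mm3(21)         # nominal balloon volume in mm^3
#' @name units
NULL

#' @rdname units
#' @export
mmHg_to_MPa <- function(x) x * 133.322e-6

#' @rdname units
#' @export
MPa_to_mmHg <- function(x) x / 133.322e-6

#' @rdname units
#' @export
atm_to_mmHg <- function(x) x * 760

#' @rdname units
#' @export
ml_to_mm3 <- function(x) x * 1000

#' @rdname units
#' @export
mm3_to_ml <- function(x) x / 1000

# internal: stop with a classed error so callers/tests can be specific
bm_stop <- function(msg, class = "balloonmech_error", call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "balloonmech_error", "error", "condition")))
}

# internal: check a scalar is a positive finite number
check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    bm_stop(sprintf("`%s` must be a positive finite number", name),
            class = "balloonmech_invalid_input")
  invisible(x)
}
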