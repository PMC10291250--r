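#' Physical constants of the measuring solution
#'
#' Viscosity and density of water at 20 degrees C, the reference temperature
#' of the conductivity measurements. The viscosity is expressed in MPa s so
#' that conductivities come out in the field's customary
#' kg m\eqn{^{-1}} MPa\eqn{^{-1}} s\eqn{^{-1}} without further conversion.
#'
#' @param eta dynamic viscosity of water, MPa s.
#' @param rho density of water, kg m\eqn{^{-3}}.
#'
#' @return An object of class `water_constants`: a list with elements `eta`
#'   and `rho`.
#' @examples
#' water_constants()
#' @export
water_constants <- function(eta = 1.002e-9, rho = 998.2) {
  stopifnot(is.numeric(eta), length(eta) == 1L, eta > 0,
            is.numeric(rho), length(rho) == 1L, rho > 0)
  structure(list(eta = eta, rho = rho), class = "water_constants")
}

#' @export
print.water_constants <- function(x, ...) {
  cat("Water constants: eta =", format(x$eta), "MPa s, rho =",
      format(x$rho), "kg m^-3\n")
  invisible(x)
}
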