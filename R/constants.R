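# Physical constants, package-wide units:
# mass g/mol, length nm, time ps (ns for transport/relaxation), time step fs,
# energy kJ/mol, temperature K.

#' Physical constants used throughout the package
#'
#' @return Named list with `kB` (Boltzmann constant, kJ/(mol K)), `xi_cubic`
#'   (dimensionless Yeh--Hummer self-term constant for a cubic box) and
#'   `avogadro` (1/mol).
#' @export
#' @examples
#' fw_constants()$kB
fw_constants <- function() {
  list(
    kB = 0.0083144621,     # kJ/(mol K)
    xi_cubic = 2.837297,   # Ewald self-term, cubic periodic box
    avogadro = 6.02214076e23
  )
}

.kB <- 0.0083144621
.xi_cubic <- 2.837297
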