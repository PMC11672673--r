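# Mass repartitioning / rescaling algebra for 3-site water.
#
# A "fast water" model is built in two exact steps: (i) repartition mass m_r
# from the oxygen to the two hydrogens symmetrically, (ii) rescale all site
# masses by a common factor so the molecular mass becomes m_tot. Configuration
# -space averages are mass-independent, so equilibrium properties are
# untouched; dynamics speed up as sqrt(M0/m_tot).

#' Site masses of a 3-site water model
#'
#' Container for the oxygen mass, hydrogen mass and molecular mass of a
#' 3-site water model. The two hydrogens are equivalent by construction.
#'
#' @param m_O oxygen site mass (g/mol), > 0
#' @param m_H hydrogen site mass (g/mol), > 0
#' @param label free-text model label
#' @return An object of class `water_masses`: list with `m_O`, `m_H`,
#'   `m_tot = m_O + 2 m_H` and `label`.
#' @export
#' @examples
#' water_masses(15.9994, 1.008, label = "TIP3P")
water_masses <- function(m_O, m_H, label = "") {
  stopifnot(is.numeric(m_O), length(m_O) == 1L, is.numeric(m_H),
            length(m_H) == 1L)
  if (!is.finite(m_O) || !is.finite(m_H) || m_O <= 0 || m_H <= 0) {
    stop("site masses must be positive and finite", call. = FALSE)
  }
  structure(
    list(m_O = m_O, m_H = m_H, m_tot = m_O + 2 * m_H,
         label = as.character(label)),
    class = "water_masses"
  )
}

#' @export
print.water_masses <- function(x, digits = 4, ...) {
  lab <- if (nzchar(x$label)) paste0(" (", x$label, ")") else ""
  cat("3-site water masses", lab, " [g/mol]\n", sep = "")
  cat(sprintf("  m_O = %s  m_H = %s  m_tot = %s\n",
              format(x$m_O, digits = digits),
              format(x$m_H, digits = digits),
              format(x$m_tot, digits = digits)))
  invisible(x)
}

#' Reference TIP3P site masses
#'
#' The unmodified TIP3P masses: m_O = 15.9994, m_H = 1.008,
#' M0 = 18.0154 g/mol.
#'
#' @return A [water_masses()] object.
#' @export
tip3p_masses <- function() water_masses(15.9994, 1.008, label = "TIP3P")

#' Repartition and rescale 3-site water masses
#'
#' Moves mass `m_r` from the oxygen to the two hydrogens (symmetrically) and
#' then rescales all site masses by `m_tot_target / M0` so the molecular mass
#' equals `m_tot_target` exactly:
#' \deqn{m_O' = (m_O - m_r)\,\frac{m_{tot}}{M_0},\qquad
#'       m_H' = (m_H + m_r/2)\,\frac{m_{tot}}{M_0}.}
#'
#' Charges and Lennard-Jones parameters are untouched; the operation only
#' affects dynamics, not configuration-space averages.
#'
#' @param m_r repartitioned mass (g/mol), `0 <= m_r < reference$m_O`
#' @param m_tot_target target molecular mass (g/mol), > 0
#' @param reference reference [water_masses()]; default TIP3P
#' @param label label for the returned model
#' @return A [water_masses()] object with full-precision masses summing to
#'   `m_tot_target` (to 1e-9 relative).
#' @seealso [round_masses()] for publication-style 3-decimal rounding,
#'   [fast_water_masses()] for the default fast model.
#' @export
#' @examples
#' repartition_and_rescale(m_r = 4, m_tot_target = 1.116)
repartition_and_rescale <- function(m_r, m_tot_target,
                                    reference = tip3p_masses(),
                                    label = "repartitioned") {
  stopifnot(inherits(reference, "water_masses"))
  if (!is.numeric(m_r) || length(m_r) != 1L || !is.finite(m_r) || m_r < 0) {
    stop("invalid spec: m_r must be a finite non-negative mass", call. = FALSE)
  }
  if (m_r >= reference$m_O) {
    stop("invalid spec: m_r >= reference oxygen mass ",
         "(oxygen mass must stay positive)", call. = FALSE)
  }
  if (!is.numeric(m_tot_target) || length(m_tot_target) != 1L ||
      !is.finite(m_tot_target) || m_tot_target <= 0) {
    stop("invalid spec: m_tot_target must be a positive mass", call. = FALSE)
  }
  s <- m_tot_target / reference$m_tot
  water_masses((reference$m_O - m_r) * s, (reference$m_H + m_r / 2) * s,
               label = label)
}

#' Round water masses for reporting, preserving the molecular mass
#'
#' Rounds the hydrogen mass to `digits` decimals and reports the oxygen mass
#' as the remainder `m_tot - 2 m_H`, so the three printed site masses sum
#' exactly to the (rounded) molecular mass. This is how the masses of a
#' published model table (and a topology file) should be quoted: a topology
#' whose site masses do not sum to the molecular mass silently changes the
#' model.
#'
#' @param masses a [water_masses()] object
#' @param digits decimals to keep (default 3)
#' @return A [water_masses()] object with rounded masses.
#' @export
#' @examples
#' round_masses(repartition_and_rescale(4, 1.116))
round_masses <- function(masses, digits = 3) {
  stopifnot(inherits(masses, "water_masses"))
  m_tot <- round(masses$m_tot, digits)
  m_H <- round(masses$m_H, digits)
  water_masses(m_tot - 2 * m_H, m_H, label = masses$label)
}

#' The default fast water model (m_r = 4, m_tot = 1.116)
#'
#' Convenience constructor for the fast TIP3P variant: 4 g/mol repartitioned
#' from oxygen to hydrogens and the molecular mass rescaled to 1.116 g/mol
#' (a factor ~16 lighter than TIP3P). With `rounded = TRUE` (default) the
#' masses are quoted to 3 decimals with the molecular mass preserved,
#' giving m_O = 0.744, m_H = 0.186.
#'
#' @param rounded quote masses to 3 decimals, total-preserving (default TRUE)
#' @return A [water_masses()] object.
#' @export
fast_water_masses <- function(rounded = TRUE) {
  m <- repartition_and_rescale(4, 1.116, label = "TIP3P-F")
  if (rounded) round_masses(m) else m
}

.check_pos <- function(...) {
  vals <- c(...)
  if (any(!is.finite(vals) | vals <= 0)) {
    stop("invalid argument: all inputs must be positive and finite",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Equivalent integration time step under mass scaling
#'
#' Scaling all masses by f^2 is equivalent to scaling time by f: a simulation
#' of water with molecular mass `m_tot` integrated at `dt` probes the same
#' per-step displacements as unscaled water (mass `m_ref`) at
#' `dt * sqrt(m_ref / m_tot)`.
#'
#' @param dt integration time step (fs), > 0
#' @param m_tot scaled molecular mass (g/mol), > 0
#' @param m_ref reference molecular mass (g/mol), default TIP3P M0
#' @return Equivalent time step (fs).
#' @export
#' @examples
#' equivalent_time_step(2, 0.5)   # ~12 fs
equivalent_time_step <- function(dt, m_tot, m_ref = tip3p_masses()$m_tot) {
  .check_pos(dt, m_tot, m_ref)
  dt * sqrt(m_ref / m_tot)
}

#' Mass that preserves stability when the time step changes
#'
#' If the integration time step is multiplied by `dt_ratio`, the molecular
#' mass must be multiplied by `dt_ratio^2` to keep per-step displacements --
#' and hence the crash rate -- unchanged.
#'
#' @param m_tot current molecular mass (g/mol), > 0
#' @param dt_ratio factor by which the time step changes, > 0
#' @return Rescaled molecular mass (g/mol).
#' @export
#' @examples
#' mass_for_time_step(1.116, 2)   # 4.464, for 4 fs steps
mass_for_time_step <- function(m_tot, dt_ratio) {
  .check_pos(m_tot, dt_ratio)
  m_tot * dt_ratio^2
}

#' Ideal mass scaling of the self-diffusion coefficient
#'
#' Under ideal time--mass equivalence the self-diffusion coefficient of neat
#' water scales as `D' = D_ref * sqrt(m_ref / m_tot)`.
#'
#' @param D_ref reference diffusion coefficient (nm^2/ns), > 0
#' @param m_ref reference molecular mass (g/mol), > 0
#' @param m_tot scaled molecular mass (g/mol), > 0
#' @return Predicted diffusion coefficient (nm^2/ns).
#' @export
ideal_diffusion_scaling <- function(D_ref, m_ref, m_tot) {
  .check_pos(D_ref, m_ref, m_tot)
  D_ref * sqrt(m_ref / m_tot)
}

#' Ideal mass scaling of the shear viscosity
#'
#' Scaling solvent masses by f^2 = m_tot/m_ref changes the viscosity by f:
#' `eta' = eta_ref * sqrt(m_tot / m_ref)`. Together with
#' [ideal_diffusion_scaling()] this leaves the Stokes--Einstein product
#' D * eta invariant.
#'
#' @param eta_ref reference viscosity, > 0 (any unit)
#' @param m_tot scaled molecular mass (g/mol), > 0
#' @param m_ref reference molecular mass (g/mol), > 0
#' @return Predicted viscosity, same unit as `eta_ref`.
#' @export
viscosity_scaling <- function(eta_ref, m_tot, m_ref) {
  .check_pos(eta_ref, m_tot, m_ref)
  eta_ref * sqrt(m_tot / m_ref)
}

#' Model card for a water-mass model
#'
#' Machine-readable summary of a mass model: full-precision and 3-decimal
#' (total-preserving) masses, the reference model, and the package version.
#'
#' @param masses a [water_masses()] object (full precision)
#' @param m_r repartitioned mass used to construct it, if known
#' @param reference reference [water_masses()]
#' @return A list suitable for JSON/YAML serialization.
#' @export
model_card <- function(masses, m_r = NA_real_, reference = tip3p_masses()) {
  stopifnot(inherits(masses, "water_masses"))
  rounded <- round_masses(masses)
  list(
    label = masses$label,
    m_O_g_mol = masses$m_O,
    m_H_g_mol = masses$m_H,
    m_tot_g_mol = masses$m_tot,
    m_O_rounded = rounded$m_O,
    m_H_rounded = rounded$m_H,
    m_r_g_mol = m_r,
    reference = list(label = reference$label, m_O_g_mol = reference$m_O,
                     m_H_g_mol = reference$m_H,
                     m_tot_g_mol = reference$m_tot),
    equivalent_time_step_fs_at_2fs =
      equivalent_time_step(2, masses$m_tot, reference$m_tot),
    ideal_diffusion_speedup = sqrt(reference$m_tot / masses$m_tot),
    ideal_viscosity_factor = sqrt(masses$m_tot / reference$m_tot),
    package = "fastwater",
    package_version = as.character(utils::packageVersion("fastwater"))
  )
}

#' Write a model card to JSON
#'
#' @param masses a [water_masses()] object
#' @param path output file path
#' @param ... passed to [model_card()]
#' @return `path`, invisibly.
#' @export
write_model_card <- function(masses, path, ...) {
  card <- model_card(masses, ...)
  jsonlite::write_json(card, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
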