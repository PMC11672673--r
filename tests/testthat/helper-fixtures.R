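# Shared fixtures and tiny oracles, all built in code.

# minimal 3-site water ITP with comments and spacing worth preserving
water_itp_lines <- function(m_O = "15.9994", m_H = "1.008") {
  c("; TIP3P-style rigid water",
    "[ moleculetype ]",
    "; molname  nrexcl",
    "SOL        2",
    "",
    "[ atoms ]",
    ";  nr  type  resnr  residue  atom  cgnr  charge    mass",
    sprintf("    1  OWT3      1      SOL    OW     1  -0.834  %s  ; oxygen",
            m_O),
    sprintf("    2  HWT3      1      SOL   HW1     1   0.417  %s", m_H),
    sprintf("    3  HWT3      1      SOL   HW2     1   0.417  %s", m_H),
    "",
    "[ settles ]",
    "; OW funct doh dhh",
    "1 1 0.09572 0.15139",
    "",
    "[ exclusions ]",
    "1 2 3",
    "2 1 3",
    "3 1 2")
}

# AR(1) series with given coefficient and innovation sd 1
ar1_series <- function(n, rho, seed) {
  set.seed(seed)
  as.numeric(stats::filter(stats::rnorm(n), rho, method = "recursive"))
}

tip3p_site_masses <- c(15.9994, 1.008, 1.008)
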