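# Physical constants, derived once from CODATA 2018 base values.
# All unit conversions in the package go through this table; nothing below
# is duplicated elsewhere.
.codata <- list(
  e_C        = 1.602176634e-19,   # elementary charge [C]
  eps0_F_m   = 8.8541878128e-12,  # vacuum permittivity [F/m]
  h_Js       = 6.62607015e-34,    # Planck constant [J s]
  c_m_s      = 2.99792458e8,      # speed of light [m/s]
  kB_J_K     = 1.380649e-23       # Boltzmann constant [J/K]
)

.eet_const <- local({
  hc_Jcm <- .codata$h_Js * .codata$c_m_s * 100  # J per cm^-1
  # Coulomb energy of two unit charges 1 Angstrom apart, in cm^-1
  coulomb_cm1 <- .codata$e_C^2 /
    (4 * pi * .codata$eps0_F_m * 1e-10) / hc_Jcm
  debye_per_eA <- .codata$e_C * 1e-10 / 1e-21 * .codata$c_m_s # 1 e*A in Debye
  hbar_cm1_s <- .codata$h_Js / (2 * pi) / hc_Jcm
  list(
    version        = "CODATA2018-1",
    coulomb_cm1_e2_ang = coulomb_cm1,          # ~1.1614e5 cm^-1 e^-2 Ang
    debye_per_e_ang    = debye_per_eA,         # ~4.8032 D per e*Ang
    dd_cm1_d2_ang3     = coulomb_cm1 / debye_per_eA^2, # dipole-dipole, cm^-1 D^-2 Ang^3
    hbar_cm1_s         = hbar_cm1_s,           # ~5.3088e-12 cm^-1 s
    rate_ps_per_cm1    = 2 * pi / hbar_cm1_s * 1e-12, # 2pi/hbar: (cm^-1)^2*(cm^-1)^-1 -> ps^-1
    kB_cm1_K           = .codata$kB_J_K / hc_Jcm      # ~0.695035 cm^-1/K
  )
})

#' Physical constants used by the package
#'
#' Returns the conversion constants the package derives once from CODATA 2018
#' base values: the Coulomb energy of two unit charges 1 Angstrom apart in
#' cm^-1 (used by the transition-charge sum), the Debye per e*Angstrom factor,
#' the dipole-dipole coupling constant in cm^-1 D^-2 Angstrom^3, hbar in
#' cm^-1 s, the `2*pi/hbar` rate prefactor expressed so that
#' (cm^-1)^2 * (cm^-1)^-1 yields ps^-1, and Boltzmann's constant in cm^-1/K.
#'
#' @return A named list of constants, including a `version` tag that output
#'   files embed so results are traceable to the constants they used.
#' @examples
#' eet_constants()$kB_cm1_K    # ~0.695035
#' @export
eet_constants <- function() .eet_const
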