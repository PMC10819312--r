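# Physical constants (CODATA) and element data used by the stopping-power and
# activation calculations. All stopping-power work is done in MeV and mg/cm^2;
# all decay math is done in hours.

.const <- list(
  me_c2_mev     = 0.51099895,      # electron rest energy
  mp_c2_mev     = 938.27208816,    # proton rest energy
  bethe_k       = 0.307075,        # 4 pi N_A r_e^2 me c^2, MeV cm^2 / mol
  e_coulomb     = 1.602176634e-19,
  n_avogadro    = 6.02214076e23,
  mb_to_cm2     = 1e-27,
  e_floor_mev   = 1.0,             # validity floor of the Bethe model here
  bohr_k_mev2   = 0.1569           # Bohr straggling constant, MeV^2 cm^2/g per (Z/A)
)

# Elements appearing in the stack materials. I is the mean excitation energy.
# "Ti48" is the isotopically pure target nuclide (same Z and I as natural Ti,
# molar mass of the single isotope).
.elements <- data.frame(
  symbol = c("H", "C", "N", "O", "Al", "Ar", "Ti", "Ti48", "Ni"),
  Z      = c(1,    6,   7,   8,   13,   18,   22,   22,     28),
  A      = c(1.008, 12.011, 14.007, 15.999, 26.9815, 39.948, 47.867, 47.9479, 58.6934),
  I_ev   = c(19.2, 78,  82,  95,  166,  188,  233,  233,    311),
  stringsAsFactors = FALSE
)

# Atomic mass excesses (MeV, AME-based) for reaction threshold computation.
.mass_excess_mev <- c(
  "Ti-48" = -48.4917,
  "Sc-47" = -44.3352,
  "Sc-46" = -41.7596,
  "Sc-44" = -37.8160,
  "Sc-43" = -36.1878,
  "V-48"  = -44.4752,
  "p"     = 7.2890,
  "n"     = 8.0713,
  "alpha" = 2.4249
)

.sc44m_excitation_mev <- 0.27124  # isomer level energy of Sc-44m

.u_target_ti48 <- 47.9479  # Ti-48 atomic mass, u
.u_proton      <- 1.00728

# Cache environment for lazily loaded fixtures.
.pkg_cache <- new.env(parent = emptyenv())
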