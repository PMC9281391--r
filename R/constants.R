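# Physical constants and per-element data pinned in-code for reproducibility.

# Boltzmann constant, eV/K
KB_EV <- 8.617333262e-5
# acceleration unit: (eV/Angstrom)/amu expressed in Angstrom/fs^2
ACC_UNIT <- 9.648533212e-3
# 1 eV/Angstrom^3 in bar
EVA3_TO_BAR <- 1.602176634e6
# amu/Angstrom^3 in g/cm^3
AMU_A3_TO_GCM3 <- 1.66053906660
# Coulomb constant e^2/(4 pi eps0), eV*Angstrom
COULOMB_EVA <- 14.399645478

# Covalent radii (Angstrom), Cordero et al. consensus values, single bond.
COVALENT_RADII <- c(
  H = 0.31, He = 0.28,
  Li = 1.28, Be = 0.96, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  Ne = 0.58, Na = 1.66, Mg = 1.41, Al = 1.21, Si = 1.11, P = 1.07, S = 1.05,
  Cl = 1.02, Ar = 1.06, K = 2.03, Ca = 1.76, Br = 1.20, I = 1.39
)

# Standard atomic masses (amu).
ATOMIC_MASSES <- c(
  H = 1.008, He = 4.0026,
  Li = 6.94, Be = 9.0122, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998, Ne = 20.180, Na = 22.990, Mg = 24.305, Al = 26.982,
  Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Ar = 39.948, K = 39.098,
  Ca = 40.078, Br = 79.904, I = 126.90
)

covalent_radius <- function(symbol) {
  r <- COVALENT_RADII[symbol]
  if (anyNA(r)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbol[is.na(r)]), collapse = ", "))
  }
  unname(r)
}

atomic_mass <- function(symbol) {
  m <- ATOMIC_MASSES[symbol]
  if (anyNA(m)) {
    stop("unknown element symbol(s): ",
         paste(unique(symbol[is.na(m)]), collapse = ", "))
  }
  unname(m)
}
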