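# Shared fixture builders. All fixtures are generated in code; independent
# physical constants used by oracles are recomputed here from CODATA base
# values, separately from the package's constants unit.

codata_coulomb_cm1 <- function() {
  # e^2/(4 pi eps0 * 1 Angstrom) expressed in cm^-1
  (1.602176634e-19)^2 / (4 * pi * 8.8541878128e-12 * 1e-10) /
    (6.62607015e-34 * 2.99792458e10)
}
codata_debye_per_eA <- function() {
  1.602176634e-19 * 1e-10 / 3.33564095198152e-30  # 1 D = 1e-21/c C m
}
codata_rate_ps_per_cm1 <- function() {
  # 2 pi / hbar with energies in cm^-1 and time in ps: (2 pi)^2 c[cm/s] 1e-12
  (2 * pi)^2 * 2.99792458e10 * 1e-12
}

rand_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# one free-standing synthetic pigment
synth_pigment <- function(id, center, axis, type = "CHL_A", chain = "A",
                          resno = 1L, separation = 1) {
  axis <- axis / sqrt(sum(axis^2))
  coords <- rbind(P1 = center + axis * separation / 2,
                  P2 = center - axis * separation / 2,
                  MG = center, NB = center - axis, ND = center + axis)
  list(id = id, chain = chain, resno = as.integer(resno), resid = "CLA",
       type = type, atom_coords = coords, center = center, qy_axis = axis)
}

# pigment set of n pigments at given centers/axes
synth_set <- function(centers, axes, types = "CHL_A", separation = 1) {
  n <- nrow(centers)
  types <- rep_len(types, n)
  pigs <- lapply(seq_len(n), function(i)
    synth_pigment(sprintf("%s:%d:CLA", LETTERS[i], i), centers[i, ],
                  axes[i, ], types[i], LETTERS[i], i, separation))
  pigment_set(pigs, source = "test", provenance = "test")
}

# minimal hand-written PDB text (fixed-width records)
pdb_line <- function(serial, name, alt, resn, chain, resno, x, y, z, occ,
                     elem) {
  sprintf("HETATM%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resn, chain, resno, x, y, z, occ, 0, elem)
}

# random lineshape parameter draw (spectral region, widths and shifts that
# bracket the chlorophyll regime)
rand_lineshape <- function() {
  lineshape_params(omega0 = stats::runif(1, 12000, 18000),
                   fwhm = stats::runif(1, 80, 600),
                   stokes = stats::runif(1, 0, 400))
}

# exhaustive simple-path enumeration oracle (independent of igraph)
enumerate_paths <- function(tau, source, target, max_steps) {
  ids <- rownames(tau)
  out <- list()
  recurse <- function(path) {
    cur <- path[length(path)]
    if (length(path) - 1L > max_steps) return()
    if (cur == target && length(path) > 1L) {
      out[[length(out) + 1L]] <<- path
      return()
    }
    if (length(path) - 1L == max_steps) return()
    for (nxt in setdiff(ids, path)) {
      if (is.finite(tau[cur, nxt])) recurse(c(path, nxt))
    }
  }
  recurse(source)
  out
}
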