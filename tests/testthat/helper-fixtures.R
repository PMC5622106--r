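# Shared fixture builders for the test suite. Everything is generated
# in code; no binary fixtures.

# A minimal hand-written PDB file with the given chains; each chain
# gets `n_res` alanine residues (N, CA, C per residue), offset so
# chains do not overlap. `order` controls the block order in the
# file, so duplicated entries create non-contiguous chain blocks.
write_tiny_pdb <- function(chains, n_res = 3, path = tempfile(fileext = ".pdb"),
                           order = seq_along(chains)) {
  lines <- character(0)
  serial <- 0
  for (bi in order) {
    ch <- chains[bi]
    zoff <- 10 * bi
    for (i in seq_len(n_res)) {
      for (at in c("N", "CA", "C")) {
        serial <- serial + 1
        xoff <- c(N = -1.2, CA = 0, C = 1.2)[[at]]
        lines <- c(lines, sprintf(
          "ATOM  %5d  %-3s ALA %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %1s",
          serial, at, ch, i, i * 3.8 + xoff, 0, zoff,
          substr(at, 1, 1)))
      }
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

# An Asp/Lys salt-bridge toy structure a controlled distance apart,
# with the backbone (and hence the two termini sites) well away from
# the bridge. Returns the file path.
toy_salt_bridge <- function(separation = 4, path = tempfile(fileext = ".pdb")) {
  generate_toy_structure(c("ASP", "LYS"),
                         rbind(c(0, 0, 0), c(separation, 0, 0)),
                         file = path)
}

# Independent 4-state partition-function oracle for one acid + one
# base coupled by a single interaction energy W (kJ/mol), evaluated
# at a given pH. Returns list(prot = c(acid, base), dG).
four_state_oracle <- function(pKa_acid, pKa_base, W, pH, RT) {
  states <- expand.grid(pa = 0:1, pb = 0:1)
  E <- log(10) * RT * (pH - pKa_acid) * states$pa +
    log(10) * RT * (pH - pKa_base) * states$pb +
    W * (states$pa - 1) * states$pb
  w <- exp(-E / RT)
  Ef <- log(10) * RT * (pH - pKa_acid) * states$pa +
    log(10) * RT * (pH - pKa_base) * states$pb
  wf <- exp(-Ef / RT)
  list(prot = c(sum(states$pa * w), sum(states$pb * w)) / sum(w),
       dG = -RT * (log(sum(w)) - log(sum(wf))))
}

# Analytic accessible area of two overlapping spheres of expanded
# radii r1, r2 with centres d apart: per-sphere accessible area after
# removing the buried spherical cap.
two_sphere_area <- function(r1, r2, d) {
  if (d >= r1 + r2) return(c(4 * pi * r1^2, 4 * pi * r2^2))
  x1 <- (d^2 + r1^2 - r2^2) / (2 * d)
  h1 <- r1 - x1
  h2 <- r2 - (d - x1)
  c(4 * pi * r1^2 - 2 * pi * r1 * h1, 4 * pi * r2^2 - 2 * pi * r2 * h2)
}

# A one-atom pdb-like object for closed-form checks, built through
# bio3d so atom_sasa sees a normal structure.
single_atom_pdb <- function(xyz = c(0, 0, 0), elety = "CA", elesy = "C",
                            n = 1, sep = 100) {
  path <- tempfile(fileext = ".pdb")
  lines <- vapply(seq_len(n), function(i) sprintf(
    "ATOM  %5d  %-3s ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
    i, elety, i, xyz[1] + (i - 1) * sep, xyz[2], xyz[3], elesy), character(1))
  writeLines(c(lines, "END"), path)
  bio3d::read.pdb(path, verbose = FALSE)
}

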