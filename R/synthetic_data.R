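# Generators for synthetic fixtures: Fab-like heavy/light chain pairs
# carrying the interdomain motifs at controlled positions (with
# coarse-grained 3-D structures), toy charged structures with
# ionisable groups at controlled coordinates, reference populations
# with known property moments, and IgSF-like cohorts of composition
# vectors with planted CH1-like members. Every generator is a pure
# function of its arguments and seed.

# Representative composition profiles used by the cohort generator.
# CL-like: a generic immunoglobulin constant-domain composition.
# CH1-like: enriched in P, S, T, V, G and depleted in D, E, F, I, Q,
# R, Y relative to CL, and concentrated enough that its composition
# entropy sits well below the CL/background level - the composition
# signature the scan is designed to detect.
.CL_PROFILE <- c(A = 0.07, C = 0.02, D = 0.05, E = 0.04, F = 0.04,
                 G = 0.07, H = 0.02, I = 0.04, K = 0.07, L = 0.08,
                 M = 0.015, N = 0.04, P = 0.05, Q = 0.05, R = 0.045,
                 S = 0.09, T = 0.08, V = 0.07, W = 0.015, Y = 0.045)
.CH1_PROFILE <- c(A = 0.07, C = 0.005, D = 0.015, E = 0.015, F = 0.01,
                  G = 0.10, H = 0.005, I = 0.015, K = 0.08, L = 0.06,
                  M = 0.005, N = 0.03, P = 0.12, Q = 0.02, R = 0.01,
                  S = 0.16, T = 0.15, V = 0.12, W = 0.005, Y = 0.01)

.norm_profile <- function(p) p / sum(p)

.rand_seq <- function(n, profile = rep(1 / 20, 20)) {
  paste(sample(AA20, n, replace = TRUE, prob = profile), collapse = "")
}

#' Generate paired Fab-like heavy/light chain sequences with planted
#' interdomain motifs
#'
#' Each heavy chain carries exactly one `VS[SA]` motif whose first
#' residue lies at the requested in-window position (the sampling
#' alphabet inside the search window excludes the letters that could
#' seed a spurious match); each light chain carries one `E[LIV]KR` or
#' `TVL[GSA]` motif likewise. Chain lengths are drawn from the
#' quartile bands observed for real Fab datasets (heavy 219-228,
#' light 213-218) unless overridden.
#'
#' @param n number of pairs.
#' @param heavy_motif_pos,light_motif_pos 1-based motif start
#'   positions, recycled over records; must lie inside the search
#'   windows (heavy 110-130, light 100-115).
#' @param light_motif `"ELKR"`-family or `"TVLG"`-family per record
#'   (`"E"` / `"T"`), recycled; default all `"E"`.
#' @param heavy_lengths,light_lengths inclusive length ranges.
#' @param seed RNG seed.
#' @return list of `n` lists with `heavy`, `light` (strings),
#'   `heavy_split`, `light_split`.
#' @export
generate_fab_sequences <- function(n, heavy_motif_pos = 118,
                                   light_motif_pos = 105,
                                   light_motif = "E",
                                   heavy_lengths = c(219, 228),
                                   light_lengths = c(213, 218),
                                   seed = 1) {
  hw <- FAB_MOTIFS$heavy$window; lw <- FAB_MOTIFS$light$window
  heavy_motif_pos <- rep_len(as.integer(heavy_motif_pos), n)
  light_motif_pos <- rep_len(as.integer(light_motif_pos), n)
  light_motif <- rep_len(light_motif, n)
  if (any(heavy_motif_pos < hw[1] | heavy_motif_pos > hw[2]))
    stop("heavy motif position outside window ", hw[1], "-", hw[2])
  if (any(light_motif_pos < lw[1] | light_motif_pos > lw[2]))
    stop("light motif position outside window ", lw[1], "-", lw[2])
  set.seed(seed)
  scrub <- function(seq, window, banned) {
    # resample window positions from an alphabet that cannot seed a
    # motif match starting inside the window
    chars <- strsplit(seq, "")[[1]]
    idx <- window[1]:min(window[2], length(chars))
    chars[idx] <- sample(setdiff(AA20, banned), length(idx), replace = TRUE)
    paste(chars, collapse = "")
  }
  plant <- function(seq, pos, motif) {
    paste0(substr(seq, 1, pos - 1), motif,
           substr(seq, pos + nchar(motif), nchar(seq)))
  }
  lapply(seq_len(n), function(i) {
    hl <- sample(heavy_lengths[1]:heavy_lengths[2], 1)
    ll <- sample(light_lengths[1]:light_lengths[2], 1)
    h <- scrub(.rand_seq(hl), hw, "V")
    h <- plant(h, heavy_motif_pos[i], paste0("VS", sample(c("S", "A"), 1)))
    l <- scrub(.rand_seq(ll), lw, c("E", "T"))
    lm <- if (light_motif[i] == "E")
      paste0("E", sample(c("L", "I", "V"), 1), "KR")
    else paste0("TVL", sample(c("G", "S", "A"), 1))
    l <- plant(l, light_motif_pos[i], lm)
    list(heavy = h, light = l,
         heavy_split = heavy_motif_pos[i], light_split = light_motif_pos[i])
  })
}

# ---- PDB writing helpers (text format) ------------------------------

.pdb_atom_line <- function(serial, name, resid, chain, resno, x, y, z,
                           element) {
  name4 <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, name4, resid, chain, resno, x, y, z, element)
}

.AA_1TO3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE",
              G = "GLY", H = "HIS", I = "ILE", K = "LYS", L = "LEU",
              M = "MET", N = "ASN", P = "PRO", Q = "GLN", R = "ARG",
              S = "SER", T = "THR", V = "VAL", W = "TRP", Y = "TYR")

# charged-group atoms added next to the CA of ionisable residues in
# coarse-grained synthetic structures (offsets in Angstrom from CA)
.SIDECHAIN_ATOMS <- list(
  ASP = list(OD1 = c(0.6, 0, 1.5), OD2 = c(-0.6, 0, 1.5)),
  GLU = list(OE1 = c(0.6, 0, 1.5), OE2 = c(-0.6, 0, 1.5)),
  LYS = list(NZ = c(0, 0, 1.5)), ARG = list(CZ = c(0, 0, 1.5)),
  HIS = list(ND1 = c(0.6, 0, 1.5), NE2 = c(-0.6, 0, 1.5)),
  TYR = list(OH = c(0, 0, 1.5)), CYS = list(SG = c(0, 0, 1.5)))

.element_of <- function(name) substr(gsub("[0-9]", "", name), 1, 1)

# lattice coordinates for m residues, spacing s, block anchored at
# `origin`; returns an m x 3 matrix
.lattice_coords <- function(m, s = 5.5, origin = c(0, 0, 0)) {
  k <- ceiling(m^(1 / 3))
  g <- as.matrix(expand.grid(x = 0:(k - 1), y = 0:(k - 1), z = 0:(k - 1)))
  g <- g[seq_len(m), , drop = FALSE] * s
  sweep(g, 2, origin, "+")
}

#' Generate a coarse-grained synthetic Fab structure
#'
#' Builds a PDB-format structure for one heavy/light pair: chains H
#' and L, one CA atom per residue on a compact lattice (one block per
#' domain), plus the charged-group atoms of ionisable residues so
#' that electrostatic sites are well defined. The domain layout
#' emulates the Fab architecture as it matters for the interface
#' calculations: the CL:CH1 blocks sit closer together than the
#' VL:VH blocks (so the constant-domain interface buries more
#' surface), and the lattice assignment turns the CH1 face basic and
#' the CL face acidic (salt-bridging across the constant-domain
#' interface). Variable-domain residues are placed in sequence order.
#'
#' @param pair one element of [generate_fab_sequences()] output.
#' @param pdb_id identifier used for the file name.
#' @param file output path; default `tempfile()`.
#' @param spacing lattice spacing, Angstrom.
#' @param gap_c,gap_v interface gaps for CL:CH1 and VL:VH, Angstrom.
#' @return the file path (invisibly readable with
#'   [load_fab_structure()]).
#' @export
generate_fab_structure <- function(pair, pdb_id = "SYNFAB",
                                   file = tempfile(fileext = ".pdb"),
                                   spacing = 5.5, gap_c = 4.5, gap_v = 6.5) {
  hs <- pair$heavy_split; ls <- pair$light_split
  doms <- list(
    VH = strsplit(substr(pair$heavy, 1, hs - 1), "")[[1]],
    CH1 = strsplit(substr(pair$heavy, hs, nchar(pair$heavy)), "")[[1]],
    VL = strsplit(substr(pair$light, 1, ls - 1), "")[[1]],
    CL = strsplit(substr(pair$light, ls, nchar(pair$light)), "")[[1]])
  k <- ceiling(max(lengths(doms))^(1 / 3))
  w <- (k - 1) * spacing  # block width
  origins <- list(VH = c(0, 0, 0), VL = c(w + gap_v, 0, 0),
                  CH1 = c(0, 0, w + 30), CL = c(w + gap_c, 0, w + 30))
  coords <- list()
  for (d in names(doms)) {
    m <- length(doms[[d]])
    pts <- .lattice_coords(m, spacing, origins[[d]])
    ord <- seq_len(m)
    if (d == "CH1") {
      # basic residues take the highest-x lattice points (face CL)
      rank_pts <- order(-pts[, 1], pts[, 2], pts[, 3])
      charged <- which(doms[[d]] %in% c("K", "R"))
      ord <- integer(m)
      ord[charged] <- rank_pts[seq_along(charged)]
      ord[-charged] <- rank_pts[-seq_along(charged)]
      if (!length(charged)) ord <- rank_pts
    } else if (d == "CL") {
      # acidic residues take the lowest-x lattice points (face CH1)
      rank_pts <- order(pts[, 1], pts[, 2], pts[, 3])
      charged <- which(doms[[d]] %in% c("D", "E"))
      ord <- integer(m)
      ord[charged] <- rank_pts[seq_along(charged)]
      ord[-charged] <- rank_pts[-seq_along(charged)]
      if (!length(charged)) ord <- rank_pts
    }
    coords[[d]] <- pts[ord, , drop = FALSE]
  }
  lines <- character(0); serial <- 0L
  emit_chain <- function(chain, dom_names) {
    resno <- 0L
    for (d in dom_names) {
      aa <- doms[[d]]
      for (i in seq_along(aa)) {
        resno <- resno + 1L
        res3 <- .AA_1TO3[[aa[i]]]
        ca <- coords[[d]][i, ]
        serial <<- serial + 1L
        lines <<- c(lines, .pdb_atom_line(serial, "N", res3, chain, resno,
                                          ca[1] - 1.2, ca[2] + 0.8, ca[3],
                                          "N"))
        serial <<- serial + 1L
        lines <<- c(lines, .pdb_atom_line(serial, "CA", res3, chain, resno,
                                          ca[1], ca[2], ca[3], "C"))
        serial <<- serial + 1L
        lines <<- c(lines, .pdb_atom_line(serial, "C", res3, chain, resno,
                                          ca[1] + 1.2, ca[2] + 0.8, ca[3],
                                          "C"))
        sc <- .SIDECHAIN_ATOMS[[res3]]
        if (!is.null(sc)) for (an in names(sc)) {
          serial <<- serial + 1L
          p <- ca + sc[[an]]
          lines <<- c(lines, .pdb_atom_line(serial, an, res3, chain, resno,
                                            p[1], p[2], p[3],
                                            .element_of(an)))
        }
      }
    }
  }
  emit_chain("H", c("VH", "CH1"))
  emit_chain("L", c("VL", "CL"))
  writeLines(c(lines, "END"), file)
  file
}

#' Generate a synthetic Fab structure dataset
#'
#' Writes `n` coarse-grained Fab structures (see
#' [generate_fab_structure()]) with motif positions sampled inside
#' the search windows, and returns the ground truth.
#'
#' @param n number of Fabs.
#' @param dir output directory (created if needed).
#' @param seed RNG seed.
#' @param ... passed to [generate_fab_sequences()].
#' @return data.frame: file, pdb_id, heavy_split, light_split.
#' @export
generate_fab_dataset <- function(n, dir = tempfile("fabset"), seed = 1, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  hw <- FAB_MOTIFS$heavy$window; lw <- FAB_MOTIFS$light$window
  hp <- sample(hw[1]:hw[2], n, replace = TRUE)
  lp <- sample(lw[1]:lw[2], n, replace = TRUE)
  lm <- sample(c("E", "T"), n, replace = TRUE, prob = c(0.85, 0.15))
  pairs <- generate_fab_sequences(n, heavy_motif_pos = hp,
                                  light_motif_pos = lp, light_motif = lm,
                                  seed = seed + 1L, ...)
  ids <- sprintf("SYNFAB%03d", seq_len(n))
  files <- character(n)
  for (i in seq_len(n))
    files[i] <- generate_fab_structure(pairs[[i]], ids[i],
                                       file.path(dir, paste0(ids[i], ".pdb")))
  data.frame(file = files, pdb_id = ids, heavy_split = hp, light_split = lp,
             stringsAsFactors = FALSE)
}

#' Generate a toy structure with ionisable groups at controlled
#' positions
#'
#' Writes a PDB-format file with one residue per requested site. Each
#' ionisable residue's charged-group atoms are placed so their
#' centroid lands exactly on the requested coordinate; `ALA` entries
#' act as neutral spacers. Backbone N/CA/C atoms are laid down next
#' to each site (the chain termini therefore contribute their usual
#' two sites).
#'
#' @param types character vector of residue types (3-letter: ASP,
#'   GLU, LYS, ARG, HIS, TYR, CYS, ALA).
#' @param coords numeric matrix (length(types) x 3) of target
#'   charged-group centroids, Angstrom.
#' @param file output path; default `tempfile()`.
#' @param chain chain id per site (recycled; default "A").
#' @return the file path.
#' @export
generate_toy_structure <- function(types, coords,
                                   file = tempfile(fileext = ".pdb"),
                                   chain = "A") {
  coords <- matrix(coords, ncol = 3)
  stopifnot(length(types) == nrow(coords), all(is.finite(coords)))
  if (nrow(coords) > 1) {
    d <- stats::dist(coords)
    if (any(d == 0)) stop("coincident sites")
  }
  chain <- rep_len(chain, length(types))
  lines <- character(0); serial <- 0L
  add <- function(name, res3, ch, resno, p) {
    serial <<- serial + 1L
    lines <<- c(lines, .pdb_atom_line(serial, name, res3, ch, resno,
                                      p[1], p[2], p[3], .element_of(name)))
  }
  resno <- 0L
  for (i in seq_along(types)) {
    resno <- resno + 1L
    res3 <- toupper(types[i])
    c0 <- coords[i, ]
    base <- c0 + c(0, 2.5, 0)  # backbone sits beside the charged group
    add("N", res3, chain[i], resno, base + c(-0.7, 0.5, 0))
    add("CA", res3, chain[i], resno, base)
    add("C", res3, chain[i], resno, base + c(0.7, 0.5, 0))
    sc <- .SIDECHAIN_ATOMS[[res3]]
    if (!is.null(sc)) {
      ctr <- colMeans(do.call(rbind, sc))
      off <- lapply(sc, function(o) o - ctr)  # centre the group on c0
      for (an in names(off)) add(an, res3, chain[i], resno, c0 + off[[an]])
    }
  }
  writeLines(c(lines, "END"), file)
  file
}

#' Merge two single-subunit PDB-format files into one dimer file
#'
#' Concatenates the ATOM records of `a` and `b` with renumbered
#' serials, so the result contains exactly the atoms of the two
#' subunits and satisfies the preconditions of the dimer subtraction
#' schemes.
#'
#' @param a,b paths to PDB-format files.
#' @param file output path.
#' @return the output path.
#' @export
merge_structures <- function(a, b, file = tempfile(fileext = ".pdb")) {
  take <- function(p) grep("^ATOM  ", readLines(p), value = TRUE)
  lines <- c(take(a), take(b))
  lines <- vapply(seq_along(lines), function(i)
    paste0(substr(lines[i], 1, 6), formatC(i, width = 5),
           substr(lines[i], 12, nchar(lines[i]))), character(1))
  writeLines(c(lines, "END"), file)
  file
}

#' Generate a reference population with controlled property moments
#'
#' Builds `n` sequences whose K-R values are drawn from a normal
#' distribution with the requested mean and standard deviation
#' (realised by construction: the lysine/arginine count difference of
#' each sequence is set from its drawn value), with the remaining
#' residues sampled from a Dirichlet-perturbed background profile.
#' When an entropy target is given, the background concentration is
#' calibrated by monotone search so the population mean entropy
#' approaches it; a target above `log2(20)` bits is infeasible and an
#' error.
#'
#' @param n number of sequences (>= 30).
#' @param k_minus_r `c(mu, sigma)` in percentage points; sigma > 0.
#' @param entropy_mean optional target mean entropy (bits).
#' @param length_range inclusive sequence-length range.
#' @param seed RNG seed.
#' @return list with `sequences` (list of `domain_sequence`) and
#'   `population` (a `reference_population` fitted to them).
#' @export
generate_reference_population <- function(n = 1000,
                                          k_minus_r = c(mu = 0, sigma = 3),
                                          entropy_mean = NULL,
                                          length_range = c(150, 350),
                                          seed = 1) {
  stopifnot(n >= 30, k_minus_r[2] > 0)
  if (!is.null(entropy_mean)) {
    if (entropy_mean > log2(20) || entropy_mean <= 0)
      stop("infeasible entropy target: must be in (0, log2(20)]")
  }
  set.seed(seed)
  other <- setdiff(AA20, c("K", "R"))
  make_seq <- function(L, t, conc) {
    d <- round(t * L / 100)
    nK <- max(0L, as.integer(round(0.05 * L + d / 2)))
    nR <- max(0L, nK - as.integer(d))
    nK <- nR + as.integer(d)          # keep the difference exact
    if (nK < 0) { nK <- 0L; nR <- as.integer(-d) }
    rest <- L - nK - nR
    prof <- stats::rgamma(length(other), shape = conc / length(other))
    prof <- prof / sum(prof)
    body <- sample(other, rest, replace = TRUE, prob = prof)
    paste(sample(c(rep("K", nK), rep("R", nR), body)), collapse = "")
  }
  mean_entropy_at <- function(conc, m = 40) {
    mean(vapply(seq_len(m), function(i) {
      L <- sample(length_range[1]:length_range[2], 1)
      sequence_entropy(make_seq(L, stats::rnorm(1, k_minus_r[1],
                                                k_minus_r[2]), conc))
    }, numeric(1)))
  }
  conc <- 90  # background concentration (sum of Dirichlet parameters)
  if (!is.null(entropy_mean)) {
    lo <- 0.5; hi <- 5000
    if (mean_entropy_at(hi) < entropy_mean - 0.02)
      stop("infeasible entropy target for these sequence lengths")
    for (it in 1:30) {
      conc <- sqrt(lo * hi)
      e <- mean_entropy_at(conc)
      if (abs(e - entropy_mean) < 0.01) break
      if (e < entropy_mean) lo <- conc else hi <- conc
    }
  }
  lens <- sample(length_range[1]:length_range[2], n, replace = TRUE)
  targets <- stats::rnorm(n, k_minus_r[1], k_minus_r[2])
  seqs <- lapply(seq_len(n), function(i)
    domain_sequence(sprintf("REF%05d", i),
                    make_seq(lens[i], targets[i], conc)))
  list(sequences = seqs,
       population = fit_reference_population(seqs, provenance = "synthetic"))
}

#' Cohort specification for the synthetic IgSF generator
#'
#' @param n_background,n_planted class sizes.
#' @param length_range inclusive domain-length range.
#' @param conc_background,conc_planted Dirichlet concentrations (sum
#'   of parameters) for per-domain profile noise around the class
#'   profile.
#' @param mix planted-class position along the CL-to-CH1 profile
#'   direction (1 = the CH1-like profile itself).
#' @param seed RNG seed.
#' @export
cohort_spec <- function(n_background = 200, n_planted = 5,
                        length_range = c(85, 110),
                        conc_background = 200, conc_planted = 400,
                        mix = 1.0, seed = 1) {
  stopifnot(n_background >= 0, n_planted >= 0, conc_background > 0,
            conc_planted > 0, mix >= 0)
  structure(list(n_background = n_background, n_planted = n_planted,
                 length_range = length_range,
                 conc_background = conc_background,
                 conc_planted = conc_planted, mix = mix, seed = seed),
            class = "cohort_spec")
}

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  g / sum(g)
}

#' Generate a synthetic IgSF cohort with planted CH1-like members
#'
#' Background domains are drawn around a near-uniform composition
#' profile (high sequence entropy, composition deviation from CL in a
#' random direction); planted domains are drawn around a profile
#' obtained by moving from the CL-like profile along the fixed
#' CL-to-CH1 direction (low entropy, composition deviation aligned
#' with CH1's). The emitted CH1/CL reference compositions are the
#' class profiles, so the planted class is constructed to satisfy
#' the scan's cosine and entropy thresholds by design.
#'
#' @param spec a [cohort_spec()].
#' @return list with `domains` (list of `domain_sequence`, shuffled
#'   order), `truth` (data.frame id/planted), `ch1_ref`, `cl_ref`
#'   (`composition_vector`s), `spec`.
#' @export
generate_igsf_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  cl <- .norm_profile(.CL_PROFILE)
  ch1 <- .norm_profile(.CH1_PROFILE)
  planted_profile <- .norm_profile(pmax(cl + spec$mix * (ch1 - cl), 1e-4))
  bg_profile <- rep(1 / 20, 20); names(bg_profile) <- AA20
  n <- spec$n_background + spec$n_planted
  planted_flag <- c(rep(FALSE, spec$n_background), rep(TRUE, spec$n_planted))
  ord <- sample(n)
  planted_flag <- planted_flag[ord]
  domains <- vector("list", n)
  for (i in seq_len(n)) {
    L <- sample(spec$length_range[1]:spec$length_range[2], 1)
    prof <- if (planted_flag[i])
      .rdirichlet1(spec$conc_planted * planted_profile)
    else .rdirichlet1(spec$conc_background * bg_profile)
    id <- sprintf("SYNIG%04d:%d-%d", i, 1L, L)
    domains[[i]] <- domain_sequence(id, .rand_seq(L, prof), region = "IgSF")
  }
  as_comp <- function(p) structure(list(fractions = p, n_residues = NA_integer_),
                                   class = "composition_vector")
  list(domains = domains,
       truth = data.frame(id = vapply(domains, `[[`, character(1), "id"),
                          planted = planted_flag, stringsAsFactors = FALSE),
       ch1_ref = as_comp(ch1), cl_ref = as_comp(cl), spec = spec)
}

#' Write a domain-sequence list as FASTA
#' @param domains list of `domain_sequence`.
#' @param path output FASTA path.
#' @export
write_domains_fasta <- function(domains, path) {
  seqinr::write.fasta(lapply(domains, `[[`, "sequence"),
                      vapply(domains, `[[`, character(1), "id"), path)
  invisible(path)
}
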