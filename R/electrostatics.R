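# Debye-Hueckel continuum electrostatics for ionisable-group
# contributions to folded-state stability and dimerisation, with
# exact partition-function enumeration for small systems and
# Metropolis Monte Carlo protonation-state sampling (with
# thermodynamic integration over a coupling parameter) for large
# ones.

#' @useDynLib fabdomains, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Physical constants (SI)
.E_CHARGE <- 1.602176634e-19   # C
.N_AVOGADRO <- 6.02214076e23   # 1/mol
.EPS0 <- 8.8541878128e-12      # F/m
.KBOLTZ <- 1.380649e-23        # J/K
.R_GAS <- 8.31446261815324e-3  # kJ/mol/K

# e^2 N_A / (4 pi eps0), in kJ * Angstrom / mol: the Coulomb energy of
# two unit charges 1 A apart in vacuum.
COULOMB_KJ_A <- .E_CHARGE^2 * .N_AVOGADRO / (4 * pi * .EPS0) * 1e10 / 1e3

#' Model pKa values for ionisable groups
#'
#' Intrinsic (unperturbed) pKas assigned to each ionisable group type;
#' the interaction model shifts apparent pKas away from these.
#' @export
MODEL_PKA <- c(ASP = 4.0, GLU = 4.4, HIS = 6.3, LYS = 10.4, ARG = 12.0,
               TYR = 9.6, CYS = 8.3, Nterm = 7.5, Cterm = 3.8)

.ACID_TYPES <- c("ASP", "GLU", "TYR", "CYS", "Cterm")

# charged-group atoms per ionisable residue type
.CHARGE_ATOMS <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                      LYS = "NZ", ARG = "CZ", HIS = c("ND1", "NE2"),
                      TYR = "OH", CYS = "SG")

#' Solvent model for screened-Coulomb electrostatics
#'
#' Water-like continuum with relative dielectric `epsilon_r` and
#' Debye screening constant kappa derived from the ionic strength:
#' `kappa^2 = 2 e^2 N_A * 1000 I / (eps0 epsilon_r kB T)`.
#'
#' @param epsilon_r relative dielectric (default 78.4, water).
#' @param ionic_strength mol/L (default 0.15, physiological).
#' @param temperature K (default 298.15).
#' @return a `solvent_model` with `kappa` in 1/Angstrom.
#' @export
solvent_model <- function(epsilon_r = 78.4, ionic_strength = 0.15,
                          temperature = 298.15) {
  stopifnot(epsilon_r > 0, ionic_strength >= 0, temperature > 0)
  kappa_m <- sqrt(2 * .E_CHARGE^2 * .N_AVOGADRO * 1000 * ionic_strength /
                    (.EPS0 * epsilon_r * .KBOLTZ * temperature))
  structure(list(epsilon_r = epsilon_r, ionic_strength = ionic_strength,
                 temperature = temperature, kappa = kappa_m * 1e-10,
                 RT = .R_GAS * temperature),
            class = "solvent_model")
}

#' @export
print.solvent_model <- function(x, ...) {
  cat(sprintf(
    "<solvent_model> eps_r = %.1f, I = %.3f M, T = %.2f K, kappa = %.4f 1/A\n",
    x$epsilon_r, x$ionic_strength, x$temperature, x$kappa))
  invisible(x)
}

#' Screened-Coulomb pair interaction energy
#'
#' Debye-Hueckel interaction between two unit charges a distance `r`
#' apart in the solvent continuum:
#' `W = C exp(-kappa r) / (epsilon_r r)` with
#' `C = e^2 N_A / (4 pi eps0)` in kJ A / mol. Multiply by the charge
#' product `q_i q_j` for the energy of an actual pair. Distances below
#' `min_dist` are clamped (with a warning): the point-charge continuum
#' model is not meaningful at sub-contact separations.
#'
#' @param r distance in Angstrom (vectorised).
#' @param solvent a [solvent_model()].
#' @param min_dist clamp distance, Angstrom (default 2).
#' @return kJ/mol per unit-charge product.
#' @export
pair_energy <- function(r, solvent = solvent_model(), min_dist = 2.0) {
  if (any(r == 0)) stop("coincident sites (r = 0)")
  if (any(r < min_dist)) {
    warning(sprintf("%d distance(s) below %.1f A clamped", sum(r < min_dist),
                    min_dist))
    r[r < min_dist] <- min_dist
  }
  COULOMB_KJ_A * exp(-solvent$kappa * r) / (solvent$epsilon_r * r)
}

#' Make an ionisable-site table by hand
#'
#' For toy systems and tests: builds the same `ionizable_sites`
#' data.frame that [extract_ionizable_sites()] derives from a
#' structure.
#'
#' @param type character vector over the types named in [MODEL_PKA].
#' @param x,y,z coordinates (Angstrom).
#' @param pka optional model pKa overrides (defaults per type).
#' @export
ionizable_sites <- function(type, x, y, z, pka = NULL) {
  if (length(type) == 0L)
    return(structure(data.frame(label = character(0), type = character(0),
                                x = numeric(0), y = numeric(0),
                                z = numeric(0), pKa = numeric(0),
                                is_acid = logical(0)),
                     class = c("ionizable_sites", "data.frame")))
  type <- match.arg(type, names(MODEL_PKA), several.ok = TRUE)
  if (is.null(pka)) pka <- MODEL_PKA[type]
  stopifnot(all(is.finite(c(x, y, z))), all(pka > 0 & pka < 14))
  structure(data.frame(label = paste0(type, "_", seq_along(type)),
                       type = type, x = x, y = y, z = z,
                       pKa = as.numeric(pka),
                       is_acid = type %in% .ACID_TYPES,
                       stringsAsFactors = FALSE),
            class = c("ionizable_sites", "data.frame"))
}

#' Extract ionisable sites from a structure
#'
#' One site per ionisable residue (Asp, Glu, His, Lys, Arg, Tyr, Cys)
#' plus the two chain termini of every chain. Each site is placed at
#' the centroid of its charged-group atoms (Asp OD1/OD2, Glu OE1/OE2,
#' Lys NZ, Arg CZ, His ND1/NE2, Tyr OH, Cys SG; termini at the N / C
#' backbone atoms). When the charged-group atoms are absent (reduced
#' representations, missing density) the residue centroid is used
#' with a warning. Cysteines whose SG atoms are within 2.5 A of
#' another SG are taken as disulphide-bonded and excluded from
#' titration.
#'
#' @param pdb a `bio3d` pdb object or a PDB-format file path.
#' @param model_pka named pKa table (default [MODEL_PKA]).
#' @return an `ionizable_sites` data.frame.
#' @export
extract_ionizable_sites <- function(pdb, model_pka = MODEL_PKA) {
  if (is.character(pdb)) pdb <- bio3d::read.pdb(pdb, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("empty structure")
  out <- list()
  fallback <- character(0)
  # disulphide detection over all SG atoms
  sg <- at[at$resid == "CYS" & at$elety == "SG", , drop = FALSE]
  ss_keys <- character(0)
  if (nrow(sg) >= 2) {
    d <- as.matrix(stats::dist(sg[, c("x", "y", "z")]))
    diag(d) <- Inf
    bonded <- apply(d < 2.5, 1, any)
    ss_keys <- paste(sg$chain, sg$resno, sg$insert)[bonded]
  }
  for (ch in unique(at$chain)) {
    ca <- at[at$chain == ch, , drop = FALSE]
    key <- paste(ca$chain, ca$resno, ca$insert)
    ukeys <- unique(key)
    for (k in seq_along(ukeys)) {
      rows <- ca[key == ukeys[k], , drop = FALSE]
      rtype <- rows$resid[1]
      if (rtype %in% names(.CHARGE_ATOMS) &&
          !(rtype == "CYS" && ukeys[k] %in% ss_keys)) {
        sel <- rows[rows$elety %in% .CHARGE_ATOMS[[rtype]], , drop = FALSE]
        if (nrow(sel) == 0L) { sel <- rows; fallback <- c(fallback, ukeys[k]) }
        out[[length(out) + 1L]] <- data.frame(
          label = paste0(ch, rows$resno[1], "_", rtype), type = rtype,
          x = mean(sel$x), y = mean(sel$y), z = mean(sel$z),
          stringsAsFactors = FALSE)
      }
      if (k == 1L) {
        nat <- rows[rows$elety == "N", , drop = FALSE]
        if (nrow(nat) == 0L) nat <- rows[1, , drop = FALSE]
        out[[length(out) + 1L]] <- data.frame(
          label = paste0(ch, rows$resno[1], "_Nterm"), type = "Nterm",
          x = nat$x[1], y = nat$y[1], z = nat$z[1], stringsAsFactors = FALSE)
      }
      if (k == length(ukeys)) {
        cat_ <- rows[rows$elety == "C", , drop = FALSE]
        if (nrow(cat_) == 0L) cat_ <- rows[nrow(rows), , drop = FALSE]
        out[[length(out) + 1L]] <- data.frame(
          label = paste0(ch, rows$resno[1], "_Cterm"), type = "Cterm",
          x = cat_$x[1], y = cat_$y[1], z = cat_$z[1],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(fallback))
    warning("charged-group atoms missing for ", length(fallback),
            " residue(s); residue centroid used: ",
            paste(fallback, collapse = ", "))
  sites <- do.call(rbind, out)
  sites$pKa <- as.numeric(model_pka[sites$type])
  sites$is_acid <- sites$type %in% .ACID_TYPES
  structure(sites, class = c("ionizable_sites", "data.frame"))
}

#' Pairwise interaction matrix for a site set
#' @inheritParams pair_energy
#' @param sites an `ionizable_sites` data.frame.
#' @return symmetric N x N matrix (kJ/mol per unit-charge product),
#'   zero diagonal.
#' @export
site_interaction_matrix <- function(sites, solvent = solvent_model(),
                                    min_dist = 2.0) {
  n <- nrow(sites)
  W <- matrix(0, n, n)
  if (n < 2) return(W)
  d <- as.matrix(stats::dist(sites[, c("x", "y", "z")]))
  if (any(d[upper.tri(d)] == 0)) stop("coincident sites")
  W[upper.tri(W)] <- pair_energy(d[upper.tri(d)], solvent, min_dist)
  W[lower.tri(W)] <- t(W)[lower.tri(W)]
  W
}

.titration_result <- function(pH, protonation, se = NULL, pKa_app, dG, dG_se,
                              method) {
  structure(list(pH = pH, protonation = protonation, se = se,
                 pKa = pKa_app, dG_charge = dG, dG_se = dG_se,
                 method = method),
            class = "titration_result")
}

#' @export
print.titration_result <- function(x, ...) {
  cat(sprintf("<titration_result> %s, %d site(s); dG_charge(pH 7) = %.3f kJ/mol",
              x$method, ncol(x$protonation), x$dG_charge))
  if (!is.null(x$dG_se) && is.finite(x$dG_se))
    cat(sprintf(" (SE %.3f)", x$dG_se))
  cat("\n")
  invisible(x)
}

# apparent pKa: pH of half-protonation, linearly interpolated on the grid
.interp_pka <- function(pH, prot) {
  apply(prot, 2, function(p) {
    below <- which(p <= 0.5)
    if (!length(below)) return(NA_real_)
    i <- below[1]
    if (i == 1L) {
      # half-protonation at or before the first grid point
      return(if (abs(p[1] - 0.5) < 1e-9) pH[1] else NA_real_)
    }
    pH[i - 1] + (0.5 - p[i - 1]) * (pH[i] - pH[i - 1]) / (p[i] - p[i - 1])
  })
}

#' Exact titration by enumeration of protonation microstates
#'
#' Sums the Boltzmann weights of all `2^N` protonation microstates.
#' The energy of microstate `x` is
#' `sum_i ln(10) RT (pH - pKa_i) prot_i(x) + sum_{i<j} W_ij q_i q_j`
#' with `q_i = prot_i - [site i is an acid]`, so an isolated site
#' recovers the Henderson-Hasselbalch curve. The ionisable-group
#' interaction free energy is `dG_charge(pH) = -RT ln(Z / Z_free)`
#' where `Z_free` sets all `W_ij = 0` (the non-interacting,
#' unfolded-state reference).
#'
#' @param sites an `ionizable_sites` data.frame.
#' @param solvent a [solvent_model()].
#' @param pH_grid pH values for the titration curves (pH 7 is always
#'   evaluated for `dG_charge`).
#' @param cap maximum N for exact enumeration (default 20).
#' @param min_dist passed to [site_interaction_matrix()].
#' @return a `titration_result`.
#' @export
enumerate_titration <- function(sites, solvent = solvent_model(),
                                pH_grid = seq(0, 14, by = 0.25), cap = 20,
                                min_dist = 2.0) {
  n <- nrow(sites)
  if (n > cap)
    stop(n, " sites exceeds exact-enumeration cap ", cap,
         "; use mc_titration()")
  pH_grid <- sort(unique(c(pH_grid, 7.0)))
  if (n == 0L)
    return(.titration_result(pH_grid,
                             matrix(0, length(pH_grid), 0), NULL,
                             numeric(0), 0, 0, "exact"))
  W <- site_interaction_matrix(sites, solvent, min_dist)
  RT <- solvent$RT
  m <- 0:(2^n - 1)
  S <- vapply(seq_len(n), function(j) as.numeric(bitwAnd(m, 2^(j - 1)) > 0),
              numeric(length(m)))
  S <- matrix(S, ncol = n)
  Q <- sweep(S, 2, as.numeric(sites$is_acid))
  E_int <- 0.5 * rowSums((Q %*% W) * Q)
  prot <- matrix(NA_real_, length(pH_grid), n)
  dG <- numeric(length(pH_grid))
  for (k in seq_along(pH_grid)) {
    cideal <- log(10) * RT * (pH_grid[k] - sites$pKa)
    E_id <- as.numeric(S %*% cideal)
    a <- -(E_id + E_int) / RT
    a0 <- max(a)
    w <- exp(a - a0)
    logZ <- a0 + log(sum(w))
    af <- -E_id / RT
    af0 <- max(af)
    logZf <- af0 + log(sum(exp(af - af0)))
    prot[k, ] <- colSums(S * w) / sum(w)
    dG[k] <- -RT * (logZ - logZf)
  }
  res <- .titration_result(pH_grid, prot, NULL, .interp_pka(pH_grid, prot),
                           dG[pH_grid == 7.0], 0, "exact")
  res$dG_curve <- dG
  res
}

#' Monte Carlo titration with thermodynamic integration
#'
#' Metropolis sampling of protonation microstates (single-site flips
#' plus paired flips for strongly coupled sites). Mean protonations
#' carry batch-means standard errors. `dG_charge(pH 7)` is obtained
#' by thermodynamic integration of the mean interaction energy over a
#' coupling parameter lambda scaling all `W_ij`, on a uniform
#' lambda ladder (trapezoidal rule). Reproducible for a fixed seed.
#'
#' @inheritParams enumerate_titration
#' @param n_sweeps,n_equil total and equilibration sweeps per run.
#' @param seed integer seed (set via `set.seed`).
#' @param lambdas coupling ladder in \[0,1\] (default 5 points).
#' @param pair_threshold kJ/mol; site pairs with `|W_ij|` above it get
#'   paired flip moves.
#' @param se_tol flag non-convergence when the `dG` standard error
#'   exceeds this (kJ/mol).
#' @return a `titration_result` with `method = "monte_carlo"`,
#'   protonation standard errors and `dG_se`; `converged` is FALSE
#'   when `dG_se > se_tol`.
#' @export
mc_titration <- function(sites, solvent = solvent_model(),
                         pH_grid = seq(0, 14, by = 0.25),
                         n_sweeps = 8000, n_equil = 1000, seed = 1,
                         lambdas = seq(0, 1, length.out = 5),
                         pair_threshold = 2.0, se_tol = 1.0,
                         min_dist = 2.0) {
  stopifnot(n_sweeps > n_equil, n_equil > 0)
  n <- nrow(sites)
  pH_grid <- sort(unique(c(pH_grid, 7.0)))
  if (n == 0L)
    return(.titration_result(pH_grid, matrix(0, length(pH_grid), 0), NULL,
                             numeric(0), 0, 0, "monte_carlo"))
  W <- site_interaction_matrix(sites, solvent, min_dist)
  RT <- solvent$RT
  set.seed(seed)
  prot <- matrix(NA_real_, length(pH_grid), n)
  se <- matrix(NA_real_, length(pH_grid), n)
  for (k in seq_along(pH_grid)) {
    r <- mc_protonation_kernel(W, sites$pKa, sites$is_acid, pH_grid[k], RT,
                               1.0, n_sweeps, n_equil, pair_threshold, 20L)
    prot[k, ] <- r$mean_prot
    se[k, ] <- r$se_prot
  }
  # thermodynamic integration at pH 7
  eint <- numeric(length(lambdas)); eint_se <- numeric(length(lambdas))
  for (k in seq_along(lambdas)) {
    r <- mc_protonation_kernel(W, sites$pKa, sites$is_acid, 7.0, RT,
                               lambdas[k], n_sweeps, n_equil,
                               pair_threshold, 20L)
    eint[k] <- r$mean_eint
    eint_se[k] <- r$se_eint
  }
  h <- diff(lambdas)
  wts <- numeric(length(lambdas))
  wts[1] <- h[1] / 2
  wts[length(wts)] <- h[length(h)] / 2
  if (length(wts) > 2)
    wts[2:(length(wts) - 1)] <- (h[-length(h)] + h[-1]) / 2
  dG <- sum(wts * eint)
  dG_se <- sqrt(sum((wts * eint_se)^2))
  res <- .titration_result(pH_grid, prot, se, .interp_pka(pH_grid, prot),
                           dG, dG_se, "monte_carlo")
  res$converged <- dG_se <= se_tol
  if (!res$converged)
    warning(sprintf("MC dG standard error %.2f exceeds tolerance %.2f kJ/mol",
                    dG_se, se_tol))
  res
}

#' Ionisable-group contribution to folded-state stability at pH 7
#'
#' The interaction free energy of the structure's ionisable groups at
#' pH 7 relative to the non-interacting (unfolded-state) reference;
#' negative values mean the charge network stabilises the fold. Uses
#' exact enumeration up to `cap` sites, Monte Carlo beyond.
#'
#' @param structure a bio3d pdb object, PDB file path, or an
#'   `ionizable_sites` table.
#' @param solvent a [solvent_model()].
#' @param pH evaluated at 7.0 (fixed reporting pH).
#' @param cap exact-enumeration cap.
#' @param ... passed to [mc_titration()] (seed, sweeps, ladder).
#' @return kJ/mol, with attributes `method`, `n_sites`, `se`.
#' @export
charge_folding_energy <- function(structure, solvent = solvent_model(),
                                  pH = 7.0, cap = 20, ...) {
  sites <- if (inherits(structure, "ionizable_sites")) structure
           else extract_ionizable_sites(structure)
  if (nrow(sites) == 0L)
    return(base::structure(0, method = "none", n_sites = 0L, se = 0))
  if (nrow(sites) <= cap) {
    res <- enumerate_titration(sites, solvent, pH_grid = pH, cap = cap)
  } else {
    res <- mc_titration(sites, solvent, pH_grid = pH, ...)
  }
  base::structure(res$dG_charge, method = res$method, n_sites = nrow(sites),
                  se = res$dG_se)
}

#' Ionisable-group contribution to dimerisation energy
#'
#' `ddG = dG_charge(AB) - dG_charge(A) - dG_charge(B)`: the charge
#' interaction free energy gained on forming the dimer, by
#' subtraction of the individual subunit contributions from that of
#' the dimer.
#'
#' @param A,B,AB subunit and dimer structures (bio3d pdb or paths);
#'   `AB` must contain exactly the atoms of `A` plus `B`.
#' @inheritParams charge_folding_energy
#' @export
dimer_charge_energy <- function(A, B, AB, solvent = solvent_model(),
                                cap = 20, ...) {
  as_pdb <- function(x) if (is.character(x))
    bio3d::read.pdb(x, verbose = FALSE) else x
  A <- as_pdb(A); B <- as_pdb(B); AB <- as_pdb(AB)
  na <- sum(A$atom$type == "ATOM"); nb <- sum(B$atom$type == "ATOM")
  nab <- sum(AB$atom$type == "ATOM")
  if (na + nb != nab)
    stop(sprintf("atom mismatch: |A| + |B| = %d but |AB| = %d", na + nb, nab))
  gA <- charge_folding_energy(A, solvent, cap = cap, ...)
  gB <- charge_folding_energy(B, solvent, cap = cap, ...)
  gAB <- charge_folding_energy(AB, solvent, cap = cap, ...)
  se <- sqrt(sum(c(attr(gA, "se"), attr(gB, "se"), attr(gAB, "se"))^2,
                 na.rm = TRUE))
  structure(as.numeric(gAB) - as.numeric(gA) - as.numeric(gB),
            se = se, components = c(AB = as.numeric(gAB), A = as.numeric(gA),
                                    B = as.numeric(gB)))
}
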