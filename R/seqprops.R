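# Sequence-based properties of immunoglobulin domains: amino-acid
# composition, sequence entropy, K-R, pI, aromatic content, a
# charge/hydropathy folding propensity, and z-scoring against a
# reference population.

#' The twenty canonical amino acids (one-letter codes)
#' @export
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Kyte-Doolittle hydropathy scale
#'
#' Per-residue hydropathy indices; more positive is more hydrophobic.
#' Used (rescaled to \[0,1\]) by [folding_propensity()].
#' @export
KD_HYDROPATHY <- c(
  A = 1.8, C = 2.5, D = -3.5, E = -3.5, F = 2.8, G = -0.4, H = -3.2,
  I = 4.5, K = -3.9, L = 3.8, M = 1.9, N = -3.5, P = -1.6, Q = -3.5,
  R = -4.5, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)

#' EMBOSS pKa values for isoelectric-point calculation
#'
#' Dissociation constants for the ionisable side chains and the chain
#' termini, as used by the EMBOSS `iep` tool. `isoelectric_point()`
#' accepts any equivalently named table.
#' @export
EMBOSS_PKA <- c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1,
                H = 6.5, K = 10.8, R = 12.5, Y = 10.1)

# Residues carrying positive charge when protonated (for pI).
.PI_BASIC <- c("Nterm", "H", "K", "R")
.PI_ACIDIC <- c("Cterm", "C", "D", "E", "Y")

#' Construct a domain sequence
#'
#' A `domain_sequence` is an amino-acid sequence with an identifier, a
#' region label and optional 1-based source coordinates in its parent
#' chain. Non-canonical letters (X, B, Z, U, O, J, gaps, `*`) are dropped
#' with a warning before analysis: composition statistics are undefined
#' for ambiguity codes.
#'
#' @param id character identifier.
#' @param sequence character scalar over the amino-acid alphabet.
#' @param region one of `"VH"`, `"CH1"`, `"VL"`, `"CL"`, `"CDR"`,
#'   `"IgSF"`, `"other"`.
#' @param source_range optional integer `c(start, end)`, 1-based
#'   inclusive, in the parent chain. Checked against the sequence
#'   length *before* non-canonical letters are removed.
#' @return an object of class `domain_sequence`.
#' @export
domain_sequence <- function(id, sequence, region = "other", source_range = NULL) {
  region <- match.arg(region, c("VH", "CH1", "VL", "CL", "CDR", "IgSF", "other"))
  if (!is.character(sequence) || length(sequence) != 1L)
    stop("'sequence' must be a single character string")
  sequence <- toupper(sequence)
  if (!is.null(source_range)) {
    if (length(source_range) != 2L)
      stop("'source_range' must be c(start, end)")
    if (source_range[2] - source_range[1] + 1L != nchar(sequence))
      stop("source_range span does not match sequence length")
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- !(chars %in% AA20)
  if (any(bad)) {
    warning(sprintf("%s: dropped %d non-canonical letter(s): %s",
                    id, sum(bad), paste(unique(chars[bad]), collapse = "")))
    chars <- chars[!bad]
  }
  if (length(chars) == 0L)
    stop(sprintf("%s: empty sequence after removing non-canonical letters", id))
  structure(list(id = as.character(id),
                 sequence = paste(chars, collapse = ""),
                 region = region,
                 source_range = source_range),
            class = "domain_sequence")
}

#' @export
print.domain_sequence <- function(x, ...) {
  cat(sprintf("<domain_sequence> %s [%s], %d aa\n",
              x$id, x$region, nchar(x$sequence)))
  invisible(x)
}

# Coerce character / domain_sequence input to a residue vector.
.residues <- function(seq) {
  if (inherits(seq, "domain_sequence")) seq <- seq$sequence
  if (inherits(seq, "composition_vector"))
    stop("expected a sequence, got a composition_vector")
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  chars <- chars[chars %in% AA20]
  if (length(chars) == 0L) stop("empty sequence")
  chars
}

#' Amino-acid composition of a sequence
#'
#' @param seq a `domain_sequence` or a character string.
#' @return a `composition_vector`: named fractions over [AA20] (sum 1)
#'   plus the residue count `n_residues`.
#' @examples
#' composition("ACDE")$fractions[c("A", "C", "D", "E")]
#' @export
composition <- function(seq) {
  chars <- .residues(seq)
  counts <- table(factor(chars, levels = AA20))
  f <- as.numeric(counts) / length(chars)
  names(f) <- AA20
  structure(list(fractions = f, n_residues = length(chars)),
            class = "composition_vector")
}

#' @export
print.composition_vector <- function(x, ...) {
  cat(sprintf("<composition_vector> n = %d\n", x$n_residues))
  print(round(x$fractions, 3))
  invisible(x)
}

.as_composition <- function(x) {
  if (inherits(x, "composition_vector")) {
    stopifnot(abs(sum(x$fractions) - 1) < 1e-9, all(x$fractions >= 0))
    return(x)
  }
  composition(x)
}

#' Shannon entropy of an amino-acid composition, in bits
#'
#' `-sum(f * log2(f))` over the non-zero composition fractions. Ranges
#' from 0 for a homopolymer to `log2(20) ~ 4.32` bits for a sequence
#' drawing equally on all twenty amino acids.
#'
#' @param comp a `composition_vector`, `domain_sequence` or string.
#' @export
sequence_entropy <- function(comp) {
  f <- .as_composition(comp)$fractions
  f <- f[f > 0]
  -sum(f * log2(f)) + 0  # + 0 normalises IEEE negative zero
}

#' Lysine minus arginine composition, in percentage points
#'
#' `100 * (f_K - f_R)`; a sequence-based solubility correlate (lysine
#' associates with higher solubility than arginine).
#' @inheritParams sequence_entropy
#' @export
lysine_minus_arginine <- function(comp) {
  f <- .as_composition(comp)$fractions
  100 * (f[["K"]] - f[["R"]])
}

#' Aromatic content (F + W + Y), percent
#' @inheritParams sequence_entropy
#' @export
aromatic_content <- function(comp) {
  f <- .as_composition(comp)$fractions
  100 * (f[["F"]] + f[["W"]] + f[["Y"]])
}

# Net charge of a sequence at a given pH under a pKa table.
.net_charge <- function(counts, pH, pka) {
  q <- 0
  for (g in names(pka)) {
    n <- counts[[g]]
    if (is.null(n) || n == 0) next
    if (g %in% .PI_BASIC) {
      q <- q + n / (1 + 10^(pH - pka[[g]]))
    } else {
      q <- q - n / (1 + 10^(pka[[g]] - pH))
    }
  }
  q
}

#' Isoelectric point
#'
#' The pH at which the Henderson-Hasselbalch net charge (side chains
#' plus both termini) crosses zero, located by bisection to
#' `|Q| < 1e-6`. A sequence with only basic (only acidic) ionisable
#' groups has no zero crossing; the declared cap 14 (0) is returned
#' with attribute `capped = TRUE`.
#'
#' @param seq a `domain_sequence` or string.
#' @param pka named pKa table; defaults to [EMBOSS_PKA].
#' @export
isoelectric_point <- function(seq, pka = EMBOSS_PKA) {
  chars <- .residues(seq)
  counts <- as.list(table(factor(chars, levels = AA20)))
  counts$Nterm <- 1L
  counts$Cterm <- 1L
  groups <- names(pka)[vapply(names(pka), function(g)
    !is.null(counts[[g]]) && counts[[g]] > 0, logical(1))]
  has_basic <- any(groups %in% .PI_BASIC)
  has_acidic <- any(groups %in% .PI_ACIDIC)
  if (!has_acidic) return(structure(14, capped = TRUE))
  if (!has_basic) return(structure(0, capped = TRUE))
  lo <- 0; hi <- 14
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    q <- .net_charge(counts, mid, pka)
    if (abs(q) < 1e-6) break
    if (q > 0) lo <- mid else hi <- mid
  }
  mid
}

#' Charge/hydropathy folding propensity
#'
#' A boundary-line discriminant between natively folded proteins and
#' intrinsically disordered ones, based on the balance of mean
#' hydrophobicity and mean net charge:
#' `FP = c1 * <H> - |<R>| - c0`, where `<H>` is the mean residue
#' hydropathy rescaled to \[0,1\] and `<R>` the mean net charge per
#' residue at neutral pH (D, E = -1; K, R = +1; H configurable,
#' default 0). `FP > 0` predicts a folded protein; `FP < 0` predicts
#' intrinsic disorder.
#'
#' @param seq a `domain_sequence` or string.
#' @param c1,c0 boundary-line coefficients; defaults 2.785 and 1.151
#'   (the classic charge/hydropathy discriminant).
#' @param hydropathy named per-residue scale; default [KD_HYDROPATHY].
#'   Rescaled internally to \[0,1\] over its own range.
#' @param his_charge charge assigned to histidine at pH 7 (default 0).
#' @export
folding_propensity <- function(seq, c1 = 2.785, c0 = 1.151,
                               hydropathy = KD_HYDROPATHY, his_charge = 0) {
  chars <- .residues(seq)
  h <- hydropathy[chars]
  if (anyNA(h)) stop("hydropathy scale missing residues: ",
                     paste(unique(chars[is.na(h)]), collapse = ", "))
  hs <- (h - min(hydropathy)) / (max(hydropathy) - min(hydropathy))
  charge <- c(D = -1, E = -1, K = 1, R = 1, H = his_charge)
  r <- mean(ifelse(chars %in% names(charge), charge[chars], 0))
  c1 * mean(hs) - abs(r) - c0
}

#' All sequence-based properties of one sequence
#'
#' @param seq a `domain_sequence` or string.
#' @param ... passed to [isoelectric_point()] / [folding_propensity()].
#' @return one-row data.frame: id, region, n, k_minus_r, pI, entropy,
#'   aromatic, fp.
#' @export
sequence_properties <- function(seq, ...) {
  if (!inherits(seq, "domain_sequence"))
    seq <- domain_sequence("seq", seq)
  comp <- composition(seq)
  data.frame(id = seq$id, region = seq$region, n = comp$n_residues,
             k_minus_r = lysine_minus_arginine(comp),
             pI = as.numeric(isoelectric_point(seq)),
             entropy = sequence_entropy(comp),
             aromatic = aromatic_content(comp),
             fp = folding_propensity(seq),
             stringsAsFactors = FALSE)
}

#' Fit a reference population for z-scoring
#'
#' Computes per-property mean and standard deviation over a set of
#' sequences, e.g. a proteome-scale solubility dataset, so domain
#' properties can be expressed as deviations from a population
#' average.
#'
#' @param seqs list of `domain_sequence`/character, or a FASTA path.
#' @param provenance label recorded with the population.
#' @return a `reference_population`: list with `mu`, `sigma` (named
#'   over the property columns of [sequence_properties()]) and
#'   `provenance`.
#' @export
fit_reference_population <- function(seqs, provenance = "user") {
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs))
    seqs <- read_fasta_domains(seqs)
  if (length(seqs) < 2L) stop("need at least 2 sequences to estimate sigma")
  props <- do.call(rbind, lapply(seqs, sequence_properties))
  num <- props[, c("k_minus_r", "pI", "entropy", "aromatic", "fp")]
  mu <- vapply(num, mean, numeric(1))
  sigma <- vapply(num, stats::sd, numeric(1))
  if (any(sigma <= 0))
    stop("zero-variance property in reference population: ",
         paste(names(sigma)[sigma <= 0], collapse = ", "))
  structure(list(mu = mu, sigma = sigma, n = nrow(props),
                 provenance = provenance),
            class = "reference_population")
}

#' @export
print.reference_population <- function(x, ...) {
  cat(sprintf("<reference_population> n = %d (%s)\n", x$n, x$provenance))
  print(rbind(mu = round(x$mu, 3), sigma = round(x$sigma, 3)))
  invisible(x)
}

#' z-score of a property value against a reference population
#'
#' `(value - mu) / sigma`: how many population standard deviations the
#' value lies from the population average, sign preserved.
#'
#' @param value numeric property value(s).
#' @param pop a `reference_population`.
#' @param property property name present in the population.
#' @export
zscore <- function(value, pop, property) {
  stopifnot(inherits(pop, "reference_population"))
  if (!property %in% names(pop$mu))
    stop("property not in reference population: ", property)
  if (!is.finite(pop$sigma[[property]]) || pop$sigma[[property]] <= 0)
    stop("sigma must be > 0 for property: ", property)
  (value - pop$mu[[property]]) / pop$sigma[[property]]
}

#' Sequence-property table for a set of sequences, with z-scores
#'
#' @param seqs list of `domain_sequence` (or FASTA path).
#' @param pop optional `reference_population`; when given, each
#'   property column gains a z-scored companion suffixed `_z`.
#' @return data.frame, one row per sequence.
#' @export
seqprops_table <- function(seqs, pop = NULL) {
  if (is.character(seqs) && length(seqs) == 1L && file.exists(seqs))
    seqs <- read_fasta_domains(seqs)
  tab <- do.call(rbind, lapply(seqs, sequence_properties))
  rownames(tab) <- NULL
  if (!is.null(pop)) {
    for (p in names(pop$mu)) tab[[paste0(p, "_z")]] <- zscore(tab[[p]], pop, p)
  }
  tab
}

#' Read sequences from FASTA as domain_sequence objects
#'
#' Headers of the form `NAME:start-end` carry the source range; a
#' `region=` token in the description, when present, sets the region.
#'
#' @param path FASTA file.
#' @param region default region label for all records.
#' @export
read_fasta_domains <- function(path, region = "other") {
  fa <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                           set.attributes = FALSE)
  lapply(seq_along(fa), function(i) {
    id <- names(fa)[i]
    rng <- NULL
    m <- regmatches(id, regexec("^(.+):([0-9]+)-([0-9]+)$", id))[[1]]
    if (length(m) == 4L) {
      rng <- as.integer(m[3:4])
      if (rng[2] - rng[1] + 1L != nchar(fa[[i]])) rng <- NULL
    }
    domain_sequence(id, fa[[i]], region = region, source_range = rng)
  })
}

#' Write a sequence-property table as TSV
#' @param tab data.frame from [seqprops_table()].
#' @param path output file.
#' @export
write_seqprops_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
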