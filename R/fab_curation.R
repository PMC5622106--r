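# Curation of Fab fragment datasets from PDB-format structures:
# H/L chain extraction, chain-length quartile filtering, splitting of
# heavy and light chains into variable and constant domains at
# conserved interdomain motifs, per-domain length filtering, and
# CDR concatenation.

# Default search windows and motifs (1-based positions of the motif's
# first residue in the observed-residue sequence).
FAB_MOTIFS <- list(
  heavy = list(patterns = "VS[SA]", window = c(110L, 130L)),
  light = list(patterns = c("E[LIV]KR", "TVL[GSA]"), window = c(100L, 115L)))

# Non-standard residue -> parent amino acid (3-letter), applied before
# bio3d's own 3->1 mapping.
.NONSTD_MAP <- c(MSE = "MET", CSO = "CYS", SEC = "CYS", SEP = "SER",
                 TPO = "THR", PTR = "TYR", HYP = "PRO", MLY = "LYS",
                 PCA = "GLU", KCX = "LYS")

# Observed-residue table for one chain of a bio3d pdb: one row per
# residue in author (file) order, with the one-letter code and the
# atom rows belonging to it.
.chain_residues <- function(pdb, chain) {
  at <- pdb$atom
  rows <- which(at$type == "ATOM" & at$chain == chain)
  key <- paste(at$resno[rows], at$insert[rows], sep = "_")
  first <- rows[!duplicated(key)]
  resid <- at$resid[first]
  mapped <- ifelse(resid %in% names(.NONSTD_MAP), .NONSTD_MAP[resid], resid)
  aa1 <- bio3d::aa321(mapped)
  list(keys = unique(key), aa = aa1,
       atom_rows = split(rows, factor(key, levels = unique(key))))
}

#' Load a Fab structure, retaining only the H and L chains
#'
#' Reads a PDB-format file, keeps the `ATOM` records of chains named
#' `H` (heavy) and `L` (light), and derives each chain's sequence from
#' the observed residues in author order (SEQRES is ignored: the
#' structural calculations need coordinates for every counted
#' residue). Other chains are discarded with a message. Non-standard
#' residues with a known parent (e.g. MSE) are mapped to it; anything
#' else becomes `X`. HETATM records are ignored.
#'
#' @param file path to a PDB-format file.
#' @param pdb_id identifier; defaults to the file base name.
#' @return a `fab_record` with elements `pdb_id`, `heavy_seq`,
#'   `light_seq` (plain strings over the observed residues), `pdb`
#'   (the H+L structure), and per-chain residue/atom bookkeeping; or a
#'   `fab_rejection` (with `$reason`) when no H or L chain is present.
#' @export
load_fab_structure <- function(file, pdb_id = NULL) {
  if (is.null(pdb_id))
    pdb_id <- sub("\\.(pdb|ent)$", "", basename(file))
  pdb <- bio3d::read.pdb(file, verbose = FALSE)
  at <- pdb$atom
  atom_rows <- which(at$type == "ATOM")
  if (length(atom_rows) == 0L) stop(pdb_id, ": no ATOM records")
  chains_seq <- at$chain[atom_rows]
  runs <- rle(chains_seq)$values
  dup <- unique(runs[duplicated(runs)])
  if (any(c("H", "L") %in% dup))
    stop(pdb_id, ": ambiguous chain ", paste(intersect(c("H", "L"), dup),
                                             collapse = ","))
  present <- unique(chains_seq)
  if (!all(c("H", "L") %in% present)) {
    return(structure(list(pdb_id = pdb_id, reason = "no H/L chains"),
                     class = "fab_rejection"))
  }
  dropped <- setdiff(present, c("H", "L"))
  if (length(dropped))
    message(pdb_id, ": discarded chain(s) ", paste(dropped, collapse = ","))
  sel <- bio3d::atom.select(pdb, "protein", chain = c("H", "L"),
                            type = "ATOM", verbose = FALSE)
  pdb <- bio3d::trim.pdb(pdb, sel)
  h <- .chain_residues(pdb, "H")
  l <- .chain_residues(pdb, "L")
  structure(list(pdb_id = pdb_id,
                 heavy_seq = paste(h$aa, collapse = ""),
                 light_seq = paste(l$aa, collapse = ""),
                 pdb = pdb, heavy_res = h, light_res = l,
                 heavy_split = NA_integer_, light_split = NA_integer_,
                 domains = NULL, dimers = NULL, cdr_seq = NULL),
            class = "fab_record")
}

#' @export
print.fab_record <- function(x, ...) {
  cat(sprintf("<fab_record> %s  H: %d aa  L: %d aa  split: %s/%s\n",
              x$pdb_id, nchar(x$heavy_seq), nchar(x$light_seq),
              x$heavy_split, x$light_split))
  invisible(x)
}

#' Chain-length quartile filter
#'
#' Keeps records whose heavy-chain length lies within the lower and
#' upper quartiles of heavy-chain lengths over the input, and likewise
#' for the light chain (bounds inclusive). Quartiles use the standard
#' linear-interpolation definition (`stats::quantile`, type 7).
#'
#' @param records list of `fab_record`.
#' @return list with `records` (the survivors) and `report` (a
#'   data.frame of the quartile bounds used per chain).
#' @export
quartile_length_filter <- function(records) {
  if (length(records) < 4L)
    stop("quartile filter needs at least 4 records")
  hl <- vapply(records, function(r) nchar(r$heavy_seq), integer(1))
  ll <- vapply(records, function(r) nchar(r$light_seq), integer(1))
  qh <- stats::quantile(hl, c(0.25, 0.75), names = FALSE)
  ql <- stats::quantile(ll, c(0.25, 0.75), names = FALSE)
  keep <- hl >= qh[1] & hl <= qh[2] & ll >= ql[1] & ll <= ql[2]
  list(records = records[keep],
       report = data.frame(chain = c("H", "L"),
                           q1 = c(qh[1], ql[1]), q3 = c(qh[2], ql[2]),
                           n_in = length(records), n_kept = sum(keep)))
}

#' Locate the variable/constant interdomain split of a Fab chain
#'
#' Heavy chains are split at the first `VS[SA]` motif whose first
#' residue lies in the window 110-130 (1-based, observed-residue
#' coordinates); light chains at the first `E[LIV]KR` match in
#' 100-115, falling back to `TVL[GSA]` only when that fails. The
#' motif's first residue starts the constant domain.
#'
#' @param seq chain sequence (string or `domain_sequence`).
#' @param chain_kind `"heavy"` or `"light"`.
#' @param motifs motif/window configuration; see `FAB_MOTIFS`.
#' @return the 1-based split position, or `NA` (with attribute
#'   `reason = "unsplittable"`) when no motif occurs in the window.
#' @export
find_interdomain_split <- function(seq, chain_kind = c("heavy", "light"),
                                   motifs = FAB_MOTIFS) {
  chain_kind <- match.arg(chain_kind)
  if (inherits(seq, "domain_sequence")) seq <- seq$sequence
  cfg <- motifs[[chain_kind]]
  if (nchar(seq) <= cfg$window[2])
    return(structure(NA_integer_, reason = "unsplittable"))
  for (pat in cfg$patterns) {
    starts <- gregexpr(pat, seq, perl = TRUE)[[1]]
    starts <- starts[starts >= cfg$window[1] & starts <= cfg$window[2]]
    if (length(starts) && starts[1] > 0)
      return(structure(as.integer(starts[1]), matched = pat))
  }
  structure(NA_integer_, reason = "unsplittable")
}

# Assemble a trimmed pdb from a set of atom-row indices.
.trim_rows <- function(pdb, rows) {
  rows <- sort(unique(rows))
  inds <- structure(list(atom = rows, xyz = bio3d::atom2xyz(rows),
                         call = NULL), class = "select")
  bio3d::trim.pdb(pdb, inds)
}

.domain_fragment <- function(record, res, from, to, id, region) {
  rows <- unlist(res$atom_rows[from:to], use.names = FALSE)
  seq_raw <- substr(if (region %in% c("VH", "CH1")) record$heavy_seq
                    else record$light_seq, from, to)
  list(seq_raw = seq_raw,
       seq = domain_sequence(paste0(record$pdb_id, "_", region),
                             gsub("X", "", seq_raw), region = region),
       pdb = if (!is.null(record$pdb)) .trim_rows(record$pdb, rows),
       atom_rows = rows, range = c(from, to))
}

#' Split a Fab record into its four domains and two dimers
#'
#' Requires both interdomain splits (found with
#' [find_interdomain_split()] or supplied). The variable domain is
#' residues `1..split-1`, the constant domain `split..end`; structure
#' atoms are partitioned by residue membership and the VL:VH and
#' CL:CH1 dimer structures assembled from the corresponding pairs.
#'
#' @param record a `fab_record`.
#' @param heavy_split,light_split 1-based split positions; when `NULL`
#'   the positions already stored in the record are used.
#' @return the completed `fab_record`, with `domains` (VH, CH1, VL,
#'   CL) and `dimers` (`VLVH`, `CLCH1`).
#' @export
split_domains <- function(record, heavy_split = NULL, light_split = NULL) {
  if (!is.null(heavy_split)) record$heavy_split <- as.integer(heavy_split)
  if (!is.null(light_split)) record$light_split <- as.integer(light_split)
  hs <- record$heavy_split; ls <- record$light_split
  if (is.na(hs) || is.na(ls)) stop(record$pdb_id, ": splits not found")
  nh <- nchar(record$heavy_seq); nl <- nchar(record$light_seq)
  if (hs <= 1L || hs > nh || ls <= 1L || ls > nl)
    stop(record$pdb_id, ": degenerate domain")
  record$domains <- list(
    VH  = .domain_fragment(record, record$heavy_res, 1L, hs - 1L,
                           record$pdb_id, "VH"),
    CH1 = .domain_fragment(record, record$heavy_res, hs, nh,
                           record$pdb_id, "CH1"),
    VL  = .domain_fragment(record, record$light_res, 1L, ls - 1L,
                           record$pdb_id, "VL"),
    CL  = .domain_fragment(record, record$light_res, ls, nl,
                           record$pdb_id, "CL"))
  if (!is.null(record$pdb)) {
    d <- record$domains
    record$dimers <- list(
      VLVH  = .trim_rows(record$pdb, c(d$VL$atom_rows, d$VH$atom_rows)),
      CLCH1 = .trim_rows(record$pdb, c(d$CL$atom_rows, d$CH1$atom_rows)))
  }
  record
}

#' Per-domain length filter
#'
#' For each domain class (VH, CH1, VL, CL) the mean length over the
#' input is computed; a record is kept iff every one of its four
#' domains is within 10 residues of its class mean (inclusive).
#'
#' @param records list of completed `fab_record`.
#' @param tol residues; default 10.
#' @export
domain_length_filter <- function(records, tol = 10) {
  if (!length(records)) return(list(records = records, report = NULL))
  classes <- c("VH", "CH1", "VL", "CL")
  lens <- sapply(classes, function(cl)
    vapply(records, function(r) nchar(r$domains[[cl]]$seq_raw), integer(1)))
  lens <- matrix(lens, nrow = length(records),
                 dimnames = list(NULL, classes))
  mu <- colMeans(lens)
  keep <- apply(abs(sweep(lens, 2, mu)) <= tol, 1, all)
  list(records = records[keep],
       report = data.frame(domain = classes, mean_length = mu,
                           n_in = length(records), n_kept = sum(keep),
                           row.names = NULL))
}

#' Concatenate a Fab's CDR subsequences into one combined sequence
#'
#' @param record a `fab_record`.
#' @param annotations data.frame with columns `pdb_id`, `chain`
#'   (`H`/`L`), `cdr_name`, `start`, `end` (1-based inclusive,
#'   observed-sequence coordinates). Rows are used in table order.
#' @return a `domain_sequence` with region `CDR`, or `NULL` when the
#'   record has no annotation rows (CDR marked absent).
#' @export
concatenate_cdrs <- function(record, annotations) {
  rows <- annotations[annotations$pdb_id == record$pdb_id, , drop = FALSE]
  if (nrow(rows) == 0L) return(NULL)
  pieces <- character(nrow(rows))
  for (i in seq_len(nrow(rows))) {
    chain_seq <- if (rows$chain[i] == "H") record$heavy_seq else record$light_seq
    if (rows$start[i] < 1L || rows$end[i] > nchar(chain_seq) ||
        rows$start[i] > rows$end[i])
      stop(sprintf("%s: CDR annotation row %s (%s %d-%d) out of chain bounds",
                   record$pdb_id, rows$cdr_name[i], rows$chain[i],
                   rows$start[i], rows$end[i]))
    pieces[i] <- substr(chain_seq, rows$start[i], rows$end[i])
  }
  domain_sequence(paste0(record$pdb_id, "_CDR"),
                  gsub("X", "", paste(pieces, collapse = "")),
                  region = "CDR")
}

#' Run the full Fab curation pipeline
#'
#' Loads structures, drops records without H/L chains, applies the
#' chain-length quartile filter, locates the interdomain motifs,
#' splits surviving chains into domains and dimers, and applies the
#' per-domain length filter. Deterministic: the same input files give
#' the same report.
#'
#' @param files paths to PDB-format files, or a list of already loaded
#'   `fab_record` objects.
#' @param cdr_annotations optional CDR table (see
#'   [concatenate_cdrs()]).
#' @param motifs motif configuration, see `FAB_MOTIFS`.
#' @return list with `records` (completed `fab_record`s), `report`
#'   (stage counts, non-increasing), `quartiles`, `exclusions`
#'   (pdb_id + reason per dropped record).
#' @export
curate_fabs <- function(files, cdr_annotations = NULL, motifs = FAB_MOTIFS) {
  if (is.character(files)) {
    loaded <- lapply(files, load_fab_structure)
  } else loaded <- files
  excl <- data.frame(pdb_id = character(0), reason = character(0))
  ok <- vapply(loaded, inherits, logical(1), "fab_record")
  for (r in loaded[!ok])
    excl <- rbind(excl, data.frame(pdb_id = r$pdb_id, reason = r$reason))
  recs <- loaded[ok]
  n0 <- length(loaded); n1 <- length(recs)

  qf <- quartile_length_filter(recs)
  kept_ids <- vapply(qf$records, `[[`, character(1), "pdb_id")
  for (r in recs)
    if (!r$pdb_id %in% kept_ids)
      excl <- rbind(excl, data.frame(pdb_id = r$pdb_id,
                                     reason = "chain length outside quartiles"))
  recs <- qf$records; n2 <- length(recs)

  split_ok <- logical(length(recs))
  for (i in seq_along(recs)) {
    hs <- find_interdomain_split(recs[[i]]$heavy_seq, "heavy", motifs)
    ls <- find_interdomain_split(recs[[i]]$light_seq, "light", motifs)
    if (is.na(hs) || is.na(ls)) {
      excl <- rbind(excl, data.frame(pdb_id = recs[[i]]$pdb_id,
                                     reason = "no interdomain motif"))
    } else {
      recs[[i]] <- split_domains(recs[[i]], hs, ls)
      split_ok[i] <- TRUE
    }
  }
  recs <- recs[split_ok]; n3 <- length(recs)

  df <- domain_length_filter(recs)
  kept_ids <- vapply(df$records, `[[`, character(1), "pdb_id")
  for (r in recs)
    if (!r$pdb_id %in% kept_ids)
      excl <- rbind(excl, data.frame(pdb_id = r$pdb_id,
                                     reason = "domain length >10 from class mean"))
  recs <- df$records; n4 <- length(recs)

  if (!is.null(cdr_annotations))
    recs <- lapply(recs, function(r) {
      r$cdr_seq <- concatenate_cdrs(r, cdr_annotations); r })

  list(records = recs,
       report = data.frame(
         stage = c("loaded", "with_HL_chains", "quartile_filter",
                   "motif_split", "domain_length_filter"),
         count = c(n0, n1, n2, n3, n4)),
       quartiles = qf$report, domain_means = df$report,
       exclusions = excl)
}

#' Write the curated domains of a record set as FASTA
#' @param records completed `fab_record` list.
#' @param path output FASTA path.
#' @param domains which domain classes to write.
#' @export
write_domain_fasta <- function(records, path,
                               domains = c("VH", "CH1", "VL", "CL")) {
  seqs <- list(); ids <- character(0)
  for (r in records) for (d in domains) {
    seqs <- c(seqs, r$domains[[d]]$seq$sequence)
    ids <- c(ids, r$domains[[d]]$seq$id)
  }
  seqinr::write.fasta(as.list(seqs), ids, path)
  invisible(path)
}
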