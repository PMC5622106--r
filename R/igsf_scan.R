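# Scan of immunoglobulin-superfamily domains for CH1-like
# amino-acid composition: the cosine between the differenced
# composition vectors (X - CL_REF) and (CH1_REF - CL_REF), combined
# with a low-sequence-entropy threshold.

#' Cosine between differenced composition vectors
#'
#' For a query composition `X` and representative CH1 and CL
#' compositions, computes the cosine of the angle between
#' `a = X - cl_ref` and `b = ch1_ref - cl_ref` over the 20
#' composition components. A cosine near 1 means the query deviates
#' from CL in the same direction composition-space as CH1 does; near
#' 0, unrelated deviation.
#'
#' @param x,ch1_ref,cl_ref `composition_vector` objects (or sequences,
#'   coerced via [composition()]).
#' @return cosine in \[-1, 1\].
#' @export
composition_difference_cosine <- function(x, ch1_ref, cl_ref) {
  fx <- .as_composition(x)$fractions
  f1 <- .as_composition(ch1_ref)$fractions
  f0 <- .as_composition(cl_ref)$fractions
  a <- fx - f0
  b <- f1 - f0
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0)
    stop("degenerate comparison: zero differenced vector")
  min(1, max(-1, sum(a * b) / (na * nb)))
}

#' Scan IgSF domains for CH1-like composition
#'
#' Scores every domain by [composition_difference_cosine()] against
#' the CH1/CL references and by sequence entropy; a domain passes
#' when `cosine > cos_threshold` and `entropy < entropy_threshold`
#' (strict inequalities). Results are ranked by cosine descending,
#' ties broken by id, so the ordering is deterministic.
#'
#' @param domains list of `domain_sequence` (or a FASTA path; ids of
#'   the form `NAME:start-end` are kept as-is).
#' @param ch1_ref,cl_ref representative compositions (or sequences).
#' @param cos_threshold default 0.3.
#' @param entropy_threshold bits; default 3.83.
#' @return data.frame (class `scan_result`): id, cosine, entropy,
#'   passes; ranked.
#' @export
scan_igsf <- function(domains, ch1_ref, cl_ref, cos_threshold = 0.3,
                      entropy_threshold = 3.83) {
  if (is.character(domains) && length(domains) == 1L && file.exists(domains))
    domains <- read_fasta_domains(domains, region = "IgSF")
  if (!length(domains))
    return(structure(data.frame(id = character(0), cosine = numeric(0),
                                entropy = numeric(0), passes = logical(0)),
                     class = c("scan_result", "data.frame")))
  ch1_ref <- .as_composition(ch1_ref)
  cl_ref <- .as_composition(cl_ref)
  rows <- lapply(domains, function(d) {
    comp <- composition(d)
    data.frame(id = d$id,
               cosine = composition_difference_cosine(comp, ch1_ref, cl_ref),
               entropy = sequence_entropy(comp),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$passes <- out$cosine > cos_threshold & out$entropy < entropy_threshold
  out <- out[order(-out$cosine, out$id), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("scan_result", "data.frame"),
            thresholds = c(cosine = cos_threshold,
                           entropy = entropy_threshold))
}

#' Write a ranked scan result as TSV
#' @param scan a `scan_result`.
#' @param path output file.
#' @export
write_scan_tsv <- function(scan, path) {
  utils::write.table(scan, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
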