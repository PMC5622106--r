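#!/usr/bin/env Rscript
# Stage 3: sequence-based properties of the curated Fab domains,
# expressed as z-score deviations from the stage-1 reference
# population. Writes the per-domain table and per-class means.

suppressPackageStartupMessages(library(fabdomains))

out <- "results"
pop <- fit_reference_population(file.path(out, "synthetic", "refpop.fasta"),
                                provenance = "synthetic reference")
message("Reference population:")
print(pop)

doms <- read_fasta_domains(file.path(out, "fab_domains.fasta"))
# region is encoded in the id suffix written by the curation stage
for (i in seq_along(doms))
  doms[[i]]$region <- sub("^.*_", "", doms[[i]]$id)

tab <- seqprops_table(doms, pop)
tab$region <- sub("^.*_", "", tab$id)
write_seqprops_tsv(tab, file.path(out, "fab_seqprops.tsv"))

zcols <- grep("_z$", names(tab), value = TRUE)
means <- aggregate(tab[, c("k_minus_r", "pI", "entropy", "aromatic", "fp",
                           zcols)],
                   by = list(region = tab$region), FUN = mean)
message("Per-class means (synthetic domains):")
print(means, digits = 3)
write.table(means, file.path(out, "fab_seqprops_by_class.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
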