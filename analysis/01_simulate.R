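#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Produces, under results/synthetic/:
#   - fabset/         50 coarse-grained Fab structures (chains H and L,
#                     interdomain motifs planted at known positions)
#   - fab_truth.tsv   planted split positions per structure
#   - refpop.fasta    1000-sequence reference population (K-R centred
#                     at 0 with SD 3 percentage points) for z-scoring
#   - igsf.fasta      205-domain IgSF-like cohort (5 planted CH1-like)
#   - igsf_truth.tsv  planted labels
# The CH1/CL reference compositions used by the scan are carried by
# the cohort generator and re-derived in stage 6 from the same spec.

suppressPackageStartupMessages(library(fabdomains))

seed <- 1
out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

message("Generating 50 synthetic Fab structures ...")
fabs <- generate_fab_dataset(50, dir = file.path(out, "fabset"), seed = seed)
write.table(fabs, file.path(out, "fab_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("  heavy splits span ", min(fabs$heavy_split), "-",
        max(fabs$heavy_split), ", light ", min(fabs$light_split), "-",
        max(fabs$light_split))

message("Generating the reference population (n = 1000) ...")
rp <- generate_reference_population(n = 1000, k_minus_r = c(mu = 0, sigma = 3),
                                    seed = seed)
write_domains_fasta(rp$sequences, file.path(out, "refpop.fasta"))
print(rp$population)

message("Generating the IgSF cohort (200 background + 5 planted) ...")
co <- generate_igsf_cohort(cohort_spec(n_background = 200, n_planted = 5,
                                       seed = seed))
write_domains_fasta(co$domains, file.path(out, "igsf.fasta"))
write.table(co$truth, file.path(out, "igsf_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message("Done. Outputs under ", out)
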