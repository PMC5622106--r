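#!/usr/bin/env Rscript
# Stage 6: scan the IgSF cohort for CH1-like composition with the
# differenced-cosine similarity plus the low-entropy threshold
# (cosine > 0.3, entropy < 3.83), and compare hits with the planted
# truth.

suppressPackageStartupMessages(library(fabdomains))

seed <- 1
out <- "results"
domains <- read_fasta_domains(file.path(out, "synthetic", "igsf.fasta"),
                              region = "IgSF")
truth <- read.delim(file.path(out, "synthetic", "igsf_truth.tsv"))
# the CH1/CL reference compositions travel with the cohort spec
refs <- generate_igsf_cohort(cohort_spec(n_background = 0, n_planted = 0,
                                         seed = seed))

scan <- scan_igsf(domains, refs$ch1_ref, refs$cl_ref,
                  cos_threshold = 0.3, entropy_threshold = 3.83)
write_scan_tsv(scan, file.path(out, "igsf_scan.tsv"))

hits <- scan$id[scan$passes]
planted <- truth$id[truth$planted]
message(length(hits), " domains pass the double threshold")
message("recovered planted CH1-like domains: ",
        sum(hits %in% planted), "/", length(planted))
message("false positives: ", sum(!hits %in% planted))
print(utils::head(scan, 8), digits = 3)
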