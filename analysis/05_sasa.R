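#!/usr/bin/env Rscript
# Stage 5: solvent-accessible surface area and interface burial for
# the two Fab interfaces, by the subtraction scheme
# buried = SASA(A) + SASA(B) - SASA(AB).

suppressPackageStartupMessages(library(fabdomains))

n_fab <- 4
n_points <- 240
out <- "results"
truth <- read.delim(file.path(out, "synthetic", "fab_truth.tsv"))

rows <- list()
for (i in seq_len(n_fab)) {
  rec <- suppressMessages(load_fab_structure(truth$file[i]))
  rec <- split_domains(rec, truth$heavy_split[i], truth$light_split[i])
  d <- rec$domains
  sasa <- vapply(d, function(x) atom_sasa(x$pdb, n_points = n_points)$total,
                 numeric(1))
  bc <- buried_surface(d$CL$pdb, d$CH1$pdb, rec$dimers$CLCH1,
                       n_points = n_points)
  bv <- buried_surface(d$VL$pdb, d$VH$pdb, rec$dimers$VLVH,
                       n_points = n_points)
  rows[[i]] <- data.frame(pdb_id = rec$pdb_id, t(sasa),
                          buried_CLCH1 = as.numeric(bc),
                          buried_VLVH = as.numeric(bv))
}
tab <- do.call(rbind, rows)
write.table(tab, file.path(out, "fab_sasa.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
print(tab, digits = 4)
message(sprintf("mean burial: CL:CH1 %.0f A^2, VL:VH %.0f A^2",
                mean(tab$buried_CLCH1), mean(tab$buried_VLVH)))
message("CL:CH1 buries more surface than VL:VH: ",
        mean(tab$buried_CLCH1) > mean(tab$buried_VLVH))
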