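test_that("load_fab_structure keeps only H and L chains and rejects or
           errors as appropriate", {
  f <- write_tiny_pdb(c("H", "L", "A"), n_res = 4)
  rec <- suppressMessages(load_fab_structure(f))
  expect_s3_class(rec, "fab_record")
  expect_setequal(unique(rec$pdb$atom$chain), c("H", "L"))
  expect_equal(rec$heavy_seq, "AAAA")

  f2 <- write_tiny_pdb(c("A", "B"), n_res = 4)
  rej <- load_fab_structure(f2)
  expect_s3_class(rej, "fab_rejection")
  expect_match(rej$reason, "no H/L")

  f3 <- write_tiny_pdb(c("H", "L", "H"), n_res = 4, order = c(1, 2, 3))
  expect_error(load_fab_structure(f3), "ambiguous chain")
})

test_that("quartile filter keeps the interquartile band inclusively", {
  # toy lengths 5..9 on both chains: linear-interpolation quartiles
  # give [6, 8], so exactly the middle three records survive
  lens <- 5:9
  recs <- lapply(lens, function(L) {
    structure(list(pdb_id = paste0("T", L),
                   heavy_seq = strrep("A", L), light_seq = strrep("G", L)),
              class = "fab_record")
  })
  expect_identical(unname(stats::quantile(lens, c(.25, .75))), c(6, 8))
  out <- quartile_length_filter(recs)
  expect_equal(vapply(out$records, `[[`, character(1), "pdb_id"),
               c("T6", "T7", "T8"))
  expect_equal(out$report$q1, c(6, 6))
  # all-identical lengths: everything survives
  same <- lapply(1:5, function(i) {
    structure(list(pdb_id = paste0("S", i), heavy_seq = strrep("A", 220),
                   light_seq = strrep("G", 214)), class = "fab_record")
  })
  expect_length(quartile_length_filter(same)$records, 5)
  expect_error(quartile_length_filter(same[1:3]), "at least 4")
})

test_that("interdomain motifs are found at planted positions with the
           documented precedence, and absence is signalled", {
  base <- paste(rep("G", 220), collapse = "")
  plant <- function(seq, pos, motif)
    paste0(substr(seq, 1, pos - 1), motif,
           substr(seq, pos + nchar(motif), nchar(seq)))
  h <- plant(base, 118, "VSS")
  expect_equal(as.integer(find_interdomain_split(h, "heavy")), 118L)
  l1 <- plant(base, 105, "ELKR")
  expect_equal(as.integer(find_interdomain_split(l1, "light")), 105L)
  l2 <- plant(base, 108, "TVLG")
  expect_equal(as.integer(find_interdomain_split(l2, "light")), 108L)
  # E[LIV]KR takes precedence over TVL[GSA] even further left
  l3 <- plant(plant(base, 112, "ELKR"), 101, "TVLG")
  expect_equal(as.integer(find_interdomain_split(l3, "light")), 112L)
  # motif outside the window is not used
  h_out <- plant(base, 140, "VSS")
  expect_true(is.na(find_interdomain_split(h_out, "heavy")))
  expect_equal(attr(find_interdomain_split(base, "heavy"), "reason"),
               "unsplittable")
})

test_that("split domains conserve sequence and partition atoms", {
  pairs <- generate_fab_sequences(3, heavy_motif_pos = c(118, 110, 130),
                                  light_motif_pos = c(105, 100, 115),
                                  seed = 21)
  for (p in pairs) {
    f <- generate_fab_structure(p)
    rec <- load_fab_structure(f)
    expect_identical(rec$heavy_seq, p$heavy)
    rec <- split_domains(rec, p$heavy_split, p$light_split)
    expect_identical(paste0(rec$domains$VH$seq_raw, rec$domains$CH1$seq_raw),
                     rec$heavy_seq)
    expect_identical(paste0(rec$domains$VL$seq_raw, rec$domains$CL$seq_raw),
                     rec$light_seq)
    expect_equal(nchar(rec$domains$VH$seq_raw), p$heavy_split - 1L)
    # atoms partition exactly between V and C fragments
    h_atoms <- sum(rec$pdb$atom$chain == "H")
    expect_equal(nrow(rec$domains$VH$pdb$atom) + nrow(rec$domains$CH1$pdb$atom),
                 h_atoms)
    expect_length(intersect(rec$domains$VH$atom_rows,
                            rec$domains$CH1$atom_rows), 0)
    # dimer atom count equals the sum of its two domains
    expect_equal(nrow(rec$dimers$CLCH1$atom),
                 nrow(rec$domains$CL$pdb$atom) +
                   nrow(rec$domains$CH1$pdb$atom))
  }
  # degenerate split positions are refused
  bad <- load_fab_structure(generate_fab_structure(pairs[[1]]))
  expect_error(split_domains(bad, 1, 105), "degenerate")
})

test_that("domain length filter removes outliers against recomputed
           class means and is idempotent-monotone", {
  mk <- function(id, hs, ls, hl, ll) {
    p <- list(heavy = strrep("A", hl), light = strrep("G", ll),
              heavy_split = hs, light_split = ls)
    r <- structure(list(pdb_id = id, heavy_seq = p$heavy,
                        light_seq = p$light, pdb = NULL,
                        heavy_res = NULL, light_res = NULL,
                        heavy_split = NA_integer_, light_split = NA_integer_),
                   class = "fab_record")
    split_domains(r, hs, ls)
  }
  base <- lapply(1:6, function(i) mk(paste0("N", i), 118, 105, 220, 214))
  expect_length(domain_length_filter(base)$records, 6)
  # one record whose CH1 is 13 residues longer than the class mean
  recs <- c(base, list(mk("OUT", 118, 105, 235, 214)))
  out <- domain_length_filter(recs)
  expect_false("OUT" %in% vapply(out$records, `[[`, character(1), "pdb_id"))
  # re-applying on random cohorts never enlarges the survivor set
  set.seed(5)
  for (i in 1:5) {
    hl <- sample(215:245, 12, replace = TRUE)
    rc <- lapply(seq_along(hl), function(j)
      mk(paste0("R", j), 118, 105, hl[j], 214))
    once <- domain_length_filter(rc)$records
    twice <- domain_length_filter(once)$records
    expect_true(all(vapply(twice, `[[`, character(1), "pdb_id") %in%
                      vapply(once, `[[`, character(1), "pdb_id")))
  }
})

test_that("CDR concatenation follows table order and checks bounds", {
  p <- generate_fab_sequences(1, seed = 31)[[1]]
  rec <- structure(list(pdb_id = "X1", heavy_seq = p$heavy,
                        light_seq = p$light), class = "fab_record")
  ann <- data.frame(pdb_id = "X1", chain = c("H", "L"),
                    cdr_name = c("CDRH1", "CDRL1"),
                    start = c(3, 5), end = c(5, 6))
  cdr <- concatenate_cdrs(rec, ann)
  expect_equal(cdr$region, "CDR")
  expect_equal(cdr$sequence,
               paste0(substr(p$heavy, 3, 5), substr(p$light, 5, 6)))
  expect_null(concatenate_cdrs(rec, ann[0, ]))
  bad <- ann; bad$end[2] <- 9999
  expect_error(concatenate_cdrs(rec, bad), "out of chain bounds")
})

test_that("the curation pipeline is deterministic with non-increasing
           stage counts and reasoned exclusions", {
  df <- generate_fab_dataset(12, seed = 77)
  run1 <- suppressMessages(curate_fabs(df$file))
  run2 <- suppressMessages(curate_fabs(df$file))
  expect_identical(run1$report, run2$report)
  expect_identical(run1$exclusions, run2$exclusions)
  expect_true(all(diff(run1$report$count) <= 0))
  expect_true(all(nchar(run1$exclusions$reason) > 0))
  # every surviving record splits at its planted position
  for (r in run1$records) {
    truth <- df[df$pdb_id == r$pdb_id, ]
    expect_equal(r$heavy_split, truth$heavy_split)
    expect_equal(r$light_split, truth$light_split)
  }
})
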