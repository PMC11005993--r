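test_that("background generation respects GC content exactly and statistically", {
  set.seed(42)
  at_only <- generate_background(500, gc = 0)
  expect_false(grepl("[GC]", at_only))
  gc_only <- generate_background(500, gc = 1)
  expect_false(grepl("[AT]", gc_only))
  # binomial concentration: observed GC within 3*sqrt(p(1-p)/n) of 0.5
  s <- generate_background(1e5, gc = 0.5)
  obs <- nchar(gsub("[AT]", "", s)) / 1e5
  expect_lt(abs(obs - 0.5), 3 * sqrt(0.25 / 1e5))
  expect_error(generate_background(10, gc = 1.5), "gc")
})

test_that("planting writes a matching instance and varies N positions", {
  set.seed(42)
  s <- strrep("A", 40)
  out <- plant_element(s, "TATAWAWR", 10)
  expect_true(iupac_match(substr(out, 10, 17), "TATAWAWR"))
  expect_identical(nchar(out), 40L)
  expect_identical(substr(out, 1, 9), strrep("A", 9))  # outside untouched

  # the two N positions of the B-box vary across draws
  draws <- vapply(1:30, function(i)
    substr(plant_element(s, "GGTTCGANNCC", 5), 12, 13), "")
  expect_gt(length(unique(draws)), 1L)

  expect_error(plant_element(s, "GGTTCGANNCC", 35), "does not fit")
  expect_error(plant_element(s, "TT", 0), "does not fit")
})

test_that("generated promoter sets honour the species mix and record truth", {
  defs <- toy_defs()
  pure <- generate_promoter_set(100, c("core-less" = 1.0), defs, seed = 42)
  expect_true(all(pure$truth$species$species == "core-less"))
  expect_identical(nrow(pure$truth$elements), 0L)

  mixed <- generate_promoter_set(300, c("core-less" = 0.5, "ALPHA" = 0.5),
                                 defs, seed = 42)
  expect_identical(nrow(mixed$truth$species), 300L)
  n_alpha <- sum(mixed$truth$species$species == "ALPHA")
  expect_identical(nrow(mixed$truth$elements), n_alpha)
  expect_true(all(abs(mixed$truth$elements$shift) <= 5))
  # planted instances really match at the recorded positions
  el <- mixed$truth$elements
  idx <- match(el$gene_id, mixed$promoters$meta$gene_id)
  win <- substr(mixed$promoters$seq[idx],
                mixed$promoters$anchor + el$planted_start + 1L,
                mixed$promoters$anchor + el$planted_start + 10L)
  expect_true(all(iupac_match(win, "TACGGATCGT") |
                  iupac_match(win, "GGCTACTTAC")))

  expect_error(generate_promoter_set(10, c("NOPE" = 1.0), defs, seed = 1),
               "unknown element")
  expect_error(generate_promoter_set(10, c("core-less" = 0.7), defs,
                                     seed = 1), "sum to 1")
})

test_that("generation is deterministic and per-sequence substreams are stable", {
  defs <- toy_defs()
  a <- generate_promoter_set(50, c("ALPHA" = 1.0), defs, seed = 7)
  b <- generate_promoter_set(50, c("ALPHA" = 1.0), defs, seed = 7)
  expect_identical(a$promoters$seq, b$promoters$seq)
  expect_identical(a$truth, b$truth)
  # growing n never reshuffles earlier sequences
  big <- generate_promoter_set(80, c("ALPHA" = 1.0), defs, seed = 7)
  expect_identical(big$promoters$seq[1:50], a$promoters$seq)
  # a different seed changes the draw
  c <- generate_promoter_set(50, c("ALPHA" = 1.0), defs, seed = 8)
  expect_false(identical(a$promoters$seq, c$promoters$seq))
})

test_that("planted-shift distribution is uniform over the jitter range", {
  defs <- toy_defs()
  syn <- generate_promoter_set(2000, c("ALPHA" = 1.0), defs, seed = 42)
  shifts <- syn$truth$elements$shift
  tab <- table(factor(shifts, levels = -5:5))
  gof <- suppressWarnings(chisq.test(tab, p = rep(1 / 11, 11)))
  expect_gt(gof$p.value, 0.01)
  # and the scanner recovers that same distribution (toy elements are
  # degenerate-poor, so recovered == planted)
  hits <- scan_cpes(syn$promoters, defs)
  rec <- hits$shift[hits$element == "ALPHA"]
  expect_identical(as.integer(sort(table(rec))),
                   as.integer(sort(table(shifts))))
})

test_that("synthetic inputs round-trip through the standard I/O path", {
  defs <- toy_defs()
  syn <- generate_promoter_set(
    20, c("core-less" = 0.5, "ALPHA" = 0.5), defs, seed = 42,
    group = c(genomic_context = "intergenic", dhs_type = "promoter"))
  dir <- withr::local_tempdir()
  paths <- write_synthetic_inputs(syn, dir)
  genome <- read_genome_fasta(paths$genome)
  tss <- read_tss_table(paths$tss)
  expect_identical(nrow(tss), 20L)
  expect_identical(unique(tss$genomic_context), "intergenic")
  back <- extract_promoters(genome, tss,
                            upstream = syn$promoters$anchor,
                            downstream = nchar(syn$promoters$seq[1]) -
                              syn$promoters$anchor - 1L)
  expect_identical(back$seq, syn$promoters$seq)
})
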