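test_that("IUPAC matching follows the standard code semantics", {
  expect_true(iupac_match("TATAAAAG", "TATAWAWR"))
  expect_true(iupac_match("GGTTCGATACC", "GGTTCGANNCC"))  # B-box instance
  expect_false(iupac_match("TANAAAAG", "TATAWAWR"))  # N in subject: never
  expect_false(iupac_match("TATACAAG", "TATAWAWR"))  # W excludes C
  expect_true(iupac_match("tataaaag", "TATAWAWR"))   # case folded
  expect_error(iupac_match("TATA", "TATAWAWR"), "length")
  expect_error(iupac_match("TATA", "TAXA"), "invalid IUPAC")
})

test_that("IUPAC matching agrees with Biostrings degenerate matching", {
  set.seed(42)
  consensi <- c("TATAWAWR", "BBCABW", "GGTTCGANNCC", "TRGYNNARBGG",
                "RGWYVT", "SSRCGCC")
  for (cs in consensi) {
    for (rep in 1:50) {
      w <- random_seq(nchar(cs))
      ref <- Biostrings::countPattern(
        Biostrings::DNAString(cs), Biostrings::DNAString(w),
        fixed = c(pattern = FALSE, subject = TRUE)) > 0L
      expect_identical(iupac_match(w, cs), ref, info = paste(cs, w))
    }
  }
})

make_set <- function(seqs, anchor) {
  promdpp:::new_promoter_set(
    seqs, anchor,
    data.frame(gene_id = sprintf("g%d", seq_along(seqs)),
               stringsAsFactors = FALSE))
}

test_that("scanning honours the shift tolerance and minimal-shift tie-break", {
  # 3-mer toy element so two in-window instances never overlap
  defs <- data.frame(name = "TOY", consensus = "TAT",
                     canonical_start = -30L, max_shift = 5L, source = "",
                     stringsAsFactors = FALSE)
  bg <- strrep("CG", 40)  # 80 nt, anchor at 50; no accidental TAT
  plant_at <- function(s, start) {  # TSS-relative start, 0-based idx 50+start
    at <- 50 + start
    paste0(substr(s, 1, at), "TAT", substr(s, at + 4, 80))
  }
  # planted at -28: shift +2
  h <- scan_cpes(make_set(plant_at(bg, -28), 50L), defs)
  expect_identical(h$shift, 2L)
  expect_identical(h$start, -28L)
  # planted at -36: shift -6 exceeds tolerance, no hit
  h <- scan_cpes(make_set(plant_at(bg, -36), 50L), defs)
  expect_identical(nrow(h), 0L)
  # matches at both -31 and -28: minimal |shift| wins
  h <- scan_cpes(make_set(plant_at(plant_at(bg, -31), -28), 50L), defs)
  expect_identical(h$start, -31L)
  # upstream wins an absolute-shift tie: matches at -32 and -28 only
  h <- scan_cpes(make_set(plant_at(plant_at(bg, -32), -28), 50L), defs)
  expect_identical(h$shift, -2L)
})

test_that("elements whose tolerance window leaves the sequence are unevaluable", {
  defs <- cpe_definitions()
  # 40 nt, anchor 20: only Inr's tolerance window (-8..+8 around -3) fits
  short <- make_set(strrep("CG", 20), 20L)
  h <- scan_cpes(short, defs)
  expect_setequal(attr(h, "unevaluable"), c("BREu", "TATA", "BREd", "DPE"))
  lab <- classify_promoters(h, defs)
  # Inr is still evaluable here, so labels are defined
  expect_false(anyNA(lab))
  # nothing evaluable -> NA labels, excluded from tabulation
  tiny <- make_set(strrep("CG", 3), 3L)
  h2 <- scan_cpes(tiny, cpe_definitions())
  lab2 <- classify_promoters(h2, cpe_definitions())
  expect_true(all(is.na(lab2)))
  expect_identical(nrow(tabulate_species("all", lab2)), 0L)
})

test_that("species labels join elements in canonical order, core-less when empty", {
  defs <- cpe_definitions()
  empty_hits <- data.frame(seq_index = integer(0), element = character(0),
                           start = integer(0), shift = integer(0))
  attr(empty_hits, "n_seq") <- 2L
  expect_identical(classify_promoters(empty_hits, defs),
                   c("core-less", "core-less"))
  # order comes from canonical_start, not hit order
  h <- data.frame(seq_index = c(1L, 1L), element = c("Inr", "TATA"),
                  start = c(-3L, -31L), shift = c(0L, 0L))
  attr(h, "n_seq") <- 1L
  expect_identical(classify_promoters(h, defs), "TATA+Inr")
  h2 <- h[2:1, ]; attr(h2, "n_seq") <- 1L
  expect_identical(classify_promoters(h2, defs), "TATA+Inr")  # permutation
})

test_that("species tabulation normalizes per group and reports top five", {
  lab <- c("core-less", "core-less", "Inr", "Inr")
  tab <- tabulate_species("g1", lab)
  expect_equal(tab$percent, c(50, 50))
  # independent groups each sum to 100
  tab2 <- tabulate_species(rep(c("a", "b"), each = 4),
                           c("x", "x", "y", "z", "x", "y", "y", "y"))
  sums <- tapply(tab2$percent, tab2$group, sum)
  expect_equal(as.numeric(sums), c(100, 100), tolerance = 1e-9)
  # 6 species in one group -> top-5 view has 5 rows
  tab3 <- tabulate_species("g", c(rep("s1", 6), rep("s2", 5), rep("s3", 4),
                                  rep("s4", 3), rep("s5", 2), "s6"))
  expect_identical(nrow(top_species(tab3)), 5L)
  expect_false("s6" %in% top_species(tab3)$species)
})

test_that("planted elements are recovered exactly; |jitter|=6 yields none", {
  defs <- toy_defs()
  mix <- c("ALPHA+BETA" = 1.0)
  syn <- generate_promoter_set(1000, mix, defs, seed = 42)
  hits <- scan_cpes(syn$promoters, defs)
  truth <- syn$truth$elements
  key <- function(d, el) d[d$element == el, ]
  for (el in defs$name) {
    ht <- key(hits, el); tt <- key(truth, el)
    expect_identical(nrow(ht), 1000L)
    got <- ht$shift[order(ht$seq_index)]
    want <- tt$shift[order(tt$gene_id)]
    expect_identical(as.integer(got), as.integer(want))
  }
  # forced shift +-6: outside the tolerance window, zero recoveries
  for (forced in c(-6L, 6L)) {
    syn6 <- generate_promoter_set(300, mix, defs, jitter = c(forced, forced),
                                  seed = 42)
    h6 <- scan_cpes(syn6$promoters, defs)
    expect_identical(nrow(h6), 0L)
  }
})
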