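test_that("FASTA reading handles wrapping, case and duplicate names", {
  tmp <- withr::local_tempfile(fileext = ".fa")
  write_fasta_text(list(chr1 = "ACGTacgtACGT", chr2 = "TTTTGGGG"), tmp,
                   width = 5L)
  g <- read_genome_fasta(tmp)
  expect_named(g, c("chr1", "chr2"))
  expect_identical(g[["chr1"]], "ACGTacgtACGT")  # wrap undone, case kept

  write_fasta_text(list(chr1 = "ACGT", chr1 = "TTTT"), tmp)
  expect_error(read_genome_fasta(tmp), "duplicate contig")

  writeLines(character(0), tmp)
  expect_error(read_genome_fasta(tmp), "empty|read")
})

test_that("TSS table parsing follows BED conventions and flags bad rows", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_bed_rows(c("chr1\t99\t100\tgeneA\t5.2\t+"), tmp)
  t <- read_tss_table(tmp)
  expect_identical(t$pos, 99L)
  expect_identical(t$strand, "+")

  write_bed_rows(c("chr1\t99\t100\tgeneA\t5.2\t."), tmp)
  expect_error(read_tss_table(tmp), "line 1.*strand")

  write_bed_rows(c("chr1\t99\t101\tgeneA\t5.2\t+"), tmp)
  expect_error(read_tss_table(tmp), "line 1.*coordinates")

  write_bed_rows(c(
    "# comment",
    "chr1\t10\t11\tg1\t1\t+\tgenomic_context=intergenic;dhs_type=promoter",
    "chr1\t20\t21\tg2\t2\t-"), tmp)
  t <- read_tss_table(tmp)
  expect_identical(t$genomic_context, c("intergenic", NA))
  expect_identical(t$dhs_type, c("promoter", NA))
})

test_that("representative TSS selection keeps the top score with deterministic ties", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_bed_rows(c(
    "chr1\t100\t101\tgeneA\t3.0\t+",
    "chr1\t150\t151\tgeneA\t7.1\t+",
    "chr2\t10\t11\tgeneB\t1.0\t-",
    "chr1\t200\t201\tgeneC\t5.0\t+",
    "chr1\t100\t101\tgeneC\t5.0\t+"), tmp)
  r <- select_representative_tss(read_tss_table(tmp))
  expect_identical(nrow(r), 3L)
  expect_identical(r$pos[r$gene_id == "geneA"], 150L)   # highest score
  expect_identical(r$pos[r$gene_id == "geneB"], 10L)    # singleton
  expect_identical(r$pos[r$gene_id == "geneC"], 100L)   # tie -> smaller pos
  expect_identical(anyDuplicated(r$gene_id), 0L)
})

test_that("subsampling is reproducible and bounds-checked", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_bed_rows(sprintf("chr1\t%d\t%d\tg%02d\t1\t+", 1:10, 2:11, 1:10), tmp)
  t <- read_tss_table(tmp)
  expect_setequal(sample_records(t, 10, seed = 1)$gene_id, t$gene_id)
  s1 <- sample_records(t, 4, seed = 99)
  s2 <- sample_records(t, 4, seed = 99)
  expect_identical(s1$gene_id, s2$gene_id)
  expect_identical(nrow(sample_records(t, 0, seed = 1)), 0L)
  expect_error(sample_records(t, 11, seed = 1), "cannot sample")
})

test_that("promoter extraction slices strand-aware windows anchored at the TSS", {
  genome <- c(chrT = "ACGTACGTAC")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_bed_rows(c("chrT\t4\t5\tgp\t1\t+",
                   "chrT\t4\t5\tgm\t1\t-"), tmp)
  t <- read_tss_table(tmp)
  p <- extract_promoters(genome, t[1, ], upstream = 2, downstream = 2)
  expect_identical(p$seq, "GTACG")
  expect_identical(p$anchor, 2L)
  m <- extract_promoters(genome, t[2, ], upstream = 2, downstream = 2)
  expect_identical(m$seq, "CGTAC")   # revcomp of genome[2..6] = "GTACG"
  # anchor base is the complement of the genomic TSS base
  expect_identical(substr(m$seq, 3, 3), "T")

  # edge overrun: skipped with a warning, counted
  write_bed_rows("chrT\t1\t2\tge\t1\t+", tmp)
  expect_warning(pe <- extract_promoters(genome, read_tss_table(tmp),
                                         upstream = 5, downstream = 0),
                 "skipped")
  expect_identical(length(pe), 0L)
  expect_identical(attr(pe, "skipped"), 1L)
})

test_that("extraction invariants hold on random genomes", {
  set.seed(42)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (rep in 1:20) {
    g <- c(chr = random_seq(200))
    pos <- sample(50:150, 1L)
    rec <- data.frame(chrom = "chr", pos = pos,
                      strand = sample(c("+", "-"), 1L),
                      gene_id = "g", score = 1, stringsAsFactors = FALSE)
    U <- sample(5:20, 1L)
    p <- extract_promoters(g, rec, upstream = U, downstream = U)
    expect_identical(nchar(p$seq), 2L * U + 1L)
    base <- substr(g[["chr"]], pos + 1L, pos + 1L)
    anchor_base <- substr(p$seq, U + 1L, U + 1L)
    expect_identical(anchor_base,
                     if (rec$strand == "+") base else unname(comp[base]))
    # '+' and '-' extracts of the same symmetric window are revcomps
    rec2 <- rec; rec2$strand <- if (rec$strand == "+") "-" else "+"
    p2 <- extract_promoters(g, rec2, upstream = U, downstream = U)
    expect_identical(p2$seq, revcomp(p$seq))
  }
})
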