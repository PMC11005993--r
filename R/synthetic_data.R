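# Deterministic per-record substream: record i depends only on (seed, i), so
# growing n never reshuffles earlier records.
subseed <- function(seed, i) (as.integer(seed) %% 1000003L) * 2011L + 7L * i

#' Generate an i.i.d. background sequence with given GC content
#'
#' Bases are drawn independently with P(G) = P(C) = gc/2 and
#' P(A) = P(T) = (1 - gc)/2, using the current RNG state (seed at a higher
#' level for reproducibility).
#'
#' @param length Sequence length.
#' @param gc GC fraction in [0, 1].
#' @return A nucleotide string.
#' @export
generate_background <- function(length, gc = 0.5) {
  if (is.na(gc) || gc < 0 || gc > 1) stop("gc must lie in [0, 1]")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
}

#' Plant an IUPAC consensus instance into a sequence
#'
#' Replaces the bases starting at \code{at} with a concrete instance of the
#' consensus: each position is drawn uniformly from its IUPAC code's base set
#' (so N positions vary between draws), guaranteeing [iupac_match()] is true
#' at \code{at} afterwards.  Uses the current RNG state.
#'
#' @param seq Nucleotide string.
#' @param consensus IUPAC consensus to plant.
#' @param at 1-based start position within \code{seq}.
#' @return The modified sequence.
#' @export
plant_element <- function(seq, consensus, at) {
  w <- nchar(consensus)
  if (at < 1L || at + w - 1L > nchar(seq))
    stop("element does not fit: start ", at, ", width ", w,
         ", sequence length ", nchar(seq))
  codes <- strsplit(toupper(consensus), "", fixed = TRUE)[[1L]]
  bad <- codes[!codes %in% names(IUPAC_SETS)]
  if (length(bad)) stop("invalid IUPAC code: '", bad[1L], "'")
  inst <- vapply(codes, function(c) {
    s <- strsplit(IUPAC_SETS[[c]], "", fixed = TRUE)[[1L]]
    if (length(s) == 1L) s else sample(s, 1L)
  }, "")
  paste0(substr(seq, 1L, at - 1L), paste(inst, collapse = ""),
         substr(seq, at + w, nchar(seq)))
}

check_species_mix <- function(species_mix, defs) {
  if (abs(sum(species_mix) - 1) > 1e-8)
    stop("species_mix probabilities must sum to 1")
  for (sp in names(species_mix)) {
    if (sp == "core-less") next
    els <- strsplit(sp, "+", fixed = TRUE)[[1L]]
    unknown <- setdiff(els, defs$name)
    if (length(unknown))
      stop("unknown element '", unknown[1L], "' in species label '", sp, "'")
  }
  invisible(TRUE)
}

#' Generate a synthetic promoter set with recorded ground truth
#'
#' Emulates an anchored promoter collection: each sequence is i.i.d.
#' background of the given GC content with the TSS at a fixed offset; its
#' species is drawn from \code{species_mix}, and for a non-core-less species
#' each listed element is planted at its canonical start plus an integer
#' jitter drawn uniformly from \code{jitter}.  Accidental background matches
#' to element consensi are possible and deliberately NOT suppressed (real
#' genomes have them too); quantify them by scanning a zero-plant control
#' set.  A single integer seed governs everything, with per-sequence
#' substreams derived from (seed, index) so earlier sequences are unchanged
#' when n grows.
#'
#' @param n Number of promoters.
#' @param species_mix Named probabilities over species labels ("core-less" or
#'   '+'-joined element names from \code{defs}).
#' @param defs Element definitions ([cpe_definitions()] by default).
#' @param length,anchor Sequence length and 0-based TSS offset (defaults 151
#'   and 100, i.e. -100..+50).
#' @param gc Background GC fraction (default 0.5).
#' @param jitter Integer range \code{c(lo, hi)} of planted-element shifts
#'   (default \code{c(-5, 5)}).
#' @param seed Integer master seed.
#' @param group Optional named character vector of metadata (e.g.
#'   \code{c(genomic_context = "intergenic", dhs_type = "promoter")}) applied
#'   to every record.
#' @param id_prefix Prefix for generated gene ids.
#' @return A list of class \code{synth_promoters}: \code{promoters} (a
#'   \code{promoter_set}), \code{truth} (data frames \code{species} and
#'   \code{elements} with planted starts and shifts) and \code{params}.
#' @export
generate_promoter_set <- function(n, species_mix = c("core-less" = 0.55,
                                                     "Inr" = 0.30,
                                                     "TATA+Inr" = 0.15),
                                  defs = cpe_definitions(),
                                  length = 151L, anchor = 100L, gc = 0.5,
                                  jitter = c(-5L, 5L), seed = 1L,
                                  group = NULL, id_prefix = "synth") {
  length <- as.integer(length); anchor <- as.integer(anchor)
  if (anchor >= length) stop("anchor must be < length")
  check_species_mix(species_mix, defs)
  jit <- jitter[1L]:jitter[2L]
  seqs <- character(n)
  species <- character(n)
  elements <- vector("list", n)
  ids <- sprintf("%s%05d", id_prefix, seq_len(n))
  for (i in seq_len(n)) {
    set.seed(subseed(seed, i))
    sp <- sample(names(species_mix), 1L, prob = species_mix)
    s <- generate_background(length, gc)
    if (sp != "core-less") {
      els <- strsplit(sp, "+", fixed = TRUE)[[1L]]
      rows <- lapply(els, function(e) {
        d <- defs[defs$name == e, , drop = FALSE]
        sh <- if (base::length(jit) == 1L) jit else sample(jit, 1L)
        start <- d$canonical_start + sh
        s <<- plant_element(s, d$consensus, anchor + start + 1L)
        data.frame(gene_id = ids[i], element = e, planted_start = start,
                   shift = sh, stringsAsFactors = FALSE)
      })
      elements[[i]] <- do.call(rbind, rows)
    }
    seqs[i] <- s
    species[i] <- sp
  }
  meta <- data.frame(gene_id = ids, stringsAsFactors = FALSE)
  if (!is.null(group)) for (k in names(group)) meta[[k]] <- group[[k]]
  truth_el <- if (any(!vapply(elements, is.null, TRUE)))
    do.call(rbind, c(elements[!vapply(elements, is.null, TRUE)],
                     make.row.names = FALSE))
  else data.frame(gene_id = character(0), element = character(0),
                  planted_start = integer(0), shift = integer(0),
                  stringsAsFactors = FALSE)
  structure(
    list(promoters = new_promoter_set(seqs, anchor, meta),
         truth = list(species = data.frame(gene_id = ids, species = species,
                                           stringsAsFactors = FALSE),
                      elements = truth_el),
         params = list(n = n, species_mix = species_mix, length = length,
                       anchor = anchor, gc = gc, jitter = jitter,
                       seed = seed, group = group)),
    class = "synth_promoters")
}

#' @export
print.synth_promoters <- function(x, ...) {
  cat("Synthetic promoter set: n =", x$params$n, "| species mix:",
      paste(names(x$params$species_mix), x$params$species_mix,
            sep = "=", collapse = ", "), "\n")
  print(x$promoters)
  invisible(x)
}

#' Generate synthetic tRNA genes with A-box/B-box structure
#'
#' Builds one contig per gene containing, in transcript orientation: a
#' background neighborhood, a TSS, a short leader, the mature 5' end, an
#' A-box instance (consensus TGGCNNAGTGG) at a fixed offset from the mature
#' 5' end, a variable A-B spacer (emulating the irregular spacing created by
#' introns and variable loops), a B-box instance (consensus GGTTCGANNCC) and
#' a discriminator base downstream.  Genes are placed on random strands so
#' strand handling is exercised.  Annotations satisfy
#' \code{tss <= mature5 < discriminator} in transcript orientation.
#'
#' @param n Number of genes.
#' @param seed Integer master seed (per-gene substreams as in
#'   [generate_promoter_set()]).
#' @param abox_offset Offset of the A-box start from the mature 5' end
#'   (default 7).
#' @param gc Background GC fraction.
#' @return A list of class \code{synth_trna}: \code{genome} (named character
#'   vector of contigs), \code{annotations} (data frame compatible with
#'   [read_trna_table()] semantics: gene_id, chrom, strand, tss, mature5,
#'   discriminator, tpm, pos, score) and \code{truth} (planted box offsets).
#' @export
generate_trna_set <- function(n, seed = 1L, abox_offset = 7L, gc = 0.5) {
  if (n < 1L) stop("n must be >= 1")
  ABOX <- "TGGCNNAGTGG"; BBOX <- "GGTTCGANNCC"
  contig_len <- 220L
  genome <- character(n)
  ann <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(subseed(seed, i) + 104729L)
    s <- generate_background(contig_len, gc)
    tss_t <- 80L
    leader <- sample(4:12, 1L)
    mature5_t <- tss_t + leader
    abox_t <- mature5_t + abox_offset
    spacer <- sample(15:30, 1L)
    bbox_t <- abox_t + nchar(ABOX) + spacer
    gap <- sample(5:15, 1L)
    disc_t <- bbox_t + nchar(BBOX) - 1L + gap
    stopifnot(disc_t < contig_len)
    s <- plant_element(s, ABOX, abox_t + 1L)
    s <- plant_element(s, BBOX, bbox_t + 1L)
    strand <- sample(c("+", "-"), 1L)
    if (strand == "+") {
      contig <- s
      g <- function(t) t
    } else {
      contig <- revcomp(s)
      g <- function(t) contig_len - 1L - t
    }
    genome[i] <- contig
    chrom <- sprintf("synthchr%04d", i)
    ann[[i]] <- data.frame(
      gene_id = sprintf("trna%04d", i), chrom = chrom, strand = strand,
      tss = g(tss_t), mature5 = g(mature5_t), discriminator = g(disc_t),
      tpm = round(stats::runif(1L, 1, 100), 2L), stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(
      gene_id = sprintf("trna%04d", i), leader = leader,
      abox_offset = abox_offset, spacer = spacer,
      bbox_end_to_discriminator = gap, stringsAsFactors = FALSE)
    names(genome)[i] <- chrom
  }
  anns <- do.call(rbind, c(ann, make.row.names = FALSE))
  anns$pos <- anns$tss
  anns$score <- anns$tpm
  structure(list(genome = genome, annotations = anns,
                 truth = do.call(rbind, c(truth, make.row.names = FALSE))),
            class = "synth_trna")
}

#' Write a synthetic promoter set as FASTA + TSS table
#'
#' Serializes a synthetic set into the same external formats real data
#' arrives in — one contig per promoter (named by gene id, TSS at the anchor
#' offset, '+' strand) plus a BED6+metadata TSS table — so synthetic data
#' flows through the identical I/O path as downloaded data.  Truth tables are
#' written alongside.
#'
#' @param synth A \code{synth_promoters} (or a list of them, concatenated).
#' @param dir Output directory (created if needed).
#' @param basename File stem (default "synthetic").
#' @return Invisibly, a named list of written paths (\code{genome},
#'   \code{tss}, \code{truth_species}, \code{truth_elements}).
#' @export
write_synthetic_inputs <- function(synth, dir, basename = "synthetic") {
  if (inherits(synth, "synth_promoters")) synth <- list(synth)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, paste0(basename, "_genome.fa"))
  tsv <- file.path(dir, paste0(basename, "_tss.tsv"))
  tsp <- file.path(dir, paste0(basename, "_truth_species.tsv"))
  tel <- file.path(dir, paste0(basename, "_truth_elements.tsv"))
  seqs <- character(0); rows <- character(0)
  spc <- list(); elc <- list()
  for (s in synth) {
    p <- s$promoters
    seqs <- c(seqs, stats::setNames(p$seq, p$meta$gene_id))
    meta_cols <- setdiff(names(p$meta), "gene_id")
    meta_str <- if (length(meta_cols))
      apply(p$meta[meta_cols], 1L, function(r)
        paste(paste0(meta_cols, "=", r), collapse = ";"))
    else rep("", length(p))
    rows <- c(rows, paste(p$meta$gene_id, p$anchor, p$anchor + 1L,
                          p$meta$gene_id, 1, "+", meta_str, sep = "\t"))
    spc[[length(spc) + 1L]] <- s$truth$species
    elc[[length(elc) + 1L]] <- s$truth$elements
  }
  if (anyDuplicated(names(seqs)))
    stop("duplicate gene ids across synthetic sets; use distinct id_prefix")
  write_genome_fasta(seqs, fa)
  writeLines(rows, tsv)
  utils::write.table(do.call(rbind, spc), tsp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(do.call(rbind, elc), tel, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(genome = fa, tss = tsv, truth_species = tsp,
                 truth_elements = tel))
}

#' Write a synthetic tRNA set as FASTA + annotation table
#'
#' @param synth A \code{synth_trna}.
#' @param dir Output directory.
#' @param basename File stem.
#' @return Invisibly, list of written paths (\code{genome}, \code{trna}).
#' @export
write_synthetic_trna <- function(synth, dir, basename = "synthetic_trna") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fa <- file.path(dir, paste0(basename, "_genome.fa"))
  tsv <- file.path(dir, paste0(basename, ".tsv"))
  write_genome_fasta(synth$genome, fa)
  cols <- c("gene_id", "chrom", "strand", "tss", "mature5", "discriminator",
            "tpm")
  utils::write.table(synth$annotations[cols], tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(list(genome = fa, trna = tsv))
}
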