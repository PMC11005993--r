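#' Read a tRNA gene annotation table
#'
#' TSV with a header and columns \code{gene_id}, \code{chrom}, \code{strand},
#' \code{tss}, \code{mature5}, \code{discriminator} (all 0-based genomic
#' coordinates) and \code{tpm}.  One row per candidate TSS; pass through
#' [select_representative_tss()] (scores = TPM) to keep the highest-TPM TSS
#' per gene.  Coordinates must satisfy, in transcript orientation,
#' \code{tss <= mature5 < discriminator}.
#'
#' @param path Path to the TSV.
#' @return A data frame with the columns above plus \code{pos} (== tss) and
#'   \code{score} (== tpm) so the representative-TSS selector applies
#'   unchanged.
#' @export
read_trna_table <- function(path) {
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss", "mature5", "discriminator",
            "tpm")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("tRNA table missing column(s): ", paste(miss, collapse = ", "))
  if (!all(d$strand %in% c("+", "-")))
    stop("unknown strand in tRNA table")
  # transcript-orientation ordering: on '-' genomic coordinates run backwards
  fwd <- d$strand == "+"
  ok <- ifelse(fwd,
               d$tss <= d$mature5 & d$mature5 < d$discriminator,
               d$tss >= d$mature5 & d$mature5 > d$discriminator)
  if (!all(ok))
    stop("row ", which(!ok)[1L],
         ": coordinates violate tss <= mature5 < discriminator ",
         "(transcript orientation)")
  d$pos <- as.integer(d$tss)
  d$score <- as.numeric(d$tpm)
  d
}

trna_extract <- function(genome, ann, anchor_col, upstream, downstream) {
  recs <- data.frame(chrom = ann$chrom, pos = as.integer(ann[[anchor_col]]),
                     strand = ann$strand, gene_id = ann$gene_id,
                     score = ann$score %||% 0, stringsAsFactors = FALSE)
  extract_promoters(genome, recs, upstream = upstream,
                    downstream = downstream)
}

#' tRNA 5'-flanking region (TSS to -50)
#'
#' The 51-nt sense-strand region covering TSS-relative positions -50..0, the
#' tRNA analogue of a Pol II core promoter, anchored at the TSS (position 0).
#'
#' @param genome Named character vector from [read_genome_fasta()].
#' @param ann Annotation data frame from [read_trna_table()] (one row per
#'   gene after representative-TSS selection).
#' @return A \code{promoter_set} of 51-nt sequences, anchor 50.
#' @export
trna_upstream_region <- function(genome, ann)
  trna_extract(genome, ann, "tss", upstream = 50L, downstream = 0L)

#' tRNA A-box-containing region (mature 5' end to +30)
#'
#' The 31-nt sense-strand region from the position corresponding to the
#' mature tRNA 5' end (anchor, position 0) to +30; contains the gene-internal
#' A-box promoter element.
#'
#' @inheritParams trna_upstream_region
#' @return A \code{promoter_set} of 31-nt sequences, anchor 0.
#' @export
trna_abox_region <- function(genome, ann)
  trna_extract(genome, ann, "mature5", upstream = 0L, downstream = 30L)

#' tRNA B-box-containing region (discriminator to -30)
#'
#' The 31-nt sense-strand region from position -30 to the discriminator base
#' (anchor, position 0); contains the gene-internal B-box promoter element.
#'
#' @inheritParams trna_upstream_region
#' @return A \code{promoter_set} of 31-nt sequences, anchor 30.
#' @export
trna_bbox_region <- function(genome, ann)
  trna_extract(genome, ann, "discriminator", upstream = 30L, downstream = 0L)
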