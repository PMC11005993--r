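#' Reverse complement, preserving case and IUPAC codes
#'
#' Biostrings' reverseComplement() normalises soft-masked lowercase to
#' uppercase; this utility keeps case so masking-aware callers can still see
#' it after strand flipping.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  y <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
              "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  vapply(strsplit(y, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), "")
}

#' Read a genome FASTA into a named vector of sequences
#'
#' Wraps Biostrings FASTA parsing but returns plain character strings with the
#' original case preserved (soft-masked regions stay lowercase).  Record names
#' are the FASTA identifiers up to the first whitespace.
#'
#' @param path Path to a (possibly line-wrapped, multi-record) FASTA file.
#' @return Named character vector, one element per contig.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("empty FASTA: ", path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids))
    stop("duplicate contig name in FASTA: ", ids[duplicated(ids)][1L])
  stats::setNames(as.character(x), ids)
}

#' Write sequences to FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, \code{path}.
#' @export
write_genome_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a TSS table (BED6 + metadata dialect)
#'
#' Expects tab-separated BED6 rows (chrom, start, end, name, score, strand)
#' describing single-base, 0-based half-open intervals (end == start + 1); the
#' TSS coordinate is \code{start}.  An optional 7th column carries
#' semicolon-delimited \code{key=value} metadata (e.g.
#' \code{genomic_context=intergenic;dhs_type=promoter}) which is expanded into
#' additional columns.
#'
#' @param path Path to the TSV file.  Lines starting '#' are skipped.
#' @return A \code{data.frame} (class \code{tss_table}) with columns
#'   \code{chrom}, \code{pos} (0-based), \code{strand}, \code{gene_id},
#'   \code{score}, plus one column per metadata key.
#' @export
read_tss_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(empty_tss_table())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 6L))
    stop("line ", lineno[which(nf < 6L)[1L]],
         ": expected at least 6 tab-separated BED fields")
  f <- function(i) vapply(parts, `[`, "", i)
  start <- suppressWarnings(as.numeric(f(2L)))
  end <- suppressWarnings(as.numeric(f(3L)))
  bad <- is.na(start) | is.na(end) | start < 0 | end != start + 1
  if (any(bad))
    stop("line ", lineno[which(bad)[1L]],
         ": malformed coordinates (need 0-based single-base interval)")
  strand <- f(6L)
  bad <- !strand %in% c("+", "-")
  if (any(bad))
    stop("line ", lineno[which(bad)[1L]], ": unknown strand '",
         strand[which(bad)[1L]], "'")
  score <- suppressWarnings(as.numeric(f(5L)))
  if (anyNA(score))
    stop("line ", lineno[which(is.na(score))[1L]], ": non-numeric score")
  out <- data.frame(chrom = f(1L), pos = as.integer(start), strand = strand,
                    gene_id = f(4L), score = score,
                    stringsAsFactors = FALSE)
  # expand key=value;key=value metadata
  meta_raw <- ifelse(nf >= 7L, vapply(parts, function(p)
    if (length(p) >= 7L) p[7L] else "", ""), "")
  if (any(nzchar(meta_raw))) {
    kvs <- lapply(meta_raw, function(s) {
      if (!nzchar(s)) return(character(0))
      pieces <- strsplit(s, ";", fixed = TRUE)[[1L]]
      pieces <- pieces[nzchar(pieces)]
      kv <- strsplit(pieces, "=", fixed = TRUE)
      stats::setNames(vapply(kv, function(z) paste(z[-1L], collapse = "="), ""),
                      vapply(kv, `[`, "", 1L))
    })
    keys <- unique(unlist(lapply(kvs, names)))
    for (k in keys)
      out[[k]] <- vapply(kvs, function(v)
        if (k %in% names(v)) v[[k]] else NA_character_, "")
  }
  class(out) <- c("tss_table", "data.frame")
  out
}

empty_tss_table <- function() {
  out <- data.frame(chrom = character(0), pos = integer(0),
                    strand = character(0), gene_id = character(0),
                    score = numeric(0), stringsAsFactors = FALSE)
  class(out) <- c("tss_table", "data.frame")
  out
}

#' Select one representative TSS per gene
#'
#' Keeps, for each \code{gene_id}, the record with the highest score (TIEScore
#' for Pol II promoters, TPM for tRNA TSSs).  Ties are broken
#' deterministically: smallest genomic coordinate first, then lexicographic
#' chromosome name.
#'
#' @param records A \code{tss_table} data frame.
#' @return The subset with exactly one row per distinct \code{gene_id}.
#' @export
select_representative_tss <- function(records) {
  if (nrow(records) == 0L) return(records)
  ord <- order(records$gene_id, -records$score, records$pos, records$chrom)
  r <- records[ord, , drop = FALSE]
  r <- r[!duplicated(r$gene_id), , drop = FALSE]
  rownames(r) <- NULL
  r
}

#' Randomly subsample TSS records without replacement
#'
#' @param records A \code{tss_table}.
#' @param n Number of records to keep (\code{n <= nrow(records)}).
#' @param seed Integer seed; the same seed always yields the same subsample.
#' @return A \code{tss_table} with \code{n} rows.
#' @export
sample_records <- function(records, n, seed) {
  n <- as.integer(n)
  if (n > nrow(records))
    stop("cannot sample ", n, " from ", nrow(records), " records")
  set.seed(as.integer(seed))
  idx <- sample.int(nrow(records), n)
  out <- records[idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}

new_promoter_set <- function(seq, anchor, meta) {
  structure(list(seq = seq, anchor = as.integer(anchor), meta = meta),
            class = "promoter_set")
}

#' @export
length.promoter_set <- function(x) length(x$seq)

#' @export
`[.promoter_set` <- function(x, i) {
  new_promoter_set(x$seq[i], x$anchor, x$meta[i, , drop = FALSE])
}

#' @export
print.promoter_set <- function(x, ...) {
  cat("Promoter set:", length(x), "sequences of length",
      if (length(x)) nchar(x$seq[1L]) else 0L,
      "- anchor (TSS) at offset", x$anchor, "\n")
  extra <- setdiff(names(x$meta),
                   c("chrom", "pos", "strand", "gene_id", "score"))
  if (length(extra)) cat("  metadata:", paste(extra, collapse = ", "), "\n")
  sk <- attr(x, "skipped")
  if (!is.null(sk) && sk > 0L) cat("  (", sk, "records skipped at contig edges)\n")
  invisible(x)
}

#' Extract strand-aware, TSS-anchored promoter windows
#'
#' For each TSS record, extracts the window covering TSS-relative positions
#' \code{-upstream .. +downstream} on the sense strand of the gene: on '+' the
#' genomic slice \code{[pos-upstream, pos+downstream]} (0-based, inclusive),
#' on '-' the reverse complement of \code{[pos-downstream, pos+upstream]}.
#' Every returned sequence has length \code{upstream + downstream + 1} with
#' the TSS base at offset \code{upstream}.  Records whose window overruns a
#' contig end are skipped (padding would distort per-position n in downstream
#' profiles); the skip count is attached as attribute \code{"skipped"} and a
#' summarizing warning is raised.
#'
#' @param genome Named character vector from [read_genome_fasta()].
#' @param records A \code{tss_table}.
#' @param upstream,downstream Non-negative window half-widths in bp.
#' @return A \code{promoter_set}: list with \code{seq} (character vector),
#'   \code{anchor} (== \code{upstream}) and \code{meta} (the kept records).
#' @export
extract_promoters <- function(genome, records, upstream = 100L,
                              downstream = 50L) {
  upstream <- as.integer(upstream); downstream <- as.integer(downstream)
  stopifnot(upstream >= 0L, downstream >= 0L)
  n <- nrow(records)
  seqs <- character(n)
  ok <- logical(n)
  for (i in seq_len(n)) {
    chrom <- records$chrom[i]
    if (!chrom %in% names(genome)) next
    L <- nchar(genome[[chrom]])
    pos <- records$pos[i]
    if (records$strand[i] == "+") {
      g0 <- pos - upstream; g1 <- pos + downstream
    } else {
      g0 <- pos - downstream; g1 <- pos + upstream
    }
    if (g0 < 0L || g1 >= L) next
    s <- substr(genome[[chrom]], g0 + 1L, g1 + 1L)
    if (records$strand[i] == "-") s <- revcomp(s)
    seqs[i] <- s
    ok[i] <- TRUE
  }
  if (any(!ok))
    warning(sum(!ok), " of ", n,
            " records skipped (window overruns contig or unknown contig): ",
            paste(utils::head(records$gene_id[!ok], 5L), collapse = ", "),
            if (sum(!ok) > 5L) ", ..." else "")
  out <- new_promoter_set(seqs[ok], upstream, records[ok, , drop = FALSE])
  attr(out, "skipped") <- sum(!ok)
  attr(out, "n_input") <- n
  out
}
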