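IUPAC_SETS <- c(A = "A", C = "C", G = "G", T = "T",
                R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

iupac_regex <- function(consensus, anchored = TRUE) {
  ch <- strsplit(toupper(consensus), "", fixed = TRUE)[[1L]]
  bad <- ch[!ch %in% names(IUPAC_SETS)]
  if (length(bad)) stop("invalid IUPAC code in consensus: '", bad[1L], "'")
  body <- paste0(vapply(ch, function(c) {
    s <- IUPAC_SETS[[c]]
    if (nchar(s) == 1L) s else paste0("[", s, "]")
  }, ""), collapse = "")
  if (anchored) paste0("^", body, "$") else body
}

#' Match a concrete window against an IUPAC consensus
#'
#' True iff every base of \code{window} belongs to the set denoted by the
#' corresponding IUPAC code of \code{consensus} (N = any of ACGT, R = A/G,
#' Y = C/T, W = A/T, B = C/G/T, ...).  Degeneracy applies to the consensus
#' only: a non-ACGT character in the window (N, ambiguity code, gap) never
#' matches anything.  Lowercase bases are folded to uppercase first.
#'
#' @param window Nucleotide string, same length as the consensus.
#' @param consensus IUPAC consensus string.
#' @return Logical; vectorized over \code{window}.
#' @examples
#' iupac_match("TATAAAAG", "TATAWAWR")   # TRUE
#' iupac_match("GGTTCGATACC", "GGTTCGANNCC")  # TRUE (B-box)
#' @export
iupac_match <- function(window, consensus) {
  if (any(nchar(window) != nchar(consensus)))
    stop("window and consensus lengths differ")
  grepl(iupac_regex(consensus), toupper(window))
}

#' Core promoter element definitions
#'
#' Loads an element-definition table: one row per element with its name,
#' IUPAC consensus, canonical TSS-relative start (TSS = 0, first base of the
#' consensus) and the allowed positional deviation \code{max_shift} (default
#' 5 bp, applied to the whole consensus window).  With no \code{path} the
#' packaged default set is returned: the human TATA, Inr, BREu, BREd and DPE
#' definitions at their canonical windows.
#'
#' @param path Optional path to a TSV with columns \code{name},
#'   \code{consensus}, \code{canonical_start}, \code{max_shift},
#'   \code{source}; '#' lines are comments.
#' @return A data frame of element definitions.
#' @export
cpe_definitions <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cpe_elements.tsv", package = "promdpp")
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("name", "consensus", "canonical_start", "max_shift")
  if (!all(need %in% names(d)))
    stop("element definition file must have columns: ",
         paste(need, collapse = ", "))
  if (!"source" %in% names(d)) d$source <- ""
  d$consensus <- toupper(d$consensus)
  bad <- !nzchar(d$consensus)
  if (any(bad)) stop("empty consensus for element ", d$name[bad][1L])
  for (cs in d$consensus) iupac_regex(cs)  # validates codes
  if (any(d$max_shift < 0)) stop("max_shift must be non-negative")
  d
}

# shift search order: 0, -1, +1, -2, +2, ... (upstream wins ties)
shift_order <- function(max_shift) {
  if (max_shift == 0L) return(0L)
  c(0L, as.vector(rbind(-seq_len(max_shift), seq_len(max_shift))))
}

#' Scan promoters for core promoter elements
#'
#' For each element and each promoter, tests the consensus at every start
#' within \code{canonical_start +/- max_shift} and keeps at most one hit: the
#' match with minimal absolute shift, with the upstream (negative) shift
#' winning ties.  The search is on the sense strand only.  An element whose
#' full tolerance window (canonical window widened by \code{max_shift}) does
#' not fit inside the extracted promoter sequence is unevaluable for this set
#' and reported in the \code{"unevaluable"} attribute rather than scanned.
#'
#' @param promoters A \code{promoter_set}.
#' @param defs Element definitions from [cpe_definitions()].
#' @return A data frame of hits with columns \code{seq_index},
#'   \code{element}, \code{start} (TSS-relative first base of the match) and
#'   \code{shift} (= start - canonical_start); attribute \code{"unevaluable"}
#'   names the elements that could not be evaluated.
#' @export
scan_cpes <- function(promoters, defs) {
  stopifnot(inherits(promoters, "promoter_set"))
  n <- length(promoters)
  anchor <- promoters$anchor
  Lmin <- if (n) min(nchar(promoters$seq)) else 0L
  hits <- list()
  uneval <- character(0)
  for (j in seq_len(nrow(defs))) {
    cs <- defs$canonical_start[j]
    ms <- defs$max_shift[j]
    w <- nchar(defs$consensus[j])
    # 0-based string index range the tolerance window needs
    if (anchor + cs - ms < 0L || anchor + cs + ms + w > Lmin) {
      uneval <- c(uneval, defs$name[j])
      next
    }
    if (n == 0L) next
    pat <- iupac_regex(defs$consensus[j])
    found <- rep(NA_integer_, n)
    for (s in shift_order(ms)) {
      todo <- which(is.na(found))
      if (!length(todo)) break
      i0 <- anchor + cs + s  # 0-based start within seq
      win <- substr(promoters$seq[todo], i0 + 1L, i0 + w)
      m <- grepl(pat, toupper(win))
      found[todo[m]] <- s
    }
    got <- which(!is.na(found))
    if (length(got))
      hits[[defs$name[j]]] <- data.frame(
        seq_index = got, element = defs$name[j],
        start = cs + found[got], shift = found[got],
        stringsAsFactors = FALSE)
  }
  out <- if (length(hits)) do.call(rbind, c(hits, make.row.names = FALSE))
         else data.frame(seq_index = integer(0), element = character(0),
                         start = integer(0), shift = integer(0),
                         stringsAsFactors = FALSE)
  attr(out, "unevaluable") <- uneval
  attr(out, "n_seq") <- n
  out
}

#' Classify promoters into element species
#'
#' Turns per-promoter element hits into a species label: promoters with no
#' hits are "core-less"; otherwise the label is the '+'-joined element names
#' ordered by canonical start (e.g. "TATA+Inr").  Presence/absence only —
#' observed shifts are not part of the label.  If every element was
#' unevaluable for the set, labels are \code{NA} (excluded from tabulation)
#' rather than a misleading "core-less".
#'
#' @param hits Hit table from [scan_cpes()].
#' @param defs The element definitions used for the scan.
#' @param n Number of promoters scanned; defaults to the value recorded by
#'   [scan_cpes()].
#' @return Character vector of species labels, one per promoter.
#' @export
classify_promoters <- function(hits, defs, n = attr(hits, "n_seq")) {
  if (is.null(n)) stop("number of promoters unknown; pass n")
  evaluable <- setdiff(defs$name, attr(hits, "unevaluable"))
  if (length(evaluable) == 0L) return(rep(NA_character_, n))
  rank <- stats::setNames(order(order(defs$canonical_start, defs$name)),
                          defs$name)
  labels <- rep("core-less", n)
  if (nrow(hits)) {
    by_seq <- split(hits$element, hits$seq_index)
    lab <- vapply(by_seq, function(e)
      paste(e[order(rank[e])], collapse = "+"), "")
    labels[as.integer(names(by_seq))] <- lab
  }
  labels
}

#' Tabulate promoter species per group
#'
#' Counts species labels group by group and converts to percentages of each
#' group's denominator (promoters with an \code{NA} label are excluded).
#'
#' @param group Character vector of group keys (recycled if length 1).
#' @param species Character vector of species labels.
#' @return A \code{species_table} data frame with columns \code{group},
#'   \code{species}, \code{count}, \code{percent}, sorted within group by
#'   decreasing percentage (ties lexicographic by species).
#' @export
tabulate_species <- function(group, species) {
  if (length(group) == 1L) group <- rep(group, length(species))
  stopifnot(length(group) == length(species))
  keep <- !is.na(species)
  group <- group[keep]; species <- species[keep]
  if (!length(species))
    return(structure(data.frame(group = character(0), species = character(0),
                                count = integer(0), percent = numeric(0),
                                stringsAsFactors = FALSE),
                     class = c("species_table", "data.frame")))
  tab <- as.data.frame(table(group = group, species = species),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, , drop = FALSE]
  names(tab)[3L] <- "count"
  denom <- tapply(tab$count, tab$group, sum)
  tab$percent <- 100 * tab$count / as.numeric(denom[tab$group])
  tab <- tab[order(tab$group, -tab$percent, tab$species), , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, class = c("species_table", "data.frame"))
}

#' Top species per group
#'
#' @param tab A \code{species_table}.
#' @param k Number of species to keep per group (default 5, as in the
#'   standard top-five reporting of promoter species).
#' @return The \code{species_table} restricted to each group's top \code{k}
#'   species by percentage (ties broken lexicographically).
#' @export
top_species <- function(tab, k = 5L) {
  idx <- unlist(lapply(split(seq_len(nrow(tab)), tab$group),
                       function(i) utils::head(i, k)), use.names = FALSE)
  out <- tab[sort(idx), , drop = FALSE]
  rownames(out) <- NULL
  out
}
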