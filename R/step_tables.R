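DPP_FILES <- c(
  duplex_free_energy   = "dpp_duplex_free_energy.tsv",
  base_stacking_energy = "dpp_base_stacking_energy.tsv",
  deformability        = "dpp_deformability.tsv",
  rigidity             = "dpp_rigidity_synthetic.tsv",
  zdna_as_energy       = "dpp_zdna_as_energy.tsv"
)

all_kmers <- function(k) {
  b <- c("A", "C", "G", "T")
  if (k == 1L) return(b)
  sort(apply(expand.grid(rep(list(b), k), stringsAsFactors = FALSE),
             1L, paste, collapse = ""))
}

new_step_param_table <- function(property_name, step_size, units, values,
                                 source = "") {
  stopifnot(is.numeric(values), !is.null(names(values)))
  x <- structure(
    list(property_name = property_name,
         step_size = as.integer(step_size),
         units = units,
         values = values,
         source = source),
    class = "step_param_table"
  )
  validate_step_table(x)
  x
}

validate_step_table <- function(x) {
  k <- x$step_size
  if (!k %in% c(2L, 4L))
    stop("step_size must be 2 or 4, got ", k)
  keys <- names(x$values)
  bad_len <- keys[nchar(keys) != k]
  if (length(bad_len))
    stop("wrong key length for step_size ", k, ": ", bad_len[1L])
  bad_chr <- keys[grepl("[^ACGT]", keys)]
  if (length(bad_chr))
    stop("key contains characters outside {A,C,G,T}: ", bad_chr[1L])
  if (anyDuplicated(keys))
    stop("duplicate key: ", keys[duplicated(keys)][1L])
  miss <- setdiff(all_kmers(k), keys)
  if (length(miss))
    stop("missing key: ", miss[1L], " (", length(miss), " of ", 4L^k,
         " k-mers absent)")
  if (anyNA(x$values))
    stop("non-numeric or missing value for key: ",
         keys[is.na(x$values)][1L])
  invisible(x)
}

#' Load a DNA physical-property step-parameter table
#'
#' Reads a step-parameter file in the package's TSV dialect: '#'-prefixed
#' header lines carrying \code{property_name}, \code{step_size}, \code{units}
#' and \code{source} as \code{"# key: value"}, followed by one
#' \code{KMER<TAB>value} row per k-mer.  The table must be complete: exactly
#' 4^k rows, one for every k-mer over {A,C,G,T}, with k either 2
#' (dinucleotide steps) or 4 (tetranucleotide steps).
#'
#' @param path Path to a step-table TSV file.
#' @return An object of class \code{step_param_table}: a list with elements
#'   \code{property_name}, \code{step_size}, \code{units}, \code{values}
#'   (named numeric vector of length 4^k) and \code{source}.
#' @seealso [dpp_tables()] for the five packaged tables,
#'   [sequence_to_chain()] to apply a table to a sequence.
#' @export
load_step_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  dat <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  meta <- list(property_name = "unnamed", step_size = NA, units = "",
               source = "")
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", h))[[1L]]
    if (length(m) == 3L && m[2L] %in% names(meta)) meta[[m[2L]]] <- m[3L]
  }
  parts <- strsplit(dat, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("malformed row (expected KMER<TAB>value): '", dat[bad[1L]], "'")
  keys <- toupper(vapply(parts, `[`, "", 1L))
  vals <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  if (anyNA(vals))
    stop("non-numeric value in row: '", dat[which(is.na(vals))[1L]], "'")
  if (anyDuplicated(keys))
    stop("duplicate key: ", keys[duplicated(keys)][1L])
  k <- suppressWarnings(as.integer(meta$step_size))
  if (is.na(k)) k <- unique(nchar(keys))[1L]
  new_step_param_table(meta$property_name, k, meta$units,
                       stats::setNames(vals, keys), meta$source)
}

#' The five packaged DNA physical-property tables
#'
#' Returns the packaged step-parameter tables for the five DNA physical
#' properties used throughout: duplex DNA free energy, base stacking energy,
#' protein-induced deformability, rigidity and Z-DNA (anti-syn) stabilizing
#' energy.  All but rigidity are dinucleotide (k = 2) scales transcribed from
#' their published sources (recorded in each file's header); the rigidity
#' table is a tetranucleotide (k = 4) composite constructed as the mean
#' inverse deformability of the three constituent dinucleotide steps — a
#' synthetic stand-in, labelled as such in its file, that users can replace
#' with any k = 4 scale via [load_step_table()].
#'
#' @return A named list of five \code{step_param_table} objects.
#' @examples
#' tabs <- dpp_tables()
#' names(tabs)
#' tabs$duplex_free_energy$values[["TA"]]
#' @export
dpp_tables <- function() {
  paths <- system.file("extdata", DPP_FILES, package = "promdpp")
  if (any(paths == ""))
    stop("packaged step-table file missing: ",
         DPP_FILES[paths == ""][1L])
  tabs <- lapply(paths, load_step_table)
  names(tabs) <- names(DPP_FILES)
  for (nm in names(tabs))
    if (tabs[[nm]]$property_name != nm)
      stop("corrupted packaged table: expected property ", nm,
           ", file says ", tabs[[nm]]$property_name)
  tabs
}

#' @export
print.step_param_table <- function(x, ...) {
  cat("Step-parameter table:", x$property_name,
      sprintf("(k=%d, %d steps)", x$step_size, length(x$values)), "\n")
  if (nzchar(x$units)) cat("  units :", x$units, "\n")
  if (nzchar(x$source)) cat("  source:", x$source, "\n")
  cat("  range : [", min(x$values), ",", max(x$values), "]\n")
  invisible(x)
}

#' Convert a nucleotide sequence into a chain of property values
#'
#' Slides a k-wide window along the sequence with a 1-bp frameshift and looks
#' up each k-mer step in the table, producing \code{L - k + 1} values.  The
#' value of a step is assigned to the TSS-relative coordinate of the step's
#' FIRST base, so every profile feature carries a right-shift ambiguity of up
#' to k - 1 bp (material only for the tetranucleotide table).  Lowercase
#' (soft-masked) bases are folded to uppercase before lookup; any step whose
#' window contains a character outside {A,C,G,T} yields \code{NA}.
#'
#' @param seq A single nucleotide string of length >= k.
#' @param table A \code{step_param_table}.
#' @param anchor 0-based index of the TSS (or other alignment anchor) within
#'   \code{seq}; position \code{i} of the chain is reported at TSS-relative
#'   coordinate \code{i - anchor}.
#' @return An object of class \code{property_chain}: list with
#'   \code{property_name}, \code{units}, \code{values} (numeric, \code{NA}
#'   for steps covering non-ACGT bases), \code{positions} (TSS-relative
#'   coordinate of each step's first base) and \code{anchor}.
#' @examples
#' tab <- dpp_tables()$duplex_free_energy
#' ch <- sequence_to_chain("TATAAAAG", tab, anchor = 4)
#' cbind(ch$positions, ch$values)
#' @export
sequence_to_chain <- function(seq, table, anchor = 0L) {
  stopifnot(inherits(table, "step_param_table"),
            is.character(seq), length(seq) == 1L)
  L <- nchar(seq)
  k <- table$step_size
  if (L == 0L) stop("empty sequence")
  if (L < k) stop("sequence shorter than step size k=", k)
  anchor <- as.integer(anchor)
  if (anchor < 0L || anchor >= L)
    stop("anchor must lie within the sequence")
  up <- toupper(seq)
  kmers <- substring(up, 1:(L - k + 1L), k:L)
  vals <- unname(table$values[kmers])   # absent k-mer (non-ACGT) -> NA
  structure(
    list(property_name = table$property_name,
         units = table$units,
         values = vals,
         positions = seq.int(0L, L - k) - anchor,
         anchor = anchor),
    class = "property_chain"
  )
}

#' @export
print.property_chain <- function(x, ...) {
  cat("Property chain:", x$property_name, "-", length(x$values), "steps,",
      sum(is.na(x$values)), "missing; positions",
      min(x$positions), "..", max(x$positions), "\n")
  invisible(x)
}
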