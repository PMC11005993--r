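# Independent brute-force oracles and small fixture builders.  These stay
# deliberately naive (character-by-character loops) so they cannot share a
# defect with the vectorized implementation they check.

# naive chain oracle: explicit loop over windows with per-character checks
oracle_chain <- function(seq, values, k) {
  s <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  L <- length(s)
  out <- rep(NA_real_, L - k + 1L)
  for (i in seq_len(L - k + 1L)) {
    km <- paste(s[i:(i + k - 1L)], collapse = "")
    if (all(s[i:(i + k - 1L)] %in% c("A", "C", "G", "T")))
      out[i] <- values[[km]]
  }
  out
}

# naive two-pass per-position mean/sd over a list of (positions, values)
oracle_aggregate <- function(chains) {
  pos_all <- sort(unique(unlist(lapply(chains, `[[`, "positions"))))
  res <- data.frame(position = pos_all, mean = NA_real_, sd = NA_real_,
                    n = 0L)
  for (j in seq_along(pos_all)) {
    vals <- c()
    for (ch in chains) {
      hit <- which(ch$positions == pos_all[j])
      if (length(hit) && !is.na(ch$values[hit])) vals <- c(vals, ch$values[hit])
    }
    res$n[j] <- length(vals)
    if (length(vals) >= 1L) res$mean[j] <- sum(vals) / length(vals)
    if (length(vals) >= 2L) {
      m <- res$mean[j]
      res$sd[j] <- sqrt(sum((vals - m)^2) / (length(vals) - 1L))
    }
  }
  res[res$n > 0L, , drop = FALSE]
}

# k=2 toy table: named defaults, everything else `fill`
toy_table <- function(values = c(AA = 1), fill = 0, name = "toy",
                      units = "u") {
  b <- c("A", "C", "G", "T")
  keys <- as.vector(outer(b, b, paste0))
  v <- stats::setNames(rep(fill, 16L), keys)
  v[names(values)] <- values
  promdpp:::new_step_param_table(name, 2L, units, v)
}

random_seq <- function(L, with_n = FALSE) {
  pool <- c("A", "C", "G", "T", if (with_n) "N")
  paste(sample(pool, L, replace = TRUE), collapse = "")
}

# toy element definitions with non-degenerate 10-mer consensi (accidental
# background matches ~1e-6 per window) for exact planted-shift recovery
toy_defs <- function() {
  data.frame(
    name = c("ALPHA", "BETA"),
    consensus = c("TACGGATCGT", "GGCTACTTAC"),
    canonical_start = c(-40L, 10L),
    max_shift = c(5L, 5L),
    source = "toy",
    stringsAsFactors = FALSE)
}

write_fasta_text <- function(records, path, width = 60L) {
  lines <- unlist(lapply(names(records), function(nm) {
    s <- records[[nm]]
    c(paste0(">", nm),
      substring(s, seq(1L, nchar(s), width),
                pmin(seq(1L, nchar(s), width) + width - 1L, nchar(s))))
  }))
  writeLines(lines, path)
}

write_bed_rows <- function(rows, path) writeLines(rows, path)
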