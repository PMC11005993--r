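#' Build a position frequency matrix over an anchored window
#'
#' Counts sense-strand bases column by column over a TSS-relative window that
#' every promoter in the set must cover.  Non-ACGT characters (after case
#' folding) are tallied as "other"; they stay in the column total n but are
#' excluded from frequencies and information content.
#'
#' @param promoters A non-empty \code{promoter_set}.
#' @param window Integer range \code{c(lo, hi)} of TSS-relative positions
#'   (default \code{c(-5, 5)}).
#' @return An object of class \code{pfm}: list with \code{counts} (5 x W
#'   matrix, rows A/C/G/T/other), \code{positions} and \code{n}.
#' @export
build_pfm <- function(promoters, window = c(-5L, 5L)) {
  stopifnot(inherits(promoters, "promoter_set"))
  if (length(promoters) == 0L) stop("empty promoter set")
  pos <- window[1L]:window[2L]
  a <- promoters$anchor
  Lmin <- min(nchar(promoters$seq))
  if (a + window[1L] < 0L || a + window[2L] >= Lmin)
    stop("window not covered by every promoter")
  counts <- matrix(0L, nrow = 5L, ncol = length(pos),
                   dimnames = list(c("A", "C", "G", "T", "other"), pos))
  for (j in seq_along(pos)) {
    idx <- a + pos[j] + 1L
    ch <- toupper(substr(promoters$seq, idx, idx))
    ch[!ch %in% c("A", "C", "G", "T")] <- "other"
    t <- table(factor(ch, levels = rownames(counts)))
    counts[, j] <- as.integer(t)
  }
  structure(list(counts = counts, positions = pos, n = length(promoters)),
            class = "pfm")
}

#' Per-position information content (bits)
#'
#' Relative-entropy logo heights: at each position,
#' IC = sum_b f_b * log2(f_b / q_b) with 0 * log 0 := 0, where f are the
#' observed ACGT frequencies (excluding "other") and q the background.  With
#' a uniform background IC lies in [0, 2] bits.  The optional small-sample
#' correction subtracts the Miller bias term 3 / (2 ln(2) n_j).
#'
#' @param pfm A \code{pfm}.
#' @param background Numeric length-4 base distribution (A,C,G,T) summing
#'   to 1; default uniform.
#' @param correct Apply the small-sample correction (default FALSE; the
#'   promoter sets profiled here are large).
#' @return Numeric vector of bits, named by position; \code{NA} where a
#'   column has no ACGT coverage.
#' @export
information_content <- function(pfm, background = rep(0.25, 4),
                                correct = FALSE) {
  stopifnot(inherits(pfm, "pfm"))
  if (abs(sum(background) - 1) > 1e-8)
    stop("background must sum to 1")
  if (any(background <= 0)) stop("background must have full support")
  cnt <- pfm$counts[c("A", "C", "G", "T"), , drop = FALSE]
  tot <- colSums(cnt)
  ic <- vapply(seq_along(tot), function(j) {
    if (tot[j] == 0L) return(NA_real_)
    f <- cnt[, j] / tot[j]
    v <- sum(ifelse(f > 0, f * log2(f / background), 0))
    if (correct) v <- max(0, v - 3 / (2 * log(2) * tot[j]))
    v
  }, 0)
  stats::setNames(ic, pfm$positions)
}

#' @export
print.pfm <- function(x, ...) {
  cat("Position frequency matrix:", x$n, "sequences, positions",
      min(x$positions), "..", max(x$positions), "\n")
  print(x$counts)
  invisible(x)
}

#' Simple sequence-logo plot of a PFM
#'
#' Draws stacked base letters whose heights are frequency times per-position
#' information content (bits), the conventional logo scaling.
#'
#' @param x A \code{pfm}.
#' @param background Passed to [information_content()].
#' @param ... Further graphics parameters.
#' @export
plot.pfm <- function(x, background = rep(0.25, 4), ...) {
  ic <- information_content(x, background)
  cnt <- x$counts[c("A", "C", "G", "T"), , drop = FALSE]
  tot <- colSums(cnt)
  cols <- c(A = "forestgreen", C = "blue", G = "orange", T = "red")
  graphics::plot(NA, xlim = range(x$positions) + c(-0.5, 0.5),
                 ylim = c(0, 2), xlab = "position", ylab = "bits", ...)
  for (j in seq_along(x$positions)) {
    if (is.na(ic[j]) || tot[j] == 0L) next
    f <- cnt[, j] / tot[j]
    h <- f * ic[j]
    ord <- order(h)
    y <- 0
    for (b in rownames(cnt)[ord]) {
      if (h[b] <= 0) next
      graphics::text(x$positions[j], y + h[b] / 2, b, col = cols[b],
                     cex = min(3, 0.6 + 4 * h[b]), font = 2L)
      y <- y + h[b]
    }
  }
  invisible(x)
}
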