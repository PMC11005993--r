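#' Property chains for every promoter in a set
#'
#' @param promoters A \code{promoter_set}.
#' @param table A \code{step_param_table}.
#' @return A list of \code{property_chain} objects (one per promoter), all
#'   anchored at the set's TSS offset.
#' @export
promoter_chains <- function(promoters, table) {
  stopifnot(inherits(promoters, "promoter_set"))
  lapply(promoters$seq, sequence_to_chain, table = table,
         anchor = promoters$anchor)
}

#' Aggregate anchor-aligned property chains into a mean/SD profile
#'
#' Aligns the chains on their TSS-relative coordinates and, at every position
#' covered by at least one chain, computes the mean and sample standard
#' deviation (n - 1 denominator) over the non-missing values, recording the
#' contributing count n.  SD is \code{NA} wherever n < 2.  Positions covered
#' by zero chains are omitted.
#'
#' @param chains A non-empty list of \code{property_chain}s sharing one
#'   property.
#' @return An \code{aggregate_profile}: a data frame with columns
#'   \code{position}, \code{mean}, \code{sd}, \code{n} and attributes
#'   \code{property_name}, \code{units}, \code{n_input} and
#'   \code{sd_convention} ("sample (n-1)").
#' @export
aggregate_chains <- function(chains) {
  if (length(chains) == 0L) stop("no chains to aggregate")
  props <- unique(vapply(chains, `[[`, "", "property_name"))
  if (length(props) != 1L)
    stop("mixed properties in one aggregation: ",
         paste(props, collapse = ", "))
  lo <- min(vapply(chains, function(c) min(c$positions), 0L))
  hi <- max(vapply(chains, function(c) max(c$positions), 0L))
  pos <- lo:hi
  m <- matrix(NA_real_, nrow = length(chains), ncol = length(pos))
  for (i in seq_along(chains)) {
    ch <- chains[[i]]
    m[i, ch$positions - lo + 1L] <- ch$values
  }
  n <- as.integer(colSums(!is.na(m)))
  keep <- n > 0L
  m <- m[, keep, drop = FALSE]; pos <- pos[keep]; n <- n[keep]
  mu <- colMeans(m, na.rm = TRUE)
  sd <- apply(m, 2L, stats::sd, na.rm = TRUE)
  sd[n < 2L] <- NA_real_
  out <- data.frame(position = pos, mean = mu, sd = sd, n = n)
  rownames(out) <- NULL
  structure(out,
            property_name = props,
            units = chains[[1L]]$units,
            n_input = length(chains),
            sd_convention = "sample (n-1)",
            class = c("aggregate_profile", "data.frame"))
}

#' Write an aggregate profile to TSV
#'
#' Emits a '#' metadata header (property, units, n_input, sd_convention)
#' followed by position/mean/sd/n rows.  Numeric values are written with 17
#' significant digits so the paired reader round-trips them exactly; missing
#' SD is written as "NA".
#'
#' @param profile An \code{aggregate_profile}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_profile_tsv <- function(profile, path) {
  num <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  lines <- c(
    paste0("# property_name: ", attr(profile, "property_name")),
    paste0("# units: ", attr(profile, "units")),
    paste0("# n_input: ", attr(profile, "n_input")),
    paste0("# sd_convention: ", attr(profile, "sd_convention")),
    paste("position", "mean", "sd", "n", sep = "\t"),
    paste(profile$position, num(profile$mean), num(profile$sd), profile$n,
          sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read an aggregate profile written by [write_profile_tsv()]
#' @param path Path to a profile TSV.
#' @return An \code{aggregate_profile}.
#' @export
read_profile_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list(property_name = "", units = "", n_input = NA,
               sd_convention = "")
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*)$", h))[[1L]]
    if (length(m) == 3L && m[2L] %in% names(meta)) meta[[m[2L]]] <- m[3L]
  }
  d <- utils::read.delim(textConnection(lines[!grepl("^#", lines)]),
                         stringsAsFactors = FALSE)
  structure(data.frame(position = as.integer(d$position), mean = d$mean,
                       sd = d$sd, n = as.integer(d$n)),
            property_name = meta$property_name,
            units = meta$units,
            n_input = as.integer(meta$n_input),
            sd_convention = meta$sd_convention,
            class = c("aggregate_profile", "data.frame"))
}

#' Locate the two distinctive profile sites (TSS and upstream ~-27)
#'
#' Operationalizes the qualitative "distinctive site" reading of a mean
#' profile: within each of two windows (default around the TSS and around
#' position -27) it finds the position of maximal deviation of the mean from
#' a baseline, where the baseline is the median of the mean over all
#' positions outside both windows.  A landmark is flagged distinctive only if
#' its deviation exceeds \code{min_effect} robust SDs (MAD) of the outside
#' baseline region, so a flat or noise-only profile yields no landmark.
#'
#' @param profile An \code{aggregate_profile} covering both windows.
#' @param window_tss,window_upstream Integer ranges \code{c(lo, hi)} in
#'   TSS-relative coordinates; defaults \code{c(-5, 5)} and \code{c(-35, -20)}.
#' @param min_effect Multiple of the outside-region MAD a deviation must
#'   exceed to be flagged distinctive (default 5).
#' @return A list of class \code{dpp_landmarks} with elements \code{tss} and
#'   \code{upstream} (each: \code{position}, \code{deviation},
#'   \code{direction} "peak"/"trough", \code{distinctive}), plus
#'   \code{baseline}, \code{spread} and \code{threshold}.
#' @export
locate_landmarks <- function(profile, window_tss = c(-5L, 5L),
                             window_upstream = c(-35L, -20L),
                             min_effect = 5) {
  pos <- profile$position
  covers <- function(w) all(w[1L]:w[2L] %in% pos)
  if (!covers(window_tss) || !covers(window_upstream))
    stop("profile does not cover the landmark windows")
  inw <- function(w) pos >= w[1L] & pos <= w[2L]
  outside <- !(inw(window_tss) | inw(window_upstream))
  baseline <- stats::median(profile$mean[outside])
  spread <- stats::mad(profile$mean[outside])
  threshold <- min_effect * spread
  one <- function(w) {
    i <- which(inw(w))
    dev <- profile$mean[i] - baseline
    j <- i[which.max(abs(dev))]
    d <- profile$mean[j] - baseline
    list(position = pos[j], deviation = d,
         direction = if (d >= 0) "peak" else "trough",
         distinctive = abs(d) > threshold)
  }
  structure(list(tss = one(window_tss), upstream = one(window_upstream),
                 baseline = baseline, spread = spread,
                 threshold = threshold),
            class = "dpp_landmarks")
}

#' @export
print.dpp_landmarks <- function(x, ...) {
  f <- function(nm, l) cat(sprintf(
    "  %-8s %s at %d (deviation %+0.4g)%s\n", nm, l$direction, l$position,
    l$deviation, if (l$distinctive) "  [distinctive]" else ""))
  cat("Profile landmarks (baseline", format(x$baseline, digits = 4),
      "; threshold", format(x$threshold, digits = 4), "):\n")
  f("TSS:", x$tss); f("upstream:", x$upstream)
  invisible(x)
}

#' Plot a mean profile with guide lines at 0 and -27
#'
#' @param x An \code{aggregate_profile}.
#' @param sd_band Draw a +/-1 SD band where SD is available.
#' @param guide_at Positions of vertical dotted guide lines.
#' @param ... Passed to \code{plot()}.
#' @export
plot.aggregate_profile <- function(x, sd_band = FALSE,
                                   guide_at = c(0L, -27L), ...) {
  graphics::plot(x$position, x$mean, type = "l",
                 xlab = "position relative to anchor (bp)",
                 ylab = paste0(attr(x, "property_name"),
                               if (nzchar(attr(x, "units") %||% ""))
                                 paste0(" (", attr(x, "units"), ")") else ""),
                 ...)
  if (sd_band && any(!is.na(x$sd))) {
    ok <- !is.na(x$sd)
    graphics::polygon(c(x$position[ok], rev(x$position[ok])),
                      c(x$mean[ok] + x$sd[ok], rev(x$mean[ok] - x$sd[ok])),
                      border = NA, col = grDevices::adjustcolor("grey", 0.4))
    graphics::lines(x$position, x$mean)
  }
  graphics::abline(v = guide_at, lty = 3L)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
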