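# Config handling: a run config is a plain named list; YAML files are
# accepted everywhere a config is. Paths are checked up front so a typo fails
# before any compute.
normalize_config <- function(config, need = character(0)) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(upstream = 100L, downstream = 50L, groups = character(0),
                   sample_n = NULL, seed = 1L, elements = NULL,
                   tables = NULL, logo_window = c(-5L, 5L))
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  if (config$upstream < 0L || config$downstream < 0L)
    stop("config error: window must be non-negative")
  if (is.null(config$out)) stop("config error: 'out' directory required")
  for (k in need) {
    if (is.null(config[[k]]))
      stop("config error: '", k, "' is required")
    if (!file.exists(config[[k]]))
      stop("config error: ", k, " file not found: ", config[[k]])
  }
  config
}

load_config_tables <- function(config) {
  if (is.null(config$tables)) return(dpp_tables())
  files <- list.files(config$tables, pattern = "\\.tsv$", full.names = TRUE)
  if (!length(files)) stop("config error: no .tsv tables in ", config$tables)
  tabs <- lapply(files, load_step_table)
  stats::setNames(tabs, vapply(tabs, `[[`, "", "property_name"))
}

load_config_defs <- function(config) cpe_definitions(config$elements)

group_key <- function(meta, groups) {
  if (!length(groups)) return(rep("all", nrow(meta)))
  miss <- setdiff(groups, names(meta))
  if (length(miss))
    stop("config error: grouping key(s) not in TSS metadata: ",
         paste(miss, collapse = ", "))
  do.call(paste, c(meta[groups], sep = ":"))
}

sanitize <- function(x) gsub("[^A-Za-z0-9._-]+", "-", x)

write_provenance <- function(config, dir, extra = list()) {
  prov <- c(list(package = "promdpp",
                 version = as.character(utils::packageVersion("promdpp")),
                 seed = config$seed,
                 config = config[!vapply(config, is.null, TRUE)]),
            extra)
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

classify_internal <- function(config) {
  genome <- read_genome_fasta(config$genome)
  tss <- read_tss_table(config$tss)
  n_read <- nrow(tss)
  tss <- select_representative_tss(tss)
  if (!is.null(config$sample_n))
    tss <- sample_records(tss, config$sample_n, config$seed)
  promoters <- withCallingHandlers(
    extract_promoters(genome, tss, config$upstream, config$downstream),
    warning = function(w) {
      message("[classify] ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  defs <- load_config_defs(config)
  hits <- scan_cpes(promoters, defs)
  species <- classify_promoters(hits, defs)
  grp <- group_key(promoters$meta, config$groups)
  list(genome = genome, promoters = promoters, defs = defs, hits = hits,
       species = species, group = grp,
       counts = list(read = n_read,
                     kept = length(promoters),
                     skipped = attr(promoters, "skipped")))
}

#' Run the promoter classification stage
#'
#' Reads the genome and TSS table, selects one representative TSS per gene
#' (highest score), optionally subsamples, extracts anchored promoter
#' windows, scans for core promoter elements and tabulates promoter species
#' group by group.  Writes \code{species_table.tsv}, \code{species_top5.tsv},
#' \code{summary.json} and \code{provenance.json} into the output directory.
#'
#' @param config A named list or path to a YAML file with at least
#'   \code{genome}, \code{tss} and \code{out}; optional \code{elements},
#'   \code{upstream}, \code{downstream}, \code{groups} (metadata column
#'   names), \code{sample_n}, \code{seed}.
#' @return Invisibly, a list with the species table, per-promoter labels and
#'   run counts.
#' @export
run_classify <- function(config) {
  config <- normalize_config(config, need = c("genome", "tss"))
  st <- classify_internal(config)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  tab <- tabulate_species(st$group, st$species)
  utils::write.table(tab, file.path(config$out, "species_table.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(top_species(tab), file.path(config$out,
                                                 "species_top5.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cl_frac <- vapply(split(st$species, st$group), function(s)
    mean(s == "core-less", na.rm = TRUE), 0)
  summary <- list(records_read = st$counts$read,
                  records_kept = st$counts$kept,
                  records_skipped = st$counts$skipped,
                  unevaluable_elements = attr(st$hits, "unevaluable"),
                  coreless_fraction = as.list(cl_frac))
  jsonlite::write_json(summary, file.path(config$out, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_provenance(config, config$out)
  invisible(list(species_table = tab, species = st$species,
                 group = st$group, counts = st$counts))
}

profile_one_set <- function(promoters, tables, out_dir, stem) {
  files <- character(0)
  for (nm in names(tables)) {
    prof <- aggregate_chains(promoter_chains(promoters, tables[[nm]]))
    f <- file.path(out_dir, sprintf("profile_%s_%s.tsv", stem, sanitize(nm)))
    write_profile_tsv(prof, f)
    files <- c(files, f)
  }
  files
}

#' Run the DPP profiling stage
#'
#' Classification is performed once (same path as [run_classify()]); then,
#' for every group, the full ("unsorted") promoter set and its core-less
#' subset are profiled with each of the five physical-property tables,
#' yielding up to 2 x 5 profile TSVs per group.  Groups whose core-less
#' subset is empty get only the unsorted profiles (with a message).
#'
#' @inheritParams run_classify
#' @return Invisibly, a list with the vectors of written unsorted and
#'   core-less profile paths and the run counts.
#' @export
run_profile <- function(config) {
  config <- normalize_config(config, need = c("genome", "tss"))
  st <- classify_internal(config)
  tables <- load_config_tables(config)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  unsorted <- character(0); coreless <- character(0)
  for (g in sort(unique(st$group))) {
    sel <- st$group == g
    set_g <- st$promoters[sel]
    unsorted <- c(unsorted,
                  profile_one_set(set_g, tables, config$out,
                                  paste0(sanitize(g), "_unsorted")))
    cl <- sel & !is.na(st$species) & st$species == "core-less"
    if (!any(cl)) {
      message("[profile] group ", g, ": empty core-less subset, skipped")
      next
    }
    coreless <- c(coreless,
                  profile_one_set(st$promoters[cl], tables, config$out,
                                  paste0(sanitize(g), "_coreless")))
  }
  write_provenance(config, config$out,
                   list(n_unsorted_profiles = length(unsorted),
                        n_coreless_profiles = length(coreless)))
  invisible(list(unsorted = unsorted, coreless = coreless,
                 counts = st$counts))
}

#' Run the tRNA three-region profiling stage
#'
#' Selects the highest-TPM TSS per tRNA gene and profiles the three regions
#' with their own anchors — 5'-flank (TSS at 0, covering -50..0), the
#' A-box-containing region (mature 5' end at 0, covering 0..+30) and the
#' B-box-containing region (discriminator at 0, covering -30..0) — with each
#' physical-property table: 3 x 5 profile TSVs.
#'
#' @param config Named list or YAML path with \code{genome}, \code{trna}
#'   (annotation TSV, see [read_trna_table()]) and \code{out}.
#' @return Invisibly, named list of written profile paths per region.
#' @export
run_trna <- function(config) {
  config <- normalize_config(config, need = c("genome", "trna"))
  genome <- read_genome_fasta(config$genome)
  ann <- read_trna_table(config$trna)
  ann <- select_representative_tss(ann)
  tables <- load_config_tables(config)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  regions <- list(
    upstream = trna_upstream_region(genome, ann),
    abox = trna_abox_region(genome, ann),
    bbox = trna_bbox_region(genome, ann))
  files <- lapply(names(regions), function(r)
    profile_one_set(regions[[r]], tables, config$out, paste0("trna_", r)))
  names(files) <- names(regions)
  write_provenance(config, config$out,
                   list(n_genes = nrow(ann),
                        n_profiles = length(unlist(files))))
  invisible(files)
}

#' Run the sequence-logo stage
#'
#' Builds a position frequency matrix and per-position information content
#' over a window around the TSS (default -5..+5) and writes them as TSVs.
#'
#' @inheritParams run_classify
#' @return Invisibly, the \code{pfm}.
#' @export
run_logo <- function(config) {
  config <- normalize_config(config, need = c("genome", "tss"))
  genome <- read_genome_fasta(config$genome)
  tss <- select_representative_tss(read_tss_table(config$tss))
  promoters <- suppressWarnings(
    extract_promoters(genome, tss, config$upstream, config$downstream))
  pfm <- build_pfm(promoters, window = config$logo_window)
  ic <- information_content(pfm)
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  cnt <- t(pfm$counts)
  utils::write.table(data.frame(position = pfm$positions, cnt,
                                ic_bits = sprintf("%.17g", ic),
                                check.names = FALSE),
                     file.path(config$out, "logo_pfm.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_provenance(config, config$out)
  invisible(pfm)
}

#' Run the synthetic-data stage
#'
#' Generates grouped synthetic promoter sets (and optionally a tRNA set) and
#' writes them in the external formats the other stages read, so a full
#' synthetic run exercises the identical I/O path as real data.
#'
#' @param config Named list or YAML path with \code{out} and optionally:
#'   \code{n_per_group}, \code{species_mix} (named numeric), \code{groups_df}
#'   (data frame of metadata combinations, one synthetic group per row; NULL
#'   for a single ungrouped set), \code{gc}, \code{length}, \code{anchor},
#'   \code{jitter}, \code{seed}, \code{trna_n} (0 to skip the tRNA set).
#' @return Invisibly, the list of written paths.
#' @export
run_simulate <- function(config) {
  config <- normalize_config(config)
  n <- config$n_per_group %||% 200L
  mix <- config$species_mix %||%
    c("core-less" = 0.55, "Inr" = 0.30, "TATA+Inr" = 0.15)
  if (is.list(mix)) mix <- unlist(mix)
  defs <- load_config_defs(config)
  gdf <- config$groups_df
  sets <- if (is.null(gdf)) {
    list(generate_promoter_set(n, mix, defs,
                               length = config$length %||% 151L,
                               anchor = config$anchor %||% 100L,
                               gc = config$gc %||% 0.5,
                               jitter = config$jitter %||% c(-5L, 5L),
                               seed = config$seed))
  } else {
    lapply(seq_len(nrow(gdf)), function(g)
      generate_promoter_set(
        n, mix, defs,
        length = config$length %||% 151L,
        anchor = config$anchor %||% 100L,
        gc = config$gc %||% 0.5,
        jitter = config$jitter %||% c(-5L, 5L),
        seed = (config$seed + g * 1000003L) %% 2147483647L,
        group = unlist(gdf[g, , drop = FALSE]),
        id_prefix = sprintf("synth_g%02d_", g)))
  }
  paths <- write_synthetic_inputs(sets, config$out)
  trna_n <- config$trna_n %||% 0L
  if (trna_n > 0L) {
    tr <- generate_trna_set(trna_n, seed = config$seed)
    tp <- write_synthetic_trna(tr, config$out)
    paths$trna_genome <- tp$genome
    paths$trna <- tp$trna
  }
  write_provenance(config, config$out)
  invisible(paths)
}
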