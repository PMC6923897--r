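#' Run configuration for the end-to-end panel-selection pipeline
#'
#' @param catalog Path to a locus-catalog TSV.
#' @param genotypes Character vector of genotype-table TSV paths (one or
#'   more; species labels come from the files themselves).
#' @param outdir Output directory (created if absent).
#' @param thresholds A [threshold_config()].
#' @param species Optional species list the panel must satisfy (default: all
#'   species present in the genotype tables). Must be non-empty and unique.
#' @param seed Integer seed recorded in outputs (the pipeline itself is
#'   deterministic).
#' @return List of class `run_config`.
#' @export
run_config <- function(catalog, genotypes, outdir,
                       thresholds = threshold_config(), species = NULL,
                       seed = 1L) {
  for (p in c(catalog, genotypes)) {
    if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  if (!is.null(species)) {
    species <- as.character(species)
    if (length(species) == 0L) stop("species list is empty")
    if (anyDuplicated(species)) stop("species list contains duplicates")
  }
  stopifnot(inherits(thresholds, "threshold_config"))
  structure(list(catalog = catalog, genotypes = genotypes, outdir = outdir,
                 thresholds = thresholds, species = species,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror [run_config()] arguments; threshold fields (`delta_d`,
#' `delta_m`, `delta_e`, `delta_h`, `delta_eta`, `delta_c`, `delta_r`) may be
#' given at the top level.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configs requires the 'yaml' package")
  }
  y <- yaml::read_yaml(path)
  thr_keys <- c("delta_d", "delta_m", "delta_e", "delta_h", "delta_eta",
                "delta_c", "delta_r")
  thr <- do.call(threshold_config, y[intersect(names(y), thr_keys)])
  run_config(catalog = y$catalog, genotypes = unlist(y$genotypes),
             outdir = y$outdir, thresholds = thr,
             species = y$species, seed = if (is.null(y$seed)) 1L else y$seed)
}

#' Run the full panel-selection pipeline
#'
#' Executes the workflow end to end: per-locus per-species statistics, the
#' shared-species / structural / forensic-threshold filter cascade, greedy
#' panel selection, and panel evaluation. Every stage's surviving locus
#' count is logged, and all artefacts are written under `config$outdir`:
#' `stats.tsv`, `pseudo_stats.tsv`, `filtered_catalog.tsv`, `panel.json`,
#' `evaluation.json`, `trace.tsv` and `pipeline.log`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `stats`, `candidates` (locus ids surviving
#'   the cascade), `selection` (a `selection_result`), `evaluation`, and
#'   `paths` of the written files. Thresholds that cannot be met leave
#'   `selection$status == "exhausted"` (a warning, not an error), and the
#'   partial panel is still written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(config$outdir, "pipeline.log")
  logf <- function(fmt, ...) {
    cat(sprintf(paste0(fmt, "\n"), ...), file = logfile, append = TRUE)
  }
  cat("", file = logfile)

  catalog <- read_locus_catalog(config$catalog)
  tables <- lapply(config$genotypes, read_genotype_table, catalog = catalog)
  table <- do.call(rbind, lapply(tables, as.data.frame))
  table <- genotype_table(table, catalog)
  species <- if (is.null(config$species)) sort(unique(table$species)) else
    config$species
  logf("[stats] %d loci in catalog, %d species, %d genotype rows",
       nrow(catalog), length(unique(table$species)), nrow(table))

  stats <- locus_species_stats(table, catalog)
  stats <- stats[stats$species %in% species, , drop = FALSE]
  logf("[stats] %d loci with data in >=1 requested species",
       length(unique(stats$locus_id)))

  shared <- shared_species_filter(stats)
  logf("[filter:shared] %d loci observed in >=2 species", length(shared))
  structural <- intersect(shared, structural_filter(catalog))
  logf("[filter:structural] %d loci after sex-chromosome/mononucleotide exclusion",
       length(structural))
  candidates <- intersect(
    structural,
    threshold_filter(stats[stats$locus_id %in% structural, , drop = FALSE],
                     config$thresholds))
  logf("[filter:thresholds] %d candidate loci", length(candidates))
  if (length(candidates) == 0L) {
    logf("[select] no candidates survive the filter cascade")
    stop("no candidate loci survive the filter cascade")
  }

  cand_stats <- stats[stats$locus_id %in% candidates, , drop = FALSE]
  selection <- withCallingHandlers(
    greedy_select(cand_stats, catalog, config$thresholds, species),
    warning = function(w) {
      logf("[select] warning: %s", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  logf("[select] %d loci selected, status=%s",
       length(selection$loci), selection$status)
  evaluation <- evaluate_panel(selection$loci, cand_stats, species)

  paths <- write_reports(
    outdir = config$outdir, catalog = catalog, stats = stats,
    candidates = candidates, selection = selection, evaluation = evaluation,
    config = config)
  logf("[done] outputs in %s", config$outdir)
  invisible(list(stats = stats, candidates = candidates,
                 selection = selection, evaluation = evaluation,
                 paths = paths))
}

#' Write pipeline reports
#'
#' Emits the standard report bundle: the per-locus stats table, pseudo-species
#' locus table, the filtered catalog (locus report with chromosome, position,
#' repeat-unit length, HE and PD per species), the ordered panel with its
#' per-species running products as JSON, the evaluation JSON (per-species
#' RMP/CPD/CPE plus the pseudo-species row), and the selection trace.
#'
#' @param outdir Output directory.
#' @param catalog Locus catalog.
#' @param stats Per-locus per-species stats.
#' @param candidates Locus ids surviving the filter cascade.
#' @param selection A `selection_result`.
#' @param evaluation Output of [evaluate_panel()].
#' @param config The `run_config` (echoed into the panel JSON).
#' @return Named character vector of written paths.
#' @export
write_reports <- function(outdir, catalog, stats, candidates, selection,
                          evaluation, config = NULL) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- c(stats = file.path(outdir, "stats.tsv"),
         pseudo = file.path(outdir, "pseudo_stats.tsv"),
         filtered = file.path(outdir, "filtered_catalog.tsv"),
         locus_report = file.path(outdir, "locus_report.tsv"),
         panel = file.path(outdir, "panel.json"),
         evaluation = file.path(outdir, "evaluation.json"),
         trace = file.path(outdir, "trace.tsv"))
  wt <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(stats, p[["stats"]])
  wt(pseudo_locus_stats(stats), p[["pseudo"]])
  wt(catalog[catalog$locus_id %in% candidates, , drop = FALSE], p[["filtered"]])

  # locus report shaped like a forensic panel table: CHR POS RUL + HE/PD
  sel_stats <- stats[stats$locus_id %in% selection$loci, , drop = FALSE]
  rep_df <- merge(catalog[, c("locus_id", "chrom", "pos", "repeat_unit_length")],
                  sel_stats[, c("locus_id", "species", "het", "pd")],
                  by = "locus_id")
  rep_df <- rep_df[order(match(rep_df$locus_id, selection$loci),
                         rep_df$species), , drop = FALSE]
  wt(rep_df, p[["locus_report"]])

  panel_obj <- list(
    loci = selection$loci,
    status = selection$status,
    species = selection$species,
    v_c = as.list(selection$v_c),
    v_r = as.list(selection$v_r),
    satisfied = as.list(selection$satisfied),
    thresholds = unclass(selection$config))
  if (!is.null(config)) panel_obj$seed <- config$seed
  jsonlite::write_json(panel_obj, p[["panel"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  eval_obj <- list(per_species = evaluation$per_species,
                   pseudo_species = evaluation$pseudo)
  jsonlite::write_json(eval_obj, p[["evaluation"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  wt(selection$trace, p[["trace"]])
  p
}

#' Write a threshold-sweep matrix as TSV
#'
#' @param sweep Matrix from [threshold_sweep()].
#' @param path Output path.
#' @export
write_sweep <- function(sweep, path) {
  df <- data.frame(delta_r = rownames(sweep), sweep, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
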