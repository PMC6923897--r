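#' Threshold configuration for locus filtering and panel selection
#'
#' Bundles the per-locus forensic-parameter thresholds, the call-rate
#' threshold, and the panel-level targets. `delta_m` is an independent knob,
#' not forced to `1 - delta_d`.
#'
#' @param delta_d Minimum power of discrimination (default 0.6).
#' @param delta_m Maximum probability of matching (default 0.4).
#' @param delta_e Minimum power of exclusion (default 0.3).
#' @param delta_h Minimum heterozygosity (default 0.5).
#' @param delta_eta Minimum call rate for a species to count as observing a
#'   locus (default 0.5).
#' @param delta_c Per-species combined-PD target (default 0.9999).
#' @param delta_r Per-species random-match-probability ceiling (default
#'   1e-7, interpretable as 1/N for population size N).
#' @return List of class `threshold_config`.
#' @export
threshold_config <- function(delta_d = 0.6, delta_m = 0.4, delta_e = 0.3,
                             delta_h = 0.5, delta_eta = 0.5,
                             delta_c = 0.9999, delta_r = 1e-7) {
  vals <- c(delta_d, delta_m, delta_e, delta_h, delta_eta, delta_c, delta_r)
  if (any(vals < 0 | vals > 1)) stop("all thresholds must lie in [0, 1]")
  structure(list(delta_d = delta_d, delta_m = delta_m, delta_e = delta_e,
                 delta_h = delta_h, delta_eta = delta_eta,
                 delta_c = delta_c, delta_r = delta_r),
            class = "threshold_config")
}

#' Keep loci observed in at least `min_species` species
#'
#' A unified cross-species panel needs loci shared between species; loci
#' observed in a single species carry no cross-species information.
#'
#' @param stats Table from [locus_species_stats()] (a row implies the
#'   species has called data at the locus).
#' @param min_species Minimum number of species (default 2).
#' @return Character vector of surviving locus ids.
#' @export
shared_species_filter <- function(stats, min_species = 2L) {
  counts <- table(stats$locus_id)
  names(counts)[counts >= min_species]
}

#' Structural locus filter
#'
#' Drops loci on the sex chromosomes (unusable for individuals of unknown
#' sex) and mononucleotide repeats (repeat-unit length 1, too noisy to type
#' reliably).
#'
#' @param catalog Locus catalog.
#' @param sex_chroms Chromosome names treated as sex chromosomes.
#' @return Character vector of surviving locus ids.
#' @export
structural_filter <- function(catalog,
                              sex_chroms = c("chrX", "chrY", "X", "Y")) {
  validate_locus_catalog(catalog)
  keep <- !(catalog$chrom %in% sex_chroms) & catalog$repeat_unit_length > 1L
  catalog$locus_id[keep]
}

#' Forensic-parameter threshold filter
#'
#' A species observes a locus when its call rate is at least `delta_eta`;
#' below that the species is treated as not observing the locus. A locus
#' survives when every observing species satisfies all four per-locus
#' constraints (PD >= delta_d, PM <= delta_m, PE >= delta_e, HE >= delta_h;
#' inclusive comparisons) and, after the call-rate screen, the locus is
#' still observed in at least `min_species` species.
#'
#' @param stats Table from [locus_species_stats()].
#' @param config A [threshold_config()].
#' @param min_species Minimum observing species after the call-rate screen.
#' @return Character vector of surviving locus ids.
#' @export
threshold_filter <- function(stats, config = threshold_config(),
                             min_species = 2L) {
  stopifnot(inherits(config, "threshold_config"))
  obs <- stats[stats$call_rate >= config$delta_eta, , drop = FALSE]
  if (nrow(obs) == 0L) return(character())
  ok <- obs$pd >= config$delta_d & obs$pm <= config$delta_m &
    obs$pe >= config$delta_e & obs$het >= config$delta_h
  survivors <- character()
  for (loc in unique(obs$locus_id)) {
    idx <- obs$locus_id == loc
    if (sum(idx) >= min_species && all(ok[idx])) survivors <- c(survivors, loc)
  }
  survivors
}

# per-species M and F matrices (loci x species), absent entries = 1
stats_matrices <- function(stats, loci, species) {
  M <- matrix(1, nrow = length(loci), ncol = length(species),
              dimnames = list(loci, species))
  F_ <- M
  sub <- stats[stats$locus_id %in% loci & stats$species %in% species, ,
               drop = FALSE]
  M[cbind(sub$locus_id, sub$species)] <- sub$pm
  F_[cbind(sub$locus_id, sub$species)] <- sub$mpf
  list(M = M, F = F_)
}

#' Greedy selection of a minimal STR panel
#'
#' Starting from an empty panel, repeatedly adds the candidate locus that
#' most reduces the product of the running combined matching probability and
#' running random-match probability over the *active* species — those not
#' yet satisfying both `C_s >= delta_c` and `R_s <= delta_r`. Because both
#' running quantities are products, the chosen locus is the one minimizing
#' `prod over active s of M[l,s] * F[l,s]`. Once a species meets both
#' targets it is skipped in later iterations. A locus with no data in an
#' active species contributes factors 1 * 1 there, deprioritizing it
#' naturally.
#'
#' Ties are broken by larger joint (pseudo-species) PD, then by (chrom, pos)
#' order, so the result is deterministic and invariant to input row order.
#'
#' @param stats Per-locus per-species table from [locus_species_stats()],
#'   restricted to candidate loci (e.g. the output of the filter cascade).
#' @param catalog Locus catalog (for coordinate tie-breaks).
#' @param config A [threshold_config()]; `delta_c` and `delta_r` are the
#'   targets.
#' @param species Species the panel must satisfy (default: all in `stats`).
#' @return List of class `selection_result`: `loci` (ordered panel),
#'   `v_c`/`v_r` (final per-species running products), `satisfied` (logical
#'   per species), `trace` (per-iteration data.frame of locus, species,
#'   v_c, v_r, active flag), `status` (`"complete"` or `"exhausted"`), and
#'   `config`.
#' @export
greedy_select <- function(stats, catalog, config = threshold_config(),
                          species = NULL) {
  stopifnot(inherits(config, "threshold_config"))
  validate_locus_catalog(catalog)
  loci <- sort(unique(stats$locus_id))
  if (length(loci) == 0L) stop("empty candidate locus set")
  if (is.null(species)) species <- sort(unique(stats$species))
  species <- as.character(species)
  if (length(species) == 0L) stop("species list is empty")
  if (anyDuplicated(species)) {
    warning("duplicate species in subset; deduplicating")
    species <- unique(species)
  }

  mats <- stats_matrices(stats, loci, species)
  M <- mats$M; F_ <- mats$F

  # tie-break keys: joint PD over the requested species, then coordinates
  jpd <- 1 - apply(M, 1L, prod)
  cat_idx <- match(loci, catalog$locus_id)
  if (anyNA(cat_idx)) {
    stop("candidate locus id(s) absent from catalog: ",
         paste(loci[is.na(cat_idx)], collapse = ", "))
  }
  ord_key <- order(catalog$chrom[cat_idx], catalog$pos[cat_idx], loci)
  coord_rank <- integer(length(loci)); coord_rank[ord_key] <- seq_along(loci)

  v_c <- stats::setNames(rep(1, length(species)), species)
  v_r <- v_c
  cpm_target <- 1 - config$delta_c
  satisfied <- function() v_c <= cpm_target & v_r <= config$delta_r

  selected <- character()
  remaining <- rep(TRUE, length(loci))
  trace <- list()
  iter <- 0L
  while (!all(satisfied())) {
    if (!any(remaining)) break
    active <- names(v_c)[!satisfied()]
    score <- apply((M[, active, drop = FALSE] * F_[, active, drop = FALSE]),
                   1L, prod)
    score[!remaining] <- Inf
    best <- min(score)
    cand <- which(score == best & remaining)
    if (length(cand) > 1L) {
      cand <- cand[jpd[cand] == max(jpd[cand])]
      if (length(cand) > 1L) cand <- cand[which.min(coord_rank[cand])]
    }
    pick <- cand[1L]
    iter <- iter + 1L
    v_c[active] <- v_c[active] * M[pick, active]
    v_r[active] <- v_r[active] * F_[pick, active]
    remaining[pick] <- FALSE
    selected <- c(selected, loci[pick])
    trace[[iter]] <- data.frame(
      iteration = iter, locus_id = loci[pick], species = species,
      active = species %in% active,
      v_c = unname(v_c), v_r = unname(v_r))
  }
  status <- if (all(satisfied())) "complete" else "exhausted"
  if (status == "exhausted") {
    warning("candidate loci exhausted before all species met the targets")
  }
  structure(list(
    loci = selected,
    v_c = v_c, v_r = v_r,
    satisfied = satisfied(),
    trace = if (length(trace)) do.call(rbind, trace) else
      data.frame(iteration = integer(), locus_id = character(),
                 species = character(), active = logical(),
                 v_c = numeric(), v_r = numeric()),
    status = status,
    species = species,
    config = config
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("STR panel selection (", x$status, "): ", length(x$loci),
      " loci for ", length(x$species), " species\n", sep = "")
  cat("loci:", paste(x$loci, collapse = ", "), "\n")
  for (s in x$species) {
    cat(sprintf("  %-12s CPD = %.6g  RMP = %.3g  %s\n", s,
                1 - x$v_c[[s]], x$v_r[[s]],
                if (x$satisfied[[s]]) "satisfied" else "NOT satisfied"))
  }
  invisible(x)
}

#' Evaluate a panel per species and for the integrated pseudo species
#'
#' Computes, per species, the panel's combined power of discrimination,
#' combined matching probability, random-match probability and combined
#' power of exclusion, plus the pseudo-species combined PD (from per-locus
#' joint PDs) and pseudo RMP (from per-locus pseudo MPFs).
#'
#' @param panel Character vector of locus ids.
#' @param stats Per-locus per-species table from [locus_species_stats()].
#' @param species Species to report (default: all in `stats`).
#' @return List with `per_species` (data.frame: species, cpd, cpm, rmp,
#'   cpe) and `pseudo` (list: cpd, rmp).
#' @export
evaluate_panel <- function(panel, stats, species = NULL) {
  if (is.null(species)) species <- sort(unique(stats$species))
  sub <- stats[stats$locus_id %in% panel, , drop = FALSE]
  per <- do.call(rbind, lapply(species, function(s) {
    rows <- sub[sub$species == s, , drop = FALSE]
    cpd <- combined_pd(rows$pm)
    data.frame(species = s, cpd = cpd, cpm = 1 - cpd,
               rmp = rmp(rows$mpf), cpe = combined_pe(rows$pe))
  }))
  ps <- pseudo_locus_stats(sub, species = species)
  # keep panel order irrelevant: products commute
  list(per_species = per,
       pseudo = list(cpd = pseudo_cpd(ps$joint_pd),
                     rmp = rmp(ps$pseudo_mpf)))
}

#' Panel sizes over a grid of CPD and RMP targets
#'
#' Runs [greedy_select()] for every combination of `delta_c` and `delta_r`
#' and tabulates the selected panel size.
#'
#' @param stats Candidate per-locus per-species stats.
#' @param catalog Locus catalog.
#' @param delta_c_grid,delta_r_grid Numeric grids of targets.
#' @param config Base [threshold_config()] supplying the other thresholds.
#' @param species Species list (default: all in `stats`).
#' @return Integer matrix, rows = `delta_r_grid`, columns = `delta_c_grid`,
#'   entries = panel size (`NA` when the targets were unreachable).
#' @export
threshold_sweep <- function(stats, catalog, delta_c_grid, delta_r_grid,
                            config = threshold_config(), species = NULL) {
  out <- matrix(NA_integer_, nrow = length(delta_r_grid),
                ncol = length(delta_c_grid),
                dimnames = list(signif(delta_r_grid, 6),
                                signif(delta_c_grid, 6)))
  for (i in seq_along(delta_r_grid)) {
    for (j in seq_along(delta_c_grid)) {
      cfg <- config
      cfg$delta_c <- delta_c_grid[j]
      cfg$delta_r <- delta_r_grid[i]
      res <- withCallingHandlers(
        greedy_select(stats, catalog, cfg, species),
        warning = function(w) invokeRestart("muffleWarning"))
      out[i, j] <- if (res$status == "complete") length(res$loci) else NA_integer_
    }
  }
  out
}

#' Panel sizes across species subsets
#'
#' Runs [greedy_select()] once per species subset on the same candidate
#' stats and reports panel size and status per subset.
#'
#' @param stats Candidate per-locus per-species stats.
#' @param catalog Locus catalog.
#' @param subsets List of character vectors of species names.
#' @param config A [threshold_config()].
#' @return data.frame with columns `subset`, `n_species`, `panel_size`,
#'   `status`.
#' @export
species_subset_sweep <- function(stats, catalog, subsets,
                                 config = threshold_config()) {
  if (length(subsets) == 0L) stop("no species subsets given")
  rows <- lapply(subsets, function(sub) {
    if (length(sub) == 0L) stop("empty species subset")
    if (anyDuplicated(sub)) {
      warning("duplicate species in subset; deduplicating")
      sub <- unique(sub)
    }
    res <- withCallingHandlers(
      greedy_select(stats, catalog, config, species = sub),
      warning = function(w) invokeRestart("muffleWarning"))
    data.frame(subset = paste(unique(sub), collapse = "+"),
               n_species = length(unique(sub)),
               panel_size = length(res$loci), status = res$status)
  })
  do.call(rbind, rows)
}
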