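#' Heterozygosity of a locus
#'
#' Observed heterozygosity (the default) is the summed frequency of genotype
#' classes whose two alleles differ. Expected heterozygosity is
#' `1 - sum(p_i^2)` from allele frequencies. The observed form is the
#' forensic convention and is what the power-of-exclusion formula consumes.
#'
#' @param genotype_freqs data.frame with columns `allele_a`, `allele_b`,
#'   `freq` (as from [estimate_genotype_frequencies()]).
#' @param mode `"observed"` (default) or `"expected"`.
#' @param allele_freqs Named allele-frequency vector; required for
#'   `mode = "expected"`.
#' @return Heterozygosity in `[0, 1]`.
#' @export
heterozygosity <- function(genotype_freqs, mode = c("observed", "expected"),
                           allele_freqs = NULL) {
  mode <- match.arg(mode)
  if (mode == "expected") {
    if (is.null(allele_freqs)) stop("expected mode needs allele_freqs")
    return(1 - sum(allele_freqs^2))
  }
  check_genotype_freqs(genotype_freqs)
  sum(genotype_freqs$freq[genotype_freqs$allele_a != genotype_freqs$allele_b])
}

#' Probability of matching (PM) at a locus
#'
#' The probability that two individuals drawn independently from the
#' genotype distribution carry the same genotype: `sum(f_G^2)` over observed
#' genotype classes. Computed from observed genotype frequencies, not from
#' Hardy-Weinberg expectations.
#'
#' @inheritParams heterozygosity
#' @return PM in `[0, 1]`.
#' @export
match_probability <- function(genotype_freqs) {
  check_genotype_freqs(genotype_freqs)
  sum(genotype_freqs$freq^2)
}

#' Power of discrimination (PD)
#'
#' The complement of the probability of matching: `1 - PM`.
#'
#' @param pm Probability of matching, in `[0, 1]`.
#' @return PD in `[0, 1]`.
#' @export
power_of_discrimination <- function(pm) {
  if (any(pm < 0 | pm > 1)) stop("pm must lie in [0, 1]")
  1 - pm
}

#' Power of exclusion (PE)
#'
#' Single-locus average probability that a random non-father is excluded in
#' a mother-child-man trio, from the standard formula
#' `PE = h^2 * (1 - 2*h*H^2)` with `h` the observed heterozygosity and
#' `H = 1 - h` the homozygosity.
#'
#' @param h Observed heterozygosity in `[0, 1]`.
#' @return PE in `[0, 1]`.
#' @export
power_of_exclusion <- function(h) {
  if (any(h < 0 | h > 1)) stop("heterozygosity must lie in [0, 1]")
  H <- 1 - h
  h^2 * (1 - 2 * h * H^2)
}

#' Maximum profile frequency (MPF) at a locus
#'
#' The largest single genotype-class frequency; the most common profile a
#' random individual could present at the locus.
#'
#' @inheritParams heterozygosity
#' @return MPF in `(0, 1]`.
#' @export
max_profile_frequency <- function(genotype_freqs) {
  check_genotype_freqs(genotype_freqs)
  max(genotype_freqs$freq)
}

check_genotype_freqs <- function(gf) {
  if (!is.data.frame(gf) || nrow(gf) == 0L) {
    stop("genotype frequency map is empty")
  }
  stopifnot(all(c("allele_a", "allele_b", "freq") %in% names(gf)))
  invisible(gf)
}

#' Joint power of discrimination of a locus across species
#'
#' For the integrated pseudo species, `1 - prod(M_s)` over per-species
#' matching probabilities. A species with no data at the locus contributes
#' `M = 1` (uninformative), so absent species neither help nor hurt.
#'
#' @param pm_by_species Numeric vector of per-species PM values in `[0, 1]`.
#' @return Joint PD in `[0, 1]`.
#' @export
joint_pd <- function(pm_by_species) {
  if (any(pm_by_species < 0 | pm_by_species > 1)) stop("PM values must lie in [0, 1]")
  1 - prod(pm_by_species)
}

#' Pseudo-species maximum profile frequency of a locus
#'
#' Product of per-species MPFs, mirroring the product structure of the joint
#' power of discrimination; absent species contribute `F = 1`.
#'
#' @param mpf_by_species Numeric vector of per-species MPF values in `[0, 1]`.
#' @return Pseudo MPF in `[0, 1]`.
#' @export
pseudo_mpf <- function(mpf_by_species) {
  if (any(mpf_by_species < 0 | mpf_by_species > 1)) stop("MPF values must lie in [0, 1]")
  prod(mpf_by_species)
}

#' Combined power of discrimination (CPD) of a panel in one species
#'
#' `C_s = 1 - prod(M_l)` over panel loci; the empty panel has CPD 0.
#'
#' @param panel_pm Per-locus PM values in the species.
#' @return CPD in `[0, 1]`.
#' @export
combined_pd <- function(panel_pm) {
  if (length(panel_pm) == 0L) return(0)
  if (any(panel_pm < 0 | panel_pm > 1)) stop("PM values must lie in [0, 1]")
  1 - prod(panel_pm)
}

#' Combined power of discrimination for the integrated pseudo species
#'
#' `1 - prod(1 - D_l)` over per-locus joint PDs; empty panel gives 0.
#'
#' @param panel_joint_pd Per-locus joint PD values.
#' @return Pseudo CPD in `[0, 1]`.
#' @export
pseudo_cpd <- function(panel_joint_pd) {
  if (length(panel_joint_pd) == 0L) return(0)
  if (any(panel_joint_pd < 0 | panel_joint_pd > 1)) stop("joint PD values must lie in [0, 1]")
  1 - prod(1 - panel_joint_pd)
}

#' Random-match probability (RMP) of a panel
#'
#' Product over panel loci of the maximum profile frequency: an upper bound
#' on the probability that a random individual matches a given full profile.
#' The empty panel has RMP 1 (every individual matches a null profile).
#'
#' @param panel_mpf Per-locus MPF values.
#' @return RMP in `[0, 1]`.
#' @export
rmp <- function(panel_mpf) {
  if (length(panel_mpf) == 0L) return(1)
  if (any(panel_mpf < 0 | panel_mpf > 1)) stop("MPF values must lie in [0, 1]")
  prod(panel_mpf)
}

#' Combined power of exclusion (CPE) of a panel
#'
#' `1 - prod(1 - E_l)` over per-locus powers of exclusion; empty panel gives 0.
#'
#' @param panel_pe Per-locus PE values.
#' @return CPE in `[0, 1]`.
#' @export
combined_pe <- function(panel_pe) {
  if (length(panel_pe) == 0L) return(0)
  if (any(panel_pe < 0 | panel_pe > 1)) stop("PE values must lie in [0, 1]")
  1 - prod(1 - panel_pe)
}

# P(genotype g transmits allele a) under Mendelian segregation
transmit_prob <- function(g, a) {
  0.5 * (g[1] == a) + 0.5 * (g[2] == a)
}

#' Paternity index at one locus for a mother-child-alleged-father trio
#'
#' The standard trio likelihood ratio
#' `PI = P(child | mother, alleged father) / P(child | mother, random man)`,
#' computed by enumerating maternal/paternal allele transmissions, with the
#' random man's transmitted allele drawn from population allele frequencies.
#' No mutation model, silent alleles, or kinship priors: an alleged father
#' carrying no copy of any obligate paternal allele yields `PI = 0`.
#'
#' @param mother,child,alleged_father Length-2 integer vectors (unordered
#'   diploid genotypes in repeat counts).
#' @param allele_freqs Named numeric vector of population allele frequencies.
#' @return Non-negative likelihood ratio. A mother-child pair that is
#'   Mendelian-inconsistent is an error, not an exclusion of the man.
#' @export
paternity_index <- function(mother, child, alleged_father, allele_freqs) {
  stopifnot(length(mother) == 2L, length(child) == 2L,
            length(alleged_father) == 2L)
  pop_freq <- function(a) {
    f <- allele_freqs[as.character(a)]
    if (is.na(f)) 0 else unname(f)
  }
  # P(child | maternal source gm, paternal allele prob function)
  child_prob <- function(pat_prob) {
    if (child[1] == child[2]) {
      transmit_prob(mother, child[1]) * pat_prob(child[1])
    } else {
      transmit_prob(mother, child[1]) * pat_prob(child[2]) +
        transmit_prob(mother, child[2]) * pat_prob(child[1])
    }
  }
  denom <- child_prob(pop_freq)
  if (transmit_prob(mother, child[1]) == 0 && transmit_prob(mother, child[2]) == 0) {
    stop("mother-child genotypes are Mendelian-inconsistent")
  }
  if (denom == 0) {
    stop("child's paternal allele has population frequency 0; PI undefined")
  }
  num <- child_prob(function(a) transmit_prob(alleged_father, a))
  num / denom
}

#' Combined paternity index (CPI) over a panel
#'
#' Product of per-locus paternity indices. Loci with `PI = 0` (exclusions)
#' are counted and, for the product, replaced by a small floor so that
#' log-scale reports remain finite; the exclusion count is always reported
#' alongside.
#'
#' @param per_locus_pi Non-negative per-locus PI values.
#' @param floor Value substituted for zero PIs in the product (default
#'   `1e-30`).
#' @return List with `cpi` (floored product), `log10_cpi`, and
#'   `n_exclusions` (count of zero-PI loci).
#' @export
combined_pi <- function(per_locus_pi, floor = 1e-30) {
  if (any(per_locus_pi < 0)) stop("PI values must be non-negative")
  n_excl <- sum(per_locus_pi == 0)
  vals <- ifelse(per_locus_pi == 0, floor, per_locus_pi)
  cpi <- prod(vals)
  list(cpi = cpi, log10_cpi = log10(cpi), n_exclusions = n_excl)
}

#' Per-locus, per-species forensic parameter table
#'
#' Computes, for every (locus, species) pair with at least one call, the
#' call rate, observed heterozygosity, PM, PD, PE and MPF.
#'
#' @param table A genotype table, possibly spanning several species.
#' @param catalog Locus catalog; loci with no calls anywhere are omitted.
#' @param het_mode Heterozygosity mode passed to [heterozygosity()];
#'   the observed form feeds PE either way (PE is defined on observed h).
#' @return data.frame with one row per (locus, species): columns `locus_id`,
#'   `species`, `n_samples`, `n_called`, `call_rate`, `het`, `pm`, `pd`,
#'   `pe`, `mpf`.
#' @export
locus_species_stats <- function(table, catalog, het_mode = "observed") {
  validate_locus_catalog(catalog)
  rows <- list()
  for (sp in unique(table$species)) {
    sub <- table[table$species == sp, , drop = FALSE]
    n_samples <- length(unique(sub$sample))
    for (loc in intersect(catalog$locus_id, unique(sub$locus_id))) {
      called <- called_rows(sub, loc)
      if (nrow(called) == 0L) next
      gf <- estimate_genotype_frequencies(sub, loc)
      af <- estimate_allele_frequencies(sub, loc)
      h_obs <- heterozygosity(gf)
      h <- if (het_mode == "observed") h_obs else
        heterozygosity(gf, mode = "expected", allele_freqs = af)
      pm <- match_probability(gf)
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = loc, species = sp,
        n_samples = n_samples,
        n_called = length(unique(called$sample)),
        call_rate = compute_call_rate(sub, loc),
        het = h,
        pm = pm,
        pd = power_of_discrimination(pm),
        pe = power_of_exclusion(h_obs),
        mpf = max_profile_frequency(gf)
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(locus_id = character(), species = character(),
                      n_samples = integer(), n_called = integer(),
                      call_rate = numeric(), het = numeric(), pm = numeric(),
                      pd = numeric(), pe = numeric(), mpf = numeric()))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Joint (pseudo-species) locus statistics
#'
#' For each locus, the joint power of discrimination `1 - prod(M_s)` and the
#' pseudo maximum profile frequency `prod(F_s)` over the species in
#' `species`; species without data at a locus contribute `M = F = 1`.
#'
#' @param stats Per-locus per-species table from [locus_species_stats()].
#' @param species Species to integrate (default: all present in `stats`).
#' @return data.frame with columns `locus_id`, `n_species`, `joint_pd`,
#'   `pseudo_mpf`.
#' @export
pseudo_locus_stats <- function(stats, species = NULL) {
  if (is.null(species)) species <- unique(stats$species)
  stats <- stats[stats$species %in% species, , drop = FALSE]
  loci <- unique(stats$locus_id)
  out <- data.frame(locus_id = loci,
                    n_species = rep(NA_integer_, length(loci)),
                    joint_pd = rep(NA_real_, length(loci)),
                    pseudo_mpf = rep(NA_real_, length(loci)))
  for (i in seq_along(loci)) {
    sub <- stats[stats$locus_id == loci[i], , drop = FALSE]
    out$n_species[i] <- nrow(sub)
    out$joint_pd[i] <- joint_pd(sub$pm)     # absent species contribute M = 1
    out$pseudo_mpf[i] <- pseudo_mpf(sub$mpf)
  }
  out
}
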