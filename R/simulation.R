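#' Specification of a synthetic multi-species STR population
#'
#' Describes the populations the generator emulates: several species sharing
#' a fraction of STR loci, each species carrying its own allele-frequency
#' spectrum at the loci it observes. Frequencies are drawn from a symmetric
#' Dirichlet; an optional minimum allele frequency keeps every allele
#' informative (frequency at least `min_freq`), implemented as a floor plus
#' a rescaled Dirichlet draw so the floor is met exactly.
#'
#' @param species Character vector of species names.
#' @param n_loci Number of loci in the catalog.
#' @param alleles_range Length-2 integer range of alleles per locus
#'   (default `c(3, 8)`).
#' @param concentration Symmetric Dirichlet concentration (default 1).
#' @param min_freq Minimum allele frequency, 0 to disable (default 0.05).
#' @param sharing Probability each species observes each locus (default 0.8);
#'   every locus is forced to be observed by at least one species.
#' @param missing_rate Per-call missingness rate for sampled genotype tables
#'   (default 0).
#' @param seed Integer seed; fully determines the generated population.
#' @return List of class `population_spec`.
#' @export
population_spec <- function(species = c("sp1", "sp2"), n_loci = 50L,
                            alleles_range = c(3L, 8L), concentration = 1,
                            min_freq = 0.05, sharing = 0.8,
                            missing_rate = 0, seed = 1L) {
  stopifnot(length(species) >= 1L, n_loci >= 1L,
            length(alleles_range) == 2L,
            alleles_range[1] >= 2L, alleles_range[2] >= alleles_range[1],
            concentration > 0, min_freq >= 0,
            sharing > 0, sharing <= 1,
            missing_rate >= 0, missing_rate < 1)
  if (min_freq * alleles_range[2] >= 1) {
    stop("min_freq too large for the maximum allele count")
  }
  structure(list(species = as.character(species), n_loci = as.integer(n_loci),
                 alleles_range = as.integer(alleles_range),
                 concentration = concentration, min_freq = min_freq,
                 sharing = sharing, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "population_spec")
}

# symmetric Dirichlet draw via normalized gammas
rdirichlet1 <- function(k, concentration) {
  g <- stats::rgamma(k, shape = concentration, rate = 1)
  if (sum(g) == 0) g <- rep(1, k)
  g / sum(g)
}

# one locus's allele frequencies: floor at min_freq, Dirichlet on the rest
draw_allele_freqs <- function(alleles, concentration, min_freq) {
  k <- length(alleles)
  f <- min_freq + (1 - k * min_freq) * rdirichlet1(k, concentration)
  stats::setNames(f, as.character(alleles))
}

#' Generate a synthetic multi-species STR population
#'
#' Produces a locus catalog and per-species allele-frequency tables that
#' emulate the output of an upstream read-mapping and STR-calling workflow:
#' loci partially shared across species, each observing species with its own
#' allele-frequency spectrum over a common allele support.
#'
#' @param spec A [population_spec()].
#' @return List of class `str_population` with `catalog` (locus catalog
#'   data.frame), `freqs` (list: species -> locus_id -> named frequency
#'   vector) and `spec`.
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  n <- spec$n_loci
  catalog <- data.frame(
    locus_id = sprintf("L%04d", seq_len(n)),
    chrom = paste0("chr", sample(1:22, n, replace = TRUE)),
    pos = sample.int(2e8, n),
    repeat_unit_length = sample(2:6, n, replace = TRUE),
    motif = "."
  )
  # de-duplicate coordinates (loci are keyed by chrom+pos)
  dup <- duplicated(paste(catalog$chrom, catalog$pos))
  while (any(dup)) {
    catalog$pos[dup] <- sample.int(2e8, sum(dup))
    dup <- duplicated(paste(catalog$chrom, catalog$pos))
  }
  freqs <- stats::setNames(vector("list", length(spec$species)), spec$species)
  for (s in spec$species) freqs[[s]] <- list()
  for (i in seq_len(n)) {
    k <- sample(seq(spec$alleles_range[1], spec$alleles_range[2]), 1L)
    base <- sample(8:20, 1L)
    alleles <- seq(base, base + k - 1L)
    observed <- stats::runif(length(spec$species)) < spec$sharing
    if (!any(observed)) observed[sample.int(length(spec$species), 1L)] <- TRUE
    for (j in which(observed)) {
      freqs[[spec$species[j]]][[catalog$locus_id[i]]] <-
        draw_allele_freqs(alleles, spec$concentration, spec$min_freq)
    }
  }
  structure(list(catalog = catalog, freqs = freqs, spec = spec),
            class = "str_population")
}

#' Hardy-Weinberg genotype distribution from allele frequencies
#'
#' Expands allele frequencies `p` into the genotype-class distribution under
#' Hardy-Weinberg equilibrium: `p_i^2` for homozygotes, `2 p_i p_j` for
#' heterozygotes.
#'
#' @param allele_freqs Named numeric vector of allele frequencies.
#' @return data.frame with columns `allele_a`, `allele_b`, `freq` in
#'   canonical order.
#' @export
hwe_genotype_freqs <- function(allele_freqs) {
  a <- as.integer(names(allele_freqs))
  ord <- order(a)
  a <- a[ord]; p <- unname(allele_freqs)[ord]
  k <- length(a)
  ia <- rep(seq_len(k), times = k)
  ib <- rep(seq_len(k), each = k)
  keep <- ia <= ib
  ia <- ia[keep]; ib <- ib[keep]
  data.frame(allele_a = a[ia], allele_b = a[ib],
             freq = ifelse(ia == ib, p[ia]^2, 2 * p[ia] * p[ib]))
}

# k allele draws from a named frequency vector (safe for a single allele)
draw_alleles <- function(allele_freqs, k) {
  alleles <- as.integer(names(allele_freqs))
  alleles[sample.int(length(alleles), k, replace = TRUE, prob = allele_freqs)]
}

# n diploid HWE draws from one locus's allele frequencies -> 2-col matrix
draw_genotypes <- function(allele_freqs, n) {
  a <- draw_alleles(allele_freqs, n)
  b <- draw_alleles(allele_freqs, n)
  cbind(pmin(a, b), pmax(a, b))
}

#' Sample a genotype table under Hardy-Weinberg equilibrium
#'
#' Each individual draws two alleles independently from the locus allele
#' frequencies; genotypes are stored in canonical order. Calls are masked as
#' missing independently at `missing_rate`.
#'
#' @param freqs List mapping locus_id to a named allele-frequency vector
#'   (one species' slice of [generate_population()] output).
#' @param n_individuals Number of diploid individuals.
#' @param seed Integer seed (set when non-NULL; pass NULL to continue the
#'   current RNG stream).
#' @param species Species label written into the table.
#' @param missing_rate Per-call missingness probability.
#' @return A `genotype_table`.
#' @export
sample_genotypes <- function(freqs, n_individuals, seed = NULL,
                             species = "sp1", missing_rate = 0) {
  stopifnot(n_individuals >= 1L)
  if (!is.null(seed)) set.seed(seed)
  samples <- sprintf("%s_ind%05d", species, seq_len(n_individuals))
  out <- lapply(names(freqs), function(loc) {
    g <- draw_genotypes(freqs[[loc]], n_individuals)
    if (missing_rate > 0) {
      miss <- stats::runif(n_individuals) < missing_rate
      g[miss, ] <- NA_integer_
    }
    data.frame(species = species, sample = samples, locus_id = loc,
               allele_a = g[, 1], allele_b = g[, 2])
  })
  genotype_table(do.call(rbind, out))
}

# population (theoretical) PD / HE / MPF for one locus under HWE
population_locus_params <- function(allele_freqs) {
  gf <- hwe_genotype_freqs(allele_freqs)
  pm <- match_probability(gf)
  c(pd = power_of_discrimination(pm),
    he = heterozygosity(gf),    # HWE observed == expected
    mpf = max_profile_frequency(gf))
}

#' Sample-size experiment: allele detection and estimator accuracy
#'
#' For each sample size n, repeatedly draws n diploid individuals per locus
#' under Hardy-Weinberg equilibrium from known population allele
#' frequencies, then measures (a) the fraction of the locus's population
#' alleles detected in the sample and (b) the absolute deviation of the
#' sample-estimated PD, HE and MPF from their population values (computed
#' from the full HWE genotype distribution). Results are averaged over loci
#' and replicates; the maximum deviations are reported alongside the means.
#'
#' With `exhaustive = TRUE` the "sample" is the population distribution
#' itself, covering the identity case (detection 1, deviations 0).
#'
#' @param freqs List mapping locus_id to named allele-frequency vectors.
#' @param sizes Integer vector of sample sizes n.
#' @param replicates Replicates per size (default 50).
#' @param seed Integer seed.
#' @param exhaustive If TRUE, skip sampling and evaluate the population
#'   against itself.
#' @return data.frame with one row per size: `n`, `detection` (mean fraction
#'   of alleles detected), `mad_pd`, `mad_he`, `mad_mpf` (mean absolute
#'   deviations) and `max_dev_pd`, `max_dev_he`, `max_dev_mpf`.
#' @export
sample_size_experiment <- function(freqs, sizes, replicates = 50L,
                                   seed = 1L, exhaustive = FALSE) {
  stopifnot(length(freqs) >= 1L, all(sizes >= 1L))
  pop <- vapply(freqs, population_locus_params, numeric(3))  # 3 x n_loci
  if (exhaustive) {
    return(data.frame(n = sizes, detection = 1,
                      mad_pd = 0, mad_he = 0, mad_mpf = 0,
                      max_dev_pd = 0, max_dev_he = 0, max_dev_mpf = 0))
  }
  set.seed(seed)
  rows <- lapply(sizes, function(n) {
    dets <- numeric(0)
    devs <- matrix(numeric(0), ncol = 3)
    for (r in seq_len(replicates)) {
      for (loc in names(freqs)) {
        af_pop <- freqs[[loc]]
        g <- draw_genotypes(af_pop, n)
        seen <- unique(c(g[, 1], g[, 2]))
        dets <- c(dets, mean(as.integer(names(af_pop)) %in% seen))
        # sample-estimated parameters from empirical genotype frequencies
        tab <- table(paste(g[, 1], g[, 2]))
        f <- as.numeric(tab) / n
        het_idx <- vapply(strsplit(names(tab), " "),
                          function(p) p[1] != p[2], logical(1))
        est <- c(pd = 1 - sum(f^2), he = sum(f[het_idx]), mpf = max(f))
        devs <- rbind(devs, abs(est - pop[, loc]))
      }
    }
    data.frame(n = n, detection = mean(dets),
               mad_pd = mean(devs[, 1]), mad_he = mean(devs[, 2]),
               mad_mpf = mean(devs[, 3]),
               max_dev_pd = max(devs[, 1]), max_dev_he = max(devs[, 2]),
               max_dev_mpf = max(devs[, 3]))
  })
  do.call(rbind, rows)
}

#' Random-match-probability distribution over simulated individuals
#'
#' Simulates diploid profiles at the panel loci under Hardy-Weinberg
#' equilibrium and returns, per individual, the product over loci of the
#' population frequency of the individual's genotype (the profile's
#' random-match probability). Suitable for log10 box plots across panels.
#'
#' @param freqs List mapping locus_id to named allele-frequency vectors.
#' @param panel Character vector of locus ids (subset of `names(freqs)`).
#' @param n_individuals Number of simulated individuals.
#' @param seed Integer seed.
#' @return Numeric vector of per-individual RMP values (all 1 for an empty
#'   panel).
#' @export
simulate_rmp_distribution <- function(freqs, panel, n_individuals,
                                      seed = 1L) {
  stopifnot(n_individuals >= 1L)
  missing_loci <- setdiff(panel, names(freqs))
  if (length(missing_loci)) {
    stop("panel loci absent from frequency table: ",
         paste(missing_loci, collapse = ", "))
  }
  set.seed(seed)
  out <- rep(1, n_individuals)
  for (loc in panel) {
    af <- freqs[[loc]]
    gf <- hwe_genotype_freqs(af)
    g <- draw_genotypes(af, n_individuals)
    idx <- match(paste(g[, 1], g[, 2]), paste(gf$allele_a, gf$allele_b))
    out <- out * gf$freq[idx]
  }
  out
}

#' Simulate true and false paternity trios and their combined PI
#'
#' True trios: mother and father drawn under Hardy-Weinberg equilibrium, the
#' child inheriting one allele from each. False trios: the child comes from
#' the true parents but the tested man is an unrelated male drawn from the
#' population. The combined paternity index is computed per family over the
#' panel, with exclusions (zero per-locus PI) counted and floored in the
#' product.
#'
#' @param freqs List mapping locus_id to named allele-frequency vectors.
#' @param panel Character vector of locus ids.
#' @param n_true,n_false Family counts (defaults 1000 each).
#' @param seed Integer seed.
#' @param floor Zero-PI floor passed to [combined_pi()].
#' @return data.frame with one row per family: `cohort` ("true"/"false"),
#'   `family`, `cpi`, `log10_cpi`, `n_exclusions`.
#' @export
simulate_trios <- function(freqs, panel, n_true = 1000L, n_false = 1000L,
                           seed = 1L, floor = 1e-30) {
  stopifnot(n_true >= 1L, n_false >= 1L)
  missing_loci <- setdiff(panel, names(freqs))
  if (length(missing_loci)) {
    stop("panel loci absent from frequency table: ",
         paste(missing_loci, collapse = ", "))
  }
  set.seed(seed)
  one_cohort <- function(n, true_father) {
    res <- vector("list", n)
    for (fam in seq_len(n)) {
      pis <- numeric(length(panel))
      for (i in seq_along(panel)) {
        af <- freqs[[panel[i]]]
        mother <- draw_alleles(af, 2L)
        father <- draw_alleles(af, 2L)
        child <- c(mother[sample.int(2L, 1L)], father[sample.int(2L, 1L)])
        tested <- if (true_father) father else draw_alleles(af, 2L)
        pis[i] <- paternity_index(mother, child, tested, af)
      }
      cp <- combined_pi(pis, floor = floor)
      res[[fam]] <- data.frame(
        cohort = if (true_father) "true" else "false", family = fam,
        cpi = cp$cpi, log10_cpi = cp$log10_cpi,
        n_exclusions = cp$n_exclusions)
    }
    do.call(rbind, res)
  }
  rbind(one_cohort(n_true, TRUE), one_cohort(n_false, FALSE))
}
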