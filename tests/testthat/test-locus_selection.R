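test_that("shared-species filter keeps loci observed in at least two species", {
  M <- matrix(c(0.3, NA, NA,
                0.3, 0.4, NA,
                0.3, 0.4, 0.2), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("s1", "s2", "s3")))
  st <- stats_from_matrices(M, M)
  expect_equal(sort(shared_species_filter(st)), c("B", "C"))
})

test_that("structural filter drops sex chromosomes and mononucleotide repeats", {
  cat <- make_catalog(c("a", "b", "c", "d"),
                      chrom = c("chrX", "chr2", "chr3", "chrY"),
                      rul = c(4L, 1L, 2L, 3L))
  expect_equal(structural_filter(cat), "c")
})

test_that("threshold filter applies Eq-style bounds per qualifying species", {
  cfg <- threshold_config()  # delta_d=0.6, delta_m=0.4, delta_e=0.3, delta_h=0.5
  base <- function(locus, species, pd, pm, pe, h, eta) {
    data.frame(locus_id = locus, species = species, n_samples = 100L,
               n_called = round(100 * eta), call_rate = eta, het = h,
               pm = pm, pd = pd, pe = pe, mpf = 0.3)
  }
  st <- rbind(
    # L1: fails PD in one qualifying species
    base("L1", "s1", 0.59, 0.41, 0.5, 0.6, 1.0),
    base("L1", "s2", 0.80, 0.20, 0.5, 0.6, 1.0),
    # L2: exactly at every boundary in both species (inclusive comparisons)
    base("L2", "s1", 0.60, 0.40, 0.30, 0.50, 1.0),
    base("L2", "s2", 0.60, 0.40, 0.30, 0.50, 1.0),
    # L3: failing values only in a species below the call-rate threshold
    base("L3", "s1", 0.10, 0.90, 0.01, 0.05, 0.4),
    base("L3", "s2", 0.80, 0.20, 0.5, 0.7, 1.0),
    base("L3", "s3", 0.80, 0.20, 0.5, 0.7, 1.0),
    # L4: passes but observed in only one species after call-rate screen
    base("L4", "s1", 0.80, 0.20, 0.5, 0.7, 1.0),
    base("L4", "s2", 0.80, 0.20, 0.5, 0.7, 0.3))
  surv <- threshold_filter(st, cfg)
  expect_equal(sort(surv), c("L2", "L3"))
})

make_greedy_instance <- function() {
  loci <- c("L1", "L2", "L3")
  M <- matrix(c(0.2, 0.2,
                0.5, 0.5,
                0.3, 0.9), nrow = 3, byrow = TRUE,
              dimnames = list(loci, c("s1", "s2")))
  F_ <- matrix(c(0.1, 0.1,
                 0.5, 0.5,
                 0.2, 0.9), nrow = 3, byrow = TRUE,
               dimnames = list(loci, c("s1", "s2")))
  list(M = M, F = F_, stats = stats_from_matrices(M, F_),
       catalog = make_catalog(loci))
}

test_that("greedy selection picks the strongest locus first and meets thresholds", {
  inst <- make_greedy_instance()
  cfg <- threshold_config(delta_c = 0.9, delta_r = 0.15)
  res <- greedy_select(inst$stats, inst$catalog, cfg)
  expect_s3_class(res, "selection_result")
  expect_equal(res$loci[1], "L1")
  expect_equal(res$status, "complete")
  expect_true(all(res$v_c <= 1 - cfg$delta_c))
  expect_true(all(res$v_r <= cfg$delta_r))
  # exhaustive subset search: the panel meets thresholds and no single
  # locus other than those found by search does better than the greedy size
  oracle <- exhaustive_min_panel(inst$M, inst$F, cfg$delta_c, cfg$delta_r)
  expect_false(is.null(oracle))
  expect_gte(length(res$loci), oracle$size)
})

test_that("degenerate and unreachable thresholds terminate correctly", {
  inst <- make_greedy_instance()
  res0 <- greedy_select(inst$stats, inst$catalog,
                        threshold_config(delta_c = 0, delta_r = 1))
  expect_equal(res0$loci, character(0))
  expect_equal(res0$status, "complete")

  flat <- matrix(1, nrow = 2, ncol = 2,
                 dimnames = list(c("A", "B"), c("s1", "s2")))
  st <- stats_from_matrices(flat, flat)
  expect_warning(
    res <- greedy_select(st, make_catalog(c("A", "B")),
                         threshold_config(delta_c = 0, delta_r = 0.5)),
    "exhausted")
  expect_equal(res$status, "exhausted")

  expect_error(greedy_select(st[0, ], make_catalog("A"), threshold_config()),
               "empty candidate")
})

test_that("greedy output is invariant to candidate input row order", {
  set.seed(41)
  loci <- sprintf("L%02d", 1:15)
  M <- matrix(runif(45, 0.1, 0.9), 15, 3, dimnames = list(loci, c("a", "b", "c")))
  F_ <- matrix(runif(45, 0.05, 0.8), 15, 3, dimnames = dimnames(M))
  st <- stats_from_matrices(M, F_)
  cat <- make_catalog(loci, chrom = sample(paste0("chr", 1:5), 15, TRUE))
  cfg <- threshold_config(delta_c = 0.999, delta_r = 1e-4)
  res1 <- greedy_select(st, cat, cfg)
  res2 <- greedy_select(st[sample(nrow(st)), ], cat, cfg)
  expect_identical(res1$loci, res2$loci)
  expect_identical(res1$v_c, res2$v_c)
})

test_that("running products in the trace match direct recomputation", {
  set.seed(43)
  loci <- sprintf("L%02d", 1:10)
  M <- matrix(runif(20, 0.2, 0.9), 10, 2, dimnames = list(loci, c("a", "b")))
  F_ <- matrix(runif(20, 0.1, 0.8), 10, 2, dimnames = dimnames(M))
  st <- stats_from_matrices(M, F_)
  res <- greedy_select(st, make_catalog(loci),
                       threshold_config(delta_c = 0.99, delta_r = 1e-3))
  tr <- res$trace
  for (s in res$species) {
    sub <- tr[tr$species == s, ]
    # v_C(s) after iteration k = product of M over iterations where s active
    run <- 1
    for (k in seq_len(nrow(sub))) {
      if (sub$active[k]) run <- run * M[sub$locus_id[k], s]
      expect_equal(sub$v_c[k], run)
    }
    expect_equal(res$v_c[[s]], run)
  }
})

test_that("greedy matches the exhaustive oracle's feasibility on small instances", {
  set.seed(47)
  for (rep in 1:8) {
    n <- sample(6:12, 1); k <- sample(1:3, 1)
    loci <- sprintf("L%02d", seq_len(n))
    sp <- paste0("s", seq_len(k))
    M <- matrix(runif(n * k, 0.15, 0.95), n, k, dimnames = list(loci, sp))
    F_ <- matrix(runif(n * k, 0.1, 0.9), n, k, dimnames = list(loci, sp))
    # random missing species-locus pairs
    drop <- matrix(runif(n * k) < 0.15, n, k)
    M[drop] <- NA; F_[drop] <- NA
    st <- stats_from_matrices(M, F_)
    cfg <- threshold_config(delta_c = runif(1, 0.5, 0.99),
                            delta_r = 10^runif(1, -3, -1))
    oracle <- exhaustive_min_panel(M, F_, cfg$delta_c, cfg$delta_r)
    res <- suppressWarnings(greedy_select(st, make_catalog(loci), cfg))
    if (is.null(oracle)) {
      expect_equal(res$status, "exhausted")
    } else {
      expect_equal(res$status, "complete")
      expect_gte(length(res$loci), oracle$size)
      expect_true(all(res$v_c <= 1 - cfg$delta_c & res$v_r <= cfg$delta_r))
    }
  }
})

test_that("evaluate_panel reproduces the product formulas", {
  loci <- c("L1", "L2")
  M <- matrix(c(0.4, 0.3, 0.2, 0.6), 2, 2, dimnames = list(loci, c("a", "b")))
  F_ <- matrix(c(0.1, 0.2, 0.3, 0.4), 2, 2, dimnames = dimnames(M))
  PE <- matrix(c(0.5, 0.4, 0.3, 0.2), 2, 2, dimnames = dimnames(M))
  st <- stats_from_matrices(M, F_, PE)

  one <- evaluate_panel("L1", st["a" == st$species & st$locus_id == "L1", ],
                        species = "a")
  expect_equal(one$per_species$rmp, 0.1)
  expect_equal(one$per_species$cpd, 0.6)
  expect_equal(one$per_species$cpe, 0.5)

  empty <- evaluate_panel(character(), st, species = c("a", "b"))
  expect_equal(empty$per_species$rmp, c(1, 1))
  expect_equal(empty$per_species$cpd, c(0, 0))
  expect_equal(empty$per_species$cpe, c(0, 0))
  expect_equal(empty$pseudo$cpd, 0)
  expect_equal(empty$pseudo$rmp, 1)

  both <- evaluate_panel(loci, st)
  for (s in c("a", "b")) {
    row <- both$per_species[both$per_species$species == s, ]
    expect_equal(row$cpd, 1 - prod(M[, s]))
    expect_equal(row$rmp, prod(F_[, s]))
    expect_equal(row$cpe, 1 - prod(1 - PE[, s]))
    expect_equal(row$cpm, 1 - row$cpd)
    # pseudo CPD dominates each per-species CPD on the same loci
    expect_gte(both$pseudo$cpd, row$cpd)
  }
  expect_equal(both$pseudo$cpd, 1 - prod(M))
  expect_equal(both$pseudo$rmp, prod(F_))
})

test_that("threshold sweep sizes grow as the RMP ceiling tightens", {
  set.seed(53)
  loci <- sprintf("L%02d", 1:30)
  M <- matrix(runif(60, 0.2, 0.6), 30, 2, dimnames = list(loci, c("a", "b")))
  F_ <- matrix(runif(60, 0.1, 0.5), 30, 2, dimnames = dimnames(M))
  st <- stats_from_matrices(M, F_)
  cat <- make_catalog(loci)
  rgrid <- 10^seq(-2, -6, by = -1)
  cgrid <- c(0.99, 0.999, 0.9999)
  sw <- threshold_sweep(st, cat, cgrid, rgrid)
  expect_equal(dim(sw), c(length(rgrid), length(cgrid)))
  for (j in seq_along(cgrid)) expect_true(all(diff(sw[, j]) >= 0))
  # degenerate thresholds need no loci
  sw0 <- threshold_sweep(st, cat, 0, 1)
  expect_equal(sw0[1, 1], 0L)
})

test_that("species-subset sweep: fewer species never require a larger panel here", {
  set.seed(59)
  loci <- sprintf("L%02d", 1:20)
  sp <- c("a", "b", "c")
  M <- matrix(runif(60, 0.2, 0.7), 20, 3, dimnames = list(loci, sp))
  F_ <- matrix(runif(60, 0.1, 0.6), 20, 3, dimnames = list(loci, sp))
  st <- stats_from_matrices(M, F_)
  cat <- make_catalog(loci)
  cfg <- threshold_config(delta_c = 0.999, delta_r = 1e-4)
  sw <- species_subset_sweep(st, cat, list("a", c("a", "b", "c")), cfg)
  expect_equal(nrow(sw), 2L)
  expect_lte(sw$panel_size[1], sw$panel_size[2])
  expect_error(species_subset_sweep(st, cat, list(), cfg), "no species")
  expect_error(species_subset_sweep(st, cat, list(character()), cfg), "empty")
  expect_warning(species_subset_sweep(st, cat, list(c("a", "a")), cfg),
                 "deduplicat")
})
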