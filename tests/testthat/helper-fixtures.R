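# Shared fixture builders: everything is generated in code at test time.

make_catalog <- function(loci, chrom = NULL, pos = NULL, rul = NULL) {
  n <- length(loci)
  data.frame(
    locus_id = loci,
    chrom = if (is.null(chrom)) rep("chr1", n) else chrom,
    pos = if (is.null(pos)) seq(1000L, by = 1000L, length.out = n) else pos,
    repeat_unit_length = if (is.null(rul)) rep(4L, n) else rul,
    motif = "."
  )
}

make_gt <- function(species, sample, locus_id, a, b, catalog = NULL) {
  genotype_table(data.frame(species = species, sample = sample,
                            locus_id = locus_id, allele_a = a, allele_b = b),
                 catalog)
}

# genotype-frequency data.frame from parallel vectors
gf_df <- function(a, b, freq) {
  data.frame(allele_a = as.integer(a), allele_b = as.integer(b), freq = freq)
}

write_tsv_text <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

# stats table for selection tests, from loci x species matrices of PM / MPF
# (and optionally PE); entries of NA mean the species has no data there.
stats_from_matrices <- function(M, F_, PE = NULL, call_rate = 1) {
  loci <- rownames(M); species <- colnames(M)
  rows <- list()
  for (l in loci) for (s in species) {
    if (is.na(M[l, s])) next
    pm <- M[l, s]
    h <- 0.6  # placeholder heterozygosity for tests not exercising Eq-1 filters
    rows[[length(rows) + 1L]] <- data.frame(
      locus_id = l, species = s, n_samples = 100L, n_called = 100L,
      call_rate = call_rate, het = h, pm = pm, pd = 1 - pm,
      pe = if (is.null(PE)) 0.3 else PE[l, s], mpf = F_[l, s])
  }
  do.call(rbind, rows)
}

# Exhaustive minimal-panel oracle: smallest subset of loci satisfying
# prod(M) <= 1 - delta_c and prod(F) <= delta_r in every species.
# NA entries (species without data) contribute factors 1.
exhaustive_min_panel <- function(M, F_, delta_c, delta_r) {
  M[is.na(M)] <- 1; F_[is.na(F_)] <- 1
  n <- nrow(M)
  best <- NULL
  for (size in 0:n) {
    for (idx in if (size == 0) list(integer(0)) else
         asplit(utils::combn(n, size), 2)) {
      vc <- apply(M[idx, , drop = FALSE], 2, prod)
      vr <- apply(F_[idx, , drop = FALSE], 2, prod)
      if (all(vc <= 1 - delta_c) && all(vr <= delta_r)) {
        return(list(size = size, idx = idx))
      }
    }
  }
  NULL
}

# random small genotype-frequency map
random_gf <- function(k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  alleles <- sort(sample(8:20, k))
  a <- sample(alleles, k, replace = TRUE)
  b <- pmax(a, sample(alleles, k, replace = TRUE))
  a2 <- pmin(a, b)
  key <- unique(paste(a2, b))
  parts <- strsplit(key, " ")
  f <- as.numeric(stats::runif(length(key)))
  f <- f / sum(f)
  gf_df(vapply(parts, function(p) as.integer(p[1]), integer(1)),
        vapply(parts, function(p) as.integer(p[2]), integer(1)), f)
}

# brute-force probability that two independent draws from a genotype
# distribution coincide (double loop over the outer product)
brute_force_pm <- function(gf) {
  total <- 0
  for (i in seq_len(nrow(gf))) for (j in seq_len(nrow(gf))) {
    same <- gf$allele_a[i] == gf$allele_a[j] && gf$allele_b[i] == gf$allele_b[j]
    if (same) total <- total + gf$freq[i] * gf$freq[j]
  }
  total
}
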