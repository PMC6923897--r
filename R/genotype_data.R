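#' Read a locus catalog
#'
#' The catalog lists candidate STR loci: one row per locus with its genomic
#' position, repeat-unit length (RUL, 1-6 bp) and optional repeat motif.
#' Positions are 1-based; loci are points keyed by chromosome and position.
#'
#' @param path Path to a tab-separated file with header
#'   `locus_id  chrom  pos  repeat_unit_length  motif` (motif may be `"."`).
#' @return A `data.frame` with columns `locus_id`, `chrom`, `pos`,
#'   `repeat_unit_length`, `motif`.
#' @export
read_locus_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          stringsAsFactors = FALSE)
  expected <- c("locus_id", "chrom", "pos", "repeat_unit_length", "motif")
  if (!identical(names(df), expected)) {
    stop("catalog header mismatch: expected ", paste(expected, collapse = " "))
  }
  df$pos <- as.integer(df$pos)
  df$repeat_unit_length <- as.integer(df$repeat_unit_length)
  validate_locus_catalog(df)
}

#' Validate a locus catalog
#'
#' @param catalog A data.frame shaped like [read_locus_catalog()] output.
#' @return The validated catalog, invisibly unchanged.
#' @export
validate_locus_catalog <- function(catalog) {
  stopifnot(is.data.frame(catalog))
  need <- c("locus_id", "chrom", "pos", "repeat_unit_length")
  miss <- setdiff(need, names(catalog))
  if (length(miss)) stop("catalog missing columns: ", paste(miss, collapse = ", "))
  if (!("motif" %in% names(catalog))) catalog$motif <- "."
  if (anyDuplicated(catalog$locus_id)) {
    stop("duplicate locus_id in catalog: ",
         paste(unique(catalog$locus_id[duplicated(catalog$locus_id)]), collapse = ", "))
  }
  if (any(is.na(catalog$pos)) || any(catalog$pos < 1)) {
    stop("catalog pos must be integer >= 1")
  }
  rul <- catalog$repeat_unit_length
  if (any(is.na(rul)) || any(rul < 1L) || any(rul > 6L)) {
    stop("repeat_unit_length must be an integer in 1..6")
  }
  catalog
}

#' Write a locus catalog to TSV
#'
#' @param catalog Locus catalog data.frame.
#' @param path Output path.
#' @export
write_locus_catalog <- function(catalog, path) {
  utils::write.table(catalog[, c("locus_id", "chrom", "pos",
                                 "repeat_unit_length", "motif")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a validated genotype table
#'
#' A genotype table holds diploid STR calls: one row per (species, sample,
#' locus) with the two allele labels in repeat-unit counts. A missing call is
#' recorded as `NA` in both allele columns; half-missing calls are invalid
#' because the upstream STR genotyper emits a full diploid call or nothing.
#' Genotypes are unordered pairs and are canonicalized so
#' `allele_a <= allele_b`.
#'
#' @param df data.frame with columns `species`, `sample`, `locus_id`,
#'   `allele_a`, `allele_b` (integer alleles or both-`NA`).
#' @param catalog Optional locus catalog; when given, every `locus_id` must
#'   appear in it.
#' @return The validated, canonicalized table with class `genotype_table`.
#' @export
genotype_table <- function(df, catalog = NULL) {
  stopifnot(is.data.frame(df))
  need <- c("species", "sample", "locus_id", "allele_a", "allele_b")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("genotype table missing columns: ", paste(miss, collapse = ", "))
  df <- df[, need]
  df$allele_a <- as.integer(df$allele_a)
  df$allele_b <- as.integer(df$allele_b)
  half <- xor(is.na(df$allele_a), is.na(df$allele_b))
  if (any(half)) {
    stop("half-missing genotype at row(s): ", paste(which(half), collapse = ", "))
  }
  # canonical unordered pair
  swap <- !is.na(df$allele_a) & df$allele_a > df$allele_b
  if (any(swap)) {
    tmp <- df$allele_a[swap]
    df$allele_a[swap] <- df$allele_b[swap]
    df$allele_b[swap] <- tmp
  }
  key <- paste(df$species, df$sample, df$locus_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (species, sample, locus) row(s): ",
         paste(which(duplicated(key)), collapse = ", "))
  }
  if (!is.null(catalog)) {
    unknown <- setdiff(unique(df$locus_id), catalog$locus_id)
    if (length(unknown)) {
      stop("locus id(s) absent from catalog: ", paste(unknown, collapse = ", "))
    }
  }
  rownames(df) <- NULL
  class(df) <- c("genotype_table", "data.frame")
  df
}

#' Read a genotype table from TSV
#'
#' @param path Tab-separated file with header
#'   `species  sample  locus_id  allele_a  allele_b`; the token `NA` in both
#'   allele columns marks a missing call. Allele labels are integer repeat
#'   counts; anything else is rejected.
#' @param catalog Optional locus catalog used to validate locus ids.
#' @return A `genotype_table`.
#' @export
read_genotype_table <- function(path, catalog = NULL) {
  if (!file.exists(path)) stop("genotype table file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          stringsAsFactors = FALSE, na.strings = "NA")
  expected <- c("species", "sample", "locus_id", "allele_a", "allele_b")
  if (!identical(names(df), expected)) {
    stop("genotype table header mismatch: expected ",
         paste(expected, collapse = " "))
  }
  for (col in c("allele_a", "allele_b")) {
    raw <- df[[col]]
    ok <- is.na(raw) | grepl("^-?[0-9]+$", raw)
    if (!all(ok)) {
      stop("non-integer allele label(s) in column ", col, " at row(s): ",
           paste(which(!ok), collapse = ", "))
    }
  }
  genotype_table(df, catalog)
}

#' Write a genotype table to TSV
#'
#' Missing calls are written as `NA` in both allele columns, so the file
#' round-trips through [read_genotype_table()].
#'
#' @param table A genotype table.
#' @param path Output path.
#' @export
write_genotype_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

# rows of `table` at `locus_id` with a non-missing call
called_rows <- function(table, locus_id) {
  sub <- table[table$locus_id == locus_id, , drop = FALSE]
  sub[!is.na(sub$allele_a), , drop = FALSE]
}

#' Call rate at a locus
#'
#' The fraction of samples in the table with a non-missing genotype call at
#' the locus. Samples are counted across the whole table, so a sample typed
#' at other loci but not this one counts as missing here.
#'
#' @param table A genotype table (single species).
#' @param locus_id Locus identifier.
#' @return Fraction in `[0, 1]`.
#' @export
compute_call_rate <- function(table, locus_id) {
  samples <- unique(table$sample)
  if (length(samples) == 0L) stop("empty genotype table")
  called <- called_rows(table, locus_id)
  length(unique(called$sample)) / length(samples)
}

#' Allele frequencies at a locus
#'
#' Maximum-likelihood allele frequencies from allele counts over called
#' samples (each diploid call contributes two chromosomes); missing calls are
#' excluded from the denominator. No pseudo-counts are applied.
#'
#' @param table A genotype table (single species).
#' @param locus_id Locus identifier.
#' @return Named numeric vector of frequencies (names are allele repeat
#'   counts), sorted by allele, summing to 1.
#' @export
estimate_allele_frequencies <- function(table, locus_id) {
  called <- called_rows(table, locus_id)
  if (nrow(called) == 0L) {
    stop("no called samples at locus ", locus_id, "; allele frequencies undefined")
  }
  alleles <- c(called$allele_a, called$allele_b)
  tab <- table(alleles)
  freqs <- as.numeric(tab) / length(alleles)
  names(freqs) <- names(tab)
  freqs[order(as.integer(names(freqs)))]
}

#' Genotype frequencies at a locus
#'
#' Empirical genotype-class frequencies over called samples. Genotypes are
#' unordered pairs in canonical order (`allele_a <= allele_b`), so (12,10)
#' and (10,12) are pooled.
#'
#' @param table A genotype table (single species).
#' @param locus_id Locus identifier.
#' @return data.frame with columns `allele_a`, `allele_b`, `freq`, sorted by
#'   alleles; `freq` sums to 1.
#' @export
estimate_genotype_frequencies <- function(table, locus_id) {
  called <- called_rows(table, locus_id)
  if (nrow(called) == 0L) {
    stop("no called samples at locus ", locus_id, "; genotype frequencies undefined")
  }
  key <- paste(called$allele_a, called$allele_b, sep = "/")
  tab <- table(key)
  parts <- strsplit(names(tab), "/", fixed = TRUE)
  gf <- data.frame(
    allele_a = vapply(parts, function(p) as.integer(p[1]), integer(1)),
    allele_b = vapply(parts, function(p) as.integer(p[2]), integer(1)),
    freq = as.numeric(tab) / nrow(called)
  )
  gf <- gf[order(gf$allele_a, gf$allele_b), , drop = FALSE]
  rownames(gf) <- NULL
  gf
}
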