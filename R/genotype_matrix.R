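#' Define a microsatellite locus
#'
#' A locus is described by its name, motif length (2 for dinucleotide,
#' 3 for trinucleotide repeats), the admissible fragment-size range in base
#' pairs, and the sentinel integer used for missing calls in input tables.
#'
#' @param name locus identifier.
#' @param motif_length repeat-motif length in bp (>= 1).
#' @param size_range numeric length-2, min < max admissible allele size (bp).
#' @param missing_code integer sentinel outside `size_range` (default 0).
#' @return a `locus_def` list.
#' @export
locus_def <- function(name, motif_length, size_range, missing_code = 0L) {
  stopifnot(length(name) == 1L, motif_length >= 1,
            length(size_range) == 2L, size_range[1] < size_range[2])
  if (missing_code >= size_range[1] && missing_code <= size_range[2])
    stop("missing_code must lie outside size_range for locus ", name)
  structure(list(name = as.character(name),
                 motif_length = as.integer(motif_length),
                 size_min = as.numeric(size_range[1]),
                 size_max = as.numeric(size_range[2]),
                 missing_code = as.integer(missing_code)),
            class = "locus_def")
}

loci_frame <- function(loci) {
  if (is.data.frame(loci)) return(loci)
  data.frame(name = vapply(loci, `[[`, "", "name"),
             motif_length = vapply(loci, `[[`, 0L, "motif_length"),
             size_min = vapply(loci, `[[`, 0, "size_min"),
             size_max = vapply(loci, `[[`, 0, "size_max"),
             missing_code = vapply(loci, `[[`, 0L, "missing_code"),
             stringsAsFactors = FALSE)
}

# internal fast constructor: alleles already canonicalised and validated
new_genotype_matrix <- function(alleles, lf, pop, meta = NULL) {
  structure(list(alleles = alleles, loci = lf, pop = pop, meta = meta),
            class = "genotype_matrix")
}

#' Construct a diploid genotype matrix
#'
#' The central container of the package: an `n x 2L` integer matrix of allele
#' fragment sizes (bp), two adjacent columns per locus, `NA` for missing
#' calls, together with locus definitions and per-individual population
#' assignments plus optional population metadata (provenance, subcontinent,
#' coordinates). Allele pairs are canonicalised in ascending order; genotypes
#' are unphased throughout the package.
#'
#' @param alleles integer matrix, n individuals x 2*L columns (locus-major).
#' @param loci list of [locus_def()] objects (or the data.frame form).
#' @param populations factor/character of length n.
#' @param metadata optional data.frame keyed by column `population` with
#'   optional columns `provenance` (wild/captive), `subcontinent`, `country`,
#'   `lat`, `lon`.
#' @param ids individual identifiers (default rownames or ind_1..n).
#' @param validate check allele sizes against locus ranges (default TRUE).
#' @return object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(alleles, loci, populations, metadata = NULL,
                            ids = NULL, validate = TRUE) {
  lf <- loci_frame(loci)
  L <- nrow(lf)
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "double"
  if (ncol(alleles) != 2L * L)
    stop("alleles must have 2 columns per locus (", 2L * L, " expected)")
  n <- nrow(alleles)
  if (length(populations) != n) stop("populations must have one entry per individual")
  populations <- factor(populations)
  if (is.null(ids)) ids <- rownames(alleles) %||% paste0("ind_", seq_len(n))
  # canonicalise pair order (ascending, NA last)
  for (j in seq_len(L)) {
    a <- alleles[, 2L * j - 1L]; b <- alleles[, 2L * j]
    bad <- xor(is.na(a), is.na(b))
    if (any(bad)) stop("half-missing call at locus ", lf$name[j],
                       " (rows ", paste(which(bad)[1:min(3, sum(bad))], collapse = ","), ")")
    swap <- !is.na(a) & !is.na(b) & a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    alleles[, 2L * j - 1L] <- a; alleles[, 2L * j] <- b
    if (validate) {
      ok <- is.na(a) | (a >= lf$size_min[j] & b <= lf$size_max[j] & a <= lf$size_max[j] & b >= lf$size_min[j])
      if (!all(ok))
        stop("allele size outside declared range at locus ", lf$name[j],
             " (rows ", paste(which(!ok)[1:min(3, sum(!ok))], collapse = ","), ")")
    }
  }
  rownames(alleles) <- ids
  colnames(alleles) <- paste0(rep(lf$name, each = 2L), c(".1", ".2"))
  if (!is.null(metadata)) {
    if (!"population" %in% names(metadata)) stop("metadata needs a 'population' column")
    metadata$population <- as.character(metadata$population)
    miss <- setdiff(levels(populations), metadata$population)
    if (length(miss)) stop("metadata missing populations: ", paste(miss, collapse = ", "))
    if ("provenance" %in% names(metadata)) {
      badp <- !metadata$provenance %in% c("wild", "captive", NA)
      if (any(badp)) stop("provenance must be 'wild' or 'captive'")
    }
    if ("subcontinent" %in% names(metadata)) {
      vocab <- c("South America", "Central America", "North America", "Africa",
                 "Asia", "Australia", "Europe")
      bads <- !metadata$subcontinent %in% c(vocab, NA)
      if (any(bads)) stop("subcontinent outside the closed vocabulary")
    }
    if ("lat" %in% names(metadata) && any(abs(metadata$lat) > 90, na.rm = TRUE))
      stop("latitude outside [-90, 90]")
    if ("lon" %in% names(metadata) && any(abs(metadata$lon) > 180, na.rm = TRUE))
      stop("longitude outside [-180, 180]")
  }
  structure(list(alleles = alleles, loci = lf, pop = populations,
                 meta = metadata), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$alleles), "individuals,",
      nrow(x$loci), "loci,", nlevels(x$pop), "populations\n")
  invisible(x)
}

n_ind <- function(gm) nrow(gm$alleles)
n_loci <- function(gm) nrow(gm$loci)

# n x 2 allele matrix for locus j (index or name)
alleles_at <- function(gm, j) {
  if (is.character(j)) j <- match(j, gm$loci$name)
  gm$alleles[, c(2L * j - 1L, 2L * j), drop = FALSE]
}

#' Subset a genotype matrix by individuals
#'
#' @param x genotype_matrix
#' @param i index vector over individuals
#' @param ... unused
#' @export
`[.genotype_matrix` <- function(x, i, ...) {
  genotype_matrix(x$alleles[i, , drop = FALSE], x$loci,
                  droplevels(x$pop[i]), x$meta, validate = FALSE)
}

#' Summarise a genotype dataset
#'
#' Counts of individuals, populations and loci, the number of distinct
#' multilocus genotypes (MLGs; missing calls are treated as a distinct allele
#' value so two individuals differing only in missingness are distinct),
#' the overall missing-call rate, and per-population sample sizes.
#'
#' @param gm genotype_matrix
#' @return list of class `dataset_summary`.
#' @export
dataset_summary <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  n <- n_ind(gm)
  if (n == 0L) stop("empty genotype matrix")
  key <- apply(gm$alleles, 1L, paste, collapse = "/")
  sizes <- table(gm$pop)
  out <- list(n_individuals = n,
              n_populations = nlevels(gm$pop),
              n_loci = n_loci(gm),
              unique_mlg_count = length(unique(key)),
              missing_rate = mean(is.na(gm$alleles)),
              pop_sizes = as.integer(sizes),
              pop_size_mean = mean(as.integer(sizes)),
              pop_size_range = range(as.integer(sizes)))
  names(out$pop_sizes) <- names(sizes)
  class(out) <- "dataset_summary"
  out
}

#' @export
print.dataset_summary <- function(x, ...) {
  cat(sprintf("%d individuals (%d unique MLGs) | %d populations | %d loci\n",
              x$n_individuals, x$unique_mlg_count, x$n_populations, x$n_loci))
  cat(sprintf("mean population size %.1f (range %d-%d); missing rate %.3f\n",
              x$pop_size_mean, x$pop_size_range[1], x$pop_size_range[2],
              x$missing_rate))
  invisible(x)
}
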