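#' Read a delimited genotype table
#'
#' Reads tabular diploid genotype data. Two dialects are supported:
#' `"two_col"`, with two columns per locus named `<locus>.1`/`<locus>.2`
#' (or `<locus>_1`/`<locus>_2`), and `"slash"`, with one column per locus
#' holding `"size1/size2"`. The delimiter is sniffed (comma vs tab) unless
#' given. A `population` column is mandatory; `provenance`, `subcontinent`,
#' `country`, `lat`, `lon` columns are picked up as population metadata.
#'
#' @param path file path.
#' @param locus_defs list of [locus_def()].
#' @param dialect `"auto"`, `"two_col"` or `"slash"`.
#' @param sep field separator; `NULL` to sniff.
#' @return [genotype_matrix()]
#' @export
read_genotype_table <- function(path, locus_defs, dialect = "auto", sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !nzchar(first)) stop("parse error: empty file")
  if (is.null(sep)) sep <- if (grepl("\t", first)) "\t" else ","
  tab <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
  if (!"population" %in% names(tab)) stop("parse error: no 'population' column")
  lf <- loci_frame(locus_defs)
  L <- nrow(lf)
  if (dialect == "auto")
    dialect <- if (all(lf$name %in% names(tab))) "slash" else "two_col"
  n <- nrow(tab)
  if (n == 0L) stop("parse error: no data rows")
  alle <- matrix(NA_real_, n, 2L * L)
  for (j in seq_len(L)) {
    if (dialect == "slash") {
      col <- tab[[lf$name[j]]]
      if (is.null(col)) stop("parse error: missing column for locus ", lf$name[j])
      parts <- strsplit(as.character(col), "/", fixed = TRUE)
      bad <- lengths(parts) != 2L
      if (any(bad)) stop("malformed row ", which(bad)[1], " at locus ", lf$name[j])
      a <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
      b <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
    } else {
      cands <- list(paste0(lf$name[j], c(".1", ".2")), paste0(lf$name[j], c("_1", "_2")))
      ok <- vapply(cands, function(cc) all(cc %in% names(tab)), TRUE)
      if (!any(ok)) stop("parse error: columns for locus ", lf$name[j], " not found")
      hit <- cands[[which(ok)[1]]]
      a <- suppressWarnings(as.numeric(tab[[hit[1]]]))
      b <- suppressWarnings(as.numeric(tab[[hit[2]]]))
    }
    if (anyNA(a) || anyNA(b)) {
      bad <- which(is.na(a) | is.na(b))[1]
      stop("malformed row ", bad, " at locus ", lf$name[j], ": non-numeric allele")
    }
    a[a == lf$missing_code[j]] <- NA; b[b == lf$missing_code[j]] <- NA
    alle[, 2L * j - 1L] <- a; alle[, 2L * j] <- b
  }
  meta_cols <- intersect(c("population", "provenance", "subcontinent",
                           "country", "lat", "lon"), names(tab))
  meta <- NULL
  if (length(meta_cols) > 1L)
    meta <- unique(tab[meta_cols])
  ids <- if ("id" %in% names(tab)) as.character(tab$id) else paste0("ind_", seq_len(n))
  genotype_matrix(alle, lf, tab$population, metadata = meta, ids = ids)
}

#' Write a genotype matrix as a delimited table
#'
#' Inverse of [read_genotype_table()] (slash dialect); missing calls are
#' written as the locus missing code.
#'
#' @param gm genotype_matrix
#' @param path output path
#' @param sep separator (default comma)
#' @export
write_genotype_table <- function(gm, path, sep = ",") {
  lf <- gm$loci
  cols <- list(id = rownames(gm$alleles), population = as.character(gm$pop))
  if (!is.null(gm$meta)) {
    m <- gm$meta[match(cols$population, gm$meta$population), , drop = FALSE]
    for (nm in setdiff(names(m), "population")) cols[[nm]] <- m[[nm]]
  }
  for (j in seq_len(nrow(lf))) {
    a <- gm$alleles[, 2L * j - 1L]; b <- gm$alleles[, 2L * j]
    a[is.na(a)] <- lf$missing_code[j]; b[is.na(b)] <- lf$missing_code[j]
    cols[[lf$name[j]]] <- paste0(a, "/", b)
  }
  df <- as.data.frame(cols, check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a GenePop file
#'
#' Alleles are encoded as 3-digit codes; when a locus carries sizes above
#' 999 bp a per-locus offset (largest multiple of 100 below the minimum
#' size) is subtracted and recorded in the title line so that
#' [read_genepop()] can restore original sizes. Missing calls become
#' `000000`.
#'
#' @param gm genotype_matrix
#' @param path output path
#' @param title free-text first line
#' @export
write_genepop <- function(gm, path, title = "msatpop export") {
  lf <- gm$loci
  offs <- integer(nrow(lf))
  for (j in seq_len(nrow(lf))) {
    mx <- suppressWarnings(max(gm$alleles[, 2L * j], na.rm = TRUE))
    if (is.finite(mx) && mx > 999) {
      mn <- min(gm$alleles[, 2L * j - 1L], na.rm = TRUE)
      offs[j] <- 100L * (floor(mn / 100) - 0L)
      if (mx - offs[j] > 999) stop("encoding error: >999 size span at locus ", lf$name[j])
    }
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste0(title, " | offsets=", paste(offs, collapse = ",")), con)
  writeLines(lf$name, con)
  for (p in levels(gm$pop)) {
    writeLines("Pop", con)
    idx <- which(gm$pop == p)
    for (i in idx) {
      codes <- vapply(seq_len(nrow(lf)), function(j) {
        a <- gm$alleles[i, 2L * j - 1L]; b <- gm$alleles[i, 2L * j]
        if (is.na(a)) "000000"
        else sprintf("%03d%03d", as.integer(a - offs[j]), as.integer(b - offs[j]))
      }, "")
      writeLines(paste0(p, "#", rownames(gm$alleles)[i], " ,  ",
                        paste(codes, collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Read a GenePop file written by [write_genepop()]
#'
#' @param path file path
#' @param locus_defs list of [locus_def()] matching the file's loci
#' @return genotype_matrix
#' @export
read_genepop <- function(path, locus_defs) {
  lines <- readLines(path)
  if (length(lines) < 3L) stop("parse error: truncated GenePop file")
  offs <- rep(0L, length(locus_defs))
  if (grepl("offsets=", lines[1]))
    offs <- as.integer(strsplit(sub(".*offsets=", "", lines[1]), ",")[[1]])
  lf <- loci_frame(locus_defs)
  L <- nrow(lf)
  locus_lines <- lines[2:(1 + L)]
  if (!identical(trimws(locus_lines), lf$name))
    stop("locus names in file do not match locus_defs")
  body <- lines[-(1:(1 + L))]
  pop_breaks <- grepl("^\\s*pop\\s*$", body, ignore.case = TRUE)
  if (!any(pop_breaks)) stop("parse error: no Pop separator")
  pop_id <- cumsum(pop_breaks)
  rows <- body[!pop_breaks & nzchar(trimws(body))]
  pops <- pop_id[!pop_breaks & nzchar(trimws(body))]
  n <- length(rows)
  alle <- matrix(NA_real_, n, 2L * L)
  ids <- character(n); popname <- character(n)
  for (i in seq_len(n)) {
    parts <- strsplit(rows[i], ",")[[1]]
    ids[i] <- trimws(parts[1])
    codes <- strsplit(trimws(parts[2]), "\\s+")[[1]]
    if (length(codes) != L) stop("malformed row ", i, ": expected ", L, " loci")
    for (j in seq_len(L)) {
      a <- as.integer(substr(codes[j], 1, 3)); b <- as.integer(substr(codes[j], 4, 6))
      if (a != 0L) alle[i, 2L * j - 1L] <- a + offs[j]
      if (b != 0L) alle[i, 2L * j] <- b + offs[j]
    }
    popname[i] <- sub("#.*$", "", ids[i])
  }
  genotype_matrix(alle, lf, factor(popname, levels = unique(popname)),
                  ids = sub("^[^#]*#", "", ids))
}

#' Export a dataset summary as JSON
#'
#' @param summary a [dataset_summary()] object
#' @param path output path
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(unclass(summary), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
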