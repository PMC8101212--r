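# Pipeline orchestration: a declarative run configuration, deterministic
# per-stage sub-seeds, and a consolidated report bundle written as plain
# text artefacts (CSV / JSON / Newick).

#' Run configuration for the full analysis pipeline
#'
#' Permutation counts default to the field-standard values for each test
#' family (HWE 10,000; LD 1,000; pairwise FST 10,000; AMOVA 99;
#' Mantel 9,999); they can be lowered for smoke runs but must stay >= 1
#' (0 disables a stage's testing explicitly via `run_tests = FALSE`).
#'
#' @param out_dir output directory
#' @param seed master seed; per-stage sub-seeds are derived from it
#' @param n_perm_hwe,n_perm_ld,n_perm_fst,n_perm_amova,n_perm_mantel counts
#' @param k_range candidate cluster numbers for model selection
#' @param run_tests run permutation significance tests (default TRUE)
#' @param run_clustering,run_ne,run_ld,run_hwe stage switches
#' @return list of class `run_config`
#' @export
run_config <- function(out_dir, seed = 1L,
                       n_perm_hwe = 10000L, n_perm_ld = 1000L,
                       n_perm_fst = 10000L, n_perm_amova = 99L,
                       n_perm_mantel = 9999L, k_range = 1:25,
                       run_tests = TRUE, run_clustering = TRUE,
                       run_ne = TRUE, run_ld = TRUE, run_hwe = TRUE) {
  counts <- c(n_perm_hwe, n_perm_ld, n_perm_fst, n_perm_amova, n_perm_mantel)
  if (any(counts < 1)) stop("validation error: permutation counts must be >= 1")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_perm_hwe = n_perm_hwe, n_perm_ld = n_perm_ld,
                 n_perm_fst = n_perm_fst, n_perm_amova = n_perm_amova,
                 n_perm_mantel = n_perm_mantel, k_range = k_range,
                 run_tests = run_tests, run_clustering = run_clustering,
                 run_ne = run_ne, run_ld = run_ld, run_hwe = run_hwe),
            class = "run_config")
}

#' Run the full analysis pipeline and write a report bundle
#'
#' Executes, in order: dataset summary, diversity table and rarefied
#' allelic richness, overall F-statistics, (optional) HWE tests, (optional)
#' pairwise LD tests with Ohta components, chord distances with a
#' neighbour-joining tree, pairwise FST, AMOVA (using metadata hierarchy if
#' present), (optional) Mantel IBD when coordinates exist, (optional)
#' clustering with KIC selection, and (optional) Ne estimation per
#' population. Every artefact is a plain-text file under `config$out_dir`,
#' and the manifest records seeds and timings so a rerun with the same seed
#' reproduces the tables byte-for-byte.
#'
#' @param gm genotype_matrix
#' @param config [run_config()]
#' @return list of class `report_bundle` (invisibly also written to disk)
#' @export
run_full_report <- function(gm, config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  manifest <- list(seed = config$seed, started = format(t0), stages = list())
  bundle <- list()
  stage <- function(name, expr) {
    st <- Sys.time()
    val <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed", error = conditionMessage(e))
      NULL
    })
    if (!is.null(val))
      manifest$stages[[name]] <<- list(
        status = "ok", seconds = as.numeric(difftime(Sys.time(), st, units = "secs")))
    val
  }
  path <- function(f) file.path(config$out_dir, f)

  bundle$summary <- stage("summary", {
    s <- dataset_summary(gm)
    write_summary_json(s, path("dataset_summary.json"))
    s
  })
  bundle$diversity <- stage("diversity", {
    d <- diversity_table(gm)
    ar <- tryCatch(rarefied_allelic_richness(gm, g = 10L), error = function(e) NULL)
    tab <- data.frame(locus = colnames(d$he),
                      n_alleles = d$n_alleles_total,
                      ho = colMeans(d$ho, na.rm = TRUE),
                      he = colMeans(d$he, na.rm = TRUE),
                      a_u = d$a_u)
    if (!is.null(ar)) tab$ar <- colMeans(ar$ar, na.rm = TRUE)
    write.csv(tab, path("locus_summary.csv"), row.names = FALSE)
    list(table = tab, diversity = d, ar = ar)
  })
  bundle$fstats <- stage("fstats", {
    f <- wc_fstats(gm, seed = spawn_seed(config$seed, "fstats"))
    out <- as.data.frame(f$per_locus)
    out$locus <- rownames(out)
    write.csv(rbind(out, data.frame(fst = f$overall["fst"], fit = f$overall["fit"],
                                    fis = f$overall["fis"], locus = "overall")),
              path("fstats.csv"), row.names = FALSE)
    f
  })
  if (config$run_hwe) bundle$hwe <- stage("hwe", {
    h <- hwe_test_all(gm, n_perm = config$n_perm_hwe,
                      seed = spawn_seed(config$seed, "hwe"))
    write.csv(h, path("hwe_tests.csv"), row.names = FALSE)
    h
  })
  if (config$run_ld) bundle$ld <- stage("ld", {
    L <- n_loci(gm)
    pairs <- combn(L, 2L)
    rows <- list(); r <- 0L
    set.seed(spawn_seed(config$seed, "ld"))
    for (p in levels(gm$pop)) for (q in seq_len(ncol(pairs))) {
      res <- tryCatch(ld_test(gm, p, pairs[, q], n_perm = config$n_perm_ld),
                      error = function(e) NULL)
      if (is.null(res)) next
      r <- r + 1L
      rows[[r]] <- data.frame(population = p,
                              locus1 = res$locus_pair[1], locus2 = res$locus_pair[2],
                              statistic = res$statistic, p_value = res$p_value)
    }
    tab <- do.call(rbind, rows)
    write.csv(tab, path("ld_tests.csv"), row.names = FALSE)
    tab
  })
  bundle$chord <- stage("chord_nj", {
    fr <- allele_frequencies(gm)
    dch <- chord_distance_matrix(fr)
    write.csv(dch$values, path("chord_distances.csv"))
    tree <- if (nlevels(gm$pop) >= 3L) neighbor_joining(dch) else NULL
    if (!is.null(tree)) writeLines(tree$newick, path("chord_nj.nwk"))
    list(dist = dch, tree = tree)
  })
  bundle$pairwise_fst <- stage("pairwise_fst", {
    pf <- pairwise_fst_matrix(gm,
                              n_perm = if (config$run_tests) config$n_perm_fst else 0L,
                              seed = spawn_seed(config$seed, "pairwise_fst"))
    write.csv(pf$fst, path("pairwise_fst.csv"))
    if (config$run_tests) write.csv(pf$p, path("pairwise_fst_p.csv"))
    pf
  })
  bundle$amova <- stage("amova", {
    hier <- if (!is.null(gm$meta) && "subcontinent" %in% names(gm$meta))
      c("subcontinent", "population") else "population"
    a <- amova(gm, hier, n_perm = config$n_perm_amova,
               seed = spawn_seed(config$seed, "amova"))
    write.csv(data.frame(level = a$levels, sigma2 = a$components,
                         percent = a$percent, p = a$p_values),
              path("amova.csv"), row.names = FALSE)
    a
  })
  if (!is.null(gm$meta) && all(c("lat", "lon") %in% names(gm$meta)))
    bundle$ibd <- stage("ibd", {
      coords <- gm$meta[match(levels(gm$pop), gm$meta$population),
                        c("population", "lat", "lon")]
      geo <- geo_distance_matrix(coords)
      m <- mantel_ibd(bundle$pairwise_fst, geo, n_perm = config$n_perm_mantel,
                      seed = spawn_seed(config$seed, "ibd"))
      jsonlite::write_json(list(r = m$r, p_value = m$p_value, n_perm = m$n_perm),
                           path("ibd.json"), auto_unbox = TRUE, digits = NA)
      m
    })
  if (config$run_clustering) bundle$clustering <- stage("clustering", {
    sk <- select_k(gm, config$k_range, criterion = "KIC",
                   seed = spawn_seed(config$seed, "clustering"),
                   n_restarts = 4L)
    write.csv(sk$table, path("kic_table.csv"), row.names = FALSE)
    memb <- data.frame(id = rownames(gm$alleles), population = as.character(gm$pop),
                       cluster = sk$model$assignment)
    write.csv(cbind(memb, round(sk$model$z, 4)), path("cluster_membership.csv"),
              row.names = FALSE)
    sk
  })
  if (config$run_ne) bundle$ne <- stage("ne", {
    rows <- lapply(levels(gm$pop), function(p) {
      e <- tryCatch(ne_ld(gm, p), error = function(e) NULL)
      if (is.null(e)) return(NULL)
      data.frame(population = p, r2 = e$r2_mean, r2_drift = e$r2_drift,
                 Ne = e$Ne_point, lo = e$CI[1], hi = e$CI[2],
                 comparisons = e$n_comparisons)
    })
    tab <- do.call(rbind, rows)
    write.csv(tab, path("ne_estimates.csv"), row.names = FALSE)
    tab
  })
  manifest$finished <- format(Sys.time())
  manifest$total_seconds <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE)
  bundle$manifest <- manifest
  class(bundle) <- "report_bundle"
  invisible(bundle)
}
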