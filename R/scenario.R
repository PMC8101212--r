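# Declarative demographic scenarios for the coalescent simulator: named
# populations with diploid sizes, time-ordered events (backward in time:
# merges, admixtures, size changes), per-population sample sizes, and
# uniform priors for any quantity given by name instead of by value.

#' Demographic events
#'
#' Constructors for the three event kinds understood by the simulator, all
#' with `time` in generations before present. Backwards in time, a `merge`
#' moves all lineages of `source` into `sink`; an `admix` sends each lineage
#' of `pop` to `source_a` with probability `rate` and to `source_b`
#' otherwise; a `size_change` sets the diploid size of `pop` from `time`
#' onwards (pastwards). Numeric fields may instead be strings naming a prior
#' parameter declared in the scenario.
#'
#' @param time generations before present (>= 0), or a parameter name
#' @param source,sink,pop,source_a,source_b population names
#' @param rate admixture proportion toward `source_a` between 0 and 1, or a parameter name
#' @param N new diploid size, or parameter name
#' @name events
NULL

#' @rdname events
#' @export
ev_merge <- function(time, source, sink)
  list(kind = "merge", time = time, p1 = source, p2 = sink)

#' @rdname events
#' @export
ev_admix <- function(time, pop, source_a, source_b, rate)
  list(kind = "admix", time = time, p1 = pop, p2 = source_a, p3 = source_b,
       rate = rate)

#' @rdname events
#' @export
ev_size <- function(time, pop, N)
  list(kind = "size_change", time = time, p1 = pop, x = N)

#' Define a demographic scenario
#'
#' @param name scenario label
#' @param populations data.frame with columns `name` and `N` (diploid size;
#'   numeric or a prior parameter name)
#' @param samples named vector: diploid individuals sampled per population
#'   (populations absent from `samples` contribute no leaves)
#' @param events list of [ev_merge()], [ev_admix()], [ev_size()] events
#' @param priors named list of `c(lo, hi)` uniform bounds, one per parameter
#'   name used in `populations` or `events`
#' @return object of class `scenario`
#' @export
scenario <- function(name, populations, samples, events = list(), priors = list()) {
  stopifnot(all(c("name", "N") %in% names(populations)))
  if (is.null(names(samples)) || !all(names(samples) %in% populations$name))
    stop("samples must be named by population")
  times <- vapply(events, function(e) {
    if (is.character(e$time)) NA_real_ else as.numeric(e$time)
  }, 0)
  if (any(diff(times[!is.na(times)]) < 0))
    stop("events must be time-ordered (ascending, pastwards)")
  # every parameter name must have a declared bounded prior
  pnames <- character()
  grab <- function(v) if (is.character(v)) v else character()
  for (e in events) for (f in c("time", "rate", "x")) pnames <- c(pnames, grab(e[[f]]))
  pnames <- c(pnames, unlist(lapply(populations$N, grab)))
  missing_p <- setdiff(pnames, names(priors))
  if (length(missing_p)) stop("no prior declared for: ", paste(missing_p, collapse = ", "))
  for (pr in priors)
    if (length(pr) != 2L || !all(is.finite(pr)) || pr[1] > pr[2])
      stop("priors must be finite c(lo, hi) bounds")
  # static reachability: after all events, lineages must be able to meet
  reach <- unique(names(samples)[samples > 0])
  for (e in events) {
    if (e$kind == "merge" && e$p1 %in% reach)
      reach <- unique(c(setdiff(reach, e$p1), e$p2))
    if (e$kind == "admix" && e$p1 %in% reach)
      reach <- unique(c(setdiff(reach, e$p1), e$p2, e$p3))
  }
  if (length(reach) > 1L)
    stop("scenario leaves lineages stranded in: ", paste(reach, collapse = ", "))
  structure(list(name = name, populations = populations, samples = samples,
                 events = events, priors = priors),
            class = "scenario")
}

#' Microsatellite mutation model with priors
#'
#' Generalised stepwise mutation model: mean per-locus mutation rate
#' `mu_mean` (uniform prior, default 1e-5 to 1e-3), geometric step parameter
#' `P` (default 0.1 to 0.99; the strict stepwise model is the `P -> 0`
#' limit), and single-nucleotide-indel rate `mu_sni` (default 1e-8 to 1e-5).
#' Per-locus rates are drawn from a Gamma with shape 2 around the drawn
#' mean (`rate_het = FALSE` shares one rate across loci).
#'
#' @param mu_mean,P,mu_sni `c(lo, hi)` uniform prior bounds
#' @param rate_het per-locus Gamma(shape 2) rate heterogeneity (default TRUE)
#' @param n_states contiguous repeat states per locus (default 40)
#' @return object of class `mutation_model`
#' @export
mutation_model <- function(mu_mean = c(1e-5, 1e-3), P = c(0.1, 0.99),
                           mu_sni = c(1e-8, 1e-5), rate_het = TRUE,
                           n_states = 40L) {
  structure(list(mu_mean = mu_mean, P = P, mu_sni = mu_sni,
                 rate_het = rate_het, n_states = as.integer(n_states)),
            class = "mutation_model")
}

#' Draw all scenario and mutation parameters from their priors
#'
#' @param scn scenario
#' @param model mutation_model
#' @param n_loci number of loci (for per-locus rate draws)
#' @param seed RNG seed (recorded in the draw)
#' @return object of class `param_draw` with `values` (named numeric vector)
#'   and `locus_rates`
#' @export
sample_priors <- function(scn, model, n_loci = 15L, seed = NULL) {
  with_seed(seed, {
    vals <- vapply(scn$priors, function(b) runif(1, b[1], b[2]), 0)
    mu <- runif(1, model$mu_mean[1], model$mu_mean[2])
    P <- runif(1, model$P[1], model$P[2])
    sni <- runif(1, model$mu_sni[1], model$mu_sni[2])
    rates <- if (model$rate_het) rgamma(n_loci, shape = 2, scale = mu / 2)
             else rep(mu, n_loci)
    structure(list(values = vals, mu_mean = mu, P = P, mu_sni = sni,
                   locus_rates = rates, scenario = scn$name, seed = seed),
              class = "param_draw")
  })
}

# Substitute drawn values into the scenario and encode events numerically.
resolve_scenario <- function(scn, draw = NULL) {
  val <- function(v) {
    if (is.character(v)) {
      if (is.null(draw)) stop("scenario has free parameters; supply a draw")
      unname(draw$values[[v]])
    } else as.numeric(v)
  }
  popnames <- scn$populations$name
  N <- vapply(scn$populations$N, val, 0)
  pidx <- function(p) match(p, popnames)
  ev <- matrix(0, nrow = length(scn$events), ncol = 6L)
  for (i in seq_along(scn$events)) {
    e <- scn$events[[i]]
    ev[i, 1] <- val(e$time)
    if (e$kind == "merge") ev[i, 2:6] <- c(1, pidx(e$p1), pidx(e$p2), 0, 0)
    if (e$kind == "admix") ev[i, 2:6] <- c(2, pidx(e$p1), pidx(e$p2), pidx(e$p3), val(e$rate))
    if (e$kind == "size_change") ev[i, 2:6] <- c(3, pidx(e$p1), 0, 0, val(e$N %||% e$x))
  }
  if (nrow(ev) > 1L) ev <- ev[order(ev[, 1]), , drop = FALSE]
  samp <- integer(length(popnames))
  samp[pidx(names(scn$samples))] <- 2L * as.integer(scn$samples)  # gene copies
  list(pop_names = popnames, N = N, samples = samp, events = ev)
}
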