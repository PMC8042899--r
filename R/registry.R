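#' The default eight-model gene-flow registry
#'
#' Eight competing demographic scenarios on the fixed topology
#' ((domcn, seasa), wild), differing only in which migration edges are
#' active: M1 none; M2 wild-domcn; M3 domcn-seasa; M4 wild-seasa;
#' M5 = M2+M3; M6 = M2+M4; M7 all three pairs (continuous); M8 all pairs
#' but active only in the most recent `t1/2` generations. Every edge is
#' symmetric (both directions share one scaled rate). Parameter priors:
#' log-uniform diploid sizes on \[1e3, 1e6\]; `t0` uniform \[1000, 10000\]
#' and `t1` uniform \[100, t0) generations (enforced by rejection);
#' founding-bottleneck size fractions log-uniform \[0.01, 1\] for the two
#' derived demes; scaled migration `4Nm` uniform \[0, 20\] per active edge.
#' The registry is plain data, so alternative model sets and priors can be
#' substituted.
#'
#' @param mu Mutation rate per bp per generation.
#' @param gen_time Generation time in years.
#' @return A named list of model templates (class `model_registry`), each
#'   with `name`, `pairs` (active migration edges), `recent_only`, and a
#'   `priors` tibble (`param`, `dist`, `lo`, `hi`).
#' @export
model_registry <- function(mu = 1.91e-9, gen_time = 1) {
  all_pairs <- list(c("wild", "domcn"), c("domcn", "seasa"), c("wild", "seasa"))
  spec <- list(
    M1 = list(pairs = list(), recent_only = FALSE),
    M2 = list(pairs = all_pairs[1], recent_only = FALSE),
    M3 = list(pairs = all_pairs[2], recent_only = FALSE),
    M4 = list(pairs = all_pairs[3], recent_only = FALSE),
    M5 = list(pairs = all_pairs[c(1, 2)], recent_only = FALSE),
    M6 = list(pairs = all_pairs[c(1, 3)], recent_only = FALSE),
    M7 = list(pairs = all_pairs, recent_only = FALSE),
    M8 = list(pairs = all_pairs, recent_only = TRUE))
  reg <- lapply(names(spec), function(nm) {
    pr <- tibble::tibble(
      param = c("ne_wild", "ne_domcn", "ne_seasa", "ne_anc",
                "t0", "t1", "bneck_domcn", "bneck_seasa"),
      dist = c(rep("logunif", 4), "unif", "unif", "logunif", "logunif"),
      lo = c(rep(1e3, 4), 1000, 100, 0.01, 0.01),
      hi = c(rep(1e6, 4), 10000, 10000, 1, 1))
    for (pair in spec[[nm]]$pairs) {
      pr <- dplyr::bind_rows(pr, tibble::tibble(
        param = paste0("m4n_", pair[1], "_", pair[2]),
        dist = "unif", lo = 0, hi = 20))
    }
    list(name = nm, pairs = spec[[nm]]$pairs,
         recent_only = spec[[nm]]$recent_only, priors = pr,
         mu = mu, gen_time = gen_time)
  })
  names(reg) <- names(spec)
  structure(reg, class = "model_registry")
}

#' Draw parameters from a model's priors
#'
#' Independent draws honoring each parameter's distribution family and
#' bounds, with the ordering constraint `t1 < t0` enforced by rejection
#' (violating rows are redrawn).
#'
#' @param entry One registry entry (e.g. `model_registry()$M7`).
#' @param n_draws Number of parameter vectors.
#' @param seed Optional seed.
#' @return Tibble of `n_draws` rows, one column per parameter.
#' @export
draw_priors <- function(entry, n_draws, seed = NULL) {
  stopifnot(n_draws >= 1)
  if (!is.null(seed)) set.seed(seed)
  pr <- entry$priors
  stopifnot(all(pr$lo < pr$hi), all(is.finite(pr$lo)), all(is.finite(pr$hi)))
  draw_once <- function(n) {
    cols <- lapply(seq_len(nrow(pr)), function(i) {
      if (pr$dist[i] == "logunif") {
        exp(runif(n, log(pr$lo[i]), log(pr$hi[i])))
      } else {
        runif(n, pr$lo[i], pr$hi[i])
      }
    })
    names(cols) <- pr$param
    tibble::as_tibble(cols)
  }
  out <- draw_once(n_draws)
  if (all(c("t0", "t1") %in% pr$param)) {
    tries <- 0
    repeat {
      bad <- which(out$t1 >= out$t0)
      if (!length(bad)) break
      tries <- tries + 1
      if (tries > 1000) stop("prior constraint t1 < t0 infeasible")
      out[bad, ] <- draw_once(length(bad))
    }
  }
  out
}

#' Instantiate a demographic model from a registry entry and parameters
#'
#' Founding bottlenecks multiply the derived demes' sizes by their fraction
#' over the oldest fifth of each deme's existence (backward interval
#' `[0.8 t1, t1]`); migration edges are symmetric and active while both
#' demes exist, or only over the most recent `t1/2` generations for
#' recent-pulse models.
#'
#' @param entry Registry entry.
#' @param params One-row tibble / named list of parameter values.
#' @return A [demographic_model()].
#' @export
build_model <- function(entry, params) {
  p <- as.list(params)
  mig <- NULL
  if (length(entry$pairs)) {
    mig <- purrr::map_dfr(entry$pairs, function(pair) {
      m4n <- p[[paste0("m4n_", pair[1], "_", pair[2])]]
      t_end <- if (entry$recent_only) p$t1 / 2 else
        if (setequal(pair, c("domcn", "seasa"))) p$t1 else p$t0
      tibble::tibble(from = c(pair[1], pair[2]), to = c(pair[2], pair[1]),
                     m4n = m4n, t_start = 0, t_end = t_end)
    })
  }
  bneck <- tibble::tibble(
    deme = c("domcn", "seasa"),
    frac = c(p$bneck_domcn, p$bneck_seasa),
    t_start = 0.8 * p$t1, t_end = p$t1)
  demographic_model(
    ne = c(wild = p$ne_wild, domcn = p$ne_domcn, seasa = p$ne_seasa,
           anc = p$ne_anc),
    t1 = p$t1, t0 = p$t0, bottlenecks = bneck, migration = mig,
    mu = entry$mu, gen_time = entry$gen_time)
}

#' Simulate a parameter + summary-statistic table for one model
#'
#' Draws `n_draws` parameter vectors from the entry's priors, simulates a
#' dataset for each, and returns parameters alongside the 37 summary
#' statistics (prefixed `stat_`).
#'
#' @inheritParams draw_priors
#' @param sample_sizes,n_loci,locus_bp Forwarded to [simulate_dataset()].
#' @return Tibble: `model`, parameter columns, `stat_*` columns.
#' @export
simulate_model_table <- function(entry, n_draws, sample_sizes = c(wild = 20,
                                                                  domcn = 20,
                                                                  seasa = 20),
                                 n_loci = 200, locus_bp = 5000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  params <- draw_priors(entry, n_draws)
  stats <- purrr::map(seq_len(n_draws), function(i) {
    ds <- simulate_dataset(build_model(entry, params[i, ]), sample_sizes,
                           n_loci, locus_bp)
    summarize_dataset(ds)
  })
  stats <- do.call(rbind, stats)
  colnames(stats) <- paste0("stat_", colnames(stats))
  dplyr::bind_cols(tibble::tibble(model = entry$name), params,
                   tibble::as_tibble(stats))
}
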