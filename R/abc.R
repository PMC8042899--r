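#' PLS-DA reduction of summary statistics
#'
#' Partial least squares with one-hot model labels as the response (PLS-DA),
#' computed by NIPALS on standardized statistics (zero mean, unit SD).
#' Constant statistic columns are dropped with a warning before fitting.
#' The fitted transformer is a fixed linear map, so it applies identically
#' to observed statistics.
#'
#' @param stats Matrix or data frame of summary statistics (simulations in
#'   rows).
#' @param labels Model label per row.
#' @param n_components Number of PLS components (default 9), at most
#'   `min(#stats, #rows - 1)`.
#' @return A `pls_reducer`: list with `center`, `scale`, `rotation`
#'   (statistics x components), `keep` (retained columns), `n_components`.
#' @export
pls_reduce <- function(stats, labels, n_components = 9) {
  X <- as.matrix(stats)
  stopifnot(nrow(X) == length(labels), length(unique(labels)) >= 2)
  n_components <- min(n_components, ncol(X), nrow(X) - 1)
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  keep <- which(scl > 0)
  if (length(keep) < ncol(X))
    warning(ncol(X) - length(keep), " constant statistic column(s) dropped")
  X <- scale(X[, keep, drop = FALSE], center = ctr[keep], scale = scl[keep])
  lv <- sort(unique(labels))
  Y <- outer(labels, lv, "==") * 1
  Y <- scale(Y, center = TRUE, scale = FALSE)
  p <- ncol(X)
  W <- P <- matrix(0, p, n_components)
  E <- X; F <- Y
  for (k in seq_len(n_components)) {
    u <- F[, which.max(colSums(F^2))]
    t_old <- rep(Inf, nrow(X))
    for (it in 1:500) {
      w <- crossprod(E, u)
      w <- w / sqrt(sum(w^2))
      tk <- E %*% w
      q <- crossprod(F, tk)
      q <- q / sqrt(sum(q^2))
      u <- F %*% q
      if (sum((tk - t_old)^2) < 1e-12 * sum(tk^2)) break
      t_old <- tk
    }
    tt <- sum(tk^2)
    pk <- crossprod(E, tk) / tt
    E <- E - tk %*% t(pk)
    F <- F - tk %*% (crossprod(tk, F) / tt)
    W[, k] <- w
    P[, k] <- pk
  }
  rotation <- W %*% solve(crossprod(P, W))
  rownames(rotation) <- colnames(X)
  structure(list(center = ctr[keep], scale = scl[keep], rotation = rotation,
                 loadings = P, keep = names(ctr)[keep],
                 n_components = n_components, labels = lv),
            class = "pls_reducer")
}

#' Project statistics into a fitted PLS-DA space
#'
#' @param object A `pls_reducer` from [pls_reduce()].
#' @param newdata Matrix/data frame of statistics (or a named vector for a
#'   single observation) with the columns the reducer was fitted on.
#' @param ... Unused.
#' @return Matrix of component scores.
#' @export
predict.pls_reducer <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- t(as.matrix(newdata))
  X <- as.matrix(newdata)[, object$keep, drop = FALSE]
  X <- scale(X, center = object$center, scale = object$scale)
  X %*% object$rotation
}

mvn_logdens <- function(x, mean, chol_sigma) {
  d <- length(x)
  z <- backsolve(chol_sigma, x - mean, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(chol_sigma))) - 0.5 * sum(z^2)
}

#' ABC model choice by rejection or GLM
#'
#' Posterior model probabilities for an observed summary-statistic vector
#' against per-model simulation tables, in a PLS-DA-reduced space. With
#' `method = "rejection"`, the posterior is proportional to each model's
#' count among the globally nearest `retain_fraction` of simulations
#' (Euclidean distance). With `method = "glm"` (the
#' Leuenberger-Wegmann construction), the nearest `retain_fraction` of each
#' model's own simulations are retained, a linear-Gaussian regression of the
#' reduced statistics on that model's parameters is fitted (ridge 1e-8 on
#' the normal equations), and the marginal density of the observed
#' statistics under the fitted model - averaged over the retained parameter
#' draws - is combined with an equal model prior. Equal simulation counts
#' per model are enforced by subsampling.
#'
#' @param observed Named vector of summary statistics (names as produced by
#'   [summarize_dataset()], with or without the `stat_` prefix).
#' @param sims Simulation table: column `model`, parameter columns, and
#'   `stat_*` columns (as from [simulate_model_table()], possibly
#'   row-bound over models).
#' @param retain_fraction Fraction of simulations retained (default 0.01).
#' @param method `"glm"` or `"rejection"`.
#' @param n_components PLS components (default 9).
#' @param reducer Optional pre-fitted `pls_reducer` to reuse.
#' @return An `abc_result`: tibble (`model`, `n_retained`, `density`,
#'   `posterior`) with the method, chosen model and reducer as attributes.
#'   Posterior probabilities are non-negative and sum to 1.
#' @export
abc_model_choice <- function(observed, sims, retain_fraction = 0.01,
                             method = c("glm", "rejection"),
                             n_components = 9, reducer = NULL) {
  method <- match.arg(method)
  stat_cols <- grep("^stat_", names(sims), value = TRUE)
  models <- sort(unique(sims$model))
  # equal counts per model by deterministic subsampling
  n_min <- min(table(sims$model))
  sims <- dplyr::slice_head(dplyr::group_by(sims, .data$model), n = n_min)
  sims <- dplyr::ungroup(sims)
  X <- as.matrix(sims[stat_cols])
  if (is.null(reducer)) reducer <- pls_reduce(X, sims$model, n_components)
  sc <- predict(reducer, X)
  obs <- observed
  names(obs) <- ifelse(grepl("^stat_", names(obs)), names(obs),
                       paste0("stat_", names(obs)))
  so <- drop(predict(reducer, obs))
  if (method == "rejection") {
    d2 <- rowSums((sc - matrix(so, nrow(sc), length(so), byrow = TRUE))^2)
    k <- max(1L, ceiling(retain_fraction * nrow(sc)))
    kept <- order(d2)[seq_len(k)]
    if (!length(kept)) stop("zero retained simulations")
    cnt <- table(factor(sims$model[kept], levels = models))
    res <- tibble::tibble(model = models,
                          n_retained = as.integer(cnt),
                          density = NA_real_,
                          posterior = as.numeric(cnt) / sum(cnt))
  } else {
    param_cols <- setdiff(names(sims), c("model", stat_cols))
    logdens <- nret <- numeric(length(models))
    for (mi in seq_along(models)) {
      rows <- which(sims$model == models[mi])
      pc <- param_cols[colSums(!is.na(sims[rows, param_cols])) > 0]
      d2 <- rowSums((sc[rows, , drop = FALSE] -
                       matrix(so, length(rows), length(so), byrow = TRUE))^2)
      # enough retained draws to estimate the regression and its residual
      # covariance; retain_fraction governs only above that floor
      k <- max(5L * (length(pc) + 1L), 20L,
               ceiling(retain_fraction * length(rows)))
      kept <- rows[order(d2)[seq_len(min(k, length(rows)))]]
      nret[mi] <- length(kept)
      Th <- scale(as.matrix(sims[kept, pc]))
      Th[is.na(Th)] <- 0                       # constant param columns
      A <- cbind(1, Th)
      S <- sc[kept, , drop = FALSE]
      AtA <- crossprod(A) + diag(1e-8, ncol(A))
      B <- solve(AtA, crossprod(A, S))
      fit <- A %*% B
      R <- S - fit
      Sg <- crossprod(R) / max(1, nrow(R) - ncol(A)) +
        diag(1e-8, ncol(S))
      ch <- chol(Sg)
      ld <- vapply(seq_len(nrow(fit)),
                   function(j) mvn_logdens(so, fit[j, ], ch), 0)
      m <- max(ld)
      logdens[mi] <- m + log(mean(exp(ld - m)))
    }
    if (!any(is.finite(logdens))) {
      warning("zero total density: returning uniform posterior")
      post <- rep(1 / length(models), length(models))
      dens <- rep(0, length(models))
    } else {
      shift <- max(logdens[is.finite(logdens)])
      dens <- exp(logdens - shift)
      dens[!is.finite(dens)] <- 0
      post <- dens / sum(dens)
      dens <- exp(logdens)                     # reported on the raw scale
    }
    res <- tibble::tibble(model = models, n_retained = as.integer(nret),
                          density = dens, posterior = post)
  }
  structure(res, class = c("abc_result", class(res)),
            method = method, chosen = res$model[which.max(res$posterior)],
            reducer = reducer)
}

#' @export
print.abc_result <- function(x, ...) {
  cat("ABC model choice (", attr(x, "method"), "): chosen = ",
      attr(x, "chosen"), "\n", sep = "")
  NextMethod()
}

#' @export
tidy.abc_result <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("model", "n_retained", "density", "posterior")])
}

#' @export
glance.abc_result <- function(x, ...) {
  tibble::tibble(method = attr(x, "method"), chosen = attr(x, "chosen"),
                 n_models = nrow(x), max_posterior = max(x$posterior))
}

#' Validate ABC model choice with pseudo-observed datasets
#'
#' For every registry model, simulates reference tables and pseudo-observed
#' datasets (PODs) from the prior, runs [abc_model_choice()] on each POD,
#' and tabulates how often the true model is recovered as the posterior
#' argmax.
#'
#' @param registry A [model_registry()] (or subset).
#' @param n_pods_per_model PODs per model.
#' @param n_sims_per_model Reference simulations per model.
#' @param seed Seed controlling every simulation.
#' @param sample_sizes,n_loci,locus_bp Simulation scale per dataset.
#' @inheritParams abc_model_choice
#' @return List (class `abc_validation`): `confusion` (true x chosen count
#'   matrix as a tibble), `recovery` (per-model diagonal rate),
#'   `mean_recovery`, and the fitted `reducer`.
#' @export
validate_model_choice <- function(registry, n_pods_per_model = 50,
                                  n_sims_per_model = 2000, seed = 1,
                                  sample_sizes = c(wild = 20, domcn = 20,
                                                   seasa = 20),
                                  n_loci = 50, locus_bp = 2000,
                                  retain_fraction = 0.01,
                                  method = "glm", n_components = 9) {
  set.seed(seed)
  sims <- purrr::map_dfr(registry, simulate_model_table,
                         n_draws = n_sims_per_model,
                         sample_sizes = sample_sizes, n_loci = n_loci,
                         locus_bp = locus_bp)
  stat_cols <- grep("^stat_", names(sims), value = TRUE)
  reducer <- pls_reduce(as.matrix(sims[stat_cols]), sims$model, n_components)
  models <- vapply(registry, `[[`, "", "name")
  chosen <- true <- character(0)
  post_sum_err <- 0
  for (entry in registry) {
    pods <- simulate_model_table(entry, n_pods_per_model,
                                 sample_sizes = sample_sizes,
                                 n_loci = n_loci, locus_bp = locus_bp)
    for (i in seq_len(n_pods_per_model)) {
      obs <- unlist(pods[i, stat_cols])
      res <- abc_model_choice(obs, sims, retain_fraction = retain_fraction,
                              method = method, n_components = n_components,
                              reducer = reducer)
      chosen <- c(chosen, attr(res, "chosen"))
      true <- c(true, entry$name)
      post_sum_err <- max(post_sum_err, abs(sum(res$posterior) - 1))
    }
  }
  conf <- table(true = factor(true, models), chosen = factor(chosen, models))
  recovery <- diag(conf) / rowSums(conf)
  structure(list(confusion = tibble::as_tibble(as.data.frame(conf)),
                 recovery = recovery,
                 mean_recovery = mean(recovery),
                 n_pods_per_model = n_pods_per_model,
                 max_posterior_sum_err = post_sum_err,
                 reducer = reducer),
            class = "abc_validation")
}

#' @export
print.abc_validation <- function(x, ...) {
  cat("ABC validation: mean diagonal recovery",
      sprintf("%.3f", x$mean_recovery), "over",
      length(x$recovery), "models x", x$n_pods_per_model, "PODs\n")
  invisible(x)
}
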