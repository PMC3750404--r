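#' Replicate simulation experiments
#'
#' Runs `replicates` independent simulate-then-estimate cycles for one of
#' the three estimation schemes and summarises the per-kb estimates.
#' Several truncation levels `z` can be evaluated on the same simulated
#' datasets (as when one table row reports \eqn{S_{>0}}, \eqn{S_{>1}},
#' \eqn{S_{>2}} side by side), which also makes the comparison across `z`
#' paired rather than independent.
#'
#' Default coverages follow the standard design: 2X per haploid genome for
#' the pooled single-platform scheme, 1X per haploid per application for
#' dual applications (same total sequencing effort), and 2X per diploid
#' individual for single-line data.
#'
#' @param scheme `"pooled_single"`, `"pooled_dual"`, or `"single_line"`.
#' @param region_length Region length in sites (default 100 kb).
#' @param theta_per_kb True diversity per kb.
#' @param n Pool size in haploid genomes (pooled schemes).
#' @param n_individuals Number of diploid individuals (single-line scheme).
#' @param mean_depth Mean coverage per haploid (pooled), per haploid per
#'   application (dual), or per individual (single-line).  `NULL` picks
#'   the scheme default (2, 1, 2 respectively).
#' @param error An [constant_error()] or [beta_error()] model.
#' @param z Truncation level(s); may be a vector.
#' @param r_min Minimum depth for a non-missing site.
#' @param multiallelic Passed to [filter_policy()].
#' @param placement Segregating-site placement passed to
#'   [simulate_truth()].  The default `"fixed_count"` holds the number of
#'   segregating sites at its expectation \eqn{round(a_n \theta l)} and
#'   redraws positions and mutant frequencies each replicate, so that the
#'   replicate spread reflects sequencing and detection noise at a given
#'   polymorphism level; `"bernoulli"` additionally lets the regional
#'   polymorphism level itself vary between replicates.
#' @param replicates Number of simulation replicates.
#' @param seed Integer root seed; replicate `i` runs on a seed derived
#'   deterministically from it, so results are reproducible and
#'   independent of the evaluation order.
#' @param shared_site_error See [simulate_pooled_counts()].
#' @return A `"theta_experiment"` data frame with one row per `z`:
#'   columns `scheme`, `theta_per_kb` (truth), `error`, `z`, `mean`,
#'   `sd`, `replicates`, `failed`.  The matrix of per-replicate estimates
#'   (replicates x z) is attached as attribute `"estimates"`.
#' @export
run_experiment <- function(scheme = c("pooled_single", "pooled_dual", "single_line"),
                           region_length = 1e5, theta_per_kb = 0.1,
                           n = 50L, n_individuals = 25L,
                           mean_depth = NULL,
                           error = constant_error(0),
                           z = 0L, r_min = 6L,
                           multiallelic = "retain",
                           placement = "fixed_count",
                           replicates = 1000L, seed = 1L,
                           shared_site_error = FALSE) {
  scheme <- match.arg(scheme)
  if (is.null(mean_depth)) {
    mean_depth <- switch(scheme, pooled_single = 2, pooled_dual = 1, single_line = 2)
  }
  theta <- theta_per_kb / 1000
  z <- vapply(z, .check_z, integer(1))
  policies <- lapply(z, function(zi) filter_policy(r_min, zi, multiallelic))
  est <- matrix(NA_real_, nrow = replicates, ncol = length(z),
                dimnames = list(NULL, paste0("z", z)))
  for (i in seq_len(replicates)) {
    set.seed(.replicate_seed(seed, i))
    est[i, ] <- tryCatch(
      .one_replicate(scheme, region_length, theta, n, n_individuals,
                     mean_depth, error, policies, z, shared_site_error,
                     placement),
      error = function(e) rep(NA_real_, length(z)))
  }
  ok <- colSums(!is.na(est))
  out <- data.frame(scheme = scheme, theta_per_kb = theta_per_kb,
                    error = format(error), z = z,
                    mean = colMeans(est, na.rm = TRUE),
                    sd = if (replicates > 1) apply(est, 2L, stats::sd, na.rm = TRUE)
                         else NA_real_,
                    replicates = ok,
                    failed = replicates - ok)
  rownames(out) <- NULL
  structure(out, class = c("theta_experiment", "data.frame"),
            estimates = est, seed = seed)
}

.replicate_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 10007 + i * 7919) %% 2147483647)
}

.one_replicate <- function(scheme, l, theta, n, n_individuals, mean_depth,
                           error, policies, z, shared_site_error, placement) {
  if (scheme == "single_line") {
    truth <- simulate_truth(l, theta, 2L * n_individuals, placement)
    sites <- simulate_single_line(truth, mean_depth, error, n_individuals)
    vapply(z, function(zi) {
      estimate_single_line(sites, zi, region_length = l)$theta_per_kb
    }, numeric(1))
  } else if (scheme == "pooled_single") {
    truth <- simulate_truth(l, theta, n, placement)
    app <- simulate_pooled_counts(truth, mean_depth, error, applications = 1L)
    vapply(policies, function(p) {
      estimate_pooled_single(app[[1L]], n, p)$theta_per_kb
    }, numeric(1))
  } else {
    truth <- simulate_truth(l, theta, n, placement)
    apps <- simulate_pooled_counts(truth, mean_depth, error, applications = 2L,
                                   shared_site_error = shared_site_error)
    vapply(policies, function(p) {
      estimate_pooled_dual(apps[[1L]], apps[[2L]], n, p)$theta_per_kb
    }, numeric(1))
  }
}

#' @export
print.theta_experiment <- function(x, ...) {
  cat(sprintf("theta experiment: %s scheme, true theta %g/kb, error %s\n",
              x$scheme[1L], x$theta_per_kb[1L], x$error[1L]))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Grid of replicate experiments in table layout
#'
#' Convenience wrapper running [run_experiment()] over a grid of true
#' theta values and error models, stacking one row per (theta, error,
#' scheme, z) combination — the layout of a simulation summary table with
#' `mean (sd)` entries.
#'
#' @param theta_per_kb Vector of true diversities per kb.
#' @param errors List of error models.
#' @param schemes Character vector of schemes.
#' @param z Truncation levels evaluated on each simulated dataset.
#' @param ... Passed on to [run_experiment()] (e.g. `replicates`,
#'   `region_length`, `r_min`).
#' @param seed Root seed; each grid cell derives its own sub-seed.
#' @return A data frame with columns `scheme`, `theta_per_kb`, `error`,
#'   `z`, `mean`, `sd`, `replicates`, `failed`.
#' @export
experiment_table <- function(theta_per_kb = c(0.1, 1),
                             errors = list(constant_error(0)),
                             schemes = c("single_line", "pooled_single", "pooled_dual"),
                             z = c(0L, 1L, 2L), seed = 1L, ...) {
  grid <- expand.grid(theta = theta_per_kb,
                      err = seq_along(errors),
                      scheme = schemes,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    res <- run_experiment(scheme = grid$scheme[i],
                          theta_per_kb = grid$theta[i],
                          error = errors[[grid$err[i]]],
                          z = z,
                          seed = .replicate_seed(seed, i * 1000L),
                          ...)
    attr(res, "estimates") <- NULL
    class(res) <- "data.frame"
    res
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
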