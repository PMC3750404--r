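#' Site filtering policy
#'
#' Bundles the two knobs of the site-classification procedure: `r_min`, the
#' minimum read depth (per application) for a site to count as observed
#' rather than missing, and `z`, the read-count truncation level (alleles
#' are retained only when supported by more than `z` reads).  `r_min` must
#' be at least `2z + 2`, otherwise no site could ever show two alleles each
#' exceeding `z` reads.
#'
#' `multiallelic` controls what happens when more than two alleles survive
#' the z-filter.  The default `"retain"` counts the site as segregating,
#' matching the behaviour validated in simulation; `"missing"` excludes the
#' site from both the segregating-site count and the denominator, which is
#' the stricter published three-step rule.  The two differ only at high
#' error rates with `z = 0`, where multi-allele error sites are common.
#'
#' @param r_min Minimum per-application depth for a non-missing site.
#' @param z Truncation level, a non-negative integer.
#' @param multiallelic `"retain"` or `"missing"`; see Details.
#' @return An object of class `"filter_policy"`.
#' @export
filter_policy <- function(r_min = 6L, z = 0L, multiallelic = c("retain", "missing")) {
  z <- .check_z(z)
  multiallelic <- match.arg(multiallelic)
  if (length(r_min) != 1L || r_min != floor(r_min)) {
    stop("`r_min` must be a single integer")
  }
  r_min <- as.integer(r_min)
  if (r_min < 2L * z + 2L) {
    stop(sprintf("`r_min` must be at least 2z + 2 = %d (got %d)", 2L * z + 2L, r_min))
  }
  structure(list(r_min = r_min, z = z, multiallelic = multiallelic),
            class = "filter_policy")
}

#' @export
print.filter_policy <- function(x, ...) {
  cat(sprintf("filter policy: r_min = %d, z = %d, multiallelic sites %s\n",
              x$r_min, x$z,
              if (x$multiallelic == "retain") "retained as segregating" else "treated as missing"))
  invisible(x)
}

#' Sequencing error models
#'
#' `constant_error()` applies the same per-read error probability `epsilon`
#' at every site.  `beta_error()` draws a per-site error rate from a
#' Beta(`alpha`, `beta`) distribution whose second shape parameter is
#' derived from the requested mean: `beta = alpha * (1 - mean_epsilon) /
#' mean_epsilon`, so that small `alpha` gives a heavy-tailed, strongly
#' site-heterogeneous error landscape at a fixed average rate.
#'
#' @param epsilon Per-read, per-site error probability in `[0, 1)`.
#' @return An object of class `"error_model"`.
#' @export
constant_error <- function(epsilon = 0) {
  if (length(epsilon) != 1L || epsilon < 0 || epsilon >= 1) {
    stop("`epsilon` must be a single value in [0, 1)")
  }
  structure(list(mode = "constant", epsilon = as.numeric(epsilon)),
            class = "error_model")
}

#' @param alpha First Beta shape parameter (> 0); smaller values give more
#'   between-site heterogeneity.
#' @param mean_epsilon Mean of the Beta distribution, in (0, 1).
#' @rdname constant_error
#' @export
beta_error <- function(alpha, mean_epsilon = 0.005) {
  if (length(alpha) != 1L || alpha <= 0) stop("`alpha` must be a single positive value")
  if (length(mean_epsilon) != 1L || mean_epsilon <= 0 || mean_epsilon >= 1) {
    stop("`mean_epsilon` must lie strictly in (0, 1)")
  }
  beta <- alpha * (1 - mean_epsilon) / mean_epsilon
  structure(list(mode = "beta", alpha = as.numeric(alpha), beta = beta,
                 mean_epsilon = as.numeric(mean_epsilon)),
            class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  if (x$mode == "constant") {
    cat(sprintf("error model: constant epsilon = %g\n", x$epsilon))
  } else {
    cat(sprintf("error model: epsilon ~ Beta(%g, %g), mean %g\n",
                x$alpha, x$beta, x$mean_epsilon))
  }
  invisible(x)
}

#' @export
format.error_model <- function(x, ...) {
  if (x$mode == "constant") sprintf("constant(%g)", x$epsilon)
  else sprintf("beta(alpha=%g, mean=%g)", x$alpha, x$mean_epsilon)
}

# draw one epsilon per site
.draw_epsilon <- function(model, l) {
  if (model$mode == "constant") rep.int(model$epsilon, l)
  else stats::rbeta(l, model$alpha, model$beta)
}
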