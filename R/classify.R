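#' Classify sites from one sequencing application
#'
#' Applies the depth and read-count filters of a [filter_policy] to each
#' site.  A site is `missing` when its depth is below `r_min`; otherwise
#' alleles supported by more than `z` reads are retained and the site is
#' `segregating` when at least two alleles survive, `monomorphic` when one
#' (or, at extreme truncation, none) survives.  With
#' `multiallelic = "missing"` a site at which more than two alleles
#' survive is reclassified as missing instead of segregating.
#'
#' @param counts A [site_counts] table.
#' @param policy A [filter_policy].
#' @return A data frame with columns `position`, `status` (factor with
#'   levels missing/monomorphic/segregating), `n_retained`, and `retained`
#'   (comma-separated surviving alleles).
#' @export
classify_sites <- function(counts, policy = filter_policy()) {
  cnt <- .count_matrix(counts)
  cls <- .classify_single(cnt, policy)
  .classification_frame(counts$position, cls$status, cnt > policy$z & !is.na(cnt))
}

#' Classify sites observed by two sequencing applications
#'
#' Dual-application classification on two count tables over the same
#' positions.  A site is `missing` when either application is below
#' `r_min`.  An allele is retained only when it exceeds `z` reads in BOTH
#' applications; the site is `segregating` when at least two alleles are
#' retained, so segregation must be reported concordantly by the two
#' applications.  With `multiallelic = "missing"`, a site where either
#' application individually retains more than two alleles is missing, and
#' segregation additionally requires that the two applications retain
#' exactly the same two alleles.
#'
#' @param app1,app2 [site_counts] tables with identical `position` columns.
#' @inheritParams classify_sites
#' @inherit classify_sites return
#' @export
classify_sites_dual <- function(app1, app2, policy = filter_policy()) {
  .check_positions_match(app1, app2)
  c1 <- .count_matrix(app1)
  c2 <- .count_matrix(app2)
  cls <- .classify_dual(c1, c2, policy)
  .classification_frame(app1$position, cls$status, cls$pass)
}

.status_levels <- c("missing", "monomorphic", "segregating")

.classification_frame <- function(position, status, pass) {
  retained <- apply(pass, 1L, function(k) paste(ALLELES[k], collapse = ","))
  retained[status == 0L] <- NA_character_
  data.frame(position = position,
             status = factor(.status_levels[status + 1L], levels = .status_levels),
             n_retained = ifelse(status == 0L, NA_integer_, rowSums(pass)),
             retained = retained)
}

# internal fast paths: status coded 0 = missing, 1 = monomorphic, 2 = segregating

.classify_single <- function(cnt, policy) {
  depth <- rowSums(cnt)
  pass <- cnt > policy$z
  nall <- rowSums(pass)
  missing <- depth < policy$r_min
  if (policy$multiallelic == "missing") missing <- missing | nall > 2L
  status <- rep.int(1L, length(depth))
  status[nall >= 2L] <- 2L
  status[missing] <- 0L
  list(status = status, depth = depth)
}

.classify_dual <- function(c1, c2, policy) {
  d1 <- rowSums(c1)
  d2 <- rowSums(c2)
  pass1 <- c1 > policy$z
  pass2 <- c2 > policy$z
  pass <- pass1 & pass2
  nall <- rowSums(pass)
  missing <- d1 < policy$r_min | d2 < policy$r_min
  if (policy$multiallelic == "missing") {
    missing <- missing | rowSums(pass1) > 2L | rowSums(pass2) > 2L
    # strict rule: segregation requires the SAME two alleles in both apps
    seg <- !missing & rowSums(pass1) == 2L & rowSums(pass2) == 2L &
      rowSums(pass1 != pass2) == 0L
  } else {
    seg <- !missing & nall >= 2L
  }
  status <- rep.int(1L, length(d1))
  status[seg] <- 2L
  status[missing] <- 0L
  list(status = status, depth1 = d1, depth2 = d2, pass = pass)
}

.check_positions_match <- function(app1, app2) {
  if (nrow(app1) != nrow(app2) || any(app1$position != app2$position)) {
    stop("the two applications must cover identical positions")
  }
  invisible(TRUE)
}
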