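ALLELES <- c("A", "C", "G", "T")

#' Per-site allele count table
#'
#' The package's central data container: one row per genomic site, with
#' the number of reads supporting each of the four nucleotides.  Read
#' depth at a site is the row sum.  For the single-line scheme the same
#' container holds one sampled haploid allele per covered individual, so
#' the "depth" is the number of covered individuals.
#'
#' @param position Strictly increasing 1-based site positions.
#' @param A,C,G,T Non-negative integer read counts per site.
#' @param n Optional pool size (haploid genomes) recorded as an attribute.
#' @param application Optional sequencing-application label.
#' @param region Optional region name.
#' @return A data frame of class `"site_counts"`.
#' @export
site_counts <- function(position, A = 0L, C = 0L, G = 0L, T = 0L,
                        n = NULL, application = NULL, region = NULL) {
  len <- length(position)
  cnt <- cbind(A = rep_len(A, len), C = rep_len(C, len),
               G = rep_len(G, len), T = rep_len(T, len))
  if (any(cnt < 0) || any(cnt != floor(cnt))) {
    stop("allele counts must be non-negative integers")
  }
  if (any(position != floor(position)) || any(position < 1)) {
    stop("positions must be positive integers")
  }
  if (len > 1L && any(diff(position) <= 0)) {
    stop("positions must be strictly increasing")
  }
  out <- data.frame(position = as.integer(position),
                    A = as.integer(cnt[, "A"]), C = as.integer(cnt[, "C"]),
                    G = as.integer(cnt[, "G"]), T = as.integer(cnt[, "T"]))
  structure(out, class = c("site_counts", "data.frame"),
            n = if (!is.null(n)) as.integer(n),
            application = if (!is.null(application)) as.character(application),
            region = if (!is.null(region)) as.character(region))
}

#' Read depth per site
#'
#' @param x A [site_counts] table.
#' @return Integer vector of per-site depths (sum of the four counts).
#' @export
site_depth <- function(x) {
  as.integer(rowSums(.count_matrix(x)))
}

# internal: l x 4 integer matrix of counts
.count_matrix <- function(x) {
  stopifnot(all(ALLELES %in% names(x)))
  as.matrix(x[ALLELES])
}

.as_site_counts <- function(mat, position, ...) {
  site_counts(position, A = mat[, 1L], C = mat[, 2L], G = mat[, 3L],
              T = mat[, 4L], ...)
}

#' @export
print.site_counts <- function(x, ...) {
  n <- attr(x, "n", exact = TRUE); app <- attr(x, "application", exact = TRUE)
  cat(sprintf("site_counts: %d sites%s%s\n", nrow(x),
              if (!is.null(n)) sprintf(", n = %s haploids", n) else "",
              if (!is.null(app)) sprintf(", application %s", app) else ""))
  NextMethod()
}
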