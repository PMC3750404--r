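#' Read a per-site allele count table
#'
#' Parses the package's native TSV dialect: any number of metadata header
#' lines starting with `#` (in `# key=value` form; recognised keys are
#' `region`, `application` and `n`), followed by tab-separated data rows
#' `position  count_A  count_C  count_G  count_T`.  Positions must be
#' strictly increasing and counts non-negative integers; malformed rows
#' are reported with their line numbers.
#'
#' @param path Path to a TSV site-count file.
#' @return A [site_counts] table with any parsed metadata attached as
#'   attributes.
#' @export
read_site_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  meta <- .parse_meta(lines[is_meta])
  data_lines <- lines[!is_meta & nzchar(lines)]
  if (!length(data_lines)) {
    return(site_counts(integer(0), integer(0), integer(0), integer(0), integer(0),
                       n = meta$n, application = meta$application,
                       region = meta$region))
  }
  fields <- strsplit(data_lines, "\t", fixed = TRUE)
  lineno <- which(!is_meta & nzchar(lines))
  bad_len <- lengths(fields) != 5L
  if (any(bad_len)) {
    stop("malformed row (expected 5 tab-separated fields) at line(s): ",
         paste(lineno[bad_len], collapse = ", "))
  }
  m <- suppressWarnings(matrix(as.numeric(unlist(fields)), ncol = 5L, byrow = TRUE))
  bad_num <- rowSums(is.na(m) | m != floor(m) | m < 0) > 0
  if (any(bad_num)) {
    stop("non-integer or negative field at line(s): ",
         paste(lineno[bad_num], collapse = ", "))
  }
  if (nrow(m) > 1L && any(diff(m[, 1L]) <= 0)) {
    stop("positions must be strictly increasing (violated at line(s): ",
         paste(lineno[-1L][diff(m[, 1L]) <= 0], collapse = ", "), ")")
  }
  site_counts(m[, 1L], m[, 2L], m[, 3L], m[, 4L], m[, 5L],
              n = meta$n, application = meta$application, region = meta$region)
}

.parse_meta <- function(lines) {
  out <- list(region = NULL, application = NULL, n = NULL)
  kv <- regmatches(lines, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(.+?)\\s*$", lines))
  for (m in kv) {
    if (length(m) == 3L && m[2L] %in% names(out)) {
      out[[m[2L]]] <- if (m[2L] == "n") as.integer(m[3L]) else m[3L]
    }
  }
  out
}

#' Write a per-site allele count table
#'
#' Inverse of [read_site_counts()].  Output is byte-stable: fixed column
#' order (`position`, A, C, G, T), tab separators, `\n` line endings, and
#' metadata attributes (`region`, `application`, `n`) emitted as
#' `# key=value` header lines in a fixed order.
#'
#' @param x A [site_counts] table.
#' @param path Output file path.
#' @export
write_site_counts <- function(x, path) {
  stopifnot(inherits(x, "site_counts"))
  meta <- character(0)
  for (key in c("region", "application", "n")) {
    val <- attr(x, key, exact = TRUE)
    if (!is.null(val)) meta <- c(meta, sprintf("# %s=%s", key, val))
  }
  body <- sprintf("%d\t%d\t%d\t%d\t%d", x$position, x$A, x$C, x$G, x$T)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(meta, body), con, sep = "\n")
  invisible(path)
}

#' Screen paired count tables for error-dominated low-MAF sites
#'
#' Reproduces the candidate-site screen used to characterise sequencing
#' error overlap between two applications: among sites deeply covered in
#' both tables, those whose minor allele frequency (second-largest count
#' over depth) is positive but below `maf_cutoff` in both are reported.
#' For a hypothesised true variant frequency `true_freq`, the report adds
#' the per-application probabilities ([maf_below_prob()]) that a genuine
#' polymorphism at that frequency would fall below the cutoff, and their
#' product: the chance of a true variant slipping into the screen in both
#' applications.
#'
#' @param app1,app2 [site_counts] tables on identical positions.
#' @param depth_min Sites must exceed this depth in both tables.
#' @param maf_cutoff MAF threshold of the screen.
#' @param true_freq Optional allele frequency at which to evaluate the
#'   binomial escape probability (e.g. `1/(2 * n_individuals)` for a
#'   singleton).
#' @return A data frame with one row per reported site: `position`,
#'   `depth1`, `depth2`, `maf1`, `maf2`, and (when `true_freq` is given)
#'   `p_below1`, `p_below2`, `p_both`.
#' @export
maf_screen <- function(app1, app2, depth_min = 2000, maf_cutoff = 0.01,
                       true_freq = NULL) {
  .check_positions_match(app1, app2)
  c1 <- .count_matrix(app1)
  c2 <- .count_matrix(app2)
  d1 <- rowSums(c1)
  d2 <- rowSums(c2)
  second <- function(cnt) apply(cnt, 1L, function(v) sort(v, decreasing = TRUE)[2L])
  m1 <- second(c1)
  m2 <- second(c2)
  maf1 <- ifelse(d1 > 0, m1 / d1, NA_real_)
  maf2 <- ifelse(d2 > 0, m2 / d2, NA_real_)
  keep <- d1 > depth_min & d2 > depth_min &
    m1 >= 1L & m2 >= 1L & maf1 < maf_cutoff & maf2 < maf_cutoff
  out <- data.frame(position = app1$position[keep],
                    depth1 = d1[keep], depth2 = d2[keep],
                    maf1 = maf1[keep], maf2 = maf2[keep])
  if (!is.null(true_freq)) {
    out$p_below1 <- maf_below_prob(out$depth1, true_freq, maf_cutoff)
    out$p_below2 <- maf_below_prob(out$depth2, true_freq, maf_cutoff)
    out$p_both <- out$p_below1 * out$p_below2
  }
  out
}
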