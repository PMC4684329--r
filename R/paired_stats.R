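# Paired tumor vs non-tumor testing shared by the methylation and
# expression arms: per-feature paired t-tests, BH-FDR adjustment,
# direction calls and magnitude classes.

#' Construct a paired tumor / non-tumor design
#'
#' @param sample_sheet data.frame with columns `sample_id`, `subject_id`
#'   and `tissue` (`"T"` or `"NT"`).
#' @return data.frame of class `paired_design` with one row per subject and
#'   columns `subject_id`, `sample_T`, `sample_NT`.
#' @export
paired_design <- function(sample_sheet) {
  stopifnot(all(c("sample_id", "subject_id", "tissue") %in% names(sample_sheet)))
  bad_tissue <- setdiff(unique(sample_sheet$tissue), c("T", "NT"))
  if (length(bad_tissue)) {
    stop_helpdm("tissue labels must be 'T' or 'NT'; found: ",
                paste(bad_tissue, collapse = ", "))
  }
  split_by <- split(sample_sheet, sample_sheet$subject_id)
  offenders <- names(split_by)[vapply(split_by, function(d) {
    sum(d$tissue == "T") != 1L || sum(d$tissue == "NT") != 1L
  }, logical(1))]
  if (length(offenders)) {
    stop_helpdm("subjects without exactly one T and one NT sample: ",
                paste(offenders, collapse = ", "))
  }
  out <- data.frame(
    subject_id = names(split_by),
    sample_T = vapply(split_by, function(d) d$sample_id[d$tissue == "T"], ""),
    sample_NT = vapply(split_by, function(d) d$sample_id[d$tissue == "NT"], ""),
    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("paired_design", "data.frame")
  out
}

#' Paired t-test for one subject-aligned feature
#'
#' Tests the mean of the per-subject differences `d = T - NT`:
#' `t = mean(d) / (sd(d) / sqrt(n))`, with a two-sided p-value from the t
#' distribution on `n - 1` degrees of freedom. Missing values are dropped
#' pairwise; a feature with fewer than 2 complete pairs yields `NA`
#' statistics with a warning. Degenerate cases: all differences zero gives
#' `t = 0, p = 1`; constant non-zero differences give `p = 0` (flagged with
#' the `degenerate` field).
#'
#' @param values_t,values_nt numeric vectors aligned by subject.
#' @return list with `mean_diff`, `t_stat`, `p`, `n`, `degenerate`.
#' @export
paired_t_test <- function(values_t, values_nt) {
  if (length(values_t) != length(values_nt)) {
    stop_helpdm("'values_t' and 'values_nt' must be subject-aligned vectors")
  }
  d <- values_t - values_nt
  d <- d[!is.na(d)]
  n <- length(d)
  if (n < 2L) {
    warning("fewer than 2 complete pairs; feature skipped", call. = FALSE)
    return(list(mean_diff = NA_real_, t_stat = NA_real_, p = NA_real_,
                n = n, degenerate = FALSE))
  }
  m <- mean(d)
  s <- sd(d)
  if (s == 0) {
    if (m == 0) {
      return(list(mean_diff = 0, t_stat = 0, p = 1, n = n, degenerate = FALSE))
    }
    return(list(mean_diff = m, t_stat = sign(m) * Inf, p = 0, n = n,
                degenerate = TRUE))
  }
  t_stat <- m / (s / sqrt(n))
  list(mean_diff = m, t_stat = t_stat, p = 2 * pt(-abs(t_stat), df = n - 1),
       n = n, degenerate = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values ("q-values"): sort p ascending, take
#' `q_(i) = min_{j >= i} p_(j) * m / j` capped at 1, and map back to the
#' input order. `NA` p-values propagate as `NA`.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of adjusted values, same length and order.
#' @export
bh_fdr <- function(p_values) {
  ok <- !is.na(p_values)
  assert_prob(p_values[ok], "p_values")
  p.adjust(p_values, method = "BH")
}

#' Direction call for a tested feature
#'
#' Negative delta at `q < alpha` is called hypermethylated-in-tumor (the
#' assay reports tumor-minus-non-tumor score differences on a scale where
#' methylation gain drives the score down); positive delta is
#' hypomethylated. Non-significant features, and a delta of exactly 0, are
#' `"none"`.
#'
#' @param delta numeric vector of paired mean differences.
#' @param q adjusted p-values.
#' @param alpha significance level (default 0.05).
#' @param labels length-2 character: labels for negative and positive
#'   significant effects. The methylation arm uses the default
#'   `c("hyper", "hypo")`; the expression arm passes `c("down", "up")` so a
#'   negative log2 fold change is called down-regulated.
#' @return character vector in `{labels, "none"}`.
#' @export
classify_direction <- function(delta, q, alpha = 0.05,
                               labels = c("hyper", "hypo")) {
  out <- rep("none", length(delta))
  sig <- !is.na(q) & q < alpha & !is.na(delta)
  out[sig & delta < 0] <- labels[1]
  out[sig & delta > 0] <- labels[2]
  out
}

#' Magnitude class of a methylation difference
#'
#' `|delta| < 0.5` is negligible, `0.5 <= |delta| < 1` small and
#' `|delta| >= 1` moderate/large (band boundaries assigned upward; values
#' above 2 stay in the top class).
#'
#' @param delta numeric vector.
#' @return character vector in `{negligible, small, moderate_large}`.
#' @export
classify_magnitude <- function(delta) {
  a <- abs(delta)
  ifelse(a < 0.5, "negligible", ifelse(a < 1, "small", "moderate_large"))
}

# Vectorized paired t statistics over the rows of T/NT matrices.
row_paired_t <- function(mat_t, mat_nt) {
  d <- mat_t - mat_nt
  n <- rowSums(!is.na(d))
  m <- rowMeans(d, na.rm = TRUE)
  ss <- rowSums((d - m)^2, na.rm = TRUE)
  s <- sqrt(ss / pmax(n - 1, 1))
  t_stat <- m / (s / sqrt(n))
  p <- 2 * pt(-abs(t_stat), df = n - 1)
  # degenerate rows
  zero_sd <- !is.na(s) & s == 0 & n >= 2
  t_stat[zero_sd & m == 0] <- 0
  p[zero_sd & m == 0] <- 1
  t_stat[zero_sd & m != 0] <- sign(m[zero_sd & m != 0]) * Inf
  p[zero_sd & m != 0] <- 0
  few <- n < 2
  if (any(few)) {
    warning(sprintf("%d feature(s) with fewer than 2 complete pairs skipped",
                    sum(few)), call. = FALSE)
    m[few] <- NA_real_; t_stat[few] <- NA_real_; p[few] <- NA_real_
  }
  list(mean_diff = m, t_stat = t_stat, p = p, n = n)
}

order_results <- function(q, effect, id) {
  order(q, -abs(effect), id, na.last = TRUE)
}

#' Per-locus paired differential-methylation testing
#'
#' Runs the paired t-test on every row of the methylation score matrix,
#' adjusts p-values by BH-FDR, and classifies direction and magnitude.
#' Rows are returned ranked by q ascending, then |delta| descending, then
#' locus id (a deterministic ordering).
#'
#' @param mat numeric matrix, loci x samples, rownames = locus ids.
#' @param design a [paired_design()].
#' @param annotation optional annotated locus table (from
#'   [annotate_loci()]); if given, `compartment`, `linked_gene` and
#'   `subcompartment` are carried into the result.
#' @param alpha significance level for the direction call.
#' @return data.frame with columns `locus_id`, `delta`, `t_stat`, `p`, `q`,
#'   `direction`, `magnitude` (+ annotation columns).
#' @export
run_dm <- function(mat, design, annotation = NULL, alpha = 0.05) {
  check_design_columns(mat, design)
  st <- row_paired_t(mat[, design$sample_T, drop = FALSE],
                     mat[, design$sample_NT, drop = FALSE])
  out <- data.frame(
    locus_id = rownames(mat),
    delta = st$mean_diff,
    t_stat = st$t_stat,
    p = st$p,
    q = bh_fdr(st$p),
    n_pairs = st$n,
    stringsAsFactors = FALSE)
  out$direction <- classify_direction(out$delta, out$q, alpha)
  out$magnitude <- classify_magnitude(out$delta)
  if (!is.null(annotation)) {
    idx <- match(out$locus_id, annotation$locus_id)
    for (col in intersect(c("chrom", "start", "end", "compartment",
                            "linked_gene", "subcompartment"),
                          names(annotation))) {
      out[[col]] <- annotation[[col]][idx]
    }
  }
  out <- out[order_results(out$q, out$delta, out$locus_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  out
}

#' Per-gene paired differential-expression testing
#'
#' Same engine as [run_dm()] on a genes x samples log2 expression matrix;
#' the paired mean difference is reported as `log2fc` and significant genes
#' are called `"down"` / `"up"` by its sign.
#'
#' @inheritParams run_dm
#' @param mat numeric matrix, genes x samples, rownames = gene ids.
#' @return data.frame with columns `gene_id`, `log2fc`, `t_stat`, `p`, `q`,
#'   `direction`.
#' @export
run_de <- function(mat, design, alpha = 0.05) {
  check_design_columns(mat, design)
  st <- row_paired_t(mat[, design$sample_T, drop = FALSE],
                     mat[, design$sample_NT, drop = FALSE])
  out <- data.frame(
    gene_id = rownames(mat),
    log2fc = st$mean_diff,
    t_stat = st$t_stat,
    p = st$p,
    q = bh_fdr(st$p),
    n_pairs = st$n,
    stringsAsFactors = FALSE)
  out$direction <- classify_direction(out$log2fc, out$q, alpha,
                                      labels = c("down", "up"))
  out <- out[order_results(out$q, out$log2fc, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  out
}

check_design_columns <- function(mat, design) {
  if (!inherits(design, "paired_design")) {
    stop_helpdm("'design' must be a paired_design object")
  }
  missing <- setdiff(c(design$sample_T, design$sample_NT), colnames(mat))
  if (length(missing)) {
    stop_helpdm("matrix is missing design samples: ",
                paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}
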