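# Tumor vs non-tumor discrimination from top-ranked DM loci under repeated
# subject-level train/test splits, plus the loco-regional consistency
# ranking used to nominate validation candidates.

#' Split a paired design into train and test subsets by subject
#'
#' Subjects (never individual samples) are partitioned, so a subject's T
#' and NT samples always travel together and no pair straddles the split.
#' The train size is the subject count times `train_fraction`, rounded to
#' the nearest subject.
#'
#' @param design a [paired_design()] with at least 3 subjects.
#' @param train_fraction fraction of subjects assigned to training
#'   (default 2/3).
#' @param seed RNG seed for the subject draw (NULL = current stream).
#' @return list with `train` and `test` paired designs.
#' @export
split_by_subject <- function(design, train_fraction = 2 / 3, seed = NULL) {
  n <- nrow(design)
  if (n < 3) stop_helpdm("need at least 3 subjects to split")
  n_train <- round(train_fraction * n)
  if (n_train < 1 || n_train >= n) {
    stop_helpdm("'train_fraction' leaves an empty train or test set")
  }
  idx <- local_rng(seed, sample.int(n, n_train))
  train <- design[sort(idx), , drop = FALSE]
  test <- design[sort(setdiff(seq_len(n), idx)), , drop = FALSE]
  class(train) <- class(test) <- c("paired_design", "data.frame")
  list(train = train, test = test)
}

#' Select the top-k loci from a DM table
#'
#' Ranks by q ascending, ties broken by |delta| descending then locus id,
#' and returns the first `k` ids (all loci with a warning if `k` exceeds
#' the table).
#'
#' @param dm_table [run_dm()] result computed on training subjects only.
#' @param k panel size (the discrimination analyses use 25 and 100).
#' @return character vector of locus ids, length `min(k, nrow)`.
#' @export
select_top_k <- function(dm_table, k) {
  if (k > nrow(dm_table)) {
    warning(sprintf("k = %d exceeds the %d available loci; returning all",
                    k, nrow(dm_table)), call. = FALSE)
    k <- nrow(dm_table)
  }
  ord <- order_results(dm_table$q, dm_table$delta, dm_table$locus_id)
  dm_table$locus_id[ord][seq_len(k)]
}

#' Nearest-centroid classification of test samples
#'
#' Computes T and NT class centroids over the selected loci from the
#' training samples and assigns each test sample to the nearest centroid
#' (Euclidean distance). Sensitivity is tumor recall, specificity
#' non-tumor recall.
#'
#' @param train_mat,test_mat score matrices (loci x samples).
#' @param train_design,test_design paired designs describing the columns.
#' @param selected character vector of locus ids (non-empty, present in
#'   both matrices).
#' @return list with `accuracy`, `sensitivity`, `specificity`,
#'   `n_test_t`, `n_test_nt`, `predictions`.
#' @export
fit_and_evaluate <- function(train_mat, test_mat, train_design, test_design,
                             selected) {
  if (length(selected) == 0L) stop_helpdm("empty locus selection")
  missing <- setdiff(selected, intersect(rownames(train_mat),
                                         rownames(test_mat)))
  if (length(missing)) {
    stop_helpdm("selected loci absent from matrices: ",
                paste(head(missing, 5), collapse = ", "))
  }
  centroid_t <- rowMeans(train_mat[selected, train_design$sample_T,
                                   drop = FALSE])
  centroid_nt <- rowMeans(train_mat[selected, train_design$sample_NT,
                                    drop = FALSE])
  test_cols <- c(test_design$sample_T, test_design$sample_NT)
  labels <- rep(c("T", "NT"), c(nrow(test_design), nrow(test_design)))
  x <- test_mat[selected, test_cols, drop = FALSE]
  d_t <- colSums((x - centroid_t)^2)
  d_nt <- colSums((x - centroid_nt)^2)
  pred <- ifelse(d_t < d_nt, "T", "NT")
  # equidistant samples default to NT (deterministic tie-break)
  sens <- mean(pred[labels == "T"] == "T")
  spec <- mean(pred[labels == "NT"] == "NT")
  list(accuracy = mean(pred == labels), sensitivity = sens,
       specificity = spec, n_test_t = sum(labels == "T"),
       n_test_nt = sum(labels == "NT"),
       predictions = setNames(pred, test_cols))
}

#' Repeated train/test evaluation of top-k DM locus panels
#'
#' Runs `n_iterations` independent 2/3-1/3 subject splits; in each, ranks
#' loci by the paired test on the training subjects only, selects the top
#' `k`, and evaluates a nearest-centroid classifier on the held-out
#' subjects. Test data never influence selection or centroids.
#'
#' @param mat score matrix (loci x samples).
#' @param design full [paired_design()].
#' @param k panel size.
#' @param n_iterations number of random splits (default 10).
#' @param seed RNG seed governing all splits.
#' @param train_fraction passed to [split_by_subject()].
#' @param alpha significance level used in per-split DM ranking.
#' @return list of class `classifier_report`: `per_iteration` data.frame
#'   (accuracy, sensitivity, specificity per split),
#'   `mean_accuracy` (average of per-split accuracies),
#'   `pooled_accuracy` (over all test samples of all splits),
#'   `mean_sensitivity`, `mean_specificity`, `selection_frequency`,
#'   `stable_loci` (selected in every iteration), `k`, `n_iterations`,
#'   `seed`.
#' @export
iterate_classification <- function(mat, design, k = 25, n_iterations = 10,
                                   seed = 1L, train_fraction = 2 / 3,
                                   alpha = 0.05) {
  res <- local_rng(seed, {
    lapply(seq_len(n_iterations), function(i) {
      sp <- split_by_subject(design, train_fraction, seed = NULL)
      dm_train <- run_dm(mat, sp$train, alpha = alpha)
      sel <- select_top_k(dm_train, k)
      ev <- fit_and_evaluate(mat, mat, sp$train, sp$test, sel)
      list(selected = sel, ev = ev)
    })
  })
  per_iter <- data.frame(
    iteration = seq_len(n_iterations),
    accuracy = vapply(res, function(r) r$ev$accuracy, 0),
    sensitivity = vapply(res, function(r) r$ev$sensitivity, 0),
    specificity = vapply(res, function(r) r$ev$specificity, 0),
    n_correct = vapply(res, function(r) {
      r$ev$accuracy * (r$ev$n_test_t + r$ev$n_test_nt)
    }, 0),
    n_test = vapply(res, function(r) r$ev$n_test_t + r$ev$n_test_nt, 0))
  all_sel <- unlist(lapply(res, `[[`, "selected"))
  freq <- sort(table(all_sel), decreasing = TRUE)
  structure(list(
    per_iteration = per_iter,
    mean_accuracy = mean(per_iter$accuracy),
    pooled_accuracy = sum(per_iter$n_correct) / sum(per_iter$n_test),
    mean_sensitivity = mean(per_iter$sensitivity),
    mean_specificity = mean(per_iter$specificity),
    selection_frequency = freq,
    stable_loci = names(freq)[freq == n_iterations],
    k = k, n_iterations = n_iterations, seed = seed),
    class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf(
    "Top-%d locus classifier over %d splits: accuracy %.3f (pooled %.3f), sensitivity %.3f, specificity %.3f\n",
    x$k, x$n_iterations, x$mean_accuracy, x$pooled_accuracy,
    x$mean_sensitivity, x$mean_specificity))
  if (length(x$stable_loci)) {
    cat("loci selected in every split:",
        paste(head(x$stable_loci, 10), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Loco-regional consistency ranking of significant DM loci
#'
#' Scores each significant locus by the number of other significant loci
#' on the same chromosome, in the same compartment and with the same
#' direction of change, whose edge-to-edge distance is strictly less than
#' `window` bp. Loci are returned ranked by score descending, then q
#' ascending, then locus id.
#'
#' @param dm_table significant DM records carrying `locus_id`, `q` and
#'   `direction`.
#' @param loci coordinate/compartment table (`locus_id`, `chrom`, `start`,
#'   `end`, `compartment`).
#' @param window neighborhood size in bp (default 2000).
#' @return data.frame with `locus_id`, `chrom`, `compartment`,
#'   `direction`, `score`, `q`.
#' @export
consistency_rank <- function(dm_table, loci, window = 2000) {
  idx <- match(dm_table$locus_id, loci$locus_id)
  out <- data.frame(locus_id = dm_table$locus_id,
                    chrom = loci$chrom[idx],
                    compartment = loci$compartment[idx],
                    direction = dm_table$direction,
                    start = loci$start[idx], end = loci$end[idx],
                    q = dm_table$q, score = 0L, stringsAsFactors = FALSE)
  if (window > 0 && nrow(out) > 1) {
    groups <- split(seq_len(nrow(out)),
                    paste(out$chrom, out$compartment, out$direction,
                          sep = "\r"))
    for (g in groups) {
      if (length(g) < 2) next
      gr <- IRanges::IRanges(start = out$start[g] + 1L, end = out$end[g])
      # maxgap = window - 1 <=> edge-to-edge distance < window
      n_nb <- IRanges::countOverlaps(gr, gr, maxgap = window - 1L) - 1L
      out$score[g] <- n_nb
    }
  }
  out <- out[order(-out$score, out$q, out$locus_id), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("locus_id", "chrom", "compartment", "direction", "score", "q")]
}
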