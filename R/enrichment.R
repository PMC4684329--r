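# Compartment over-representation of DM loci (random-sampling permutation
# test, with an exact hypergeometric mode) and categorical chi-square tests.

#' Permutation test for compartment over-representation
#'
#' Draws `B` random locus sets of the same size as the DM set, uniformly
#' without replacement from the annotated universe, and compares the count
#' of loci in the target compartment against the observed count. The
#' one-sided (over-representation) empirical p-value uses the add-one rule
#' `p = (1 + #\{null >= observed\}) / (B + 1)`, so its resolution is
#' `1/(B+1)` and it is never exactly 0. Because tiny p-values lie below
#' that resolution, a Gaussian approximation from the null draws' mean and
#' standard deviation is reported alongside (labelled as an approximation).
#' `mode = "exact"` skips sampling and evaluates the hypergeometric tail
#' probability, which is the exact null distribution of the count.
#'
#' @param dm_locus_ids character vector of significant locus ids (must be a
#'   subset of the universe).
#' @param universe data.frame with `locus_id` and `compartment` for every
#'   locus on the array.
#' @param target compartment tested for over-representation (default "GB").
#' @param B number of Monte-Carlo iterations (default 1000).
#' @param seed RNG seed for the Monte-Carlo draws.
#' @param mode `"monte-carlo"` or `"exact"`.
#' @return object of class `enrichment_result`: a list with
#'   `observed_counts`, `observed`, `null_mean`, `null_sd`, `empirical_p`,
#'   `gaussian_p`, `B`, `seed`, `mode`, `target` and (Monte-Carlo mode)
#'   `null_draws`.
#' @export
permutation_compartment_test <- function(dm_locus_ids, universe,
                                         target = "GB", B = 1000,
                                         seed = NULL,
                                         mode = c("monte-carlo", "exact")) {
  mode <- match.arg(mode)
  stopifnot(all(c("locus_id", "compartment") %in% names(universe)))
  if (B < 1) stop_helpdm("'B' must be >= 1")
  if (!all(dm_locus_ids %in% universe$locus_id)) {
    stop_helpdm("DM set contains loci outside the universe")
  }
  m <- length(dm_locus_ids)
  N <- nrow(universe)
  if (m > N) stop_helpdm("DM set larger than the universe")
  is_target <- universe$compartment == target
  K <- sum(is_target)
  dm_comp <- universe$compartment[match(dm_locus_ids, universe$locus_id)]
  observed_counts <- table(factor(dm_comp, levels = sort(unique(universe$compartment))))
  observed <- sum(dm_comp == target)

  if (mode == "exact") {
    empirical_p <- phyper(observed - 1, K, N - K, m, lower.tail = FALSE)
    null_mean <- m * K / N
    null_sd <- sqrt(m * (K / N) * (1 - K / N) * (N - m) / max(N - 1, 1))
    null_draws <- NULL
  } else {
    null_draws <- local_rng(seed, {
      vapply(seq_len(B), function(b) sum(is_target[sample.int(N, m)]),
             integer(1))
    })
    empirical_p <- (1 + sum(null_draws >= observed)) / (B + 1)
    null_mean <- mean(null_draws)
    null_sd <- sd(null_draws)
  }
  gaussian_p <- if (!is.na(null_sd) && null_sd > 0) {
    pnorm(observed, mean = null_mean, sd = null_sd, lower.tail = FALSE)
  } else {
    as.numeric(observed <= null_mean)
  }
  structure(list(observed_counts = observed_counts, observed = observed,
                 null_mean = null_mean, null_sd = null_sd,
                 empirical_p = empirical_p, gaussian_p = gaussian_p,
                 B = if (mode == "monte-carlo") B else NA_integer_,
                 seed = seed, mode = mode, target = target,
                 null_draws = null_draws),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Compartment over-representation test (target %s, %s mode)\n",
              x$target, x$mode))
  cat(sprintf("  observed %d vs null %.1f +/- %.2f\n",
              x$observed, x$null_mean, x$null_sd))
  cat(sprintf("  empirical p = %.4g", x$empirical_p))
  if (x$mode == "monte-carlo") {
    cat(sprintf(" (resolution 1/%d); gaussian approx p = %.3g",
                x$B + 1, x$gaussian_p))
  }
  cat("\n")
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' Pearson statistic without continuity correction on an r x c count
#' table, `df = (r-1)(c-1)`, upper-tail p-value. Tables with any expected
#' count below 5 trigger a warning (not a refusal); a zero row or column
#' marginal is an error.
#'
#' @param counts matrix (or table) of non-negative counts.
#' @return list with `chi2`, `df`, `p`, `expected`.
#' @export
chi_square_independence <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop_helpdm("'counts' must be non-negative finite numbers")
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop_helpdm("chi-square test undefined: zero row or column marginal")
  }
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected < 5)) {
    warning("expected counts below 5; chi-square approximation may be poor",
            call. = FALSE)
  }
  res <- suppressWarnings(chisq.test(counts, correct = FALSE))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = unname(res$p.value), expected = expected)
}

#' Genomic distribution summary of DM loci
#'
#' Per-compartment accounting of a DM run against the annotated universe:
#' loci on the array, DM count, percent of represented loci that are DM,
#' and the hypo/hyper percentage split among DM loci (integer-rounded
#' percentages of the DM count; any direction-`none` remainder among
#' nominally significant loci accounts for the gap to 100).
#'
#' @param dm_table result of [run_dm()].
#' @param universe annotated locus table ([annotate_loci()]).
#' @param alpha significance threshold on `q`.
#' @return data.frame with one row per compartment: `compartment`,
#'   `n_array`, `n_dm`, `pct_of_array`, `pct_hypo`, `pct_hyper`.
#' @export
compartment_summary <- function(dm_table, universe, alpha = 0.05) {
  comp_levels <- COMPARTMENTS
  n_array <- table(factor(universe$compartment, levels = comp_levels))
  idx <- match(dm_table$locus_id, universe$locus_id)
  comp <- universe$compartment[idx]
  sig <- !is.na(dm_table$q) & dm_table$q < alpha
  n_dm <- table(factor(comp[sig], levels = comp_levels))
  n_hypo <- table(factor(comp[sig & dm_table$direction == "hypo"],
                         levels = comp_levels))
  n_hyper <- table(factor(comp[sig & dm_table$direction == "hyper"],
                          levels = comp_levels))
  pct <- function(num, den) ifelse(den > 0, round(100 * num / den), NA_real_)
  data.frame(
    compartment = comp_levels,
    n_array = as.integer(n_array),
    n_dm = as.integer(n_dm),
    pct_of_array = pct(as.integer(n_dm), as.integer(n_array)),
    pct_hypo = pct(as.integer(n_hypo), as.integer(n_dm)),
    pct_hyper = pct(as.integer(n_hyper), as.integer(n_dm)),
    stringsAsFactors = FALSE)
}
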