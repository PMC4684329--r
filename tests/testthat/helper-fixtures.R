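# Fixture builders and independent brute-force oracles used across tests.

# A bare locus table (no coordinates needed) for methylome-only simulations:
# n loci per compartment, each genic locus its own gene so per-locus draws
# are independent and binomial bounds are exact.
bare_loci <- function(n_pr = 0, n_gb = 0, n_ig = 0) {
  comp <- rep(c("PR", "GB", "IG"), c(n_pr, n_gb, n_ig))
  n <- length(comp)
  data.frame(
    locus_id = sprintf("L%06d", seq_len(n)),
    chrom = "chr1",
    start = seq_len(n) * 3000L,
    end = seq_len(n) * 3000L + 500L,
    compartment = comp,
    linked_gene = ifelse(comp == "IG", NA_character_,
                         sprintf("G%06d", seq_len(n))),
    subcompartment = NA_character_,
    stringsAsFactors = FALSE)
}

# Small paired matrix with per-feature planted effects, built by hand
# (independent of the generator module).
toy_paired_matrix <- function(delta, n_subjects, sd = 0, seed = 1) {
  withr::with_seed(seed, {
    n <- length(delta)
    subjects <- sprintf("S%02d", seq_len(n_subjects))
    nt <- matrix(rnorm(n * n_subjects, 0, max(sd, 1e-12)), n, n_subjects)
    t_ <- nt + delta + matrix(rnorm(n * n_subjects, 0, max(sd, 1e-12)),
                              n, n_subjects)
    m <- cbind(t_, nt)
    dimnames(m) <- list(sprintf("L%06d", seq_len(n)),
                        c(paste0(subjects, "_T"), paste0(subjects, "_NT")))
    m
  })
}

toy_design <- function(n_subjects) {
  subjects <- sprintf("S%02d", seq_len(n_subjects))
  paired_design(data.frame(
    sample_id = c(paste0(subjects, "_T"), paste0(subjects, "_NT")),
    subject_id = rep(subjects, 2),
    tissue = rep(c("T", "NT"), each = n_subjects)))
}

# Brute-force BH step-up by the definition: q_(i) = min_{j>=i} p_(j)*m/j.
bf_step_up <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(pmin(ps[i:m] * m / (i:m), 1))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Brute-force digest: scan every offset for CCGG, build consecutive-cut
# fragments, filter by size.
bf_digest <- function(sequence, size_range) {
  s <- toupper(sequence)
  n <- nchar(s)
  cuts <- integer(0)
  for (i in seq_len(max(n - 3, 0))) {
    if (substr(s, i, i + 3) == "CCGG") cuts <- c(cuts, i)  # cut = offset + 1
  }
  if (length(cuts) < 2) {
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0)))
  }
  start <- cuts[-length(cuts)]
  end <- cuts[-1]
  len <- end - start
  keep <- len >= size_range[1] & len <= size_range[2]
  data.frame(start = start[keep], end = end[keep], length = len[keep])
}

random_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

# Brute-force all-pairs DM x DE linking (dedup = "pair" semantics).
bf_link <- function(dm_sig, de_sig, loci, genes, promoter_width = 2000,
                    gb_start_offset = 0) {
  out <- NULL
  for (li in seq_len(nrow(dm_sig))) {
    lrow <- loci[loci$locus_id == dm_sig$locus_id[li], ]
    for (gi in seq_len(nrow(de_sig))) {
      grow <- genes[genes$gene_id == de_sig$gene_id[gi], ]
      if (grow$chrom != lrow$chrom) next
      pw <- promoter_window(grow, promoter_width)
      gb <- gene_body_region(grow, gb_start_offset)
      rel <- if (overlaps(lrow$start, lrow$end, pw$start, pw$end)) {
        "PR"
      } else if (overlaps(lrow$start, lrow$end, gb$start, gb$end)) {
        "GB"
      } else {
        NA_character_
      }
      if (!is.na(rel)) {
        out <- rbind(out, data.frame(
          locus_id = lrow$locus_id, gene_id = grow$gene_id,
          compartment = rel, stringsAsFactors = FALSE))
      }
    }
  }
  out
}

# Brute-force consistency scores: all-pairs edge-to-edge distance < window.
bf_consistency <- function(df, window) {
  score <- integer(nrow(df))
  for (i in seq_len(nrow(df))) {
    for (j in seq_len(nrow(df))) {
      if (i == j) next
      same <- df$chrom[i] == df$chrom[j] &&
        df$compartment[i] == df$compartment[j] &&
        df$direction[i] == df$direction[j]
      if (!same) next
      gap <- max(df$start[j] - df$end[i], df$start[i] - df$end[j], 0)
      if (gap < window) score[i] <- score[i] + 1L
    }
  }
  score
}
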