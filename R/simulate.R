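# Synthetic paired tumor / non-tumor methylome + transcriptome generator
# with planted, fully recorded ground truth.
#
# Generative model (per locus i, subject s, score units = normalized
# log-ratio scale):
#   NT score = mu_i + b_s + eps,   T score = mu_i + delta_i + b_s + eps
# with subject effect b_s ~ N(0, subject_sd^2) and residual
# eps ~ N(0, residual_sd^2). delta_i = 0 unless the locus is planted DM;
# planted |delta| is drawn from the configured magnitude-band mixture
# (bands [0,0.5), [0.5,1), [1,2]) and its sign is negative
# (hypermethylated-in-tumor) with a compartment-specific probability.
#
# DM planting is hierarchical: each gene deregulates in at most one
# compartment (promoter or body, chosen with probability proportional to
# the compartment DM rates), and only loci of that compartment can be
# planted DM, at a rate calibrated so the per-locus marginal DM rate
# equals dm_rate_by_compartment exactly (for PR + GB rates summing to at
# most 1). The *sign* is likewise drawn once per linked gene, per locus
# only for intergenic loci. Both choices emulate the loco-regional
# concordance of methylation change within a gene and make gene-level
# coupling to expression unambiguous: all planted records of a gene share
# one compartment and one direction, so the canonical/non-canonical label
# of a coupled gene is a single coherent draw.

#' Simulation configuration
#'
#' Bundles and validates every tunable of the synthetic-data generator.
#' Defaults emulate the study conditions the package's recovery suites
#' assume: 16 tumor / non-tumor pairs, CCGG fragments of 200-2000 bp, and
#' compartment-specific planted DM rates and hyper/hypo splits.
#'
#' @param n_subjects number of subjects (each contributes one T and one NT
#'   sample).
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param n_genes total gene count across chromosomes.
#' @param gene_length_range bp interval for gene lengths.
#' @param cgi_promoter_fraction fraction of genes whose promoter overlaps a
#'   generated CpG island.
#' @param locus_density expected fragments per 10 kb (direct placement).
#' @param fragment_size_range retained fragment lengths, bp.
#' @param dm_rate_by_compartment named probabilities `c(PR=, GB=, IG=)` of a
#'   locus being planted DM.
#' @param hyper_given_dm_by_compartment named probabilities that a planted
#'   DM effect is hypermethylation (negative delta).
#' @param delta_magnitude_distribution named probabilities
#'   `c(negligible=, small=, moderate=)` over the |delta| bands
#'   [0,0.5), [0.5,1), [1,2].
#' @param subject_sd,residual_sd noise standard deviations, score units.
#' @param de_rate background differential-expression rate for genes not
#'   coupled to a planted DM locus.
#' @param log2fc_magnitude |log2 fold change| planted for DE genes.
#' @param canonical_coupling probability that a gene coupled to a planted
#'   DM locus receives DE in the canonical direction (anti-canonical
#'   otherwise).
#' @param seed integer seed; all generator stages derive their streams
#'   from it.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 16,
                       chrom_lengths = c(chr1 = 3e6, chr2 = 2e6, chr3 = 1e6),
                       n_genes = 300,
                       gene_length_range = c(2000, 20000),
                       cgi_promoter_fraction = 0.6,
                       locus_density = 5,
                       fragment_size_range = c(200, 2000),
                       dm_rate_by_compartment = c(PR = 0.26, GB = 0.38, IG = 0.48),
                       hyper_given_dm_by_compartment = c(PR = 0.31, GB = 0.25, IG = 0.06),
                       delta_magnitude_distribution = c(negligible = 0.2, small = 0.5, moderate = 0.3),
                       subject_sd = 0.2,
                       residual_sd = 0.3,
                       de_rate = 0.35,
                       log2fc_magnitude = 1.5,
                       canonical_coupling = 0.087,
                       seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              chrom_lengths = chrom_lengths, n_genes = as.integer(n_genes),
              gene_length_range = gene_length_range,
              cgi_promoter_fraction = cgi_promoter_fraction,
              locus_density = locus_density,
              fragment_size_range = fragment_size_range,
              dm_rate_by_compartment = dm_rate_by_compartment,
              hyper_given_dm_by_compartment = hyper_given_dm_by_compartment,
              delta_magnitude_distribution = delta_magnitude_distribution,
              subject_sd = subject_sd, residual_sd = residual_sd,
              de_rate = de_rate, log2fc_magnitude = log2fc_magnitude,
              canonical_coupling = canonical_coupling,
              seed = as.integer(seed))
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_subjects < 0) stop_helpdm("'n_subjects' must be >= 0")
  if (length(cfg$chrom_lengths) == 0 || is.null(names(cfg$chrom_lengths))) {
    stop_helpdm("'chrom_lengths' must be a non-empty named vector")
  }
  check_size_range(cfg$fragment_size_range)
  if (cfg$gene_length_range[1] < 1 ||
      cfg$gene_length_range[1] > cfg$gene_length_range[2]) {
    stop_helpdm("'gene_length_range' must be c(min, max) with 1 <= min <= max")
  }
  assert_named_map(cfg$dm_rate_by_compartment, COMPARTMENTS,
                   "dm_rate_by_compartment")
  assert_named_map(cfg$hyper_given_dm_by_compartment, COMPARTMENTS,
                   "hyper_given_dm_by_compartment")
  assert_named_map(cfg$delta_magnitude_distribution, MAGNITUDE_BANDS,
                   "delta_magnitude_distribution")
  assert_prob(cfg$dm_rate_by_compartment, "dm_rate_by_compartment")
  assert_prob(cfg$hyper_given_dm_by_compartment,
              "hyper_given_dm_by_compartment")
  assert_prob(cfg$cgi_promoter_fraction, "cgi_promoter_fraction")
  assert_prob(cfg$de_rate, "de_rate")
  assert_prob(cfg$canonical_coupling, "canonical_coupling")
  if (any(cfg$delta_magnitude_distribution < 0) ||
      sum(cfg$delta_magnitude_distribution) <= 0) {
    stop_helpdm("'delta_magnitude_distribution' needs non-negative weights with positive sum")
  }
  assert_pos(cfg$subject_sd, "subject_sd")
  assert_pos(cfg$residual_sd, "residual_sd")
  assert_pos(cfg$log2fc_magnitude, "log2fc_magnitude")
  if (cfg$locus_density < 0) stop_helpdm("'locus_density' must be >= 0")
  structure(cfg, class = "sim_config")
}

# fixed per-stage seed derivation so stages are individually reproducible
stage_seed <- function(cfg, stage) {
  offsets <- c(annotation = 101L, loci = 202L, methylome = 303L,
               expression = 404L)
  (cfg$seed + offsets[[stage]]) %% .Machine$integer.max
}

#' Generate a synthetic gene and CpG-island annotation
#'
#' Genes are placed without overlap on each chromosome (allocated
#' proportionally to chromosome length), with random strands, lengths
#' uniform in `gene_length_range`, and a margin keeping promoter windows
#' inside the chromosome. For `cgi_promoter_fraction` of genes an 800 bp
#' CpG island centered on the TSS is created, guaranteeing overlap with the
#' promoter window. Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with `genes` (gene_id, chrom, strand, tss, tes), `cgis`
#'   (cgi_id, chrom, start, end) and `chrom_lengths`.
#' @export
generate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  local_rng(stage_seed(cfg, "annotation"), {
    chroms <- names(cfg$chrom_lengths)
    n_per <- apportion(cfg$n_genes, cfg$chrom_lengths)
    margin <- 2100
    genes <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
      n <- n_per[ci]
      if (n == 0L) return(NULL)
      L <- cfg$chrom_lengths[[ci]]
      lens <- sample(seq(cfg$gene_length_range[1], cfg$gene_length_range[2]),
                     n, replace = TRUE)
      starts <- pack_intervals(lens, L, margin)
      strand <- sample(c("+", "-"), n, replace = TRUE)
      data.frame(chrom = chroms[ci], strand = strand,
                 tss = ifelse(strand == "+", starts, starts + lens - 1L),
                 tes = ifelse(strand == "+", starts + lens, starts - 1L),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(genes)) {
      genes <- data.frame(gene_id = character(0), chrom = character(0),
                          strand = character(0), tss = integer(0),
                          tes = integer(0), stringsAsFactors = FALSE)
      cgis <- data.frame(cgi_id = character(0), chrom = character(0),
                         start = integer(0), end = integer(0),
                         stringsAsFactors = FALSE)
      return(list(genes = genes, cgis = cgis,
                  chrom_lengths = cfg$chrom_lengths))
    }
    genes <- data.frame(gene_id = sprintf("G%05d", seq_len(nrow(genes))),
                        genes, stringsAsFactors = FALSE)
    has_cgi <- runif(nrow(genes)) < cfg$cgi_promoter_fraction
    cgi_half <- 400L
    cgis <- genes[has_cgi, , drop = FALSE]
    cgis <- data.frame(
      cgi_id = sprintf("CGI%05d", seq_len(nrow(cgis))),
      chrom = cgis$chrom,
      start = pmax(cgis$tss - cgi_half, 0L),
      end = pmin(cgis$tss + cgi_half,
                 unname(cfg$chrom_lengths[cgis$chrom])),
      stringsAsFactors = FALSE)
    list(genes = genes, cgis = cgis, chrom_lengths = cfg$chrom_lengths)
  })
}

#' Generate fragment loci
#'
#' Direct placement (default) scatters non-overlapping fragments with
#' lengths uniform in `fragment_size_range` at `locus_density` fragments
#' per 10 kb. Digest mode generates a random nucleotide sequence per
#' chromosome and takes the in-silico MspI fragments passing the size
#' filter ([digest_genome()]). Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param chrom_lengths named chromosome lengths (defaults to the config's).
#' @param mode `"direct-placement"` or `"random-sequence-digest"`.
#' @return data.frame `locus_id`, `chrom`, `start`, `end`, `length`; in
#'   digest mode the generated sequences are attached as attribute
#'   `"sequences"`.
#' @export
generate_loci <- function(cfg, chrom_lengths = cfg$chrom_lengths,
                          mode = c("direct-placement",
                                   "random-sequence-digest")) {
  stopifnot(inherits(cfg, "sim_config"))
  mode <- match.arg(mode)
  local_rng(stage_seed(cfg, "loci"), {
    chroms <- names(chrom_lengths)
    if (mode == "random-sequence-digest") {
      seqs <- vapply(chroms, function(ch) {
        paste(sample(c("A", "C", "G", "T"), chrom_lengths[[ch]],
                     replace = TRUE), collapse = "")
      }, character(1))
      loci <- digest_genome(seqs, cfg$fragment_size_range)
      attr(loci, "sequences") <- seqs
      return(loci)
    }
    per_chrom <- lapply(chroms, function(ch) {
      L <- chrom_lengths[[ch]]
      n <- round(cfg$locus_density * L / 1e4)
      if (n == 0L) return(NULL)
      lens <- sample(seq(cfg$fragment_size_range[1],
                         cfg$fragment_size_range[2]), n, replace = TRUE)
      starts <- tryCatch(pack_intervals(lens, L, 0),
                         error = function(e) stop_helpdm(
                           sprintf("locus density infeasible on %s: %s",
                                   ch, conditionMessage(e))))
      data.frame(chrom = ch, start = starts, end = starts + lens,
                 length = lens, stringsAsFactors = FALSE)
    })
    loci <- do.call(rbind, per_chrom)
    if (is.null(loci)) {
      loci <- data.frame(chrom = character(0), start = integer(0),
                         end = integer(0), length = integer(0))
    }
    loci <- loci[order(loci$chrom, loci$start), , drop = FALSE]
    data.frame(locus_id = sprintf("L%06d", seq_len(nrow(loci))), loci,
               row.names = NULL, stringsAsFactors = FALSE)
  })
}

sample_band_magnitudes <- function(n, band_probs) {
  bands <- sample(MAGNITUDE_BANDS, n, replace = TRUE,
                  prob = band_probs / sum(band_probs))
  lo <- c(negligible = 0, small = 0.5, moderate = 1)[bands]
  hi <- c(negligible = 0.5, small = 1, moderate = 2)[bands]
  runif(n, lo, hi)
}

#' Simulate the paired methylome
#'
#' Plants DM effects with compartment-specific rates and hyper/hypo
#' splits, then draws the score matrix under the subject-plus-residual
#' Gaussian model (see the generator notes at the top of this file).
#' Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param loci annotated locus table (must carry `compartment` and
#'   `linked_gene`; see [annotate_loci()]).
#' @return list with `scores` (matrix loci x samples), `design`
#'   ([paired_design()]), `sample_sheet`, and `truth_loci` (locus_id,
#'   compartment, is_dm, true_delta).
#' @export
simulate_methylome <- function(cfg, loci) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!"compartment" %in% names(loci) || any(is.na(loci$compartment))) {
    stop_helpdm("loci must carry compartment labels; run annotate_loci() first")
  }
  local_rng(stage_seed(cfg, "methylome"), {
    n_loci <- nrow(loci)
    subjects <- sprintf("S%02d", seq_len(cfg$n_subjects))
    sample_sheet <- data.frame(
      sample_id = c(paste0(subjects, "_T"), paste0(subjects, "_NT")),
      subject_id = rep(subjects, 2),
      tissue = rep(c("T", "NT"), each = cfg$n_subjects),
      stringsAsFactors = FALSE)
    design <- paired_design(sample_sheet)

    comp <- loci$compartment
    rate <- cfg$dm_rate_by_compartment
    no_gene <- comp == "IG" | is.na(loci$linked_gene)

    # hierarchical planting: one deregulated compartment per gene,
    # calibrated to preserve the per-locus marginal rates
    r_sum <- rate[["PR"]] + rate[["GB"]]
    if (r_sum > 1) {
      warning("PR + GB DM rates exceed 1; per-locus marginal DM rates ",
              "saturate below the configured values", call. = FALSE)
    }
    w_pr <- if (r_sum > 0) rate[["PR"]] / r_sum else 0.5
    gene_ids <- unique(loci$linked_gene[!no_gene])
    gene_comp <- setNames(ifelse(runif(length(gene_ids)) < w_pr, "PR", "GB"),
                          gene_ids)
    is_dm <- logical(n_loci)
    is_dm[no_gene] <- runif(sum(no_gene)) < rate[["IG"]]
    genic <- which(!no_gene)
    if (length(genic)) {
      active <- gene_comp[loci$linked_gene[genic]] == comp[genic]
      is_dm[genic] <- active & (runif(length(genic)) < min(r_sum, 1))
    }

    # direction: one draw per linked gene for PR/GB, per locus for IG
    hyper_p <- unname(cfg$hyper_given_dm_by_compartment[comp])
    gene_key <- ifelse(no_gene, paste0(".locus.", loci$locus_id),
                       loci$linked_gene)
    keys <- unique(gene_key)
    key_draw <- setNames(runif(length(keys)), keys)
    is_hyper <- key_draw[gene_key] < hyper_p

    magnitude <- sample_band_magnitudes(n_loci,
                                        cfg$delta_magnitude_distribution)
    true_delta <- ifelse(is_dm, ifelse(is_hyper, -magnitude, magnitude), 0)

    mu <- rnorm(n_loci, 0, 1)
    b <- rnorm(cfg$n_subjects, 0, cfg$subject_sd)
    n_s <- cfg$n_subjects
    eps_t <- matrix(rnorm(n_loci * n_s, 0, cfg$residual_sd), n_loci, n_s)
    eps_nt <- matrix(rnorm(n_loci * n_s, 0, cfg$residual_sd), n_loci, n_s)
    scores_t <- mu + true_delta + eps_t
    scores_nt <- mu + eps_nt
    scores_t <- sweep(scores_t, 2, b, `+`)
    scores_nt <- sweep(scores_nt, 2, b, `+`)
    scores <- cbind(scores_t, scores_nt)
    dimnames(scores) <- list(loci$locus_id,
                             c(paste0(subjects, "_T"),
                               paste0(subjects, "_NT")))
    truth_loci <- data.frame(locus_id = loci$locus_id, compartment = comp,
                             linked_gene = loci$linked_gene,
                             is_dm = is_dm, true_delta = true_delta,
                             stringsAsFactors = FALSE)
    list(scores = scores, design = design, sample_sheet = sample_sheet,
         truth_loci = truth_loci)
  })
}

#' Simulate paired gene expression coupled to the planted methylome
#'
#' Each gene with at least one planted DM locus in its promoter or body is
#' coupled to the nearest such locus (midpoint-to-TSS distance; one gene
#' couples to at most one locus) and is always differentially expressed:
#' in the canonical direction with probability `canonical_coupling`,
#' anti-canonically otherwise. Uncoupled genes are DE with probability
#' `de_rate` and random sign. |log2 fold change| is `log2fc_magnitude`.
#' The paired noise model matches the methylome arm. Deterministic given
#' `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @param genes gene model table.
#' @param truth_loci planted methylome truth ([simulate_methylome()]).
#' @param loci annotated locus table (for midpoint distances).
#' @return list with `expr` (matrix genes x samples) and `truth_genes`
#'   (gene_id, is_de, true_log2fc, coupled_locus, coupling_category,
#'   coupling_canonical).
#' @export
simulate_expression <- function(cfg, genes, truth_loci, loci) {
  stopifnot(inherits(cfg, "sim_config"))
  local_rng(stage_seed(cfg, "expression"), {
    n_g <- nrow(genes)
    subjects <- sprintf("S%02d", seq_len(cfg$n_subjects))

    planted <- truth_loci[truth_loci$is_dm &
                            truth_loci$compartment %in% c("PR", "GB") &
                            !is.na(truth_loci$linked_gene), , drop = FALSE]
    mid <- (loci$start + loci$end) / 2
    planted$mid <- mid[match(planted$locus_id, loci$locus_id)]
    planted$tss <- genes$tss[match(planted$linked_gene, genes$gene_id)]
    planted$dist <- abs(planted$mid - planted$tss)
    planted <- planted[order(planted$linked_gene, planted$dist,
                             planted$locus_id), , drop = FALSE]
    coupled <- planted[!duplicated(planted$linked_gene), , drop = FALSE]

    truth_genes <- data.frame(
      gene_id = genes$gene_id, is_de = FALSE, true_log2fc = 0,
      coupled_locus = NA_character_, coupling_category = NA_character_,
      coupling_canonical = NA, stringsAsFactors = FALSE)
    ci <- match(coupled$linked_gene, truth_genes$gene_id)
    if (length(ci)) {
      canonical <- runif(length(ci)) < cfg$canonical_coupling
      dm_dir <- ifelse(coupled$true_delta < 0, "hyper", "hypo")
      # canonical sign rules in delta terms (hyper <=> delta < 0):
      #   PR canonical: expression moves with delta sign (HyperDown/HypoUp)
      #   GB canonical: expression moves against it (HyperUp/HypoDown)
      canon_sign <- ifelse(coupled$compartment == "PR",
                           sign(coupled$true_delta),
                           -sign(coupled$true_delta))
      fc_sign <- ifelse(canonical, canon_sign, -canon_sign)
      truth_genes$is_de[ci] <- TRUE
      truth_genes$true_log2fc[ci] <- fc_sign * cfg$log2fc_magnitude
      truth_genes$coupled_locus[ci] <- coupled$locus_id
      de_dir <- ifelse(fc_sign > 0, "up", "down")
      cat_df <- categorize(coupled$compartment, dm_dir, de_dir)
      truth_genes$coupling_category[ci] <- cat_df$category
      truth_genes$coupling_canonical[ci] <- cat_df$canonical
    }
    uncoupled <- which(!truth_genes$is_de)
    bg_de <- uncoupled[runif(length(uncoupled)) < cfg$de_rate]
    if (length(bg_de)) {
      truth_genes$is_de[bg_de] <- TRUE
      truth_genes$true_log2fc[bg_de] <-
        sample(c(-1, 1), length(bg_de), replace = TRUE) * cfg$log2fc_magnitude
    }

    base <- rnorm(n_g, 8, 2)
    b <- rnorm(cfg$n_subjects, 0, cfg$subject_sd)
    n_s <- cfg$n_subjects
    eps_t <- matrix(rnorm(n_g * n_s, 0, cfg$residual_sd), n_g, n_s)
    eps_nt <- matrix(rnorm(n_g * n_s, 0, cfg$residual_sd), n_g, n_s)
    expr_t <- sweep(base + truth_genes$true_log2fc + eps_t, 2, b, `+`)
    expr_nt <- sweep(base + eps_nt, 2, b, `+`)
    expr <- cbind(expr_t, expr_nt)
    dimnames(expr) <- list(genes$gene_id,
                           c(paste0(subjects, "_T"),
                             paste0(subjects, "_NT")))
    list(expr = expr, truth_genes = truth_genes)
  })
}

#' Run the whole generator: annotation, loci, methylome, expression
#'
#' @param cfg a [sim_config()].
#' @param mode locus generation mode (see [generate_loci()]).
#' @param promoter_width,gb_start_offset,shore_width,shore_mode annotation
#'   parameters.
#' @return list of class `sim_dataset` with `annotation`, `loci`
#'   (annotated), `meth` (scores matrix), `expr`, `design`,
#'   `sample_sheet`, `truth` (list of `loci` and `genes` tables), and the
#'   `config`.
#' @export
simulate_dataset <- function(cfg = sim_config(),
                             mode = c("direct-placement",
                                      "random-sequence-digest"),
                             promoter_width = 2000, gb_start_offset = 0,
                             shore_width = 2000,
                             shore_mode = c("both-flanks", "upstream-only")) {
  mode <- match.arg(mode)
  shore_mode <- match.arg(shore_mode)
  ann <- generate_annotation(cfg)
  loci <- generate_loci(cfg, mode = mode)
  loci <- annotate_loci(loci, ann$genes, ann$cgis, promoter_width,
                        gb_start_offset, shore_width, shore_mode,
                        chrom_lengths = ann$chrom_lengths)
  meth <- simulate_methylome(cfg, loci)
  expr <- simulate_expression(cfg, ann$genes, meth$truth_loci, loci)
  structure(list(annotation = ann, loci = loci, meth = meth$scores,
                 expr = expr$expr, design = meth$design,
                 sample_sheet = meth$sample_sheet,
                 truth = list(loci = meth$truth_loci,
                              genes = expr$truth_genes),
                 config = cfg),
            class = "sim_dataset")
}

#' Recovery metrics of a DM run against planted truth
#'
#' @param dm_table [run_dm()] result.
#' @param truth_loci planted truth table.
#' @param alpha significance threshold.
#' @param min_abs_delta restrict sensitivity/bias to planted loci with
#'   |true delta| at or above this value (default 0: all planted loci).
#' @return list with `sensitivity` (planted loci recovered), `fdp`
#'   (false-discovery proportion among calls), `delta_bias` (mean of
#'   estimated minus true delta over planted loci), `n_called`,
#'   `n_planted`.
#' @export
evaluate_dm_recovery <- function(dm_table, truth_loci, alpha = 0.05,
                                 min_abs_delta = 0) {
  idx <- match(dm_table$locus_id, truth_loci$locus_id)
  is_dm <- truth_loci$is_dm[idx]
  true_delta <- truth_loci$true_delta[idx]
  called <- !is.na(dm_table$q) & dm_table$q < alpha
  planted <- is_dm & abs(true_delta) >= min_abs_delta
  list(
    sensitivity = if (any(planted)) mean(called[planted]) else NA_real_,
    fdp = if (any(called)) mean(!is_dm[called]) else 0,
    delta_bias = if (any(planted)) {
      mean(dm_table$delta[planted] - true_delta[planted])
    } else NA_real_,
    n_called = sum(called), n_planted = sum(planted))
}
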