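test_that("sim_config validates probabilities, ranges, and map keys", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(dm_rate_by_compartment = c(PR = 0.2, GB = 0.3)),
               "keys")
  expect_error(sim_config(dm_rate_by_compartment = c(PR = 1.2, GB = 0, IG = 0)),
               "\\[0, 1\\]")
  expect_error(sim_config(subject_sd = 0), "> 0")
  expect_error(sim_config(fragment_size_range = c(2000, 200)), "size_range")
  expect_error(sim_config(chrom_lengths = numeric(0)), "chrom_lengths")
})

test_that("generate_annotation is deterministic and honors the CGI fraction", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 1e6), n_genes = 50,
                    cgi_promoter_fraction = 1, seed = 11)
  a1 <- generate_annotation(cfg)
  a2 <- generate_annotation(cfg)
  expect_identical(a1, a2)
  expect_equal(nrow(a1$genes), 50)
  expect_equal(nrow(a1$cgis), 50)

  # each CGI overlaps its gene's promoter window
  pw <- promoter_window(a1$genes)
  expect_true(all(overlaps(a1$cgis$start, a1$cgis$end, pw$start, pw$end)))

  # strand conventions hold
  plus <- a1$genes$strand == "+"
  expect_true(all(a1$genes$tss[plus] < a1$genes$tes[plus]))
  expect_true(all(a1$genes$tss[!plus] > a1$genes$tes[!plus]))

  # genes do not overlap on the chromosome axis
  iv_start <- pmin(a1$genes$tss, a1$genes$tes + 1)
  iv_end <- pmax(a1$genes$tss + 1, a1$genes$tes)
  o <- order(iv_start)
  expect_true(all(iv_start[o][-1] >= iv_end[o][-length(o)]))
})

test_that("generate_annotation degenerate and infeasible inputs", {
  empty <- generate_annotation(sim_config(n_genes = 0))
  expect_equal(nrow(empty$genes), 0)
  expect_equal(nrow(empty$cgis), 0)

  too_many <- sim_config(chrom_lengths = c(chr1 = 1e5), n_genes = 100,
                         gene_length_range = c(5000, 5000))
  expect_error(generate_annotation(too_many), "infeasible")
})

test_that("generate_loci direct placement respects density, size and bounds", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 1e5), locus_density = 5,
                    seed = 13)
  loci <- generate_loci(cfg)
  expect_equal(nrow(loci), 50)
  expect_true(all(loci$length >= 200 & loci$length <= 2000))
  expect_true(all(loci$start >= 0 & loci$end <= 1e5))
  o <- order(loci$start)
  expect_true(all(loci$start[o][-1] >= loci$end[o][-50]))
  expect_identical(loci, generate_loci(cfg))

  none <- generate_loci(sim_config(chrom_lengths = c(chr1 = 1e5),
                                   locus_density = 0))
  expect_equal(nrow(none), 0)

  expect_error(generate_loci(sim_config(chrom_lengths = c(chr1 = 1e4),
                                        locus_density = 50,
                                        fragment_size_range = c(1900, 2000))),
               "infeasible")
})

test_that("generate_loci digest mode digests a seeded random genome", {
  cfg <- sim_config(chrom_lengths = c(chrA = 3e4, chrB = 2e4),
                    fragment_size_range = c(50, 2000), seed = 17)
  loci <- generate_loci(cfg, mode = "random-sequence-digest")
  seqs <- attr(loci, "sequences")
  expect_equal(names(seqs), c("chrA", "chrB"))
  # agrees with digesting the attached sequences directly
  expect_equal(loci[, -1], digest_genome(seqs, c(50, 2000))[, -1],
               ignore_attr = TRUE)
  expect_identical(loci, generate_loci(cfg, mode = "random-sequence-digest"))
})

test_that("simulate_methylome plants effects with the configured rates", {
  loci <- bare_loci(n_pr = 3000, n_gb = 3000, n_ig = 3000)
  cfg <- sim_config(n_subjects = 3, seed = 19,
                    dm_rate_by_compartment = c(PR = 0.2, GB = 0.4, IG = 0.1))
  sim <- simulate_methylome(cfg, loci)
  truth <- sim$truth_loci
  planted <- tapply(truth$is_dm, truth$compartment, sum)
  for (comp in c("PR", "GB", "IG")) {
    p <- cfg$dm_rate_by_compartment[[comp]]
    expect_lt(abs(planted[[comp]] - 3000 * p), 3 * sqrt(3000 * p * (1 - p)))
  }
  # truth invariants
  expect_equal(sort(truth$locus_id), sort(loci$locus_id))
  expect_true(all(truth$true_delta[!truth$is_dm] == 0))
  expect_true(all(abs(truth$true_delta[truth$is_dm]) > 0))
  expect_true(all(abs(truth$true_delta) <= 2))
  # matrix shape and determinism
  expect_equal(dim(sim$scores), c(9000, 6))
  expect_identical(sim$scores, simulate_methylome(cfg, loci)$scores)
})

test_that("hierarchical planting never splits a gene across compartments", {
  # genes with loci in both PR and GB: planted DM stays in one compartment
  n_g <- 300
  loci <- rbind(
    data.frame(locus_id = sprintf("P%04d", 1:n_g), compartment = "PR",
               linked_gene = sprintf("G%04d", 1:n_g)),
    data.frame(locus_id = sprintf("B%04d", 1:n_g), compartment = "GB",
               linked_gene = sprintf("G%04d", 1:n_g)))
  cfg <- sim_config(n_subjects = 2, seed = 23,
                    dm_rate_by_compartment = c(PR = 0.4, GB = 0.5, IG = 0))
  truth <- simulate_methylome(cfg, loci)$truth_loci
  dm <- truth[truth$is_dm, ]
  split_comp <- tapply(dm$compartment, dm$linked_gene,
                       function(x) length(unique(x)))
  expect_true(all(split_comp == 1))
  # signs are shared within a gene
  sgn <- tapply(sign(dm$true_delta), dm$linked_gene,
                function(x) length(unique(x)))
  expect_true(all(sgn == 1))
})

test_that("the noise-free limit recovers planted deltas exactly", {
  loci <- bare_loci(n_pr = 6, n_gb = 6, n_ig = 6)
  cfg <- sim_config(n_subjects = 4, seed = 29, subject_sd = 1e-12,
                    residual_sd = 1e-12,
                    dm_rate_by_compartment = c(PR = 1, GB = 0, IG = 0))
  sim <- simulate_methylome(cfg, loci)
  d <- sim$scores[, paste0(sim$design$subject_id, "_T")] -
    sim$scores[, paste0(sim$design$subject_id, "_NT")]
  expect_equal(unname(rowMeans(d)), sim$truth_loci$true_delta,
               tolerance = 1e-9)
})

test_that("simulate_expression couples genes to their nearest planted locus", {
  cfg_base <- list(chrom_lengths = c(chr1 = 2e6), n_genes = 100,
                   locus_density = 5, seed = 31,
                   delta_magnitude_distribution =
                     c(negligible = 0, small = 0, moderate = 1))

  # coupling = 1: every coupled gene is canonical
  cfg <- do.call(sim_config, c(cfg_base, canonical_coupling = 1))
  ds <- simulate_dataset(cfg)
  tg <- ds$truth$genes
  coupled <- tg[!is.na(tg$coupled_locus), ]
  expect_gt(nrow(coupled), 10)
  expect_true(all(coupled$coupling_canonical))
  expect_true(all(coupled$is_de))
  expect_true(all(abs(coupled$true_log2fc) == cfg$log2fc_magnitude))

  # coupling = 0: every coupled gene is anti-canonical
  cfg0 <- do.call(sim_config, c(cfg_base, canonical_coupling = 0))
  tg0 <- simulate_dataset(cfg0)$truth$genes
  expect_true(all(!tg0$coupling_canonical[!is.na(tg0$coupled_locus)]))

  # a coupled gene's locus really is its nearest planted DM locus
  tl <- ds$truth$loci
  g1 <- coupled$gene_id[1]
  mine <- tl[tl$is_dm & !is.na(tl$linked_gene) & tl$linked_gene == g1, ]
  mid <- (ds$loci$start + ds$loci$end) / 2
  tssd <- abs(mid[match(mine$locus_id, ds$loci$locus_id)] -
                ds$annotation$genes$tss[ds$annotation$genes$gene_id == g1])
  expect_equal(coupled$coupled_locus[1],
               mine$locus_id[order(tssd, mine$locus_id)][1])

  # truth invariants
  expect_true(all(tg$true_log2fc[!tg$is_de] == 0))
  expect_equal(sort(tg$gene_id), sort(ds$annotation$genes$gene_id))
})

test_that("a fully null generator yields a quiet DE and DM pipeline", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 1e6), n_genes = 80,
                    locus_density = 4, seed = 37, de_rate = 0,
                    canonical_coupling = 0,
                    dm_rate_by_compartment = c(PR = 0, GB = 0, IG = 0))
  ds <- simulate_dataset(cfg)
  expect_true(all(!ds$truth$loci$is_dm))
  expect_true(all(!ds$truth$genes$is_de))
  de <- run_de(ds$expr, ds$design)
  expect_lte(mean(de$q < 0.05), 0.05)
  dm <- run_dm(ds$meth, ds$design)
  expect_lte(mean(dm$q < 0.05), 0.05)
})

test_that("whole-dataset generation is seed-deterministic", {
  cfg <- sim_config(chrom_lengths = c(chr1 = 5e5), n_genes = 40,
                    locus_density = 4, seed = 41)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$meth, d2$meth)
  expect_identical(d1$expr, d2$expr)
  expect_identical(d1$truth, d2$truth)
  # a different seed changes the data
  d3 <- simulate_dataset(sim_config(chrom_lengths = c(chr1 = 5e5),
                                    n_genes = 40, locus_density = 4,
                                    seed = 42))
  expect_false(identical(d1$meth, d3$meth))
})
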