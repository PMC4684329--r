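test_that("categorize is exhaustive, exclusive, and matches the canonical map", {
  combos <- expand.grid(compartment = c("PR", "GB"),
                        dm = c("hyper", "hypo"), de = c("up", "down"),
                        stringsAsFactors = FALSE)
  res <- categorize(combos$compartment, combos$dm, combos$de)
  expect_equal(nrow(res), 8)
  # each triple maps to exactly one category; canonical iff named
  expect_true(all((res$category != "other") == res$canonical))

  one <- function(comp, dm, de) categorize(comp, dm, de)
  expect_equal(one("PR", "hyper", "down")$category, "HyperDown")
  expect_true(one("PR", "hypo", "up")$canonical)
  expect_equal(one("GB", "hyper", "up")$category, "HyperUp")
  expect_true(one("GB", "hypo", "down")$canonical)
  expect_equal(one("PR", "hypo", "down")$category, "other")
  expect_equal(one("GB", "hyper", "down")$category, "other")
  expect_false(one("PR", "hyper", "up")$canonical)

  expect_error(categorize("IG", "hyper", "up"), "PR or GB")
  expect_error(categorize("PR", "none", "up"), "significant")
})

make_tables <- function(deltas, lfcs, qs_dm = 0.01, qs_de = 0.01) {
  dm <- data.frame(locus_id = names(deltas), delta = unname(deltas),
                   q = qs_dm,
                   direction = ifelse(deltas < 0, "hyper", "hypo"),
                   stringsAsFactors = FALSE)
  de <- data.frame(gene_id = names(lfcs), log2fc = unname(lfcs), q = qs_de,
                   direction = ifelse(lfcs < 0, "down", "up"),
                   stringsAsFactors = FALSE)
  list(dm = dm, de = de)
}

test_that("link_loci_to_genes applies the 2 kb location rules", {
  genes <- data.frame(gene_id = "G1", chrom = "chr1", strand = "+",
                      tss = 10000L, tes = 20000L, stringsAsFactors = FALSE)
  loci <- data.frame(locus_id = c("Lpr", "Lgb", "Lig"), chrom = "chr1",
                     start = c(8100L, 15000L, 40000L),
                     end = c(8400L, 15300L, 40400L), stringsAsFactors = FALSE)
  tb <- make_tables(c(Lpr = -1, Lgb = 0.8, Lig = -1), c(G1 = -2))
  rec <- link_loci_to_genes(tb$dm, tb$de, loci, genes)
  expect_equal(nrow(rec), 2)  # the intergenic locus never links
  pr <- rec[rec$locus_id == "Lpr", ]
  expect_equal(pr$compartment, "PR")
  expect_equal(pr$category, "HyperDown")
  expect_true(pr$canonical)
  gb <- rec[rec$locus_id == "Lgb", ]
  expect_equal(gb$category, "HypoDown")
  expect_true(gb$canonical)

  # promoter-hypo + downregulated gene is non-canonical
  tb2 <- make_tables(c(Lpr = 1), c(G1 = -2))
  rec2 <- link_loci_to_genes(tb2$dm, tb2$de, loci, genes)
  expect_equal(rec2$category, "other")
  expect_false(rec2$canonical)

  # non-significant platforms produce no records
  tb3 <- make_tables(c(Lpr = -1), c(G1 = -2), qs_de = 0.5)
  tb3$de$direction <- "none"
  expect_equal(nrow(link_loci_to_genes(tb3$dm, tb3$de, loci, genes)), 0)
})

test_that("locus dedup prefers PR relations, then the nearest TSS", {
  genes <- data.frame(gene_id = c("GA", "GB1"), chrom = "chr1",
                      strand = c("+", "+"), tss = c(1000L, 12500L),
                      tes = c(12000L, 20000L), stringsAsFactors = FALSE)
  # locus inside GA's body and GB1's promoter window
  loci <- data.frame(locus_id = "L1", chrom = "chr1",
                     start = 11000L, end = 11400L, stringsAsFactors = FALSE)
  tb <- make_tables(c(L1 = -1), c(GA = 2, GB1 = -2))
  rec <- link_loci_to_genes(tb$dm, tb$de, loci, genes, dedup = "locus")
  expect_equal(rec$gene_id, "GB1")
  expect_equal(rec$compartment, "PR")
  both <- link_loci_to_genes(tb$dm, tb$de, loci, genes, dedup = "pair")
  expect_equal(nrow(both), 2)
  expect_setequal(both$compartment, c("PR", "GB"))
})

test_that("pair-mode linking equals the brute-force all-pairs oracle", {
  withr::with_seed(91, {
    genes <- data.frame(
      gene_id = sprintf("G%02d", 1:8), chrom = "chr1",
      strand = sample(c("+", "-"), 8, replace = TRUE),
      stringsAsFactors = FALSE)
    anchors <- sort(sample(seq(5000, 2e5, by = 100), 8)) + c(0, cumsum(rep(8000, 7)))
    len <- sample(3000:9000, 8)
    genes$tss <- ifelse(genes$strand == "+", anchors, anchors + len - 1L)
    genes$tes <- ifelse(genes$strand == "+", anchors + len, anchors - 1L)
    loci <- data.frame(
      locus_id = sprintf("L%03d", 1:60), chrom = "chr1",
      start = sort(sample(seq(1000, 3e5, by = 50), 60)),
      stringsAsFactors = FALSE)
    loci$end <- loci$start + sample(200:2000, 60, replace = TRUE)
    deltas <- setNames(sample(c(-1, 1), 60, TRUE) * runif(60, 0.5, 2),
                       loci$locus_id)
    lfcs <- setNames(sample(c(-2, 2), 8, TRUE), genes$gene_id)
    tb <- make_tables(deltas, lfcs)
    rec <- link_loci_to_genes(tb$dm, tb$de, loci, genes, dedup = "pair")
    oracle <- bf_link(tb$dm, tb$de, loci, genes)
    key <- function(d) sort(paste(d$locus_id, d$gene_id, d$compartment))
    if (is.null(oracle)) {
      expect_equal(nrow(rec), 0)
    } else {
      expect_equal(key(rec), key(oracle))
    }
  })
})

test_that("build_counts_table reproduces published-style accounting", {
  fixture <- system.file("extdata", "dmxde_counts_adenocarcinoma.tsv",
                         package = "helpdm")
  counts <- read.delim(fixture)
  ct <- build_counts_table(records_from_counts(counts))
  expect_equal(ct$total, 37056)
  expect_equal(ct$canonical_total, 3216)
  expect_equal(ct$canonical_fraction, 8.7)
  expect_equal(ct$table$n, counts$n[match(paste(ct$table$compartment,
                                                ct$table$category),
                                          paste(counts$compartment,
                                                counts$category))])
})

test_that("build_counts_table handles degenerate record sets", {
  empty <- build_counts_table(data.frame(compartment = character(0),
                                         category = character(0),
                                         canonical = logical(0)))
  expect_equal(empty$total, 0)
  expect_true(is.na(empty$canonical_fraction))

  allc <- records_from_counts(data.frame(
    compartment = c("PR", "GB"), category = c("HyperDown", "HypoDown"),
    n = c(10, 5)))
  expect_equal(build_counts_table(allc)$canonical_fraction, 100.0)
})

test_that("accounting is conserved under both dedup policies", {
  withr::with_seed(92, {
    cfg <- sim_config(chrom_lengths = c(chr1 = 2e6), n_genes = 120,
                      locus_density = 6, seed = 8,
                      delta_magnitude_distribution =
                        c(negligible = 0, small = 0.3, moderate = 0.7))
    ds <- simulate_dataset(cfg)
    dm <- run_dm(ds$meth, ds$design, annotation = ds$loci)
    de <- run_de(ds$expr, ds$design)
    for (policy in c("locus", "pair")) {
      rec <- link_loci_to_genes(dm, de, ds$loci, ds$annotation$genes,
                                ds$annotation$cgis, dedup = policy)
      ct <- build_counts_table(rec)
      expect_equal(ct$total, nrow(rec))
      expect_equal(sum(ct$table$n), nrow(rec))
      expect_equal(ct$canonical_total, sum(rec$canonical))
    }
  })
})

test_that("subcompartment_breakdown counts promoter records on the 3-way grid", {
  rec <- records_from_counts(data.frame(
    compartment = "PR", category = "HyperDown", n = 4))
  rec$subcompartment <- "CGI"
  bd <- subcompartment_breakdown(rec)
  expect_equal(bd$grid["CGI", "HyperDown"], 4)
  expect_equal(sum(bd$grid), 4)
  expect_null(bd$chi2)  # single informative cell: no test possible

  withr::with_seed(93, {
    rec2 <- data.frame(
      compartment = "PR",
      category = sample(c("HyperDown", "HypoUp", "other"), 300, TRUE),
      subcompartment = sample(c("CGI", "CGS", "other"), 300, TRUE),
      stringsAsFactors = FALSE)
    rec2$canonical <- rec2$category != "other"
    bd2 <- subcompartment_breakdown(rec2)
    expect_equal(sum(bd2$grid), 300)
    expect_s3_class(data.frame(p = bd2$chi2$p), "data.frame")
    expect_gt(bd2$chi2$p, 1e-4)  # independent labels: no strong signal
  })
})
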