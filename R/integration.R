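# DM x DE integration: link significant methylation loci to significant
# expression genes by the 2 kb location rules and account for canonical vs
# non-canonical methylation-expression relationships.

CANONICAL_MAP <- list(
  PR = c(HyperDown = "canonical", HypoUp = "canonical"),
  GB = c(HyperUp = "canonical", HypoDown = "canonical"))

CATEGORY_LEVELS <- list(
  PR = c("HyperDown", "HypoUp", "other"),
  GB = c("HyperUp", "HypoDown", "other"))

#' Categorize a (compartment, DM direction, DE direction) triple
#'
#' Canonical promoter relationships are hypermethylation with
#' down-regulation and hypomethylation with up-regulation; canonical
#' gene-body relationships are the reverse pairing (hypermethylation with
#' up-regulation, hypomethylation with down-regulation). Canonical triples
#' are named (`HyperDown`, `HypoUp`, `HyperUp`, `HypoDown`); every
#' non-canonical triple is `other`. Vectorized.
#'
#' @param compartment `"PR"` or `"GB"`.
#' @param dm_direction `"hyper"` or `"hypo"`.
#' @param de_direction `"up"` or `"down"`.
#' @return data.frame with columns `category` and `canonical` (logical).
#' @export
categorize <- function(compartment, dm_direction, de_direction) {
  if (any(!compartment %in% c("PR", "GB"))) {
    stop_helpdm("'compartment' must be PR or GB")
  }
  if (any(!dm_direction %in% c("hyper", "hypo")) ||
      any(!de_direction %in% c("up", "down"))) {
    stop_helpdm("directions must be significant (hyper/hypo and up/down)")
  }
  name <- paste0(ifelse(dm_direction == "hyper", "Hyper", "Hypo"),
                 ifelse(de_direction == "up", "Up", "Down"))
  canonical <- ifelse(compartment == "PR",
                      name %in% c("HyperDown", "HypoUp"),
                      name %in% c("HyperUp", "HypoDown"))
  data.frame(category = ifelse(canonical, name, "other"),
             canonical = canonical, stringsAsFactors = FALSE)
}

#' Link significant DM loci to significant DE genes by location
#'
#' Emits a record for every significant DM locus lying in the promoter
#' window or gene-body region of a significant DE gene (the annotation
#' rules; intergenic loci never link). A locus in the promoter of one DE
#' gene and the body of another is a promoter record (PR takes precedence,
#' the same rule used throughout). With `dedup = "locus"` (default,
#' matching per-locus accounting) each locus keeps a single record: PR
#' relations are preferred over GB, then the gene whose TSS is nearest to
#' the locus midpoint, then gene id. `dedup = "pair"` keeps every
#' (locus, gene) pair.
#'
#' @param dm_table [run_dm()] result (filtered internally to `q < alpha`).
#' @param de_table [run_de()] result (filtered internally to `q < alpha`).
#' @param loci locus coordinate table (`locus_id`, `chrom`, `start`, `end`).
#' @param genes gene model table (`gene_id`, `chrom`, `strand`, `tss`,
#'   `tes`).
#' @param cgis CpG island intervals for the promoter subcompartment label.
#' @param alpha significance threshold applied to both platforms.
#' @param promoter_width,gb_start_offset,shore_width,shore_mode annotation
#'   parameters (see [annotate_loci()]).
#' @param dedup `"locus"` or `"pair"`.
#' @param chrom_lengths optional, for window clipping.
#' @return data.frame of integration records: `locus_id`, `gene_id`,
#'   `compartment`, `dm_direction`, `de_direction`, `category`,
#'   `canonical`, `subcompartment` (PR records only).
#' @export
link_loci_to_genes <- function(dm_table, de_table, loci, genes, cgis = NULL,
                               alpha = 0.05, promoter_width = 2000,
                               gb_start_offset = 0, shore_width = 2000,
                               shore_mode = c("both-flanks", "upstream-only"),
                               dedup = c("locus", "pair"),
                               chrom_lengths = NULL) {
  dedup <- match.arg(dedup)
  shore_mode <- match.arg(shore_mode)
  empty <- data.frame(locus_id = character(0), gene_id = character(0),
                      compartment = character(0), dm_direction = character(0),
                      de_direction = character(0), category = character(0),
                      canonical = logical(0), subcompartment = character(0),
                      stringsAsFactors = FALSE)
  dm_sig <- dm_table[!is.na(dm_table$q) & dm_table$q < alpha &
                       dm_table$direction != "none", , drop = FALSE]
  de_sig <- de_table[!is.na(de_table$q) & de_table$q < alpha &
                       de_table$direction != "none", , drop = FALSE]
  if (nrow(dm_sig) == 0L || nrow(de_sig) == 0L) return(empty)

  loci_sig <- loci[match(dm_sig$locus_id, loci$locus_id), , drop = FALSE]
  genes_sig <- genes[genes$gene_id %in% de_sig$gene_id, , drop = FALSE]
  if (nrow(genes_sig) == 0L) return(empty)
  loci_gr <- as_granges(loci_sig)
  mid <- (loci_sig$start + loci_sig$end) / 2

  pairs_for <- function(regions, relation) {
    keep <- regions$end > regions$start
    if (!any(keep)) return(NULL)
    ov <- GenomicRanges::findOverlaps(loci_gr, as_granges(
      data.frame(chrom = genes_sig$chrom[keep],
                 regions[keep, c("start", "end")])))
    if (length(ov) == 0L) return(NULL)
    gi <- which(keep)[S4Vectors::subjectHits(ov)]
    li <- S4Vectors::queryHits(ov)
    data.frame(li = li, gi = gi, relation = relation,
               tss_dist = abs(genes_sig$tss[gi] - mid[li]),
               stringsAsFactors = FALSE)
  }

  prom <- promoter_window(genes_sig, promoter_width, chrom_lengths)
  body <- gene_body_region(genes_sig, gb_start_offset, chrom_lengths)
  hits <- rbind(pairs_for(prom, "PR"), pairs_for(body, "GB"))
  if (is.null(hits) || nrow(hits) == 0L) return(empty)

  # same (locus, gene) pair qualifying as both PR and GB -> PR wins
  hits <- hits[order(hits$li, hits$gi, hits$relation != "PR"), , drop = FALSE]
  hits <- hits[!duplicated(hits[, c("li", "gi")]), , drop = FALSE]
  if (dedup == "locus") {
    ord <- order(hits$li, hits$relation != "PR", hits$tss_dist,
                 genes_sig$gene_id[hits$gi])
    hits <- hits[ord, , drop = FALSE]
    hits <- hits[!duplicated(hits$li), , drop = FALSE]
  }

  rec <- data.frame(
    locus_id = dm_sig$locus_id[hits$li],
    gene_id = genes_sig$gene_id[hits$gi],
    compartment = hits$relation,
    dm_direction = dm_sig$direction[hits$li],
    de_direction = de_sig$direction[match(genes_sig$gene_id[hits$gi],
                                          de_sig$gene_id)],
    stringsAsFactors = FALSE)
  cat_df <- categorize(rec$compartment, rec$dm_direction, rec$de_direction)
  rec$category <- cat_df$category
  rec$canonical <- cat_df$canonical
  rec$subcompartment <- NA_character_
  is_pr <- rec$compartment == "PR"
  if (any(is_pr) && !is.null(cgis)) {
    pr_loci <- loci[match(rec$locus_id[is_pr], loci$locus_id), , drop = FALSE]
    rec$subcompartment[is_pr] <-
      assign_subcompartments(pr_loci[, c("locus_id", "chrom", "start", "end")],
                             cgis, shore_width, shore_mode)
  }
  rec <- rec[order(rec$locus_id, rec$gene_id), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}

#' Canonical / non-canonical accounting of integration records
#'
#' Tabulates records per compartment and category, with the grand total,
#' the canonical total, and the canonical fraction as a percentage rounded
#' to one decimal.
#'
#' @param records integration records ([link_loci_to_genes()]), or any
#'   data.frame with `compartment`, `category` and `canonical` columns.
#' @return list of class `dmxde_counts` with `table` (compartment,
#'   category, n), `total`, `canonical_total`, `canonical_fraction`.
#' @export
build_counts_table <- function(records) {
  rows <- do.call(rbind, lapply(c("PR", "GB"), function(comp) {
    lev <- CATEGORY_LEVELS[[comp]]
    n <- table(factor(records$category[records$compartment == comp],
                      levels = lev))
    data.frame(compartment = comp, category = lev, n = as.integer(n),
               stringsAsFactors = FALSE)
  }))
  total <- nrow(records)
  canonical_total <- sum(records$canonical)
  structure(list(
    table = rows,
    total = total,
    canonical_total = canonical_total,
    canonical_fraction = if (total > 0) {
      round(100 * canonical_total / total, 1)
    } else NA_real_),
    class = "dmxde_counts")
}

#' @export
print.dmxde_counts <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("total %d, canonical %d (%.1f%%)\n", x$total,
              x$canonical_total, x$canonical_fraction))
  invisible(x)
}

#' Expand a tabulated category count table into records
#'
#' Convenience for re-running the accounting on published per-category
#' counts: each row `(compartment, category, n)` becomes `n` records with
#' the canonical flag implied by the category/compartment pair.
#'
#' @param counts data.frame with `compartment`, `category`, `n`.
#' @return records data.frame usable by [build_counts_table()].
#' @export
records_from_counts <- function(counts) {
  stopifnot(all(c("compartment", "category", "n") %in% names(counts)))
  idx <- rep(seq_len(nrow(counts)), counts$n)
  rec <- data.frame(compartment = counts$compartment[idx],
                    category = counts$category[idx],
                    stringsAsFactors = FALSE)
  rec$canonical <- mapply(function(comp, cat) {
    cat %in% names(CANONICAL_MAP[[comp]])
  }, rec$compartment, rec$category, USE.NAMES = FALSE)
  rec
}

#' Promoter subcompartment breakdown of integration records
#'
#' Counts promoter records on a (CGI / CGS / other) x category grid and
#' tests the grid for independence with the Pearson chi-square test
#' (zero-margin rows/columns are dropped from the test, never from the
#' grid).
#'
#' @param records integration records; only `compartment == "PR"` rows are
#'   used, and they must carry `subcompartment`.
#' @return list with `grid` (subcompartment x category count matrix) and
#'   `chi2` (result of [chi_square_independence()], or `NULL` if the grid
#'   has fewer than 2 informative rows or columns).
#' @export
subcompartment_breakdown <- function(records) {
  pr <- records[records$compartment == "PR", , drop = FALSE]
  grid <- table(factor(pr$subcompartment, levels = SUBCOMPARTMENTS),
                factor(pr$category, levels = CATEGORY_LEVELS$PR))
  grid <- unclass(grid)
  keep_r <- rowSums(grid) > 0
  keep_c <- colSums(grid) > 0
  chi2 <- NULL
  if (sum(keep_r) >= 2 && sum(keep_c) >= 2) {
    chi2 <- chi_square_independence(grid[keep_r, keep_c, drop = FALSE])
  }
  list(grid = grid, chi2 = chi2)
}
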