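# Compartment annotation: promoter (PR) / gene body (GB) / intergenic (IG)
# and promoter subcompartments (CGI / CGS / other).
#
# Coordinate conventions, used everywhere in the package:
#  * intervals are 0-based half-open [start, end)
#  * a + strand gene occupies [tss, tes); a - strand gene has tss > tes and
#    occupies [tes + 1, tss + 1), so mirroring coordinates maps one strand
#    exactly onto the other.

#' Promoter window of a gene
#'
#' The promoter is the `width` bp immediately upstream of the transcription
#' start site: `[tss - width, tss)` on the + strand and the half-open
#' mirror `[tss + 1, tss + width + 1)` on the - strand, clipped at
#' chromosome bounds.
#'
#' @param genes data.frame with columns `strand` (`+`/`-`) and `tss`;
#'   optionally `chrom`.
#' @param width promoter width in bp upstream of the TSS (default 2000).
#' @param chrom_lengths optional named vector of chromosome lengths used to
#'   clip windows; unclipped if missing.
#' @return data.frame with columns `start`, `end` (0-based half-open), one
#'   row per gene.
#' @export
promoter_window <- function(genes, width = 2000, chrom_lengths = NULL) {
  stopifnot(all(c("strand", "tss") %in% names(genes)))
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - width, genes$tss + 1)
  end <- ifelse(plus, genes$tss, genes$tss + width + 1)
  clip_intervals(start, end, genes, chrom_lengths)
}

#' Gene-body region of a gene
#'
#' Runs from `gb_start_offset` bp downstream of the TSS to the gene end, in
#' strand orientation. An offset reaching past the gene end yields an empty
#' (zero-width) interval, not an error. The default offset of 0 starts the
#' body at the TSS; promoter overlap is resolved by compartment precedence,
#' and an offset of 2000 reproduces a body that begins past the promoter-
#' proximal zone.
#'
#' @param genes data.frame with columns `strand`, `tss`, `tes`.
#' @param gb_start_offset bp downstream of the TSS at which the body starts.
#' @inheritParams promoter_window
#' @return data.frame with columns `start`, `end`; zero-width rows denote
#'   empty regions.
#' @export
gene_body_region <- function(genes, gb_start_offset = 0, chrom_lengths = NULL) {
  stopifnot(all(c("strand", "tss", "tes") %in% names(genes)))
  if (gb_start_offset < 0) stop_helpdm("'gb_start_offset' must be >= 0")
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss + gb_start_offset, genes$tes + 1)
  end <- ifelse(plus, genes$tes, genes$tss + 1 - gb_start_offset)
  # degenerate (offset beyond gene length) => empty interval
  start <- pmin(start, ifelse(plus, end, start))
  end <- pmax(end, start)
  clip_intervals(start, end, genes, chrom_lengths)
}

clip_intervals <- function(start, end, genes, chrom_lengths) {
  start <- pmax(start, 0)
  if (!is.null(chrom_lengths) && "chrom" %in% names(genes)) {
    lim <- unname(chrom_lengths[as.character(genes$chrom)])
    end <- pmin(end, lim)
  }
  end <- pmax(end, start)
  data.frame(start = as.integer(start), end = as.integer(end))
}

#' CG-shore regions flanking CpG islands
#'
#' @param cgis data.frame with `chrom`, `start`, `end`.
#' @param shore_width shore width in bp (default 2000).
#' @param shore_mode `"both-flanks"` (standard usage) places a shore on each
#'   side of the island; `"upstream-only"` places it only on the
#'   lower-coordinate flank (islands are unstranded, so "upstream" is read
#'   as the lower-coordinate side).
#' @return data.frame of shore intervals (`chrom`, `start`, `end`).
#' @export
shore_regions <- function(cgis, shore_width = 2000,
                          shore_mode = c("both-flanks", "upstream-only")) {
  shore_mode <- match.arg(shore_mode)
  if (nrow(cgis) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  }
  up <- data.frame(chrom = cgis$chrom,
                   start = pmax(cgis$start - shore_width, 0),
                   end = cgis$start)
  if (shore_mode == "upstream-only") return(up[up$end > up$start, ])
  down <- data.frame(chrom = cgis$chrom, start = cgis$end,
                     end = cgis$end + shore_width)
  out <- rbind(up, down)
  out[out$end > out$start, ]
}

as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
}

#' Assign each fragment locus a genomic compartment
#'
#' A locus overlapping (by at least 1 bp) any promoter window is `PR`;
#' otherwise a locus overlapping any gene-body region is `GB`; otherwise it
#' is `IG`. PR/GB loci are linked to the gene whose TSS is nearest to the
#' locus midpoint among qualifying genes (ties broken by gene id); IG loci
#' carry no linked gene. Every locus receives exactly one label.
#'
#' @param loci data.frame with `locus_id`, `chrom`, `start`, `end`.
#' @param genes data.frame with `gene_id`, `chrom`, `strand`, `tss`, `tes`.
#' @param promoter_width bp upstream of the TSS treated as promoter.
#' @param gb_start_offset see [gene_body_region()].
#' @param chrom_lengths optional, for window clipping.
#' @return `loci` with added columns `compartment` and `linked_gene`.
#' @export
assign_compartments <- function(loci, genes, promoter_width = 2000,
                                gb_start_offset = 0, chrom_lengths = NULL) {
  compartment <- rep("IG", nrow(loci))
  linked_gene <- rep(NA_character_, nrow(loci))
  if (nrow(genes) > 0L && nrow(loci) > 0L) {
    loci_gr <- as_granges(loci)
    mid <- (loci$start + loci$end) / 2

    hit_link <- function(regions) {
      keep <- regions$end > regions$start
      if (!any(keep)) return(NULL)
      reg <- cbind(regions[keep, ], genes[keep, c("gene_id", "tss")])
      ov <- GenomicRanges::findOverlaps(loci_gr, as_granges(
        data.frame(chrom = genes$chrom[keep], reg[, c("start", "end")])))
      if (length(ov) == 0L) return(NULL)
      qh <- S4Vectors::queryHits(ov)
      sh <- S4Vectors::subjectHits(ov)
      d <- abs(reg$tss[sh] - mid[qh])
      ord <- order(qh, d, reg$gene_id[sh])
      first <- ord[!duplicated(qh[ord])]
      list(locus = qh[first], gene = reg$gene_id[sh[first]])
    }

    prom <- promoter_window(genes, promoter_width, chrom_lengths)
    pr <- hit_link(prom)
    if (!is.null(pr)) {
      compartment[pr$locus] <- "PR"
      linked_gene[pr$locus] <- pr$gene
    }
    body <- gene_body_region(genes, gb_start_offset, chrom_lengths)
    gb <- hit_link(body)
    if (!is.null(gb)) {
      todo <- compartment[gb$locus] == "IG"
      compartment[gb$locus[todo]] <- "GB"
      linked_gene[gb$locus[todo]] <- gb$gene[todo]
    }
  }
  out <- loci
  out$compartment <- compartment
  out$linked_gene <- linked_gene
  out
}

#' Assign promoter loci a CGI / CG-shore / other subcompartment
#'
#' A PR locus overlapping a CpG island is `CGI`; otherwise, if it overlaps a
#' shore flank (see [shore_regions()]) it is `CGS`; otherwise `other`. CGI
#' takes precedence over CGS on overlap.
#'
#' @param loci data.frame of promoter loci (`compartment` must be `"PR"`
#'   for every row if the column is present).
#' @param cgis CpG island intervals (`chrom`, `start`, `end`).
#' @inheritParams shore_regions
#' @return character vector of subcompartment labels, one per locus.
#' @export
assign_subcompartments <- function(loci, cgis, shore_width = 2000,
                                   shore_mode = c("both-flanks", "upstream-only")) {
  shore_mode <- match.arg(shore_mode)
  if ("compartment" %in% names(loci) && any(loci$compartment != "PR")) {
    stop_helpdm("assign_subcompartments() expects promoter (PR) loci only")
  }
  sub <- rep("other", nrow(loci))
  if (nrow(loci) == 0L) return(sub)
  if (nrow(cgis) > 0L) {
    loci_gr <- as_granges(loci)
    in_cgi <- IRanges::overlapsAny(loci_gr, as_granges(cgis))
    sub[in_cgi] <- "CGI"
    shores <- shore_regions(cgis, shore_width, shore_mode)
    if (nrow(shores) > 0L) {
      in_shore <- IRanges::overlapsAny(loci_gr, as_granges(shores))
      sub[!in_cgi & in_shore] <- "CGS"
    }
  }
  sub
}

#' Full locus annotation: compartments plus promoter subcompartments
#'
#' @inheritParams assign_compartments
#' @inheritParams assign_subcompartments
#' @param cgis CpG island intervals.
#' @return `loci` with `compartment`, `linked_gene` and `subcompartment`
#'   columns (`subcompartment` is `NA` outside promoters).
#' @export
annotate_loci <- function(loci, genes, cgis, promoter_width = 2000,
                          gb_start_offset = 0, shore_width = 2000,
                          shore_mode = c("both-flanks", "upstream-only"),
                          chrom_lengths = NULL) {
  shore_mode <- match.arg(shore_mode)
  out <- assign_compartments(loci, genes, promoter_width, gb_start_offset,
                             chrom_lengths)
  out$subcompartment <- NA_character_
  is_pr <- out$compartment == "PR"
  if (any(is_pr)) {
    out$subcompartment[is_pr] <-
      assign_subcompartments(out[is_pr, , drop = FALSE], cgis,
                             shore_width, shore_mode)
  }
  out
}
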