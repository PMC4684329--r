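# Readers and writers for the interchange formats: BED (0-based
# half-open), TSV matrices, gene tables and sample sheets. Tab-separated,
# header rows, UTF-8, '.' for missing values.

#' Read a BED3/BED6 file
#'
#' @param path file path. Lines must have chrom, start, end and optionally
#'   name, score, strand; 0-based half-open coordinates.
#' @return data.frame with `chrom`, `start`, `end` (+ `name`, `score`,
#'   `strand` when present).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3)) {
    stop_helpdm("malformed BED line ", which(nf < 3)[1], ": fewer than 3 fields")
  }
  start <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(parts, `[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start >= end)
  if (length(bad)) {
    stop_helpdm("malformed BED line ", bad[1],
                ": start/end not integers with 0 <= start < end")
  }
  out <- data.frame(chrom = vapply(parts, `[`, "", 1), start = start,
                    end = end, stringsAsFactors = FALSE)
  if (all(nf >= 4)) out$name <- vapply(parts, `[`, "", 4)
  if (all(nf >= 5)) out$score <- vapply(parts, `[`, "", 5)
  if (all(nf >= 6)) out$strand <- vapply(parts, `[`, "", 6)
  out
}

#' Write intervals as BED
#'
#' @param df data.frame with `chrom`, `start`, `end` and optional `name`,
#'   `score`, `strand` columns.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(df))
  write.table(df[, cols, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a feature x sample matrix from TSV
#'
#' First column holds feature ids, remaining columns one sample each;
#' header row required; '.' is read as missing.
#'
#' @param path file path.
#' @return numeric matrix with feature rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, na.strings = c("NA", "."),
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop_helpdm("non-numeric values in matrix ", path)
  rownames(m) <- df[[1]]
  m
}

#' Write a feature x sample matrix as TSV
#'
#' @param mat numeric matrix with rownames.
#' @param path output path.
#' @param id_col name of the id column in the header (default "feature_id").
#' @export
write_matrix_tsv <- function(mat, path, id_col = "feature_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

#' Write a data.frame as TSV ('.' for missing)
#'
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(path)
}

#' Read a sample sheet and validate its paired design
#'
#' @param path TSV with columns `sample_id`, `subject_id`, `tissue`
#'   (T/NT).
#' @return list with `sample_sheet` and the validated `design`
#'   ([paired_design()]).
#' @export
read_sample_sheet <- function(path) {
  ss <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "subject_id", "tissue")
  if (!all(need %in% names(ss))) {
    stop_helpdm("sample sheet must have columns: ",
                paste(need, collapse = ", "))
  }
  list(sample_sheet = ss, design = paired_design(ss))
}

#' Read a gene model table
#'
#' Tab-separated with header; requires `gene_id`, `chrom`, `strand`,
#' `tss`, `tes`. Coordinates are declared 1-based inclusive in the file
#' and converted to the package's 0-based convention on read
#' (`coords = "1-based"`), or taken as-is (`coords = "0-based"`).
#'
#' @param path file path.
#' @param coords coordinate convention of the file.
#' @return gene data.frame in 0-based coordinates.
#' @export
read_gene_table <- function(path, coords = c("1-based", "0-based")) {
  coords <- match.arg(coords)
  g <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "strand", "tss", "tes")
  if (!all(need %in% names(g))) {
    stop_helpdm("gene table must have columns: ", paste(need, collapse = ", "))
  }
  if (coords == "1-based") {
    g$tss <- g$tss - 1L
    g$tes <- g$tes - 1L
  }
  bad <- (g$strand == "+" & g$tss >= g$tes) |
    (g$strand == "-" & g$tss <= g$tes) |
    !g$strand %in% c("+", "-")
  if (any(bad)) {
    stop_helpdm("invalid gene rows (strand/tss/tes inconsistent): ",
                paste(head(g$gene_id[bad], 5), collapse = ", "))
  }
  g
}
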