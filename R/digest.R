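#' In-silico MspI digest of a nucleotide sequence
#'
#' Fragments a sequence at every `CCGG` site (cut between the first and
#' second base, `C^CGG`) and returns the fragments bounded by *two* cut
#' sites, i.e. the internal fragments whose both ends carry the
#' recognition motif. Terminal chromosome ends are never returned, matching
#' the assay's requirement that methylation be read at paired CCGG ends.
#' Only fragments whose length falls inside `size_range` are kept
#' (default 200-2000 bp, the assay's size selection window).
#'
#' @param sequence single character string over A/C/G/T/N (case
#'   insensitive).
#' @param size_range length-2 numeric, minimum and maximum retained
#'   fragment length in bp (`min >= 1`, `min <= max`).
#' @return data.frame with columns `start`, `end` (0-based half-open) and
#'   `length`, sorted by `start`.
#' @examples
#' msp_digest("AAACCGGTTTTCCGGAA", size_range = c(1, 2000))
#' @export
msp_digest <- function(sequence, size_range = c(200, 2000)) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  check_size_range(size_range)
  seq_up <- toupper(sequence)
  bad <- regexpr("[^ACGTN]", seq_up)
  if (bad != -1L) {
    stop_helpdm(sprintf("invalid character '%s' at position %d",
                        substr(sequence, bad, bad), as.integer(bad)))
  }
  # lookahead so overlapping motif placements are all seen
  hits <- gregexpr("(?=CCGG)", seq_up, perl = TRUE)[[1]]
  if (hits[1] == -1L) {
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0)))
  }
  # 1-based match position m => 0-based motif offset m-1 => cut at offset+1 = m
  cuts <- as.integer(hits)
  if (length(cuts) < 2L) {
    return(data.frame(start = integer(0), end = integer(0),
                      length = integer(0)))
  }
  start <- cuts[-length(cuts)]
  end <- cuts[-1]
  len <- end - start
  keep <- len >= size_range[1] & len <= size_range[2]
  data.frame(start = start[keep], end = end[keep], length = len[keep])
}

check_size_range <- function(size_range) {
  if (length(size_range) != 2L || any(!is.finite(size_range)) ||
      size_range[1] < 1 || size_range[1] > size_range[2]) {
    stop_helpdm("'size_range' must be c(min, max) with 1 <= min <= max")
  }
  invisible(size_range)
}

#' Digest a set of chromosome sequences into fragment loci
#'
#' Applies [msp_digest()] per chromosome and assembles a locus table with
#' stable, sorted locus identifiers.
#'
#' @param sequences named character vector (or `Biostrings::DNAStringSet`)
#'   of chromosome sequences.
#' @inheritParams msp_digest
#' @return data.frame with columns `locus_id`, `chrom`, `start`, `end`,
#'   `length`.
#' @export
digest_genome <- function(sequences, size_range = c(200, 2000)) {
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- setNames(as.character(sequences), names(sequences))
  }
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop_helpdm("'sequences' must be named by chromosome")
  }
  per_chrom <- lapply(names(sequences), function(chrom) {
    frags <- msp_digest(sequences[[chrom]], size_range)
    if (nrow(frags)) cbind(chrom = chrom, frags) else NULL
  })
  loci <- do.call(rbind, per_chrom)
  if (is.null(loci)) {
    loci <- data.frame(chrom = character(0), start = integer(0),
                       end = integer(0), length = integer(0))
  }
  loci <- loci[order(loci$chrom, loci$start), , drop = FALSE]
  data.frame(locus_id = sprintf("L%06d", seq_len(nrow(loci))), loci,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Digest chromosomes stored in a FASTA file
#'
#' @param fasta path to a FASTA file.
#' @inheritParams msp_digest
#' @return as [digest_genome()].
#' @export
digest_fasta <- function(fasta, size_range = c(200, 2000)) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  digest_genome(seqs, size_range)
}
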