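#' Read trimming rule
#'
#' Default trimming removes 4 bases from the 5' end (residual adapter) and
#' 1 base from the 3' end, truncating the standard 101-base read to 96
#' bases before alignment.
#'
#' @param trim5 Bases removed from the 5' end.
#' @param trim3 Bases removed from the 3' end.
#' @return An object of class `trim_rule`.
#' @export
trim_rule <- function(trim5 = 4L, trim3 = 1L) {
  if (trim5 < 0 || trim3 < 0) abort("trim lengths must be >= 0")
  structure(
    list(trim5 = as.integer(trim5), trim3 = as.integer(trim3)),
    class = "trim_rule"
  )
}

#' Trim reads
#'
#' Slices bases and qualities identically; the trimmed length is
#' `original - trim5 - trim3`.
#'
#' @param reads Read tibble.
#' @param rule A [trim_rule()].
#' @return The read tibble with trimmed `bases` and `quals`.
#' @export
trim_reads <- function(reads, rule = trim_rule()) {
  stopifnot(inherits(rule, "trim_rule"))
  len <- nchar(reads$bases)
  if (any(rule$trim5 + rule$trim3 >= len)) {
    abort("trim5 + trim3 must be smaller than every read length")
  }
  reads$bases <- substr(reads$bases, rule$trim5 + 1L, len - rule$trim3)
  reads$quals <- substr(reads$quals, rule$trim5 + 1L, len - rule$trim3)
  reads
}

#' Alignment parameters
#'
#' Seed-and-count parameters of the three-letter aligner: candidate loci
#' must have at most `seed_mismatch_max` mismatches in the read's first
#' `seed_len` bases and at most `total_mismatch_max` over the full read.
#' The seed length and seed mismatch defaults follow standard bisulfite
#' alignment practice for 100-base reads; the total cap of 3 mismatches per
#' read is this package's conservative choice that keeps random placements
#' out on small references.
#'
#' @param seed_len Seed length in bases.
#' @param seed_mismatch_max Maximum mismatches inside the seed.
#' @param total_mismatch_max Maximum mismatches over the whole read.
#' @return An object of class `align_params`.
#' @export
align_params <- function(seed_len = 28L, seed_mismatch_max = 1L,
                         total_mismatch_max = 3L) {
  if (seed_len < 1) abort("seed_len must be >= 1")
  if (seed_mismatch_max < 0 || total_mismatch_max < 0) {
    abort("mismatch limits must be >= 0")
  }
  structure(
    list(
      seed_len = as.integer(seed_len),
      seed_mismatch_max = as.integer(seed_mismatch_max),
      total_mismatch_max = as.integer(total_mismatch_max)
    ),
    class = "align_params"
  )
}

# reduction code of a read: GA for the mate that carries 5mC as G
# (PBAT R1 / MethylC R2), CT for the converted-strand mate
read_reduction <- function(protocol, mate) {
  ifelse((protocol == "PBAT") == (mate == "R1"), "GA", "CT")
}

#' Align bisulfite reads to a small reference
#'
#' A desk-scale three-letter aligner. Each read is reduced according to its
#' chemistry (G->A for the mate that reads 5mC as G, C->T for the
#' converted-strand mate) and scanned against the matching reduced reference
#' views in both orientations. Candidate loci must satisfy the seed and
#' total mismatch limits of [align_params()]; a single strictly best locus
#' (fewest mismatches) gives status `unique`, tied best loci `ambiguous`,
#' and no admissible locus `unmapped`. Only unique alignments carry
#' coordinates. Candidate enumeration uses an exact pigeonhole seed index,
#' so results are identical to an exhaustive scan of every position.
#'
#' @param reads Read tibble (columns `id`, `mate`, `protocol`, `bases`).
#' @param genome Genome tibble.
#' @param params An [align_params()].
#' @return A tibble with columns `id`, `mate`, `status`, `chrom`, `pos`
#'   (0-based leftmost plus-strand coordinate), `view` (`"CT"` = plus-strand
#'   cytosines interrogated, `"GA"` = minus-strand), `orient` (`"fwd"` /
#'   `"rev"`) and `mismatches`.
#' @export
align_reads <- function(reads, genome, params = align_params()) {
  genome <- validate_genome(genome)
  stopifnot(inherits(params, "align_params"))
  if (nrow(reads) == 0) {
    return(tibble(
      id = character(), mate = character(), status = character(),
      chrom = character(), pos = integer(), view = character(),
      orient = character(), mismatches = integer()
    ))
  }
  if (any(nchar(reads$bases) < params$seed_len)) {
    abort("read shorter than seed_len")
  }
  red <- read_reduction(reads$protocol, reads$mate)
  res <- align_batch_cpp(
    reads$bases, red, genome$seq,
    params$seed_len, params$seed_mismatch_max, params$total_mismatch_max
  )
  tibble(
    id = reads$id,
    mate = reads$mate,
    status = as.character(res$status),
    chrom = genome$chrom[res$chrom_idx],
    pos = res$pos,
    view = as.character(res$view),
    orient = as.character(res$orient),
    mismatches = res$mismatches
  )
}

#' Alignment summary
#'
#' Counts per status plus mapped fraction (unique + ambiguous over all) and
#' unique fraction, the quantity used to report "uniquely mapped reads".
#'
#' @param alignments Output of [align_reads()].
#' @return A one-row tibble.
#' @export
alignment_summary <- function(alignments) {
  n <- nrow(alignments)
  n_unique <- sum(alignments$status == "unique")
  n_amb <- sum(alignments$status == "ambiguous")
  n_unmapped <- sum(alignments$status == "unmapped")
  tibble(
    n_reads = n, n_unique = n_unique, n_ambiguous = n_amb,
    n_unmapped = n_unmapped,
    mapped_fraction = if (n > 0) (n_unique + n_amb) / n else NA_real_,
    unique_fraction = if (n > 0) n_unique / n else NA_real_
  )
}

#' Write alignments as a minimal SAM file
#'
#' Emits header plus the mandatory fields; the mismatch count is carried in
#' the `NM` tag. Reverse-orientation unique alignments get FLAG 16 with
#' sequence and qualities written in reference orientation; non-unique reads
#' are written unmapped (FLAG 4).
#'
#' @param alignments Output of [align_reads()].
#' @param reads The read tibble that was aligned.
#' @param genome Genome tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, reads, genome, path) {
  genome <- validate_genome(genome)
  key <- paste(reads$id, reads$mate)
  akey <- paste(alignments$id, alignments$mate)
  m <- match(akey, key)
  if (anyNA(m)) abort("alignment refers to a read absent from `reads`")
  hdr <- c(
    "@HD\tVN:1.6\tSO:unknown",
    paste0("@SQ\tSN:", genome$chrom, "\tLN:", genome$length)
  )
  uniq <- alignments$status == "unique"
  rev <- uniq & alignments$orient == "rev"
  seq_out <- reads$bases[m]
  qual_out <- reads$quals[m]
  seq_out[rev] <- revcomp(seq_out[rev])
  qual_out[rev] <- strrev(qual_out[rev])
  flag <- ifelse(!uniq, 4L, ifelse(rev, 16L, 0L))
  lines <- paste(
    alignments$id, flag,
    ifelse(uniq, alignments$chrom, "*"),
    ifelse(uniq, alignments$pos + 1L, 0L),
    ifelse(uniq, 255L, 0L),
    ifelse(uniq, paste0(nchar(seq_out), "M"), "*"),
    "*", 0L, 0L, seq_out, qual_out,
    ifelse(uniq, paste0("NM:i:", alignments$mismatches), "NM:i:0"),
    sep = "\t"
  )
  writeLines(c(hdr, lines), path)
  invisible(path)
}
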