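#' Load a reference genome from a FASTA file
#'
#' Reads a (possibly multi-record, line-wrapped) FASTA file into the tabular
#' genome representation used throughout the package: one row per record with
#' its name and uppercased sequence. Only the unambiguous DNA alphabet plus
#' `N` is accepted.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `chrom` (record name), `seq` (uppercase DNA
#'   string) and `length` (sequence length in bases).
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTACGT"), fa)
#' load_fasta(fa)
load_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file does not exist: ", path))
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) {
    abort("FASTA file contains no records")
  }
  nm <- names(set)
  # drop FASTA description after first whitespace
  nm <- sub("\\s.*$", "", nm)
  if (any(!nzchar(nm))) abort("FASTA record with empty name")
  if (anyDuplicated(nm)) abort("duplicate FASTA record names")
  seqs <- toupper(as.character(set))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    abort(paste0(
      "record '", nm[which(bad)[1]],
      "' contains characters outside {A,C,G,T,N}"
    ))
  }
  new_genome(nm, seqs)
}

new_genome <- function(chrom, seq) {
  tibble(chrom = chrom, seq = unname(seq), length = nchar(seq))
}

validate_genome <- function(genome) {
  stopifnot(is.data.frame(genome), all(c("chrom", "seq") %in% names(genome)))
  if (!"length" %in% names(genome)) genome$length <- nchar(genome$seq)
  genome
}

#' Generate the default synthetic calibration genome
#'
#' Builds a GC-balanced random DNA sequence used as a stand-in for a
#' lambda-scale spike-in reference. The default length is 48,502 bp (the
#' length of the lambda phage genome) and the default seed is fixed, so the
#' same sequence is produced in every session without downloading any
#' accession. The sequence is synthetic: it reproduces lambda's length and an
#' approximately uniform base composition, not its actual sequence.
#'
#' @param length Sequence length in bases.
#' @param seed Integer seed controlling the sequence; the default gives the
#'   package's canonical calibration genome.
#' @param chrom Record name.
#' @return A genome tibble as returned by [load_fasta()].
#' @export
synthetic_genome <- function(length = 48502L, seed = 48502L, chrom = "lambda_synth") {
  stopifnot(length >= 1)
  seq <- withr::with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
  })
  new_genome(chrom, seq)
}

#' Construct a genome from explicit sequences
#'
#' Convenience constructor for tests and examples: takes a named character
#' vector of DNA sequences and returns the genome tibble.
#'
#' @param ... Named DNA sequences (or a single named character vector).
#' @return A genome tibble.
#' @export
genome_from_seq <- function(...) {
  seqs <- c(...)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    abort("all sequences must be named")
  }
  seqs <- toupper(seqs)
  if (any(grepl("[^ACGTN]", seqs))) abort("sequences restricted to {A,C,G,T,N}")
  new_genome(names(seqs), seqs)
}

#' Index every cytosine on both strands with its dinucleotide context
#'
#' Scans each record for cytosines on the plus strand (base `C`) and on the
#' minus strand (base `G` on the plus-strand coordinate system) and assigns
#' the dinucleotide context from the next base in the strand's own 5'->3'
#' direction: `CpG`, `CpA`, `CpT` or `CpC`. Cytosines whose neighbor is `N`
#' or absent (chromosome end) get context `unknown` and are excluded from all
#' methylation statistics downstream.
#'
#' @param genome A genome tibble.
#' @return A tibble with columns `chrom`, `pos` (0-based plus-strand
#'   coordinate of the cytosine), `strand` (`"+"` or `"-"`) and `context`,
#'   sorted by (chrom, pos, strand).
#' @export
index_cytosines <- function(genome) {
  genome <- validate_genome(genome)
  res <- purrr::map2(genome$chrom, genome$seq, function(chrom, seq) {
    ch <- strsplit(seq, "", fixed = TRUE)[[1]]
    L <- length(ch)
    if (L == 0) return(NULL)
    ip <- which(ch == "C")
    im <- which(ch == "G")
    nxt_p <- ifelse(ip < L, ch[pmin(ip + 1L, L)], NA_character_)
    nxt_m_plus <- ifelse(im > 1L, ch[pmax(im - 1L, 1L)], NA_character_)
    ctx_plus <- c(G = "CpG", A = "CpA", T = "CpT", C = "CpC")
    # next base on the minus strand is the complement of the plus base at pos-1
    ctx_minus <- c(C = "CpG", T = "CpA", A = "CpT", G = "CpC")
    cp <- unname(ctx_plus[nxt_p])
    cm <- unname(ctx_minus[nxt_m_plus])
    cp[is.na(cp)] <- "unknown"
    cm[is.na(cm)] <- "unknown"
    tibble(
      chrom = chrom,
      pos = c(ip, im) - 1L,
      strand = rep(c("+", "-"), c(length(ip), length(im))),
      context = c(cp, cm)
    )
  })
  out <- bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble(
      chrom = character(), pos = integer(),
      strand = character(), context = character()
    ))
  }
  out[order(match(out$chrom, genome$chrom), out$pos, out$strand), ] |>
    as_tibble()
}

#' Tile a genome into fixed-size non-overlapping windows
#'
#' Produces the non-overlapping window grid used for windowed methylation
#' statistics (100-kb windows) and PMD calling (10-kb windows). Only full
#' windows are kept: a trailing partial window is dropped so CpG counts are
#' comparable across windows.
#'
#' @param genome A genome tibble.
#' @param size Window size in bases (>= 1).
#' @return A tibble with columns `chrom`, `start`, `end` (0-based half-open),
#'   disjoint and sorted within each record.
#' @export
tile_windows <- function(genome, size) {
  genome <- validate_genome(genome)
  if (length(size) != 1 || is.na(size) || size < 1) {
    abort("window size must be a positive integer")
  }
  size <- as.integer(size)
  res <- purrr::map2(genome$chrom, genome$length, function(chrom, len) {
    k <- len %/% size
    if (k == 0) return(NULL)
    start <- (seq_len(k) - 1L) * size
    tibble(chrom = chrom, start = start, end = start + size)
  })
  out <- bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer()))
  }
  out
}

#' Write intervals as BED
#'
#' Writes windows or PMD intervals as 0-based half-open BED. If a `level`
#' column is present it is written in the score column scaled by 10 (so
#' 63.1% becomes 631), a convention that keeps one decimal of the percent
#' level inside BED's integer score.
#'
#' @param x A tibble with `chrom`, `start`, `end` and optionally `level`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  name <- if ("name" %in% names(x)) x$name else "."
  score <- if ("level" %in% names(x)) {
    ifelse(is.na(x$level), 0L, as.integer(round(x$level * 10)))
  } else {
    0L
  }
  df <- data.frame(x$chrom, x$start, x$end, name, score)
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

# reverse complement of a character vector of DNA strings
revcomp <- function(x) {
  if (length(x) == 0) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# plain string reversal (used for quality strings)
strrev <- function(x) {
  vapply(
    strsplit(x, "", fixed = TRUE),
    function(ch) paste(rev(ch), collapse = ""),
    character(1)
  )
}
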