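#' Write reads to FASTQ
#'
#' Writes standard 4-line FASTQ with Phred+33 qualities. For paired output,
#' give `path2`: R1 records go to `path`, R2 records to `path2`, in
#' synchronized order with matching ids; an id mismatch between the two
#' mate sets is an error.
#'
#' @param reads Read tibble (columns `id`, `bases`, `quals`, and `mate`
#'   when writing paired output).
#' @param path Output path (R1 for paired output).
#' @param path2 Optional R2 output path.
#' @return `path` (and `path2`), invisibly.
#' @export
write_fastq <- function(reads, path, path2 = NULL) {
  if (is.null(path2)) {
    write_fastq_one(reads, path)
    return(invisible(path))
  }
  r1 <- reads[reads$mate == "R1", ]
  r2 <- reads[reads$mate == "R2", ]
  r1 <- r1[order(r1$id), ]
  r2 <- r2[order(r2$id), ]
  if (nrow(r1) != nrow(r2) || !identical(r1$id, r2$id)) {
    abort("R1/R2 id sets do not match; cannot write synchronized pairs")
  }
  write_fastq_one(r1, path)
  write_fastq_one(r2, path2)
  invisible(c(path, path2))
}

write_fastq_one <- function(reads, path) {
  if (nrow(reads) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  stopifnot(all(nchar(reads$bases) == nchar(reads$quals)))
  lines <- as.vector(rbind(paste0("@", reads$id), reads$bases, "+", reads$quals))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into a read tibble
#'
#' Reads uncompressed 4-line FASTQ (Phred+33). The mate label is supplied by
#' the caller since plain FASTQ does not carry it.
#'
#' @param path FASTQ file path.
#' @param mate Mate label to assign (`"R1"` default).
#' @param protocol Protocol label to assign.
#' @return A read tibble with columns `id`, `mate`, `protocol`, `bases`,
#'   `quals`.
#' @export
read_fastq <- function(path, mate = "R1", protocol = "PBAT") {
  if (!file.exists(path)) abort(paste0("FASTQ file does not exist: ", path))
  lines <- readLines(path)
  if (length(lines) %% 4 != 0) abort("truncated FASTQ (line count not a multiple of 4)")
  if (length(lines) == 0) {
    return(tibble(
      id = character(), mate = character(), protocol = character(),
      bases = character(), quals = character()
    ))
  }
  hdr <- lines[seq(1, length(lines), by = 4)]
  if (any(substr(hdr, 1, 1) != "@")) abort("malformed FASTQ header line")
  tibble(
    id = sub("\\s.*$", "", substring(hdr, 2)),
    mate = mate, protocol = protocol,
    bases = lines[seq(2, length(lines), by = 4)],
    quals = lines[seq(4, length(lines), by = 4)]
  )
}

# Phred+33 helpers
qual_to_int <- function(q) lapply(q, function(s) utf8ToInt(s) - 33L)
int_to_qual <- function(x) vapply(x, function(v) intToUtf8(v + 33L), character(1))
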