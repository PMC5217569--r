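#' Alignments from simulation truth
#'
#' Builds an alignment tibble directly from the truth provenance carried by
#' simulated reads, bypassing the aligner. Useful for closed-form checks of
#' the methylation estimator where alignment is not the quantity under
#' study.
#'
#' @param reads Simulated read tibble with `truth_*` columns.
#' @return An alignment tibble compatible with [extract_calls()].
#' @export
truth_alignments <- function(reads) {
  stopifnot(all(c("truth_chrom", "truth_pos", "truth_view", "truth_orient") %in% names(reads)))
  tibble(
    id = reads$id, mate = reads$mate, status = "unique",
    chrom = reads$truth_chrom, pos = reads$truth_pos,
    view = reads$truth_view, orient = reads$truth_orient,
    mismatches = 0L
  )
}

#' Extract per-cytosine methylation calls from alignments
#'
#' At every indexed cytosine covered by a uniquely aligned read, the read
#' base (in reference orientation) is interpreted in the alignment's view:
#' where the read carries the converted strand (view `"CT"`, plus-strand
#' cytosines), C is a methylated call and T unmethylated; on the
#' complementary view (`"GA"`, minus-strand cytosines), G is methylated and
#' A unmethylated. Any other base gives no call and is dropped — a mismatch
#' at a cytosine is not evidence of unmethylation. Counts accumulate into
#' the read's mate stratum.
#'
#' @param alignments Alignment tibble ([align_reads()] or
#'   [truth_alignments()]); only `status == "unique"` rows are used.
#' @param reads The read tibble the alignments refer to (post-trimming when
#'   the aligner was run on trimmed reads).
#' @param index Cytosine index of the same genome.
#' @return A call table: one row per cytosine with at least one call, with
#'   columns `chrom`, `pos`, `strand`, `context`, `meth_r1`, `unmeth_r1`,
#'   `meth_r2`, `unmeth_r2`.
#' @export
extract_calls <- function(alignments, reads, index) {
  aln <- alignments[alignments$status == "unique", ]
  empty <- tibble(
    chrom = character(), pos = integer(), strand = character(),
    context = character(), meth_r1 = integer(), unmeth_r1 = integer(),
    meth_r2 = integer(), unmeth_r2 = integer()
  )
  if (nrow(aln) == 0) return(empty)
  key <- paste(reads$id, reads$mate)
  m <- match(paste(aln$id, aln$mate), key)
  if (anyNA(m)) abort("alignment refers to a read absent from `reads`")
  if (!all(aln$chrom %in% unique(index$chrom))) {
    abort("alignment refers to a chromosome absent from the cytosine index")
  }
  oriented <- reads$bases[m]
  rev <- aln$orient == "rev"
  oriented[rev] <- revcomp(oriented[rev])
  L <- nchar(oriented)

  pieces <- list()
  for (cname in unique(aln$chrom)) {
    for (v in c("CT", "GA")) {
      sel <- which(aln$chrom == cname & aln$view == v)
      if (length(sel) == 0) next
      st <- if (v == "CT") "+" else "-"
      cyt <- index[index$chrom == cname & index$strand == st, ]
      if (nrow(cyt) == 0) next
      P <- cyt$pos
      lo <- findInterval(aln$pos[sel] - 0.5, P) + 1L
      hi <- findInterval(aln$pos[sel] + L[sel] - 0.5, P)
      nsites <- pmax(0L, hi - lo + 1L)
      if (sum(nsites) == 0) next
      aid <- rep(sel, nsites)
      sidx <- sequence(nsites, from = lo[nsites > 0L])
      off <- P[sidx] - aln$pos[aid] + 1L
      base <- substring(oriented[aid], off, off)
      call <- if (v == "CT") {
        ifelse(base == "C", "meth", ifelse(base == "T", "unmeth", NA))
      } else {
        ifelse(base == "G", "meth", ifelse(base == "A", "unmeth", NA))
      }
      keep <- !is.na(call)
      if (!any(keep)) next
      pieces[[length(pieces) + 1]] <- tibble(
        chrom = cname, pos = P[sidx][keep], strand = st,
        mate = aln$mate[aid][keep], call = call[keep]
      )
    }
  }
  if (length(pieces) == 0) return(empty)
  calls <- bind_rows(pieces)
  counts <- calls |>
    dplyr::count(.data$chrom, .data$pos, .data$strand, .data$mate, .data$call) |>
    tidyr::pivot_wider(
      names_from = c("call", "mate"),
      values_from = "n", values_fill = 0L,
      names_glue = "{call}_{tolower(mate)}"
    )
  for (col in c("meth_r1", "unmeth_r1", "meth_r2", "unmeth_r2")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  out <- counts |>
    left_join(
      index[, c("chrom", "pos", "strand", "context")],
      by = c("chrom", "pos", "strand")
    ) |>
    select(
      "chrom", "pos", "strand", "context",
      "meth_r1", "unmeth_r1", "meth_r2", "unmeth_r2"
    ) |>
    arrange(match(.data$chrom, unique(index$chrom)), .data$pos, .data$strand)
  out
}

#' Depth-weighted methylation level
#'
#' The weighted level is the ratio of methylated calls to total calls pooled
#' over the selected cytosines, times 100 — each call contributes equally,
#' so deeply covered sites weigh more than shallow ones (this is not the
#' mean of per-site levels). Selection can be restricted by context, mate
#' stratum and genomic region.
#'
#' @param table Call table from [extract_calls()].
#' @param contexts Character vector of contexts to include (default
#'   `"CpG"`); `"unknown"` rows are never included unless named explicitly.
#' @param mates Mate strata to pool, subset of `c("R1", "R2")`.
#' @param region Optional one-row tibble/list with `chrom`, `start`, `end`
#'   (0-based half-open) restricting the selection.
#' @return The level in percent (scalar). Zero total calls in the selection
#'   is an error, not 0.
#' @export
weighted_level <- function(table, contexts = "CpG", mates = c("R1", "R2"),
                           region = NULL) {
  sel <- table$context %in% contexts
  if (!is.null(region)) {
    sel <- sel & table$chrom == region$chrom &
      table$pos >= region$start & table$pos < region$end
  }
  meth <- unmeth <- 0
  if ("R1" %in% mates) {
    meth <- meth + sum(table$meth_r1[sel])
    unmeth <- unmeth + sum(table$unmeth_r1[sel])
  }
  if ("R2" %in% mates) {
    meth <- meth + sum(table$meth_r2[sel])
    unmeth <- unmeth + sum(table$unmeth_r2[sel])
  }
  if (meth + unmeth == 0) {
    abort("weighted level undefined: zero calls in the selection")
  }
  100 * meth / (meth + unmeth)
}

weighted_level_or_na <- function(...) {
  tryCatch(weighted_level(...), error = function(e) NA_real_)
}

#' Merge two call tables
#'
#' Sums the per-cytosine, per-stratum counts of two call tables over the
#' union of their cytosines.
#'
#' @param a,b Call tables.
#' @return A merged call table.
#' @export
merge_call_tables <- function(a, b) {
  cols <- c("meth_r1", "unmeth_r1", "meth_r2", "unmeth_r2")
  bind_rows(a, b) |>
    group_by(.data$chrom, .data$pos, .data$strand, .data$context) |>
    summarise(across(dplyr::all_of(cols), sum), .groups = "drop") |>
    arrange(.data$chrom, .data$pos, .data$strand)
}

#' Global level report
#'
#' Summarises a call table the way runs are compared: global weighted CpG
#' level (pooled and per mate), the R1 minus R2 gap in percentage points,
#' non-CpG levels (pooled and per context) as a conversion/artifact sanity
#' check, and — when the reads are supplied — the G fraction among called
#' bases in R1, the base-composition signature of the G undercall.
#' Strata with zero calls are reported as `NA`.
#'
#' @param table Call table.
#' @param reads Optional read tibble used for `g_fraction_r1`.
#' @return A one-row tibble with columns `cpg_all`, `cpg_r1`, `cpg_r2`,
#'   `r1_r2_gap`, `noncpg_all`, `cpa`, `cpt`, `cpc`, `g_fraction_r1`.
#' @export
level_report <- function(table, reads = NULL) {
  if (nrow(table) == 0) abort("empty call table")
  noncpg <- c("CpA", "CpT", "CpC")
  r1 <- weighted_level_or_na(table, mates = "R1")
  r2 <- weighted_level_or_na(table, mates = "R2")
  g_frac <- NA_real_
  if (!is.null(reads)) {
    b <- paste(reads$bases[reads$mate == "R1"], collapse = "")
    counts <- table(strsplit(b, "", fixed = TRUE)[[1]])
    acgt <- sum(counts[names(counts) %in% c("A", "C", "G", "T")])
    g_frac <- if (acgt > 0) unname(counts["G"] %||% 0) / acgt else NA_real_
    if (is.na(g_frac)) g_frac <- 0
  }
  tibble(
    cpg_all = weighted_level_or_na(table),
    cpg_r1 = r1,
    cpg_r2 = r2,
    r1_r2_gap = r1 - r2,
    noncpg_all = weighted_level_or_na(table, contexts = noncpg),
    cpa = weighted_level_or_na(table, contexts = "CpA"),
    cpt = weighted_level_or_na(table, contexts = "CpT"),
    cpc = weighted_level_or_na(table, contexts = "CpC"),
    g_fraction_r1 = g_frac
  )
}

#' Write a per-cytosine report
#'
#' Tab-separated cytosine report: chromosome, 1-based position, strand,
#' methylated count, unmethylated count, context — counts pooled over
#' mates.
#'
#' @param table Call table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(table, path) {
  df <- tibble(
    chrom = table$chrom, pos = table$pos + 1L, strand = table$strand,
    meth = table$meth_r1 + table$meth_r2,
    unmeth = table$unmeth_r1 + table$unmeth_r2,
    context = table$context
  )
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write per-cytosine levels as bedGraph
#'
#' One line per cytosine with at least one call: chrom, 0-based start,
#' end, weighted level in percent (mates pooled).
#'
#' @param table Call table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(table, path) {
  meth <- table$meth_r1 + table$meth_r2
  tot <- meth + table$unmeth_r1 + table$unmeth_r2
  keep <- tot > 0
  df <- tibble(
    chrom = table$chrom[keep], start = table$pos[keep],
    end = table$pos[keep] + 1L,
    level = round(100 * meth[keep] / tot[keep], 4)
  )
  writeLines(
    c(
      "track type=bedGraph",
      paste(df$chrom, df$start, df$end, df$level, sep = "\t")
    ),
    path
  )
  invisible(path)
}
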