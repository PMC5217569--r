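#' Per-cycle base composition
#'
#' Fractions of A/C/G/T per sequencing cycle over the four called bases
#' (N is excluded from the four-base normalization but reported as its own
#' fraction of all bases at the cycle). Ragged read lengths are allowed;
#' per-cycle denominators adjust. The overall per-base composition is
#' attached as attribute `"overall"`.
#'
#' A depressed G fraction in the mate that reads 5mC as G is the
#' base-composition signature of the G-undercall artifact.
#'
#' @param reads Read tibble (optionally pre-filtered to one mate).
#' @return A tibble with columns `cycle`, `base`, `count`, `fraction`.
#' @export
base_composition <- function(reads) {
  if (nrow(reads) == 0) abort("empty read set")
  L <- nchar(reads$bases)
  maxL <- max(L)
  cyc <- sequence(L)
  base <- unlist(strsplit(reads$bases, "", fixed = TRUE), use.names = FALSE)
  code <- match(base, c("A", "C", "G", "T", "N"))
  if (anyNA(code)) abort("reads contain bases outside {A,C,G,T,N}")
  tab <- tabulate(cyc + (code - 1L) * maxL, nbins = 5L * maxL)
  counts <- matrix(tab, nrow = maxL, ncol = 5)
  colnames(counts) <- c("A", "C", "G", "T", "N")
  denom4 <- rowSums(counts[, 1:4, drop = FALSE])
  denom_all <- rowSums(counts)
  frac <- counts[, 1:4, drop = FALSE] / ifelse(denom4 > 0, denom4, NA)
  nfrac <- counts[, 5] / ifelse(denom_all > 0, denom_all, NA)
  out <- tibble(
    cycle = rep(seq_len(maxL), 5),
    base = rep(c("A", "C", "G", "T", "N"), each = maxL),
    count = as.integer(counts),
    fraction = c(as.numeric(frac), nfrac)
  )
  tot <- colSums(counts)
  overall <- tibble(
    base = c("A", "C", "G", "T", "N"),
    count = as.integer(tot),
    fraction = c(tot[1:4] / sum(tot[1:4]), tot[5] / sum(tot))
  )
  attr(out, "overall") <- overall
  out
}

#' Quality-score classes for one base identity
#'
#' Groups every call of the given base into the four Phred classes
#' [0,10), [10,20), [20,30), [30,Inf) and reports the fraction with
#' quality at least 30 (Q30, 99.9% call accuracy).
#'
#' @param reads Read tibble.
#' @param base Base identity to profile (e.g. `"G"`).
#' @return A tibble with columns `base`, `class`, `count`, `fraction` and
#'   `q30_fraction` (constant across rows).
#' @export
quality_classes <- function(reads, base = "G") {
  if (nrow(reads) == 0) abort("empty read set")
  b <- unlist(strsplit(reads$bases, "", fixed = TRUE), use.names = FALSE)
  q <- utf8ToInt(paste(reads$quals, collapse = "")) - 33L
  sel <- b == base
  qs <- q[sel]
  cls <- findInterval(qs, c(10, 20, 30)) + 1L
  counts <- tabulate(cls, nbins = 4L)
  total <- sum(counts)
  tibble(
    base = base,
    class = c("[0,10)", "[10,20)", "[20,30)", "[30,Inf)"),
    count = counts,
    fraction = if (total > 0) counts / total else rep(NA_real_, 4),
    q30_fraction = if (total > 0) sum(qs >= 30) / total else NA_real_
  )
}

#' Detect steep quality drops within one read
#'
#' A steep drop is an adjacent-cycle decrease in quality greater than
#' `threshold` Phred points: position `i` (1-based, `i >= 2`) is reported
#' iff `qual[i-1] - qual[i] > threshold`. The alternative
#' `method = "running_max"` compares each position against the running
#' maximum of the preceding cycles instead, which also catches slow
#' two-step collapses.
#'
#' @param read One-row read tibble (or any list with `bases` and `quals`).
#' @param threshold Drop threshold in Phred points (default 10; a drop must
#'   exceed it strictly).
#' @param method `"adjacent"` (default) or `"running_max"`.
#' @return A tibble with columns `position` (1-based), `base`, `magnitude`.
#' @export
detect_drops <- function(read, threshold = 10, method = c("adjacent", "running_max")) {
  method <- match.arg(method)
  q <- utf8ToInt(read$quals[[1]]) - 33L
  b <- strsplit(read$bases[[1]], "", fixed = TRUE)[[1]]
  if (length(q) < 2) {
    return(tibble(position = integer(), base = character(), magnitude = integer()))
  }
  ref <- if (method == "adjacent") q[-length(q)] else cummax(q)[-length(q)]
  mag <- ref - q[-1]
  hit <- which(mag > threshold) + 1L
  tibble(position = hit, base = b[hit], magnitude = mag[hit - 1L])
}

#' Fraction of G-containing reads with a steep drop at a G
#'
#' Among reads containing at least one G, the fraction having at least one
#' steep quality drop (see [detect_drops()]) whose position carries a G.
#' This is the read-level statistic that flags the G-undercall artifact's
#' quality signature.
#'
#' @param reads Read tibble.
#' @param threshold Drop threshold in Phred points.
#' @param method Drop definition, as in [detect_drops()].
#' @return A proportion between 0 and 1. No G-containing read is an error.
#' @export
g_drop_fraction <- function(reads, threshold = 10, method = "adjacent") {
  has_g <- grepl("G", reads$bases, fixed = TRUE)
  if (!any(has_g)) abort("no read contains a G; fraction undefined")
  idx <- which(has_g)
  hit <- vapply(idx, function(i) {
    d <- detect_drops(reads[i, ], threshold = threshold, method = method)
    any(d$base == "G")
  }, logical(1))
  mean(hit)
}

#' Read-level QC report
#'
#' Mate-stratified summary: overall base composition, per-base Q30
#' fractions, mean quality, and the steep-drop-at-G statistic (NA when the
#' mate has no G-containing reads).
#'
#' @param reads Read tibble.
#' @param threshold Drop threshold passed to [g_drop_fraction()].
#' @return A tibble with one row per (mate, base) for composition plus
#'   attributes; see also [base_composition()] and [quality_classes()].
#' @export
qc_report <- function(reads, threshold = 10) {
  purrr::map(unique(reads$mate), function(mt) {
    r <- reads[reads$mate == mt, ]
    comp <- attr(base_composition(r), "overall")
    q30 <- vapply(c("A", "C", "G", "T"), function(b) {
      quality_classes(r, b)$q30_fraction[1]
    }, numeric(1))
    q <- utf8ToInt(paste(r$quals, collapse = "")) - 33L
    gdrop <- tryCatch(
      g_drop_fraction(r, threshold = threshold),
      error = function(e) NA_real_
    )
    tibble(
      mate = mt, base = comp$base, composition = comp$fraction,
      q30_fraction = c(q30, NA)[match(comp$base, c("A", "C", "G", "T", "N"))],
      mean_quality = mean(q),
      g_drop_fraction = gdrop
    )
  }) |> bind_rows()
}
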