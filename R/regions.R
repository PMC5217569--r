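#' Windowed CpG methylation statistics
#'
#' For each window of a tiling, counts CpG cytosines (from the index), CpG
#' cytosines with at least one call, and the depth-weighted CpG level
#' restricted to the window. Windows with zero calls get `level = NA`
#' (undefined, never zero).
#'
#' @param table Call table from [extract_calls()].
#' @param windows Window tibble from [tile_windows()].
#' @param index Cytosine index of the same genome.
#' @param mates Mate strata to pool.
#' @return The window tibble with added `n_cpg`, `n_covered`, `level`.
#' @export
window_levels <- function(table, windows, index, mates = c("R1", "R2")) {
  out <- windows
  out$n_cpg <- 0L
  out$n_covered <- 0L
  out$level <- NA_real_
  meth <- rep(0, nrow(table))
  tot <- rep(0, nrow(table))
  if ("R1" %in% mates) {
    meth <- meth + table$meth_r1
    tot <- tot + table$meth_r1 + table$unmeth_r1
  }
  if ("R2" %in% mates) {
    meth <- meth + table$meth_r2
    tot <- tot + table$meth_r2 + table$unmeth_r2
  }
  for (cname in unique(windows$chrom)) {
    wsel <- which(out$chrom == cname)
    icpg <- index[index$chrom == cname & index$context == "CpG", ]
    tsel <- which(table$chrom == cname & table$context == "CpG" & tot > 0)
    tpos <- table$pos[tsel]
    ord <- order(tpos)
    tpos <- tpos[ord]
    cm <- cumsum(meth[tsel][ord])
    ct <- cumsum(tot[tsel][ord])
    # index and per-window lookups via sorted-position prefix sums
    ipos <- sort(icpg$pos)
    s <- out$start[wsel]
    e <- out$end[wsel]
    out$n_cpg[wsel] <- findInterval(e - 0.5, ipos) - findInterval(s - 0.5, ipos)
    lo <- findInterval(s - 0.5, tpos)
    hi <- findInterval(e - 0.5, tpos)
    out$n_covered[wsel] <- hi - lo
    wm <- ifelse(hi > 0, cm[pmax(hi, 1)], 0) - ifelse(lo > 0, cm[pmax(lo, 1)], 0)
    wt <- ifelse(hi > 0, ct[pmax(hi, 1)], 0) - ifelse(lo > 0, ct[pmax(lo, 1)], 0)
    out$level[wsel] <- ifelse(wt > 0, 100 * wm / wt, NA_real_)
  }
  out
}

#' Assign windows to CpG-density classes
#'
#' Groups windows into `k` classes by their CpG count using equal-count
#' (quantile) boundaries. Tied counts fall into the same class, so heavily
#' tied inputs can occupy fewer than `k` classes.
#'
#' @param stats Window statistics from [window_levels()] (needs `n_cpg`).
#' @param k Number of classes (default 9).
#' @return `stats` with an added integer `density_class` column (1 =
#'   CpG-poorest).
#' @export
density_classes <- function(stats, k = 9) {
  if (k < 1) abort("k must be >= 1")
  x <- stats$n_cpg
  if (sum(!is.na(x)) < k) abort("need at least k windows with defined n_cpg")
  br <- unique(quantile(x, probs = seq(0, 1, length.out = k + 1), na.rm = TRUE))
  cls <- if (length(br) < 2) {
    rep(1L, length(x))
  } else {
    as.integer(cut(x, breaks = br, include.lowest = TRUE))
  }
  stats$density_class <- cls
  stats
}

#' Compare two runs window by window
#'
#' Joins two sets of window statistics on the window grid, computes the
#' per-window level difference (A minus B), fits the ordinary least-squares
#' regression of run A's levels on run B's, and — when CpG counts are
#' available — summarises the difference per CpG-density class.
#'
#' @param stats_a,stats_b Window statistics of the two runs over the same
#'   tiling.
#' @param k Number of density classes for the stratified summary.
#' @return An object of class `run_comparison`: list with `windows`
#'   (per-window tibble incl. `delta`), `fit` (the `lm` object),
#'   `by_class` (mean delta per density class) and `n`.
#' @export
compare_runs <- function(stats_a, stats_b, k = 9) {
  j <- inner_join(
    stats_a, stats_b,
    by = c("chrom", "start", "end"), suffix = c("_a", "_b")
  )
  j <- j[!is.na(j$level_a) & !is.na(j$level_b), ]
  if (nrow(j) == 0) abort("no windows with defined levels in both runs")
  j$delta <- j$level_a - j$level_b
  fit <- lm(level_a ~ level_b, data = j)
  by_class <- NULL
  if ("n_cpg_a" %in% names(j) && nrow(j) >= k) {
    jc <- j
    jc$n_cpg <- jc$n_cpg_a
    jc <- density_classes(jc, k = k)
    by_class <- jc |>
      group_by(.data$density_class) |>
      summarise(
        n = n(), mean_delta = mean(.data$delta),
        mean_n_cpg = mean(.data$n_cpg), .groups = "drop"
      )
  }
  structure(
    list(windows = as_tibble(j), fit = fit, by_class = by_class, n = nrow(j)),
    class = "run_comparison"
  )
}

#' @export
print.run_comparison <- function(x, ...) {
  g <- glance(x)
  cat("<run_comparison>", x$n, "windows\n")
  cat(sprintf(
    "  slope %.4f  intercept %.4f  r %.4f  mean delta %.4f\n",
    g$slope, g$intercept, g$correlation, g$mean_delta
  ))
  invisible(x)
}

#' Tidy a run comparison
#'
#' Broom-style coefficient table of the window-level OLS regression of run
#' A on run B.
#'
#' @param x A `run_comparison`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std.error`,
#'   `statistic`, `p.value`.
#' @method tidy run_comparison
#' @export
tidy.run_comparison <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = rownames(s),
    estimate = unname(s[, 1]), std.error = unname(s[, 2]),
    statistic = unname(s[, 3]), p.value = unname(s[, 4])
  )
}

#' Glance at a run comparison
#'
#' @param x A `run_comparison`.
#' @param ... Unused.
#' @return A one-row tibble: `slope`, `intercept`, `correlation`,
#'   `r.squared`, `mean_delta`, `n`.
#' @method glance run_comparison
#' @export
glance.run_comparison <- function(x, ...) {
  cf <- coef(x$fit)
  tibble(
    slope = unname(cf[2]), intercept = unname(cf[1]),
    correlation = cor(x$windows$level_a, x$windows$level_b),
    r.squared = summary(x$fit)$r.squared,
    mean_delta = mean(x$windows$delta),
    n = x$n
  )
}

#' Call partially methylated domains
#'
#' Sliding-window PMD calling: the genome is tiled into 10-kb
#' non-overlapping windows; a window is eligible when it has at least ten
#' CpG sites each covered at least once; an eligible window whose weighted
#' CpG level is below 70% is a PMD window; maximal runs of contiguous PMD
#' windows are collapsed into candidate domains (an ineligible window
#' breaks contiguity); only candidates longer than 100 kb (strictly) are
#' returned.
#'
#' @param table Call table.
#' @param genome Genome tibble.
#' @param index Cytosine index (computed from `genome` if omitted).
#' @param window_size Window size in bases (default 10,000).
#' @param min_cpg Minimum covered CpG sites for eligibility (default 10).
#' @param max_level PMD level threshold in percent (default 70, strict).
#' @param min_length Minimum domain length in bases (default 100,000,
#'   strict).
#' @return A tibble with columns `chrom`, `start`, `end`, `length`,
#'   `n_windows`, `mean_level` (pooled weighted level of the domain).
#' @export
call_pmds <- function(table, genome, index = NULL,
                      window_size = 10000L, min_cpg = 10L,
                      max_level = 70, min_length = 100000L) {
  genome <- validate_genome(genome)
  index <- index %||% index_cytosines(genome)
  windows <- tile_windows(genome, window_size)
  empty <- tibble(
    chrom = character(), start = integer(), end = integer(),
    length = integer(), n_windows = integer(), mean_level = numeric()
  )
  if (nrow(windows) == 0) return(empty)
  stats <- window_levels(table, windows, index)
  is_pmd <- stats$n_covered >= min_cpg & !is.na(stats$level) &
    stats$level < max_level
  if (!any(is_pmd)) return(empty)
  # runs of genomically adjacent PMD windows; any intervening window
  # (ineligible or above threshold) breaks contiguity
  p <- stats[is_pmd, ]
  adjacent <- p$chrom[-1] == p$chrom[-nrow(p)] & p$start[-1] == p$end[-nrow(p)]
  run_id <- cumsum(c(TRUE, !adjacent))
  cand <- tibble(
    chrom = p$chrom, start = p$start, end = p$end, run = run_id
  ) |>
    group_by(.data$run) |>
    summarise(
      chrom = dplyr::first(.data$chrom),
      start = min(.data$start), end = max(.data$end),
      n_windows = n(), .groups = "drop"
    )
  cand$length <- cand$end - cand$start
  cand <- cand[cand$length > min_length, ]
  if (nrow(cand) == 0) return(empty)
  cand$mean_level <- vapply(seq_len(nrow(cand)), function(i) {
    weighted_level(table, region = cand[i, ])
  }, numeric(1))
  cand[order(match(cand$chrom, genome$chrom), cand$start),
       c("chrom", "start", "end", "length", "n_windows", "mean_level")]
}

#' Calibrate a spike-in mixture series
#'
#' For a series of runs with known predetermined methylation levels (the
#' spike-in mixture proportions), computes the observed weighted CpG level
#' per mate stratum and the observed-minus-predetermined differences, plus
#' the R1 minus R2 gap — the quantities that expose a mate-specific
#' base-calling bias.
#'
#' @param runs A list; each element a list with `predetermined` (percent)
#'   and `table` (call table).
#' @return A tibble with one row per run: `predetermined`, `observed_all`,
#'   `observed_r1`, `observed_r2`, `diff_r1`, `diff_r2`, `r1_r2_gap`.
#' @export
calibrate_mixtures <- function(runs) {
  if (length(runs) == 0) abort("need at least one run")
  purrr::map(runs, function(r) {
    o_r1 <- weighted_level(r$table, mates = "R1")
    o_r2 <- weighted_level(r$table, mates = "R2")
    tibble(
      predetermined = r$predetermined,
      observed_all = weighted_level(r$table),
      observed_r1 = o_r1, observed_r2 = o_r2,
      diff_r1 = o_r1 - r$predetermined,
      diff_r2 = o_r2 - r$predetermined,
      r1_r2_gap = o_r1 - o_r2
    )
  }) |> bind_rows()
}
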