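# Independent brute-force oracles used to validate the implementation.
# These deliberately re-derive results from first principles with simple
# loops; they never call the code paths they check.

# two-strand scan for cytosines and contexts
oracle_index_cytosines <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  rows <- list()
  for (i in seq_along(ch)) {
    if (ch[i] == "C") {
      nxt <- if (i < length(ch)) ch[i + 1] else "N"
      ctx <- switch(nxt, G = "CpG", A = "CpA", T = "CpT", C = "CpC", "unknown")
      rows[[length(rows) + 1]] <- list(pos = i - 1L, strand = "+", context = ctx)
    }
    if (ch[i] == "G") {
      nxt <- if (i > 1) comp[[ch[i - 1]]] else "N"
      ctx <- switch(nxt, G = "CpG", A = "CpA", T = "CpT", C = "CpC", "unknown")
      rows[[length(rows) + 1]] <- list(pos = i - 1L, strand = "-", context = ctx)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) return(out)
  out[order(out$pos, out$strand), ]
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# exhaustive all-positions, all-views three-letter alignment scorer
oracle_align <- function(read, reduction, genome, seed_len, seed_mm_max, total_mm_max) {
  reduce <- function(s, ct) {
    if (ct) gsub("C", "T", s, fixed = TRUE) else gsub("G", "A", s, fixed = TRUE)
  }
  L <- nchar(read)
  hits <- list()
  for (combo in 1:2) {
    fwd <- combo == 1
    vct <- if (fwd) reduction == "CT" else reduction != "CT"
    oriented <- reduce(if (fwd) read else oracle_revcomp(read), vct)
    oc <- strsplit(oriented, "")[[1]]
    seed_start <- if (fwd) 0L else L - seed_len
    seed_idx <- seq(seed_start + 1L, seed_start + seed_len)
    for (ci in seq_len(nrow(genome))) {
      ref <- reduce(genome$seq[ci], vct)
      rc <- strsplit(ref, "")[[1]]
      if (length(rc) < L) next
      for (start in 0:(length(rc) - L)) {
        seg <- rc[(start + 1):(start + L)]
        mism <- oc != seg | oc == "N"
        if (sum(mism) > total_mm_max) next
        if (sum(mism[seed_idx]) > seed_mm_max) next
        hits[[length(hits) + 1]] <- list(
          chrom = genome$chrom[ci], pos = start, mism = sum(mism),
          view = if (vct) "CT" else "GA", orient = if (fwd) "fwd" else "rev"
        )
      }
    }
  }
  if (length(hits) == 0) {
    return(list(status = "unmapped", chrom = NA, pos = NA, mismatches = NA))
  }
  h <- dplyr::bind_rows(hits)
  best <- min(h$mism)
  hb <- h[h$mism == best, ]
  hb <- hb[!duplicated(hb[, c("chrom", "pos")]), ]
  if (nrow(hb) > 1) {
    return(list(status = "ambiguous", chrom = NA, pos = NA, mismatches = best))
  }
  list(
    status = "unique", chrom = hb$chrom[1], pos = hb$pos[1],
    mismatches = hb$mism[1], view = hb$view[1], orient = hb$orient[1]
  )
}

# one-pass pooled-ratio methylation level from a long call list
oracle_weighted_level <- function(meth, unmeth) {
  100 * sum(meth) / (sum(meth) + sum(unmeth))
}

# brute-force sliding-window PMD scan over a call table
oracle_pmds <- function(table, chrom_len, chrom = unique(table$chrom),
                        window_size = 10000, min_cpg = 10,
                        max_level = 70, min_length = 100000) {
  n_win <- chrom_len %/% window_size
  is_pmd <- logical(n_win)
  for (w in seq_len(n_win)) {
    s <- (w - 1) * window_size
    e <- s + window_size
    rows <- table[table$pos >= s & table$pos < e & table$context == "CpG", ]
    tot <- rows$meth_r1 + rows$unmeth_r1 + rows$meth_r2 + rows$unmeth_r2
    covered <- sum(tot > 0)
    if (covered < min_cpg) next
    lvl <- 100 * sum(rows$meth_r1 + rows$meth_r2) / sum(tot)
    is_pmd[w] <- lvl < max_level
  }
  out <- list()
  w <- 1
  while (w <= n_win) {
    if (is_pmd[w]) {
      w2 <- w
      while (w2 < n_win && is_pmd[w2 + 1]) w2 <- w2 + 1
      len <- (w2 - w + 1) * window_size
      if (len > min_length) {
        out[[length(out) + 1]] <- list(
          chrom = chrom, start = (w - 1) * window_size,
          end = w2 * window_size, length = len
        )
      }
      w <- w2 + 1
    } else {
      w <- w + 1
    }
  }
  dplyr::bind_rows(out)
}

# call-table constructor for hand-built cases
make_call_table <- function(chrom, pos, strand = "+", context = "CpG",
                            meth_r1 = 0L, unmeth_r1 = 0L,
                            meth_r2 = 0L, unmeth_r2 = 0L) {
  tibble::tibble(
    chrom = chrom, pos = as.integer(pos), strand = strand, context = context,
    meth_r1 = as.integer(meth_r1), unmeth_r1 = as.integer(unmeth_r1),
    meth_r2 = as.integer(meth_r2), unmeth_r2 = as.integer(unmeth_r2)
  )
}

random_genome <- function(len, seed, chrom = "rnd") {
  withr::with_seed(seed, genome_from_seq(stats::setNames(
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    chrom
  )))
}
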