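test_that("window levels pool counts within windows and flag undefined ones", {
  g <- genome_from_seq(c = strrep("ACGT", 2500)) # 10 kb, CpG at every ACGT unit? no: CG at pos 1-2 of each unit
  ix <- index_cytosines(g)
  win <- tile_windows(g, 1000)

  # all covered CpGs methylated -> every covered window at 100%
  cpg <- ix[ix$context == "CpG" & ix$strand == "+", ]
  tab <- make_call_table("c", cpg$pos[cpg$pos < 5000], meth_r1 = 3L)
  st <- window_levels(tab, win, ix)
  expect_true(all(st$level[1:5] == 100))
  expect_true(all(is.na(st$level[6:10]))) # uncovered windows undefined, not zero
  expect_equal(st$n_covered[6:10], rep(0L, 5))
  expect_true(all(st$n_cpg > 0))

  # constructed counts match hand-pooled ratios
  tab2 <- make_call_table(
    "c", c(10, 500, 1500),
    meth_r1 = c(3L, 1L, 2L), unmeth_r1 = c(1L, 3L, 2L)
  )
  st2 <- window_levels(tab2, win, ix)
  expect_equal(st2$level[1], 100 * (3 + 1) / 8)
  expect_equal(st2$level[2], 50)
})

test_that("density classes use equal-count boundaries with tie collapse", {
  st <- tibble::tibble(
    chrom = "c", start = 0:8 * 1000L, end = 1:9 * 1000L,
    n_cpg = c(5L, 10L, 15L, 20L, 25L, 30L, 35L, 40L, 45L), level = 50
  )
  d <- density_classes(st, k = 9)
  expect_equal(sort(unique(d$density_class)), 1:9)
  expect_equal(as.integer(table(d$density_class)), rep(1L, 9))

  st_tied <- st
  st_tied$n_cpg <- rep(7L, 9)
  d2 <- density_classes(st_tied, k = 9)
  expect_true(all(d2$density_class == 1L))

  st90 <- tibble::tibble(
    chrom = "c", start = 0:89 * 1000L, end = 1:90 * 1000L,
    n_cpg = withr::with_seed(1, sample(1000L, 90)), level = 50
  )
  d3 <- density_classes(st90, k = 9)
  expect_equal(unname(as.integer(table(d3$density_class))), rep(10L, 9))

  expect_error(density_classes(st, k = 0), ">= 1")
})

test_that("run comparison of a run against itself is the identity regression", {
  st <- tibble::tibble(
    chrom = "c", start = 0:19 * 1000L, end = 1:20 * 1000L,
    n_cpg = withr::with_seed(2, sample(50:200, 20)),
    level = withr::with_seed(3, runif(20, 20, 90))
  )
  cmp <- compare_runs(st, st)
  # perfect fits make lm's summary complain; the point estimates are exact
  g <- suppressWarnings(glance(cmp))
  expect_equal(g$slope, 1, tolerance = 1e-9)
  expect_equal(g$intercept, 0, tolerance = 1e-9)
  expect_equal(g$correlation, 1, tolerance = 1e-9)
  expect_true(all(cmp$windows$delta == 0))

  shifted <- st
  shifted$level <- st$level + 5
  cmp2 <- compare_runs(shifted, st)
  g2 <- suppressWarnings(glance(cmp2))
  expect_equal(g2$slope, 1, tolerance = 1e-9)
  expect_equal(g2$intercept, 5, tolerance = 1e-9)
  expect_equal(g2$mean_delta, 5, tolerance = 1e-9)

  td <- suppressWarnings(tidy(cmp2))
  expect_equal(td$term, c("(Intercept)", "level_b"))
  expect_equal(td$estimate, c(5, 1), tolerance = 1e-9)

  empty_a <- st
  empty_a$level <- NA_real_
  expect_error(compare_runs(empty_a, st), "no windows")
})

test_that("artifact-vs-clean comparison shows the closed-form negative bias", {
  g <- random_genome(40000, 151)
  ix <- index_cytosines(g)
  m <- 0.6
  q <- 0.1
  reads <- simulate_library(
    g, methylome_spec("uniform", cpg_level = m), 4000,
    sim_config("PBAT", seed = 152), index = ix
  )
  art <- apply_artifact(
    reads, artifact_model(g_to_a_rate = q, target_mate = "R1"), seed = 153
  )
  win <- tile_windows(g, 4000)
  calls_c <- extract_calls(truth_alignments(reads), reads, ix)
  calls_a <- extract_calls(truth_alignments(art), art, ix)
  st_c <- window_levels(calls_c, win, ix, mates = "R1")
  st_a <- window_levels(calls_a, win, ix, mates = "R1")
  cmp <- compare_runs(st_a, st_c)
  gl <- glance(cmp)
  # E[delta] = -100 * m * q
  expect_lt(abs(gl$mean_delta - (-100 * m * q)), 1.5)
  expect_gt(gl$correlation, 0.5)
})

test_that("PMD calling enforces the coverage, level and length rules", {
  # synthetic 400-kb single-chromosome call table built directly: one CpG
  # dyad site every 500 bp, 20 covered CpGs per 10-kb window
  n_win <- 40
  win_size <- 10000L
  pos <- seq(0, n_win * win_size - 1, by = 500)
  g <- genome_from_seq(c = strrep("A", n_win * win_size)) # coordinates only
  ix <- tibble::tibble(
    chrom = "c", pos = as.integer(pos), strand = "+", context = "CpG"
  )
  lvl_of_window <- function(w, level) {
    sel <- pos >= (w - 1) * win_size & pos < w * win_size
    meth <- as.integer(round(level / 100 * 10))
    make_call_table("c", pos[sel], meth_r1 = meth, unmeth_r1 = 10L - meth)
  }
  build <- function(levels) {
    dplyr::bind_rows(lapply(seq_along(levels), function(w) {
      lvl_of_window(w, levels[w])
    }))
  }

  # uniform 80%: no PMDs
  t80 <- build(rep(80, n_win))
  expect_equal(nrow(call_pmds(t80, g, ix, window_size = win_size)), 0L)

  # 12 contiguous windows at 50% flanked by 80%: one PMD of exactly 120 kb
  lv <- rep(80, n_win)
  lv[11:22] <- 50
  t12 <- build(lv)
  pmd <- call_pmds(t12, g, ix, window_size = win_size)
  expect_equal(nrow(pmd), 1L)
  expect_equal(pmd$start, 10 * win_size)
  expect_equal(pmd$end, 22 * win_size)
  expect_equal(pmd$length, 120000L)
  expect_equal(pmd$mean_level, 50)

  # 10 qualifying windows = 100 kb exactly: not LONGER than 100 kb, no PMD
  lv10 <- rep(80, n_win)
  lv10[11:20] <- 50
  expect_equal(nrow(call_pmds(build(lv10), g, ix, window_size = win_size)), 0L)

  # an ineligible (undercovered) window breaks contiguity
  lv_split <- rep(80, n_win)
  lv_split[5:27] <- 50
  t_split <- build(lv_split)
  gap <- pos >= 15 * win_size & pos < 16 * win_size
  t_split <- t_split[!(t_split$pos %in% pos[gap]), ] # window 16 now has 0 covered CpGs
  pmd_split <- call_pmds(t_split, g, ix, window_size = win_size)
  expect_equal(nrow(pmd_split), 2L)
  expect_equal(pmd_split$length, c(110000L, 110000L))

  # every reported PMD satisfies the three printed thresholds
  chk <- dplyr::bind_rows(pmd, pmd_split)
  expect_true(all(chk$length > 100000))
  expect_true(all(chk$mean_level < 70))
  expect_true(all(chk$n_windows >= 10))
})

test_that("PMD calls match the brute-force window scan on random tables", {
  for (seed in 1:3) {
    n_win <- 60
    win_size <- 10000L
    pos <- seq(0, n_win * win_size - 1, by = 400)
    g <- genome_from_seq(c = strrep("A", n_win * win_size))
    ix <- tibble::tibble(
      chrom = "c", pos = as.integer(pos), strand = "+", context = "CpG"
    )
    tab <- withr::with_seed(seed + 400, make_call_table(
      "c", pos,
      meth_r1 = rbinom(length(pos), 10, runif(length(pos), 0.3, 0.95)),
      unmeth_r1 = 0L
    ))
    tab$unmeth_r1 <- 10L - tab$meth_r1
    # randomly uncover some sites
    drop <- withr::with_seed(seed + 500, runif(length(pos)) < 0.1)
    tab$meth_r1[drop] <- 0L
    tab$unmeth_r1[drop] <- 0L
    got <- call_pmds(tab, g, ix, window_size = win_size)
    exp <- oracle_pmds(tab, n_win * win_size, window_size = win_size)
    if (nrow(exp) == 0) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$start, exp$start)
      expect_equal(got$end, exp$end)
      expect_equal(got$length, exp$length)
    }
  }
})

test_that("mixture calibration recovers predetermined levels and artifact bias", {
  g <- random_genome(30000, 161)
  ix <- index_cytosines(g)
  run_tbl <- function(pi, artifact = NULL, seed = 162) {
    reads <- simulate_library(
      g, methylome_spec("mixture", mixture_proportion = pi), 1500,
      sim_config("PBAT", seed = seed), artifact = artifact, index = ix
    )
    extract_calls(truth_alignments(reads), reads, ix)
  }
  clean <- calibrate_mixtures(list(
    list(predetermined = 44, table = run_tbl(0.44, seed = 163)),
    list(predetermined = 0, table = run_tbl(0, seed = 164))
  ))
  expect_equal(nrow(clean), 2L)
  # the mixture draws 1500 molecules, so molecule-level binomial noise
  # dominates the observed-minus-predetermined differences
  mol_tol <- 4 * 100 * sqrt(0.44 * 0.56 / 1500)
  expect_lt(abs(clean$diff_r1[1]), mol_tol)
  expect_lt(abs(clean$diff_r2[1]), mol_tol)
  # the mate gap cancels molecule sampling and is tight
  expect_lt(abs(clean$r1_r2_gap[1]), 2)
  expect_equal(clean$observed_all[2], 0)
  expect_equal(clean$diff_r1[2], 0)

  q <- 0.1
  art <- calibrate_mixtures(list(list(
    predetermined = 44,
    table = run_tbl(0.44, artifact_model(g_to_a_rate = q, target_mate = "R1"),
      seed = 165)
  )))
  # mate gap ~ -100 * pi * q, R2 unbiased up to molecule noise
  expect_lt(abs(art$r1_r2_gap - (-4.4)), 2)
  expect_lt(abs(art$diff_r2), mol_tol)
  expect_error(calibrate_mixtures(list()), "at least one")
})
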