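small_setup <- function(len = 4000, seed = 5) {
  g <- random_genome(len, seed)
  list(genome = g, index = index_cytosines(g))
}

test_that("realize_methylome assigns levels by mode", {
  s <- small_setup()
  m0 <- realize_methylome(s$index, methylome_spec("uniform", cpg_level = 0))
  expect_true(all(m0$level[m0$context == "CpG"] == 0))

  ms <- realize_methylome(s$index, methylome_spec("sssi"))
  expect_true(all(ms$level[ms$context == "CpG"] == 0.979))
  expect_true(all(ms$level[ms$context %in% c("CpA", "CpT", "CpC")] == 0))

  mm <- realize_methylome(
    s$index,
    methylome_spec("mixture", mixture_proportion = 0.5)
  )
  expect_true(all(mm$level[mm$context == "CpG"] == 0.5))
  expect_true(all(mm$level_meth[mm$context == "CpG"] == 1))
  expect_true(all(mm$level_unmeth[mm$context == "CpG"] == 0))

  expect_error(methylome_spec("mixture"), "mixture_proportion")
  expect_error(methylome_spec("uniform", cpg_level = 1.2), "probability")
})

test_that("fragment conversion follows methylation state", {
  s <- small_setup()
  cfg <- sim_config(read_len = 50, fragment_len_mean = 100, fragment_len_sd = 5, seed = 2)

  # all cytosines methylated: fragment is the genomic strand verbatim
  m1 <- realize_methylome(
    s$index, methylome_spec("uniform", cpg_level = 1, noncpg_level = 1)
  )
  fr1 <- simulate_fragments(s$genome, m1, 20, cfg, strand = "plus")
  for (i in seq_len(nrow(fr1))) {
    expect_identical(
      fr1$seq[i], substr(s$genome$seq, fr1$start[i] + 1, fr1$end[i])
    )
  }

  # all unmethylated, complete conversion: no C anywhere
  m0 <- realize_methylome(s$index, methylome_spec("uniform", cpg_level = 0))
  fr0 <- simulate_fragments(s$genome, m0, 50, cfg)
  expect_false(any(grepl("C", fr0$seq, fixed = TRUE)))

  # minus-strand fragments are converted on their own strand
  frm <- simulate_fragments(s$genome, m0, 20, cfg, strand = "minus")
  expect_false(any(grepl("C", frm$seq, fixed = TRUE)))
})

test_that("incomplete conversion leaves a binomial number of residual Cs", {
  g <- random_genome(30000, 77)
  ix <- index_cytosines(g)
  m0 <- realize_methylome(ix, methylome_spec("uniform", cpg_level = 0))
  cfg <- sim_config(
    read_len = 100, fragment_len_mean = 200, fragment_len_sd = 0,
    conversion_rate = 0.99, seed = 31
  )
  fr <- simulate_fragments(g, m0, 200, cfg)
  # count genomic Cs drawn, on the fragment strand
  n_c <- sum(vapply(seq_len(nrow(fr)), function(i) {
    seg <- substr(g$seq, fr$start[i] + 1, fr$end[i])
    if (fr$strand[i] == "+") {
      lengths(regmatches(seg, gregexpr("C", seg)))
    } else {
      lengths(regmatches(seg, gregexpr("G", seg)))
    }
  }, integer(1)))
  residual <- sum(lengths(regmatches(fr$seq, gregexpr("C", fr$seq))))
  expected <- n_c * 0.01
  sd <- sqrt(n_c * 0.01 * 0.99)
  expect_lt(abs(residual - expected), 4 * sd)
})

test_that("read chemistry codes 5mC as G/C per mate and protocol", {
  s <- small_setup()
  m1 <- realize_methylome(
    s$index, methylome_spec("uniform", cpg_level = 1, noncpg_level = 1)
  )
  cfg_p <- sim_config("PBAT", read_len = 60, fragment_len_mean = 60,
    fragment_len_sd = 0, seed = 3)
  fr <- simulate_fragments(s$genome, m1, 10, cfg_p)
  reads_p <- reads_from_fragments(fr, cfg_p)
  r1 <- reads_p[reads_p$mate == "R1", ]
  r2 <- reads_p[reads_p$mate == "R2", ]
  # fully methylated fragment: R1 is revcomp of R2 when read_len = fragment
  expect_identical(
    r1$bases,
    vapply(r2$bases, oracle_revcomp, character(1), USE.NAMES = FALSE)
  )
  # 5mC positions: C in the fragment -> G in R1, C in R2
  frag_c <- lengths(regmatches(fr$seq, gregexpr("C", fr$seq)))
  r1_g <- lengths(regmatches(r1$bases, gregexpr("G", r1$bases)))
  r2_c <- lengths(regmatches(r2$bases, gregexpr("C", r2$bases)))
  expect_equal(r1_g, frag_c)
  expect_equal(r2_c, frag_c)

  # MethylC swaps the mate roles
  cfg_m <- sim_config("MethylC", read_len = 60, fragment_len_mean = 60,
    fragment_len_sd = 0, seed = 3)
  reads_m <- reads_from_fragments(fr, cfg_m)
  expect_identical(
    reads_m$bases[reads_m$mate == "R1"], r2$bases
  )
  expect_identical(
    reads_m$bases[reads_m$mate == "R2"], r1$bases
  )
})

test_that("PBAT R1 of a fully unmethylated error-free library has no G", {
  s <- small_setup()
  m0 <- realize_methylome(s$index, methylome_spec("uniform", cpg_level = 0))
  cfg <- sim_config("PBAT", read_len = 80, fragment_len_mean = 150,
    fragment_len_sd = 10, seed = 4)
  fr <- simulate_fragments(s$genome, m0, 100, cfg)
  reads <- reads_from_fragments(fr, cfg)
  expect_false(any(grepl("G", reads$bases[reads$mate == "R1"], fixed = TRUE)))
})

test_that("apply_errors substitutes at the configured rate", {
  s <- small_setup()
  m <- realize_methylome(s$index, methylome_spec("uniform", cpg_level = 0.5))
  cfg0 <- sim_config(read_len = 100, fragment_len_mean = 150, seed = 6)
  fr <- simulate_fragments(s$genome, m, 50, cfg0)
  reads <- reads_from_fragments(fr, cfg0)

  expect_identical(apply_errors(reads, cfg0), reads) # rate 0

  cfg1 <- sim_config(read_len = 100, fragment_len_mean = 150,
    error_rate = 1, seed = 6)
  r1 <- apply_errors(reads, cfg1)
  a <- strsplit(paste(reads$bases, collapse = ""), "")[[1]]
  b <- strsplit(paste(r1$bases, collapse = ""), "")[[1]]
  expect_true(all(a != b))

  cfg2 <- sim_config(read_len = 100, fragment_len_mean = 150,
    error_rate = 0.01, seed = 8)
  r2 <- apply_errors(reads, cfg2)
  b2 <- strsplit(paste(r2$bases, collapse = ""), "")[[1]]
  n <- length(a)
  diff <- sum(a != b2)
  expect_lt(abs(diff - n * 0.01), 4 * sqrt(n * 0.01 * 0.99))
  # qualities untouched
  expect_identical(r2$quals, reads$quals)
})

test_that("G-undercall artifact removes Gs and biases the observed level", {
  s <- small_setup(len = 20000, seed = 12)
  reads <- simulate_library(
    s$genome, methylome_spec("uniform", cpg_level = 0.63), 800,
    sim_config("PBAT", seed = 13), index = s$index
  )
  # identity when switched off
  expect_identical(
    apply_artifact(reads, artifact_model(), seed = 1), reads
  )
  # q = 1 strips every G from the targeted mate
  r_all <- apply_artifact(
    reads, artifact_model(g_to_a_rate = 1, target_mate = "R1"), seed = 1
  )
  expect_false(any(grepl("G", r_all$bases[r_all$mate == "R1"], fixed = TRUE)))
  expect_identical(
    r_all$bases[r_all$mate == "R2"], reads$bases[reads$mate == "R2"]
  )
  # non-targeted mate untouched by construction, observed level scales by 1-q
  q <- 0.08
  r_art <- apply_artifact(
    reads, artifact_model(g_to_a_rate = q, target_mate = "R1"), seed = 2
  )
  calls <- extract_calls(truth_alignments(r_art), r_art, s$index)
  lvl <- weighted_level(calls, mates = "R1")
  n <- sum(calls$meth_r1 + calls$unmeth_r1)
  p <- 0.63 * (1 - q)
  expect_lt(abs(lvl - 100 * p), 4 * 100 * sqrt(p * (1 - p) / n))
})

test_that("R2 quality collapse caps qualities as density rises", {
  reads <- tibble::tibble(
    id = c("a", "a"), mate = c("R1", "R2"), protocol = "PBAT",
    bases = c("ACGT", "ACGT"),
    quals = rep(intToUtf8(rep(38 + 33, 4)), 2)
  )
  m <- artifact_model(
    target_mate = "R2",
    r2_collapse = list(density = 700, quality_floor = 8)
  )
  out <- apply_artifact(reads, m, seed = 1)
  expect_equal(utf8ToInt(out$quals[out$mate == "R2"]) - 33L, rep(8L, 4))
  expect_equal(utf8ToInt(out$quals[out$mate == "R1"]) - 33L, rep(38L, 4))
  # lower density, milder cap
  m2 <- artifact_model(
    target_mate = "R2",
    r2_collapse = list(density = 350, quality_floor = 8)
  )
  out2 <- apply_artifact(reads, m2, seed = 1)
  expect_equal(utf8ToInt(out2$quals[out2$mate == "R2"]) - 33L, rep(24L, 4))
})

test_that("FASTQ writing round-trips and is deterministic under a seed", {
  s <- small_setup()
  spec <- methylome_spec("uniform", cpg_level = 0.4)
  cfg <- sim_config(read_len = 60, fragment_len_mean = 100, seed = 99)
  reads <- simulate_library(s$genome, spec, 40, cfg, index = s$index)
  d <- withr::local_tempdir()
  p1 <- file.path(d, "r1.fastq")
  p2 <- file.path(d, "r2.fastq")
  write_fastq(reads, p1, p2)
  back <- dplyr::bind_rows(
    read_fastq(p1, "R1", "PBAT"), read_fastq(p2, "R2", "PBAT")
  )
  back <- back[order(back$id, back$mate), ]
  fwd <- reads[order(reads$id, reads$mate), ]
  expect_identical(back$bases, fwd$bases)
  expect_identical(back$quals, fwd$quals)
  expect_identical(back$id, fwd$id)

  # same seed, byte-identical files
  reads_b <- simulate_library(s$genome, spec, 40, cfg, index = s$index)
  p1b <- file.path(d, "r1b.fastq")
  p2b <- file.path(d, "r2b.fastq")
  write_fastq(reads_b, p1b, p2b)
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p1b)))
  expect_identical(unname(tools::md5sum(p2)), unname(tools::md5sum(p2b)))

  # quality 41 encodes as J
  r <- tibble::tibble(id = "x", mate = "R1", protocol = "PBAT",
    bases = "A", quals = intToUtf8(41 + 33))
  expect_equal(r$quals, "J")
  pq <- file.path(d, "q.fastq")
  write_fastq(r, pq)
  expect_equal(readLines(pq)[4], "J")

  # empty read set gives an empty, readable file
  pe <- file.path(d, "empty.fastq")
  write_fastq(reads[0, ], pe)
  expect_equal(nrow(read_fastq(pe)), 0L)

  # mate id mismatch rejected
  bad <- reads
  bad$id[bad$mate == "R2"][1] <- "someone_else"
  expect_error(write_fastq(bad, p1, p2), "id")
})
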