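#' Pipeline run configuration
#'
#' Bundles paths and stage parameters for [run_stage()] and [reproduce()].
#' A single global seed fans out deterministically to per-stage seeds, so
#' stages can be rerun independently yet reproducibly.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Global integer seed.
#' @param genome_fasta Optional FASTA path; by default the synthetic
#'   calibration genome is generated.
#' @param n_fragments Fragments per simulated library.
#' @param protocol Library chemistry.
#' @param methylome List of arguments for [methylome_spec()].
#' @param sim List of arguments for [sim_config()] (seed is managed by the
#'   pipeline).
#' @param artifact Optional list of arguments for [artifact_model()].
#' @param trim List of arguments for [trim_rule()].
#' @param align List of arguments for [align_params()].
#' @param window_size Window size for the windows stage.
#' @param mixtures Mixture proportions for [reproduce()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("bsartifact_run_"),
                       seed = 1L,
                       genome_fasta = NULL,
                       n_fragments = 6000L,
                       protocol = "PBAT",
                       methylome = list(mode = "uniform", cpg_level = 0.6),
                       sim = list(),
                       artifact = NULL,
                       trim = list(),
                       align = list(),
                       window_size = 10000L,
                       mixtures = c(0.10, 0.44, 0.88)) {
  structure(
    list(
      out_dir = out_dir, seed = as.integer(seed), genome_fasta = genome_fasta,
      n_fragments = as.integer(n_fragments), protocol = protocol,
      methylome = methylome, sim = sim, artifact = artifact,
      trim = trim, align = align, window_size = as.integer(window_size),
      mixtures = mixtures
    ),
    class = "run_config"
  )
}

# deterministic per-stage seed fan-out from the global seed
stage_seed <- function(seed, stage) {
  offsets <- c(
    simulate = 101L, align = 211L, call = 307L, qc = 401L,
    windows = 503L, pmd = 601L, calibrate = 701L
  )
  (as.integer(seed) * 977L + offsets[[stage]]) %% 2147483647L
}

pipeline_genome <- function(config) {
  if (!is.null(config$genome_fasta)) {
    load_fasta(config$genome_fasta)
  } else {
    synthetic_genome()
  }
}

write_manifest <- function(stage, config, params, inputs, outputs, out_dir) {
  manifest <- list(
    stage = stage,
    seed = unname(stage_seed(config$seed, stage)),
    parameters = params,
    inputs = as.list(inputs),
    outputs = as.list(setNames(
      unname(tools::md5sum(outputs)), basename(outputs)
    ))
  )
  path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  path
}

require_inputs <- function(paths) {
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    abort(paste0(
      "missing stage input(s): ", paste(missing, collapse = ", ")
    ), class = "bsartifact_missing_input")
  }
}

#' Run one pipeline stage
#'
#' Executes one stage of the simulate -> align -> call -> qc / windows /
#' pmd pipeline against the files in `config$out_dir`, writing the stage's
#' outputs plus a machine-readable manifest (parameters, derived seed, md5
#' checksums of outputs). Stages consume the files earlier stages wrote;
#' a missing input is an error of class `bsartifact_missing_input`.
#'
#' @param stage One of `"simulate"`, `"align"`, `"call"`, `"qc"`,
#'   `"windows"`, `"pmd"`.
#' @param config A [run_config()].
#' @return Invisibly, a named list of output paths (including the
#'   manifest).
#' @export
run_stage <- function(stage = c("simulate", "align", "call", "qc", "windows", "pmd"),
                      config) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- config$out_dir
  p <- function(...) file.path(od, ...)
  genome <- pipeline_genome(config)
  index <- index_cytosines(genome)

  out <- switch(stage,
    simulate = {
      spec <- do.call(methylome_spec, config$methylome)
      sim_args <- config$sim
      sim_args$protocol <- sim_args$protocol %||% config$protocol
      sim_args$seed <- stage_seed(config$seed, "simulate")
      cfg <- do.call(sim_config, sim_args)
      art <- if (!is.null(config$artifact)) do.call(artifact_model, config$artifact)
      reads <- simulate_library(
        genome, spec, config$n_fragments, cfg,
        artifact = art, index = index
      )
      if (cfg$paired) {
        write_fastq(reads, p("reads_1.fastq"), p("reads_2.fastq"))
      } else {
        write_fastq(reads, p("reads_1.fastq"))
      }
      readr::write_tsv(
        reads[, c("id", "mate", "truth_chrom", "truth_pos", "truth_strand")],
        p("truth.tsv"), progress = FALSE
      )
      outs <- c(
        p("reads_1.fastq"),
        if (cfg$paired) p("reads_2.fastq"), p("truth.tsv")
      )
      list(
        outputs = outs,
        params = c(config$methylome, list(
          n_fragments = config$n_fragments, protocol = cfg$protocol,
          read_len = cfg$read_len, paired = cfg$paired,
          conversion_rate = cfg$conversion_rate, error_rate = cfg$error_rate
        ))
      )
    },
    align = {
      require_inputs(p("reads_1.fastq"))
      r1 <- read_fastq(p("reads_1.fastq"), mate = "R1", protocol = config$protocol)
      reads <- if (file.exists(p("reads_2.fastq"))) {
        bind_rows(r1, read_fastq(p("reads_2.fastq"), mate = "R2", protocol = config$protocol))
      } else {
        r1
      }
      rule <- do.call(trim_rule, config$trim)
      params <- do.call(align_params, config$align)
      trimmed <- trim_reads(reads, rule)
      aln <- align_reads(trimmed, genome, params)
      readr::write_tsv(aln, p("alignments.tsv"), progress = FALSE)
      write_sam(aln, trimmed, genome, p("alignments.sam"))
      readr::write_tsv(alignment_summary(aln), p("align_summary.tsv"), progress = FALSE)
      list(
        outputs = p(c("alignments.tsv", "alignments.sam", "align_summary.tsv")),
        params = list(
          trim5 = rule$trim5, trim3 = rule$trim3,
          seed_len = params$seed_len,
          seed_mismatch_max = params$seed_mismatch_max,
          total_mismatch_max = params$total_mismatch_max
        ),
        inputs = p("reads_1.fastq")
      )
    },
    call = {
      require_inputs(p(c("reads_1.fastq", "alignments.tsv")))
      reads <- pipeline_read_trimmed(config, p)
      aln <- readr::read_tsv(p("alignments.tsv"), show_col_types = FALSE, progress = FALSE)
      calls <- extract_calls(aln, reads, index)
      readr::write_tsv(calls, p("calls.tsv"), progress = FALSE)
      write_cytosine_report(calls, p("cytosine_report.tsv"))
      write_bedgraph(calls, p("levels.bedGraph"))
      rep <- level_report(calls, reads = reads)
      jsonlite::write_json(
        as.list(rep), p("level_report.json"),
        auto_unbox = TRUE, digits = NA
      )
      list(
        outputs = p(c(
          "calls.tsv", "cytosine_report.tsv", "levels.bedGraph",
          "level_report.json"
        )),
        inputs = p(c("reads_1.fastq", "alignments.tsv"))
      )
    },
    qc = {
      require_inputs(p("reads_1.fastq"))
      reads <- pipeline_read_raw(config, p)
      rep <- qc_report(reads)
      readr::write_tsv(rep, p("qc_report.tsv"), progress = FALSE)
      comp <- base_composition(reads[reads$mate == "R1", ])
      readr::write_tsv(comp, p("composition_r1.tsv"), progress = FALSE)
      list(
        outputs = p(c("qc_report.tsv", "composition_r1.tsv")),
        inputs = p("reads_1.fastq")
      )
    },
    windows = {
      require_inputs(p("calls.tsv"))
      calls <- readr::read_tsv(p("calls.tsv"), show_col_types = FALSE, progress = FALSE)
      windows <- tile_windows(genome, config$window_size)
      stats <- window_levels(calls, windows, index)
      readr::write_tsv(stats, p("window_levels.tsv"), progress = FALSE)
      write_bed(stats, p("windows.bed"))
      list(
        outputs = p(c("window_levels.tsv", "windows.bed")),
        params = list(window_size = config$window_size),
        inputs = p("calls.tsv")
      )
    },
    pmd = {
      require_inputs(p("calls.tsv"))
      calls <- readr::read_tsv(p("calls.tsv"), show_col_types = FALSE, progress = FALSE)
      pmds <- call_pmds(calls, genome, index)
      readr::write_tsv(pmds, p("pmds.tsv"), progress = FALSE)
      pmds$level <- pmds$mean_level
      write_bed(pmds, p("pmds.bed"))
      list(
        outputs = p(c("pmds.tsv", "pmds.bed")),
        inputs = p("calls.tsv")
      )
    }
  )
  manifest <- write_manifest(
    stage, config, out$params %||% list(),
    out$inputs %||% character(), out$outputs, od
  )
  invisible(c(as.list(setNames(out$outputs, basename(out$outputs))),
    manifest = manifest
  ))
}

pipeline_read_raw <- function(config, p) {
  r1 <- read_fastq(p("reads_1.fastq"), mate = "R1", protocol = config$protocol)
  if (file.exists(p("reads_2.fastq"))) {
    bind_rows(r1, read_fastq(p("reads_2.fastq"), mate = "R2", protocol = config$protocol))
  } else {
    r1
  }
}

pipeline_read_trimmed <- function(config, p) {
  trim_reads(pipeline_read_raw(config, p), do.call(trim_rule, config$trim))
}

#' Reproduce the synthetic mixture-calibration analysis end to end
#'
#' Runs the package's synthetic analogue of a spike-in calibration
#' experiment: for each mixture proportion (default 10, 44, 88% methylated
#' molecules), a paired-end library is simulated, aligned, and called under
#' two conditions — clean base calling and the G-undercall artifact model on
#' R1 — and calibrated against the predetermined level. A QC report is
#' produced for one artifact-affected library, and PMD calling is
#' demonstrated on a constructed two-domain genome with a 150-kb partially
#' methylated region. All outputs and a JSON report land in
#' `config$out_dir`; the same config and seed give byte-identical outputs.
#'
#' @param config A [run_config()]; `mixtures`, `n_fragments`, `seed` and
#'   `out_dir` are the knobs that matter. The artifact condition uses
#'   `config$artifact` when supplied, else a G-to-A rate of 0.08 with a
#'   20-point quality penalty on R1.
#' @return Invisibly, a list with `calibration_clean`,
#'   `calibration_artifact` (tibbles, one row per mixture), `qc`, `pmds`
#'   and `out_dir`.
#' @export
reproduce <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- config$out_dir
  genome <- pipeline_genome(config)
  index <- index_cytosines(genome)
  art <- if (!is.null(config$artifact)) {
    do.call(artifact_model, config$artifact)
  } else {
    artifact_model(g_to_a_rate = 0.08, g_quality_penalty = 20, target_mate = "R1")
  }
  rule <- do.call(trim_rule, config$trim)
  params <- do.call(align_params, config$align)
  base_seed <- stage_seed(config$seed, "calibrate")

  one_run <- function(pi, seed, artifact) {
    spec <- methylome_spec("mixture", mixture_proportion = pi)
    sim_args <- config$sim
    sim_args$protocol <- sim_args$protocol %||% config$protocol
    sim_args$seed <- seed
    cfg <- do.call(sim_config, sim_args)
    reads <- simulate_library(
      genome, spec, config$n_fragments, cfg,
      artifact = artifact, index = index
    )
    trimmed <- trim_reads(reads, rule)
    aln <- align_reads(trimmed, genome, params)
    extract_calls(aln, trimmed, index)
  }

  runs_clean <- purrr::imap(config$mixtures, function(pi, i) {
    list(
      predetermined = 100 * pi,
      table = one_run(pi, (base_seed + 10L * i) %% 2147483647L, NULL)
    )
  })
  runs_art <- purrr::imap(config$mixtures, function(pi, i) {
    list(
      predetermined = 100 * pi,
      table = one_run(pi, (base_seed + 10L * i + 5L) %% 2147483647L, art)
    )
  })
  calib_clean <- calibrate_mixtures(runs_clean)
  calib_art <- calibrate_mixtures(runs_art)
  readr::write_tsv(calib_clean, file.path(od, "calibration_clean.tsv"), progress = FALSE)
  readr::write_tsv(calib_art, file.path(od, "calibration_artifact.tsv"), progress = FALSE)

  # QC on one artifact-affected library (middle mixture)
  spec_mid <- methylome_spec("mixture", mixture_proportion = config$mixtures[2])
  sim_args <- config$sim
  sim_args$protocol <- sim_args$protocol %||% config$protocol
  sim_args$seed <- stage_seed(config$seed, "qc")
  cfg <- do.call(sim_config, sim_args)
  qc_reads <- simulate_library(
    genome, spec_mid, min(config$n_fragments, 2000L), cfg,
    artifact = art, index = index
  )
  qc <- qc_report(qc_reads)
  readr::write_tsv(qc, file.path(od, "qc_report.tsv"), progress = FALSE)

  pmds <- reproduce_pmd_demo(config)
  readr::write_tsv(pmds, file.path(od, "pmds.tsv"), progress = FALSE)

  report <- list(
    seed = config$seed,
    mixtures = config$mixtures,
    calibration_clean = calib_clean,
    calibration_artifact = calib_art,
    pmds = pmds
  )
  jsonlite::write_json(
    report, file.path(od, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(list(
    calibration_clean = calib_clean, calibration_artifact = calib_art,
    qc = qc, pmds = pmds, out_dir = od
  ))
}

# two-domain demonstration genome: highly methylated background with one
# 150-kb partially methylated region
reproduce_pmd_demo <- function(config) {
  genome <- synthetic_genome(
    length = 600000L,
    seed = stage_seed(config$seed, "pmd"), chrom = "demo"
  )
  index <- index_cytosines(genome)
  methylome <- realize_methylome(index, methylome_spec("uniform", cpg_level = 0.85))
  in_pmd <- methylome$pos >= 200000 & methylome$pos < 350000
  methylome$level[in_pmd & methylome$context == "CpG"] <- 0.40
  cfg <- sim_config(
    protocol = "PBAT", paired = TRUE,
    seed = (stage_seed(config$seed, "pmd") + 1L) %% 2147483647L
  )
  frags <- simulate_fragments(genome, methylome, 12000L, cfg)
  reads <- reads_from_fragments(frags, cfg)
  calls <- extract_calls(truth_alignments(reads), reads, index)
  call_pmds(calls, genome, index)
}
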