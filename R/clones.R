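#' Simulate clone bisulfite sequencing of an SssI-treated amplicon
#'
#' Emulates the clone-validation experiment used to measure the actual
#' methylation level of SssI-treated DNA: a synthetic amplicon carrying
#' `n_sites` CpG sites is methylated per molecule at `level`, bisulfite
#' converted, and each clone is sequenced full-length on the converted
#' strand; the estimate is the fraction of methylated CpG observations over
#' all clones and sites.
#'
#' @param n_sites Number of CpG sites on the amplicon (default 58, spread
#'   over a repeated `TTCGAA` unit).
#' @param n_clones Number of sequenced clones (default 1000).
#' @param level Per-site methylation probability (default the SssI model's
#'   0.979).
#' @param conversion_rate Bisulfite conversion efficiency.
#' @param seed Optional seed.
#' @return A one-row tibble: `level_estimate` (percent), `n_sites`,
#'   `n_clones`, `n_calls`.
#' @export
simulate_clone_sequencing <- function(n_sites = 58L, n_clones = 1000L,
                                      level = 0.979, conversion_rate = 1.0,
                                      seed = NULL) {
  stopifnot(n_sites >= 1, n_clones >= 1)
  genome <- genome_from_seq(amplicon = strrep("TTCGAA", n_sites))
  index <- index_cytosines(genome)
  spec <- methylome_spec("sssi", sssi_level = level)
  methylome <- realize_methylome(index, spec)
  len <- genome$length[1]
  config <- sim_config(
    protocol = "MethylC", read_len = len, paired = FALSE,
    fragment_len_mean = len, fragment_len_sd = 0,
    conversion_rate = conversion_rate, seed = seed
  )
  frags <- simulate_fragments(genome, methylome, n_clones, config, strand = "plus")
  reads <- reads_from_fragments(frags, config)
  calls <- extract_calls(truth_alignments(reads), reads, index)
  est <- weighted_level(calls, mates = "R1")
  tibble(
    level_estimate = est, n_sites = as.integer(n_sites),
    n_clones = as.integer(n_clones),
    n_calls = sum(calls$meth_r1 + calls$unmeth_r1)
  )
}
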