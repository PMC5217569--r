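#' Simulation configuration for a bisulfite sequencing library
#'
#' Collects the library-level parameters of the read simulator. The defaults
#' follow the sequencing setup the package emulates: 101-nt reads, paired-end
#' PBAT chemistry, complete bisulfite conversion and error-free base calls
#' at a uniform Phred quality of 38. Fragment lengths are drawn from a
#' normal distribution truncated below at `read_len`.
#'
#' @param protocol `"PBAT"` (first read complementary to the converted
#'   strand, so 5mC is read as G in R1 and C in R2) or `"MethylC"` (the
#'   mirror image: 5mC as C in R1 and G in R2).
#' @param read_len Read length in bases (default 101).
#' @param paired Produce read pairs (default `TRUE`); if `FALSE` only R1 is
#'   produced.
#' @param fragment_len_mean,fragment_len_sd Fragment length distribution in
#'   bases.
#' @param conversion_rate Probability that an unmethylated cytosine is read
#'   as T (bisulfite conversion efficiency), default 1.
#' @param error_rate Per-base substitution error probability, default 0.
#' @param base_quality Uniform Phred quality assigned to simulated bases.
#' @param seed Optional integer seed; when set, simulation is reproducible
#'   and the same seed yields byte-identical FASTQ output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(protocol = c("PBAT", "MethylC"),
                       read_len = 101L,
                       paired = TRUE,
                       fragment_len_mean = 300,
                       fragment_len_sd = 30,
                       conversion_rate = 1.0,
                       error_rate = 0,
                       base_quality = 38L,
                       seed = NULL) {
  protocol <- match.arg(protocol)
  if (read_len < 1) abort("read_len must be >= 1")
  if (conversion_rate < 0 || conversion_rate > 1) abort("conversion_rate in [0,1]")
  if (error_rate < 0 || error_rate > 1) abort("error_rate in [0,1]")
  if (base_quality < 2 || base_quality > 41) abort("base_quality in [2,41]")
  structure(
    list(
      protocol = protocol, read_len = as.integer(read_len), paired = paired,
      fragment_len_mean = fragment_len_mean, fragment_len_sd = fragment_len_sd,
      conversion_rate = conversion_rate, error_rate = error_rate,
      base_quality = as.integer(base_quality), seed = seed
    ),
    class = "sim_config"
  )
}

#' Simulate bisulfite-converted single-strand fragments
#'
#' Draws `n` DNA fragments from the genome, picks a genomic strand for each
#' (uniformly, unless restricted via `strand`), realizes methylation at every
#' cytosine of that strand per molecule, and applies bisulfite conversion:
#' an unmethylated cytosine becomes T with probability `conversion_rate`,
#' a methylated cytosine always stays C. In mixture mode the molecule's
#' component (methylated or unmethylated pool) is drawn once per fragment and
#' its component level applies at every site, emulating a physical mixture of
#' two DNA preparations.
#'
#' @param genome Genome tibble.
#' @param methylome Output of [realize_methylome()].
#' @param n Number of fragments.
#' @param config A [sim_config()].
#' @param strand `"both"` (default, uniform choice), `"plus"` or `"minus"`;
#'   restricting the strand models directional clone sequencing of one
#'   PCR strand.
#' @return A tibble with columns `frag_id`, `chrom`, `start`, `end` (0-based
#'   half-open plus-strand coordinates), `strand`, `component` (mixture
#'   component, `NA` otherwise) and `seq` — the converted single-strand
#'   sequence written 5'->3'.
#' @export
simulate_fragments <- function(genome, methylome, n, config,
                               strand = c("both", "plus", "minus")) {
  genome <- validate_genome(genome)
  strand <- match.arg(strand)
  stopifnot(inherits(config, "sim_config"), n >= 1)
  spec <- attr(methylome, "spec")
  run <- function() {
    ci <- sample.int(nrow(genome), n, replace = TRUE, prob = genome$length)
    len <- genome$length[ci]
    if (any(len < config$read_len)) abort("record shorter than read_len")
    flen <- pmin(len, pmax(config$read_len, as.integer(round(
      rnorm(n, config$fragment_len_mean, config$fragment_len_sd)
    ))))
    start <- as.integer(floor(runif(n) * (len - flen + 1)))
    fstrand <- switch(strand,
      both = ifelse(runif(n) < 0.5, "+", "-"),
      plus = rep("+", n),
      minus = rep("-", n)
    )
    comp <- if (!is.null(spec) && spec$mode == "mixture") {
      ifelse(runif(n) < spec$mixture_proportion, "meth", "unmeth")
    } else {
      rep(NA_character_, n)
    }
    frags <- tibble(
      frag_id = sprintf("frag%07d", seq_len(n)),
      chrom = genome$chrom[ci], start = start, end = start + flen,
      strand = fstrand, component = comp
    )
    frags$seq <- convert_fragments(frags, genome, methylome, config)
    frags
  }
  if (!is.null(config$seed)) withr::with_seed(config$seed, run()) else run()
}

# bisulfite-convert each fragment on its genomic strand; vectorized over a
# (fragment x cytosine) pairs table, sequence assembly per fragment
convert_fragments <- function(frags, genome, methylome, config) {
  spec <- attr(methylome, "spec")
  mixture <- !is.null(spec) && spec$mode == "mixture"
  seqs <- character(nrow(frags))
  for (cname in unique(frags$chrom)) {
    chars <- strsplit(genome$seq[genome$chrom == cname][1], "", fixed = TRUE)[[1]]
    for (st in c("+", "-")) {
      sel <- which(frags$chrom == cname & frags$strand == st)
      if (length(sel) == 0) next
      m <- methylome[methylome$chrom == cname & methylome$strand == st, ]
      P <- m$pos # sorted 0-based positions of this strand's cytosines
      fs <- frags$start[sel]
      fe <- frags$end[sel]
      lo <- findInterval(fs - 0.5, P) + 1L
      hi <- findInterval(fe - 0.5, P)
      nsites <- pmax(0L, hi - lo + 1L)
      fid <- rep(seq_along(sel), nsites)
      sidx <- sequence(nsites, from = lo[nsites > 0L])
      if (length(sidx) > 0) {
        lvl <- if (mixture) {
          ifelse(frags$component[sel][fid] == "meth",
            m$level_meth[sidx], m$level_unmeth[sidx]
          )
        } else {
          m$level[sidx]
        }
        meth <- runif(length(sidx)) < lvl
        conv <- !meth & (runif(length(sidx)) < config$conversion_rate)
        conv_pos <- split(P[sidx][conv], fid[conv])
      } else {
        conv_pos <- list()
      }
      for (k in seq_along(sel)) {
        i <- sel[k]
        v <- chars[(fs[k] + 1L):fe[k]]
        cp <- conv_pos[[as.character(k)]]
        if (!is.null(cp)) {
          # plus strand: C -> T; minus strand: the plus-coordinate base is G,
          # whose minus-strand C converts, i.e. plus base G -> A before revcomp
          v[cp - fs[k] + 1L] <- if (st == "+") "T" else "A"
        }
        seqs[i] <- paste(v, collapse = "")
      }
    }
  }
  minus <- frags$strand == "-"
  if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
  seqs
}

#' Generate sequencing reads from converted fragments
#'
#' Implements the two WGBS read chemistries. With PBAT, R1 is the first
#' `read_len` bases of the reverse complement of the converted fragment
#' (so 5mC appears as G in R1) and R2 is the first `read_len` bases of the
#' converted fragment itself (5mC as C). MethylC-seq swaps the mate roles.
#' A uniform base quality is assigned. Truth provenance columns record where
#' each read maps on the plus-strand coordinate system and in which
#' converted-reference view, which downstream code and tests can use to
#' bypass alignment.
#'
#' @param fragments Output of [simulate_fragments()].
#' @param config A [sim_config()].
#' @return A read tibble with columns `id`, `mate`, `protocol`, `bases`,
#'   `quals` (Phred+33 string) and truth columns `truth_chrom`, `truth_pos`
#'   (0-based leftmost plus-strand coordinate), `truth_view` (`"CT"` if the
#'   read carries the converted strand's C/T code, `"GA"` if its complement),
#'   `truth_orient` (`"fwd"`/`"rev"` relative to the plus strand) and
#'   `truth_strand` (genomic strand of the source fragment).
#' @export
reads_from_fragments <- function(fragments, config) {
  stopifnot(inherits(config, "sim_config"))
  L <- config$read_len
  flen <- fragments$end - fragments$start
  if (any(flen < L)) abort("read_len exceeds a fragment length")
  fwd <- substr(fragments$seq, 1L, L) # converted-strand code (C/T at 5mC sites)
  rc <- substr(revcomp(fragments$seq), 1L, L) # complementary code (G/A)
  qual <- strrep(intToUtf8(config$base_quality + 33L), L)
  plus <- fragments$strand == "+"
  # prefix of the fragment covers [start, start+L) when the fragment runs
  # with the plus strand, [end-L, end) when it runs against it
  pos_fwd <- ifelse(plus, fragments$start, fragments$end - L)
  pos_rc <- ifelse(plus, fragments$end - L, fragments$start)
  view <- ifelse(plus, "CT", "GA") # interrogated strand = fragment strand
  orient_fwd <- ifelse(plus, "fwd", "rev")
  orient_rc <- ifelse(plus, "rev", "fwd")
  ct_mate <- if (config$protocol == "PBAT") "R2" else "R1"
  ga_mate <- if (config$protocol == "PBAT") "R1" else "R2"
  mk <- function(bases, mate, pos, orient) {
    tibble(
      id = fragments$frag_id, mate = mate, protocol = config$protocol,
      bases = bases, quals = qual,
      truth_chrom = fragments$chrom, truth_pos = as.integer(pos),
      truth_view = view, truth_orient = orient,
      truth_strand = fragments$strand
    )
  }
  r_ga <- mk(rc, ga_mate, pos_rc, orient_rc)
  r_ct <- mk(fwd, ct_mate, pos_fwd, orient_fwd)
  if (!config$paired) {
    # single-end runs sequence R1 only
    return(if (ga_mate == "R1") r_ga else r_ct)
  }
  out <- bind_rows(r_ct, r_ga)
  out[order(out$id, out$mate), ]
}

#' Apply uniform sequencing errors to reads
#'
#' Substitutes each base independently with probability `error_rate`,
#' choosing uniformly among the other three bases. Qualities are unchanged:
#' the model separates random sequencing error from the systematic,
#' quality-linked base-caller artifacts of [apply_artifact()].
#'
#' @param reads Read tibble.
#' @param config A [sim_config()]; `error_rate` and (if set) `seed` are used.
#' @return The read tibble with substituted bases.
#' @export
apply_errors <- function(reads, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$error_rate == 0 || nrow(reads) == 0) return(reads)
  run <- function() {
    n_err <- rbinom(nrow(reads), nchar(reads$bases), config$error_rate)
    hit <- which(n_err > 0)
    bases <- reads$bases
    for (i in hit) {
      ch <- strsplit(bases[i], "", fixed = TRUE)[[1]]
      pos <- sample.int(length(ch), n_err[i])
      for (p in pos) {
        ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      }
      bases[i] <- paste(ch, collapse = "")
    }
    bases
  }
  reads$bases <- if (!is.null(config$seed)) {
    withr::with_seed(config$seed + 1L, run())
  } else {
    run()
  }
  reads
}

#' Specify a base-caller artifact model
#'
#' Parameterizes the two instrument-software artifacts the package studies
#' in low-diversity bisulfite libraries:
#'
#' * G undercall: in the targeted mate, each called G is independently
#'   miscalled with probability `g_to_a_rate` and its quality reduced by
#'   `g_quality_penalty` Phred points (floored at 2). The miscall target is
#'   A by default because A is the unmethylated partner of G at
#'   5mC-coding positions in both chemistries, so a single parameter
#'   reproduces both the depressed G fraction and the depressed methylation
#'   level; set `uniform_miscall = TRUE` to draw the wrong base uniformly
#'   instead. With `quality_only = TRUE` the quality penalty is also applied
#'   to Gs whose base call survives.
#' * R2 quality collapse: optional cluster-density-dependent cap on all
#'   qualities of the targeted mate, via `r2_collapse = list(density =,
#'   quality_floor =, density_saturation =)`. The cap falls linearly from 41
#'   toward `quality_floor` as density approaches `density_saturation`
#'   (default 700 K clusters per mm^2, the top of the densities the model
#'   emulates).
#'
#' @param g_to_a_rate Probability a called G in the targeted mate is
#'   replaced.
#' @param g_quality_penalty Phred points subtracted at affected positions.
#' @param target_mate `"R1"` or `"R2"`.
#' @param quality_only Penalize quality at every G, not only miscalled ones.
#' @param uniform_miscall Replace a miscalled G by a uniform non-G base
#'   instead of A.
#' @param r2_collapse Optional list as described above.
#' @return An object of class `artifact_model`.
#' @export
artifact_model <- function(g_to_a_rate = 0,
                           g_quality_penalty = 0,
                           target_mate = c("R1", "R2"),
                           quality_only = FALSE,
                           uniform_miscall = FALSE,
                           r2_collapse = NULL) {
  target_mate <- match.arg(target_mate)
  if (g_to_a_rate < 0 || g_to_a_rate > 1) abort("g_to_a_rate in [0,1]")
  if (g_quality_penalty < 0) abort("g_quality_penalty must be >= 0")
  if (!is.null(r2_collapse)) {
    stopifnot(is.list(r2_collapse), all(c("density", "quality_floor") %in% names(r2_collapse)))
    r2_collapse$density_saturation <- r2_collapse$density_saturation %||% 700
  }
  structure(
    list(
      g_to_a_rate = g_to_a_rate, g_quality_penalty = g_quality_penalty,
      target_mate = target_mate, quality_only = quality_only,
      uniform_miscall = uniform_miscall, r2_collapse = r2_collapse
    ),
    class = "artifact_model"
  )
}

#' Apply a base-caller artifact model to reads
#'
#' Reads whose mate does not match the model's `target_mate` are returned
#' unchanged. See [artifact_model()] for the artifact definitions.
#'
#' @param reads Read tibble.
#' @param model An [artifact_model()].
#' @param seed Optional seed for reproducibility.
#' @return The read tibble with artifact-affected bases and qualities.
#' @export
apply_artifact <- function(reads, model, seed = NULL) {
  stopifnot(inherits(model, "artifact_model"))
  run <- function() {
    target <- which(reads$mate == model$target_mate)
    bases <- reads$bases
    quals <- reads$quals
    if (model$g_to_a_rate > 0 || model$g_quality_penalty > 0 || model$quality_only) {
      for (i in target) {
        gpos <- gregexpr("G", bases[i], fixed = TRUE)[[1]]
        if (gpos[1] == -1L) next
        miscall <- runif(length(gpos)) < model$g_to_a_rate
        bc <- strsplit(bases[i], "", fixed = TRUE)[[1]]
        qc <- utf8ToInt(quals[i]) - 33L
        if (any(miscall)) {
          repl <- if (model$uniform_miscall) {
            sample(c("A", "C", "T"), sum(miscall), replace = TRUE)
          } else {
            "A"
          }
          bc[gpos[miscall]] <- repl
        }
        pen <- if (model$quality_only) gpos else gpos[miscall]
        qc[pen] <- pmax(2L, qc[pen] - model$g_quality_penalty)
        bases[i] <- paste(bc, collapse = "")
        quals[i] <- intToUtf8(qc + 33L)
      }
    }
    if (!is.null(model$r2_collapse)) {
      rc <- model$r2_collapse
      frac <- min(1, rc$density / rc$density_saturation)
      cap <- as.integer(max(2, round(41 - (41 - rc$quality_floor) * frac)))
      for (i in target) {
        qc <- pmin(utf8ToInt(quals[i]) - 33L, cap)
        quals[i] <- intToUtf8(qc + 33L)
      }
    }
    list(bases = bases, quals = quals)
  }
  res <- if (!is.null(seed)) withr::with_seed(seed, run()) else run()
  reads$bases <- res$bases
  reads$quals <- res$quals
  reads
}

#' Simulate a complete bisulfite library
#'
#' Convenience wrapper chaining [simulate_fragments()],
#' [reads_from_fragments()], [apply_errors()] and (optionally)
#' [apply_artifact()] under a single seed.
#'
#' @param genome Genome tibble.
#' @param spec A [methylome_spec()].
#' @param n_fragments Number of fragments (pairs when `config$paired`).
#' @param config A [sim_config()].
#' @param artifact Optional [artifact_model()].
#' @param index Optional precomputed [index_cytosines()] result.
#' @param strand Strand restriction passed to [simulate_fragments()].
#' @return A read tibble.
#' @export
simulate_library <- function(genome, spec, n_fragments, config,
                             artifact = NULL, index = NULL,
                             strand = "both") {
  index <- index %||% index_cytosines(genome)
  methylome <- realize_methylome(index, spec)
  frags <- simulate_fragments(genome, methylome, n_fragments, config, strand = strand)
  reads <- reads_from_fragments(frags, config)
  reads <- apply_errors(reads, config)
  if (!is.null(artifact)) {
    aseed <- if (!is.null(config$seed)) config$seed + 2L else NULL
    reads <- apply_artifact(reads, artifact, seed = aseed)
  }
  reads
}
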