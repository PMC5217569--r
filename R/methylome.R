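#' Specify a methylome model
#'
#' Describes how per-CpG methylation probabilities are assigned when a
#' methylome is realized over a cytosine index. Three modes are supported:
#'
#' * `"uniform"`: every CpG cytosine gets probability `cpg_level`.
#' * `"sssi"`: emulates in vitro CpG-methyltransferase (SssI) treated DNA;
#'   every CpG gets `sssi_level`, default 0.979 — the near-complete
#'   methylation level validated by clone bisulfite sequencing of
#'   SssI-treated lambda DNA.
#' * `"mixture"`: a physical mixture of two DNA pools; each molecule is
#'   drawn wholly from the first (methylated) component with probability
#'   `mixture_proportion`, otherwise from the second. Component CpG levels
#'   default to 1 and 0, which is how spike-in mixture series with known
#'   predetermined levels are modeled.
#'
#' Non-CpG cytosines (CpA, CpT, CpC) always get `noncpg_level`.
#'
#' @param mode One of `"uniform"`, `"sssi"`, `"mixture"`.
#' @param cpg_level CpG methylation probability for `"uniform"` mode.
#' @param sssi_level CpG probability for `"sssi"` mode (default 0.979).
#' @param mixture_proportion Fraction of molecules drawn from the methylated
#'   component in `"mixture"` mode.
#' @param component_levels Length-2 numeric: CpG levels of the methylated and
#'   unmethylated mixture components.
#' @param noncpg_level Methylation probability at non-CpG cytosines.
#' @return An object of class `methylome_spec`.
#' @export
methylome_spec <- function(mode = c("uniform", "sssi", "mixture"),
                           cpg_level = 0,
                           sssi_level = 0.979,
                           mixture_proportion = NULL,
                           component_levels = c(1, 0),
                           noncpg_level = 0) {
  mode <- match.arg(mode)
  chk_prob <- function(p, what) {
    if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
      abort(paste0(what, " must be a probability in [0, 1]"))
    }
  }
  chk_prob(cpg_level, "cpg_level")
  chk_prob(sssi_level, "sssi_level")
  chk_prob(noncpg_level, "noncpg_level")
  if (mode == "mixture") {
    if (is.null(mixture_proportion)) {
      abort("mixture mode requires mixture_proportion")
    }
    chk_prob(mixture_proportion, "mixture_proportion")
    if (length(component_levels) != 2) {
      abort("mixture mode requires two component levels")
    }
    chk_prob(component_levels, "component_levels")
  }
  structure(
    list(
      mode = mode, cpg_level = cpg_level, sssi_level = sssi_level,
      mixture_proportion = mixture_proportion,
      component_levels = component_levels, noncpg_level = noncpg_level
    ),
    class = "methylome_spec"
  )
}

#' @export
print.methylome_spec <- function(x, ...) {
  cat("<methylome_spec>", x$mode, "\n")
  if (x$mode == "uniform") cat("  cpg_level:", x$cpg_level, "\n")
  if (x$mode == "sssi") cat("  sssi_level:", x$sssi_level, "\n")
  if (x$mode == "mixture") {
    cat(
      "  mixture_proportion:", x$mixture_proportion,
      " components:", paste(x$component_levels, collapse = "/"), "\n"
    )
  }
  cat("  noncpg_level:", x$noncpg_level, "\n")
  invisible(x)
}

#' Realize a methylome over a cytosine index
#'
#' Maps every indexed cytosine to a methylation probability according to a
#' [methylome_spec()]. For `"uniform"` and `"sssi"` modes the `level` column
#' is the per-molecule Bernoulli probability at that site. For `"mixture"`
#' mode `level` is the marginal expectation
#' `pi * level_meth + (1 - pi) * level_unmeth`, and the two component levels
#' are carried in `level_meth` / `level_unmeth`; the component itself is
#' drawn once per molecule during fragment simulation, emulating a physical
#' mixture of two DNA pools.
#'
#' @param index Cytosine index from [index_cytosines()].
#' @param spec A [methylome_spec()].
#' @return The index tibble with added columns `level`, `level_meth`,
#'   `level_unmeth`; the spec is attached as attribute `"spec"`.
#' @export
realize_methylome <- function(index, spec) {
  stopifnot(inherits(spec, "methylome_spec"))
  is_cpg <- index$context == "CpG"
  cpg_level <- switch(spec$mode,
    uniform = spec$cpg_level,
    sssi = spec$sssi_level,
    mixture = spec$mixture_proportion * spec$component_levels[1] +
      (1 - spec$mixture_proportion) * spec$component_levels[2]
  )
  out <- index
  out$level <- ifelse(is_cpg, cpg_level, spec$noncpg_level)
  # context "unknown" sites are excluded from statistics but still convert
  # like any cytosine; give them the non-CpG level
  if (spec$mode == "mixture") {
    out$level_meth <- ifelse(is_cpg, spec$component_levels[1], spec$noncpg_level)
    out$level_unmeth <- ifelse(is_cpg, spec$component_levels[2], spec$noncpg_level)
  } else {
    out$level_meth <- out$level
    out$level_unmeth <- out$level
  }
  attr(out, "spec") <- spec
  out
}
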