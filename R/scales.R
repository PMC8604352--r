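#' Construct residue propensity scales
#'
#' Bundles the two residue-level statistical scales the model uses: a
#' helical propensity in `[0, 1]` per residue (the backbone coil-propensity
#' term is the mean of `1 - helical` over a window) and per-residue rotamer
#' probabilities `(p_r, p_0)` for the side-chain propensity term, where
#' `p_r` is the probability of the bound (lowest-energy) rotamer and `p_0`
#' the highest rotamer probability in the beta-strand backbone basin.
#'
#' @param helical Named numeric vector over [AA_STANDARD], values in
#'   `[0, 1]`.
#' @param rotamer Data frame with columns `residue`, `p_r`, `p_0`, one row
#'   per standard residue, `0 < p_r <= p_0 <= 1`.
#' @return An object of class `dnak_scales`.
#' @export
propensity_scales <- function(helical, rotamer) {
  helical <- helical[AA_STANDARD]
  if (anyNA(helical) || any(helical < 0) || any(helical > 1)) {
    stop("`helical` must cover all 20 residues with values in [0, 1]")
  }
  if (!is.data.frame(rotamer) ||
      !all(c("residue", "p_r", "p_0") %in% names(rotamer))) {
    stop("`rotamer` needs columns residue, p_r, p_0")
  }
  rotamer <- rotamer[match(AA_STANDARD, rotamer$residue), ]
  if (anyNA(rotamer$residue)) {
    stop("`rotamer` must cover all 20 standard residues")
  }
  with(rotamer, {
    if (any(!is.finite(p_r)) || any(!is.finite(p_0)) ||
        any(p_r <= 0) || any(p_0 > 1) || any(p_r > p_0)) {
      stop("rotamer probabilities must satisfy 0 < p_r <= p_0 <= 1")
    }
  })
  structure(list(helical = helical, rotamer = rotamer),
            class = "dnak_scales")
}

#' @export
print.dnak_scales <- function(x, ...) {
  cat("Residue propensity scales: helical in [",
      paste(sprintf("%.2f", range(x$helical)), collapse = ", "),
      "]; rotamer (p_r, p_0) for 20 residues\n", sep = "")
  invisible(x)
}

#' Default side-chain solvation scale (cyclohexane -> water)
#'
#' Experimental transfer free energies of amino-acid side-chain analogs
#' from cyclohexane to water (Radzicka & Wolfenden 1988), in kcal/mol.
#' Positive values mark hydrophobic side chains that prefer the apolar
#' phase, so burial (see [desolvation_energy()]) is favorable for them.
#' Proline has no measured analog; the shipped table documents an aliphatic
#' estimate. The backbone contribution is conventionally approximated with
#' the asparagine value. The scale is configuration, loaded from a TSV in
#' `inst/extdata`, and can be replaced by any table with the same columns.
#'
#' @param path Optional path to an alternative two-column TSV
#'   (`residue`, `dg_transfer`).
#' @return Named numeric vector over [AA_STANDARD] (kcal/mol).
#' @export
default_solvation_scale <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "solvation_chx_water.tsv",
                        package = "dnakscan", mustWork = TRUE)
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("residue", "dg_transfer") %in% names(tab))) {
    stop("solvation scale needs columns `residue`, `dg_transfer`")
  }
  sc <- setNames(tab$dg_transfer, tab$residue)[AA_STANDARD]
  if (anyNA(sc) || !all(is.finite(sc))) {
    stop("solvation scale must cover all 20 residues with finite values")
  }
  sc
}

#' Default residue propensity scales
#'
#' Helical propensities are Chou-Fasman alpha-helix propensities min-max
#' normalized to `[0, 1]` (G and P -> 0, E -> 1); the coil propensity used
#' by [backbone_propensity()] is their complement. The default rotamer
#' table sets `p_r = p_0` for every residue, making the side-chain
#' propensity energy identically zero: the published model assigns that
#' term zero weight, and the underlying rotamer-library statistics are
#' simulation inputs, not package data. Supply your own table to activate
#' the term.
#'
#' @param helical_path,rotamer_path Optional paths to alternative TSVs
#'   (`residue`, `helical` / `residue`, `p_r`, `p_0`).
#' @return A `dnak_scales` object.
#' @export
default_propensity_scales <- function(helical_path = NULL,
                                      rotamer_path = NULL) {
  if (is.null(helical_path)) {
    helical_path <- system.file("extdata", "helical_propensity.tsv",
                                package = "dnakscan", mustWork = TRUE)
  }
  if (is.null(rotamer_path)) {
    rotamer_path <- system.file("extdata", "rotamer_probabilities.tsv",
                                package = "dnakscan", mustWork = TRUE)
  }
  h <- utils::read.table(helical_path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("residue", "helical") %in% names(h))) {
    stop("helical scale needs columns `residue`, `helical`")
  }
  r <- utils::read.table(rotamer_path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "#")
  propensity_scales(setNames(h$helical, h$residue), r)
}
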