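#' Construct a weight set for the linear binding model
#'
#' The model combines six per-(site, residue) energy terms with
#' dimensionless term weights and per-site weights, adds a weighted
#' backbone coil-propensity term for the whole five-mer, and a scalar
#' penalty for reverse-orientation binding:
#' \deqn{E = w_{cp} E_{cp} + E_{reverse} +
#'       \sum_{site} w_{site} \sum_{term} w_{term} E^{res}_{site,term}}
#'
#' @param term_weights Named numeric vector over [ENERGY_TERMS].
#' @param w_cp Weight of the backbone coil-propensity term.
#' @param site_weights Named numeric vector over [DNAK_SITES].
#' @param e_reverse Energy penalty (kcal/mol) added to reverse-orientation
#'   scores.
#' @return An object of class `dnak_weights`.
#' @seealso [default_weights()] for the published values.
#' @export
weight_set <- function(term_weights, w_cp, site_weights, e_reverse) {
  term_weights <- term_weights[ENERGY_TERMS]
  site_weights <- site_weights[DNAK_SITES]
  if (anyNA(names(term_weights)) || anyNA(term_weights) ||
      !all(is.finite(term_weights))) {
    stop("`term_weights` must be finite and named over: ",
         paste(ENERGY_TERMS, collapse = ", "))
  }
  if (anyNA(names(site_weights)) || anyNA(site_weights) ||
      !all(is.finite(site_weights))) {
    stop("`site_weights` must be finite and named over: ",
         paste(DNAK_SITES, collapse = ", "))
  }
  if (!is.finite(w_cp) || !is.finite(e_reverse)) {
    stop("`w_cp` and `e_reverse` must be finite")
  }
  structure(
    list(term_weights = term_weights, w_cp = as.numeric(w_cp),
         site_weights = site_weights, e_reverse = as.numeric(e_reverse)),
    class = "dnak_weights"
  )
}

#' Published weights of the binding model
#'
#' The weight set selected by Monte-Carlo training against the DnaK
#' peptide-array data plus empirical choice of the site weights: van der
#' Waals 0.1, electrostatics 0.6, backbone strain 0, backbone
#' conformational (coil) propensity 0, side-chain conformational propensity
#' 0, substrate side-chain desolvation 1.0, site desolvation 0.4; site
#' weights 0.5, 0.5, 1.0, 0.2, 0.1 for sites -2 ... +2; reverse-orientation
#' penalty 0 kcal/mol.
#'
#' @return A `dnak_weights` object.
#' @export
default_weights <- function() {
  weight_set(
    term_weights = c(vdw = 0.1, elec = 0.6, strain = 0,
                     desolv_substrate = 1.0, desolv_site = 0.4,
                     sc_propensity = 0),
    w_cp = 0,
    site_weights = c("-2" = 0.5, "-1" = 0.5, "0" = 1.0,
                     "+1" = 0.2, "+2" = 0.1),
    e_reverse = 0
  )
}

#' @export
print.dnak_weights <- function(x, ...) {
  cat("DnaK model weights\n")
  cat("  term weights:\n")
  for (t in ENERGY_TERMS) cat(sprintf("    %-17s %g\n", t, x$term_weights[[t]]))
  cat(sprintf("    %-17s %g\n", "w_cp", x$w_cp))
  cat("  site weights: ",
      paste(sprintf("%s=%g", DNAK_SITES, x$site_weights), collapse = "  "),
      "\n", sep = "")
  cat(sprintf("  reverse penalty: %g kcal/mol\n", x$e_reverse))
  invisible(x)
}

#' Construct the energy-term basis set
#'
#' A complete 5-site x 20-residue x 6-term array of mean interaction
#' energies (kcal/mol), optionally with standard errors of the mean. All
#' values are binding free energies referenced to an all-glycine substrate.
#'
#' @param values Numeric array `5 x 20 x 6` with dimnames
#'   `list(DNAK_SITES, AA_STANDARD, ENERGY_TERMS)`, or an array whose
#'   dimnames cover those labels (it is re-indexed into canonical order).
#' @param sem Optional array of the same shape with non-negative standard
#'   errors.
#' @return An object of class `dnak_terms` with elements `values` and
#'   `sem` (possibly `NULL`).
#' @export
energy_term_matrix <- function(values, sem = NULL) {
  values <- canonical_term_array(values, "values")
  if (!all(is.finite(values))) stop("energy values must all be finite")
  if (!is.null(sem)) {
    sem <- canonical_term_array(sem, "sem")
    if (any(!is.finite(sem)) || any(sem < 0)) {
      stop("`sem` must be finite and >= 0")
    }
  }
  structure(list(values = values, sem = sem), class = "dnak_terms")
}

canonical_term_array <- function(a, what) {
  if (!is.array(a) || length(dim(a)) != 3L) {
    stop("`", what, "` must be a 3-d array (site x residue x term)")
  }
  dn <- dimnames(a)
  if (is.null(dn) || length(dn) != 3L) {
    stop("`", what, "` must carry dimnames (site, residue, term)")
  }
  miss_site <- setdiff(DNAK_SITES, dn[[1]])
  miss_res <- setdiff(AA_STANDARD, dn[[2]])
  miss_term <- setdiff(ENERGY_TERMS, dn[[3]])
  if (length(miss_site) || length(miss_res) || length(miss_term)) {
    stop("`", what, "` is missing cells for ",
         paste(c(
           if (length(miss_site)) paste("sites:", paste(miss_site, collapse = " ")),
           if (length(miss_res)) paste("residues:", paste(miss_res, collapse = " ")),
           if (length(miss_term)) paste("terms:", paste(miss_term, collapse = " "))
         ), collapse = "; "))
  }
  extra_res <- setdiff(dn[[2]], AA_STANDARD)
  if (length(extra_res)) {
    stop("unknown residue(s) in `", what, "`: ",
         paste(extra_res, collapse = ", "),
         " (only the 20 standard amino acids are modeled)")
  }
  a[DNAK_SITES, AA_STANDARD, ENERGY_TERMS, drop = FALSE]
}

#' @export
print.dnak_terms <- function(x, ...) {
  cat("DnaK energy-term basis set: 5 sites x 20 residues x 6 terms",
      if (!is.null(x$sem)) "(with SEMs)" else "(no SEMs)", "\n")
  cat("  value range:", paste(sprintf("%.3f", range(x$values)), collapse = " .. "),
      "kcal/mol\n")
  invisible(x)
}

#' Construct a position-specific scoring matrix (PSSM)
#'
#' A 5 x 20 matrix of combined per-site, per-residue scores in kcal/mol.
#' Site weights are already multiplied in; scoring a window is a plain sum
#' of five matrix lookups (plus the coil-propensity and reverse terms,
#' which are never folded into the matrix).
#'
#' @param scores Numeric matrix, rows named by [DNAK_SITES], columns by
#'   [AA_STANDARD] (any order; re-indexed into canonical order).
#' @param provenance Free-text note recording how the matrix was produced.
#' @return An object of class `dnak_pssm` (a matrix with a `provenance`
#'   attribute).
#' @export
pssm <- function(scores, provenance = "unspecified") {
  if (!is.matrix(scores) || !is.numeric(scores)) {
    stop("`scores` must be a numeric matrix")
  }
  if (is.null(rownames(scores)) || is.null(colnames(scores))) {
    stop("`scores` must have site rownames and residue colnames")
  }
  miss_site <- setdiff(DNAK_SITES, rownames(scores))
  miss_res <- setdiff(AA_STANDARD, colnames(scores))
  if (length(miss_site)) {
    stop("PSSM is missing site row(s): ", paste(miss_site, collapse = ", "))
  }
  if (length(miss_res)) {
    stop("PSSM is missing residue column(s): ", paste(miss_res, collapse = ", "))
  }
  extra <- setdiff(colnames(scores), AA_STANDARD)
  if (length(extra)) {
    stop("unknown residue column(s): ", paste(extra, collapse = ", "))
  }
  scores <- scores[DNAK_SITES, AA_STANDARD]
  if (!all(is.finite(scores))) stop("all 100 PSSM cells must be finite")
  structure(scores, provenance = provenance, class = c("dnak_pssm", "matrix"))
}

#' @export
print.dnak_pssm <- function(x, digits = 2, ...) {
  cat("DnaK 5 x 20 PSSM (kcal/mol); provenance:",
      attr(x, "provenance"), "\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Combine the energy basis set and weights into a PSSM
#'
#' Each cell is the site-weighted, term-weighted sum of the six energy
#' terms:
#' \deqn{S(site, res) = w_{site} \sum_{term} w_{term} E^{res}_{site,term}}
#' The coil-propensity weight `w_cp` and the reverse penalty `e_reverse`
#' are *not* folded in; they enter at scoring time (see
#' [score_fivemer()]).
#'
#' @param terms A `dnak_terms` basis set.
#' @param weights A `dnak_weights` object.
#' @return A `dnak_pssm`.
#' @export
combine_terms <- function(terms, weights) {
  if (!inherits(terms, "dnak_terms")) {
    stop("`terms` must be a dnak_terms object (see energy_term_matrix())")
  }
  if (!inherits(weights, "dnak_weights")) {
    stop("`weights` must be a dnak_weights object")
  }
  v <- terms$values
  sc <- matrix(0, nrow = 5, ncol = 20,
               dimnames = list(DNAK_SITES, AA_STANDARD))
  for (t in ENERGY_TERMS) {
    sc <- sc + weights$term_weights[[t]] * v[, , t]
  }
  sc <- sc * weights$site_weights[DNAK_SITES]
  pssm(sc, provenance = "combined from energy-term basis set and weights")
}
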