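#' Desolvation free energy from fractional side-chain burial
#'
#' Estimates the free-energy gain of burying a side chain on binding as the
#' buried fraction of its solvent-accessible surface area (SASA) times its
#' experimental transfer free energy from cyclohexane to water:
#' \deqn{E_{desolv} = -\frac{\Delta SASA_{bind}}{SASA_{tot}}
#'       \Delta G_{chx \to wat}}
#' Hydrophobic residues (positive transfer free energy) yield negative,
#' favorable desolvation energies when buried. The same formula, fed the
#' complementary SASA change of the neighbouring betaSBD atoms, gives the
#' site-desolvation term.
#'
#' @param delta_sasa SASA buried on binding, in square Angstroms; must lie
#'   in `[0, sasa_total]`.
#' @param sasa_total Total side-chain SASA (> 0).
#' @param dg_transfer Transfer free energy cyclohexane -> water, kcal/mol.
#' @return Energy in kcal/mol. Vectorized over all arguments.
#' @export
desolvation_energy <- function(delta_sasa, sasa_total, dg_transfer) {
  if (any(!is.finite(delta_sasa)) || any(!is.finite(sasa_total)) ||
      any(!is.finite(dg_transfer))) {
    stop("all arguments must be finite")
  }
  if (any(sasa_total <= 0)) stop("`sasa_total` must be > 0")
  if (any(delta_sasa < 0 | delta_sasa > sasa_total)) {
    stop("`delta_sasa` must lie in [0, sasa_total]")
  }
  -(delta_sasa / sasa_total) * dg_transfer
}

#' Side-chain rotamer conformational-propensity energy
#'
#' Entropic cost of restricting a side chain to its bound rotamer,
#' estimated from rotamer-library statistics as
#' \deqn{E_r = -kT \ln(P_r / P_0)}
#' where `P_r` is the probability of the lowest-energy (bound) rotamer and
#' `P_0` the highest rotamer probability for that residue in the
#' beta-strand backbone basin. Always non-negative; zero when the bound
#' rotamer is the most probable one.
#'
#' @param p_r Probability of the bound rotamer, `0 < p_r <= p_0`.
#' @param p_0 Highest rotamer probability, `p_r <= p_0 <= 1`.
#' @param kT Thermal energy in kcal/mol (default 0.6).
#' @return Energy in kcal/mol. Vectorized.
#' @export
sidechain_propensity_energy <- function(p_r, p_0, kT = KT_KCAL) {
  if (any(!is.finite(p_r)) || any(!is.finite(p_0))) {
    stop("probabilities must be finite")
  }
  if (any(p_r <= 0) || any(p_0 <= 0)) stop("probabilities must be positive")
  if (any(p_0 > 1)) stop("`p_0` must be <= 1")
  if (any(p_r > p_0)) stop("`p_r` must be <= `p_0`")
  -kT * log(p_r / p_0)
}

#' Backbone coil propensity of a five-mer
#'
#' Estimates the entropic cost of fixing the substrate backbone in the
#' extended bound conformation as the mean coil propensity, i.e. the mean
#' of (1 - helical propensity), over the five residues. Dimensionless; it
#' enters the model scaled by the weight `w_cp`.
#'
#' @param window Five-residue sequence (character scalar).
#' @param scales A `dnak_scales` object (see [propensity_scales()]).
#' @return Mean coil propensity in `[0, 1]`.
#' @export
backbone_propensity <- function(window, scales = default_propensity_scales()) {
  chars <- seq_chars(window)
  if (length(chars) != 5L) stop("`window` must have exactly 5 residues")
  bad <- setdiff(chars, AA_STANDARD)
  if (length(bad)) {
    stop("non-standard residue(s) in window: ", paste(bad, collapse = ", "))
  }
  mean(1 - scales$helical[chars])
}

#' Construct a per-frame energy trace
#'
#' Holds the per-frame records of one production simulation of a single
#' side chain bound at one site: van der Waals and electrostatic
#' interaction energies, backbone-restraint energy, side-chain SASA, and
#' total potential energy.
#'
#' @param frames A data frame with numeric columns `vdw`, `elec`,
#'   `restraint`, `sasa`, `total` (an optional `frame` index column is
#'   kept if present), at least 2 rows, all values finite.
#' @param residue,site,rotamer Optional metadata.
#' @return An object of class `dnak_trace`.
#' @export
frame_energy_trace <- function(frames, residue = NA_character_,
                               site = NA_character_, rotamer = NA_integer_) {
  need <- c("vdw", "elec", "restraint", "sasa", "total")
  if (!is.data.frame(frames)) stop("`frames` must be a data frame")
  miss <- setdiff(need, names(frames))
  if (length(miss)) {
    stop("`frames` is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(frames) < 2L) stop("a trace needs at least 2 frames")
  vals <- as.matrix(frames[need])
  if (!is.numeric(vals) || !all(is.finite(vals))) {
    stop("all trace values must be finite numbers")
  }
  if (is.null(frames$frame)) frames$frame <- seq_len(nrow(frames))
  structure(
    list(frames = frames[c("frame", need)],
         residue = residue, site = site, rotamer = rotamer),
    class = "dnak_trace"
  )
}

#' @export
print.dnak_trace <- function(x, ...) {
  cat(sprintf("Energy trace: %d frames (residue %s, site %s, rotamer %s)\n",
              nrow(x$frames), x$residue, x$site, x$rotamer))
  invisible(x)
}

# trailing frames kept after discarding the equilibration prefix
retained_frames <- function(trace, discard_fraction) {
  if (!inherits(trace, "dnak_trace")) stop("`trace` must be a dnak_trace")
  if (!is.finite(discard_fraction) || discard_fraction < 0 ||
      discard_fraction >= 1) {
    stop("`discard_fraction` must lie in [0, 1)")
  }
  n <- nrow(trace$frames)
  keep <- ceiling((1 - discard_fraction) * n)
  if (keep < 2L) {
    stop("fewer than 2 frames retained after discarding ",
         discard_fraction, " of ", n)
  }
  trace$frames[(n - keep + 1L):n, , drop = FALSE]
}

#' Aggregate a trace into per-term means and standard errors
#'
#' Production averages are taken over the trailing portion of each
#' trajectory: by default the first 2/5 of frames (the equilibration-like
#' prefix, 1.2 ns of a 3 ns run) are discarded and the last 3/5 retained.
#' The SEM is the sample standard deviation over retained frames divided by
#' the square root of their count (no autocorrelation correction).
#'
#' @param trace A `dnak_trace`.
#' @param discard_fraction Leading fraction of frames to drop, in `[0, 1)`;
#'   default `2/5`.
#' @return A data frame with columns `term` (`vdw`, `elec`, `restraint`,
#'   `sasa`, `total`), `mean`, `sem`, and `n_frames`.
#' @export
aggregate_trace <- function(trace, discard_fraction = 2 / 5) {
  kept <- retained_frames(trace, discard_fraction)
  terms <- c("vdw", "elec", "restraint", "sasa", "total")
  n <- nrow(kept)
  data.frame(
    term = terms,
    mean = vapply(terms, function(t) mean(kept[[t]]), numeric(1)),
    sem = vapply(terms, function(t) sd(kept[[t]]) / sqrt(n), numeric(1)),
    n_frames = n,
    row.names = NULL
  )
}

#' Select the run with the lowest mean total potential energy
#'
#' Among several rotamer-initiated runs of the same (residue, site), the
#' trajectory with the lowest aggregated mean total potential energy is the
#' one used for the basis set.
#'
#' @param traces Non-empty list of `dnak_trace` objects.
#' @param discard_fraction Passed to [aggregate_trace()].
#' @return Integer index of the selected trace (ties: lowest index).
#' @export
select_lowest_energy_run <- function(traces, discard_fraction = 2 / 5) {
  if (!is.list(traces) || length(traces) == 0L) {
    stop("`traces` must be a non-empty list")
  }
  means <- vapply(traces, function(tr) {
    agg <- aggregate_trace(tr, discard_fraction)
    agg$mean[agg$term == "total"]
  }, numeric(1))
  which.min(means)
}

#' Backbone strain energy relative to the all-glycine reference
#'
#' The restraint-violation energy measures how far the complex is pushed
#' from the conserved bound backbone conformation. Subtracting the
#' restraint energy of the same site with an all-glycine substrate isolates
#' the strain attributable to the probed side chain.
#'
#' @param trace A `dnak_trace` for the probed side chain.
#' @param glycine_reference_mean Aggregated mean restraint energy of the
#'   all-glycine complex at the same site (kcal/mol).
#' @param discard_fraction Passed to [aggregate_trace()].
#' @return Strain energy in kcal/mol.
#' @export
strain_energy <- function(trace, glycine_reference_mean,
                          discard_fraction = 2 / 5) {
  if (!is.finite(glycine_reference_mean)) {
    stop("`glycine_reference_mean` must be finite")
  }
  agg <- aggregate_trace(trace, discard_fraction)
  agg$mean[agg$term == "restraint"] - glycine_reference_mean
}
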