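#' Map window positions onto binding sites
#'
#' In the forward (N-to-C) orientation, window positions 1..5 occupy sites
#' -2, -1, 0, +1, +2; in the reverse (C-to-N) orientation they occupy +2,
#' +1, 0, -1, -2. The central residue sits at site 0 either way, so
#' `assign_sites(w, "reverse")` equals `assign_sites(reversed w,
#' "forward")`.
#'
#' @param window Five-residue sequence (in N-to-C order as it appears in
#'   the parent sequence).
#' @param orientation `"forward"` or `"reverse"`.
#' @return Named character vector: site label -> residue.
#' @export
assign_sites <- function(window, orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  chars <- seq_chars(window)
  if (length(chars) != 5L) stop("`window` must have exactly 5 residues")
  if (orientation == "forward") {
    setNames(chars, DNAK_SITES)
  } else {
    setNames(chars, rev(DNAK_SITES))[DNAK_SITES]
  }
}

# integer residue indices (NA for non-standard letters)
residue_index <- function(chars) match(chars, AA_STANDARD)

# Vectorized per-window scoring of one sequence. Returns per-site
# contribution matrices (5 x n windows) for both orientations, the coil
# propensity per window, and totals. Windows containing non-standard
# residues come out NA.
scan_core <- function(chars, scores, weights, scales) {
  idx <- residue_index(chars)
  L <- length(chars)
  n <- L - 4L
  cf <- cr <- matrix(NA_real_, nrow = 5L, ncol = n,
                     dimnames = list(DNAK_SITES, NULL))
  for (s in 1:5) {
    # forward: position s of the window occupies site s
    cf[s, ] <- scores[cbind(s, idx[s:(s + n - 1L)])]
    # reverse: site s is occupied by window position 6 - s
    p <- 6L - s
    cr[s, ] <- scores[cbind(s, idx[p:(p + n - 1L)])]
  }
  coil <- 1 - scales$helical[chars]
  ecp <- vapply(seq_len(n), function(j) mean(coil[j:(j + 4L)]), numeric(1))
  base_f <- colSums(cf)
  base_r <- colSums(cr)
  list(
    contrib_forward = cf,
    contrib_reverse = cr,
    ecp = as.numeric(ecp),
    total_forward = base_f + weights$w_cp * ecp,
    total_reverse = base_r + weights$w_cp * ecp + weights$e_reverse
  )
}

#' Score one five-mer window in a given orientation
#'
#' The score is the sum of the five PSSM lookups for the window's
#' site assignment, plus the weighted backbone coil-propensity term, plus
#' the reverse penalty when the orientation is reverse:
#' \deqn{E = \sum_{site} S(site, res_{site}) + w_{cp} E_{cp} + E_{reverse}}
#' Site weights are already folded into the PSSM and are not re-applied.
#'
#' @param window Five-residue sequence (N-to-C order).
#' @param orientation `"forward"` or `"reverse"`.
#' @param pssm A `dnak_pssm`.
#' @param weights A `dnak_weights`; only `w_cp` and `e_reverse` are used.
#' @param scales A `dnak_scales` for the coil-propensity term.
#' @return An object of class `dnak_fivemer` with fields `window`, `start`
#'   (NA unless produced by a scan), `orientation`, `site_assignment`,
#'   `site_contributions` (kcal/mol), `e_cp`, `e_cp_contribution`, and
#'   `total` (kcal/mol).
#' @export
score_fivemer <- function(window, orientation = c("forward", "reverse"),
                          pssm, weights = default_weights(),
                          scales = default_propensity_scales()) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(pssm, "dnak_pssm"), inherits(weights, "dnak_weights"))
  chars <- seq_chars(window)
  if (length(chars) != 5L) stop("`window` must have exactly 5 residues")
  bad <- setdiff(chars, AA_STANDARD)
  if (length(bad)) {
    stop("non-standard residue(s) in window '", window, "': ",
         paste(bad, collapse = ", "))
  }
  assignment <- assign_sites(window, orientation)
  contrib <- setNames(
    unclass(pssm)[cbind(DNAK_SITES, assignment[DNAK_SITES])], DNAK_SITES)
  e_cp <- backbone_propensity(window, scales)
  total <- sum(contrib) + weights$w_cp * e_cp +
    if (orientation == "reverse") weights$e_reverse else 0
  structure(
    list(window = paste(chars, collapse = ""), start = NA_integer_,
         orientation = orientation, site_assignment = assignment,
         site_contributions = contrib, e_cp = e_cp,
         e_cp_contribution = weights$w_cp * e_cp, total = total),
    class = "dnak_fivemer"
  )
}

#' @export
print.dnak_fivemer <- function(x, ...) {
  cat(sprintf("%s (%s%s): %.3f kcal/mol\n", x$window, x$orientation,
              if (!is.na(x$start)) sprintf(", start %d", x$start) else "",
              x$total))
  cat("  sites: ",
      paste(sprintf("%s:%s %.2f", DNAK_SITES, x$site_assignment,
                    x$site_contributions), collapse = " | "), "\n", sep = "")
  invisible(x)
}

#' Scan a sequence: score every five-mer window in both orientations
#'
#' Every admissible window/orientation pair of the (sanitized) sequence is
#' scored; windows containing non-standard residues are excluded from the
#' results with a logged warning and never become bests. Rows are ordered
#' by (start, forward-before-reverse); start offsets are 0-based.
#'
#' @param seq Sequence string (uppercased; `*` and whitespace stripped).
#' @param pssm A `dnak_pssm`.
#' @param weights A `dnak_weights`.
#' @param scales A `dnak_scales`.
#' @param id Optional sequence identifier carried into the result.
#' @return An object of class `dnak_scan`: a list with `id`, `sequence`,
#'   `scores` (data frame with columns `start`, `window`, `orientation`,
#'   residue and contribution columns per site, `e_cp`, `total`,
#'   `site0_pos` -- the 1-based position of the site-0 residue),
#'   `best_forward` and `best_reverse` (row indices into `scores`, NA when
#'   an orientation has no valid window), and `excluded` (data frame of
#'   skipped windows with reasons).
#' @export
scan_sequence <- function(seq, pssm, weights = default_weights(),
                          scales = default_propensity_scales(), id = NULL) {
  stopifnot(inherits(pssm, "dnak_pssm"), inherits(weights, "dnak_weights"))
  seq <- sanitize_sequence(seq)
  chars <- seq_chars(seq)
  L <- length(chars)
  if (L < 5L) stop("sequence too short to scan (need >= 5 residues, got ",
                   L, ")")
  core <- scan_core(chars, unclass(pssm), weights, scales)
  n <- L - 4L
  starts <- 0:(n - 1L)
  windows <- substring(seq, starts + 1L, starts + 5L)

  one_orientation <- function(orientation) {
    contrib <- if (orientation == "forward") core$contrib_forward
               else core$contrib_reverse
    res <- do.call(rbind, lapply(starts, function(st) {
      assign_sites(windows[st + 1L], orientation)
    }))
    out <- data.frame(start = starts, window = windows,
                      orientation = orientation, stringsAsFactors = FALSE)
    for (s in 1:5) out[[paste0("res_", DNAK_SITES[s])]] <- res[, s]
    for (s in 1:5) out[[paste0("e_", DNAK_SITES[s])]] <- contrib[s, ]
    out$e_cp <- core$ecp
    out$total <- if (orientation == "forward") core$total_forward
                 else core$total_reverse
    out$site0_pos <- starts + 3L
    out
  }
  scores <- rbind(one_orientation("forward"), one_orientation("reverse"))
  scores <- scores[order(scores$start,
                         scores$orientation != "forward"), , drop = FALSE]
  rownames(scores) <- NULL

  invalid <- is.na(scores$total)
  excluded <- data.frame(start = scores$start[invalid],
                         window = scores$window[invalid],
                         orientation = scores$orientation[invalid],
                         reason = rep("non-standard residue", sum(invalid)),
                         stringsAsFactors = FALSE)
  if (nrow(excluded) > 0L) {
    warning(sprintf(
      "%d window/orientation pair(s) skipped (non-standard residues): %s",
      nrow(excluded),
      paste(unique(excluded$window), collapse = ", ")))
    scores <- scores[!invalid, , drop = FALSE]
    rownames(scores) <- NULL
  }
  best_in <- function(orientation) {
    rows <- which(scores$orientation == orientation)
    if (length(rows) == 0L) return(NA_integer_)
    tot <- scores$total[rows]
    hits <- rows[tot == min(tot)]
    if (length(hits) > 1L) {
      message("tie for best ", orientation, " window at starts ",
              paste(scores$start[hits], collapse = ", "),
              "; keeping the smallest start")
    }
    hits[1L]  # rows are start-ordered, so this is the smallest start
  }
  structure(
    list(id = if (is.null(id)) NA_character_ else id, sequence = seq,
         scores = scores, best_forward = best_in("forward"),
         best_reverse = best_in("reverse"), excluded = excluded),
    class = "dnak_scan"
  )
}

#' @export
print.dnak_scan <- function(x, ...) {
  cat(sprintf("Scan of %s (%d residues): %d scored window/orientation pairs\n",
              if (is.na(x$id)) "sequence" else x$id, nchar(x$sequence),
              nrow(x$scores)))
  for (b in c("best_forward", "best_reverse")) {
    i <- x[[b]]
    if (!is.na(i)) {
      cat(sprintf("  %s: %s (start %d) %.3f kcal/mol\n", b,
                  x$scores$window[i], x$scores$start[i], x$scores$total[i]))
    }
  }
  if (nrow(x$excluded)) {
    cat("  excluded:", nrow(x$excluded), "window/orientation pair(s)\n")
  }
  invisible(x)
}

#' Predict the binding register within one orientation
#'
#' Returns the minimum-score window of the requested orientation; ties are
#' broken toward the smallest start offset (and logged). The register is
#' reported as the window string plus the 1-based position of the residue
#' that occupies site 0.
#'
#' @inheritParams scan_sequence
#' @param orientation Orientation to search within.
#' @return A `dnak_fivemer` (with `start` filled in).
#' @export
predict_register <- function(seq, pssm, weights = default_weights(),
                             scales = default_propensity_scales(),
                             orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  scan <- scan_sequence(seq, pssm, weights, scales)
  i <- if (orientation == "forward") scan$best_forward else scan$best_reverse
  if (is.na(i)) {
    stop("no valid ", orientation, " window in sequence")
  }
  out <- score_fivemer(scan$scores$window[i], orientation, pssm, weights,
                       scales)
  out$start <- scan$scores$start[i]
  out
}

#' Predict the binding orientation of a peptide
#'
#' Compares the best (minimum) forward and reverse window scores:
#' `delta = min forward - min reverse`. The call is `"forward"` when
#' `delta < -threshold`, `"reverse"` when `delta > threshold`, and
#' `"ambiguous"` when the gap is within the thermal-noise threshold
#' (kT = 0.6 kcal/mol by default). The threshold applies only to
#' orientation calls, never to register calls.
#'
#' @inheritParams scan_sequence
#' @param ambiguity_threshold Gap (kcal/mol) below which the orientation is
#'   reported ambiguous.
#' @return A list with `call` (`"forward"`, `"reverse"` or `"ambiguous"`),
#'   `delta` (kcal/mol), `best_forward` and `best_reverse`
#'   (`dnak_fivemer`s).
#' @export
predict_orientation <- function(seq, pssm, weights = default_weights(),
                                scales = default_propensity_scales(),
                                ambiguity_threshold = KT_KCAL) {
  scan <- scan_sequence(seq, pssm, weights, scales)
  if (is.na(scan$best_forward) || is.na(scan$best_reverse)) {
    stop("sequence has no valid window in at least one orientation")
  }
  bf <- score_fivemer(scan$scores$window[scan$best_forward], "forward",
                      pssm, weights, scales)
  bf$start <- scan$scores$start[scan$best_forward]
  br <- score_fivemer(scan$scores$window[scan$best_reverse], "reverse",
                      pssm, weights, scales)
  br$start <- scan$scores$start[scan$best_reverse]
  delta <- bf$total - br$total
  call <- if (delta < -ambiguity_threshold) "forward"
          else if (delta > ambiguity_threshold) "reverse"
          else "ambiguous"
  list(call = call, delta = delta, best_forward = bf, best_reverse = br)
}

#' Score a 13-mer as in peptide-array training
#'
#' A 13-mer has nine five-residue windows; its array-prediction score is
#' the minimum forward-orientation window score (arrays carry no
#' orientation information, so only the forward orientation is scanned).
#'
#' @param seq13 A 13-residue sequence.
#' @inheritParams scan_sequence
#' @return Score in kcal/mol (NA with a warning if no window is valid).
#' @export
score_13mer <- function(seq13, pssm, weights = default_weights(),
                        scales = default_propensity_scales()) {
  seq13 <- sanitize_sequence(seq13)
  chars <- seq_chars(seq13)
  if (length(chars) != 13L) {
    stop("`seq13` must have exactly 13 residues (got ", length(chars), ")")
  }
  core <- scan_core(chars, unclass(pssm), weights, scales)
  tot <- core$total_forward
  if (all(is.na(tot))) {
    warning("no valid forward window in 13-mer '", seq13, "'")
    return(NA_real_)
  }
  min(tot, na.rm = TRUE)
}

#' Screen a sequence set for reverse-orientation binding candidates
#'
#' Scans each sequence in both orientations and selects those whose best
#' reverse window beats the best forward window by more than `margin`
#' kcal/mol, ranked by that gap (most reverse-favoring first).
#'
#' @param seqs Character vector of sequences (names become ids).
#' @inheritParams scan_sequence
#' @param margin Required reverse-over-forward advantage in kcal/mol.
#' @return Data frame with columns `id`, `sequence`, `delta`
#'   (`min reverse - min forward`, negative for selected rows),
#'   `best_reverse_window`, `best_reverse_start`, `min_forward`,
#'   `min_reverse`, sorted by `delta` ascending. Possibly empty.
#' @export
find_reverse_candidates <- function(seqs, pssm, weights = default_weights(),
                                    scales = default_propensity_scales(),
                                    margin = 3.0) {
  if (length(seqs) == 0L) {
    return(data.frame(id = character(), sequence = character(),
                      delta = numeric(), best_reverse_window = character(),
                      best_reverse_start = integer(),
                      min_forward = numeric(), min_reverse = numeric()))
  }
  ids <- if (is.null(names(seqs))) sprintf("seq%04d", seq_along(seqs))
         else names(seqs)
  rows <- lapply(seq_along(seqs), function(i) {
    scan <- scan_sequence(seqs[[i]], pssm, weights, scales, id = ids[[i]])
    if (is.na(scan$best_forward) || is.na(scan$best_reverse)) return(NULL)
    mf <- scan$scores$total[scan$best_forward]
    mr <- scan$scores$total[scan$best_reverse]
    data.frame(id = ids[[i]], sequence = scan$sequence, delta = mr - mf,
               best_reverse_window = scan$scores$window[scan$best_reverse],
               best_reverse_start = scan$scores$start[scan$best_reverse],
               min_forward = mf, min_reverse = mr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  out <- out[out$delta < -margin, , drop = FALSE]
  out <- out[order(out$delta), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Min-max normalize 13-mer scores into array-like intensities
#'
#' Maps predicted 13-mer scores onto `[0, 1]` for visual comparison with
#' peptide-array fluorescence: scores are clamped to `[low, high]`, then
#' `low` (strong predicted binding) maps to 1 and `high` (no predicted
#' binding) maps to 0.
#'
#' @param scores Numeric vector of 13-mer scores (kcal/mol).
#' @param low,high Clamp thresholds in kcal/mol (defaults -10 and -6);
#'   `low < high` required.
#' @return Numeric vector of intensities in `[0, 1]`.
#' @export
normalize_array_prediction <- function(scores, low = -10, high = -6) {
  if (!is.finite(low) || !is.finite(high) || low >= high) {
    stop("`low` must be strictly less than `high`")
  }
  x <- pmin(pmax(scores, low), high)
  (high - x) / (high - low)
}
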