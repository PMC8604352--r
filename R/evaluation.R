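#' ROC curve for binder classification
#'
#' Scores are energies: lower means predicted binder, so records are
#' swept from the most negative score upward. At each distinct threshold
#' every record with a score at or below it is called positive, giving one
#' (FPR, TPR) point. The AUC is the trapezoidal area and equals the
#' Mann-Whitney concordance statistic (ties counted 1/2).
#'
#' @param scores Numeric scores (kcal/mol; lower = stronger predicted
#'   binding).
#' @param labels Logical (or 0/1) vector; `TRUE` marks a true binder. Both
#'   classes must be present.
#' @return An object of class `dnak_curve` with `type = "roc"`, a `points`
#'   data frame (`x` = FPR, `y` = TPR, `threshold`), and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  cs <- curve_sweep(scores, labels)
  pts <- data.frame(
    x = c(0, cs$fp / cs$n_neg),
    y = c(0, cs$tp / cs$n_pos),
    threshold = c(-Inf, cs$thresholds)
  )
  structure(list(type = "roc", points = pts, auc = trapezoid_auc(pts)),
            class = "dnak_curve")
}

#' Precision-recall curve for binder classification
#'
#' Same threshold sweep as [roc_curve()], reporting precision versus
#' recall. The leading point anchors recall 0 at the precision of the most
#' confident call; the AUC is the trapezoidal area over recall. A random
#' predictor's precision hovers at the positive prevalence.
#'
#' @inheritParams roc_curve
#' @return A `dnak_curve` with `type = "pr"`, `points` (`x` = recall,
#'   `y` = precision, `threshold`), and `auc`.
#' @export
pr_curve <- function(scores, labels) {
  cs <- curve_sweep(scores, labels)
  recall <- cs$tp / cs$n_pos
  precision <- cs$tp / (cs$tp + cs$fp)
  pts <- data.frame(
    x = c(0, recall),
    y = c(precision[1], precision),
    threshold = c(-Inf, cs$thresholds)
  )
  structure(list(type = "pr", points = pts, auc = trapezoid_auc(pts)),
            class = "dnak_curve")
}

# cumulative TP/FP counts at each distinct score threshold (ascending:
# most-confident energy first)
curve_sweep <- function(scores, labels) {
  if (is.numeric(labels)) labels <- labels != 0
  if (!is.logical(labels) || length(labels) != length(scores)) {
    stop("`labels` must be logical (or 0/1) and match `scores` in length")
  }
  if (anyNA(scores) || anyNA(labels) || !all(is.finite(scores))) {
    stop("scores and labels must be complete and finite")
  }
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC undefined: both classes must be present")
  }
  ord <- order(scores)
  s <- scores[ord]
  l <- labels[ord]
  cum_tp <- cumsum(l)
  cum_fp <- cumsum(!l)
  last <- which(diff(s) != 0)  # last index of each tie group
  keep <- c(last, length(s))
  list(thresholds = s[keep], tp = cum_tp[keep], fp = cum_fp[keep],
       n_pos = n_pos, n_neg = n_neg)
}

trapezoid_auc <- function(pts) {
  dx <- diff(pts$x)
  sum(dx * (head(pts$y, -1) + tail(pts$y, -1)) / 2)
}

#' @export
print.dnak_curve <- function(x, ...) {
  cat(sprintf("%s curve: %d points, AUC = %.4f\n",
              toupper(x$type), nrow(x$points), x$auc))
  invisible(x)
}

# shared benchmark-record validation; returns kept and excluded data frames
benchmark_prepare <- function(records, min_length) {
  need <- c("sequence", "orientation", "core")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("benchmark records missing column(s): ", paste(miss, collapse = ", "))
  }
  records$sequence <- vapply(records$sequence, sanitize_sequence, character(1))
  reasons <- character(nrow(records))
  reasons[!vapply(records$sequence, is_standard_sequence, logical(1))] <-
    "non-standard residue"
  short <- reasons == "" & nchar(records$sequence) < min_length
  reasons[short] <- sprintf("shorter than %d residues", min_length)
  list(kept = records[reasons == "", , drop = FALSE],
       excluded = cbind(records[reasons != "", , drop = FALSE],
                        reason = reasons[reasons != ""]))
}

#' Benchmark register predictions against observed structures
#'
#' For each forward-bound benchmark peptide, the observed core five-mer is
#' counted correct only when it attains the *global* minimum score across
#' all windows of both orientations -- a forward-bound peptide predicted to
#' bind reverse counts as incorrect. Register prediction needs more than
#' five residues, so peptides of length 5 and peptides with non-standard
#' residues (e.g. cyclohexylalanine) are excluded and listed in the report.
#'
#' @param records Data frame with columns `sequence`, `orientation`
#'   (observed; only `"forward"` rows are benchmarked), `core` (observed
#'   five-mer), `offset` (0-based start of the core in the sequence;
#'   derived from the first match if absent), and optionally
#'   `structure_id`.
#' @param pssm,weights,scales Model to benchmark.
#' @return List with `n_correct`, `n_total`, `report` (per-record predicted
#'   vs observed with score margins), and `excluded`.
#' @export
benchmark_registers <- function(records, pssm, weights = default_weights(),
                                scales = default_propensity_scales()) {
  prep <- benchmark_prepare(records, min_length = 6L)
  kept <- prep$kept[prep$kept$orientation == "forward", , drop = FALSE]
  if (is.null(kept$offset)) {
    kept$offset <- vapply(seq_len(nrow(kept)), function(i) {
      regexpr(kept$core[i], kept$sequence[i], fixed = TRUE)[[1]] - 1L
    }, integer(1))
  }
  rows <- lapply(seq_len(nrow(kept)), function(i) {
    rec <- kept[i, ]
    if (rec$offset < 0 ||
        substring(rec$sequence, rec$offset + 1, rec$offset + 5) != rec$core) {
      stop("benchmark row ", i, ": core '", rec$core,
           "' not found at offset ", rec$offset, " of '", rec$sequence, "'")
    }
    scan <- scan_sequence(rec$sequence, pssm, weights, scales)
    best <- which.min(scan$scores$total)
    obs <- which(scan$scores$start == rec$offset &
                   scan$scores$orientation == "forward")
    obs_total <- if (length(obs)) scan$scores$total[obs] else NA_real_
    data.frame(
      sequence = rec$sequence,
      structure_id = if (!is.null(rec$structure_id)) rec$structure_id
                     else NA_character_,
      observed_core = rec$core, observed_offset = rec$offset,
      predicted_window = scan$scores$window[best],
      predicted_offset = scan$scores$start[best],
      predicted_orientation = scan$scores$orientation[best],
      predicted_total = scan$scores$total[best],
      observed_total = obs_total,
      margin = obs_total - scan$scores$total[best],
      correct = length(obs) == 1L && obs == best,
      stringsAsFactors = FALSE
    )
  })
  report <- do.call(rbind, rows)
  list(n_correct = sum(report$correct), n_total = nrow(report),
       report = report, excluded = prep$excluded)
}

#' Benchmark orientation predictions against observed structures
#'
#' Calls [predict_orientation()] on each benchmark peptide; a record is
#' correct when the call matches the observed orientation, and ambiguous
#' calls (forward/reverse gap within the kT threshold) are counted
#' separately -- never as correct, even when the gap has the right sign.
#'
#' @inheritParams benchmark_registers
#' @param threshold Ambiguity threshold in kcal/mol (default 0.6).
#' @return List with `n_correct`, `n_ambiguous`, `n_total`, `report`, and
#'   `excluded`.
#' @export
benchmark_orientations <- function(records, pssm,
                                   weights = default_weights(),
                                   scales = default_propensity_scales(),
                                   threshold = KT_KCAL) {
  prep <- benchmark_prepare(records, min_length = 5L)
  kept <- prep$kept
  rows <- lapply(seq_len(nrow(kept)), function(i) {
    rec <- kept[i, ]
    pred <- predict_orientation(rec$sequence, pssm, weights, scales,
                                ambiguity_threshold = threshold)
    data.frame(
      sequence = rec$sequence,
      structure_id = if (!is.null(rec$structure_id)) rec$structure_id
                     else NA_character_,
      observed = rec$orientation, call = pred$call, delta = pred$delta,
      correct = pred$call == rec$orientation,
      ambiguous = pred$call == "ambiguous",
      stringsAsFactors = FALSE
    )
  })
  report <- do.call(rbind, rows)
  list(n_correct = sum(report$correct), n_ambiguous = sum(report$ambiguous),
       n_total = nrow(report), report = report, excluded = prep$excluded)
}
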