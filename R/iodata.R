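# --- shared tabular helpers -------------------------------------------------

# detect the delimiter of a headered text table from its first line
sniff_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L) stop("file is empty: ", path)
  if (grepl("\t", first)) "\t" else ","
}

read_table_file <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(delim)) delim <- sniff_delim(path)
  utils::read.table(path, header = TRUE, sep = delim,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "#")
}

write_table_file <- function(df, path, delim = "\t", digits = 6) {
  num <- vapply(df, is.double, logical(1))  # keep integer columns unpadded
  df[num] <- lapply(df[num], function(x) formatC(x, digits = digits,
                                                 format = "f"))
  utils::write.table(df, path, sep = delim, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, " file is missing column(s): ", paste(miss, collapse = ", "))
  }
}

# attach provenance per the Dataset contract: kept/excluded accounting
with_provenance <- function(x, path, n_rows, excluded) {
  attr(x, "provenance") <- list(path = path, n_rows = n_rows,
                                n_kept = n_rows - nrow(excluded),
                                excluded = excluded)
  x
}

#' Provenance of a read dataset
#'
#' Readers never silently drop rows: every exclusion is enumerated with its
#' row number and reason, and kept + excluded always equals the file's row
#' count.
#'
#' @param x An object returned by one of the `read_*` functions.
#' @return List with `path`, `n_rows`, `n_kept`, and an `excluded` data
#'   frame (`row`, `reason`, plus the offending fields).
#' @export
dataset_provenance <- function(x) attr(x, "provenance")

no_exclusions <- function() {
  data.frame(row = integer(), reason = character(),
             stringsAsFactors = FALSE)
}

# --- FASTA ------------------------------------------------------------------

#' Read protein sequences from FASTA
#'
#' Wrapped lines are joined and sequences uppercased. Empty records and
#' files without a single record are rejected.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e))
  )
  if (length(set) == 0L) stop("FASTA '", path, "' contains no records")
  if (any(Biostrings::width(set) == 0L)) {
    stop("FASTA '", path, "' has empty record(s): ",
         paste(names(set)[Biostrings::width(set) == 0L], collapse = ", "))
  }
  # keep only the id token of each header
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[[`, character(1), 1L)
  setNames(toupper(as.character(set)), ids)
}

#' Write protein sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%04d", seq_along(seqs))
  set <- Biostrings::AAStringSet(toupper(seqs))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# --- PSSM -------------------------------------------------------------------

#' Read a 5 x 20 PSSM from a delimited text file
#'
#' Expects a header row with a `site` column plus the 20 standard residue
#' columns, and exactly five rows labeled `-2, -1, 0, +1, +2`. A transposed
#' file (residues as rows) or a missing/duplicated site is reported as a
#' schema error naming the offending cell, never silently misread. The
#' published 5 x 20 score matrix, distributed as a spreadsheet, can be
#' ingested by exporting it to CSV with this layout.
#'
#' @param path Input path (TSV or CSV; delimiter sniffed, override with
#'   `delim`).
#' @param delim Optional delimiter override.
#' @return A `dnak_pssm` with provenance recording the path.
#' @export
read_pssm <- function(path, delim = NULL) {
  tab <- read_table_file(path, delim)
  if (!"site" %in% names(tab)) {
    if (nrow(tab) == 20L) {
      stop("PSSM file '", path,
           "' looks transposed (20 rows); expected 5 site rows x 20 ",
           "residue columns with a `site` column")
    }
    stop("PSSM file '", path, "' is missing the `site` column")
  }
  sites <- as.character(tab$site)
  sites[sites %in% c("1", "2")] <- paste0("+", sites[sites %in% c("1", "2")])
  if (anyDuplicated(sites)) {
    stop("duplicate site row(s) in '", path, "': ",
         paste(sites[duplicated(sites)], collapse = ", "))
  }
  miss <- setdiff(DNAK_SITES, sites)
  if (length(miss)) {
    stop("PSSM file '", path, "' is missing site row(s): ",
         paste(miss, collapse = ", "))
  }
  miss_res <- setdiff(AA_STANDARD, names(tab))
  if (length(miss_res)) {
    stop("PSSM file '", path, "' is missing residue column(s): ",
         paste(miss_res, collapse = ", "))
  }
  m <- matrix(NA_real_, 5, 20, dimnames = list(DNAK_SITES, AA_STANDARD))
  for (res in AA_STANDARD) {
    col <- tab[[res]]
    if (!is.numeric(col)) {
      bad_row <- which(is.na(suppressWarnings(as.numeric(col))))[1]
      stop("non-numeric cell in '", path, "': site ", sites[bad_row],
           ", residue ", res, " = '", col[bad_row], "'")
    }
    m[sites, res] <- col
  }
  pssm(m, provenance = paste("loaded from", path))
}

#' Write a PSSM to a delimited text file
#'
#' Fixed at 6 decimal places (kcal/mol implied) so round trips are lossless
#' at that precision and diffs are reproducible.
#'
#' @param pssm A `dnak_pssm`.
#' @param path Output path.
#' @param delim Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_pssm <- function(pssm, path, delim = "\t") {
  stopifnot(inherits(pssm, "dnak_pssm"))
  df <- data.frame(site = DNAK_SITES, unclass(pssm), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table_file(df, path, delim)
}

# --- energy-term matrix -----------------------------------------------------

#' Read an energy-term basis set from tidy tabular text
#'
#' One row per (site, residue, term) with columns `site`, `residue`,
#' `term`, `value`, and optionally `sem`. All 5 x 20 x 6 cells must be
#' present exactly once; violations are reported with row numbers.
#'
#' @inheritParams read_pssm
#' @return A `dnak_terms`.
#' @export
read_terms <- function(path, delim = NULL) {
  tab <- read_table_file(path, delim)
  require_columns(tab, c("site", "residue", "term", "value"), "terms")
  tab$site <- as.character(tab$site)
  tab$site[tab$site %in% c("1", "2")] <-
    paste0("+", tab$site[tab$site %in% c("1", "2")])
  bad <- which(!(tab$site %in% DNAK_SITES) |
                 !(tab$residue %in% AA_STANDARD) |
                 !(tab$term %in% ENERGY_TERMS))
  if (length(bad)) {
    stop("terms file '", path, "' has invalid site/residue/term at row(s): ",
         paste(head(bad, 10), collapse = ", "))
  }
  key <- paste(tab$site, tab$residue, tab$term)
  if (anyDuplicated(key)) {
    stop("terms file '", path, "' has duplicate cell(s) at row(s): ",
         paste(head(which(duplicated(key)), 10), collapse = ", "))
  }
  values <- array(NA_real_, dim = c(5, 20, 6),
                  dimnames = list(DNAK_SITES, AA_STANDARD, ENERGY_TERMS))
  values[cbind(tab$site, tab$residue, tab$term)] <- tab$value
  if (anyNA(values)) {
    stop("terms file '", path, "' is missing ",
         sum(is.na(values)), " of 600 cells")
  }
  sem <- NULL
  if ("sem" %in% names(tab) && !all(is.na(tab$sem))) {
    sem <- array(NA_real_, dim = dim(values), dimnames = dimnames(values))
    sem[cbind(tab$site, tab$residue, tab$term)] <- tab$sem
  }
  energy_term_matrix(values, sem)
}

#' Write an energy-term basis set to tidy tabular text
#'
#' @param terms A `dnak_terms`.
#' @inheritParams write_pssm
#' @return `path`, invisibly.
#' @export
write_terms <- function(terms, path, delim = "\t") {
  stopifnot(inherits(terms, "dnak_terms"))
  grid <- expand.grid(site = DNAK_SITES, residue = AA_STANDARD,
                      term = ENERGY_TERMS, stringsAsFactors = FALSE)
  grid$value <- terms$values[cbind(grid$site, grid$residue, grid$term)]
  if (!is.null(terms$sem)) {
    grid$sem <- terms$sem[cbind(grid$site, grid$residue, grid$term)]
  }
  write_table_file(grid, path, delim)
}

# --- peptide-array table ----------------------------------------------------

#' Read a classed peptide-array table
#'
#' Columns `sequence` (13-mers) and `label` (one of `strong`, `binder`,
#' `neutral`, `nonbinder`), plus an optional `protein_id`. Rows with a
#' wrong-length or non-standard sequence or an unknown label are excluded
#' with a logged reason (see [dataset_provenance()]) and a warning.
#'
#' @inheritParams read_pssm
#' @return Data frame of kept records with provenance attached.
#' @export
read_array_table <- function(path, delim = NULL) {
  tab <- read_table_file(path, delim)
  require_columns(tab, c("sequence", "label"), "peptide-array")
  tab$sequence <- vapply(tab$sequence, sanitize_sequence, character(1))
  reason <- character(nrow(tab))
  reason[nchar(tab$sequence) != 13L] <- "not a 13-mer"
  reason[reason == "" &
           !vapply(tab$sequence, is_standard_sequence, logical(1))] <-
    "non-standard residue"
  reason[reason == "" & !(tab$label %in% ARRAY_CLASSES)] <- "unknown label"
  excluded <- data.frame(row = which(reason != ""),
                         reason = reason[reason != ""],
                         sequence = tab$sequence[reason != ""],
                         stringsAsFactors = FALSE)
  if (nrow(excluded)) {
    warning("excluded ", nrow(excluded), " of ", nrow(tab),
            " peptide-array row(s); see dataset_provenance()")
  }
  kept <- tab[reason == "", , drop = FALSE]
  rownames(kept) <- NULL
  with_provenance(kept, path, nrow(tab), excluded)
}

#' Write a classed peptide-array table
#'
#' @param records Data frame with columns `sequence`, `label` (and
#'   optionally `protein_id`).
#' @inheritParams write_pssm
#' @return `path`, invisibly.
#' @export
write_array_table <- function(records, path, delim = "\t") {
  require_columns(records, c("sequence", "label"), "peptide-array")
  write_table_file(records, path, delim)
}

# --- structure-benchmark table ----------------------------------------------

#' Read a structural benchmark table
#'
#' Mirrors the layout of published DnaK-substrate structure tables: one row
#' per peptide with columns `sequence`, `orientation` (`forward` or
#' `reverse`), `core` (observed core five-mer), optional `offset` (0-based
#' position of the core; derived from the first match when absent) and
#' `structure_id`. Peptides containing residues outside the 20-letter
#' alphabet (e.g. Z, cyclohexylalanine) are excluded with a logged reason
#' -- the basis set does not cover them -- as are rows whose core is not a
#' substring at the stated offset.
#'
#' @inheritParams read_pssm
#' @return Data frame of kept records with provenance attached.
#' @export
read_benchmark_table <- function(path, delim = NULL) {
  tab <- read_table_file(path, delim)
  require_columns(tab, c("sequence", "orientation", "core"), "benchmark")
  tab$sequence <- vapply(tab$sequence, sanitize_sequence, character(1))
  tab$core <- vapply(tab$core, sanitize_sequence, character(1))
  if (is.null(tab$offset)) {
    tab$offset <- vapply(seq_len(nrow(tab)), function(i) {
      regexpr(tab$core[i], tab$sequence[i], fixed = TRUE)[[1]] - 1L
    }, integer(1))
  }
  reason <- character(nrow(tab))
  reason[!vapply(tab$sequence, is_standard_sequence, logical(1))] <-
    "non-standard residue"
  reason[reason == "" & !(tab$orientation %in% c("forward", "reverse"))] <-
    "unknown orientation"
  core_ok <- vapply(seq_len(nrow(tab)), function(i) {
    nchar(tab$core[i]) == 5L && tab$offset[i] >= 0L &&
      substring(tab$sequence[i], tab$offset[i] + 1L,
                tab$offset[i] + 5L) == tab$core[i]
  }, logical(1))
  reason[reason == "" & !core_ok] <- "core not at stated offset"
  excluded <- data.frame(row = which(reason != ""),
                         reason = reason[reason != ""],
                         sequence = tab$sequence[reason != ""],
                         stringsAsFactors = FALSE)
  if (nrow(excluded)) {
    warning("excluded ", nrow(excluded), " of ", nrow(tab),
            " benchmark row(s); see dataset_provenance()")
  }
  kept <- tab[reason == "", , drop = FALSE]
  kept$length <- nchar(kept$sequence)  # both register denominators stay recoverable
  rownames(kept) <- NULL
  with_provenance(kept, path, nrow(tab), excluded)
}

#' Write a structural benchmark table
#'
#' @param records Data frame with columns `sequence`, `orientation`,
#'   `core` (and optionally `offset`, `structure_id`).
#' @inheritParams write_pssm
#' @return `path`, invisibly.
#' @export
write_benchmark_table <- function(records, path, delim = "\t") {
  require_columns(records, c("sequence", "orientation", "core"), "benchmark")
  records$length <- NULL
  write_table_file(records, path, delim)
}

# --- frame-energy traces ----------------------------------------------------

#' Read a per-frame energy trace
#'
#' One row per simulation frame with columns `frame`, `vdw`, `elec`,
#' `restraint`, `sasa`, `total` (kcal/mol except `sasa`, square Angstroms).
#'
#' @inheritParams read_pssm
#' @param residue,site,rotamer Optional metadata to attach.
#' @return A `dnak_trace`.
#' @export
read_trace <- function(path, delim = NULL, residue = NA_character_,
                       site = NA_character_, rotamer = NA_integer_) {
  tab <- read_table_file(path, delim)
  require_columns(tab, c("frame", "vdw", "elec", "restraint", "sasa",
                         "total"), "trace")
  frame_energy_trace(tab, residue = residue, site = site, rotamer = rotamer)
}

#' Write a per-frame energy trace
#'
#' @param trace A `dnak_trace`.
#' @inheritParams write_pssm
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, delim = "\t") {
  stopifnot(inherits(trace, "dnak_trace"))
  write_table_file(trace$frames, path, delim)
}

# --- scan output ------------------------------------------------------------

#' Write scan results to a per-window TSV
#'
#' One row per scored window/orientation pair with the residue occupying
#' each site, per-site energy contributions, the coil propensity, and the
#' total (kcal/mol).
#'
#' @param scans A `dnak_scan` or list of them.
#' @inheritParams write_pssm
#' @return `path`, invisibly.
#' @export
write_scan_table <- function(scans, path, delim = "\t") {
  if (inherits(scans, "dnak_scan")) scans <- list(scans)
  rows <- lapply(scans, function(sc) {
    cbind(seq_id = sc$id, sc$scores, stringsAsFactors = FALSE)
  })
  write_table_file(do.call(rbind, rows), path, delim)
}

#' Write a per-sequence orientation summary TSV
#'
#' One row per sequence: best forward and reverse windows and totals, the
#' forward-minus-reverse gap, and the orientation call.
#'
#' @param scans A `dnak_scan` or list of them.
#' @param threshold Ambiguity threshold in kcal/mol.
#' @inheritParams write_pssm
#' @return `path`, invisibly.
#' @export
write_scan_summary <- function(scans, path, delim = "\t",
                               threshold = KT_KCAL) {
  if (inherits(scans, "dnak_scan")) scans <- list(scans)
  rows <- lapply(scans, function(sc) {
    bf <- sc$best_forward
    br <- sc$best_reverse
    delta <- if (!is.na(bf) && !is.na(br)) {
      sc$scores$total[bf] - sc$scores$total[br]
    } else NA_real_
    call <- if (is.na(delta)) NA_character_
            else if (delta < -threshold) "forward"
            else if (delta > threshold) "reverse" else "ambiguous"
    data.frame(
      seq_id = sc$id,
      best_forward_window = if (is.na(bf)) NA else sc$scores$window[bf],
      best_forward_total = if (is.na(bf)) NA else sc$scores$total[bf],
      best_reverse_window = if (is.na(br)) NA else sc$scores$window[br],
      best_reverse_total = if (is.na(br)) NA else sc$scores$total[br],
      delta = delta, orientation_call = call,
      stringsAsFactors = FALSE
    )
  })
  write_table_file(do.call(rbind, rows), path, delim)
}

# --- weights config ----------------------------------------------------------

WEIGHT_KEYS <- c("vdw", "elec", "strain", "backbone_propensity",
                 "sc_propensity", "desolv_substrate", "desolv_site",
                 "site_-2", "site_-1", "site_0", "site_+1", "site_+2",
                 "reverse_penalty")

#' Read a weight set from a flat key-value config file
#'
#' JSON (default) or YAML by extension. Keys: the six energy-term names
#' (with `backbone_propensity` for the coil-propensity weight), the five
#' `site_*` weights, and `reverse_penalty` (kcal/mol). Missing keys are an
#' error; unknown keys are reported.
#'
#' @param path Path to a `.json`, `.yml` or `.yaml` file.
#' @return A `dnak_weights`.
#' @export
read_weights <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML weights needs the `yaml` package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  miss <- setdiff(WEIGHT_KEYS, names(vals))
  if (length(miss)) {
    stop("weights file '", path, "' is missing key(s): ",
         paste(miss, collapse = ", "))
  }
  extra <- setdiff(names(vals), WEIGHT_KEYS)
  if (length(extra)) {
    stop("weights file '", path, "' has unknown key(s): ",
         paste(extra, collapse = ", "))
  }
  vals <- vapply(vals, as.numeric, numeric(1))
  weight_set(
    term_weights = c(vdw = vals[["vdw"]], elec = vals[["elec"]],
                     strain = vals[["strain"]],
                     desolv_substrate = vals[["desolv_substrate"]],
                     desolv_site = vals[["desolv_site"]],
                     sc_propensity = vals[["sc_propensity"]]),
    w_cp = vals[["backbone_propensity"]],
    site_weights = setNames(vals[paste0("site_", DNAK_SITES)], DNAK_SITES),
    e_reverse = vals[["reverse_penalty"]]
  )
}

#' Write a weight set to a flat key-value JSON config
#'
#' @param weights A `dnak_weights`.
#' @param path Output path (JSON).
#' @return `path`, invisibly.
#' @export
write_weights <- function(weights, path) {
  stopifnot(inherits(weights, "dnak_weights"))
  vals <- c(as.list(weights$term_weights["vdw"]),
            list(elec = weights$term_weights[["elec"]],
                 strain = weights$term_weights[["strain"]],
                 backbone_propensity = weights$w_cp,
                 sc_propensity = weights$term_weights[["sc_propensity"]],
                 desolv_substrate = weights$term_weights[["desolv_substrate"]],
                 desolv_site = weights$term_weights[["desolv_site"]]),
            setNames(as.list(weights$site_weights),
                     paste0("site_", DNAK_SITES)),
            list(reverse_penalty = weights$e_reverse))
  jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
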