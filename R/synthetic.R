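#' Specification of a synthetic fixture set
#'
#' Controls the seeded generators that produce every input the pipeline
#' needs with planted ground truth: an energy basis set and its PSSM, a
#' classed peptide array, a structural benchmark, and per-frame energy
#' traces. The class proportions default to the composition of the DnaK
#' peptide-array study (7% strong binders, 23% binders, 21% neutral, 48%
#' nonbinders; renormalized to sum to 1) and the default noise scale of
#' 1 kcal/mol stands in for the semi-quantitative nature of array
#' fluorescence.
#'
#' @param seed Integer seed; fully determines every generator's output.
#' @param n_peptides Number of array 13-mers.
#' @param n_proteins,protein_length Synthetic source proteins to tile.
#' @param class_proportions Named numeric over `strong`, `binder`,
#'   `neutral`, `nonbinder`; normalized to sum to 1.
#' @param noise_scale Gaussian noise (kcal/mol) added to truth scores
#'   before class assignment.
#' @param n_benchmark Number of benchmark peptides.
#' @param benchmark_lengths Candidate peptide lengths for the benchmark.
#' @param corruption_rate Fraction of benchmark records whose planted
#'   core/orientation is deliberately mislabeled (to test imperfect-accuracy
#'   reporting).
#' @param n_traces,trace_frames Energy-trace set dimensions.
#' @return An object of class `dnak_fixture_spec`.
#' @export
fixture_spec <- function(seed = 1, n_peptides = 400, n_proteins = 8,
                         protein_length = 160,
                         class_proportions = c(strong = 0.07, binder = 0.23,
                                               neutral = 0.21,
                                               nonbinder = 0.48),
                         noise_scale = 1, n_benchmark = 30,
                         benchmark_lengths = 7:10, corruption_rate = 0,
                         n_traces = 5, trace_frames = 60) {
  if (!all(ARRAY_CLASSES %in% names(class_proportions))) {
    stop("`class_proportions` must name all of: ",
         paste(ARRAY_CLASSES, collapse = ", "))
  }
  class_proportions <- class_proportions[ARRAY_CLASSES]
  if (any(class_proportions <= 0)) stop("class proportions must be positive")
  class_proportions <- class_proportions / sum(class_proportions)
  if (corruption_rate < 0 || corruption_rate > 1) {
    stop("`corruption_rate` must be in [0, 1]")
  }
  structure(
    list(seed = as.integer(seed), n_peptides = as.integer(n_peptides),
         n_proteins = as.integer(n_proteins),
         protein_length = as.integer(protein_length),
         class_proportions = class_proportions,
         noise_scale = noise_scale, n_benchmark = as.integer(n_benchmark),
         benchmark_lengths = as.integer(benchmark_lengths),
         corruption_rate = corruption_rate,
         n_traces = as.integer(n_traces),
         trace_frames = as.integer(trace_frames)),
    class = "dnak_fixture_spec"
  )
}

# residues the binding motif clusters on (branched hydrophobics + F)
HYDROPHOBIC_CORE <- c("L", "I", "V", "M", "F")

# draw one random protein-like sequence: mostly background composition,
# with occasional DnaK-motif-like clusters of 3-5 branched hydrophobics
# flanked by basic residues, so binders occur at realistic rates
random_protein <- function(length_out) {
  background <- setdiff(AA_STANDARD, character(0))
  out <- character(0)
  while (length(out) < length_out) {
    if (runif(1) < 0.10) {
      cluster <- sample(HYDROPHOBIC_CORE, sample(3:5, 1), replace = TRUE)
      out <- c(out, sample(c("K", "R"), 1), cluster, sample(c("K", "R"), 1))
    } else {
      out <- c(out, sample(background, 1))
    }
  }
  paste(out[seq_len(length_out)], collapse = "")
}

#' Generate a synthetic energy basis set and its PSSM
#'
#' Builds a plausible 5 x 20 x 6 term array: burial-fraction-scaled
#' desolvation from the packaged solvation scale (site 0 most buried),
#' size-correlated van der Waals terms that weaken toward the outer sites,
#' small electrostatic/strain/propensity terms, plus seeded Gaussian noise.
#' By construction hydrophobic residues are favored at sites -2..0 and the
#' site-0 score spread exceeds the site +2 spread.
#'
#' @param spec A `dnak_fixture_spec`.
#' @param weights Weights used to combine the planted terms (default
#'   [default_weights()]).
#' @return List with `pssm` (a `dnak_pssm`), `terms` (the raw
#'   `dnak_terms`), and `weights`.
#' @export
gen_pssm <- function(spec = fixture_spec(), weights = default_weights()) {
  stopifnot(inherits(spec, "dnak_fixture_spec"))
  solv <- default_solvation_scale()
  with_seed(spec$seed, {
    burial <- c("-2" = 0.55, "-1" = 0.65, "0" = 0.90, "+1" = 0.35,
                "+2" = 0.25)
    depth <- c("-2" = 0.6, "-1" = 0.8, "0" = 1.0, "+1" = 0.4, "+2" = 0.3)
    # crude side-chain size proxy: heavy-atom-ish ordering
    size <- c(A = 1, C = 2, D = 4, E = 5, F = 7, G = 0.5, H = 6, I = 4,
              K = 5, L = 4, M = 4, N = 4, P = 3, Q = 5, R = 7, S = 2,
              T = 3, V = 3, W = 10, Y = 8)[AA_STANDARD]
    v <- array(0, dim = c(5, 20, 6),
               dimnames = list(DNAK_SITES, AA_STANDARD, ENERGY_TERMS))
    noise <- function() matrix(rnorm(100, sd = 0.25), 5, 20)
    v[, , "vdw"] <- outer(depth, -0.6 * size) + noise()
    v[, , "elec"] <- matrix(rnorm(100, sd = 0.4), 5, 20)
    v[, , "strain"] <- pmax(outer(depth, 0.15 * size) + noise() * 0.2, 0)
    v[, , "desolv_substrate"] <- outer(burial, -solv) + noise() * 0.3
    v[, , "desolv_site"] <- outer(burial, -0.3 * pmax(solv, 0)) +
      noise() * 0.2
    v[, , "sc_propensity"] <- pmax(matrix(rnorm(100, 0.2, 0.15), 5, 20), 0)
    sem <- array(abs(rnorm(600, 0.05, 0.02)), dim = dim(v),
                 dimnames = dimnames(v))
    terms <- energy_term_matrix(v, sem)
    list(pssm = combine_terms(terms, weights), terms = terms,
         weights = weights)
  })
}

#' Generate a classed synthetic peptide array with planted truth
#'
#' Tiles 13-mers from random motif-biased protein sequences, scores each
#' with the truth model (forward-only minimum over its nine windows), adds
#' Gaussian noise, and assigns the four array classes by score quantiles in
#' the spec's proportions (strong = lowest scores). The hidden truth and
#' noisy scores are attached as attributes for oracle tests.
#'
#' @param spec A `dnak_fixture_spec`.
#' @param truth_pssm The `dnak_pssm` acting as ground truth.
#' @param truth_weights,scales Scoring context of the truth model.
#' @return Data frame with columns `sequence`, `label`, `protein_id`, and
#'   attributes `truth_scores` and `noisy_scores`.
#' @export
gen_peptide_array <- function(spec = fixture_spec(), truth_pssm,
                              truth_weights = default_weights(),
                              scales = default_propensity_scales()) {
  stopifnot(inherits(spec, "dnak_fixture_spec"),
            inherits(truth_pssm, "dnak_pssm"))
  with_seed(spec$seed + 1L, {
    proteins <- vapply(seq_len(spec$n_proteins),
                       function(i) random_protein(spec$protein_length),
                       character(1))
    tiles <- do.call(rbind, lapply(seq_along(proteins), function(i) {
      starts <- seq(1L, spec$protein_length - 12L, by = 3L)
      data.frame(sequence = substring(proteins[i], starts, starts + 12L),
                 protein_id = sprintf("synprot%02d", i),
                 stringsAsFactors = FALSE)
    }))
    if (nrow(tiles) < spec$n_peptides) {
      stop("not enough tiled 13-mers (", nrow(tiles), ") for n_peptides = ",
           spec$n_peptides, "; increase n_proteins or protein_length")
    }
    tiles <- tiles[sample.int(nrow(tiles), spec$n_peptides), , drop = FALSE]
    truth <- vapply(tiles$sequence, function(s) {
      score_13mer(s, truth_pssm, truth_weights, scales)
    }, numeric(1), USE.NAMES = FALSE)
    noisy <- truth + rnorm(length(truth), sd = spec$noise_scale)
    # class counts matching the proportions to within one record
    n <- length(noisy)
    bounds <- round(cumsum(spec$class_proportions) * n)
    counts <- diff(c(0, bounds))
    label <- character(n)
    label[order(noisy)] <- rep(ARRAY_CLASSES, counts)
    out <- data.frame(sequence = tiles$sequence, label = label,
                      protein_id = tiles$protein_id,
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    attr(out, "truth_scores") <- truth
    attr(out, "noisy_scores") <- noisy
    out
  })
}

#' Generate a synthetic structural benchmark with planted truth
#'
#' For each random peptide the planted observed core and orientation are
#' the truth model's global minimum-score window, optionally corrupted at a
#' stated rate (the corrupted rows get a different window/orientation, so
#' reported accuracy should approximate `1 - corruption_rate`).
#'
#' @inheritParams gen_peptide_array
#' @return Data frame with columns `sequence`, `orientation`, `core`,
#'   `offset` (0-based), `structure_id`, and attribute `corrupted` (logical
#'   vector).
#' @export
gen_benchmark <- function(spec = fixture_spec(), truth_pssm,
                          truth_weights = default_weights(),
                          scales = default_propensity_scales()) {
  stopifnot(inherits(spec, "dnak_fixture_spec"),
            inherits(truth_pssm, "dnak_pssm"))
  with_seed(spec$seed + 2L, {
    rows <- vector("list", spec$n_benchmark)
    corrupted <- logical(spec$n_benchmark)
    for (i in seq_len(spec$n_benchmark)) {
      len <- sample(spec$benchmark_lengths, 1L)
      seq <- random_protein(len)
      scan <- scan_sequence(seq, truth_pssm, truth_weights, scales)
      best <- which.min(scan$scores$total)
      pick <- best
      if (runif(1) < spec$corruption_rate) {
        corrupted[i] <- TRUE
        others <- setdiff(seq_len(nrow(scan$scores)), best)
        pick <- others[sample.int(length(others), 1L)]
      }
      rows[[i]] <- data.frame(
        sequence = seq,
        orientation = scan$scores$orientation[pick],
        core = scan$scores$window[pick],
        offset = scan$scores$start[pick],
        structure_id = sprintf("SYN%03d", i),
        stringsAsFactors = FALSE
      )
    }
    out <- do.call(rbind, rows)
    attr(out, "corrupted") <- corrupted
    out
  })
}

#' Generate synthetic per-frame energy traces
#'
#' Draws i.i.d. Gaussian frames around per-trace true means, emulating the
#' per-frame records of short restrained production runs; aggregation
#' recovers the true means to within a few SEM.
#'
#' @param spec A `dnak_fixture_spec`.
#' @return List of `dnak_trace` objects with attribute `true_means` (one
#'   row per trace: vdw, elec, restraint, sasa, total).
#' @export
gen_traces <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "dnak_fixture_spec"))
  with_seed(spec$seed + 3L, {
    terms <- c("vdw", "elec", "restraint", "sasa", "total")
    sds <- c(vdw = 1.5, elec = 2, restraint = 0.8, sasa = 8, total = 4)
    means <- data.frame(
      vdw = rnorm(spec$n_traces, -8, 2),
      elec = rnorm(spec$n_traces, -3, 2),
      restraint = abs(rnorm(spec$n_traces, 2, 1)),
      sasa = rnorm(spec$n_traces, 120, 20),
      total = rnorm(spec$n_traces, -1200, 15)
    )
    traces <- lapply(seq_len(spec$n_traces), function(i) {
      frames <- as.data.frame(lapply(setNames(terms, terms), function(t) {
        rnorm(spec$trace_frames, mean = means[[t]][i], sd = sds[[t]])
      }))
      frames$frame <- seq_len(spec$trace_frames)
      frame_energy_trace(frames, residue = "L", site = "0", rotamer = i)
    })
    attr(traces, "true_means") <- means
    traces
  })
}

#' Write a full synthetic fixture set to a directory
#'
#' Emits the planted terms and PSSM, the peptide-array and benchmark
#' tables, one TSV per energy trace, and a `manifest.json` recording the
#' seed, sizes, and truth weights. Byte-identical for identical specs.
#'
#' @param spec A `dnak_fixture_spec`.
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_fixtures <- function(spec = fixture_spec(), dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  truth <- gen_pssm(spec)
  array_tab <- gen_peptide_array(spec, truth$pssm, truth$weights)
  bench <- gen_benchmark(spec, truth$pssm, truth$weights)
  traces <- gen_traces(spec)
  paths <- list(
    terms = file.path(dir, "terms.tsv"),
    pssm = file.path(dir, "pssm.tsv"),
    array = file.path(dir, "array.tsv"),
    benchmark = file.path(dir, "benchmark.tsv"),
    manifest = file.path(dir, "manifest.json")
  )
  write_terms(truth$terms, paths$terms)
  write_pssm(truth$pssm, paths$pssm)
  write_array_table(array_tab, paths$array)
  write_benchmark_table(bench, paths$benchmark)
  for (i in seq_along(traces)) {
    p <- file.path(dir, sprintf("trace_%02d.tsv", i))
    write_trace(traces[[i]], p)
    paths[[sprintf("trace_%02d", i)]] <- p
  }
  manifest <- list(
    seed = spec$seed,
    n_peptides = spec$n_peptides,
    n_benchmark = spec$n_benchmark,
    class_proportions = as.list(spec$class_proportions),
    noise_scale = spec$noise_scale,
    corruption_rate = spec$corruption_rate,
    truth_weights = list(
      term_weights = as.list(truth$weights$term_weights),
      w_cp = truth$weights$w_cp,
      site_weights = as.list(truth$weights$site_weights),
      e_reverse = truth$weights$e_reverse
    ),
    files = lapply(paths, basename)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
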