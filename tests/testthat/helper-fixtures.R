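# shared in-code fixtures: everything is generated, nothing is stored

# a small deterministic random term array (not via gen_pssm, so core tests
# do not depend on the synthetic module)
random_terms <- function(seed = 1, sd = 1) {
  set.seed(seed)
  v <- array(rnorm(5 * 20 * 6, sd = sd), dim = c(5, 20, 6),
             dimnames = list(DNAK_SITES, AA_STANDARD, ENERGY_TERMS))
  energy_term_matrix(v)
}

random_pssm <- function(seed = 1, sd = 1) {
  set.seed(seed)
  m <- matrix(rnorm(100, sd = sd), 5, 20,
              dimnames = list(DNAK_SITES, AA_STANDARD))
  pssm(m, provenance = "random test matrix")
}

zero_pssm <- function() {
  pssm(matrix(0, 5, 20, dimnames = list(DNAK_SITES, AA_STANDARD)),
       provenance = "all zeros")
}

random_aa_seq <- function(n) {
  paste(sample(AA_STANDARD, n, replace = TRUE), collapse = "")
}

# flat scales: coil propensity 0.5 everywhere, propensity energies zero
flat_scales <- function() {
  propensity_scales(
    helical = setNames(rep(0.5, 20), AA_STANDARD),
    rotamer = data.frame(residue = AA_STANDARD, p_r = 0.5, p_0 = 0.5)
  )
}

# brute-force oracle: score one window by explicit per-site lookup
oracle_fivemer <- function(window, orientation, pssm_mat, weights, ecp) {
  chars <- strsplit(window, "")[[1]]
  sites <- if (orientation == "forward") 1:5 else 5:1
  total <- 0
  for (i in 1:5) {
    total <- total + pssm_mat[sites[i], match(chars[i], AA_STANDARD)]
  }
  total + weights$w_cp * ecp +
    if (orientation == "reverse") weights$e_reverse else 0
}

# brute-force oracle: enumerate all windows of a sequence in both
# orientations, returning a data frame (independent of scan_sequence)
oracle_scan <- function(seq, pssm_mat, weights, scales) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  out <- NULL
  for (st in 0:(L - 5)) {
    w <- substr(seq, st + 1, st + 5)
    wc <- chars[(st + 1):(st + 5)]
    ecp <- mean(1 - scales$helical[wc])
    for (orientation in c("forward", "reverse")) {
      out <- rbind(out, data.frame(
        start = st, window = w, orientation = orientation,
        total = oracle_fivemer(w, orientation, pssm_mat, weights, ecp)))
    }
  }
  out
}

# Mann-Whitney concordance oracle for ROC AUC: fraction of
# (positive, negative) pairs where the positive scores lower (ties = 1/2)
oracle_concordance <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) {
    total <- total + sum(p < neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}
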