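test_that("site assignment maps window positions onto sites", {
  expect_equal(assign_sites("KTLFI", "reverse"),
               c("-2" = "I", "-1" = "F", "0" = "L", "+1" = "T", "+2" = "K"))
  expect_equal(assign_sites("LLLTG", "forward"),
               c("-2" = "L", "-1" = "L", "0" = "L", "+1" = "T", "+2" = "G"))
  # definitional symmetry: reverse of w == forward of reversed w
  set.seed(5)
  for (i in 1:25) {
    w <- random_aa_seq(5)
    wr <- paste(rev(strsplit(w, "")[[1]]), collapse = "")
    expect_equal(assign_sites(w, "reverse"), assign_sites(wr, "forward"))
  }
  expect_error(assign_sites("ABC", "forward"), "5 residues")
})

test_that("five-mer scores decompose into site, coil, and reverse parts", {
  scales <- flat_scales()
  w <- default_weights()
  expect_equal(score_fivemer("MQKWV", "forward", zero_pssm(), w,
                             scales)$total, 0)
  p <- random_pssm(seed = 21)
  fs <- score_fivemer("MQKWV", "reverse", p, w, scales)
  expect_equal(fs$total, sum(fs$site_contributions) + fs$e_cp_contribution)
  expect_equal(fs$site_assignment, assign_sites("MQKWV", "reverse"))
  # matches the by-hand oracle with nonzero w_cp and e_reverse
  w2 <- w; w2$w_cp <- 0.7; w2$e_reverse <- 1.3
  set.seed(6)
  for (i in 1:25) {
    win <- random_aa_seq(5)
    for (orientation in c("forward", "reverse")) {
      expect_equal(
        score_fivemer(win, orientation, p, w2, scales)$total,
        oracle_fivemer(win, orientation, unclass(p), w2, 0.5))
    }
  }
  expect_error(score_fivemer("MQKBV", "forward", p, w, scales), "B")
})

test_that("reverse-orientation identity holds exactly", {
  p <- random_pssm(seed = 8)
  w <- default_weights()
  w$e_reverse <- 0.42
  w$w_cp <- 0.3
  scales <- default_propensity_scales()
  set.seed(9)
  for (i in 1:200) {
    win <- random_aa_seq(5)
    wr <- paste(rev(strsplit(win, "")[[1]]), collapse = "")
    expect_equal(score_fivemer(win, "reverse", p, w, scales)$total,
                 score_fivemer(wr, "forward", p, w, scales)$total +
                   w$e_reverse)
  }
})

test_that("scan_sequence enumerates all windows and finds the bests", {
  p <- random_pssm(seed = 10)
  w <- default_weights()
  scales <- default_propensity_scales()
  sc <- scan_sequence("MQKWVLA", p, w, scales)   # 7-mer: 3 windows x 2
  expect_equal(nrow(sc$scores), 6)
  expect_equal(sc$scores$start, rep(0:2, each = 2))

  # brute-force oracle on random 12-mers
  set.seed(11)
  for (i in 1:20) {
    seq <- random_aa_seq(12)
    sc <- scan_sequence(seq, p, w, scales)
    oracle <- oracle_scan(seq, unclass(p), w, scales)
    m <- merge(sc$scores[c("start", "orientation", "total")], oracle,
               by = c("start", "orientation"))
    expect_equal(nrow(m), 16)
    expect_equal(m$total.x, m$total.y)
    of <- oracle[oracle$orientation == "forward", ]
    expect_equal(sc$scores$total[sc$best_forward], min(of$total))
    or <- oracle[oracle$orientation == "reverse", ]
    expect_equal(sc$scores$total[sc$best_reverse], min(or$total))
  }
  expect_error(scan_sequence("MQKW", p), "too short")
})

test_that("non-standard residues invalidate only their windows", {
  p <- random_pssm(seed = 14)
  expect_warning(sc <- scan_sequence("MQKWVXLAPDE", p), "skipped")
  # X at 1-based position 6 kills windows starting at offsets 1..5
  expect_setequal(unique(sc$excluded$start), 1:5)
  expect_equal(nrow(sc$scores), 2 * 7 - 10)
  expect_false(sc$scores$start[sc$best_forward] %in% 1:5)
})

test_that("scores are linear in the PSSM: constant shift adds 5c", {
  p <- random_pssm(seed = 15)
  shifted <- pssm(unclass(p) + 1.7, provenance = "shifted")
  scales <- default_propensity_scales()
  seq <- "MQKWVLAPDE"
  a <- scan_sequence(seq, p, scales = scales)$scores$total
  b <- scan_sequence(seq, shifted, scales = scales)$scores$total
  expect_equal(b, a + 5 * 1.7)
})

test_that("predict_register finds the planted minimum", {
  # a PSSM favoring W at site 0 only: best window centers the W
  m <- matrix(0, 5, 20, dimnames = list(DNAK_SITES, AA_STANDARD))
  m["0", "W"] <- -5
  p <- pssm(m)
  reg <- predict_register("AAAWAAA", p, scales = flat_scales())
  expect_equal(reg$window, "AAWAA")
  expect_equal(reg$site_assignment[["0"]], "W")
  expect_equal(reg$start, 1)
  expect_equal(reg$total, -5)
  # register prediction agrees with exhaustive enumeration
  p2 <- random_pssm(seed = 16)
  scales <- default_propensity_scales()
  set.seed(17)
  for (i in 1:20) {
    seq <- random_aa_seq(10)
    oracle <- oracle_scan(seq, unclass(p2), default_weights(), scales)
    of <- oracle[oracle$orientation == "forward", ]
    reg <- predict_register(seq, p2, scales = scales)
    expect_equal(reg$total, min(of$total))
  }
})

test_that("orientation calls use the kT ambiguity threshold", {
  p <- random_pssm(seed = 18)
  scales <- default_propensity_scales()
  # palindromes with e_reverse = 0 are exactly ambiguous at delta 0
  for (seq in c("MQKWVWKQM", "ACDCA", "LVIVIVL")) {
    po <- predict_orientation(seq, p, scales = scales)
    expect_equal(po$delta, 0)
    expect_equal(po$call, "ambiguous")
  }
  # a huge reverse penalty forces forward calls
  w <- default_weights()
  w$e_reverse <- 100
  po <- predict_orientation("MQKWVLAPDE", p, w, scales)
  expect_equal(po$call, "forward")
  expect_lt(po$delta, -0.6)
})

test_that("13-mer scores are the forward minimum over nine windows", {
  p <- random_pssm(seed = 19)
  scales <- default_propensity_scales()
  expect_equal(score_13mer(strrep("G", 13), zero_pssm(), scales = scales), 0)
  # homopolymer: equals its single distinct five-mer score
  expect_equal(score_13mer(strrep("L", 13), p, scales = scales),
               score_fivemer("LLLLL", "forward", p,
                             scales = scales)$total)
  set.seed(20)
  for (i in 1:50) {
    seq <- random_aa_seq(13)
    oracle <- min(vapply(0:8, function(st) {
      score_fivemer(substr(seq, st + 1, st + 5), "forward", p,
                    scales = scales)$total
    }, numeric(1)))
    expect_equal(score_13mer(seq, p, scales = scales), oracle)
  }
  expect_error(score_13mer("SHORT", p), "13 residues")
})

test_that("reverse-candidate screening ranks by the reverse margin", {
  p <- random_pssm(seed = 22)
  scales <- default_propensity_scales()
  set.seed(23)
  seqs <- setNames(vapply(1:40, function(i) random_aa_seq(9), character(1)),
                   sprintf("pep%02d", 1:40))
  hits <- find_reverse_candidates(seqs, p, scales = scales, margin = 0.5)
  # membership and order match a brute-force scan
  deltas <- vapply(seqs, function(s) {
    oracle <- oracle_scan(s, unclass(p), default_weights(), scales)
    min(oracle$total[oracle$orientation == "reverse"]) -
      min(oracle$total[oracle$orientation == "forward"])
  }, numeric(1))
  expect_setequal(hits$id, names(deltas)[deltas < -0.5])
  expect_equal(hits$delta, sort(deltas[deltas < -0.5]), ignore_attr = TRUE)
  # an overwhelming reverse penalty empties the list
  w <- default_weights()
  w$e_reverse <- 1000
  expect_equal(nrow(find_reverse_candidates(seqs, p, w, scales,
                                            margin = 0.5)), 0)
})

test_that("array-prediction normalization is clamped min-max", {
  expect_equal(normalize_array_prediction(-10), 1)
  expect_equal(normalize_array_prediction(-6), 0)
  expect_equal(normalize_array_prediction(-8), 0.5)
  expect_equal(normalize_array_prediction(c(-100, 5)), c(1, 0))
  expect_error(normalize_array_prediction(0, low = -6, high = -10), "less")
})
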