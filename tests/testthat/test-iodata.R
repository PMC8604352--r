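test_that("FASTA round trip, uppercasing, and error reporting", {
  tmp <- tempfile(fileext = ".fasta")
  on.exit(unlink(tmp))
  set.seed(71)
  seqs <- setNames(vapply(1:5, function(i) random_aa_seq(30), character(1)),
                   sprintf("prot%02d", 1:5))
  write_fasta(seqs, tmp)
  expect_identical(read_fasta(tmp), seqs)

  writeLines(c(">a desc", "mklv", "avst", ">b", "ACDE"), tmp)
  got <- read_fasta(tmp)
  expect_identical(got, c(a = "MKLVAVST", b = "ACDE"))

  writeLines(character(0), tmp)
  expect_error(read_fasta(tmp), "no records|malformed")
  expect_error(read_fasta(file.path(tempdir(), "absent.fasta")), "no such")
})

test_that("PSSM files round-trip losslessly and fail loudly on bad schema", {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  p <- random_pssm(seed = 72)
  write_pssm(p, tmp)
  p2 <- read_pssm(tmp)
  expect_equal(unclass(p2), unclass(p), tolerance = 1e-6, ignore_attr = TRUE)
  # CSV dialect is sniffed
  write_pssm(p, tmp, delim = ",")
  expect_equal(unclass(read_pssm(tmp)), unclass(p), tolerance = 1e-6,
               ignore_attr = TRUE)

  # missing residue column
  tab <- read.table(tmp, header = TRUE, sep = ",", check.names = FALSE)
  write.table(tab[setdiff(names(tab), "W")], tmp, sep = ",",
              row.names = FALSE, quote = FALSE)
  expect_error(read_pssm(tmp), "missing residue column.*W")

  # transposed file is a schema error, not a silent misread
  tr <- data.frame(residue = AA_STANDARD, t(unclass(p)), check.names = FALSE)
  write.table(tr, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_pssm(tmp), "transposed|site")

  # non-numeric cell named precisely
  df <- data.frame(site = DNAK_SITES, unclass(p), check.names = FALSE)
  df$L[3] <- "oops"
  write.table(df, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_pssm(tmp), "site 0, residue L")
})

test_that("energy-term tables round-trip and validate cells", {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  terms <- gen_pssm(fixture_spec(seed = 73))$terms
  write_terms(terms, tmp)
  t2 <- read_terms(tmp)
  # files carry 6 decimal places, so round trips are exact to ~5e-7 absolute
  expect_lt(max(abs(t2$values - terms$values)), 1e-6)
  expect_lt(max(abs(t2$sem - terms$sem)), 1e-6)

  tab <- read.table(tmp, header = TRUE, sep = "\t")
  write.table(tab[-1, ], tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_terms(tmp), "missing 1 of 600")
  write.table(rbind(tab, tab[1, ]), tmp, sep = "\t", row.names = FALSE,
              quote = FALSE)
  expect_error(read_terms(tmp), "duplicate")
  tab$term[5] <- "magnetism"
  write.table(tab, tmp, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(read_terms(tmp), "invalid site/residue/term.*5")
})

test_that("peptide-array tables round-trip and log exclusions", {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  spec <- fixture_spec(seed = 74, n_peptides = 60, n_proteins = 3)
  arr <- gen_peptide_array(spec, gen_pssm(spec)$pssm)
  write_array_table(arr, tmp)
  back <- read_array_table(tmp)
  expect_equal(back$sequence, arr$sequence)
  expect_equal(back$label, arr$label)
  prov <- dataset_provenance(back)
  expect_equal(prov$n_rows, 60)
  expect_equal(prov$n_kept + nrow(prov$excluded), prov$n_rows)

  bad <- arr
  bad$sequence[2] <- "TOOSHORT"
  bad$sequence[5] <- paste0("Z", substr(bad$sequence[5], 2, 13))
  bad$label[9] <- "superbinder"
  write_array_table(bad, tmp)
  expect_warning(back <- read_array_table(tmp), "excluded 3")
  prov <- dataset_provenance(back)
  expect_equal(nrow(back), 57)
  expect_equal(prov$excluded$row, c(2, 5, 9))
  expect_setequal(prov$excluded$reason,
                  c("not a 13-mer", "non-standard residue", "unknown label"))
})

test_that("benchmark tables round-trip, derive offsets, and drop Z peptides", {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  spec <- fixture_spec(seed = 75, n_benchmark = 12)
  bench <- gen_benchmark(spec, gen_pssm(spec)$pssm)
  write_benchmark_table(bench, tmp)
  back <- read_benchmark_table(tmp)
  expect_equal(back$sequence, bench$sequence)
  expect_equal(back$core, bench$core)
  expect_equal(back$offset, bench$offset)
  expect_equal(back$length, nchar(bench$sequence))

  # offset derived from the first core match when the column is absent
  write_benchmark_table(bench[setdiff(names(bench), "offset")], tmp)
  back2 <- read_benchmark_table(tmp)
  first_match <- vapply(seq_len(nrow(bench)), function(i) {
    regexpr(bench$core[i], bench$sequence[i], fixed = TRUE)[[1]] - 1L
  }, integer(1))
  expect_equal(back2$offset, first_match)

  bad <- bench
  bad$sequence[1] <- sub("^.", "Z", bad$sequence[1])
  bad$core[3] <- "AAAAA"
  write_benchmark_table(bad, tmp)
  expect_warning(back3 <- read_benchmark_table(tmp), "excluded")
  prov <- dataset_provenance(back3)
  expect_equal(nrow(back3) + nrow(prov$excluded), 12)
  expect_true("non-standard residue" %in% prov$excluded$reason)
})

test_that("trace files round-trip", {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  tr <- gen_traces(fixture_spec(seed = 76, n_traces = 1))[[1]]
  write_trace(tr, tmp)
  back <- read_trace(tmp, residue = "L", site = "0")
  expect_equal(back$frames$total, tr$frames$total, tolerance = 1e-6)
  expect_equal(aggregate_trace(back)$mean, aggregate_trace(tr)$mean,
               tolerance = 1e-5)
})

test_that("scan tables carry per-site residues and contributions", {
  tmp <- tempfile(fileext = ".tsv")
  tmp2 <- tempfile(fileext = ".tsv")
  on.exit(unlink(c(tmp, tmp2)))
  p <- random_pssm(seed = 77)
  sc <- scan_sequence("MQKWVLAPDE", p, id = "demo")
  write_scan_table(sc, tmp)
  tab <- read.table(tmp, header = TRUE, sep = "\t", check.names = FALSE)
  expect_equal(nrow(tab), nrow(sc$scores))
  expect_true(all(c("seq_id", "start", "window", "orientation",
                    "res_-2", "e_-2", "e_cp", "total") %in% names(tab)))
  expect_equal(tab$total, sc$scores$total, tolerance = 1e-6)
  write_scan_summary(sc, tmp2)
  summ <- read.table(tmp2, header = TRUE, sep = "\t")
  expect_equal(nrow(summ), 1)
  expect_true(summ$orientation_call %in% c("forward", "reverse", "ambiguous"))
})

test_that("weight configs round-trip through JSON and YAML", {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  w <- default_weights()
  w$term_weights[["elec"]] <- 0.55
  w$w_cp <- 0.12
  w$e_reverse <- 0.3
  write_weights(w, tmp)
  back <- read_weights(tmp)
  expect_equal(back$term_weights, w$term_weights)
  expect_equal(back$w_cp, w$w_cp)
  expect_equal(back$site_weights, w$site_weights)
  expect_equal(back$e_reverse, w$e_reverse)

  skip_if_not_installed("yaml")
  tmpy <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmpy), add = TRUE)
  writeLines(yaml::as.yaml(jsonlite::read_json(tmp)), tmpy)
  backy <- read_weights(tmpy)
  expect_equal(backy$term_weights, w$term_weights)
  expect_equal(backy$e_reverse, w$e_reverse)

  writeLines("{\"vdw\": 0.1}", tmp)
  expect_error(read_weights(tmp), "missing key")
})
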