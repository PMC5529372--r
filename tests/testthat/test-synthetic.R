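test_that("generated loci are valid stem-loops with planted structure", {
  p <- sim_params(n_loci = 15, seed = 5, mismatch_pos9_prob = 0,
                  mismatch_3p_prob = 0)
  sim <- generate_loci(p)
  expect_length(sim$loci, 15)
  for (lc in sim$loci) {
    expect_equal(nchar(lc$structure), nchar(lc$hairpin_seq))
    agosort:::parse_dotbracket(lc$structure)   # balanced
    # all-zero mismatch probabilities: every duplex position 1..20 paired
    expect_equal(substr(lc$structure, 1, 20),
                 paste(rep("(", 20), collapse = ""))
  }
  # planted central mismatch shows as unpaired base at 5p position 9
  p9 <- sim_params(n_loci = 10, seed = 5, mismatch_pos9_prob = 1,
                   mismatch_3p_prob = 0)
  sim9 <- generate_loci(p9)
  for (lc in sim9$loci) {
    expect_equal(substr(lc$structure, 9, 9), ".")
    expect_equal(duplex_pairing_profile(lc, "5p")[9], 0L)
  }
})

test_that("simulation is deterministic: same seed gives byte-identical files", {
  p <- sim_params(n_loci = 8, seed = 11, library_depth = 2000)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(p, d1)
  write_simulation(p, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  expect_setequal(list.files(d1),
                  c("hairpins.fa", "mature.gff3", "structures.vienna",
                    sprintf("%s_%02dh.fa", rep(c("total", "ago1", "ago2"),
                                               each = 6),
                            c(0, 12, 24, 36, 48, 72)),
                    "ground_truth.tsv", "params.lock.yaml"))
})

test_that("every simulated library conserves the configured depth", {
  p <- sim_params(n_loci = 10, seed = 2, library_depth = 5000)
  sim <- generate_loci(p)
  out <- simulate_libraries(sim, p)
  expect_length(out$libraries, 18)
  for (lib in out$libraries) {
    expect_equal(sum(lib$reads$count), 5000)
  }
})

test_that("zero Ago bias gives symmetric partitioning", {
  p <- sim_params(n_loci = 25, seed = 3, arm_asymmetry_sd = 2,
                  background_fraction = c(total = 0.2, ago1 = 0.2, ago2 = 0.2),
                  library_depth = 60000)
  sim <- generate_loci(p)
  expect_true(all(sim$strands$ago1_fraction_true == 0.5))
  out <- simulate_libraries(sim, p)
  a1 <- sum(vapply(out$libraries, function(l)
    if (l$pool == "ago1") sum(l$reads$count) else 0, numeric(1)))
  q <- quantify_libraries(out$libraries, sim$loci, tpm_min = 0)
  meta <- q$lib_meta
  m1 <- rowMeans(q$counts$raw[, meta$library_id[meta$pool == "ago1"]])
  m2 <- rowMeans(q$counts$raw[, meta$library_id[meta$pool == "ago2"]])
  frac <- sum(m1) / (sum(m1) + sum(m2))
  expect_lt(abs(frac - 0.5), 0.02)
})

test_that("Ago2 mono-addition rate matches its parameter within binomial error", {
  p <- sim_params(n_loci = 10, seed = 9,
                  mono_addition_prob = c(total = 0.1, ago1 = 0.1, ago2 = 0.35),
                  trim_prob = 0.1, library_depth = 30000,
                  background_fraction = c(total = 0.3, ago1 = 0.3, ago2 = 0.3))
  sim <- generate_loci(p)
  out <- simulate_libraries(sim, p)
  cc <- out$truth$class_counts
  ago2 <- cc[grepl("^ago2", cc$library_id), ]
  n <- sum(ago2$canonical + ago2$add1 + ago2$trim1)
  phat <- sum(ago2$add1) / n
  expect_lt(abs(phat - 0.35), 3 * sqrt(0.35 * 0.65 / n))
})

test_that("the upregulated cluster is planted in the fold-change truth", {
  p <- sim_params(n_loci = 12, seed = 4,
                  upregulated_cluster = list(size = 3, fold = 8, onset_h = 12),
                  library_depth = 1000)
  sim <- generate_loci(p)
  cl <- unique(sim$strands$locus_id[sim$strands$cluster])
  expect_length(cl, 3)
  expect_true(all(sim$fold_truth[cl, c("t12", "t24", "t36", "t48", "t72")] == 8))
  expect_true(all(sim$fold_truth[cl, "t0"] == 1))
  expect_true(all(sim$fold_truth[setdiff(rownames(sim$fold_truth), cl), ] == 1))
})

test_that("paper-like configuration encodes the published design", {
  p <- paper_like_config(seed = 1)
  expect_equal(p$mono_addition_prob[["ago2"]], 0.35)
  expect_lt(p$mono_addition_prob[["total"]], 0.10)
  # 3 pools x 6 time points = 18 libraries
  sim <- generate_loci(sim_params(n_loci = 4, seed = 1, library_depth = 500))
  out <- simulate_libraries(sim, sim_params(n_loci = 4, seed = 1,
                                            library_depth = 500))
  expect_length(out$libraries, 18)
  meta <- library_metadata(out$libraries)
  expect_setequal(unique(meta$pool), c("total", "ago1", "ago2"))
  expect_setequal(unique(meta$time_h_pbm), c(0L, 12L, 24L, 36L, 48L, 72L))
})

test_that("parameter validation rejects out-of-range settings", {
  expect_error(sim_params(n_loci = 0), "n_loci")
  expect_error(sim_params(mono_addition_prob = c(total = 1.2, ago1 = 0,
                                                 ago2 = 0)))
  expect_error(sim_params(upregulated_cluster = list(size = 2, fold = 0.5,
                                                     onset_h = 12)),
               "fold")
  expect_error(sim_params(background_fraction = c(total = 1, ago1 = 0,
                                                  ago2 = 0)))
})
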