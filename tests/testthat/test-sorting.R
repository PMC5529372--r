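make_tpm <- function(values, strand_ids, lib_ids) {
  matrix(values, length(strand_ids), length(lib_ids),
         dimnames = list(strand_ids, lib_ids))
}

toy_strands <- data.frame(
  strand_id = c("m1-5p", "m1-3p", "m2-3p"),
  locus_id = c("m1", "m1", "m2"), arm = c("5p", "3p", "3p"),
  stringsAsFactors = FALSE)

test_that("strand curation follows the abundance rule with 5p tie-break", {
  tpm <- make_tpm(c(100, 10, 50), toy_strands$strand_id, "total_00h")
  cur <- curate_strands(tpm, toy_strands)
  expect_equal(cur$star, c("miR", "miR*", "miR"))  # one-strand locus = miR

  tpm <- make_tpm(c(10, 100, 50), toy_strands$strand_id, "total_00h")
  expect_equal(curate_strands(tpm, toy_strands)$star,
               c("miR*", "miR", "miR"))

  tie <- make_tpm(c(40, 40, 1), toy_strands$strand_id, "total_00h")
  expect_equal(curate_strands(tie, toy_strands)$star[1:2],
               c("miR", "miR*"))
})

test_that("curation is invariant to library order and uniform scaling", {
  withr::local_seed(12)
  tpm <- make_tpm(runif(12, 1, 500), c("a-5p", "a-3p"),
                  paste0("total_", 1:6))
  strands <- data.frame(strand_id = c("a-5p", "a-3p"),
                        locus_id = "a", arm = c("5p", "3p"))
  base <- curate_strands(tpm, strands)$star
  expect_equal(curate_strands(tpm[, sample(6)], strands)$star, base)
  expect_equal(curate_strands(tpm * 37.5, strands)$star, base)
})

test_that("partition fractions and >70% bias calls", {
  t1 <- make_tpm(c(80, 50, 0), toy_strands$strand_id, "ago1_00h")
  t2 <- make_tpm(c(20, 50, 0), toy_strands$strand_id, "ago2_00h")
  pf <- partition_fractions(t1, t2)
  expect_equal(pf$ago1_fraction, c(0.8, 0.5, NA))
  expect_equal(pf$bias, c("ago1", "none", "none"))
  pf <- partition_fractions(t2, t1)
  expect_equal(pf$bias[1], "ago2")
})

test_that("Fisher enrichment p matches exhaustive enumeration", {
  expect_equal(star_enrichment_test(8, 12, 2, 48), fisher_oracle(8, 12, 2, 48),
               tolerance = 1e-12)
  expect_equal(star_enrichment_test(0, 10, 0, 30), 1)
  expect_gt(star_enrichment_test(5, 45, 10, 90), 0.5)  # identical proportions
  expect_error(star_enrichment_test(-1, 2, 3, 4), "non-negative")
  withr::local_seed(33)
  for (i in 1:50) {
    n <- sample(20:200, 1)
    a <- sample(0:min(20, n - 3), 1); b <- sample(1:20, 1)
    c <- sample(0:20, 1); d <- n - a - b - c
    if (d < 1) next
    expect_equal(star_enrichment_test(a, b, c, d), fisher_oracle(a, b, c, d),
                 tolerance = 1e-10)
  }
})

test_that("nucleotide composition counts positions and tests position 1", {
  nc <- nt_composition(c("UGAGG", "UCAGG"))
  expect_equal(nc$freq["U", 1], 1)
  expect_equal(colSums(nc$freq), rep(1, 5), ignore_attr = TRUE)
  expect_error(nt_composition(character(0)), "empty")

  withr::local_seed(4)
  seqs <- vapply(1:800, function(i)
    paste(sample(c("A", "C", "G", "U"), 22, TRUE), collapse = ""),
    character(1))
  nc <- nt_composition(seqs)
  sigma <- sqrt(0.25 * 0.75 / 800)
  expect_true(all(abs(nc$freq[, 1] - 0.25) < 3.5 * sigma))

  biased <- c(paste0("U", substring(seqs[1:60], 2)), seqs[61:80])
  out <- nt_composition(biased, background = seqs)
  expect_gt(out$position1$freq[out$position1$nt == "U"],
            out$position1$bg_freq[out$position1$nt == "U"])
  expect_lt(out$position1$p[out$position1$nt == "U"], 0.01)
})

test_that("duplex pairing profiles score planted structure", {
  lc <- toy_locus()
  prof <- duplex_pairing_profile(lc, "5p")
  expect_equal(prof[1:20], rep(1L, 20))
  expect_equal(prof[21:22], c(0L, 0L))   # 3' overhang unpaired

  lc9 <- toy_locus(mismatch_at = 9L)
  expect_equal(duplex_pairing_profile(lc9, "5p")[9], 0L)
  expect_equal(duplex_pairing_profile(lc9, "3p")[21 - 9], 0L)

  agg <- aggregate_pairing_profile(list(
    duplex_pairing_profile(lc, "5p"), duplex_pairing_profile(lc, "5p"),
    duplex_pairing_profile(lc9, "5p")))
  expect_equal(agg[9], 1)                # median of {1,1,0}
})

test_that("fold fallback pairs a perfect toy hairpin and is flagged", {
  lc <- toy_locus()
  bare <- mirna_locus("bare", lc$hairpin_seq, arm5p = c(0L, 22L),
                      arm3p = c(28L, 50L))
  expect_error(duplex_pairing_profile(bare, "5p", fold_fallback = FALSE),
               "no structure")
  prof <- duplex_pairing_profile(bare, "5p")
  expect_true(attr(prof, "folded"))
  # max-pairing fold recovers most of the planted 20-bp stem
  expect_gte(sum(prof[1:20]), 16)

  db <- nussinov_fold("GGGGAAAACCCC")
  expect_equal(agosort:::parse_dotbracket(db)[1], 12L)
})

test_that("stronger is_star Ago2 bias lowers star Ago1 fractions (sweep)", {
  frac_at <- function(bias) {
    p <- sim_params(n_loci = 30, seed = 21, arm_asymmetry_sd = 2,
                    ago1_logit_bias = c(intercept = 0, is_star = bias),
                    library_depth = 40000,
                    background_fraction = c(total = 0.2, ago1 = 0.2,
                                            ago2 = 0.2))
    sim <- generate_loci(p)
    out <- simulate_libraries(sim, p)
    q <- quantify_libraries(out$libraries, sim$loci, tpm_min = 0)
    meta <- q$lib_meta
    pf <- partition_fractions(
      q$counts$tpm[, meta$library_id[meta$pool == "ago1"]],
      q$counts$tpm[, meta$library_id[meta$pool == "ago2"]])
    stars <- sim$strands$strand_id[sim$strands$star == "miR*"]
    mean(pf$ago1_fraction[pf$strand_id %in% stars], na.rm = TRUE)
  }
  f <- vapply(c(0, -1.25, -2.5), frac_at, numeric(1))
  expect_true(all(diff(f) < 0))
  expect_lt(abs(f[1] - 0.5), 0.05)
})
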