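test_that("adapter trimming removes the leftmost adapter occurrence", {
  adapter <- "AGAUCGGAAGAGC"
  insert <- "UGAGGUAGUAGGUUGUAUAGUU"
  r <- trim_adapter(toy_reads(list(paste0(insert, adapter), "4")), adapter)
  expect_equal(r$seq, insert)
  expect_equal(r$count, 4)

  r <- trim_adapter(toy_reads(list(insert, "2")), adapter)
  expect_equal(r$seq, insert)

  # adapter-only read collapses to the empty insert, dropped by size select
  r <- trim_adapter(toy_reads(list(adapter, "1")), adapter)
  expect_equal(r$seq, "")
  expect_equal(nrow(size_select(r)), 0)

  # partial 3' adapter (>= 6 nt overlap) is also removed
  r <- trim_adapter(toy_reads(list(paste0(insert, substr(adapter, 1, 7)), "1")),
                    adapter)
  expect_equal(r$seq, insert)
  expect_error(trim_adapter(toy_reads(list("ACGU", "1")), "ACGUA"), "6 nt")
})

test_that("size selection keeps inclusive bounds and counts", {
  reads <- data.frame(seq = c(strrep("A", 14), strrep("C", 15),
                              strrep("G", 30), strrep("U", 31)),
                      count = c(5, 5, 2, 2))
  out <- size_select(reads, 15, 30)
  expect_equal(nchar(out$seq), c(15, 30))
  expect_equal(out$count, c(5, 2))
  expect_equal(nrow(size_select(reads[0, ], 15, 30)), 0)
  expect_equal(size_select(reads, 14, 31), reads)
})

test_that("aligner handles identity, tails, and template precedence", {
  lc <- toy_locus()
  mature <- substr(lc$hairpin_seq, 1, 22)
  next_template <- substr(lc$hairpin_seq, 23, 23)  # loop base "G"
  non_template <- setdiff(c("A", "C", "G", "U"), next_template)[1]

  al <- align_to_hairpins(toy_reads(list(mature, "3")), list(lc))
  a <- al$assignments
  expect_equal(a$strand_id, "toy-1-5p")
  expect_equal(a$offset5, 0L)
  expect_equal(a$tail, "")
  expect_equal(a$weight, 1)

  # non-template 3' addition -> tail
  al <- align_to_hairpins(toy_reads(list(paste0(mature, non_template), "1")),
                          list(lc))
  expect_equal(al$assignments$tail, non_template)
  expect_equal(al$assignments$templated_len, 22L)

  # template extension takes precedence over a tail call
  al <- align_to_hairpins(toy_reads(list(paste0(mature, next_template), "1")),
                          list(lc))
  expect_equal(al$assignments$tail, "")
  expect_equal(al$assignments$templated_len, 23L)
})

test_that("multimapping reads split weight equally and conserve mass", {
  lc1 <- toy_locus("dup-1")
  lc2 <- toy_locus("dup-2")      # identical hairpin: every read multimaps
  mature <- substr(lc1$hairpin_seq, 1, 22)
  al <- align_to_hairpins(toy_reads(list(mature, "10")), list(lc1, lc2))
  expect_equal(nrow(al$assignments), 2)
  expect_equal(sum(al$assignments$weight), 1)
  expect_true(all(al$assignments$weight == 0.5))
})

test_that("aligner equals the brute-force oracle on random small instances", {
  withr::local_seed(101)
  for (rep in 1:20) {
    p <- sim_params(n_loci = 3, seed = rep, library_depth = 40,
                    background_fraction = c(total = 0.3, ago1 = 0.3,
                                            ago2 = 0.3))
    sim <- generate_loci(p)
    out <- suppressWarnings(simulate_libraries(sim, p))  # tiny depth on purpose
    reads <- out$libraries[[1]]$reads
    got <- align_to_hairpins(reads, sim$loci)$assignments
    want <- bf_align(reads, sim$loci)
    key <- function(d) {
      if (NROW(d) == 0) return(character(0))
      sort(sprintf("%s|%s|%d|%d|%s|%.6f", d$seq, d$strand_id, d$offset5,
                   d$templated_len, d$tail, d$weight))
    }
    expect_identical(key(got), key(want))
  }
})

test_that("category cascade respects priority order", {
  reads <- toy_reads(list("AAAACCCCGGGGUUUU", "2"), list("ACGUACGUACGUACG", "1"))
  tracks <- list(repeats = "AAAACCCCGGGGUUUU", mRNA = "AAAACCCCGGGGUUUU")
  ann <- annotate_categories(reads, tracks)
  expect_equal(ann$category, c("repeats", "unannotated"))
  expect_equal(annotate_categories(reads)$category,
               rep("unannotated", 2))
})

test_that("TPM normalizes to one million and respects the basis", {
  lc <- toy_locus()
  mature <- substr(lc$hairpin_seq, 1, 22)
  libs <- list(list(library_id = "total_00h", pool = "total", time_h_pbm = 0L,
                    reads = toy_reads(list(mature, "10"))))
  q <- quantify_libraries(libs, list(lc), tpm_min = 0, tpm_basis = "mirna")
  expect_equal(q$counts$tpm["toy-1-5p", "total_00h"], 1e6)

  # two strands sharing the pool 50/50
  mature3 <- substr(lc$hairpin_seq, 29, 50)
  libs[[1]]$reads <- toy_reads(list(mature, "5"), list(mature3, "5"))
  q <- quantify_libraries(libs, list(lc), tpm_min = 0, tpm_basis = "mirna")
  expect_equal(unname(q$counts$tpm[, 1]), c(5e5, 5e5))
  expect_equal(sum(q$counts$tpm[, 1]), 1e6, tolerance = 1e-6)

  # with background, per-library mapped-basis TPMs over all entities sum to 1e6
  libs[[1]]$reads <- rbind(libs[[1]]$reads,
                           toy_reads(list("ACGUACGUACGUACGUA", "10")))
  q <- quantify_libraries(libs, list(lc), tpm_min = 0, tpm_basis = "mapped")
  cat_tpm <- q$counts$categories[, 1] / sum(q$counts$categories[, 1]) * 1e6
  expect_equal(sum(q$counts$tpm[, 1]) + sum(cat_tpm[-1]), 1e6,
               tolerance = 1e-6)
  # empty matrix has no libraries, nothing to divide
  expect_no_error(compute_tpm(build_count_matrix(list(), character(0))))
})

test_that("low-abundance filter boundary and monotonicity", {
  cm <- structure(list(
    raw = matrix(1, 3, 2, dimnames = list(c("a", "b", "c"), c("l1", "l2"))),
    tpm = matrix(c(19.9, 19.9, 20, 5, 15, 10), 3, 2,
                 dimnames = list(c("a", "b", "c"), c("l1", "l2"))),
    categories = matrix(0, 5, 2)), class = "mirna_counts")
  out <- filter_low_abundance(cm, 20)
  expect_equal(rownames(out$tpm), "c")      # 20.0 retained, 19.9 dropped
  expect_equal(attr(out, "n_removed"), 2)
  expect_equal(rownames(filter_low_abundance(cm, 0)$tpm), c("a", "b", "c"))
  # raising the threshold never grows the retained set
  prev <- nrow(filter_low_abundance(cm, 0)$tpm)
  for (thr in c(5, 10, 15, 20, 25)) {
    cur <- nrow(filter_low_abundance(cm, thr)$tpm)
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("length histogram fractions sum to one", {
  expect_equal(nrow(length_histogram(toy_reads()[0, ])), 0)
  h <- length_histogram(toy_reads(list(strrep("A", 22), "3")))
  expect_equal(h$fraction, 1)
  h <- length_histogram(toy_reads(list(strrep("A", 21), "5"),
                                  list(strrep("C", 22), "5")))
  expect_equal(h$fraction, c(0.5, 0.5))

  # synthetic miRNA-only library: modal length 22 (oracle: direct count)
  p <- sim_params(n_loci = 10, seed = 6, library_depth = 20000,
                  background_fraction = c(total = 0, ago1 = 0, ago2 = 0),
                  trim_prob = 0.1,
                  mono_addition_prob = c(total = 0.1, ago1 = 0.1, ago2 = 0.1))
  sim <- generate_loci(p)
  out <- simulate_libraries(sim, p)
  h <- length_histogram(out$libraries$total_00h$reads)
  expect_equal(h$length[which.max(h$fraction)], 22L)
  expect_equal(sum(h$fraction), 1)
})
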