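# Independent brute-force oracles. These deliberately share no code with the
# package implementations they check.

# Exhaustive hairpin aligner: tries every (strand, 5' offset) and takes the
# maximal exact templated prefix, applying the same policy constraints.
bf_align <- function(reads, loci, policy = align_policy()) {
  strands <- mature_strands(loci)
  out <- list(); k <- 0L
  for (r in seq_len(nrow(reads))) {
    read <- reads$seq[r]
    cand <- list()
    for (i in seq_len(nrow(strands))) {
      lc <- loci[[strands$locus_id[i]]]
      iv <- lc[[paste0("arm", strands$arm[i])]]
      hp <- strsplit(lc$hairpin_seq, "")[[1]]
      rd <- strsplit(read, "")[[1]]
      best_t <- -1L; best_off <- NA_integer_
      for (off in -policy$max_offset5:policy$max_offset5) {
        start <- iv[1] + 1L + off
        if (start < 1L) next
        t <- 0L
        while (t < length(rd) && start + t <= length(hp) &&
               rd[t + 1L] == hp[start + t]) {
          t <- t + 1L
        }
        if (t < policy$min_match) next
        if (length(rd) - t > policy$max_tail) next
        if (t > best_t || (t == best_t && abs(off) < abs(best_off))) {
          best_t <- t; best_off <- off
        }
      }
      if (best_t >= 0) {
        cand[[length(cand) + 1L]] <- data.frame(
          seq = read, count = reads$count[r],
          strand_id = strands$strand_id[i], locus_id = strands$locus_id[i],
          arm = strands$arm[i], offset5 = best_off, templated_len = best_t,
          tail = substr(read, best_t + 1L, nchar(read)),
          stringsAsFactors = FALSE)
      }
    }
    if (length(cand) > 0) {
      cd <- do.call(rbind, cand)
      cd$weight <- 1 / nrow(cd)
      k <- k + 1L
      out[[k]] <- cd
    }
  }
  if (k == 0) return(data.frame())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Exhaustive isomiR classifier over all (offset, split) decompositions.
bf_classify <- function(read, locus, arm, ref_seq,
                        policy = align_policy()) {
  iv <- locus[[paste0("arm", arm)]]
  hp <- strsplit(locus$hairpin_seq, "")[[1]]
  decomp <- function(sq) {
    rd <- strsplit(sq, "")[[1]]
    best <- NULL
    for (off in -policy$max_offset5:policy$max_offset5) {
      start <- iv[1] + 1L + off
      if (start < 1L) next
      for (t in seq(length(rd), 0)) {   # longest templated prefix first
        if (t > 0 && (start + t - 1L > length(hp) ||
                      !all(rd[seq_len(t)] == hp[start + seq_len(t) - 1L]))) {
          next
        }
        if (t < policy$min_match || length(rd) - t > policy$max_tail) break
        if (is.null(best) || t > best$t ||
            (t == best$t && abs(off) < abs(best$off))) {
          best <- list(off = off, t = t)
        }
        break
      }
    }
    best
  }
  a <- decomp(read); rf <- decomp(ref_seq)
  if (is.null(a) || is.null(rf)) return(NULL)
  d5 <- a$off - rf$off
  class5 <- if (d5 == 0) "canonical" else if (abs(d5) <= 3) {
    sprintf("template_shift_%+d", d5)
  } else "unclassified"
  tail_len <- nchar(read) - a$t
  d3 <- (a$off + a$t) - (rf$off + rf$t)
  class3 <- if (tail_len >= 3) "nontemplate_add_3plus"
  else if (tail_len == 2) "nontemplate_add_2"
  else if (tail_len == 1) "nontemplate_add_1"
  else if (d3 == 0) "canonical"
  else if (d3 > 0 && d3 <= 3) sprintf("template_shift_%+d", d3)
  else if (d3 < 0 && d3 >= -3) sprintf("trim_%d", -d3)
  else "unclassified"
  list(class5 = class5, class3 = class3)
}

# One-sided Fisher enrichment p by full enumeration with fixed margins,
# using only choose().
fisher_oracle <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  ks <- max(0, k - n):min(k, m)
  probs <- choose(m, ks) * choose(n, k - ks) / choose(m + n, k)
  sum(probs[ks >= a])
}

# Deterministic toy hairpin: 20-nt arms fully complementary, 6-nt loop.
toy_locus <- function(id = "toy-1", mismatch_at = integer(0)) {
  arm5 <- "UGAGGUAGUAGGUUGUAUAGUU"          # 22 nt
  arm5v <- strsplit(arm5, "")[[1]]
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  t3 <- character(22)
  for (kk in 1:20) {
    d <- 21 - kk
    t3[kk] <- if (d %in% mismatch_at) {
      setdiff(c("A", "C", "G", "U"), comp[[arm5v[d]]])[1]
    } else comp[[arm5v[d]]]
  }
  t3[21:22] <- c("C", "A")
  loop <- "GCAAAG"
  hp <- paste(c(arm5v, strsplit(loop, "")[[1]], t3), collapse = "")
  db5 <- rep("(", 22); db5[c(mismatch_at, 21, 22)] <- "."
  db3 <- rep(")", 22); db3[21 - mismatch_at] <- "."; db3[21:22] <- "."
  st <- paste(c(db5, rep(".", 6), db3), collapse = "")
  mirna_locus(id, hp, structure = st, arm5p = c(0L, 22L),
              arm3p = c(28L, 50L), energy_kcal_mol = -25)
}

toy_reads <- function(...) {
  x <- list(...)
  data.frame(seq = vapply(x, `[[`, "", 1),
             count = as.numeric(vapply(x, `[[`, "", 2)),
             stringsAsFactors = FALSE)
}
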