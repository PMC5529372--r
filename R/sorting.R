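#' Curate miR / miR* strand labels from the total-RNA pool
#'
#' For loci with two detected mature strands, the strand with the higher mean
#' TPM across the total-pool time points is the non-star strand (miR) and the
#' other is miR*. Loci with a single detectable strand have that strand
#' treated as the non-star sequence. Exact ties go to the 5p arm.
#'
#' @param tpm_total TPM matrix restricted to total-pool libraries (strand x
#'   library).
#' @param strands data.frame with `strand_id`, `locus_id`, `arm`.
#' @param detect_min a strand counts as detected when its mean TPM exceeds
#'   this floor (default 0: any signal).
#' @return data.frame `strand_id`, `locus_id`, `arm`, `mean_tpm`, `star`
#'   (`"miR"`/`"miR*"`/`"undetected"`).
#' @export
curate_strands <- function(tpm_total, strands, detect_min = 0) {
  mt <- rowMeans(tpm_total)[strands$strand_id]
  mt[is.na(mt)] <- 0
  out <- data.frame(strand_id = strands$strand_id,
                    locus_id = strands$locus_id, arm = strands$arm,
                    mean_tpm = as.numeric(mt), star = "undetected",
                    stringsAsFactors = FALSE)
  for (lid in unique(out$locus_id)) {
    i <- which(out$locus_id == lid & out$mean_tpm > detect_min)
    if (length(i) == 0) next
    if (length(i) == 1) {
      out$star[i] <- "miR"
    } else {
      # ties: 5p wins
      ord <- i[order(-out$mean_tpm[i], out$arm[i] != "5p")]
      out$star[ord[1]] <- "miR"
      out$star[ord[-1]] <- "miR*"
    }
  }
  out
}

#' Ago1/Ago2 partition fractions and bias calls
#'
#' Computes, per strand, mean TPM over the Ago1-IP and Ago2-IP libraries and
#' the Ago1 fraction `ago1 / (ago1 + ago2)`. A strand is called Ago1-biased
#' when the fraction exceeds `threshold` (default 0.70), Ago2-biased when it
#' is below `1 - threshold`, otherwise unbiased. Per-library fractions are
#' also returned for heatmap-style displays.
#'
#' @param tpm_ago1,tpm_ago2 TPM matrices for the two IP pools (same strands).
#' @param star optional curated star labels (data.frame from
#'   [curate_strands()]); merged into the result when given.
#' @param threshold bias threshold on the Ago1 fraction.
#' @return data.frame `strand_id`, `ago1_tpm_mean`, `ago2_tpm_mean`,
#'   `ago1_fraction` (`NA` when both means are 0), `bias`; per-time-point
#'   fractions as attribute `"per_library"`.
#' @export
partition_fractions <- function(tpm_ago1, tpm_ago2, star = NULL,
                                threshold = 0.70) {
  stopifnot(identical(rownames(tpm_ago1), rownames(tpm_ago2)))
  m1 <- rowMeans(tpm_ago1); m2 <- rowMeans(tpm_ago2)
  frac <- ifelse(m1 + m2 > 0, m1 / (m1 + m2), NA_real_)
  bias <- rep("none", length(frac))
  bias[!is.na(frac) & frac > threshold] <- "ago1"
  bias[!is.na(frac) & frac < 1 - threshold] <- "ago2"
  out <- data.frame(strand_id = rownames(tpm_ago1),
                    ago1_tpm_mean = as.numeric(m1),
                    ago2_tpm_mean = as.numeric(m2),
                    ago1_fraction = as.numeric(frac), bias = bias,
                    stringsAsFactors = FALSE)
  if (!is.null(star)) {
    out$star <- star$star[match(out$strand_id, star$strand_id)]
  }
  per_lib <- tpm_ago1 / (tpm_ago1 + tpm_ago2)
  attr(out, "per_library") <- per_lib
  out
}

#' One-sided Fisher's exact test for miR* enrichment
#'
#' Tests whether the star strand is over-represented in an Ago-IP pool
#' relative to the total-RNA pool, on the 2x2 table
#' `[[star_ago, nonstar_ago], [star_total, nonstar_total]]`. The p-value is
#' the one-sided hypergeometric tail in the enrichment direction.
#'
#' @param star_ago,nonstar_ago,star_total,nonstar_total non-negative counts.
#' @return the p-value.
#' @export
star_enrichment_test <- function(star_ago, nonstar_ago,
                                 star_total, nonstar_total) {
  k <- c(star_ago, nonstar_ago, star_total, nonstar_total)
  if (any(k < 0)) stop("counts must be non-negative")
  if (star_ago + star_total == 0) return(1)
  # P(X >= star_ago), X ~ Hypergeometric over tables with fixed margins
  stats::phyper(star_ago - 1, star_ago + star_total,
                nonstar_ago + nonstar_total, star_ago + nonstar_ago,
                lower.tail = FALSE)
}

#' Per-strand miR* enrichment over a strand table
#'
#' For each miR* strand, compares its reads against all other miRNA reads in
#' the Ago pool versus the total pool (one Fisher test per strand) and
#' attaches Benjamini-Hochberg q-values. The headline `enriched` flag uses
#' the raw p at `alpha` (default 0.01), matching the published threshold.
#'
#' @param counts_ago,counts_total named numeric vectors of per-strand read
#'   counts (same strand universe) in the Ago-IP and total pools.
#' @param star_ids ids of the miR* strands to test.
#' @param alpha raw-p significance threshold.
#' @return data.frame `strand_id`, `p`, `q`, `enriched`.
#' @export
star_enrichment_table <- function(counts_ago, counts_total, star_ids,
                                  alpha = 0.01) {
  tot_a <- sum(unlist(counts_ago)); tot_t <- sum(unlist(counts_total))
  p <- vapply(star_ids, function(id) {
    a <- round(if (id %in% names(counts_ago)) counts_ago[[id]] else 0)
    t <- round(if (id %in% names(counts_total)) counts_total[[id]] else 0)
    star_enrichment_test(a, round(tot_a) - a, t, round(tot_t) - t)
  }, numeric(1))
  q <- stats::p.adjust(p, method = "BH")
  data.frame(strand_id = star_ids, p = as.numeric(p), q = as.numeric(q),
             enriched = p <= alpha, stringsAsFactors = FALSE)
}

#' Positional nucleotide composition of a strand set
#'
#' Aligns sequences at their 5' ends and tabulates per-position nucleotide
#' frequencies (positions beyond a sequence's length are skipped). When a
#' background set is supplied, the position-1 composition is compared against
#' the background frequency with a two-sided exact binomial test per
#' nucleotide (the minimal test for a single-position bias; reported as such).
#'
#' @param sequences character vector of mature sequences (non-empty).
#' @param background optional character vector of background sequences.
#' @return list with `freq` (4 x L matrix, columns sum to 1) and, when a
#'   background is given, `position1` (data.frame `nt`, `freq`, `bg_freq`,
#'   `p`).
#' @export
nt_composition <- function(sequences, background = NULL) {
  if (length(sequences) == 0) stop("empty sequence set")
  sequences <- norm_rna(sequences)
  L <- max(nchar(sequences))
  freq <- matrix(0, 4, L, dimnames = list(RNA_BASES, seq_len(L)))
  for (pos in seq_len(L)) {
    ch <- substr(sequences, pos, pos)
    ch <- ch[nzchar(ch)]
    t <- table(factor(ch, levels = RNA_BASES))
    freq[, pos] <- as.numeric(t) / sum(t)
  }
  out <- list(freq = freq)
  if (!is.null(background)) {
    bg1 <- table(factor(substr(norm_rna(background), 1, 1),
                        levels = RNA_BASES))
    bg1 <- as.numeric(bg1) / sum(bg1)
    first <- factor(substr(sequences, 1, 1), levels = RNA_BASES)
    n <- length(sequences)
    out$position1 <- data.frame(
      nt = RNA_BASES, freq = as.numeric(table(first)) / n, bg_freq = bg1,
      p = vapply(seq_along(RNA_BASES), function(i) {
        stats::binom.test(sum(first == RNA_BASES[i]), n, bg1[i])$p.value
      }, numeric(1)))
  }
  out
}

#' Maximum base-pairing fold (Nussinov) fallback
#'
#' Dynamic-programming maximum-pairing structure with minimum loop length 3
#' and Watson-Crick plus G:U wobble pairs; ties are broken toward pairing the
#' 5'-most positions. This is a combinatorial fallback for synthetic or toy
#' hairpins that arrive without a structure; it is not a thermodynamic (MFE)
#' model and structures are flagged accordingly downstream.
#'
#' @param seq RNA sequence.
#' @param min_loop minimum hairpin loop length.
#' @return dot-bracket string.
#' @export
nussinov_fold <- function(seq, min_loop = 3L) {
  s <- strsplit(norm_rna(seq), "")[[1]]
  n <- length(s)
  can_pair <- function(a, b) {
    paste0(a, b) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
  }
  if (n < min_loop + 2) return(paste(rep(".", n), collapse = ""))
  dp <- matrix(0L, n, n)
  for (span in (min_loop + 1L):(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- dp[i + 1, j - 1] + if (can_pair(s[i], s[j])) 1L else 0L
      best <- max(best, dp[i + 1, j], dp[i, j - 1])
      if (j - i > 1) {
        for (k in (i + 1):(j - 1)) {
          best <- max(best, dp[i, k] + dp[k + 1, j])
        }
      }
      dp[i, j] <- best
    }
  }
  db <- rep(".", n)
  trace <- function(i, j) {
    while (i < j) {
      if (j - i <= min_loop) return(invisible(NULL))
      # prefer pairing (i,j) first: ties broken toward 5'-most pairing
      if (can_pair(s[i], s[j]) && dp[i, j] == dp[i + 1, j - 1] + 1L) {
        db[i] <<- "("; db[j] <<- ")"
        i <- i + 1; j <- j - 1
      } else if (dp[i, j] == dp[i + 1, j]) {
        i <- i + 1
      } else if (dp[i, j] == dp[i, j - 1]) {
        j <- j - 1
      } else {
        for (k in (i + 1):(j - 1)) {
          if (dp[i, j] == dp[i, k] + dp[k + 1, j]) {
            trace(i, k); i <- k + 1; break
          }
        }
      }
    }
    invisible(NULL)
  }
  trace(1L, n)
  paste(db, collapse = "")
}

#' Per-position duplex pairing vector of a mature strand
#'
#' Position `i` of the mature strand scores 1 when that hairpin base is
#' paired, in the locus dot-bracket structure, with a base lying on the
#' partner arm; bulges and mismatches (unpaired on either strand) score 0.
#' When the locus has no structure, a Nussinov maximum-pairing fold is used
#' if `fold_fallback` is allowed (result attribute `folded` says so).
#'
#' @param locus a [mirna_locus()].
#' @param arm `"5p"` or `"3p"`.
#' @param fold_fallback fold the hairpin when no structure is present.
#' @return integer vector (0/1) of the mature strand length; attribute
#'   `folded` TRUE when the fallback fold was used.
#' @export
duplex_pairing_profile <- function(locus, arm, fold_fallback = TRUE) {
  iv <- locus[[paste0("arm", arm)]]
  if (is.null(iv)) stop("locus ", locus$locus_id, " has no ", arm, " arm")
  st <- locus$structure
  folded <- FALSE
  if (is.na(st)) {
    if (!fold_fallback) {
      stop("locus ", locus$locus_id, " has no structure and folding is disabled")
    }
    st <- nussinov_fold(locus$hairpin_seq)
    folded <- TRUE
  }
  partner <- parse_dotbracket(st)
  other <- locus[[paste0("arm", if (arm == "5p") "3p" else "5p")]]
  pos <- (iv[1] + 1L):iv[2]
  paired <- vapply(pos, function(p) {
    q <- partner[p]
    if (is.na(q)) return(0L)
    if (is.null(other)) return(1L)             # partner arm unannotated
    if (q > other[1] && q <= other[2]) 1L else 0L
  }, integer(1))
  attr(paired, "folded") <- folded
  paired
}

#' Median pairing profile over a strand set
#'
#' @param profiles list of 0/1 pairing vectors from
#'   [duplex_pairing_profile()].
#' @param length_out profile length (default 22; shorter strands contribute
#'   nothing beyond their length).
#' @return numeric vector of per-position medians.
#' @export
aggregate_pairing_profile <- function(profiles, length_out = 22L) {
  m <- matrix(NA_real_, length(profiles), length_out)
  for (i in seq_along(profiles)) {
    v <- profiles[[i]]
    m[i, seq_len(min(length(v), length_out))] <-
      v[seq_len(min(length(v), length_out))]
  }
  apply(m, 2, stats::median, na.rm = TRUE)
}
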