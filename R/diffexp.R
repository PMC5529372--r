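#' MA-plot z-test for two libraries without replicates
#'
#' MARS-style test (MA-plot with a random-sampling model): for counts `k1`,
#' `k2` out of library totals `n1`, `n2`,
#' `M = log2(p1) - log2(p2)` and `A = (log2(p1) + log2(p2)) / 2` with
#' `pi = ki / ni`. Under the null of equal proportions and binomial sampling,
#' `z = M / sqrt(VarM)` with
#' `VarM = (1/ln(2)^2) * ((1 - p1)/k1 + (1 - p2)/k2)`, and the p-value is the
#' two-sided normal tail. A pseudo-count `c` (default 0.5) replaces zero
#' counts only, so non-zero data are untouched and equal proportions give
#' exactly `M = 0`. The variance is a per-observation binomial approximation,
#' not DEGSeq's A-conditional smoothing; output is labeled MARS-style, not
#' claimed identical.
#'
#' @param k1,k2 read counts (vectors allowed). Non-integer counts are
#'   rejected unless `weighted = TRUE`.
#' @param n1,n2 library totals (> 0).
#' @param pseudo pseudo-count applied to zero counts.
#' @param weighted allow non-integer (fractionally weighted) counts.
#' @return data.frame with columns `M`, `A`, `z`, `p`.
#' @export
mars_test <- function(k1, n1, k2, n2, pseudo = 0.5, weighted = FALSE) {
  if (any(n1 <= 0) || any(n2 <= 0)) stop("library totals must be positive")
  if (any(k1 < 0) || any(k2 < 0)) stop("counts must be non-negative")
  if (!weighted && (any(k1 != floor(k1)) || any(k2 != floor(k2)))) {
    stop("non-integer counts; use weighted = TRUE for fractional counts")
  }
  a1 <- ifelse(k1 == 0, pseudo, k1)
  a2 <- ifelse(k2 == 0, pseudo, k2)
  p1 <- a1 / n1
  p2 <- a2 / n2
  M <- log2(p1) - log2(p2)
  A <- (log2(p1) + log2(p2)) / 2
  varM <- ((1 - p1) / a1 + (1 - p2) / a2) / log(2)^2
  z <- M / sqrt(varM)
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(M = M, A = A, z = z, p = p)
}

#' Differential abundance over the time course
#'
#' Per pool and strand, compares every post-blood-meal time point against the
#' 0 h (non-blood-fed) baseline with [mars_test()], attaches
#' Benjamini-Hochberg q-values within each (pool, time) comparison, and flags
#' strands whose |log2 fold change| reaches `log2(fold_cut)` with `q <=
#' alpha` at one or more time points. The design carries no biological
#' replicates; interpret p-values accordingly (a warning banner is attached).
#'
#' @param raw strand-by-library raw count matrix.
#' @param lib_meta data.frame `library_id`, `pool`, `time_h_pbm` describing
#'   the columns of `raw`.
#' @param totals named per-library totals used as sampling denominators
#'   (default: column sums of `raw`).
#' @param alpha q-value threshold for the significance-qualified flag.
#' @param fold_cut fold-change threshold (default 4, i.e. |M| >= 2).
#' @param baseline_h baseline time point (default 0).
#' @return list with `table` (per strand/pool/time M, A, z, p, q) and `flags`
#'   (per strand/pool: `flag4x` in `up`/`down`/`none`, plus a raw-fold-only
#'   flag `flag4x_rawfold`).
#' @export
de_table <- function(raw, lib_meta, totals = NULL, alpha = 0.01,
                     fold_cut = 4, baseline_h = 0L) {
  if (is.null(totals)) totals <- colSums(raw)
  thr <- log2(fold_cut)
  res <- list(); r <- 0L
  for (pool in unique(lib_meta$pool)) {
    meta_p <- lib_meta[lib_meta$pool == pool, ]
    base <- meta_p$library_id[meta_p$time_h_pbm == baseline_h]
    if (length(base) != 1) {
      stop("pool '", pool, "': no unique baseline library at ",
           baseline_h, " h")
    }
    for (tp in sort(setdiff(meta_p$time_h_pbm, baseline_h))) {
      lib <- meta_p$library_id[meta_p$time_h_pbm == tp]
      mt <- mars_test(raw[, lib], totals[[lib]], raw[, base],
                      totals[[base]], weighted = TRUE)
      mt$q <- stats::p.adjust(mt$p, method = "BH")
      r <- r + 1L
      res[[r]] <- data.frame(strand_id = rownames(raw), pool = pool,
                             time_h = tp, mt, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, res)
  flags <- do.call(rbind, lapply(split(tab, paste(tab$strand_id, tab$pool)),
    function(d) {
      sig_up <- any(d$M >= thr & d$q <= alpha)
      sig_dn <- any(d$M <= -thr & d$q <= alpha)
      raw_up <- any(d$M >= thr); raw_dn <- any(d$M <= -thr)
      data.frame(strand_id = d$strand_id[1], pool = d$pool[1],
                 flag4x = if (sig_up) "up" else if (sig_dn) "down" else "none",
                 flag4x_rawfold = if (raw_up) "up" else if (raw_dn) "down"
                 else "none",
                 stringsAsFactors = FALSE)
    }))
  rownames(flags) <- NULL
  out <- list(table = tab, flags = flags)
  attr(out, "warning") <- paste(
    "no biological replicates: p-values reflect sampling variation only")
  out
}

#' Cluster time-course fold-change profiles
#'
#' Agglomerative hierarchical clustering (Euclidean distance, complete
#' linkage) of per-strand log2 fold-change profiles, cut at `k` clusters.
#'
#' @param log2fc matrix (strands x time points) of log2 fold changes.
#' @param k number of clusters.
#' @return list with `cluster` (named integer vector), `order` (dendrogram
#'   leaf order), `hclust` (the tree).
#' @export
cluster_profiles <- function(log2fc, k = 3L) {
  if (nrow(log2fc) < 2) stop("need at least 2 profiles to cluster")
  hc <- stats::hclust(stats::dist(log2fc, method = "euclidean"),
                      method = "complete")
  list(cluster = stats::cutree(hc, k = min(k, nrow(log2fc))),
       order = hc$order, hclust = hc)
}
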