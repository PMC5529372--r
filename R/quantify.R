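#' 3' adapter trimming
#'
#' Removes, from each read, the leftmost exact occurrence of the adapter's
#' prefix (minimum overlap 6 nt, no mismatches) and everything 3' of it.
#' Reads without an adapter hit are kept unchanged. Reads reduced to an empty
#' insert are kept here and removed by [size_select()].
#'
#' @param reads data.frame with `seq`, `count`.
#' @param adapter adapter sequence (>= 6 nt; DNA accepted, normalized to RNA).
#' @return data.frame with `seq`, `count` (identical sequences merged).
#' @export
trim_adapter <- function(reads, adapter) {
  adapter <- norm_rna(adapter)
  if (nchar(adapter) < 6) stop("adapter must be at least 6 nt")
  probe <- substr(adapter, 1, 6)
  pos <- regexpr(probe, reads$seq, fixed = TRUE)
  keep_full <- pos < 0
  ins <- reads$seq
  hit <- which(!keep_full)
  for (i in hit) {
    # leftmost occurrence whose following bases keep matching the adapter
    p <- pos[i]
    read <- reads$seq[i]
    avail <- nchar(read) - p + 1L
    want <- substr(adapter, 1, min(avail, nchar(adapter)))
    # scan leftmost 6-mer seeds until the full available overlap matches
    while (p > 0 && substr(read, p, p + nchar(want) - 1L) != want) {
      nx <- regexpr(probe, substr(read, p + 1L, nchar(read)), fixed = TRUE)
      p <- if (nx < 0) -1L else p + nx
      if (p > 0) {
        avail <- nchar(read) - p + 1L
        want <- substr(adapter, 1, min(avail, nchar(adapter)))
      }
    }
    if (p > 0) ins[i] <- substr(read, 1, p - 1L)
  }
  agg <- rowsum(reads$count, ins)
  out <- data.frame(seq = rownames(agg), count = as.numeric(agg[, 1]),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[nchar(out$seq) >= 0, , drop = FALSE]
}

#' Size selection
#'
#' Keeps reads whose length lies in `[min_len, max_len]` (inclusive bounds,
#' matching gel size selection).
#'
#' @param reads data.frame with `seq`, `count`.
#' @param min_len,max_len inclusive length bounds.
#' @return filtered data.frame.
#' @export
size_select <- function(reads, min_len = 15L, max_len = 30L) {
  stopifnot(min_len > 0, min_len <= max_len)
  len <- nchar(reads$seq)
  reads[len >= min_len & len <= max_len, , drop = FALSE]
}

#' Drop reads containing ambiguous bases
#' @param reads data.frame with `seq`, `count`.
#' @return filtered data.frame.
#' @export
drop_ambiguous <- function(reads) {
  reads[!grepl("N", reads$seq, fixed = TRUE), , drop = FALSE]
}

#' Alignment policy for the hairpin-first cascade
#'
#' @param max_tail maximum non-templated 3' tail length.
#' @param max_offset5 maximum distance between a read's 5' start and the
#'   annotated mature 5' end (the `arm_window`).
#' @param min_match minimum templated match length (guards against chance
#'   matches of short background reads).
#' @return a named list.
#' @export
align_policy <- function(max_tail = 3L, max_offset5 = 3L, min_match = 14L) {
  list(max_tail = as.integer(max_tail), max_offset5 = as.integer(max_offset5),
       min_match = as.integer(min_match))
}

# longest common prefix of `read` and `hairpin` starting at hairpin position
# `start` (1-based); both are character scalars
lcp_at <- function(read, hairpin, start) {
  maxn <- min(nchar(read), nchar(hairpin) - start + 1L)
  if (maxn <= 0) return(0L)
  rs <- utf8ToInt(read)
  hs <- utf8ToInt(substr(hairpin, start, start + maxn - 1L))
  d <- which(rs[seq_len(maxn)] != hs)
  if (length(d) == 0) maxn else d[1L] - 1L
}

#' Align reads to precursor hairpins
#'
#' Hairpin-first exact alignment: a read is assigned to a mature strand when
#' its maximal exact match to the hairpin begins within `max_offset5` of that
#' arm's annotated 5' end and the unmatched 3' suffix is at most `max_tail`
#' long. Template extension takes precedence over calling a tail: the match
#' is extended along the hairpin as far as the read allows, so a suffix is
#' recorded as a non-templated tail only when it cannot be explained by the
#' template. Reads matching k > 1 strands receive weight 1/k each.
#'
#' @param reads data.frame with `seq`, `count`.
#' @param loci list of [mirna_locus()] objects.
#' @param policy an [align_policy()].
#' @return list with `assignments` (data.frame: `seq`, `count`, `strand_id`,
#'   `locus_id`, `arm`, `offset5`, `templated_len`, `tail`, `weight`) and
#'   `unassigned` (data.frame `seq`, `count`).
#' @export
align_to_hairpins <- function(reads, loci, policy = align_policy()) {
  names(loci) <- vapply(loci, `[[`, "", "locus_id")
  strands <- mature_strands(loci)
  # candidate (strand, start) table with a 10-mer seed keyed on the read 5' end
  cand <- list(); k <- 0L
  for (i in seq_len(nrow(strands))) {
    lc <- loci[[strands$locus_id[i]]]
    iv <- lc[[paste0("arm", strands$arm[i])]]
    for (off in -policy$max_offset5:policy$max_offset5) {
      start <- iv[1] + 1L + off   # 1-based hairpin position
      if (start < 1L || start + 9L > nchar(lc$hairpin_seq)) next
      k <- k + 1L
      cand[[k]] <- data.frame(
        strand_id = strands$strand_id[i], locus_id = strands$locus_id[i],
        arm = strands$arm[i], start = start, offset5 = off,
        seed = substr(lc$hairpin_seq, start, start + 9L),
        stringsAsFactors = FALSE)
    }
  }
  cand <- do.call(rbind, cand)
  if (nrow(reads) == 0) {
    return(list(assignments = data.frame(), unassigned = reads))
  }
  read_seed <- substr(reads$seq, 1, 10)
  hits <- list(); h <- 0L
  seed_index <- split(seq_len(nrow(cand)), cand$seed)
  for (r in seq_len(nrow(reads))) {
    ci <- seed_index[[read_seed[r]]]
    if (is.null(ci)) next
    best <- NULL
    for (j in ci) {
      lc <- loci[[cand$locus_id[j]]]
      tl <- lcp_at(reads$seq[r], lc$hairpin_seq, cand$start[j])
      tail_len <- nchar(reads$seq[r]) - tl
      if (tl < policy$min_match || tail_len > policy$max_tail) next
      rec <- data.frame(
        seq = reads$seq[r], count = reads$count[r],
        strand_id = cand$strand_id[j], locus_id = cand$locus_id[j],
        arm = cand$arm[j], offset5 = cand$offset5[j], templated_len = tl,
        tail = substr(reads$seq[r], tl + 1L, nchar(reads$seq[r])),
        stringsAsFactors = FALSE)
      best <- rbind(best, rec)
    }
    if (is.null(best)) next
    # one best candidate per strand: longest templated match, then smallest
    # |offset5|
    best <- best[order(best$strand_id, -best$templated_len,
                       abs(best$offset5)), ]
    best <- best[!duplicated(best$strand_id), , drop = FALSE]
    best$weight <- 1 / nrow(best)
    h <- h + 1L
    hits[[h]] <- best
  }
  assignments <- if (h > 0) do.call(rbind, hits) else data.frame()
  assigned_seqs <- unique(assignments$seq)
  unassigned <- reads[!(reads$seq %in% assigned_seqs), , drop = FALSE]
  rownames(assignments) <- NULL
  list(assignments = assignments, unassigned = unassigned)
}

CATEGORY_ORDER <- c("miRNA", "repeats", "ncRNA", "mRNA", "unannotated")

#' Annotate unassigned reads by category cascade
#'
#' Reads are matched exactly against optional feature tracks in the fixed
#' priority order `miRNA > repeats > ncRNA > mRNA`; reads matching nothing
#' are `unannotated`.
#'
#' @param reads data.frame with `seq`, `count` (the unassigned reads).
#' @param tracks named list of character vectors of sequences; recognized
#'   names: `miRNA`, `repeats`, `ncRNA`, `mRNA`. Missing tracks are skipped.
#' @return data.frame `seq`, `count`, `category`.
#' @export
annotate_categories <- function(reads, tracks = list()) {
  category <- rep("unannotated", nrow(reads))
  for (tr in c("miRNA", "repeats", "ncRNA", "mRNA")) {
    if (is.null(tracks[[tr]])) next
    hit <- category == "unannotated" & reads$seq %in% tracks[[tr]]
    category[hit] <- tr
  }
  cbind(reads, category = category, stringsAsFactors = FALSE)
}

#' Build a strand-by-library count matrix from per-library alignments
#'
#' @param aligned named list (by library id) of [align_to_hairpins()] results.
#' @param strand_ids character vector fixing row order.
#' @param tracks optional feature tracks for [annotate_categories()].
#' @return an object of class `mirna_counts`: list with `raw` (matrix),
#'   `categories` (matrix category x library, read counts), `tpm` (`NULL`
#'   until [compute_tpm()]), `tpm_basis`.
#' @export
build_count_matrix <- function(aligned, strand_ids, tracks = list()) {
  libs <- names(aligned)
  raw <- matrix(0, length(strand_ids), length(libs),
                dimnames = list(strand_ids, libs))
  cats <- matrix(0, length(CATEGORY_ORDER), length(libs),
                 dimnames = list(CATEGORY_ORDER, libs))
  for (lib in libs) {
    a <- aligned[[lib]]$assignments
    if (NROW(a) > 0) {
      w <- rowsum(a$count * a$weight, a$strand_id)
      raw[rownames(w), lib] <- w[, 1]
      cats["miRNA", lib] <- sum(a$count * a$weight)
    }
    u <- annotate_categories(aligned[[lib]]$unassigned, tracks)
    if (nrow(u) > 0) {
      t <- rowsum(u$count, u$category)
      cats[rownames(t), lib] <- t[, 1]
    }
  }
  structure(list(raw = raw, categories = cats, tpm = NULL, tpm_basis = NULL),
            class = "mirna_counts")
}

#' @export
print.mirna_counts <- function(x, ...) {
  cat("<mirna_counts> ", nrow(x$raw), " strands x ", ncol(x$raw),
      " libraries; TPM: ",
      if (is.null(x$tpm)) "not computed" else x$tpm_basis, "\n", sep = "")
  invisible(x)
}

#' Convert raw counts to transcripts per million (TPM)
#'
#' `tpm[i,j] = raw[i,j] / mapped_total[j] * 1e6`. The per-library
#' denominator is controlled by `basis`: `"mapped"` counts every annotated
#' category except `unannotated` reads that did not map (here: miRNA +
#' repeats + ncRNA + mRNA + unannotated, i.e. all size-selected reads, since
#' synthetic reads have no genome to fail to map to), `"annotated"` excludes
#' the unannotated fraction, and `"mirna"` uses miRNA-assigned reads only (in
#' which case strand TPMs sum to 1e6 per library).
#'
#' @param cm a `mirna_counts` object.
#' @param basis denominator definition, see above.
#' @return the `mirna_counts` object with `tpm` filled in.
#' @export
compute_tpm <- function(cm, basis = c("mapped", "annotated", "mirna")) {
  basis <- match.arg(basis)
  rows <- switch(basis,
                 mapped = CATEGORY_ORDER,
                 annotated = setdiff(CATEGORY_ORDER, "unannotated"),
                 mirna = "miRNA")
  total <- colSums(cm$categories[rows, , drop = FALSE])
  if (any(total <= 0)) {
    stop("mapped-read total is zero for library: ",
         paste(colnames(cm$raw)[total <= 0], collapse = ", "))
  }
  cm$tpm <- sweep(cm$raw, 2, total, "/") * 1e6
  cm$tpm_basis <- basis
  cm$mapped_total <- total
  cm
}

#' Discard strands below a TPM floor in every library
#'
#' A strand is retained iff its TPM is at or above `threshold` in at least
#' one library (the published rule discards strands `< 20` TPM everywhere, so
#' exactly 20.0 is retained).
#'
#' @param cm a `mirna_counts` object with TPM computed.
#' @param threshold TPM floor (default 20).
#' @return the filtered `mirna_counts`; attribute `n_removed` records how
#'   many strands were dropped.
#' @export
filter_low_abundance <- function(cm, threshold = 20) {
  if (is.null(cm$tpm)) stop("compute_tpm() first")
  keep <- apply(cm$tpm, 1, function(x) any(x >= threshold))
  out <- cm
  out$raw <- cm$raw[keep, , drop = FALSE]
  out$tpm <- cm$tpm[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Read length distribution
#'
#' @param reads data.frame with `seq`, `count`.
#' @return data.frame `length`, `fraction` (fractions sum to 1); zero rows
#'   for empty input.
#' @export
length_histogram <- function(reads) {
  if (nrow(reads) == 0) {
    return(data.frame(length = integer(0), fraction = numeric(0)))
  }
  t <- rowsum(reads$count, nchar(reads$seq))
  data.frame(length = as.integer(rownames(t)),
             fraction = as.numeric(t[, 1]) / sum(t[, 1]))
}
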