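#' Choose the classification reference sequence per strand
#'
#' The most abundant assigned read sequence per strand, summed (weighted)
#' over all libraries, becomes the reference mature sequence — which may
#' differ from the annotated sequence. Ties go to the longer sequence, then
#' lexicographically smaller.
#'
#' @param assignments data.frame of assignments pooled over libraries
#'   (columns `strand_id`, `seq`, `count`, `weight`, `offset5`,
#'   `templated_len`, `tail`).
#' @return data.frame `strand_id`, `ref_seq`, `ref_offset5`,
#'   `ref_templated_len`.
#' @export
choose_reference <- function(assignments) {
  if (NROW(assignments) == 0) {
    return(data.frame(strand_id = character(0), ref_seq = character(0),
                      ref_offset5 = integer(0),
                      ref_templated_len = integer(0)))
  }
  key <- paste(assignments$strand_id, assignments$seq, sep = "\r")
  tot <- rowsum(assignments$count * assignments$weight, key)
  first <- assignments[match(rownames(tot), key), ]
  first$total <- tot[, 1]
  ord <- order(first$strand_id, -first$total, -nchar(first$seq), first$seq)
  first <- first[ord, ]
  ref <- first[!duplicated(first$strand_id), ]
  data.frame(strand_id = ref$strand_id, ref_seq = ref$seq,
             ref_offset5 = ref$offset5,
             ref_templated_len = ref$templated_len,
             stringsAsFactors = FALSE)
}

#' Classify assignments into the isomiR taxonomy
#'
#' Each assigned read is classified independently at both ends, relative to
#' the per-strand reference from [choose_reference()]:
#' * 5' class: `canonical` (same 5' start as the reference),
#'   `template_shift_{-3..+3}` for template-directed shifts, or
#'   `unclassified` beyond 3 nt.
#' * 3' class: non-templated tails give `nontemplate_add_1`,
#'   `nontemplate_add_2`, `nontemplate_add_3plus`; otherwise the templated 3'
#'   end versus the reference gives `canonical`, `template_shift_+k`
#'   (extension) or `trim_k` (shortening). A 3' addition whose nucleotide
#'   equals the next template base is, by the aligner's template-precedence
#'   rule, already a template shift — genuinely undecidable from sequence,
#'   and classified as template.
#'
#' @param assignments assignment data.frame (may span libraries; a
#'   `library_id` column is carried through when present).
#' @param refs reference table from [choose_reference()].
#' @return the assignments with `class5`, `class3`, `tail_seq` columns.
#' @export
classify_assignments <- function(assignments, refs) {
  if (NROW(assignments) == 0) return(assignments)
  i <- match(assignments$strand_id, refs$strand_id)
  if (anyNA(i)) stop("assignments contain strands without a reference")
  d5 <- assignments$offset5 - refs$ref_offset5[i]
  class5 <- ifelse(d5 == 0, "canonical",
                   ifelse(abs(d5) <= 3,
                          sprintf("template_shift_%+d", d5), "unclassified"))
  # 3' templated end in arm coordinates
  end3 <- assignments$offset5 + assignments$templated_len
  ref_end3 <- refs$ref_offset5[i] + refs$ref_templated_len[i]
  d3 <- end3 - ref_end3
  tl <- nchar(assignments$tail)
  class3 <- ifelse(
    tl >= 3, "nontemplate_add_3plus",
    ifelse(tl == 2, "nontemplate_add_2",
           ifelse(tl == 1, "nontemplate_add_1",
                  ifelse(d3 == 0, "canonical",
                         ifelse(d3 > 0 & d3 <= 3, sprintf("template_shift_%+d", d3),
                                ifelse(d3 < 0 & d3 >= -3, sprintf("trim_%d", -d3),
                                       "unclassified"))))))
  assignments$class5 <- class5
  assignments$class3 <- class3
  assignments$tail_seq <- assignments$tail
  assignments
}

#' Per-library isomiR class fractions
#'
#' Fractions of each 5' and 3' class among classified miRNA-assigned reads,
#' per library; within each end the fractions over the taxonomy sum to 1.
#'
#' @param records classified assignments with a `library_id` column.
#' @return list of two data.frames (`end5`, `end3`) with columns
#'   `library_id`, `class`, `fraction`; plus `per_strand` (weighted class3
#'   counts per strand/library) for strand-level breakdowns.
#' @export
isomir_summary <- function(records) {
  stopifnot("library_id" %in% names(records))
  w <- records$count * records$weight
  frac_tab <- function(cls) {
    keep <- cls != "unclassified"
    t <- rowsum(w[keep], paste(records$library_id[keep], cls[keep], sep = "\r"))
    parts <- do.call(rbind, strsplit(rownames(t), "\r", fixed = TRUE))
    df <- data.frame(library_id = parts[, 1], class = parts[, 2],
                     count = t[, 1], stringsAsFactors = FALSE)
    tot <- rowsum(df$count, df$library_id)
    df$fraction <- df$count / tot[df$library_id, 1]
    rownames(df) <- NULL
    df
  }
  per_strand <- rowsum(w, paste(records$library_id, records$strand_id,
                                records$class3, sep = "\r"))
  parts <- do.call(rbind, strsplit(rownames(per_strand), "\r", fixed = TRUE))
  ps <- data.frame(library_id = parts[, 1], strand_id = parts[, 2],
                   class3 = parts[, 3], count = per_strand[, 1],
                   stringsAsFactors = FALSE, row.names = NULL)
  list(end5 = frac_tab(records$class5), end3 = frac_tab(records$class3),
       per_strand = ps)
}
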