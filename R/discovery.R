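#' Novel-miRNA candidate retention filter
#'
#' Applies the published retention rules to externally predicted candidate
#' hairpins: (1) predicted by at least two independent algorithms; (2) at
#' least `min_reads` perfectly aligned reads in more than one Ago-IP library
#' (strictly more than one: `>= min_libs`, default 2); (3) hairpin free
#' energy below `energy_max` (default -20 kcal/mol); (4) a "vast majority"
#' of mapped reads falling on one or two arms, quantified as
#' `arm_read_fraction >= arm_fraction_min` (default 0.9, configurable — the
#' source rule gives no number).
#'
#' @param candidates data.frame with columns `candidate_id`, `energy`,
#'   `n_predictors` (count of predicting algorithms), `arm_read_fraction`,
#'   and `ago_counts` (a list-column of per-Ago-IP-library perfect-match read
#'   counts, or a plain matrix-like column set `agoN`).
#' @param min_reads per-library read support threshold.
#' @param min_libs minimum number of Ago-IP libraries meeting `min_reads`.
#' @param energy_max retain only energies strictly below this (kcal/mol).
#' @param arm_fraction_min minimum arm read fraction.
#' @return the input with logical columns `rule_predictors`, `rule_reads`,
#'   `rule_energy`, `rule_arms`, `pass`, and a `reasons` character column
#'   listing violated rules.
#' @export
filter_novel_candidates <- function(candidates, min_reads = 20L,
                                    min_libs = 2L, energy_max = -20,
                                    arm_fraction_min = 0.9) {
  stopifnot(all(c("candidate_id", "energy") %in% names(candidates)))
  n <- nrow(candidates)
  get_counts <- function(i) {
    if (!is.null(candidates$ago_counts)) {
      as.numeric(candidates$ago_counts[[i]])
    } else {
      as.numeric(candidates[i, grep("^ago", names(candidates)), drop = TRUE])
    }
  }
  rule_pred <- if (!is.null(candidates$n_predictors)) {
    candidates$n_predictors >= 2
  } else rep(TRUE, n)
  rule_reads <- vapply(seq_len(n), function(i) {
    sum(get_counts(i) >= min_reads) >= min_libs
  }, logical(1))
  rule_energy <- candidates$energy < energy_max
  rule_arms <- if (!is.null(candidates$arm_read_fraction)) {
    candidates$arm_read_fraction >= arm_fraction_min
  } else rep(TRUE, n)
  pass <- rule_pred & rule_reads & rule_energy & rule_arms
  reasons <- vapply(seq_len(n), function(i) {
    paste(c(if (!rule_pred[i]) "predictors",
            if (!rule_reads[i]) "read_support",
            if (!rule_energy[i]) "energy",
            if (!rule_arms[i]) "arm_fraction"), collapse = ";")
  }, character(1))
  cbind(candidates,
        data.frame(rule_predictors = rule_pred, rule_reads = rule_reads,
                   rule_energy = rule_energy, rule_arms = rule_arms,
                   pass = pass, reasons = reasons, stringsAsFactors = FALSE))
}

#' The published novel-miRNA table
#'
#' The thirteen novel candidate loci as printed (chromosome, genomic span,
#' arm, mature sequence, hairpin free energy in kcal/mol); packaged as input
#' for the energy-rule worked example.
#'
#' @return data.frame with columns `candidate_id`, `chrom`, `start`, `end`,
#'   `strand`, `arm`, `mature_seq`, `energy`.
#' @export
novel_mirna_table <- function() {
  path <- system.file("extdata", "novel_mirna_candidates.tsv",
                      package = "agosort", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# top hit per query: lowest e-value, ties by higher identity then subject id
top_hits <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  ord <- order(hits$query_id, hits$evalue, -hits$pct_identity,
               hits$subject_id)
  h <- hits[ord, ]
  h[!duplicated(h$query_id), , drop = FALSE]
}

#' Reciprocal-best-hit ortholog calls
#'
#' A query precursor has an ortholog in the target genome iff its top forward
#' BLAST hit passes both thresholds (identity >= `id_min`, e-value <=
#' `e_max`) and the top reverse hit of that subject locus maps back to the
#' query and passes the same thresholds.
#'
#' @param forward BLAST outfmt-6 hits of queries against the target genome
#'   ([read_blast_tab6()] layout).
#' @param reverse hits of target loci back against the query genome/set.
#' @param queries optional character vector of query ids to report (defaults
#'   to the queries present in `forward`).
#' @param id_min,e_max thresholds (defaults 80, 0.1).
#' @return data.frame `query_id`, `status` (`found`/`not_found`),
#'   `best_identity`, `best_evalue`, `reciprocal`.
#' @export
reciprocal_best_hit <- function(forward, reverse, queries = NULL,
                                id_min = 80, e_max = 0.1) {
  fwd <- top_hits(forward)
  rev_ <- top_hits(reverse)
  if (is.null(queries)) queries <- unique(forward$query_id)
  out <- data.frame(query_id = queries, status = "not_found",
                    best_identity = NA_real_, best_evalue = NA_real_,
                    reciprocal = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(queries)) {
    f <- fwd[fwd$query_id == queries[i], ]
    if (nrow(f) == 0) next
    out$best_identity[i] <- f$pct_identity
    out$best_evalue[i] <- f$evalue
    if (f$pct_identity < id_min || f$evalue > e_max) next
    r <- rev_[rev_$query_id == f$subject_id, ]
    if (nrow(r) == 0) next
    recip <- r$subject_id == queries[i] &&
      r$pct_identity >= id_min && r$evalue <= e_max
    out$reciprocal[i] <- recip
    if (recip) out$status[i] <- "found"
  }
  out
}

#' Presence/absence conservation matrix over genomes
#'
#' @param calls named list (by target genome) of [reciprocal_best_hit()]
#'   results covering the same queries.
#' @param queries optional row universe; pairs absent from a genome's call
#'   table are reported as `"untested"`, never silently dropped.
#' @return character matrix (queries x genomes) of `"x"` / `"-"` /
#'   `"untested"`; attribute `genome_counts` gives per-query found counts.
#' @export
conservation_matrix <- function(calls, queries = NULL) {
  if (is.null(queries)) {
    queries <- unique(unlist(lapply(calls, `[[`, "query_id")))
  }
  m <- matrix("untested", length(queries), length(calls),
              dimnames = list(queries, names(calls)))
  for (g in names(calls)) {
    cl <- calls[[g]]
    i <- match(cl$query_id, queries)
    ok <- !is.na(i)
    m[i[ok], g] <- ifelse(cl$status[ok] == "found", "x", "-")
  }
  attr(m, "genome_counts") <- apply(m, 1, function(r) sum(r == "x"))
  m
}
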