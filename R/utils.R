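#' @keywords internal
"_PACKAGE"

RNA_BASES <- c("A", "C", "G", "U")

#' Normalize a nucleotide string to uppercase RNA
#'
#' DNA input is accepted and transcribed in place (T -> U). The pipeline works
#' in RNA space throughout, matching how mature miRNA sequences are reported.
#'
#' @param x character vector of sequences.
#' @return character vector over `{A,C,G,U,N}`.
#' @export
norm_rna <- function(x) {
  nm <- names(x)
  x <- toupper(as.character(x))
  x <- gsub("T", "U", x, fixed = TRUE)
  names(x) <- nm
  bad <- grepl("[^ACGUN]", x)
  if (any(bad)) {
    stop("sequence contains characters outside {A,C,G,U,N,T}: ",
         x[which(bad)[1L]])
  }
  x
}

rna_complement <- function(base) {
  c(A = "U", C = "G", G = "C", U = "A", N = "N")[base]
}

#' Reverse-complement an RNA sequence
#' @param x character vector of RNA sequences.
#' @return character vector.
#' @export
rna_revcomp <- function(x) {
  vapply(strsplit(norm_rna(x), ""), function(ch) {
    paste(rev(unname(rna_complement(ch))), collapse = "")
  }, character(1))
}

# Stable derivation of per-stage child seeds from one user-facing seed.
# Keeps every derived value a valid 32-bit R integer.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  as.integer((abs(seed) * 7919 + stage * 104729) %% 2147483647L)
}

# Run `expr` under a local RNG state seeded with `seed`; the caller's RNG
# stream is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
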