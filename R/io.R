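#' Read a collapsed small-RNA FASTA file
#'
#' Small-RNA pipelines commonly collapse identical reads into one FASTA record
#' whose header carries the read count as an `_x<count>` suffix (e.g.
#' `>seq1_x57`). This reader accepts that dialect, and plain FASTA where every
#' record counts once. Identical sequences are merged (counts summed), so the
#' result is an order-independent multiset. Sequences are normalized to
#' uppercase RNA (T -> U).
#'
#' @param path path to a FASTA (or FASTQ; qualities are ignored) file.
#' @return a `data.frame` with columns `seq` (character) and `count` (numeric),
#'   one row per distinct sequence.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">r1_x3", "TGAGGTAG", ">r2", "UGAGGUAG"), tf)
#' read_collapsed_fasta(tf)  # single row, count 4
#' @export
read_collapsed_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  fastq <- grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)
  set <- tryCatch(
    if (fastq) Biostrings::readBStringSet(path, format = "fastq")
    else Biostrings::readBStringSet(path),
    error = function(e) {
      if (file.size(path) == 0 ||
          !any(grepl("^[>@]", readLines(path, warn = FALSE)))) {
        return(Biostrings::BStringSet())
      }
      stop("cannot parse ", path, ": ", conditionMessage(e))
    })
  if (length(set) == 0) {
    warning("empty read file: ", path)
    return(data.frame(seq = character(0), count = numeric(0)))
  }
  ids <- sub("\\s.*$", "", names(set))
  counts <- rep(1, length(set))
  has_x <- grepl("_x[^_]*$", ids)
  if (any(has_x)) {
    tok <- sub("^.*_x", "", ids[has_x])
    val <- suppressWarnings(as.numeric(tok))
    bad <- is.na(val) | val < 1 | val != floor(val)
    if (any(bad)) {
      stop("malformed collapsed-read count in record '",
           ids[has_x][which(bad)[1L]], "'")
    }
    counts[has_x] <- val
  }
  seqs <- norm_rna(as.character(set))
  agg <- rowsum(counts, seqs)
  data.frame(seq = rownames(agg), count = as.numeric(agg[, 1]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write reads as a collapsed FASTA file
#'
#' Inverse of [read_collapsed_fasta()]: one record per distinct sequence with
#' the count in an `_x<count>` header suffix.
#'
#' @param reads data.frame with columns `seq`, `count`.
#' @param path output path.
#' @param prefix record id prefix.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(reads, path, prefix = "r") {
  stopifnot(all(c("seq", "count") %in% names(reads)))
  lines <- character(0)
  if (nrow(reads) > 0) {
    hdr <- sprintf(">%s%d_x%d", prefix, seq_len(nrow(reads)),
                   as.integer(round(reads$count)))
    lines <- as.vector(rbind(hdr, reads$seq))
  }
  writeLines(lines, path)
  invisible(path)
}

parse_dotbracket <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  if (!all(ch %in% c("(", ")", "."))) {
    stop("dot-bracket string contains characters other than '(', ')', '.'")
  }
  partner <- rep(NA_integer_, length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (length(stack) == 0) stop("unbalanced dot-bracket: unmatched ')'")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  if (length(stack) > 0) stop("unbalanced dot-bracket: unmatched '('")
  partner
}

#' Read a Vienna dot-bracket structure file
#'
#' Records are `>id` headers followed by either a single dot-bracket line, or a
#' sequence line and then the dot-bracket line, optionally suffixed with a
#' free energy in parentheses (RNAfold style, e.g. `((..)) (-12.30)`).
#'
#' @param path Vienna file path.
#' @return named list with elements `structure` (character) and `energy`
#'   (numeric, `NA` when absent), both named by record id.
#' @export
read_vienna <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) stop("no '>' records in Vienna file: ", path)
  structure <- character(0); energy <- numeric(0)
  ends <- c(hdr[-1] - 1L, length(lines))
  for (k in seq_along(hdr)) {
    id <- sub("\\s.*$", "", sub("^>", "", lines[hdr[k]]))
    body <- lines[seq(hdr[k] + 1L, ends[k])]
    # sequence line, if present, comes first; the structure line is the last
    # line made of dot-bracket characters (plus an optional energy suffix)
    db <- body[grepl("^[().]+( ?\\(-?[0-9.]+\\))?$", trimws(body))]
    if (length(db) == 0) stop("record '", id, "' has no dot-bracket line")
    db <- trimws(db[length(db)])
    en <- NA_real_
    m <- regmatches(db, regexec("^([().]+)\\s*\\((-?[0-9.]+)\\)$", db))[[1]]
    if (length(m) == 3) {
      en <- as.numeric(m[3]); db <- m[2]
    }
    parse_dotbracket(db)  # validates balance
    structure[id] <- db; energy[id] <- en
  }
  list(structure = structure, energy = energy)
}

#' Write Vienna dot-bracket structures
#' @param structures named character vector of dot-bracket strings.
#' @param path output path.
#' @param sequences optional named character vector written between header and
#'   structure lines.
#' @param energy optional named numeric appended as ` (-xx.x)`.
#' @return `path`, invisibly.
#' @export
write_vienna <- function(structures, path, sequences = NULL, energy = NULL) {
  out <- character(0)
  for (id in names(structures)) {
    out <- c(out, paste0(">", id))
    if (!is.null(sequences)) out <- c(out, unname(sequences[id]))
    line <- structures[[id]]
    if (!is.null(energy) && !is.na(energy[id])) {
      line <- sprintf("%s (%.2f)", line, energy[id])
    }
    out <- c(out, line)
  }
  writeLines(out, path)
  invisible(path)
}

#' Construct a miRNA precursor locus
#'
#' A `mirna_locus` bundles a hairpin precursor with its (optional) dot-bracket
#' secondary structure and the hairpin-local coordinates of the 5p/3p mature
#' arms. Arm intervals are 0-based half-open on the hairpin.
#'
#' @param locus_id,chrom,start,end,strand genomic identity of the hairpin
#'   (1-based inclusive genomic coordinates; strand `"+"` or `"-"`).
#' @param hairpin_seq RNA sequence of the precursor (5' to 3').
#' @param structure dot-bracket string of the same length, or `NA`.
#' @param arm5p,arm3p integer length-2 vectors `c(start0, end0)` (half-open)
#'   or `NULL` when the arm is not annotated. At least one arm is required.
#' @param energy_kcal_mol hairpin folding free energy (<= 0) or `NA`.
#' @return an object of class `mirna_locus`.
#' @export
mirna_locus <- function(locus_id, hairpin_seq, structure = NA_character_,
                        arm5p = NULL, arm3p = NULL,
                        chrom = "synthetic", start = 1L,
                        end = NULL, strand = "+",
                        energy_kcal_mol = NA_real_) {
  hairpin_seq <- norm_rna(hairpin_seq)
  L <- nchar(hairpin_seq)
  if (is.null(end)) end <- start + L - 1L
  if (!is.na(structure)) {
    if (nchar(structure) != L) {
      stop("locus ", locus_id, ": structure length ", nchar(structure),
           " != hairpin length ", L)
    }
    parse_dotbracket(structure)
  }
  for (arm in list(arm5p, arm3p)) {
    if (!is.null(arm)) {
      if (length(arm) != 2 || arm[1] < 0 || arm[2] > L || arm[1] >= arm[2]) {
        stop("locus ", locus_id, ": arm interval outside hairpin [0,", L, ")")
      }
    }
  }
  if (is.null(arm5p) && is.null(arm3p)) {
    stop("locus ", locus_id, ": at least one mature arm is required")
  }
  if (!is.null(arm5p) && !is.null(arm3p) &&
      max(arm5p[1], arm3p[1]) < min(arm5p[2], arm3p[2])) {
    stop("locus ", locus_id, ": 5p and 3p arms overlap")
  }
  if (!is.na(energy_kcal_mol) && energy_kcal_mol > 0) {
    stop("locus ", locus_id, ": hairpin free energy must be <= 0")
  }
  structure(
    list(locus_id = locus_id, chrom = chrom, start = as.integer(start),
         end = as.integer(end), strand = strand, hairpin_seq = hairpin_seq,
         structure = structure, arm5p = arm5p, arm3p = arm3p,
         energy_kcal_mol = energy_kcal_mol),
    class = "mirna_locus")
}

#' @export
print.mirna_locus <- function(x, ...) {
  cat("<mirna_locus>", x$locus_id, " ", nchar(x$hairpin_seq), "nt ",
      x$chrom, ":", x$start, "-", x$end, "(", x$strand, ")\n", sep = "")
  arms <- c(if (!is.null(x$arm5p)) sprintf("5p[%d,%d)", x$arm5p[1], x$arm5p[2]),
            if (!is.null(x$arm3p)) sprintf("3p[%d,%d)", x$arm3p[1], x$arm3p[2]))
  cat("  arms:", paste(arms, collapse = " "), "\n")
  invisible(x)
}

#' Extract mature strand records from loci
#'
#' @param loci list of [mirna_locus()] objects.
#' @return data.frame with one row per annotated arm: `strand_id`, `locus_id`,
#'   `arm` (`"5p"`/`"3p"`), `sequence`, `star` (initialized `"unassigned"`).
#' @export
mature_strands <- function(loci) {
  rows <- lapply(loci, function(lc) {
    out <- list()
    for (arm in c("5p", "3p")) {
      iv <- lc[[paste0("arm", arm)]]
      if (is.null(iv)) next
      sq <- substr(lc$hairpin_seq, iv[1] + 1L, iv[2])
      if (nchar(sq) < 15 || nchar(sq) > 30) {
        stop("locus ", lc$locus_id, ": mature ", arm, " arm length ",
             nchar(sq), " outside [15,30]")
      }
      out[[arm]] <- data.frame(
        strand_id = paste0(lc$locus_id, "-", arm), locus_id = lc$locus_id,
        arm = arm, sequence = sq, star = "unassigned",
        stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# genomic (1-based inclusive) -> hairpin-local 0-based half-open
genomic_to_local <- function(gstart, gend, hp_start, hp_end, strand) {
  if (strand == "-") {
    c(hp_end - gend, hp_end - gstart + 1L)
  } else {
    c(gstart - hp_start, gend - hp_start + 1L)
  }
}

# hairpin-local half-open -> genomic 1-based inclusive
local_to_genomic <- function(l0, l1, hp_start, hp_end, strand) {
  if (strand == "-") {
    c(hp_end - l1 + 1L, hp_end - l0)
  } else {
    c(hp_start + l0, hp_start + l1 - 1L)
  }
}

#' Read hairpin precursors with mature-arm annotations
#'
#' Loads precursor sequences from FASTA, mature-arm coordinates from a GFF3
#' file (miRBase layout: `miRNA_primary_transcript` features for hairpins and
#' `miRNA` features whose `Parent`/`Derives_from` attribute names the
#' hairpin), and optionally dot-bracket structures from a Vienna file.
#' Genomic GFF3 coordinates (1-based inclusive) are mapped into hairpin-local
#' 0-based half-open intervals; minus-strand annotations are reverse-mapped.
#'
#' @param fasta hairpin FASTA path (ids must match GFF3 hairpin ids).
#' @param gff3 GFF3 annotation path.
#' @param vienna optional Vienna structure path; hairpins without an entry get
#'   `NA` structure (a fold fallback is available downstream).
#' @return list of [mirna_locus()] objects.
#' @export
read_hairpin_annotations <- function(fasta, gff3, vienna = NULL) {
  set <- Biostrings::readBStringSet(fasta)
  names(set) <- sub("\\s.*$", "", names(set))
  seqs <- norm_rna(as.character(set))
  gr <- rtracklayer::import(gff3)
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  get_id <- function(i) {
    id <- meta$ID[i] %||% NA_character_
    if (is.na(id)) id <- meta$Name[i]
    as.character(id)
  }
  hp_idx <- which(type == "miRNA_primary_transcript")
  hp <- list()
  for (i in hp_idx) {
    id <- get_id(i)
    hp[[id]] <- list(start = GenomicRanges::start(gr)[i],
                     end = GenomicRanges::end(gr)[i],
                     strand = as.character(GenomicRanges::strand(gr)[i]))
  }
  struct <- list(structure = character(0), energy = numeric(0))
  if (!is.null(vienna)) struct <- read_vienna(vienna)

  arms <- list()
  mi_idx <- which(type == "miRNA")
  for (i in mi_idx) {
    parent <- meta$Parent[i] %||% meta$Derives_from[i]
    parent <- as.character(unlist(parent))[1]
    if (is.na(parent) || !parent %in% names(hp)) {
      stop("miRNA feature '", get_id(i), "' has no hairpin parent in GFF3")
    }
    h <- hp[[parent]]
    iv <- genomic_to_local(GenomicRanges::start(gr)[i],
                           GenomicRanges::end(gr)[i],
                           h$start, h$end, h$strand)
    L <- nchar(seqs[parent])
    if (is.na(L)) stop("hairpin '", parent, "' missing from FASTA")
    if (iv[1] < 0 || iv[2] > L) {
      stop("mature arm '", get_id(i), "' falls outside hairpin '", parent, "'")
    }
    nm <- as.character(meta$Name[i] %||% get_id(i))
    arm <- if (grepl("-5p$", nm)) "5p" else if (grepl("-3p$", nm)) "3p"
    else if (mean(iv) <= L / 2) "5p" else "3p"
    arms[[parent]][[arm]] <- iv
  }

  loci <- list()
  for (id in names(set)) {
    h <- hp[[id]]
    if (is.null(h)) h <- list(start = 1L, end = nchar(seqs[id]), strand = "+")
    st <- if (id %in% names(struct$structure)) struct$structure[[id]] else NA_character_
    en <- if (id %in% names(struct$energy)) struct$energy[[id]] else NA_real_
    loci[[id]] <- mirna_locus(
      locus_id = id, hairpin_seq = seqs[id], structure = st,
      arm5p = arms[[id]][["5p"]], arm3p = arms[[id]][["3p"]],
      chrom = "unknown", start = h$start, end = h$end, strand = h$strand,
      energy_kcal_mol = en)
  }
  loci
}

#' Write hairpin loci as FASTA + GFF3 (+ Vienna)
#'
#' Inverse of [read_hairpin_annotations()]; used by the simulator so its
#' output round-trips through the standard readers.
#'
#' @param loci list of [mirna_locus()] objects.
#' @param fasta,gff3 output paths.
#' @param vienna optional output path for structures.
#' @return invisibly, `NULL`.
#' @export
write_hairpin_annotations <- function(loci, fasta, gff3, vienna = NULL) {
  fa <- character(0); gff <- c("##gff-version 3")
  st <- character(0); sq <- character(0); en <- numeric(0)
  for (lc in loci) {
    fa <- c(fa, paste0(">", lc$locus_id), lc$hairpin_seq)
    gff <- c(gff, paste(lc$chrom, "agosort", "miRNA_primary_transcript",
                        lc$start, lc$end, ".", lc$strand, ".",
                        paste0("ID=", lc$locus_id, ";Name=", lc$locus_id),
                        sep = "\t"))
    for (arm in c("5p", "3p")) {
      iv <- lc[[paste0("arm", arm)]]
      if (is.null(iv)) next
      g <- local_to_genomic(iv[1], iv[2], lc$start, lc$end, lc$strand)
      gff <- c(gff, paste(lc$chrom, "agosort", "miRNA", g[1], g[2], ".",
                          lc$strand, ".",
                          paste0("ID=", lc$locus_id, "-", arm,
                                 ";Name=", lc$locus_id, "-", arm,
                                 ";Parent=", lc$locus_id),
                          sep = "\t"))
    }
    if (!is.na(lc$structure)) {
      st[lc$locus_id] <- lc$structure
      sq[lc$locus_id] <- lc$hairpin_seq
      en[lc$locus_id] <- lc$energy_kcal_mol
    }
  }
  writeLines(fa, fasta)
  writeLines(gff, gff3)
  if (!is.null(vienna) && length(st) > 0) {
    write_vienna(st, vienna, sequences = sq, energy = en)
  }
  invisible(NULL)
}

BLAST6_COLS <- c("query_id", "subject_id", "pct_identity", "length",
                 "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Read BLAST tabular output (outfmt 6)
#'
#' Standard 12-column tab-separated BLAST output. No filtering is applied.
#'
#' @param path file path.
#' @return data.frame with the 12 standard columns (`query_id`, `subject_id`,
#'   `pct_identity`, ..., `evalue`, `bitscore`); zero rows for an empty file.
#' @export
read_blast_tab6 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  empty <- data.frame(matrix(nrow = 0, ncol = 12))
  names(empty) <- BLAST6_COLS
  if (length(lines) == 0) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12)) {
    stop("line ", which(nf != 12)[1L], ": expected 12 tab-separated columns, got ",
         nf[nf != 12][1L])
  }
  m <- do.call(rbind, fields)
  out <- data.frame(m, stringsAsFactors = FALSE)
  names(out) <- BLAST6_COLS
  num <- c("pct_identity", "length", "mismatch", "gapopen", "qstart", "qend",
           "sstart", "send", "evalue", "bitscore")
  out[num] <- lapply(out[num], as.numeric)
  if (any(!is.finite(out$evalue)) || any(out$evalue < 0)) {
    stop("non-finite or negative e-value in ", path)
  }
  if (any(out$pct_identity < 0 | out$pct_identity > 100)) {
    stop("percent identity outside [0,100] in ", path)
  }
  out
}

#' Write / read a strand-by-library count matrix as TSV
#'
#' First column `strand_id`, remaining columns one per library. Round-trips
#' exactly for integer counts and to full double precision for TPM values.
#'
#' @param m numeric matrix with row and column names.
#' @param path file path.
#' @return `write_count_matrix()` returns `path` invisibly;
#'   `read_count_matrix()` returns the matrix.
#' @export
write_count_matrix <- function(m, path) {
  if (is.null(rownames(m)) && nrow(m) > 0) stop("matrix must have row ids")
  if (anyDuplicated(rownames(m))) stop("duplicate row ids in count matrix")
  df <- data.frame(strand_id = rownames(m) %||% character(0), m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(df$strand_id)) stop("duplicate row ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df$strand_id
  m
}
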