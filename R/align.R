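#' Alignment scoring scheme
#'
#' Scoring for global clone-to-reference alignment. A gap run of length `g`
#' scores `gap_open + g * gap_extend`, so a single-base gap costs
#' `gap_open + gap_extend` (-5 under the defaults). Setting `gap_open = 0`
#' gives linear gap costs. `N` is scored 0 against every base (neither match
#' nor mismatch); it never supports an allele downstream.
#'
#' @param match match score (default +1).
#' @param mismatch mismatch score (default -1).
#' @param gap_open gap opening score (default -4).
#' @param gap_extend per-base gap extension score (default -1).
#' @return an `alignment_scoring` list.
#' @export
alignment_scoring <- function(match = 1, mismatch = -1,
                              gap_open = -4, gap_extend = -1) {
  if (gap_extend > 0 || gap_open > 0) {
    stop("gap penalties must be <= 0", call. = FALSE)
  }
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment_scoring")
}

dna_submat <- function(scoring) {
  alpha <- c("A", "C", "G", "T", "N")
  m <- matrix(scoring$mismatch, 5, 5, dimnames = list(alpha, alpha))
  diag(m) <- scoring$match
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

check_dna_input <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || nchar(x) == 0L) {
    stop(what, " must be a non-empty sequence", call. = FALSE)
  }
  if (grepl("[^ACGTN]", x)) {
    stop(what, " contains characters outside {A,C,G,T,N} ",
         "(IUPAC ambiguity codes other than N are rejected)", call. = FALSE)
  }
  invisible(x)
}

#' Globally align one clone to a reference fragment
#'
#' Optimal global (Needleman-Wunsch, affine-gap) alignment of a clone to the
#' reference, projected onto reference coordinates: clone bases aligned to
#' reference gaps (insertions) are dropped with a warning, clone gaps become
#' `-`. Identity is the fraction of reference positions carrying the
#' identical clone base.
#'
#' @param clone_sequence clone nucleotide sequence (A/C/G/T/N).
#' @param reference reference nucleotide sequence.
#' @param scoring an [alignment_scoring()].
#' @return list with `row` (character vector, one entry per reference
#'   position), `score`, `identity`, and `n_insertions_dropped`.
#' @export
align_clone <- function(clone_sequence, reference,
                        scoring = alignment_scoring()) {
  check_dna_input(clone_sequence, "clone sequence")
  check_dna_input(reference, "reference")
  aln <- nw_align_cpp(reference, clone_sequence, dna_submat(scoring),
                      scoring$gap_open, scoring$gap_extend)
  ra <- s2c(aln$a)
  rc <- s2c(aln$b)
  keep <- ra != "-"
  n_ins <- sum(!keep)
  if (n_ins > 0L) {
    warning(sprintf("dropped %d clone base(s) inserted relative to the reference",
                    n_ins), call. = FALSE)
  }
  row <- rc[keep]
  matches <- sum(row == ra[keep] & row != "N")
  list(row = row, score = aln$score,
       identity = matches / nchar(reference),
       n_insertions_dropped = n_ins)
}

#' Build an aligned clone library against a locus reference
#'
#' Aligns every clone to the reference and assembles the retained rows into
#' a clones x positions matrix. Clones whose identity falls below
#' `min_identity` are excluded and reported; excluding every clone is an
#' error.
#'
#' @param clones named character vector of clone sequences.
#' @param locus a [locus_model()] (or a plain reference string).
#' @param min_identity minimum identity fraction to retain a clone
#'   (default 0.90, an automated stand-in for manual quality trimming).
#' @param scoring an [alignment_scoring()].
#' @param gene_id,species_id identifiers recorded on the result (defaulted
#'   from `locus` where possible).
#' @return an `aligned_library`: `matrix` (character, rows = clones),
#'   `excluded` data.frame (`clone_id`, `identity`, `reason`), `identity`
#'   per retained clone, plus identifiers.
#' @export
build_aligned_library <- function(clones, locus, min_identity = 0.9,
                                  scoring = alignment_scoring(),
                                  gene_id = NULL, species_id = NA_character_) {
  if (length(clones) < 1L) stop("need at least one clone", call. = FALSE)
  reference <- if (inherits(locus, "locus_model")) locus$sequence else locus
  if (is.null(gene_id)) {
    gene_id <- if (inherits(locus, "locus_model")) locus$gene_id else NA_character_
  }
  if (is.null(names(clones))) {
    names(clones) <- sprintf("clone%03d", seq_along(clones))
  }
  L <- nchar(reference)
  rows <- matrix(NA_character_, length(clones), L,
                 dimnames = list(names(clones), NULL))
  ident <- numeric(length(clones))
  n_ins <- 0L
  for (i in seq_along(clones)) {
    a <- withCallingHandlers(
      align_clone(clones[[i]], reference, scoring),
      warning = function(w) invokeRestart("muffleWarning"))
    rows[i, ] <- a$row
    ident[i] <- a$identity
    n_ins <- n_ins + a$n_insertions_dropped
  }
  if (n_ins > 0L) {
    warning(sprintf("dropped %d inserted base(s) across the library", n_ins),
            call. = FALSE)
  }
  keep <- ident >= min_identity
  excluded <- data.frame(clone_id = names(clones)[!keep],
                         identity = ident[!keep],
                         reason = sprintf("identity %.3f < %.3f",
                                          ident[!keep], min_identity),
                         stringsAsFactors = FALSE)
  if (!any(keep)) {
    stop("all clones excluded at min_identity = ", min_identity, call. = FALSE)
  }
  structure(list(gene_id = gene_id, species_id = species_id,
                 matrix = rows[keep, , drop = FALSE],
                 identity = ident[keep],
                 excluded = excluded,
                 min_identity = min_identity),
            class = "aligned_library")
}

#' @export
print.aligned_library <- function(x, ...) {
  cat("Aligned library", x$gene_id, "/", x$species_id, "-",
      nrow(x$matrix), "clones retained,", nrow(x$excluded), "excluded,",
      ncol(x$matrix), "bp\n")
  invisible(x)
}

#' Write an aligned library as gapped FASTA plus an exclusion report
#'
#' @param alib an `aligned_library`.
#' @param fasta_path output FASTA path (rows written with `-` gaps).
#' @param exclusions_path optional TSV path for the exclusion report.
#' @return `fasta_path`, invisibly.
#' @export
write_aligned_library <- function(alib, fasta_path, exclusions_path = NULL) {
  seqs <- Biostrings::BStringSet(apply(alib$matrix, 1L, c2s))
  Biostrings::writeXStringSet(seqs, fasta_path)
  if (!is.null(exclusions_path)) {
    utils::write.table(alib$excluded, exclusions_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(fasta_path)
}

#' Global protein alignment under BLOSUM62
#'
#' Affine-gap global alignment of two amino-acid sequences with BLOSUM62
#' scores and gap penalties -11 (open) / -1 (per base).
#'
#' @param a,b amino-acid sequences.
#' @return list with gapped `a`, `b`, and `score`.
#' @export
align_proteins <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty", call. = FALSE)
  nw_align_cpp(a, b, blosum62(), -11, -1)
}

blosum62_cache <- new.env(parent = emptyenv())
blosum62 <- function() {
  if (is.null(blosum62_cache$m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    blosum62_cache$m <- e$BLOSUM62
  }
  blosum62_cache$m
}
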