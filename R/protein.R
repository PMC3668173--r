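#' Extract the coding subsequence of a fragment
#'
#' Concatenates the locus' exon intervals in order, trims the leading
#' `frame_offset` bases (which complete a codon started upstream of the
#' fragment) and any trailing partial codon, yielding an in-frame CDS.
#'
#' @param fragment_sequence full fragment sequence (reference-length).
#' @param locus the [locus_model()] carrying exon intervals and frame.
#' @return in-frame coding sequence (length a multiple of 3).
#' @export
extract_cds <- function(fragment_sequence, locus) {
  stopifnot(inherits(locus, "locus_model"))
  if (nchar(fragment_sequence) != nchar(locus$sequence)) {
    stop("fragment length does not match the locus", call. = FALSE)
  }
  ex <- locus$regions[locus$regions$label == "exon", , drop = FALSE]
  bases <- s2c(fragment_sequence)
  cds <- unlist(lapply(seq_len(nrow(ex)), function(i)
    bases[ex$start[i]:ex$end[i]]))
  if (locus$frame_offset > 0L) cds <- cds[-seq_len(locus$frame_offset)]
  n <- 3L * (length(cds) %/% 3L)
  if (n < 3L) stop("no complete codon in the exonic sequence", call. = FALSE)
  c2s(cds[seq_len(n)])
}

#' Translate an in-frame coding sequence
#'
#' Standard genetic code. A stop codon is rendered as `*` and translation
#' ends there. Codons containing characters outside A/C/G/T raise a warning
#' naming the codon index and are rendered as `X`.
#'
#' @param cds coding sequence; length must be divisible by 3.
#' @return amino-acid sequence (possibly `*`-terminated).
#' @export
translate_cds <- function(cds) {
  if (nchar(cds) %% 3L != 0L) {
    stop("CDS length must be divisible by 3", call. = FALSE)
  }
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  out <- character(0)
  for (i in seq_along(codons)) {
    aa <- Biostrings::GENETIC_CODE[codons[i]]
    if (is.na(aa)) {
      warning(sprintf("codon %d (%s) is untranslatable", i, codons[i]),
              call. = FALSE)
      aa <- "X"
    }
    out <- c(out, aa)
    if (aa == "*") break
  }
  c2s(out)
}

#' Deduce protein variants from a haplotype table
#'
#' Translates the exonic portion of every haplotype's representative
#' sequence and deduplicates identical amino-acid sequences within the
#' gene x species context. Haplotypes differing only at intronic positions
#' or by synonymous codon changes collapse into one protein variant.
#'
#' @param hap_table an [infer_haplotypes()] result.
#' @param locus the gene's [locus_model()].
#' @return a `protein_variants` data.frame: `gene_id`, `species_id`,
#'   `protein_id`, `sequence`, `haplotype_ids`, `n_haplotypes`,
#'   `synonymous_class` (TRUE when >1 haplotype maps to the variant).
#' @export
deduce_proteins <- function(hap_table, locus) {
  if (nrow(hap_table) == 0L) {
    return(data.frame(gene_id = character(0), species_id = character(0),
                      protein_id = character(0), sequence = character(0),
                      haplotype_ids = character(0), n_haplotypes = integer(0),
                      synonymous_class = logical(0), stringsAsFactors = FALSE))
  }
  aa <- vapply(hap_table$rep_sequence, function(s)
    translate_cds(extract_cds(s, locus)), character(1), USE.NAMES = FALSE)
  aa_clean <- sub("\\*$", "", aa)
  groups <- split(seq_len(nrow(hap_table)), aa_clean)
  out <- do.call(rbind, lapply(seq_along(groups), function(i) {
    idx <- groups[[i]]
    data.frame(
      gene_id = hap_table$gene_id[idx[1]],
      species_id = hap_table$species_id[idx[1]],
      sequence = names(groups)[i],
      haplotype_ids = paste(hap_table$haplotype_id[idx], collapse = ","),
      n_haplotypes = length(idx),
      synonymous_class = length(idx) > 1L,
      stringsAsFactors = FALSE
    )
  }))
  out <- out[order(-out$n_haplotypes, out$sequence), ]
  out$protein_id <- sprintf("%s_%s_p%02d", out$gene_id, out$species_id,
                            seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("gene_id", "species_id", "protein_id", "sequence",
          "haplotype_ids", "n_haplotypes", "synonymous_class")]
}

#' Count unique deduced proteins per gene and species
#'
#' @param variants a combined `protein_variants` data.frame (or list of
#'   them).
#' @return list with `counts` (species x gene matrix of unique protein
#'   counts) and `totals` (per-species row sums).
#' @export
count_unique_proteins <- function(variants) {
  df <- if (is.data.frame(variants)) variants else do.call(rbind, variants)
  if (is.null(df) || nrow(df) == 0L) {
    return(list(counts = matrix(0L, 0, 0), totals = integer(0)))
  }
  tab <- table(df$species_id, df$gene_id)
  counts <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                   dimnames = dimnames(tab))
  list(counts = counts,
       totals = stats::setNames(as.integer(rowSums(counts)), rownames(counts)))
}

# Expasy average residue masses (Da) and the mass of water.
AA_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.0153

# EMBOSS pKa set used for the isoelectric point (declared, bit-exact).
PKA_POSITIVE <- c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5)
PKA_NEGATIVE <- c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1)

#' Net charge of a peptide at a given pH
#'
#' Henderson-Hasselbalch per ionizable group, EMBOSS pKa set (N-terminus
#' 8.6, C-terminus 3.6, C 8.5, D 3.9, E 4.1, H 6.5, K 10.8, R 12.5, Y 10.1).
#'
#' @param sequence amino-acid sequence (20-letter alphabet).
#' @param pH pH value.
#' @return net charge (can be any real number).
#' @export
peptide_net_charge <- function(sequence, pH) {
  aa <- s2c(sequence)
  pos_groups <- c(PKA_POSITIVE["Nterm"],
                  PKA_POSITIVE[aa[aa %in% names(PKA_POSITIVE)]])
  neg_groups <- c(PKA_NEGATIVE["Cterm"],
                  PKA_NEGATIVE[aa[aa %in% names(PKA_NEGATIVE)]])
  sum(1 / (1 + 10^(pH - pos_groups))) - sum(1 / (1 + 10^(neg_groups - pH)))
}

#' Protein descriptors: length, molecular mass, isoelectric point
#'
#' Mass is the sum of Expasy average residue masses plus one water;
#' the isoelectric point is found by bisection on [peptide_net_charge()]
#' over pH 0--14 to within 1e-4.
#'
#' @param sequence amino-acid sequence; a trailing `*` is ignored.
#' @return list with `length`, `mass_da`, `mass_kda`, `pi`.
#' @export
protein_descriptors <- function(sequence) {
  sequence <- sub("\\*$", "", sequence)
  if (!nzchar(sequence)) stop("empty protein sequence", call. = FALSE)
  aa <- s2c(sequence)
  unknown <- setdiff(aa, names(AA_RESIDUE_MASS))
  if (length(unknown)) {
    stop("unknown residue(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  mass <- sum(AA_RESIDUE_MASS[aa]) + WATER_MASS
  lo <- 0
  hi <- 14
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (peptide_net_charge(sequence, mid) > 0) lo <- mid else hi <- mid
  }
  list(length = length(aa), mass_da = mass, mass_kda = mass / 1000,
       pi = (lo + hi) / 2)
}

#' Pairwise protein similarity
#'
#' Global alignment under BLOSUM62 with affine gap penalties -11/-1;
#' similarity is the fraction of alignment columns with identical residues.
#'
#' @param seq_a,seq_b amino-acid sequences.
#' @return similarity fraction in `[0, 1]`.
#' @export
pairwise_protein_similarity <- function(seq_a, seq_b) {
  aln <- align_proteins(sub("\\*$", "", seq_a), sub("\\*$", "", seq_b))
  a <- s2c(aln$a)
  b <- s2c(aln$b)
  sum(a == b & a != "-") / length(a)
}

#' Pairwise similarity matrix for a set of proteins
#'
#' @param sequences named character vector of amino-acid sequences.
#' @return symmetric matrix of [pairwise_protein_similarity()] values with
#'   unit diagonal.
#' @export
protein_similarity_matrix <- function(sequences) {
  n <- length(sequences)
  m <- diag(1, n)
  dimnames(m) <- list(names(sequences), names(sequences))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        m[i, j] <- m[j, i] <- pairwise_protein_similarity(sequences[[i]],
                                                          sequences[[j]])
      }
    }
  }
  m
}
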