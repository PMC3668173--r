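#' Call SNPs from an aligned clone library
#'
#' A reference column is called a SNP when at least two alleles each reach
#' `min_support` clones (the reference allele counts toward its own
#' threshold). `N` and gap characters never support an allele. Columns with
#' more than two qualifying alleles are reported as multi-allelic sites (one
#' site, several alternates). Each call carries its exon/intron label from
#' the locus annotation.
#'
#' The clone-support filter is the study design's guard against PCR
#' recombination and sequencing error: the default of 3 follows the
#' reporting rule "found in at least three sequences"; the protocol-level
#' rule "observed in at least two colonies" is available via
#' `min_support = 2`.
#'
#' @param aligned_library an [build_aligned_library()] result.
#' @param locus the [locus_model()] the library was aligned to.
#' @param min_support minimum clone support per allele (>= 2).
#' @return a `snp_calls` data.frame: `gene_id`, `species_id`, `pos`,
#'   `region`, `ref_allele`, `alleles` (qualifying alleles, `/`-separated,
#'   alphabetical), `supports` (matching counts), `alt_alleles`,
#'   `n_ignored` (N/gap clones at the column).
#' @export
call_snps <- function(aligned_library, locus, min_support = 3L) {
  stopifnot(inherits(aligned_library, "aligned_library"))
  if (min_support < 2L) stop("`min_support` must be >= 2", call. = FALSE)
  mat <- aligned_library$matrix
  if (nrow(mat) < 1L) stop("aligned library is empty", call. = FALSE)
  ref <- s2c(if (inherits(locus, "locus_model")) locus$sequence else locus)
  if (length(ref) != ncol(mat)) {
    stop("locus length does not match the aligned matrix", call. = FALSE)
  }
  out <- list()
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    counts <- table(factor(col[col %in% DNA_BASES], levels = DNA_BASES))
    qual <- counts[counts >= min_support]
    if (length(qual) >= 2L) {
      alleles <- sort(names(qual))
      supports <- as.integer(qual[alleles])
      out[[length(out) + 1L]] <- data.frame(
        gene_id = aligned_library$gene_id,
        species_id = aligned_library$species_id,
        pos = j,
        ref_allele = ref[j],
        alleles = paste(alleles, collapse = "/"),
        supports = paste(supports, collapse = "/"),
        alt_alleles = paste(setdiff(alleles, ref[j]), collapse = "/"),
        n_ignored = sum(!col %in% DNA_BASES),
        stringsAsFactors = FALSE
      )
    }
  }
  calls <- if (length(out)) do.call(rbind, out) else data.frame(
    gene_id = character(0), species_id = character(0), pos = integer(0),
    ref_allele = character(0), alleles = character(0),
    supports = character(0), alt_alleles = character(0),
    n_ignored = integer(0), stringsAsFactors = FALSE)
  if (inherits(locus, "locus_model") && nrow(calls)) {
    calls$region <- region_label(locus, calls$pos)
  } else {
    calls$region <- rep(NA_character_, nrow(calls))
  }
  calls <- calls[, c("gene_id", "species_id", "pos", "region", "ref_allele",
                     "alleles", "supports", "alt_alleles", "n_ignored")]
  class(calls) <- c("snp_calls", "data.frame")
  calls
}

snp_identity <- function(calls) {
  paste(calls$pos, calls$alleles, sep = ":")
}

#' SNPs shared between two call sets (identical position and allele pair)
#'
#' A SNP is shared when both its reference position and its full qualifying
#' allele set match exactly; a position called with different allele pairs in
#' the two sets is not shared. Symmetric in its arguments.
#'
#' @param calls_a,calls_b `snp_calls` for the same gene.
#' @return the shared subset of `calls_a` rows.
#' @export
shared_snps <- function(calls_a, calls_b) {
  ga <- unique(calls_a$gene_id)
  gb <- unique(calls_b$gene_id)
  if (length(ga) == 1L && length(gb) == 1L && !is.na(ga) && !is.na(gb) &&
      ga != gb) {
    stop("call sets come from different genes: ", ga, " vs ", gb,
         call. = FALSE)
  }
  calls_a[snp_identity(calls_a) %in% snp_identity(calls_b), , drop = FALSE]
}

#' Deduplicated union of SNP identities across call sets
#'
#' SNP identities (position + allele set) are merged across species; each
#' site/allele-pair combination counts once.
#'
#' @param calls_list list of `snp_calls` for the same gene.
#' @return data.frame of unique SNP identities with a `species` column
#'   listing contributors.
#' @export
union_snps <- function(calls_list) {
  genes <- unique(unlist(lapply(calls_list, function(x) unique(x$gene_id))))
  genes <- genes[!is.na(genes)]
  if (length(genes) > 1L) {
    stop("call sets come from different genes: ",
         paste(genes, collapse = ", "), call. = FALSE)
  }
  all <- do.call(rbind, calls_list)
  if (is.null(all) || nrow(all) == 0L) {
    return(data.frame(gene_id = character(0), pos = integer(0),
                      alleles = character(0), species = character(0),
                      stringsAsFactors = FALSE))
  }
  key <- snp_identity(all)
  agg <- stats::aggregate(list(species = all$species_id),
                          by = list(key = key),
                          FUN = function(s) paste(sort(unique(s)), collapse = ","))
  first <- all[!duplicated(key), c("gene_id", "pos", "alleles")]
  first$key <- key[!duplicated(key)]
  out <- merge(first, agg, by = "key")
  out <- out[order(out$pos, out$alleles), c("gene_id", "pos", "alleles", "species")]
  rownames(out) <- NULL
  out
}

#' Tabulate per-gene SNP counts into a Table-3-style density summary
#'
#' Given a species (or species-combination) x gene matrix of SNP counts and
#' the per-gene fragment lengths, computes each row's total SNPs, total bp,
#' and bp/SNP (inverse SNP density, rounded half-up to an integer; `NA` when
#' a row has no SNPs).
#'
#' @param counts integer matrix, rows = species or combinations, columns =
#'   genes.
#' @param lengths per-gene fragment lengths (bp).
#' @return data.frame with `total_snps`, `total_bp`, `bp_per_snp` per row.
#' @export
snp_density_table <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (ncol(counts) != length(lengths)) {
    stop("counts and fragment lengths differ in gene number", call. = FALSE)
  }
  total <- rowSums(counts)
  total_bp <- sum(lengths)
  data.frame(
    row = if (is.null(rownames(counts))) as.character(seq_len(nrow(counts)))
          else rownames(counts),
    total_snps = as.integer(total),
    total_bp = as.integer(total_bp),
    bp_per_snp = ifelse(total > 0, round_half_up(total_bp / total), NA),
    stringsAsFactors = FALSE
  )
}

#' Summarize SNP density per species from call sets
#'
#' Counts called SNP sites per gene x species and aggregates them with
#' [snp_density_table()].
#'
#' @param calls a `snp_calls` data.frame combined over genes and species (or
#'   a list of them).
#' @param loci named list of [locus_model()] objects covering every gene.
#' @return list with `per_gene` (species x gene count matrix) and `summary`
#'   (the density table).
#' @export
summarize_snp_density <- function(calls, loci) {
  if (is.list(calls) && !is.data.frame(calls)) calls <- do.call(rbind, calls)
  genes <- names(loci)
  if (nrow(calls) && !all(unique(calls$gene_id) %in% genes)) {
    stop("calls refer to genes absent from `loci`", call. = FALSE)
  }
  species <- sort(unique(calls$species_id))
  counts <- matrix(0L, length(species), length(genes),
                   dimnames = list(species, genes))
  if (nrow(calls)) {
    tab <- table(calls$species_id, calls$gene_id)
    counts[rownames(tab), colnames(tab)] <- as.integer(tab)
  }
  lengths <- vapply(loci, function(l) nchar(l$sequence), numeric(1))
  list(per_gene = counts, summary = snp_density_table(counts, lengths))
}

#' Cross-species SNP sharing and union summary for one gene set
#'
#' For every species pair and the full species set, computes per-gene
#' shared-SNP counts (identical position and allele pair) and union counts
#' (deduplicated identities), with bp/SNP aggregation.
#'
#' @param calls combined `snp_calls` over genes and species.
#' @param loci named list of [locus_model()] objects.
#' @return list with count matrices `shared` and `union` (rows = species
#'   combinations) and the corresponding density tables.
#' @export
summarize_snp_sharing <- function(calls, loci) {
  genes <- names(loci)
  species <- sort(unique(calls$species_id))
  combos <- c(utils::combn(species, 2L, simplify = FALSE),
              if (length(species) > 2L) list(species))
  combo_names <- vapply(combos, paste, character(1), collapse = "+")
  shared <- matrix(0L, length(combos), length(genes),
                   dimnames = list(combo_names, genes))
  uni <- shared
  for (ci in seq_along(combos)) {
    for (g in genes) {
      sets <- lapply(combos[[ci]], function(s)
        calls[calls$species_id == s & calls$gene_id == g, , drop = FALSE])
      uni[ci, g] <- nrow(union_snps(sets))
      keys <- lapply(sets, snp_identity)
      shared[ci, g] <- length(Reduce(intersect, keys))
    }
  }
  lengths <- vapply(loci, function(l) nchar(l$sequence), numeric(1))
  list(shared = shared, union = uni,
       shared_summary = snp_density_table(shared, lengths),
       union_summary = snp_density_table(uni, lengths))
}

#' Write SNP calls as a minimal VCF
#'
#' One record per called site: `CHROM` = gene, 1-based `POS`, `REF`, comma-
#' separated `ALT`, and INFO fields `SUP` (per-allele clone support, ref
#' first) and `REGION` (exon/intron).
#'
#' @param calls a `snp_calls` data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=polyhap",
    "##INFO=<ID=SUP,Number=.,Type=Integer,Description=\"Clone support per allele, ref allele first\">",
    "##INFO=<ID=REGION,Number=1,Type=String,Description=\"exon or intron\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  for (i in seq_len(nrow(calls))) {
    r <- calls[i, ]
    alleles <- strsplit(r$alleles, "/", fixed = TRUE)[[1]]
    sup <- strsplit(r$supports, "/", fixed = TRUE)[[1]]
    ord <- order(alleles != r$ref_allele, alleles)  # ref first
    alts <- alleles[ord][-1]
    if (!r$ref_allele %in% alleles) {
      ord <- order(alleles)
      alts <- alleles[ord]
    }
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tSUP=%s;REGION=%s",
                       r$gene_id, r$pos, r$ref_allele,
                       paste(alts, collapse = ","),
                       paste(sup[ord], collapse = ","),
                       ifelse(is.na(r$region), ".", r$region)), con)
  }
  invisible(path)
}
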