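#' Published per-fragment summary counts for the SuSy study system
#'
#' Loads the published per-gene SNP, haplotype and deduced-protein counts
#' for the five sucrose synthase fragments surveyed in the three octoploid
#' *Saccharum* species, shipped with the package as plain TSV. These counts
#' are the study's printed inputs for re-running the aggregation arithmetic
#' (totals, bp/SNP, consensus frequency) and for calibrating the simulator.
#'
#' @return list with `fragment_lengths` (named integer), `snp` (count
#'   data.frame with `row`, `block`, per-gene columns, printed totals),
#'   `haplotypes`, `proteins` (count data.frames), and `consensus` (named
#'   numeric of published consensus-haplotype figures).
#' @export
load_published_counts <- function() {
  path <- function(f) system.file("extdata", f, package = "polyhap",
                                  mustWork = TRUE)
  read <- function(f) utils::read.delim(path(f), check.names = FALSE,
                                        stringsAsFactors = FALSE)
  fl <- read("published_fragment_lengths.tsv")
  cons <- read("published_consensus.tsv")
  list(
    fragment_lengths = stats::setNames(as.integer(fl$length_bp), fl$gene),
    snp = read("published_snp_counts.tsv"),
    haplotypes = read("published_haplotype_counts.tsv"),
    proteins = read("published_protein_counts.tsv"),
    consensus = stats::setNames(as.numeric(cons$value), cons$quantity)
  )
}

count_matrix <- function(df, genes) {
  m <- as.matrix(df[, genes, drop = FALSE])
  rownames(m) <- df$row
  storage.mode(m) <- "integer"
  m
}

#' Flag rows whose printed total disagrees with the row sum
#'
#' Self-consistency audit of a published count table: for every row the
#' per-gene counts are summed and compared with the printed total; rows
#' where the two differ are flagged rather than silently reproduced.
#'
#' @param counts species(-combination) x gene count matrix.
#' @param printed_totals printed row totals, same order as `counts` rows.
#' @return data.frame with `row`, `computed_total`, `printed_total`,
#'   `discrepant`.
#' @export
flag_total_discrepancies <- function(counts, printed_totals) {
  computed <- as.integer(rowSums(counts))
  data.frame(
    row = rownames(counts),
    computed_total = computed,
    printed_total = as.integer(printed_totals),
    discrepant = computed != as.integer(printed_totals),
    stringsAsFactors = FALSE
  )
}

#' Audit the published summary tables for internal inconsistencies
#'
#' Recomputes every row total of the published SNP, haplotype and protein
#' count tables from their per-gene cells and flags disagreements with the
#' printed totals (for the SNP table also the bp/SNP implied by the row
#' sum). The published tables contain rows whose printed totals do not
#' equal their own row sums; this audit surfaces them as data instead of
#' guessing the intended value.
#'
#' @return list of discrepancy data.frames: `snp` (with recomputed
#'   `bp_per_snp_from_rowsum`), `haplotypes`, `proteins`.
#' @export
audit_published_tables <- function() {
  pub <- load_published_counts()
  genes <- names(pub$fragment_lengths)
  total_bp <- sum(pub$fragment_lengths)
  snp_counts <- count_matrix(pub$snp, genes)
  snp <- flag_total_discrepancies(snp_counts, pub$snp$printed_total)
  snp$block <- pub$snp$block
  snp$bp_per_snp_from_rowsum <- ifelse(
    snp$computed_total > 0, round_half_up(total_bp / snp$computed_total), NA)
  snp$printed_bp_per_snp <- pub$snp$printed_bp_per_snp
  hap <- flag_total_discrepancies(count_matrix(pub$haplotypes, genes),
                                  pub$haplotypes$printed_total)
  prot <- flag_total_discrepancies(count_matrix(pub$proteins, genes),
                                   pub$proteins$printed_total)
  list(snp = snp, haplotypes = hap, proteins = prot)
}
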