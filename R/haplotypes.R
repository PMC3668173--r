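#' Infer haplotypes from an aligned library and its SNP calls
#'
#' Haplotypes are the unique combinations of alleles at the called SNP
#' positions. Clones carrying `N` or a gap at any SNP position are excluded
#' from haplotyping; allele-vector groups with clone support below
#' `min_haplotype_support` (default 2, the "observed in at least two
#' colonies" rule) are discarded. With zero SNPs the library is monomorphic:
#' a single haplotype containing every clone. Haplotypes are reported in
#' descending clone support, ties broken by lexicographic allele vector.
#'
#' Each haplotype carries a representative full-length sequence
#' (`rep_sequence`): the per-column majority base over its member clones
#' (alphabetically first base on ties), used for cross-species comparison
#' and protein deduction.
#'
#' @param aligned_library an [build_aligned_library()] result.
#' @param snp_calls the [call_snps()] result for the same library.
#' @param min_haplotype_support minimum clone support per haplotype.
#' @return a `haplotype_table` data.frame: `gene_id`, `species_id`,
#'   `haplotype_id`, `allele_vector`, `clone_support`, `clone_ids`,
#'   `rep_sequence`; attributes `snp_positions`, `discarded` (under-supported
#'   groups), `excluded_clones` (N/gap at a SNP position).
#' @export
infer_haplotypes <- function(aligned_library, snp_calls,
                             min_haplotype_support = 2L) {
  stopifnot(inherits(aligned_library, "aligned_library"))
  mat <- aligned_library$matrix
  pos <- sort(unique(snp_calls$pos))
  if (length(pos)) {
    sub <- mat[, pos, drop = FALSE]
    ok <- apply(sub, 1L, function(r) all(r %in% DNA_BASES))
    vec <- apply(sub[ok, , drop = FALSE], 1L, c2s)
  } else {
    ok <- rep(TRUE, nrow(mat))
    vec <- rep("", nrow(mat))
    names(vec) <- rownames(mat)
  }
  excluded <- rownames(mat)[!ok]
  groups <- split(names(vec), vec)
  support <- lengths(groups)
  keep <- support >= min_haplotype_support
  discarded <- data.frame(
    allele_vector = names(groups)[!keep],
    clone_support = as.integer(support[!keep]),
    clone_ids = vapply(groups[!keep], paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
  groups <- groups[keep]
  support <- support[keep]
  ord <- order(-support, names(groups))
  groups <- groups[ord]
  support <- support[ord]
  rep_seq <- vapply(groups, function(ids) {
    sub <- mat[ids, , drop = FALSE]
    c2s(apply(sub, 2L, function(col) {
      col <- col[col %in% DNA_BASES]
      if (!length(col)) return("N")
      tab <- table(col)
      names(tab)[which.max(tab)]  # ties: alphabetically first
    }))
  }, character(1))
  tab <- data.frame(
    gene_id = rep(aligned_library$gene_id, length(groups)),
    species_id = rep(aligned_library$species_id, length(groups)),
    haplotype_id = sprintf("%s_%s_h%02d", aligned_library$gene_id,
                           aligned_library$species_id, seq_along(groups)),
    allele_vector = if (length(groups)) names(groups) else character(0),
    clone_support = as.integer(support),
    clone_ids = vapply(groups, paste, character(1), collapse = ","),
    rep_sequence = unname(rep_seq),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  attr(tab, "snp_positions") <- pos
  attr(tab, "discarded") <- discarded
  attr(tab, "excluded_clones") <- excluded
  class(tab) <- c("haplotype_table", "data.frame")
  tab
}

#' Tabulate haplotype counts per gene and species
#'
#' @param tables list of `haplotype_table` objects (one per gene x species),
#'   or a combined data.frame with `gene_id`/`species_id` columns.
#' @return list with `counts` (species x gene matrix) and `totals`
#'   (per-species row sums, plus a per-gene column-sum row `Total`).
#' @export
summarize_haplotype_counts <- function(tables) {
  df <- if (is.data.frame(tables)) tables else do.call(rbind, lapply(tables, as.data.frame))
  if (is.null(df) || nrow(df) == 0L) {
    return(list(counts = matrix(0L, 0, 0), totals = integer(0)))
  }
  tab <- table(df$species_id, df$gene_id)
  counts <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                   dimnames = dimnames(tab))
  list(counts = counts,
       totals = stats::setNames(as.integer(rowSums(counts)), rownames(counts)),
       per_gene_totals = stats::setNames(as.integer(colSums(counts)),
                                         colnames(counts)))
}

#' Identify consensus haplotypes across species
#'
#' Haplotypes from different species belong to one cross-species class when
#' their representative full-fragment sequences, restricted to the gene's
#' union SNP coordinate set (positions called in any species), are
#' identical. A class is a consensus class when at least two species
#' contribute a haplotype; consensus haplotypes are interpreted as allele
#' combinations predating speciation. The consensus frequency is the
#' percentage of all retained clone fragments that fall in consensus
#' classes.
#'
#' @param hap_tables list of `haplotype_table` objects covering all species
#'   for the genes of interest.
#' @param union_positions named list: per gene, the union SNP coordinate
#'   vector (e.g. unique `pos` from per-species [call_snps()] combined).
#' @return a `consensus_report`: `classes` data.frame (gene, class pattern,
#'   contributing species, haplotype ids, clone support, consensus flag),
#'   `pairwise` shared-class counts per species pair, and `totals`
#'   (`n_fragments`, `n_fragments_in_consensus`,
#'   `consensus_frequency_percent`, `n_haplotypes`, `n_consensus_classes`).
#' @export
find_consensus_haplotypes <- function(hap_tables, union_positions) {
  df <- do.call(rbind, lapply(hap_tables, as.data.frame))
  if (is.null(df) || nrow(df) == 0L) stop("no haplotypes supplied", call. = FALSE)
  species_all <- sort(unique(df$species_id))
  if (length(species_all) < 2L) {
    warning("fewer than two species supplied; no consensus classes possible",
            call. = FALSE)
  }
  df$pattern <- vapply(seq_len(nrow(df)), function(i) {
    pos <- union_positions[[df$gene_id[i]]]
    if (is.null(pos) || !length(pos)) return("")
    c2s(s2c(df$rep_sequence[i])[sort(pos)])
  }, character(1))
  key <- paste(df$gene_id, df$pattern, sep = "|")
  classes <- do.call(rbind, lapply(split(seq_len(nrow(df)), key), function(idx) {
    sp <- sort(unique(df$species_id[idx]))
    data.frame(
      gene_id = df$gene_id[idx[1]],
      pattern = df$pattern[idx[1]],
      species = paste(sp, collapse = ","),
      n_species = length(sp),
      haplotype_ids = paste(df$haplotype_id[idx], collapse = ","),
      clone_support = sum(df$clone_support[idx]),
      consensus = length(sp) >= 2L,
      stringsAsFactors = FALSE
    )
  }))
  classes <- classes[order(classes$gene_id, -classes$clone_support,
                           classes$pattern), ]
  rownames(classes) <- NULL
  pairs <- utils::combn(species_all, 2L, simplify = FALSE)
  pairwise <- data.frame(
    pair = vapply(pairs, paste, character(1), collapse = "+"),
    shared_classes = vapply(pairs, function(p) {
      sum(vapply(strsplit(classes$species, ",", fixed = TRUE),
                 function(s) all(p %in% s), logical(1)))
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  n_frag <- sum(df$clone_support)
  n_cons <- sum(classes$clone_support[classes$consensus])
  structure(list(
    classes = classes,
    pairwise = pairwise,
    totals = list(
      n_fragments = n_frag,
      n_fragments_in_consensus = n_cons,
      consensus_frequency_percent = consensus_frequency(n_cons, n_frag),
      n_haplotypes = nrow(df),
      n_consensus_classes = sum(classes$consensus)
    )
  ), class = "consensus_report")
}

#' Consensus-haplotype frequency in percent
#'
#' @param n_in_consensus clone fragments belonging to consensus classes.
#' @param n_total all retained clone fragments.
#' @return `100 * n_in_consensus / n_total`.
#' @export
consensus_frequency <- function(n_in_consensus, n_total) {
  if (n_total <= 0) stop("total fragment count must be positive", call. = FALSE)
  100 * n_in_consensus / n_total
}

#' @export
print.consensus_report <- function(x, ...) {
  cat("Consensus haplotype report:", x$totals$n_haplotypes, "haplotypes in",
      nrow(x$classes), "cross-species classes (",
      x$totals$n_consensus_classes, "consensus )\n")
  cat(sprintf("  consensus frequency: %.1f%% (%d/%d fragments)\n",
              x$totals$consensus_frequency_percent,
              x$totals$n_fragments_in_consensus, x$totals$n_fragments))
  invisible(x)
}

#' Welch t-test of consensus-haplotype clone-support enrichment
#'
#' Two-sample Welch t-test comparing per-haplotype clone support between
#' consensus classes and the remaining haplotypes. Degenerate inputs that
#' the textbook formula still covers are handled explicitly: equal means
#' with zero pooled standard error give `t = 0`, `p = 1`; unequal means with
#' zero standard error give an infinite statistic and `p = 0`.
#'
#' @param consensus_supports clone-support counts of consensus haplotypes.
#' @param other_supports clone-support counts of the remaining haplotypes.
#' @return list with `statistic`, `df`, `p_value`, and the group means.
#' @export
test_consensus_enrichment <- function(consensus_supports, other_supports) {
  x <- as.numeric(consensus_supports)
  y <- as.numeric(other_supports)
  if (length(x) < 2L || length(y) < 2L) {
    stop("both groups need at least two values", call. = FALSE)
  }
  se2 <- stats::var(x) / length(x) + stats::var(y) / length(y)
  if (se2 == 0) {
    d <- mean(x) - mean(y)
    t_stat <- if (d == 0) 0 else sign(d) * Inf
    return(list(statistic = t_stat, df = NA_real_,
                p_value = if (d == 0) 1 else 0,
                mean_consensus = mean(x), mean_other = mean(y)))
  }
  ht <- stats::t.test(x, y)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_consensus = mean(x), mean_other = mean(y))
}

#' Compare inferred haplotypes with simulation truth
#'
#' Maps each true haplotype to its allele vector at the called SNP
#' positions (distinct true haplotypes may merge when a true SNP went
#' uncalled) and scores the inferred set against these true vectors.
#'
#' @param hap_table an [infer_haplotypes()] result.
#' @param truth the `truth_set` for the gene.
#' @param species_id species to evaluate.
#' @return list with `n_true` (distinct true vectors), `n_recovered`,
#'   `recall_percent`, and `n_false` (inferred vectors matching no true
#'   haplotype).
#' @export
evaluate_haplotype_recovery <- function(hap_table, truth, species_id) {
  st <- truth$species[[species_id]]
  pos <- attr(hap_table, "snp_positions")
  true_vec <- unique(vapply(st$haplotypes, function(h) {
    if (length(pos)) c2s(s2c(h)[pos]) else ""
  }, character(1), USE.NAMES = FALSE))
  inferred <- hap_table$allele_vector
  n_rec <- sum(true_vec %in% inferred)
  list(n_true = length(true_vec),
       n_recovered = n_rec,
       recall_percent = 100 * n_rec / length(true_vec),
       n_false = sum(!inferred %in% true_vec))
}
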