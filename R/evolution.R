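split_codons <- function(x) {
  if (length(x) == 1L && nchar(x) > 3L) {
    if (nchar(x) %% 3L != 0L) stop("sequence length not a multiple of 3", call. = FALSE)
    substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))
  } else {
    x
  }
}

#' Back-translate a protein alignment into a codon alignment
#'
#' Replaces every aligned residue by its source codon from the matching
#' coding sequence; residue gaps become `---` codon gaps. Each protein must
#' translate exactly from its CDS (a trailing stop codon in the CDS is
#' tolerated); mismatches raise an error naming the residue position.
#'
#' @param protein_alignment named character vector of gapped, equal-length
#'   amino-acid sequences.
#' @param cds_map named character vector of in-frame coding sequences, names
#'   matching `protein_alignment`.
#' @return a `codon_alignment`: character matrix, rows = sequences,
#'   columns = codon columns, entries 3-base codons or `---`.
#' @export
back_translate <- function(protein_alignment, cds_map) {
  if (is.null(names(protein_alignment))) {
    names(protein_alignment) <- paste0("seq", seq_along(protein_alignment))
  }
  widths <- nchar(protein_alignment)
  if (length(unique(widths)) != 1L) {
    stop("protein alignment rows differ in length", call. = FALSE)
  }
  n_col <- widths[1]
  out <- matrix("---", length(protein_alignment), n_col,
                dimnames = list(names(protein_alignment), NULL))
  for (id in names(protein_alignment)) {
    cds <- cds_map[[id]]
    if (is.null(cds)) stop("no CDS supplied for ", id, call. = FALSE)
    codons <- split_codons(cds)
    res <- s2c(protein_alignment[[id]])
    k <- 0L
    for (j in seq_len(n_col)) {
      if (res[j] == "-") next
      k <- k + 1L
      if (k > length(codons)) {
        stop(sprintf("CDS of %s shorter than its protein (residue %d)", id, j),
             call. = FALSE)
      }
      aa <- Biostrings::GENETIC_CODE[codons[k]]
      if (is.na(aa) || aa != res[j]) {
        stop(sprintf("CDS/protein mismatch for %s at residue %d (%s vs %s)",
                     id, j, codons[k], res[j]), call. = FALSE)
      }
      out[id, j] <- codons[k]
    }
    leftover <- length(codons) - k
    if (leftover > 1L ||
        (leftover == 1L && Biostrings::GENETIC_CODE[codons[k + 1L]] != "*")) {
      stop("CDS of ", id, " longer than its protein", call. = FALSE)
    }
  }
  class(out) <- c("codon_alignment", class(out))
  out
}

ng_env <- new.env(parent = emptyenv())

# Per-codon fraction of synonymous sites under NG86: at each position the 3
# single-base neighbors are enumerated; changes creating stop codons are
# excluded from numerator and denominator.
ng_syn_fraction <- function(codon) {
  if (is.null(ng_env$syn)) {
    code <- Biostrings::GENETIC_CODE
    sense <- names(code)[code != "*"]
    syn <- stats::setNames(numeric(length(sense)), sense)
    for (cd in sense) {
      bases <- s2c(cd)
      s <- 0
      for (p in 1:3) {
        neigh <- vapply(setdiff(DNA_BASES, bases[p]), function(b) {
          x <- bases
          x[p] <- b
          c2s(x)
        }, character(1))
        aa <- code[neigh]
        valid <- aa != "*"
        if (any(valid)) {
          s <- s + sum(aa[valid] == code[cd]) / sum(valid)
        }
      }
      syn[cd] <- s
    }
    ng_env$syn <- syn
  }
  ng_env$syn[codon]
}

# Synonymous/nonsynonymous difference counts between two codons, averaging
# with equal weight over all orderings of the observed changes; pathways
# passing through a stop codon are excluded. If every pathway is blocked,
# all pathways are used with stop treated as an ordinary distinct residue.
ng_codon_differences <- function(ca, cb) {
  code <- Biostrings::GENETIC_CODE
  a <- s2c(ca)
  b <- s2c(cb)
  diff_pos <- which(a != b)
  if (!length(diff_pos)) return(c(syn = 0, nonsyn = 0))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    unlist(lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))), recursive = FALSE)
  }
  score_path <- function(order, allow_stop) {
    cur <- a
    syn <- 0
    nonsyn <- 0
    for (p in order) {
      nxt <- cur
      nxt[p] <- b[p]
      aa_cur <- code[c2s(cur)]
      aa_nxt <- code[c2s(nxt)]
      if (!allow_stop && aa_nxt == "*" && !identical(nxt, b)) return(NULL)
      if (!allow_stop && (aa_cur == "*" || aa_nxt == "*")) return(NULL)
      if (aa_cur == aa_nxt) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn = syn, nonsyn = nonsyn)
  }
  paths <- perms(diff_pos)
  scored <- Filter(Negate(is.null), lapply(paths, score_path, allow_stop = FALSE))
  if (!length(scored)) {
    scored <- lapply(paths, score_path, allow_stop = TRUE)
  }
  Reduce(`+`, scored) / length(scored)
}

#' Nei-Gojobori dN/dS for a pair of aligned coding sequences
#'
#' Classic unweighted NG86: per-codon synonymous site fractions enumerate
#' the three single-base neighbors per position (changes through stop codons
#' excluded from numerator and denominator); site counts are averaged over
#' the two sequences. Differences in codons with multiple changes are
#' averaged with equal weight over all mutational orderings, excluding
#' pathways crossing a stop codon. Proportions are corrected for multiple
#' hits with Jukes-Cantor, `d = -(3/4) log(1 - (4/3) p)`; `p >= 3/4` is
#' reported as saturated (`NA` rate). Codon columns containing a gap, `N`,
#' or a stop codon in either sequence are masked pairwise.
#'
#' @param codons_a,codons_b codon vectors (or in-frame CDS strings) of equal
#'   codon length.
#' @return list of class `pairwise_evolution`: `Nd`, `Sd`, `N`, `S`, `pN`,
#'   `pS`, `dN`, `dS`, `dnds`, `n_codons` (unmasked), and saturation flags.
#' @export
nei_gojobori <- function(codons_a, codons_b) {
  a <- split_codons(codons_a)
  b <- split_codons(codons_b)
  if (length(a) != length(b)) {
    stop("codon sequences differ in length", call. = FALSE)
  }
  code <- Biostrings::GENETIC_CODE
  ok_codon <- function(x) !grepl("[^ACGT]", x) & !is.na(code[x]) & code[x] != "*"
  keep <- ok_codon(a) & ok_codon(b)
  if (!any(keep)) stop("no unmasked codon columns", call. = FALSE)
  a <- a[keep]
  b <- b[keep]
  S_a <- sum(ng_syn_fraction(a))
  S_b <- sum(ng_syn_fraction(b))
  S <- (S_a + S_b) / 2
  N <- 3 * length(a) - S
  diffs <- c(syn = 0, nonsyn = 0)
  for (i in which(a != b)) {
    diffs <- diffs + ng_codon_differences(a[i], b[i])
  }
  Sd <- unname(diffs["syn"])
  Nd <- unname(diffs["nonsyn"])
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  dS <- jc(pS)
  dN <- jc(pN)
  structure(list(
    Nd = Nd, Sd = Sd, N = N, S = S, pN = pN, pS = pS,
    dN = dN, dS = dS,
    dnds = if (!is.na(dN) && !is.na(dS) && dS > 0) dN / dS else NA_real_,
    n_codons = length(a),
    dn_saturated = is.na(dN), ds_saturated = is.na(dS)
  ), class = "pairwise_evolution")
}

#' @export
print.pairwise_evolution <- function(x, ...) {
  cat(sprintf("NG86: Nd=%.3g Sd=%.3g N=%.4g S=%.4g dN=%s dS=%s dN/dS=%s (%d codons)\n",
              x$Nd, x$Sd, x$N, x$S,
              format(x$dN, digits = 4), format(x$dS, digits = 4),
              format(x$dnds, digits = 4), x$n_codons))
  invisible(x)
}

#' Classify sequence pairs by selection signature
#'
#' Pairs with saturated or unusually large dS (`dS > ks_max`) are flagged as
#' Ks outliers and excluded; the remainder are partitioned into
#' `Ka >= Ks` (candidate positive selection) and `Ka < Ks` (purifying).
#' A pair with `dN` saturated but `dS` in range is kept and lands in
#' `Ka >= Ks`.
#'
#' @param pairs data.frame with columns `dN`, `dS` (one row per pair), e.g.
#'   from rbinding [nei_gojobori()] results.
#' @param ks_max maximum admissible dS (default 3.0).
#' @return list with `n_ka_ge_ks`, `n_ka_lt_ks`, `n_outliers`, and the
#'   annotated data.frame (`ks_outlier`, `ka_ge_ks` columns).
#' @export
classify_selection <- function(pairs, ks_max = 3.0) {
  pairs <- as.data.frame(pairs)
  outlier <- is.na(pairs$dS) | pairs$dS > ks_max
  ge <- !outlier & (is.na(pairs$dN) | pairs$dN >= pairs$dS)
  pairs$ks_outlier <- outlier
  pairs$ka_ge_ks <- ifelse(outlier, NA, ge)
  list(n_ka_ge_ks = sum(ge, na.rm = TRUE),
       n_ka_lt_ks = sum(!outlier & !ge),
       n_outliers = sum(outlier),
       pairs = pairs)
}

#' Pairwise distance matrix for aligned protein sequences
#'
#' p-distance (default) or Poisson-corrected distance `-log(1 - p)`.
#' Alignment columns with a gap in either member of a pair are ignored for
#' that pair.
#'
#' @param sequences named character vector of equal-length (gapped)
#'   amino-acid sequences.
#' @param method `"p"` or `"poisson"`.
#' @return symmetric distance matrix with zero diagonal.
#' @export
protein_distance_matrix <- function(sequences, method = c("p", "poisson")) {
  method <- match.arg(method)
  if (length(unique(nchar(sequences))) != 1L) {
    stop("sequences must be aligned to equal length", call. = FALSE)
  }
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  chars <- lapply(sequences, s2c)
  n <- length(sequences)
  D <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      a <- chars[[i]]
      b <- chars[[j]]
      use <- a != "-" & b != "-"
      if (!any(use)) stop("no comparable positions for pair ",
                          names(sequences)[i], "/", names(sequences)[j],
                          call. = FALSE)
      p <- mean(a[use] != b[use])
      d <- if (method == "p") p else {
        if (p >= 1) stop("Poisson correction saturated for pair ",
                         names(sequences)[i], "/", names(sequences)[j],
                         call. = FALSE)
        -log(1 - p)
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via [ape::nj()]) on a validated
#' symmetric matrix; negative branch lengths are clamped to zero with a
#' warning.
#'
#' @param distance_matrix square symmetric numeric matrix, n >= 3.
#' @return an unrooted `phylo` tree.
#' @export
neighbor_joining <- function(distance_matrix) {
  D <- as.matrix(distance_matrix)
  if (nrow(D) != ncol(D) || nrow(D) < 3L) {
    stop("need a square matrix over at least 3 taxa", call. = FALSE)
  }
  if (max(abs(D - t(D))) > 1e-8) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  tree <- ape::nj(D)
  if (any(tree$edge.length < 0)) {
    warning(sprintf("%d negative branch length(s) clamped to 0",
                    sum(tree$edge.length < 0)), call. = FALSE)
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

# Non-trivial bipartitions of an unrooted tree, canonicalized as the sorted
# tip-label set on the side NOT containing the alphabetically first label.
tree_bipartitions <- function(tree) {
  n_tip <- length(tree$tip.label)
  desc <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) desc[[i]] <- i
  edges <- tree$edge[order(-tree$edge[, 1]), , drop = FALSE]
  for (k in seq_len(nrow(edges))) {
    par <- edges[k, 1]
    chd <- edges[k, 2]
    desc[[par]] <- c(desc[[par]], desc[[chd]])
  }
  anchor <- sort(tree$tip.label)[1]
  keys <- character(0)
  for (k in seq_len(nrow(tree$edge))) {
    chd <- tree$edge[k, 2]
    if (chd <= n_tip) next  # trivial split
    tips <- sort(tree$tip.label[desc[[chd]]])
    if (length(tips) <= 1L || length(tips) >= n_tip - 1L) next
    if (anchor %in% tips) {
      tips <- sort(setdiff(tree$tip.label, tips))
    }
    keys <- c(keys, paste(tips, collapse = "|"))
  }
  unique(keys)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement `n_replicates` times,
#' rebuilds the NJ tree per replicate, and reports for every internal edge
#' of the full-data tree the percentage of replicate trees containing its
#' bipartition. The replicate column indices are kept for audit.
#'
#' @param sequences named character vector of equal-length aligned sequences
#'   (amino acids by default).
#' @param n_replicates number of bootstrap replicates (>= 1; the study
#'   design used 100).
#' @param seed integer RNG seed.
#' @param method distance method passed to [protein_distance_matrix()].
#' Replicates whose resampled columns leave some sequence pair without any
#' comparable position (possible when gap-padded, truncated sequences are
#' present) are skipped; support percentages are taken over the replicates
#' that produced a tree, and their number is reported as `n_effective`.
#'
#' @return list with `tree` (full-data NJ tree, `node.label` carrying
#'   supports), `support` data.frame (`bipartition`, `percent`),
#'   `n_effective` (replicates yielding a tree), and attribute
#'   `replicate_columns` (matrix of resampled indices).
#' @export
bootstrap_support <- function(sequences, n_replicates = 100L, seed = 42L,
                              method = "p") {
  if (length(sequences) < 3L) stop("need at least 3 sequences", call. = FALSE)
  if (n_replicates < 1L) stop("need at least one replicate", call. = FALSE)
  chars <- do.call(rbind, lapply(sequences, s2c))
  n_col <- ncol(chars)
  full_tree <- neighbor_joining(protein_distance_matrix(sequences, method))
  target <- tree_bipartitions(full_tree)
  hits <- stats::setNames(numeric(length(target)), target)
  cols <- matrix(0L, n_replicates, n_col)
  n_effective <- 0L
  with_seed(seed, {
    for (r in seq_len(n_replicates)) {
      idx <- sample(n_col, n_col, replace = TRUE)
      cols[r, ] <- idx
      boot_seqs <- apply(chars[, idx, drop = FALSE], 1L, c2s)
      names(boot_seqs) <- names(sequences)
      bt <- tryCatch(
        suppressWarnings(
          neighbor_joining(protein_distance_matrix(boot_seqs, method))),
        error = function(e) NULL)
      if (is.null(bt)) next
      n_effective <- n_effective + 1L
      found <- tree_bipartitions(bt)
      hits[target %in% found] <- hits[target %in% found] + 1
    }
  })
  if (n_effective == 0L) {
    stop("no bootstrap replicate produced a tree", call. = FALSE)
  }
  percent <- 100 * hits / n_effective
  # attach supports as node labels of the matching internal nodes
  n_tip <- length(full_tree$tip.label)
  labels <- rep("", full_tree$Nnode)
  desc_keys <- local({
    desc <- vector("list", n_tip + full_tree$Nnode)
    for (i in seq_len(n_tip)) desc[[i]] <- i
    edges <- full_tree$edge[order(-full_tree$edge[, 1]), , drop = FALSE]
    for (k in seq_len(nrow(edges))) {
      desc[[edges[k, 1]]] <- c(desc[[edges[k, 1]]], desc[[edges[k, 2]]])
    }
    anchor <- sort(full_tree$tip.label)[1]
    vapply(seq_len(full_tree$Nnode), function(i) {
      tips <- sort(full_tree$tip.label[desc[[n_tip + i]]])
      if (length(tips) <= 1L || length(tips) >= n_tip - 1L) return("")
      if (anchor %in% tips) tips <- sort(setdiff(full_tree$tip.label, tips))
      paste(tips, collapse = "|")
    }, character(1))
  })
  hit_idx <- match(desc_keys, names(percent))
  labels[!is.na(hit_idx)] <- format(round(percent[hit_idx[!is.na(hit_idx)]]))
  full_tree$node.label <- labels
  out <- list(tree = full_tree,
              support = data.frame(bipartition = names(percent),
                                   percent = unname(percent),
                                   stringsAsFactors = FALSE),
              n_effective = n_effective)
  attr(out, "replicate_columns") <- cols
  out
}
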