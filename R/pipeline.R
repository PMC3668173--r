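#' Pipeline configuration
#'
#' Bundles every stage parameter of the amplicon haplotype pipeline. Input
#' is either a simulated study (`sim_config`) or a directory of files laid
#' out as written by [write_study()] (`input_dir`: `reference.fasta`,
#' `loci.gff3`, `clones_<gene>_<species>.fasta`). Referenced paths are
#' validated up front.
#'
#' @param sim_config a [simulation_config()]; used when `input_dir` is NULL.
#' @param input_dir optional directory of clone FASTA + locus annotation.
#' @param min_identity clone-retention identity threshold for alignment.
#' @param min_support minimum clone support per SNP allele.
#' @param min_haplotype_support minimum clone support per haplotype.
#' @param ks_max dS outlier threshold for selection classification.
#' @param bootstrap_replicates bootstrap replicates for the per-gene trees
#'   (0 disables trees).
#' @param seed top-level pipeline seed (bootstrap streams derive from it).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(sim_config = simulation_config(),
                            input_dir = NULL,
                            min_identity = 0.9,
                            min_support = 3L,
                            min_haplotype_support = 2L,
                            ks_max = 3.0,
                            bootstrap_replicates = 100L,
                            seed = 1L) {
  if (!is.null(input_dir)) {
    for (f in c("reference.fasta", "loci.gff3")) {
      p <- file.path(input_dir, f)
      if (!file.exists(p)) stop("required input file not found: ", p,
                                call. = FALSE)
    }
    if (!length(list.files(input_dir, pattern = "^clones_.*\\.fasta$"))) {
      stop("no clone FASTA files (clones_<gene>_<species>.fasta) in ",
           input_dir, call. = FALSE)
    }
  }
  structure(list(sim_config = sim_config, input_dir = input_dir,
                 min_identity = min_identity,
                 min_support = as.integer(min_support),
                 min_haplotype_support = as.integer(min_haplotype_support),
                 ks_max = ks_max,
                 bootstrap_replicates = as.integer(bootstrap_replicates),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

read_clone_libraries <- function(input_dir) {
  files <- list.files(input_dir, pattern = "^clones_.*\\.fasta$",
                      full.names = TRUE)
  libs <- list()
  for (f in files) {
    parts <- strsplit(sub("^clones_(.*)\\.fasta$", "\\1", basename(f)),
                      "_")[[1]]
    g <- parts[1]
    s <- paste(parts[-1], collapse = "_")
    fa <- Biostrings::readDNAStringSet(f)
    libs[[g]][[s]] <- list(gene_id = g, species_id = s,
                           sequences = stats::setNames(as.character(fa),
                                                       names(fa)))
  }
  libs
}

#' Run the full amplicon haplotype pipeline
#'
#' Executes align -> call -> haplotype -> protein -> evolve -> report over
#' every gene x species library. Simulated runs additionally score SNP and
#' haplotype recovery against the simulation truth. The result is fully
#' determined by the configuration (all randomness derives from its seeds).
#'
#' @param config a [pipeline_config()].
#' @return a `run_report`: stage tables (`snp_calls`, `snp_density`,
#'   `snp_sharing`, `haplotypes`, `haplotype_counts`, `consensus`,
#'   `enrichment`, `proteins`, `protein_counts`, `dnds`, `selection`,
#'   `trees`), per-stage `log` counts, `truth_eval` (simulated runs),
#'   `published_audit` discrepancy flags, `config` echo and package
#'   `version`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  simulated <- is.null(config$input_dir)
  if (simulated) {
    study <- simulate_study(config$sim_config)
    loci <- study$loci
    libraries <- study$libraries
  } else {
    study <- NULL
    loci <- read_loci(file.path(config$input_dir, "loci.gff3"),
                      file.path(config$input_dir, "reference.fasta"))
    libraries <- read_clone_libraries(config$input_dir)
    missing <- setdiff(names(libraries), names(loci))
    if (length(missing)) {
      stop("no locus annotation for gene(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }

  log <- list()
  calls_all <- list()
  hap_tables <- list()
  prot_all <- list()
  aligned <- list()
  for (g in names(libraries)) {
    for (s in names(libraries[[g]])) {
      lib <- libraries[[g]][[s]]
      alib <- tryCatch(
        suppressWarnings(build_aligned_library(
          lib$sequences, loci[[g]], min_identity = config$min_identity,
          species_id = s)),
        error = function(e) stop("stage alignment failed for ", g, " x ", s,
                                 ": ", conditionMessage(e), call. = FALSE))
      calls <- call_snps(alib, loci[[g]], min_support = config$min_support)
      haps <- infer_haplotypes(alib, calls,
                               min_haplotype_support = config$min_haplotype_support)
      aligned[[paste(g, s, sep = ".")]] <- alib
      calls_all[[paste(g, s, sep = ".")]] <- calls
      hap_tables[[paste(g, s, sep = ".")]] <- haps
      prot_all[[paste(g, s, sep = ".")]] <- deduce_proteins(haps, loci[[g]])
      log[[paste(g, s, sep = ".")]] <- data.frame(
        gene_id = g, species_id = s,
        clones_in = length(lib$sequences),
        clones_retained = nrow(alib$matrix),
        clones_excluded = nrow(alib$excluded),
        snps_called = nrow(calls),
        haplotypes_retained = nrow(haps),
        haplotypes_discarded = nrow(attr(haps, "discarded")),
        clones_unassignable = length(attr(haps, "excluded_clones")),
        stringsAsFactors = FALSE)
    }
  }
  log <- do.call(rbind, log)
  rownames(log) <- NULL
  calls_df <- do.call(rbind, calls_all)
  rownames(calls_df) <- NULL

  snp_density <- summarize_snp_density(calls_df, loci)
  snp_sharing <- summarize_snp_sharing(calls_df, loci)
  hap_counts <- summarize_haplotype_counts(hap_tables)

  union_positions <- lapply(names(loci), function(g)
    sort(unique(calls_df$pos[calls_df$gene_id == g])))
  names(union_positions) <- names(loci)
  consensus <- find_consensus_haplotypes(hap_tables, union_positions)

  hap_df <- do.call(rbind, lapply(hap_tables, as.data.frame))
  rownames(hap_df) <- NULL
  cons_ids <- unlist(strsplit(
    consensus$classes$haplotype_ids[consensus$classes$consensus], ","))
  in_cons <- hap_df$haplotype_id %in% cons_ids
  enrichment <- if (sum(in_cons) >= 2L && sum(!in_cons) >= 2L) {
    test_consensus_enrichment(hap_df$clone_support[in_cons],
                              hap_df$clone_support[!in_cons])
  } else NULL

  prot_df <- do.call(rbind, prot_all)
  rownames(prot_df) <- NULL
  prot_counts <- count_unique_proteins(prot_df)

  # dN/dS between species' top-supported haplotypes per gene (all fragments
  # of a gene share the locus frame, so their CDSs are codon-aligned)
  dnds_rows <- list()
  for (g in names(loci)) {
    sub <- hap_df[hap_df$gene_id == g, , drop = FALSE]
    reps <- sub[!duplicated(sub$species_id), , drop = FALSE]  # top per species
    if (nrow(reps) < 2L) next
    for (i in seq_len(nrow(reps) - 1L)) {
      for (j in seq(i + 1L, nrow(reps))) {
        cds_i <- extract_cds(reps$rep_sequence[i], loci[[g]])
        cds_j <- extract_cds(reps$rep_sequence[j], loci[[g]])
        ng <- nei_gojobori(cds_i, cds_j)
        dnds_rows[[length(dnds_rows) + 1L]] <- data.frame(
          gene_id = g, id_a = reps$haplotype_id[i], id_b = reps$haplotype_id[j],
          Nd = ng$Nd, Sd = ng$Sd, N = ng$N, S = ng$S,
          pN = ng$pN, pS = ng$pS, dN = ng$dN, dS = ng$dS, dnds = ng$dnds,
          stringsAsFactors = FALSE)
      }
    }
  }
  dnds <- if (length(dnds_rows)) do.call(rbind, dnds_rows) else NULL
  selection <- if (!is.null(dnds)) classify_selection(dnds, config$ks_max)
               else NULL

  trees <- list()
  if (config$bootstrap_replicates > 0L) {
    for (g in names(loci)) {
      sub <- hap_df[hap_df$gene_id == g, , drop = FALSE]
      if (nrow(sub) < 3L) next
      prots <- vapply(sub$rep_sequence, function(x)
        sub("\\*$", "", translate_cds(extract_cds(x, loci[[g]]))),
        character(1), USE.NAMES = FALSE)
      names(prots) <- sub$haplotype_id
      # severely truncated variants (premature stop before half the modal
      # protein length) carry too few comparable residues for distances
      prots <- prots[nchar(prots) >= stats::median(nchar(prots)) / 2]
      if (length(prots) < 3L) next
      # stop-truncated variants are padded with gaps to a common length
      width <- max(nchar(prots))
      prots <- vapply(prots, function(p)
        paste0(p, strrep("-", width - nchar(p))), character(1))
      trees[[g]] <- bootstrap_support(
        prots, n_replicates = config$bootstrap_replicates,
        seed = derive_seed(config$seed, "bootstrap", g))
    }
  }

  truth_eval <- NULL
  if (simulated) {
    rows <- lapply(names(hap_tables), function(key) {
      ht <- hap_tables[[key]]
      g <- ht$gene_id[1]
      s <- ht$species_id[1]
      if (is.na(g)) {
        parts <- strsplit(key, ".", fixed = TRUE)[[1]]
        g <- parts[1]
        s <- parts[2]
      }
      ev <- evaluate_haplotype_recovery(ht, study$truth[[g]], s)
      true_snp <- study$truth[[g]]$species[[s]]$snps
      called <- calls_all[[key]]
      true_key <- paste(true_snp$pos,
                        paste(pmin(true_snp$ref_allele, true_snp$alt_allele),
                              pmax(true_snp$ref_allele, true_snp$alt_allele),
                              sep = "/"), sep = ":")
      call_key <- snp_identity(called)
      data.frame(gene_id = g, species_id = s,
                 n_true_snps = nrow(true_snp),
                 n_called_snps = nrow(called),
                 n_true_called = sum(true_key %in% call_key),
                 n_false_snps = sum(!call_key %in% true_key),
                 n_true_haplotypes = ev$n_true,
                 n_recovered_haplotypes = ev$n_recovered,
                 n_false_haplotypes = ev$n_false,
                 stringsAsFactors = FALSE)
    })
    truth_eval <- do.call(rbind, rows)
    rownames(truth_eval) <- NULL
  }

  structure(list(
    simulated = simulated,
    loci = loci,
    aligned = aligned,
    snp_calls = calls_df,
    snp_density = snp_density,
    snp_sharing = snp_sharing,
    haplotypes = hap_df,
    haplotype_tables = hap_tables,
    haplotype_counts = hap_counts,
    consensus = consensus,
    enrichment = enrichment,
    proteins = prot_df,
    protein_counts = prot_counts,
    dnds = dnds,
    selection = selection,
    trees = trees,
    truth_eval = truth_eval,
    log = log,
    published_audit = audit_published_tables(),
    config = config,
    version = as.character(utils::packageVersion("polyhap"))
  ), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("polyhap run report (v", x$version, ")\n", sep = "")
  cat("  SNP calls:", nrow(x$snp_calls), " haplotypes:", nrow(x$haplotypes),
      " protein variants:", nrow(x$proteins), "\n")
  cat(sprintf("  consensus frequency: %.1f%%\n",
              x$consensus$totals$consensus_frequency_percent))
  invisible(x)
}

cell_counts <- function(counts, lengths) {
  m <- counts
  for (j in seq_len(ncol(m))) {
    m[, j] <- sprintf("%s/%d", counts[, j], lengths[j])
  }
  m
}

#' Render a run report to TSV tables and a text summary
#'
#' Writes, under `dir`: the SNP summary (per-gene cells as `count/length`
#' with total and bp/SNP columns, separate within-species, union and
#' shared-SNP blocks), haplotype and protein count tables, the consensus
#' class table and statistic, the dN/dS table, per-gene Newick trees, the
#' per-stage log, the published-table discrepancy audit, and a
#' human-readable `report.txt`.
#'
#' @param report a `run_report`.
#' @param dir output directory.
#' @return character vector of written paths, invisibly.
#' @export
render_tables <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written <<- c(written, p)
    p
  }
  lengths <- vapply(report$loci, function(l) nchar(l$sequence), numeric(1))

  per_gene <- report$snp_density$per_gene
  snp_tab <- data.frame(row = rownames(per_gene),
                        cell_counts(per_gene, lengths),
                        total_snps = report$snp_density$summary$total_snps,
                        bp_per_snp = report$snp_density$summary$bp_per_snp,
                        check.names = FALSE, stringsAsFactors = FALSE)
  wr(snp_tab, "snp_summary.tsv")
  sh <- report$snp_sharing
  wr(data.frame(row = rownames(sh$union), cell_counts(sh$union, lengths),
                total_snps = sh$union_summary$total_snps,
                bp_per_snp = sh$union_summary$bp_per_snp,
                check.names = FALSE), "snp_union.tsv")
  wr(data.frame(row = rownames(sh$shared), cell_counts(sh$shared, lengths),
                total_snps = sh$shared_summary$total_snps,
                bp_per_snp = sh$shared_summary$bp_per_snp,
                check.names = FALSE), "snp_shared.tsv")
  write_snp_vcf(report$snp_calls, file.path(dir, "snp_calls.vcf"))
  written <- c(written, file.path(dir, "snp_calls.vcf"))

  hc <- report$haplotype_counts$counts
  wr(data.frame(row = rownames(hc), hc,
                total = report$haplotype_counts$totals, check.names = FALSE),
     "haplotype_counts.tsv")
  wr(report$haplotypes[, setdiff(names(report$haplotypes), "rep_sequence")],
     "haplotypes.tsv")
  wr(report$consensus$classes, "consensus_classes.tsv")
  pc <- report$protein_counts$counts
  wr(data.frame(row = rownames(pc), pc,
                total = report$protein_counts$totals, check.names = FALSE),
     "protein_counts.tsv")
  wr(report$proteins, "protein_variants.tsv")
  if (!is.null(report$dnds)) wr(report$selection$pairs, "dnds_pairs.tsv")
  wr(report$log, "stage_log.tsv")
  aud <- report$published_audit
  wr(aud$snp, "published_audit_snp.tsv")
  for (g in names(report$trees)) {
    p <- file.path(dir, sprintf("tree_%s.nwk", g))
    ape::write.tree(report$trees[[g]]$tree, p)
    written <- c(written, p)
  }

  txt <- file.path(dir, "report.txt")
  con <- file(txt, "w")
  writeLines(sprintf("polyhap v%s run report", report$version), con)
  writeLines(sprintf("consensus haplotype frequency: %.1f%% (%d/%d fragments), %d consensus classes",
                     report$consensus$totals$consensus_frequency_percent,
                     report$consensus$totals$n_fragments_in_consensus,
                     report$consensus$totals$n_fragments,
                     report$consensus$totals$n_consensus_classes), con)
  if (!is.null(report$enrichment)) {
    writeLines(sprintf("consensus support enrichment: t=%.3f, p=%.3g (means %.1f vs %.1f)",
                       report$enrichment$statistic, report$enrichment$p_value,
                       report$enrichment$mean_consensus,
                       report$enrichment$mean_other), con)
  }
  if (!is.null(report$selection)) {
    writeLines(sprintf("selection classes: %d pairs Ka>=Ks, %d Ka<Ks, %d Ks outliers excluded",
                       report$selection$n_ka_ge_ks, report$selection$n_ka_lt_ks,
                       report$selection$n_outliers), con)
  }
  flagged <- aud$snp[aud$snp$discrepant, ]
  if (nrow(flagged)) {
    writeLines("published-table rows whose printed total differs from the row sum:", con)
    writeLines(sprintf("  %s: printed %d, row sum %d", flagged$row,
                       flagged$printed_total, flagged$computed_total), con)
  }
  close(con)
  written <- c(written, txt)
  invisible(written)
}
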