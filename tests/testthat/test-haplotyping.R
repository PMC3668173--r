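two_snp_fixture <- function(vectors, ref_len = 30L) {
  # vectors: character vector of 2-letter allele combinations placed at
  # positions 5 and 20 of an otherwise constant reference
  ref <- strrep("A", ref_len)
  subs <- lapply(vectors, function(v) {
    s <- strsplit(v, "")[[1]]
    out <- character(0)
    if (s[1] != "A") out <- c(out, stats::setNames(s[1], "5"))
    if (s[2] != "A") out <- c(out, stats::setNames(s[2], "20"))
    out
  })
  clones <- clones_from_reference(ref, subs)
  alib <- suppressWarnings(build_aligned_library(clones, ref,
                                                 gene_id = "g",
                                                 species_id = "sp"))
  calls <- call_snps(alib, ref, min_support = 2L)
  list(alib = alib, calls = calls)
}

test_that("clones group into haplotypes by exact allele vector", {
  fx <- two_snp_fixture(c("AT", "AT", "AT", "GC", "GC", "GC"))
  haps <- infer_haplotypes(fx$alib, fx$calls)
  expect_equal(nrow(haps), 2L)
  expect_setequal(haps$allele_vector, c("AT", "GC"))
  expect_equal(haps$clone_support, c(3L, 3L))
})

test_that("under-supported haplotypes are discarded and logged", {
  # both columns are SNPs (allele support >= 2) but the GC combination is
  # seen in a single clone only
  fx <- two_snp_fixture(c(rep("AT", 3), rep("GT", 2), rep("AC", 2), "GC"))
  haps <- infer_haplotypes(fx$alib, fx$calls, min_haplotype_support = 2L)
  expect_equal(nrow(haps), 3L)
  expect_setequal(haps$allele_vector, c("AT", "GT", "AC"))
  disc <- attr(haps, "discarded")
  expect_equal(disc$allele_vector, "GC")
  expect_equal(disc$clone_support, 1L)
})

test_that("zero SNPs yield a single monomorphic haplotype holding every clone", {
  ref <- strrep("C", 25)
  clones <- clones_from_reference(ref, rep(list(character(0)), 6))
  alib <- build_aligned_library(clones, ref, gene_id = "g", species_id = "sp")
  calls <- call_snps(alib, ref)
  expect_equal(nrow(calls), 0L)
  haps <- infer_haplotypes(alib, calls)
  expect_equal(nrow(haps), 1L)
  expect_equal(haps$clone_support, 6L)
  expect_equal(haps$allele_vector, "")
  expect_identical(haps$rep_sequence, ref)
})

test_that("clones with N at a SNP position are excluded from haplotyping", {
  fx <- two_snp_fixture(c("AT", "AT", "AT", "GT", "GT", "GT", "NT"))
  haps <- infer_haplotypes(fx$alib, fx$calls)
  expect_equal(nrow(haps), 2L)
  expect_length(attr(haps, "excluded_clones"), 1L)
  # partition: retained + discarded + excluded = aligned clones
  expect_equal(sum(haps$clone_support) +
                 sum(attr(haps, "discarded")$clone_support) +
                 length(attr(haps, "excluded_clones")),
               nrow(fx$alib$matrix))
})

test_that("haplotypes are ordered by support then allele vector", {
  fx <- two_snp_fixture(c(rep("GT", 4), rep("AT", 2), rep("AC", 2)))
  haps <- infer_haplotypes(fx$alib, fx$calls)
  expect_equal(haps$allele_vector, c("GT", "AC", "AT"))
  expect_equal(haps$clone_support, c(4L, 2L, 2L))
})

test_that("noiseless simulation recovers the true haplotype set exactly", {
  for (seed in c(4L, 12L)) {
    cfg <- quiet_config(seed)
    truth <- simulate_species_haplotypes(simulate_locus(cfg, "g1"), cfg)
    for (s in cfg$species) {
      res <- run_library(truth, s, cfg)
      ev <- evaluate_haplotype_recovery(res$haplotypes, truth, s)
      expect_equal(ev$recall_percent, 100)
      expect_equal(ev$n_false, 0L)
      # allele vectors at called positions match truth exactly
      pos <- attr(res$haplotypes, "snp_positions")
      true_vec <- unique(vapply(truth$species[[s]]$haplotypes, function(h)
        paste0(strsplit(h, "")[[1]][pos], collapse = ""), character(1),
        USE.NAMES = FALSE))
      expect_setequal(res$haplotypes$allele_vector, true_vec)
    }
  }
})

test_that("haplotype counts never exceed clones or combinatorial bounds", {
  cfg <- quiet_config(77L, error = 0.002, chimera = 0.1)
  truth <- simulate_species_haplotypes(simulate_locus(cfg, "g1"), cfg)
  res <- run_library(truth, "Ss", cfg)
  n_snp <- length(attr(res$haplotypes, "snp_positions"))
  expect_lte(nrow(res$haplotypes),
             min(nrow(res$aligned$matrix), 4^n_snp))
})

test_that("noisy libraries still recover haplotypes with few false positives", {
  stats <- t(vapply(1:30, function(seed) {
    cfg <- quiet_config(seed, error = 0.001, chimera = 0.05)
    truth <- simulate_species_haplotypes(simulate_locus(cfg, "g1"), cfg)
    res <- run_library(truth, "So", cfg)
    ev <- evaluate_haplotype_recovery(res$haplotypes, truth, "So")
    c(recall = ev$recall_percent, false = ev$n_false)
  }, numeric(2)))
  expect_gte(median(stats[, "recall"]), 90)
  expect_lte(median(stats[, "false"]), 1)
})

test_that("haplotype count tables aggregate to the published totals", {
  counts <- rbind(So = c(4, 6, 8, 6, 3),
                  Sr = c(6, 5, 8, 8, 8),
                  Ss = c(8, 7, 8, 5, 4))
  df <- do.call(rbind, lapply(rownames(counts), function(sp)
    do.call(rbind, lapply(seq_len(ncol(counts)), function(g)
      if (counts[sp, g] > 0) data.frame(
        gene_id = paste0("SuSy", g), species_id = sp,
        haplotype_id = sprintf("%s_%d_%d", sp, g, seq_len(counts[sp, g])))
      else NULL))))
  hs <- summarize_haplotype_counts(df)
  expect_equal(unname(hs$totals[c("So", "Sr", "Ss")]), c(27L, 35L, 32L))
  # 94 haplotype observations across species; the published per-gene totals
  # (15/15/16/17/11, summing to 74) instead count haplotypes deduplicated
  # across species, which the consensus-class report provides
  expect_equal(sum(hs$totals), 94L)
  expect_equal(unname(hs$per_gene_totals), c(18L, 18L, 24L, 19L, 15L))
})

test_that("consensus classes require identity at union SNP coordinates", {
  # two species, one gene; species y's second haplotype differs at pos 5
  mk_tab <- function(sp, vectors, seqs, support) {
    structure(data.frame(
      gene_id = "g", species_id = sp,
      haplotype_id = sprintf("g_%s_h%02d", sp, seq_along(vectors)),
      allele_vector = vectors, clone_support = support,
      clone_ids = "", rep_sequence = seqs, stringsAsFactors = FALSE),
      class = c("haplotype_table", "data.frame"))
  }
  base <- strrep("A", 10)
  alt5 <- sub("^(.{4})A", "\\1G", base)
  tabs <- list(
    mk_tab("x", c("A", "G"), c(base, alt5), c(6L, 2L)),
    mk_tab("y", c("A", "G"), c(base, alt5), c(5L, 3L)))
  rep1 <- find_consensus_haplotypes(tabs, list(g = 5L))
  expect_equal(nrow(rep1$classes), 2L)
  expect_true(all(rep1$classes$consensus))
  expect_equal(rep1$totals$consensus_frequency_percent, 100)

  # make species y's sequences unique outside the union set: still consensus
  tabs2 <- tabs
  tabs2[[2]]$rep_sequence <- sub("A$", "T", tabs2[[2]]$rep_sequence)
  rep2 <- find_consensus_haplotypes(tabs2, list(g = 5L))
  expect_true(all(rep2$classes$consensus))
  # ... but including position 10 in the union set splits the classes
  rep3 <- find_consensus_haplotypes(tabs2, list(g = c(5L, 10L)))
  expect_false(any(rep3$classes$consensus))
  expect_equal(rep3$totals$consensus_frequency_percent, 0)
})

test_that("the published consensus fraction arises from its printed inputs", {
  pub <- load_published_counts()
  freq <- consensus_frequency(pub$consensus[["n_fragments_in_consensus"]],
                              pub$consensus[["n_fragments_total"]])
  expect_equal(round(freq, 1), 53.1)
})

test_that("consensus enrichment test matches closed-form Welch and handles degeneracy", {
  # identical groups: t = 0, p = 1
  res <- test_consensus_enrichment(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  # zero variance, distinct means: infinitely strong evidence
  res <- test_consensus_enrichment(c(10, 10, 10), c(1, 1, 1))
  expect_true(is.infinite(res$statistic))
  expect_lt(res$p_value, 0.05)
  # non-degenerate inputs match the closed-form Welch statistic
  set.seed(5)
  for (i in 1:10) {
    x <- rpois(sample(3:12, 1), 20)
    y <- rpois(sample(3:12, 1), 5)
    got <- test_consensus_enrichment(x, y)
    want <- oracle_welch(x, y)
    expect_equal(got$statistic, want$statistic, tolerance = 1e-10)
    expect_equal(got$df, want$df, tolerance = 1e-10)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-10)
  }
  expect_error(test_consensus_enrichment(1, c(1, 2)), "at least two")
})

test_that("simulated consensus haplotypes carry higher clone support on average", {
  hits <- vapply(1:20, function(seed) {
    cfg <- simulation_config(genes = paste0("g", 1:3),
                             fragment_lengths = c(489L, 484L, 569L),
                             clones_range = c(40L, 40L), seed = seed)
    report <- suppressWarnings(run_pipeline(pipeline_config(
      sim_config = cfg, bootstrap_replicates = 0L, seed = seed)))
    cons_ids <- unlist(strsplit(
      report$consensus$classes$haplotype_ids[report$consensus$classes$consensus],
      ","))
    in_cons <- report$haplotypes$haplotype_id %in% cons_ids
    if (!any(in_cons) || all(in_cons)) return(NA)
    mean(report$haplotypes$clone_support[in_cons]) >
      mean(report$haplotypes$clone_support[!in_cons])
  }, logical(1))
  expect_gte(mean(hits, na.rm = TRUE), 0.9)
})
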