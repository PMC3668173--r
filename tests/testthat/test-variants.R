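toy_library <- function(clones, reference) {
  # toy fragments are short, so a couple of substitutions already depress
  # identity; relax the retention threshold accordingly
  suppressWarnings(build_aligned_library(clones, reference,
                                         min_identity = 0.7,
                                         species_id = "sp"))
}

test_that("clone-support threshold governs SNP calling", {
  ref <- strrep("A", 20)
  # column 10: A x4 vs T x2 -> below min_support 3 for T, no SNP
  clones <- clones_from_reference(ref, list(
    character(0), character(0), character(0), character(0),
    c("10" = "T"), c("10" = "T")))
  calls <- call_snps(toy_library(clones, ref), ref, min_support = 3L)
  expect_equal(nrow(calls), 0L)

  # column 10: A x3 vs T x3 -> SNP with supports 3/3
  clones <- clones_from_reference(ref, list(
    character(0), character(0), character(0),
    c("10" = "T"), c("10" = "T"), c("10" = "T")))
  calls <- call_snps(toy_library(clones, ref), ref, min_support = 3L)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$pos, 10L)
  expect_equal(calls$alleles, "A/T")
  expect_equal(calls$supports, "3/3")

  # the same column qualifies at min_support 2 even with supports 4/2
  clones <- clones_from_reference(ref, list(
    character(0), character(0), character(0), character(0),
    c("10" = "T"), c("10" = "T")))
  calls <- call_snps(toy_library(clones, ref), ref, min_support = 2L)
  expect_equal(nrow(calls), 1L)
  expect_error(call_snps(toy_library(clones, ref), ref, min_support = 1L),
               ">= 2")
})

test_that("multi-allelic columns are reported as one site and N never supports", {
  ref <- strrep("G", 12)
  clones <- clones_from_reference(ref, list(
    character(0), character(0), character(0),
    c("6" = "A"), c("6" = "A"), c("6" = "A"),
    c("6" = "T"), c("6" = "T"), c("6" = "T"),
    c("6" = "N"), c("6" = "N"), c("6" = "N")))
  calls <- call_snps(toy_library(clones, ref), ref, min_support = 3L)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$alleles, "A/G/T")  # N absent despite 3 copies
  expect_equal(calls$n_ignored, 3L)
})

test_that("support conservation holds at every called column", {
  cfg <- quiet_config(21L, error = 0.002, chimera = 0.05)
  truth <- simulate_species_haplotypes(simulate_locus(cfg, "g1"), cfg)
  res <- run_library(truth, "So", cfg)
  expect_gt(nrow(res$calls), 0L)
  for (i in seq_len(nrow(res$calls))) {
    col <- res$aligned$matrix[, res$calls$pos[i]]
    qualifying <- sum(as.integer(strsplit(res$calls$supports[i], "/")[[1]]))
    below_threshold <- sum(col %in% c("A", "C", "G", "T")) - qualifying
    expect_gte(below_threshold, 0)
    expect_equal(res$calls$n_ignored[i], sum(!col %in% c("A", "C", "G", "T")))
    expect_equal(qualifying + below_threshold + res$calls$n_ignored[i],
                 nrow(res$aligned$matrix))
  }
})

test_that("raising min_support never increases the number of calls", {
  cfg <- quiet_config(33L, error = 0.01, chimera = 0.1)
  truth <- simulate_species_haplotypes(simulate_locus(cfg, "g1"), cfg)
  lib <- simulate_clone_library(truth, "Sr", cfg)
  alib <- suppressWarnings(build_aligned_library(lib$sequences, truth$locus,
                                                 species_id = "Sr"))
  n_prev <- Inf
  for (ms in 2:6) {
    n <- nrow(call_snps(alib, truth$locus, min_support = ms))
    expect_lte(n, n_prev)
    n_prev <- n
  }
})

test_that("noiseless simulations recover the true SNP set exactly", {
  for (seed in c(2L, 9L, 17L)) {
    cfg <- quiet_config(seed)
    truth <- simulate_species_haplotypes(simulate_locus(cfg, "g1"), cfg)
    for (s in cfg$species) {
      res <- run_library(truth, s, cfg)
      expect_setequal(called_snp_keys(res$calls), true_snp_keys(truth, s))
    }
  }
})

test_that("SNP calls carry exon/intron labels from the locus annotation", {
  loc <- toy_locus()
  ref <- loc$sequence
  clones <- clones_from_reference(ref, c(
    rep(list(character(0)), 3),
    rep(list(c("3" = "C", "9" = "A")), 3)))
  calls <- call_snps(toy_library(clones, loc), loc, min_support = 3L)
  expect_equal(calls$region[calls$pos == 3], "exon")
  expect_equal(calls$region[calls$pos == 9], "intron")
})

test_that("bp/SNP aggregation reproduces the published arithmetic", {
  lengths <- c(489, 484, 569, 470, 577)
  counts <- rbind(so = c(4, 4, 7, 7, 2),
                  ss = c(11, 6, 7, 9, 3),
                  none = c(0, 0, 0, 0, 0))
  tab <- snp_density_table(counts, lengths)
  expect_equal(tab$total_bp, rep(2589L, 3))
  expect_equal(tab$total_snps, c(24L, 36L, 0L))
  expect_equal(tab$bp_per_snp, c(108, 72, NA))
  expect_error(snp_density_table(counts[, 1:4], lengths), "differ")
})

test_that("round_half_up rounds .5 upward, unlike banker's rounding", {
  expect_equal(round_half_up(c(107.875, 80.9, 0.5, 1.5, 2.4)),
               c(108, 81, 1, 2, 2))
})

test_that("shared SNPs require identical position and allele pair", {
  a <- data.frame(gene_id = "g", species_id = "x", pos = 77L,
                  region = NA, ref_allele = "A", alleles = "A/T",
                  supports = "5/5", alt_alleles = "T", n_ignored = 0L)
  b <- a
  b$species_id <- "y"
  expect_equal(nrow(shared_snps(a, b)), 1L)
  b2 <- b
  b2$alleles <- "A/G"
  expect_equal(nrow(shared_snps(a, b2)), 0L)
  b3 <- b
  b3$gene_id <- "other"
  expect_error(shared_snps(a, b3), "different genes")
})

test_that("union of SNP identities deduplicates across species", {
  mk <- function(sp, pos, alleles) data.frame(
    gene_id = "g", species_id = sp, pos = pos, region = NA,
    ref_allele = substr(alleles, 1, 1), alleles = alleles,
    supports = "3/3", alt_alleles = substr(alleles, 3, 3), n_ignored = 0L)
  a <- mk("x", 1:4, rep("A/T", 4))
  b <- mk("y", 11:17, rep("C/G", 7))
  expect_equal(nrow(union_snps(list(a, b))), 11L)    # disjoint: 4 + 7
  expect_equal(nrow(union_snps(list(a, a[1:2, ]))), 4L)  # subset: |B|
})

test_that("per-gene sharing summary matches hand-computed intersections", {
  cfg <- quiet_config(13L)
  truth <- simulate_species_haplotypes(simulate_locus(cfg, "g1"), cfg)
  calls <- do.call(rbind, lapply(cfg$species, function(s)
    run_library(truth, s, cfg)$calls))
  sharing <- summarize_snp_sharing(calls, list(g1 = truth$locus))
  keys <- lapply(cfg$species, function(s)
    called_snp_keys(calls[calls$species_id == s, ]))
  expect_equal(unname(sharing$shared["So+Sr", "g1"]),
               length(intersect(keys[[1]], keys[[2]])))
  expect_equal(unname(sharing$union["So+Sr+Ss", "g1"]),
               length(unique(unlist(keys))))
})

test_that("published tables are audited, not silently reproduced", {
  audit <- audit_published_tables()
  snp <- audit$snp
  # self-consistent rows
  so <- snp[snp$row == "S.officinarum", ]
  expect_false(so$discrepant)
  expect_equal(so$bp_per_snp_from_rowsum, 108)
  expect_equal(snp$bp_per_snp_from_rowsum[snp$row == "S.robustum"], 81)
  # the printed S. spontaneum total (38) conflicts with its row sum (36)
  ss <- snp[snp$row == "S.spontaneum", ]
  expect_true(ss$discrepant)
  expect_equal(ss$computed_total, 36L)
  expect_equal(ss$bp_per_snp_from_rowsum, 72)
  # the printed three-species union (51) conflicts with its row sum (68)
  u3 <- snp[snp$row == "S.o+S.r+S.s", ]
  expect_true(u3$discrepant)
  expect_equal(u3$computed_total, 68L)
  expect_equal(u3$bp_per_snp_from_rowsum, 38)
  # two-species union rows are self-consistent: 42/53/58 -> 62/49/45
  u2 <- snp[snp$row %in% c("S.o+S.r", "S.o+S.s", "S.r+S.s"), ]
  expect_false(any(u2$discrepant))
  expect_equal(u2$bp_per_snp_from_rowsum, c(62, 49, 45))
  # shared-SNP totals 15/7/11 are self-consistent
  sh <- snp[snp$block == "shared", ]
  expect_equal(sh$computed_total[1:3], c(15L, 7L, 11L))
  expect_false(any(sh$discrepant))
})

test_that("SNP calls round-trip through the minimal VCF writer", {
  loc <- toy_locus()
  ref <- loc$sequence
  clones <- clones_from_reference(ref, c(
    rep(list(character(0)), 3), rep(list(c("9" = "A")), 3)))
  calls <- call_snps(toy_library(clones, loc), loc)
  path <- tempfile(fileext = ".vcf")
  write_snp_vcf(calls, path)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  expect_length(body, 1L)
  fields <- strsplit(body, "\t")[[1]]
  expect_equal(fields[1], "toy")
  expect_equal(as.integer(fields[2]), 9L)
  expect_equal(fields[4], substr(ref, 9, 9))
  expect_equal(fields[5], "A")
  expect_match(fields[8], "REGION=intron")
  unlink(path)
})
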