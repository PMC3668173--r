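test_that("back-translation replaces residues by source codons and propagates gaps", {
  aln <- back_translate(c(x = "MF", y = "MF"),
                        c(x = "ATGTTT", y = "ATGTTC"))
  expect_equal(dim(aln), c(2L, 2L))
  expect_equal(unname(aln["x", ]), c("ATG", "TTT"))
  expect_equal(unname(aln["y", ]), c("ATG", "TTC"))

  aln <- back_translate(c(x = "MF-", y = "MFK"),
                        c(x = "ATGTTT", y = "ATGTTTAAA"))
  expect_equal(unname(aln["x", 3]), "---")
  expect_equal(unname(aln["y", 3]), "AAA")

  expect_error(back_translate(c(x = "MF"), c(x = "ATGCTT")), "mismatch")
  expect_error(back_translate(c(x = "MF"), c(x = "ATGTTTAAA")), "longer")
  # a trailing stop codon on the CDS is tolerated
  expect_silent(back_translate(c(x = "MF"), c(x = "ATGTTTTAA")))
})

test_that("back-translation round-trips through translation", {
  set.seed(23)
  for (i in 1:25) {
    codons <- random_sense_codons(sample(3:15, 1))
    cds <- paste0(codons, collapse = "")
    prot <- translate_cds(cds)
    aln <- back_translate(stats::setNames(prot, "s"),
                          stats::setNames(cds, "s"))
    expect_equal(paste0(aln["s", ], collapse = ""), cds)
    expect_equal(translate_cds(paste0(aln["s", ], collapse = "")), prot)
  }
})

test_that("NG86 reproduces the hand-enumerated two-codon example", {
  ng <- nei_gojobori("ATGATG", "ATGATA")
  expect_equal(ng$Nd, 1)
  expect_equal(ng$Sd, 0)
  expect_equal(ng$S, 1 / 3)
  expect_equal(ng$N, 17 / 3)
  expect_equal(ng$pN, 3 / 17)
  expect_equal(ng$dN, -0.75 * log(1 - 4 / 3 * 3 / 17))
  expect_equal(ng$dS, 0)
})

test_that("NG86 limits: identical pairs and pure synonymous divergence", {
  cds <- paste0(random_sense_codons(20), collapse = "")
  ng <- nei_gojobori(cds, cds)
  expect_equal(ng$Nd + ng$Sd, 0)
  expect_equal(ng$dN, 0)
  expect_equal(ng$dS, 0)

  # one synonymous third-position change in 20 codons (CTT -> CTC, both Leu)
  a <- paste0(c("CTT", random_sense_codons(19)), collapse = "")
  b <- paste0(c("CTC", substring(a, 4, 60)), collapse = "")
  ng <- nei_gojobori(a, b)
  expect_equal(ng$dN, 0)
  expect_gt(ng$dS, 0)
})

test_that("NG86 equals the independent enumeration oracle on short pairs", {
  set.seed(41)
  for (i in 1:40) {
    n <- sample(1:3, 1)
    a <- random_sense_codons(n)
    b <- random_sense_codons(n)
    got <- nei_gojobori(a, b)
    want <- oracle_ng86(a, b)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-12, info = paste(a, b, collapse = " "))
    expect_equal(got$Sd, want$Sd, tolerance = 1e-12)
    expect_equal(got$N, want$N, tolerance = 1e-12)
    expect_equal(got$S, want$S, tolerance = 1e-12)
    expect_equal(got$dN, want$dN, tolerance = 1e-12)
    expect_equal(got$dS, want$dS, tolerance = 1e-12)
  }
})

test_that("NG86 is symmetric and conserves N + S = 3 x codons", {
  set.seed(59)
  for (i in 1:20) {
    n <- sample(2:30, 1)
    a <- random_sense_codons(n)
    b <- random_sense_codons(n)
    ab <- nei_gojobori(a, b)
    ba <- nei_gojobori(b, a)
    expect_equal(ab$N + ab$S, 3 * ab$n_codons, tolerance = 1e-9)
    expect_equal(ab[c("Nd", "Sd", "N", "S", "dN", "dS")],
                 ba[c("Nd", "Sd", "N", "S", "dN", "dS")], tolerance = 1e-12)
  }
})

test_that("gap, N, and stop codon columns are masked pairwise", {
  ng <- nei_gojobori(c("ATG", "---", "AAA"), c("ATG", "AAA", "AAA"))
  expect_equal(ng$n_codons, 2L)
  ng <- nei_gojobori(c("ATG", "ANA"), c("ATG", "AAA"))
  expect_equal(ng$n_codons, 1L)
  expect_error(nei_gojobori("---", "ATG"), "no unmasked")
})

test_that("directional simulations recover pure-dN and pure-dS signals", {
  set.seed(67)
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  code <- Biostrings::GENETIC_CODE
  # synonymous-only divergence: swap codons within a synonym class, changing
  # only the third position so every mutational path is silent
  a <- random_sense_codons(30)
  b <- vapply(a, function(cd) {
    syn <- sense[code[sense] == code[cd] &
                   substr(sense, 1, 2) == substr(cd, 1, 2)]
    syn[sample.int(length(syn), 1)]
  }, character(1), USE.NAMES = FALSE)
  ng <- nei_gojobori(a, b)
  expect_equal(ng$Nd, 0)
  expect_equal(ng$dN, 0)
})

test_that("selection classification flags Ks outliers and partitions the rest", {
  pairs <- data.frame(dN = c(0.2, 0.01, 0.5, 0.1),
                      dS = c(0.1, 0.30, NA, 4.0))
  cls <- classify_selection(pairs, ks_max = 3.0)
  expect_equal(cls$n_ka_ge_ks, 1L)
  expect_equal(cls$n_ka_lt_ks, 1L)
  expect_equal(cls$n_outliers, 2L)
  expect_true(all(cls$pairs$ks_outlier[3:4]))
})

test_that("protein distances follow p-distance and Poisson correction", {
  D <- protein_distance_matrix(c(a = "MFK", b = "MFK"))
  expect_equal(unname(D["a", "b"]), 0)
  D <- protein_distance_matrix(c(a = "MFK", b = "MFR"))
  expect_equal(unname(D["a", "b"]), 1 / 3)
  Dp <- protein_distance_matrix(c(a = "MFK", b = "MFR"), method = "poisson")
  expect_equal(unname(Dp["a", "b"]), -log(1 - 1 / 3), tolerance = 1e-4)
  expect_equal(round(unname(Dp["a", "b"]), 4), 0.4055)
  # gapped columns are ignored pairwise
  D <- protein_distance_matrix(c(a = "MF-", b = "MFK"))
  expect_equal(unname(D["a", "b"]), 0)
})

test_that("neighbor joining recovers the four-taxon additive example exactly", {
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tree <- neighbor_joining(D)
  expect_s3_class(tree, "phylo")
  # the generating tree ((A:1,B:2):1,(C:3,D:4)) is recovered as a metric
  expect_equal(as.matrix(stats::cophenetic(tree))[rownames(D), colnames(D)],
               D, tolerance = 1e-9)
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "3 taxa")
  bad <- D
  bad[1, 2] <- 99
  expect_error(neighbor_joining(bad), "symmetric")
})

test_that("neighbor joining solves the three-taxon closed form", {
  D <- matrix(c(0, 2, 4,
                2, 0, 4,
                4, 4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- neighbor_joining(D)
  d <- as.matrix(stats::cophenetic(tree))[rownames(D), colnames(D)]
  expect_equal(d, D, tolerance = 1e-9)
})

test_that("random additive metrics are recovered exactly for n <= 8", {
  skip_if_not_installed("phangorn")
  set.seed(73)
  for (i in 1:15) {
    n <- sample(4:8, 1)
    gen <- ape::rtree(n, br = function(k) stats::runif(k, 0.1, 2))
    D <- stats::cophenetic(gen)
    tree <- neighbor_joining(D)
    expect_equal(phangorn::RF.dist(ape::unroot(gen), tree), 0)
    expect_equal(as.matrix(stats::cophenetic(tree))[rownames(D), colnames(D)],
                 D, tolerance = 1e-8)
  }
})

test_that("bootstrap supports are deterministic and bounded by design", {
  seqs <- c(a = "MMMMKKKKFF", b = "MMMMKKKKFL", c = "WWWWRRRRFF",
            d = "WWWWRRRRFL")
  one <- bootstrap_support(seqs, n_replicates = 1L, seed = 5L)
  expect_true(all(one$support$percent %in% c(0, 100)))

  b1 <- bootstrap_support(seqs, n_replicates = 50L, seed = 9L)
  b2 <- bootstrap_support(seqs, n_replicates = 50L, seed = 9L)
  expect_identical(b1$support, b2$support)
  b3 <- bootstrap_support(seqs, n_replicates = 50L, seed = 10L)
  expect_false(identical(attr(b1, "replicate_columns"),
                         attr(b3, "replicate_columns")))

  # two clades separated by many fixed differences: maximal support
  sep <- bootstrap_support(seqs, n_replicates = 100L, seed = 11L)
  key <- paste(sort(c("a", "b")), collapse = "|")
  split_row <- sep$support[sep$support$bipartition %in%
                             c(key, paste(sort(c("c", "d")), collapse = "|")), ]
  expect_gte(max(split_row$percent), 95)
  expect_equal(nrow(attr(sep, "replicate_columns")), 100L)
})
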