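# Small reusable fixtures, built in code.

# A minimal two-exon locus with known reference, for hand-constructed tests.
toy_locus <- function() {
  # exon 1-6 | intron 7-12 | exon 13-18; CDS = ATGAAA GGGTTT -> "MKGF"
  locus_model("toy", "ATGAAATTTTTTGGGTTT",
              data.frame(start = c(1L, 7L, 13L),
                         end = c(6L, 12L, 18L),
                         label = c("exon", "intron", "exon")),
              frame_offset = 0L)
}

# Clone set derived from a reference by named substitutions:
# subs is a list of integer-named character vectors, one per clone.
clones_from_reference <- function(reference, subs, ids = NULL) {
  out <- vapply(subs, function(s) {
    b <- strsplit(reference, "")[[1]]
    if (length(s)) b[as.integer(names(s))] <- s
    paste0(b, collapse = "")
  }, character(1))
  names(out) <- if (is.null(ids)) sprintf("c%02d", seq_along(out)) else ids
  out
}

# A low-noise, single-gene configuration used by recovery tests.
quiet_config <- function(seed, error = 0, chimera = 0, n_hap = c(3L, 8L)) {
  simulation_config(
    genes = "g1", fragment_lengths = 489L,
    n_haplotypes_range = n_hap,
    clones_range = c(100L, 100L),
    per_base_error_rate = error,
    chimera_rate = chimera,
    seed = seed
  )
}

# Run one gene x species through align -> call -> haplotype.
run_library <- function(truth, species, config, min_support = 3L,
                        min_hap_support = 2L) {
  lib <- simulate_clone_library(truth, species, config)
  alib <- suppressWarnings(build_aligned_library(
    lib$sequences, truth$locus, species_id = species))
  calls <- call_snps(alib, truth$locus, min_support = min_support)
  haps <- infer_haplotypes(alib, calls,
                           min_haplotype_support = min_hap_support)
  list(library = lib, aligned = alib, calls = calls, haplotypes = haps)
}

true_snp_keys <- function(truth, species) {
  df <- truth$species[[species]]$snps
  paste(df$pos, paste(pmin(df$ref_allele, df$alt_allele),
                      pmax(df$ref_allele, df$alt_allele), sep = "/"),
        sep = ":")
}

called_snp_keys <- function(calls) {
  paste(calls$pos, calls$alleles, sep = ":")
}
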