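#' Simulation configuration for octoploid amplicon clone libraries
#'
#' Defines the study conditions emulated by the simulator: five gene
#' fragments surveyed across three octoploid *Saccharum*-like species related
#' as `((A, B), C)` -- A standing for the *S. officinarum* analog, B for
#' *S. robustum*, C for *S. spontaneum*. Defaults reproduce the published
#' study design: fragment lengths 489/484/569/470/577 bp (2589 bp total),
#' 70--119 clones sequenced per gene per species, 3--8 haplotypes drawn from
#' 8 homologous chromosomes, within-species SNP densities of 24/2589,
#' 32/2589 and 36/2589 per bp, and cross-species shared polymorphism
#' densities calibrated to the published shared-SNP counts (6 sites shared by
#' all three species, 9 extra shared by A and B, 1 by A and C, 5 by B and C,
#' per 2589 bp).
#'
#' @param genes character vector of gene identifiers.
#' @param fragment_lengths integer vector of fragment lengths (bp), one per
#'   gene.
#' @param species character vector of exactly three species identifiers,
#'   ordered `(A, B, C)` with C the early-diverging species.
#' @param intron_fraction fraction of each fragment occupied by the central
#'   intron (each fragment is laid out exon--intron--exon).
#' @param n_haplotypes_range integer range `[lo, hi]` for the number of true
#'   haplotypes per gene per species; `hi` cannot exceed `n_chromosomes`.
#' @param n_chromosomes number of homologous chromosomes (8 for octoploids).
#' @param clones_range integer range for the number of clones sequenced per
#'   gene per species.
#' @param within_species_snp_density expected segregating sites per bp for
#'   each species (length-3 numeric, ordered as `species`).
#' @param shared_snp_density named numeric with elements `ab`, `ac`, `bc`,
#'   `abc`: expected per-bp density of sites polymorphic jointly in the given
#'   species subsets (each in addition to the others). For every species the
#'   sum of the shared densities involving it must not exceed its
#'   within-species density.
#' @param divergence_rate per-bp, per-branch-unit rate of fixed substitutions
#'   between species. Branch units: A and B sit one unit from their common
#'   ancestor, which sits one unit from the root; C sits two units from the
#'   root, so the C lineage carries roughly twice the A/B split depth.
#' @param per_base_error_rate per-base PCR/sequencing substitution error
#'   probability applied independently to every clone base.
#' @param chimera_rate probability that a clone is a PCR template-switching
#'   chimera (a single switch at a uniform internal breakpoint).
#' @param ancestral_weight Dirichlet concentration weight of the ancestral
#'   haplotype relative to weight 1 for each derived haplotype, when
#'   multiplicities over the 8 chromosomes are drawn; values above 1 make
#'   the ancestral (consensus-forming) haplotype more frequent, as observed
#'   for consensus haplotypes in the study system.
#' @param seed integer top-level seed; every stream used by the simulator is
#'   derived from it.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(genes = paste0("SuSy", 1:5),
                              fragment_lengths = c(489L, 484L, 569L, 470L, 577L),
                              species = c("So", "Sr", "Ss"),
                              intron_fraction = 0.4,
                              n_haplotypes_range = c(3L, 8L),
                              n_chromosomes = 8L,
                              clones_range = c(70L, 119L),
                              within_species_snp_density = c(24, 32, 36) / 2589,
                              shared_snp_density = c(ab = 9, ac = 1, bc = 5, abc = 6) / 2589,
                              divergence_rate = 6e-4,
                              per_base_error_rate = 0.001,
                              chimera_rate = 0.05,
                              ancestral_weight = 4,
                              seed = 1L) {
  if (length(genes) < 1L || anyDuplicated(genes)) {
    stop("`genes` must be a non-empty vector of unique identifiers", call. = FALSE)
  }
  if (length(fragment_lengths) != length(genes) || any(fragment_lengths <= 0)) {
    stop("`fragment_lengths` must be positive, one per gene", call. = FALSE)
  }
  if (length(species) != 3L || anyDuplicated(species)) {
    stop("`species` must name exactly three distinct species (A, B, C)", call. = FALSE)
  }
  stopifnot_scalar_prob(intron_fraction, "intron_fraction")
  stopifnot_scalar_prob(per_base_error_rate, "per_base_error_rate")
  stopifnot_scalar_prob(chimera_rate, "chimera_rate")
  if (length(n_haplotypes_range) != 2L || n_haplotypes_range[1] < 1L ||
      n_haplotypes_range[2] < n_haplotypes_range[1] ||
      n_haplotypes_range[2] > n_chromosomes) {
    stop("`n_haplotypes_range` must be within [1, n_chromosomes]", call. = FALSE)
  }
  if (length(clones_range) != 2L || clones_range[1] < 1L ||
      clones_range[2] < clones_range[1]) {
    stop("`clones_range` must be a valid positive range", call. = FALSE)
  }
  if (length(within_species_snp_density) != 3L ||
      any(within_species_snp_density < 0) || any(within_species_snp_density > 1)) {
    stop("`within_species_snp_density` must be three per-bp rates in [0, 1]",
         call. = FALSE)
  }
  need <- c("ab", "ac", "bc", "abc")
  if (!all(need %in% names(shared_snp_density)) ||
      any(shared_snp_density < 0) || any(shared_snp_density > 1)) {
    stop("`shared_snp_density` must be named rates ab, ac, bc, abc in [0, 1]",
         call. = FALSE)
  }
  shared_snp_density <- shared_snp_density[need]
  shared_per_species <- c(
    sum(shared_snp_density[c("ab", "ac", "abc")]),
    sum(shared_snp_density[c("ab", "bc", "abc")]),
    sum(shared_snp_density[c("ac", "bc", "abc")])
  )
  if (any(shared_per_species > within_species_snp_density + 1e-12)) {
    stop("shared SNP densities exceed a species' within-species density",
         call. = FALSE)
  }
  if (!is.numeric(divergence_rate) || divergence_rate < 0) {
    stop("`divergence_rate` must be non-negative", call. = FALSE)
  }
  if (!is.numeric(ancestral_weight) || ancestral_weight <= 0) {
    stop("`ancestral_weight` must be positive", call. = FALSE)
  }
  structure(list(
    genes = as.character(genes),
    fragment_lengths = as.integer(fragment_lengths),
    species = as.character(species),
    intron_fraction = intron_fraction,
    n_haplotypes_range = as.integer(n_haplotypes_range),
    n_chromosomes = as.integer(n_chromosomes),
    clones_range = as.integer(clones_range),
    within_species_snp_density = as.numeric(within_species_snp_density),
    shared_snp_density = as.numeric(shared_snp_density[need]) |>
      stats::setNames(need),
    divergence_rate = divergence_rate,
    per_base_error_rate = per_base_error_rate,
    chimera_rate = chimera_rate,
    ancestral_weight = ancestral_weight,
    seed = as.integer(seed)
  ), class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Simulation configuration (", length(x$genes), " genes x ",
      length(x$species), " species)\n", sep = "")
  cat("  fragments:", paste0(x$genes, "=", x$fragment_lengths, "bp",
                             collapse = ", "), "\n")
  cat("  clones/library:", paste(x$clones_range, collapse = "-"),
      " haplotypes:", paste(x$n_haplotypes_range, collapse = "-"),
      "over", x$n_chromosomes, "chromosomes\n")
  cat("  error:", x$per_base_error_rate, " chimera:", x$chimera_rate,
      " seed:", x$seed, "\n")
  invisible(x)
}

#' Read or write a simulation configuration as YAML
#'
#' @param path file path.
#' @param config a `simulation_config`.
#' @return `read_simulation_config()` returns a `simulation_config`;
#'   `write_simulation_config()` returns `path` invisibly.
#' @export
read_simulation_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$shared_snp_density <- unlist(raw$shared_snp_density)
  do.call(simulation_config, raw)
}

#' @rdname read_simulation_config
#' @export
write_simulation_config <- function(config, path) {
  x <- unclass(config)
  x$shared_snp_density <- as.list(x$shared_snp_density)
  yaml::write_yaml(x, path)
  invisible(path)
}
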