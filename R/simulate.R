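#' Locus model: reference fragment with exon/intron annotation
#'
#' A gene fragment's reference sequence together with its ordered
#' exon/intron intervals (1-based, inclusive) and the reading-frame phase of
#' the first exon base. Intervals must tile `[1, length]` without overlap.
#'
#' @param gene_id gene identifier.
#' @param sequence reference nucleotide sequence (A/C/G/T string).
#' @param regions data.frame with columns `start`, `end`, `label`
#'   (`"exon"` or `"intron"`), ordered along the fragment.
#' @param frame_offset 0--2: number of bases of the first exon that complete
#'   a codon started upstream of the fragment.
#' @return an object of class `locus_model`.
#' @export
locus_model <- function(gene_id, sequence, regions, frame_offset = 0L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  L <- nchar(sequence)
  if (!all(c("start", "end", "label") %in% names(regions))) {
    stop("`regions` needs columns start, end, label", call. = FALSE)
  }
  regions <- regions[order(regions$start), , drop = FALSE]
  if (any(!regions$label %in% c("exon", "intron"))) {
    stop("region labels must be 'exon' or 'intron'", call. = FALSE)
  }
  if (any(regions$end < regions$start)) {
    stop("region intervals must have start <= end", call. = FALSE)
  }
  if (regions$start[1] != 1L || regions$end[nrow(regions)] != L ||
      (nrow(regions) > 1L &&
       any(regions$start[-1] != regions$end[-nrow(regions)] + 1L))) {
    stop("regions must tile [1, fragment length] without overlap or gap",
         call. = FALSE)
  }
  if (grepl("[^ACGT]", sequence)) {
    stop("reference sequence must be over A/C/G/T", call. = FALSE)
  }
  if (!frame_offset %in% 0:2) {
    stop("`frame_offset` must be 0, 1 or 2", call. = FALSE)
  }
  structure(list(gene_id = gene_id, sequence = sequence,
                 regions = as.data.frame(regions, stringsAsFactors = FALSE),
                 frame_offset = as.integer(frame_offset)),
            class = "locus_model")
}

#' @export
print.locus_model <- function(x, ...) {
  cat("Locus", x$gene_id, "-", nchar(x$sequence), "bp,",
      sum(x$regions$label == "exon"), "exon(s) /",
      sum(x$regions$label == "intron"), "intron(s), frame offset",
      x$frame_offset, "\n")
  invisible(x)
}

#' Total exonic length of a locus
#' @param locus a `locus_model`.
#' @return integer number of exonic bases.
#' @export
locus_exon_length <- function(locus) {
  ex <- locus$regions[locus$regions$label == "exon", , drop = FALSE]
  sum(ex$end - ex$start + 1L)
}

#' Label reference positions as exon or intron
#' @param locus a `locus_model`.
#' @param positions 1-based reference coordinates.
#' @return character vector of labels.
#' @export
region_label <- function(locus, positions) {
  lab <- character(length(positions))
  for (i in seq_len(nrow(locus$regions))) {
    r <- locus$regions[i, ]
    hit <- positions >= r$start & positions <= r$end
    lab[hit] <- r$label
  }
  if (any(lab == "")) stop("position outside fragment", call. = FALSE)
  lab
}

# Sense codons of the standard genetic code (no stops).
sense_codons <- function() {
  code <- Biostrings::GENETIC_CODE
  names(code)[code != "*"]
}

#' Simulate a reference locus (exon--intron--exon amplicon fragment)
#'
#' Generates a random reference fragment with a central intron, mirroring the
#' intron-containing ~500 bp amplicons of the study design. The exonic
#' portion is built from sense codons so that, honoring `frame_offset`, the
#' reference coding sequence translates without internal stops.
#'
#' @param config a [simulation_config()].
#' @param gene_id one of `config$genes`.
#' @return a [locus_model()].
#' @export
simulate_locus <- function(config, gene_id) {
  idx <- match(gene_id, config$genes)
  if (is.na(idx)) stop("unknown gene_id: ", gene_id, call. = FALSE)
  L <- config$fragment_lengths[idx]
  with_seed(derive_seed(config$seed, "locus", gene_id), {
    n_intron <- max(1L, round(config$intron_fraction * L))
    n_exonic <- L - n_intron
    if (n_exonic < 6L) {
      stop("fragment too short to host an exon-intron-exon layout",
           call. = FALSE)
    }
    n_exon1 <- max(3L, round(stats::runif(1, 0.35, 0.65) * n_exonic))
    n_exon1 <- min(n_exon1, n_exonic - 3L)
    n_exon2 <- n_exonic - n_exon1
    frame_offset <- sample(0:2, 1L)

    # exonic bases: leading phase bases, full sense codons, trailing remainder
    n_lead <- frame_offset
    n_codons <- (n_exonic - n_lead) %/% 3L
    n_tail <- n_exonic - n_lead - 3L * n_codons
    exonic <- c(
      sample(DNA_BASES, n_lead, replace = TRUE),
      s2c(c2s(sample(sense_codons(), n_codons, replace = TRUE))),
      sample(DNA_BASES, n_tail, replace = TRUE)
    )
    intron <- sample(DNA_BASES, n_intron, replace = TRUE)
    bases <- c(exonic[seq_len(n_exon1)], intron,
               exonic[n_exon1 + seq_len(n_exon2)])
    regions <- data.frame(
      start = c(1L, n_exon1 + 1L, n_exon1 + n_intron + 1L),
      end = c(n_exon1, n_exon1 + n_intron, L),
      label = c("exon", "intron", "exon"),
      stringsAsFactors = FALSE
    )
    locus_model(gene_id, c2s(bases), regions, frame_offset)
  })
}

#' Simulate true haplotypes for the three species at one locus
#'
#' Species follow the fixed topology `((A, B), C)`. Fixed inter-species
#' differences accumulate along branches at `divergence_rate` (the C lineage
#' carrying about twice the A/B split depth). Polymorphic sites are laid
#' down in four tiers -- shared by all three species, by A and B, by A and C,
#' by B and C -- plus species-private sites, so that each species' expected
#' segregating-site density equals its `within_species_snp_density` and
#' sharing is strongest between the sister species A and B. At every
#' polymorphic site the first ("ancestral") haplotype carries the reference
#' allele; derived haplotypes carry the alternate in random subsets.
#' Haplotype multiplicities over the 8 homologous chromosomes are 1 each
#' plus a Dirichlet-multinomial allocation of the remainder, with the
#' ancestral haplotype up-weighted by `ancestral_weight`.
#'
#' @param locus a [locus_model()].
#' @param config a [simulation_config()].
#' @return an object of class `truth_set`: per species, haplotype sequences,
#'   multiplicities over chromosomes, and the true SNP table
#'   (`pos`, `ref_allele`, `alt_allele`, `carriers`); plus `shared_sites`,
#'   the cross-species site bookkeeping.
#' @export
simulate_species_haplotypes <- function(locus, config) {
  stopifnot(inherits(locus, "locus_model"))
  L <- nchar(locus$sequence)
  ref <- s2c(locus$sequence)
  sp <- config$species
  with_seed(derive_seed(config$seed, "haplotypes", locus$gene_id), {
    d <- config$divergence_rate
    draw_sites <- function(rate, avoid) {
      n <- stats::rbinom(1L, L, min(1, rate))
      pool <- setdiff(seq_len(L), avoid)
      sort(resample(pool, min(n, length(pool))))
    }
    # fixed substitutions along branches (branch units: A,B = 1 from the AB
    # ancestor, AB ancestor = 1 from root, C = 2 from root)
    anc_ab <- mutate_bases(ref, draw_sites(d, integer(0)))
    base <- list(mutate_bases(anc_ab, draw_sites(d, integer(0))),
                 mutate_bases(anc_ab, draw_sites(d, integer(0))),
                 mutate_bases(ref, draw_sites(2 * d, integer(0))))
    names(base) <- sp

    # polymorphic sites: shared tiers then private, all disjoint positions;
    # shared sites are restricted to positions where the carrier species'
    # backgrounds agree, so the ref/alt allele pair is identical across them
    carriers_of <- list(abc = 1:3, ab = 1:2, ac = c(1L, 3L), bc = 2:3)
    rates <- config$shared_snp_density[c("abc", "ab", "ac", "bc")]
    used <- integer(0)
    site_tab <- data.frame(pos = integer(0), alt = character(0),
                           tier = character(0), stringsAsFactors = FALSE)
    site_carriers <- list()
    for (tier in names(carriers_of)) {
      idx <- carriers_of[[tier]]
      agree <- which(Reduce(`&`, lapply(base[idx[-1]],
                                        function(b) b == base[[idx[1]]])))
      n <- stats::rbinom(1L, L, min(1, rates[[tier]]))
      pool <- setdiff(agree, used)
      pos <- sort(resample(pool, min(n, length(pool))))
      used <- c(used, pos)
      for (p in pos) {
        alt <- sample(setdiff(DNA_BASES, base[[idx[1]]][p]), 1L)
        site_tab <- rbind(site_tab, data.frame(
          pos = p, alt = alt, tier = tier, stringsAsFactors = FALSE))
        site_carriers[[length(site_carriers) + 1L]] <- idx
      }
    }
    shared_per_species <- c(
      sum(rates[c("abc", "ab", "ac")]),
      sum(rates[c("abc", "ab", "bc")]),
      sum(rates[c("abc", "ac", "bc")])
    )
    for (s in 1:3) {
      priv_rate <- max(0, config$within_species_snp_density[s] -
                         shared_per_species[s])
      pos <- draw_sites(priv_rate, used)
      used <- c(used, pos)
      for (p in pos) {
        alt <- sample(setdiff(DNA_BASES, base[[s]][p]), 1L)
        site_tab <- rbind(site_tab, data.frame(
          pos = p, alt = alt, tier = sp[s], stringsAsFactors = FALSE))
        site_carriers[[length(site_carriers) + 1L]] <- s
      }
    }

    k_range <- config$n_haplotypes_range
    species_truth <- list()
    for (s in 1:3) {
      mine <- which(vapply(site_carriers, function(x) s %in% x, logical(1)))
      snp <- site_tab[mine, , drop = FALSE]
      k <- if (k_range[1] == k_range[2]) k_range[1] else
        resample(seq(k_range[1], k_range[2]), 1L)
      haps <- matrix(rep(base[[s]], k), nrow = k, byrow = TRUE)
      carrier_sets <- vector("list", nrow(snp))
      for (j in seq_len(nrow(snp))) {
        if (k > 1L) {
          repeat {
            set <- which(stats::runif(k - 1L) < 0.5) + 1L
            if (length(set) > 0L) break
          }
        } else {
          set <- integer(0)  # single haplotype: site cannot segregate
        }
        carrier_sets[[j]] <- set
        haps[set, snp$pos[j]] <- snp$alt[j]
      }
      seg <- lengths(carrier_sets) > 0L
      snp <- snp[seg, , drop = FALSE]
      carrier_sets <- carrier_sets[seg]
      # multiplicities: 1 each + Dirichlet-multinomial remainder, ancestral
      # haplotype up-weighted
      alpha <- c(config$ancestral_weight, rep(1, k - 1L))
      w <- stats::rgamma(k, alpha, 1)
      w <- w / sum(w)
      extra <- config$n_chromosomes - k
      mult <- rep(1L, k)
      if (extra > 0L) {
        mult <- mult + as.integer(stats::rmultinom(1L, extra, w))
      }
      seqs <- apply(haps, 1L, c2s)
      # collapse haplotypes that received identical allele subsets
      uniq <- !duplicated(seqs)
      map <- match(seqs, seqs[uniq])
      mult <- as.integer(tapply(mult, map, sum))
      seqs <- seqs[uniq]
      snp_df <- if (nrow(snp)) data.frame(
        pos = snp$pos,
        ref_allele = base[[s]][snp$pos],
        alt_allele = snp$alt,
        carriers = vapply(seq_along(carrier_sets), function(j)
          paste(sort(unique(map[carrier_sets[[j]]])), collapse = ","),
          character(1)),
        tier = snp$tier,
        stringsAsFactors = FALSE
      ) else data.frame(pos = integer(0), ref_allele = character(0),
                        alt_allele = character(0), carriers = character(0),
                        tier = character(0), stringsAsFactors = FALSE)
      species_truth[[sp[s]]] <- list(
        haplotypes = seqs,
        multiplicities = mult,
        snps = snp_df[order(snp_df$pos), , drop = FALSE]
      )
    }
    structure(list(gene_id = locus$gene_id, locus = locus,
                   species = species_truth,
                   shared_sites = site_tab),
              class = "truth_set")
  })
}

#' Simulate a clone library for one gene x species
#'
#' Each clone copies one chromosome's haplotype; with probability
#' `chimera_rate` it is a PCR template-switching chimera, recombined once at
#' a uniformly chosen internal breakpoint with the haplotype of another
#' chromosome (5' part from the source, 3' part from the partner). Per-base
#' substitution errors are then injected at `per_base_error_rate`. All truth
#' labels (source haplotype, partner, breakpoint, error positions) are
#' recorded.
#'
#' @param truth a `truth_set` from [simulate_species_haplotypes()].
#' @param species_id one of the configured species.
#' @param config a [simulation_config()].
#' @param n_clones optional clone count; defaults to a uniform draw from
#'   `config$clones_range`.
#' @return an object of class `clone_library` with elements `sequences`
#'   (named character vector) and `truth` (per-clone provenance data.frame).
#' @export
simulate_clone_library <- function(truth, species_id, config,
                                   n_clones = NULL) {
  stopifnot(inherits(truth, "truth_set"))
  st <- truth$species[[species_id]]
  if (is.null(st)) stop("unknown species: ", species_id, call. = FALSE)
  if (length(st$haplotypes) < 1L) stop("truth contains no haplotypes", call. = FALSE)
  L <- nchar(truth$locus$sequence)
  with_seed(derive_seed(config$seed, "clones", truth$gene_id, species_id), {
    if (is.null(n_clones)) {
      n_clones <- resample(seq(config$clones_range[1], config$clones_range[2]), 1L)
    }
    chrom_hap <- rep(seq_along(st$haplotypes), st$multiplicities)
    ids <- sprintf("%s|%s|clone%03d", truth$gene_id, species_id,
                   seq_len(n_clones))
    seqs <- character(n_clones)
    prov <- data.frame(clone_id = ids, haplotype = NA_integer_,
                       chimera = FALSE, partner = NA_integer_,
                       breakpoint = NA_integer_, n_errors = 0L,
                       error_positions = "", stringsAsFactors = FALSE)
    for (i in seq_len(n_clones)) {
      chrom <- sample(length(chrom_hap), 1L)
      hap <- chrom_hap[chrom]
      bases <- s2c(st$haplotypes[hap])
      prov$haplotype[i] <- hap
      if (stats::runif(1) < config$chimera_rate && length(chrom_hap) > 1L) {
        partner_chrom <- resample(setdiff(seq_along(chrom_hap), chrom), 1L)
        partner <- chrom_hap[partner_chrom]
        bp <- sample(2:L, 1L)
        bases <- c(bases[seq_len(bp - 1L)], s2c(st$haplotypes[partner])[bp:L])
        prov$chimera[i] <- TRUE
        prov$partner[i] <- partner
        prov$breakpoint[i] <- bp
      }
      n_err <- stats::rbinom(1L, L, config$per_base_error_rate)
      if (n_err > 0L) {
        pos <- sort(sample(L, n_err))
        bases <- mutate_bases(bases, pos)
        prov$n_errors[i] <- n_err
        prov$error_positions[i] <- paste(pos, collapse = ",")
      }
      seqs[i] <- c2s(bases)
    }
    names(seqs) <- ids
    structure(list(gene_id = truth$gene_id, species_id = species_id,
                   sequences = seqs, truth = prov),
              class = "clone_library")
  })
}

#' Simulate the full study: all genes x species
#'
#' @param config a [simulation_config()].
#' @return an object of class `study`: `config`, named lists `loci` and
#'   `truth` (per gene), and `libraries` (per gene, per species).
#' @export
simulate_study <- function(config) {
  loci <- lapply(config$genes, function(g) simulate_locus(config, g))
  names(loci) <- config$genes
  truth <- lapply(loci, simulate_species_haplotypes, config = config)
  libraries <- lapply(truth, function(tr) {
    libs <- lapply(config$species, function(s)
      simulate_clone_library(tr, s, config))
    names(libs) <- config$species
    libs
  })
  structure(list(config = config, loci = loci, truth = truth,
                 libraries = libraries), class = "study")
}

#' @export
print.study <- function(x, ...) {
  n_clones <- sum(vapply(x$libraries, function(libs)
    sum(vapply(libs, function(l) length(l$sequences), integer(1))), numeric(1)))
  cat("Simulated study:", length(x$loci), "genes x", length(x$config$species),
      "species,", n_clones, "clones total\n")
  invisible(x)
}

#' Write a simulated study to disk
#'
#' Emits, under `dir`: one clone FASTA per gene x species, the reference
#' FASTA, a GFF3 locus annotation (features `exon`/`intron`, 1-based
#' inclusive), per-gene truth tables as TSV, and the configuration as YAML.
#'
#' @param study a `study` from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  refs <- Biostrings::DNAStringSet(vapply(study$loci, function(l) l$sequence,
                                          character(1)))
  names(refs) <- names(study$loci)
  Biostrings::writeXStringSet(refs, file.path(dir, "reference.fasta"))

  gr <- do.call(c, unname(lapply(study$loci, function(l) {
    GenomicRanges::GRanges(
      seqnames = l$gene_id,
      ranges = IRanges::IRanges(l$regions$start, l$regions$end),
      type = l$regions$label,
      frame_offset = l$frame_offset
    )
  })))
  rtracklayer::export(gr, file.path(dir, "loci.gff3"), format = "gff3")

  for (g in names(study$libraries)) {
    for (s in names(study$libraries[[g]])) {
      lib <- study$libraries[[g]][[s]]
      fa <- Biostrings::DNAStringSet(lib$sequences)
      Biostrings::writeXStringSet(
        fa, file.path(dir, sprintf("clones_%s_%s.fasta", g, s)))
      utils::write.table(
        lib$truth, file.path(dir, sprintf("truth_clones_%s_%s.tsv", g, s)),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    snp_truth <- do.call(rbind, lapply(names(study$truth[[g]]$species),
      function(s) {
        df <- study$truth[[g]]$species[[s]]$snps
        if (nrow(df)) cbind(gene_id = g, species_id = s, df) else NULL
      }))
    if (!is.null(snp_truth)) {
      utils::write.table(snp_truth,
                         file.path(dir, sprintf("truth_snps_%s.tsv", g)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  write_simulation_config(study$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read locus models from a GFF3 annotation plus reference FASTA
#'
#' @param gff_path GFF3 with `exon`/`intron` features per gene and a
#'   `frame_offset` attribute.
#' @param fasta_path reference FASTA with one record per gene.
#' @return named list of [locus_model()] objects.
#' @export
read_loci <- function(gff_path, fasta_path) {
  if (!file.exists(gff_path)) stop("locus file not found: ", gff_path, call. = FALSE)
  if (!file.exists(fasta_path)) stop("reference not found: ", fasta_path, call. = FALSE)
  gr <- rtracklayer::import(gff_path, format = "gff3")
  refs <- Biostrings::readDNAStringSet(fasta_path)
  names(refs) <- sub("\\s.*$", "", names(refs))
  loci <- lapply(unique(as.character(GenomicRanges::seqnames(gr))), function(g) {
    sub_gr <- gr[as.character(GenomicRanges::seqnames(gr)) == g]
    regions <- data.frame(
      start = GenomicRanges::start(sub_gr),
      end = GenomicRanges::end(sub_gr),
      label = as.character(sub_gr$type),
      stringsAsFactors = FALSE
    )
    fo <- suppressWarnings(as.integer(sub_gr$frame_offset[1]))
    locus_model(g, as.character(refs[[g]]), regions,
                if (is.na(fo)) 0L else fo)
  })
  names(loci) <- vapply(loci, function(l) l$gene_id, character(1))
  loci
}
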