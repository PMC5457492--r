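#' Configuration of a synthetic paired-modality screen
#'
#' Defines the study conditions of a simulated pooled screen: gene count and
#' layout, essential-gene effect size, amplicon copy number, bidirectional
#' promoter pairs, the distance-dependent CRISPRi efficiency curve, the
#' per-cut cutting-toxicity cost, growth duration, sequencing depth and
#' count overdispersion.
#'
#' @param n_genes Total genes (default 300).
#' @param n_essential Truly essential genes (default 30), including the
#'   amplified drivers and the essential member of each bidirectional pair.
#' @param essential_effect Fitness cost per doubling, log2 units (default
#'   0.2: a fully effective guide reaches LFC -2 over 10 doublings).
#' @param guides_per_gene Guides per gene and class in simulated libraries
#'   (default 4).
#' @param n_amplified Genes inside the amplicon (default 20).
#' @param amplicon_cn Copy number of the amplicon (default 8).
#' @param n_amplified_essential Essential "driver" genes inside the amplicon
#'   (default 1).
#' @param n_bidirectional_pairs Divergent promoter pairs, each an essential
#'   gene sharing a sub-kilobase promoter with a non-essential partner
#'   (default 10).
#' @param bidirectional_coupling When `TRUE` (default) a CRISPRi guide in a
#'   shared promoter silences both genes with the same efficiency.
#' @param efficiency_curve Function mapping signed TSS distance (bp) to
#'   knockdown in `[0, 1]`; default a Gaussian bump centered +100 bp
#'   downstream with 150 bp width.
#' @param cutting_toxicity_per_site Fitness cost per doubling per cut site
#'   beyond the first (default 0.03); applies to active Cas9 only.
#' @param doublings Population doublings between early and late sampling
#'   (default 10, a proxy for a three-week screen).
#' @param sequencing_depth Mean reads per guide per sample (default 500).
#' @param dispersion Negative-binomial overdispersion of counts
#'   (default 0.05).
#' @param replicates Biological replicates (default 2).
#' @param intrinsic_efficiency Range of the per-guide intrinsic efficiency
#'   multiplier (default `c(0.4, 1)`), a proxy for sequence features the
#'   distance model does not capture.
#' @param n_multicopy Guide target sites planted at multiple genomic copies
#'   (default 8), for multiplicity analyses.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 300L, n_essential = 30L,
                       essential_effect = 0.2, guides_per_gene = 4L,
                       n_amplified = 20L, amplicon_cn = 8L,
                       n_amplified_essential = 1L,
                       n_bidirectional_pairs = 10L,
                       bidirectional_coupling = TRUE,
                       efficiency_curve = NULL,
                       cutting_toxicity_per_site = 0.03, doublings = 10L,
                       sequencing_depth = 500, dispersion = 0.05,
                       replicates = 2L, intrinsic_efficiency = c(0.4, 1),
                       n_multicopy = 8L) {
  if (is.null(efficiency_curve)) {
    efficiency_curve <- function(d) exp(-(d - 100)^2 / (2 * 150^2))
  }
  cfg <- list(n_genes = as.integer(n_genes),
              n_essential = as.integer(n_essential),
              essential_effect = essential_effect,
              guides_per_gene = as.integer(guides_per_gene),
              n_amplified = as.integer(n_amplified),
              amplicon_cn = as.integer(amplicon_cn),
              n_amplified_essential = min(as.integer(n_amplified_essential),
                                          as.integer(n_amplified)),
              n_bidirectional_pairs = as.integer(n_bidirectional_pairs),
              bidirectional_coupling = isTRUE(bidirectional_coupling),
              efficiency_curve = efficiency_curve,
              cutting_toxicity_per_site = cutting_toxicity_per_site,
              doublings = as.integer(doublings),
              sequencing_depth = sequencing_depth,
              dispersion = dispersion,
              replicates = as.integer(replicates),
              intrinsic_efficiency = intrinsic_efficiency,
              n_multicopy = as.integer(n_multicopy))
  rates <- c(cfg$essential_effect, cfg$cutting_toxicity_per_site,
             cfg$sequencing_depth, cfg$dispersion)
  if (any(rates < 0)) abort("rates must be >= 0")
  if (cfg$n_essential < cfg$n_bidirectional_pairs +
        cfg$n_amplified_essential) {
    abort("n_essential must cover the pair-essential and driver genes")
  }
  if (cfg$n_genes < 2 * cfg$n_bidirectional_pairs + cfg$n_amplified + 1) {
    abort("n_genes too small for the requested pairs and amplicon")
  }
  if (cfg$n_amplified_essential > cfg$n_amplified) {
    abort("more amplified drivers than amplified genes")
  }
  structure(cfg, class = "sim_config")
}

random_dna <- function(n) {
  intToUtf8(sample(c(65L, 67L, 71L, 84L), n, replace = TRUE))
}

# per-unit gene geometry (0-based offsets within a layout unit)
GENE_UNIT <- 7000L
PAIR_UNIT <- 9000L

single_gene_layout <- function(base, strand) {
  if (strand == "+") {
    tss <- base + 3000L
    exons <- cbind(c(tss + 1500L, tss + 2400L), c(tss + 2200L, tss + 3000L))
  } else {
    tss <- base + 4000L
    exons <- cbind(c(tss - 3000L, tss - 2200L), c(tss - 2400L, tss - 1500L))
  }
  list(tss = tss, exons = exons)
}

#' Build a synthetic genome with annotation and ground truth
#'
#' Lays out random-sequence contigs holding the configured genes: normal
#' genes and bidirectional pairs on `chr1`, the amplicon (elevated copy
#' number) on `chr2`, a neutral AAVS1-like safe-harbor contig, and a repeat
#' contig carrying extra copies of planted guide target sites. Each gene has
#' 1-3 CAGE-style TSS peaks (the highest is primary) and two coding-exon
#' intervals downstream of the TSS.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; fully determines the output.
#' @return A list of class `crispr_sim`: `genome` (a `genome_model`), `tss`
#'   (ranked tibble), `exons`, `aavs1_region`, `truth` (per-gene effects,
#'   pair map, planted multi-copy sites), `config`, `seed`.
#' @export
make_genome <- function(cfg = sim_config(), seed = 1L) {
  with_seed(seed, {
    n_pairs <- cfg$n_bidirectional_pairs
    n_singles <- cfg$n_genes - cfg$n_amplified - 2L * n_pairs
    if (n_singles < 0) abort("infeasible layout: not enough genes")
    gene_ids <- sprintf("G%03d", seq_len(cfg$n_genes))
    amp_genes <- if (cfg$n_amplified > 0) {
      gene_ids[seq_len(cfg$n_amplified)]
    } else character(0)
    pair_a <- if (n_pairs > 0) {
      gene_ids[cfg$n_amplified + seq_len(n_pairs)]          # essential
    } else character(0)
    pair_b <- if (n_pairs > 0) {
      gene_ids[cfg$n_amplified + n_pairs + seq_len(n_pairs)] # partner
    } else character(0)
    single_genes <- setdiff(gene_ids, c(amp_genes, pair_a, pair_b))
    drivers <- amp_genes[seq_len(cfg$n_amplified_essential)]
    n_more <- cfg$n_essential - length(drivers) - length(pair_a)
    ess_singles <- single_genes[sample.int(length(single_genes), n_more)]
    essential <- c(drivers, pair_a, ess_singles)

    # chr1: shuffled single-gene and pair units
    units <- c(as.list(single_genes),
               lapply(seq_len(n_pairs), function(i) c(pair_a[i], pair_b[i])))
    units <- units[sample.int(length(units))]
    widths <- ifelse(lengths(units) == 1L, GENE_UNIT, PAIR_UNIT)
    bases <- cumsum(c(0L, widths))[seq_along(units)]
    chr1_len <- sum(widths)

    tss_rows <- list()
    exon_rows <- list()
    gene_rows <- list()
    add_gene <- function(gene, chrom, strand, tss, exons, n_extra_tss,
                         amplified) {
      heights <- c(runif(1, 60, 100),
                   if (n_extra_tss > 0) runif(n_extra_tss, 5, 50))
      offs <- if (strand == "+") c(-600L, -1200L) else c(600L, 1200L)
      pos <- c(tss, tss + offs[seq_len(n_extra_tss)])
      tss_rows[[length(tss_rows) + 1]] <<- tibble::tibble(
        gene = gene, chrom = chrom, position = as.integer(pos),
        strand = strand, peak_height = heights)
      exon_rows[[length(exon_rows) + 1]] <<- tibble::tibble(
        gene = gene, chrom = chrom, start = as.integer(exons[, 1]),
        end = as.integer(exons[, 2]))
      gene_rows[[length(gene_rows) + 1]] <<- tibble::tibble(
        gene = gene, chrom = chrom, strand = strand,
        tss_primary = as.integer(tss), amplified = amplified)
    }

    for (u in seq_along(units)) {
      if (length(units[[u]]) == 1L) {
        g <- units[[u]]
        strand <- sample(c("+", "-"), 1)
        lay <- single_gene_layout(bases[u], strand)
        add_gene(g, "chr1", strand, lay$tss, lay$exons,
                 sample(0:2, 1), FALSE)
      } else {
        ga <- units[[u]][1]  # left gene, minus strand (transcribes left)
        gb <- units[[u]][2]  # right gene, plus strand
        tss_a <- bases[u] + 4000L
        gap <- sample(300:900, 1)
        tss_b <- tss_a + gap
        exons_a <- cbind(c(tss_a - 3000L, tss_a - 2200L),
                         c(tss_a - 2400L, tss_a - 1500L))
        exons_b <- cbind(c(tss_b + 1500L, tss_b + 2400L),
                         c(tss_b + 2200L, tss_b + 3000L))
        add_gene(ga, "chr1", "-", tss_a, exons_a, 0L, FALSE)
        add_gene(gb, "chr1", "+", tss_b, exons_b, 0L, FALSE)
      }
    }
    # chr2: the amplicon
    chr2_len <- max(cfg$n_amplified, 1L) * GENE_UNIT
    for (i in seq_along(amp_genes)) {
      strand <- sample(c("+", "-"), 1)
      lay <- single_gene_layout((i - 1L) * GENE_UNIT, strand)
      add_gene(amp_genes[i], "chr2", strand, lay$tss, lay$exons,
               sample(0:1, 1), TRUE)
    }

    sequences <- c(chr1 = random_dna(chr1_len), chr2 = random_dna(chr2_len),
                   chr_aavs1 = random_dna(3000L))

    # plant extra genomic copies of some TSS-proximal target sites
    planted <- tibble::tibble(gene = character(), spacer_seq = character(),
                              extra_copies = integer())
    if (cfg$n_multicopy > 0 && length(single_genes) >= cfg$n_multicopy) {
      host <- sample(single_genes, cfg$n_multicopy)
      genes_tbl <- dplyr::bind_rows(gene_rows)
      rep_parts <- character(0)
      for (g in host) {
        row <- genes_tbl[genes_tbl$gene == g, ]
        sites <- pam_sites_in_region(sequences[[row$chrom]],
                                     row$tss_primary - 200L,
                                     row$tss_primary + 200L)
        if (nrow(sites) == 0) next
        s <- sites[sample.int(nrow(sites), 1), ]
        proto <- if (s$strand == "+") {
          substr(sequences[[row$chrom]], s$pam_n_position - 19L,
                 s$pam_n_position + 3L)
        } else {
          paste0(revcomp_chr(substr(sequences[[row$chrom]],
                                    s$pam_n_position - 1L,
                                    s$pam_n_position + 1L + 20L)), "")
        }
        extra <- sample(1:7, 1)
        rep_parts <- c(rep_parts,
                       rep(paste0(proto, random_dna(40L)), extra))
        planted <- dplyr::bind_rows(planted, tibble::tibble(
          gene = g, spacer_seq = s$spacer_seq,
          extra_copies = as.integer(extra)))
      }
      if (length(rep_parts) > 0) {
        sequences <- c(sequences,
                       chr_rep = paste(rep_parts, collapse = ""))
      }
    }

    cn_segments <- if (cfg$n_amplified > 0) {
      tibble::tibble(chrom = "chr2", start = 0L, end = chr2_len,
                     cn = cfg$amplicon_cn)
    } else NULL
    genome <- genome_model(sequences, cn_segments)

    genes_tbl <- dplyr::bind_rows(gene_rows) |>
      dplyr::mutate(
        essential = .data$gene %in% essential,
        effect = ifelse(.data$essential, cfg$essential_effect, 0),
        partner = NA_character_)
    if (n_pairs > 0) {
      genes_tbl$partner[match(pair_a, genes_tbl$gene)] <- pair_b
      genes_tbl$partner[match(pair_b, genes_tbl$gene)] <- pair_a
    }
    structure(list(
      genome = genome,
      tss = rank_tss(dplyr::bind_rows(tss_rows)),
      exons = dplyr::bind_rows(exon_rows),
      aavs1_region = tibble::tibble(chrom = "chr_aavs1", start = 0L,
                                    end = 3000L),
      truth = list(genes = genes_tbl,
                   pairs = tibble::tibble(gene_a = pair_a, gene_b = pair_b),
                   planted = planted),
      config = cfg,
      seed = as.integer(seed)), class = "crispr_sim")
  })
}

#' @export
print.crispr_sim <- function(x, ...) {
  cat(sprintf(
    "<crispr_sim> %d genes (%d essential, %d amplified, %d bidirectional pairs), seed %d\n",
    x$config$n_genes, x$config$n_essential, x$config$n_amplified,
    x$config$n_bidirectional_pairs, x$seed))
  invisible(x)
}

#' Draw a screening library directly from a simulated genome
#'
#' Samples real NGG-anchored guides near each gene's primary TSS (class
#' `tss_1`) and inside its coding exons (class `exon`), plus AAVS1
#' safe-harbor and non-targeting controls. Unlike [assemble_library()] no
#' exclusion filters are applied, emulating a naive tiling library in which
#' multi-target and other problematic guides are present.
#'
#' @param sim A `crispr_sim`.
#' @param guides_per_gene Guides per gene and class (default from config).
#' @param window TSS search half-width in bp (default 200).
#' @param n_aavs1,n_nontargeting Control counts (default 100 each).
#' @param classes Which targeting classes to include.
#' @param seed Seed for guide sampling.
#' @return A validated library tibble.
#' @export
simulate_library <- function(sim, guides_per_gene = NULL, window = 200L,
                             n_aavs1 = 100L, n_nontargeting = 100L,
                             classes = c("tss_1", "exon"), seed = 1L) {
  if (is.null(guides_per_gene)) guides_per_gene <- sim$config$guides_per_gene
  chars <- as.character(sim$genome$sequences)
  genes <- sim$truth$genes
  with_seed(seed, {
    rows <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
      g <- genes$gene[i]
      out <- list()
      if ("tss_1" %in% classes) {
        sites <- pam_sites_in_region(chars[[genes$chrom[i]]],
                                     genes$tss_primary[i] - window,
                                     genes$tss_primary[i] + window)
        take <- min(guides_per_gene, nrow(sites))
        if (take > 0) {
          idx <- sort(sample.int(nrow(sites), take))
          # planted multi-copy sites always enter the library of their host
          forced <- which(sites$spacer_seq %in%
                            sim$truth$planted$spacer_seq)
          idx <- sort(union(idx, forced))
          sel <- sites[idx, ]
          out$tss <- tibble::tibble(
            spacer_id = sprintf("%s_tss1_g%02d", g, seq_len(nrow(sel))),
            spacer_seq = sel$spacer_seq, chrom = genes$chrom[i],
            cut_anchor = sel$pam_n_position, strand = sel$strand,
            target_gene = g, target_class = "tss_1", tss_rank = 1L)
        }
      }
      if ("exon" %in% classes) {
        ex <- sim$exons[sim$exons$gene == g, ]
        sites <- purrr::map_dfr(seq_len(nrow(ex)), function(k) {
          pam_sites_in_region(chars[[genes$chrom[i]]], ex$start[k],
                              ex$end[k] - 1L)
        })
        take <- min(guides_per_gene, nrow(sites))
        if (take > 0) {
          sel <- sites[sort(sample.int(nrow(sites), take)), ]
          out$exon <- tibble::tibble(
            spacer_id = sprintf("%s_exon_g%02d", g, seq_len(take)),
            spacer_seq = sel$spacer_seq, chrom = genes$chrom[i],
            cut_anchor = sel$pam_n_position, strand = sel$strand,
            target_gene = g, target_class = "exon", tss_rank = NA_integer_)
        }
      }
      dplyr::bind_rows(out)
    })
    ctrl <- list()
    if (n_aavs1 > 0) {
      reg <- sim$aavs1_region
      sites <- pam_sites_in_region(chars[[reg$chrom]], reg$start,
                                   reg$end - 1L)
      take <- min(n_aavs1, nrow(sites))
      sel <- sites[sort(sample.int(nrow(sites), take)), ]
      ctrl$aavs1 <- tibble::tibble(
        spacer_id = sprintf("AAVS1_g%03d", seq_len(take)),
        spacer_seq = sel$spacer_seq, chrom = reg$chrom,
        cut_anchor = sel$pam_n_position, strand = sel$strand,
        target_gene = NA_character_, target_class = "aavs1",
        tss_rank = NA_integer_)
    }
    if (n_nontargeting > 0) {
      nt <- make_nontargeting_spacers(sim$genome, n_nontargeting,
                                      seed = sim$seed + 8881L)
      ctrl$nt <- tibble::tibble(
        spacer_id = sprintf("NT_g%03d", seq_along(nt)), spacer_seq = nt,
        chrom = NA_character_, cut_anchor = NA_integer_,
        strand = NA_character_, target_gene = NA_character_,
        target_class = "nontargeting", tss_rank = NA_integer_)
    }
    validate_library(dplyr::bind_rows(rows, dplyr::bind_rows(ctrl)))
  })
}

#' Ground-truth annotation of library guides
#'
#' Computes, per guide: the signed distance `d` to the target gene's primary
#' TSS, exact genomic target multiplicity, local copy number at the cut
#' site, the seeded intrinsic efficiency multiplier, the CRISPRi knockdown
#' (intrinsic efficiency times the distance curve), and the per-doubling
#' fitness of the guide under each modality.
#'
#' Cas9 fitness combines the on-target gene effect (exon guides only, via
#' knockout) with gene-independent cutting toxicity proportional to the
#' number of cut sites beyond the first (target multiplicity times local
#' copy number). KRAB-dCas9 fitness is the knockdown-weighted gene effect of
#' every gene whose promoter the guide occupies (both members of a coupled
#' bidirectional pair) and carries no toxicity term.
#'
#' @param library Library tibble.
#' @param sim A `crispr_sim`.
#' @return The library joined with columns `d`, `multiplicity`, `cn`,
#'   `intrinsic`, `knockdown`, `fitness_cas9`, `fitness_krab`.
#' @export
annotate_guides <- function(library, sim) {
  cfg <- sim$config
  genes <- sim$truth$genes
  ann <- library |>
    dplyr::left_join(
      genes |>
        dplyr::select("gene", "strand", "tss_primary", "effect", "partner") |>
        dplyr::rename(target_gene = "gene", gene_strand = "strand"),
      by = "target_gene")
  targeted <- !is.na(ann$cut_anchor)
  ann$d <- NA_integer_
  has_tss <- targeted & !is.na(ann$tss_primary)
  ann$d[has_tss] <- signed_tss_distance(ann$cut_anchor[has_tss],
                                        ann$tss_primary[has_tss],
                                        ann$gene_strand[has_tss])
  ann$multiplicity <- 0L
  ann$multiplicity[targeted] <- target_multiplicity(
    ann$spacer_seq[targeted], sim$genome, mode = "exact")
  ann$cn <- copy_number_at(sim$genome, ann$chrom, ann$cut_anchor)
  ann$cn[!targeted] <- 0L
  ann$intrinsic <- with_seed(sim$seed + 4242L,
                             runif(nrow(ann), cfg$intrinsic_efficiency[1],
                                   cfg$intrinsic_efficiency[2]))
  curve_val <- rep(0, nrow(ann))
  curve_val[has_tss] <- cfg$efficiency_curve(ann$d[has_tss])
  ann$knockdown <- ann$intrinsic * curve_val

  effect <- tidyr::replace_na(ann$effect, 0)
  partner_effect <- tidyr::replace_na(
    genes$effect[match(ann$partner, genes$gene)], 0)
  cut_sites <- ann$multiplicity * ann$cn
  tox <- cfg$cutting_toxicity_per_site * pmax(cut_sites - 1L, 0L)
  on_target_cut <- ifelse(ann$target_class == "exon" & !is.na(ann$effect),
                          effect * ann$intrinsic, 0)
  ann$fitness_cas9 <- -on_target_cut - tox
  coupled <- cfg$bidirectional_coupling & !is.na(ann$partner)
  ann$fitness_krab <- -(effect * ann$knockdown +
                          ifelse(coupled, partner_effect * ann$knockdown, 0))
  dplyr::select(ann, -"gene_strand", -"tss_primary", -"effect", -"partner")
}

sample_counts <- function(fitness, cfg, depth, replicates, seed) {
  n <- length(fitness)
  growth <- 2^(fitness * cfg$doublings)
  purrr::map(seq_len(replicates), function(r) {
    with_seed(seed + r, {
      w <- rlnorm(n, meanlog = 0, sdlog = 0.5)
      early <- as.integer(rmultinom(1, size = round(depth * n),
                                    prob = w / sum(w)))
      wl <- w * growth
      mu <- depth * n * wl / sum(wl)
      late <- if (cfg$dispersion > 0) {
        rnbinom(n, mu = mu, size = 1 / cfg$dispersion)
      } else {
        stats::rpois(n, mu)
      }
      list(early = early, late = as.integer(late))
    })
  })
}

counts_tibble <- function(library, reps) {
  sample_ids <- c(vapply(seq_along(reps), function(r)
    paste0("early.rep", r), character(1)),
    vapply(seq_along(reps), function(r) paste0("late.rep", r), character(1)))
  blocks <- c(lapply(seq_along(reps), function(r) {
    tibble::tibble(sgrna_id = library$spacer_id,
                   sample_id = paste0("early.rep", r),
                   condition = "early", replicate = paste0("rep", r),
                   count = reps[[r]]$early)
  }), lapply(seq_along(reps), function(r) {
    tibble::tibble(sgrna_id = library$spacer_id,
                   sample_id = paste0("late.rep", r),
                   condition = "late", replicate = paste0("rep", r),
                   count = reps[[r]]$late)
  }))
  out <- dplyr::bind_rows(blocks)
  out$sample_id <- factor(out$sample_id, levels = sample_ids)
  out
}

#' Simulate a pooled proliferation screen
#'
#' Early counts are multinomial draws over a lognormal library
#' representation; guide abundance then grows as `2^(fitness * doublings)`
#' and late counts are negative-binomial draws around the renormalized late
#' representation. Replicates are independent.
#'
#' @param library Library tibble.
#' @param sim A `crispr_sim` (supplies truth and config).
#' @param modality `"cas9"` (cutting) or `"krab_dcas9"` (CRISPRi).
#' @param seed Seed for the count sampling.
#' @param depth,replicates Override the config values when given.
#' @return A long count tibble (as [read_counts()]), with the guide truth
#'   annotation attached as attribute `guide_truth`.
#' @export
simulate_screen <- function(library, sim,
                            modality = c("cas9", "krab_dcas9"), seed = 1L,
                            depth = NULL, replicates = NULL) {
  modality <- match.arg(modality)
  cfg <- sim$config
  if (is.null(depth)) depth <- cfg$sequencing_depth
  if (is.null(replicates)) replicates <- cfg$replicates
  ann <- annotate_guides(library, sim)
  fitness <- if (modality == "cas9") ann$fitness_cas9 else ann$fitness_krab
  reps <- sample_counts(fitness, cfg, depth, replicates, seed)
  out <- counts_tibble(library, reps)
  attr(out, "guide_truth") <- ann
  attr(out, "modality") <- modality
  out
}

#' Simulate a positive-selection (rescue) screen
#'
#' Models a 6TG-style selection: every cell suffers a strong fitness cost
#' unless its guide disables the sentinel gene (e.g. HPRT1). Under Cas9 both
#' exon guides (knockout) and TSS guides (suppression) of the sentinel
#' rescue; under KRAB-dCas9 only TSS guides do. Used to exercise the
#' outlier robustness of trimmed-mean normalization.
#'
#' @inheritParams simulate_screen
#' @param sentinel Gene whose disabling rescues the selection.
#' @param selection_strength Per-doubling fitness cost of the selection
#'   (default 1: near-total arrest of unrescued cells).
#' @return A long count tibble.
#' @export
rescue_screen <- function(library, sim, sentinel,
                          modality = c("cas9", "krab_dcas9"),
                          selection_strength = 1, seed = 1L) {
  modality <- match.arg(modality)
  cfg <- sim$config
  if (!sentinel %in% library$target_gene) {
    abort(paste0("sentinel gene not in library: ", sentinel))
  }
  ann <- annotate_guides(library, sim)
  base <- if (modality == "cas9") ann$fitness_cas9 else ann$fitness_krab
  is_sent <- !is.na(ann$target_gene) & ann$target_gene == sentinel
  disable <- rep(0, nrow(ann))
  if (modality == "cas9") {
    disable[is_sent & ann$target_class == "exon"] <-
      ann$intrinsic[is_sent & ann$target_class == "exon"]
    disable[is_sent & ann$target_class == "tss_1"] <-
      ann$knockdown[is_sent & ann$target_class == "tss_1"]
  } else {
    disable[is_sent] <- ann$knockdown[is_sent]
  }
  fitness <- base + selection_strength * (disable - 1)
  reps <- sample_counts(fitness, cfg, cfg$sequencing_depth, cfg$replicates,
                        seed)
  out <- counts_tibble(library, reps)
  attr(out, "guide_truth") <- ann
  out
}

#' Simulated CRISPRi activation-score training data
#'
#' Generates guide-level training labels for the distance-to-TSS efficiency
#' model: activation scores follow the configured efficiency curve plus
#' Gaussian noise, over distances drawn uniformly in `d_range`.
#'
#' @param n_genes Number of genes (default 40).
#' @param guides_per_gene Guides per gene (default 12).
#' @param curve Efficiency curve (default the [sim_config()] default).
#' @param d_range Distance range sampled (default `c(-1000, 1000)` bp).
#' @param noise_sd Label noise SD (default 0.15).
#' @param seed Seed.
#' @return A tibble `gene`, `d`, `activation_score`.
#' @export
simulate_activation_data <- function(n_genes = 40L, guides_per_gene = 12L,
                                     curve = NULL,
                                     d_range = c(-1000, 1000),
                                     noise_sd = 0.15, seed = 1L) {
  if (is.null(curve)) curve <- sim_config()$efficiency_curve
  with_seed(seed, {
    n <- n_genes * guides_per_gene
    d <- round(runif(n, d_range[1], d_range[2]))
    tibble::tibble(
      gene = rep(sprintf("T%03d", seq_len(n_genes)), each = guides_per_gene),
      d = as.integer(d),
      activation_score = curve(d) + rnorm(n, sd = noise_sd))
  })
}
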