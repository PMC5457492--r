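revcomp_chr <- function(x) {
  stringi::stri_reverse(chartr("ACGT", "TGCA", x))
}

# all NGG PAM 'N' anchors (0-based) on both strands of one contig whose 'N'
# lies in [lo, hi] (0-based, inclusive); spacers must fit inside the contig
pam_sites_in_region <- function(contig_seq, lo, hi) {
  n <- nchar(contig_seq)
  lo <- max(lo, 0L)
  hi <- min(hi, n - 1L)
  if (hi < lo) {
    return(tibble::tibble(pam_n_position = integer(), strand = character(),
                          spacer_seq = character()))
  }
  # inspect a slab two bases beyond the window so PAM GG/CC checks stay local
  slab_lo <- max(lo - 2L, 0L)
  slab_hi <- min(hi + 2L, n - 1L)
  ch <- strsplit(substr(contig_seq, slab_lo + 1L, slab_hi + 1L), "",
                 fixed = TRUE)[[1]]
  pos <- slab_lo + seq_along(ch) - 1L   # 0-based positions of slab chars
  idx <- seq_along(ch)
  # plus strand: bases at p+1, p+2 are G,G; spacer occupies [p-20, p-1]
  plus_ok <- idx <= length(ch) - 2L &
    ch[pmin(idx + 1L, length(ch))] == "G" &
    ch[pmin(idx + 2L, length(ch))] == "G"
  plus_p <- pos[which(plus_ok)]
  plus_p <- plus_p[plus_p >= lo & plus_p <= hi & plus_p >= 20L &
                     plus_p + 2L <= n - 1L]
  # minus strand: plus-strand bases at p-2, p-1 are C,C; spacer at [p+1, p+20]
  minus_ok <- idx >= 3L &
    ch[pmax(idx - 2L, 1L)] == "C" & ch[pmax(idx - 1L, 1L)] == "C"
  minus_p <- pos[which(minus_ok)]
  minus_p <- minus_p[minus_p >= lo & minus_p <= hi & minus_p - 2L >= 0L &
                       minus_p + 20L <= n - 1L]
  spacer_plus <- if (length(plus_p)) {
    substring(contig_seq, plus_p - 20L + 1L, plus_p)
  } else character(0)
  spacer_minus <- if (length(minus_p)) {
    revcomp_chr(substring(contig_seq, minus_p + 1L + 1L,
                          minus_p + 20L + 1L))
  } else character(0)
  pam <- c(plus_p, minus_p)
  strand <- c(rep("+", length(plus_p)), rep("-", length(minus_p)))
  spacer <- c(spacer_plus, spacer_minus)
  ord <- order(pam, strand)
  tibble::tibble(pam_n_position = pam[ord], strand = strand[ord],
                 spacer_seq = spacer[ord])
}

#' Select up to k TSSs per gene
#'
#' Ranks CAGE peaks within each gene by descending peak height (ties to the
#' leftmost coordinate) and keeps the top k; rank 1 is the primary TSS.
#'
#' @param tss TSS tibble; ranked with [rank_tss()] if needed.
#' @param k Maximum TSSs per gene (default 3).
#' @param genes Optional subset of genes.
#' @return The filtered, ranked TSS tibble.
#' @export
select_tss <- function(tss, k = 3L, genes = NULL) {
  if (!"rank_within_gene" %in% names(tss)) tss <- rank_tss(tss)
  if (!is.null(genes)) tss <- tss[tss$gene %in% genes, ]
  tss[tss$rank_within_gene <= k, ]
}

#' Enumerate candidate guides around a TSS
#'
#' Finds every 20-nt spacer immediately 5' of an NGG motif, on either
#' strand, whose PAM 'N' lies within `window` bp of the CAGE peak center
#' (inclusive on both ends; truncated at contig boundaries). The signed
#' distance `d` to the TSS follows the gene's orientation.
#'
#' @param genome A `genome_model`.
#' @param tss_row A one-row TSS tibble (gene, chrom, position, strand).
#' @param window Half-width of the search window in bp (default 200).
#' @return A tibble of candidates: `spacer_seq`, `chrom`, `pam_n_position`,
#'   `strand`, `gene`, `d`.
#' @export
enumerate_candidates <- function(genome, tss_row, window = 200L) {
  if (!tss_row$chrom %in% names(genome$sequences)) {
    abort(paste0("TSS contig not in genome: ", tss_row$chrom))
  }
  contig <- as.character(genome$sequences[[tss_row$chrom]])
  sites <- pam_sites_in_region(contig, tss_row$position - window,
                               tss_row$position + window)
  tibble::tibble(
    spacer_seq = sites$spacer_seq,
    chrom = tss_row$chrom,
    pam_n_position = sites$pam_n_position,
    strand = sites$strand,
    gene = tss_row$gene,
    d = signed_tss_distance(sites$pam_n_position, tss_row$position,
                            rep(tss_row$strand, nrow(sites))))
}

#' Flag candidate guides on exclusion rules
#'
#' Three independent exclusion flags are set: `multimap` (the spacer has a
#' perfect match at more than one genomic locus, both strands),
#' `polyt` (the spacer contains four consecutive T's, a Pol III terminator),
#' and `gc_high` (at least 80 percent C or G). `excluded` is their union.
#'
#' @param cands Candidate tibble ([enumerate_candidates()]).
#' @param genome `genome_model` used for the perfect-match multiplicity scan.
#' @param gc_max Inclusive GC fraction threshold (default 0.8).
#' @return `cands` with added logical columns `multimap`, `polyt`,
#'   `gc_high`, `excluded`.
#' @export
filter_candidates <- function(cands, genome, gc_max = 0.8) {
  if (nrow(cands) == 0) {
    cands$multimap <- logical()
    cands$polyt <- logical()
    cands$gc_high <- logical()
    cands$excluded <- logical()
    return(cands)
  }
  mult <- target_multiplicity(cands$spacer_seq, genome, mode = "exact")
  gc <- (stringr::str_count(cands$spacer_seq, "G") +
           stringr::str_count(cands$spacer_seq, "C")) /
    nchar(cands$spacer_seq)
  cands |>
    dplyr::mutate(
      multimap = mult > 1L,
      polyt = stringr::str_detect(.data$spacer_seq, "TTTT"),
      gc_high = gc >= gc_max,
      excluded = .data$multimap | .data$polyt | .data$gc_high)
}

#' Rank filtered candidates by predicted efficiency and pick the top n
#'
#' Unflagged candidates are scored with the distance-to-TSS efficiency model
#' and the `n` highest-scoring guides are returned (ties break toward the
#' smaller genomic coordinate, then the + strand, for determinism). Fewer
#' than `n` guides may be returned when supply is short.
#'
#' @param cands Filtered candidate tibble ([filter_candidates()]).
#' @param model A fitted `efficiency_model`.
#' @param n Number of guides to keep (7 for the multi-TSS design, 5 for the
#'   genome-scale design).
#' @return The top candidates with an added `predicted_score` column.
#' @export
rank_and_pick <- function(cands, model, n = 7L) {
  pool <- cands[!cands$excluded, , drop = FALSE]
  if (nrow(pool) == 0) {
    pool$predicted_score <- numeric()
    return(pool)
  }
  pool$predicted_score <- predict_efficiency(model, pool$d)
  pool |>
    dplyr::arrange(dplyr::desc(.data$predicted_score),
                   .data$pam_n_position, .data$strand) |>
    head(n)
}

#' Design exon-targeting guides by NGG enumeration
#'
#' Enumerates every NGG-anchored guide whose PAM 'N' falls inside the given
#' coding-exon intervals (which should exclude the first exon) and
#' subsamples uniformly to `n` guides when supply exceeds `n`.
#'
#' @param genome A `genome_model`.
#' @param exons Tibble of 0-based half-open exon intervals: `gene`, `chrom`,
#'   `start`, `end`.
#' @param n Guides to return per call (default 50).
#' @param seed Seed for the uniform subsample.
#' @return A candidate tibble (`spacer_seq`, `chrom`, `pam_n_position`,
#'   `strand`, `gene`).
#' @export
design_exon_tiling <- function(genome, exons, n = 50L, seed = 1L) {
  cand <- purrr::map_dfr(seq_len(nrow(exons)), function(i) {
    contig <- as.character(genome$sequences[[exons$chrom[i]]])
    sites <- pam_sites_in_region(contig, exons$start[i], exons$end[i] - 1L)
    if (nrow(sites) == 0) return(NULL)
    tibble::tibble(spacer_seq = sites$spacer_seq, chrom = exons$chrom[i],
                   pam_n_position = sites$pam_n_position,
                   strand = sites$strand, gene = exons$gene[i])
  })
  if (nrow(cand) > n) {
    cand <- cand[with_seed(seed, sort(sample(nrow(cand), n))), ]
  }
  cand
}

# random ACGT spacers with zero perfect genomic matches
make_nontargeting_spacers <- function(genome, n, seed = 1L,
                                      max_rounds = 50L) {
  found <- character(0)
  with_seed(seed, {
    for (round in seq_len(max_rounds)) {
      if (length(found) >= n) break
      draw <- vapply(seq_len(2L * (n - length(found))), function(i) {
        paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
              collapse = "")
      }, character(1))
      draw <- setdiff(unique(draw), found)
      hits <- target_multiplicity(draw, genome, mode = "exact")
      found <- c(found, draw[hits == 0L])
    }
  })
  if (length(found) < n) {
    abort("could not generate enough genome-free nontargeting spacers")
  }
  found[seq_len(n)]
}

#' Assemble a screening library
#'
#' Builds a full library table from a genome and TSS annotation: per gene,
#' up to `tss_per_gene` CAGE-ranked TSSs each contribute `n_per_tss` guides
#' (SVM-ranked when a model is supplied, otherwise a seeded NGG-only random
#' pick); optional exon guides per gene; AAVS1 safe-harbor guides drawn from
#' a designated neutral region; and non-targeting spacers with zero perfect
#' genome matches.
#'
#' @param genome A `genome_model`.
#' @param tss Ranked TSS tibble.
#' @param genes Genes to design for (default: all genes in `tss`).
#' @param model Optional `efficiency_model`; `NULL` gives NGG-only random
#'   selection within the window.
#' @param tss_per_gene,n_per_tss Design breadth (defaults 1 TSS, 5 guides).
#' @param window Search half-width around each TSS (default 200).
#' @param exons Optional exon interval tibble for exon guides.
#' @param n_exon Exon guides per gene (default 6).
#' @param aavs1_region One-row tibble `chrom`, `start`, `end` of the neutral
#'   locus, or `NULL` to skip AAVS1 guides.
#' @param n_aavs1,n_nontargeting Control guide counts (defaults 100 each).
#' @param seed Seed for all random selections.
#' @return A validated library tibble ([read_library()] layout).
#' @export
assemble_library <- function(genome, tss, genes = NULL, model = NULL,
                             tss_per_gene = 1L, n_per_tss = 5L,
                             window = 200L, exons = NULL, n_exon = 6L,
                             aavs1_region = NULL, n_aavs1 = 100L,
                             n_nontargeting = 100L, seed = 1L) {
  if (is.null(genes)) genes <- unique(tss$gene)
  picked <- select_tss(tss, k = tss_per_gene, genes = genes)
  rows <- list()
  for (i in seq_len(nrow(picked))) {
    tr <- picked[i, ]
    cand <- filter_candidates(enumerate_candidates(genome, tr, window),
                              genome)
    if (is.null(model)) {
      pool <- cand[!cand$excluded, , drop = FALSE]
      take <- min(n_per_tss, nrow(pool))
      sel <- pool[with_seed(seed + i, sort(sample(nrow(pool), take))), ]
      sel$predicted_score <- NA_real_
    } else {
      sel <- rank_and_pick(cand, model, n = n_per_tss)
    }
    if (nrow(sel) == 0) next
    rows[[length(rows) + 1]] <- tibble::tibble(
      spacer_id = sprintf("%s_tss%d_g%02d", tr$gene, tr$rank_within_gene,
                          seq_len(nrow(sel))),
      spacer_seq = sel$spacer_seq, chrom = sel$chrom,
      cut_anchor = sel$pam_n_position, strand = sel$strand,
      target_gene = tr$gene,
      target_class = paste0("tss_", tr$rank_within_gene),
      tss_rank = tr$rank_within_gene)
  }
  if (!is.null(exons)) {
    for (g in intersect(genes, unique(exons$gene))) {
      ex <- design_exon_tiling(genome, exons[exons$gene == g, ], n = n_exon,
                               seed = seed + match(g, genes))
      if (nrow(ex) == 0) next
      rows[[length(rows) + 1]] <- tibble::tibble(
        spacer_id = sprintf("%s_exon_g%02d", g, seq_len(nrow(ex))),
        spacer_seq = ex$spacer_seq, chrom = ex$chrom,
        cut_anchor = ex$pam_n_position, strand = ex$strand,
        target_gene = g, target_class = "exon", tss_rank = NA_integer_)
    }
  }
  if (!is.null(aavs1_region) && n_aavs1 > 0) {
    contig <- as.character(genome$sequences[[aavs1_region$chrom]])
    sites <- pam_sites_in_region(contig, aavs1_region$start,
                                 aavs1_region$end - 1L)
    sites <- filter_candidates(
      tibble::tibble(spacer_seq = sites$spacer_seq,
                     chrom = aavs1_region$chrom,
                     pam_n_position = sites$pam_n_position,
                     strand = sites$strand), genome)
    sites <- sites[!sites$excluded, ]
    take <- min(n_aavs1, nrow(sites))
    sel <- sites[with_seed(seed + 7771L, sort(sample(nrow(sites), take))), ]
    rows[[length(rows) + 1]] <- tibble::tibble(
      spacer_id = sprintf("AAVS1_g%03d", seq_len(nrow(sel))),
      spacer_seq = sel$spacer_seq, chrom = sel$chrom,
      cut_anchor = sel$pam_n_position, strand = sel$strand,
      target_gene = NA_character_, target_class = "aavs1",
      tss_rank = NA_integer_)
  }
  if (n_nontargeting > 0) {
    nt <- make_nontargeting_spacers(genome, n_nontargeting,
                                    seed = seed + 8881L)
    rows[[length(rows) + 1]] <- tibble::tibble(
      spacer_id = sprintf("NT_g%03d", seq_along(nt)),
      spacer_seq = nt, chrom = NA_character_, cut_anchor = NA_integer_,
      strand = NA_character_, target_gene = NA_character_,
      target_class = "nontargeting", tss_rank = NA_integer_)
  }
  validate_library(dplyr::bind_rows(rows))
}
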