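#' Genomic target multiplicity of spacers
#'
#' Counts matching loci on both strands of the genome under three match
#' modes: `exact` (perfect 20-nt match), `one_mismatch` (at most one
#' mismatch), and `partial` (perfect match of the PAM-proximal 3' seed,
#' default 12 nt, the region dominating Cas9 target recognition).
#'
#' @param spacers Character vector of spacer sequences.
#' @param genome A `genome_model`.
#' @param mode Match mode.
#' @param seed_length 3' seed length for `partial` mode (default 12).
#' @return Integer vector of per-spacer match counts.
#' @export
target_multiplicity <- function(spacers,
                                genome,
                                mode = c("exact", "one_mismatch", "partial"),
                                seed_length = 12L) {
  mode <- match.arg(mode)
  if (length(spacers) == 0) return(integer(0))
  query <- spacers
  if (mode == "partial") {
    if (any(nchar(spacers) < seed_length)) {
      abort(sprintf("spacer shorter than the %d-nt partial seed",
                    seed_length))
    }
    query <- substring(spacers, nchar(spacers) - seed_length + 1L,
                       nchar(spacers))
  }
  subject <- genome$sequences
  if (mode == "one_mismatch") {
    counts <- vapply(query, function(q) {
      fwd <- Biostrings::DNAString(q)
      rev <- Biostrings::reverseComplement(fwd)
      sum(Biostrings::vcountPattern(fwd, subject, max.mismatch = 1)) +
        sum(Biostrings::vcountPattern(rev, subject, max.mismatch = 1))
    }, integer(1), USE.NAMES = FALSE)
    return(counts)
  }
  pd_fwd <- Biostrings::PDict(Biostrings::DNAStringSet(query))
  pd_rev <- Biostrings::PDict(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(query)))
  fwd <- rowSums(Biostrings::vcountPDict(pd_fwd, subject))
  rev <- rowSums(Biostrings::vcountPDict(pd_rev, subject))
  as.integer(fwd + rev)
}

#' Fold-change summaries by target-multiplicity bin
#'
#' Summarises guide depletion per multiplicity bin and modality: cutting
#' toxicity makes multi-target guides progressively more depleted under
#' active Cas9, while KRAB-dCas9 guides are insensitive to target count.
#'
#' @param lfc Tibble with columns `sgrna_id`, `modality`, `lfc` (stack the
#'   per-modality fold-change tibbles with a `modality` label).
#' @param multiplicities Tibble with columns `sgrna_id`, `multiplicity`.
#' @param breaks Right-closed bin edges over multiplicity; the default
#'   yields bins 1, 2-5, >5.
#' @return A tibble per (modality, bin): `n`, `median_lfc`, `q25`, `q75`.
#'   Empty bins are reported with `n = 0` and `NA` summaries.
#' @export
multiplicity_effect <- function(lfc, multiplicities,
                                breaks = c(0, 1, 5, Inf)) {
  labels <- vapply(seq_len(length(breaks) - 1L), function(i) {
    lo <- breaks[i] + 1
    hi <- breaks[i + 1]
    if (is.infinite(hi)) paste0(">", breaks[i])
    else if (lo == hi) as.character(hi)
    else paste0(lo, "-", hi)
  }, character(1))
  dat <- dplyr::inner_join(lfc, multiplicities, by = "sgrna_id")
  dat$bin <- cut(dat$multiplicity, breaks = breaks, labels = labels,
                 right = TRUE)
  filled <- tidyr::expand_grid(modality = unique(dat$modality),
                               bin = factor(labels, levels = labels))
  dat |>
    dplyr::group_by(.data$modality, .data$bin) |>
    dplyr::summarise(n = dplyr::n(),
                     median_lfc = median(.data$lfc),
                     q25 = quantile(.data$lfc, 0.25, names = FALSE),
                     q75 = quantile(.data$lfc, 0.75, names = FALSE),
                     .groups = "drop") |>
    dplyr::right_join(filled, by = c("modality", "bin")) |>
    dplyr::mutate(n = tidyr::replace_na(.data$n, 0L)) |>
    dplyr::arrange(.data$modality, .data$bin)
}

#' Per-gene scores across a genomic region
#'
#' The score of a gene is the mean fold-change of its scoring guides:
#' primary-TSS guides for KRAB-dCas9, exon guides for Cas9. Used to scan
#' amplicons, where cutting toxicity depresses every gene under Cas9 but
#' only true drivers under KRAB-dCas9.
#'
#' @param lfc Fold-change tibble.
#' @param library Library tibble.
#' @param genes Genes in the region to score.
#' @param modality `"cas9"` or `"krab_dcas9"`.
#' @return A tibble `gene`, `score`, `n_guides`; genes without guides of the
#'   scoring class get `NA` score and `n_guides = 0`.
#' @export
amplicon_scan <- function(lfc, library, genes,
                          modality = c("cas9", "krab_dcas9")) {
  modality <- match.arg(modality)
  cls <- if (modality == "cas9") "exon" else "tss_1"
  scored <- library |>
    dplyr::filter(.data$target_class == cls, .data$target_gene %in% genes) |>
    dplyr::inner_join(lfc, by = c(spacer_id = "sgrna_id")) |>
    dplyr::group_by(gene = .data$target_gene) |>
    dplyr::summarise(score = mean(.data$lfc), n_guides = dplyr::n(),
                     .groups = "drop")
  tibble::tibble(gene = genes) |>
    dplyr::left_join(scored, by = "gene") |>
    dplyr::mutate(n_guides = tidyr::replace_na(.data$n_guides, 0L))
}

#' Categorize genes by modality-specific essentiality
#'
#' Partitions the gene universe into `both` (called in Cas9 and KRAB-dCas9),
#' `cas9_only`, `krab_only` and `neither`.
#'
#' @param cas9_calls,krab_calls Character vectors of called genes.
#' @param universe All genes under consideration.
#' @return A tibble `gene`, `category` (factor).
#' @export
categorize_genes <- function(cas9_calls, krab_calls, universe) {
  if (length(setdiff(c(cas9_calls, krab_calls), universe)) > 0) {
    abort("call sets must be subsets of the universe")
  }
  in_c <- universe %in% cas9_calls
  in_k <- universe %in% krab_calls
  category <- dplyr::case_when(in_c & in_k ~ "both",
                               in_c ~ "cas9_only",
                               in_k ~ "krab_only",
                               TRUE ~ "neither")
  tibble::tibble(gene = universe,
                 category = factor(category, levels = c("both", "cas9_only",
                                                        "krab_only",
                                                        "neither")))
}

#' Fisher's exact enrichment of a property in a gene category
#'
#' Builds the 2x2 table (in/out of category) x (has/lacks property) over the
#' universe and computes the exact two-sided hypergeometric p-value (sum of
#' all table probabilities not exceeding the observed one). The odds ratio
#' is the sample OR, with a Haldane 0.5 correction when any cell is zero.
#'
#' @param category_members,property_members Character vectors (subsets of
#'   `universe`).
#' @param universe The gene universe.
#' @return A one-row tibble: `odds_ratio`, `p`, and the table cells `a`
#'   (category & property), `b`, `c`, `d`.
#' @export
fisher_enrichment <- function(category_members, property_members, universe) {
  if (length(universe) == 0) abort("empty universe")
  cat_in <- unique(universe) %in% category_members
  prop_in <- unique(universe) %in% property_members
  a <- sum(cat_in & prop_in)
  b <- sum(cat_in & !prop_in)
  c <- sum(!cat_in & prop_in)
  d <- sum(!cat_in & !prop_in)
  p <- fisher_p_two_sided(a, b, c, d)
  or <- if (min(a, b, c, d) == 0) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    (a * d) / (b * c)
  }
  tibble::tibble(odds_ratio = or, p = p, a = a, b = b, c = c, d = d)
}

# exact two-sided p for a 2x2 table with fixed margins: sum the
# hypergeometric probabilities of all tables at most as probable as observed
fisher_p_two_sided <- function(a, b, c, d) {
  m <- a + b          # category size
  n <- c + d
  k <- a + c          # property size
  if (k == 0 || m == 0 || n == 0 || b + d == 0) return(1)
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-07)])
}

#' Detect bidirectional promoters
#'
#' Finds pairs of genes on opposite strands whose primary TSSs lie within
#' `max_dist` bp of each other in divergent orientation (each gene
#' transcribing away from the other, i.e. sharing a promoter region). Such
#' pairs are co-silenced by a single KRAB-dCas9 guide, a CRISPRi-specific
#' off-target source.
#'
#' @param tss Ranked TSS tibble.
#' @param max_dist Maximum TSS-TSS distance in bp (default 1000, inclusive).
#' @return A list with `pairs` (tibble `gene_a`, `gene_b`, `tss_distance`,
#'   `orientation`) and `fraction` (genes in at least one divergent pair
#'   over all genes with a primary TSS).
#' @export
detect_bidirectional <- function(tss, max_dist = 1000L) {
  if (!"rank_within_gene" %in% names(tss)) tss <- rank_tss(tss)
  prim <- tss[tss$rank_within_gene == 1L, ] |>
    dplyr::arrange(.data$chrom, .data$position, .data$gene)
  pairs <- list()
  if (nrow(prim) > 1) {
    for (i in seq_len(nrow(prim) - 1L)) {
      j <- i + 1L
      while (j <= nrow(prim) && prim$chrom[j] == prim$chrom[i] &&
               prim$position[j] - prim$position[i] <= max_dist) {
        if (prim$strand[i] != prim$strand[j]) {
          left <- i
          right <- j
          orientation <- if (prim$strand[left] == "-" &&
                               prim$strand[right] == "+") "divergent"
          else "convergent"
          if (orientation == "divergent") {
            pairs[[length(pairs) + 1]] <- tibble::tibble(
              gene_a = min(prim$gene[i], prim$gene[j]),
              gene_b = max(prim$gene[i], prim$gene[j]),
              tss_distance = prim$position[j] - prim$position[i],
              orientation = orientation)
          }
        }
        j <- j + 1L
      }
    }
  }
  pairs <- if (length(pairs) > 0) dplyr::bind_rows(pairs) else {
    tibble::tibble(gene_a = character(), gene_b = character(),
                   tss_distance = integer(), orientation = character())
  }
  genes_in_pairs <- unique(c(pairs$gene_a, pairs$gene_b))
  list(pairs = pairs,
       fraction = length(genes_in_pairs) / max(nrow(prim), 1L))
}

#' Essentiality calls versus distance to the nearest reference essential
#'
#' For every gene outside the reference-essential set, measures the distance
#' from its primary TSS to the nearest reference-essential primary TSS and
#' reports, per distance bin, the fraction of genes called essential. A
#' raised fraction in the sub-kilobase bin indicates promoter-sharing
#' off-targets.
#'
#' @param tss Ranked TSS tibble.
#' @param reference_essential Character vector of reference essential genes.
#' @param calls Genes called essential (e.g. in the CRISPRi screen).
#' @param breaks Right-open distance bin edges covering `[0, Inf)`.
#' @return A tibble per bin: `n_genes`, `n_called`, `fraction` (`NA` when
#'   the bin is empty or no reference gene shares the contig).
#' @export
proximity_to_essential <- function(tss, reference_essential, calls,
                                   breaks = c(0, 1000, 10000, Inf)) {
  if (!"rank_within_gene" %in% names(tss)) tss <- rank_tss(tss)
  prim <- tss[tss$rank_within_gene == 1L, ]
  ref <- prim[prim$gene %in% reference_essential, ]
  other <- prim[!prim$gene %in% reference_essential, ]
  labels <- vapply(seq_len(length(breaks) - 1L), function(i) {
    if (is.infinite(breaks[i + 1])) paste0(">=", breaks[i])
    else paste0("[", breaks[i], ",", breaks[i + 1], ")")
  }, character(1))
  if (nrow(ref) == 0 || nrow(other) == 0) {
    return(tibble::tibble(bin = factor(labels, levels = labels),
                          n_genes = 0L, n_called = 0L, fraction = NA_real_))
  }
  nearest <- vapply(seq_len(nrow(other)), function(i) {
    same <- ref[ref$chrom == other$chrom[i], ]
    if (nrow(same) == 0) return(Inf)
    min(abs(same$position - other$position[i]))
  }, numeric(1))
  bin <- cut(nearest, breaks = breaks, labels = labels, right = FALSE)
  tibble::tibble(gene = other$gene, bin = bin,
                 called = other$gene %in% calls) |>
    dplyr::filter(!is.na(.data$bin)) |>
    dplyr::group_by(.data$bin, .drop = FALSE) |>
    dplyr::summarise(n_genes = dplyr::n(), n_called = sum(.data$called),
                     .groups = "drop") |>
    dplyr::mutate(fraction = ifelse(.data$n_genes > 0,
                                    .data$n_called / .data$n_genes,
                                    NA_real_))
  }
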