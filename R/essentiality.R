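#' Negative-control statistics from AAVS1-targeting guides
#'
#' AAVS1 guides cut (or bind) a safe-harbor locus, so they experience the
#' gene-independent part of the modality's effect (e.g. cutting toxicity)
#' without any on-target fitness consequence; they define the null for the
#' gene Z-test. The standard deviation uses the n-1 denominator.
#'
#' @param lfc Fold-change tibble ([log_fold_change()]).
#' @param library Library tibble ([read_library()]).
#' @param control_class Library class of the control guides (`"aavs1"`).
#' @return A one-row tibble with `m_control`, `sigma_control`, `n_controls`.
#' @export
control_stats <- function(lfc, library, control_class = "aavs1") {
  ids <- library$spacer_id[library$target_class == control_class]
  x <- lfc$lfc[lfc$sgrna_id %in% ids]
  if (length(x) < 2) abort("need at least 2 control guides with fold-changes")
  s <- sd(x)
  if (s <= 0) abort("control fold-changes have zero spread; Z-test undefined")
  tibble::tibble(m_control = mean(x), sigma_control = s,
                 n_controls = length(x))
}

# guides used for gene scoring in each modality: exon guides for Cas9
# knockout, primary-TSS guides for KRAB-dCas9 silencing
scoring_class <- function(mode) {
  switch(mode, exon = "exon", primary_tss = "tss_1",
         abort(paste0("unknown scoring mode: ", mode)))
}

#' Gene essentiality Z-scores against AAVS1 controls
#'
#' For each gene g with N_g scoring guides of mean fold-change m_g,
#' z = (m_g - m_control) / (sigma_control / sqrt(N_g)) and p is the
#' one-sided lower-tail normal probability (essentiality manifests as
#' guide depletion).
#'
#' @inheritParams control_stats
#' @param mode `"exon"` (CRISPRc) or `"primary_tss"` (CRISPRi): which guide
#'   class scores a gene.
#' @param controls Control statistics from [control_stats()]; computed from
#'   `lfc` when `NULL`.
#' @param genes Genes to score; defaults to every gene with scoring guides.
#' @return A tibble with columns `gene`, `mode`, `n_g`, `m_g`, `z`, `p`.
#' @export
score_genes <- function(lfc, library, mode = c("exon", "primary_tss"),
                        controls = NULL, genes = NULL) {
  mode <- match.arg(mode)
  if (is.null(controls)) controls <- control_stats(lfc, library)
  cls <- scoring_class(mode)
  guides <- library |>
    dplyr::filter(.data$target_class == cls, !is.na(.data$target_gene)) |>
    dplyr::inner_join(lfc, by = c(spacer_id = "sgrna_id"))
  if (!is.null(genes)) {
    missing <- setdiff(genes, guides$target_gene)
    if (length(missing) > 0) {
      abort(paste0("no '", cls, "' guides with fold-changes for gene(s): ",
                   paste(missing, collapse = ", ")))
    }
    guides <- guides[guides$target_gene %in% genes, ]
  }
  if (nrow(guides) == 0) abort("no scoring guides found")
  guides |>
    dplyr::group_by(gene = .data$target_gene) |>
    dplyr::summarise(n_g = dplyr::n(), m_g = mean(.data$lfc),
                     .groups = "drop") |>
    dplyr::mutate(
      mode = mode,
      z = (.data$m_g - controls$m_control) /
        (controls$sigma_control / sqrt(.data$n_g)),
      p = pnorm(.data$z)) |>
    dplyr::select("gene", "mode", "n_g", "m_g", "z", "p") |>
    dplyr::arrange(.data$p, .data$gene)
}

#' Z-score for a single gene
#'
#' @inheritParams score_genes
#' @param gene Gene symbol.
#' @return A one-row tibble (see [score_genes()]).
#' @export
gene_zscore <- function(lfc, library, gene, mode = c("exon", "primary_tss"),
                        controls = NULL) {
  score_genes(lfc, library, mode = mode, controls = controls, genes = gene)
}

#' Call essential genes at a P threshold
#'
#' @param scores Gene score tibble from [score_genes()].
#' @param p_threshold Strict upper bound on the one-sided P (default 0.01).
#' @return Character vector of called genes.
#' @export
call_essential <- function(scores, p_threshold = 0.01) {
  scores$gene[scores$p < p_threshold]
}

#' Sensitivity against a reference essential-gene set
#'
#' @param calls Called genes.
#' @param reference Reference set (e.g. core essential genes).
#' @return Fraction of the reference recovered, in `[0, 1]`.
#' @export
sensitivity <- function(calls, reference) {
  if (length(reference) == 0) abort("reference set is empty")
  length(intersect(calls, reference)) / length(unique(reference))
}

#' Fraction of effective guides
#'
#' A guide is counted as effective when its fold-change falls below the
#' q-quantile of the negative-control fold-change distribution, i.e. it is
#' depleted beyond what q of null guides reach. This control-calibrated
#' definition transfers across screens without a fixed fold-change cutoff.
#'
#' @param lfc Fold-change tibble.
#' @param guide_ids Ids of the guides to assess.
#' @param null_lfc Numeric vector of negative-control fold-changes.
#' @param q Null quantile defining the effectiveness threshold (default 0.05).
#' @return Fraction in `[0, 1]`.
#' @export
effective_fraction <- function(lfc, guide_ids, null_lfc, q = 0.05) {
  if (length(null_lfc) == 0) abort("null fold-change set is empty")
  x <- lfc$lfc[lfc$sgrna_id %in% guide_ids]
  if (length(x) == 0) abort("no guides with fold-changes in the given set")
  if (q <= 0) return(0)
  mean(x < quantile(null_lfc, probs = q, type = 7, names = FALSE))
}
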