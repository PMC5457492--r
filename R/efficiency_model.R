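# evaluate `code` under a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Signed distance from a guide's PAM to the TSS
#'
#' The distance anchor is the genomic position of the 'N' in the NGG PAM;
#' sign follows the gene's orientation: negative upstream of the TSS,
#' positive downstream. For plus-strand genes d = pam - tss; for
#' minus-strand genes the sign flips.
#'
#' @param pam_position 0-based genomic position(s) of the PAM 'N'.
#' @param tss_position 0-based TSS position(s).
#' @param gene_strand `"+"` or `"-"` per element.
#' @param pam_chrom,tss_chrom Optional contig names; a mismatch is an error.
#' @return Integer vector of signed distances in bp.
#' @export
signed_tss_distance <- function(pam_position, tss_position, gene_strand,
                                pam_chrom = NULL, tss_chrom = NULL) {
  if (!is.null(pam_chrom) && !is.null(tss_chrom)) {
    bad <- which(pam_chrom != tss_chrom)
    if (length(bad) > 0) {
      abort(sprintf("guide and TSS on different contigs (%s vs %s)",
                    pam_chrom[bad[1]], tss_chrom[bad[1]]))
    }
  }
  d <- as.integer(pam_position) - as.integer(tss_position)
  as.integer(ifelse(gene_strand == "-", -d, d))
}

#' Distances of library guides to their gene's primary TSS
#'
#' @param library Library tibble.
#' @param tss Ranked TSS tibble ([read_tss_bed()]).
#' @param rank TSS rank to measure against (default 1, the primary TSS).
#' @return The library tibble with an added `d` column (NA for guides with
#'   no annotated gene/TSS).
#' @export
guide_tss_distances <- function(library, tss, rank = 1L) {
  prim <- tss[tss$rank_within_gene == rank,
              c("gene", "chrom", "position", "strand")]
  names(prim) <- c("target_gene", "tss_chrom", "tss_position", "gene_strand")
  out <- dplyr::left_join(library, prim, by = "target_gene")
  ok <- !is.na(out$tss_position) & !is.na(out$cut_anchor)
  out$d <- NA_integer_
  out$d[ok] <- signed_tss_distance(out$cut_anchor[ok], out$tss_position[ok],
                                   out$gene_strand[ok], out$chrom[ok],
                                   out$tss_chrom[ok])
  dplyr::select(out, -"tss_chrom", -"tss_position", -"gene_strand")
}

#' Refine an activation-score training set
#'
#' Keeps only genes that (i) appear in both the RefSeq and FANTOM gene
#' annotations, (ii) contribute at least `min_guides` guides, and (iii) show
#' an interquartile range of activation scores strictly greater than
#' `min_iqr`, i.e. genes with both efficient and inefficient guides.
#'
#' @param train Tibble with columns `gene`, `d`, `activation_score` (one row
#'   per guide).
#' @param refseq_genes,fantom_genes Character vectors of annotated gene
#'   symbols.
#' @param min_guides Minimum guides per gene (default 7).
#' @param min_iqr Strict lower bound on P75 - P25 of activation scores
#'   (default 0.5).
#' @return The filtered tibble (possibly empty), all guides of passing genes.
#' @export
refine_training_set <- function(train, refseq_genes, fantom_genes,
                                min_guides = 7L, min_iqr = 0.5) {
  keep <- train |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n = dplyr::n(),
      iqr = diff(quantile(.data$activation_score, c(0.25, 0.75),
                          type = 7, names = FALSE)),
      .groups = "drop") |>
    dplyr::filter(.data$gene %in% refseq_genes,
                  .data$gene %in% fantom_genes,
                  .data$n >= min_guides,
                  .data$iqr > min_iqr)
  train[train$gene %in% keep$gene, ]
}

# RBF eps-SVR fit reduced to its dual solution; prediction is computed from
# the support expansion directly so empty models (all residuals inside the
# tube) degenerate gracefully to the constant -rho
svr_fit <- function(d, y, gamma, cost, epsilon) {
  fit <- e1071::svm(x = matrix(d, ncol = 1), y = y,
                    type = "eps-regression", kernel = "radial",
                    gamma = gamma, cost = cost, epsilon = epsilon,
                    scale = FALSE, fitted = FALSE)
  list(support_d = as.numeric(fit$SV[, 1]),
       coefs = as.numeric(fit$coefs[, 1]),
       rho = as.numeric(fit$rho),
       gamma = gamma)
}

svr_predict <- function(fit, d) {
  if (length(fit$support_d) == 0) return(rep(-fit$rho, length(d)))
  k <- exp(-fit$gamma * outer(as.numeric(d), fit$support_d, "-")^2)
  as.numeric(k %*% fit$coefs - fit$rho)
}

#' Fit the distance-to-TSS efficiency model
#'
#' Support-vector eps-regression of guide activation score on the signed
#' PAM-to-TSS distance, with a Gaussian (RBF) kernel on the scalar distance.
#' Kernel bandwidth and regularization cost are selected by a small internal
#' k-fold cross-validation grid; the fitted model is a pure deterministic
#' function of distance and serializes to plain JSON.
#'
#' @param train Tibble with columns `d` (signed bp) and `activation_score`;
#'   a `gene` column is carried through to metadata when present.
#' @param bandwidths Candidate RBF bandwidths in bp (kernel
#'   `exp(-(d - d')^2 / (2 * bw^2))`).
#' @param costs Candidate regularization costs.
#' @param epsilon Width of the eps-insensitive tube (default 0.1).
#' @param cv_folds Internal CV folds for grid selection (default 5).
#' @param seed Seed for the internal fold assignment.
#' @param tss_source Annotation label stored in metadata (`"fantom"` or
#'   `"refseq"`).
#' @return An object of class `efficiency_model`.
#' @export
fit_distance_svm <- function(train, bandwidths = c(50, 100, 200),
                             costs = c(1, 10), epsilon = 0.1, cv_folds = 5L,
                             seed = 1L, tss_source = "fantom") {
  d <- as.numeric(train$d)
  y <- as.numeric(train$activation_score)
  if (length(d) < 2 || length(unique(d)) < 2) {
    abort("degenerate training set: need >= 2 distinct distances")
  }
  grid <- expand.grid(bandwidth = bandwidths, cost = costs)
  if (nrow(grid) > 1 && length(d) >= 2 * cv_folds) {
    folds <- with_seed(seed, sample(rep_len(seq_len(cv_folds), length(d))))
    grid$cv_mse <- vapply(seq_len(nrow(grid)), function(g) {
      gamma <- 1 / (2 * grid$bandwidth[g]^2)
      errs <- vapply(seq_len(cv_folds), function(k) {
        tr <- folds != k
        fit <- svr_fit(d[tr], y[tr], gamma, grid$cost[g], epsilon)
        mean((y[!tr] - svr_predict(fit, d[!tr]))^2)
      }, numeric(1))
      mean(errs)
    }, numeric(1))
    best <- which.min(grid$cv_mse)
  } else {
    grid$cv_mse <- NA_real_
    best <- 1L
  }
  bw <- grid$bandwidth[best]
  cost <- grid$cost[best]
  gamma <- 1 / (2 * bw^2)
  fit <- svr_fit(d, y, gamma, cost, epsilon)
  structure(list(
    kernel = "rbf",
    bandwidth = bw,
    gamma = gamma,
    cost = cost,
    epsilon = epsilon,
    support_d = fit$support_d,
    coefs = fit$coefs,
    rho = fit$rho,
    domain = range(d),
    n_train = length(d),
    n_genes = if ("gene" %in% names(train)) length(unique(train$gene))
              else NA_integer_,
    tss_source = tss_source,
    cv_grid = tibble::as_tibble(grid)
  ), class = "efficiency_model")
}

#' Predict guide efficiency from distance to the TSS
#'
#' Distances outside the training domain are clamped to the nearest edge to
#' avoid kernel extrapolation artifacts.
#'
#' @param model An `efficiency_model`.
#' @param d Signed distances in bp.
#' @return Numeric efficiency scores, one per distance.
#' @export
predict_efficiency <- function(model, d) {
  if (!inherits(model, "efficiency_model") || is.null(model$support_d)) {
    abort("not a fitted efficiency_model")
  }
  d <- pmin(pmax(as.numeric(d), model$domain[1]), model$domain[2])
  svr_predict(model, d)
}

#' @export
predict.efficiency_model <- function(object, d, ...) {
  predict_efficiency(object, d)
}

#' @export
print.efficiency_model <- function(x, ...) {
  cat(sprintf(
    "<efficiency_model> RBF eps-SVR on TSS distance (%s TSS annotation)\n",
    x$tss_source))
  cat(sprintf("  bandwidth %g bp, cost %g, epsilon %g, %d support points\n",
              x$bandwidth, x$cost, x$epsilon, length(x$support_d)))
  cat(sprintf("  trained on %d guides, domain [%g, %g] bp\n",
              x$n_train, x$domain[1], x$domain[2]))
  invisible(x)
}

#' Distance of peak predicted efficiency
#'
#' @param model An `efficiency_model`.
#' @param step Grid step in bp for the search (default 1).
#' @return The distance (bp) maximizing the predicted efficiency over the
#'   training domain.
#' @export
peak_efficiency_distance <- function(model, step = 1) {
  grid <- seq(model$domain[1], model$domain[2], by = step)
  grid[which.max(predict_efficiency(model, grid))]
}

#' Gene-level cross-validation of the efficiency model
#'
#' Genes (never individual guides of one gene) are split into a training
#' fraction and a held-out test fraction; the model is fitted on the
#' training genes and evaluated on the held-out guides. The reported metric
#' is the Spearman correlation between predicted and observed activation
#' scores, computed within each held-out gene (with >= 3 guides and
#' non-constant scores) and averaged across genes.
#'
#' @param train Tibble with columns `gene`, `d`, `activation_score`.
#' @param prop_train Fraction of genes used for training (default 2/3).
#' @param seed Seed controlling the gene split.
#' @param ... Passed to [fit_distance_svm()].
#' @return A one-row tibble: `metric`, `n_train_genes`, `n_test_genes`,
#'   `n_test_guides`, `seed`.
#' @export
cross_validate_model <- function(train, prop_train = 2 / 3, seed = 1L, ...) {
  genes <- unique(train$gene)
  if (length(genes) < 3) abort("need >= 3 genes for a gene-level split")
  n_tr <- max(1L, round(length(genes) * prop_train))
  tr_genes <- with_seed(seed, sample(genes, n_tr))
  tr <- train[train$gene %in% tr_genes, ]
  te <- train[!train$gene %in% tr_genes, ]
  model <- fit_distance_svm(tr, seed = seed, ...)
  te$pred <- predict_efficiency(model, te$d)
  per_gene <- te |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      rho = if (dplyr::n() >= 3 && sd(.data$activation_score) > 0 &&
                  sd(.data$pred) > 0) {
        cor(.data$pred, .data$activation_score, method = "spearman")
      } else NA_real_,
      .groups = "drop")
  tibble::tibble(metric = mean(per_gene$rho, na.rm = TRUE),
                 n_train_genes = length(tr_genes),
                 n_test_genes = length(unique(te$gene)),
                 n_test_guides = nrow(te),
                 seed = as.integer(seed))
}

#' Serialize / restore an efficiency model
#'
#' Models are written as self-describing JSON (kernel parameters, support
#' points, weights, domain, metadata) and reload to bit-identical
#' predictions.
#'
#' @param model An `efficiency_model`.
#' @param path Output/input path.
#' @return `path` invisibly for write; the model for read.
#' @export
write_efficiency_model <- function(model, path) {
  obj <- model[c("kernel", "bandwidth", "gamma", "cost", "epsilon",
                 "support_d", "coefs", "rho", "domain", "n_train",
                 "n_genes", "tss_source")]
  obj$format_version <- 1L
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_efficiency_model
#' @export
read_efficiency_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$format_version <- NULL
  obj$cv_grid <- NULL
  structure(obj, class = "efficiency_model")
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' Tidy an efficiency model
#'
#' @param x An `efficiency_model`.
#' @param ... Unused.
#' @return A tibble of support points (`support_d`) and their dual weights
#'   (`weight`).
#' @export
tidy.efficiency_model <- function(x, ...) {
  tibble::tibble(support_d = x$support_d, weight = x$coefs)
}

#' One-row summary of an efficiency model
#'
#' @param x An `efficiency_model`.
#' @param ... Unused.
#' @return A one-row tibble with kernel hyperparameters, training size and
#'   prediction domain.
#' @export
glance.efficiency_model <- function(x, ...) {
  tibble::tibble(kernel = x$kernel, bandwidth = x$bandwidth, cost = x$cost,
                 epsilon = x$epsilon, n_support = length(x$support_d),
                 n_train = x$n_train, n_genes = x$n_genes,
                 domain_lo = x$domain[1], domain_hi = x$domain[2],
                 tss_source = x$tss_source)
}
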