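# independent oracle: position-by-position scan for 20-mer + NGG on both
# strands of a contig string (0-based coordinates)
scan_pams_oracle <- function(seq, lo, hi) {
  n <- nchar(seq)
  rc1 <- function(b) chartr("ACGT", "TGCA", b)
  hits <- list()
  for (p in max(lo, 0):min(hi, n - 1)) {
    i <- p + 1  # 1-based
    if (p >= 20 && p + 2 <= n - 1 &&
          substr(seq, i + 1, i + 1) == "G" &&
          substr(seq, i + 2, i + 2) == "G") {
      hits[[length(hits) + 1]] <- list(p = p, s = "+",
                                       sp = substr(seq, i - 20, i - 1))
    }
    if (p - 2 >= 0 && p + 20 <= n - 1 &&
          substr(seq, i - 1, i - 1) == "C" &&
          substr(seq, i - 2, i - 2) == "C") {
      sp <- paste(rev(vapply((i + 1):(i + 20), function(k) {
        rc1(substr(seq, k, k))
      }, character(1))), collapse = "")
      hits[[length(hits) + 1]] <- list(p = p, s = "-", sp = sp)
    }
  }
  hits
}

test_that("TSS selection keeps the top-k peaks with deterministic ties", {
  tss <- tibble::tibble(gene = "G", chrom = "chr1",
                        position = c(10L, 20L, 30L, 40L, 50L) * 100L,
                        strand = "+", peak_height = c(5, 50, 20, 30, 10))
  top <- select_tss(tss, k = 3)
  expect_equal(sort(top$position), c(2000L, 3000L, 4000L))
  expect_equal(top$position[top$rank_within_gene == 1], 2000L)
  expect_equal(nrow(select_tss(tss[1:2, ], k = 3)), 2L)
  tied <- tibble::tibble(gene = "G", chrom = "chr1",
                         position = c(900L, 100L), strand = "+",
                         peak_height = c(9, 9))
  expect_equal(select_tss(tied, k = 1)$position, 100L)
})

test_that("candidate enumeration finds the one planted site, else matches the oracle", {
  contig <- single_site_contig()
  gm <- genome_model(c(chr1 = contig))
  pam_pos <- as.integer(regexpr("AGG", contig)) - 1L + 0L  # 0-based 'A' of AGG
  tss <- tibble::tibble(gene = "G", chrom = "chr1", position = pam_pos,
                        strand = "+")
  cand <- enumerate_candidates(gm, tss, window = 200L)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$d, 0L)
  expect_equal(cand$pam_n_position, pam_pos)

  # no GG or CC anywhere: no candidates
  atat <- genome_model(c(chr1 = strrep("AT", 300)))
  tss2 <- tibble::tibble(gene = "G", chrom = "chr1", position = 300L,
                         strand = "+")
  expect_equal(nrow(enumerate_candidates(atat, tss2, 200L)), 0L)

  # random contig: exhaustive-scan oracle agreement (both strands)
  set.seed(77)
  rand <- paste(sample(c("A", "C", "G", "T"), 700, replace = TRUE),
                collapse = "")
  gmr <- genome_model(c(chr1 = rand))
  tss3 <- tibble::tibble(gene = "G", chrom = "chr1", position = 350L,
                         strand = "-")
  cand3 <- enumerate_candidates(gmr, tss3, window = 150L)
  oracle <- scan_pams_oracle(rand, 200, 500)
  expect_equal(nrow(cand3), length(oracle))
  key <- function(p, s) paste(p, s)
  expect_setequal(key(cand3$pam_n_position, cand3$strand),
                  key(vapply(oracle, `[[`, numeric(1), "p"),
                      vapply(oracle, `[[`, character(1), "s")))
  expect_setequal(cand3$spacer_seq,
                  vapply(oracle, `[[`, character(1), "sp"))
  # minus-strand gene: d sign flips
  expect_equal(cand3$d, -(cand3$pam_n_position - 350L))
  expect_error(enumerate_candidates(gmr,
                                    dplyr::mutate(tss3, chrom = "chrX")),
               "not in genome")
})

test_that("exclusion flags implement the poly-T, GC and multimap rules", {
  base <- single_site_contig()
  dup_spacer <- "ACACACACACACACACACAC"        # will be planted twice
  genome <- genome_model(c(
    chr1 = base,
    chr2 = paste0(strrep("AT", 30), dup_spacer, "AGG", strrep("TA", 30),
                  dup_spacer, "TGG", strrep("AT", 10))))
  cands <- tibble::tibble(
    spacer_seq = c("AAATACGTACGTACGTAAAT",       # clean: no flags apply
                   "ACGTATTTTCGTACGTACGT",       # poly-T at positions 5-8
                   "GCGCGCGCGCGCGCGCATAT",       # 16/20 = 80% GC exactly
                   dup_spacer),                  # two perfect loci
    chrom = "chr1", pam_n_position = 230L, strand = "+",
    gene = "G", d = 0L)
  out <- filter_candidates(cands, genome)
  expect_equal(out$polyt, c(FALSE, TRUE, FALSE, FALSE))
  expect_equal(out$gc_high, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(out$multimap, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(out$excluded, c(FALSE, TRUE, TRUE, TRUE))
  # 15/20 GC stays clean
  out2 <- filter_candidates(
    dplyr::mutate(cands[3, ], spacer_seq = "GCGCGCGCGCGCGCGATATA"), genome)
  expect_false(out2$gc_high)
})

test_that("ranking keeps the top-n unflagged candidates deterministically", {
  train <- simulate_activation_data(n_genes = 20, seed = 31)
  model <- fit_distance_svm(train, bandwidths = 150, costs = 1)
  cands <- tibble::tibble(
    spacer_seq = strrep("ACGT", 5), chrom = "chr1",
    pam_n_position = c(100L, 200L, 300L, 400L),
    strand = "+", gene = "G",
    d = c(100L, -700L, 250L, 900L),
    multimap = FALSE, polyt = c(FALSE, FALSE, FALSE, TRUE),
    gc_high = FALSE, excluded = c(FALSE, FALSE, FALSE, TRUE))
  picks <- rank_and_pick(cands, model, n = 2)
  scores <- predict_efficiency(model, cands$d[1:3])
  expect_equal(nrow(picks), 2L)
  expect_equal(picks$d, cands$d[1:3][order(-scores)][1:2])
  expect_false(any(picks$excluded))
  # undersupply returns what exists
  expect_equal(nrow(rank_and_pick(cands, model, n = 10)), 3L)
  # identical across runs
  expect_identical(rank_and_pick(cands, model, n = 2), picks)
})

test_that("exon tiling stays inside intervals and subsamples reproducibly", {
  set.seed(55)
  seq <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE),
               collapse = "")
  gm <- genome_model(c(chr1 = seq))
  exons <- tibble::tibble(gene = "G", chrom = "chr1",
                          start = c(500L, 2000L), end = c(1200L, 2600L))
  all_g <- design_exon_tiling(gm, exons, n = 10000L)
  expect_true(all((all_g$pam_n_position >= 500 &
                     all_g$pam_n_position < 1200) |
                    (all_g$pam_n_position >= 2000 &
                       all_g$pam_n_position < 2600)))
  sub1 <- design_exon_tiling(gm, exons, n = 50L, seed = 4)
  sub2 <- design_exon_tiling(gm, exons, n = 50L, seed = 4)
  expect_equal(nrow(sub1), 50L)
  expect_identical(sub1, sub2)
  none <- design_exon_tiling(gm, tibble::tibble(gene = "G", chrom = "chr1",
                                                start = 500L, end = 505L))
  expect_equal(nrow(none), 0L)
})

test_that("assembled libraries honor class counts and nontargeting purity", {
  sim <- make_genome(sim_config(n_genes = 12, n_essential = 2,
                                n_amplified = 0, n_bidirectional_pairs = 0,
                                n_multicopy = 0), seed = 19)
  genes <- sim$truth$genes$gene[1:2]
  lib <- assemble_library(sim$genome, sim$tss, genes = genes, model = NULL,
                          tss_per_gene = 1, n_per_tss = 5,
                          aavs1_region = sim$aavs1_region, n_aavs1 = 5,
                          n_nontargeting = 10, seed = 2)
  tab <- table(lib$target_class)
  expect_equal(unname(tab[["tss_1"]]), 10L)
  expect_equal(unname(tab[["aavs1"]]), 5L)
  expect_equal(unname(tab[["nontargeting"]]), 10L)
  expect_equal(nrow(lib), 25L)

  # independent oracle for nontargeting purity: plain string search
  nt <- lib$spacer_seq[lib$target_class == "nontargeting"]
  contigs <- as.character(sim$genome$sequences)
  rc <- function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }
  for (sp in nt) {
    hit <- any(vapply(contigs, function(ct) {
      grepl(sp, ct, fixed = TRUE) || grepl(rc(sp), ct, fixed = TRUE)
    }, logical(1)))
    expect_false(hit)
  }
})
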