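test_that("target multiplicity counts loci under exact, mismatch and seed modes", {
  sp <- "ACGATCAGGATCCTAGCTAA"
  rc <- function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }
  pad <- strrep("T", 30)
  one_mm <- paste0("CCGATCAGGATCCTAGCTAA")  # one substitution at position 1
  gm <- genome_model(c(
    chr1 = paste0(pad, sp, pad, sp, pad),
    chr2 = paste0(pad, rc(sp), pad, one_mm, pad)))
  expect_equal(target_multiplicity(sp, gm, "exact"), 3L)
  expect_equal(target_multiplicity(sp, gm, "one_mismatch"), 4L)
  expect_equal(target_multiplicity("GGGGGGGGGGGGGGGGGGGG", gm, "exact"), 0L)
  # 3' 12-nt seed is shared by sp and one_mm -> partial finds all four
  expect_equal(target_multiplicity(sp, gm, "partial"), 4L)
  expect_error(target_multiplicity("ACGTACG", gm, "partial"),
               "partial seed")
  # vectorized over spacers
  expect_equal(target_multiplicity(c(sp, "AAAACCCCAAAACCCCAAAA"), gm,
                                   "exact"), c(3L, 0L))
})

test_that("multiplicity bins show cutting toxicity in Cas9 but not CRISPRi", {
  scr <- default_screens()
  truth <- scr$truth
  mult <- tibble::tibble(sgrna_id = truth$spacer_id,
                         multiplicity = truth$multiplicity)
  targeting <- truth$spacer_id[truth$target_class %in% c("tss_1", "exon") &
                                 !truth$target_gene %in%
                                   scr$sim$truth$genes$gene[
                                     scr$sim$truth$genes$essential] &
                                 truth$cn == 2L]
  both <- dplyr::bind_rows(
    dplyr::mutate(scr$lfc_cas9[scr$lfc_cas9$sgrna_id %in% targeting, ],
                  modality = "cas9"),
    dplyr::mutate(scr$lfc_krab[scr$lfc_krab$sgrna_id %in% targeting, ],
                  modality = "krab_dcas9"))
  eff <- multiplicity_effect(both, mult)
  cas9 <- eff[eff$modality == "cas9", ]
  krab <- eff[eff$modality == "krab_dcas9", ]
  expect_true(all(cas9$n > 0))
  expect_true(all(diff(cas9$median_lfc) < 0))   # 1 > 2-5 > >5
  expect_true(all(abs(krab$median_lfc) < 0.25, na.rm = TRUE))

  # single-bin input reduces to a plain summary
  single <- multiplicity_effect(
    tibble::tibble(sgrna_id = c("a", "b"), modality = "cas9",
                   lfc = c(-1, -3)),
    tibble::tibble(sgrna_id = c("a", "b"), multiplicity = 1L),
    breaks = c(0, Inf))
  expect_equal(single$median_lfc, -2)
  expect_equal(single$n, 2L)
})

test_that("amplicon scans depress every gene under Cas9 but only drivers under CRISPRi", {
  scr <- default_screens()
  genes <- scr$sim$truth$genes
  amp <- genes$gene[genes$amplified]
  driver <- genes$gene[genes$amplified & genes$essential]
  passenger <- setdiff(amp, driver)
  cas9 <- amplicon_scan(scr$lfc_cas9, scr$lib, amp, "cas9")
  krab <- amplicon_scan(scr$lfc_krab, scr$lib, amp, "krab_dcas9")
  expect_true(all(cas9$score < -1))
  expect_true(all(krab$score[krab$gene %in% passenger] > -0.75))
  expect_true(all(krab$score[krab$gene %in% driver] < -0.75))

  # definition: score is exactly the mean of the gene's scoring-guide lfc
  g <- driver[1]
  ids <- scr$lib$spacer_id[scr$lib$target_gene == g &
                             scr$lib$target_class == "tss_1"]
  expect_equal(krab$score[krab$gene == g],
               mean(scr$lfc_krab$lfc[scr$lfc_krab$sgrna_id %in% ids]))

  # a diploid region without essential genes scores near zero in both
  null_genes <- genes$gene[!genes$essential & !genes$amplified &
                             is.na(genes$partner)][1:10]
  c0 <- amplicon_scan(scr$lfc_cas9, scr$lib, null_genes, "cas9")
  k0 <- amplicon_scan(scr$lfc_krab, scr$lib, null_genes, "krab_dcas9")
  expect_true(all(abs(c0$score + 0.3) < 0.5))  # small uniform cutting term
  expect_true(all(abs(k0$score) < 0.5))
  # genes without scoring guides are reported missing, not errors
  miss <- amplicon_scan(scr$lfc_cas9, scr$lib, c(amp[1], "ABSENT"), "cas9")
  expect_true(is.na(miss$score[miss$gene == "ABSENT"]))
  expect_equal(miss$n_guides[miss$gene == "ABSENT"], 0L)
})

test_that("gene categorization partitions the universe", {
  cats <- categorize_genes(c("A", "B"), c("B", "C"), c("A", "B", "C", "D"))
  expect_equal(as.character(cats$category),
               c("cas9_only", "both", "krab_only", "neither"))
  expect_equal(nrow(cats), 4L)
  same <- categorize_genes(c("A", "B"), c("A", "B"), c("A", "B", "C"))
  expect_equal(sum(same$category == "cas9_only"), 0L)
  expect_equal(sum(same$category == "krab_only"), 0L)
  expect_equal(sum(table(cats$category)), 4L)
  expect_error(categorize_genes("Z", "A", c("A", "B")), "subsets")
})

test_that("fisher enrichment matches hand enumeration and handles extremes", {
  # table [[3,1],[1,3]]: p = 34/70 by full hypergeometric enumeration
  universe <- sprintf("u%d", 1:8)
  res <- fisher_enrichment(universe[1:4], universe[c(1:3, 5)], universe)
  expect_equal(res$a, 3L)
  expect_equal(res$p, 34 / 70, tolerance = 1e-12)
  expect_equal(res$odds_ratio, 9)

  # perfect association: Haldane-corrected finite OR, minimal p
  res2 <- fisher_enrichment(universe[1:4], universe[1:4], universe)
  expect_lt(res2$p, 0.05)
  expect_equal(res2$p, 2 / choose(8, 4), tolerance = 1e-12)
  expect_true(is.finite(res2$odds_ratio))
  expect_error(fisher_enrichment("a", "a", character(0)), "empty universe")

  # random tables agree with stats::fisher.test
  set.seed(31)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    u <- sprintf("g%d", seq_len(n))
    catm <- sample(u, sample.int(n, 1))
    prop <- sample(u, sample.int(n, 1))
    mine <- fisher_enrichment(catm, prop, u)
    ft <- fisher.test(matrix(c(mine$a, mine$b, mine$c, mine$d), 2,
                             byrow = TRUE))
    expect_equal(mine$p, ft$p.value, tolerance = 1e-9)
  }
})

test_that("bidirectional detection requires divergence within the window", {
  mk <- function(pos_a, strand_a, pos_b, strand_b) {
    tibble::tibble(gene = c("A", "B"), chrom = "chr1",
                   position = c(pos_a, pos_b),
                   strand = c(strand_a, strand_b), peak_height = c(10, 9))
  }
  div800 <- detect_bidirectional(mk(1000L, "-", 1800L, "+"))
  expect_equal(nrow(div800$pairs), 1L)
  expect_equal(div800$pairs$tss_distance, 800L)
  expect_equal(div800$fraction, 1)
  # beyond 1 kb: no pair
  expect_equal(nrow(detect_bidirectional(mk(1000L, "-", 2200L, "+"))$pairs),
               0L)
  # convergent (facing) promoters are not shared promoters
  expect_equal(nrow(detect_bidirectional(mk(1000L, "+", 1500L, "-"))$pairs),
               0L)
  # tandem (same strand) is not bidirectional
  expect_equal(nrow(detect_bidirectional(mk(1000L, "+", 1500L, "+"))$pairs),
               0L)
  # inclusive at exactly the threshold
  expect_equal(nrow(detect_bidirectional(mk(1000L, "-", 2000L, "+"))$pairs),
               1L)
  # symmetric in gene order and row order
  swapped <- mk(1000L, "-", 1800L, "+")[2:1, ]
  expect_equal(detect_bidirectional(swapped)$pairs, div800$pairs)
  # only primary TSSs count
  multi <- dplyr::bind_rows(
    mk(1000L, "-", 1800L, "+"),
    tibble::tibble(gene = "A", chrom = "chr1", position = 5000L,
                   strand = "-", peak_height = 50))
  expect_equal(nrow(detect_bidirectional(multi)$pairs), 0L)
})

test_that("proximity profiling flags sub-kilobase neighbors of essential genes", {
  tss <- tibble::tibble(
    gene = c("E1", "N1", "N2", "E2", "N3"),
    chrom = "chr1",
    position = c(10000L, 10600L, 30000L, 50000L, 55000L),
    strand = c("+", "-", "+", "+", "-"),
    peak_height = 10)
  prof <- proximity_to_essential(tss, c("E1", "E2"), calls = c("N1"),
                                 breaks = c(0, 1000, 10000, Inf))
  expect_equal(prof$fraction[1], 1)       # N1, 600 bp from E1, called
  expect_equal(prof$n_genes[2], 1L)       # N3 at 5 kb
  expect_equal(prof$fraction[2], 0)
  expect_equal(prof$n_genes[3], 1L)       # N2 at 20 kb
  expect_equal(prof$fraction[3], 0)
  # no essential genes: all bins missing
  none <- proximity_to_essential(tss, character(0), calls = "N1")
  expect_true(all(is.na(none$fraction)))
})
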