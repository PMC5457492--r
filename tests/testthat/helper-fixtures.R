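# shared fixtures, built once per test run and cached
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

default_sim <- function() {
  fixture("sim", function() make_genome(sim_config(), seed = 101L))
}

# paired CRISPRc/CRISPRi screens of one naive tiling library on default_sim
default_screens <- function() {
  fixture("screens", function() {
    sim <- default_sim()
    lib <- simulate_library(sim, seed = 5L)
    cas9 <- simulate_screen(lib, sim, "cas9", seed = 201L)
    krab <- simulate_screen(lib, sim, "krab_dcas9", seed = 202L)
    nt <- lib$spacer_id[lib$target_class == "nontargeting"]
    lfc_c <- counts_to_lfc(cas9, nt)
    lfc_k <- counts_to_lfc(krab, nt)
    list(sim = sim, lib = lib, cas9 = cas9, krab = krab,
         lfc_cas9 = lfc_c, lfc_krab = lfc_k,
         truth = attr(cas9, "guide_truth"),
         calls_cas9 = call_essential(score_genes(lfc_c, lib, "exon")),
         calls_krab = call_essential(score_genes(lfc_k, lib, "primary_tss")))
  })
}

# a tiny deterministic library for I/O tests
toy_library <- function(n_target = 2L) {
  tibble::tibble(
    spacer_id = c(sprintf("g%02d", seq_len(n_target)), "nt01"),
    spacer_seq = c(vapply(seq_len(n_target), function(i) {
      paste(rep(c("A", "C", "G", "T"), 5), collapse = "")
    }, character(1)), paste(rep("A", 20), collapse = "")),
    chrom = c(rep("chr1", n_target), NA),
    cut_anchor = c(100L + seq_len(n_target), NA),
    strand = c(rep("+", n_target), NA),
    target_gene = c(rep("GENE1", n_target), NA),
    target_class = c(rep("exon", n_target), "nontargeting"),
    tss_rank = NA_integer_)
}

# contig with a single NGG site: spacer without GG/CC followed by AGG,
# embedded in a GG/CC-free background
single_site_contig <- function(flank = 209L) {
  bg <- function(n) paste(rep_len(c("A", "T"), n), collapse = "")
  spacer <- paste(rep_len(c("A", "C", "G", "T"), 20), collapse = "")
  paste0(bg(flank - 20L + 1L), spacer, "AGG", bg(flank - 2L))
}
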