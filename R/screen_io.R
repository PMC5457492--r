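#' Read an sgRNA library table
#'
#' The library table is a TSV with one row per sgRNA and columns
#' `spacer_id`, `spacer_seq`, `chrom`, `cut_anchor`, `strand`, `target_gene`,
#' `target_class`, `tss_rank`. `cut_anchor` is the 0-based genomic position of
#' the 'N' of the NGG PAM. Non-targeting controls leave the coordinate fields
#' empty. `target_class` is one of `exon`, `tss_1`, `tss_2`, `tss_3`,
#' `aavs1`, `nontargeting`.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A tibble with one row per sgRNA.
#' @export
read_library <- function(path) {
  lib <- readr::read_tsv(path, col_types = readr::cols(
    spacer_id = readr::col_character(),
    spacer_seq = readr::col_character(),
    chrom = readr::col_character(),
    cut_anchor = readr::col_integer(),
    strand = readr::col_character(),
    target_gene = readr::col_character(),
    target_class = readr::col_character(),
    tss_rank = readr::col_integer()
  ), na = "", progress = FALSE)
  required <- c("spacer_id", "spacer_seq", "target_gene", "target_class")
  missing_cols <- setdiff(required, names(lib))
  if (length(missing_cols) > 0) {
    abort(paste0("library table is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  validate_library(lib)
}

#' Validate an sgRNA library tibble
#'
#' Checks spacer uniqueness, spacer alphabet/length, class labels, and the
#' consistency between `target_class` and `tss_rank`.
#'
#' @param lib A library tibble as returned by [read_library()].
#' @return The validated tibble, invisibly unchanged.
#' @export
validate_library <- function(lib) {
  dup <- lib$spacer_id[duplicated(lib$spacer_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate spacer_id: ", paste(unique(dup), collapse = ", ")))
  }
  bad <- which(!grepl("^[ACGT]{20}$", lib$spacer_seq))
  if (length(bad) > 0) {
    abort(sprintf(
      "malformed spacer at row %d (spacer_id '%s'): '%s' is not a 20-nt ACGT sequence",
      bad[1], lib$spacer_id[bad[1]], lib$spacer_seq[bad[1]]))
  }
  classes <- c("exon", "tss_1", "tss_2", "tss_3", "aavs1", "nontargeting")
  unknown <- setdiff(unique(lib$target_class), classes)
  if (length(unknown) > 0) {
    abort(paste0("unknown target_class: ", paste(unknown, collapse = ", ")))
  }
  if ("chrom" %in% names(lib)) {
    nt <- lib$target_class == "nontargeting"
    if (any(nt & !is.na(lib$chrom))) {
      abort("nontargeting records must have empty coordinates")
    }
  }
  is_tss <- grepl("^tss_[0-9]+$", lib$target_class)
  if ("tss_rank" %in% names(lib) && any(is_tss)) {
    expected <- as.integer(sub("^tss_", "", lib$target_class[is_tss]))
    got <- lib$tss_rank[is_tss]
    if (any(is.na(got) | got != expected)) {
      abort("target_class tss_k requires tss_rank = k")
    }
  }
  lib
}

#' Write an sgRNA library table
#'
#' @param lib A library tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_library <- function(lib, path) {
  cols <- c("spacer_id", "spacer_seq", "chrom", "cut_anchor", "strand",
            "target_gene", "target_class", "tss_rank")
  out <- lib
  for (cc in setdiff(cols, names(out))) out[[cc]] <- NA
  readr::write_tsv(out[cols], path, na = "", progress = FALSE)
  invisible(path)
}

#' Read an sgRNA read-count matrix
#'
#' Expects a TSV whose first column holds sgRNA identifiers and whose
#' remaining columns are samples named `condition.replicate`
#' (e.g. `early.rep1`, `late.rep2`). Counts must be non-negative integers.
#' An optional sidecar metadata table overrides the naming convention.
#'
#' @param path Path to the count TSV.
#' @param meta Optional tibble/data frame with columns `sample_id`,
#'   `condition`, `replicate`; when `NULL`, metadata is parsed from the
#'   column names.
#' @return A long tibble with columns `sgrna_id`, `sample_id`, `condition`,
#'   `replicate`, `count`.
#' @export
read_counts <- function(path, meta = NULL) {
  wide <- readr::read_tsv(path,
                          col_types = readr::cols(
                            .default = readr::col_character()),
                          progress = FALSE)
  names(wide)[1] <- "sgrna_id"
  counts_to_long(wide, meta = meta)
}

counts_to_long <- function(wide, meta = NULL) {
  samples <- setdiff(names(wide), "sgrna_id")
  if (anyDuplicated(wide$sgrna_id)) abort("duplicate sgRNA ids in count table")
  long <- tidyr::pivot_longer(wide, -"sgrna_id",
                              names_to = "sample_id", values_to = "count")
  long$count <- suppressWarnings(as.numeric(long$count))
  if (any(is.na(long$count)) || any(long$count < 0) ||
      any(long$count != round(long$count))) {
    abort("counts must be non-negative integers")
  }
  long$count <- as.integer(long$count)
  if (is.null(meta)) meta <- parse_sample_names(samples)
  long <- dplyr::left_join(long, meta, by = "sample_id")
  long$sample_id <- factor(long$sample_id, levels = samples)
  long[, c("sgrna_id", "sample_id", "condition", "replicate", "count")]
}

#' Parse `condition.replicate` sample names
#'
#' @param sample_ids Character vector of sample names.
#' @return A tibble with columns `sample_id`, `condition`, `replicate`.
#'   A name with no `.` separator yields replicate `"rep1"`.
#' @export
parse_sample_names <- function(sample_ids) {
  has_dot <- grepl(".", sample_ids, fixed = TRUE)
  condition <- ifelse(has_dot, sub("\\..*$", "", sample_ids), sample_ids)
  replicate <- ifelse(has_dot, sub("^[^.]*\\.", "", sample_ids), "rep1")
  tibble::tibble(sample_id = sample_ids, condition = condition,
                 replicate = replicate)
}

#' Write a read-count matrix
#'
#' Writes the wide TSV layout read by [read_counts()]; columns appear in the
#' order of the `sample_id` factor levels so write-read-write round-trips are
#' byte-identical.
#'
#' @param counts A long count tibble from [read_counts()] or
#'   [simulate_screen()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  wide <- tidyr::pivot_wider(
    counts[, c("sgrna_id", "sample_id", "count")],
    names_from = "sample_id", values_from = "count")
  readr::write_tsv(wide, path, progress = FALSE)
  invisible(path)
}

#' Read a TSS annotation from BED6
#'
#' Each row is one CAGE-style TSS cluster center: `chrom start end name
#' score strand` with `name` = gene symbol and `score` = CAGE peak height.
#' The TSS position is the 0-based `start`. Within each gene, TSSs are
#' ranked by descending peak height; ties break toward the smaller genomic
#' coordinate so rank 1 (the primary TSS) is always unique.
#'
#' @param path Path to a header-less BED6 file.
#' @return A tibble with columns `gene`, `chrom`, `position`, `strand`,
#'   `peak_height`, `rank_within_gene`.
#' @export
read_tss_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name",
                                             "score", "strand"),
                         col_types = "ciicdc", progress = FALSE)
  tss <- tibble::tibble(gene = bed$name, chrom = bed$chrom,
                        position = bed$start, strand = bed$strand,
                        peak_height = bed$score)
  rank_tss(tss)
}

#' Rank TSS records within each gene
#'
#' @param tss Tibble with columns `gene`, `chrom`, `position`, `strand`,
#'   `peak_height`.
#' @return The same tibble with `rank_within_gene` (1 = highest peak;
#'   ties broken by leftmost coordinate).
#' @export
rank_tss <- function(tss) {
  tss |>
    dplyr::group_by(.data$gene) |>
    dplyr::arrange(dplyr::desc(.data$peak_height), .data$position,
                   .by_group = TRUE) |>
    dplyr::mutate(rank_within_gene = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' Write a TSS annotation to BED6
#'
#' @param tss A TSS tibble as from [read_tss_bed()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tss_bed <- function(tss, path) {
  bed <- tibble::tibble(chrom = tss$chrom, start = tss$position,
                        end = tss$position + 1L, name = tss$gene,
                        score = tss$peak_height, strand = tss$strand)
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read copy-number segments from BED4
#'
#' Fourth column is the integer copy number of the segment; regions not
#' covered by any segment are assumed diploid (CN = 2).
#'
#' @param path Path to a header-less BED4 file.
#' @return A tibble with columns `chrom`, `start`, `end`, `cn`.
#' @export
read_copy_number <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "cn"),
                  col_types = "ciii", progress = FALSE)
}

#' @rdname read_copy_number
#' @param segments Copy-number tibble.
#' @export
write_copy_number <- function(segments, path) {
  readr::write_tsv(segments[, c("chrom", "start", "end", "cn")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Bundle genome sequences with copy-number segments
#'
#' All coordinates in the package are 0-based half-open; 1-based formats are
#' converted at the file boundary.
#'
#' @param sequences A named character vector of contig sequences or a
#'   [Biostrings::DNAStringSet].
#' @param copy_number Optional copy-number segment tibble (`chrom`, `start`,
#'   `end`, `cn`); default is diploid everywhere.
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(sequences, copy_number = NULL) {
  if (!inherits(sequences, "DNAStringSet")) {
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    abort("genome contigs must have unique names")
  }
  if (is.null(copy_number)) {
    copy_number <- tibble::tibble(chrom = character(), start = integer(),
                                  end = integer(), cn = integer())
  }
  if (nrow(copy_number) > 0) {
    if (any(copy_number$cn < 0)) abort("copy number must be >= 0")
    len <- setNames(Biostrings::width(sequences), names(sequences))
    bad_chrom <- setdiff(copy_number$chrom, names(sequences))
    if (length(bad_chrom) > 0) {
      abort(paste0("copy-number segment on unknown contig: ",
                   paste(bad_chrom, collapse = ", ")))
    }
    if (any(copy_number$start < 0) ||
        any(copy_number$end > len[copy_number$chrom])) {
      abort("copy-number segment outside contig bounds")
    }
  }
  structure(list(sequences = sequences, copy_number = copy_number),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("<genome_model> %d contig(s), %s bp total, %d copy-number segment(s)\n",
              length(x$sequences),
              format(sum(Biostrings::width(x$sequences)), big.mark = ","),
              nrow(x$copy_number)))
  invisible(x)
}

#' Read genome sequences from FASTA
#'
#' @param path FASTA path.
#' @param copy_number Optional copy-number tibble or BED4 path.
#' @return A `genome_model`.
#' @export
read_genome_fasta <- function(path, copy_number = NULL) {
  if (is.character(copy_number)) copy_number <- read_copy_number(copy_number)
  genome_model(Biostrings::readDNAStringSet(path), copy_number)
}

#' Write genome sequences to FASTA
#'
#' @param genome A `genome_model`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome$sequences, path)
  invisible(path)
}

#' Copy number at genomic positions
#'
#' @param genome A `genome_model`.
#' @param chrom,position Parallel vectors of contig names and 0-based
#'   positions.
#' @return Integer copy number per position (2 where no segment applies).
#' @export
copy_number_at <- function(genome, chrom, position) {
  cn <- rep(2L, length(chrom))
  seg <- genome$copy_number
  if (nrow(seg) == 0) return(cn)
  for (i in seq_len(nrow(seg))) {
    hit <- !is.na(chrom) & chrom == seg$chrom[i] &
      position >= seg$start[i] & position < seg$end[i]
    cn[hit] <- seg$cn[i]
  }
  cn
}
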