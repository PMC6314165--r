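#' Read a differentially-methylated-region marker map
#'
#' The map places each DMR marker on the five-chromosome genetic map
#' (centiMorgan) and records the physical interval it tags (0-based
#' half-open base pairs).
#'
#' @param path CSV with columns `marker_id, chrom, pos_cM, phys_start, phys_end`.
#' @return A tibble sorted by `(chrom, pos_cM)`.
#' @export
read_marker_map <- function(path) {
  map <- readr::read_csv(path, show_col_types = FALSE)
  map <- arrange(map, .data$chrom, .data$pos_cM)
  validate_marker_map(map)
  as_tibble(map)
}

#' Read an epiRIL epigenotype matrix
#'
#' Epigenotypes are the inherited parental epialleles at each DMR marker:
#' `COL` (Col-0 wild-type methylation state) or `DDM1` (hypomethylated
#' *ddm1-2* state). Missing calls are `NA`.
#'
#' @param path CSV whose header row holds marker ids and whose first column
#'   (`line`) holds epiRIL line ids.
#' @param map Optional marker map tibble; if given, every marker column must
#'   appear in the map.
#' @return A wide tibble: `line` plus one character column per marker.
#' @export
read_epigenotypes <- function(path, map = NULL) {
  geno <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
  names(geno)[1] <- "line"
  assert_that(!anyDuplicated(geno$line), "duplicate line ids in epigenotype file")
  geno_matrix(geno, map)  # validates calls + marker membership
  as_tibble(geno)
}

#' Write an epigenotype matrix
#' @param geno wide epigenotype tibble
#' @param path output CSV path
#' @return `path`, invisibly.
#' @export
write_epigenotypes <- function(geno, path) {
  readr::write_csv(geno, path, na = "NA")
  invisible(path)
}

#' Read probe-level methylation posteriors
#'
#' Long format: one row per `(probe, line)` with the posterior probabilities
#' that the probe is unmethylated (`post_U`) or methylated (`post_M`).
#' The methylation-level score `ml = -post_U + post_M` is added on ingest.
#'
#' @param path CSV with columns
#'   `probe_id, chrom, start, end, line, post_U, post_M` (0-based half-open bp).
#' @return Long tibble with an `ml` column in \[-1, 1\].
#' @export
read_probe_posteriors <- function(path) {
  pr <- readr::read_csv(path, show_col_types = FALSE)
  pr$ml <- methylation_level(pr$post_U, pr$post_M)
  as_tibble(pr)
}

#' Read a long metabolite intensity table
#'
#' @param path CSV with columns `tissue, line, batch, metabolite, intensity`
#'   (raw non-negative intensities; `NA` = not detected).
#' @return Long tibble.
#' @export
read_metabolites <- function(path) {
  m <- readr::read_csv(path, show_col_types = FALSE)
  assert_that(all(c("line", "batch", "metabolite", "intensity") %in% names(m)),
              "metabolite table needs line, batch, metabolite, intensity")
  assert_that(all(m$intensity >= 0, na.rm = TRUE), "negative intensity")
  as_tibble(m)
}

#' Read gene and transposable-element annotation with sequences
#'
#' Converts GFF3 1-based inclusive coordinates to the package-internal
#' 0-based half-open convention and derives strand-aware promoter,
#' gene-body and 1-kb-downstream intervals for every gene.
#'
#' @param gff_path GFF3 with `gene` and `transposable_element` features.
#' @param fasta_path genome FASTA (chromosome names must cover all features).
#' @param promoter_len promoter extent upstream of the TSS in bp (default 1000).
#' @return A list with `genes` (tibble: gene_id, chrom, strand, tss and the
#'   three derived intervals plus a `clipped` flag), `tes` (tibble of TE
#'   intervals with family), and `seqs` (a [Biostrings::DNAStringSet]).
#' @export
read_annotation <- function(gff_path, fasta_path, promoter_len = 1000) {
  gr <- rtracklayer::import(gff_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  chrom_len <- setNames(Biostrings::width(seqs), names(seqs))

  feat <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(gr$type),
    id = if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_,
    family = if (!is.null(gr$family)) as.character(gr$family) else NA_character_
  )
  missing_chr <- setdiff(unique(feat$chrom), names(chrom_len))
  if (length(missing_chr) > 0) {
    abort(paste("chromosomes absent from FASTA:",
                paste(missing_chr, collapse = ", ")))
  }
  beyond <- feat$end > chrom_len[feat$chrom] | feat$start < 0
  if (any(beyond)) {
    abort(paste("features beyond chromosome bounds:",
                paste(feat$id[beyond], collapse = ", ")))
  }

  genes <- filter(feat, .data$type == "gene")
  genes <- mutate(genes, strand = if_else(.data$strand %in% c("+", "-"),
                                          .data$strand, "+"))
  g <- gene_intervals(genes$id, genes$chrom, genes$strand,
                      genes$start, genes$end,
                      promoter_len, chrom_len)
  tes <- feat |>
    filter(.data$type == "transposable_element") |>
    transmute(te_id = .data$id, chrom = .data$chrom, start = .data$start,
              end = .data$end, family = .data$family)
  list(genes = g, tes = tes, seqs = seqs)
}

# Strand-aware promoter / gene body / downstream-1kb interval arithmetic,
# 0-based half-open; promoter abuts the TSS on the upstream side.
gene_intervals <- function(gene_id, chrom, strand, start, end,
                           promoter_len, chrom_len) {
  len <- unname(chrom_len[chrom])
  plus <- strand == "+"
  tss <- ifelse(plus, start, end)
  prom_start <- ifelse(plus, start - promoter_len, end)
  prom_end <- ifelse(plus, start, end + promoter_len)
  down_start <- ifelse(plus, end, start - 1000)
  down_end <- ifelse(plus, end + 1000, start)
  clip <- function(x) pmin(pmax(x, 0), len)
  clipped <- prom_start < 0 | prom_end > len | down_start < 0 | down_end > len
  tibble(
    gene_id = gene_id, chrom = chrom, strand = strand, tss = tss,
    body_start = start, body_end = end,
    prom_start = clip(prom_start), prom_end = clip(prom_end),
    down_start = clip(down_start), down_end = clip(down_end),
    clipped = clipped
  )
}

#' Read a small-RNA library FASTA
#'
#' Headers carry read counts as `>id|count=N`. Sequences are normalised to
#' the DNA alphabet (U to T, uppercase) on ingest.
#'
#' @param path FASTA path.
#' @param source library label, e.g. `"WT"` or `"ddm1"`.
#' @param len_range allowed sRNA length range (default 18-30 nt).
#' @return Tibble `source, srna_id, sequence, count`.
#' @export
read_srna_library <- function(path, source, len_range = c(18L, 30L)) {
  ss <- Biostrings::readDNAStringSet(path)
  # readDNAStringSet rejects U; re-read as BStringSet if needed
  seqs <- toupper(chartr("Uu", "Tt", as.character(ss)))
  hdr <- names(ss)
  count <- suppressWarnings(as.integer(sub("^.*count=([0-9]+).*$", "\\1", hdr)))
  assert_that(!anyNA(count) && all(count >= 1),
              "every sRNA FASTA header must carry '|count=N' with N >= 1")
  lens <- nchar(seqs)
  assert_that(all(lens >= len_range[1] & lens <= len_range[2]),
              "sRNA length outside the configured range")
  tibble(source = source, srna_id = sub("\\|.*$", "", hdr),
         sequence = unname(seqs), count = count)
}

#' Write stage result tables with a run manifest
#'
#' Writes each table as CSV with a deterministic column order and stable
#' float formatting, plus `manifest.json` recording the seed and a hash of
#' the configuration, so a rerun with identical inputs is byte-identical.
#'
#' @param tables named list of data frames.
#' @param out_dir output directory (created if absent).
#' @param config optional list recorded (hashed) in the manifest.
#' @param seed optional integer seed recorded in the manifest.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(tables, out_dir, config = NULL, seed = NULL) {
  assert_that(is.list(tables) && !is.null(names(tables)),
              "tables must be a named list")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    tb <- as_tibble(tables[[nm]])
    tb <- mutate(tb, across(dplyr::where(is.numeric), fmt_num))
    p <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(tb, p, na = "NA")
    paths <- c(paths, p)
  }
  cfg_hash <- if (is.null(config)) NA_character_ else
    as.character(sum(utf8ToInt(paste(deparse(config), collapse = ""))))
  manifest <- list(tables = names(tables), seed = seed, config_hash = cfg_hash)
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(paths, mp))
}
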