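random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

str_overwrite <- function(s, at0, insert) {
  # overwrite s at 0-based offset at0 with insert (no length change)
  paste0(substring(s, 1, at0), insert,
         substring(s, at0 + nchar(insert) + 1, nchar(s)))
}

#' Simulate genome, annotation, promoter probes and sRNA libraries
#'
#' Builds a synthetic substrate for the trans-discovery pipeline with known
#' ground truth: random background chromosomes; a TE-like repeat inside
#' every QTL interval that hosts a planted trans target; for each target,
#' an exact copy of a repeat segment (>= 24 bp) written into the target's
#' promoter within 1000 bp of an annotated promoter TE; one cis candidate
#' gene whose body overlaps its QTL marker's DMR; decoy genes that fail the
#' screen criteria in rotation (no promoter probes, invariant methylation,
#' uncoupled methylation); promoter methylation probes for targets coupled
#' to the trans QTL marker (with polymorphic parents); and WT/ddm1 sRNA
#' libraries tiling the repeats with the ddm1 counts depleted by
#' `srna_depletion`.
#'
#' @param cfg a [sim_config()].
#' @param geno wide epigenotype tibble (for probe coupling).
#' @param cis_marker marker whose interval carries the cis candidate
#'   (default: first planted QTL marker).
#' @param seed optional override.
#' @return List: `seqs` ([Biostrings::DNAStringSet]), `genes`, `tes`,
#'   `probes` (promoter probes incl. parental rows), `srna`
#'   (`source, srna_id, sequence, count`), `pathways`, and `truth`
#'   (`gene_id, role, qtl_marker, segment_length, seg_prom_off`).
#' @export
simulate_sequences <- function(cfg, geno,
                               cis_marker = cfg$planted_qtl$marker_id[1],
                               seed = cfg$seed) {
  tt <- cfg$trans_targets
  assert_that(is.null(tt) || all(tt$segment_length >= 24),
              "trans segment length must be >= 24 (the largest artsRNA window)")
  map <- cfg$map
  with_seed(seed + 5L, {
    chroms <- unique(map$chrom)
    n_mk <- table(factor(map$chrom, levels = chroms))
    marker_zone <- as.integer(n_mk) * 2000L
    names(marker_zone) <- chroms

    # assign genes: trans targets on a different chromosome than their QTL
    genes_plan <- list()
    if (!is.null(tt) && nrow(tt) > 0) {
      for (k in seq_len(nrow(tt))) {
        qchr <- map$chrom[map$marker_id == tt$qtl_marker[k]]
        gchr <- chroms[(match(qchr, chroms) %% length(chroms)) + 1]
        genes_plan[[length(genes_plan) + 1]] <-
          tibble(gene_id = tt$gene_id[k], chrom = gchr, role = "trans_target",
                 qtl_marker = tt$qtl_marker[k],
                 segment_length = tt$segment_length[k])
      }
    }
    decoy_modes <- c("no_probes", "invariant", "uncoupled")
    for (k in seq_len(cfg$n_decoy_genes)) {
      genes_plan[[length(genes_plan) + 1]] <-
        tibble(gene_id = sprintf("G_decoy%02d", k),
               chrom = chroms[(k - 1) %% length(chroms) + 1],
               role = paste0("decoy_", decoy_modes[(k - 1) %% 3 + 1]),
               qtl_marker = NA_character_, segment_length = NA_integer_)
    }
    plan <- bind_rows(genes_plan)
    plan <- plan |> group_by(.data$chrom) |>
      mutate(slot = row_number() - 1) |> ungroup()

    gz_start <- marker_zone
    chrom_len <- marker_zone +
      4000L * as.integer(table(factor(plan$chrom, levels = chroms))) + 1000L
    names(chrom_len) <- chroms
    seqs <- lapply(chrom_len, random_dna)

    # gene coordinates in the gene zone: promoter 1 kb, body 1.5 kb, + strand
    plan <- plan |>
      mutate(gstart = unname(gz_start[.data$chrom]) + .data$slot * 4000L,
             prom_start = .data$gstart, prom_end = .data$gstart + 1000L,
             body_start = .data$gstart + 1000L,
             body_end = .data$gstart + 2500L,
             down_start = .data$gstart + 2500L,
             down_end = .data$gstart + 3500L,
             tss = .data$gstart + 1000L, strand = "+")

    # cis candidate: body over the marker DMR, promoter immediately upstream
    mrow <- map[map$marker_id == cis_marker, ]
    cis <- tibble(gene_id = "G_cis", chrom = mrow$chrom, role = "cis_causal",
                  qtl_marker = cis_marker, segment_length = NA_integer_,
                  slot = NA_integer_, gstart = mrow$phys_start - 1000L,
                  prom_start = mrow$phys_start - 1000L,
                  prom_end = mrow$phys_start,
                  body_start = mrow$phys_start,
                  body_end = mrow$phys_start + 1500L,
                  down_start = mrow$phys_start + 1500L,
                  down_end = mrow$phys_start + 2500L,
                  tss = mrow$phys_start, strand = "+")
    plan <- bind_rows(plan, cis)

    tes <- list(); truth <- list(); srna <- list()
    repeats <- list()
    if (!is.null(tt) && nrow(tt) > 0) {
      for (mk in unique(tt$qtl_marker)) {
        mr <- map[map$marker_id == mk, ]
        rep_seq <- random_dna(400)
        seqs[[mr$chrom]] <- str_overwrite(seqs[[mr$chrom]],
                                          mr$phys_start + 100, rep_seq)
        repeats[[mk]] <- list(seq = rep_seq, chrom = mr$chrom,
                              start = mr$phys_start + 100)
        tes[[length(tes) + 1]] <- tibble(
          te_id = paste0("TE_", mk), chrom = mr$chrom,
          start = mr$phys_start + 100, end = mr$phys_start + 500,
          family = "simTE_qtl")
        # sRNA libraries: 24-nt tiling of the repeat, ddm1 depleted
        win <- substring(rep_seq, 1:(400 - 23), 24:400)
        srna[[length(srna) + 1]] <- tibble(
          source = "WT", srna_id = sprintf("wt_%s_%03d", mk, seq_along(win)),
          sequence = win, count = pmax(rpois(length(win), 200), 1))
        srna[[length(srna) + 1]] <- tibble(
          source = "ddm1",
          srna_id = sprintf("dd_%s_%03d", mk, seq_along(win)),
          sequence = win,
          count = pmax(rpois(length(win), 200 / cfg$srna_depletion), 1))
      }
      for (k in seq_len(nrow(tt))) {
        g <- plan[plan$gene_id == tt$gene_id[k], ]
        L <- tt$segment_length[k]
        seg <- substring(repeats[[tt$qtl_marker[k]]]$seq, 51, 50 + L)
        # promoter TE at offset 100..220, planted segment at offset 400
        te_seq <- random_dna(120)
        seqs[[g$chrom]] <- str_overwrite(seqs[[g$chrom]],
                                         g$prom_start + 100, te_seq)
        seqs[[g$chrom]] <- str_overwrite(seqs[[g$chrom]],
                                         g$prom_start + 400, seg)
        tes[[length(tes) + 1]] <- tibble(
          te_id = paste0("TE_", g$gene_id), chrom = g$chrom,
          start = g$prom_start + 100, end = g$prom_start + 220,
          family = "simTE_promoter")
        truth[[length(truth) + 1]] <- tibble(
          gene_id = g$gene_id, role = "trans_target",
          qtl_marker = tt$qtl_marker[k], segment_length = L,
          seg_prom_off = 400L)
      }
    }

    # promoter methylation probes
    n <- nrow(geno)
    probes <- list()
    coupled <- filter(plan, .data$role %in% c("trans_target", "cis_causal"))
    if (nrow(coupled) > 0) {
      coupling <- tibble(marker_id = coupled$qtl_marker,
                         chrom = coupled$chrom,
                         start = coupled$prom_start, end = coupled$prom_end,
                         n_probes = 3L, probe_prefix = coupled$gene_id,
                         polymorphic = TRUE)
      probes[[1]] <- simulate_region_probes(geno, coupling,
                                            cfg$reversion_rate,
                                            cfg$probe_noise_sd,
                                            seed + 6L, parents = TRUE)
    }
    dec <- filter(plan, .data$role %in% c("decoy_invariant", "decoy_uncoupled"))
    if (nrow(dec) > 0) {
      probes[[2]] <- purrr::map(seq_len(nrow(dec)), function(i) {
        g <- dec[i, ]
        starts <- g$prom_start + c(100L, 400L, 700L)
        lines <- c(geno$line, "Col-0", "ddm1-2")
        purrr::map(1:3, function(pi) {
          latent <- if (g$role == "decoy_invariant") {
            rep(1, length(lines))               # methylated everywhere
          } else {
            c(rbinom(n, 1, 0.5), 1, 0)          # uncoupled to any marker
          }
          post_M <- pmin(pmax(latent +
            rnorm(length(lines), 0, cfg$probe_noise_sd), 0), 1)
          tibble(probe_id = sprintf("%s_p%d", g$gene_id, pi),
                 chrom = g$chrom, start = starts[pi], end = starts[pi] + 60,
                 line = lines, post_U = 1 - post_M, post_M = post_M,
                 ml = -(1 - post_M) + post_M)
        }) |> bind_rows()
      }) |> bind_rows()
    }
    probes <- bind_rows(probes)

    pathways <- tibble(
      gene_id = c("G_cis", plan$gene_id[grepl("^G_decoy0[12]$", plan$gene_id)]),
      pathway = c("flavonoid", rep("glucosinolate",
                                   sum(grepl("^G_decoy0[12]$", plan$gene_id)))))

    genes <- plan |>
      select("gene_id", "chrom", "strand", "tss", "body_start", "body_end",
             "prom_start", "prom_end", "down_start", "down_end") |>
      mutate(clipped = FALSE)
    truth <- bind_rows(
      if (length(truth)) bind_rows(truth) else NULL,
      tibble(gene_id = "G_cis", role = "cis_causal", qtl_marker = cis_marker,
             segment_length = NA_integer_, seg_prom_off = NA_integer_),
      plan |> filter(grepl("^decoy", .data$role)) |>
        transmute(gene_id = .data$gene_id, role = .data$role,
                  qtl_marker = NA_character_,
                  segment_length = NA_integer_, seg_prom_off = NA_integer_))
    list(seqs = Biostrings::DNAStringSet(unlist(seqs)),
         genes = genes,
         tes = if (length(tes)) bind_rows(tes) else
           tibble(te_id = character(0), chrom = character(0),
                  start = integer(0), end = integer(0), family = character(0)),
         probes = probes,
         srna = if (length(srna)) bind_rows(srna) else
           tibble(source = character(0), srna_id = character(0),
                  sequence = character(0), count = integer(0)),
         pathways = pathways,
         truth = truth)
  })
}

#' Write simulated annotation and genome to GFF3 + FASTA
#'
#' The GFF gene feature spans the gene body (1-based inclusive, as GFF
#' requires); [read_annotation()] re-derives promoter and downstream
#' intervals, so a write/read round trip reproduces the gene models.
#'
#' @param sim list from [simulate_sequences()] (uses `genes`, `tes`, `seqs`).
#' @param gff_path,fasta_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_annotation <- function(sim, gff_path, fasta_path) {
  g <- sim$genes
  gr_genes <- GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$body_start + 1, end = g$body_end),
    strand = g$strand, type = "gene", ID = g$gene_id)
  t <- sim$tes
  gr <- gr_genes
  if (nrow(t) > 0) {
    gr_tes <- GenomicRanges::GRanges(
      seqnames = t$chrom,
      ranges = IRanges::IRanges(start = t$start + 1, end = t$end),
      strand = "+", type = "transposable_element", ID = t$te_id,
      family = t$family)
    gr <- suppressWarnings(c(gr_genes, gr_tes))
  }
  rtracklayer::export(gr, gff_path, format = "gff3")
  Biostrings::writeXStringSet(sim$seqs, fasta_path)
  invisible(c(gff_path, fasta_path))
}

#' Write an sRNA library tibble as FASTA with counts in headers
#' @param srna tibble `source, srna_id, sequence, count` (one source).
#' @param path output FASTA.
#' @return `path`, invisibly.
#' @export
write_srna_fasta <- function(srna, path) {
  ss <- Biostrings::DNAStringSet(srna$sequence)
  names(ss) <- sprintf("%s|count=%d", srna$srna_id, srna$count)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
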