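#' Pipeline run configuration
#'
#' Collects the thresholds of the whole inference chain with defaults at
#' the study's stated values: 1.5-LOD support intervals, 1000 permutations
#' at genome-wide alpha 0.05, the -0.3 hypomethylation boundary, the 0.2
#' correlation threshold, 21-nt minimum match segments and a 0.5 AGO-score
#' cutoff.
#'
#' @param sim a [sim_config()] describing the synthetic study.
#' @param n_perm,alpha permutation-threshold settings.
#' @param lod_drop support-interval LOD drop.
#' @param step_cM pseudomarker spacing for scans.
#' @param cor_threshold correlation-summary threshold.
#' @param alpha_assoc,alpha_coseg cis funnel stage levels.
#' @param min_match,ago_min,max_mismatch trans-stage settings.
#' @param ft_correct divide traits by flowering time before mapping.
#' @param cofactors `"none"` or `"auto"` (backward-elimination selection).
#' @param stages character vector of stages to run, a subset of
#'   `c("preprocess", "mapqtl", "cis", "trans")`.
#' @param seed integer seed for everything downstream of the simulator.
#' @return A `run_config` list.
#' @export
run_config <- function(sim, n_perm = 1000, alpha = 0.05, lod_drop = 1.5,
                       step_cM = 0, cor_threshold = 0.2,
                       alpha_assoc = 0.05, alpha_coseg = 0.05,
                       min_match = 21, ago_min = 0.5, max_mismatch = 0,
                       ft_correct = FALSE, cofactors = c("none", "auto"),
                       stages = c("preprocess", "mapqtl", "cis", "trans"),
                       seed = sim$seed) {
  cofactors <- match.arg(cofactors)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full synthetic-study pipeline
#'
#' simulate -> preprocess -> QTL mapping -> cis funnel -> trans discovery,
#' writing every stage table plus a markdown summary into `out_dir`. Pure
#' function of (config, seed): identical reruns are byte-identical.
#'
#' @param cfg a [run_config()].
#' @param out_dir output directory.
#' @return Invisibly, a list of all stage results.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- cfg$sim
  res <- list()

  geno <- simulate_epigenotypes(sim)
  met <- simulate_metabolome(geno, sim)
  probs <- genotype_probabilities(geno, sim$map, step_cM = cfg$step_cM)
  res$geno <- geno; res$truth <- met$truth

  if ("preprocess" %in% cfg$stages) {
    corrected <- batch_correct(met$metabolites)
    cv <- coefficient_of_variation(corrected)
    parent_flags <- met$truth |>
      transmute(metabolite = .data$trait_id,
                col_detected = .data$kind != "transgressive",
                ddm1_detected = .data$kind != "transgressive")
    det <- classify_detection(corrected, parent_flags)
    cs <- correlation_summary(corrected, threshold = cfg$cor_threshold)
    res$metabolites <- corrected; res$cv <- cv; res$detection <- det
    res$correlation <- glance(cs)
    write_results(list(cv = cv, detection_classes = det,
                       correlation_summary = glance(cs)),
                  out_dir, config = cfg, seed = cfg$seed)
  } else {
    res$metabolites <- batch_correct(met$metabolites)
  }

  if (any(c("mapqtl", "cis", "trans") %in% cfg$stages)) {
    traits <- res$metabolites |>
      filter(!is.na(.data$intensity), .data$intensity > 0) |>
      mutate(value = log10(.data$intensity)) |>
      select(trait_id = "metabolite", "line", "value")
    if (cfg$ft_correct) {
      traits <- traits |>
        group_by(.data$trait_id) |>
        dplyr::group_modify(~ {
          tr <- mutate(.x, value = 10^.data$value)
          mutate(flowering_correct(tr, met$ft), value = log10(.data$value))
        }) |> ungroup()
    }
    peak_tables <- list(); scans <- list()
    for (id in unique(traits$trait_id)) {
      tr <- filter(traits, .data$trait_id == id)
      if (nrow(tr) < 10) next
      co <- if (cfg$cofactors == "auto")
        select_cofactors(tr, probs) else NULL
      thr <- permutation_threshold(tr, probs, cofactors = co,
                                   n_perm = cfg$n_perm, alpha = cfg$alpha,
                                   seed = cfg$seed + utf8_sum(id))
      sc <- hk_scan(tr, probs, cofactors = co, trait_id = id)
      sc <- call_peaks(sc, thr, lod_drop = cfg$lod_drop)
      scans[[id]] <- sc
      peak_tables[[id]] <- peaks(sc)
    }
    peak_table <- bind_rows(peak_tables)
    res$scans <- scans; res$peaks <- peak_table
    if ("mapqtl" %in% cfg$stages) {
      plei <- pleiotropy_regions(peak_table)
      res$pleiotropy <- plei$regions |> select(-"traits")
      write_results(list(qtl_peaks = peak_table,
                         pleiotropy_regions = res$pleiotropy),
                    out_dir, config = cfg, seed = cfg$seed)
    }
  }

  if (any(c("cis", "trans") %in% cfg$stages)) {
    seqsim <- simulate_sequences(sim, geno)
    res$seqsim <- seqsim
  }

  if ("cis" %in% cfg$stages && !is.null(res$peaks) && nrow(res$peaks) > 0) {
    cis_marker <- sim$planted_qtl$marker_id[1]
    cpos <- sim$map[sim$map$marker_id == cis_marker, ]
    qtl <- res$peaks |>
      filter(.data$chrom == cpos$chrom, .data$ci_lo <= cpos$pos_cM,
             .data$ci_hi >= cpos$pos_cM) |>
      arrange(dplyr::desc(.data$lod)) |> slice(1)
    if (nrow(qtl) == 1) {
      tr <- filter(traits, .data$trait_id == qtl$trait_id) |>
        mutate(value = 10^.data$value)
      all_probes <- bind_rows(simulate_probe_methylation(geno, sim),
                              seqsim$probes)
      fun <- run_funnel(seqsim$genes, qtl, all_probes, tr, geno, sim$map,
                        pathway_table = seqsim$pathways,
                        pathway_class = "flavonoid", tes = seqsim$tes,
                        alpha_assoc = cfg$alpha_assoc,
                        alpha_coseg = cfg$alpha_coseg)
      res$funnel <- fun
      res$funnel_counts <- funnel_counts(fun)
      write_results(list(cis_funnel = fun, cis_funnel_counts =
                           res$funnel_counts),
                    out_dir, config = cfg, seed = cfg$seed)
    }
  }

  if ("trans" %in% cfg$stages && !is.null(res$peaks) && nrow(res$peaks) > 0) {
    res$trans <- run_trans_stage(cfg, sim, geno, res$peaks, seqsim, probs)
    if (!is.null(res$trans)) {
      write_results(list(trans_report = res$trans), out_dir,
                    config = cfg, seed = cfg$seed)
    }
  }

  write_summary_md(res, file.path(out_dir, "summary.md"))
  invisible(res)
}

utf8_sum <- function(x) sum(utf8ToInt(x)) %% 10000L

# trans stage: screen genes against each QTL hosting a planted trans link,
# extract promoter/QTL sequences, segments, artsRNAs, libraries, eQTL
run_trans_stage <- function(cfg, sim, geno, peak_table, seqsim, probs) {
  reports <- list()
  for (mk in unique(sim$trans_targets$qtl_marker)) {
    mpos <- sim$map[sim$map$marker_id == mk, ]
    qtl <- peak_table |>
      filter(.data$chrom == mpos$chrom, .data$ci_lo <= mpos$pos_cM,
             .data$ci_hi >= mpos$pos_cM) |>
      arrange(dplyr::desc(.data$lod)) |> slice(1)
    if (nrow(qtl) == 0) next
    screened <- screen_trans_genes(seqsim$probes, seqsim$genes, geno, qtl,
                                   sim$map)
    if (nrow(screened) == 0) {
      reports[[mk]] <- trans_report(screened, tibble(gene_id = character(0)),
                                    tibble(gene_id = character(0)))
      next
    }
    # the physical QTL region: span of the DMR intervals of every marker
    # inside the 1.5-LOD support interval (never narrower than the peak DMR)
    mks_in <- filter(sim$map, .data$chrom == qtl$chrom,
                     .data$pos_cM >= qtl$ci_lo, .data$pos_cM <= qtl$ci_hi)
    qchr_len <- Biostrings::width(seqsim$seqs[qtl$chrom])
    qbp <- c(min(mks_in$phys_start), min(max(mks_in$phys_end), qchr_len))
    qtl_seq <- substring(as.character(seqsim$seqs[[qtl$chrom]]),
                         qbp[1] + 1, qbp[2])
    seg_all <- list(); art_all <- list()
    for (gid in screened$gene_id) {
      g <- seqsim$genes[seqsim$genes$gene_id == gid, ]
      prom_seq <- substring(as.character(seqsim$seqs[[g$chrom]]),
                            g$prom_start + 1, g$prom_end)
      segs <- find_match_segments(prom_seq, qtl_seq,
                                  min_match = cfg$min_match)
      if (nrow(segs) == 0) next
      segs$gene_id <- gid
      segs$chrom <- g$chrom
      segs$genome_start <- g$prom_start + segs$prom_start
      arts <- decompose_artsrnas(segs)
      arts <- score_ago_loading(arts, min_prob = cfg$ago_min)
      arts <- match_srna_library(arts, seqsim$srna,
                                 max_mismatch = cfg$max_mismatch)
      arts <- annotate_te_proximity(arts, segs, seqsim$tes)
      arts$gene_id <- gid
      seg_all[[gid]] <- segs; art_all[[gid]] <- arts
    }
    seg_all <- bind_rows(seg_all)
    art_all <- bind_rows(art_all)
    if (!"gene_id" %in% names(seg_all)) {
      seg_all <- tibble(gene_id = character(0), segment_id = character(0))
    }
    if (!"gene_id" %in% names(art_all)) {
      art_all <- tibble(gene_id = character(0), ago_max = numeric(0),
                        te_within_1kb = logical(0))
    }
    # eQTL colocalization for screened genes with segments
    coloc <- NULL
    if (nrow(seg_all) > 0) {
      eqtl_cfg <- sim$trans_targets |>
        filter(.data$gene_id %in% unique(seg_all$gene_id)) |>
        transmute(gene = .data$gene_id, marker_id = .data$qtl_marker,
                  log2_effect = 1)
      if (nrow(eqtl_cfg) > 0) {
        ct <- simulate_expression(geno, eqtl_cfg, ct_sd = 0.1,
                                  expr_sd = 0.25, seed = sim$seed)
        expr <- qpcr_normalize(ct, c("SAND", "TIP41"))
        coloc <- purrr::map(unique(seg_all$gene_id), function(gid) {
          ex <- filter(expr, .data$trait_id == gid)
          if (nrow(ex) == 0) {
            return(tibble(gene_id = gid, colocalized = FALSE))
          }
          thr <- permutation_threshold(
            mutate(ex, value = log2(.data$value)), probs,
            n_perm = max(cfg$n_perm, 100), alpha = cfg$alpha,
            seed = cfg$seed + utf8_sum(gid))
          esc <- call_peaks(eqtl_scan(ex, probs, trait_id = gid), thr,
                            lod_drop = cfg$lod_drop)
          tibble(gene_id = gid,
                 colocalized = colocalize(esc, qtl$chrom, qtl$ci_lo,
                                          qtl$ci_hi))
        }) |> bind_rows()
      }
    }
    reports[[mk]] <- trans_report(screened, seg_all, art_all, coloc)
  }
  if (length(reports) == 0) return(NULL)
  bind_rows(reports) |> arrange(.data$rank)
}

write_summary_md <- function(res, path) {
  lines <- c("# Pipeline summary", "")
  if (!is.null(res$peaks)) {
    lines <- c(lines, sprintf("- QTL peaks called: %d (traits scanned: %d)",
                              nrow(res$peaks), length(res$scans)),
               sprintf("- negative effect signs: %d / %d",
                       sum(res$peaks$effect_sign == -1), nrow(res$peaks)))
  }
  if (!is.null(res$pleiotropy)) {
    lines <- c(lines, sprintf("- pleiotropy regions: %d (>= 2 traits: %d)",
                              nrow(res$pleiotropy),
                              sum(res$pleiotropy$n_traits >= 2)))
  }
  if (!is.null(res$funnel_counts)) {
    fc <- res$funnel_counts
    lines <- c(lines, sprintf(
      "- cis funnel: %d in interval -> %d pathway -> %d associated -> %d cosegregating",
      fc$n_in_interval, fc$n_pathway, fc$n_assoc, fc$n_coseg))
  }
  if (!is.null(res$trans)) {
    lines <- c(lines, sprintf("- trans report rows: %d (colocalized: %d)",
                              nrow(res$trans),
                              sum(res$trans$eqtl_colocalized)))
  }
  writeLines(lines, path)
}

#' Compare metabolite levels between a knockout and wild type
#'
#' Per metabolite: group means of log10 intensities, raw-scale fold change
#' (mutant/WT geometric means), Welch's two-sample t-test, and significance
#' stars at 0.05/0.01/0.001. Metabolites with fewer than two replicates in
#' a group are skipped.
#'
#' @param mutant,wt long metabolite tibbles (`metabolite, intensity`, raw
#'   scale) for the two genotypes; >= 3 replicates per group recommended.
#' @param adjust p-value adjustment method (default `"none"`, matching raw
#'   per-metabolite reporting; e.g. `"BH"` for Benjamini-Hochberg).
#' @return Tibble `metabolite, n_mutant, n_wt, mean_log10_mutant,
#'   mean_log10_wt, fold_change, p_value, stars`.
#' @export
knockout_compare <- function(mutant, wt, adjust = "none") {
  shared <- intersect(unique(mutant$metabolite), unique(wt$metabolite))
  out <- purrr::map(shared, function(met) {
    a <- mutant$intensity[mutant$metabolite == met]
    b <- wt$intensity[wt$metabolite == met]
    a <- log10(a[!is.na(a) & a > 0]); b <- log10(b[!is.na(b) & b > 0])
    if (length(a) < 2 || length(b) < 2) {
      message("skipping '", met, "': fewer than 2 replicates in a group")
      return(NULL)
    }
    p <- if (sd(a) == 0 && sd(b) == 0 && mean(a) == mean(b)) 1 else
      t.test(a, b)$p.value
    tibble(metabolite = met, n_mutant = length(a), n_wt = length(b),
           mean_log10_mutant = mean(a), mean_log10_wt = mean(b),
           fold_change = 10^(mean(a) - mean(b)), p_value = p)
  }) |> purrr::compact() |> bind_rows()
  if (nrow(out) == 0) return(out)
  out$p_value <- stats::p.adjust(out$p_value, method = adjust)
  out$stars <- dplyr::case_when(out$p_value < 0.001 ~ "***",
                                out$p_value < 0.01 ~ "**",
                                out$p_value < 0.05 ~ "*",
                                TRUE ~ "")
  out
}
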