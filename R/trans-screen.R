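#' Screen genes for trans-acting methylation coupling to a QTL
#'
#' Applies the five criteria for RdDM-style trans targets: (1) probes fall
#' inside the gene promoter; (2) the methylation calls vary across the
#' epiRILs; (3) the parental lines (Col-0, ddm1-2) are polymorphic for
#' methylation at those probes; (4) at least two consecutive promoter
#' probes (adjacent in genomic order) correlate with the QTL peak-marker
#' coding, significantly and with the same sign; (5) the gene lies outside
#' the QTL support interval.
#'
#' @param probes long probe tibble; parental measurements are rows whose
#'   `line` is `"Col-0"` / `"ddm1-2"`.
#' @param genes gene tibble.
#' @param geno wide epigenotype tibble.
#' @param qtl one peak row (`trait_id, chrom, marker_id, ci_lo, ci_hi`).
#' @param map marker map tibble.
#' @param alpha probe-marker correlation significance level (default 0.05).
#' @return Tibble of passing genes: `gene_id, trait_id, marker_id,
#'   n_sig_probes, run_probes` (ids of the consecutive significant run)
#'   plus a `summary` attribute counting genes failing each criterion.
#' @export
screen_trans_genes <- function(probes, genes, geno, qtl, map, alpha = 0.05) {
  g01 <- as.integer(geno[[qtl$marker_id]] == "DDM1")
  names(g01) <- geno$line
  bp <- cm_to_bp(map, qtl$chrom, c(qtl$ci_lo, qtl$ci_hi))
  fail <- c(no_promoter_probes = 0L, zero_variance = 0L,
            parents_monomorphic = 0L, no_consecutive_run = 0L,
            inside_interval = 0L)
  out <- purrr::map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    pp <- filter(probes, .data$chrom == g$chrom,
                 .data$start < g$prom_end, .data$end > g$prom_start)
    if (nrow(pp) == 0) {                       # criterion 1
      fail["no_promoter_probes"] <<- fail["no_promoter_probes"] + 1L
      return(NULL)
    }
    epi <- filter(pp, !.data$line %in% c("Col-0", "ddm1-2"))
    v <- epi |> group_by(.data$probe_id) |>
      summarise(v = var(methylation_state(.data$ml) == "methylated",
                        na.rm = TRUE), .groups = "drop")
    if (all(v$v == 0 | is.na(v$v))) {          # criterion 2: calls invariant
      fail["zero_variance"] <<- fail["zero_variance"] + 1L
      return(NULL)
    }
    par <- filter(pp, .data$line %in% c("Col-0", "ddm1-2")) |>
      mutate(state = methylation_state(.data$ml)) |>
      tidyr::pivot_wider(id_cols = "probe_id", names_from = "line",
                         values_from = "state")
    poly <- all(c("Col-0", "ddm1-2") %in% names(par)) &&
      any(par[["Col-0"]] != par[["ddm1-2"]], na.rm = TRUE)
    if (!poly) {                               # criterion 3
      fail["parents_monomorphic"] <<- fail["parents_monomorphic"] + 1L
      return(NULL)
    }
    # criterion 4: consecutive same-sign significant probe-marker correlations
    stats_by_probe <- epi |>
      group_by(.data$probe_id) |>
      summarise(start = first(.data$start), r = {
        gg <- g01[.data$line]
        ok <- !is.na(gg) & !is.na(.data$ml)
        if (sum(ok) < 3 || sd(.data$ml[ok]) == 0 || sd(gg[ok]) == 0)
          NA_real_ else cor(.data$ml[ok], gg[ok])
      }, n = sum(!is.na(.data$ml)), .groups = "drop") |>
      arrange(.data$start) |>
      mutate(p = 2 * pt(abs(.data$r) * sqrt((.data$n - 2) / (1 - .data$r^2)),
                        .data$n - 2, lower.tail = FALSE),
             sig = !is.na(.data$p) & .data$p < alpha)
    run <- with(stats_by_probe, {
      hit <- integer(0)
      for (k in seq_len(max(0, nrow(stats_by_probe) - 1))) {
        if (sig[k] && sig[k + 1] && sign(r[k]) == sign(r[k + 1]))
          hit <- union(hit, c(k, k + 1))
      }
      hit
    })
    if (length(run) < 2) {                     # criterion 4
      fail["no_consecutive_run"] <<- fail["no_consecutive_run"] + 1L
      return(NULL)
    }
    inside <- g$chrom == qtl$chrom &&
      g$body_start < bp[2] && g$body_end > bp[1]
    if (inside) {                              # criterion 5
      fail["inside_interval"] <<- fail["inside_interval"] + 1L
      return(NULL)
    }
    tibble(gene_id = g$gene_id, trait_id = qtl$trait_id,
           marker_id = qtl$marker_id,
           n_sig_probes = sum(stats_by_probe$sig),
           run_probes = paste(stats_by_probe$probe_id[run], collapse = ";"))
  }) |> purrr::compact() |> bind_rows()
  if (nrow(out) == 0) {
    out <- tibble(gene_id = character(0), trait_id = character(0),
                  marker_id = character(0), n_sig_probes = integer(0),
                  run_probes = character(0))
  }
  attr(out, "summary") <- fail
  out
}

#' Ranked trans-target report
#'
#' Aggregates the evidence per screened gene: number of perfect-similarity
#' segments against the QTL interval, number of artsRNAs passing the AGO
#' filter, sRNA library support, TE proximity of the matched promoter
#' region, and eQTL colocalization with the trans QTL interval. Ranked by
#' (colocalization, library support, best AGO score); genes with no
#' segments are dropped.
#'
#' @param screened tibble from [screen_trans_genes()].
#' @param segments_by_gene tibble of segments with a `gene_id` column.
#' @param artsrnas scored + library-matched artsRNA tibble with `gene_id`
#'   (columns from [score_ago_loading()] and [match_srna_library()], and
#'   `te_within_1kb` if annotated).
#' @param eqtl_coloc optional tibble `gene_id, colocalized` (logical).
#' @return Ranked tibble, one row per gene: `gene_id, trait_id, marker_id,
#'   n_segments, n_artsrnas, library_support, best_ago, te_within_1kb,
#'   eqtl_colocalized, rank`.
#' @export
trans_report <- function(screened, segments_by_gene, artsrnas,
                         eqtl_coloc = NULL) {
  if (nrow(screened) == 0) {
    return(tibble(gene_id = character(0), trait_id = character(0),
                  marker_id = character(0), n_segments = integer(0),
                  n_artsrnas = integer(0), library_support = numeric(0),
                  best_ago = numeric(0), te_within_1kb = logical(0),
                  eqtl_colocalized = logical(0), rank = integer(0)))
  }
  segs <- segments_by_gene |> group_by(.data$gene_id) |>
    summarise(n_segments = n(), .groups = "drop")
  hit_cols <- grep("^hits_", names(artsrnas), value = TRUE)
  arts <- artsrnas |> group_by(.data$gene_id) |>
    summarise(n_artsrnas = n(),
              library_support = if (length(hit_cols))
                sum(dplyr::pick(dplyr::all_of(hit_cols))) else 0,
              best_ago = max(.data$ago_max),
              te_within_1kb = if ("te_within_1kb" %in% names(artsrnas))
                any(.data$te_within_1kb) else FALSE,
              .groups = "drop")
  out <- screened |>
    inner_join(segs, by = "gene_id") |>
    left_join(arts, by = "gene_id") |>
    mutate(n_artsrnas = dplyr::coalesce(.data$n_artsrnas, 0L),
           library_support = dplyr::coalesce(.data$library_support, 0),
           best_ago = dplyr::coalesce(.data$best_ago, 0),
           te_within_1kb = dplyr::coalesce(.data$te_within_1kb, FALSE))
  coloc <- if (is.null(eqtl_coloc)) {
    tibble(gene_id = out$gene_id, eqtl_colocalized = FALSE)
  } else eqtl_coloc |> rename(eqtl_colocalized = "colocalized")
  out |>
    left_join(coloc, by = "gene_id") |>
    mutate(eqtl_colocalized = dplyr::coalesce(.data$eqtl_colocalized, FALSE)) |>
    arrange(dplyr::desc(.data$eqtl_colocalized),
            dplyr::desc(.data$library_support),
            dplyr::desc(.data$best_ago), .data$gene_id) |>
    mutate(rank = row_number()) |>
    select("gene_id", "trait_id", "marker_id", "n_segments", "n_artsrnas",
           "library_support", "best_ago", "te_within_1kb",
           "eqtl_colocalized", "rank")
}
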