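#' Project a genetic-map position to physical coordinates
#'
#' Linear interpolation between the midpoints of the flanking markers'
#' physical DMR intervals; positions beyond the first/last marker clip to
#' the chromosome ends (0 and +Inf respectively), with a message.
#'
#' @param map marker map tibble.
#' @param chrom chromosome.
#' @param cM position(s) in centiMorgan.
#' @return Numeric vector of base-pair positions.
#' @export
cm_to_bp <- function(map, chrom, cM) {
  mc <- filter(map, .data$chrom == !!chrom) |> arrange(.data$pos_cM)
  assert_that(nrow(mc) > 0, sprintf("no markers on chromosome '%s'", chrom))
  mid <- (mc$phys_start + mc$phys_end) / 2
  out <- numeric(length(cM))
  below <- cM < min(mc$pos_cM); above <- cM > max(mc$pos_cM)
  if (any(below | above)) {
    message("map position(s) outside marker range; clipped to chromosome ends")
  }
  out[below] <- 0
  out[above] <- Inf
  inr <- !below & !above
  if (any(inr)) {
    out[inr] <- stats::approx(mc$pos_cM, mid, xout = cM[inr],
                              ties = "ordered")$y
  }
  out
}

#' Genes inside a QTL support interval
#'
#' Projects the cM support interval to base pairs via [cm_to_bp()] and
#' returns the genes whose gene body overlaps the projection (half-open
#' overlap) on the same chromosome.
#'
#' @param genes gene tibble (as from [read_annotation()]`$genes`).
#' @param map marker map tibble.
#' @param chrom,cM_lo,cM_hi the support interval.
#' @return The subset of `genes`, with `bp_lo, bp_hi` columns recording the
#'   projection.
#' @export
genes_in_interval <- function(genes, map, chrom, cM_lo, cM_hi) {
  bp <- cm_to_bp(map, chrom, c(cM_lo, cM_hi))
  out <- filter(genes, .data$chrom == !!chrom,
                .data$body_start < bp[2], .data$body_end > bp[1])
  mutate(out, bp_lo = bp[1], bp_hi = bp[2])
}

#' Filter genes by pathway membership
#'
#' Keeps genes annotated to the trait's pathway class in a local two-column
#' table; unannotated genes are treated as non-members.
#'
#' @param genes gene tibble with `gene_id`.
#' @param pathway_table tibble `gene_id, pathway`.
#' @param pathway_class pathway (or vector of pathways) to keep.
#' @return The filtered gene tibble; empty with a warning when the table is
#'   empty.
#' @export
filter_pathway <- function(genes, pathway_table, pathway_class) {
  if (is.null(pathway_table) || nrow(pathway_table) == 0) {
    warn("empty pathway table: no genes retained")
    return(genes[0, ])
  }
  keep <- pathway_table$gene_id[pathway_table$pathway %in% pathway_class]
  filter(genes, .data$gene_id %in% keep)
}

#' Staged cis-candidate funnel
#'
#' For each gene inside a QTL support interval, evaluates in order (with
#' short-circuiting): pathway membership (optional), methylation-trait
#' association (P below `alpha_assoc` in at least one of promoter, gene
#' body, 1 kb downstream), cosegregation of the best region's methylation
#' state with the QTL peak marker (P below `alpha_coseg`), then ranks the
#' survivors. The rank score weights the position of the significant DMR
#' (promoter 3, gene body 2, downstream 1, the strongest significant region
#' counting), adds 1 for a TE within 1 kb of the gene, and 1 for supplied
#' expression-difference evidence.
#'
#' @param genes gene tibble.
#' @param qtl one peak row (`trait_id, chrom, marker_id, ci_lo, ci_hi`).
#' @param probes long probe tibble covering gene regions.
#' @param trait tibble `line, value` for the QTL trait.
#' @param geno wide epigenotype tibble (for the peak-marker calls).
#' @param map marker map tibble.
#' @param pathway_table optional `gene_id, pathway`; with `pathway_class`,
#'   enables the pathway stage (NULL disables it).
#' @param pathway_class pathway label(s) matching the trait.
#' @param tes optional TE tibble for the TE-proximity rank bonus.
#' @param expression_evidence optional tibble `gene_id, significant`.
#' @param alpha_assoc,alpha_coseg stage significance levels (default 0.05).
#' @param region_weights promoter/gene body/downstream rank weights.
#' @return A funnel tibble, one row per gene: stage flags (`in_interval,
#'   pathway_member, assoc_significant, coseg_significant`), p-values, best
#'   region, `rank_score`, `surviving`; ordered by surviving, rank score,
#'   gene id.
#' @export
run_funnel <- function(genes, qtl, probes, trait, geno, map,
                       pathway_table = NULL, pathway_class = NULL,
                       tes = NULL, expression_evidence = NULL,
                       alpha_assoc = 0.05, alpha_coseg = 0.05,
                       region_weights = c(promoter = 3, gene_body = 2,
                                          downstream = 1)) {
  ing <- genes_in_interval(genes, map, qtl$chrom, qtl$ci_lo, qtl$ci_hi)
  use_pathway <- !is.null(pathway_table) && !is.null(pathway_class)
  marker_calls <- tibble(line = geno$line, call = geno[[qtl$marker_id]])
  rows <- purrr::map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    rec <- tibble(gene_id = g$gene_id, trait_id = qtl$trait_id,
                  marker_id = qtl$marker_id,
                  in_interval = g$gene_id %in% ing$gene_id,
                  pathway_member = NA, assoc_significant = NA,
                  assoc_p = NA_real_, best_region = NA_character_,
                  coseg_significant = NA, coseg_p = NA_real_,
                  rank_score = NA_real_, surviving = FALSE)
    if (!rec$in_interval) return(rec)
    rec$pathway_member <- if (use_pathway) {
      nrow(filter_pathway(g, pathway_table, pathway_class)) > 0
    } else TRUE
    if (!rec$pathway_member) return(rec)
    regions <- tibble(
      region = c("promoter", "gene_body", "downstream"),
      start = c(g$prom_start, g$body_start, g$down_start),
      end = c(g$prom_end, g$body_end, g$down_end))
    res <- purrr::map(seq_len(3), function(r) {
      rm <- suppressWarnings(
        region_methylation(probes, g$chrom, regions$start[r], regions$end[r]))
      rm <- filter(rm, .data$line %in% trait$line)
      if (nrow(rm) < 10) return(NULL)
      as_ <- tryCatch(associate_methylation_trait(rm, trait),
                      error = function(e) NULL)
      if (is.null(as_)) return(NULL)
      tibble(region = regions$region[r], p = as_$p_value, rm = list(rm))
    }) |> purrr::compact() |> bind_rows()
    if (nrow(res) == 0) return(rec)   # no probes in any region: drops out
    sig <- filter(res, !is.na(.data$p), .data$p <= alpha_assoc)
    rec$assoc_p <- suppressWarnings(min(res$p, na.rm = TRUE))
    rec$assoc_significant <- nrow(sig) > 0
    if (!rec$assoc_significant) return(rec)
    # strongest significant region by weight, for ranking and cosegregation
    sig <- mutate(sig, w = region_weights[.data$region]) |>
      arrange(dplyr::desc(.data$w), .data$p)
    rec$best_region <- sig$region[1]
    states <- mutate(sig$rm[[1]], state = methylation_state(.data$ml))
    cs <- tryCatch(
      cosegregation_test(select(states, "line", "state"), marker_calls),
      error = function(e) NULL)
    if (is.null(cs)) return(rec)
    rec$coseg_p <- cs$p_value
    rec$coseg_significant <- isTRUE(cs$p_value <= alpha_coseg)
    if (!rec$coseg_significant) return(rec)
    te_bonus <- 0
    if (!is.null(tes) && nrow(tes) > 0) {
      tc <- tes[tes$chrom == g$chrom, ]
      if (nrow(tc) > 0) {
        gap <- pmax(tc$start - g$down_end, g$prom_start - tc$end, 0)
        te_bonus <- as.numeric(any(gap < 1000))
      }
    }
    expr_bonus <- 0
    if (!is.null(expression_evidence)) {
      hit <- filter(expression_evidence, .data$gene_id == g$gene_id,
                    .data$significant)
      expr_bonus <- as.numeric(nrow(hit) > 0)
    }
    rec$rank_score <- unname(region_weights[rec$best_region]) +
      te_bonus + expr_bonus
    rec$surviving <- TRUE
    rec
  }) |> bind_rows()
  arrange(rows, dplyr::desc(.data$surviving),
          dplyr::desc(dplyr::coalesce(.data$rank_score, -Inf)),
          .data$gene_id)
}

#' Stage counts of a funnel run
#'
#' @param funnel tibble from [run_funnel()].
#' @return One-row tibble `n_in_interval, n_pathway, n_assoc, n_coseg`
#'   (monotone non-increasing by construction).
#' @export
funnel_counts <- function(funnel) {
  tibble(
    n_in_interval = sum(funnel$in_interval, na.rm = TRUE),
    n_pathway = sum(funnel$in_interval & funnel$pathway_member, na.rm = TRUE),
    n_assoc = sum(funnel$assoc_significant, na.rm = TRUE),
    n_coseg = sum(funnel$coseg_significant, na.rm = TRUE))
}
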