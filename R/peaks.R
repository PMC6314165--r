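#' Call QTL peaks with 1.5-LOD support intervals
#'
#' Within each chromosome, local LOD maxima at or above the genome-wide
#' threshold are accepted greedily (highest first) subject to a minimum
#' separation. The support interval is the contiguous run of positions with
#' `LOD >= peak - lod_drop`, extended outward to the flanking marker
#' positions. The effect sign follows the convention
#' `sign(mean(trait | COL) - mean(trait | DDM1))`: a negative sign means
#' higher trait values in ddm1-derived epigenotypes.
#'
#' @param scan an `epiqtl_scan` from [hk_scan()].
#' @param threshold genome-wide LOD threshold (e.g. from
#'   [permutation_threshold()]).
#' @param lod_drop LOD drop defining the support interval (default 1.5).
#' @param min_sep_cM minimum separation between peaks (default 10).
#' @return The scan object with `$threshold` set and `$peaks` a tibble
#'   `trait_id, chrom, peak_cM, marker_id, lod, threshold, ci_lo, ci_hi,
#'   effect_size, effect_sign` (zero rows when nothing clears the threshold).
#' @export
call_peaks <- function(scan, threshold, lod_drop = 1.5, min_sep_cM = 10) {
  stopifnot(inherits(scan, "epiqtl_scan"))
  d <- scan$result
  peaks <- list()
  for (chr in unique(d$chrom)) {
    dc <- filter(d, .data$chrom == chr)
    nj <- nrow(dc)
    locmax <- dc$lod >= c(-Inf, dc$lod[-nj]) & dc$lod >= c(dc$lod[-1], -Inf)
    cand <- which(dc$lod >= threshold & locmax)
    accepted <- integer(0)
    for (j in cand[order(-dc$lod[cand])]) {
      if (all(abs(dc$pos_cM[accepted] - dc$pos_cM[j]) >= min_sep_cM)) {
        accepted <- c(accepted, j)
      }
    }
    mk_cm <- dc$pos_cM[!dc$is_pseudomarker]
    for (j in accepted) {
      lo <- j; hi <- j
      cut <- dc$lod[j] - lod_drop
      while (lo > 1 && dc$lod[lo - 1] >= cut) lo <- lo - 1
      while (hi < nrow(dc) && dc$lod[hi + 1] >= cut) hi <- hi + 1
      ci_lo <- max(c(mk_cm[mk_cm <= dc$pos_cM[lo]], min(dc$pos_cM)))
      ci_hi <- min(c(mk_cm[mk_cm >= dc$pos_cM[hi]], max(dc$pos_cM)))
      nearest_mk <- dc$marker_id[!dc$is_pseudomarker][
        which.min(abs(mk_cm - dc$pos_cM[j]))]
      peaks[[length(peaks) + 1]] <- tibble(
        trait_id = scan$trait_id, chrom = chr, peak_cM = dc$pos_cM[j],
        marker_id = nearest_mk, lod = dc$lod[j], threshold = threshold,
        ci_lo = ci_lo, ci_hi = ci_hi,
        effect_size = dc$coef[j],
        effect_sign = if (dc$coef[j] > 0) -1L else 1L)
    }
  }
  scan$threshold <- threshold
  scan$peaks <- if (length(peaks)) bind_rows(peaks) else
    tibble(trait_id = character(0), chrom = character(0),
           peak_cM = numeric(0), marker_id = character(0), lod = numeric(0),
           threshold = numeric(0), ci_lo = numeric(0), ci_hi = numeric(0),
           effect_size = numeric(0), effect_sign = integer(0))
  scan
}

#' Peak table of a called scan
#' @param scan an `epiqtl_scan` after [call_peaks()].
#' @return The peaks tibble.
#' @export
peaks <- function(scan) {
  stopifnot(inherits(scan, "epiqtl_scan"))
  if (is.null(scan$peaks)) abort("call_peaks() has not been run on this scan")
  scan$peaks
}

#' Does any peak fall inside a QTL support interval?
#'
#' Both endpoints are included (closed interval in cM).
#'
#' @param scan an `epiqtl_scan` with called peaks (e.g. an eQTL scan).
#' @param chrom,cM_lo,cM_hi the region, on the shared marker map.
#' @return TRUE iff some peak lies inside the region.
#' @export
colocalize <- function(scan, chrom, cM_lo, cM_hi) {
  pk <- peaks(scan)
  if (!chrom %in% unique(scan$result$chrom)) {
    abort(sprintf("chromosome '%s' is not on the scan's marker map", chrom))
  }
  any(pk$chrom == chrom & pk$peak_cM >= cM_lo & pk$peak_cM <= cM_hi)
}

#' Select marker cofactors by backward elimination
#'
#' Starting from candidate markers (by default evenly spaced in cM), fits
#' the trait on all candidates jointly and repeatedly removes the least
#' significant one until every remaining cofactor's partial-F p-value is at
#' or below `drop_alpha`.
#'
#' @param trait tibble `line, value`.
#' @param probs `epi_probs` (supplies marker genotype probabilities).
#' @param candidates marker ids; default: markers spaced >= `spacing_cM` apart.
#' @param drop_alpha retention threshold (default 0.02).
#' @param spacing_cM spacing for the default candidate grid (default 10).
#' @param window_cM exclusion window stored in the returned set (default 10).
#' @return A [cofactor_set()] (possibly empty).
#' @export
select_cofactors <- function(trait, probs, candidates = NULL,
                             drop_alpha = 0.02, spacing_cM = 10,
                             window_cM = 10) {
  mkpos <- filter(probs$pos, !.data$is_pseudomarker)
  if (is.null(candidates)) {
    candidates <- mkpos |>
      group_by(.data$chrom) |>
      dplyr::reframe(marker_id = {
        keep <- integer(0); lastcm <- -Inf
        for (k in seq_along(.data$pos_cM)) {
          if (.data$pos_cM[k] - lastcm >= spacing_cM) {
            keep <- c(keep, k); lastcm <- .data$pos_cM[k]
          }
        }
        .data$marker_id[keep]
      }) |> pull("marker_id")
  }
  al <- align_trait(trait, probs)
  y <- al$y
  jm <- match(candidates, probs$pos$marker_id)
  assert_that(!anyNA(jm), "candidate marker absent from scan positions")
  X <- probs$P[al$rows, jm, drop = FALSE]
  colnames(X) <- candidates
  # thin by doubling the spacing until the model is estimable
  while (length(y) < ncol(X) + 2 && ncol(X) > 1) {
    message("thinning cofactor candidates: n too small for ", ncol(X),
            " candidates")
    X <- X[, seq(1, ncol(X), by = 2), drop = FALSE]
  }
  active <- colnames(X)
  repeat {
    if (length(active) == 0) break
    Xa <- cbind(`(Intercept)` = 1, X[, active, drop = FALSE])
    fit <- lm.fit(Xa, y)
    dfres <- length(y) - fit$rank
    if (dfres <= 0) { active <- active[-length(active)]; next }
    rss <- sum(fit$residuals^2)
    pvals <- vapply(active, function(mk) {
      f0 <- lm.fit(Xa[, setdiff(colnames(Xa), mk), drop = FALSE], y)
      rss0 <- sum(f0$residuals^2)
      Fst <- (rss0 - rss) / (rss / dfres)
      pf(Fst, 1, dfres, lower.tail = FALSE)
    }, numeric(1))
    pvals[is.na(pvals)] <- 1
    if (max(pvals) <= drop_alpha) break
    active <- setdiff(active, names(which.max(pvals)))
  }
  cofactor_set(active, window_cM = window_cM)
}

#' Merge overlapping QTL support intervals into pleiotropy regions
#'
#' Single-linkage merge of overlapping (or touching) 1.5-LOD support
#' intervals across traits; a region spanned by two or more traits is a
#' candidate pleiotropic region. If trait values are supplied, each trait
#' pair sharing a region is annotated with its Pearson correlation and the
#' correlation t-test p-value.
#'
#' @param peak_table tibble of peaks across traits (as from [call_peaks()]),
#'   optionally with a `trait_group` column.
#' @param trait_values optional long tibble `trait_id, line, value`.
#' @return A list: `regions` (region_id, chrom, cM_lo, cM_hi, n_traits,
#'   n_groups, traits as a list-column) and `trait_pairs` (per shared-region
#'   trait pair: correlation and p-value; empty when `trait_values` absent).
#' @export
pleiotropy_regions <- function(peak_table, trait_values = NULL) {
  if (nrow(peak_table) == 0) {
    return(list(regions = tibble(region_id = integer(0), chrom = character(0),
                                 cM_lo = numeric(0), cM_hi = numeric(0),
                                 n_traits = integer(0), n_groups = integer(0),
                                 traits = list()),
                trait_pairs = tibble()))
  }
  if (!"trait_group" %in% names(peak_table)) {
    peak_table$trait_group <- "trait"
  }
  regions <- list()
  for (chr in unique(peak_table$chrom)) {
    pc <- arrange(filter(peak_table, .data$chrom == chr), .data$ci_lo)
    cur_lo <- pc$ci_lo[1]; cur_hi <- pc$ci_hi[1]; members <- 1
    for (k in seq_len(nrow(pc))[-1]) {
      if (pc$ci_lo[k] <= cur_hi) {         # overlap or touch: merge
        cur_hi <- max(cur_hi, pc$ci_hi[k]); members <- c(members, k)
      } else {
        regions[[length(regions) + 1]] <- list(chrom = chr, lo = cur_lo,
                                               hi = cur_hi, m = pc[members, ])
        cur_lo <- pc$ci_lo[k]; cur_hi <- pc$ci_hi[k]; members <- k
      }
    }
    regions[[length(regions) + 1]] <- list(chrom = chr, lo = cur_lo,
                                           hi = cur_hi, m = pc[members, ])
  }
  reg <- purrr::imap(regions, function(r, i) {
    tibble(region_id = i, chrom = r$chrom, cM_lo = r$lo, cM_hi = r$hi,
           n_traits = length(unique(r$m$trait_id)),
           n_groups = length(unique(r$m$trait_group)),
           traits = list(sort(unique(r$m$trait_id))))
  }) |> bind_rows()

  pairs <- tibble()
  if (!is.null(trait_values)) {
    pr <- purrr::imap(regions, function(r, i) {
      tr <- sort(unique(r$m$trait_id))
      if (length(tr) < 2) return(NULL)
      cmb <- utils::combn(tr, 2)
      purrr::map(seq_len(ncol(cmb)), function(k) {
        a <- filter(trait_values, .data$trait_id == cmb[1, k])
        b <- filter(trait_values, .data$trait_id == cmb[2, k])
        d <- inner_join(select(a, "line", va = "value"),
                        select(b, "line", vb = "value"), by = "line")
        d <- filter(d, complete.cases(d))
        if (nrow(d) < 3 || sd(d$va) == 0 || sd(d$vb) == 0) {
          return(tibble(region_id = i, trait_a = cmb[1, k],
                        trait_b = cmb[2, k], cor = NA_real_,
                        p_value = NA_real_))
        }
        ct <- stats::cor.test(d$va, d$vb)
        tibble(region_id = i, trait_a = cmb[1, k], trait_b = cmb[2, k],
               cor = unname(ct$estimate), p_value = ct$p.value)
      }) |> bind_rows()
    })
    pairs <- bind_rows(purrr::compact(pr))
  }
  list(regions = reg, trait_pairs = pairs)
}

#' Relative expression from qPCR Ct values
#'
#' Normalises each target gene against the mean Ct of the reference genes:
#' `relative expression = efficiency^(mean(Ct_refs) - Ct_target)`, the
#' delta-Ct method with configurable amplification efficiency (default 2,
#' i.e. perfect doubling per cycle).
#'
#' @param ct long tibble `line, gene, ct`.
#' @param reference_genes character vector of reference gene names present
#'   in `ct` (at least one per line).
#' @param efficiency amplification efficiency (default 2).
#' @return Tibble `trait_id, line, value, log2_value` for every non-reference
#'   gene; missing target Ct gives missing expression.
#' @export
qpcr_normalize <- function(ct, reference_genes, efficiency = 2) {
  assert_that(all(reference_genes %in% ct$gene),
              "reference genes absent from Ct table")
  refs <- ct |>
    filter(.data$gene %in% reference_genes) |>
    group_by(.data$line) |>
    summarise(ref_ct = mean(.data$ct, na.rm = TRUE), .groups = "drop")
  assert_that(all(!is.na(refs$ref_ct)),
              "every line needs at least one reference-gene Ct")
  ct |>
    filter(!.data$gene %in% reference_genes) |>
    inner_join(refs, by = "line") |>
    transmute(trait_id = .data$gene, line = .data$line,
              value = efficiency^(.data$ref_ct - .data$ct),
              log2_value = log2(.data$value))
}

#' Expression QTL scan on log2 relative expression
#'
#' Convenience wrapper: log2-transforms relative expression (as produced by
#' [qpcr_normalize()]) and runs [hk_scan()].
#'
#' @param expression tibble `line, value` of relative expression (raw scale).
#' @inheritParams hk_scan
#' @return An `epiqtl_scan`.
#' @export
eqtl_scan <- function(expression, probs, cofactors = NULL,
                      trait_id = NULL, min_lines = 10) {
  expr2 <- mutate(expression, value = log2(.data$value))
  hk_scan(expr2, probs, cofactors = cofactors, trait_id = trait_id,
          min_lines = min_lines)
}
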