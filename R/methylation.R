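#' Methylation-level score from probe posteriors
#'
#' A probe's methylation level is defined from the posterior probabilities of
#' its unmethylated and methylated states as `ml = -post_U + post_M`, a score
#' in \[-1, 1\]: -1 means certainly unmethylated, +1 certainly methylated.
#'
#' @param post_U,post_M posterior probabilities; must sum to 1 within 1e-6.
#' @return Numeric vector of ml scores.
#' @export
methylation_level <- function(post_U, post_M) {
  assert_that(all(post_U >= 0 & post_U <= 1, na.rm = TRUE) &&
              all(post_M >= 0 & post_M <= 1, na.rm = TRUE),
              "posteriors must lie in [0, 1]")
  dev <- abs(post_U + post_M - 1)
  if (any(dev > 1e-6, na.rm = TRUE)) {
    abort("post_U + post_M must equal 1 (tolerance 1e-6)")
  }
  -post_U + post_M
}

#' Classify methylation state from the ml score
#'
#' Scores in \[-1, -0.3) are hypomethylated; scores in \[-0.3, 1\] are
#' methylated (the boundary -0.3 belongs to the methylated side).
#'
#' @param ml methylation-level scores in \[-1, 1\].
#' @return Character vector, `"hypomethylated"` or `"methylated"`.
#' @export
methylation_state <- function(ml) {
  assert_that(all(ml >= -1 - 1e-9 & ml <= 1 + 1e-9, na.rm = TRUE),
              "ml must lie in [-1, 1]")
  if_else(ml < -0.3, "hypomethylated", "methylated")
}

#' Per-line methylation of a genomic region
#'
#' Averages ml over all probes overlapping the region (half-open interval
#' overlap) and classifies the per-line mean with the -0.3 threshold.
#'
#' @param probes long probe tibble (`probe_id, chrom, start, end, line, ml`).
#' @param chrom,start,end region, 0-based half-open.
#' @return Tibble `line, ml, state, n_probes`; zero rows (with a warning) if
#'   no probe overlaps the region.
#' @export
region_methylation <- function(probes, chrom, start, end) {
  hit <- filter(probes, .data$chrom == !!chrom,
                .data$start < !!end, .data$end > !!start)
  if (nrow(hit) == 0) {
    warn(sprintf("no probes overlap %s:[%d,%d); region skipped",
                 chrom, as.integer(start), as.integer(end)))
    return(tibble(line = character(0), ml = numeric(0),
                  state = character(0), n_probes = integer(0)))
  }
  hit |>
    group_by(.data$line) |>
    summarise(ml = mean(.data$ml, na.rm = TRUE),
              n_probes = dplyr::n_distinct(.data$probe_id), .groups = "drop") |>
    mutate(state = methylation_state(.data$ml)) |>
    select("line", "ml", "state", "n_probes")
}

#' Association between region methylation and a trait
#'
#' Simple linear regression of log10 trait value on the per-line region
#' methylation level, with a two-sided t-test on the slope. The binary
#' alternative (two-group t-test on the hypomethylated/methylated state)
#' is available via `use_state = TRUE`.
#'
#' @param region_ml tibble `line, ml` (and `state` if `use_state`).
#' @param trait tibble `line, value` (raw scale; log10 applied internally).
#' @param min_pairs minimum complete pairs (default 10).
#' @param use_state if TRUE, Welch t-test of log10 trait between states.
#' @return One-row tibble `slope, p_value, n`; slope/p are `NA` when the
#'   methylation level has zero variance.
#' @export
associate_methylation_trait <- function(region_ml, trait, min_pairs = 10,
                                        use_state = FALSE) {
  d <- inner_join(region_ml, trait, by = "line")
  d <- filter(d, !is.na(.data$ml), !is.na(.data$value), .data$value > 0)
  d$y <- log10(d$value)
  if (nrow(d) < min_pairs) {
    abort(sprintf("only %d complete pairs; need >= %d", nrow(d), min_pairs))
  }
  if (use_state) {
    d$state <- methylation_state(d$ml)
    if (length(unique(d$state)) < 2) {
      return(tibble(slope = NA_real_, p_value = NA_real_, n = nrow(d)))
    }
    tt <- t.test(y ~ state, data = d)
    return(tibble(slope = unname(diff(rev(tt$estimate))),
                  p_value = tt$p.value, n = nrow(d)))
  }
  if (sd(d$ml) == 0) {
    return(tibble(slope = NA_real_, p_value = NA_real_, n = nrow(d)))
  }
  fit <- summary(lm(y ~ ml, data = d))$coefficients
  tibble(slope = fit["ml", "Estimate"], p_value = fit["ml", "Pr(>|t|)"],
         n = nrow(d))
}

#' Cosegregation of a DMR methylation state with a marker
#'
#' 2x2 contingency test (hypomethylated/methylated x COL/DDM1) across
#' lines: chi-square without continuity correction, switching to Fisher's
#' exact test when any expected cell count is below 5.
#'
#' @param states tibble `line, state`.
#' @param calls tibble `line, call` with calls `"COL"`/`"DDM1"`.
#' @param min_lines minimum shared lines (default 10).
#' @return One-row tibble `chi2, p_value, test, degenerate, n` plus the
#'   contingency table in the `table` attribute.
#' @export
cosegregation_test <- function(states, calls, min_lines = 10) {
  d <- inner_join(states, calls, by = "line")
  d <- filter(d, !is.na(.data$state), !is.na(.data$call))
  assert_that(nrow(d) >= min_lines,
              sprintf("need >= %d shared lines, got %d", min_lines, nrow(d)))
  tab <- table(factor(d$state, levels = c("hypomethylated", "methylated")),
               factor(d$call, levels = c("COL", "DDM1")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    out <- tibble(chi2 = NA_real_, p_value = 1, test = "degenerate",
                  degenerate = TRUE, n = nrow(d))
    attr(out, "table") <- tab
    return(out)
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    ft <- fisher.test(tab)
    out <- tibble(chi2 = NA_real_, p_value = ft$p.value, test = "fisher",
                  degenerate = FALSE, n = nrow(d))
  } else {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    out <- tibble(chi2 = unname(ct$statistic), p_value = ct$p.value,
                  test = "chisq", degenerate = FALSE, n = nrow(d))
  }
  attr(out, "table") <- tab
  out
}
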