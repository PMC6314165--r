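#' Batch-correct metabolite intensities
#'
#' Divides every sample intensity by the mean intensity of that metabolite
#' within the sample's measurement batch (over non-missing samples), so the
#' corrected values have per-(metabolite, batch) mean 1. Idempotent.
#'
#' @param m long metabolite tibble `line, batch, metabolite, intensity`.
#' @return The tibble with `intensity` replaced by corrected values; missing
#'   values stay missing. A batch whose metabolite is entirely missing
#'   stays missing, with a warning.
#' @export
batch_correct <- function(m) {
  assert_that(all(c("line", "batch", "metabolite", "intensity") %in% names(m)),
              "need columns line, batch, metabolite, intensity")
  out <- m |>
    group_by(.data$metabolite, .data$batch) |>
    mutate(.bmean = mean(.data$intensity, na.rm = TRUE)) |>
    ungroup()
  allmiss <- is.nan(out$.bmean)
  if (any(allmiss)) {
    warn(sprintf("%d (metabolite, batch) cells are entirely missing",
                 length(unique(paste(out$metabolite[allmiss],
                                     out$batch[allmiss])))))
  }
  out |>
    mutate(intensity = if_else(is.nan(.data$.bmean), .data$intensity,
                               .data$intensity / .data$.bmean)) |>
    select(-".bmean")
}

#' Per-metabolite coefficient of variation (%)
#'
#' `100 * sd / mean` on the (batch-corrected) raw scale over non-missing
#' lines. Undefined (missing) for zero mean or fewer than two values.
#'
#' @param m long metabolite tibble.
#' @return Tibble `metabolite, cv, n`.
#' @export
coefficient_of_variation <- function(m) {
  m |>
    group_by(.data$metabolite) |>
    summarise(n = sum(!is.na(.data$intensity)),
              .mean = mean(.data$intensity, na.rm = TRUE),
              .sd = sd(.data$intensity, na.rm = TRUE), .groups = "drop") |>
    mutate(cv = if_else(.data$n >= 2 & .data$.mean != 0,
                        100 * .data$.sd / .data$.mean, NA_real_)) |>
    select("metabolite", "cv", "n")
}

#' Classify metabolite detection relative to the parents
#'
#' Each metabolite is assigned to one of four classes from its detection in
#' the two parents (Col-0, ddm1-2) and the epiRILs: `both_parents`,
#' `col_only`, `ddm1_only`, or `epiRIL_only` (transgressive: absent from
#' both parents, detected in at least one epiRIL).
#'
#' @param m long metabolite tibble for the epiRILs (`NA` intensity = not
#'   detected).
#' @param parent_flags tibble `metabolite, col_detected, ddm1_detected`
#'   (logical).
#' @return Tibble `metabolite, detection_class, n_epirils_detected`;
#'   metabolites detected nowhere are dropped with a warning.
#' @export
classify_detection <- function(m, parent_flags) {
  epi <- m |>
    group_by(.data$metabolite) |>
    summarise(n_epirils_detected = sum(!is.na(.data$intensity) &
                                         .data$intensity > 0),
              .groups = "drop")
  d <- left_join(epi, parent_flags, by = "metabolite") |>
    mutate(col_detected = dplyr::coalesce(.data$col_detected, FALSE),
           ddm1_detected = dplyr::coalesce(.data$ddm1_detected, FALSE))
  nowhere <- !d$col_detected & !d$ddm1_detected & d$n_epirils_detected == 0
  if (any(nowhere)) {
    warn(sprintf("%d metabolite(s) detected nowhere; excluded", sum(nowhere)))
    d <- d[!nowhere, ]
  }
  d |>
    mutate(detection_class = dplyr::case_when(
      .data$col_detected & .data$ddm1_detected ~ "both_parents",
      .data$col_detected & !.data$ddm1_detected ~ "col_only",
      !.data$col_detected & .data$ddm1_detected ~ "ddm1_only",
      TRUE ~ "epiRIL_only")) |>
    select("metabolite", "detection_class", "n_epirils_detected")
}

#' Pairwise metabolite correlation summary
#'
#' Correlates metabolites of one tissue with those of another (or itself)
#' over shared lines on log10 batch-corrected intensities, pairwise-complete.
#' Summarises the fraction of metabolites with at least one correlated
#' partner (`|rho| > threshold`) and the fraction of pairs with
#' `rho < -threshold`.
#'
#' @param m1,m2 long metabolite tibbles (same or different tissue).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param threshold correlation threshold (default 0.2).
#' @param log10_transform log10 before correlating (default TRUE).
#' @return A `correlation_summary` list: `matrix` (metabolites of m1 x
#'   metabolites of m2), `fraction_correlated`, `fraction_negative`,
#'   `threshold`, `n_lines`.
#' @export
correlation_summary <- function(m1, m2 = m1, method = c("pearson", "spearman"),
                                threshold = 0.2, log10_transform = TRUE) {
  method <- match.arg(method)
  w1 <- tidyr::pivot_wider(m1, id_cols = "line", names_from = "metabolite",
                           values_from = "intensity")
  w2 <- tidyr::pivot_wider(m2, id_cols = "line", names_from = "metabolite",
                           values_from = "intensity")
  shared <- intersect(w1$line, w2$line)
  assert_that(length(shared) >= 3, "need >= 3 shared lines")
  a <- as.matrix(w1[match(shared, w1$line), -1, drop = FALSE])
  b <- as.matrix(w2[match(shared, w2$line), -1, drop = FALSE])
  if (log10_transform) {
    a <- log10(replace(a, !is.na(a) & a <= 0, NA))
    b <- log10(replace(b, !is.na(b) & b <= 0, NA))
  }
  suppressWarnings({
    cm <- cor(a, b, use = "pairwise.complete.obs", method = method)
  })
  same <- identical(colnames(cm), rownames(cm))
  offdiag <- cm
  if (same) diag(offdiag) <- NA
  frac_corr <- mean(apply(abs(offdiag) > threshold, 1, any, na.rm = TRUE))
  pair_vals <- if (same) offdiag[upper.tri(offdiag)] else as.vector(cm)
  frac_neg <- mean(pair_vals < -threshold, na.rm = TRUE)
  structure(list(matrix = cm, fraction_correlated = frac_corr,
                 fraction_negative = frac_neg, threshold = threshold,
                 method = method, n_lines = length(shared)),
            class = "correlation_summary")
}

#' @export
print.correlation_summary <- function(x, ...) {
  cat(sprintf(
    "<correlation_summary> %dx%d (%s, n=%d): %.1f%% correlated (|rho|>%g), %.1f%% negative pairs\n",
    nrow(x$matrix), ncol(x$matrix), x$method, x$n_lines,
    100 * x$fraction_correlated, x$threshold, 100 * x$fraction_negative))
  invisible(x)
}

#' @export
glance.correlation_summary <- function(x, ...) {
  tibble(fraction_correlated = x$fraction_correlated,
         fraction_negative = x$fraction_negative,
         threshold = x$threshold, method = x$method, n_lines = x$n_lines)
}

#' Flowering-time correction of a trait
#'
#' Divides each line's raw-scale trait value by its flowering time, removing
#' variation that tracks flowering time (e.g. pleiotropic effects of
#' flowering-time loci on metabolite accumulation).
#'
#' @param trait tibble `line, value`.
#' @param ft tibble `line, ft` (days; must be positive wherever the trait is
#'   observed).
#' @return The trait tibble with corrected `value` and attribute
#'   `ft_corrected = TRUE`.
#' @export
flowering_correct <- function(trait, ft) {
  d <- left_join(trait, ft, by = "line")
  bad <- !is.na(d$value) & (is.na(d$ft) | d$ft <= 0)
  if (any(bad)) {
    abort(paste("non-positive or missing flowering time for line(s):",
                paste(d$line[bad], collapse = ", ")))
  }
  out <- mutate(d, value = .data$value / .data$ft) |> select(-"ft")
  attr(out, "ft_corrected") <- TRUE
  out
}
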