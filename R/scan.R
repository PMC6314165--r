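#' Genotype probabilities along the DMR marker map
#'
#' Computes, for every line and every scan position (markers plus optional
#' pseudomarkers on a regular centiMorgan grid), the probability that the
#' local epiallele is DDM1-derived, conditioning on the nearest observed
#' flanking markers through a reversible two-state Markov chain whose
#' switch probabilities follow the Haldane map function
#' `r = (1 - exp(-2d/100)) / 2` and whose stationary DDM1 frequency is
#' `prior_p` (estimated from the observed calls by default). These expected
#' genotypes are the regressors of Haley-Knott interval mapping.
#'
#' @param geno wide epigenotype tibble (`line` + marker columns).
#' @param map marker map tibble.
#' @param step_cM pseudomarker spacing; 0 scans at markers only.
#' @param prior_p stationary DDM1 epiallele frequency; default: observed mean.
#' @return An object of class `epi_probs`: positions tibble (`chrom, pos_cM,
#'   marker_id, is_pseudomarker`), a lines-by-positions probability matrix
#'   `P`, and the line ids. `tidy()` returns the long probability table.
#' @export
genotype_probabilities <- function(geno, map, step_cM = 0, prior_p = NULL) {
  assert_that(step_cM >= 0, "step_cM must be >= 0")
  validate_marker_map(map)
  G <- geno_matrix(geno, map)
  keep <- intersect(map$marker_id, colnames(G))
  if (length(keep) < nrow(map)) {
    map <- filter(map, .data$marker_id %in% keep)
  }
  G <- G[, map$marker_id, drop = FALSE]
  p <- prior_p %||% mean(G, na.rm = TRUE)
  assert_that(p > 0 && p < 1, "prior DDM1 frequency must lie in (0, 1)")

  pos <- map |>
    group_by(.data$chrom) |>
    dplyr::reframe({
      cm <- .data$pos_cM
      mid <- .data$marker_id
      grid <- if (step_cM > 0 && max(cm) > min(cm)) {
        setdiff(seq(min(cm), max(cm), by = step_cM), cm)
      } else numeric(0)
      tibble(pos_cM = c(cm, grid),
             marker_id = c(mid, rep(NA_character_, length(grid))),
             is_pseudomarker = c(rep(FALSE, length(cm)),
                                 rep(TRUE, length(grid))))
    }) |>
    arrange(.data$chrom, .data$pos_cM)

  P <- matrix(NA_real_, nrow(G), nrow(pos),
              dimnames = list(rownames(G), NULL))
  for (chr in unique(pos$chrom)) {
    jpos <- which(pos$chrom == chr)
    x <- pos$pos_cM[jpos]
    mk <- map$marker_id[map$chrom == chr]
    cmk <- map$pos_cM[map$chrom == chr]
    Gc <- G[, mk, drop = FALSE]
    for (i in seq_len(nrow(Gc))) {
      obs <- which(!is.na(Gc[i, ]))
      if (length(obs) == 0) { P[i, jpos] <- p; next }
      co <- cmk[obs]; go <- Gc[i, obs]
      iL <- findInterval(x, co)
      iR <- iL + 1L
      hasL <- iL >= 1L
      hasR <- iR <= length(co)
      pr <- rep(p, length(x))
      # left flank only contribution: P(DDM1 | left state, gap dL)
      p1L <- ifelse(hasL,
                    chain_transition(go[pmax(iL, 1L)], x - co[pmax(iL, 1L)], p),
                    p)
      # right flank: P(right state | genotype here) over gap dR
      bR <- go[pmin(iR, length(co))]
      dR <- co[pmin(iR, length(co))] - x
      pb1 <- ifelse(bR == 1, chain_transition(1, dR, p),
                    1 - chain_transition(1, dR, p))
      pb0 <- ifelse(bR == 1, chain_transition(0, dR, p),
                    1 - chain_transition(0, dR, p))
      both <- hasL & hasR
      num1 <- p1L * pb1; num0 <- (1 - p1L) * pb0
      pr[both] <- (num1 / (num1 + num0))[both]
      pr[hasL & !hasR] <- p1L[hasL & !hasR]
      # reversibility: conditioning on the right flank alone mirrors the left
      onlyR <- !hasL & hasR
      pr[onlyR] <- chain_transition(bR, dR, p)[onlyR]
      P[i, jpos] <- pr
    }
  }
  structure(list(pos = pos, P = P, lines = rownames(G), prior_p = p, map = map),
            class = "epi_probs")
}

#' @export
print.epi_probs <- function(x, ...) {
  cat(sprintf("<epi_probs> %d lines x %d positions (%d markers, prior DDM1 %.3f)\n",
              length(x$lines), nrow(x$pos), sum(!x$pos$is_pseudomarker),
              x$prior_p))
  invisible(x)
}

#' @export
tidy.epi_probs <- function(x, ...) {
  bind_cols(x$pos[rep(seq_len(nrow(x$pos)), each = length(x$lines)), ],
            tibble(line = rep(x$lines, nrow(x$pos)),
                   p_ddm1 = as.vector(x$P)))
}

#' Marker cofactor set for multiple-QTL scans
#'
#' @param markers marker ids used as covariates.
#' @param window_cM exclusion window: cofactors within this distance of the
#'   test position (same chromosome) are dropped from the model there.
#' @return A `cofactor_set` object.
#' @export
cofactor_set <- function(markers, window_cM = 10) {
  structure(list(markers = unique(as.character(markers)),
                 window_cM = window_cM), class = "cofactor_set")
}

# align a trait tibble (line, value) to probability object lines,
# returning complete-case y and row index
align_trait <- function(trait, probs) {
  assert_that(all(c("line", "value") %in% names(trait)),
              "trait needs columns line, value")
  assert_that(!anyDuplicated(trait$line), "duplicate line ids in trait")
  idx <- match(probs$lines, trait$line)
  y <- trait$value[idx]
  keep <- which(!is.na(y))
  list(y = y[keep], rows = keep)
}

# LOD profile for a single y against probability matrix X (no cofactors),
# via the closed form LOD = -(n/2) log10(1 - r^2)
lod_simple <- function(y, X) {
  n <- length(y)
  ys <- y - mean(y)
  sy <- sqrt(sum(ys^2))
  if (sy == 0) return(rep(0, ncol(X)))
  Xc <- sweep(X, 2, colMeans(X))
  sx <- sqrt(colSums(Xc^2))
  r <- as.vector(crossprod(Xc, ys)) / (sx * sy)
  r[!is.finite(r)] <- 0
  r <- pmin(pmax(r, -1), 1)
  lod <- -(n / 2) * log10(pmax(1 - r^2, .Machine$double.xmin))
  lod
}

#' Haley-Knott genome scan
#'
#' At each scan position, regresses the trait on the expected DDM1 genotype
#' probability, optionally with marker cofactors (multiple-QTL model);
#' cofactors within `window_cM` of the test position are excluded there.
#' `LOD = (n/2) log10(RSS0 / RSS1)` where the null model retains the
#' cofactors but drops the position term.
#'
#' @param trait tibble `line, value` (one trait; missing values dropped).
#' @param probs `epi_probs` from [genotype_probabilities()].
#' @param cofactors a [cofactor_set()] or NULL for plain interval mapping.
#' @param trait_id label carried into results.
#' @param min_lines minimum complete lines (default 10).
#' @return An `epiqtl_scan` object; `tidy()` gives the LOD profile
#'   (`chrom, pos_cM, marker_id, is_pseudomarker, lod, coef`), where `coef`
#'   is the fitted DDM1 - COL effect on the trait scale used.
#' @export
hk_scan <- function(trait, probs, cofactors = NULL,
                    trait_id = NULL, min_lines = 10) {
  trait_id <- trait_id %||% (if ("trait_id" %in% names(trait))
    as.character(trait$trait_id[1]) else "trait")
  al <- align_trait(trait, probs)
  y <- al$y
  assert_that(length(y) >= min_lines,
              sprintf("need >= %d lines with trait data, got %d",
                      min_lines, length(y)))
  X <- probs$P[al$rows, , drop = FALSE]
  pos <- probs$pos
  n <- length(y)

  if (is.null(cofactors) || length(cofactors$markers) == 0) {
    lod <- lod_simple(y, X)
    cf <- vapply(seq_len(ncol(X)), function(j) {
      v <- var(X[, j])
      if (v == 0) return(0)
      cov(X[, j], y) / v
    }, numeric(1))
    out <- mutate(pos, lod = lod, coef = cf)
  } else {
    mkr <- cofactors$markers
    jmk <- match(mkr, pos$marker_id)
    assert_that(!anyNA(jmk), "cofactor marker absent from scan positions")
    C <- X[, jmk, drop = FALSE]
    cchr <- pos$chrom[jmk]; ccm <- pos$pos_cM[jmk]
    lod <- numeric(nrow(pos)); cf <- numeric(nrow(pos))
    for (j in seq_len(nrow(pos))) {
      keep_cf <- !(cchr == pos$chrom[j] &
                   abs(ccm - pos$pos_cM[j]) < cofactors$window_cM)
      Cj <- C[, keep_cf, drop = FALSE]
      # position column first so pivoting drops a collinear cofactor, not it
      X1 <- cbind(1, X[, j], Cj)
      f1 <- lm.fit(X1, y)
      dropped <- is.na(f1$coefficients)
      rss1 <- sum(f1$residuals^2)
      X0 <- cbind(1, Cj[, !dropped[-(1:2)], drop = FALSE])
      f0 <- lm.fit(X0, y)
      rss0 <- sum(f0$residuals^2)
      lod[j] <- if (rss1 <= 0 || is.na(f1$coefficients[2])) {
        if (is.na(f1$coefficients[2])) 0 else
          (n / 2) * log10(rss0 / .Machine$double.xmin)
      } else (n / 2) * log10(rss0 / rss1)
      cf[j] <- f1$coefficients[2]
      if (is.na(cf[j])) cf[j] <- 0
    }
    lod <- pmax(lod, 0)
    out <- mutate(pos, lod = lod, coef = cf)
  }
  structure(list(trait_id = trait_id, result = out, n = n,
                 threshold = NA_real_, peaks = NULL,
                 cofactors = cofactors),
            class = "epiqtl_scan")
}

#' @export
print.epiqtl_scan <- function(x, ...) {
  cat(sprintf("<epiqtl_scan> trait '%s': %d positions, n = %d, max LOD %.3f",
              x$trait_id, nrow(x$result), x$n, max(x$result$lod)))
  if (!is.na(x$threshold)) cat(sprintf(", threshold %.3f", x$threshold))
  if (!is.null(x$peaks)) cat(sprintf(", %d peak(s)", nrow(x$peaks)))
  cat("\n")
  invisible(x)
}

#' @export
tidy.epiqtl_scan <- function(x, ...) {
  mutate(x$result, trait_id = x$trait_id, .before = 1)
}

#' @export
glance.epiqtl_scan <- function(x, ...) {
  tibble(trait_id = x$trait_id, n = x$n, n_positions = nrow(x$result),
         max_lod = max(x$result$lod), threshold = x$threshold,
         n_peaks = if (is.null(x$peaks)) NA_integer_ else nrow(x$peaks))
}

#' LOD profile plot
#' @param object an `epiqtl_scan`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.epiqtl_scan <- function(object, ...) {
  d <- tidy(object)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pos_cM, y = .data$lod)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (cM)", y = "LOD",
                  title = object$trait_id)
  if (!is.na(object$threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = object$threshold,
                                 linetype = "dashed", colour = "darkgreen")
  }
  if (!is.null(object$peaks) && nrow(object$peaks) > 0) {
    p <- p + ggplot2::geom_point(data = object$peaks,
                                 ggplot2::aes(x = .data$peak_cM, y = .data$lod),
                                 colour = "red")
  }
  p
}

# run code with a private RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Permutation-derived genome-wide LOD threshold
#'
#' Shuffles trait values across lines (epigenotype rows intact, preserving
#' marker linkage) and records the genome-wide maximum LOD of each permuted
#' scan; the threshold is the empirical `1 - alpha` quantile, giving a
#' genome-wide type-I error of `alpha`.
#'
#' @inheritParams hk_scan
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param alpha genome-wide type-I error (default 0.05).
#' @param seed integer seed (mandatory; permutation order is deterministic).
#' @return The LOD threshold, with the permutation maxima in attribute
#'   `"perm_max"`.
#' @export
permutation_threshold <- function(trait, probs, cofactors = NULL,
                                  n_perm = 1000, alpha = 0.05, seed) {
  assert_that(n_perm >= 100, "n_perm must be >= 100 (quantile unstable below)")
  assert_that(!missing(seed), "seed is required")
  al <- align_trait(trait, probs)
  y <- al$y
  n <- length(y)
  if (is.null(cofactors) || length(cofactors$markers) == 0) {
    X <- probs$P[al$rows, , drop = FALSE]
    Xc <- sweep(X, 2, colMeans(X))
    sx <- sqrt(colSums(Xc^2))
    sx[sx == 0] <- Inf
    Xs <- sweep(Xc, 2, sx, "/")
    ys <- y - mean(y)
    sy <- sqrt(sum(ys^2))
    if (sy == 0) {
      out <- 0; attr(out, "perm_max") <- rep(0, n_perm); return(out)
    }
    ys <- ys / sy
    Yp <- with_seed(seed,
      vapply(seq_len(n_perm), function(k) ys[sample.int(n)], numeric(n)))
    R <- crossprod(Xs, Yp)
    R <- pmin(pmax(R, -1), 1)
    maxlod <- apply(-(n / 2) * log10(pmax(1 - R^2, .Machine$double.xmin)),
                    2, max)
  } else {
    perms <- with_seed(seed,
      replicate(n_perm, sample.int(n), simplify = FALSE))
    tr <- tibble(line = probs$lines[al$rows], value = y)
    maxlod <- vapply(perms, function(pp) {
      tr$value <- y[pp]
      max(hk_scan(tr, probs, cofactors, min_lines = 2)$result$lod)
    }, numeric(1))
  }
  out <- unname(quantile(maxlod, probs = 1 - alpha, type = 7))
  attr(out, "perm_max") <- maxlod
  out
}
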