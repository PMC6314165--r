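#' Simulate flowering time with an epiallele effect
#'
#' Flowering time (days) = `ft_base + ft_effect * I(DDM1 at ft_marker) +
#' Gaussian noise`, giving one marker a pleiotropic handle on any trait
#' later divided by flowering time.
#'
#' @param geno wide epigenotype tibble.
#' @param cfg a [sim_config()].
#' @param seed optional override.
#' @return Tibble `line, ft`.
#' @export
simulate_flowering <- function(geno, cfg, seed = cfg$seed) {
  with_seed(seed + 2L, {
    g <- as.integer(geno[[cfg$ft_marker]] == "DDM1")
    g[is.na(g)] <- 0L
    tibble(line = geno$line,
           ft = pmax(cfg$ft_base + cfg$ft_effect * g +
                       rnorm(nrow(geno), 0, cfg$ft_sd), 1))
  })
}

#' Simulate a metabolite matrix with planted QTL effects
#'
#' Log10 intensity = baseline + planted epiallele effects + batch offset +
#' residual Gaussian noise. A planted fractional effect `f` with sign `-1`
#' shifts the DDM1 group up by `log10(1 + f)`, so the raw-scale
#' DDM1/COL geometric-mean ratio is `1 + f` and the recovered effect sign
#' (`sign(mean COL - mean DDM1)`) equals the planted sign. Also generates
#' null metabolites, flowering-time-driven metabolites (value proportional
#' to the line's flowering time), and transgressive presence/absence
#' metabolites present only when a specified two-marker DDM1 combination
#' occurs. Values below the detection floor (1% of the metabolite median)
#' are set missing.
#'
#' @param geno wide epigenotype tibble.
#' @param cfg a [sim_config()].
#' @param ft optional flowering-time tibble from [simulate_flowering()]
#'   (generated internally if absent and `ft_traits` is non-empty).
#' @param seed optional override.
#' @return List: `metabolites` (long tibble `tissue, line, batch, metabolite,
#'   intensity`), `ft`, and `truth` (every planted signal:
#'   `trait_id, kind, marker_id, marker2, effect, sign`).
#' @export
simulate_metabolome <- function(geno, cfg, ft = NULL, seed = cfg$seed) {
  pq <- cfg$planted_qtl
  assert_that(all(pq$marker_id %in% names(geno)),
              "planted QTL references a marker absent from the epigenotypes")
  n <- nrow(geno)
  if (is.null(ft) && length(cfg$ft_traits) > 0) {
    ft <- simulate_flowering(geno, cfg, seed)
  }
  with_seed(seed + 3L, {
    batch <- sprintf("B%d", (seq_len(n) - 1) %% cfg$n_batches + 1)
    traits <- list(); truth <- list()
    gmat <- function(mk) {
      g <- as.integer(geno[[mk]] == "DDM1"); g[is.na(g)] <- 0L; g
    }
    add_trait <- function(id, log10_vals) {
      boff <- rnorm(cfg$n_batches, 0, cfg$batch_sd)[as.integer(sub("B", "", batch))]
      traits[[id]] <<- 10^(log10_vals + boff + rnorm(n, 0, cfg$noise_sd))
    }
    for (k in seq_len(nrow(pq))) {
      delta <- log10(1 + pq$effect[k]) * (-pq$sign[k])
      add_trait(pq$trait_id[k], cfg$baseline_log10 + delta * gmat(pq$marker_id[k]))
      truth[[length(truth) + 1]] <- tibble(
        trait_id = pq$trait_id[k], kind = "qtl", marker_id = pq$marker_id[k],
        marker2 = NA_character_, effect = pq$effect[k], sign = pq$sign[k])
    }
    for (k in seq_len(cfg$n_null_traits)) {
      add_trait(sprintf("null_%d", k), cfg$baseline_log10)
      truth[[length(truth) + 1]] <- tibble(
        trait_id = sprintf("null_%d", k), kind = "null",
        marker_id = NA_character_, marker2 = NA_character_,
        effect = 0, sign = NA_integer_)
    }
    for (id in cfg$ft_traits) {
      # driven purely by flowering time (on the raw scale), so dividing by
      # flowering time removes the marker signal entirely
      traits[[id]] <- 10^(cfg$baseline_log10 + rnorm(n, 0, 0.02)) *
        (ft$ft[match(geno$line, ft$line)] / cfg$ft_base)
      truth[[length(truth) + 1]] <- tibble(
        trait_id = id, kind = "ft_pleiotropy", marker_id = cfg$ft_marker,
        marker2 = NA_character_, effect = cfg$ft_effect / cfg$ft_base,
        sign = -1L)
    }
    if (cfg$n_transgressive > 0) {
      mks <- filter(cfg$map, .data$chrom %in% c("chr4", "chr5")) |>
        group_by(.data$chrom) |> slice(2) |> pull("marker_id")
      for (k in seq_len(cfg$n_transgressive)) {
        present <- gmat(mks[1]) == 1 & gmat(mks[2]) == 1
        v <- 10^(cfg$baseline_log10 + rnorm(n, 0, cfg$noise_sd))
        v[!present] <- NA_real_
        traits[[sprintf("transgressive_%d", k)]] <- v
        truth[[length(truth) + 1]] <- tibble(
          trait_id = sprintf("transgressive_%d", k), kind = "transgressive",
          marker_id = mks[1], marker2 = mks[2], effect = NA_real_,
          sign = NA_integer_)
      }
    }
    long <- purrr::imap(traits, function(v, id) {
      tibble(tissue = cfg$tissue, line = geno$line, batch = batch,
             metabolite = id, intensity = v)
    }) |> bind_rows()
    # detection floor: below 1% of the metabolite median counts as absent
    long <- long |>
      group_by(.data$metabolite) |>
      mutate(intensity = if_else(!is.na(.data$intensity) &
               .data$intensity < 0.01 * median(.data$intensity, na.rm = TRUE),
               NA_real_, .data$intensity)) |>
      ungroup()
    list(metabolites = long, ft = ft, truth = bind_rows(truth))
  })
}

#' Simulate a qPCR Ct table with planted expression QTL
#'
#' Reference-gene Ct values are Gaussian around `ref_mean`; a target gene's
#' Ct equals the line's reference mean minus log2 of its relative
#' expression, which carries the planted epiallele effects:
#' `log2(rel expr) = log2_effect * I(DDM1 at marker) + noise`.
#'
#' @param geno wide epigenotype tibble.
#' @param eqtl tibble `gene, marker_id, log2_effect` of planted eQTL
#'   (a gene may appear with zero rows of effect = pure noise expression).
#' @param genes character vector of target genes to emit (default: those in
#'   `eqtl`).
#' @param reference_genes names of reference genes (default SAND, TIP41).
#' @param ref_mean,ct_sd,expr_sd Ct baseline, technical Ct noise, and log2
#'   biological expression noise.
#' @param seed integer seed.
#' @return Long Ct tibble `line, gene, ct`.
#' @export
simulate_expression <- function(geno, eqtl, genes = unique(eqtl$gene),
                                reference_genes = c("SAND", "TIP41"),
                                ref_mean = 24, ct_sd = 0, expr_sd = 0,
                                seed) {
  n <- nrow(geno)
  with_seed(seed + 4L, {
    refs <- purrr::map(reference_genes, function(rg) {
      tibble(line = geno$line, gene = rg, ct = rnorm(n, ref_mean, ct_sd))
    }) |> bind_rows()
    ref_mean_line <- refs |> group_by(.data$line) |>
      summarise(rm = mean(.data$ct), .groups = "drop")
    targets <- purrr::map(genes, function(gid) {
      l2 <- rep(0, n)
      for (k in which(eqtl$gene == gid)) {
        g <- as.integer(geno[[eqtl$marker_id[k]]] == "DDM1")
        g[is.na(g)] <- 0L
        l2 <- l2 + eqtl$log2_effect[k] * g
      }
      l2 <- l2 + rnorm(n, 0, expr_sd)
      tibble(line = geno$line, gene = gid,
             ct = ref_mean_line$rm[match(geno$line, ref_mean_line$line)] - l2)
    }) |> bind_rows()
    bind_rows(refs, targets)
  })
}
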