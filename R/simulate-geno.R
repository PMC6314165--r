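#' Simulation configuration for a synthetic epiRIL study
#'
#' Bundles the study design emulated by the generators: a 126-DMR map over
#' five chromosomes, two parental epialleles per marker with an expected
#' DDM1 frequency of 0.3 (the epiRIL backcross design biases toward Col-0
#' epialleles), probe posteriors coupled to the local epigenotype with a
#' reversion parameter, log-normal metabolite intensities with batch
#' effects and planted QTL effects in the 4-41% range, transgressive
#' (presence/absence) metabolites, flowering-time pleiotropy, and trans
#' targets whose promoters carry TE-derived segments copied from QTL
#' intervals.
#'
#' @param n_lines number of epiRILs (default 100).
#' @param markers_per_chrom markers on each of the 5 chromosomes
#'   (default c(26, 25, 25, 25, 25) = 126).
#' @param spacing_cM centiMorgan gap between adjacent markers (default 4).
#' @param p_ddm1 expected DDM1 epiallele frequency in (0,1) (default 0.3).
#' @param reversion_rate per-line-per-DMR probability that a DDM1 epiallele
#'   reverts to WT-like methylation (default 0.05).
#' @param missing_rate per-call missing probability (default 0).
#' @param probes_per_dmr probes simulated inside each DMR (default 3).
#' @param probe_noise_sd Gaussian noise on emitted posteriors (default 0.05).
#' @param planted_qtl tibble `marker_id, trait_id, effect, sign`: fractional
#'   effect `f` (raw-scale group ratio `1 + f`), sign -1 = higher in DDM1.
#' @param n_null_traits metabolites with no planted QTL (default 5).
#' @param n_batches measurement batches (default 4).
#' @param batch_sd log10 SD of batch offsets (default 0.05).
#' @param noise_sd log10 SD of residual intensity noise (default 0.1).
#' @param baseline_log10 log10 baseline intensity (default 3).
#' @param tissue tissue label (default "flower").
#' @param n_transgressive presence/absence metabolites conditional on a
#'   two-marker epiallele combination (default 1).
#' @param ft_marker marker with a flowering-time effect (default: first
#'   marker of chromosome 5); `ft_base`, `ft_effect`, `ft_sd` parameterise
#'   flowering time in days.
#' @param ft_traits trait ids driven purely by flowering-time pleiotropy
#'   (default "ft_driven").
#' @param trans_targets tibble `qtl_marker, gene_id, segment_length` of
#'   planted trans-regulation links (promoter segment copied from the QTL
#'   interval; lengths >= 24).
#' @param n_decoy_genes genes with no planted trans link (default 10).
#' @param srna_depletion WT/ddm1 sRNA count depletion factor (default 10).
#' @param seed mandatory integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_lines = 100,
                       markers_per_chrom = c(26L, 25L, 25L, 25L, 25L),
                       spacing_cM = 4,
                       p_ddm1 = 0.3,
                       reversion_rate = 0.05,
                       missing_rate = 0,
                       probes_per_dmr = 3,
                       probe_noise_sd = 0.05,
                       planted_qtl = default_planted_qtl(),
                       n_null_traits = 5,
                       n_batches = 4,
                       batch_sd = 0.05,
                       noise_sd = 0.1,
                       baseline_log10 = 3,
                       tissue = "flower",
                       n_transgressive = 1,
                       ft_marker = "M5_01",
                       ft_base = 25, ft_effect = 5, ft_sd = 1,
                       ft_traits = "ft_driven",
                       trans_targets = default_trans_targets(),
                       n_decoy_genes = 10,
                       srna_depletion = 10,
                       seed) {
  assert_that(!missing(seed), "seed is mandatory")
  assert_that(p_ddm1 > 0 && p_ddm1 < 1, "p_ddm1 must lie in (0,1)")
  assert_that(all(planted_qtl$effect > 0), "planted effects must be positive")
  assert_that(noise_sd >= 0 && probe_noise_sd >= 0, "noise sd must be >= 0")
  cfg <- as.list(environment())
  cfg$map <- default_marker_map(markers_per_chrom, spacing_cM)
  assert_that(all(planted_qtl$marker_id %in% cfg$map$marker_id),
              "planted_qtl references unknown markers")
  structure(cfg, class = "sim_config")
}

#' Default planted QTL effects spanning the 4-41% range
#' @return tibble `marker_id, trait_id, effect, sign`
#' @export
default_planted_qtl <- function() {
  tibble(marker_id = c("M1_05", "M2_10", "M3_15", "M4_08"),
         trait_id = c("met_a", "met_b", "met_c", "met_d"),
         effect = c(0.41, 0.25, 0.10, 0.04),
         sign = c(-1L, -1L, 1L, 1L))
}

#' Default planted trans-regulation targets
#' @return tibble `qtl_marker, gene_id, segment_length`
#' @export
default_trans_targets <- function() {
  tibble(qtl_marker = c("M2_10", "M3_15"),
         gene_id = c("G_trans1", "G_trans2"),
         segment_length = c(30L, 40L))
}

#' Default DMR marker map (126 markers over 5 chromosomes)
#' @param markers_per_chrom integer vector of markers per chromosome.
#' @param spacing_cM marker spacing in cM.
#' @return marker map tibble with 1-kb physical DMR intervals every 2 kb.
#' @export
default_marker_map <- function(markers_per_chrom = c(26L, 25L, 25L, 25L, 25L),
                               spacing_cM = 4) {
  purrr::imap(markers_per_chrom, function(nm, ci) {
    tibble(marker_id = sprintf("M%d_%02d", ci, seq_len(nm)),
           chrom = paste0("chr", ci),
           pos_cM = (seq_len(nm) - 1) * spacing_cM,
           phys_start = (seq_len(nm) - 1) * 2000,
           phys_end = (seq_len(nm) - 1) * 2000 + 1000)
  }) |> bind_rows()
}

#' Simulate epiRIL epigenotypes
#'
#' Per chromosome, each line's epialleles follow a two-state Markov chain
#' over the ordered markers: the first marker is DDM1 with probability
#' `p_ddm1`; transitions between adjacent markers use the Haldane
#' recombination fraction for the cM gap, with detailed-balance transition
#' probabilities preserving the stationary DDM1 frequency
#' (`P(COL->DDM1) = 2 r p`, `P(DDM1->COL) = 2 r (1-p)`).
#'
#' @param cfg a [sim_config()].
#' @param seed optional seed overriding `cfg$seed`.
#' @return Wide epigenotype tibble (`line` + marker columns).
#' @export
simulate_epigenotypes <- function(cfg, seed = cfg$seed) {
  map <- cfg$map
  p <- cfg$p_ddm1
  n <- cfg$n_lines
  with_seed(seed, {
    cols <- list()
    for (chr in unique(map$chrom)) {
      cm <- map$pos_cM[map$chrom == chr]
      mk <- map$marker_id[map$chrom == chr]
      G <- matrix(NA_integer_, n, length(mk))
      G[, 1] <- rbinom(n, 1, p)
      if (length(mk) > 1) {
        for (j in 2:length(mk)) {
          pr <- chain_transition(G[, j - 1], cm[j] - cm[j - 1], p)
          G[, j] <- rbinom(n, 1, pr)
        }
      }
      cols[[chr]] <- G
    }
    G <- do.call(cbind, cols)
    colnames(G) <- map$marker_id
    calls <- matrix(ifelse(G == 1, "DDM1", "COL"), nrow = n,
                    dimnames = list(NULL, map$marker_id))
    if (cfg$missing_rate > 0) {
      calls[matrix(runif(length(calls)) < cfg$missing_rate,
                   nrow = n)] <- NA_character_
    }
    bind_cols(tibble(line = sprintf("epiRIL_%03d", seq_len(n))),
              as_tibble(calls))
  })
}

# probes coupled to a marker epigenotype: latent post_M = 1 for COL lines
# (methylated), 0 for DDM1 lines unless the line reverted at this DMR
simulate_region_probes <- function(geno, coupling, reversion_rate, noise_sd,
                                   seed, parents = FALSE) {
  assert_that(noise_sd >= 0, "noise_sd must be >= 0")
  with_seed(seed, {
    out <- purrr::map(seq_len(nrow(coupling)), function(k) {
      co <- coupling[k, ]
      g <- geno[[co$marker_id]]
      revert <- rbinom(length(g), 1, reversion_rate) == 1
      latent <- if_else(g == "COL" | revert, 1, 0)
      starts <- floor(seq(co$start, co$end - 60,
                          length.out = co$n_probes))
      lines <- geno$line
      if (parents) {
        lines <- c(lines, "Col-0", "ddm1-2")
        latent <- c(latent, 1, if (co$polymorphic %||% TRUE) 0 else 1)
      }
      purrr::map(seq_along(starts), function(pi) {
        post_M <- pmin(pmax(latent + rnorm(length(latent), 0, noise_sd), 0), 1)
        tibble(probe_id = sprintf("%s_p%d", co$probe_prefix, pi),
               chrom = co$chrom, start = starts[pi], end = starts[pi] + 60,
               line = lines, post_U = 1 - post_M, post_M = post_M,
               ml = -(1 - post_M) + post_M)
      }) |> bind_rows()
    }) |> bind_rows()
    out
  })
}

#' Simulate probe-level methylation posteriors at the DMR markers
#'
#' Each DMR carries `probes_per_dmr` probes inside its physical interval.
#' The latent state is methylated (post_M = 1) for COL epialleles and
#' unmethylated (post_M = 0) for DDM1 epialleles, except that each
#' (line, DMR) pair reverts to WT-like methylation with probability
#' `reversion_rate`; emitted posteriors add truncated Gaussian noise.
#'
#' @param geno wide epigenotype tibble.
#' @param cfg a [sim_config()].
#' @param seed optional override of `cfg$seed`.
#' @return Long probe tibble `probe_id, chrom, start, end, line, post_U,
#'   post_M, ml`.
#' @export
simulate_probe_methylation <- function(geno, cfg, seed = cfg$seed) {
  map <- cfg$map
  coupling <- tibble(marker_id = map$marker_id, chrom = map$chrom,
                     start = map$phys_start, end = map$phys_end,
                     n_probes = cfg$probes_per_dmr,
                     probe_prefix = map$marker_id, polymorphic = TRUE)
  simulate_region_probes(geno, coupling, cfg$reversion_rate,
                         cfg$probe_noise_sd, seed + 1L)
}
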