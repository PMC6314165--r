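# two-state chain enumeration oracle: conditional P(DDM1) at a position given
# flanking observed states, built from explicit transition matrices
chain_T <- function(d, p) {
  lam <- exp(-2 * d / 100)
  rbind(c(1 - p * (1 - lam), p * (1 - lam)),
        c((1 - p) * (1 - lam), lam + p * (1 - lam)))
}
oracle_p_ddm1 <- function(a, b, dL, dR, p) {
  TL <- chain_T(dL, p); TR <- chain_T(dR, p)
  num <- TL[a + 1, 2] * TR[2, b + 1]
  den <- num + TL[a + 1, 1] * TR[1, b + 1]
  num / den
}

test_that("genotype probabilities match the chain enumeration oracle", {
  map <- tiny_map(2, spacing = 10)
  geno <- geno_from_matrix(matrix(c(0, 1, 1, 0, 1, 1, 0, 0), 4, 2), map)
  probs <- genotype_probabilities(geno, map, step_cM = 5, prior_p = 0.3)
  expect_equal(probs$pos$pos_cM, c(0, 5, 10))
  # at observed markers the probability is exactly the call
  expect_equal(unname(probs$P[, 1]), c(0, 1, 1, 0))
  expect_equal(unname(probs$P[, 3]), c(1, 1, 0, 0))
  # midpoint between discordant/concordant flanks: enumeration oracle
  for (i in 1:4) {
    a <- probs$P[i, 1]; b <- probs$P[i, 3]
    expect_equal(unname(probs$P[i, 2]), oracle_p_ddm1(a, b, 5, 5, 0.3),
                 tolerance = 1e-12)
  }
  # concordant DDM1 flanks at a tiny gap pin the pseudomarker to DDM1
  map2 <- tiny_map(2, spacing = 0.2)
  geno2 <- geno_from_matrix(matrix(c(1, 1), 1, 2), map2)
  pr2 <- genotype_probabilities(geno2, map2, step_cM = 0.1, prior_p = 0.3)
  expect_gt(min(pr2$P), 0.999)
})

test_that("missing flanks fall back to one-sided or prior probabilities", {
  map <- tiny_map(3, spacing = 10)
  geno <- geno_from_matrix(matrix(c(1, 0, 1), 1, 3), map)
  geno[1, 3] <- NA   # middle marker missing
  probs <- genotype_probabilities(geno, map, prior_p = 0.4)
  # at the missing marker: conditional on both outer flanks
  expect_equal(unname(probs$P[1, 2]), oracle_p_ddm1(1, 1, 10, 10, 0.4),
               tolerance = 1e-12)
  # a line with no observed markers sits at the prior
  geno2 <- geno_from_matrix(matrix(c(1, 0, 1), 1, 3), map)
  geno2[1, 2:4] <- NA
  pr2 <- genotype_probabilities(geno2, map, prior_p = 0.4)
  expect_equal(unname(pr2$P[1, ]), rep(0.4, 3))
})

test_that("interval-mapping LOD equals the closed form on the worked example", {
  map <- tiny_map(1)
  geno <- geno_from_matrix(matrix(c(0, 0, 1, 1), 4, 1), map)
  probs <- genotype_probabilities(geno, map)
  trait <- tibble::tibble(line = geno$line, value = c(1, 2, 3, 4))
  sc <- hk_scan(trait, probs, min_lines = 4)
  # r^2 = 0.8, LOD = (4/2) log10(1 / 0.2) = 1.39794
  expect_equal(sc$result$lod, (4 / 2) * log10(1 / (1 - 0.8)),
               tolerance = 1e-10)
  expect_equal(sc$result$lod, 1.39794, tolerance = 1e-5)
  # effect coefficient: DDM1 mean - COL mean = 2
  expect_equal(sc$result$coef, 2, tolerance = 1e-10)
})

test_that("scan LOD matches an independent regression oracle at markers", {
  set.seed(42)
  map <- tiny_map(6, spacing = 8)
  G <- matrix(rbinom(180, 1, 0.4), 30, 6)
  geno <- geno_from_matrix(G, map)
  probs <- genotype_probabilities(geno, map)
  y <- rnorm(30) + 0.8 * G[, 3]
  trait <- tibble::tibble(line = geno$line, value = y)
  sc <- hk_scan(trait, probs)
  for (j in 1:6) {
    fit1 <- lm(y ~ G[, j])
    fit0 <- lm(y ~ 1)
    lod_oracle <- (30 / 2) * log10(sum(resid(fit0)^2) / sum(resid(fit1)^2))
    expect_equal(sc$result$lod[j], lod_oracle, tolerance = 1e-10)
  }
  # LOD is invariant to affine transformation of the trait
  sc2 <- hk_scan(dplyr::mutate(trait, value = -3.2 * value + 11), probs)
  expect_equal(sc2$result$lod, sc$result$lod, tolerance = 1e-9)
  # constant trait scores zero everywhere
  sc3 <- hk_scan(dplyr::mutate(trait, value = 5), probs)
  expect_equal(sc3$result$lod, rep(0, 6))
})

test_that("cofactor scans drop windowed and collinear cofactors correctly", {
  set.seed(7)
  map <- tiny_map(8, spacing = 15)
  G <- matrix(rbinom(400, 1, 0.5), 50, 8)
  geno <- geno_from_matrix(G, map)
  probs <- genotype_probabilities(geno, map)
  y <- 1.5 * G[, 2] + 1.0 * G[, 6] + rnorm(50, 0, 0.7)
  trait <- tibble::tibble(line = geno$line, value = y)
  co <- cofactor_set(c("chr1_m2", "chr1_m6"), window_cM = 10)
  sc <- hk_scan(trait, probs, cofactors = co)
  # at marker 2 the m2 cofactor is inside the window: model reduces to
  # trait ~ position + m6; oracle by explicit regression
  rss <- function(f) sum(resid(f)^2)
  lod_oracle <- (50 / 2) * log10(rss(lm(y ~ G[, 6])) /
                                 rss(lm(y ~ G[, 2] + G[, 6])))
  expect_equal(sc$result$lod[2], lod_oracle, tolerance = 1e-10)
  # at a far marker both cofactors are retained
  lod_oracle4 <- (50 / 2) * log10(rss(lm(y ~ G[, 2] + G[, 6])) /
                                  rss(lm(y ~ G[, 4] + G[, 2] + G[, 6])))
  expect_equal(sc$result$lod[4], lod_oracle4, tolerance = 1e-10)
  # a cofactor perfectly collinear with the test position is dropped from
  # both models rather than zeroing the scan
  G2 <- G; G2[, 5] <- G2[, 4]
  geno2 <- geno_from_matrix(G2, map)
  probs2 <- genotype_probabilities(geno2, map)
  co2 <- cofactor_set("chr1_m5", window_cM = 5)   # m5 == m4, outside window
  sc2 <- hk_scan(tibble::tibble(line = geno2$line, value = y), probs2,
                 cofactors = co2)
  lod_alone <- (50 / 2) * log10(rss(lm(y ~ 1)) / rss(lm(y ~ G2[, 4])))
  expect_equal(sc2$result$lod[4], lod_alone, tolerance = 1e-10)
})

test_that("permutation thresholds are deterministic quantiles of max LOD", {
  set.seed(5)
  map <- tiny_map(10, spacing = 10)
  geno <- geno_from_matrix(matrix(rbinom(500, 1, 0.3), 50, 10), map)
  probs <- genotype_probabilities(geno, map)
  trait <- tibble::tibble(line = geno$line, value = rnorm(50))
  t1 <- permutation_threshold(trait, probs, n_perm = 200, alpha = 0.05,
                              seed = 11)
  t2 <- permutation_threshold(trait, probs, n_perm = 200, alpha = 0.05,
                              seed = 11)
  expect_identical(as.numeric(t1), as.numeric(t2))
  # alpha = 0 degenerates to the maximum over permutations
  t0 <- permutation_threshold(trait, probs, n_perm = 100, alpha = 0, seed = 3)
  expect_equal(as.numeric(t0), max(attr(t0, "perm_max")))
  expect_error(permutation_threshold(trait, probs, n_perm = 50, seed = 1),
               "n_perm")
  # cofactor path agrees with the fast path when the cofactor set is empty
  t3 <- permutation_threshold(trait, probs, cofactors = cofactor_set(
    character(0)), n_perm = 100, alpha = 0.1, seed = 4)
  t4 <- permutation_threshold(trait, probs, n_perm = 100, alpha = 0.1,
                              seed = 4)
  expect_equal(as.numeric(t3), as.numeric(t4), tolerance = 1e-9)
})

test_that("backward elimination keeps true QTL and prunes null cofactors", {
  set.seed(13)
  map <- tiny_map(10, spacing = 12)
  G <- matrix(rbinom(2000, 1, 0.5), 200, 10)
  geno <- geno_from_matrix(G, map)
  probs <- genotype_probabilities(geno, map)
  y <- 2 * G[, 4] + rnorm(200, 0, 0.5)
  co <- select_cofactors(tibble::tibble(line = geno$line, value = y), probs,
                         candidates = map$marker_id, drop_alpha = 0.02)
  expect_true("chr1_m4" %in% co$markers)
  expect_lte(length(co$markers), 3)
  # pure noise: retained count is approximately drop_alpha * n_candidates
  retained <- replicate(100, {
    y0 <- rnorm(200)
    length(select_cofactors(tibble::tibble(line = geno$line, value = y0),
                            probs, candidates = map$marker_id,
                            drop_alpha = 0.05)$markers)
  })
  expect_lt(abs(mean(retained) - 0.5), 0.4)
  # empty candidate list reduces to plain interval mapping
  co0 <- select_cofactors(tibble::tibble(line = geno$line, value = y), probs,
                          candidates = character(0))
  expect_length(co0$markers, 0)
  sc_a <- hk_scan(tibble::tibble(line = geno$line, value = y), probs,
                  cofactors = co0)
  sc_b <- hk_scan(tibble::tibble(line = geno$line, value = y), probs)
  expect_equal(sc_a$result$lod, sc_b$result$lod, tolerance = 1e-9)
})

test_that("peak calling respects threshold, separation and sign convention", {
  set.seed(17)
  # short chromosome: any secondary ripple is within the separation window
  map <- tiny_map(5, spacing = 4)
  map2 <- tiny_map(5, spacing = 4, chrom = "chr2")
  map2$marker_id <- sub("chr1", "chr2", map2$marker_id)
  full_map <- dplyr::bind_rows(map, map2)
  G <- matrix(rbinom(2000, 1, 0.5), 200, 10)
  geno <- geno_from_matrix(G, full_map)
  probs <- genotype_probabilities(geno, full_map, step_cM = 2)
  # huge effect at the middle marker of chr1, higher values in DDM1 group
  y <- 5 * G[, 3] + rnorm(200, 0, 0.3)
  sc <- hk_scan(tibble::tibble(line = geno$line, value = y), probs)
  sc <- call_peaks(sc, threshold = 5, lod_drop = 1.5)
  pk <- peaks(sc)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$marker_id, "chr1_m3")
  expect_equal(pk$effect_sign, -1L)
  expect_true(pk$ci_lo <= pk$peak_cM && pk$peak_cM <= pk$ci_hi)
  # the support interval ends at marker positions
  expect_true(pk$ci_lo %in% full_map$pos_cM && pk$ci_hi %in% full_map$pos_cM)
  # flat profile below threshold yields no peaks
  scf <- sc; scf$result$lod <- rep(4.999, nrow(scf$result))
  expect_equal(nrow(peaks(call_peaks(scf, threshold = 5))), 0)
  # opposite effect direction flips the sign
  sc2 <- call_peaks(hk_scan(tibble::tibble(line = geno$line, value = -y),
                            probs), threshold = 5)
  expect_equal(peaks(sc2)$effect_sign, 1L)
})

test_that("colocalization uses a closed cM interval on the shared map", {
  map <- tiny_map(10, spacing = 5, chrom = "chr4")
  map$marker_id <- sub("chr1", "chr4", map$marker_id)
  set.seed(2)
  G <- matrix(rbinom(600, 1, 0.5), 60, 10)
  geno <- geno_from_matrix(G, map)
  probs <- genotype_probabilities(geno, map)
  y <- 4 * G[, 8] + rnorm(60, 0, 0.4)
  sc <- call_peaks(hk_scan(tibble::tibble(line = geno$line, value = y),
                           probs), threshold = 3)
  pk <- peaks(sc)[1, ]
  expect_true(colocalize(sc, "chr4", pk$peak_cM - 5, pk$peak_cM + 5))
  expect_true(colocalize(sc, "chr4", pk$peak_cM, pk$peak_cM))  # boundary
  expect_false(colocalize(sc, "chr4", pk$peak_cM + 1, pk$peak_cM + 10))
  expect_error(colocalize(sc, "chrX", 0, 10), "chrX")
})

test_that("pleiotropy regions single-link overlapping support intervals", {
  pk <- tibble::tibble(
    trait_id = c("t1", "t2", "t3"), chrom = "chr1",
    peak_cM = c(15, 22, 50), marker_id = NA, lod = 5, threshold = 3,
    ci_lo = c(10, 18, 45), ci_hi = c(20, 30, 55),
    effect_size = 1, effect_sign = 1L)
  out <- pleiotropy_regions(pk)
  expect_equal(nrow(out$regions), 2)
  expect_equal(out$regions$cM_lo, c(10, 45))
  expect_equal(out$regions$cM_hi, c(30, 55))
  expect_equal(out$regions$n_traits, c(2, 1))
  # trait pair correlation over shared region
  tv <- tibble::tibble(
    trait_id = rep(c("t1", "t2"), each = 20),
    line = rep(sprintf("L%02d", 1:20), 2),
    value = c(1:20, 2 * (1:20) + rnorm(20, 0, 0.01)))
  out2 <- pleiotropy_regions(pk, trait_values = tv)
  expect_equal(nrow(out2$trait_pairs), 1)
  expect_gt(out2$trait_pairs$cor, 0.99)
  expect_lt(out2$trait_pairs$p_value, 1e-6)
  # empty input gives an empty table
  expect_equal(nrow(pleiotropy_regions(pk[0, ])$regions), 0)
})

test_that("qPCR normalisation follows the delta-Ct rule", {
  ct <- tibble::tibble(
    line = rep("L1", 3), gene = c("SAND", "TIP41", "target"),
    ct = c(24, 26, 24))
  out <- qpcr_normalize(ct, c("SAND", "TIP41"))
  expect_equal(out$value, 2^(25 - 24))
  ct2 <- tibble::tibble(line = "L1", gene = c("SAND", "target"),
                        ct = c(24, 24))
  expect_equal(qpcr_normalize(ct2, "SAND")$value, 1)
  ct3 <- tibble::tibble(line = "L1", gene = c("SAND", "target"),
                        ct = c(24, 23))
  expect_equal(qpcr_normalize(ct3, "SAND")$value, 2)
  # efficiency is configurable
  expect_equal(qpcr_normalize(ct3, "SAND", efficiency = 1.9)$value, 1.9)
})

test_that("tidy, glance and autoplot expose scan results", {
  map <- tiny_map(4)
  geno <- geno_from_matrix(matrix(rbinom(40, 1, 0.5), 10, 4), map)
  probs <- genotype_probabilities(geno, map)
  trait <- tibble::tibble(line = geno$line, value = rnorm(10))
  sc <- call_peaks(hk_scan(trait, probs), threshold = 2)
  td <- tidy(sc)
  expect_true(all(c("trait_id", "chrom", "pos_cM", "lod", "coef") %in%
                    names(td)))
  gl <- glance(sc)
  expect_equal(gl$n, 10)
  expect_s3_class(autoplot(sc), "ggplot")
  expect_true(all(td$lod >= 0))
})
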