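# Shared fixture builders; everything is generated in code at test time.

tiny_map <- function(n_markers = 5, chrom = "chr1", spacing = 10,
                     phys_gap = 2000, dmr_len = 1000) {
  tibble::tibble(
    marker_id = sprintf("%s_m%d", chrom, seq_len(n_markers)),
    chrom = chrom,
    pos_cM = (seq_len(n_markers) - 1) * spacing,
    phys_start = (seq_len(n_markers) - 1) * phys_gap,
    phys_end = (seq_len(n_markers) - 1) * phys_gap + dmr_len)
}

# deterministic epigenotype table from a 0/1 matrix
geno_from_matrix <- function(G, map) {
  calls <- matrix(ifelse(G == 1, "DDM1", "COL"), nrow = nrow(G))
  colnames(calls) <- map$marker_id
  dplyr::bind_cols(tibble::tibble(line = sprintf("L%03d", seq_len(nrow(G)))),
                   tibble::as_tibble(calls))
}

# noise-free probe table for one region coupled to a state vector
probes_from_states <- function(lines, post_M, probe_id = "p1",
                               chrom = "chr1", start = 0, end = 60) {
  tibble::tibble(probe_id = probe_id, chrom = chrom, start = start, end = end,
                 line = lines, post_U = 1 - post_M, post_M = post_M,
                 ml = -(1 - post_M) + post_M)
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# independent brute-force maximal-exact-match oracle: full equality matrix,
# run-length scan of every diagonal, forward and reverse-complement
oracle_mems <- function(p, q, min_match) {
  one_strand <- function(p, q) {
    pc <- strsplit(p, "")[[1]]; qc <- strsplit(q, "")[[1]]
    np <- length(pc); nq <- length(qc)
    res <- list()
    for (d in (-(np - 1)):(nq - 1)) {
      i0 <- max(1, 1 - d); j0 <- i0 + d
      len <- min(np - i0, nq - j0) + 1
      if (len < min_match) next
      eq <- pc[i0:(i0 + len - 1)] == qc[j0:(j0 + len - 1)] &
        pc[i0:(i0 + len - 1)] != "N"
      r <- rle(eq)
      endpos <- cumsum(r$lengths)
      for (k in which(r$values & r$lengths >= min_match)) {
        st <- endpos[k] - r$lengths[k]   # 0-based offset within diagonal
        res[[length(res) + 1]] <- c(i0 + st - 1, j0 + st - 1, r$lengths[k])
      }
    }
    res
  }
  fw <- one_strand(p, q)
  qr <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(q)))
  rv <- one_strand(p, qr)
  nq <- nchar(q)
  rows <- list()
  for (m in fw) rows[[length(rows) + 1]] <-
    data.frame(prom_start = m[1], qtl_start = m[2], length = m[3],
               strand = "+")
  for (m in rv) rows[[length(rows) + 1]] <-
    data.frame(prom_start = m[1], qtl_start = nq - m[2] - m[3],
               length = m[3], strand = "-")
  if (length(rows) == 0) {
    return(data.frame(prom_start = integer(0), qtl_start = integer(0),
                      length = integer(0), strand = character(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$prom_start, out$length, out$strand), , drop = FALSE]
}

seg_key <- function(d) {
  if (nrow(d) == 0) return(character(0))
  sort(sprintf("%d:%d:%d:%s", d$prom_start, d$qtl_start, d$length, d$strand))
}

# fixture: a QTL at the middle marker of a 5-marker chromosome, 20 genes in
# the support interval, one of them causal (promoter probes tracking the
# peak marker and driving the trait)
cis_fixture <- function(n_lines = 80, n_genes = 20, seed = 19,
                        causal_coseg = TRUE) {
  set.seed(seed)
  map <- tiny_map(5, spacing = 10, phys_gap = 40000, dmr_len = 1000)
  G <- matrix(rbinom(n_lines * 5, 1, 0.4), n_lines, 5)
  geno <- geno_from_matrix(G, map)
  lines <- geno$line
  # genes tiled across the projected interval (markers 2..4 span 20-60 kC)
  gstart <- seq(41000, 117000, by = 4000)[seq_len(n_genes)]
  genes <- tibble::tibble(
    gene_id = sprintf("gene%02d", seq_len(n_genes)),
    chrom = "chr1", strand = "+", tss = gstart + 1000,
    body_start = gstart + 1000, body_end = gstart + 2000,
    prom_start = gstart, prom_end = gstart + 1000,
    down_start = gstart + 2000, down_end = gstart + 3000,
    clipped = FALSE)
  causal <- "gene10"
  g3 <- G[, 3]
  # causal promoter methylation mirrors the marker epiallele (COL methylated)
  ml_state <- if (causal_coseg) 1 - g3 else rbinom(n_lines, 1, 0.5)
  # balanced decoy states: within each epiallele group, half methylated --
  # orthogonal to the peak marker by construction
  balanced <- integer(n_lines)
  for (grp in unique(g3)) {
    idx <- which(g3 == grp)
    balanced[idx] <- rep_len(c(0L, 1L), length(idx))
  }
  probes <- list()
  for (i in seq_len(n_genes)) {
    gid <- genes$gene_id[i]
    post_M <- if (gid == causal) {
      pmin(pmax(ml_state + rnorm(n_lines, 0, 0.05), 0), 1)
    } else {
      pmin(pmax(balanced + rnorm(n_lines, 0, 0.05), 0), 1)
    }
    probes[[i]] <- probes_from_states(lines, post_M,
                                      probe_id = paste0(gid, "_p1"),
                                      start = genes$prom_start[i],
                                      end = genes$prom_start[i] + 60)
  }
  probes <- dplyr::bind_rows(probes)
  # trait driven by the causal promoter methylation state
  trait <- tibble::tibble(line = lines,
                          value = 10^(2 + 0.3 * ml_state +
                                        rnorm(n_lines, 0, 0.05)))
  qtl <- tibble::tibble(trait_id = "met_x", chrom = "chr1",
                        marker_id = "chr1_m3", ci_lo = 10, ci_hi = 30)
  list(map = map, geno = geno, genes = genes, probes = probes,
       trait = trait, qtl = qtl, causal = causal)
}

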