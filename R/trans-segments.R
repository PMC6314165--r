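#' Reverse complement of DNA strings
#' @param x character vector over ACGTN.
#' @return character vector.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# all maximal exact matches between two strings (forward orientation only),
# seeded on shared k-mers and extended to maximality; windows containing N
# never seed and N never extends a match
mem_forward <- function(p, q, k) {
  np <- nchar(p); nq <- nchar(q)
  if (np < k || nq < k) return(NULL)
  pc <- strsplit(p, "")[[1]]; qc <- strsplit(q, "")[[1]]
  pk <- substring(p, 1:(np - k + 1), k:np)
  qk <- substring(q, 1:(nq - k + 1), k:nq)
  ok_p <- !grepl("N", pk, fixed = TRUE)
  qpos <- split(seq_along(qk), qk)
  qpos <- qpos[!grepl("N", names(qpos), fixed = TRUE)]
  seen <- new.env(hash = TRUE, parent = emptyenv())
  out <- list()
  for (i in which(ok_p)) {
    hits <- qpos[[pk[i]]]
    if (is.null(hits)) next
    for (j in hits) {
      # extend left
      a <- i; b <- j
      while (a > 1 && b > 1 && pc[a - 1] == qc[b - 1] &&
             pc[a - 1] != "N") { a <- a - 1; b <- b - 1 }
      key <- paste(a, b, sep = ",")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      # extend right from the seed end
      e <- i + k - 1; f <- j + k - 1
      while (e < np && f < nq && pc[e + 1] == qc[f + 1] &&
             pc[e + 1] != "N") { e <- e + 1; f <- f + 1 }
      out[[length(out) + 1]] <- c(a, e, b, f)
    }
  }
  if (length(out) == 0) return(NULL)
  m <- do.call(rbind, out)
  m[!duplicated(m), , drop = FALSE]
}

#' Maximal exact-match segments between a promoter and a QTL interval
#'
#' Finds every maximal segment of length at least `min_match` shared
#' perfectly between the promoter sequence and the QTL interval sequence,
#' on the forward strand and as exact reverse complements. Coordinates are
#' 0-based half-open offsets into each input sequence (QTL coordinates
#' always on the forward strand). Results are ordered by promoter offset,
#' then length.
#'
#' @param promoter_seq,qtl_seq DNA strings (ACGT; N breaks matches).
#' @param min_match minimum segment length (>= 21, default 21 nt, the
#'   smallest artificial-sRNA window).
#' @return Tibble `segment_id, prom_start, prom_end, qtl_start, qtl_end,
#'   strand, length, sequence` (promoter-strand sequence).
#' @export
find_match_segments <- function(promoter_seq, qtl_seq, min_match = 21) {
  assert_that(min_match >= 21, "min_match must be >= 21")
  promoter_seq <- toupper(promoter_seq); qtl_seq <- toupper(qtl_seq)
  if (nchar(promoter_seq) == 0 || nchar(qtl_seq) == 0) {
    return(empty_segments())
  }
  nq <- nchar(qtl_seq)
  fw <- mem_forward(promoter_seq, qtl_seq, min_match)
  rv <- mem_forward(promoter_seq, revcomp(qtl_seq), min_match)
  rows <- list()
  if (!is.null(fw)) {
    rows[[1]] <- tibble(prom_start = fw[, 1] - 1L, prom_end = fw[, 2],
                        qtl_start = fw[, 3] - 1L, qtl_end = fw[, 4],
                        strand = "+")
  }
  if (!is.null(rv)) {
    # map reverse-complement coordinates back to forward QTL coordinates
    rows[[2]] <- tibble(prom_start = rv[, 1] - 1L, prom_end = rv[, 2],
                        qtl_start = nq - rv[, 4], qtl_end = nq - rv[, 3] + 1L,
                        strand = "-")
  }
  if (length(rows) == 0) return(empty_segments())
  seg <- bind_rows(rows) |>
    mutate(length = .data$prom_end - .data$prom_start) |>
    filter(.data$length >= min_match) |>
    arrange(.data$prom_start, .data$length, .data$strand) |>
    mutate(segment_id = sprintf("seg_%03d", row_number()),
           sequence = substring(promoter_seq, .data$prom_start + 1,
                                .data$prom_end)) |>
    select("segment_id", "prom_start", "prom_end", "qtl_start", "qtl_end",
           "strand", "length", "sequence")
  seg
}

empty_segments <- function() {
  tibble(segment_id = character(0), prom_start = integer(0),
         prom_end = integer(0), qtl_start = integer(0), qtl_end = integer(0),
         strand = character(0), length = integer(0), sequence = character(0))
}

#' Decompose a matched segment into artificial small RNAs
#'
#' Cuts every window of each configured length (default 21-24 nt, the
#' canonical plant sRNA size classes) from the segment, on both strands,
#' deduplicated by (sequence, strand, offset). A segment of length L yields
#' `sum over k of 2 * (L - k + 1)` artsRNAs (window lengths k <= L).
#'
#' @param segments segment tibble from [find_match_segments()] (or any tibble
#'   with `segment_id, sequence`).
#' @param lengths window sizes (default `21:24`).
#' @return Tibble `artsrna_id, segment_id, sequence, length, strand, offset`
#'   (offset is the window start within the segment, 0-based, promoter
#'   strand).
#' @export
decompose_artsrnas <- function(segments, lengths = 21:24) {
  out <- purrr::map(seq_len(nrow(segments)), function(i) {
    s <- segments$sequence[i]
    L <- nchar(s)
    purrr::map(lengths[lengths <= L], function(k) {
      off <- 0:(L - k)
      fwd <- substring(s, off + 1, off + k)
      tibble(segment_id = segments$segment_id[i],
             sequence = c(fwd, revcomp(fwd)),
             length = k, strand = rep(c("+", "-"), each = length(off)),
             offset = rep(off, 2))
    }) |> bind_rows()
  }) |> bind_rows()
  if (nrow(out) == 0) {
    return(tibble(artsrna_id = character(0), segment_id = character(0),
                  sequence = character(0), length = integer(0),
                  strand = character(0), offset = integer(0)))
  }
  out |>
    distinct(.data$segment_id, .data$sequence, .data$strand, .data$offset,
             .keep_all = TRUE) |>
    mutate(artsrna_id = sprintf("artsRNA_%04d", row_number()), .before = 1)
}

#' Default heuristic ARGONAUTE-loading scorer
#'
#' A documented stand-in for a trained AGO-loading classifier, encoding the
#' canonical plant sorting signals: 24-nt sRNAs with a 5' adenine are the
#' hallmark RdDM class and score AGO4 = 0.9; 21-22 nt sRNAs with a 5'
#' uridine (T in DNA alphabet) are post-transcriptional classes and score
#' AGO4 = 0.1 with AGO6 = AGO9 = 0.4; everything else scores 0.2 for all
#' three. Deterministic and a pure function of the sequence.
#'
#' @param sequences character vector (DNA alphabet).
#' @return Tibble `AGO4, AGO6, AGO9` in \[0, 1\].
#' @export
default_ago_scorer <- function(sequences) {
  len <- nchar(sequences)
  first <- substring(sequences, 1, 1)
  ago4 <- rep(0.2, length(sequences))
  ago6 <- rep(0.2, length(sequences))
  ago9 <- rep(0.2, length(sequences))
  rddm <- len == 24 & first == "A"
  ptgs <- len %in% c(21, 22) & first == "T"
  ago4[rddm] <- 0.9
  ago4[ptgs] <- 0.1
  ago6[ptgs] <- 0.4
  ago9[ptgs] <- 0.4
  tibble(AGO4 = ago4, AGO6 = ago6, AGO9 = ago9)
}

#' Score and filter artsRNAs by predicted AGO loading
#'
#' Applies an AGO-loading scorer (any function from sequences to AGO4/6/9
#' probabilities; default [default_ago_scorer()]) and keeps candidates whose
#' maximum score reaches `min_prob`. All three scores are retained in the
#' output.
#'
#' @param candidates artsRNA tibble with a `sequence` column.
#' @param scorer scoring function (default [default_ago_scorer()]).
#' @param min_prob retention threshold on the maximum AGO score (default 0.5).
#' @return The filtered tibble with `AGO4, AGO6, AGO9, ago_max` columns.
#' @export
score_ago_loading <- function(candidates, scorer = default_ago_scorer,
                              min_prob = 0.5) {
  if (nrow(candidates) == 0) {
    return(bind_cols(candidates, tibble(AGO4 = numeric(0), AGO6 = numeric(0),
                                        AGO9 = numeric(0),
                                        ago_max = numeric(0))))
  }
  sc <- as_tibble(scorer(candidates$sequence))
  assert_that(all(c("AGO4", "AGO6", "AGO9") %in% names(sc)),
              "scorer must return AGO4, AGO6, AGO9")
  assert_that(all(as.matrix(sc[, c("AGO4", "AGO6", "AGO9")]) >= 0 &
                  as.matrix(sc[, c("AGO4", "AGO6", "AGO9")]) <= 1),
              "AGO scores must lie in [0, 1]")
  out <- bind_cols(candidates, sc[, c("AGO4", "AGO6", "AGO9")])
  out$ago_max <- pmax(out$AGO4, out$AGO6, out$AGO9)
  filter(out, .data$ago_max >= min_prob)
}

# hamming distance helper for same-length strings
hamming_le <- function(a, b, maxmm) {
  if (nchar(a) != nchar(b)) return(FALSE)
  sum(charToRaw(a) != charToRaw(b)) <= maxmm
}

#' Match artsRNAs against sequenced sRNA libraries
#'
#' For each candidate, sums the read counts of library records matching the
#' candidate exactly (default) or within `max_mismatch` substitutions, in
#' sense or antisense orientation, per library source. Reports the WT/ddm1
#' count ratio where both are nonzero.
#'
#' @param candidates artsRNA tibble with `sequence`.
#' @param libraries sRNA library tibble (`source, sequence, count`), e.g.
#'   rows from [read_srna_library()] for WT and ddm1.
#' @param max_mismatch 0 (default), 1 or 2; more is not supported.
#' @return Candidates with one `hits_<source>` column per source, a
#'   `supported` flag (any hit), and `wt_ddm1_ratio` when both sources hit.
#' @export
match_srna_library <- function(candidates, libraries, max_mismatch = 0) {
  assert_that(max_mismatch <= 2, "max_mismatch > 2 is not supported")
  sources <- unique(libraries$source)
  hits <- matrix(0, nrow(candidates), length(sources),
                 dimnames = list(NULL, sources))
  if (nrow(candidates) > 0 && nrow(libraries) > 0) {
    cand_rc <- revcomp(candidates$sequence)
    for (s in seq_along(sources)) {
      lib <- libraries[libraries$source == sources[s], ]
      if (max_mismatch == 0) {
        tab <- tapply(lib$count, lib$sequence, sum)
        h <- unname(tab[candidates$sequence]); h[is.na(h)] <- 0
        h2 <- unname(tab[cand_rc]); h2[is.na(h2)] <- 0
        hits[, s] <- h + h2
      } else {
        for (i in seq_len(nrow(candidates))) {
          m <- vapply(lib$sequence, function(ls)
            hamming_le(candidates$sequence[i], ls, max_mismatch) ||
            hamming_le(cand_rc[i], ls, max_mismatch), logical(1))
          hits[i, s] <- sum(lib$count[m])
        }
      }
    }
  }
  out <- candidates
  for (s in sources) out[[paste0("hits_", s)]] <- unname(hits[, s])
  out$supported <- rowSums(hits) > 0
  if (all(c("WT", "ddm1") %in% sources)) {
    out$wt_ddm1_ratio <- if_else(hits[, "WT"] > 0 & hits[, "ddm1"] > 0,
                                 hits[, "WT"] / hits[, "ddm1"], NA_real_)
  }
  out
}

#' Annotate artsRNA candidates with transposable-element proximity
#'
#' A candidate is TE-proximal when its promoter-side match interval (in
#' genome coordinates) overlaps a TE or lies strictly within 1000 bp of one.
#'
#' @param candidates artsRNA tibble with `segment_id, offset, length`.
#' @param segments segment tibble carrying genome coordinates
#'   (`segment_id, chrom, genome_start` = genomic bp of the segment's
#'   promoter-side start).
#' @param tes TE tibble `chrom, start, end` (0-based half-open); empty or
#'   NULL gives all-FALSE with a warning.
#' @return Candidates with a logical `te_within_1kb` column.
#' @export
annotate_te_proximity <- function(candidates, segments, tes) {
  if (is.null(tes) || nrow(tes) == 0) {
    warn("no TE annotation; te_within_1kb is FALSE everywhere")
    candidates$te_within_1kb <- FALSE
    return(candidates)
  }
  seg <- segments[, c("segment_id", "chrom", "genome_start")]
  d <- left_join(candidates, seg, by = "segment_id")
  st <- d$genome_start + d$offset
  en <- st + d$length
  d$te_within_1kb <- vapply(seq_len(nrow(d)), function(i) {
    tc <- tes[tes$chrom == d$chrom[i], ]
    if (nrow(tc) == 0) return(FALSE)
    # half-open gap: 0 when overlapping
    gap <- pmax(tc$start - en[i], st[i] - tc$end, 0)
    any(gap < 1000)
  }, logical(1))
  candidates$te_within_1kb <- d$te_within_1kb
  candidates
}
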