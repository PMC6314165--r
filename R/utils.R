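#' @importFrom rlang %||% abort warn .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join inner_join bind_rows bind_cols distinct rename pull n across
#'   row_number slice first last transmute if_else
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats lm coef quantile sd cor rnorm runif rbinom rpois
#'   pt pf pchisq chisq.test fisher.test t.test complete.cases setNames
#'   anova as.formula lm.fit median var
#' @importFrom utils head tail
NULL

# Haldane map function: recombination fraction for a gap of d centiMorgan
haldane_r <- function(d) (1 - exp(-2 * d / 100)) / 2

# Second eigenvalue of the two-state transition matrix over d cM; multiplicative
# under chain composition, so conditioning across gaps composes exactly.
haldane_lambda <- function(d) exp(-2 * d / 100)

# Transition probabilities of the reversible two-state chain with stationary
# DDM1 frequency p: P(COL->DDM1) = p*(1-lambda), P(DDM1->COL) = (1-p)*(1-lambda).
# At p = 1/2 both equal the Haldane recombination fraction r(d).
chain_transition <- function(from, d, p) {
  lam <- haldane_lambda(d)
  n <- max(length(from), length(lam))
  from <- rep_len(from, n); lam <- rep_len(lam, n)
  # returns P(DDM1 at far end | state `from` (0=COL, 1=DDM1) at near end)
  ifelse(from == 1, lam + p * (1 - lam), p * (1 - lam))
}

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) abort(msg)
  invisible(TRUE)
}

# Wide epigenotype tibble (line + one column per marker, values "COL"/"DDM1"/NA)
# -> numeric matrix coded COL=0, DDM1=1, rownames = line ids.
geno_matrix <- function(geno, map = NULL) {
  assert_that(is.data.frame(geno) && "line" %in% names(geno),
              "epigenotype table must have a 'line' column")
  markers <- setdiff(names(geno), "line")
  if (!is.null(map)) {
    orphan <- setdiff(markers, map$marker_id)
    if (length(orphan) > 0) {
      abort(paste0("markers absent from map: ", paste(orphan, collapse = ", ")))
    }
    markers <- intersect(map$marker_id, markers)
  }
  m <- as.matrix(geno[, markers, drop = FALSE])
  bad <- !(m %in% c("COL", "DDM1", NA))
  if (any(bad)) {
    idx <- which(matrix(bad, nrow(m)), arr.ind = TRUE)[1, ]
    abort(sprintf("invalid epigenotype call '%s' at line '%s', marker '%s'",
                  m[idx[1], idx[2]], geno$line[idx[1]], markers[idx[2]]))
  }
  out <- matrix(NA_real_, nrow(m), ncol(m),
                dimnames = list(geno$line, markers))
  out[m == "COL"] <- 0
  out[m == "DDM1"] <- 1
  out
}

validate_marker_map <- function(map) {
  need <- c("marker_id", "chrom", "pos_cM")
  assert_that(all(need %in% names(map)),
              paste("marker map needs columns:", paste(need, collapse = ", ")))
  assert_that(!anyDuplicated(map$marker_id), "duplicate marker ids in map")
  by_chr <- split(map$pos_cM, map$chrom)
  ok <- all(vapply(by_chr, function(x) all(diff(x) > 0) || length(x) == 1,
                   logical(1)))
  assert_that(ok, "pos_cM must be strictly increasing within each chromosome")
  invisible(map)
}

# stable float formatting for CSV round-trips
fmt_num <- function(x) formatC(x, digits = 10, format = "g")
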