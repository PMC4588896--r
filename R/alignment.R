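#' Scoring scheme for local alignment
#'
#' The default reproduces the scoring contract of a LAST-style aligner run
#' with `-s 2 -T 0 -Q 0 -a 1`: match +1, mismatch -1, affine gaps costing
#' `gap_open + gap_extend * length` (so a gap of length 1 costs 2), local
#' alignment on both strands, qualities ignored. All penalties are given as
#' non-negative magnitudes.
#'
#' @param match Reward per identical column (default 1).
#' @param mismatch Penalty magnitude per substituted column (default 1).
#' @param gap_open Gap opening cost (default 1).
#' @param gap_extend Cost per gapped base (default 1).
#' @param both_strands Also try the reverse-complement orientation and keep
#'   the better of the two (default `TRUE`).
#' @return A `scoring_scheme` object.
#' @export
#' @examples
#' scoring_scheme()
scoring_scheme <- function(match = 1, mismatch = 1, gap_open = 1,
                           gap_extend = 1, both_strands = TRUE) {
  vals <- c(match = match, mismatch = mismatch, gap_open = gap_open,
            gap_extend = gap_extend)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals != floor(vals))) {
    abort("scoring parameters must be non-negative integers (magnitudes)")
  }
  structure(
    list(match = as.integer(match), mismatch = as.integer(mismatch),
         gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
         both_strands = isTRUE(both_strands)),
    class = "scoring_scheme"
  )
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf(
    "<scoring_scheme> match +%d, mismatch -%d, gap open %d + extend %d per base, %s\n",
    x$match, x$mismatch, x$gap_open, x$gap_extend,
    if (x$both_strands) "both strands" else "forward strand only"
  ))
  invisible(x)
}

as_scoring_scheme <- function(scheme) {
  if (is.null(scheme)) return(scoring_scheme())
  if (!inherits(scheme, "scoring_scheme")) {
    abort("`scheme` must be created with scoring_scheme()")
  }
  scheme
}

#' Exact local alignment (Smith-Waterman with affine gaps)
#'
#' Computes a maximal-scoring local alignment of each query against the
#' target by full Gotoh dynamic programming — no seeding heuristics, so the
#' reported score is exact under the scheme. With `both_strands`, the query
#' is also aligned to the reverse complement of the target and the better
#' orientation is kept (forward wins ties); minus-strand target intervals
#' are reported in forward coordinates. Among equal-scoring alignments the
#' one with the smaller query start, then smaller target start, then fewer
#' columns is returned, so results are deterministic.
#'
#' @param query,target Character vectors of A/C/G/T sequences (recycled to
#'   a common length).
#' @param scheme A [scoring_scheme()].
#' @return A tibble with one row per pair: `score`, `strand`, 0-based
#'   half-open `q_start`/`q_end`/`t_start`/`t_end`, aligned `columns`,
#'   identical `matches`, and `identity` = matches/columns.
#' @export
#' @examples
#' align_local("ACGTT", "ACGAT")
align_local <- function(query, target, scheme = scoring_scheme()) {
  scheme <- as_scoring_scheme(scheme)
  query <- check_dna(query, "query")
  target <- check_dna(target, "target")
  n <- max(length(query), length(target))
  if (n %% length(query) != 0 || n %% length(target) != 0) {
    abort("`query` and `target` lengths are not compatible for recycling")
  }
  query <- rep_len(query, n)
  target <- rep_len(target, n)
  rows <- lapply(seq_len(n), function(i) {
    fwd <- .sw_align_full(query[i], target[i], scheme$match, scheme$mismatch,
                          scheme$gap_open, scheme$gap_extend)
    strand <- "+"
    aln <- fwd
    if (scheme$both_strands) {
      rc <- .sw_align_full(query[i], revcomp(target[i]), scheme$match,
                           scheme$mismatch, scheme$gap_open, scheme$gap_extend)
      if (rc$score > fwd$score) {
        aln <- rc
        strand <- "-"
        tn <- nchar(target[i])
        ts <- tn - aln$t_end
        te <- tn - aln$t_start
        aln$t_start <- ts
        aln$t_end <- te
      }
    }
    tibble(
      score = aln$score, strand = strand,
      q_start = aln$q_start, q_end = aln$q_end,
      t_start = aln$t_start, t_end = aln$t_end,
      columns = aln$columns, matches = aln$matches
    )
  })
  out <- bind_rows(rows)
  out$identity <- ifelse(out$columns > 0, out$matches / out$columns, NA_real_)
  out
}

#' Percent identity of an alignment
#'
#' Identical columns divided by total aligned columns; gapped columns count
#' in the denominator.
#'
#' @param aln A tibble from [align_local()] (or any data frame with
#'   `matches` and `columns` columns).
#' @return Numeric vector of identities in `[0, 1]`.
#' @export
percent_identity <- function(aln) {
  if (!all(c("matches", "columns") %in% names(aln))) {
    abort("`aln` must have columns `matches` and `columns`")
  }
  if (any(aln$columns < 1)) {
    abort("percent identity is undefined for zero aligned columns")
  }
  aln$matches / aln$columns
}

#' Batch local-alignment scores
#'
#' Score-only Smith-Waterman of every query against every target, using a
#' vectorized batch kernel. With `both_strands` the score is the better of
#' the two orientations.
#'
#' @param queries,targets Character vectors of A/C/G/T sequences.
#' @param scheme A [scoring_scheme()].
#' @return An integer matrix of `length(queries)` rows by `length(targets)`
#'   columns.
#' @export
align_scores <- function(queries, targets, scheme = scoring_scheme()) {
  scheme <- as_scoring_scheme(scheme)
  queries <- check_dna(queries, "query")
  targets <- check_dna(targets, "target")
  fwd <- .sw_score_block(queries, targets, scheme$match, scheme$mismatch,
                         scheme$gap_open, scheme$gap_extend)
  if (scheme$both_strands) {
    rev <- .sw_score_block(revcomp(queries), targets, scheme$match,
                           scheme$mismatch, scheme$gap_open, scheme$gap_extend)
    fwd <- pmax(fwd, rev)
  }
  dimnames(fwd) <- list(names(queries), names(targets))
  fwd
}
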