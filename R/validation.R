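#' Count exon variants in short amplicon reads
#'
#' The short-read cross-validation counter: a read is considered only if
#' the cluster primer occurs in it exactly (zero mismatches); the sequence
#' following the primer is then aligned against the leading
#' `prefix_length` bases of every variant of the cluster (whole variant if
#' shorter) and assigned to the best-scoring one. Exact best-score ties
#' are discarded as ambiguous.
#'
#' @param reads Character vector of read sequences, or a tibble with a
#'   `sequence` column.
#' @param primer The primer sequence that must match exactly.
#' @param cluster A cluster tibble with `variant_id` and `sequence`.
#' @param scheme A [scoring_scheme()]; the same local-alignment contract
#'   as the long-read path.
#' @param prefix_length Bases of each variant used as reference
#'   (default 51).
#' @return A tibble `variant_id`, `count` (zeros included), with
#'   attributes `n_reads`, `n_primer_matched`, `n_assigned`,
#'   `n_ambiguous`.
#' @export
short_read_exon_count <- function(reads, primer, cluster,
                                  scheme = scoring_scheme(),
                                  prefix_length = 51) {
  cluster <- as_tibble(cluster)
  if (nrow(cluster) == 0) abort("`cluster` has no variants")
  scheme <- as_scoring_scheme(scheme)
  primer <- check_dna(primer, "primer")
  seqs <- if (is.character(reads)) reads else as_tibble(reads)$sequence
  seqs <- check_dna(seqs, "read")

  hit <- regexpr(primer, seqs, fixed = TRUE)
  keep <- hit >= 1
  inserts <- substring(seqs[keep], hit[keep] + nchar(primer))
  inserts <- inserts[nzchar(inserts)]

  prefixes <- substring(cluster$sequence, 1, prefix_length)
  counts <- setNames(integer(nrow(cluster)), cluster$variant_id)
  n_amb <- 0L
  if (length(inserts) > 0) {
    s <- .sw_score_block(prefixes, inserts, scheme$match, scheme$mismatch,
                         scheme$gap_open, scheme$gap_extend)
    top <- apply(s, 2, max)
    n_top <- colSums(s == rep(top, each = nrow(s)))
    assigned <- n_top == 1
    n_amb <- sum(!assigned)
    if (any(assigned)) {
      idx <- apply(s[, assigned, drop = FALSE], 2, which.max)
      tab <- table(factor(cluster$variant_id[idx],
                          levels = cluster$variant_id))
      counts[names(tab)] <- as.integer(tab)
    }
  }
  structure(
    tibble(variant_id = cluster$variant_id, count = unname(counts)),
    n_reads = length(seqs),
    n_primer_matched = length(inserts),
    n_assigned = sum(counts),
    n_ambiguous = n_amb,
    class = c("exon_count", class(tibble()))
  )
}

#' Per-cluster variant inclusion frequencies
#'
#' Normalizes variant counts into inclusion frequencies per cluster (the
#' cluster of each variant is read off its `"<cluster>.<index>"` id).
#' Accepts an `isoform_table` (long-read path, via [cluster_marginals()]),
#' a counts table from [short_read_exon_count()], or any data frame with
#' `variant_id` and `count`.
#'
#' @param x Counts in any of the accepted forms.
#' @param source Label recorded in the `source` column.
#' @return A tibble `cluster`, `variant_id`, `count`, `frequency`,
#'   `source`; frequencies sum to 1 within each cluster.
#' @export
cluster_frequencies <- function(x, source = "counts") {
  df <- if (inherits(x, "isoform_table")) {
    cluster_marginals(x)
  } else {
    d <- as_tibble(x)
    if (!all(c("variant_id", "count") %in% names(d))) {
      abort("`x` must have columns `variant_id` and `count`")
    }
    d |>
      mutate(cluster = variant_cluster(.data$variant_id)) |>
      group_by(.data$cluster) |>
      mutate(frequency = .data$count / sum(.data$count)) |>
      ungroup()
  }
  df$source <- source
  select(df, "cluster", "variant_id", "count", "frequency", "source")
}

#' Agreement between two frequency tables (R-squared)
#'
#' Squared Pearson correlation of paired per-variant inclusion
#' frequencies. By default all clusters are pooled into one paired vector
#' over the union of variants (missing variants count as frequency 0);
#' `by_cluster = TRUE` returns one R-squared per cluster instead.
#'
#' @param a,b Frequency tables from [cluster_frequencies()].
#' @param by_cluster Compute per-cluster values instead of pooling.
#' @return A single number in `[0, 1]`, or a tibble `cluster`,
#'   `r_squared` when `by_cluster`.
#' @export
compare_frequencies <- function(a, b, by_cluster = FALSE) {
  paired <- dplyr::full_join(
    select(as_tibble(a), "cluster", "variant_id", fa = "frequency"),
    select(as_tibble(b), "cluster", "variant_id", fb = "frequency"),
    by = c("cluster", "variant_id")
  ) |>
    mutate(
      fa = dplyr::coalesce(.data$fa, 0),
      fb = dplyr::coalesce(.data$fb, 0)
    )
  r2 <- function(x, y) {
    if (length(x) < 2 || sd(x) == 0 || sd(y) == 0) {
      abort("R-squared is undefined when either frequency vector is constant")
    }
    cor(x, y)^2
  }
  if (by_cluster) {
    paired |>
      group_by(.data$cluster) |>
      summarise(r_squared = r2(.data$fa, .data$fb), .groups = "drop")
  } else {
    r2(paired$fa, paired$fb)
  }
}
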