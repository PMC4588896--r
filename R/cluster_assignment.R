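#' Assign a read to its best exon variant within one cluster
#'
#' Aligns the read to every variant of the cluster (both strands under the
#' default scheme) and ranks variants by their best local-alignment score.
#' Variants below `min_score` are dropped; if none reaches it the read has
#' no hit in this cluster. The score margin (best minus second-best) is the
#' confidence of the assignment: a margin of zero means two variants tie
#' and the assignment is flagged ambiguous (ties are broken by variant
#' order in the cluster, mirroring a "first top-scoring alignment" rule).
#'
#' @param read A single A/C/G/T string.
#' @param cluster A cluster tibble (`model$clusters[[name]]`) with columns
#'   `variant_id` and `sequence`.
#' @param scheme A [scoring_scheme()].
#' @param min_score Minimum alignment score for a variant to count as a hit
#'   (default 50; rejects spurious hits of noise reads).
#' @return A tibble of hits ranked by descending score with columns
#'   `variant_id`, `score`, `strand`, `rank`, and attributes `best`,
#'   `margin`, `strand`, `ambiguous`. Zero rows if no variant reaches
#'   `min_score`.
#' @export
assign_exon <- function(read, cluster, scheme = scoring_scheme(),
                        min_score = 50) {
  stopifnot(length(read) == 1)
  cluster <- as_tibble(cluster)
  res <- assign_cluster_block(read, cluster, scheme)
  ranked <- tibble(
    variant_id = cluster$variant_id,
    score = res$score,
    strand = res$strand
  )
  ranked <- ranked[order(-ranked$score), , drop = FALSE]
  ranked <- ranked[ranked$score >= min_score, , drop = FALSE]
  ranked$rank <- seq_len(nrow(ranked))
  if (nrow(ranked) == 0) {
    attr(ranked, "best") <- NA_character_
    attr(ranked, "margin") <- NA_real_
    attr(ranked, "ambiguous") <- NA
    return(ranked)
  }
  margin <- if (nrow(cluster) >= 2) {
    sorted <- sort(res$score, decreasing = TRUE)
    sorted[1] - sorted[2]
  } else {
    NA_real_
  }
  attr(ranked, "best") <- ranked$variant_id[1]
  attr(ranked, "margin") <- margin
  attr(ranked, "ambiguous") <- isTRUE(margin == 0)
  ranked
}

# score one read against every variant of one cluster; returns per-variant
# best-over-strand scores and the strand of each
assign_cluster_block <- function(read, cluster, scheme) {
  scheme <- as_scoring_scheme(scheme)
  read <- check_dna(read, "read")
  fwd <- .sw_score_block(cluster$sequence, read, scheme$match, scheme$mismatch,
                         scheme$gap_open, scheme$gap_extend)[, 1]
  if (scheme$both_strands) {
    rev <- .sw_score_block(revcomp(cluster$sequence), read, scheme$match,
                           scheme$mismatch, scheme$gap_open,
                           scheme$gap_extend)[, 1]
  } else {
    rev <- rep(-1L, length(fwd))
  }
  list(
    score = pmax(fwd, rev),
    strand = ifelse(fwd >= rev, "+", "-")
  )
}

#' Assign reads to exon variants across all clusters of a model
#'
#' The per-read, per-cluster assignment underlying isoform calling: every
#' read is aligned to every variant of every cluster and the top-scoring
#' variant per cluster is kept, with its score margin over the runner-up. A
#' read is `full_length` when every cluster has a hit at or above
#' `min_score` and all best hits fall on one strand (a single cDNA molecule
#' has one orientation, so strand-discordant hits indicate a problem read).
#'
#' @param reads A tibble with columns `read_id` and `sequence` (optional
#'   `molecule_id`, `read_class` are carried through), or a character
#'   vector of sequences.
#' @param model A [gene_model()].
#' @param scheme A [scoring_scheme()].
#' @param min_score Minimum per-cluster alignment score (default 50).
#' @return A tibble with one row per read x cluster: `read_id`, `cluster`,
#'   `variant_id` (NA when no variant reaches `min_score`), `score`,
#'   `margin`, `strand`, `ambiguous`, plus the read-level `full_length`
#'   flag (repeated across the read's rows).
#' @export
assign_reads <- function(reads, model, scheme = scoring_scheme(),
                         min_score = 50) {
  stopifnot(inherits(model, "gene_model"))
  scheme <- as_scoring_scheme(scheme)
  reads <- as_read_tbl(reads)
  seqs <- check_dna(reads$sequence, "read")
  n_reads <- nrow(reads)
  carry <- intersect(c("read_id", "molecule_id", "read_class"), names(reads))

  per_cluster <- lapply(names(model$clusters), function(nm) {
    cl <- model$clusters[[nm]]
    fwd <- .sw_score_block(cl$sequence, seqs, scheme$match, scheme$mismatch,
                           scheme$gap_open, scheme$gap_extend)
    if (scheme$both_strands) {
      rev <- .sw_score_block(revcomp(cl$sequence), seqs, scheme$match,
                             scheme$mismatch, scheme$gap_open,
                             scheme$gap_extend)
    } else {
      rev <- matrix(-1L, nrow(fwd), ncol(fwd))
    }
    s <- pmax(fwd, rev) # variants x reads
    best_idx <- apply(s, 2, which.max) # first top scorer wins ties
    best <- s[cbind(best_idx, seq_len(n_reads))]
    margin <- if (nrow(cl) >= 2) {
      s2 <- s
      s2[cbind(best_idx, seq_len(n_reads))] <- -1L
      second <- apply(s2, 2, max)
      as.numeric(best - second)
    } else {
      rep(NA_real_, n_reads)
    }
    strand <- ifelse(
      fwd[cbind(best_idx, seq_len(n_reads))] >=
        rev[cbind(best_idx, seq_len(n_reads))], "+", "-"
    )
    hit <- best >= min_score
    tibble(
      row = seq_len(n_reads),
      cluster = nm,
      variant_id = ifelse(hit, cl$variant_id[best_idx], NA_character_),
      score = as.integer(best),
      margin = ifelse(hit, margin, NA_real_),
      strand = ifelse(hit, strand, NA_character_),
      ambiguous = ifelse(hit & !is.na(margin), margin == 0, NA)
    )
  })
  out <- bind_rows(per_cluster)
  out <- out[order(out$row, match(out$cluster, names(model$clusters))), ]

  flags <- out |>
    group_by(.data$row) |>
    summarise(
      strand_concordant =
        length(unique(.data$strand[!is.na(.data$strand)])) <= 1,
      full_length = all(!is.na(.data$variant_id)) && strand_concordant,
      .groups = "drop"
    )
  out <- left_join(out, flags, by = "row")
  meta <- reads[out$row, carry, drop = FALSE]
  out <- bind_cols(meta, out[setdiff(names(out), "row")])
  as_tibble(out)
}

as_read_tbl <- function(reads) {
  if (is.character(reads)) {
    ids <- names(reads) %||% sprintf("read%05d", seq_along(reads))
    return(tibble(read_id = ids, sequence = unname(reads)))
  }
  reads <- as_tibble(reads)
  if (!"sequence" %in% names(reads)) {
    abort("`reads` must have a `sequence` column")
  }
  if (!"read_id" %in% names(reads)) {
    reads$read_id <- sprintf("read%05d", seq_len(nrow(reads)))
  }
  reads
}

#' Pairwise discriminability of exon variants within clusters
#'
#' Aligns every variant of each cluster against every variant of the same
#' cluster and ranks, for each variant, the scores in decreasing order.
#' Rank 1 is always the variant's self-alignment (score = its length under
#' the default scheme); the drop from rank 1 to rank 2 measures how easily
#' the most similar sibling variant could be confused with it.
#'
#' @param x A `gene_model` or a single cluster tibble.
#' @param scheme A [scoring_scheme()].
#' @return A tibble with columns `cluster`, `variant_id`, `rank`,
#'   `other_id`, `score`, of class `discriminability`.
#' @export
exon_discriminability <- function(x, scheme = scoring_scheme()) {
  scheme <- as_scoring_scheme(scheme)
  clusters <- if (inherits(x, "gene_model")) {
    x$clusters
  } else {
    list(cluster = as_tibble(x))
  }
  out <- bind_rows(lapply(names(clusters), function(nm) {
    cl <- clusters[[nm]]
    s <- align_scores(cl$sequence, cl$sequence, scheme)
    bind_rows(lapply(seq_len(nrow(cl)), function(i) {
      ord <- order(-s[, i], seq_len(nrow(cl)))
      tibble(
        cluster = nm,
        variant_id = cl$variant_id[i],
        rank = seq_len(nrow(cl)),
        other_id = cl$variant_id[ord],
        score = as.integer(s[ord, i])
      )
    }))
  }))
  class(out) <- c("discriminability", class(out))
  out
}

#' Summarise discriminability margins by rank
#'
#' @param x A `discriminability` table from [exon_discriminability()].
#' @param ... Unused.
#' @return One row per cluster and rank with the min/median/max score and
#'   the margin of rank 1 over that rank.
#' @exportS3Method
glance.discriminability <- function(x, ...) {
  firsts <- x |>
    filter(.data$rank == 1) |>
    select("cluster", "variant_id", first = "score")
  x |>
    left_join(firsts, by = c("cluster", "variant_id")) |>
    group_by(.data$cluster, .data$rank) |>
    summarise(
      min_score = min(.data$score),
      median_score = stats::median(.data$score),
      max_score = max(.data$score),
      min_margin = min(.data$first - .data$score),
      median_margin = stats::median(.data$first - .data$score),
      .groups = "drop"
    )
}
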