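CALL_STATUSES <- c("accepted_2d", "accepted_1d_pair", "rejected_single_1d",
                   "rejected_discordant_pair", "rejected_partial",
                   "rejected_unaligned")

#' Reconcile read classes into per-molecule isoform calls
#'
#' A nanopore event yields up to three reads of one cDNA molecule: a
#' template and a complement strand read (the 1D classes) and, when both
#' strands are linked, a higher-accuracy 2D consensus. Calls are made per
#' molecule, never per read, so one molecule is counted once:
#'
#' * if a 2D read exists and is usable (full-length, no ambiguous cluster),
#'   its variant tuple is the call (`accepted_2d`) — the 2D consensus takes
#'   precedence over the 1D reads;
#' * otherwise, if both template and complement are usable and agree on the
#'   best variant in every cluster, that tuple is the call
#'   (`accepted_1d_pair`);
#' * otherwise the molecule is rejected with a typed reason: a lone usable
#'   1D read (`rejected_single_1d`), a usable but disagreeing
#'   template/complement pair (`rejected_discordant_pair`), reads aligned
#'   in some but not all clusters or flagged ambiguous
#'   (`rejected_partial`), or no cluster hit at all (`rejected_unaligned`).
#'
#' A read is *usable* when it is full-length (see [assign_reads()]) and no
#' cluster assignment is an exact score tie: "uniquely or preferentially
#' aligned" is read strictly as a score margin of at least `min_margin`.
#'
#' @param assignments Output of [assign_reads()]; must carry `molecule_id`
#'   and `read_class` (`template`, `complement`, or `twodir`) columns.
#' @param min_margin Minimum best-minus-second-best score for a cluster
#'   assignment to count as unique (default 1).
#' @return A tibble with one row per molecule: `molecule_id`, `status`,
#'   `isoform` (NA unless accepted), `n_reads`.
#' @export
call_isoforms <- function(assignments, min_margin = 1) {
  need <- c("molecule_id", "read_class", "cluster", "variant_id", "margin",
            "full_length")
  missing <- setdiff(need, names(assignments))
  if (length(missing)) {
    abort(sprintf("`assignments` is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  bad_class <- setdiff(unique(assignments$read_class),
                       c("template", "complement", "twodir"))
  if (length(bad_class)) {
    abort(sprintf("unknown read class(es): %s",
                  paste(bad_class, collapse = ", ")))
  }

  n_clusters <- length(unique(assignments$cluster))
  per_read <- assignments |>
    group_by(.data$molecule_id, .data$read_class) |>
    summarise(
      n_ids = dplyr::n_distinct(.data$read_id),
      usable = .data$full_length[1] &&
        all(is.na(.data$margin) | .data$margin >= min_margin),
      any_hit = any(!is.na(.data$variant_id)),
      tuple = paste(.data$variant_id, collapse = ","),
      .groups = "drop"
    )
  dup <- per_read[per_read$n_ids > 1, ]
  if (nrow(dup)) {
    abort(sprintf(
      "conflicting duplicate read class(es) within molecule(s): %s",
      paste(unique(dup$molecule_id), collapse = ", ")
    ))
  }

  call_one <- function(df) {
    cls <- df$read_class
    get <- function(class, col) {
      i <- match(class, cls)
      if (is.na(i)) NA else df[[col]][i]
    }
    t_u <- isTRUE(get("template", "usable"))
    c_u <- isTRUE(get("complement", "usable"))
    if (isTRUE(get("twodir", "usable"))) {
      return(c("accepted_2d", get("twodir", "tuple")))
    }
    if (t_u && c_u) {
      if (identical(get("template", "tuple"), get("complement", "tuple"))) {
        return(c("accepted_1d_pair", get("template", "tuple")))
      }
      return(c("rejected_discordant_pair", NA))
    }
    if (xor(t_u, c_u)) {
      return(c("rejected_single_1d", NA))
    }
    if (any(df$any_hit)) {
      return(c("rejected_partial", NA))
    }
    c("rejected_unaligned", NA)
  }

  split_reads <- split(per_read, per_read$molecule_id)
  res <- vapply(split_reads, call_one, character(2))
  tibble(
    molecule_id = names(split_reads),
    status = factor(unname(res[1, ]), levels = CALL_STATUSES),
    isoform = unname(res[2, ]),
    n_reads = unname(vapply(split_reads, nrow, integer(1)))
  )
}

#' Tabulate isoform calls into a count table
#'
#' Counts accepted calls per isoform. Alongside the counts, the table
#' records how many isoforms were seen once versus more than once — the
#' singleton excess is the usual sign that sequencing has not saturated
#' the isoform pool.
#'
#' @param calls Output of [call_isoforms()], or a character vector of
#'   isoform labels (taken as already-accepted calls).
#' @return A tibble of class `isoform_table` with columns `isoform`,
#'   `count`, `frequency`, sorted by descending count; attributes
#'   `n_reads`, `n_isoforms`, `singletons`, `multiples`.
#' @export
tabulate_isoforms <- function(calls) {
  labels <- accepted_labels(calls)
  if (length(labels) == 0) {
    out <- tibble(isoform = character(), count = integer(),
                  frequency = double())
  } else {
    out <- tibble(isoform = labels) |>
      dplyr::count(.data$isoform, name = "count") |>
      arrange(desc(.data$count), .data$isoform) |>
      mutate(frequency = .data$count / sum(.data$count))
  }
  structure(
    out,
    n_reads = sum(out$count),
    n_isoforms = nrow(out),
    singletons = sum(out$count == 1),
    multiples = sum(out$count > 1),
    class = c("isoform_table", class(out))
  )
}

# pull accepted isoform labels out of calls in any accepted form
accepted_labels <- function(calls) {
  if (is.character(calls)) return(calls[!is.na(calls)])
  if (inherits(calls, "isoform_table")) {
    return(rep(calls$isoform, calls$count))
  }
  df <- as_tibble(calls)
  if (!"isoform" %in% names(df)) {
    abort("`calls` must be a character vector or have an `isoform` column")
  }
  if ("status" %in% names(df)) {
    df <- df[startsWith(as.character(df$status), "accepted"), ]
  }
  df$isoform[!is.na(df$isoform)]
}

#' @exportS3Method
glance.isoform_table <- function(x, ...) {
  tibble(
    n_reads = attr(x, "n_reads"),
    n_isoforms = attr(x, "n_isoforms"),
    singletons = attr(x, "singletons"),
    multiples = attr(x, "multiples")
  )
}

#' @exportS3Method
tidy.isoform_table <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "isoform_table")
  as_tibble(out)
}

#' Per-cluster marginal variant frequencies
#'
#' Decomposes an isoform count table into, for each cluster, the frequency
#' with which each variant is included (read-weighted). Frequencies sum to
#' 1 within each cluster.
#'
#' @param table An `isoform_table` from [tabulate_isoforms()].
#' @return A tibble `cluster`, `variant_id`, `count`, `frequency`.
#' @export
cluster_marginals <- function(table) {
  if (nrow(table) == 0) {
    return(tibble(cluster = character(), variant_id = character(),
                  count = integer(), frequency = double()))
  }
  parts <- split_isoform(table$isoform)
  long <- tibble(
    variant_id = unlist(parts),
    count = rep(table$count, lengths(parts))
  )
  long |>
    mutate(cluster = variant_cluster(.data$variant_id)) |>
    group_by(.data$cluster, .data$variant_id) |>
    summarise(count = sum(.data$count), .groups = "drop_last") |>
    mutate(frequency = .data$count / sum(.data$count)) |>
    ungroup() |>
    arrange(.data$cluster, desc(.data$count))
}

#' Cumulative read share of rank-ordered isoforms
#'
#' Isoforms are ranked by descending read count (ties broken by isoform
#' id); the curve of cumulative read share against rank shows how
#' concentrated expression is in the most frequent isoforms.
#'
#' @param table An `isoform_table` from [tabulate_isoforms()].
#' @return A tibble `rank`, `isoform`, `count`, `cumulative` (nondecreasing,
#'   ending at 1).
#' @export
cumulative_isoform_distribution <- function(table) {
  if (nrow(table) == 0) {
    abort("cannot compute a cumulative distribution of an empty table")
  }
  out <- table |>
    arrange(desc(.data$count), .data$isoform) |>
    mutate(
      rank = row_number(),
      cumulative = cumsum(.data$count) / sum(.data$count)
    )
  select(as_tibble(out), "rank", "isoform", "count", "cumulative")
}
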