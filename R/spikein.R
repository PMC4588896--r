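#' The six-isoform spike-in truth set
#'
#' The classic control pool for template-switch quantification in the
#' Dscam1 exon 3-10 system: six in vitro transcribed isoforms chosen so
#' that no two share a variant in any cluster, which makes every
#' single-crossover chimera between two pool members detectable as a
#' non-input isoform.
#'
#' @return Character vector of six isoform ids.
#' @export
#' @examples
#' dscam_spikein_isoforms()
dscam_spikein_isoforms <- function() {
  c("4.2,6.32,9.31", "4.1,6.46,9.30", "4.3,6.33,9.9",
    "4.12,6.44,9.32", "4.7,6.8,9.15", "4.5,6.4,9.4")
}

check_truth <- function(truth, model = NULL) {
  if (!is.character(truth) || length(truth) == 0 || anyDuplicated(truth)) {
    abort("`truth` must be a nonempty character vector of distinct isoform ids")
  }
  if (!is.null(model)) check_isoforms(model, truth)
  truth
}

#' Classify observed isoforms against a spike-in truth set
#'
#' When a sequencing library is built from a known pool of isoforms, any
#' observed isoform outside the pool must be an RT-PCR template-switch
#' chimera (assignment to pool exons being unambiguous). This labels every
#' observed isoform genuine or chimeric, attaches single-crossover parent
#' explanations for the chimeras, and reports the chimeric *read* fraction
#' (chimeric reads / accepted reads), the quantity that tracks PCR cycle
#' number.
#'
#' @param table An `isoform_table` from [tabulate_isoforms()].
#' @param truth Character vector of input-pool isoform ids.
#' @param model Optional [gene_model()]; when given, truth ids are
#'   validated against it.
#' @return A tibble of class `chimera_report`: `isoform`, `count`, `label`
#'   (`genuine`/`chimeric`), `n_parent_pairs`, `resolved` (single-crossover
#'   explainable), and a `parents` list-column of [infer_parents()] tables.
#'   Attributes: `chimeric_read_fraction`, `n_reads`.
#' @export
classify_isoforms <- function(table, truth, model = NULL) {
  truth <- check_truth(truth, model)
  if (!is.null(model)) check_isoforms(model, table$isoform)
  out <- as_tibble(tidy(table))
  out$label <- ifelse(out$isoform %in% truth, "genuine", "chimeric")
  out$parents <- lapply(seq_len(nrow(out)), function(i) {
    if (out$label[i] == "genuine") {
      empty_parents()
    } else {
      infer_parents(out$isoform[i], truth)
    }
  })
  out$n_parent_pairs <- vapply(out$parents, nrow, integer(1))
  out$resolved <- out$label == "genuine" | out$n_parent_pairs > 0
  n_reads <- sum(out$count)
  frac <- if (n_reads > 0) {
    sum(out$count[out$label == "chimeric"]) / n_reads
  } else {
    NA_real_
  }
  structure(out,
            chimeric_read_fraction = frac,
            n_reads = n_reads,
            class = c("chimera_report", class(out)))
}

#' @exportS3Method
glance.chimera_report <- function(x, ...) {
  tibble(
    n_reads = attr(x, "n_reads"),
    n_isoforms = nrow(x),
    n_genuine = sum(x$label == "genuine"),
    n_chimeric = sum(x$label == "chimeric"),
    n_unresolved = sum(!x$resolved),
    chimeric_read_fraction = attr(x, "chimeric_read_fraction")
  )
}

#' Chimeric read fraction of a report
#'
#' @param report A `chimera_report` from [classify_isoforms()].
#' @return The fraction of accepted reads carried by non-input isoforms.
#' @export
chimeric_read_fraction <- function(report) {
  attr(report, "chimeric_read_fraction")
}

empty_parents <- function() {
  tibble(parent_a = character(), parent_b = character(),
         crossover = integer())
}

#' Single-crossover parent pairs of a chimeric isoform
#'
#' A template switch at one point between clusters `k` and `k + 1` turns
#' parents A and B into the chimera whose first `k` variants come from A
#' and the rest from B. This enumerates every ordered pair of truth
#' isoforms and every inter-cluster position consistent with the observed
#' isoform. An empty result means no single switch explains it (at least
#' two switches are required); such isoforms stay chimeric with parents
#' unresolved. The crossover is localized only to the constitutive
#' interval between clusters — base-level breakpoints are not inferred.
#'
#' @param isoform A single isoform id not present in `truth`.
#' @param truth Character vector of input-pool isoform ids.
#' @return A tibble `parent_a`, `parent_b`, `crossover` (the index `k`
#'   such that the switch lies between cluster `k` and cluster `k + 1`).
#' @export
#' @examples
#' infer_parents("4.2,6.32,9.30",
#'               c("4.2,6.32,9.31", "4.1,6.46,9.30"))
infer_parents <- function(isoform, truth) {
  stopifnot(length(isoform) == 1)
  truth <- check_truth(truth)
  if (isoform %in% truth) {
    abort("`isoform` is in the truth set; parents are only inferred for chimeras")
  }
  obs <- split_isoform(isoform)[[1]]
  nc <- length(obs)
  tparts <- split_isoform(truth)
  if (any(lengths(tparts) != nc)) {
    abort("truth isoforms and `isoform` must span the same clusters")
  }
  rows <- list()
  for (a in seq_along(truth)) {
    for (b in seq_along(truth)) {
      if (a == b) next
      pa <- tparts[[a]]
      pb <- tparts[[b]]
      for (k in seq_len(nc - 1)) {
        if (all(obs[seq_len(k)] == pa[seq_len(k)]) &&
            all(obs[(k + 1):nc] == pb[(k + 1):nc])) {
          rows[[length(rows) + 1]] <-
            tibble(parent_a = truth[a], parent_b = truth[b], crossover = k)
        }
      }
    }
  }
  if (length(rows) == 0) return(empty_parents())
  bind_rows(rows)
}

#' Rank-abundance data with genuine/chimeric labels
#'
#' The plotting table behind rank-order versus log10 read count displays:
#' isoforms sorted by descending count (ties by id), labeled against the
#' truth set.
#'
#' @inheritParams classify_isoforms
#' @return A tibble `rank`, `isoform`, `count`, `label`.
#' @export
rank_abundance <- function(table, truth, model = NULL) {
  if (nrow(table) == 0) {
    abort("cannot rank an empty isoform table")
  }
  rep <- classify_isoforms(table, truth, model)
  rep |>
    as_tibble() |>
    arrange(desc(.data$count), .data$isoform) |>
    mutate(rank = row_number()) |>
    select("rank", "isoform", "count", "label")
}
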