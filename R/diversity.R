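#' Subsampled unique-isoform counts (rarefaction by read pools)
#'
#' Draws `reps` random pools of `n` reads without replacement from the
#' accepted calls and counts the distinct isoforms in each — the Monte
#' Carlo rarefaction behind saturation curves. At `n` equal to the total
#' read count the draw is exhaustive and the count equals the observed
#' number of distinct isoforms, with zero variance.
#'
#' @param calls Accepted isoform labels: a character vector, a
#'   [call_isoforms()] table, or an `isoform_table`.
#' @param n Pool size (reads per draw), `1 <= n <= total`.
#' @param reps Number of random pools (default 100).
#' @param seed Integer seed; required for reproducibility.
#' @return A tibble `size`, `rep`, `unique` of class `saturation_curve`.
#' @export
subsample_unique_isoforms <- function(calls, n, reps = 100, seed) {
  labels <- accepted_labels(calls)
  total <- length(labels)
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != floor(n)) {
    abort("`n` must be a single positive integer")
  }
  if (n > total) {
    abort(sprintf("`n` (%d) exceeds the number of accepted reads (%d)",
                  n, total))
  }
  if (reps < 1) abort("`reps` must be >= 1")
  code <- as.integer(factor(labels))
  uniq <- with_seed(seed, vapply(seq_len(reps), function(r) {
    length(unique(code[sample.int(total, n)]))
  }, integer(1)))
  structure(
    tibble(size = as.integer(n), rep = seq_len(reps), unique = uniq),
    class = c("saturation_curve", class(tibble())),
    total_reads = total
  )
}

#' Exact expected unique-isoform count under subsampling
#'
#' The closed-form expectation of the rarefaction draw in
#' [subsample_unique_isoforms()], computed with `vegan::rarefy()`: the
#' hypergeometric probability that each isoform appears at least once in a
#' pool of `n` reads, summed over isoforms.
#'
#' @inheritParams subsample_unique_isoforms
#' @param n Pool size(s).
#' @return Numeric vector of expectations, one per element of `n`.
#' @export
#' @examples
#' expected_unique_isoforms(c("A", "A", "B"), 2) # 5/3
expected_unique_isoforms <- function(calls, n) {
  labels <- accepted_labels(calls)
  counts <- table(labels)
  if (any(n < 1) || any(n > length(labels))) {
    abort("`n` must lie in [1, total reads]")
  }
  # rarefy() warns when no isoform is a singleton; the expectation is exact
  # either way, so that data-plausibility note is silenced
  as.numeric(suppressWarnings(vegan::rarefy(as.integer(counts), sample = n)))
}

#' Saturation scan across subsample sizes
#'
#' One rarefaction point per size: `reps` random pools of each size,
#' without replacement. Mean unique counts are nondecreasing in size.
#'
#' @inheritParams subsample_unique_isoforms
#' @param sizes Increasing vector of pool sizes.
#' @return A `saturation_curve` tibble with `size`, `rep`, `unique`.
#' @export
saturation_scan <- function(calls, sizes, reps = 100, seed) {
  if (is.unsorted(sizes, strictly = FALSE)) {
    abort("`sizes` must be sorted ascending")
  }
  seeds <- derive_seeds(seed, length(sizes))
  out <- bind_rows(lapply(seq_along(sizes), function(i) {
    subsample_unique_isoforms(calls, sizes[i], reps = reps, seed = seeds[i])
  }))
  structure(out,
            class = c("saturation_curve", class(tibble())),
            total_reads = length(accepted_labels(calls)))
}

#' @exportS3Method
glance.saturation_curve <- function(x, ...) {
  x |>
    group_by(.data$size) |>
    summarise(
      reps = n(),
      mean_unique = mean(.data$unique),
      sd_unique = sd(.data$unique),
      .groups = "drop"
    )
}

#' Capture-recapture point estimators
#'
#' Closed-form two-pool richness estimators from the unique counts `u1`,
#' `u2` of each pool and the shared count `m`: Lincoln-Petersen
#' `u1 * u2 / m` and the bias-corrected Chapman
#' `(u1 + 1)(u2 + 1)/(m + 1) - 1`. [capture_recapture()] applies them to
#' read pools; these are exposed for direct use on pre-computed counts.
#'
#' @param u1,u2 Distinct isoforms in pool one / pool two.
#' @param m Distinct isoforms present in both pools.
#' @return The estimated total number of distinct isoforms.
#' @export
#' @examples
#' lincoln_petersen_estimate(3, 3, 2) # 4.5
#' chapman_estimate(3, 3, 2) # 4.333...
lincoln_petersen_estimate <- function(u1, u2, m) {
  if (m == 0) {
    abort(paste0(
      "no isoforms are shared between the pools (m = 0); the ",
      "Lincoln-Petersen estimate is undefined - use method = \"chapman\""
    ))
  }
  u1 * u2 / m
}

#' @rdname lincoln_petersen_estimate
#' @export
chapman_estimate <- function(u1, u2, m) {
  (u1 + 1) * (u2 + 1) / (m + 1) - 1
}

# one two-pool capture-recapture draw; returns u1, u2, m, estimate
cr_draw <- function(code, pool_size, method, disjoint) {
  total <- length(code)
  if (disjoint) {
    idx <- sample.int(total, 2 * pool_size)
    p1 <- code[idx[seq_len(pool_size)]]
    p2 <- code[idx[pool_size + seq_len(pool_size)]]
  } else {
    p1 <- code[sample.int(total, pool_size)]
    p2 <- code[sample.int(total, pool_size)]
  }
  s1 <- unique(p1)
  s2 <- unique(p2)
  u1 <- length(s1)
  u2 <- length(s2)
  m <- length(intersect(s1, s2))
  est <- switch(method,
    lincoln_petersen = lincoln_petersen_estimate(u1, u2, m),
    chapman = chapman_estimate(u1, u2, m)
  )
  list(u1 = u1, u2 = u2, m = m, estimate = est)
}

#' Two-pool capture-recapture estimate of isoform richness
#'
#' Estimates the total number of distinct isoforms in a library from the
#' overlap between two random read pools, by analogy with ecological
#' mark-recapture: pool one "marks" `u1` isoforms, pool two recaptures
#' `m` of its `u2`. Presence/absence per pool is what matters (species,
#' not individuals). Two estimators are available:
#' Lincoln-Petersen `u1 * u2 / m` (undefined at `m = 0`) and the
#' bias-corrected Chapman `(u1 + 1)(u2 + 1)/(m + 1) - 1` (the default:
#' defined at `m = 0` and less biased when the overlap is small).
#'
#' Pools are drawn disjoint by default (one read feeds at most one pool,
#' mimicking a split of the read set); set `disjoint = FALSE` for two
#' independent draws. The 95% confidence interval is a nonparametric
#' bootstrap over pool redraws: the two-pool draw is repeated `n_boot`
#' times and the interval is `estimate +/- 1.96 * sd(redraw estimates)`
#' (`ci = "bootstrap"`), or the Chapman closed-form variance can be used
#' instead (`ci = "analytic"`).
#'
#' @inheritParams subsample_unique_isoforms
#' @param pool_size Reads per pool; `2 * pool_size <= total` when
#'   `disjoint`.
#' @param method `"chapman"` (default) or `"lincoln_petersen"`.
#' @param ci `"bootstrap"` (default) or `"analytic"`.
#' @param n_boot Bootstrap redraws for the CI (default 200).
#' @param disjoint Draw the two pools without sharing reads (default).
#' @return A one-row tibble of class `diversity_estimate`: `method`,
#'   `pool_size`, `n1`, `n2`, `u1`, `u2`, `m`, `estimate`, `ci_low`,
#'   `ci_high`, `ci_method`.
#' @export
capture_recapture <- function(calls, pool_size, seed,
                              method = c("chapman", "lincoln_petersen"),
                              ci = c("bootstrap", "analytic"),
                              n_boot = 200, disjoint = TRUE) {
  method <- match.arg(method)
  ci <- match.arg(ci)
  labels <- accepted_labels(calls)
  total <- length(labels)
  if (pool_size < 1 || pool_size != floor(pool_size)) {
    abort("`pool_size` must be a positive integer")
  }
  needed <- if (disjoint) 2 * pool_size else pool_size
  if (needed > total) {
    abort(sprintf(
      "pool_size %d needs %d reads but only %d accepted calls are available",
      pool_size, needed, total
    ))
  }
  code <- as.integer(factor(labels))
  seeds <- derive_seeds(seed, 2)
  draw <- with_seed(seeds[1], cr_draw(code, pool_size, method, disjoint))
  if (ci == "bootstrap") {
    boots <- with_seed(seeds[2], vapply(seq_len(n_boot), function(b) {
      cr_draw(code, pool_size, method, disjoint)$estimate
    }, double(1)))
    half <- 1.96 * sd(boots)
  } else {
    v <- with(draw, (u1 + 1) * (u2 + 1) * (u1 - m) * (u2 - m) /
                ((m + 1)^2 * (m + 2)))
    half <- 1.96 * sqrt(v)
  }
  structure(
    tibble(
      method = method, pool_size = as.integer(pool_size),
      n1 = as.integer(pool_size), n2 = as.integer(pool_size),
      u1 = draw$u1, u2 = draw$u2, m = draw$m,
      estimate = draw$estimate,
      ci_low = draw$estimate - half,
      ci_high = draw$estimate + half,
      ci_method = ci
    ),
    class = c("diversity_estimate", class(tibble()))
  )
}

#' @exportS3Method
glance.diversity_estimate <- function(x, ...) as_tibble(x)

#' Capture-recapture across pool sizes
#'
#' Repeats [capture_recapture()] at each pool size for which two pools fit
#' in the read set; paired with [saturation_scan()] this shows whether the
#' richness estimate has stabilized with sequencing depth.
#'
#' @inheritParams capture_recapture
#' @param pool_sizes Increasing vector of pool sizes; sizes needing more
#'   reads than available are skipped.
#' @return A `diversity_estimate` tibble with one row per usable size.
#' @export
capture_recapture_scan <- function(calls, pool_sizes, seed,
                                   method = c("chapman", "lincoln_petersen"),
                                   ci = c("bootstrap", "analytic"),
                                   n_boot = 200, disjoint = TRUE) {
  method <- match.arg(method)
  ci <- match.arg(ci)
  total <- length(accepted_labels(calls))
  keep <- if (disjoint) pool_sizes[2 * pool_sizes <= total] else
    pool_sizes[pool_sizes <= total]
  seeds <- derive_seeds(seed, length(keep))
  out <- bind_rows(lapply(seq_along(keep), function(i) {
    capture_recapture(calls, keep[i], seed = seeds[i], method = method,
                      ci = ci, n_boot = n_boot, disjoint = disjoint)
  }))
  structure(out, class = c("diversity_estimate", class(tibble())))
}
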