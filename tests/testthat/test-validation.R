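primer <- "ACGTACGTACGTACGTACGT"

test_that("reads count only with an exact primer match", {
  cl <- tibble::tibble(
    variant_id = c("v.1", "v.2"),
    sequence = c(paste(rep("ACCTGA", 12), collapse = ""),
                 paste(rep("GGATCC", 12), collapse = ""))
  )
  good <- paste0(primer, substr(cl$sequence[1], 1, 51))
  no_primer <- paste0("TTTTTTTTTTTTTTTTTTTT", substr(cl$sequence[1], 1, 51))
  mut_primer <- paste0(sub("^A", "C", primer), substr(cl$sequence[1], 1, 51))
  counts <- short_read_exon_count(c(good, no_primer, mut_primer), primer, cl)
  expect_equal(counts$count[counts$variant_id == "v.1"], 1)
  expect_equal(attr(counts, "n_primer_matched"), 1)
  expect_equal(attr(counts, "n_reads"), 3)
})

test_that("best-score ties between identical prefixes are discarded", {
  cl <- tibble::tibble(variant_id = c("v.1", "v.2"),
                       sequence = c("ACCTGAACCTGAACCTGA", "ACCTGAACCTGAACCTGA"))
  read <- paste0(primer, cl$sequence[1])
  counts <- short_read_exon_count(read, primer, cl)
  expect_equal(sum(counts$count), 0)
  expect_equal(attr(counts, "n_ambiguous"), 1)
  expect_error(short_read_exon_count(read, primer, cl[0, ]), "no variants")
})

test_that("an error-free mixture is recovered exactly", {
  cfg <- sim_config(cluster_sizes = c(6, 4), exon_length_range = c(120, 140),
                    constitutive_length = 40, seed = 81)
  model <- make_exon_clusters(cfg)
  cl <- model$clusters[[1]]
  mix <- setNames(c(0.5, 0.3, 0.2), cl$variant_id[1:3])
  sr <- simulate_short_reads(model, cluster_names(model)[1], mix, n = 200,
                             error = 0, config = cfg)
  counts <- short_read_exon_count(sr$reads, sr$primer, cl)
  truth <- table(factor(sr$ledger$variant_id, levels = cl$variant_id))
  expect_equal(counts$count, as.integer(truth))
})

test_that("a noisy mixture is recovered within the multinomial interval", {
  cfg <- sim_config(cluster_sizes = 8, exon_length_range = c(120, 140),
                    constitutive_length = 40, seed = 82)
  model <- make_exon_clusters(cfg)
  cl <- model$clusters[[1]]
  mix <- setNames(rep(1 / 4, 4), cl$variant_id[1:4])
  n <- 600
  sr <- simulate_short_reads(model, cluster_names(model)[1], mix, n = n,
                             error = 0.01, config = cfg)
  counts <- short_read_exon_count(sr$reads, sr$primer, cl)
  freq <- counts$count / sum(counts$count)
  half <- 1.96 * sqrt(0.25 * 0.75 / n)
  for (v in names(mix)) {
    expect_lt(abs(freq[counts$variant_id == v] - 1 / 4), 3 * half)
  }
})

test_that("cluster frequencies normalize per cluster", {
  tab <- tabulate_isoforms(c("x.1,y.1", "x.1,y.2", "x.2,y.2", "x.2,y.2"))
  f <- cluster_frequencies(tab, source = "long")
  expect_equal(unique(f$source), "long")
  sums <- f |>
    dplyr::group_by(cluster) |>
    dplyr::summarise(s = sum(frequency))
  expect_true(all(abs(sums$s - 1) < 1e-9))
})

test_that("r-squared follows its closed form and is symmetric", {
  a <- tibble::tibble(cluster = "c", variant_id = paste0("c.", 1:3),
                      count = 1, frequency = c(0.1, 0.2, 0.7), source = "a")
  b <- tibble::tibble(cluster = "c", variant_id = paste0("c.", 1:3),
                      count = 1, frequency = c(0.7, 0.2, 0.1), source = "b")
  # closed-form Pearson on three points, computed from raw sums
  x <- a$frequency; y <- b$frequency
  r_hand <- (mean(x * y) - mean(x) * mean(y)) /
    sqrt((mean(x^2) - mean(x)^2) * (mean(y^2) - mean(y)^2))
  expect_equal(compare_frequencies(a, b), r_hand^2)
  expect_equal(compare_frequencies(a, b), compare_frequencies(b, a))
  expect_equal(compare_frequencies(a, a), 1)
  const <- dplyr::mutate(b, frequency = 1 / 3)
  expect_error(compare_frequencies(a, const), "constant")
})

test_that("independent frequency tables decorrelate over many variants", {
  set.seed(83)
  r2s <- vapply(1:15, function(i) {
    f1 <- runif(93); f2 <- runif(93)
    a <- tibble::tibble(cluster = "c", variant_id = paste0("c.", 1:93),
                        count = 1, frequency = f1 / sum(f1), source = "a")
    b <- tibble::tibble(cluster = "c", variant_id = paste0("c.", 1:93),
                        count = 1, frequency = f2 / sum(f2), source = "b")
    compare_frequencies(a, b)
  }, double(1))
  expect_lt(mean(r2s), 0.15)
})

test_that("matched long- and short-read frequencies agree on shared truth", {
  # one underlying mixture drives both counters: pooled R^2 is high
  cfg <- sim_config(cluster_sizes = c(5, 4), exon_length_range = c(100, 120),
                    constitutive_length = 50, seed = 84,
                    error_2d = c(sub = 0, ins = 0, del = 0),
                    read_truncation_prob = 0, fraction_with_2d = 1)
  model <- make_exon_clusters(cfg)
  ab <- isoform_abundances(model, 12, cfg)
  sim <- simulate_reads(model, ab, 250, cfg)
  tab <- tabulate_isoforms(
    call_isoforms(assign_reads(
      dplyr::filter(sim$reads, read_class == "twodir"), model
    ))
  )
  long_f <- cluster_frequencies(tab, source = "long")
  truth_tab <- tabulate_isoforms(sim$ledger$isoform)
  truth_f <- cluster_frequencies(truth_tab, source = "truth")
  expect_gt(compare_frequencies(long_f, truth_f), 0.99)
})
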