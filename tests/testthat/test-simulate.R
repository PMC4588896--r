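test_that("generation is deterministic under a fixed config", {
  cfg <- sim_config(cluster_sizes = c(3, 3), exon_length_range = c(60, 80),
                    constitutive_length = 30, seed = 91,
                    switch_rate = 0.1, fraction_with_2d = 0.5)
  m1 <- make_exon_clusters(cfg)
  m2 <- make_exon_clusters(cfg)
  expect_identical(m1, m2)
  ab <- isoform_abundances(m1, 5, cfg)
  s1 <- simulate_reads(m1, ab, 40, cfg)
  s2 <- simulate_reads(m2, ab, 40, cfg)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$ledger, s2$ledger)
  # and byte-identical on disk
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_sequences(s1$reads, f1)
  write_sequences(s2$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("identity targets are realized within three points", {
  cfg <- sim_config(cluster_sizes = 10, exon_length_range = c(400, 400),
                    constitutive_length = 30,
                    target_pairwise_identity = 0.80, seed = 92)
  model <- make_exon_clusters(cfg)
  ident <- cluster_identity(model)
  expect_gte(ident$mean_identity, 0.77)
  expect_lte(ident$mean_identity, 0.83)
  # degenerate target: identical variants, flagged
  cfg1 <- sim_config(cluster_sizes = 3, exon_length_range = c(50, 50),
                     constitutive_length = 20,
                     target_pairwise_identity = 1, seed = 93)
  expect_warning(m1 <- make_exon_clusters(cfg1), "degenerate")
  expect_equal(dplyr::n_distinct(m1$clusters[[1]]$sequence), 1)
  expect_error(sim_config(cluster_sizes = 3, target_pairwise_identity = 1.2,
                          seed = 94) |> make_exon_clusters(),
               "identity")
})

test_that("the default model reproduces the three-cluster topology", {
  model <- make_exon_clusters(sim_config(seed = 95))
  expect_equal(unname(cluster_sizes(model)), c(12L, 48L, 33L))
  expect_equal(cluster_names(model), c("4", "6", "9"))
  expect_equal(isoform_space_size(model), 19008)
})

test_that("error-free 2D reads are exact isoform sequences", {
  cfg <- sim_config(cluster_sizes = c(3, 3), exon_length_range = c(60, 60),
                    constitutive_length = 30, seed = 96,
                    error_2d = c(sub = 0, ins = 0, del = 0),
                    read_truncation_prob = 0, fraction_with_2d = 1)
  model <- make_exon_clusters(cfg)
  ab <- isoform_abundances(model, 4, cfg)
  sim <- simulate_reads(model, ab, 30, cfg)
  r2d <- dplyr::filter(sim$reads, read_class == "twodir")
  expect_equal(nrow(r2d), 30)
  truth <- isoform_sequence(
    model, sim$ledger$isoform[match(r2d$molecule_id, sim$ledger$molecule_id)]
  )
  expect_equal(r2d$sequence, truth)
  expect_true(all(r2d$n_sub + r2d$n_ins + r2d$n_del == 0))
})

test_that("ten percent total 2D error lands near ninety percent identity", {
  cfg <- sim_config(cluster_sizes = c(3, 3), exon_length_range = c(120, 120),
                    constitutive_length = 120, seed = 97,
                    read_truncation_prob = 0, fraction_with_2d = 1)
  model <- make_exon_clusters(cfg)
  ab <- isoform_abundances(model, 6, cfg)
  sim <- simulate_reads(model, ab, 80, cfg)
  r2d <- dplyr::filter(sim$reads, read_class == "twodir")
  truth <- isoform_sequence(
    model, sim$ledger$isoform[match(r2d$molecule_id, sim$ledger$molecule_id)]
  )
  aln <- align_local(r2d$sequence, truth,
                     scoring_scheme(both_strands = FALSE))
  expect_lt(abs(mean(aln$identity) - 0.90), 0.01)
})

test_that("ledger chimera fractions follow the injected switch rate", {
  r <- 0.32
  n <- 2000
  cfg <- sim_config(cluster_sizes = c(2, 2), exon_length_range = c(40, 40),
                    constitutive_length = 20, seed = 98, switch_rate = r,
                    fraction_with_2d = 0, abundance_model = "uniform")
  model <- make_exon_clusters(cfg)
  ab <- isoform_abundances(model, 4, cfg)
  sim <- simulate_reads(model, ab, n, cfg)
  ci <- qbinom(c(0.025, 0.975), n, r) / n
  frac <- mean(sim$ledger$chimeric)
  expect_gte(frac, ci[1])
  expect_lte(frac, ci[2])
  # chimeric ledger rows carry distinct parents and a crossover point
  ch <- dplyr::filter(sim$ledger, chimeric)
  expect_true(all(!is.na(ch$parent_a) & !is.na(ch$parent_b)))
  expect_true(all(ch$parent_a != ch$parent_b))
  expect_true(all(ch$crossover %in% 1:1))
})

test_that("injected chimeras are single-crossover products of their parents", {
  cfg <- sim_config(cluster_sizes = c(2, 3, 2), exon_length_range = c(40, 40),
                    constitutive_length = 20, seed = 99, switch_rate = 0.5,
                    abundance_model = "uniform")
  model <- make_exon_clusters(cfg)
  ab <- isoform_abundances(model, 6, cfg)
  sim <- simulate_reads(model, ab, 60, cfg)
  ch <- dplyr::filter(sim$ledger, chimeric)
  expect_gt(nrow(ch), 5)
  for (i in seq_len(nrow(ch))) {
    pa <- split_isoform(ch$parent_a[i])[[1]]
    pb <- split_isoform(ch$parent_b[i])[[1]]
    k <- ch$crossover[i]
    expect_equal(ch$isoform[i], isoform_id(c(pa[seq_len(k)], pb[(k + 1):3])))
    # explained by parent inference whenever it is a non-input tuple
    if (!ch$isoform[i] %in% ab$isoform) {
      par <- infer_parents(ch$isoform[i], ab$isoform)
      expect_gt(nrow(par), 0)
    }
  }
})

test_that("read classes, truncation and abundance shapes behave as configured", {
  cfg <- sim_config(cluster_sizes = c(2, 2), exon_length_range = c(50, 50),
                    constitutive_length = 25, seed = 100,
                    read_truncation_prob = 1, fraction_with_2d = 1)
  model <- make_exon_clusters(cfg)
  ab <- isoform_abundances(model, 3, cfg)
  sim <- simulate_reads(model, ab, 20, cfg)
  expect_equal(sort(unique(sim$reads$read_class)),
               c("complement", "template", "twodir"))
  expect_true(all(sim$reads$truncated))
  full_len <- nchar(isoform_sequence(model, sim$ledger$isoform[1]))
  expect_true(all(nchar(sim$reads$sequence) < full_len))
  expect_error(simulate_reads(model, ab, 0, cfg), "n_molecules")
  bad_ab <- dplyr::mutate(ab, abundance = abundance * 2)
  expect_error(simulate_reads(model, bad_ab, 5, cfg), "sum to 1")
})

test_that("short-read simulation respects its degenerate cases", {
  cfg <- sim_config(cluster_sizes = 4, exon_length_range = c(80, 80),
                    constitutive_length = 30, seed = 101)
  model <- make_exon_clusters(cfg)
  cl <- model$clusters[[1]]
  mix <- setNames(c(1, 0, 0, 0), cl$variant_id)
  empty <- simulate_short_reads(model, cluster_names(model), mix, n = 0,
                                config = cfg)
  expect_equal(nrow(empty$reads), 0)
  expect_error(
    simulate_short_reads(model, cluster_names(model), mix, n = 5,
                         read_length = 10, config = cfg),
    "primer"
  )
  sr <- simulate_short_reads(model, cluster_names(model), mix, n = 10,
                             error = 0, config = cfg)
  expect_true(all(sr$ledger$variant_id == cl$variant_id[1]))
  expect_true(all(startsWith(sr$reads$sequence, sr$primer)))
})
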