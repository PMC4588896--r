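make_cluster <- function(n, len, seed) {
  cfg <- sim_config(cluster_sizes = n, exon_length_range = c(len, len),
                    constitutive_length = 10, seed = seed)
  make_exon_clusters(cfg)$clusters[[1]]
}

test_that("an exact embedded variant outscores its siblings", {
  set.seed(21)
  cl <- make_cluster(6, 120, seed = 22)
  read <- paste0(random_seq(80), cl$sequence[3], random_seq(80))
  hit <- assign_exon(read, cl)
  expect_equal(attr(hit, "best"), cl$variant_id[3])
  expect_gt(attr(hit, "margin"), 0)
  expect_false(attr(hit, "ambiguous"))
  expect_equal(hit$score[1], 120)
})

test_that("random reads have no hit above the score floor", {
  set.seed(23)
  cl <- make_cluster(6, 120, seed = 24)
  for (i in 1:5) {
    hit <- assign_exon(random_seq(1000), cl, min_score = 50)
    expect_equal(nrow(hit), 0)
  }
})

test_that("identical variants tie with margin zero and are flagged ambiguous", {
  cl <- tibble::tibble(variant_id = c("x.1", "x.2"),
                       sequence = c("ACGTACGTACGT", "ACGTACGTACGT"))
  read <- paste0("TTTT", "ACGTACGTACGT", "TTTT")
  hit <- assign_exon(read, cl, min_score = 5)
  expect_equal(attr(hit, "best"), "x.1") # tie broken by cluster order
  expect_equal(attr(hit, "margin"), 0)
  expect_true(attr(hit, "ambiguous"))
})

test_that("full-length status needs every cluster on one strand", {
  model <- make_exon_clusters(sim_config(cluster_sizes = c(3, 4, 3),
                                         exon_length_range = c(100, 100),
                                         constitutive_length = 40, seed = 25))
  iso <- enumerate_isoforms(model)$isoform[5]
  perfect <- isoform_sequence(model, iso)
  asn <- assign_reads(perfect, model)
  expect_true(all(asn$full_length))
  expect_equal(asn$variant_id, split_isoform(iso)[[1]])

  # truncation before the last cluster loses full-length status
  truncated <- substr(perfect, 1, 240)
  asn_t <- assign_reads(truncated, model)
  expect_false(any(asn_t$full_length))
  expect_true(is.na(asn_t$variant_id[asn_t$cluster ==
                                       cluster_names(model)[3]]))

  # a strand-discordant read: last cluster region reverse-complemented
  parts <- split_isoform(iso)[[1]]
  seg <- model$segments
  cl3 <- model$clusters[[3]]
  disc <- paste0(
    seg[1], model$clusters[[1]]$sequence[match(parts[1], model$clusters[[1]]$variant_id)],
    seg[2], model$clusters[[2]]$sequence[match(parts[2], model$clusters[[2]]$variant_id)],
    seg[3], revcomp(cl3$sequence[match(parts[3], cl3$variant_id)]), seg[4]
  )
  asn_d <- assign_reads(disc, model)
  expect_false(any(asn_d$full_length))
  expect_false(any(asn_d$strand_concordant))
  expect_setequal(unique(asn_d$strand), c("+", "-"))
})

test_that("complement reads assign on the minus strand", {
  model <- make_exon_clusters(sim_config(cluster_sizes = c(3, 3),
                                         exon_length_range = c(90, 90),
                                         constitutive_length = 30, seed = 26))
  iso <- enumerate_isoforms(model)$isoform[1]
  asn <- assign_reads(revcomp(isoform_sequence(model, iso)), model)
  expect_true(all(asn$full_length))
  expect_true(all(asn$strand == "-"))
  expect_equal(asn$variant_id, split_isoform(iso)[[1]])
})

test_that("error-free reads always recover the true variant", {
  cfg <- sim_config(cluster_sizes = c(4, 5), exon_length_range = c(80, 100),
                    constitutive_length = 50, seed = 27,
                    error_2d = c(sub = 0, ins = 0, del = 0),
                    read_truncation_prob = 0, fraction_with_2d = 1)
  model <- make_exon_clusters(cfg)
  ab <- isoform_abundances(model, 10, cfg)
  sim <- simulate_reads(model, ab, 40, cfg)
  r2d <- dplyr::filter(sim$reads, read_class == "twodir")
  asn <- assign_reads(r2d, model)
  called <- asn |>
    dplyr::arrange(molecule_id, match(cluster, cluster_names(model))) |>
    dplyr::group_by(molecule_id) |>
    dplyr::summarise(isoform = paste(variant_id, collapse = ","))
  truth <- sim$ledger[match(called$molecule_id, sim$ledger$molecule_id), ]
  expect_equal(called$isoform, truth$isoform)
})

test_that("discriminability ranks self-alignment first at its own length", {
  cl <- make_cluster(5, 150, seed = 28)
  tab <- exon_discriminability(cl)
  firsts <- dplyr::filter(tab, rank == 1)
  expect_equal(firsts$other_id, firsts$variant_id)
  expect_true(all(firsts$score == 150))
  # ranks are non-increasing in score
  expect_true(all(
    dplyr::group_by(tab, variant_id) |>
      dplyr::summarise(ok = all(diff(score) <= 0)) |>
      dplyr::pull(ok)
  ))
})

test_that("unrelated exons are far more discriminable than 80%-identical ones", {
  set.seed(29)
  random_cl <- tibble::tibble(variant_id = c("r.1", "r.2"),
                              sequence = c(random_seq(300), random_seq(300)))
  tab <- exon_discriminability(random_cl)
  second <- dplyr::filter(tab, rank == 2)
  expect_true(all(300 - second$score > 0.5 * 300))

  # the default ~80%-identity regime still separates every variant
  sim_cl <- make_cluster(10, 300, seed = 30)
  tab80 <- exon_discriminability(sim_cl)
  margins <- tab80 |>
    dplyr::group_by(variant_id) |>
    dplyr::summarise(margin = score[rank == 1] - score[rank == 2])
  expect_true(all(margins$margin > 0))
})
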