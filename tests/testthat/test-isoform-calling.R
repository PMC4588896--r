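# hand-built assignment rows: one row per cluster for one read
asn_rows <- function(molecule, class, variants, margins = 5,
                     full_length = TRUE, read_id = NULL) {
  k <- length(variants)
  tibble::tibble(
    read_id = read_id %||% paste0(molecule, "_", class),
    molecule_id = molecule,
    read_class = class,
    cluster = paste0("c", seq_len(k)),
    variant_id = variants,
    score = 100,
    margin = rep_len(margins, k),
    strand = "+",
    ambiguous = rep_len(margins, k) == 0,
    full_length = full_length
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("a usable 2D read takes precedence over the 1D pair", {
  asn <- dplyr::bind_rows(
    asn_rows("m1", "template", c("c1.1", "c2.2", "c3.3")),
    asn_rows("m1", "complement", c("c1.1", "c2.2", "c3.5")), # disagrees
    asn_rows("m1", "twodir", c("c1.1", "c2.12", "c3.30"))
  )
  calls <- call_isoforms(asn)
  expect_equal(as.character(calls$status), "accepted_2d")
  expect_equal(calls$isoform, "c1.1,c2.12,c3.30")
})

test_that("an agreeing template/complement pair is called without a 2D read", {
  asn <- dplyr::bind_rows(
    asn_rows("m1", "template", c("c1.1", "c2.2")),
    asn_rows("m1", "complement", c("c1.1", "c2.2"))
  )
  calls <- call_isoforms(asn)
  expect_equal(as.character(calls$status), "accepted_1d_pair")
  expect_equal(calls$isoform, "c1.1,c2.2")
})

test_that("disagreeing pairs, lone 1D reads and partial reads are rejected", {
  asn <- dplyr::bind_rows(
    asn_rows("m1", "template", c("c1.1", "c2.2", "c3.3")),
    asn_rows("m1", "complement", c("c1.1", "c2.2", "c3.5")),
    asn_rows("m2", "template", c("c1.1", "c2.2", "c3.3")),
    asn_rows("m3", "template", c("c1.1", "c2.2", NA), full_length = FALSE),
    asn_rows("m4", "template", c(NA, NA, NA), full_length = FALSE),
    asn_rows("m4", "complement", c(NA, NA, NA), full_length = FALSE)
  )
  calls <- call_isoforms(asn)
  got <- setNames(as.character(calls$status), calls$molecule_id)
  expect_equal(got[["m1"]], "rejected_discordant_pair")
  expect_equal(got[["m2"]], "rejected_single_1d")
  expect_equal(got[["m3"]], "rejected_partial")
  expect_equal(got[["m4"]], "rejected_unaligned")
  expect_true(all(is.na(calls$isoform)))
})

test_that("ambiguous (margin-zero) clusters block acceptance", {
  asn <- asn_rows("m1", "twodir", c("c1.1", "c2.2"), margins = c(5, 0))
  calls <- call_isoforms(asn)
  expect_equal(as.character(calls$status), "rejected_partial")
})

test_that("duplicate read classes within a molecule are an error", {
  asn <- dplyr::bind_rows(
    asn_rows("m1", "twodir", c("c1.1", "c2.2"), read_id = "r1"),
    asn_rows("m1", "twodir", c("c1.1", "c2.3"), read_id = "r2")
  )
  expect_error(call_isoforms(asn), "duplicate")
})

test_that("every molecule gets exactly one status on simulated data", {
  cfg <- sim_config(cluster_sizes = c(3, 4), exon_length_range = c(90, 110),
                    constitutive_length = 40, seed = 31,
                    read_truncation_prob = 0.3)
  model <- make_exon_clusters(cfg)
  ab <- isoform_abundances(model, 8, cfg)
  sim <- simulate_reads(model, ab, 60, cfg)
  calls <- call_isoforms(assign_reads(sim$reads, model))
  expect_setequal(calls$molecule_id, sim$ledger$molecule_id)
  expect_false(any(is.na(calls$status)))
  expect_equal(sum(table(calls$status)), nrow(sim$ledger))
  # isoform present iff accepted
  expect_equal(is.na(calls$isoform),
               !startsWith(as.character(calls$status), "accepted"))
})

test_that("tabulation counts accepted calls and singletons", {
  tab <- tabulate_isoforms(c("A", "A", "B"))
  expect_equal(tab$isoform, c("A", "B"))
  expect_equal(tab$count, c(2, 1))
  expect_equal(tab$frequency, c(2 / 3, 1 / 3))
  expect_equal(glance(tab)$singletons, 1)
  expect_equal(glance(tab)$multiples, 1)

  empty <- tabulate_isoforms(character())
  expect_equal(nrow(empty), 0)
  expect_equal(glance(empty)$n_reads, 0)
})

test_that("zero-error simulation tabulates exactly as the ledger", {
  cfg <- sim_config(cluster_sizes = c(3, 3), exon_length_range = c(80, 80),
                    constitutive_length = 40, seed = 32,
                    error_2d = c(sub = 0, ins = 0, del = 0),
                    error_1d = c(sub = 0, ins = 0, del = 0),
                    read_truncation_prob = 0, fraction_with_2d = 1)
  model <- make_exon_clusters(cfg)
  ab <- isoform_abundances(model, 6, cfg)
  sim <- simulate_reads(model, ab, 50, cfg)
  calls <- call_isoforms(assign_reads(sim$reads, model))
  expect_true(all(startsWith(as.character(calls$status), "accepted")))
  tab <- tabulate_isoforms(calls)
  truth_tab <- tabulate_isoforms(sim$ledger$isoform)
  expect_equal(tidy(tab), tidy(truth_tab))
})

test_that("cluster marginals are read-weighted and sum to one", {
  tab <- tabulate_isoforms(c("x.1,y.1", "x.1,y.2", "x.1,y.2", "x.2,y.1"))
  marg <- cluster_marginals(tab)
  x <- dplyr::filter(marg, cluster == "x")
  expect_equal(sum(x$frequency), 1)
  expect_equal(x$frequency[x$variant_id == "x.1"], 3 / 4)
  y <- dplyr::filter(marg, cluster == "y")
  expect_equal(sum(y$frequency), 1)
})

test_that("cumulative distribution is nondecreasing and ends at one", {
  tab <- tabulate_isoforms(c("A", "A", "A", "B"))
  cd <- cumulative_isoform_distribution(tab)
  expect_equal(cd$cumulative, c(0.75, 1))
  uniform <- tabulate_isoforms(rep(letters[1:4], each = 2))
  cdu <- cumulative_isoform_distribution(uniform)
  expect_equal(cdu$cumulative, (1:4) / 4)
  expect_error(cumulative_isoform_distribution(tabulate_isoforms(character())),
               "empty")
})
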