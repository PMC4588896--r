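#' Simulation configuration
#'
#' One object holds every knob of the synthetic-data generator. The
#' defaults emulate a Dscam1-like exon 3-10 amplicon experiment: three
#' clusters of 12/48/33 mutually exclusive exons whose variants are ~80%
#' identical to one another, 2D consensus reads at ~90% identity with the
#' 1D strand reads noisier, and a controllable fraction of single-crossover
#' template-switch chimeras.
#'
#' @param cluster_sizes Variants per cluster (default `c(12, 48, 33)`).
#' @param cluster_names Cluster names (default `"4", "6", "9"` for the
#'   default sizes, else `"c1"`, `"c2"`, ...).
#' @param exon_length_range Variable-exon length range in bases (default
#'   110-140; one length is drawn per cluster and shared by its variants).
#' @param target_pairwise_identity Mean pairwise identity of variants
#'   within a cluster (default 0.80).
#' @param constitutive_length Length of each constitutive segment
#'   (default 90).
#' @param abundance_model `"log_skewed"` (default; reproduces the
#'   singleton-heavy regime of real libraries) or `"uniform"`.
#' @param abundance_shape sdlog of the log-normal skew (default 1.5).
#' @param error_2d,error_1d Per-base (substitution, insertion, deletion)
#'   rates for 2D and 1D reads. Defaults `c(0.06, 0.02, 0.02)` (2D, ~90%
#'   read identity) and `c(0.09, 0.03, 0.03)` (1D).
#' @param read_truncation_prob Probability a read is truncated
#'   (default 0.05).
#' @param switch_rate Fraction of molecules replaced by single-crossover
#'   template-switch chimeras (default 0).
#' @param fraction_with_2d Probability a molecule's strand pair yields a
#'   2D consensus read (default 0.43).
#' @param seed Integer seed; mandatory, all generator output is
#'   deterministic given the config.
#' @return A `sim_config` list.
#' @export
sim_config <- function(cluster_sizes = c(12, 48, 33),
                       cluster_names = NULL,
                       exon_length_range = c(110, 140),
                       target_pairwise_identity = 0.80,
                       constitutive_length = 90,
                       abundance_model = c("log_skewed", "uniform"),
                       abundance_shape = 1.5,
                       error_2d = c(sub = 0.06, ins = 0.02, del = 0.02),
                       error_1d = c(sub = 0.09, ins = 0.03, del = 0.03),
                       read_truncation_prob = 0.05,
                       switch_rate = 0,
                       fraction_with_2d = 0.43,
                       seed) {
  if (missing(seed)) abort("`seed` is mandatory: simulations must be reproducible")
  abundance_model <- match.arg(abundance_model)
  if (any(cluster_sizes < 1) || any(cluster_sizes != floor(cluster_sizes))) {
    abort("`cluster_sizes` must be positive integers")
  }
  if (is.null(cluster_names)) {
    cluster_names <- if (identical(as.integer(cluster_sizes),
                                   c(12L, 48L, 33L))) {
      c("4", "6", "9")
    } else {
      paste0("c", seq_along(cluster_sizes))
    }
  }
  if (length(cluster_names) != length(cluster_sizes)) {
    abort("`cluster_names` must match `cluster_sizes` in length")
  }
  rates <- c(error_2d, error_1d, read_truncation_prob, switch_rate,
             fraction_with_2d)
  if (any(rates < 0) || any(rates > 1)) {
    abort("all rates must lie in [0, 1]")
  }
  if (length(error_2d) != 3 || length(error_1d) != 3) {
    abort("error rates must be length-3: (substitution, insertion, deletion)")
  }
  structure(
    list(
      cluster_sizes = as.integer(cluster_sizes),
      cluster_names = as.character(cluster_names),
      exon_length_range = exon_length_range,
      target_pairwise_identity = target_pairwise_identity,
      constitutive_length = as.integer(constitutive_length),
      abundance_model = abundance_model,
      abundance_shape = abundance_shape,
      error_2d = setNames(as.numeric(error_2d), c("sub", "ins", "del")),
      error_1d = setNames(as.numeric(error_1d), c("sub", "ins", "del")),
      read_truncation_prob = read_truncation_prob,
      switch_rate = switch_rate,
      fraction_with_2d = fraction_with_2d,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# per-base substitution probability giving a target expected pairwise
# identity between two independently mutated copies of one ancestor:
# identity(p) = (1 - p)^2 + p^2 / 3
divergence_for_identity <- function(target) {
  if (target > 1 || target < 0.25) {
    abort("`target_pairwise_identity` must lie in [0.25, 1]")
  }
  (2 - sqrt(4 - 16 / 3 * (1 - target))) / (8 / 3)
}

# substitute each base independently with probability p (to a different base)
mutate_bases <- function(chars, p) {
  hit <- runif(length(chars)) < p
  if (any(hit)) {
    code <- match(chars[hit], DNA_BASES)
    chars[hit] <- DNA_BASES[1 + (code - 1 + sample(1:3, sum(hit),
                                                   replace = TRUE)) %% 4]
  }
  chars
}

#' Generate a gene model with mutually exclusive exon clusters
#'
#' Each cluster's variants are independently mutated copies of a random
#' cluster ancestor, with the per-base divergence chosen so the expected
#' mean pairwise identity equals `target_pairwise_identity`. Constitutive
#' segments are random sequence. Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return A [gene_model()].
#' @export
#' @examples
#' model <- make_exon_clusters(sim_config(cluster_sizes = c(2, 3), seed = 1))
#' cluster_sizes(model)
make_exon_clusters <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  p <- divergence_for_identity(config$target_pairwise_identity)
  if (config$target_pairwise_identity == 1) {
    warn("target identity 1: all variants within each cluster are identical (degenerate)")
  }
  with_seed(config$seed, {
    nc <- length(config$cluster_sizes)
    clusters <- lapply(seq_len(nc), function(k) {
      nm <- config$cluster_names[k]
      lens <- seq(config$exon_length_range[1], config$exon_length_range[2])
      len <- lens[sample.int(length(lens), 1)]
      ancestor <- strsplit(random_dna(1, len), "")[[1]]
      tibble(
        variant_id = paste0(nm, ".", seq_len(config$cluster_sizes[k])),
        sequence = vapply(seq_len(config$cluster_sizes[k]), function(i) {
          paste(mutate_bases(ancestor, p), collapse = "")
        }, character(1))
      )
    })
    names(clusters) <- config$cluster_names
    segments <- setNames(
      random_dna(nc + 1, config$constitutive_length),
      paste0("s", seq_len(nc + 1))
    )
    gene_model("simulated_gene", segments = segments, clusters = clusters)
  })
}

#' Mean pairwise identity of variants within each cluster
#'
#' Aligns all variant pairs within each cluster and averages the percent
#' identity of the local alignments — the realized counterpart of
#' `target_pairwise_identity`.
#'
#' @param model A [gene_model()].
#' @param scheme A [scoring_scheme()].
#' @return A tibble `cluster`, `n_pairs`, `mean_identity`.
#' @export
cluster_identity <- function(model, scheme = scoring_scheme()) {
  bind_rows(lapply(names(model$clusters), function(nm) {
    cl <- model$clusters[[nm]]
    if (nrow(cl) < 2) {
      return(tibble(cluster = nm, n_pairs = 0L, mean_identity = NA_real_))
    }
    pairs <- utils::combn(nrow(cl), 2)
    aln <- align_local(cl$sequence[pairs[1, ]], cl$sequence[pairs[2, ]],
                       scheme)
    tibble(cluster = nm, n_pairs = ncol(pairs),
           mean_identity = mean(aln$identity))
  }))
}

#' Draw an isoform abundance distribution
#'
#' Samples `n_isoforms` distinct isoforms from the model's space and
#' assigns them abundances: uniform, or log-normal ("log-skewed", the
#' default) so a few isoforms dominate and many are rare.
#'
#' @param model A [gene_model()].
#' @param n_isoforms Number of distinct isoforms in the pool.
#' @param config A [sim_config()] (supplies the abundance model, shape
#'   and seed).
#' @return A tibble `isoform`, `abundance` (summing to 1).
#' @export
isoform_abundances <- function(model, n_isoforms, config) {
  space <- enumerate_isoforms(model)
  if (n_isoforms > nrow(space)) {
    abort(sprintf("`n_isoforms` (%d) exceeds the isoform space (%d)",
                  n_isoforms, nrow(space)))
  }
  with_seed(seed_offset(config$seed, 1L), {
    iso <- sample(space$isoform, n_isoforms)
    w <- switch(config$abundance_model,
      uniform = rep(1, n_isoforms),
      log_skewed = rlnorm(n_isoforms, meanlog = 0,
                          sdlog = config$abundance_shape)
    )
    tibble(isoform = iso, abundance = w / sum(w))
  })
}

# apply per-base iid substitution/insertion/deletion errors to sequences;
# returns list(sequence, n_sub, n_ins, n_del)
apply_read_errors <- function(seqs, rates) {
  if (length(seqs) == 0) {
    return(list(sequence = character(), n_sub = integer(),
                n_ins = integer(), n_del = integer()))
  }
  chars <- strsplit(seqs, "", fixed = TRUE)
  lens <- lengths(chars)
  flat <- unlist(chars, use.names = FALSE)
  read_of <- rep(seq_along(seqs), lens)
  nb <- length(flat)

  del <- runif(nb) < rates[["del"]]
  sub <- !del & runif(nb) < rates[["sub"]]
  ins <- runif(nb) < rates[["ins"]]

  if (any(sub)) {
    code <- match(flat[sub], DNA_BASES)
    flat[sub] <- DNA_BASES[1 + (code - 1 + sample(1:3, sum(sub),
                                                  replace = TRUE)) %% 4]
  }
  ins_base <- character(nb)
  if (any(ins)) {
    ins_base[ins] <- sample(DNA_BASES, sum(ins), replace = TRUE)
  }

  # interleave kept bases and insertions in original order: the kept copy
  # of base i sorts at 2i, an insertion after base i at 2i + 1
  idx_keep <- which(!del)
  idx_ins <- which(ins)
  order_key <- c(2 * idx_keep, 2 * idx_ins + 1)
  pieces <- c(flat[idx_keep], ins_base[idx_ins])
  piece_read <- c(read_of[idx_keep], read_of[idx_ins])
  o <- order(piece_read, order_key)
  pieces <- pieces[o]
  piece_read <- piece_read[o]
  sequence <- vapply(split(pieces, factor(piece_read,
                                          levels = seq_along(seqs))),
                     paste, character(1), collapse = "")
  list(
    sequence = unname(sequence),
    n_sub = as.integer(rowsum_by(as.integer(sub), read_of, length(seqs))),
    n_ins = as.integer(rowsum_by(as.integer(ins), read_of, length(seqs))),
    n_del = as.integer(rowsum_by(as.integer(del), read_of, length(seqs)))
  )
}

rowsum_by <- function(x, g, n) {
  out <- numeric(n)
  s <- rowsum(x, g)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# truncate a fraction of reads: keep a random 20-90% window anchored at a
# random end (5' or 3'), emulating incomplete molecules/pore dropouts
truncate_reads <- function(seqs, prob) {
  n <- length(seqs)
  hit <- runif(n) < prob
  if (any(hit)) {
    lens <- nchar(seqs[hit])
    keep <- pmax(1L, as.integer(round(lens * runif(sum(hit), 0.2, 0.9))))
    from_start <- runif(sum(hit)) < 0.5
    seqs[hit] <- ifelse(
      from_start,
      substring(seqs[hit], 1, keep),
      substring(seqs[hit], lens - keep + 1, lens)
    )
  }
  list(sequence = seqs, truncated = hit)
}

#' Simulate long reads with template/complement/2D structure
#'
#' Per molecule: an isoform is drawn from `abundances`; with probability
#' `switch_rate` it is replaced by a single-crossover template-switch
#' chimera of two distinct isoforms drawn from the same pool (crossover
#' position uniform over the inter-cluster intervals). The molecule then
#' emits a template read (forward strand, 1D errors) and a complement
#' read (reverse complement, 1D errors), and with probability
#' `fraction_with_2d` also a 2D consensus read (forward, 2D errors).
#' Truncation applies independently per read. The ledger records the
#' ground truth for every molecule.
#'
#' Read ids follow the `<molecule>_t` / `_c` / `_2d` dialect used
#' throughout the package.
#'
#' @param model A [gene_model()].
#' @param abundances Tibble `isoform`, `abundance` (see
#'   [isoform_abundances()]).
#' @param n_molecules Number of molecules to simulate.
#' @param config A [sim_config()].
#' @return A list of class `sim_reads`: `reads` (tibble `read_id`,
#'   `molecule_id`, `read_class`, `sequence`, `n_sub`, `n_ins`, `n_del`,
#'   `truncated`) and `ledger` (tibble `molecule_id`, `isoform`,
#'   `chimeric`, `parent_a`, `parent_b`, `crossover`, `has_2d`).
#' @export
simulate_reads <- function(model, abundances, n_molecules, config) {
  stopifnot(inherits(model, "gene_model"), inherits(config, "sim_config"))
  if (n_molecules < 1) abort("`n_molecules` must be >= 1")
  abundances <- as_tibble(abundances)
  if (abs(sum(abundances$abundance) - 1) > 1e-8) {
    abort("`abundances` must sum to 1")
  }
  check_isoforms(model, abundances$isoform)
  nc <- length(model$clusters)

  with_seed(seed_offset(config$seed, 2L), {
    iso <- sample(abundances$isoform, n_molecules, replace = TRUE,
                  prob = abundances$abundance)
    chim <- runif(n_molecules) < config$switch_rate &
      nrow(abundances) >= 2 & nc >= 2
    parent_a <- rep(NA_character_, n_molecules)
    parent_b <- rep(NA_character_, n_molecules)
    crossover <- rep(NA_integer_, n_molecules)
    if (any(chim)) {
      for (i in which(chim)) {
        pair <- sample(abundances$isoform, 2, replace = FALSE,
                       prob = abundances$abundance)
        k <- sample.int(nc - 1, 1)
        pa <- split_isoform(pair[1])[[1]]
        pb <- split_isoform(pair[2])[[1]]
        iso[i] <- isoform_id(c(pa[seq_len(k)], pb[(k + 1):nc]))
        parent_a[i] <- pair[1]
        parent_b[i] <- pair[2]
        crossover[i] <- k
      }
    }
    molecule_id <- sprintf("mol%06d", seq_len(n_molecules))
    truth_seq <- isoform_sequence(model, iso)
    has_2d <- runif(n_molecules) < config$fraction_with_2d

    emit <- function(idx, source_seq, class, rates) {
      res <- apply_read_errors(source_seq, rates)
      tr <- truncate_reads(res$sequence, config$read_truncation_prob)
      tag <- c(template = "t", complement = "c", twodir = "2d")[[class]]
      tibble(
        read_id = paste0(molecule_id[idx], "_", tag),
        molecule_id = molecule_id[idx],
        read_class = class,
        sequence = tr$sequence,
        n_sub = res$n_sub, n_ins = res$n_ins, n_del = res$n_del,
        truncated = tr$truncated
      )
    }
    reads <- bind_rows(
      emit(seq_len(n_molecules), truth_seq, "template", config$error_1d),
      emit(seq_len(n_molecules), revcomp(truth_seq), "complement",
           config$error_1d),
      if (any(has_2d)) {
        emit(which(has_2d), truth_seq[has_2d], "twodir", config$error_2d)
      }
    )
    reads <- arrange(reads, .data$molecule_id, .data$read_class)
    ledger <- tibble(
      molecule_id = molecule_id, isoform = iso, chimeric = chim,
      parent_a = parent_a, parent_b = parent_b, crossover = crossover,
      has_2d = has_2d
    )
    structure(list(reads = reads, ledger = ledger, config = config),
              class = "sim_reads")
  })
}

#' @export
print.sim_reads <- function(x, ...) {
  cat(sprintf(
    "<sim_reads> %d molecules, %d reads (%s), %d chimeric\n",
    nrow(x$ledger), nrow(x$reads),
    paste(sprintf("%s:%d", names(table(x$reads$read_class)),
                  as.integer(table(x$reads$read_class))), collapse = ", "),
    sum(x$ledger$chimeric)
  ))
  invisible(x)
}

#' Simulate short amplicon reads for one cluster
#'
#' Each read is the primer followed by the leading bases of a variant
#' drawn from `mixture`, with substitution errors applied to the
#' variant-derived portion (the primer is emitted intact; primer-filter
#' behaviour is exercised separately). The ledger records the true
#' variant of every read.
#'
#' @param model A [gene_model()].
#' @param cluster Cluster name.
#' @param mixture Tibble `variant_id`, `proportion` summing to 1 (or a
#'   named numeric vector).
#' @param n Number of reads.
#' @param read_length Total read length including the primer (default 75).
#' @param primer Primer sequence (default: a fixed random 20-mer drawn
#'   from the config seed).
#' @param error Per-base substitution rate on the variant portion
#'   (default 0.01).
#' @param config A [sim_config()] (seed source).
#' @return List of class `sim_short_reads`: `reads` (tibble `read_id`,
#'   `sequence`), `primer`, `ledger` (tibble `read_id`, `variant_id`).
#' @export
simulate_short_reads <- function(model, cluster, mixture, n,
                                 read_length = 75, primer = NULL,
                                 error = 0.01, config) {
  stopifnot(inherits(model, "gene_model"))
  cl <- model$clusters[[cluster]]
  if (is.null(cl)) abort(sprintf("unknown cluster '%s'", cluster))
  if (is.numeric(mixture)) {
    mixture <- tibble(variant_id = names(mixture),
                      proportion = unname(mixture))
  }
  mixture <- as_tibble(mixture)
  if (abs(sum(mixture$proportion) - 1) > 1e-8) {
    abort("`mixture` proportions must sum to 1")
  }
  bad <- setdiff(mixture$variant_id, cl$variant_id)
  if (length(bad)) {
    abort(sprintf("unknown variant id(s) for cluster '%s': %s",
                  cluster, paste(bad, collapse = ", ")))
  }
  with_seed(seed_offset(config$seed, 3L), {
    if (is.null(primer)) primer <- random_dna(1, 20)
    primer <- check_dna(primer, "primer")
    if (read_length <= nchar(primer)) {
      abort("`read_length` must exceed the primer length")
    }
    if (n == 0) {
      return(structure(
        list(reads = tibble(read_id = character(), sequence = character()),
             primer = primer,
             ledger = tibble(read_id = character(), variant_id = character())),
        class = "sim_short_reads"
      ))
    }
    picked <- sample(mixture$variant_id, n, replace = TRUE,
                     prob = mixture$proportion)
    insert_len <- read_length - nchar(primer)
    inserts <- substring(cl$sequence[match(picked, cl$variant_id)],
                         1, insert_len)
    if (error > 0) {
      inserts <- apply_read_errors(inserts,
                                   c(sub = error, ins = 0, del = 0))$sequence
    }
    read_id <- sprintf("sr%06d", seq_len(n))
    structure(
      list(
        reads = tibble(read_id = read_id,
                       sequence = paste0(primer, inserts)),
        primer = primer,
        ledger = tibble(read_id = read_id, variant_id = picked)
      ),
      class = "sim_short_reads"
    )
  })
}
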