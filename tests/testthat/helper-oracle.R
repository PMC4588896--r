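# Independent local-alignment oracle for short sequences.
#
# A local alignment is determined by a monotone chain of aligned column
# pairs (i, j): aligned columns score +match / -mismatch by equality, and
# the unaligned residues between consecutive chain links must be gapped,
# a run of k residues costing gap_open + k * gap_extend. Residues outside
# the chain's span are free (local alignment). The best local score is
# the maximum over all chains (the empty chain scoring 0). This maximizes
# over exactly the space of local alignments but shares none of the
# affine-gap state machinery of the production DP.
oracle_local_score <- function(q, t, match = 1, mismatch = 1,
                               gap_open = 1, gap_extend = 1) {
  qc <- strsplit(q, "")[[1]]
  tc <- strsplit(t, "")[[1]]
  m <- length(qc)
  n <- length(tc)
  gap <- function(k) ifelse(k > 0, gap_open + k * gap_extend, 0)
  # best[i, j]: best score of a chain ending with aligned pair (i, j)
  best <- matrix(-Inf, m, n)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      s <- if (qc[i] == tc[j]) match else -mismatch
      prev <- 0
      if (i > 1 && j > 1) {
        pi <- seq_len(i - 1)
        pj <- seq_len(j - 1)
        cand <- best[pi, pj, drop = FALSE] -
          outer(gap(i - pi - 1), gap(j - pj - 1), `+`)
        prev <- max(0, cand)
      }
      best[i, j] <- s + prev
    }
  }
  max(0, best)
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# tiny two-cluster model used across tests
toy_model <- function() {
  gene_model(
    "toy",
    segments = c(s1 = "AAAA", s2 = "TTTT", s3 = "GGGG"),
    clusters = list(
      x = tibble::tibble(variant_id = c("x.1", "x.2"),
                         sequence = c("CCCCCCCC", "GGGGGGGG")),
      y = tibble::tibble(variant_id = c("y.1", "y.2", "y.3"),
                         sequence = c("ACACACAC", "TGTGTGTG", "AATTAATT"))
    )
  )
}
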