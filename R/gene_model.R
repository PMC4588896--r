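#' Gene models with mutually exclusive exon clusters
#'
#' A gene model is an ordered alternation of constitutive segments and
#' clusters of mutually exclusive exon variants, beginning and ending with a
#' constitutive segment. Every mature isoform contains all constitutive
#' segments and exactly one variant from each cluster, so a model with
#' cluster sizes \eqn{k_1, \dots, k_c} defines \eqn{\prod_i k_i} possible
#' isoforms. This mirrors genes such as Drosophila Dscam1, whose exon 4, 6,
#' and 9 clusters hold 12, 48, and 33 variants.
#'
#' Variant identifiers follow the `"<cluster>.<index>"` convention (e.g.
#' `"6.32"` for variant 32 of cluster 6), so an isoform is written as the
#' comma-joined tuple of its variant ids, e.g. `"4.2,6.32,9.31"`.
#'
#' @param gene Gene name.
#' @param segments Named character vector of constitutive segment sequences,
#'   in layout order. There must be one more segment than clusters.
#' @param clusters Named list of cluster tibbles/data frames with columns
#'   `variant_id` and `sequence`, in layout order. Variant ids must be
#'   prefixed with the cluster name followed by a dot.
#' @return An object of class `gene_model`.
#' @export
#' @examples
#' m <- gene_model(
#'   "toy",
#'   segments = c(s1 = "AA", s2 = "TT"),
#'   clusters = list(x = data.frame(
#'     variant_id = c("x.1", "x.2"), sequence = c("CC", "GG")
#'   ))
#' )
#' isoform_space_size(m)
gene_model <- function(gene, segments, clusters) {
  if (!is.character(gene) || length(gene) != 1 || !nzchar(gene)) {
    abort("`gene` must be a single nonempty string")
  }
  if (is.null(names(segments)) || any(!nzchar(names(segments)))) {
    abort("constitutive segments must be named")
  }
  if (is.null(names(clusters)) || any(!nzchar(names(clusters)))) {
    abort("clusters must be named")
  }
  if (length(segments) != length(clusters) + 1) {
    abort(paste0(
      "the layout must alternate segment/cluster and begin and end with a ",
      "constitutive segment: expected ", length(clusters) + 1,
      " segments for ", length(clusters), " cluster(s), got ", length(segments)
    ))
  }
  if (anyDuplicated(names(clusters))) {
    abort("cluster names must be distinct")
  }
  if (anyDuplicated(names(segments))) {
    abort("segment names must be distinct")
  }
  segments <- setNames(check_dna(unname(segments), "constitutive segment"),
                       names(segments))
  clusters <- lapply(setNames(names(clusters), names(clusters)), function(nm) {
    cl <- as_tibble(clusters[[nm]])
    if (!all(c("variant_id", "sequence") %in% names(cl)) || nrow(cl) < 1) {
      abort(sprintf(
        "cluster '%s' must have >= 1 row and columns variant_id, sequence", nm
      ))
    }
    if (anyDuplicated(cl$variant_id)) {
      dup <- unique(cl$variant_id[duplicated(cl$variant_id)])
      abort(sprintf("duplicate variant id(s) in cluster '%s': %s",
                    nm, paste(dup, collapse = ", ")))
    }
    ok <- startsWith(cl$variant_id, paste0(nm, ".")) &
      nchar(cl$variant_id) > nchar(nm) + 1 & !grepl(",", cl$variant_id)
    if (!all(ok)) {
      abort(sprintf(
        "variant ids in cluster '%s' must look like '%s.<index>': %s",
        nm, nm, paste(cl$variant_id[!ok], collapse = ", ")
      ))
    }
    cl$sequence <- check_dna(cl$sequence,
                             sprintf("cluster '%s' variant sequence", nm))
    cl$length <- nchar(cl$sequence)
    cl[c("variant_id", "sequence", "length")]
  })
  structure(
    list(gene = gene, segments = segments, clusters = clusters),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  sizes <- vapply(x$clusters, nrow, integer(1))
  cat(sprintf(
    "<gene_model> %s: %d cluster(s) [%s], %s possible isoforms\n",
    x$gene, length(x$clusters),
    paste(sprintf("%s:%d", names(sizes), sizes), collapse = ", "),
    format(prod(sizes), big.mark = ",")
  ))
  invisible(x)
}

#' @rdname gene_model
#' @param model,x A `gene_model`.
#' @export
cluster_names <- function(model) names(model$clusters)

#' @rdname gene_model
#' @export
cluster_sizes <- function(model) {
  vapply(model$clusters, nrow, integer(1))
}

# cluster a variant id belongs to, by the "<cluster>.<index>" convention
variant_cluster <- function(variant_id) {
  sub("\\.[^.]*$", "", variant_id)
}

#' @exportS3Method
tidy.gene_model <- function(x, ...) {
  bind_rows(lapply(names(x$clusters), function(nm) {
    mutate(x$clusters[[nm]], cluster = nm, .before = 1)
  }))
}

#' @exportS3Method
glance.gene_model <- function(x, ...) {
  tibble(
    gene = x$gene,
    n_clusters = length(x$clusters),
    n_variants = sum(cluster_sizes(x)),
    n_isoforms = prod(cluster_sizes(x))
  )
}

# resolve per-cluster allowed variant subsets, honouring `allowed`
# (named list of variant ids) and `exclude` (variant ids to drop)
resolve_allowed <- function(model, allowed = NULL, exclude = NULL) {
  out <- lapply(model$clusters, function(cl) cl$variant_id)
  if (!is.null(allowed)) {
    if (is.null(names(allowed)) ||
        !all(names(allowed) %in% names(out))) {
      abort("`allowed` must be a named list keyed by cluster name")
    }
    for (nm in names(allowed)) {
      sub <- allowed[[nm]]
      bad <- setdiff(sub, out[[nm]])
      if (length(bad)) {
        abort(sprintf("unknown variant id(s) for cluster '%s': %s",
                      nm, paste(bad, collapse = ", ")))
      }
      out[[nm]] <- intersect(out[[nm]], sub)
    }
  }
  if (!is.null(exclude)) {
    all_ids <- unlist(out, use.names = FALSE)
    bad <- setdiff(exclude, unlist(lapply(model$clusters, `[[`, "variant_id")))
    if (length(bad)) {
      abort(sprintf("unknown variant id(s) in `exclude`: %s",
                    paste(bad, collapse = ", ")))
    }
    out <- lapply(out, setdiff, y = exclude)
  }
  empty <- names(out)[lengths(out) == 0]
  if (length(empty)) {
    abort(sprintf("no variants left for cluster(s): %s",
                  paste(empty, collapse = ", ")))
  }
  out
}

#' Size of the combinatorial isoform space
#'
#' The number of distinct isoforms a model can generate: the product of the
#' per-cluster variant counts. Accepts either a `gene_model` (optionally
#' restricted with `allowed`/`exclude`) or a bare vector of cluster sizes.
#'
#' @param x A `gene_model` or a numeric vector of cluster sizes.
#' @param allowed Optional named list of per-cluster variant id subsets.
#' @param exclude Optional variant ids to exclude (their cluster is inferred
#'   from the id).
#' @return A single number.
#' @export
#' @examples
#' isoform_space_size(c(12, 48, 33, 2)) # 38016
isoform_space_size <- function(x, allowed = NULL, exclude = NULL) {
  if (is.numeric(x)) {
    if (length(x) == 0 || any(x < 1) || any(x != floor(x))) {
      abort("cluster sizes must be positive integers")
    }
    return(prod(x))
  }
  stopifnot(inherits(x, "gene_model"))
  prod(lengths(resolve_allowed(x, allowed, exclude)))
}

#' Enumerate the isoform space
#'
#' Yields every isoform id exactly once, in lexicographic cluster order (the
#' first cluster varies slowest). Each isoform is the comma-joined tuple of
#' one variant id per cluster.
#'
#' @inheritParams isoform_space_size
#' @param model A `gene_model`.
#' @return A tibble with one column per cluster plus an `isoform` id column.
#' @export
enumerate_isoforms <- function(model, allowed = NULL, exclude = NULL) {
  stopifnot(inherits(model, "gene_model"))
  allowed <- resolve_allowed(model, allowed, exclude)
  grid <- tidyr::expand_grid(!!!allowed)
  grid$isoform <- do.call(paste, c(unname(as.list(grid)), sep = ","))
  grid
}

#' Compose and split isoform identifiers
#'
#' @param variant_ids Character vector of variant ids, one per cluster, in
#'   cluster order.
#' @return `isoform_id()` returns the comma-joined id; `split_isoform()`
#'   returns a list of per-cluster variant id vectors.
#' @export
isoform_id <- function(variant_ids) paste(variant_ids, collapse = ",")

#' @rdname isoform_id
#' @param isoform Character vector of isoform ids.
#' @export
split_isoform <- function(isoform) strsplit(isoform, ",", fixed = TRUE)

# validate isoform ids against a model; returns a matrix of variant ids
# (rows = isoforms, cols = clusters)
check_isoforms <- function(model, isoform) {
  parts <- split_isoform(isoform)
  nc <- length(model$clusters)
  bad_arity <- lengths(parts) != nc
  if (any(bad_arity)) {
    abort(sprintf(
      "isoform id(s) with wrong arity (expected %d variant ids): %s",
      nc, paste(isoform[bad_arity], collapse = "; ")
    ))
  }
  m <- matrix(unlist(parts), ncol = nc, byrow = TRUE)
  for (k in seq_len(nc)) {
    nm <- names(model$clusters)[k]
    bad <- setdiff(unique(m[, k]), model$clusters[[nm]]$variant_id)
    if (length(bad)) {
      abort(sprintf("unknown variant id(s) for cluster '%s': %s",
                    nm, paste(bad, collapse = ", ")))
    }
  }
  m
}

#' Realize an isoform as its mRNA sequence
#'
#' Concatenates the constitutive segments with the chosen variant of each
#' cluster, in layout order.
#'
#' @param model A `gene_model`.
#' @param isoform Character vector of isoform ids (see [isoform_id()]).
#' @return Character vector of sequences, one per isoform.
#' @export
isoform_sequence <- function(model, isoform) {
  stopifnot(inherits(model, "gene_model"))
  m <- check_isoforms(model, isoform)
  nc <- length(model$clusters)
  seqs <- lapply(seq_len(nc), function(k) {
    cl <- model$clusters[[k]]
    cl$sequence[match(m[, k], cl$variant_id)]
  })
  pieces <- vector("list", 2 * nc + 1)
  for (k in seq_len(nc)) {
    pieces[[2 * k - 1]] <- model$segments[[k]]
    pieces[[2 * k]] <- seqs[[k]]
  }
  pieces[[2 * nc + 1]] <- model$segments[[nc + 1]]
  do.call(paste0, pieces)
}

#' Read and write gene models on disk
#'
#' A model is stored as one FASTA per cluster (`cluster_<name>.fasta`,
#' headers = variant ids), a `constitutive.fasta` (headers = segment names),
#' and a tab-separated `layout.tsv` listing the ordered alternation of
#' segments and clusters. `read_gene_model()` round-trips with
#' [write_gene_model()].
#'
#' @param dir Directory holding (or to receive) the model files.
#' @return `read_gene_model()` returns a `gene_model`;
#'   `write_gene_model()` returns `dir` invisibly.
#' @export
read_gene_model <- function(dir) {
  layout_path <- file.path(dir, "layout.tsv")
  if (!file.exists(layout_path)) {
    abort(sprintf("layout file not found: %s", layout_path))
  }
  layout <- readr::read_tsv(layout_path, col_types = "cc", comment = "#",
                            progress = FALSE)
  if (!all(c("type", "name") %in% names(layout))) {
    abort("layout.tsv must have columns: type, name")
  }
  if (!all(layout$type %in% c("segment", "cluster"))) {
    abort("layout type must be 'segment' or 'cluster'")
  }
  gene_line <- grep("^#\\s*gene:", readr::read_lines(layout_path), value = TRUE)
  gene_name <- if (length(gene_line)) {
    sub("^#\\s*gene:\\s*", "", gene_line[1])
  } else {
    basename(dir)
  }

  seg_set <- read_fasta_named(file.path(dir, "constitutive.fasta"))
  seg_names <- layout$name[layout$type == "segment"]
  missing <- setdiff(seg_names, names(seg_set))
  if (length(missing)) {
    abort(sprintf("constitutive.fasta is missing segment(s): %s",
                  paste(missing, collapse = ", ")))
  }
  clus_names <- layout$name[layout$type == "cluster"]
  clusters <- lapply(setNames(clus_names, clus_names), function(nm) {
    path <- file.path(dir, paste0("cluster_", nm, ".fasta"))
    if (!file.exists(path)) {
      abort(sprintf("layout references cluster '%s' but %s does not exist",
                    nm, path))
    }
    v <- read_fasta_named(path)
    tibble(variant_id = names(v), sequence = unname(v))
  })
  gene_model(gene_name, segments = seg_set[seg_names], clusters = clusters)
}

#' @rdname read_gene_model
#' @param model A `gene_model`.
#' @export
write_gene_model <- function(model, dir) {
  stopifnot(inherits(model, "gene_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  layout <- tibble(
    type = c(rbind(rep("segment", length(model$segments)),
                   c(rep("cluster", length(model$clusters)), NA)))[
                     seq_len(2 * length(model$clusters) + 1)],
    name = c(rbind(names(model$segments),
                   c(names(model$clusters), NA)))[
                     seq_len(2 * length(model$clusters) + 1)]
  )
  header <- sprintf("# gene: %s", model$gene)
  readr::write_lines(
    c(header, paste(names(layout), collapse = "\t"),
      paste(layout$type, layout$name, sep = "\t")),
    file.path(dir, "layout.tsv")
  )
  write_fasta_named(model$segments, file.path(dir, "constitutive.fasta"))
  for (nm in names(model$clusters)) {
    cl <- model$clusters[[nm]]
    write_fasta_named(setNames(cl$sequence, cl$variant_id),
                      file.path(dir, paste0("cluster_", nm, ".fasta")))
  }
  invisible(dir)
}

read_fasta_named <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  set <- Biostrings::readDNAStringSet(path)
  if (anyDuplicated(names(set))) {
    dup <- unique(names(set)[duplicated(names(set))])
    abort(sprintf("duplicate FASTA header(s) in %s: %s",
                  path, paste(dup, collapse = ", ")))
  }
  setNames(check_dna(as.character(set), sprintf("sequence in %s", path)),
           names(set))
}

write_fasta_named <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path, width = 70)
  invisible(path)
}
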