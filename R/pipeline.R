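#' Read sequences from FASTA or FASTQ
#'
#' FASTQ qualities are ignored (reads are handled as plain sequence, as
#' with quality-blind alignment). Multi-line FASTA and CRLF line endings
#' are accepted; empty records are rejected.
#'
#' @param path Path to a FASTA or FASTQ file.
#' @param format `"auto"` (default; by extension), `"fasta"`, or
#'   `"fastq"`.
#' @return A tibble `name`, `sequence` in file order.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)) {
      "fastq"
    } else {
      "fasta"
    }
  }
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = format),
    error = function(e) {
      abort(sprintf("malformed %s in %s: %s", toupper(format), path,
                    conditionMessage(e)))
    }
  )
  if (length(set) == 0) {
    abort(sprintf("no records in %s", path))
  }
  if (any(Biostrings::width(set) == 0)) {
    bad <- which(Biostrings::width(set) == 0)[1]
    abort(sprintf("empty record #%d ('%s') in %s", bad, names(set)[bad], path))
  }
  nm <- sub("\\s.*$", "", names(set))
  tibble(name = nm, sequence = unname(as.character(set)))
}

#' Parse read-class annotations from sequence names
#'
#' Long-read records carry their molecule id and read class in the name,
#' as `<molecule>_t` (template), `<molecule>_c` (complement), or
#' `<molecule>_2d` (2D consensus).
#'
#' @param seqs A tibble from [read_sequences()] (columns `name`,
#'   `sequence`).
#' @return A tibble `read_id`, `molecule_id`, `read_class`, `sequence`.
#' @export
parse_read_records <- function(seqs) {
  seqs <- as_tibble(seqs)
  suffix <- sub("^.*_", "", seqs$name)
  cls <- c(t = "template", c = "complement", `2d` = "twodir")[suffix]
  if (any(is.na(cls)) || !all(grepl("_", seqs$name))) {
    bad <- seqs$name[is.na(cls) | !grepl("_", seqs$name)]
    abort(sprintf(
      "read name(s) without a _t/_c/_2d read-class suffix: %s",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  tibble(
    read_id = seqs$name,
    molecule_id = sub("_[^_]*$", "", seqs$name),
    read_class = unname(cls),
    sequence = seqs$sequence
  )
}

#' Write reads as FASTA
#'
#' Headers follow the `<molecule>_t/_c/_2d` dialect when the table has
#' `molecule_id`/`read_class` columns (via `read_id`), else the
#' `read_id`/`name` column is used.
#'
#' @param reads A tibble with `sequence` and `read_id` (or `name`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(reads, path) {
  reads <- as_tibble(reads)
  nm <- reads[["read_id"]] %||% reads[["name"]]
  if (is.null(nm)) abort("`reads` needs a `read_id` or `name` column")
  write_fasta_named(setNames(reads$sequence, nm), path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles the stage parameters of [run_pipeline()]. Unknown keys are
#' rejected so typos cannot silently fall back to defaults.
#'
#' @param sim A [sim_config()].
#' @param n_molecules Molecules to simulate (default 500).
#' @param n_isoforms Distinct isoforms in the simulated pool
#'   (default 50).
#' @param abundances Optional explicit pool (tibble `isoform`,
#'   `abundance`); when given it overrides `n_isoforms`.
#' @param scheme A [scoring_scheme()].
#' @param min_score Assignment score floor (default 50).
#' @param min_margin Uniqueness margin for calling (default 1).
#' @param truth Optional spike-in truth set (character vector of isoform
#'   ids) switching on chimera evaluation.
#' @param saturation_sizes Optional subsample sizes for the diversity
#'   stage; defaults to a spread over the accepted read count.
#' @param saturation_reps Replicates per size (default 50).
#' @param out_dir Optional directory; when given, stage outputs are
#'   written there as TSV.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim, n_molecules = 500, n_isoforms = 50,
                            abundances = NULL,
                            scheme = scoring_scheme(), min_score = 50,
                            min_margin = 1, truth = NULL,
                            saturation_sizes = NULL, saturation_reps = 50,
                            out_dir = NULL) {
  stopifnot(inherits(sim, "sim_config"))
  structure(
    list(sim = sim, n_molecules = n_molecules, n_isoforms = n_isoforms,
         abundances = abundances,
         scheme = as_scoring_scheme(scheme), min_score = min_score,
         min_margin = min_margin, truth = truth,
         saturation_sizes = saturation_sizes,
         saturation_reps = saturation_reps, out_dir = out_dir),
    class = "pipeline_config"
  )
}

# serialize the resolved configuration for the run log
config_lines <- function(config) {
  s <- config$scheme
  c(
    sprintf("scheme: match=+%d mismatch=-%d gap_open=%d gap_extend=%d both_strands=%s",
            s$match, s$mismatch, s$gap_open, s$gap_extend, s$both_strands),
    sprintf("min_score: %d", config$min_score),
    sprintf("min_margin: %d", config$min_margin),
    sprintf("n_molecules: %d", config$n_molecules),
    sprintf("n_isoforms: %d", config$n_isoforms),
    sprintf("seed: %d", config$sim$seed),
    sprintf("switch_rate: %g", config$sim$switch_rate),
    sprintf("fraction_with_2d: %g", config$sim$fraction_with_2d),
    sprintf("truth: %s",
            if (is.null(config$truth)) "none"
            else paste(config$truth, collapse = "; "))
  )
}

#' Run the full long-read isoform pipeline on simulated data
#'
#' Composes the stages end to end: generate a gene model and reads,
#' assign every read per cluster, reconcile read classes into molecule
#' calls, tabulate isoforms, and (optionally) evaluate template switching
#' against a truth set and scan diversity by subsampling and
#' capture-recapture. With `out_dir` set, every stage table is written as
#' TSV along with a run log that serializes the resolved configuration.
#'
#' @param config A [pipeline_config()].
#' @return A list with `model`, `sim`, `assignments`, `calls`,
#'   `status_counts`, `table`, `marginals`, `read_lengths`, and, when
#'   enabled, `chimera` and `saturation`/`estimates`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  model <- make_exon_clusters(config$sim)
  abund <- config$abundances %||%
    isoform_abundances(model, config$n_isoforms, config$sim)
  sim <- simulate_reads(model, abund, config$n_molecules, config$sim)
  assignments <- assign_reads(sim$reads, model, config$scheme,
                              config$min_score)
  calls <- call_isoforms(assignments, config$min_margin)
  status_counts <- calls |>
    dplyr::count(.data$status, name = "n_molecules", .drop = FALSE)
  table <- tabulate_isoforms(calls)
  marginals <- cluster_marginals(table)
  read_lengths <- sim$reads |>
    mutate(length = nchar(.data$sequence)) |>
    select("read_id", "read_class", "length")

  out <- list(model = model, sim = sim, assignments = assignments,
              calls = calls, status_counts = status_counts, table = table,
              marginals = marginals, read_lengths = read_lengths)

  if (!is.null(config$truth)) {
    out$chimera <- classify_isoforms(table, config$truth, model)
  }
  accepted <- accepted_labels(calls)
  if (length(accepted) >= 4) {
    sizes <- config$saturation_sizes %||%
      unique(pmax(1, round(seq_len(5) / 5 * length(accepted))))
    out$saturation <- saturation_scan(calls, sizes,
                                      reps = config$saturation_reps,
                                      seed = seed_offset(config$sim$seed, 11L))
    cr_sizes <- sizes[2 * sizes <= length(accepted)]
    if (length(cr_sizes)) {
      out$estimates <- capture_recapture_scan(
        calls, cr_sizes, seed = seed_offset(config$sim$seed, 12L)
      )
    }
  }

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, name) {
      readr::write_tsv(as_tibble(x), file.path(config$out_dir,
                                               paste0(name, ".tsv")))
    }
    readr::write_lines(config_lines(config),
                       file.path(config$out_dir, "run_log.txt"))
    wt(select(assignments, -dplyr::any_of("parents")), "assignments")
    wt(calls, "calls")
    wt(status_counts, "status_counts")
    wt(tidy(table), "isoform_table")
    wt(marginals, "cluster_marginals")
    wt(read_lengths, "read_lengths")
    if (!is.null(out$chimera)) {
      wt(select(as_tibble(out$chimera), -"parents"), "chimera_report")
    }
    if (!is.null(out$saturation)) wt(out$saturation, "saturation")
    if (!is.null(out$estimates)) wt(out$estimates, "estimates")
    write_sequences(sim$reads, file.path(config$out_dir, "reads.fasta"))
    write_gene_model(model, file.path(config$out_dir, "model"))
  }
  invisible(out)
}
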