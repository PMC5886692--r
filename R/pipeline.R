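# Pipeline orchestration: validated config, staged execution, reports.

PIPELINE_CONFIG_KEYS <- c(
  "out_dir", "seed", "recipient_fasta", "donor_fasta", "reads_fastq",
  "barcode_tsv", "fluctuation_tsv", "n_events", "mechanism", "depth",
  "error_rate", "p_daughter_loss", "induced", "params", "min_reads",
  "min_support", "major_fraction", "homology_len", "n_markers", "site_start"
)

#' Validate a pipeline configuration
#'
#' Unknown keys are rejected; required keys are checked per mode. The config
#' round-trips through YAML unchanged.
#'
#' @param config Named list, or path to a YAML file.
#' @param mode Pipeline mode.
#' @return The validated config list.
#' @export
validate_config <- function(config, mode = "all") {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  unknown <- setdiff(names(config), PIPELINE_CONFIG_KEYS)
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (is.null(config$out_dir)) stop("config needs out_dir", call. = FALSE)
  if (mode %in% c("simulate", "all") && is.null(config$seed)) {
    stop("simulate mode requires a seed", call. = FALSE)
  }
  for (key in c("recipient_fasta", "donor_fasta", "reads_fastq", "barcode_tsv", "fluctuation_tsv")) {
    if (!is.null(config[[key]]) && !file.exists(config[[key]])) {
      stop("config path does not exist: ", key, " = ", config[[key]], call. = FALSE)
    }
  }
  config
}

pipeline_references <- function(config, out_dir) {
  if (!is.null(config$recipient_fasta)) {
    pair <- load_allele_pair(config$recipient_fasta, config$donor_fasta)
  } else {
    syn <- synthetic_substrates(
      homology_len = config$homology_len %||% 4100,
      n_markers = config$n_markers %||% 82,
      site_start = config$site_start %||% 2000
    )
    pair <- allele_pair(syn$recipient_seq, syn$donor_seq)
    writeLines(c(">recipient_synthetic", syn$recipient_seq), file.path(out_dir, "recipient_synthetic.fa"))
    writeLines(c(">donor_synthetic", syn$donor_seq), file.path(out_dir, "donor_synthetic.fa"))
  }
  bs <- locate_break(pair)
  map <- derive_marker_map(pair, bs)
  list(pair = pair, break_site = bs, map = map)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order, writing every intermediate
#' artifact under `out_dir`: simulated reads/truth (`simulate`), per-event
#' genotypes and QC (`call`), classification tables (`classify`), summary
#' statistics (`stats`). A manifest records the seed, config hash and
#' per-stage counts; reruns with identical config and inputs produce
#' identical outputs.
#'
#' @param config Config list or YAML path (see [validate_config()]).
#' @param mode One of `"simulate"`, `"call"`, `"classify"`, `"stats"`,
#'   `"all"`.
#' @return Invisibly, a list with the run manifest and the main result
#'   tibbles.
#' @export
run_pipeline <- function(config, mode = c("all", "simulate", "call", "classify", "stats")) {
  mode <- match.arg(mode)
  config <- validate_config(config, mode)
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)

  refs <- pipeline_references(config, out_dir)
  write_marker_map(refs$map, file.path(out_dir, "marker_map.tsv"))
  write_break_site(refs$break_site, file.path(out_dir, "break_site.json"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("hetmapr")),
    seed = config$seed,
    # hash of the analysis parameters (output location excluded)
    config_hash = rlang::hash(config[sort(setdiff(names(config), "out_dir"))]),
    mode = mode, stages = list()
  )
  results <- list(manifest = manifest)

  do_simulate <- mode %in% c("simulate", "all")
  do_call <- mode %in% c("call", "all")
  do_classify <- mode %in% c("classify", "all")
  do_stats <- mode %in% c("stats", "all")

  if (do_simulate) {
    n <- config$n_events %||% 50
    params <- do.call(mechanism_params, config$params %||% list())
    mech <- config$mechanism %||% "DSBR"
    events <- switch(mech,
      DSBR = simulate_dsbr(params, refs$map, refs$break_site, n),
      MR_NICK = simulate_mr_nick(params, refs$map, refs$break_site$cut_center, n),
      GAP = simulate_gap(
        params, refs$map,
        c(refs$break_site$cut_center - 50, refs$break_site$cut_center + 50), n
      ),
      DLOOP_CLEAVAGE = simulate_dloop_cleavage(params, refs$map, refs$break_site, n),
      stop("unknown mechanism: ", mech, call. = FALSE)
    )
    obs <- observe_colony(events, config$p_daughter_loss %||% 0)
    bcs <- random_barcodes(n)
    reads <- emit_reads(obs, refs$pair, refs$map, bcs,
      depth = config$depth %||% 20, error_rate = config$error_rate %||% 0
    )
    write_fastq(reads, file.path(out_dir, "reads.fastq"))
    readr::write_tsv(bcs, file.path(out_dir, "barcodes.tsv"))
    readr::write_tsv(
      select(as_tibble(events), -"duplex_trunc", -"duplex_full", -"repairs"),
      file.path(out_dir, "truth.tsv")
    )
    manifest$stages$simulate <- list(n_events = n, n_reads = nrow(reads), mechanism = mech)
    config$reads_fastq <- file.path(out_dir, "reads.fastq")
    config$barcode_tsv <- file.path(out_dir, "barcodes.tsv")
    results$sim_events <- events
  }

  called <- NULL
  if (do_call) {
    if (is.null(config$reads_fastq)) stop("call mode requires reads_fastq", call. = FALSE)
    reads <- read_fastq(config$reads_fastq)
    bcs <- readr::read_tsv(config$barcode_tsv, show_col_types = FALSE)
    called <- call_events(reads, bcs, refs$pair, refs$map,
      min_reads = config$min_reads %||% 3,
      min_support = config$min_support %||% 2,
      major_fraction = config$major_fraction %||% 0.10
    )
    write_genotypes(called, refs$map, file.path(out_dir, "genotypes.tsv"))
    readr::write_tsv(
      select(called, -"genotype_trunc", -"genotype_full"),
      file.path(out_dir, "qc_report.tsv")
    )
    un <- attr(called, "unassigned")
    if (!is.null(un) && nrow(un) > 0) {
      readr::write_tsv(un, file.path(out_dir, "unassigned_reads.tsv"))
    }
    manifest$stages$call <- list(
      n_events = nrow(called), n_qc_pass = sum(called$qc_pass),
      n_unassigned = if (is.null(un)) 0L else nrow(un)
    )
    results$called <- called
  }

  classified <- NULL
  if (do_classify) {
    if (is.null(called)) {
      called <- read_genotypes(file.path(out_dir, "genotypes.tsv"), refs$map)
    }
    usable <- filter(called, .data$qc_pass)
    anchor <- if (isTRUE(config$induced) || is.null(config$induced)) refs$break_site else NULL
    classified <- classify_events(usable, refs$map, anchor)
    readr::write_tsv(
      select(classified, -"genotype_trunc", -"genotype_full"),
      file.path(out_dir, "classification.tsv")
    )
    jsonlite::write_json(
      select(classified, -"genotype_trunc", -"genotype_full"),
      file.path(out_dir, "classification.json"),
      auto_unbox = TRUE, digits = NA
    )
    manifest$stages$classify <- list(
      n_classified = nrow(classified),
      class_counts = as.list(table(classified$klass))
    )
    results$classified <- classified
  }

  if (do_stats) {
    if (is.null(classified)) {
      called <- called %||% read_genotypes(file.path(out_dir, "genotypes.tsv"), refs$map)
      anchor <- if (isTRUE(config$induced) || is.null(config$induced)) refs$break_site else NULL
      classified <- classify_events(filter(called, .data$qc_pass), refs$map, anchor)
    }
    anchors <- if ("anchor" %in% names(classified) && any(!is.na(classified$anchor))) {
      classified$anchor
    } else {
      refs$break_site$cut_center
    }
    lt <- hetdna_length_table(
      filter(mutate(classified, anchor = rep_len(anchors, nrow(classified))), !is.na(.data$anchor)),
      refs$map
    )
    report <- write_report(classified, lt, out_dir)
    stats_out <- list(class_counts = report$class_counts, medians = report$medians)
    if (!is.null(config$fluctuation_tsv)) {
      fl <- readr::read_tsv(config$fluctuation_tsv, show_col_types = FALSE)
      est <- lea_coulson_rate(fl$mutant_count, mean(fl$viable_cells))
      stats_out$rate <- tidy(est)
      jsonlite::write_json(as.list(tidy(est)), file.path(out_dir, "rate_estimate.json"),
        auto_unbox = TRUE, digits = NA
      )
    }
    jsonlite::write_json(
      purrr::map(stats_out, ~ if (is.data.frame(.x)) as.list(.x) else .x),
      file.path(out_dir, "stats_report.json"),
      auto_unbox = TRUE, digits = NA
    )
    manifest$stages$stats <- list(n_events = nrow(classified))
    results$stats <- stats_out
  }

  results$manifest <- manifest
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(results)
}

#' Write per-event genotype vectors as a long TSV
#'
#' One row per (event, marker) with the calls of both products.
#'
#' @param events Event tibble with `genotype_trunc`, `genotype_full`.
#' @param map A `marker_map`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(events, map, path) {
  m <- as_tibble(map)
  long <- purrr::map(seq_len(nrow(events)), function(i) {
    tibble(
      event_id = events$event_id[i],
      marker_index = m$index,
      pos_recipient = m$pos_recipient,
      call_trunc = events$genotype_trunc[[i]],
      call_full = events$genotype_full[[i]],
      qc_pass = events$qc_pass[i] %||% TRUE
    )
  }) |> list_rbind()
  readr::write_tsv(long, path)
  invisible(path)
}

#' Read a genotype TSV back into the event-table form
#'
#' @param path TSV written by [write_genotypes()].
#' @param map A `marker_map` (for marker-count validation).
#' @return Event tibble with genotype list-columns.
#' @export
read_genotypes <- function(path, map) {
  long <- readr::read_tsv(path, show_col_types = FALSE)
  n_mark <- nrow(as_tibble(map))
  long |>
    group_by(.data$event_id) |>
    summarise(
      genotype_trunc = list(.data$call_trunc[order(.data$marker_index)]),
      genotype_full = list(.data$call_full[order(.data$marker_index)]),
      qc_pass = first(.data$qc_pass),
      .groups = "drop"
    ) |>
    mutate(ok = vapply(.data$genotype_trunc, length, integer(1)) == n_mark) |>
    (\(d) {
      stopifnot(all(d$ok))
      select(d, -"ok")
    })()
}

#' Write the event report tables
#'
#' Emits the class-count table (mirroring the analysis' accounting
#' categories) and the median-length table.
#'
#' @param classified Classified event tibble.
#' @param length_table Per-event length table.
#' @param out_dir Output directory.
#' @return List with `class_counts` and `medians` tibbles.
#' @export
write_report <- function(classified, length_table, out_dir) {
  counts <- classified |>
    count(.data$klass, name = "n_events") |>
    mutate(fraction = .data$n_events / sum(.data$n_events))
  readr::write_tsv(counts, file.path(out_dir, "class_counts.tsv"))
  medians <- if (nrow(length_table) > 0 && any(length_table$has_hetdna)) {
    median_summary(length_table)
  } else {
    tibble(quantity = character(), median_bp = numeric(), n = integer())
  }
  readr::write_tsv(medians, file.path(out_dir, "median_lengths.tsv"))
  list(class_counts = counts, medians = medians)
}
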