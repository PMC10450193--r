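# End-to-end orchestration: simulate (or load) -> call operons -> termination
# statistics -> motif profile -> summary JSON, plus recovery scoring against
# simulation ground truth.

#' Run the full analysis pipeline
#'
#' Executes simulate (or load from a file manifest), operon calling,
#' per-ioTTS termination statistics and terminator-motif profiling, writing
#' per-stage outputs and a machine-readable \code{summary.json} stamped with
#' the seed and a config hash.
#'
#' @param config Either a \code{\link{simulation_config}} (the evidence set
#'   is simulated) or a \code{run_config} list from
#'   \code{\link{load_run_config}} pointing at input files.
#' @param out_dir Output directory.
#' @param params List of calling/statistics parameters: \code{delta5},
#'   \code{delta3}, \code{min_read_support}, \code{pseudocount},
#'   \code{window_up}, \code{window_down}.
#' @return An \code{operonterm_run}: list with \code{opset}, \code{tder},
#'   \code{motif} (or NULL when no ioTTS), \code{summary}, \code{truth}
#'   (simulation runs only), \code{out_dir}.
#' @export
run_pipeline <- function(config, out_dir,
                         params = list(delta5 = 20L, delta3 = 50L,
                                       min_read_support = 1L,
                                       pseudocount = 0.1,
                                       window_up = 36L, window_down = 1L)) {
  defaults <- list(delta5 = 20L, delta3 = 50L, min_read_support = 1L,
                   pseudocount = 0.1, window_up = 36L, window_down = 1L)
  params <- utils::modifyList(defaults, params)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  if (inherits(config, "simulation_config")) {
    dataset <- simulate_dataset(config)
    sim_dir <- file.path(out_dir, "simulated")
    write_dataset(dataset, sim_dir)
    truth <- dataset$truth
    genome <- truth$genome
    genes <- truth$genes
    sites <- dataset$sites
    reads <- dataset$reads
    coverage <- dataset$coverage
    reference <- unname(config$conditions[["reference"]])
    depletion <- if (is.na(config$depletion_factor)) NA else
      unname(config$conditions[["depletion"]])
    seed <- config$seed
  } else {
    loaded <- load_inputs(config)
    truth <- NULL
    genome <- loaded$genome; genes <- loaded$genes; sites <- loaded$sites
    reads <- loaded$reads; coverage <- loaded$coverage
    reference <- loaded$reference; depletion <- loaded$depletion
    seed <- if (!is.null(config$seed)) config$seed else NA_integer_
  }

  tss <- sites[sites$kind == "TSS", , drop = FALSE]
  tts <- sites[sites$kind == "TTS", , drop = FALSE]

  tus <- build_transcription_units(genes, tss, tts, reads,
                                   delta5 = params$delta5,
                                   delta3 = params$delta3,
                                   min_read_support = params$min_read_support)
  opset <- call_operons(tus, tss, tts, genes)
  write_operons(opset, out_dir)

  n_warn <- 0L
  tder <- withCallingHandlers(
    analyze_all_iotts(opset, coverage, genes, reference = reference,
                      depletion = depletion, pseudocount = params$pseudocount),
    warning = function(w) { n_warn <<- n_warn + 1L; invokeRestart("muffleWarning") })
  write_tder_table(tder, file.path(out_dir, "tder.tsv"))

  iotts_sites <- opset$internal_sites[opset$internal_sites$kind == "TTS", , drop = FALSE]
  motif <- NULL
  n_window_skipped <- 0L
  if (nrow(iotts_sites) > 0L) {
    win <- withCallingHandlers(
      extract_terminator_windows(genome, iotts_sites,
                                 upstream = params$window_up,
                                 downstream = params$window_down),
      warning = function(w) { invokeRestart("muffleWarning") })
    n_window_skipped <- attr(win, "n_skipped")
    if (nrow(win) > 0L) {
      motif <- build_motif_profile(win)
      write_motif_profile(motif, file.path(out_dir, "motif_profile.tsv"))
    }
  }

  summ <- summarize_operons(opset)
  out_summary <- list(
    seed = seed,
    config_hash = config_hash(config),
    n_units = summ$n_units,
    n_operons = summ$n_operons,
    n_single_gene_tus = summ$n_single_gene_tus,
    type_counts = as.list(summ$type_counts),
    type_pct = as.list(summ$type_pct),
    pct_with_iotts = summ$pct_with_iotts,
    pct_with_iotss = summ$pct_with_iotss,
    median_operon_length = summ$median_operon_length,
    tder_tier_counts = tier_counts(tder, reference),
    tte_summary = tte_summary(tder),
    motif_info_content = if (is.null(motif)) NULL else unname(motif$info_content),
    warnings = list(skipped_iotts_records = n_warn,
                    skipped_motif_windows = n_window_skipped),
    files = list(operons = "operons.tsv", internal_sites = "internal_sites.bed",
                 tder = "tder.tsv",
                 motif = if (is.null(motif)) NULL else "motif_profile.tsv")
  )
  jsonlite::write_json(out_summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  structure(list(opset = opset, tder = tder, motif = motif, truth = truth,
                 summary = out_summary, out_dir = out_dir),
            class = "operonterm_run")
}

tier_counts <- function(tder, reference) {
  ref <- tder[tder$condition == reference, , drop = FALSE]
  as.list(vapply(c("high", "mid", "low"), function(t) sum(ref$tier == t),
                 integer(1)))
}

tte_summary <- function(tder) {
  out <- list()
  for (cond in unique(tder$condition)) {
    v <- tder$tte[tder$condition == cond]
    out[[cond]] <- list(n = length(v), mean = mean(v),
                        median = stats::median(v), min = min(v), max = max(v))
  }
  out
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(unclass(config), tmp, version = 2)
  unname(tools::md5sum(tmp))
}

#' @export
print.operonterm_run <- function(x, ...) {
  cat("<operonterm_run>\n")
  print(summarize_operons(x$opset))
  cat(sprintf("  %d TDER records; outputs in %s\n", nrow(x$tder), x$out_dir))
  invisible(x)
}

#' Load a run configuration from a JSON file
#'
#' The JSON mirrors the input manifest: paths to the genome FASTA, GFF3,
#' per-condition TSS/TTS BED6, reads BED6 and bedGraphs (each tagged with
#' strand/condition/replicate), plus the reference and depletion condition
#' names and parameter blocks.
#'
#' @param path JSON file path.
#' @return A \code{run_config} list.
#' @export
load_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(cfg, class = "run_config")
}

load_inputs <- function(config) {
  base <- if (!is.null(config$base_dir)) config$base_dir else "."
  p <- function(f) {
    fp <- file.path(base, f)
    if (!file.exists(fp)) stop(sprintf("input file missing: %s", fp))
    fp
  }
  genome <- read_genome(p(config$genome))
  genes <- read_annotation(p(config$annotation))
  contig_lengths <- stats::setNames(Biostrings::width(genome), names(genome))
  sites <- list(); reads <- list(); coverage <- list()
  for (i in seq_len(nrow(config$tss))) {
    sites[[length(sites) + 1L]] <- read_sites(p(config$tss$file[i]), "TSS",
                                              config$tss$condition[i])
  }
  for (i in seq_len(nrow(config$tts))) {
    sites[[length(sites) + 1L]] <- read_sites(p(config$tts$file[i]), "TTS",
                                              config$tts$condition[i])
  }
  reads <- read_reads(p(config$reads))
  for (i in seq_len(nrow(config$coverage))) {
    coverage <- c(coverage, read_coverage(p(config$coverage$file[i]),
                                          strand = config$coverage$strand[i],
                                          condition = config$coverage$condition[i],
                                          replicate = config$coverage$replicate[i],
                                          contig_lengths = contig_lengths))
  }
  list(genome = genome, genes = genes,
       sites = reset_rownames(do.call(rbind, sites)), reads = reads,
       coverage = coverage,
       reference = config$reference,
       depletion = if (is.null(config$depletion)) NA else config$depletion)
}

#' Score a pipeline run against simulation ground truth
#'
#' @param run An \code{operonterm_run} produced on simulated data (or an
#'   \code{operon_set} plus \code{tder_table}).
#' @param truth A \code{simulation_truth} (defaults to \code{run$truth}).
#' @param reference Reference condition name.
#' @param depletion Depletion condition name (\code{NA} for none).
#' @return A \code{recovery_report}: list with \code{operon_precision},
#'   \code{operon_recall}, \code{type_accuracy}, \code{tte_pairs} (per
#'   terminator: true epsilon vs measured TTE), \code{tte_mae},
#'   \code{tte_max_abs_error}, \code{dependency_pairs},
#'   \code{dependency_mae}. Metrics are \code{NA} when undefined (no calls or
#'   empty truth), never 0/0 errors.
#' @export
compare_to_truth <- function(run, truth = NULL, reference = "wt", depletion = "dep") {
  if (inherits(run, "operonterm_run")) {
    if (is.null(truth)) truth <- run$truth
    opset <- run$opset
    tder <- run$tder
  } else {
    opset <- run$opset
    tder <- run$tder
  }
  if (is.null(truth)) stop("no simulation truth available to compare against")
  if (nrow(truth$operons) > 0L && nrow(opset$operons) > 0L &&
      !all(opset$operons$contig %in% truth$operons$contig)) {
    stop("truth and calls are on different contigs")
  }
  # operon identity = exact (strand, ordered gene set)
  key <- function(strand, genes) paste(strand, genes, sep = "|")
  true_keys <- key(truth$operons$strand, truth$operons$gene_tags)
  call_keys <- key(opset$operons$strand, opset$operons$genes)
  n_true <- length(true_keys); n_call <- length(call_keys)
  tp <- sum(call_keys %in% true_keys)
  precision <- if (n_call == 0L) NA_real_ else tp / n_call
  recall <- if (n_true == 0L) NA_real_ else tp / n_true
  matched <- intersect(call_keys, true_keys)
  type_acc <- if (length(matched) == 0L) NA_real_ else {
    mean(vapply(matched, function(k) {
      truth$operons$type[true_keys == k] == opset$operons$type[call_keys == k][1L]
    }, logical(1)))
  }
  # terminator recovery: match called ioTTS records to true terminators by
  # (position, strand)
  tt <- truth$terminators[truth$terminators$role == "ioTTS", , drop = FALSE]
  ref_rows <- tder[tder$condition == reference, , drop = FALSE]
  idx <- match(paste(ref_rows$iotts_position, ref_rows$strand),
               paste(tt$position, tt$strand))
  ok <- !is.na(idx)
  tte_pairs <- data.frame(position = ref_rows$iotts_position[ok],
                          epsilon = tt$epsilon[idx[ok]],
                          tte = ref_rows$tte[ok], stringsAsFactors = FALSE)
  tte_mae <- if (nrow(tte_pairs)) mean(abs(tte_pairs$tte - tte_pairs$epsilon)) else NA_real_
  tte_max <- if (nrow(tte_pairs)) max(abs(tte_pairs$tte - tte_pairs$epsilon)) else NA_real_
  terminator_recall <- if (nrow(tt) == 0L) NA_real_ else nrow(tte_pairs) / nrow(tt)

  dep_pairs <- NULL; dep_mae <- NA_real_
  f <- truth$config$depletion_factor
  if (!is.na(depletion) && !is.na(f) && any(tder$condition == depletion)) {
    dep_rows <- tder[tder$condition == depletion, , drop = FALSE]
    di <- match(paste(dep_rows$iotts_position, dep_rows$strand),
                paste(tt$position, tt$strand))
    okd <- !is.na(di)
    eps <- tt$epsilon[di[okd]]
    expected <- (1 - eps) / (1 - f * eps)
    dep_pairs <- data.frame(position = dep_rows$iotts_position[okd],
                            epsilon = eps, expected_dependency = expected,
                            dependency = dep_rows$dependency[okd],
                            stringsAsFactors = FALSE)
    if (nrow(dep_pairs)) dep_mae <- mean(abs(dep_pairs$dependency -
                                               dep_pairs$expected_dependency))
  }
  structure(list(operon_precision = precision, operon_recall = recall,
                 type_accuracy = type_acc, terminator_recall = terminator_recall,
                 tte_pairs = tte_pairs, tte_mae = tte_mae,
                 tte_max_abs_error = tte_max,
                 dependency_pairs = dep_pairs, dependency_mae = dep_mae),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)
  cat("<recovery_report>\n")
  cat(sprintf("  operon precision %s, recall %s, type accuracy %s\n",
              fmt(x$operon_precision), fmt(x$operon_recall), fmt(x$type_accuracy)))
  cat(sprintf("  terminator recall %s; TTE MAE %s (max |err| %s)\n",
              fmt(x$terminator_recall), fmt(x$tte_mae), fmt(x$tte_max_abs_error)))
  if (!is.null(x$dependency_pairs)) {
    cat(sprintf("  dependency MAE %s over %d terminators\n",
                fmt(x$dependency_mae), nrow(x$dependency_pairs)))
  }
  invisible(x)
}
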