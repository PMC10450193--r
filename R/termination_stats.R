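# Per-ioTTS termination statistics. TDER (ioTTS-based differential expression
# ratio) = abundance of the gene upstream of the ioTTS / abundance of the gene
# downstream. TTE (termination efficacy) = 1 - 1/TDER, the fraction of
# transcription events terminated at the site. Dependency = TDER in the
# factor-depletion condition / TDER in the reference condition; values < 1
# indicate factor-dependent termination.

#' Mean per-base abundance of a gene from a coverage track
#'
#' @param track A \code{coverage_track}.
#' @param gene One-row gene record (0-based half-open coordinates).
#' @param pseudocount Added to the mean so downstream ratios are defined.
#' @return List (\code{gene_abundance}) with \code{locus_tag},
#'   \code{condition}, \code{replicate}, \code{abundance}.
#' @export
quantify_gene_abundance <- function(track, gene, pseudocount = 0.1) {
  stopifnot(inherits(track, "coverage_track"), pseudocount >= 0)
  if (gene$end <= gene$start) stop("zero-length gene: start must be < end")
  if (gene$contig != track$contig) stop("gene and track are on different contigs")
  if (gene$end > length(track$values)) stop("gene extends beyond the coverage track")
  v <- track$values[(gene$start + 1L):gene$end]
  structure(list(locus_tag = gene$locus_tag, condition = track$condition,
                 replicate = track$replicate,
                 abundance = sum(v) / (gene$end - gene$start) + pseudocount),
            class = "gene_abundance")
}

#' ioTTS-based differential expression ratio
#'
#' @param a_up Abundance of the gene upstream of the ioTTS.
#' @param a_down Abundance of the gene downstream.
#' @return \code{a_up / a_down} (unrounded; reporting rounds to 1 decimal).
#' @export
compute_tder <- function(a_up, a_down) {
  stopifnot(a_up >= 0)
  if (any(a_down == 0)) {
    stop("downstream abundance is zero; quantify with a positive pseudocount")
  }
  a_up / a_down
}

#' Significance tier of a TDER
#'
#' Ratios of at least 2 are high significance, at least 1.5 but below 2 mid,
#' below 1.5 low (boundaries assigned to the upper tier).
#'
#' @param tder TDER value(s), > 0.
#' @return Character vector in \code{c("high", "mid", "low")}.
#' @export
classify_tder <- function(tder) {
  stopifnot(all(tder > 0))
  ifelse(tder >= 2, "high", ifelse(tder >= 1.5, "mid", "low"))
}

#' Transcription termination efficacy
#'
#' \code{TTE = 1 - 1/TDER}: the fraction of transcription events terminated
#' at the site. TDER below 1 gives a negative TTE, reported raw (callers flag
#' it).
#'
#' @param tder TDER value(s), > 0.
#' @return Numeric TTE in (-Inf, 1).
#' @export
compute_tte <- function(tder) {
  stopifnot(all(tder > 0))
  1 - 1 / tder
}

#' Condition dependency of termination
#'
#' @param tder_depletion TDER in the factor-depletion condition.
#' @param tder_reference TDER in the reference condition.
#' @return \code{tder_depletion / tder_reference}; near 1 means
#'   factor-independent termination, below 1 factor-dependent.
#' @export
compute_dependency <- function(tder_depletion, tder_reference) {
  stopifnot(all(tder_depletion > 0), all(tder_reference > 0))
  tder_depletion / tder_reference
}

#' Welch t-test on log2 abundances across replicates
#'
#' @param up_replicates,down_replicates Per-replicate abundances (> 0) of the
#'   upstream and downstream gene.
#' @return Two-sided p-value. Degenerate zero-variance inputs return 1 when
#'   the means are equal and 0 otherwise.
#' @export
tder_ttest <- function(up_replicates, down_replicates) {
  if (length(up_replicates) < 2L || length(down_replicates) < 2L) {
    stop("tder_ttest needs >= 2 replicates per side; with one replicate report p as missing")
  }
  lu <- log2(up_replicates); ld <- log2(down_replicates)
  if (stats::sd(lu) == 0 && stats::sd(ld) == 0) {
    return(if (isTRUE(all.equal(mean(lu), mean(ld)))) 1 else 0)
  }
  stats::t.test(lu, ld, var.equal = FALSE)$p.value
}

#' Compute TDER statistics for every ioTTS in an operon set
#'
#' For each internal terminator and condition: the flanking genes are the
#' operon genes immediately adjacent to the intergenic region holding the
#' ioTTS (in strand orientation); per-replicate gene abundances come from the
#' matching coverage tracks; replicate means feed the TDER; replicates feed a
#' Welch t-test on log2 abundances. When a depletion condition is named, its
#' rows carry \code{dependency} = TDER(depletion) / TDER(reference). Records
#' where an ioTSS lies between the ioTTS and the downstream gene are flagged
#' \code{confounded_by_ioTSS}; a TDER below 1 adds a \code{negative_tte}
#' flag. An ioTTS with no flanking gene on one side is skipped with a
#' warning.
#'
#' @param opset An \code{operon_set} from \code{\link{call_operons}}.
#' @param coverage List of \code{coverage_track}s (all conditions and
#'   replicates).
#' @param genes Gene table.
#' @param reference Reference condition name.
#' @param depletion Depletion condition name, or \code{NA} for none.
#' @param pseudocount Passed to \code{\link{quantify_gene_abundance}}.
#' @return A \code{tder_table} data.frame: one row per (ioTTS, condition)
#'   with columns \code{operon_id}, \code{iotts_position}, \code{strand},
#'   \code{upstream_gene}, \code{downstream_gene}, \code{condition},
#'   \code{a_up}, \code{a_down}, \code{tder}, \code{tier}, \code{tte},
#'   \code{dependency}, \code{p_value}, \code{flags}.
#' @export
analyze_all_iotts <- function(opset, coverage, genes, reference = "wt",
                              depletion = NA, pseudocount = 0.1) {
  stopifnot(inherits(opset, "operon_set"))
  io <- opset$internal_sites
  iotts <- io[io$kind == "TTS", , drop = FALSE]
  iotss <- io[io$kind == "TSS", , drop = FALSE]
  conds <- unique(vapply(coverage, function(tr) tr$condition, character(1)))
  stopifnot(reference %in% conds, is.na(depletion) || depletion %in% conds)

  rows <- list()
  for (i in seq_len(nrow(iotts))) {
    site <- iotts[i, , drop = FALSE]
    op <- opset$operons[opset$operons$operon_id == site$operon_id, , drop = FALSE]
    og <- genes[genes$contig == op$contig & genes$strand == op$strand &
                  genes$locus_tag %in% strsplit(op$genes, ",")[[1L]], , drop = FALSE]
    og <- og[order(og$start), , drop = FALSE]
    left <- og[og$end <= site$position, , drop = FALSE]
    right <- og[og$start > site$position, , drop = FALSE]
    if (nrow(left) == 0L || nrow(right) == 0L) {
      warning(sprintf("ioTTS at %s:%d has no flanking operon gene on one side; skipped",
                      site$contig, site$position))
      next
    }
    left <- left[nrow(left), , drop = FALSE]    # nearest on the left
    right <- right[1L, , drop = FALSE]          # nearest on the right
    if (op$strand == "+") { up <- left; down <- right } else { up <- right; down <- left }
    # ioTSS between the ioTTS and the downstream gene start (strand oriented)
    conf <- if (op$strand == "+") {
      any(iotss$operon_id == site$operon_id &
            iotss$position > site$position & iotss$position < down$start)
    } else {
      any(iotss$operon_id == site$operon_id &
            iotss$position < site$position & iotss$position >= down$end)
    }
    per_cond <- list()
    for (cond in conds) {
      trks <- Filter(function(tr) tr$condition == cond & tr$strand == op$strand &
                       tr$contig == op$contig, coverage)
      a_up_rep <- vapply(trks, function(tr)
        quantify_gene_abundance(tr, up, pseudocount)$abundance, numeric(1))
      a_down_rep <- vapply(trks, function(tr)
        quantify_gene_abundance(tr, down, pseudocount)$abundance, numeric(1))
      a_up <- mean(a_up_rep); a_down <- mean(a_down_rep)
      tder <- compute_tder(a_up, a_down)
      pv <- if (length(a_up_rep) >= 2L) tder_ttest(a_up_rep, a_down_rep) else NA_real_
      per_cond[[cond]] <- list(a_up = a_up, a_down = a_down, tder = tder, p = pv)
    }
    for (cond in conds) {
      pc <- per_cond[[cond]]
      dep <- if (!is.na(depletion) && cond == depletion) {
        compute_dependency(pc$tder, per_cond[[reference]]$tder)
      } else NA_real_
      flags <- c(if (conf) "confounded_by_ioTSS",
                 if (pc$tder < 1) "negative_tte")
      rows[[length(rows) + 1L]] <- data.frame(
        operon_id = site$operon_id, iotts_position = site$position,
        strand = op$strand, upstream_gene = up$locus_tag,
        downstream_gene = down$locus_tag, condition = cond,
        a_up = pc$a_up, a_down = pc$a_down, tder = pc$tder,
        tier = classify_tder(pc$tder), tte = compute_tte(pc$tder),
        dependency = dep, p_value = pc$p,
        flags = paste(flags, collapse = ";"), stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) reset_rownames(do.call(rbind, rows)) else
    data.frame(operon_id = character(0), iotts_position = integer(0),
               strand = character(0), upstream_gene = character(0),
               downstream_gene = character(0), condition = character(0),
               a_up = numeric(0), a_down = numeric(0), tder = numeric(0),
               tier = character(0), tte = numeric(0), dependency = numeric(0),
               p_value = numeric(0), flags = character(0),
               stringsAsFactors = FALSE)
  class(out) <- c("tder_table", "data.frame")
  out
}

#' @export
print.tder_table <- function(x, ...) {
  cat(sprintf("<tder_table> %d records (%d ioTTSs x %d conditions)\n",
              nrow(x), length(unique(paste(x$operon_id, x$iotts_position))),
              length(unique(x$condition))))
  if (nrow(x) > 0L) {
    y <- as.data.frame(x)
    y$tder <- round_half_away(y$tder, 1)
    y$tte <- round(y$tte, 3)
    print(utils::head(y[, c("operon_id", "iotts_position", "condition",
                            "tder", "tier", "tte", "dependency", "p_value")], 10))
    if (nrow(x) > 10L) cat(sprintf("  ... %d more rows\n", nrow(x) - 10L))
  }
  invisible(x)
}

#' Histogram of TDER values by significance tier
#' @param x A \code{tder_table}.
#' @param condition Condition to plot (default: first present).
#' @param ... Passed to \code{graphics::hist}.
#' @method plot tder_table
#' @export
plot.tder_table <- function(x, condition = NULL, ...) {
  if (is.null(condition)) condition <- x$condition[1L]
  v <- x$tder[x$condition == condition]
  graphics::hist(v, breaks = 20, xlab = "TDER",
                 main = sprintf("TDER distribution (%s)", condition),
                 col = "grey80", ...)
  graphics::abline(v = c(1.5, 2), lty = 2)
  invisible(x)
}

#' Write a TDER table as TSV
#'
#' TDER is reported to one decimal (rounded half away from zero, matching the
#' printed precision of ratio reporting); tier boundaries are closed on the
#' upper tier (TDER = 2 is high, = 1.5 mid).
#'
#' @param tab A \code{tder_table}.
#' @param path Output path.
#' @export
write_tder_table <- function(tab, path) {
  out <- as.data.frame(tab)
  out$tder <- round_half_away(out$tder, 1)
  header <- c("# TDER = mean upstream abundance / mean downstream abundance (1 decimal, half away from zero)",
              "# tier: TDER >= 2 high; 1.5 <= TDER < 2 mid; TDER < 1.5 low",
              "# TTE = 1 - 1/TDER; dependency = TDER(depletion)/TDER(reference)")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
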