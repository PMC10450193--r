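# Transcription-unit and operon calling. A (TSS, TTS) same-strand pair is a
# transcription unit when at least `min_read_support` full-length reads start
# within delta5 nt of the TSS and end within delta3 nt of the TTS (strand
# oriented). TUs sharing genes are grouped into operons; the TU with the most
# genes defines the operon extent; TSS/TTS sites falling strictly inside the
# extent and within an intergenic gap between consecutive operon genes are
# internal sites (ioTSS / ioTTS).

#' Build transcription units from site and read evidence
#'
#' @param genes Gene table (0-based half-open; see
#'   \code{\link{read_annotation}}).
#' @param tss_list,tts_list Site tables (see \code{\link{read_sites}}); sites
#'   are unioned across conditions by (contig, position, strand).
#' @param reads Full-length read table.
#' @param delta5 Max distance (nt) between a read 5' end and the TSS.
#' @param delta3 Max distance (nt) between a read 3' end and the TTS.
#' @param min_read_support Minimum reads matching both ends.
#' @return \code{data.frame} of TUs: \code{contig}, \code{strand},
#'   \code{tss}, \code{tts}, \code{start}, \code{end} (span, 0-based
#'   half-open), \code{n_genes}, \code{genes} (comma-joined locus tags),
#'   \code{supporting_reads}.
#' @export
build_transcription_units <- function(genes, tss_list, tts_list, reads,
                                      delta5 = 20L, delta3 = 50L,
                                      min_read_support = 1L) {
  stopifnot(delta5 >= 0, delta3 >= 0, min_read_support >= 1)
  tss <- unique_sites(tss_list)
  tts <- unique_sites(tts_list)
  if (nrow(tss) == 0L || nrow(tts) == 0L || nrow(reads) == 0L) {
    return(empty_tu_table())
  }
  five <- ifelse(reads$strand == "+", reads$start, reads$end - 1L)
  three <- ifelse(reads$strand == "+", reads$end - 1L, reads$start)
  out <- list()
  for (ctg in unique(reads$contig)) {
    for (strand in c("+", "-")) {
      sel_r <- reads$contig == ctg & reads$strand == strand
      if (!any(sel_r)) next
      s_tss <- tss[tss$contig == ctg & tss$strand == strand, , drop = FALSE]
      s_tts <- tts[tts$contig == ctg & tts$strand == strand, , drop = FALSE]
      if (nrow(s_tss) == 0L || nrow(s_tts) == 0L) next
      f <- five[sel_r]; t3 <- three[sel_r]
      # pair counts: reads matching TSS i at the 5' end and TTS j at the 3' end
      pair <- new.env(parent = emptyenv())
      for (k in seq_along(f)) {
        mi <- which(abs(s_tss$position - f[k]) <= delta5)
        mj <- which(abs(s_tts$position - t3[k]) <= delta3)
        for (i in mi) for (j in mj) {
          key <- paste0(i, "_", j)
          pair[[key]] <- (if (is.null(pair[[key]])) 0L else pair[[key]]) + 1L
        }
      }
      g <- genes[genes$contig == ctg & genes$strand == strand, , drop = FALSE]
      for (key in ls(pair)) {
        n_support <- pair[[key]]
        if (n_support < min_read_support) next
        ij <- as.integer(strsplit(key, "_", fixed = TRUE)[[1L]])
        tss_pos <- s_tss$position[ij[1L]]
        tts_pos <- s_tts$position[ij[2L]]
        # TSS must precede TTS in strand orientation
        if (strand == "+" && tss_pos >= tts_pos) next
        if (strand == "-" && tss_pos <= tts_pos) next
        span <- sort(c(tss_pos, tts_pos))
        lo <- span[1L]; hi <- span[2L] + 1L
        contained <- g$start >= lo & g$end <= hi
        if (!any(contained)) next
        gl <- g[contained, , drop = FALSE]
        gl <- gl[order(if (strand == "+") gl$start else -gl$start), , drop = FALSE]
        out[[length(out) + 1L]] <- data.frame(
          contig = ctg, strand = strand, tss = tss_pos, tts = tts_pos,
          start = lo, end = hi, n_genes = nrow(gl),
          genes = paste(gl$locus_tag, collapse = ","),
          supporting_reads = n_support, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) return(empty_tu_table())
  tus <- reset_rownames(do.call(rbind, out))
  tus[order(tus$contig, tus$start, tus$end), , drop = FALSE] |> reset_rownames()
}

empty_tu_table <- function() {
  data.frame(contig = character(0), strand = character(0), tss = integer(0),
             tts = integer(0), start = integer(0), end = integer(0),
             n_genes = integer(0), genes = character(0),
             supporting_reads = integer(0), stringsAsFactors = FALSE)
}

# union sites across conditions; counts summed per (contig, position, strand)
unique_sites <- function(sites) {
  if (nrow(sites) == 0L) return(sites)
  key <- paste(sites$contig, sites$position, sites$strand, sep = "\r")
  agg <- tapply(sites$count, key, sum)
  first <- sites[!duplicated(key), , drop = FALSE]
  first$count <- as.integer(agg[paste(first$contig, first$position,
                                      first$strand, sep = "\r")])
  reset_rownames(first[order(first$contig, first$position), , drop = FALSE])
}

#' Call operons from transcription units
#'
#' TUs sharing any gene are grouped; within a group the TU with the most
#' genes (ties: longest span, then leftmost) defines the operon extent and
#' gene list. Groups whose defining TU has a single gene are reported as
#' single-gene TUs, not operons. TSS/TTS sites lying strictly inside the
#' extent and within an intergenic gap between consecutive operon genes are
#' recorded as ioTSS / ioTTS. An operon's 3' boundary is flagged
#' \code{boundary_confirmed} when the next same-strand gene beyond the TTS
#' has an assigned TSS of its own (a confidence flag only; never changes the
#' call).
#'
#' @param tus TU table from \code{\link{build_transcription_units}}.
#' @param tss_list,tts_list Site tables (unioned across conditions).
#' @param genes Gene table.
#' @return An \code{operon_set}: list with \code{operons} (one row per
#'   operon, \code{type} in I--IV), \code{internal_sites} (one row per
#'   ioTSS/ioTTS with host \code{operon_id}), \code{single_gene_tus},
#'   \code{tus}.
#' @export
call_operons <- function(tus, tss_list, tts_list, genes) {
  tss <- unique_sites(tss_list)
  tts <- unique_sites(tts_list)
  if (nrow(tus) == 0L) {
    return(new_operon_set(empty_operon_table(), empty_internal_sites(),
                          empty_tu_table(), tus))
  }
  gene_sets <- strsplit(tus$genes, ",", fixed = TRUE)
  groups <- group_by_shared_genes(gene_sets, tus$strand, tus$contig)

  operons <- list(); internal <- list(); singles <- list()
  for (grp in groups) {
    sub <- tus[grp, , drop = FALSE]
    # defining TU: most genes -> longest span -> leftmost
    o <- order(-sub$n_genes, -(sub$end - sub$start), sub$start)
    def <- sub[o[1L], , drop = FALSE]
    if (def$n_genes < 2L) {
      singles[[length(singles) + 1L]] <- def
      next
    }
    op_id <- sprintf("OP_%s_%d_%s", def$contig, def$start, def$strand)
    op_genes <- genes[genes$contig == def$contig & genes$strand == def$strand &
                        genes$locus_tag %in% strsplit(def$genes, ",")[[1L]], ,
                      drop = FALSE]
    op_genes <- op_genes[order(op_genes$start), , drop = FALSE]
    io <- internal_sites_for(def, op_genes, tss, tts, op_id)
    n_iotss <- sum(io$kind == "TSS")
    n_iotts <- sum(io$kind == "TTS")
    type <- classify_operon_type(n_iotss = n_iotss, n_iotts = n_iotts)
    operons[[length(operons) + 1L]] <- data.frame(
      operon_id = op_id, contig = def$contig, start = def$start, end = def$end,
      strand = def$strand, tss = def$tss, tts = def$tts,
      n_genes = def$n_genes, genes = def$genes,
      n_iotss = n_iotss, n_iotts = n_iotts, type = type,
      supporting_reads = def$supporting_reads,
      boundary_confirmed = boundary_confirmed(def, genes, tss),
      stringsAsFactors = FALSE)
    if (nrow(io) > 0L) internal[[length(internal) + 1L]] <- io
  }
  op_tab <- if (length(operons)) reset_rownames(do.call(rbind, operons)) else
    empty_operon_table()
  op_tab <- reset_rownames(op_tab[order(op_tab$contig, op_tab$start), , drop = FALSE])
  io_tab <- if (length(internal)) reset_rownames(do.call(rbind, internal)) else
    empty_internal_sites()
  sg_tab <- if (length(singles)) reset_rownames(do.call(rbind, singles)) else
    empty_tu_table()
  new_operon_set(op_tab, io_tab, sg_tab, tus)
}

empty_operon_table <- function() {
  data.frame(operon_id = character(0), contig = character(0), start = integer(0),
             end = integer(0), strand = character(0), tss = integer(0),
             tts = integer(0), n_genes = integer(0), genes = character(0),
             n_iotss = integer(0), n_iotts = integer(0), type = character(0),
             supporting_reads = integer(0), boundary_confirmed = logical(0),
             stringsAsFactors = FALSE)
}

empty_internal_sites <- function() {
  data.frame(operon_id = character(0), contig = character(0),
             position = integer(0), strand = character(0), kind = character(0),
             count = integer(0), stringsAsFactors = FALSE)
}

new_operon_set <- function(operons, internal_sites, single_gene_tus, tus) {
  structure(list(operons = operons, internal_sites = internal_sites,
                 single_gene_tus = single_gene_tus, tus = tus),
            class = "operon_set")
}

# connected components over shared gene membership (same contig+strand only;
# gene locus tags are unique so sharing implies both)
group_by_shared_genes <- function(gene_sets, strands, contigs) {
  n <- length(gene_sets)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  gene_owner <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    for (g in gene_sets[[i]]) {
      j <- gene_owner[[g]]
      if (is.null(j)) gene_owner[[g]] <- i
      else { ri <- find(i); rj <- find(j); if (ri != rj) parent[ri] <- rj }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(seq_len(n), roots)
}

# sites strictly inside the operon extent and within an IGR between
# consecutive operon genes
internal_sites_for <- function(def, op_genes, tss, tts, op_id) {
  res <- list()
  for (kind in c("TSS", "TTS")) {
    s <- if (kind == "TSS") tss else tts
    s <- s[s$contig == def$contig & s$strand == def$strand &
             s$position > def$start & s$position < def$end - 1L, , drop = FALSE]
    if (nrow(s) == 0L) next
    in_igr <- rep(FALSE, nrow(s))
    for (i in seq_len(nrow(op_genes) - 1L)) {
      igr_lo <- op_genes$end[i]          # first base after gene i
      igr_hi <- op_genes$start[i + 1L]   # first base of gene i+1
      in_igr <- in_igr | (s$position >= igr_lo & s$position < igr_hi)
    }
    if (any(in_igr)) {
      hit <- s[in_igr, , drop = FALSE]
      res[[length(res) + 1L]] <- data.frame(
        operon_id = op_id, contig = hit$contig, position = hit$position,
        strand = hit$strand, kind = kind, count = hit$count,
        stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L) return(empty_internal_sites())
  reset_rownames(do.call(rbind, res))
}

boundary_confirmed <- function(def, genes, tss) {
  g <- genes[genes$contig == def$contig & genes$strand == def$strand, , drop = FALSE]
  if (def$strand == "+") {
    nxt <- g[g$start >= def$end, , drop = FALSE]
    if (nrow(nxt) == 0L) return(NA)
    nxt <- nxt[which.min(nxt$start), , drop = FALSE]
    any(tss$contig == def$contig & tss$strand == "+" &
          tss$position <= nxt$start & tss$position >= def$end)
  } else {
    nxt <- g[g$end <= def$start, , drop = FALSE]
    if (nrow(nxt) == 0L) return(NA)
    nxt <- nxt[which.max(nxt$end), , drop = FALSE]
    any(tss$contig == def$contig & tss$strand == "-" &
          tss$position >= nxt$end - 1L & tss$position < def$start)
  }
}

#' Classify an operon architecture type
#'
#' Type I has no internal sites; type II at least one ioTTS; type III at
#' least one ioTSS; type IV both.
#'
#' @param operon Optionally a one-row operon record with \code{n_iotss} /
#'   \code{n_iotts} columns.
#' @param n_iotss,n_iotts Internal site counts (used when \code{operon} is
#'   missing).
#' @return \code{"I"}, \code{"II"}, \code{"III"} or \code{"IV"}.
#' @export
classify_operon_type <- function(operon = NULL, n_iotss = NULL, n_iotts = NULL) {
  if (!is.null(operon)) {
    n_iotss <- operon$n_iotss
    n_iotts <- operon$n_iotts
  }
  stopifnot(n_iotss >= 0, n_iotts >= 0)
  if (n_iotss == 0L && n_iotts == 0L) "I"
  else if (n_iotss == 0L) "II"
  else if (n_iotts == 0L) "III"
  else "IV"
}

#' Round half away from zero
#' @param x Numeric.
#' @param digits Decimal digits.
#' @return Rounded numeric (0.5 rounds up in magnitude, unlike base
#'   \code{round}'s half-to-even).
#' @export
round_half_away <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Summarize an operon call set
#'
#' @param x An \code{operon_set} (or its \code{operons} table plus
#'   \code{single_gene_tus}).
#' @param ... Unused.
#' @return List with unit/operon counts, per-type counts and integer
#'   percentages (rounded half away from zero), percentage of operons with
#'   ioTSS / ioTTS, gene-count histogram, and median operon length (nt).
#' @export
summarize_operons <- function(x, ...) {
  stopifnot(inherits(x, "operon_set"))
  op <- x$operons
  n_op <- nrow(op)
  n_single <- nrow(x$single_gene_tus)
  type_counts <- vapply(c("I", "II", "III", "IV"),
                        function(t) sum(op$type == t), integer(1))
  pct <- function(k, n) if (n == 0L) 0 else round_half_away(100 * k / n)
  gene_hist <- if (n_op) table(op$n_genes) else table(integer(0))
  res <- list(
    n_units = n_op + n_single,
    n_operons = n_op,
    n_single_gene_tus = n_single,
    type_counts = type_counts,
    type_pct = vapply(type_counts, pct, numeric(1), n = n_op),
    n_with_iotts = sum(op$n_iotts > 0L),
    n_with_iotss = sum(op$n_iotss > 0L),
    pct_with_iotts = pct(sum(op$n_iotts > 0L), n_op),
    pct_with_iotss = pct(sum(op$n_iotss > 0L), n_op),
    gene_count_histogram = gene_hist,
    median_operon_length = if (n_op) stats::median(op$end - op$start) else NA_real_
  )
  class(res) <- "operon_summary"
  res
}

#' @method summary operon_set
#' @export
summary.operon_set <- function(object, ...) summarize_operons(object, ...)

#' @export
print.operon_set <- function(x, ...) {
  cat(sprintf("<operon_set> %d operons, %d single-gene TUs, %d internal sites (%d ioTSS, %d ioTTS)\n",
              nrow(x$operons), nrow(x$single_gene_tus), nrow(x$internal_sites),
              sum(x$internal_sites$kind == "TSS"),
              sum(x$internal_sites$kind == "TTS")))
  if (nrow(x$operons) > 0L) {
    tt <- table(x$operons$type)
    cat("  types:", paste(sprintf("%s=%d", names(tt), as.integer(tt)),
                          collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
print.operon_summary <- function(x, ...) {
  cat(sprintf("Transcription units: %d (%d operons, %d single-gene TUs)\n",
              x$n_units, x$n_operons, x$n_single_gene_tus))
  for (t in names(x$type_counts)) {
    cat(sprintf("  Type %-3s %4d (%d%%)\n", t, x$type_counts[[t]], x$type_pct[[t]]))
  }
  cat(sprintf("  with ioTTS: %d (%d%%); with ioTSS: %d (%d%%)\n",
              x$n_with_iotts, x$pct_with_iotts, x$n_with_iotss, x$pct_with_iotss))
  cat(sprintf("  median operon length: %s nt\n", format(x$median_operon_length)))
  invisible(x)
}

#' Write operon calls to TSV/BED files
#'
#' @param opset An \code{operon_set}.
#' @param out_dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_operons <- function(opset, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p1 <- file.path(out_dir, "operons.tsv")
  utils::write.table(opset$operons, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  p2 <- file.path(out_dir, "internal_sites.bed")
  io <- opset$internal_sites
  write_bed6(data.frame(contig = io$contig, start = io$position,
                        end = io$position + 1L,
                        name = sprintf("%s|io%s", io$operon_id, io$kind),
                        score = io$count, strand = io$strand,
                        stringsAsFactors = FALSE), p2)
  p3 <- file.path(out_dir, "single_gene_tus.tsv")
  utils::write.table(opset$single_gene_tus, p3, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(p1, p2, p3))
}
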