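# Terminator motif profiling. Windows cover positions -36..+1 around the TTS
# base (38 nt, strand oriented: the TTS base sits at 0-based offset 36, one
# downstream base at 37). Analysis is in DNA space: the polyU tract of an
# intrinsic terminator appears as a T-run on the coding strand.

#' Extract strand-oriented terminator windows around ioTTSs
#'
#' For a site on the plus strand at 0-based position p the window is
#' \code{genome[p-36, p+2)}; minus-strand windows are the mirrored interval
#' reverse-complemented. Sites whose window would leave the contig are
#' skipped with a warning.
#'
#' @param genome A \code{DNAStringSet} (or path to a FASTA).
#' @param sites Site table with \code{contig}, \code{position},
#'   \code{strand} (e.g. the \code{internal_sites} of an \code{operon_set},
#'   TTS kind).
#' @param upstream,downstream Window extent in nt around the TTS base
#'   (defaults 36 and 1).
#' @return \code{data.frame} with \code{contig}, \code{position},
#'   \code{strand}, \code{sequence}; attribute \code{n_skipped} counts
#'   out-of-bounds sites.
#' @export
extract_terminator_windows <- function(genome, sites, upstream = 36L,
                                       downstream = 1L) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- read_genome(genome)
  }
  stopifnot(methods::is(genome, "DNAStringSet"))
  width <- upstream + downstream + 1L
  seqs <- character(nrow(sites))
  keep <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    ctg <- sites$contig[i]
    if (!ctg %in% names(genome)) {
      stop(sprintf("contig '%s' missing from the genome FASTA", ctg))
    }
    p <- sites$position[i]
    len <- length(genome[[ctg]])
    if (sites$strand[i] == "+") {
      lo <- p - upstream; hi <- p + downstream + 1L    # 0-based half-open
    } else {
      lo <- p - downstream; hi <- p + upstream + 1L
    }
    if (lo < 0L || hi > len) next
    s <- Biostrings::subseq(genome[[ctg]], start = lo + 1L, end = hi)
    if (sites$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    seqs[i] <- as.character(s)
    keep[i] <- TRUE
  }
  n_skipped <- sum(!keep)
  if (n_skipped > 0L) {
    warning(sprintf("%d site(s) skipped: window leaves the contig", n_skipped))
  }
  out <- data.frame(contig = sites$contig[keep], position = sites$position[keep],
                    strand = sites$strand[keep], sequence = seqs[keep],
                    stringsAsFactors = FALSE)
  stopifnot(all(nchar(out$sequence) == width))
  attr(out, "n_skipped") <- n_skipped
  attr(out, "upstream") <- upstream
  attr(out, "downstream") <- downstream
  out
}

#' Build a position frequency/information profile from terminator windows
#'
#' Per-column base counts, pseudocount-smoothed column-stochastic
#' frequencies, and Shannon information content (2 minus the column entropy,
#' in bits; no small-sample correction).
#'
#' @param windows Window table from
#'   \code{\link{extract_terminator_windows}} (or a character vector of
#'   equal-length sequences).
#' @param pseudocount Added per base per column before normalising (default
#'   0.25: one pseudo-observation split evenly).
#' @return A \code{motif_profile}: list with \code{counts} (4 x width),
#'   \code{frequencies}, \code{info_content} (bits), \code{n_windows},
#'   \code{pseudocount}.
#' @export
build_motif_profile <- function(windows, pseudocount = 0.25) {
  seqs <- if (is.data.frame(windows)) windows$sequence else as.character(windows)
  if (length(seqs) == 0L) stop("no terminator windows to profile")
  stopifnot(pseudocount >= 0)
  width <- unique(nchar(seqs))
  if (length(width) != 1L) stop("windows must all have the same length")
  bases <- c("A", "C", "G", "T")
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  if (!all(mat %in% bases)) stop("windows must be over the {A,C,G,T} alphabet")
  counts <- vapply(seq_len(width), function(j)
    tabulate(factor(mat[, j], levels = bases), nbins = 4L), integer(4))
  dimnames(counts) <- list(bases, NULL)
  freq <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), "/")
  plogp <- ifelse(freq > 0, freq * log2(freq), 0)
  info <- 2 + colSums(plogp)
  structure(list(counts = counts, frequencies = freq, info_content = info,
                 n_windows = length(seqs), pseudocount = pseudocount),
            class = "motif_profile")
}

#' Longest T-run score over the terminal window positions
#'
#' The length of the longest run of T within the last \code{tail_len}
#' positions of a terminator window (the region holding the polyU tract of
#' an intrinsic terminator).
#'
#' @param window A window sequence (character scalar) or a window table row
#'   set; vectorised.
#' @param tail_len Terminal region length (default 12).
#' @return Integer score(s) in [0, tail_len].
#' @export
u_tract_score <- function(window, tail_len = 12L) {
  seqs <- if (is.data.frame(window)) window$sequence else as.character(window)
  vapply(seqs, function(s) {
    n <- nchar(s)
    tail_s <- substr(s, max(1L, n - tail_len + 1L), n)
    runs <- rle(strsplit(tail_s, "", fixed = TRUE)[[1L]] == "T")
    hit <- runs$lengths[runs$values]
    if (length(hit)) max(hit) else 0L
  }, integer(1), USE.NAMES = FALSE)
}

#' @export
print.motif_profile <- function(x, ...) {
  cat(sprintf("<motif_profile> %d windows, width %d, pseudocount %g\n",
              x$n_windows, ncol(x$counts), x$pseudocount))
  cat(sprintf("  info content: mean %.3f bits, max %.3f bits at offset %d\n",
              mean(x$info_content), max(x$info_content),
              which.max(x$info_content) - 1L))
  invisible(x)
}

#' Plot a motif information-content profile
#'
#' Stacked per-base bar heights proportional to frequency times column
#' information content (a text-free sequence-logo analogue).
#'
#' @param x A \code{motif_profile}.
#' @param rna Relabel T as U in the legend.
#' @param ... Passed to \code{graphics::barplot}.
#' @method plot motif_profile
#' @export
plot.motif_profile <- function(x, rna = FALSE, ...) {
  h <- sweep(x$frequencies, 2, x$info_content, "*")
  labs <- rownames(h)
  if (rna) labs[labs == "T"] <- "U"
  width <- ncol(h)
  graphics::barplot(h, names.arg = seq_len(width) - 1L - (width - 2L),
                    col = c("#33a02c", "#1f78b4", "#ff7f00", "#e31a1c"),
                    border = NA, xlab = "position relative to TTS",
                    ylab = "information (bits)", ylim = c(0, 2),
                    legend.text = labs, ...)
  invisible(x)
}

#' Write a motif profile as TSV
#' @param profile A \code{motif_profile}.
#' @param path Output path.
#' @export
write_motif_profile <- function(profile, path) {
  width <- ncol(profile$counts)
  out <- data.frame(offset = seq_len(width) - 1L,
                    t(profile$counts),
                    t(round(profile$frequencies, 6)),
                    info_bits = round(profile$info_content, 6))
  names(out) <- c("offset", paste0("count_", rownames(profile$counts)),
                  paste0("freq_", rownames(profile$counts)), "info_bits")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
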