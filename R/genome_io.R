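#' @keywords internal
"_PACKAGE"

# All coordinates inside the package are 0-based half-open intervals; single-base
# sites are stored as the 0-based index of the base itself. Writers convert back
# to each format's native convention (GFF3: 1-based inclusive; BED/bedGraph:
# 0-based half-open).

#' Read gene annotation from a GFF3 file
#'
#' Parses \code{gene} (or \code{CDS}) features carrying a \code{locus_tag}
#' attribute into a gene table. GFF3's 1-based inclusive coordinates are
#' converted to the package's 0-based half-open convention.
#'
#' @param path Path to a GFF3 file.
#' @param feature_types Feature types (column 3) to keep.
#' @return A \code{data.frame} with columns \code{contig}, \code{start},
#'   \code{end} (0-based half-open), \code{strand} (\code{"+"}/\code{"-"}) and
#'   \code{locus_tag}, sorted by (contig, start).
#' @export
read_annotation <- function(path, feature_types = c("gene", "CDS")) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(empty_gene_table())
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- idx[which(nf != 9L)[1L]]
    stop(sprintf("malformed GFF3 line %d in '%s': expected 9 tab-separated columns, got %d",
                 bad, path, nf[which(nf != 9L)[1L]]))
  }
  m <- do.call(rbind, fields)
  sel <- m[, 3L] %in% feature_types
  if (!any(sel)) {
    return(empty_gene_table())
  }
  m <- m[sel, , drop = FALSE]
  lnum <- idx[sel]
  start1 <- suppressWarnings(as.integer(m[, 4L]))
  end1 <- suppressWarnings(as.integer(m[, 5L]))
  if (anyNA(start1) || anyNA(end1)) {
    bad <- lnum[which(is.na(start1) | is.na(end1))[1L]]
    stop(sprintf("malformed GFF3 line %d in '%s': non-integer coordinate", bad, path))
  }
  strand <- m[, 7L]
  if (!all(strand %in% c("+", "-"))) {
    bad <- lnum[which(!strand %in% c("+", "-"))[1L]]
    stop(sprintf("malformed GFF3 line %d in '%s': strand must be '+' or '-'", bad, path))
  }
  tags <- vapply(m[, 9L], gff3_attr, character(1), name = "locus_tag", USE.NAMES = FALSE)
  if (anyNA(tags)) {
    bad <- lnum[which(is.na(tags))[1L]]
    stop(sprintf("GFF3 line %d in '%s': missing locus_tag attribute", bad, path))
  }
  if (anyDuplicated(tags)) {
    dup <- tags[duplicated(tags)][1L]
    stop(sprintf("duplicate locus_tag '%s' in '%s'", dup, path))
  }
  genes <- data.frame(
    contig = m[, 1L],
    start = start1 - 1L,   # 1-based inclusive -> 0-based half-open
    end = end1,
    strand = strand,
    locus_tag = tags,
    stringsAsFactors = FALSE
  )
  if (any(genes$start >= genes$end)) {
    stop(sprintf("invalid gene interval (start >= end) in '%s'", path))
  }
  genes[order(genes$contig, genes$start), , drop = FALSE][, , drop = FALSE] |>
    reset_rownames()
}

empty_gene_table <- function() {
  data.frame(contig = character(0), start = integer(0), end = integer(0),
             strand = character(0), locus_tag = character(0),
             stringsAsFactors = FALSE)
}

reset_rownames <- function(df) {
  rownames(df) <- NULL
  df
}

gff3_attr <- function(attrs, name) {
  parts <- strsplit(attrs, ";", fixed = TRUE)[[1L]]
  parts <- trimws(parts)
  hit <- grep(paste0("^", name, "="), parts, value = TRUE)
  if (length(hit) == 0L) return(NA_character_)
  sub(paste0("^", name, "="), "", hit[1L])
}

#' Write a gene table as GFF3
#'
#' @param genes Gene table as returned by \code{\link{read_annotation}}.
#' @param path Output path.
#' @param source Value for GFF3 column 2.
#' @param feature Feature type for column 3.
#' @export
write_annotation <- function(genes, path, source = "operonterm", feature = "gene") {
  header <- "##gff-version 3"
  if (nrow(genes) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\tID=%s;locus_tag=%s",
                   genes$contig, source, feature,
                   genes$start + 1L, genes$end,   # back to 1-based inclusive
                   genes$strand, genes$locus_tag, genes$locus_tag)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' Read single-base TSS or TTS sites from a BED6 file
#'
#' Each BED record is one site: \code{chromStart} is the 0-based position of
#' the transcribed base (first transcribed base for a TSS, last for a TTS),
#' the score column is the supporting read count.
#'
#' @param path BED6 file path.
#' @param kind \code{"TSS"} or \code{"TTS"}.
#' @param condition Condition label attached to every record.
#' @return \code{data.frame} with columns \code{contig}, \code{position},
#'   \code{strand}, \code{kind}, \code{count}, \code{condition}, \code{name}.
#' @export
read_sites <- function(path, kind = c("TSS", "TTS"), condition = "default") {
  kind <- match.arg(kind)
  bed <- read_bed6(path)
  if (nrow(bed) > 0L && any(bed$end != bed$start + 1L)) {
    bad <- which(bed$end != bed$start + 1L)[1L]
    stop(sprintf("site record %d in '%s': chromEnd must equal chromStart + 1 for single-base sites",
                 bad, path))
  }
  if (nrow(bed) > 0L && any(bed$score < 0L)) {
    stop(sprintf("negative site count in '%s'", path))
  }
  data.frame(contig = bed$contig, position = bed$start, strand = bed$strand,
             kind = rep(kind, nrow(bed)), count = bed$score,
             condition = rep(condition, nrow(bed)), name = bed$name,
             stringsAsFactors = FALSE)
}

#' Write a site table as BED6
#'
#' @param sites Site table (\code{contig}, \code{position}, \code{strand},
#'   \code{count}; optional \code{name}).
#' @param path Output path.
#' @export
write_sites <- function(sites, path) {
  nm <- if ("name" %in% names(sites) && nrow(sites) > 0L) sites$name else
    sprintf("site%d", seq_len(nrow(sites)))
  write_bed6(data.frame(contig = sites$contig, start = sites$position,
                        end = sites$position + 1L, name = nm,
                        score = sites$count, strand = sites$strand,
                        stringsAsFactors = FALSE), path)
}

#' Read full-length transcript reads from a BED6 file
#'
#' Each record is one contiguous mapped full-length read; the name column is
#' the read identifier, the score column is ignored.
#'
#' @param path BED6 file path.
#' @return \code{data.frame} with columns \code{contig}, \code{start},
#'   \code{end} (0-based half-open), \code{strand}, \code{read_id}.
#' @export
read_reads <- function(path) {
  bed <- read_bed6(path)
  if (nrow(bed) > 0L && any(bed$start >= bed$end)) {
    stop(sprintf("read interval with start >= end in '%s'", path))
  }
  data.frame(contig = bed$contig, start = bed$start, end = bed$end,
             strand = bed$strand, read_id = bed$name, stringsAsFactors = FALSE)
}

#' Write full-length reads as BED6
#' @param reads Read table (\code{contig}, \code{start}, \code{end},
#'   \code{strand}, \code{read_id}).
#' @param path Output path.
#' @export
write_reads <- function(reads, path) {
  write_bed6(data.frame(contig = reads$contig, start = reads$start,
                        end = reads$end, name = reads$read_id,
                        score = rep(0L, nrow(reads)), strand = reads$strand,
                        stringsAsFactors = FALSE), path)
}

read_bed6 <- function(path) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !grepl("^(track|browser|#)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(data.frame(contig = character(0), start = integer(0), end = integer(0),
                      name = character(0), score = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[idx], "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    bad <- idx[which(nf < 6L)[1L]]
    stop(sprintf("malformed BED6 line %d in '%s': expected >= 6 fields", bad, path))
  }
  m <- t(vapply(fields, function(f) f[1:6], character(6)))
  start <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  score <- suppressWarnings(as.integer(m[, 5L]))
  if (anyNA(start) || anyNA(end)) {
    bad <- idx[which(is.na(start) | is.na(end))[1L]]
    stop(sprintf("malformed BED6 line %d in '%s': non-integer coordinate", bad, path))
  }
  if (anyNA(score) || any(m[, 5L] != as.character(score))) {
    bad <- idx[which(is.na(score) | m[, 5L] != as.character(score))[1L]]
    stop(sprintf("malformed BED6 line %d in '%s': score must be an integer", bad, path))
  }
  if (!all(m[, 6L] %in% c("+", "-"))) {
    bad <- idx[which(!m[, 6L] %in% c("+", "-"))[1L]]
    stop(sprintf("malformed BED6 line %d in '%s': strand must be '+' or '-'", bad, path))
  }
  data.frame(contig = m[, 1L], start = start, end = end, name = m[, 4L],
             score = score, strand = m[, 6L], stringsAsFactors = FALSE)
}

write_bed6 <- function(bed, path) {
  if (nrow(bed) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   bed$contig, bed$start, bed$end, bed$name, bed$score, bed$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read strand-specific coverage from a bedGraph file
#'
#' The sparse bedGraph intervals (0-based half-open, non-overlapping) are
#' expanded to a dense per-base vector over the contig; unlisted positions
#' are zero.
#'
#' @param path bedGraph file path.
#' @param strand Strand the file covers (\code{"+"}/\code{"-"}).
#' @param condition Condition label.
#' @param replicate Replicate label.
#' @param contig_lengths Named integer vector of contig lengths.
#' @return A list of \code{coverage_track} objects (one per contig present in
#'   \code{contig_lengths}), each a list with \code{contig}, \code{strand},
#'   \code{condition}, \code{replicate}, \code{values}.
#' @export
read_coverage <- function(path, strand, condition, replicate, contig_lengths) {
  stopifnot(strand %in% c("+", "-"), length(contig_lengths) >= 1L,
            !is.null(names(contig_lengths)))
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !grepl("^(track|browser|#)", lines)
  idx <- which(keep)
  tracks <- lapply(names(contig_lengths), function(ctg) {
    new_coverage_track(ctg, strand, condition, replicate,
                       numeric(contig_lengths[[ctg]]))
  })
  names(tracks) <- names(contig_lengths)
  if (length(idx) > 0L) {
    fields <- strsplit(lines[idx], "[ \t]+")
    nf <- lengths(fields)
    if (any(nf < 4L)) {
      bad <- idx[which(nf < 4L)[1L]]
      stop(sprintf("malformed bedGraph line %d in '%s': expected 4 fields", bad, path))
    }
    m <- t(vapply(fields, function(f) f[1:4], character(4)))
    start <- suppressWarnings(as.integer(m[, 2L]))
    end <- suppressWarnings(as.integer(m[, 3L]))
    val <- suppressWarnings(as.numeric(m[, 4L]))
    if (anyNA(start) || anyNA(end) || anyNA(val)) {
      stop(sprintf("malformed bedGraph record in '%s'", path))
    }
    for (ctg in unique(m[, 1L])) {
      if (!ctg %in% names(contig_lengths)) {
        stop(sprintf("bedGraph '%s' names contig '%s' absent from contig_lengths", path, ctg))
      }
      sel <- m[, 1L] == ctg
      s <- start[sel]; e <- end[sel]; v <- val[sel]
      len <- contig_lengths[[ctg]]
      if (any(e > len) || any(s < 0L)) {
        stop(sprintf("bedGraph '%s': interval beyond contig '%s' length %d", path, ctg, len))
      }
      o <- order(s)
      s <- s[o]; e <- e[o]; v <- v[o]
      if (length(s) > 1L && any(s[-1L] < e[-length(e)])) {
        stop(sprintf("bedGraph '%s': overlapping intervals on contig '%s'", path, ctg))
      }
      vals <- tracks[[ctg]]$values
      for (i in seq_along(s)) vals[(s[i] + 1L):e[i]] <- v[i]
      tracks[[ctg]]$values <- vals
    }
  }
  unname(tracks)
}

new_coverage_track <- function(contig, strand, condition, replicate, values) {
  stopifnot(all(values >= 0))
  structure(list(contig = contig, strand = strand, condition = condition,
                 replicate = replicate, values = values),
            class = "coverage_track")
}

#' Write a dense coverage track as bedGraph
#'
#' Runs of equal value are collapsed to single intervals; zero runs are
#' omitted (bedGraph is sparse).
#'
#' @param track A \code{coverage_track}.
#' @param path Output path.
#' @export
write_coverage <- function(track, path) {
  v <- track$values
  if (length(v) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  nz <- r$values != 0
  lines <- sprintf("%s\t%d\t%d\t%s", track$contig, starts[nz], ends[nz],
                   fmt_num(r$values[nz]))
  writeLines(lines, path)
  invisible(path)
}

# %.17g round-trips any double through decimal text; integers print plainly.
fmt_num <- function(x) {
  ifelse(is.finite(x) & x == round(x) & abs(x) < 2^31,
         sprintf("%d", as.integer(round(x))),
         sprintf("%.17g", x))
}

#' Read a genome FASTA
#' @param path FASTA path.
#' @return A \code{Biostrings::DNAStringSet}.
#' @export
read_genome <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write a genome FASTA
#' @param genome A \code{DNAStringSet} (or named character vector).
#' @param path Output path.
#' @export
write_genome <- function(genome, path) {
  if (!methods::is(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(genome)
  }
  Biostrings::writeXStringSet(genome, path, width = 70L)
  invisible(path)
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> contig=%s strand=%s condition=%s replicate=%s length=%d mean=%.3f\n",
              x$contig, x$strand, x$condition, x$replicate,
              length(x$values), mean(x$values)))
  invisible(x)
}
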