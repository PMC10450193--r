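# Small in-code fixtures shared across tests.

# two plus-strand genes with an IGR at [400, 500): the worked TU fixture
fixture_genes <- function() {
  data.frame(contig = "chr1",
             start = c(100L, 500L), end = c(400L, 900L),
             strand = "+", locus_tag = c("geneA", "geneB"),
             stringsAsFactors = FALSE)
}

fixture_site <- function(position, kind, strand = "+", count = 10L,
                         condition = "wt", contig = "chr1") {
  data.frame(contig = contig, position = as.integer(position), strand = strand,
             kind = kind, count = as.integer(count), condition = condition,
             name = sprintf("%s_%d", kind, position), stringsAsFactors = FALSE)
}

fixture_read <- function(start, end, strand = "+", id = "read1", contig = "chr1") {
  data.frame(contig = contig, start = as.integer(start), end = as.integer(end),
             strand = strand, read_id = id, stringsAsFactors = FALSE)
}

fixture_track <- function(values, strand = "+", condition = "wt",
                          replicate = "rep1", contig = "chr1") {
  operonterm:::new_coverage_track(contig, strand, condition, replicate, values)
}

# mirror a dataset: coordinates reflected around the contig, strands flipped
mirror_pos <- function(pos, len) len - 1L - pos
mirror_interval <- function(start, end, len) list(start = len - end, end = len - start)
flip_strand <- function(s) ifelse(s == "+", "-", "+")

mirror_genes <- function(genes, len) {
  iv <- mirror_interval(genes$start, genes$end, len)
  out <- genes
  out$start <- iv$start; out$end <- iv$end
  out$strand <- flip_strand(genes$strand)
  out[order(out$start), , drop = FALSE]
}

mirror_sites <- function(sites, len) {
  out <- sites
  out$position <- mirror_pos(sites$position, len)
  out$strand <- flip_strand(sites$strand)
  out
}

mirror_reads <- function(reads, len) {
  iv <- mirror_interval(reads$start, reads$end, len)
  out <- reads
  out$start <- iv$start; out$end <- iv$end
  out$strand <- flip_strand(reads$strand)
  out
}

# tiny simulation configs used by several tests
quick_cfg <- function(...) {
  simulation_config(seed = 11L,
                    n_operons_by_type = c(I = 1L, II = 1L, III = 1L, IV = 1L),
                    gene_length = c(500L, 800L),
                    n_replicates = 2L, noise = "none", ...)
}
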