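# TU assembly, operon grouping, internal-site detection, type classification
# and summary arithmetic.

test_that("a same-strand TSS/TTS pair with one spanning read becomes a TU", {
  genes <- fixture_genes()
  tss <- fixture_site(80L, "TSS")
  tts <- fixture_site(949L, "TTS")
  read <- fixture_read(78L, 951L)
  tus <- build_transcription_units(genes, tss, tts, read,
                                   delta5 = 20L, delta3 = 50L,
                                   min_read_support = 1L)
  expect_equal(nrow(tus), 1L)
  expect_equal(tus$genes, "geneA,geneB")
  expect_equal(tus$supporting_reads, 1L)

  # read evidence is mandatory
  no_reads <- read[0, ]
  expect_equal(nrow(build_transcription_units(genes, tss, tts, no_reads)), 0L)

  # strand mismatch between the read and the TSS yields nothing
  tss_minus <- fixture_site(80L, "TSS", strand = "-")
  expect_equal(nrow(build_transcription_units(genes, tss_minus, tts, read)), 0L)
})

test_that("end-matching tolerances delta5/delta3 are enforced", {
  genes <- fixture_genes()
  tss <- fixture_site(80L, "TSS")
  tts <- fixture_site(949L, "TTS")
  read <- fixture_read(78L, 951L)   # 5' off by 2, 3' off by 1
  expect_equal(nrow(build_transcription_units(genes, tss, tts, read,
                                              delta5 = 1L)), 0L)
  expect_equal(nrow(build_transcription_units(genes, tss, tts, read,
                                              delta5 = 2L)), 1L)
  # genes only partially inside the span are excluded
  tss_mid <- fixture_site(200L, "TSS")
  read_mid <- fixture_read(200L, 951L)
  tus <- build_transcription_units(genes, tss_mid, tts, read_mid)
  expect_equal(tus$genes, "geneB")
})

test_that("TUs sharing genes group into one operon and inner TTS becomes ioTTS", {
  genes <- fixture_genes()
  tss <- fixture_site(80L, "TSS")
  tts <- rbind(fixture_site(949L, "TTS"), fixture_site(450L, "TTS"))
  reads <- rbind(fixture_read(78L, 951L, id = "r1"),
                 fixture_read(80L, 451L, id = "r2"))
  tus <- build_transcription_units(genes, tss, tts, reads)
  expect_equal(nrow(tus), 2L)   # {A,B} and {A}
  ops <- call_operons(tus, tss, tts, genes)
  expect_equal(nrow(ops$operons), 1L)
  expect_equal(ops$operons$n_genes, 2L)
  expect_equal(nrow(ops$single_gene_tus), 0L)   # the {A} TU joined the operon
  io <- ops$internal_sites
  expect_equal(nrow(io), 1L)
  expect_equal(io$position, 450L)               # in the IGR [400, 500)
  expect_equal(io$kind, "TTS")
  expect_equal(ops$operons$type, "II")
})

test_that("a TTS inside a CDS is not an ioTTS; operons keep empty lists", {
  genes <- fixture_genes()
  tss <- fixture_site(80L, "TSS")
  tts <- rbind(fixture_site(949L, "TTS"), fixture_site(600L, "TTS"))  # inside geneB
  reads <- fixture_read(78L, 951L)
  ops <- call_operons(build_transcription_units(genes, tss, tts, reads),
                      tss, tts, genes)
  expect_equal(nrow(ops$internal_sites), 0L)
  expect_equal(ops$operons$type, "I")
})

test_that("operon type classification follows the internal-site counts", {
  expect_equal(classify_operon_type(n_iotss = 0, n_iotts = 0), "I")
  expect_equal(classify_operon_type(n_iotss = 0, n_iotts = 1), "II")
  expect_equal(classify_operon_type(n_iotss = 1, n_iotts = 0), "III")
  expect_equal(classify_operon_type(n_iotss = 2, n_iotts = 3), "IV")
})

test_that("summary percentages round half away from zero", {
  expect_equal(round_half_away(100 * 157 / 410), 38)
  expect_equal(round_half_away(100 * 210 / 410), 51)
  expect_equal(round_half_away(100 * 0 / 410), 0)
  expect_equal(round_half_away(2.5), 3)      # base round() would give 2
  expect_equal(round_half_away(-2.5), -3)
  expect_equal(round_half_away(14.25, 1), 14.3)
})

test_that("summarize_operons reports counts, percentages and median length", {
  cfg <- quick_cfg()
  ds <- simulate_dataset(cfg)
  tss <- ds$sites[ds$sites$kind == "TSS", ]
  tts <- ds$sites[ds$sites$kind == "TTS", ]
  ops <- call_operons(build_transcription_units(ds$truth$genes, tss, tts, ds$reads),
                      tss, tts, ds$truth$genes)
  s <- summarize_operons(ops)
  expect_equal(s$n_operons, 4L)
  expect_equal(unname(s$type_counts), c(1L, 1L, 1L, 1L))
  expect_equal(s$pct_with_iotts, 50)   # types II and IV
  expect_equal(s$pct_with_iotss, 50)   # types III and IV
  expect_equal(s$median_operon_length,
               median(ops$operons$end - ops$operons$start))
})

test_that("adding reads never removes a TU (monotonicity in evidence)", {
  cfg <- quick_cfg()
  ds <- simulate_dataset(cfg)
  tss <- ds$sites[ds$sites$kind == "TSS", ]
  tts <- ds$sites[ds$sites$kind == "TTS", ]
  base_tus <- build_transcription_units(ds$truth$genes, tss, tts, ds$reads)
  set.seed(1)
  extra <- ds$reads[sample(nrow(ds$reads), 30, replace = TRUE), ]
  extra$read_id <- paste0("extra", seq_len(nrow(extra)))
  more_tus <- build_transcription_units(ds$truth$genes, tss, tts,
                                        rbind(ds$reads, extra))
  key <- function(t) paste(t$contig, t$strand, t$tss, t$tts)
  expect_true(all(key(base_tus) %in% key(more_tus)))
  idx <- match(key(base_tus), key(more_tus))
  expect_true(all(more_tus$supporting_reads[idx] >= base_tus$supporting_reads))
})

test_that("reverse-complementing the dataset mirrors the calls (strand symmetry)", {
  cfg <- quick_cfg()
  ds <- simulate_dataset(cfg)
  len <- length(ds$truth$genome[[1]])
  genes <- ds$truth$genes[, c("contig", "start", "end", "strand", "locus_tag")]
  tss <- ds$sites[ds$sites$kind == "TSS", ]
  tts <- ds$sites[ds$sites$kind == "TTS", ]
  ops <- call_operons(build_transcription_units(genes, tss, tts, ds$reads),
                      tss, tts, genes)
  m_genes <- mirror_genes(genes, len)
  m_tss <- mirror_sites(tss, len)
  m_tts <- mirror_sites(tts, len)
  m_reads <- mirror_reads(ds$reads, len)
  m_ops <- call_operons(build_transcription_units(m_genes, m_tss, m_tts, m_reads),
                        m_tss, m_tts, m_genes)
  expect_equal(nrow(m_ops$operons), nrow(ops$operons))
  # spans mirror exactly; types are preserved
  orig <- ops$operons[order(ops$operons$start), ]
  mirr <- m_ops$operons[order(-m_ops$operons$end), ]
  expect_equal(mirr$start, len - orig$end)
  expect_equal(mirr$end, len - orig$start)
  expect_equal(mirr$type, orig$type)
  expect_equal(nrow(m_ops$internal_sites), nrow(ops$internal_sites))
})

test_that("every reported ioTTS lies in an IGR between consecutive operon genes", {
  cfg <- simulation_config(seed = 37L,
                           n_operons_by_type = c(II = 4L, IV = 3L),
                           noise = "none")
  ds <- simulate_dataset(cfg)
  tss <- ds$sites[ds$sites$kind == "TSS", ]
  tts <- ds$sites[ds$sites$kind == "TTS", ]
  ops <- call_operons(build_transcription_units(ds$truth$genes, tss, tts, ds$reads),
                      tss, tts, ds$truth$genes)
  io <- ops$internal_sites
  expect_gt(nrow(io), 0)
  for (i in seq_len(nrow(io))) {
    op <- ops$operons[ops$operons$operon_id == io$operon_id[i], ]
    g <- ds$truth$genes[ds$truth$genes$locus_tag %in%
                          strsplit(op$genes, ",")[[1]], ]
    g <- g[order(g$start), ]
    in_igr <- any(vapply(seq_len(nrow(g) - 1), function(j)
      io$position[i] >= g$end[j] && io$position[i] < g$start[j + 1], logical(1)))
    expect_true(in_igr)
    expect_true(io$position[i] > op$start && io$position[i] < op$end - 1)
  }
})
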