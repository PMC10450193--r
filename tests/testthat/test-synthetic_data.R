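# Synthetic evidence generator: determinism, architecture truth invariants,
# read termination sampling, coverage closed forms, dataset writing.

test_that("fixed seed gives byte-identical simulated datasets", {
  cfg <- quick_cfg()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(simulate_dataset(cfg), d1)
  write_dataset(simulate_dataset(cfg), d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_identical(f1, f2)
  h1 <- unname(tools::md5sum(file.path(d1, f1)))
  h2 <- unname(tools::md5sum(file.path(d2, f2)))
  expect_identical(h1, h2)
})

test_that("type-I-only configs carry no internal sites in the truth", {
  cfg <- simulation_config(seed = 3L, n_operons_by_type = c(I = 4L),
                           noise = "none")
  truth <- simulate_architecture(cfg)
  expect_equal(nrow(truth$terminators[truth$terminators$role == "ioTTS", ]), 0L)
  expect_equal(nrow(truth$promoters[truth$promoters$role == "ioTSS", ]), 0L)
  expect_true(all(truth$operons$type == "I"))
})

test_that("truth expected abundances follow the (1 - epsilon) read-through rule", {
  cfg <- simulation_config(seed = 5L, n_operons_by_type = c(II = 3L),
                           epsilon = c(0.5, 0.5), noise = "none")
  truth <- simulate_architecture(cfg)
  ea <- truth$expected_abundance
  for (op in truth$operons$operon_id) {
    g <- truth$genes[truth$genes$operon_id == op, ]
    wt <- ea[ea$condition == "wt" & ea$operon_id == op, ]
    a <- wt$expected[match(g$locus_tag, wt$locus_tag)]
    # single ioTTS between genes 1 and 2, epsilon = 0.5
    expect_equal(a[2], 0.5 * a[1])
    # depletion condition: epsilon scaled by f = 0.5
    dep <- ea[ea$condition == "dep" & ea$operon_id == op, ]
    ad <- dep$expected[match(g$locus_tag, dep$locus_tag)]
    expect_equal(ad[2], 0.75 * ad[1])
  }
})

test_that("read termination honours epsilon at the extremes", {
  base <- list(seed = 9L, n_operons_by_type = c(II = 2L),
               terminal_tte = c(1, 1), end_jitter_sd = 0, noise = "none",
               genes_per_operon = c(2L, 2L))
  for (eps in c(0, 1)) {
    cfg <- do.call(simulation_config, c(base, list(epsilon = c(eps, eps))))
    truth <- simulate_architecture(cfg)
    reads <- simulate_reads(truth, cfg, "wt")
    three <- ifelse(reads$strand == "+", reads$end - 1L, reads$start)
    io <- truth$terminators[truth$terminators$role == "ioTTS", ]
    n_at_io <- sum(three %in% io$position)
    if (eps == 1) expect_equal(n_at_io, nrow(reads))  # every read ends there
    else expect_equal(n_at_io, 0L)
  }
})

test_that("read end fraction at an ioTTS matches epsilon within 3 binomial sd", {
  cfg <- simulation_config(seed = 21L, n_operons_by_type = c(II = 1L),
                           genes_per_operon = c(2L, 2L),
                           epsilon = c(0.5, 0.5), terminal_tte = c(1, 1),
                           read_depth = 10000, end_jitter_sd = 0,
                           noise = "poisson")
  truth <- simulate_architecture(cfg)
  reads <- simulate_reads(truth, cfg, "wt")
  io <- truth$terminators[truth$terminators$role == "ioTTS", ]
  three <- ifelse(reads$strand == "+", reads$end - 1L, reads$start)
  frac <- sum(three == io$position) / nrow(reads)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / nrow(reads)))
})

test_that("noise-free coverage follows the read-through product closed form", {
  # one ioTTS, epsilon 0.75: downstream gene coverage exactly 0.25 x upstream
  cfg <- simulation_config(seed = 13L, n_operons_by_type = c(II = 1L),
                           genes_per_operon = c(2L, 2L),
                           epsilon = c(0.75, 0.75), noise = "none",
                           n_replicates = 1L)
  truth <- simulate_architecture(cfg)
  cov <- simulate_coverage(truth, cfg, "wt", "rep1")
  strand <- truth$operons$strand[1]
  tr <- Filter(function(x) x$strand == strand, cov)[[1]]
  g <- truth$genes
  mean_cov <- function(i) mean(tr$values[(g$start[i] + 1):g$end[i]])
  up <- which(g$gene_index == 1); down <- which(g$gene_index == 2)
  expect_equal(mean_cov(down), 0.25 * mean_cov(up))
})

test_that("two stacked terminators multiply read-through: third gene at 0.25 x first", {
  # build a 3-gene operon and stack two ioTTSs manually via two type II truths
  cfg <- simulation_config(seed = 17L, n_operons_by_type = c(II = 1L),
                           genes_per_operon = c(3L, 3L),
                           epsilon = c(0.5, 0.5), noise = "none",
                           n_replicates = 1L)
  truth <- simulate_architecture(cfg)
  # add a second terminator in the IGR between genes 2 and 3
  g <- truth$genes
  strand <- g$strand[1]
  if (strand == "+") {
    pos2 <- g$end[2] + 19L
  } else {
    pos2 <- g$start[2] - 20L
  }
  extra <- truth$terminators[truth$terminators$role == "ioTTS", ][1, ]
  extra$position <- pos2
  truth$terminators <- rbind(truth$terminators, extra)
  cov <- simulate_coverage(truth, cfg, "wt", "rep1")
  tr <- Filter(function(x) x$strand == strand, cov)[[1]]
  mean_cov <- function(i) mean(tr$values[(g$start[i] + 1):g$end[i]])
  expect_equal(mean_cov(3), 0.25 * mean_cov(1))
  expect_equal(mean_cov(2), 0.5 * mean_cov(1))
})

test_that("Poisson coverage concentrates on the expectation", {
  cfg <- simulation_config(seed = 19L, n_operons_by_type = c(I = 1L),
                           genes_per_operon = c(2L, 2L),
                           gene_length = c(1000L, 1000L),
                           promoter_strength = c(1, 1),
                           coverage_depth = 100, noise = "poisson",
                           n_replicates = 1L)
  truth <- simulate_architecture(cfg)
  cov <- simulate_coverage(truth, cfg, "wt", "rep1")
  strand <- truth$operons$strand[1]
  tr <- Filter(function(x) x$strand == strand, cov)[[1]]
  g <- truth$genes[1, ]
  m <- mean(tr$values[(g$start + 1):g$end])
  expect_lt(abs(m - 100), 3 * sqrt(100 / 1000))
})

test_that("depletion scales the realized end fraction toward f * epsilon", {
  cfg <- simulation_config(seed = 23L, n_operons_by_type = c(II = 1L),
                           genes_per_operon = c(2L, 2L),
                           epsilon = c(0.6, 0.6), terminal_tte = c(1, 1),
                           depletion_factor = 0.5, read_depth = 20000,
                           end_jitter_sd = 0, noise = "poisson")
  truth <- simulate_architecture(cfg)
  reads <- simulate_reads(truth, cfg, "dep")
  io <- truth$terminators[truth$terminators$role == "ioTTS", ]
  three <- ifelse(reads$strand == "+", reads$end - 1L, reads$start)
  frac <- sum(three == io$position) / nrow(reads)
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / nrow(reads)))
})

test_that("write_dataset emits the full manifest and re-reads exactly", {
  cfg <- simulation_config(seed = 29L, n_operons_by_type = c(II = 2L),
                           n_replicates = 2L, noise = "none")
  ds <- simulate_dataset(cfg)
  d <- withr::local_tempdir()
  manifest <- write_dataset(ds, d)
  # 2 conditions x 2 replicates x 2 strands = 8 bedGraphs
  expect_equal(sum(manifest$type == "bedgraph"), 8L)
  # truth TSV row count = number of internal terminators
  tt <- read.delim(file.path(d, "truth_terminators.tsv"))
  expect_equal(nrow(tt),
               sum(ds$truth$terminators$role == "ioTTS"))
  # round trip: site positions identical
  s <- read_sites(file.path(d, "tts_wt.bed"), "TTS", "wt")
  orig <- ds$sites[ds$sites$kind == "TTS" & ds$sites$condition == "wt", ]
  expect_setequal(s$position, orig$position)
  g <- read_annotation(file.path(d, "genes.gff3"))
  expect_equal(sort(g$start), sort(ds$truth$genes$start))
})

test_that("jittered read ends stay inside the contig and keep intervals valid", {
  cfg <- simulation_config(seed = 31L, n_operons_by_type = c(II = 2L),
                           end_jitter_sd = 3, noise = "poisson")
  truth <- simulate_architecture(cfg)
  reads <- simulate_reads(truth, cfg, "wt")
  expect_true(all(reads$start >= 0))
  expect_true(all(reads$end <= length(truth$genome[[1]])))
  expect_true(all(reads$start < reads$end))
})
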