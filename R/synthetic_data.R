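# Synthetic evidence-set generator. The statistical structure mirrors the data
# model of archaeal full-length-transcript operon mapping: operons of 1-10
# genes on both strands, single-base TSS/TTS sites with read-count scores,
# full-length reads whose 3' ends split between internal terminators (ioTTS)
# and the operon TTS according to a per-terminator termination efficiency
# epsilon, coverage dropping by (1 - epsilon) downstream of each ioTTS,
# Poisson count noise, replicates, and a depletion condition in which every
# termination efficiency is scaled by a factor f (emulating depletion of a
# general termination factor).

#' Build a simulation configuration
#'
#' Defaults encode the stated world: internal-terminator efficiencies span
#' 0.3--0.8 (the 30--80\% termination observed for most terminators),
#' the depletion condition scales every efficiency by \code{depletion_factor}
#' (default 0.5), and each internal terminator carries a polyU tract
#' (\code{polyu_length} T's on the coding strand) ending at the ioTTS base.
#'
#' @param seed Integer RNG seed.
#' @param n_operons_by_type Named counts of operons per architecture type:
#'   \code{I} (no internal sites), \code{II} (>=1 ioTTS), \code{III}
#'   (>=1 ioTSS), \code{IV} (both).
#' @param genes_per_operon Integer range (min, max) of genes per operon
#'   (type IV needs >= 3 so the ioTTS and ioTSS occupy different intergenic
#'   regions).
#' @param gene_length,igr_length,utr_length Integer ranges in nt.
#' @param promoter_strength Range of relative promoter strengths; the operon
#'   promoter defines 1x read/coverage depth, internal promoters (ioTSS) get
#'   an independent strength from this range.
#' @param epsilon Range of per-ioTTS termination efficiency in [0, 1].
#' @param terminal_tte Range of operon-end terminator efficiency; reads that
#'   read through the operon TTS run off and end \code{runoff_distance} nt
#'   downstream.
#' @param depletion_factor Scalar f in (0, 1] multiplying every termination
#'   efficiency in the depletion condition; set \code{NA} to simulate a
#'   single condition.
#' @param read_depth Expected full-length reads initiating at an operon
#'   promoter per condition.
#' @param coverage_depth Expected per-base coverage at the operon 5' end.
#' @param n_replicates Coverage replicates per condition.
#' @param end_jitter_sd SD (nt) of rounded Gaussian jitter on read ends.
#' @param noise \code{"poisson"} (Poisson/Bernoulli sampling) or
#'   \code{"none"} (exact expectations; deterministic quota termination).
#' @param polyu_length T-tract length embedded upstream of each ioTTS.
#' @param runoff_distance nt a terminal read-through read extends past the
#'   operon TTS.
#' @param spacer_length Range of inter-operon gaps (must exceed
#'   \code{runoff_distance}).
#' @param conditions Names of the reference and depletion conditions.
#' @param contig Contig name of the single simulated chromosome.
#' @return A \code{simulation_config} list.
#' @export
simulation_config <- function(seed = 1L,
                              n_operons_by_type = c(I = 3L, II = 3L, III = 2L, IV = 2L),
                              genes_per_operon = c(2L, 5L),
                              gene_length = c(500L, 1500L),
                              igr_length = c(60L, 120L),
                              utr_length = c(20L, 60L),
                              promoter_strength = c(0.5, 1.5),
                              epsilon = c(0.3, 0.8),
                              terminal_tte = c(0.8, 1.0),
                              depletion_factor = 0.5,
                              read_depth = 50,
                              coverage_depth = 100,
                              n_replicates = 3L,
                              end_jitter_sd = 0,
                              noise = c("poisson", "none"),
                              polyu_length = 8L,
                              runoff_distance = 100L,
                              spacer_length = c(250L, 400L),
                              conditions = c(reference = "wt", depletion = "dep"),
                              contig = "chr") {
  noise <- match.arg(noise)
  cfg <- list(seed = as.integer(seed),
              n_operons_by_type = norm_type_counts(n_operons_by_type),
              genes_per_operon = as.integer(genes_per_operon),
              gene_length = as.integer(gene_length),
              igr_length = as.integer(igr_length),
              utr_length = as.integer(utr_length),
              promoter_strength = as.numeric(promoter_strength),
              epsilon = as.numeric(epsilon),
              terminal_tte = as.numeric(terminal_tte),
              depletion_factor = if (is.null(depletion_factor)) NA_real_ else as.numeric(depletion_factor),
              read_depth = as.numeric(read_depth),
              coverage_depth = as.numeric(coverage_depth),
              n_replicates = as.integer(n_replicates),
              end_jitter_sd = as.numeric(end_jitter_sd),
              noise = noise,
              polyu_length = as.integer(polyu_length),
              runoff_distance = as.integer(runoff_distance),
              spacer_length = as.integer(spacer_length),
              conditions = conditions,
              contig = contig)
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

norm_type_counts <- function(x) {
  out <- c(I = 0L, II = 0L, III = 0L, IV = 0L)
  out[names(x)] <- as.integer(x)
  out
}

validate_simulation_config <- function(cfg) {
  rng_ok <- function(r) length(r) == 2L && r[1] <= r[2]
  stopifnot(
    all(cfg$n_operons_by_type >= 0L), sum(cfg$n_operons_by_type) > 0L,
    rng_ok(cfg$genes_per_operon), cfg$genes_per_operon[1] >= 2L,
    rng_ok(cfg$gene_length), cfg$gene_length[1] > 0L,
    rng_ok(cfg$igr_length), rng_ok(cfg$utr_length),
    rng_ok(cfg$promoter_strength), cfg$promoter_strength[1] > 0,
    rng_ok(cfg$epsilon), cfg$epsilon[1] >= 0, cfg$epsilon[2] <= 1,
    rng_ok(cfg$terminal_tte), cfg$terminal_tte[1] >= 0, cfg$terminal_tte[2] <= 1,
    is.na(cfg$depletion_factor) ||
      (cfg$depletion_factor > 0 && cfg$depletion_factor <= 1),
    cfg$read_depth > 0, cfg$coverage_depth > 0, cfg$n_replicates >= 1L,
    cfg$end_jitter_sd >= 0, cfg$polyu_length >= 1L,
    cfg$runoff_distance >= 0L, rng_ok(cfg$spacer_length),
    cfg$spacer_length[1] > cfg$runoff_distance
  )
  # the ioTTS sits 20 nt into an IGR and the ioTSS 15 nt before the next gene;
  # the polyU tract must fit upstream of the ioTTS inside the IGR
  if (cfg$igr_length[1] < cfg$polyu_length + 12L + 20L) {
    stop("igr_length minimum too small to host a polyU tract, an ioTTS and an ioTSS")
  }
  invisible(cfg)
}

runif_int <- function(n, rng) {
  if (rng[1] == rng[2]) rep(as.integer(rng[1]), n)
  else as.integer(sample(seq.int(rng[1], rng[2]), n, replace = TRUE))
}

runif_rng <- function(n, rng) {
  if (rng[1] == rng[2]) rep(rng[1], n) else stats::runif(n, rng[1], rng[2])
}

#' Simulate the genome architecture and ground truth
#'
#' Places operons of the four architecture types on alternating strands with
#' at least an inter-operon spacer between them, embeds a polyU tract (T-run
#' on the coding strand, ending at the ioTTS base) under every internal
#' terminator, and records the full generative truth: per-operon gene lists,
#' type labels, boundary sites, and per-terminator termination efficiency in
#' every condition.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return A \code{simulation_truth} list with elements \code{genome}
#'   (\code{DNAStringSet}), \code{genes}, \code{operons}, \code{promoters},
#'   \code{terminators}, \code{expected_abundance}, \code{config}.
#' @export
simulate_architecture <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  types <- rep(names(config$n_operons_by_type), config$n_operons_by_type)
  n_op <- length(types)
  # interleave types so strand alternation is not confounded with type
  types <- types[order(rep_len(seq_len(n_op), n_op))]
  types <- sample(types)

  genes <- list(); promoters <- list(); terminators <- list(); operons <- list()
  cursor <- 100L   # left margin
  gid <- 0L
  for (k in seq_len(n_op)) {
    type <- types[k]
    strand <- if (k %% 2L == 1L) "+" else "-"
    ng <- max(runif_int(1L, config$genes_per_operon),
              if (type == "IV") 3L else 2L)
    glen <- runif_int(ng, config$gene_length)
    igr <- runif_int(max(ng - 1L, 0L), config$igr_length)
    utr5 <- runif_int(1L, config$utr_length)
    utr3 <- runif_int(1L, config$utr_length)

    # layout on the transcript axis (0 = first transcribed base)
    gstart <- utr5 + c(0L, cumsum(glen[-ng] + igr))
    gend <- gstart + glen
    tx_len <- utr5 + sum(glen) + sum(igr) + utr3
    tss_ax <- 0L
    tts_ax <- tx_len - 1L

    # internal sites on the axis; ioTTS 20 nt into IGR 1, ioTSS 15 nt before
    # the gene after IGR 2 (types III with one IGR: ioTSS in IGR 1)
    iotts_ax <- integer(0); iotss_ax <- integer(0)
    if (type %in% c("II", "IV")) iotts_ax <- gend[1L] + 19L
    if (type %in% c("III", "IV")) {
      igr_idx <- if (type == "IV") 2L else 1L
      iotss_ax <- gstart[igr_idx + 1L] - 15L
    }

    # genomic placement
    span <- tx_len
    ostart <- cursor
    ax2gen <- function(ax) if (strand == "+") ostart + ax else ostart + (span - 1L) - ax
    g_lo <- if (strand == "+") ostart + gstart else ostart + span - gend
    g_hi <- g_lo + glen
    op_id <- sprintf("op%03d", k)
    lt <- sprintf("%s_g%d", op_id, seq_len(ng))
    genes[[k]] <- data.frame(contig = config$contig, start = g_lo, end = g_hi,
                             strand = strand, locus_tag = lt,
                             operon_id = op_id, gene_index = seq_len(ng),
                             stringsAsFactors = FALSE)
    gid <- gid + ng

    tss_pos <- ax2gen(tss_ax); tts_pos <- ax2gen(tts_ax)
    strength0 <- runif_rng(1L, config$promoter_strength)
    promoters[[k]] <- data.frame(
      operon_id = op_id, contig = config$contig,
      position = c(tss_pos, vapply(iotss_ax, ax2gen, integer(1))),
      strand = strand,
      role = c("TSS", rep("ioTSS", length(iotss_ax))),
      # relative strength: 1 for the operon promoter so read/coverage depth
      # semantics hold exactly at the 5' end
      rel_strength = c(1, runif_rng(length(iotss_ax), config$promoter_strength) / strength0),
      stringsAsFactors = FALSE)

    eps <- runif_rng(length(iotts_ax), config$epsilon)
    ttte <- runif_rng(1L, config$terminal_tte)
    terminators[[k]] <- data.frame(
      operon_id = op_id, contig = config$contig,
      position = c(vapply(iotts_ax, ax2gen, integer(1)), tts_pos),
      strand = strand,
      role = c(rep("ioTTS", length(iotts_ax)), "TTS"),
      epsilon = c(eps, ttte),
      polyu_length = c(rep(config$polyu_length, length(iotts_ax)), 0L),
      stringsAsFactors = FALSE)

    operons[[k]] <- data.frame(
      operon_id = op_id, contig = config$contig,
      start = min(tss_pos, tts_pos), end = max(tss_pos, tts_pos) + 1L,
      strand = strand, type = type, n_genes = ng,
      tss = tss_pos, tts = tts_pos,
      gene_tags = paste(lt, collapse = ","),
      stringsAsFactors = FALSE)

    cursor <- cursor + span + runif_int(1L, config$spacer_length)
  }
  genome_len <- cursor + config$runoff_distance + 100L
  genes <- reset_rownames(do.call(rbind, genes))
  promoters <- reset_rownames(do.call(rbind, promoters))
  terminators <- reset_rownames(do.call(rbind, terminators))
  operons <- reset_rownames(do.call(rbind, operons))

  seq <- sample(c("A", "C", "G", "T"), genome_len, replace = TRUE)
  # polyU tract: T-run on the coding strand ending at the ioTTS base
  io <- terminators[terminators$role == "ioTTS", , drop = FALSE]
  for (i in seq_len(nrow(io))) {
    p <- io$position[i]; L <- io$polyu_length[i]
    if (io$strand[i] == "+") seq[(p - L + 2L):(p + 1L)] <- "T"
    else seq[(p + 1L):(p + L)] <- "A"   # sense T = reference A on the minus strand
  }
  genome <- Biostrings::DNAStringSet(paste(seq, collapse = ""))
  names(genome) <- config$contig

  truth <- structure(list(genome = genome, genes = genes, operons = operons,
                          promoters = promoters, terminators = terminators,
                          config = config),
                     class = "simulation_truth")
  truth$expected_abundance <- expected_gene_abundance(truth)
  truth
}

condition_epsilon <- function(truth, condition) {
  cfg <- truth$config
  eps <- truth$terminators$epsilon
  if (!is.na(cfg$depletion_factor) &&
      identical(condition, unname(cfg$conditions[["depletion"]]))) {
    eps <- eps * cfg$depletion_factor
  }
  eps
}

sim_conditions <- function(config) {
  if (is.na(config$depletion_factor)) unname(config$conditions[["reference"]])
  else unname(config$conditions)
}

# Expected per-gene per-condition abundance (per-base coverage units):
# coverage_depth x (sum over upstream promoters of rel_strength x
# read-through product over terminators between promoter and gene).
expected_gene_abundance <- function(truth) {
  cfg <- truth$config
  out <- list()
  for (cond in sim_conditions(cfg)) {
    eps <- condition_epsilon(truth, cond)
    for (op in truth$operons$operon_id) {
      g <- truth$genes[truth$genes$operon_id == op, , drop = FALSE]
      pr <- truth$promoters[truth$promoters$operon_id == op, , drop = FALSE]
      tm <- truth$terminators[truth$terminators$operon_id == op, , drop = FALSE]
      e <- eps[match(rownames(tm), rownames(truth$terminators))]
      strand <- g$strand[1L]
      # transcript-axis position of the 5'-most base of each feature
      ax <- function(pos) if (strand == "+") pos else -pos
      for (i in seq_len(nrow(g))) {
        gene_ax <- ax(if (strand == "+") g$start[i] else g$end[i] - 1L)
        lvl <- 0
        for (j in seq_len(nrow(pr))) {
          p_ax <- ax(pr$position[j])
          if (p_ax > gene_ax) next
          between <- ax(tm$position) > p_ax & ax(tm$position) < gene_ax &
            tm$role == "ioTTS"
          lvl <- lvl + pr$rel_strength[j] * prod(1 - e[between])
        }
        out[[length(out) + 1L]] <- data.frame(
          locus_tag = g$locus_tag[i], operon_id = op, condition = cond,
          expected = cfg$coverage_depth * lvl, stringsAsFactors = FALSE)
      }
    }
  }
  reset_rownames(do.call(rbind, out))
}

#' Simulate full-length transcript reads for one condition
#'
#' Each read initiates at a promoter (operon TSS or ioTSS, in proportion to
#' relative promoter strength) and, at each internal terminator it crosses,
#' terminates with the condition's efficiency \eqn{\epsilon}, else reads
#' through; survivors terminate at the operon TTS with the terminal
#' efficiency or run off \code{runoff_distance} nt further. Read ends receive
#' rounded Gaussian jitter (sd \code{end_jitter_sd}) truncated to the contig.
#' Under \code{noise = "none"} counts are deterministic quotas
#' (\code{round(eps * n)} of n crossing reads end at the terminator).
#'
#' @param truth A \code{simulation_truth}.
#' @param config The configuration (defaults to \code{truth$config}).
#' @param condition Condition name.
#' @return Read table: \code{contig}, \code{start}, \code{end} (0-based
#'   half-open), \code{strand}, \code{read_id}, \code{condition}.
#' @export
simulate_reads <- function(truth, config = truth$config, condition) {
  eps <- condition_epsilon(truth, condition)
  poisson <- config$noise == "poisson"
  glen <- length(truth$genome[[1L]])
  out <- list()
  rid <- 0L
  for (op in truth$operons$operon_id) {
    o <- truth$operons[truth$operons$operon_id == op, ]
    pr <- truth$promoters[truth$promoters$operon_id == op, , drop = FALSE]
    tm <- truth$terminators[truth$terminators$operon_id == op, , drop = FALSE]
    e <- eps[match(rownames(tm), rownames(truth$terminators))]
    strand <- o$strand
    ax <- function(pos) if (strand == "+") pos else -pos
    ord <- order(ax(tm$position))
    tm <- tm[ord, , drop = FALSE]; e <- e[ord]
    runoff_ax <- ax(o$tts) + config$runoff_distance
    for (j in seq_len(nrow(pr))) {
      n0 <- config$read_depth * pr$rel_strength[j]
      n <- if (poisson) stats::rpois(1L, n0) else as.integer(round(n0))
      if (n == 0L) next
      p_ax <- ax(pr$position[j])
      remaining <- n
      ends_ax <- integer(0)
      downstream <- which(ax(tm$position) > p_ax)
      for (t in downstream) {
        if (remaining == 0L) break
        stopp <- if (poisson) stats::rbinom(1L, remaining, e[t])
                 else as.integer(round(remaining * e[t]))
        if (stopp > 0L) ends_ax <- c(ends_ax, rep(ax(tm$position[t]), stopp))
        remaining <- remaining - stopp
      }
      if (remaining > 0L) ends_ax <- c(ends_ax, rep(runoff_ax, remaining))
      starts_ax <- rep(p_ax, n)
      if (config$end_jitter_sd > 0) {
        starts_ax <- starts_ax + as.integer(round(stats::rnorm(n, 0, config$end_jitter_sd)))
        ends_ax <- ends_ax + as.integer(round(stats::rnorm(n, 0, config$end_jitter_sd)))
        ends_ax <- pmax(ends_ax, starts_ax)   # keep intervals non-degenerate
      }
      # back to genomic: + strand read covers [start_ax, end_ax]; - strand mirrored
      if (strand == "+") {
        gs <- starts_ax; ge <- ends_ax + 1L
      } else {
        gs <- -ends_ax; ge <- -starts_ax + 1L
      }
      gs <- pmax(gs, 0L); ge <- pmin(ge, glen)
      keep <- gs < ge
      if (!any(keep)) next
      ids <- sprintf("%s_%s_p%d_r%d", condition, op, j, seq_len(sum(keep)))
      out[[length(out) + 1L]] <- data.frame(
        contig = o$contig, start = gs[keep], end = ge[keep], strand = strand,
        read_id = ids, condition = condition, stringsAsFactors = FALSE)
      rid <- rid + sum(keep)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(contig = character(0), start = integer(0), end = integer(0),
                      strand = character(0), read_id = character(0),
                      condition = character(0), stringsAsFactors = FALSE))
  }
  reset_rownames(do.call(rbind, out))
}

# TSS/TTS site tables derived from the simulated reads: records sit at the
# true site positions, count = reads whose (jittered) 5'/3' end falls exactly
# on the site base.
sites_from_reads <- function(truth, reads, condition) {
  five <- ifelse(reads$strand == "+", reads$start, reads$end - 1L)
  three <- ifelse(reads$strand == "+", reads$end - 1L, reads$start)
  pr <- truth$promoters
  tm <- truth$terminators
  tss <- data.frame(contig = pr$contig, position = pr$position, strand = pr$strand,
                    kind = "TSS",
                    count = vapply(seq_len(nrow(pr)), function(i)
                      sum(five == pr$position[i] & reads$strand == pr$strand[i]), integer(1)),
                    condition = condition,
                    name = sprintf("%s_%s", pr$operon_id, pr$role),
                    stringsAsFactors = FALSE)
  tts <- data.frame(contig = tm$contig, position = tm$position, strand = tm$strand,
                    kind = "TTS",
                    count = vapply(seq_len(nrow(tm)), function(i)
                      sum(three == tm$position[i] & reads$strand == tm$strand[i]), integer(1)),
                    condition = condition,
                    name = sprintf("%s_%s", tm$operon_id, tm$role),
                    stringsAsFactors = FALSE)
  reset_rownames(rbind(tss, tts))
}

#' Simulate strand-specific coverage for one condition and replicate
#'
#' Expected per-base coverage inside an operon is \code{coverage_depth} times
#' the cumulative read-through product over all upstream internal terminators
#' plus ioTSS contributions; past the operon TTS the terminal read-through
#' fraction persists for \code{runoff_distance} nt. Values are drawn Poisson
#' per base (or exact under \code{noise = "none"}).
#'
#' @param truth A \code{simulation_truth}.
#' @param config Configuration (defaults to \code{truth$config}).
#' @param condition Condition name.
#' @param replicate Replicate label.
#' @return List of two \code{coverage_track}s (strands \code{+} and \code{-}).
#' @export
simulate_coverage <- function(truth, config = truth$config, condition,
                              replicate = "rep1") {
  glen <- length(truth$genome[[1L]])
  eps <- condition_epsilon(truth, condition)
  mu <- list(`+` = numeric(glen), `-` = numeric(glen))
  for (op in truth$operons$operon_id) {
    o <- truth$operons[truth$operons$operon_id == op, ]
    pr <- truth$promoters[truth$promoters$operon_id == op, , drop = FALSE]
    tm <- truth$terminators[truth$terminators$operon_id == op, , drop = FALSE]
    e <- eps[match(rownames(tm), rownames(truth$terminators))]
    strand <- o$strand
    ax <- function(pos) if (strand == "+") pos else -pos
    tts_ax <- ax(o$tts)
    runoff_ax <- tts_ax + config$runoff_distance
    # breakpoints on the transcript axis where the level changes
    for (j in seq_len(nrow(pr))) {
      p_ax <- ax(pr$position[j])
      tm_ds <- which(ax(tm$position) > p_ax)
      tm_ds <- tm_ds[order(ax(tm$position)[tm_ds])]
      seg_start <- p_ax
      lvl <- config$coverage_depth * pr$rel_strength[j]
      for (t in tm_ds) {
        seg_end <- ax(tm$position[t])
        mu[[strand]] <- add_segment(mu[[strand]], strand, seg_start, seg_end, lvl, glen)
        lvl <- lvl * (1 - e[t])
        seg_start <- seg_end + 1L
      }
      if (lvl > 0) {
        mu[[strand]] <- add_segment(mu[[strand]], strand, seg_start, runoff_ax, lvl, glen)
      }
    }
  }
  lapply(c("+", "-"), function(s) {
    vals <- if (config$noise == "poisson") as.numeric(stats::rpois(glen, mu[[s]]))
            else mu[[s]]
    new_coverage_track(truth$operons$contig[1L], s, condition, replicate, vals)
  })
}

# add `lvl` over axis interval [a_ax, b_ax] inclusive, mapped back to genome
add_segment <- function(v, strand, a_ax, b_ax, lvl, glen) {
  if (b_ax < a_ax) return(v)
  if (strand == "+") { lo <- a_ax; hi <- b_ax } else { lo <- -b_ax; hi <- -a_ax }
  lo <- max(lo, 0L); hi <- min(hi, glen - 1L)
  if (lo > hi) return(v)
  v[(lo + 1L):(hi + 1L)] <- v[(lo + 1L):(hi + 1L)] + lvl
  v
}

#' Simulate the complete evidence set
#'
#' Runs \code{\link{simulate_architecture}}, \code{\link{simulate_reads}} and
#' \code{\link{simulate_coverage}} for every condition and replicate under
#' the configured seed.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return List with \code{truth}, \code{reads} (all conditions), \code{sites}
#'   (per-condition TSS/TTS tables), \code{coverage} (list of
#'   \code{coverage_track}s).
#' @export
simulate_dataset <- function(config) {
  truth <- simulate_architecture(config)
  conds <- sim_conditions(config)
  reads <- list(); sites <- list(); coverage <- list()
  for (cond in conds) {
    r <- simulate_reads(truth, config, cond)
    reads[[cond]] <- r
    sites[[cond]] <- sites_from_reads(truth, r, cond)
    for (rep_i in seq_len(config$n_replicates)) {
      coverage <- c(coverage, simulate_coverage(truth, config, cond,
                                                sprintf("rep%d", rep_i)))
    }
  }
  list(truth = truth,
       reads = reset_rownames(do.call(rbind, unname(reads))),
       sites = reset_rownames(do.call(rbind, unname(sites))),
       coverage = coverage)
}

#' Write a simulated dataset to disk
#'
#' Emits FASTA, GFF3, per-condition TSS/TTS BED6 (scores = read-count
#' support), reads BED6, per-condition per-replicate per-strand bedGraphs, a
#' truth TSV (one row per internal terminator with its efficiency in every
#' condition), and a manifest TSV tagging every file.
#'
#' @param dataset Output of \code{\link{simulate_dataset}}.
#' @param out_dir Output directory (created if needed).
#' @return The manifest \code{data.frame} (also written as
#'   \code{manifest.tsv}).
#' @export
write_dataset <- function(dataset, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  truth <- dataset$truth
  cfg <- truth$config
  manifest <- list()
  add <- function(file, type, condition = NA, replicate = NA, strand = NA) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      file = file, type = type, condition = condition, replicate = replicate,
      strand = strand, stringsAsFactors = FALSE)
  }
  p <- function(f) file.path(out_dir, f)

  write_genome(truth$genome, p("genome.fa")); add("genome.fa", "fasta")
  write_annotation(truth$genes[, c("contig", "start", "end", "strand", "locus_tag")],
                   p("genes.gff3")); add("genes.gff3", "gff3")
  write_reads(dataset$reads, p("reads.bed")); add("reads.bed", "reads_bed")

  for (cond in unique(dataset$sites$condition)) {
    for (kind in c("TSS", "TTS")) {
      s <- dataset$sites[dataset$sites$condition == cond &
                           dataset$sites$kind == kind, , drop = FALSE]
      f <- sprintf("%s_%s.bed", tolower(kind), cond)
      write_sites(s, p(f)); add(f, paste0(tolower(kind), "_bed"), cond)
    }
  }
  for (tr in dataset$coverage) {
    stag <- if (tr$strand == "+") "fwd" else "rev"
    f <- sprintf("coverage_%s_%s_%s.bedgraph", tr$condition, tr$replicate, stag)
    write_coverage(tr, p(f))
    add(f, "bedgraph", tr$condition, tr$replicate, tr$strand)
  }

  tt <- truth_terminator_table(truth)
  utils::write.table(tt, p("truth_terminators.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  add("truth_terminators.tsv", "truth_tsv")
  ot <- truth$operons
  utils::write.table(ot, p("truth_operons.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  add("truth_operons.tsv", "truth_operons_tsv")

  manifest <- reset_rownames(do.call(rbind, manifest))
  utils::write.table(manifest, p("manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest
}

# one row per internal terminator: position, polyU length, epsilon per condition
truth_terminator_table <- function(truth) {
  io <- truth$terminators[truth$terminators$role == "ioTTS", , drop = FALSE]
  cfg <- truth$config
  out <- io[, c("operon_id", "contig", "position", "strand", "polyu_length")]
  out$epsilon_reference <- io$epsilon
  if (!is.na(cfg$depletion_factor)) {
    out$epsilon_depletion <- io$epsilon * cfg$depletion_factor
  }
  reset_rownames(out)
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf("<simulation_truth> %d operons (%s), %d genes, genome %d nt\n",
              nrow(x$operons),
              paste(sprintf("%s:%d", names(table(x$operons$type)),
                            as.integer(table(x$operons$type))), collapse = " "),
              nrow(x$genes), length(x$genome[[1L]])))
  invisible(x)
}
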