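#' Configuration of the synthetic fragment-library generator
#'
#' Bundles the ground-truth parameters of every bias the generator can plant:
#' positional fragmentation propensity, fragment-end sequence preference,
#' GC-dependent PCR amplification efficiency, and 3' degradation. Defaults
#' follow standard bulk library preparation: 13 PCR cycles, transcripts of
#' 600--7000 bases, lognormal expression, ~200 bp fragments size-selected to
#' 100--400 bp, 8-base UMIs.
#'
#' @param n_genes Number of single-exon genes.
#' @param length_range Inclusive transcript-length range in bases.
#' @param gc_profile Per-gene target GC fraction (scalar recycled, or vector
#'   of length `n_genes`).
#' @param gc_wave Optional within-gene positional GC modulation,
#'   `list(amplitude=, period=)` (bases): target GC at position p becomes
#'   `gc + amplitude * sin(2*pi*p/period)`. Couples position to fragment GC
#'   so GC-dependent PCR efficiency becomes positional.
#' @param expression `list(meanlog=, sdlog=)` of the lognormal expression
#'   weights.
#' @param frag_len `list(mean=, sd=, min=, max=)`: fragment length is Normal
#'   (rounded, clipped at the transcript 3' end) and the size-selection
#'   window keeps lengths in `[min, max]`.
#' @param frag_propensity `list(type="flat")` or `list(type="troughs",
#'   centers=, amplitude=, width=)`: relative fragment retention weight
#'   `1 - amplitude * sum_j exp(-(p - c_j)^2 / (2 width^2))`, evaluated at
#'   the fragment midpoint, with trough centers given as fractions of
#'   transcript length. Fragments whose midpoint falls in a trough are
#'   preferentially lost, planting a coverage valley centered on the trough.
#' @param end_pwm `NULL` (no end bias) or `list(start=, end=)` of 4 x 12
#'   probability matrices (rows A,C,G,T); fragments are accepted by rejection
#'   sampling with probability proportional to the PWM likelihood of their
#'   first and last 12 bases.
#' @param decay_3p Per-base 3' degradation rate delta >= 0: each molecule
#'   survives as a 3'-side suffix whose length is Exponential(delta) capped
#'   at the transcript length, so the chance that the position at distance d
#'   from the 3' end is still present is exp(-delta * d).
#' @param pcr_cycles Number of PCR cycles E >= 0.
#' @param gc_efficiency `list(e_min=, e_max=, midpoint=, slope=)`: per-cycle
#'   duplication probability of a fragment with GC fraction g is
#'   `e_min + (e_max - e_min) * plogis(slope * (g - midpoint))`. Set
#'   `e_min == e_max` for a constant efficiency.
#' @param depth Total sequenced fragments (drawn without replacement from the
#'   amplified pool, so duplicates arise only through amplification).
#' @param oversample Library complexity factor: molecules are generated until
#'   the amplified pool holds at least `oversample * depth` copies, so
#'   sequencing samples about `1/oversample` of the library (default 3).
#' @param umi_len UMI length in bases.
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @return A `BiasConfig` list.
#' @export
bias_config <- function(n_genes = 100,
                        length_range = c(600, 7000),
                        gc_profile = 0.5,
                        gc_wave = NULL,
                        expression = list(meanlog = 0, sdlog = 1),
                        frag_len = list(mean = 200, sd = 40, min = 100, max = 400),
                        frag_propensity = list(type = "flat"),
                        end_pwm = NULL,
                        decay_3p = 0,
                        pcr_cycles = 13,
                        gc_efficiency = list(e_min = 0.05, e_max = 0.35,
                                             midpoint = 0.5, slope = 5),
                        depth = 1e5,
                        oversample = 3,
                        umi_len = 8,
                        seed = 1) {
  stopifnot(is_count(n_genes),
            length(length_range) == 2L, length_range[1] <= length_range[2],
            frag_len$min <= frag_len$max,
            decay_3p >= 0, is_count(pcr_cycles), oversample >= 1,
            gc_efficiency$e_min >= 0, gc_efficiency$e_max <= 1,
            gc_efficiency$e_min <= gc_efficiency$e_max,
            is_count(depth), is_count(umi_len), umi_len >= 1)
  gc_profile <- rep_len(gc_profile, max(1L, n_genes))
  if (any(gc_profile <= 0 | gc_profile >= 1)) stop2("gc_profile must be in (0,1)")
  structure(list(n_genes = n_genes, length_range = length_range,
                 gc_profile = gc_profile, gc_wave = gc_wave,
                 expression = expression, frag_len = frag_len,
                 frag_propensity = frag_propensity, end_pwm = end_pwm,
                 decay_3p = decay_3p, pcr_cycles = pcr_cycles,
                 gc_efficiency = gc_efficiency, depth = depth,
                 oversample = oversample, umi_len = umi_len, seed = seed),
            class = "BiasConfig")
}

gc_curve <- function(cfg) {
  g <- cfg$gc_efficiency
  function(gc) g$e_min + (g$e_max - g$e_min) * stats::plogis(g$slope * (gc - g$midpoint))
}

propensity_weights <- function(cfg, L) {
  fp <- cfg$frag_propensity
  if (is.null(fp) || identical(fp$type, "flat")) return(rep(1, L))
  if (!identical(fp$type, "troughs")) stop2("unknown frag_propensity type")
  p <- seq_len(L) - 1L
  w <- rep(1, L)
  width <- fp$width %||% 150
  for (c_rel in fp$centers) {
    w <- w - fp$amplitude * exp(-(p - c_rel * L)^2 / (2 * width^2))
  }
  pmax(w, 0.01)
}

#' Generate a synthetic single-isoform transcriptome
#'
#' Single-exon genes with i.i.d. bases at each gene's target GC fraction
#' (optionally modulated along the transcript by `gc_wave`) and lengths
#' uniform over `length_range`. Deterministic under `cfg$seed`.
#'
#' @param cfg A [bias_config()].
#' @return List with `models` (named list of [transcript_model()], one
#'   single-exon gene each) and `sequences` (named character vector keyed by
#'   transcript id).
#' @export
make_transcriptome <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_genes
  if (n == 0L) return(list(models = list(), sequences = character(0)))
  if (cfg$length_range[1] < 600 || cfg$length_range[2] > 7000) {
    warning("length_range outside [600, 7000]: genes would fail annotation filters")
  }
  lens <- sample.int(cfg$length_range[2] - cfg$length_range[1] + 1L, n,
                     replace = TRUE) + cfg$length_range[1] - 1L
  gids <- sprintf("SIMG%04d", seq_len(n))
  tids <- sprintf("SIMT%04d", seq_len(n))
  models <- list()
  sequences <- character(n)
  for (i in seq_len(n)) {
    L <- lens[i]
    gc <- rep(cfg$gc_profile[i], L)
    if (!is.null(cfg$gc_wave)) {
      p <- seq_len(L) - 1L
      gc <- gc + cfg$gc_wave$amplitude * sin(2 * pi * p / cfg$gc_wave$period)
      gc <- pmin(0.95, pmax(0.05, gc))
    }
    is_gc <- runif(L) < gc
    pick <- runif(L) < 0.5
    base <- ifelse(is_gc, ifelse(pick, "G", "C"), ifelse(pick, "A", "T"))
    sequences[i] <- paste(base, collapse = "")
    models[[gids[i]]] <- transcript_model(
      gene_id = gids[i], transcript_id = tids[i],
      chrom = paste0("chr_", gids[i]), strand = "+",
      exons = cbind(0, L), biotype = "protein_coding")
  }
  names(sequences) <- tids
  list(models = models, sequences = sequences)
}

#' Simulate a sequenced fragment library with planted biases
#'
#' Emulates the library-preparation chain molecule by molecule: expression-
#' weighted gene draw; 3' degradation to an exponentially distributed 3'
#' suffix; fragmentation with uniform starts, Normal length and size
#' selection (a candidate fragment falling outside the surviving suffix is
#' lost, so degradation reduces yield and coverage at distance d from the 3'
#' end decays as exp(-delta d)); positional retention by the fragmentation-
#' propensity profile at the fragment midpoint; fragment-end PWM acceptance by
#' rejection sampling; UMI attachment; per-cycle Bernoulli PCR amplification
#' with GC-dependent efficiency (a Galton--Watson branching process); and
#' finally sequencing of `depth` copies drawn without replacement from the
#' pooled amplified copies, so PCR duplicates arise only through
#' amplification, mirroring UMI semantics.
#'
#' @param cfg A [bias_config()].
#' @param models,sequences Output of [make_transcriptome()] (or compatible
#'   single-exon models).
#' @return List with `fragments` -- one row per sequenced raw copy
#'   (`transcript_id`, 0-based `start`/`end`, `umi`, `read1_gc`,
#'   `unique_mapping`) ready for [dedup_fragments()] -- and `truth`, a
#'   `TruthBundle`: the planted PWMs, per-gene propensity weights, the GC
#'   efficiency curve parameters, expression weights, and the pre-PCR
#'   molecule table with amplified copy and sequenced counts.
#' @export
simulate_library <- function(cfg, models, sequences) {
  set.seed(cfg$seed + 1L)
  n <- base::length(models)
  if (n == 0L) stop2("no models to simulate from")
  tids <- vapply(models, `[[`, "", "transcript_id")
  lens <- vapply(models, `[[`, 0, "length")
  seqs <- as_sequence_set(sequences)[tids]

  expr_w <- stats::rlnorm(n, cfg$expression$meanlog, cfg$expression$sdlog)
  prop_w <- lapply(lens, function(L) propensity_weights(cfg, L))
  cum_gc <- lapply(seqs, function(s) {
    b <- base_codes(s)
    c(0, cumsum(b == 2L | b == 3L))
  })
  eff <- gc_curve(cfg)

  use_pwm <- !is.null(cfg$end_pwm)
  if (use_pwm) {
    sp <- end_pwm(cfg$end_pwm$start, "fragment_start", pseudocount = 0)
    ep <- end_pwm(cfg$end_pwm$end, "fragment_end", pseudocount = 0)
    ll_s <- lapply(seqs, function(s) window_loglik(base_codes(s), sp))
    ll_e <- lapply(seqs, function(s) window_loglik(base_codes(s), ep))
    ll_max <- sum(log2(apply(sp$freqs, 2, max))) +
      sum(log2(apply(ep$freqs, 2, max)))
  }

  fl <- cfg$frag_len
  E <- cfg$pcr_cycles
  mol <- list()
  pool <- 0
  n_mol <- 0
  cand_total <- 0
  acc_total <- 0
  batch <- 0L
  amp_est <- (1 + mean(c(cfg$gc_efficiency$e_min, cfg$gc_efficiency$e_max)))^E

  pool_target <- (cfg$oversample %||% 3) * cfg$depth
  while (pool < pool_target) {
    batch <- batch + 1L
    if (batch > 500L) stop2("simulation failed to reach requested depth")
    acc_frac <- if (cand_total > 0) max(acc_total / cand_total, 1e-4) else 0.5
    B <- max(20000L, ceiling(1.3 * (pool_target - pool) / (amp_est * acc_frac)))

    g <- sample.int(n, B, replace = TRUE, prob = expr_w)
    Lg <- lens[g]
    # 3' degradation: surviving suffix length ~ Exp(delta), capped
    surv_start <- if (cfg$decay_3p > 0) {
      pmax(0, ceiling(Lg - rexp(B, cfg$decay_3p)))
    } else {
      rep(0, B)
    }
    st <- as.integer(floor(runif(B) * Lg))
    flen <- round(rnorm(B, fl$mean, fl$sd))
    en <- pmin(st + flen, Lg)
    flen <- en - st
    keep <- st >= surv_start & flen >= max(fl$min, if (use_pwm) 12 else 1) &
      flen <= fl$max
    cand_total <- cand_total + sum(keep)
    g <- g[keep]; st <- st[keep]; en <- en[keep]; flen <- flen[keep]
    if (base::length(g) == 0L) next

    # positional fragmentation propensity: retain a candidate with
    # probability given by the trough profile at its midpoint, so a planted
    # trough center coincides with the resulting coverage-valley center
    flat <- identical(cfg$frag_propensity$type %||% "flat", "flat")
    if (!flat) {
      pacc <- numeric(base::length(g))
      mid <- (st + en) %/% 2L
      for (gi in unique(g)) {
        sel <- which(g == gi)
        w <- prop_w[[gi]]
        pacc[sel] <- w[mid[sel] + 1L] / max(w)
      }
      acc <- runif(base::length(g)) < pacc
      g <- g[acc]; st <- st[acc]; en <- en[acc]; flen <- flen[acc]
      if (base::length(g) == 0L) next
    }

    if (use_pwm) {
      lls <- numeric(base::length(g))
      lle <- numeric(base::length(g))
      for (gi in unique(g)) {
        sel <- which(g == gi)
        lls[sel] <- ll_s[[gi]][st[sel] + 1L]
        lle[sel] <- ll_e[[gi]][en[sel] - 11L]
      }
      acc <- runif(base::length(g)) < 2^(lls + lle - ll_max)
      g <- g[acc]; st <- st[acc]; en <- en[acc]; flen <- flen[acc]
    }
    acc_total <- acc_total + base::length(g)
    if (cand_total >= 10000 && acc_total / cand_total < 1e-3) {
      stop2("PWM acceptance rate below 1e-3; use a weaker end PWM")
    }
    if (base::length(g) == 0L) next

    r1len <- pmin(100L, flen)
    frag_gc <- numeric(base::length(g))
    read1_gc <- numeric(base::length(g))
    for (gi in unique(g)) {
      sel <- which(g == gi)
      cg <- cum_gc[[gi]]
      frag_gc[sel] <- (cg[en[sel] + 1L] - cg[st[sel] + 1L]) / flen[sel]
      read1_gc[sel] <- (cg[st[sel] + r1len[sel] + 1L] - cg[st[sel] + 1L]) / r1len[sel]
    }

    nm <- base::length(g)
    umi_mat <- matrix(BASES[sample.int(4L, nm * cfg$umi_len, replace = TRUE)],
                      nrow = nm)
    umi <- do.call(paste0, as.data.frame(umi_mat, stringsAsFactors = FALSE))

    e <- eff(frag_gc)
    copies <- rep(1L, nm)
    for (cyc in seq_len(E)) {
      copies <- copies + rbinom(nm, copies, e)
    }

    mol[[batch]] <- data.frame(gene = g, transcript_id = tids[g],
                               start = st, end = en, umi = umi,
                               frag_gc = frag_gc, read1_gc = read1_gc,
                               efficiency = e, copies = copies,
                               stringsAsFactors = FALSE)
    pool <- pool + sum(copies)
    n_mol <- n_mol + nm
  }

  mol <- do.call(rbind, mol)
  rownames(mol) <- NULL
  idx <- rep.int(seq_len(nrow(mol)), mol$copies)
  sel <- sample(idx, cfg$depth)
  mol$n_sequenced <- tabulate(sel, nbins = nrow(mol))

  seen <- which(mol$n_sequenced > 0L)
  rows <- rep.int(seen, mol$n_sequenced[seen])
  fragments <- data.frame(
    transcript_id = mol$transcript_id[rows],
    start = mol$start[rows], end = mol$end[rows],
    umi = mol$umi[rows], read1_gc = mol$read1_gc[rows],
    unique_mapping = TRUE, stringsAsFactors = FALSE)

  truth <- structure(list(
    end_pwm = cfg$end_pwm,
    frag_propensity = list(spec = cfg$frag_propensity, weights = prop_w),
    gc_efficiency = cfg$gc_efficiency,
    decay_3p = cfg$decay_3p,
    expression = stats::setNames(expr_w, names(models)),
    molecules = mol,
    seed = cfg$seed), class = "TruthBundle")
  list(fragments = fragments, truth = truth)
}

#' Export a simulated library to plain-text files
#'
#' Writes the fragment table (TSV dialect of [read_fragments()]), the
#' transcript FASTA, a toy GTF of the single-exon genes, and a JSON file of
#' the planted ground truth. Byte-identical across runs for a fixed seed.
#'
#' @param sim Output of [simulate_library()].
#' @param models,sequences The simulated transcriptome.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the paths written.
#' @export
export_library <- function(sim, models, sequences, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(fragments = file.path(dir, "fragments.tsv"),
             fasta = file.path(dir, "transcriptome.fa"),
             gtf = file.path(dir, "annotation.gtf"),
             truth = file.path(dir, "truth.json"))
  write_fragments(sim$fragments, paths[["fragments"]])
  seqs <- as_sequence_set(sequences)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), paths[["fasta"]])
  write_toy_gtf(models, paths[["gtf"]])
  truth <- sim$truth
  jsonlite::write_json(
    list(end_pwm = truth$end_pwm,
         frag_propensity = truth$frag_propensity$spec,
         gc_efficiency = truth$gc_efficiency,
         decay_3p = truth$decay_3p,
         expression = as.list(truth$expression),
         seed = truth$seed),
    paths[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Write transcript models as an Ensembl-dialect GTF
#'
#' @param models Named list of [transcript_model()].
#' @param path Output path.
#' @export
write_toy_gtf <- function(models, path) {
  lines <- character(0)
  for (m in models) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                     m$gene_id, m$transcript_id, m$biotype)
    span <- c(min(m$exons[, 1]) + 1, max(m$exons[, 2]))
    lines <- c(lines,
               paste(m$chrom, "sim", "gene", span[1], span[2], ".",
                     m$strand, ".",
                     sprintf('gene_id "%s"; gene_biotype "%s";',
                             m$gene_id, m$biotype), sep = "\t"),
               paste(m$chrom, "sim", "transcript", span[1], span[2], ".",
                     m$strand, ".", attrs, sep = "\t"))
    for (i in seq_len(nrow(m$exons))) {
      lines <- c(lines,
                 paste(m$chrom, "sim", "exon",
                       m$exons[i, 1] + 1, m$exons[i, 2], ".",
                       m$strand, ".", attrs, sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
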