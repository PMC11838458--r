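test_that("synthetic transcriptomes hit target GC, length range, and are seed-stable", {
  cfg <- bias_config(n_genes = 8, length_range = c(1900, 2100),
                     gc_profile = 0.5, seed = 141)
  tx <- make_transcriptome(cfg)
  expect_length(tx$models, 8)
  lens <- vapply(tx$models, `[[`, 0, "length")
  expect_true(all(lens >= 1900 & lens <= 2100))
  gc_real <- vapply(tx$sequences, function(s) {
    b <- strsplit(s, "")[[1]]
    mean(b %in% c("G", "C"))
  }, numeric(1))
  expect_true(all(abs(gc_real - 0.5) < 0.03))

  tx2 <- make_transcriptome(cfg)
  expect_identical(tx$sequences, tx2$sequences)

  empty <- make_transcriptome(bias_config(n_genes = 0, seed = 1))
  expect_length(empty$models, 0)
  expect_length(empty$sequences, 0)

  expect_warning(make_transcriptome(bias_config(n_genes = 1,
                                                length_range = c(200, 300),
                                                seed = 1)),
                 "filters")
})

test_that("no amplification means no duplicates; full efficiency doubles per cycle", {
  cfg0 <- bias_config(n_genes = 4, length_range = c(800, 1200), depth = 4000,
                      pcr_cycles = 0, seed = 151)
  lib0 <- quick_library(cfg0)
  expect_true(all(lib0$dedup$dup_group_size == 1L))

  cfg1 <- bias_config(n_genes = 4, length_range = c(800, 1200), depth = 4000,
                      pcr_cycles = 3,
                      gc_efficiency = list(e_min = 1, e_max = 1,
                                           midpoint = 0.5, slope = 0),
                      seed = 152)
  tx <- make_transcriptome(cfg1)
  sim <- simulate_library(cfg1, tx$models, tx$sequences)
  expect_true(all(sim$truth$molecules$copies == 8L))
})

test_that("expected amplified pool size follows the branching process (1+e)^E", {
  e <- 0.2; E <- 5
  cfg <- bias_config(n_genes = 5, length_range = c(1000, 1400), depth = 10000,
                     pcr_cycles = E,
                     gc_efficiency = list(e_min = e, e_max = e,
                                          midpoint = 0.5, slope = 0),
                     oversample = 2, seed = 161)
  tx <- make_transcriptome(cfg)
  sim <- simulate_library(cfg, tx$models, tx$sequences)
  expect_gt(nrow(sim$truth$molecules), 10000)
  expect_equal(mean(sim$truth$molecules$copies), (1 + e)^E, tolerance = 0.02)
})

test_that("sequenced depth, fragment bounds, and UMI format are honored", {
  cfg <- bias_config(n_genes = 6, length_range = c(700, 1500), depth = 9000,
                     pcr_cycles = 4, seed = 171)
  lib <- quick_library(cfg)
  expect_equal(nrow(lib$sim$fragments), 9000)
  expect_equal(sum(lib$dedup$dup_group_size), 9000)
  lens <- setNames(vapply(lib$tx$models, `[[`, 0, "length"),
                   vapply(lib$tx$models, `[[`, "", "transcript_id"))
  expect_true(all(lib$dedup$start >= 0))
  expect_true(all(lib$dedup$end <= lens[lib$dedup$transcript_id]))
  flen <- lib$dedup$end - lib$dedup$start
  expect_true(all(flen >= 100 & flen <= 400))
  expect_true(all(nchar(lib$sim$fragments$umi) == 8))
})

test_that("null configuration: no 3' trend, near-zero valley scores, flat GC dupe rates", {
  cfg <- bias_config(n_genes = 10, length_range = c(1500, 2500), depth = 30000,
                     expression = list(meanlog = 0, sdlog = 0),
                     pcr_cycles = 6,
                     gc_efficiency = list(e_min = 0.15, e_max = 0.15,
                                          midpoint = 0.5, slope = 0),
                     seed = 181)
  lib <- quick_library(cfg)
  gvs <- vapply(lib$tracks, global_valley_score, numeric(1))
  expect_lt(median(gvs), 0.05)

  tab <- gc_binned_dupe_rate(lib$dedup)
  occ <- tab[!is.na(tab$rate) & tab$n >= 100, ]
  expect_lt(max(occ$rate) - min(occ$rate), 0.1)
})

test_that("export then ingest reproduces the fragment multiset and the planted truth", {
  pw <- planted_pwm(0.3)
  cfg <- bias_config(n_genes = 3, length_range = c(700, 900), depth = 2000,
                     end_pwm = list(start = pw, end = pw),
                     pcr_cycles = 2, oversample = 2, seed = 191)
  tx <- make_transcriptome(cfg)
  sim <- simulate_library(cfg, tx$models, tx$sequences)
  dir1 <- withr::local_tempdir()
  paths <- export_library(sim, tx$models, tx$sequences, dir1)

  back <- read_fragments(paths[["fragments"]])
  key <- function(df) sort(paste(df$transcript_id, df$start, df$end, df$umi))
  expect_identical(key(back), key(sim$fragments))

  fa <- Biostrings::readDNAStringSet(paths[["fasta"]])
  expect_identical(as.character(fa), tx$sequences)

  models_back <- load_annotation(paths[["gtf"]])
  expect_setequal(names(models_back), names(tx$models))
  expect_equal(vapply(models_back, `[[`, 0, "length")[names(tx$models)],
               vapply(tx$models, `[[`, 0, "length"))

  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_equal(as.matrix(truth$end_pwm$start), pw,
               tolerance = 1e-12, ignore_attr = TRUE)

  # byte-identical re-export under the same seed
  sim2 <- simulate_library(cfg, tx$models, tx$sequences)
  dir2 <- withr::local_tempdir()
  paths2 <- export_library(sim2, tx$models, tx$sequences, dir2)
  for (f in names(paths)) {
    expect_identical(readLines(paths[[f]]), readLines(paths2[[f]]))
  }
})

test_that("planted fragmentation troughs carve valleys at the planted positions", {
  cfg <- bias_config(n_genes = 8, length_range = c(1500, 2500), depth = 40000,
                     expression = list(meanlog = 0, sdlog = 0),
                     frag_propensity = list(type = "troughs", centers = c(0.35, 0.7),
                                            amplitude = 0.85, width = 120),
                     pcr_cycles = 0, oversample = 1, seed = 301)
  lib <- quick_library(cfg)
  hits <- vapply(lib$tx$models, function(m) {
    sm <- smooth_track(lib$tracks[[m$gene_id]], 30)
    vl <- find_valleys(sm)
    if (nrow(vl) == 0) return(0)
    planted <- c(0.35, 0.7) * m$length
    mean(vapply(planted, function(pc) any(abs(vl$min_pos - pc) <= 100), logical(1)))
  }, numeric(1))
  expect_gte(mean(hits), 0.8)
})

test_that("an overly strong acceptance PWM is rejected with advice", {
  sharp <- matrix(0.01, 4, 12, dimnames = list(c("A", "C", "G", "T"), NULL))
  sharp[1, ] <- 0.97
  cfg <- bias_config(n_genes = 2, length_range = c(700, 900), depth = 500,
                     end_pwm = list(start = sharp, end = sharp),
                     pcr_cycles = 0, oversample = 1, seed = 201)
  tx <- make_transcriptome(cfg)
  expect_error(simulate_library(cfg, tx$models, tx$sequences), "weaker")
})
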