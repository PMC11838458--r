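test_that("multi-isoform genes are excluded and exons merged on load", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(toy_gtf_lines(), gtf)
  models <- load_annotation(gtf)
  expect_setequal(names(models), c("gA", "gC"))
  expect_equal(models$gA$length, 200)
  expect_equal(models$gA$exons, cbind(start = c(100, 300), end = c(200, 400)))
  expect_equal(models$gC$strand, "-")
  expect_equal(models$gC$biotype, "lncRNA")
})

test_that("malformed GTF lines are reported with their line number", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(toy_gtf_lines(), "chr1 broken line without tabs"), gtf)
  expect_error(load_annotation(gtf), "line 7")
})

test_that("random single-isoform GTFs match a line-by-line hand parser", {
  set.seed(42)
  models_in <- list()
  for (i in 1:50) {
    n_ex <- sample(1:4, 1)
    starts <- cumsum(sample(50:500, n_ex * 2))
    exons <- cbind(starts[seq(1, 2 * n_ex, 2)], starts[seq(2, 2 * n_ex, 2)])
    gid <- sprintf("rg%02d", i)
    models_in[[gid]] <- transcript_model(
      gene_id = gid, transcript_id = paste0(gid, ".t1"),
      chrom = sample(c("chr1", "chr2"), 1),
      strand = sample(c("+", "-"), 1), exons = exons,
      biotype = sample(c("protein_coding", "lncRNA", "snoRNA"), 1))
  }
  gtf <- withr::local_tempfile(fileext = ".gtf")
  write_toy_gtf(models_in, gtf)

  got <- load_annotation(gtf)
  want <- oracle_parse_gtf(gtf)
  expect_setequal(names(got), names(want))
  for (g in names(want)) {
    expect_equal(got[[g]]$transcript_id, want[[g]]$transcript_id)
    expect_equal(got[[g]]$length, want[[g]]$length)
    expect_equal(got[[g]]$strand, want[[g]]$strand)
    expect_equal(got[[g]]$biotype, want[[g]]$biotype)
    expect_equal(unname(got[[g]]$exons), unname(want[[g]]$exons))
  }
})

make_model <- function(id, len, biotype = "protein_coding") {
  transcript_model(gene_id = id, transcript_id = paste0(id, ".t"),
                   chrom = "chr1", strand = "+", exons = cbind(0, len),
                   biotype = biotype)
}

test_that("gene selection filters by length and biotype with inclusive bounds", {
  lens <- c(500, 650, 7000, 7500, 3000)
  models <- setNames(
    lapply(seq_along(lens), function(i) make_model(paste0("g", i), lens[i])),
    paste0("g", seq_along(lens)))
  expr <- setNames(rep(10, 5), names(models))
  sel <- suppressWarnings(select_genes(models, expr, n = 5))
  expect_setequal(vapply(sel, `[[`, 0, "length"), c(650, 7000, 3000))

  models$g2$biotype <- "snoRNA"
  sel2 <- suppressWarnings(select_genes(models, expr, n = 5))
  expect_setequal(vapply(sel2, `[[`, 0, "length"), c(7000, 3000))
})

test_that("expression ties break lexicographically and ranking matches a sort oracle", {
  models <- setNames(lapply(c("A", "B", "C"), make_model, len = 1000),
                     c("A", "B", "C"))
  sel <- select_genes(models, c(A = 10, B = 10, C = 5), n = 2)
  expect_equal(unname(vapply(sel, `[[`, "", "gene_id")), c("A", "B"))

  set.seed(7)
  ids <- sprintf("g%03d", 1:200)
  models <- setNames(lapply(ids, make_model, len = 2000), ids)
  expr <- setNames(sample(0:50, 200, replace = TRUE), ids)
  sel <- select_genes(models, expr, n = 100)
  got <- unname(vapply(sel, `[[`, "", "gene_id"))
  want <- ids[order(-expr, ids)][1:100]
  expect_equal(got, unname(want))

  expect_error(select_genes(list(), expr, n = 1), "empty")
  expect_warning(select_genes(models[1:3], expr, n = 100), "only 3")
})

test_that("fragment projection removes introns, flips strand, rejects intronic ends", {
  plus <- transcript_model("g", "t", "chr1", "+",
                           exons = cbind(c(0, 200), c(100, 300)))
  expect_equal(project_fragment(50, 250, plus), c(50, 150))
  expect_null(project_fragment(150, 160, plus))
  expect_error(project_fragment(200, 200, plus), "start")

  minus <- transcript_model("g", "t", "chr1", "-", exons = cbind(0, 100))
  expect_equal(project_fragment(10, 20, minus), c(80, 90))
})

test_that("projection preserves exonic overlap length and partitions the transcript", {
  set.seed(11)
  for (rep in 1:20) {
    n_ex <- sample(1:4, 1)
    bounds <- cumsum(sample(20:200, n_ex * 2))
    exons <- cbind(bounds[seq(1, 2 * n_ex, 2)], bounds[seq(2, 2 * n_ex, 2)])
    m <- transcript_model("g", "t", "chr1", sample(c("+", "-"), 1), exons)

    # brute-force per-base genomic -> transcript map
    gpos <- unlist(lapply(seq_len(n_ex), function(i) seq.int(exons[i, 1], exons[i, 2] - 1)))
    span <- range(gpos)
    for (k in 1:20) {
      gs <- sample(seq.int(span[1] - 10, span[2] + 10), 1)
      ge <- gs + sample(1:150, 1)
      tv <- project_fragment(gs, ge, m)
      overlap <- sum(gpos >= gs & gpos < ge)
      ends_exonic <- any(gpos == gs) && any(gpos == ge - 1)
      if (!ends_exonic) {
        expect_null(tv)
      } else {
        # interior introns removed: transcript width = full span of exonic
        # positions between the endpoints in transcript space
        expect_false(is.null(tv))
        expect_true(tv[1] >= 0 && tv[2] <= m$length && tv[1] < tv[2])
        expect_equal(tv[2] - tv[1],
                     sum(gpos >= gs & gpos < ge &
                           gpos >= min(gpos[gpos >= gs]) &
                           gpos <= max(gpos[gpos < ge])))
        expect_equal(tv[2] - tv[1], overlap)
      }
    }
    # exon intervals project onto a partition of [0, length)
    projected <- lapply(seq_len(n_ex), function(i)
      project_fragment(exons[i, 1], exons[i, 2], m))
    covered <- sort(unlist(lapply(projected, function(p) seq.int(p[1], p[2] - 1))))
    expect_equal(covered, seq.int(0, m$length - 1))
  }
})

test_that("gene list writer round-trips the selection table", {
  models <- setNames(lapply(c("A", "B"), make_model, len = 1000), c("A", "B"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gene_list(models, c(A = 5, B = 2), path)
  df <- read.delim(path)
  expect_equal(df$gene_id, c("A", "B"))
  expect_equal(df$count, c(5, 2))
})
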