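test_that("tblout parsing skips comments, preserves fields, dedupes", {
  f <- withr::local_tempfile(fileext = ".tblout")
  writeLines(c(
    "# comment", "#", "# target name  accession query ...",
    "geneA - NuoB - 3.2e-50 210.5 0.0 4e-50 209.0 0.0 1.0 1 0 0 1 1 1 1 desc here",
    "geneB - NuoL - 1e-8 40.1 0.0 2e-8 39.0 0.0 1.0 1 0 0 1 1 1 1 -",
    rep("# trailing", 7)), f)
  hits <- read_hmm_hits(f, "tblout")
  expect_equal(nrow(hits), 2)
  expect_equal(hits$evalue[hits$gene_id == "geneA"], 3.2e-50)
  expect_equal(hits$profile, c("NuoB", "NuoL"))
  expect_true(all(is.na(hits$env_from)))

  # best-domain switch picks column 8
  hits_bd <- read_hmm_hits(f, "tblout", score_type = "best_domain")
  expect_equal(hits_bd$evalue[hits_bd$gene_id == "geneA"], 4e-50)

  # duplicate (gene, profile) rows keep the smallest e-value
  writeLines(c(
    "geneA - NuoB - 1e-10 50 0.0 1e-10 50 0.0 1.0 1 0 0 1 1 1 1 -",
    "geneA - NuoB - 1e-40 150 0.0 1e-40 150 0.0 1.0 1 0 0 1 1 1 1 -"), f)
  expect_equal(read_hmm_hits(f, "tblout")$evalue, 1e-40)
  expect_equal(nrow(read_hmm_hits(f, "tblout", dedupe = FALSE)), 2)
})

test_that("domtblout keeps one hit per domain row with its envelope", {
  f <- withr::local_tempfile(fileext = ".domtblout")
  # two domains of NuoG on one protein (a fused-gene signature)
  writeLines(c(
    "#",
    "geneF - 900 NuoG - 850 2.2e-80 270.0 0.0 1 2 1e-50 1.2e-49 170.0 0.0 3 420 10 430 5 440 0.95 -",
    "geneF - 900 NuoG - 850 2.2e-80 270.0 0.0 2 2 1e-30 1.5e-29 100.0 0.0 430 840 450 880 445 890 0.93 -"), f)
  hits <- read_hmm_hits(f, "domtblout")
  expect_equal(nrow(hits), 2)
  expect_equal(unique(hits$gene_id), "geneF")
  expect_equal(unique(hits$evalue), 2.2e-80)
  expect_equal(hits$env_from, c(5L, 445L))
  expect_equal(hits$env_to, c(440L, 890L))
})

test_that("malformed rows raise parse errors naming the line", {
  f <- withr::local_tempfile()
  writeLines(c("# ok", "geneA - NuoB - 1e-10"), f)
  expect_error(read_hmm_hits(f, "tblout"), "line 2")
  writeLines(c(
    "geneA - NuoB - not_a_number 50 0.0 1e-10 50 0.0 1.0 1 0 0 1 1 1 1 -"), f)
  expect_error(read_hmm_hits(f, "tblout"), "non-numeric e-value at line 1")
  writeLines("# only comments", f)
  expect_warning(h <- read_hmm_hits(f, "tblout"), "no data rows")
  expect_equal(nrow(h), 0)
})

test_that("parsing is independent of record order", {
  sim <- simulate_dataset(sim_config(n_species = 8, seed = 3))
  d <- withr::local_tempdir()
  write_fixture(sim, d)
  lines <- readLines(file.path(d, "hits.tblout"))
  data_rows <- !grepl("^#", lines)
  shuffled <- lines
  set.seed(1)
  shuffled[data_rows] <- sample(lines[data_rows])
  f2 <- file.path(d, "shuffled.tblout")
  writeLines(shuffled, f2)
  expect_equal(read_hmm_hits(file.path(d, "hits.tblout")),
               read_hmm_hits(f2))
})

test_that("prodigal deflines parse coordinates, strand and length", {
  f <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(
    ">ctg1_1 # 2 # 308 # 1 # ID=1_1;partial=00",
    ">ctg1_2 # 400 # 1000 # -1 # ID=1_2",
    "MSEQUENCE"), f)
  g <- read_gene_calls(f, "prodigal_headers")
  g1 <- g[g$gene_id == "ctg1_1", ]
  expect_equal(g1$start, 2L)
  expect_equal(g1$end, 308L)
  expect_equal(g1$strand, "+")
  expect_equal(g1$protein_length, 101L)  # (308-2+1)/3 - 1
  expect_equal(g$strand[g$gene_id == "ctg1_2"], "-")
  expect_equal(unique(g$replicon_id), "ctg1")

  writeLines(">ctg1_1 # 500 # 100 # 1 # x", f)
  expect_warning(g2 <- read_gene_calls(f, "prodigal_headers"),
                 "end < start")
  expect_equal(nrow(g2), 0)
  writeLines(">ctg1_1 # 1 # 99 # ? # x", f)
  expect_error(read_gene_calls(f, "prodigal_headers"), "strand")
})

test_that("gff3 reading preserves coordinates and types replicons", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tCDS\t100\t400\t.\t+\t0\tID=gA",
    "plasmid_p1\tsrc\tCDS\t10\t312\t.\t-\t0\tID=gB",
    "scaffold9\tsrc\tCDS\t5\t307\t.\t+\t0\tID=gC"), f)
  g <- read_gene_calls(f, "gff3")
  expect_equal(g$start[g$gene_id == "gA"], 100L)
  expect_equal(g$end[g$gene_id == "gA"], 400L)
  expect_equal(g$strand[g$gene_id == "gA"], "+")
  expect_equal(g$protein_length[g$gene_id == "gA"], 99L)
  # keyword typing when no replicon map is given
  expect_equal(g$replicon_type[g$gene_id == "gA"], "chromosome")
  expect_equal(g$replicon_type[g$gene_id == "gB"], "plasmid")
  expect_equal(g$replicon_type[g$gene_id == "gC"], "unknown")
  # explicit metadata beats the keyword
  rmap <- tibble::tibble(replicon_id = c("chr1", "plasmid_p1", "scaffold9"),
                         genome_id = "G1",
                         replicon_type = c("chromosome", "chromosome",
                                           "plasmid"))
  g2 <- read_gene_calls(f, "gff3", replicons = rmap)
  expect_equal(g2$replicon_type[g2$gene_id == "gB"], "chromosome")
  expect_equal(g2$replicon_type[g2$gene_id == "gC"], "plasmid")
  expect_equal(unique(g2$genome_id), "G1")
})

test_that("genome curation applies the retention rules idempotently", {
  md <- tibble::tibble(
    genome_id = sprintf("G%d", 1:6),
    assembly_level = c("complete", "chromosome", "scaffold", "complete",
                       "complete", "Complete"),
    phylum = c("P", "P", "P", "", "P", "P"),
    genus = c("g", "g", "g", "g", "g", NA),
    candidatus_flag = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE))
  cur <- curate_genomes(md)
  expect_equal(cur$genome_id, c("G1", "G2"))
  excl <- attr(cur, "exclusions")
  expect_equal(excl$n_excluded[excl$rule == "candidatus"], 1L)
  expect_equal(excl$n_excluded[excl$rule == "missing_phylum"], 1L)
  expect_equal(excl$n_excluded[excl$rule == "missing_genus"], 1L)
  expect_equal(excl$n_excluded[excl$rule == "assembly_level"], 1L)
  # subset of input, and idempotent
  expect_true(all(cur$genome_id %in% md$genome_id))
  cur2 <- curate_genomes(cur)
  expect_equal(cur2, cur, ignore_attr = TRUE)
})

test_that("result tables round-trip through TSV including list columns", {
  d <- withr::local_tempdir()
  # cluster-like table with list columns
  x <- tibble::tibble(
    cluster_id = c("a", "b"),
    member_genes = list(c("g1", "g2"), "g3"),
    n = c(2L, 1L))
  p <- file.path(d, "x.tsv")
  write_result_tsv(x, p)
  y <- read_result_tsv(p, list_cols = "member_genes")
  expect_equal(y$member_genes, x$member_genes)
  expect_equal(y$n, x$n)
  # variant-call and contingency-style plain tables
  sim <- simulate_dataset(sim_config(n_species = 8, seed = 5))
  for (tab in list(sim$metadata, sim$truth)) {
    p2 <- file.path(d, "t.tsv")
    write_result_tsv(tab, p2)
    back <- read_result_tsv(p2)
    expect_equal(as.data.frame(back),
                 as.data.frame(dplyr::arrange(tab, dplyr::pick(
                   dplyr::everything()))))
  }
})
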