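test_that("intergenic gap is clamped and replicon-checked", {
  a <- tibble::tibble(replicon_id = "r", start = 100L, end = 400L)
  expect_equal(intergenic_gap(a, tibble::tibble(replicon_id = "r",
                                                start = 600L, end = 900L)),
               199L)
  expect_equal(intergenic_gap(a, tibble::tibble(replicon_id = "r",
                                                start = 401L, end = 700L)),
               0L)
  expect_equal(intergenic_gap(a, tibble::tibble(replicon_id = "r",
                                                start = 350L, end = 700L)),
               0L)
  expect_error(intergenic_gap(a, tibble::tibble(replicon_id = "r2",
                                                start = 600L, end = 900L)),
               "different replicons")
})

test_that("gaps of (100, 300) at max_gap 250 split into {g1,g2} and {g3}", {
  op <- make_operon(c("NuoA", "NuoB", "NuoC"), gaps = c(100, 300))
  cl <- cluster_hits(op$genes, op$hits, max_gap = 250)
  expect_equal(nrow(cl), 2)
  expect_equal(sort(vapply(cl$member_genes, paste, "", collapse = ",")),
               c("g1,g2", "g3"))
})

test_that("opposite-strand neighbours never merge; singletons allowed", {
  op <- make_operon(c("NuoA", "NuoB"), gaps = 50)
  op$genes$strand <- c("+", "-")
  cl <- cluster_hits(op$genes, op$hits, max_gap = 250)
  expect_equal(nrow(cl), 2)
  expect_equal(sort(cl$n_genes), c(1L, 1L))
  one <- make_operon("NuoA", gaps = integer(0))
  expect_equal(nrow(cluster_hits(one$genes, one$hits, 250)), 1)
})

test_that("intervening non-hit genes count toward the gap but never join", {
  op <- make_operon(c("NuoA", "NuoB"), gaps = 400)
  # a hit-less 200 bp-spanning gene inside the 400 bp gap does not bridge
  filler <- tibble::tibble(
    gene_id = "filler", genome_id = "G1", replicon_id = "r1",
    replicon_type = "chromosome",
    start = op$genes$end[1] + 100L, end = op$genes$end[1] + 280L,
    strand = "+", protein_length = 59L)
  genes <- dplyr::bind_rows(op$genes, filler)
  cl <- cluster_hits(genes, op$hits, max_gap = 250)
  expect_equal(nrow(cl), 2)
  expect_false("filler" %in% unlist(cl$member_genes))
})

test_that("unresolvable hits raise an error naming the gene ids", {
  op <- make_operon(c("NuoA", "NuoB"), gaps = 10)
  bad <- dplyr::bind_rows(op$hits,
                          tibble::tibble(gene_id = "ghost", profile = "NuoC",
                                         evalue = 1e-50, bitscore = 100,
                                         env_from = NA, env_to = NA))
  expect_error(cluster_hits(op$genes, bad, 250), "ghost")
})

test_that("clustering matches the union-find transitive-closure oracle", {
  for (seed in c(0:24, 100:109)) {
    genes <- random_cluster_instance(seed)
    hits <- tibble::tibble(gene_id = genes$gene_id, profile = "NuoA",
                           evalue = 1e-50, bitscore = 100,
                           env_from = NA_integer_, env_to = NA_integer_)
    max_gap <- sample(c(0, 100, 250, 500), 1)
    cl <- cluster_hits(genes, hits, max_gap)
    got <- canonical_partition(cl$member_genes)
    want <- canonical_partition(oracle_cluster_partition(genes, max_gap))
    expect_equal(got, want, info = paste("seed", seed))
  }
})

test_that("clustering is invariant to input row order", {
  genes <- random_cluster_instance(123)
  hits <- tibble::tibble(gene_id = genes$gene_id, profile = "NuoB",
                         evalue = 1e-40, bitscore = 90,
                         env_from = NA_integer_, env_to = NA_integer_)
  cl1 <- cluster_hits(genes, hits, 250)
  set.seed(9)
  cl2 <- cluster_hits(genes[sample(nrow(genes)), ],
                      hits[sample(nrow(hits)), ], 250)
  expect_equal(cl1, cl2)
})

test_that("clusters refine monotonically in max_gap", {
  for (seed in 200:204) {
    genes <- random_cluster_instance(seed, n_max = 40)
    hits <- tibble::tibble(gene_id = genes$gene_id, profile = "NuoA",
                           evalue = 1e-50, bitscore = 100,
                           env_from = NA_integer_, env_to = NA_integer_)
    lo <- cluster_hits(genes, hits, 100)
    hi <- cluster_hits(genes, hits, 400)
    # each tight cluster is contained in some loose cluster
    for (m in lo$member_genes) {
      containing <- vapply(hi$member_genes,
                           function(h) all(m %in% h), logical(1))
      expect_equal(sum(containing), 1L)
    }
  }
})

test_that("cluster typing is fusion-aware", {
  profiles <- c("NuoA", "NuoB", "NuoCD", paste0("Nuo", LETTERS[5:14]))
  op <- make_operon(profiles, gaps = rep(50, length(profiles) - 1))
  cl <- cluster_hits(op$genes, op$hits, 250)
  expect_equal(cl$cluster_type, "Complete")
  expect_true(cl$has_fused)
  # drop one subunit -> Partial
  op2 <- make_operon(profiles[-1], gaps = rep(50, length(profiles) - 2))
  expect_equal(cluster_hits(op2$genes, op2$hits, 250)$cluster_type,
               "Partial")
})

test_that("the complete count is non-decreasing along a gap scan", {
  sim <- simulate_dataset(sim_config(n_species = 10, seed = 11))
  scan <- scan_gap_thresholds(sim$gene_calls, sim$hits,
                              thresholds = seq(0, 500, 50),
                              taxonomy = sim$metadata)
  expect_true(all(diff(scan$n_complete) >= 0))
  # brute-force spot check at two thresholds via full re-clustering
  for (t in c(100, 400)) {
    cl <- cluster_hits(sim$gene_calls, sim$hits, t)
    per <- dplyr::summarise(
      dplyr::group_by(dplyr::inner_join(
        cl, sim$metadata[c("genome_id", "species")], by = "genome_id"),
        species),
      complete = any(cluster_type == "Complete"), .groups = "drop")
    expect_equal(scan$n_complete[scan$max_gap == t], sum(per$complete))
  }
})

test_that("plateau detection follows the relative-growth rule", {
  # growth stops after 250
  scan <- tibble::tibble(max_gap = seq(0, 500, 25),
                         n_complete = pmin(seq(0, 500, 25), 250) / 5,
                         n_partial = 0)
  expect_equal(detect_plateau(scan), 250)
  # constant scan: first threshold
  flat <- tibble::tibble(max_gap = seq(0, 100, 25), n_complete = 7,
                         n_partial = 3)
  expect_equal(detect_plateau(flat), 0)
  # strictly linear growth: falls back to the last threshold, warns
  lin <- tibble::tibble(max_gap = seq(0, 100, 25),
                        n_complete = seq(5, 25, 5), n_partial = 0)
  expect_warning(p <- detect_plateau(lin), "plateau")
  expect_equal(p, 100)
})
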