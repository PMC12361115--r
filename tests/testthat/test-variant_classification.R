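mk_hit <- function(gene, profile, evalue = 1e-60, from = NA, to = NA) {
  tibble::tibble(gene_id = gene, profile = profile, evalue = evalue,
                 bitscore = 100, env_from = as.integer(from),
                 env_to = as.integer(to))
}

test_that("fused-profile hits expand to their mapped subunits", {
  expect_equal(resolve_gene_subunits(mk_hit("g", "NuoCD")),
               c("NuoC", "NuoD"))
  expect_equal(resolve_gene_subunits(mk_hit("g", "NuoBCD")),
               c("NuoB", "NuoC", "NuoD"))
})

test_that("non-overlapping envelopes fuse, coinciding envelopes collapse", {
  # NuoB aa 1-180 and NuoC aa 200-380: overlap 0 -> genuine fusion
  h <- dplyr::bind_rows(mk_hit("g", "NuoB", 1e-60, 1, 180),
                        mk_hit("g", "NuoC", 1e-55, 200, 380))
  expect_equal(resolve_gene_subunits(h), c("NuoB", "NuoC"))
  # NuoL and NuoM both spanning aa 1-500: paralog ambiguity, best e-value
  h2 <- dplyr::bind_rows(mk_hit("g", "NuoL", 1e-70, 1, 500),
                         mk_hit("g", "NuoM", 1e-60, 1, 500))
  expect_equal(resolve_gene_subunits(h2), "NuoL")
  # hits without envelopes are treated as full-length -> collapse too
  h3 <- dplyr::bind_rows(mk_hit("g", "NuoL", 1e-60),
                         mk_hit("g", "NuoM", 1e-70))
  expect_equal(resolve_gene_subunits(h3), "NuoM")
  # 11% envelope overlap: tolerated at the 0.2 default, collapsed at 0.1
  h4 <- dplyr::bind_rows(mk_hit("g", "NuoB", 1e-60, 1, 100),
                         mk_hit("g", "NuoC", 1e-55, 90, 189))
  expect_equal(resolve_gene_subunits(h4, max_overlap_frac = 0.2),
               c("NuoB", "NuoC"))
  expect_equal(resolve_gene_subunits(h4, max_overlap_frac = 0.1),
               "NuoB")
})

classify_fixture <- function(op) {
  cl <- cluster_hits(op$genes, op$hits, 250)
  classify_genomes(cl, op$hits, op$genes)
}

test_that("a single 14-gene cluster is Complete14/single_cluster", {
  op <- make_operon(nuo14(), gaps = rep(50, 13))
  call <- classify_fixture(op)
  expect_equal(call$variant, "Complete14")
  expect_equal(call$arrangement, "single_cluster")
  expect_equal(call$n_complete_sets, 1L)
  expect_equal(call$on_plasmid, "none")
})

test_that("fused CD and fused BCD genomes get their variants", {
  cd <- make_operon(c("NuoA", "NuoB", "NuoCD", paste0("Nuo", LETTERS[5:14])),
                    gaps = rep(50, 12))
  expect_equal(classify_fixture(cd)$variant, "Complete13_fusedCD")
  bcd <- make_operon(c("NuoA", "NuoBCD", paste0("Nuo", LETTERS[5:14])),
                     gaps = rep(50, 11))
  expect_equal(classify_fixture(bcd)$variant, "Complete_fusedBCD")
})

test_that("missing {E,F} or {E,F,G} is CI-like, other misses Incomplete", {
  ef <- make_operon(setdiff(nuo14(), c("NuoE", "NuoF")), gaps = rep(50, 11))
  expect_equal(classify_fixture(ef)$variant, "CI_like")
  efg <- make_operon(setdiff(nuo14(), c("NuoE", "NuoF", "NuoG")),
                     gaps = rep(50, 10))
  expect_equal(classify_fixture(efg)$variant, "CI_like")
  other <- make_operon(setdiff(nuo14(), c("NuoE", "NuoL")),
                       gaps = rep(50, 11))
  expect_equal(classify_fixture(other)$variant, "Incomplete")
  one <- make_operon("NuoB", gaps = integer(0))
  expect_equal(classify_fixture(one)$variant, "Incomplete")
})

test_that("split operons still classify complete, via the union", {
  a <- make_operon(nuo14()[1:7], gaps = rep(50, 6), id_prefix = "a")
  b <- make_operon(nuo14()[8:14], gaps = rep(50, 6), id_prefix = "b",
                   start0 = 50000)
  genes <- dplyr::bind_rows(a$genes, b$genes)
  hits <- dplyr::bind_rows(a$hits, b$hits)
  call <- classify_genomes(cluster_hits(genes, hits, 250), hits, genes)
  expect_equal(call$variant, "Complete14")
  expect_equal(call$arrangement, "split")
  expect_equal(call$n_complete_sets, 1L)
})

test_that("two disjoint full operons count two complete sets", {
  a <- make_operon(nuo14(), gaps = rep(50, 13), id_prefix = "a")
  b <- make_operon(nuo14(), gaps = rep(50, 13), id_prefix = "b",
                   start0 = 80000)
  genes <- dplyr::bind_rows(a$genes, b$genes)
  hits <- dplyr::bind_rows(a$hits, b$hits)
  call <- classify_genomes(cluster_hits(genes, hits, 250), hits, genes)
  expect_equal(call$variant, "Complete14")
  expect_equal(call$n_complete_sets, 2L)
  expect_equal(call$arrangement, "single_cluster")
})

test_that("plasmid placement is tracked through to the genome call", {
  p <- make_operon(nuo14(), gaps = rep(50, 13), replicon = "p1",
                   replicon_type = "plasmid")
  call <- classify_fixture(p)
  expect_equal(call$on_plasmid, "exclusive")
  # chromosome hits alongside a full plasmid set -> complete
  chrom <- make_operon("NuoB", gaps = integer(0), replicon = "c1",
                       id_prefix = "c")
  genes <- dplyr::bind_rows(p$genes, chrom$genes)
  hits <- dplyr::bind_rows(p$hits, chrom$hits)
  call2 <- classify_genomes(cluster_hits(genes, hits, 250), hits, genes)
  expect_equal(call2$on_plasmid, "complete")
  # only part of the set on a plasmid -> partial
  pp <- make_operon(nuo14()[1:3], gaps = rep(50, 2), replicon = "p1",
                    replicon_type = "plasmid", id_prefix = "p")
  genes3 <- dplyr::bind_rows(pp$genes, chrom$genes)
  hits3 <- dplyr::bind_rows(pp$hits, chrom$hits)
  call3 <- classify_genomes(cluster_hits(genes3, hits3, 250), hits3, genes3)
  expect_equal(call3$on_plasmid, "partial")
})

test_that("genomes without hits are Absent", {
  op <- make_operon(nuo14(), gaps = rep(50, 13))
  empty_hits <- op$hits[0, ]
  call <- classify_genomes(cluster_hits(op$genes, empty_hits, 250),
                           empty_hits, op$genes)
  expect_equal(call$variant, "Absent")
  expect_equal(call$subunits_found[[1]], character(0))
  expect_equal(call$n_complete_sets, 0L)
})

test_that("classification is invariant to input ordering", {
  sim <- simulate_dataset(sim_config(n_species = 8, seed = 31))
  cl <- cluster_hits(sim$gene_calls, sim$hits, 250)
  c1 <- classify_genomes(cl, sim$hits, sim$gene_calls)
  set.seed(5)
  c2 <- classify_genomes(cl[sample(nrow(cl)), ],
                         sim$hits[sample(nrow(sim$hits)), ],
                         sim$gene_calls[sample(nrow(sim$gene_calls)), ])
  expect_equal(c1, c2)
})

test_that("greedy disjoint-cover count matches exhaustive search", {
  # realistic instances: 0-2 full operon copies in their own clusters,
  # plus scattered singleton extras (single subunits or a fused CD gene)
  required <- c("A", "B", "C", "D")
  sch <- subunit_scheme("toy", required,
                        fused_profiles = list(FCD = c("C", "D")))
  set.seed(77)
  for (rep in 1:20) {
    k <- sample(0:2, 1)
    extras <- sample(c("A", "B", "C", "D", "FCD"), sample(0:4, 1),
                     replace = TRUE)
    parts <- list()
    if (k > 0) {
      parts <- lapply(seq_len(k), function(i) {
        make_operon(required, gaps = rep(50, 3),
                    start0 = i * 50000, id_prefix = paste0("c", i, "_"),
                    evalue = 10^-runif(1, 40, 60))
      })
    }
    parts <- c(parts, lapply(seq_along(extras), function(i) {
      make_operon(extras[i], gaps = integer(0),
                  start0 = 500000 + i * 50000,
                  id_prefix = paste0("e", i, "_"),
                  evalue = 10^-runif(1, 40, 60))
    }))
    if (length(parts) == 0) next
    genes <- dplyr::bind_rows(lapply(parts, `[[`, "genes"))
    hits <- dplyr::bind_rows(lapply(parts, `[[`, "hits"))
    sets <- c(rep(as.list(required), k),
              lapply(extras, function(p) if (p == "FCD") c("C", "D")
                     else p))
    cl <- cluster_hits(genes, hits, 250, scheme = sch)
    call <- classify_genomes(cl, hits, genes, scheme = sch)
    want <- oracle_max_complete_sets(sets, required)
    expect_equal(call$n_complete_sets, want, info = paste("rep", rep))
  }
})

test_that("species aggregation flags inconsistency and breaks ties", {
  calls <- tibble::tibble(
    genome_id = sprintf("G%d", 1:6),
    variant = c("Complete14", "Complete14", "Complete14",
                "Complete14", "Complete13_fusedCD", "Absent"))
  tax <- tibble::tibble(genome_id = sprintf("G%d", 1:6),
                        species = c("s1", "s1", "s1", "s2", "s2", "s3"))
  agg <- aggregate_species(calls, tax)
  expect_true(agg$consistent[agg$species == "s1"])
  expect_false(agg$consistent[agg$species == "s2"])
  expect_equal(agg$variants_observed[agg$species == "s2"][[1]],
               c("Complete13_fusedCD", "Complete14"))
  # 1-1 tie resolves toward the more complete variant
  expect_equal(agg$representative_variant[agg$species == "s2"],
               "Complete14")
  expect_true(agg$consistent[agg$species == "s3"])
  tax2 <- tax[tax$genome_id != "G6", ]
  expect_warning(agg2 <- aggregate_species(calls, tax2), "without species")
  expect_equal(nrow(agg2), 2)
})

test_that("rank summaries exclude small taxa and sum to 100%", {
  summaries <- tibble::tibble(
    species = sprintf("s%02d", 1:19),
    representative_variant = c(rep("Complete14", 4), rep("Absent", 6),
                               rep("CI_like", 9)))
  tax <- tibble::tibble(species = summaries$species,
                        phylum = c(rep("BigPhylum", 10),
                                   rep("SmallPhylum", 9)))
  out <- summarize_by_rank(summaries, tax, "phylum", min_species = 10)
  expect_equal(unique(out$taxon), "BigPhylum")
  expect_equal(out$pct[out$variant == "Complete14"], 40)
  expect_equal(out$pct[out$variant == "Absent"], 60)
  sums <- dplyr::summarise(dplyr::group_by(out, taxon),
                           s = sum(pct))$s
  expect_true(all(abs(sums - 100) < 0.01))
})
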