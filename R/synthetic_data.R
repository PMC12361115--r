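#' Simulation configuration
#'
#' Parameters for generating a synthetic dataset of prokaryotic genomes
#' with planted subunit operons, decoy homolog hits, fused genes, plasmid
#' replicons and multi-strain species, together with a ground-truth table
#' for scoring every pipeline stage.
#'
#' Defaults emulate the structure of real profile-HMM searches for the Nuo
#' operon: intra-operon intergenic gaps are uniform on \[0, 100\] bp (real
#' operons are tightly packed, and the Complete-cluster count in real data
#' levels off beyond roughly 100 bp); genuine hits draw log10 e-values from
#' N(-50, 2) and decoy cross-hits (wrong-subunit homologs, the classic
#' NuoB/HycG confusion) from N(-5, 2), i.e. populations tens of decades
#' apart as observed for well-conserved subunits; operon copies or split
#' fragments are separated by at least `inter_cluster_gap_min` bp (at
#' least ten times `gap_max`) so distinct clusters never merge within the
#' scanned threshold range.
#'
#' @param n_species Number of species (default 40; with the strain
#'   distribution below this yields about 50 genomes).
#' @param strains_per_species Named probability vector over strain counts.
#' @param variant_mix Named probability vector over the six variants;
#'   species counts are allocated by largest remainder with at least one
#'   species per variant.
#' @param gap_max Upper bound of the uniform intra-operon gap (bp).
#' @param inter_cluster_gap_min Minimum separation between independent
#'   gene runs (bp); must be > 10 * `gap_max`.
#' @param true_evalue,decoy_evalue `c(mean, sd)` of log10 e-values of
#'   genuine and decoy hits; decoy mean must exceed true mean.
#' @param decoy_rate Expected decoy hits per genome (Poisson).
#' @param decoy_profiles Profiles decoys mimic.
#' @param split_fraction,dual_copy_fraction,plasmid_fraction Fractions of
#'   complete-variant species with a split operon, a second full operon
#'   copy, or a plasmid-exclusive operon (disjoint sets, at least one
#'   species each).
#' @param length_sd_frac Protein-length standard deviation as a fraction
#'   of the subunit mean.
#' @param n_background Background (non-subunit) genes per genome.
#' @param seed Single global seed; all randomness flows from it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_species = 40,
                       strains_per_species = c("1" = 0.75, "2" = 0.20,
                                               "3" = 0.05),
                       variant_mix = c(Complete14 = 0.30,
                                       Complete13_fusedCD = 0.14,
                                       Complete_fusedBCD = 0.10,
                                       CI_like = 0.12,
                                       Incomplete = 0.16,
                                       Absent = 0.18),
                       gap_max = 100,
                       inter_cluster_gap_min = 2000,
                       true_evalue = c(mean = -50, sd = 2),
                       decoy_evalue = c(mean = -5, sd = 2),
                       decoy_rate = 2,
                       decoy_profiles = c("NuoB", "NuoD", "NuoL", "NuoM"),
                       split_fraction = 0.10,
                       dual_copy_fraction = 0.06,
                       plasmid_fraction = 0.08,
                       length_sd_frac = 0.05,
                       n_background = 8,
                       seed = 1) {
  stopifnot(abs(sum(variant_mix) - 1) < 1e-8,
            abs(sum(strains_per_species) - 1) < 1e-8,
            setequal(names(variant_mix), variant_levels()),
            decoy_evalue[["mean"]] > true_evalue[["mean"]],
            inter_cluster_gap_min > 10 * gap_max,
            n_species >= 6)
  structure(
    list(n_species = n_species,
         strains_per_species = strains_per_species,
         variant_mix = variant_mix, gap_max = gap_max,
         inter_cluster_gap_min = inter_cluster_gap_min,
         true_evalue = true_evalue, decoy_evalue = decoy_evalue,
         decoy_rate = decoy_rate, decoy_profiles = decoy_profiles,
         split_fraction = split_fraction,
         dual_copy_fraction = dual_copy_fraction,
         plasmid_fraction = plasmid_fraction,
         length_sd_frac = length_sd_frac,
         n_background = n_background, seed = seed),
    class = "sim_config"
  )
}

# mean protein lengths (aa), loosely anchored on E. coli Nuo subunits
sim_subunit_lengths <- function() {
  c(NuoA = 147, NuoB = 220, NuoC = 200, NuoD = 416, NuoE = 166,
    NuoF = 445, NuoG = 908, NuoH = 325, NuoI = 180, NuoJ = 184,
    NuoK = 100, NuoL = 613, NuoM = 509, NuoN = 485,
    NuoCD = 600, NuoBCD = 780)
}

# largest-remainder allocation of n units to probabilities, >= 1 each
alloc_counts <- function(probs, n) {
  raw <- probs * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    add <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[add] <- cnt[add] + 1
  }
  while (any(cnt == 0 & probs > 0)) {
    i <- which(cnt == 0 & probs > 0)[1]
    j <- which.max(cnt)
    cnt[i] <- 1
    cnt[j] <- cnt[j] - 1
  }
  stats::setNames(as.integer(cnt), names(probs))
}

sim_lifestyle_probs <- function(variant) {
  # aerobe, anaerobe, facultative_anaerobe, microaerobe
  switch(variant,
         Complete14         = c(0.65, 0.02, 0.30, 0.03),
         Complete13_fusedCD = c(0.60, 0.05, 0.30, 0.05),
         Complete_fusedBCD  = c(0.05, 0.85, 0.05, 0.05),
         CI_like            = c(0.05, 0.15, 0.10, 0.70),
         Incomplete         = c(0.20, 0.30, 0.45, 0.05),
         Absent             = c(0.03, 0.80, 0.12, 0.05))
}

# profiles of the genes of a planted operon, in canonical gene order
variant_gene_profiles <- function(variant, missing_set, subs) {
  switch(variant,
         Complete14 = subs,
         Complete13_fusedCD =
           c("NuoA", "NuoB", "NuoCD", subs[5:14]),
         Complete_fusedBCD = c("NuoA", "NuoBCD", subs[5:14]),
         CI_like = setdiff(subs, missing_set),
         Incomplete = missing_set,  # here: the *kept* subset
         Absent = character(0))
}

#' Generate a synthetic dataset with planted ground truth
#'
#' Deterministic given the config seed. Each species receives a variant
#' (all strains consistent); each genome gets a chromosome (and a plasmid
#' for plasmid-exclusive species) carrying background genes, the planted
#' same-strand operon with intra-operon gaps drawn from the bounded gap
#' distribution, genuine hits from the low-e-value component, and decoy
#' wrong-profile hits from the high-e-value component on background genes.
#'
#' @param config A [sim_config()].
#' @return Object of class `nuoscan_sim`: list with tibbles `gene_calls`,
#'   `hits`, `metadata`, `replicons`, `truth` (per-genome planted variant,
#'   copy count, arrangement, plasmid status), `hit_truth` (per-hit decoy
#'   flag) and the `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(config$seed)
  subs <- paste0("Nuo", LETTERS[1:14])
  lens <- sim_subunit_lengths()

  # species-level plan
  vcnt <- alloc_counts(config$variant_mix, config$n_species)
  variants <- sample(rep(names(vcnt), vcnt))
  comp_idx <- which(variants %in% c("Complete14", "Complete13_fusedCD",
                                    "Complete_fusedBCD"))
  pick <- function(pool, frac) {
    n <- min(max(1L, round(frac * length(comp_idx))), length(pool))
    sort(pool[sample.int(length(pool))][seq_len(n)])
  }
  dual_idx <- pick(comp_idx, config$dual_copy_fraction)
  plasmid_idx <- pick(setdiff(comp_idx, dual_idx),
                      config$plasmid_fraction)
  split_idx <- pick(setdiff(comp_idx, c(dual_idx, plasmid_idx)),
                    config$split_fraction)
  ci_idx <- which(variants == "CI_like")
  missing_sets <- vector("list", config$n_species)
  for (k in seq_along(ci_idx)) {
    missing_sets[[ci_idx[k]]] <- if (k %% 2 == 1) c("NuoE", "NuoF")
                                 else c("NuoE", "NuoF", "NuoG")
  }
  for (i in which(variants == "Incomplete")) {
    missing_sets[[i]] <- sort(sample(subs, sample(5:9, 1)))  # kept subset
  }
  phyla <- c("Pseudomonadota", "Bacillota", "Actinomycetota",
             "Thermodesulfobacteriota")

  genes <- list(); hits <- list(); meta <- list(); truth <- list()
  hit_truth <- list(); repl <- list()
  genome_no <- 0L
  strain_counts <- as.integer(names(config$strains_per_species))

  for (sp in seq_len(config$n_species)) {
    species <- sprintf("Species_%03d", sp)
    variant <- variants[sp]
    lifestyle <- sample(lifestyle_levels(), 1,
                        prob = sim_lifestyle_probs(variant))
    n_strains <- sample(strain_counts, 1,
                        prob = config$strains_per_species)
    for (st in seq_len(n_strains)) {
      genome_no <- genome_no + 1L
      gid <- sprintf("G%04d", genome_no)
      g <- simulate_genome(
        gid, variant, missing_sets[[sp]], subs, lens, config,
        dual = sp %in% dual_idx, split = sp %in% split_idx,
        on_plasmid = sp %in% plasmid_idx)
      genes[[gid]] <- g$genes
      hits[[gid]] <- g$hits
      hit_truth[[gid]] <- g$hit_truth
      repl[[gid]] <- g$replicons
      rl <- g$replicons$length
      meta[[gid]] <- tibble(
        genome_id = gid, assembly_level = "complete",
        n50 = compute_n50(rl), total_length = sum(rl),
        n_contigs = length(rl),
        taxid = sprintf("tx%04d", sp), species = species,
        genus = sprintf("Genus_%02d", (sp - 1) %/% 2 + 1),
        phylum = phyla[(sp - 1) %% length(phyla) + 1],
        class = paste0(phyla[(sp - 1) %% length(phyla) + 1], "_c1"),
        candidatus_flag = FALSE, lifestyle = lifestyle)
      truth[[gid]] <- tibble(
        genome_id = gid, species = species, variant = variant,
        n_complete_sets = g$n_sets, arrangement = g$arrangement,
        on_plasmid = g$plasmid_status)
    }
  }
  structure(
    list(gene_calls = bind_rows(genes),
         hits = bind_rows(hits),
         metadata = bind_rows(meta),
         replicons = bind_rows(repl)[c("replicon_id", "genome_id",
                                       "replicon_type")],
         replicon_lengths = bind_rows(repl),
         truth = bind_rows(truth),
         hit_truth = bind_rows(hit_truth),
         config = config),
    class = "nuoscan_sim"
  )
}

# lay a run of genes left to right; returns rows and the next free pos
lay_genes <- function(replicon_id, genome_id, pos, aa, strand, ids,
                      gaps) {
  start <- integer(length(aa)); end <- integer(length(aa))
  for (i in seq_along(aa)) {
    start[i] <- pos
    end[i] <- pos + 3L * (aa[i] + 1L) - 1L
    pos <- end[i] + (if (i < length(aa)) gaps[i] else 0L) + 1L
  }
  list(rows = tibble(gene_id = ids, genome_id = genome_id,
                     replicon_id = replicon_id, start = start, end = end,
                     strand = strand, protein_length = as.integer(aa)),
       pos = pos)
}

simulate_genome <- function(gid, variant, missing_set, subs, lens,
                            config, dual, split, on_plasmid) {
  chrom <- paste0(gid, "_chr")
  plasmid <- paste0(gid, "_plasmid1")
  main_rep <- if (on_plasmid) plasmid else chrom

  profiles <- variant_gene_profiles(variant, missing_set, subs)
  draw_aa <- function(p) {
    m <- lens[[p]]
    max(50L, as.integer(round(rnorm(1, m, m * config$length_sd_frac))))
  }
  big_gap <- function() {
    as.integer(round(runif(1, config$inter_cluster_gap_min,
                           1.5 * config$inter_cluster_gap_min)))
  }
  gene_rows <- list(); gene_no <- 0L
  next_id <- function(rep_id) {
    gene_no <<- gene_no + 1L
    paste0(rep_id, "_", gene_no)
  }
  pos <- 1000L

  add_background <- function(rep_id, n) {
    if (n == 0) return(character(0))
    ids <- map_chr(seq_len(n), function(i) next_id(rep_id))
    aa <- pmax(50L, as.integer(round(rnorm(n, 300, 60))))
    out <- character(0)
    for (i in seq_len(n)) {
      laid <- lay_genes(rep_id, gid, pos, aa[i],
                        sample(c("+", "-"), 1), ids[i], integer(0))
      gene_rows[[length(gene_rows) + 1]] <<- laid$rows
      pos <<- laid$pos + big_gap()
      out <- c(out, ids[i])
    }
    out
  }
  add_operon <- function(rep_id, prof) {
    if (length(prof) == 0) return(character(0))
    strand <- sample(c("+", "-"), 1)
    aa <- map_int(prof, draw_aa)
    # hierarchical gaps: each operon has its own spacing scale below
    # gap_max, so the Complete count rises gradually with the threshold
    # and levels off at gap_max
    cap <- floor(runif(1, 0, config$gap_max))
    gaps <- if (length(prof) > 1) {
      as.integer(sample.int(cap + 1L, length(prof) - 1L,
                            replace = TRUE) - 1L)
    } else integer(0)
    ids <- map_chr(prof, function(p) next_id(rep_id))
    laid <- lay_genes(rep_id, gid, pos, aa, strand, ids, gaps)
    gene_rows[[length(gene_rows) + 1]] <<- laid$rows
    pos <<- laid$pos + big_gap()
    ids
  }

  bg_pre <- add_background(main_rep, config$n_background %/% 2)
  operon_ids <- character(0); operon_prof <- character(0)
  if (split && length(profiles) >= 4) {
    cut <- sample(2:(length(profiles) - 2), 1)
    operon_ids <- c(add_operon(main_rep, profiles[1:cut]),
                    add_operon(main_rep,
                               profiles[(cut + 1):length(profiles)]))
    operon_prof <- profiles
  } else {
    operon_ids <- add_operon(main_rep, profiles)
    operon_prof <- profiles
  }
  if (dual) {
    operon_ids <- c(operon_ids, add_operon(main_rep, profiles))
    operon_prof <- c(operon_prof, profiles)
  }
  bg_post <- add_background(main_rep, config$n_background -
                              config$n_background %/% 2)
  main_len <- pos + 1000L

  # plasmid-exclusive genomes still carry a short, hit-free chromosome
  chrom_len <- main_len
  if (on_plasmid) {
    pos <- 1000L
    ids <- map_chr(1:2, function(i) next_id(chrom))
    for (id in ids) {
      laid <- lay_genes(chrom, gid, pos, 310L, "+", id, integer(0))
      gene_rows[[length(gene_rows) + 1]] <- laid$rows
      pos <- laid$pos + big_gap()
    }
    chrom_len <- pos + 1000L
  }

  genes <- bind_rows(gene_rows)
  genes$replicon_type <- ifelse(genes$replicon_id == plasmid,
                                "plasmid", "chromosome")

  # genuine hits on operon genes
  true_hits <- if (length(operon_ids) > 0) {
    tibble(gene_id = operon_ids, profile = operon_prof,
           evalue = 10^rnorm(length(operon_ids),
                             config$true_evalue[["mean"]],
                             config$true_evalue[["sd"]]))
  } else {
    tibble(gene_id = character(), profile = character(),
           evalue = double())
  }
  # decoy cross-hits on background genes of the main replicon
  bg_ids <- c(bg_pre, bg_post)
  n_dec <- min(rpois(1, config$decoy_rate), length(bg_ids))
  decoy_hits <- if (n_dec > 0) {
    tibble(gene_id = sample(bg_ids, n_dec),
           profile = sample(config$decoy_profiles, n_dec, replace = TRUE),
           evalue = 10^rnorm(n_dec, config$decoy_evalue[["mean"]],
                             config$decoy_evalue[["sd"]]))
  } else {
    tibble(gene_id = character(), profile = character(),
           evalue = double())
  }
  hits <- bind_rows(true_hits, decoy_hits) |>
    mutate(bitscore = round(pmax(10, -1.1 * log10(pmax(evalue, 1e-300)) +
                                   rnorm(n(), 0, 3)), 1),
           env_from = NA_integer_, env_to = NA_integer_) |>
    arrange(.data$gene_id, .data$profile)

  is_complete <- variant %in% c("Complete14", "Complete13_fusedCD",
                                "Complete_fusedBCD")
  reps <- tibble(
    replicon_id = c(chrom, if (on_plasmid) plasmid),
    genome_id = gid,
    replicon_type = c("chromosome", if (on_plasmid) "plasmid"),
    length = c(chrom_len, if (on_plasmid) main_len))
  list(
    genes = genes[c("gene_id", "genome_id", "replicon_id",
                    "replicon_type", "start", "end", "strand",
                    "protein_length")],
    hits = hits,
    hit_truth = mutate(hits[c("gene_id", "profile")],
                       is_decoy = .data$gene_id %in% decoy_hits$gene_id &
                         !(.data$gene_id %in% operon_ids)),
    replicons = reps,
    n_sets = if (!is_complete) 0L else if (dual) 2L else 1L,
    arrangement = if (!is_complete) "none"
                  else if (split) "split" else "single_cluster",
    plasmid_status = if (length(hits$gene_id) > 0 && on_plasmid)
      "exclusive" else "none"
  )
}

#' @export
print.nuoscan_sim <- function(x, ...) {
  cat("<nuoscan_sim> ", nrow(x$metadata), " genomes, ",
      length(unique(x$metadata$species)), " species, ",
      nrow(x$gene_calls), " genes, ", nrow(x$hits), " hits (",
      sum(x$hit_truth$is_decoy), " decoys)\n", sep = "")
  print(count(x$truth, .data$variant))
  invisible(x)
}

#' Write a simulated dataset as standard-format fixture files
#'
#' Emits `hits.tblout` (HMMER3 tblout dialect), `genes.gff3`,
#' `genes_prodigal.faa` (deflines only, Prodigal dialect),
#' `metadata.tsv`, `replicons.tsv`, `truth_genomes.tsv` and
#' `truth_hits.tsv` into `out_dir`, in exactly the dialects the package
#' readers parse; reading them back reproduces the in-memory tables.
#'
#' @param dataset A `nuoscan_sim` from [simulate_dataset()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_fixture <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "nuoscan_sim"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tblout(dataset$hits, file.path(out_dir, "hits.tblout"))
  write_gff3(dataset$gene_calls, file.path(out_dir, "genes.gff3"))
  write_prodigal_headers(dataset$gene_calls,
                         file.path(out_dir, "genes_prodigal.faa"))
  write_result_tsv(dataset$metadata, file.path(out_dir, "metadata.tsv"),
                   sort_by = "genome_id")
  write_result_tsv(dataset$replicons, file.path(out_dir, "replicons.tsv"),
                   sort_by = c("genome_id", "replicon_id"))
  write_result_tsv(dataset$truth, file.path(out_dir, "truth_genomes.tsv"),
                   sort_by = "genome_id")
  write_result_tsv(dataset$hit_truth, file.path(out_dir, "truth_hits.tsv"),
                   sort_by = c("gene_id", "profile"))
  invisible(out_dir)
}

# HMMER3 tblout writer (19 columns; e-values at full double precision so
# fixtures round-trip exactly)
write_tblout <- function(hits, path) {
  lines <- c(
    "#                                               --- full sequence ---- --- best 1 domain ---- --- domain number estimation ----",
    "# target name        accession  query name           accession    E-value  score  bias   E-value  score  bias   exp reg clu  ov env dom rep inc description of target",
    "#------------------- ---------- -------------------- ---------- --------- ------ ----- --------- ------ ----- ----- --- --- --- --- --- --- --- ---------------------"
  )
  if (nrow(hits) > 0) {
    lines <- c(lines, sprintf(
      "%s - %s - %.17g %.1f 0.0 %.17g %.1f 0.0 1.0 1 0 0 1 1 1 1 -",
      hits$gene_id, hits$profile, hits$evalue, hits$bitscore,
      hits$evalue, hits$bitscore))
  }
  writeLines(c(lines, "#"), path)
  invisible(path)
}

write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tnuoscan_sim\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;protein_length=%d",
                     genes$replicon_id, genes$start, genes$end,
                     genes$strand, genes$gene_id, genes$protein_length))
  writeLines(lines, path)
  invisible(path)
}

write_prodigal_headers <- function(genes, path) {
  writeLines(sprintf(">%s # %d # %d # %s # ID=%s;partial=00",
                     genes$gene_id, genes$start, genes$end,
                     ifelse(genes$strand == "-", "-1", "1"),
                     genes$gene_id),
             path)
  invisible(path)
}
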