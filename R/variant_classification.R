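#' Resolve the subunit content of one gene
#'
#' A gene may carry hits from several profiles. Fused-gene profiles (e.g.
#' NuoCD) expand to their mapped subunit lists. Accepted single-subunit
#' profiles each contribute their subunit when their domain envelopes are
#' essentially non-overlapping (overlap at most `max_overlap_frac` of the
#' shorter envelope): that is the signature of a genuine fusion. Profiles
#' whose envelopes coincide are paralog ambiguity (e.g. the antiporter-like
#' NuoL/M/N), and only the best-e-value profile is kept. Hits without an
#' envelope are treated as spanning the whole protein.
#'
#' @param hits_on_gene Hit rows sharing one `gene_id`.
#' @param scheme A [subunit_scheme()].
#' @param max_overlap_frac Maximum tolerated envelope overlap as a fraction
#'   of the shorter envelope (default 0.2).
#' @return Character vector of subunit labels (possibly empty).
#' @export
resolve_gene_subunits <- function(hits_on_gene, scheme = nuo_scheme(),
                                  max_overlap_frac = 0.2) {
  if (nrow(hits_on_gene) == 0) return(character(0))
  stopifnot(length(unique(hits_on_gene$gene_id)) == 1)
  fused <- hits_on_gene$profile %in% names(scheme$fused_profiles)
  single <- hits_on_gene$profile %in% scheme$subunits
  out <- unique(unlist(map(hits_on_gene$profile[fused],
                           profile_subunits, scheme = scheme)))
  sgl <- hits_on_gene[single, ] |>
    group_by(.data$profile) |>
    slice_min(.data$evalue, n = 1, with_ties = FALSE) |>
    ungroup() |>
    arrange(.data$evalue, .data$profile)
  if (nrow(sgl) > 0) {
    # missing envelopes span everything and therefore always clash
    from <- ifelse(is.na(sgl$env_from), 1L, sgl$env_from)
    to <- ifelse(is.na(sgl$env_to), .Machine$integer.max, sgl$env_to)
    len <- to - from + 1
    accepted <- integer(0)
    for (i in seq_len(nrow(sgl))) {
      ok <- TRUE
      for (j in accepted) {
        ov <- max(0, min(to[i], to[j]) - max(from[i], from[j]) + 1)
        if (ov > max_overlap_frac * min(len[i], len[j])) {
          ok <- FALSE
          break
        }
      }
      if (ok) accepted <- c(accepted, i)
    }
    out <- union(out, sgl$profile[accepted])
  }
  sort(out)
}

#' Resolve subunit content for every hit-bearing gene
#'
#' @param hits Hit table (filtered or not).
#' @inheritParams resolve_gene_subunits
#' @return Tibble with `gene_id`, `subunits` (list of character vectors),
#'   `fused` (more than one subunit on the gene), `best_evalue`.
#' @export
resolve_subunits <- function(hits, scheme = nuo_scheme(),
                             max_overlap_frac = 0.2) {
  if (nrow(hits) == 0) {
    return(tibble(gene_id = character(), subunits = list(),
                  fused = logical(), best_evalue = double()))
  }
  hits |>
    group_by(.data$gene_id) |>
    group_map(function(df, key) {
      df$gene_id <- key$gene_id[[1]]
      subs <- resolve_gene_subunits(df, scheme, max_overlap_frac)
      tibble(gene_id = key$gene_id[[1]], subunits = list(subs),
             fused = length(subs) > 1, best_evalue = min(df$evalue))
    }) |>
    bind_rows()
}

variant_for_fusion <- function(fp_name) {
  switch(fp_name,
         NuoBCD = "Complete_fusedBCD",
         NuoCD = "Complete13_fusedCD",
         paste0("Complete_fused_", fp_name))
}

# core classification for one genome's (filtered) hits and clusters
classify_one_genome <- function(gid, clusters, resolved_genes, scheme) {
  required <- scheme$required_for_complete
  rg <- resolved_genes[resolved_genes$genome_id == gid, , drop = FALSE]
  cl <- clusters[clusters$genome_id == gid, , drop = FALSE]
  S <- sort(unique(unlist(rg$subunits))) %||% character(0)
  absent_row <- function(variant) {
    tibble(genome_id = gid, variant = variant,
           n_complete_sets = 0L,
           arrangement = "none", on_plasmid = "none",
           has_fused_gene = any(rg$fused),
           n_hit_genes = nrow(rg),
           subunits_found = list(S))
  }
  if (length(S) == 0) return(absent_row("Absent"))
  missing <- setdiff(required, S)
  if (length(missing) == 0) {
    variant <- "Complete14"
    fps <- scheme$fused_profiles[
      order(-lengths(scheme$fused_profiles))]
    for (fp in names(fps)) {
      if (any(map_lgl(rg$subunits,
                      function(s) all(fps[[fp]] %in% s)))) {
        variant <- variant_for_fusion(fp)
        break
      }
    }
    n_sets <- count_complete_sets(rg, cl, required)
    single <- any(map_lgl(cl$subunits_present,
                          function(s) all(required %in% s)))
    arrangement <- if (single) "single_cluster" else "split"
  } else if (any(map_lgl(scheme$complex_like_rule,
                         function(r) setequal(r, missing)))) {
    variant <- "CI_like"
    n_sets <- 0L
    arrangement <- "none"
  } else {
    variant <- "Incomplete"
    n_sets <- 0L
    arrangement <- "none"
  }
  on_plasmid <- plasmid_status(rg, required)
  tibble(genome_id = gid, variant = variant,
         n_complete_sets = as.integer(n_sets),
         arrangement = arrangement, on_plasmid = on_plasmid,
         has_fused_gene = any(rg$fused),
         n_hit_genes = nrow(rg),
         subunits_found = list(S))
}

# greedy count of disjoint gene sets each covering the required subunits:
# genes are consumed in cluster-priority order (most subunit-complete
# cluster first, then best mean e-value), then by gene e-value
count_complete_sets <- function(rg, cl, required) {
  cl_rank <- cl |>
    mutate(n_sub = map_int(.data$subunits_present,
                           function(s) length(unique(s)))) |>
    arrange(desc(.data$n_sub), .data$mean_log10_evalue) |>
    mutate(rank = row_number())
  gene_rank <- cluster_members(cl) |>
    left_join(cl_rank[c("cluster_id", "rank")], by = "cluster_id")
  g <- rg |>
    left_join(gene_rank[c("gene_id", "rank")], by = "gene_id") |>
    arrange(.data$rank, .data$best_evalue, .data$gene_id)
  used <- rep(FALSE, nrow(g))
  n_sets <- 0L
  repeat {
    needed <- required
    picked <- integer(0)
    for (i in seq_len(nrow(g))) {
      if (used[i] || length(needed) == 0) next
      contrib <- intersect(g$subunits[[i]], needed)
      if (length(contrib) > 0) {
        picked <- c(picked, i)
        needed <- setdiff(needed, contrib)
      }
    }
    if (length(needed) > 0) break
    used[picked] <- TRUE
    n_sets <- n_sets + 1L
  }
  n_sets
}

plasmid_status <- function(rg, required) {
  if (nrow(rg) == 0 || !"replicon_type" %in% names(rg)) return("none")
  on_p <- rg$replicon_type == "plasmid"
  if (!any(on_p)) return("none")
  if (all(on_p)) return("exclusive")
  p_sub <- unique(unlist(rg$subunits[on_p]))
  if (all(required %in% p_sub)) "complete" else "partial"
}

#' Classify one genome into a complex variant
#'
#' Uses the genome-wide union of fusion-resolved subunits: `Absent` when no
#' subunit is found; a `Complete*` variant when the union covers the
#' scheme's required set (with fused-gene sub-variants); `CI_like` when the
#' missing set exactly matches one of the scheme's complex-like rules
#' ({E,F} or {E,F,G} for Nuo); otherwise `Incomplete`. Completeness uses
#' the union across clusters because genuinely complete complexes may be
#' encoded in split gene clusters.
#'
#' Also reported: the greedy count of disjoint gene sets each covering the
#' required subunits (`n_complete_sets`, e.g. 2 for genomes carrying two
#' full operons), the arrangement (`single_cluster` when one cluster alone
#' covers the required set, `split` when only the union does), and plasmid
#' placement (`none`/`partial`/`complete`/`exclusive`).
#'
#' @param clusters [cluster_hits()] output built from filtered hits.
#' @param hits Filtered hit table.
#' @param genes Gene calls.
#' @param scheme A [subunit_scheme()].
#' @param max_overlap_frac Envelope-overlap tolerance for fusion calls.
#' @return One-row tibble (see [classify_genomes()] for columns).
#' @export
classify_genome <- function(clusters, hits, genes, scheme = nuo_scheme(),
                            max_overlap_frac = 0.2) {
  gids <- unique(genes$genome_id)
  if (length(gids) != 1) {
    abort("classify_genome: expected exactly one genome; use classify_genomes()")
  }
  classify_genomes(clusters, hits, genes, scheme,
                   max_overlap_frac = max_overlap_frac)
}

#' Classify every genome in a dataset
#'
#' @inheritParams classify_genome
#' @param genome_ids Genomes to report (default: all genomes in `genes`);
#'   genomes without hits are reported as `Absent`.
#' @return Tibble with one row per genome: `genome_id`, `variant`,
#'   `n_complete_sets`, `arrangement`, `on_plasmid`, `has_fused_gene`,
#'   `n_hit_genes`, `subunits_found` (list).
#' @export
classify_genomes <- function(clusters, hits, genes, scheme = nuo_scheme(),
                             genome_ids = NULL,
                             max_overlap_frac = 0.2) {
  genome_ids <- genome_ids %||% sort(unique(genes$genome_id))
  resolved <- resolve_subunits(hits, scheme, max_overlap_frac) |>
    inner_join(genes[c("gene_id", "genome_id", "replicon_type")],
               by = "gene_id")
  bind_rows(map(sort(genome_ids), classify_one_genome,
                clusters = clusters, resolved_genes = resolved,
                scheme = scheme))
}

#' Aggregate genome calls to species
#'
#' @param calls Output of [classify_genomes()].
#' @param taxonomy Tibble with `genome_id` and `species`; genomes without a
#'   species mapping are excluded with a warning.
#' @return Tibble with `species`, `n_strains`, `variants_observed` (list),
#'   `consistent` (single variant across strains) and
#'   `representative_variant` (modal variant; ties broken toward the more
#'   complete variant).
#' @export
aggregate_species <- function(calls, taxonomy) {
  joined <- left_join(calls, distinct(taxonomy[c("genome_id", "species")]),
                      by = "genome_id")
  unmapped <- is.na(joined$species)
  if (any(unmapped)) {
    warn(paste0("aggregate_species: ", sum(unmapped),
                " genome(s) without species mapping excluded"))
    joined <- joined[!unmapped, ]
  }
  joined |>
    group_by(.data$species) |>
    summarise(
      n_strains = n(),
      variants_observed = list(sort(unique(.data$variant))),
      consistent = length(unique(.data$variant)) == 1,
      representative_variant = {
        tab <- table(factor(.data$variant, levels = variant_levels()))
        names(tab)[which.max(tab)]  # which.max takes the first (most
      },                            # complete) level on ties
      .groups = "drop"
    ) |>
    arrange(.data$species)
}

#' Variant distribution by taxonomic rank
#'
#' Percentage of species per variant within each taxon at the chosen rank.
#' Taxa with fewer than `min_species` species are excluded. Percentages
#' within a taxon sum to 100.
#'
#' @param summaries Output of [aggregate_species()].
#' @param taxonomy Tibble mapping `species` to the rank column.
#' @param rank One of `"phylum"`, `"class"`, `"genus"`.
#' @param min_species Minimum species per taxon (default 10).
#' @return Long tibble: `taxon`, `n_species`, `variant`, `n`, `pct`.
#' @export
summarize_by_rank <- function(summaries, taxonomy,
                              rank = c("phylum", "class", "genus"),
                              min_species = 10) {
  rank <- match.arg(rank)
  if (!rank %in% names(taxonomy)) {
    abort(paste0("summarize_by_rank: taxonomy lacks a '", rank, "' column"))
  }
  tax <- distinct(taxonomy[c("species", rank)])
  summaries |>
    inner_join(tax, by = "species") |>
    rename(taxon = all_of(rank)) |>
    group_by(.data$taxon) |>
    mutate(n_species = n()) |>
    ungroup() |>
    filter(.data$n_species >= min_species) |>
    count(.data$taxon, .data$n_species,
          variant = factor(.data$representative_variant,
                           levels = variant_levels())) |>
    group_by(.data$taxon) |>
    mutate(pct = 100 * .data$n / sum(.data$n)) |>
    ungroup() |>
    mutate(variant = as.character(.data$variant)) |>
    arrange(.data$taxon, .data$variant)
}
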