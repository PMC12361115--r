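#' Run the full post-search annotation pipeline
#'
#' Executes, in order: genome curation, assembly QC, provisional hit
#' clustering at `max_gap`, per-profile e-value/length threshold
#' derivation from cluster-segregated distributions, hit filtering,
#' re-clustering of the retained hits (decoy removal can split clusters;
#' one pass by default, to a fixpoint with `iterate = TRUE`), the gap
#' threshold scan, genome variant classification, species aggregation,
#' per-rank summaries, and - when a `lifestyle` column is present - the
#' variant-lifestyle chi-square association.
#'
#' Output is a pure function of the inputs and parameters. When
#' `out_dir` is given, deterministic TSV reports are written
#' (`gap_scan.tsv`, `thresholds.tsv`, `clusters.tsv`, `variants.tsv`,
#' `species_summary.tsv`, `rank_distribution.tsv`, `contingency.tsv`,
#' `residuals.tsv`) plus a `manifest.json` with versions, parameters, a
#' parameter hash, and the timestamp (the only non-deterministic field).
#' A failing stage writes a `FAILED` marker naming the stage.
#'
#' @param hits Hit table from [read_hmm_hits()] (or a simulated dataset's
#'   `hits`).
#' @param genes Gene calls from [read_gene_calls()].
#' @param metadata Genome metadata (see [curate_genomes()]); taxonomy
#'   columns `species`/`genus`/`phylum`/`class` and optional `lifestyle`
#'   are used downstream.
#' @param scheme A [subunit_scheme()].
#' @param out_dir Optional output directory for TSV reports.
#' @param max_gap Maximum intergenic distance for clustering (bp).
#' @param scan_thresholds Grid for [scan_gap_thresholds()].
#' @param bandwidth_rule,bw Passed to [estimate_kde()].
#' @param lo_pct,hi_pct Passed to [derive_length_range()].
#' @param use_reference_lengths Passed to [derive_thresholds()].
#' @param min_species Passed to [summarize_by_rank()].
#' @param rank Taxonomic rank for the distribution summary.
#' @param iterate Re-cluster/re-filter to a fixpoint (at most 10 rounds).
#' @param default_cutoff Passed to [filter_hits()].
#' @param max_overlap_frac Envelope-overlap tolerance for fusion calls.
#' @return Invisibly, a list with elements `curated`, `assembly`,
#'   `clusters` (final), `thresholds`, `filtered`, `gap_scan`, `plateau`,
#'   `variants`, `species`, `rank_distribution`, `contingency`,
#'   `association`.
#' @export
run_pipeline <- function(hits, genes, metadata, scheme = nuo_scheme(),
                         out_dir = NULL, max_gap = 250,
                         scan_thresholds = seq(0, 500, by = 25),
                         bandwidth_rule = "silverman", bw = NULL,
                         lo_pct = 1, hi_pct = 99,
                         use_reference_lengths = TRUE,
                         min_species = 10, rank = "phylum",
                         iterate = FALSE, default_cutoff = NULL,
                         max_overlap_frac = 0.2) {
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir)) {
        writeLines(paste0("stage: ", name, "\n", conditionMessage(e)),
                   file.path(out_dir, "FAILED"))
      }
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  curated <- stage("curate", curate_genomes(metadata))
  assembly <- stage("assembly_qc", assembly_stats(curated))
  genes_c <- genes[genes$genome_id %in% curated$genome_id, ]
  hits_c <- hits[hits$gene_id %in% genes_c$gene_id, ]
  taxonomy <- curated[intersect(c("genome_id", "species", "genus",
                                  "phylum", "class"), names(curated))]

  provisional <- stage("cluster",
    cluster_hits(genes_c, hits_c, max_gap, scheme, max_overlap_frac))
  thresholds <- stage("threshold",
    derive_thresholds(hits_c, genes_c, provisional, scheme,
                      bandwidth_rule, bw, lo_pct, hi_pct,
                      use_reference_lengths))
  filtered <- stage("filter",
    filter_hits(hits_c, genes_c, thresholds, default_cutoff))
  clusters <- stage("recluster", {
    cl <- cluster_hits(genes_c, filtered$retained, max_gap, scheme,
                       max_overlap_frac)
    if (iterate) {
      for (i in seq_len(10)) {
        thr <- derive_thresholds(hits_c, genes_c, cl, scheme,
                                 bandwidth_rule, bw, lo_pct, hi_pct,
                                 use_reference_lengths)
        flt <- filter_hits(hits_c, genes_c, thr, default_cutoff)
        cl2 <- cluster_hits(genes_c, flt$retained, max_gap, scheme,
                            max_overlap_frac)
        same <- identical(flt$retained, filtered$retained)
        thresholds <- thr
        filtered <- flt
        cl <- cl2
        if (same) break
      }
    }
    cl
  })
  gap_scan <- stage("gap_scan",
    scan_gap_thresholds(genes_c, filtered$retained, scan_thresholds,
                        scheme,
                        taxonomy = if ("species" %in% names(taxonomy))
                          taxonomy else NULL,
                        max_overlap_frac = max_overlap_frac))
  plateau <- stage("plateau", detect_plateau(gap_scan))
  variants <- stage("classify",
    classify_genomes(clusters, filtered$retained, genes_c, scheme,
                     genome_ids = curated$genome_id,
                     max_overlap_frac = max_overlap_frac))
  species <- NULL
  rank_distribution <- NULL
  if ("species" %in% names(taxonomy)) {
    species <- stage("aggregate", aggregate_species(variants, taxonomy))
    if (rank %in% names(taxonomy)) {
      rank_distribution <- stage("summarize_rank",
        summarize_by_rank(species,
                          distinct(taxonomy[c("species", rank)]),
                          rank = rank, min_species = min_species))
    }
  }
  contingency <- NULL
  association <- NULL
  if (!is.null(species) && "lifestyle" %in% names(curated) &&
      any(!is.na(curated$lifestyle))) {
    lifestyles <- curated |>
      filter(!is.na(.data$lifestyle)) |>
      distinct(.data$species, .data$lifestyle)
    contingency <- stage("contingency",
                         build_contingency(species, lifestyles))
    association <- stage("association",
                         chi_square_independence(contingency))
  } else {
    inform("run_pipeline: no lifestyle labels; association stage skipped")
  }

  out <- list(curated = curated, assembly = assembly,
              clusters = clusters, thresholds = thresholds,
              filtered = filtered, gap_scan = gap_scan,
              plateau = plateau, variants = variants, species = species,
              rank_distribution = rank_distribution,
              contingency = contingency, association = association)
  if (!is.null(out_dir)) {
    stage("write", write_pipeline_outputs(out, out_dir, list(
      max_gap = max_gap, scan_thresholds = scan_thresholds,
      bandwidth_rule = bandwidth_rule, bw = bw, lo_pct = lo_pct,
      hi_pct = hi_pct, use_reference_lengths = use_reference_lengths,
      min_species = min_species, rank = rank, iterate = iterate,
      default_cutoff = default_cutoff,
      max_overlap_frac = max_overlap_frac, scheme = scheme$name)))
  }
  invisible(out)
}

write_pipeline_outputs <- function(out, out_dir, params) {
  write_result_tsv(out$gap_scan, file.path(out_dir, "gap_scan.tsv"),
                   sort_by = "max_gap")
  write_result_tsv(out$thresholds, file.path(out_dir, "thresholds.tsv"),
                   sort_by = "profile")
  write_result_tsv(out$clusters, file.path(out_dir, "clusters.tsv"),
                   sort_by = "cluster_id")
  write_result_tsv(out$variants, file.path(out_dir, "variants.tsv"),
                   sort_by = "genome_id")
  write_result_tsv(out$assembly, file.path(out_dir, "assembly_qc.tsv"),
                   sort_by = "genome_id")
  if (!is.null(out$species)) {
    write_result_tsv(out$species,
                     file.path(out_dir, "species_summary.tsv"),
                     sort_by = "species")
  }
  if (!is.null(out$rank_distribution)) {
    write_result_tsv(out$rank_distribution,
                     file.path(out_dir, "rank_distribution.tsv"),
                     sort_by = c("taxon", "variant"))
  }
  if (!is.null(out$association)) {
    td <- tidy(out$association)
    write_result_tsv(td[c("lifestyle", "variant", "observed",
                          "expected")],
                     file.path(out_dir, "contingency.tsv"),
                     sort_by = c("lifestyle", "variant"))
    write_result_tsv(td[c("lifestyle", "variant", "residual")],
                     file.path(out_dir, "residuals.tsv"),
                     sort_by = c("lifestyle", "variant"))
    write_result_tsv(glance(out$association),
                     file.path(out_dir, "association_test.tsv"))
  }
  cfg <- params[order(names(params))]
  cfg_file <- tempfile()
  saveRDS(cfg, cfg_file)
  manifest <- list(
    package = "nuoscan",
    package_version =
      as.character(utils::packageVersion("nuoscan")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    parameters = cfg,
    parameter_hash = unname(tools::md5sum(cfg_file)),
    plateau = out$plateau,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(out_dir)
}
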