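#' Intergenic distance between two gene calls
#'
#' Distance in bp between the end of gene `a` and the start of gene `b`,
#' computed as `max(0, b$start - a$end - 1)`. Overlapping or book-ended
#' genes return 0. Vectorised over rows; both inputs must lie on the same
#' replicon and `a` must not start after `b`.
#'
#' @param a,b Gene-call data frames (as from [read_gene_calls()]) with equal
#'   row counts.
#' @return Integer vector of gaps in bp.
#' @export
#' @examples
#' a <- tibble::tibble(replicon_id = "r", start = 100, end = 400)
#' b <- tibble::tibble(replicon_id = "r", start = 600, end = 900)
#' intergenic_gap(a, b)  # 199
intergenic_gap <- function(a, b) {
  a <- as_tibble(a); b <- as_tibble(b)
  stopifnot(nrow(a) == nrow(b))
  if (all(c("replicon_id") %in% names(a)) &&
      all(c("replicon_id") %in% names(b)) &&
      any(a$replicon_id != b$replicon_id)) {
    abort("intergenic_gap: genes on different replicons")
  }
  if (any(a$start > b$start)) {
    abort("intergenic_gap: `a` must not start after `b`")
  }
  as.integer(pmax(0, b$start - a$end - 1))
}

#' Cluster subunit hits by genomic context
#'
#' Hit-bearing genes are partitioned, per replicon and strand, into maximal
#' runs in which each consecutive pair of hit-bearing genes is separated by
#' at most `max_gap` bp of intergenic distance. Intervening genes without
#' hits do not join a cluster, but their span counts toward the gap, so a
#' long foreign insertion naturally breaks a cluster. Clusters never span
#' replicons, singletons are allowed, and every hit-bearing gene belongs to
#' exactly one cluster.
#'
#' Each cluster is typed `Complete` when its fusion-resolved subunit
#' content covers the scheme's required set, else `Partial`.
#'
#' @param genes Gene calls (see [read_gene_calls()]).
#' @param hits Hit table (see [read_hmm_hits()]); every `gene_id` must
#'   resolve to a gene.
#' @param max_gap Maximum intergenic distance in bp (default 250).
#' @param scheme A [subunit_scheme()]; default [nuo_scheme()].
#' @param max_overlap_frac Envelope-overlap tolerance passed to
#'   [resolve_gene_subunits()].
#' @return A tibble, one row per cluster: `cluster_id`, `genome_id`,
#'   `replicon_id`, `strand`, `n_genes`, `member_genes` (list),
#'   `subunits_present` (list; multiset of fusion-resolved labels),
#'   `has_fused`, `span_start`, `span_end`, `mean_log10_evalue`,
#'   `cluster_type`. The `max_gap` used is attached as an attribute.
#' @export
cluster_hits <- function(genes, hits, max_gap = 250, scheme = nuo_scheme(),
                         max_overlap_frac = 0.2) {
  stopifnot(max_gap >= 0)
  missing_ids <- setdiff(unique(hits$gene_id), genes$gene_id)
  if (length(missing_ids) > 0) {
    abort(paste0("cluster_hits: hits reference unknown gene_id(s): ",
                 paste(head(missing_ids, 5), collapse = ", "),
                 if (length(missing_ids) > 5) ", ..."))
  }
  resolved <- resolve_subunits(hits, scheme, max_overlap_frac)
  cluster_resolved(inner_join(genes, resolved, by = "gene_id"),
                   max_gap, scheme)
}

# core clustering on genes already joined to their resolved subunits
cluster_resolved <- function(hit_genes, max_gap, scheme) {
  required <- scheme$required_for_complete
  if (nrow(hit_genes) == 0) {
    out <- tibble(cluster_id = character(), genome_id = character(),
                  replicon_id = character(), strand = character(),
                  n_genes = integer(), member_genes = list(),
                  subunits_present = list(), has_fused = logical(),
                  span_start = integer(), span_end = integer(),
                  mean_log10_evalue = double(), cluster_type = character())
    attr(out, "max_gap") <- max_gap
    return(out)
  }
  out <- hit_genes |>
    arrange(.data$genome_id, .data$replicon_id, .data$strand, .data$start,
            .data$gene_id) |>
    group_by(.data$genome_id, .data$replicon_id, .data$strand) |>
    mutate(
      gap_prev = pmax(0, .data$start - lag(cummax(.data$end)) - 1),
      run = cumsum(is.na(.data$gap_prev) | .data$gap_prev > max_gap)
    ) |>
    group_by(.data$run, .add = TRUE) |>
    summarise(
      n_genes = n(),
      member_genes = list(.data$gene_id),
      subunits_present = list(sort(unlist(.data$subunits))),
      has_fused = any(.data$fused),
      span_start = min(.data$start),
      span_end = max(.data$end),
      mean_log10_evalue = mean(log10(pmax(.data$best_evalue, 1e-300))),
      .groups = "drop"
    ) |>
    mutate(
      cluster_type = ifelse(
        map_lgl(.data$subunits_present,
                function(s) all(required %in% s)),
        "Complete", "Partial"),
      cluster_id = paste(.data$genome_id, .data$replicon_id, .data$strand,
                         sprintf("%03d", .data$run), sep = "|")
    ) |>
    select("cluster_id", "genome_id", "replicon_id", "strand", "n_genes",
           "member_genes", "subunits_present", "has_fused", "span_start",
           "span_end", "mean_log10_evalue", "cluster_type") |>
    arrange(.data$genome_id, .data$replicon_id, .data$strand,
            .data$span_start)
  attr(out, "max_gap") <- max_gap
  out
}

#' Gene-level view of a cluster table
#'
#' @param clusters Output of [cluster_hits()].
#' @return Tibble with one row per member gene (`gene_id`, `cluster_id`,
#'   `genome_id`, `replicon_id`, `strand`, `cluster_type`).
#' @export
cluster_members <- function(clusters) {
  clusters |>
    select("cluster_id", "genome_id", "replicon_id", "strand",
           "cluster_type", "member_genes") |>
    tidyr::unnest(cols = "member_genes") |>
    rename(gene_id = "member_genes")
}

#' Scan maximum-gap thresholds
#'
#' Re-clusters the dataset at each threshold and counts how many genomes
#' (or species, when a taxonomy is supplied) hold at least one Complete
#' cluster versus only Partial clusters. The Complete count is
#' non-decreasing in the threshold because clusters only merge as the gap
#' is relaxed.
#'
#' @inheritParams cluster_hits
#' @param thresholds Ascending vector of max-gap values in bp; default
#'   `seq(0, 500, by = 25)`.
#' @param taxonomy Optional tibble with `genome_id` and `species` columns.
#' @param unit Counting unit: `"auto"` (species when taxonomy given, else
#'   genome), `"species"` or `"genome"`.
#' @return Tibble with columns `max_gap`, `n_complete`, `n_partial`.
#' @export
scan_gap_thresholds <- function(genes, hits,
                                thresholds = seq(0, 500, by = 25),
                                scheme = nuo_scheme(), taxonomy = NULL,
                                unit = c("auto", "species", "genome"),
                                max_overlap_frac = 0.2) {
  unit <- match.arg(unit)
  stopifnot(!is.unsorted(thresholds))
  if (unit == "auto") {
    unit <- if (is.null(taxonomy)) "genome" else "species"
  }
  if (unit == "species" && is.null(taxonomy)) {
    abort("unit = 'species' requires `taxonomy` (genome_id, species)")
  }
  resolved <- resolve_subunits(hits, scheme, max_overlap_frac)
  hit_genes <- inner_join(genes, resolved, by = "gene_id")
  rows <- map(thresholds, function(t) {
    cl <- cluster_resolved(hit_genes, t, scheme)
    per_genome <- cl |>
      group_by(.data$genome_id) |>
      summarise(complete = any(.data$cluster_type == "Complete"),
                .groups = "drop")
    if (unit == "species") {
      per_genome <- per_genome |>
        inner_join(taxonomy, by = "genome_id") |>
        group_by(.data$species) |>
        summarise(complete = any(.data$complete), .groups = "drop")
    }
    tibble(max_gap = t,
           n_complete = sum(per_genome$complete),
           n_partial = sum(!per_genome$complete))
  })
  bind_rows(rows)
}

#' Locate the plateau of a gap-threshold scan
#'
#' Returns the smallest scanned threshold `t` at which the relative growth
#' of the Complete count over the next step falls below `rel_epsilon`,
#' i.e. `(n_complete(t + step) - n_complete(t)) / max(1, n_complete(t)) <
#' rel_epsilon`. If growth never slows below that, the largest scanned
#' threshold is returned with a warning.
#'
#' @param scan Output of [scan_gap_thresholds()] at uniform threshold
#'   spacing, at least two rows.
#' @param rel_epsilon Relative-growth tolerance (default 0.01).
#' @return A single max-gap value in bp.
#' @export
detect_plateau <- function(scan, rel_epsilon = 0.01) {
  stopifnot(nrow(scan) >= 2)
  t <- scan$max_gap
  steps <- diff(t)
  if (length(unique(steps)) != 1) {
    abort("detect_plateau: thresholds must be uniformly spaced")
  }
  nc <- scan$n_complete
  growth <- diff(nc) / pmax(1, nc[-length(nc)])
  hit <- which(growth < rel_epsilon)
  if (length(hit) == 0) {
    warn("detect_plateau: no plateau within scanned range; returning the largest threshold")
    return(t[length(t)])
  }
  t[hit[1]]
}
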