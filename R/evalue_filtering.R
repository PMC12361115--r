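#' Kernel density estimate of log10 e-values
#'
#' Gaussian KDE of `log10(evalue)` (zeros floored to 1e-300 first) on a
#' 512-point grid spanning `[min - 4h, max + 4h]` where `h` is the
#' bandwidth. Modes (local maxima, after discarding negligible ripples
#' below `min_density_frac` of the peak) and the antimodes between
#' consecutive modes are located from discrete differences of the density.
#'
#' E-value distributions of profile-HMM searches against large proteomes
#' are typically multimodal: a low-e-value mode of genuine subunit
#' homologs and one or more high-e-value modes of cross-hits to related
#' families. The antimode between them is a natural per-subunit cutoff.
#'
#' @param evalues Numeric vector of e-values (>= 0), at least 2 values.
#' @param bandwidth_rule `"silverman"` (rule-of-thumb, default) or
#'   `"fixed"` (supply `bw`).
#' @param bw Bandwidth in log10 units when `bandwidth_rule = "fixed"`.
#' @param min_density_frac Modes with density below this fraction of the
#'   global maximum are ignored (default 0.001).
#' @return An object of class `nuoscan_kde`: list with `grid`, `density`,
#'   `bandwidth`, `modes`, `antimodes` (grid indices), `n`.
#' @export
estimate_kde <- function(evalues,
                         bandwidth_rule = c("silverman", "fixed"),
                         bw = NULL, min_density_frac = 0.001) {
  bandwidth_rule <- match.arg(bandwidth_rule)
  if (length(evalues) < 2) {
    abort("estimate_kde: need at least 2 e-values; supply a manual cutoff instead")
  }
  if (any(evalues < 0)) abort("estimate_kde: e-values must be >= 0")
  x <- log10(pmax(evalues, 1e-300))
  h <- if (bandwidth_rule == "silverman") {
    hh <- tryCatch(stats::bw.nrd0(x), error = function(e) 0)
    if (!is.finite(hh) || hh <= 0) 0.1 else hh
  } else {
    if (is.null(bw) || bw <= 0) abort("estimate_kde: fixed rule needs bw > 0")
    bw
  }
  d <- stats::density(x, bw = h, kernel = "gaussian", n = 512,
                      from = min(x) - 4 * h, to = max(x) + 4 * h)
  y <- d$y
  # interior local maxima by sign change of first differences
  ds <- sign(diff(y))
  modes <- which(diff(ds) < 0) + 1L
  modes <- modes[y[modes] >= min_density_frac * max(y)]
  antimodes <- integer(0)
  if (length(modes) >= 2) {
    antimodes <- map_int(seq_len(length(modes) - 1), function(i) {
      lo <- modes[i]; hi <- modes[i + 1]
      lo + which.min(y[lo:hi]) - 1L
    })
  }
  structure(
    list(grid = d$x, density = y, bandwidth = h,
         modes = modes, antimodes = antimodes, n = length(x)),
    class = "nuoscan_kde"
  )
}

#' @export
print.nuoscan_kde <- function(x, ...) {
  cat("<nuoscan_kde> n = ", x$n, ", bandwidth = ",
      format(x$bandwidth, digits = 3), " log10 units\n", sep = "")
  cat("  modes at log10(e-value): ",
      paste(format(x$grid[x$modes], digits = 3), collapse = ", "), "\n",
      sep = "")
  if (length(x$antimodes) > 0) {
    cat("  antimodes at: ",
        paste(format(x$grid[x$antimodes], digits = 3), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Derive an e-value cutoff from cluster-segregated score distributions
#'
#' Hits that fall inside Complete operon-like clusters ("members")
#' concentrate in the low-e-value mode of the pooled distribution. The
#' cutoff is placed at the first antimode to the right of the
#' member-dominated mode (the mode with the highest member density). When
#' the pooled density is unimodal there is no antimode and no separate
#' cross-hit population to exclude; the fallback cutoff is then the right
#' edge of the dominant mode - the first grid point past the mode where
#' the density falls below `min_density_frac` of the peak - so the whole
#' genuine-hit mode passes, including hits from genomes whose clusters are
#' incomplete (recorded as `mode_edge_fallback`). In all cases the cutoff
#' is raised, if needed, so that at least 99% of member hits pass, and
#' capped at 1.
#'
#' @param kde [estimate_kde()] result over all hits of one subunit profile.
#' @param member_log_evalues log10 e-values of hits inside Complete
#'   clusters (non-empty; floor zeros to 1e-300 before log10).
#' @param all_log_evalues Optional log10 e-values of all hits (used only
#'   for a containment sanity check).
#' @param subunit Label recorded in the output.
#' @param min_density_frac Density floor (fraction of the peak) defining
#'   the dominant mode's right edge in the unimodal fallback.
#' @return One-row tibble: `profile`, `evalue_cutoff`, `cutoff_log10`,
#'   `source` (`"antimode"` or `"mode_edge_fallback"`).
#' @export
derive_threshold <- function(kde, member_log_evalues,
                             all_log_evalues = NULL,
                             subunit = NA_character_,
                             min_density_frac = 0.001) {
  if (length(member_log_evalues) == 0) {
    abort("derive_threshold: no cluster-member hits; supply a manual cutoff")
  }
  if (!is.null(all_log_evalues) &&
      min(member_log_evalues) < min(all_log_evalues) - 1e-9) {
    abort("derive_threshold: member e-values must be a subset of all e-values")
  }
  # member density on the same grid/bandwidth as the pooled KDE
  member_dens <- if (length(member_log_evalues) >= 2) {
    stats::density(member_log_evalues, bw = kde$bandwidth, n = 512,
                   from = kde$grid[1], to = kde$grid[length(kde$grid)])$y
  } else {
    # single member: nearest-grid-point indicator
    ind <- rep(0, length(kde$grid))
    ind[which.min(abs(kde$grid - member_log_evalues))] <- 1
    ind
  }
  dominant <- kde$modes[which.max(member_dens[kde$modes])]
  right_anti <- kde$antimodes[kde$antimodes > dominant]
  if (length(right_anti) > 0) {
    cutoff_log <- kde$grid[right_anti[1]]
    src <- "antimode"
  } else {
    past <- which(kde$density < min_density_frac * max(kde$density) &
                    seq_along(kde$grid) > dominant)
    cutoff_log <- if (length(past) > 0) kde$grid[past[1]]
                  else kde$grid[length(kde$grid)]
    src <- "mode_edge_fallback"
  }
  # never cut off more than 1% of the member hits
  q99 <- unname(quantile(member_log_evalues, 0.99, type = 1))
  cutoff_log <- min(max(cutoff_log, q99), 0)
  tibble(profile = subunit,
         evalue_cutoff = 10^cutoff_log,
         cutoff_log10 = cutoff_log,
         source = src)
}

#' Protein-length acceptance range from cluster members
#'
#' Percentile band of the protein lengths of cluster-member hits; hits far
#' outside the band are discarded as unusual-length outliers. A
#' user-supplied reference range (e.g. curated from reviewed sequence
#' databases) overrides the empirical band.
#'
#' @param member_lengths Protein lengths (aa) of cluster-member hits; at
#'   least 5 values unless `override` is given.
#' @param lo_pct,hi_pct Percentiles in \[0, 100\] (defaults 1 and 99).
#' @param override Optional length-2 numeric `c(min, max)` returned
#'   unchanged with source `"user"`.
#' @return Named numeric `c(length_min, length_max)` with a `"source"`
#'   attribute (`"percentile"` or `"user"`).
#' @export
derive_length_range <- function(member_lengths, lo_pct = 1, hi_pct = 99,
                                override = NULL) {
  if (!is.null(override)) {
    stopifnot(length(override) == 2, override[1] < override[2])
    out <- c(length_min = override[1], length_max = override[2])
    attr(out, "source") <- "user"
    return(out)
  }
  if (length(member_lengths) < 5) {
    abort("derive_length_range: fewer than 5 member lengths; supply a manual range")
  }
  q <- unname(quantile(member_lengths, c(lo_pct, hi_pct) / 100))
  out <- c(length_min = q[1], length_max = q[2])
  attr(out, "source") <- "percentile"
  out
}

#' Derive per-profile thresholds from a clustered dataset
#'
#' For every profile with hits, pools all its e-values into a KDE,
#' takes hits on genes inside any Complete cluster as members, and applies
#' [derive_threshold()] and [derive_length_range()]. Profiles whose hits
#' never occur in a Complete cluster get `evalue_cutoff = NA` (source
#' `"no_members"`); [filter_hits()] rejects such hits unless a
#' `default_cutoff` is supplied there.
#'
#' @inheritParams cluster_hits
#' @param clusters Output of [cluster_hits()] on the same data.
#' @param bandwidth_rule,bw Passed to [estimate_kde()].
#' @param lo_pct,hi_pct Passed to [derive_length_range()].
#' @param use_reference_lengths Use the scheme's bundled `length_ranges`
#'   (when present) instead of empirical percentiles. Default `TRUE`.
#' @return Tibble with one row per profile: `profile`, `evalue_cutoff`,
#'   `cutoff_log10`, `source`, `length_min`, `length_max`,
#'   `length_source`, `n_hits`, `n_members`.
#' @export
derive_thresholds <- function(hits, genes, clusters, scheme = nuo_scheme(),
                              bandwidth_rule = "silverman", bw = NULL,
                              lo_pct = 1, hi_pct = 99,
                              use_reference_lengths = TRUE) {
  member_ids <- clusters |>
    filter(.data$cluster_type == "Complete") |>
    cluster_members() |>
    pull(.data$gene_id)
  hg <- left_join(hits,
                  genes[c("gene_id", "protein_length")], by = "gene_id")
  if (nrow(hg) == 0) {
    return(tibble(profile = character(), evalue_cutoff = double(),
                  cutoff_log10 = double(), source = character(),
                  length_min = double(), length_max = double(),
                  length_source = character(), n_hits = integer(),
                  n_members = integer()))
  }
  ref <- if (use_reference_lengths) scheme$length_ranges else NULL
  rows <- hg |>
    group_by(.data$profile) |>
    group_map(function(df, key) {
      prof <- key$profile[[1]]
      mem <- df[df$gene_id %in% member_ids, ]
      n_hits <- nrow(df); n_members <- nrow(mem)
      if (n_members == 0 || n_hits < 2) {
        thr <- tibble(profile = prof, evalue_cutoff = NA_real_,
                      cutoff_log10 = NA_real_, source = "no_members")
      } else {
        kde <- estimate_kde(df$evalue, bandwidth_rule = bandwidth_rule,
                            bw = bw)
        thr <- derive_threshold(
          kde, log10(pmax(mem$evalue, 1e-300)),
          log10(pmax(df$evalue, 1e-300)), subunit = prof)
      }
      ref_row <- if (!is.null(ref)) ref[ref$profile == prof, ] else NULL
      lr <- if (!is.null(ref_row) && nrow(ref_row) == 1) {
        derive_length_range(NULL, override = c(ref_row$length_min,
                                               ref_row$length_max))
      } else if (n_members >= 5) {
        derive_length_range(mem$protein_length, lo_pct, hi_pct)
      } else {
        structure(c(length_min = 1, length_max = Inf),
                  source = "unbounded")
      }
      mutate(thr,
             length_min = lr[["length_min"]],
             length_max = lr[["length_max"]],
             length_source = attr(lr, "source") %||% "unbounded",
             n_hits = n_hits, n_members = n_members)
    }) |>
    bind_rows()
  arrange(rows, .data$profile)
}

#' Apply e-value and length thresholds to hits
#'
#' A hit is retained iff its e-value is at or below its profile's cutoff
#' and its protein length lies inside the profile's length range. Rejected
#' hits carry a reason: `evalue`, `length`, `both`, or `no_threshold`
#' (profile had no derivable cutoff and no default). Filtering is
#' idempotent; retained and rejected partition the input.
#'
#' @param hits Hit table.
#' @param genes Gene calls supplying `protein_length`.
#' @param thresholds Output of [derive_thresholds()] (or a tibble with
#'   `profile`, `evalue_cutoff`, `length_min`, `length_max`).
#' @param default_cutoff Optional e-value cutoff for profiles missing from
#'   `thresholds`; without it such profiles raise an error.
#' @return List with tibbles `retained` (hit columns) and `rejected`
#'   (hit columns plus `reason`).
#' @export
filter_hits <- function(hits, genes, thresholds, default_cutoff = NULL) {
  hit_cols <- names(hits)
  unknown <- setdiff(unique(hits$profile), thresholds$profile)
  if (length(unknown) > 0 && is.null(default_cutoff)) {
    abort(paste0("filter_hits: no threshold for profile(s): ",
                 paste(unknown, collapse = ", "),
                 "; supply `default_cutoff` or add rows"))
  }
  hg <- hits |>
    left_join(genes[c("gene_id", "protein_length")], by = "gene_id") |>
    left_join(thresholds[c("profile", "evalue_cutoff", "length_min",
                           "length_max")], by = "profile") |>
    mutate(
      evalue_cutoff = if (is.null(default_cutoff)) .data$evalue_cutoff
                      else coalesce(.data$evalue_cutoff, default_cutoff),
      length_min = coalesce(.data$length_min, 1),
      length_max = coalesce(.data$length_max, Inf),
      pass_e = !is.na(.data$evalue_cutoff) &
        .data$evalue <= .data$evalue_cutoff,
      pass_l = .data$protein_length >= .data$length_min &
        .data$protein_length <= .data$length_max,
      reason = case_when(
        is.na(.data$evalue_cutoff)  ~ "no_threshold",
        !.data$pass_e & !.data$pass_l ~ "both",
        !.data$pass_e               ~ "evalue",
        !.data$pass_l               ~ "length",
        TRUE                        ~ NA_character_
      )
    )
  list(
    retained = hg |> filter(is.na(.data$reason)) |> select(all_of(hit_cols)),
    rejected = hg |> filter(!is.na(.data$reason)) |>
      select(all_of(c(hit_cols, "reason")))
  )
}
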