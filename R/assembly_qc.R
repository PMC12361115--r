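#' Assembly N50
#'
#' N50 is the contig length L such that contigs of length >= L cover at
#' least half of the total assembly length; computed by the common
#' descending-sort cumulative-sum convention.
#'
#' @param contig_lengths Numeric vector of positive contig lengths (bp).
#' @return The N50 in bp.
#' @export
#' @examples
#' compute_n50(c(8, 7, 5, 3, 2))  # 7
compute_n50 <- function(contig_lengths) {
  if (length(contig_lengths) == 0) {
    abort("compute_n50: empty contig length list")
  }
  if (anyNA(contig_lengths) || any(contig_lengths <= 0)) {
    abort("compute_n50: contig lengths must be positive")
  }
  s <- sort(contig_lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Assembly quality category
#'
#' Four tiers from N50 relative to total length plus contig count:
#' Excellent if N50 >= 90% of total and at most 5 contigs; Good if
#' N50 >= 70% and at most 10 contigs; Moderate if N50 >= 50% and at most
#' 50 contigs; otherwise Poor. Tiers are evaluated strictly in that order
#' and both conditions of a tier must hold. Vectorised.
#'
#' @param n50 N50 in bp.
#' @param total_length Total assembly length in bp.
#' @param n_contigs Number of contigs.
#' @return Factor with levels Excellent, Good, Moderate, Poor.
#' @export
classify_assembly <- function(n50, total_length, n_contigs) {
  stopifnot(all(n50 <= total_length), all(n_contigs >= 1))
  frac <- n50 / total_length
  out <- case_when(
    frac >= 0.9 & n_contigs <= 5  ~ "Excellent",
    frac >= 0.7 & n_contigs <= 10 ~ "Good",
    frac >= 0.5 & n_contigs <= 50 ~ "Moderate",
    TRUE                          ~ "Poor"
  )
  factor(out, levels = c("Excellent", "Good", "Moderate", "Poor"))
}

#' Per-genome assembly statistics
#'
#' Convenience wrapper: accepts genome metadata carrying either a
#' `contig_lengths` list column or precomputed `n50`, `total_length` and
#' `n_contigs` columns, and returns one row per genome with the quality
#' category appended.
#'
#' @param metadata Tibble with a `genome_id` column plus either
#'   `contig_lengths` (list of numeric vectors) or `n50`/`total_length`/
#'   `n_contigs`.
#' @return Tibble with `genome_id`, `n50`, `total_length`, `n_contigs`,
#'   `category`.
#' @export
assembly_stats <- function(metadata) {
  metadata <- as_tibble(metadata)
  if ("contig_lengths" %in% names(metadata)) {
    out <- tibble(
      genome_id = metadata$genome_id,
      n50 = map_dbl(metadata$contig_lengths, compute_n50),
      total_length = map_dbl(metadata$contig_lengths, sum),
      n_contigs = map_int(metadata$contig_lengths, length)
    )
  } else {
    stopifnot(all(c("n50", "total_length", "n_contigs") %in%
                    names(metadata)))
    out <- metadata[c("genome_id", "n50", "total_length", "n_contigs")]
  }
  out$category <- classify_assembly(out$n50, out$total_length,
                                    out$n_contigs)
  out
}
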