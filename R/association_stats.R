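#' Build a lifestyle-by-variant contingency table
#'
#' Counts species per (metabolic lifestyle, representative variant) cell.
#' Lifestyle labels must be one of `aerobe`, `anaerobe`,
#' `facultative_anaerobe`, `microaerobe`; species without a lifestyle are
#' excluded and counted in the `"n_excluded"` attribute.
#'
#' @param summaries Output of [aggregate_species()].
#' @param lifestyles Tibble with `species` and `lifestyle` columns (or a
#'   named character vector keyed by species).
#' @return Integer matrix (rows = lifestyle, columns = variant) with an
#'   `"n_excluded"` attribute.
#' @export
build_contingency <- function(summaries, lifestyles) {
  if (is.character(lifestyles) && !is.null(names(lifestyles))) {
    lifestyles <- tibble(species = names(lifestyles),
                         lifestyle = unname(lifestyles))
  }
  lifestyles <- as_tibble(lifestyles)
  stopifnot(all(c("species", "lifestyle") %in% names(lifestyles)))
  known <- lifestyles$lifestyle[!is.na(lifestyles$lifestyle)]
  bad <- setdiff(unique(known), lifestyle_levels())
  if (length(bad) > 0) {
    abort(paste0("build_contingency: unknown lifestyle label(s): ",
                 paste(bad, collapse = ", ")))
  }
  joined <- left_join(summaries, distinct(lifestyles), by = "species")
  n_excluded <- sum(is.na(joined$lifestyle))
  joined <- joined[!is.na(joined$lifestyle), ]
  if (nrow(joined) == 0) {
    abort("build_contingency: no species with lifestyle")
  }
  tab <- table(
    lifestyle = factor(joined$lifestyle, levels = lifestyle_levels()),
    variant = factor(joined$representative_variant,
                     levels = variant_levels())
  )
  m <- unclass(tab)[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  storage.mode(m) <- "integer"
  attr(m, "n_excluded") <- n_excluded
  m
}

#' Chi-square test of independence with Pearson residuals
#'
#' Tests independence of the rows and columns of a count matrix: expected
#' counts `E = row_total * col_total / grand_total`, statistic
#' `sum((O - E)^2 / E)`, degrees of freedom `(rows - 1)(cols - 1)`, upper
#' tail p-value, and cellwise Pearson residuals `(O - E) / sqrt(E)`
#' (positive = association, negative = dissociation). No continuity
#' correction is applied. Zero-marginal rows or columns are dropped with a
#' warning before testing; a warning is also raised when any expected
#' count is below 5.
#'
#' @param observed Count matrix, e.g. from [build_contingency()].
#' @return Object of class `contingency_result` with elements `observed`,
#'   `expected`, `chi2`, `dof`, `p_value`, `residuals`. Has [tidy()],
#'   [glance()] and [autoplot()] methods.
#' @export
#' @examples
#' res <- chi_square_independence(matrix(c(30, 10, 10, 30), 2))
#' res$chi2  # 20
chi_square_independence <- function(observed) {
  observed <- as.matrix(observed)
  if (any(observed < 0)) abort("counts must be non-negative")
  keep_r <- rowSums(observed) > 0
  keep_c <- colSums(observed) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warn(paste0("dropping ", sum(!keep_r), " zero-marginal row(s) and ",
                sum(!keep_c), " zero-marginal column(s)"))
    observed <- observed[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(observed) < 2 || ncol(observed) < 2) {
    abort("need at least 2 rows and 2 columns with positive marginals")
  }
  ct <- suppressWarnings(stats::chisq.test(observed, correct = FALSE))
  if (any(ct$expected < 5)) {
    warn("some expected counts are below 5; the chi-square approximation may be poor")
  }
  structure(
    list(observed = observed,
         expected = ct$expected,
         chi2 = unname(ct$statistic),
         dof = unname(ct$parameter),
         p_value = unname(ct$p.value),
         residuals = (observed - ct$expected) / sqrt(ct$expected)),
    class = "contingency_result"
  )
}

#' @export
print.contingency_result <- function(x, ...) {
  cat("<contingency_result> ", nrow(x$observed), " x ", ncol(x$observed),
      " table\n", sep = "")
  cat("  chi2 = ", format(x$chi2, digits = 5), ", df = ", x$dof,
      ", p = ", format.pval(x$p_value, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @rdname chi_square_independence
#' @param x A `contingency_result`.
#' @param ... Unused.
#' @method tidy contingency_result
#' @export
tidy.contingency_result <- function(x, ...) {
  rn <- rownames(x$observed) %||% as.character(seq_len(nrow(x$observed)))
  cn <- colnames(x$observed) %||% as.character(seq_len(ncol(x$observed)))
  tidyr::expand_grid(lifestyle = rn, variant = cn) |>
    mutate(
      observed = as.vector(t(x$observed)),
      expected = as.vector(t(x$expected)),
      residual = as.vector(t(x$residuals))
    )
}

#' @rdname chi_square_independence
#' @method glance contingency_result
#' @export
glance.contingency_result <- function(x, ...) {
  tibble(chi2 = x$chi2, dof = x$dof, p_value = x$p_value,
         n = sum(x$observed))
}
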