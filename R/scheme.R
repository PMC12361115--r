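#' Define a multi-subunit complex scheme
#'
#' A scheme describes the subunit composition of a respiratory complex: the
#' full subunit set, its functional modules, which HMM profiles represent
#' fused genes, which subunits are required for a "complete" call, and which
#' missing sets still qualify as a complex-like variant. The machinery is
#' generic; [nuo_scheme()] ships the default for the 14-subunit
#' NADH:quinone oxidoreductase (Complex I).
#'
#' @param name Scheme name (used in reports).
#' @param subunits Ordered character vector of subunit labels. Each label is
#'   also the name of the single-subunit HMM profile.
#' @param modules Named list of character vectors; each element is a
#'   functional module (subset of `subunits`). Modules must not overlap.
#' @param fused_profiles Named list mapping a fused-gene profile name to the
#'   subunit labels it covers, e.g. `list(NuoCD = c("NuoC", "NuoD"))`.
#' @param required_for_complete Subunits that must all be present for a
#'   genome to be called complete. Defaults to all subunits.
#' @param complex_like_rule List of character vectors; a genome whose missing
#'   set equals one of these exactly is classified as complex-like
#'   (`CI_like`) rather than `Incomplete`.
#' @param length_ranges Optional tibble with columns `profile`,
#'   `length_min`, `length_max` giving reference protein-length ranges (for
#'   example UniProt-derived) that override cluster-derived percentile
#'   ranges.
#'
#' @return An object of class `subunit_scheme`.
#' @seealso [nuo_scheme()], [read_scheme()]
#' @export
#' @examples
#' sch <- nuo_scheme()
#' sch$fused_profiles$NuoCD
subunit_scheme <- function(name,
                           subunits,
                           modules = list(),
                           fused_profiles = list(),
                           required_for_complete = subunits,
                           complex_like_rule = list(),
                           length_ranges = NULL) {
  stopifnot(is.character(subunits), length(subunits) >= 1,
            !anyDuplicated(subunits))
  for (m in modules) {
    if (!all(m %in% subunits)) {
      abort("module members must be a subset of `subunits`")
    }
  }
  if (anyDuplicated(unlist(modules))) {
    abort("modules must partition a subset of `subunits` (no overlaps)")
  }
  for (fp in fused_profiles) {
    if (!all(fp %in% subunits)) {
      abort("fused-profile targets must be a subset of `subunits`")
    }
  }
  if (!all(required_for_complete %in% subunits)) {
    abort("`required_for_complete` must be a subset of `subunits`")
  }
  if (!is.null(length_ranges)) {
    length_ranges <- as_tibble(length_ranges)
    stopifnot(all(c("profile", "length_min", "length_max") %in%
                    names(length_ranges)))
  }
  structure(
    list(name = name,
         subunits = subunits,
         modules = modules,
         fused_profiles = fused_profiles,
         required_for_complete = required_for_complete,
         complex_like_rule = complex_like_rule,
         length_ranges = length_ranges),
    class = "subunit_scheme"
  )
}

#' The default Complex I (Nuo) scheme
#'
#' Fourteen subunits NuoA--NuoN grouped into the NADH-oxidising N-module
#' (E, F, G), the quinone-reducing Q-module (B, C, D, H, I) and the
#' proton-translocating P-module (A, J, K, L, M, N); two fused-gene profiles
#' (NuoCD and NuoBCD); all 14 subunits required for a complete call; and the
#' complex-like rule that tolerates a missing N-module ({E,F} or {E,F,G}).
#' Reference protein-length ranges are bundled for the 16 profiles, loosely
#' anchored on reviewed bacterial sequences; cluster-derived percentile
#' ranges are used instead when `use_reference_lengths = FALSE` is passed to
#' [derive_thresholds()].
#'
#' @return A `subunit_scheme`.
#' @export
nuo_scheme <- function() {
  subs <- paste0("Nuo", LETTERS[1:14])
  subunit_scheme(
    name = "NuoComplexI",
    subunits = subs,
    modules = list(
      N = c("NuoE", "NuoF", "NuoG"),
      Q = c("NuoB", "NuoC", "NuoD", "NuoH", "NuoI"),
      P = c("NuoA", "NuoJ", "NuoK", "NuoL", "NuoM", "NuoN")
    ),
    fused_profiles = list(
      NuoCD  = c("NuoC", "NuoD"),
      NuoBCD = c("NuoB", "NuoC", "NuoD")
    ),
    required_for_complete = subs,
    complex_like_rule = list(c("NuoE", "NuoF"), c("NuoE", "NuoF", "NuoG")),
    length_ranges = tibble(
      profile = c(subs, "NuoCD", "NuoBCD"),
      length_min = c(70, 100, 90, 250, 80, 250, 450, 180, 100, 90,
                     50, 350, 300, 280, 400, 500),
      length_max = c(300, 400, 400, 700, 350, 700, 1300, 500, 350, 350,
                     250, 900, 800, 700, 1100, 1300)
    )
  )
}

#' @export
print.subunit_scheme <- function(x, ...) {
  cat("<subunit_scheme> ", x$name, "\n", sep = "")
  cat("  subunits (", length(x$subunits), "): ",
      paste(x$subunits, collapse = " "), "\n", sep = "")
  for (m in names(x$modules)) {
    cat("  module ", m, ": ", paste(x$modules[[m]], collapse = " "),
        "\n", sep = "")
  }
  for (fp in names(x$fused_profiles)) {
    cat("  fused profile ", fp, " -> ",
        paste(x$fused_profiles[[fp]], collapse = "+"), "\n", sep = "")
  }
  cat("  complex-like if missing: ",
      paste(map_chr(x$complex_like_rule, paste, collapse = "+"),
            collapse = " or "), "\n", sep = "")
  invisible(x)
}

# map a profile name to the subunit labels it contributes
profile_subunits <- function(profile, scheme) {
  if (profile %in% names(scheme$fused_profiles)) {
    scheme$fused_profiles[[profile]]
  } else if (profile %in% scheme$subunits) {
    profile
  } else {
    character(0)
  }
}

#' Read or write a scheme as YAML
#'
#' The YAML schema mirrors the arguments of [subunit_scheme()]:
#' `name`, `subunits` (list), `modules` (map of lists), `fused_profiles`
#' (map of lists), `required_for_complete` (list), `complex_like_rule`
#' (list of lists) and optional `length_ranges` (list of
#' `{profile, length_min, length_max}` maps).
#'
#' @param path File path.
#' @return `read_scheme()` returns a `subunit_scheme`; `write_scheme()`
#'   returns `path` invisibly.
#' @export
read_scheme <- function(path) {
  y <- yaml::read_yaml(path)
  lr <- NULL
  if (!is.null(y$length_ranges)) {
    lr <- bind_rows(lapply(y$length_ranges, as_tibble))
  }
  subunit_scheme(
    name = y$name %||% tools::file_path_sans_ext(basename(path)),
    subunits = unlist(y$subunits),
    modules = lapply(y$modules %||% list(), unlist),
    fused_profiles = lapply(y$fused_profiles %||% list(), unlist),
    required_for_complete =
      unlist(y$required_for_complete %||% y$subunits),
    complex_like_rule = lapply(y$complex_like_rule %||% list(), unlist),
    length_ranges = lr
  )
}

#' @rdname read_scheme
#' @param scheme A `subunit_scheme`.
#' @export
write_scheme <- function(scheme, path) {
  y <- list(
    name = scheme$name,
    subunits = as.list(scheme$subunits),
    modules = lapply(scheme$modules, as.list),
    fused_profiles = lapply(scheme$fused_profiles, as.list),
    required_for_complete = as.list(scheme$required_for_complete),
    complex_like_rule = lapply(scheme$complex_like_rule, as.list)
  )
  if (!is.null(scheme$length_ranges)) {
    y$length_ranges <- lapply(seq_len(nrow(scheme$length_ranges)),
                              function(i) as.list(scheme$length_ranges[i, ]))
  }
  yaml::write_yaml(y, path)
  invisible(path)
}
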