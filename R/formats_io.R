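#' Read HMMER3 tabular search output
#'
#' Parses `hmmsearch --tblout` (one row per target sequence) or
#' `--domtblout` (one row per domain) files into a tidy hit table. Comment
#' lines (`#`) are skipped. The profile name is taken from the query-name
#' column and the gene identifier from the target-name column, matching a
#' search of subunit profiles against a predicted proteome.
#'
#' E-values of zero are kept as `0` at parse time; they are floored to
#' `1e-300` only when log-transformed for density estimation.
#'
#' @param path Path to a HMMER3 tabular file.
#' @param dialect `"tblout"` (default) or `"domtblout"`.
#' @param score_type For `tblout`, which e-value/score pair to report:
#'   `"full"` (full sequence, default) or `"best_domain"`. Ignored for
#'   `domtblout`, where the full-sequence e-value is reported alongside the
#'   per-domain envelope.
#' @param dedupe Keep only the smallest-e-value row per `(gene_id, profile)`
#'   pair (per `(gene_id, profile, envelope)` for `domtblout`). Default
#'   `TRUE`: downstream steps assume one score per gene-profile pair.
#'
#' @return A tibble with columns `gene_id`, `profile`, `evalue`, `bitscore`,
#'   `env_from`, `env_to` (envelope columns are `NA` for `tblout`).
#' @export
read_hmm_hits <- function(path,
                          dialect = c("tblout", "domtblout"),
                          score_type = c("full", "best_domain"),
                          dedupe = TRUE) {
  dialect <- match.arg(dialect)
  score_type <- match.arg(score_type)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    warn(paste0("no data rows in ", path))
    return(tibble(gene_id = character(), profile = character(),
                  evalue = double(), bitscore = double(),
                  env_from = integer(), env_to = integer()))
  }
  fields <- strsplit(trimws(lines), "\\s+")
  min_cols <- if (dialect == "tblout") 18L else 22L
  nf <- lengths(fields)
  if (any(nf < min_cols)) {
    bad <- line_no[which(nf < min_cols)[1]]
    abort(paste0("malformed ", dialect, " row at line ", bad, " of ", path,
                 ": expected >= ", min_cols, " columns"))
  }
  col <- function(i) map_chr(fields, i)
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(col(i)))
    if (anyNA(v)) {
      bad <- line_no[which(is.na(v))[1]]
      abort(paste0("non-numeric ", what, " at line ", bad, " of ", path))
    }
    v
  }
  hits <- if (dialect == "tblout") {
    ecol <- if (score_type == "full") 5L else 8L
    scol <- if (score_type == "full") 6L else 9L
    tibble(gene_id = col(1), profile = col(3),
           evalue = num(ecol, "e-value"), bitscore = num(scol, "bit score"),
           env_from = NA_integer_, env_to = NA_integer_)
  } else {
    tibble(gene_id = col(1), profile = col(4),
           evalue = num(7, "e-value"), bitscore = num(8, "bit score"),
           env_from = as.integer(num(20, "envelope start")),
           env_to = as.integer(num(21, "envelope end")))
  }
  if (any(hits$evalue < 0)) {
    abort(paste0("negative e-value in ", path))
  }
  if (dedupe) {
    hits <- hits |>
      group_by(.data$gene_id, .data$profile, .data$env_from, .data$env_to) |>
      slice_min(.data$evalue, n = 1, with_ties = FALSE) |>
      ungroup()
    if (dialect == "tblout") {
      hits <- hits |>
        group_by(.data$gene_id, .data$profile) |>
        slice_min(.data$evalue, n = 1, with_ties = FALSE) |>
        ungroup()
    }
  }
  arrange(hits, .data$gene_id, .data$profile, .data$env_from)
}

#' Read gene coordinates
#'
#' Reads predicted gene calls either from a GFF3 file (CDS features, via
#' \pkg{rtracklayer}) or from Prodigal-style FASTA deflines of the form
#' `>id # start # end # strand # ...` with strand coded 1/-1. Coordinates
#' are 1-based inclusive in both dialects and kept that way internally.
#'
#' Protein length is taken from a `protein_length` GFF attribute when
#' present, otherwise computed as `floor((end - start + 1)/3) - 1`
#' (excluding the stop codon).
#'
#' Replicon typing precedence: an explicit `replicons` map beats a keyword
#' match on the replicon identifier (`"plasmid"`, case-insensitive, then
#' `"chromosome"`/`"chr"`), which beats `"unknown"`.
#'
#' @param path Input file.
#' @param dialect `"gff3"` or `"prodigal_headers"`.
#' @param replicons Optional tibble with columns `replicon_id`, `genome_id`,
#'   `replicon_type` mapping each sequence to its genome and molecule type.
#' @param genome_id Fallback genome identifier when `replicons` is absent;
#'   default uses the replicon identifier itself.
#'
#' @return A tibble with columns `gene_id`, `genome_id`, `replicon_id`,
#'   `replicon_type`, `start`, `end`, `strand`, `protein_length`.
#' @export
read_gene_calls <- function(path,
                            dialect = c("gff3", "prodigal_headers"),
                            replicons = NULL,
                            genome_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  genes <- if (dialect == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    df <- as.data.frame(gr, stringsAsFactors = FALSE)
    if ("type" %in% names(df)) df <- df[df$type == "CDS", , drop = FALSE]
    if (nrow(df) == 0) {
      warn(paste0("no CDS features in ", path))
    }
    strand <- as.character(df$strand)
    if (any(!strand %in% c("+", "-"))) {
      abort(paste0("unknown strand symbol in ", path,
                   " (expected '+' or '-')"))
    }
    id <- df$ID
    if (is.null(id)) id <- df$locus_tag
    if (is.null(id)) id <- paste0(df$seqnames, "_", df$start)
    plen <- suppressWarnings(as.numeric(df$protein_length %||% NA))
    plen <- ifelse(is.na(plen),
                   floor((df$end - df$start + 1) / 3) - 1, plen)
    tibble(gene_id = as.character(id),
           replicon_id = as.character(df$seqnames),
           start = as.integer(df$start), end = as.integer(df$end),
           strand = strand, protein_length = as.integer(plen))
  } else {
    lines <- readLines(path, warn = FALSE)
    defs <- grep("^>", lines, value = TRUE)
    if (length(defs) == 0) {
      warn(paste0("no deflines in ", path))
      return(empty_gene_calls())
    }
    parts <- strsplit(sub("^>", "", defs), "\\s+#\\s+")
    nf <- lengths(parts)
    if (any(nf < 4)) {
      abort(paste0("malformed Prodigal defline in ", path, ": ",
                   defs[which(nf < 4)[1]]))
    }
    id <- map_chr(parts, 1)
    start <- suppressWarnings(as.integer(map_chr(parts, 2)))
    end <- suppressWarnings(as.integer(map_chr(parts, 3)))
    strand_raw <- map_chr(parts, 4)
    if (anyNA(start) || anyNA(end)) {
      abort(paste0("non-numeric coordinate in Prodigal defline in ", path))
    }
    if (!all(strand_raw %in% c("1", "+1", "-1"))) {
      abort(paste0("unknown strand symbol '",
                   setdiff(strand_raw, c("1", "+1", "-1"))[1],
                   "' in ", path))
    }
    bad <- end < start
    if (any(bad)) {
      warn(paste0(sum(bad), " record(s) with end < start rejected in ",
                  path))
    }
    tibble(gene_id = id,
           replicon_id = sub("_[0-9]+$", "", id),
           start = start, end = end,
           strand = ifelse(strand_raw == "-1", "-", "+"),
           protein_length =
             as.integer(floor((end - start + 1) / 3) - 1))[!bad, ]
  }
  if (nrow(genes) > 0 && any(genes$end < genes$start)) {
    bad <- genes$end < genes$start
    warn(paste0(sum(bad), " record(s) with end < start rejected in ", path))
    genes <- genes[!bad, ]
  }
  attach_replicons(genes, replicons, genome_id) |>
    arrange(.data$genome_id, .data$replicon_id, .data$start)
}

empty_gene_calls <- function() {
  tibble(gene_id = character(), genome_id = character(),
         replicon_id = character(), replicon_type = character(),
         start = integer(), end = integer(), strand = character(),
         protein_length = integer())
}

attach_replicons <- function(genes, replicons, genome_id) {
  if (!is.null(replicons)) {
    replicons <- as_tibble(replicons)
    stopifnot(all(c("replicon_id", "genome_id", "replicon_type") %in%
                    names(replicons)))
    genes <- left_join(genes, replicons, by = "replicon_id")
    miss <- is.na(genes$genome_id)
    genes$genome_id[miss] <- genes$replicon_id[miss]
    genes$replicon_type[miss] <- keyword_replicon_type(genes$replicon_id[miss])
  } else {
    genes$genome_id <- genome_id %||% genes$replicon_id
    genes$replicon_type <- keyword_replicon_type(genes$replicon_id)
  }
  genes[c("gene_id", "genome_id", "replicon_id", "replicon_type",
          "start", "end", "strand", "protein_length")]
}

keyword_replicon_type <- function(replicon_id) {
  case_when(
    grepl("plasmid", replicon_id, ignore.case = TRUE) ~ "plasmid",
    grepl("chr(omosome)?", replicon_id, ignore.case = TRUE) ~ "chromosome",
    TRUE ~ "unknown"
  )
}

#' Apply genome-curation filters
#'
#' Retains genomes with assembly level `complete` or `chromosome`, a
#' designated (non-empty) phylum and genus, and no *Candidatus* status.
#' Per-rule exclusion counts are attached as the `"exclusions"` attribute
#' (a record failing several rules is counted under each).
#'
#' @param metadata Tibble with columns `genome_id`, `assembly_level`,
#'   `phylum`, `genus` and optionally `candidatus_flag` (absent treated as
#'   `FALSE`).
#' @return The retained rows, with an `"exclusions"` attribute. Applying
#'   the filter twice equals applying it once.
#' @export
curate_genomes <- function(metadata) {
  metadata <- as_tibble(metadata)
  stopifnot(all(c("genome_id", "assembly_level", "phylum", "genus") %in%
                  names(metadata)))
  cand <- metadata$candidatus_flag %||% rep(FALSE, nrow(metadata))
  cand[is.na(cand)] <- FALSE
  blank <- function(x) is.na(x) | !nzchar(trimws(x))
  fail_level <- !tolower(metadata$assembly_level) %in%
    c("complete", "chromosome")
  fail_phylum <- blank(metadata$phylum)
  fail_genus <- blank(metadata$genus)
  fail_cand <- as.logical(cand)
  keep <- !(fail_level | fail_phylum | fail_genus | fail_cand)
  out <- metadata[keep, , drop = FALSE]
  excl <- tibble(
    rule = c("assembly_level", "missing_phylum", "missing_genus",
             "candidatus"),
    n_excluded = c(sum(fail_level), sum(fail_phylum), sum(fail_genus),
                   sum(fail_cand))
  )
  if (nrow(out) < nrow(metadata)) {
    inform(paste0("curate_genomes: retained ", nrow(out), "/",
                  nrow(metadata), " genomes"))
  }
  attr(out, "exclusions") <- excl
  out
}

#' Write and re-read result tables as TSV
#'
#' Tab-separated, UTF-8, header row, deterministic column order and row
#' sort. List columns of character vectors (e.g. cluster member genes) are
#' collapsed with commas on write and re-split on read via `list_cols`.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param sort_by Columns to sort rows by; default all non-list columns in
#'   order.
#' @return `write_result_tsv()` returns `path` invisibly;
#'   `read_result_tsv()` returns a tibble.
#' @export
write_result_tsv <- function(x, path, sort_by = NULL) {
  x <- as_tibble(x)
  is_list <- map_lgl(x, is.list)
  for (cn in names(x)[is_list]) {
    x[[cn]] <- map_chr(x[[cn]], function(v) {
      if (length(v) == 0) "" else paste(v, collapse = ",")
    })
  }
  sort_by <- sort_by %||% names(x)[!is_list]
  if (length(sort_by) > 0 && nrow(x) > 0) {
    x <- arrange(x, across(all_of(sort_by)))
  }
  readr::write_tsv(x, path, na = "NA")
  invisible(path)
}

#' @rdname write_result_tsv
#' @param list_cols Character vector of columns to re-split into character
#'   list columns on read.
#' @export
read_result_tsv <- function(path, list_cols = character()) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       na = "NA")
  for (cn in intersect(list_cols, names(x))) {
    x[[cn]] <- map(as.character(x[[cn]]), function(v) {
      if (is.na(v) || !nzchar(v)) character(0)
      else strsplit(v, ",", fixed = TRUE)[[1]]
    })
  }
  x
}
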