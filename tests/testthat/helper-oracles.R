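# Independent brute-force oracles and tiny fixture builders used across
# the suite. Oracles deliberately share no code with the implementation.

# --- clustering oracle: transitive closure by union-find -----------------

# pairwise relation: same replicon, same strand, intergenic gap <= max_gap
# (gap between the earlier-starting and the other gene, clamped at 0)
oracle_cluster_partition <- function(genes, max_gap) {
  n <- nrow(genes)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      if (genes$replicon_id[i] != genes$replicon_id[j]) next
      if (genes$strand[i] != genes$strand[j]) next
      a <- if (genes$start[i] <= genes$start[j]) i else j
      b <- if (a == i) j else i
      gap <- max(0, genes$start[b] - genes$end[a] - 1)
      if (gap <= max_gap) {
        ra <- find(i); rb <- find(j)
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(lapply(split(genes$gene_id, roots), sort))
}

# canonical form of a partition for set-equality comparison
canonical_partition <- function(parts) {
  parts <- lapply(parts, sort)
  parts[order(vapply(parts, `[`, "", 1))]
}

# random clustering instance: <= n_max hit-bearing genes over 1-2
# replicons, random strands, overlaps allowed
random_cluster_instance <- function(seed, n_max = 50) {
  set.seed(seed)
  n <- sample(1:n_max, 1)
  start <- sort(sample(1:8000, n))
  len <- sample(50:600, n, replace = TRUE)
  tibble::tibble(
    gene_id = sprintf("g%03d", seq_len(n)),
    genome_id = "G1",
    replicon_id = sample(c("r1", "r2"), n, replace = TRUE),
    replicon_type = "chromosome",
    start = start,
    end = start + len,
    strand = sample(c("+", "-"), n, replace = TRUE),
    protein_length = pmax(50L, as.integer(len %/% 3 - 1))
  )
}

# --- N50 category oracle: literal transcription of the tier rules --------

oracle_assembly_category <- function(n50, total, contigs) {
  if (n50 >= 0.9 * total && contigs <= 5) return("Excellent")
  if (n50 >= 0.7 * total && contigs <= 10) return("Good")
  if (n50 >= 0.5 * total && contigs <= 50) return("Moderate")
  "Poor"
}

# --- disjoint complete-set cover oracle ----------------------------------

# maximum number of disjoint gene sets covering `required`, by exhaustive
# recursion over minimal covering subsets (feasible for <= ~12 genes)
oracle_max_complete_sets <- function(subunit_sets, required) {
  n <- length(subunit_sets)
  covers <- function(idx) {
    all(required %in% unique(unlist(subunit_sets[idx])))
  }
  minimal <- function(idx) {
    all(vapply(seq_along(idx),
               function(i) !covers(idx[-i]), logical(1)))
  }
  best <- 0L
  recurse <- function(available, depth) {
    best <<- max(best, depth)
    if (!covers(available)) return()
    m <- length(available)
    for (mask in seq_len(2^m) - 1L) {
      idx <- available[bitwAnd(mask, 2^(seq_len(m) - 1)) > 0]
      if (length(idx) == 0 || !covers(idx) || !minimal(idx)) next
      recurse(setdiff(available, idx), depth + 1L)
    }
  }
  recurse(seq_len(n), 0L)
  best
}

# --- fixture builders ----------------------------------------------------

# a run of same-strand genes on one replicon with the given intergenic
# gaps, each carrying one hit of the given profile
make_operon <- function(profiles, gaps, genome = "G1", replicon = "r1",
                        strand = "+", start0 = 1000, evalue = 1e-60,
                        aa = 300, id_prefix = "g",
                        replicon_type = "chromosome") {
  n <- length(profiles)
  stopifnot(length(gaps) == n - 1 || n == 1)
  start <- integer(n); end <- integer(n)
  pos <- start0
  for (i in seq_len(n)) {
    start[i] <- pos
    end[i] <- pos + 3 * (aa + 1) - 1
    pos <- end[i] + (if (i < n) gaps[i] else 0) + 1
  }
  genes <- tibble::tibble(
    gene_id = paste0(id_prefix, seq_len(n)),
    genome_id = genome, replicon_id = replicon,
    replicon_type = replicon_type,
    start = start, end = end, strand = strand,
    protein_length = as.integer(aa))
  hits <- tibble::tibble(
    gene_id = genes$gene_id, profile = profiles,
    evalue = evalue, bitscore = 200,
    env_from = NA_integer_, env_to = NA_integer_)
  list(genes = genes, hits = hits)
}

nuo14 <- function() paste0("Nuo", LETTERS[1:14])
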