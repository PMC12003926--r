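#' Scoring scheme for pairwise local alignment
#'
#' BLOSUM62 with affine gaps (a gap of length k costs
#' `gap_open + (k - 1) * gap_extend`) and the standard gapped
#' BLOSUM62/11/1 Karlin-Altschul parameters (lambda = 0.267 nats per raw
#' score unit, K = 0.041), the convention EFI-EST-style alignment scores are
#' built on. `X` scores 0 against every residue.
#'
#' @param gap_open Gap-opening penalty (charged on the first gap residue;
#'   default 11).
#' @param gap_extend Gap-extension penalty (default 1).
#' @param lambda_ka Karlin-Altschul lambda (default 0.267).
#' @param k_ka Karlin-Altschul K (default 0.041).
#' @return A `scoring_scheme` object.
#' @export
scoring_scheme <- function(gap_open = 11, gap_extend = 1,
                           lambda_ka = 0.267, k_ka = 0.041) {
  stopifnot(gap_open >= gap_extend, gap_extend > 0, lambda_ka > 0, k_ka > 0)
  structure(list(matrix = blosum62_matrix(), gap_open = gap_open,
                 gap_extend = gap_extend, lambda_ka = lambda_ka,
                 k_ka = k_ka),
            class = "scoring_scheme")
}

# 21x21 BLOSUM62 (canonical residues + X, with X scoring 0 everywhere)
blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[AA20, AA20]
  m <- rbind(cbind(m, X = 0), X = 0)
  colnames(m)[21] <- "X"
  m
}

#' Optimal gapped local alignment of two protein sequences
#'
#' Smith-Waterman local alignment under affine gap costs, reported with
#' Karlin-Altschul statistics: raw score, bit score, E-value for the two
#' sequence lengths, the EFI-EST-style alignment score `-log10(E)`, and the
#' percent identity of one optimal traceback (identities over aligned
#' columns, gap columns included). Scores are symmetric in the two inputs.
#'
#' @param a,b Amino-acid sequences.
#' @param scheme A [scoring_scheme()].
#' @param id1,id2 Optional sequence identifiers carried into the result.
#' @return A one-row `data.frame`: `id1`, `id2`, `raw_score`, `bit_score`,
#'   `e_value`, `alignment_score`, `pct_identity`, `aligned_columns`.
#' @export
local_align <- function(a, b, scheme = scoring_scheme(),
                        id1 = "seq1", id2 = "seq2") {
  stopifnot(nzchar(a), nzchar(b))
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open - scheme$gap_extend,
    gapExtension = scheme$gap_extend)
  pp <- pid_cols(aln)
  pair_alignment(id1, id2, Biostrings::score(aln), nchar(a), nchar(b),
                 pp$pid, pp$cols, scheme)
}

# percent identity (PID1 convention: identities over aligned columns,
# internal gap columns included) and column count from alignment counters
pid_cols <- function(aln) {
  ni <- Biostrings::nindel(aln)
  cols <- Biostrings::nmatch(aln) + Biostrings::nmismatch(aln) +
    Biostrings::insertion(ni)[, "WidthSum"] +
    Biostrings::deletion(ni)[, "WidthSum"]
  list(pid = ifelse(cols > 0, 100 * Biostrings::nmatch(aln) / cols,
                    NA_real_),
       cols = unname(cols))
}

# assemble the PairAlignment row from a raw score
pair_alignment <- function(id1, id2, raw, m, n, pid, cols, scheme) {
  raw <- pmax(raw, 0)
  bits <- bit_score(raw, scheme)
  ev <- m * n * 2^(-bits)
  data.frame(id1 = id1, id2 = id2, raw_score = raw, bit_score = bits,
             e_value = ev, alignment_score = alignment_score(bits, m, n),
             pct_identity = pid, aligned_columns = cols,
             stringsAsFactors = FALSE)
}

#' Karlin-Altschul bit score of a raw alignment score
#'
#' `bits = (lambda_ka * raw - ln k_ka) / ln 2`.
#'
#' @param raw Raw alignment score(s) in matrix units (>= 0).
#' @param scheme A [scoring_scheme()].
#' @return Bit score(s).
#' @export
bit_score <- function(raw, scheme = scoring_scheme()) {
  stopifnot(all(raw >= 0))
  (scheme$lambda_ka * raw - log(scheme$k_ka)) / log(2)
}

#' EFI-EST-style alignment score
#'
#' `AS = -log10(E)` with `E = m * n * 2^(-bits)`, i.e.
#' `AS = bits * log10(2) - log10(m * n)`. The network edge threshold of 115
#' used for the SbmA/BacA-like superfamily corresponds to roughly >= 35
#' percent sequence identity for full-length transporter sequences.
#'
#' @param bits Bit score(s).
#' @param m,n The two sequence lengths.
#' @return Alignment score(s).
#' @export
alignment_score <- function(bits, m, n) {
  stopifnot(all(m >= 1), all(n >= 1))
  bits * log10(2) - log10(m) - log10(n)
}

#' All-vs-all local alignment of a protein set
#'
#' Evaluates every unordered pair (self-alignments excluded), optionally
#' restricted to pairs sharing at least one exact k-mer of size
#' `prefilter_kmer` (the filter is lossless for such pairs; pairs sharing no
#' word are dropped without alignment).
#'
#' @param proteins Protein record table (>= 2 rows).
#' @param scheme A [scoring_scheme()].
#' @param prefilter_kmer Word size for the shared-k-mer prefilter, or `NULL`
#'   (default) to align every pair.
#' @return A `data.frame` of pair alignments (see [local_align()]).
#' @export
all_vs_all <- function(proteins, scheme = scoring_scheme(),
                       prefilter_kmer = NULL) {
  n <- nrow(proteins)
  stopifnot(n >= 2)
  ids <- proteins$protein_id
  seqs <- proteins$sequence
  lens <- nchar(seqs)

  keep_pair <- NULL
  if (!is.null(prefilter_kmer)) {
    k <- as.integer(prefilter_kmer)
    kmers <- lapply(seqs, function(s) {
      L <- nchar(s)
      if (L < k) return(character(0))
      unique(substring(s, 1:(L - k + 1), k:L))
    })
    idx <- new.env(parent = emptyenv())
    for (i in seq_len(n)) {
      for (w in kmers[[i]]) assign(w, c(idx[[w]], i), envir = idx)
    }
    keep_pair <- new.env(parent = emptyenv())
    for (w in ls(idx)) {
      members <- idx[[w]]
      if (length(members) > 1) {
        pr <- utils::combn(members, 2)
        for (q in seq_len(ncol(pr))) {
          assign(paste(pr[1, q], pr[2, q]), TRUE, envir = keep_pair)
        }
      }
    }
  }

  aa <- Biostrings::AAStringSet(seqs)
  out <- vector("list", n - 1)
  for (j in 2:n) {
    i_set <- seq_len(j - 1)
    if (!is.null(keep_pair)) {
      i_set <- i_set[vapply(i_set, function(i)
        isTRUE(keep_pair[[paste(i, j)]]), TRUE)]
    }
    if (length(i_set) == 0) next
    aln <- Biostrings::pairwiseAlignment(
      aa[i_set], aa[[j]], type = "local",
      substitutionMatrix = scheme$matrix,
      gapOpening = scheme$gap_open - scheme$gap_extend,
      gapExtension = scheme$gap_extend)
    pp <- pid_cols(aln)
    out[[j - 1]] <- pair_alignment(ids[i_set], ids[j],
                                   Biostrings::score(aln),
                                   lens[i_set], lens[j],
                                   pp$pid, pp$cols, scheme)
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- pair_alignment(character(), character(), numeric(), numeric(),
                          numeric(), numeric(), numeric(), scheme)
  }
  rownames(out) <- NULL
  out
}

#' Build a sequence similarity network
#'
#' Nodes are proteins; edges are the pair alignments whose alignment score is
#' at least `threshold`. Connected components are numbered by decreasing size
#' with ties broken by the lexicographically smallest member, so component
#' ids are stable across reruns.
#'
#' @param pairs Pair-alignment table from [all_vs_all()].
#' @param threshold Alignment-score edge threshold (the superfamily analysis
#'   uses 115).
#' @param node_ids All protein ids in the network (so that proteins with no
#'   passing edge appear as singleton components). Defaults to the ids seen
#'   in `pairs`.
#' @return An `ssn` object: list with `nodes`, `edges`, `threshold`,
#'   `components` (named integer vector) and `component_sizes`.
#' @export
build_network <- function(pairs, threshold, node_ids = NULL) {
  stopifnot(is.finite(threshold))
  if (is.null(node_ids)) node_ids <- unique(c(pairs$id1, pairs$id2))
  node_ids <- as.character(node_ids)
  edges <- pairs[pairs$id1 != pairs$id2 &
                   pairs$alignment_score >= threshold, , drop = FALSE]
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(node_ids), name = node_ids)
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(match(edges$id1, node_ids),
                                    match(edges$id2, node_ids)))
  }
  memb <- igraph::components(g)$membership
  comp <- relabel_components(setNames(as.integer(memb), node_ids))
  structure(list(nodes = node_ids, edges = edges, threshold = threshold,
                 components = comp,
                 component_sizes = table(comp)),
            class = "ssn")
}

# stable component ids: decreasing size, ties by smallest member id
relabel_components <- function(memb) {
  if (length(memb) == 0) return(memb)
  grp <- split(names(memb), memb)
  key <- vapply(grp, function(m) min(m), "")
  ord <- order(-lengths(grp), key)
  new_id <- integer(length(grp)); new_id[ord] <- seq_along(grp)
  out <- setNames(new_id[match(memb, as.integer(names(grp)))], names(memb))
  out
}

#' @export
print.ssn <- function(x, ...) {
  cat("SSN: ", length(x$nodes), " proteins, ", nrow(x$edges),
      " edges at alignment score >= ", x$threshold, ", ",
      max(c(0L, x$components)), " components\n", sep = "")
  invisible(x)
}

#' Per-component summary statistics
#'
#' @param ssn An `ssn` object.
#' @param pairs Optional pair table (from [all_vs_all()]) used to compute the
#'   median percent identity of each component's internal retained edges;
#'   defaults to the network's own edges.
#' @return A `data.frame` with `component_id`, `size`, `median_pct_identity`
#'   (`NA` for edge-free components) and `members` (comma-separated, sorted).
#' @export
component_stats <- function(ssn, pairs = NULL) {
  edges <- pairs %||% ssn$edges
  comp <- ssn$components
  ids <- sort(unique(comp))
  res <- lapply(ids, function(cid) {
    members <- sort(names(comp)[comp == cid])
    internal <- edges[edges$id1 %in% members & edges$id2 %in% members &
                        edges$alignment_score >= ssn$threshold, , drop = FALSE]
    data.frame(component_id = cid, size = length(members),
               median_pct_identity = if (nrow(internal))
                 median(internal$pct_identity) else NA_real_,
               members = paste(members, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(component_id = integer(), size = integer(),
                      median_pct_identity = numeric(), members = character(),
                      stringsAsFactors = FALSE)
  }
  out
}
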