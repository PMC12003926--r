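#' Align proteins to a profile HMM (match-column alignment)
#'
#' Each sequence is aligned by its local Viterbi path: residues emitted by
#' match states are placed in the corresponding match column, insert-state
#' residues are dropped, and delete states (and columns outside the aligned
#' span) yield `-`. The resulting alignment width equals the model's number
#' of match states. A sequence with an empty Viterbi alignment becomes an
#' all-gap row with a warning.
#'
#' @param hmm A `profile_hmm`.
#' @param proteins Protein record table.
#' @return A `profile_msa` object: list with `rows` (named character vector),
#'   `width` and `column_gap_fraction`.
#' @export
align_to_profile <- function(hmm, proteins) {
  stopifnot(nrow(proteins) >= 1)
  K <- hmm$n_match
  lo <- hmm_log_odds(hmm); ltr <- hmm_log_tr(hmm)
  rows <- vapply(seq_len(nrow(proteins)), function(i) {
    obs <- encode_seq(proteins$sequence[i])
    vp <- .hmm_viterbi_path(lo, ltr, obs)
    row <- rep("-", K)
    hit <- vp$cols > 0
    if (!any(hit) || !is.finite(vp$bits)) {
      warning("empty Viterbi alignment for ", proteins$protein_id[i],
              "; emitting an all-gap row")
    } else {
      row[vp$cols[hit]] <- AA21[obs[hit]]
    }
    paste(row, collapse = "")
  }, "")
  names(rows) <- proteins$protein_id
  new_msa(rows)
}

new_msa <- function(rows) {
  w <- unique(nchar(rows))
  stopifnot(length(w) == 1)
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  structure(list(rows = rows, width = w,
                 column_gap_fraction = colMeans(mat == "-")),
            class = "profile_msa")
}

#' @export
print.profile_msa <- function(x, ...) {
  cat("profile MSA: ", length(x$rows), " rows x ", x$width, " columns\n",
      sep = "")
  invisible(x)
}

#' Remove gap-rich alignment columns
#'
#' Keeps exactly the columns whose gap fraction is `<= max_gap_fraction`
#' (a deterministic substitute for automated trimming heuristics). Row order
#' is preserved and the operation is idempotent at a fixed threshold.
#'
#' @param msa A `profile_msa`.
#' @param max_gap_fraction Maximum tolerated per-column gap fraction
#'   (default 0.5).
#' @return A trimmed `profile_msa`.
#' @export
trim_columns <- function(msa, max_gap_fraction = 0.5) {
  stopifnot(max_gap_fraction > 0, max_gap_fraction <= 1)
  keep <- which(msa$column_gap_fraction <= max_gap_fraction)
  if (length(keep) == 0) stop("no alignment column survives trimming at ",
                              max_gap_fraction)
  mat <- do.call(rbind, strsplit(msa$rows, "", fixed = TRUE))
  rows <- apply(mat[, keep, drop = FALSE], 1, paste, collapse = "")
  names(rows) <- names(msa$rows)
  new_msa(rows)
}

#' Poisson-corrected pairwise distances from an alignment
#'
#' For each pair, `p` is the mismatch fraction over columns where both rows
#' have residues (`X` counts as a residue and mismatches everything but
#' itself); the distance is the Poisson correction `d = -ln(1 - p)` with `p`
#' capped at 0.95 so saturated pairs stay finite. Pairs sharing zero columns
#' are set to the matrix maximum + 1 with a warning.
#'
#' @param msa A (trimmed) `profile_msa`.
#' @return A `dist_matrix` object: list with `ids` and the symmetric matrix
#'   `d` (zero diagonal).
#' @export
distance_matrix <- function(msa) {
  ids <- names(msa$rows)
  n <- length(ids)
  mat <- do.call(rbind, strsplit(msa$rows, "", fixed = TRUE))
  res <- mat != "-"
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  none_shared <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- res[i, ] & res[j, ]
      ns <- sum(shared)
      if (ns == 0) { d[i, j] <- d[j, i] <- NA_real_; none_shared <- TRUE; next }
      p <- min(sum(mat[i, shared] != mat[j, shared]) / ns, 0.95)
      d[i, j] <- d[j, i] <- -log(1 - p)
    }
  }
  if (none_shared) {
    warning("pairs with zero shared columns set to max distance + 1")
    mx <- max(d, na.rm = TRUE)
    d[is.na(d)] <- mx + 1
  }
  structure(list(ids = ids, d = d), class = "dist_matrix")
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard Q-criterion neighbour joining (via [ape::nj()]); negative branch
#' lengths are then clamped to zero with the deficit moved to the sibling
#' branch, keeping path lengths between leaves through the parent unchanged.
#'
#' @param dm A `dist_matrix` (or a plain symmetric matrix with dimnames).
#' @return An unrooted `phylo` object.
#' @export
nj_tree <- function(dm) {
  d <- if (inherits(dm, "dist_matrix")) dm$d else as.matrix(dm)
  if (nrow(d) < 3) stop("neighbour joining needs at least 3 taxa")
  phy <- ape::nj(d)
  clamp_negative_branches(phy)
}

clamp_negative_branches <- function(phy) {
  repeat {
    neg <- which(phy$edge.length < 0)
    if (length(neg) == 0) break
    e <- neg[[1]]
    parent <- phy$edge[e, 1]
    sibs <- setdiff(which(phy$edge[, 1] == parent), e)
    deficit <- phy$edge.length[e]
    phy$edge.length[e] <- 0
    if (length(sibs)) {
      s <- sibs[[1]]
      phy$edge.length[s] <- phy$edge.length[s] + deficit
      if (phy$edge.length[s] < 0) phy$edge.length[s] <- 0
    }
  }
  phy
}

#' Root a tree on an outgroup
#'
#' Places the root at the midpoint of the branch subtending the smallest
#' clade (bipartition side) containing every outgroup id. If no proper
#' bipartition side contains the whole outgroup (e.g. the outgroup is all
#' leaves), the tree is midpoint-rooted with a warning.
#'
#' @param tree An (unrooted) `phylo` object.
#' @param outgroup_ids Character vector of outgroup leaf labels.
#' @return A rooted `phylo` object with the same unrooted split set.
#' @export
root_tree <- function(tree, outgroup_ids) {
  if (length(outgroup_ids) == 0) stop("empty outgroup set")
  miss <- setdiff(outgroup_ids, tree$tip.label)
  if (length(miss)) stop("outgroup ids absent from tree: ",
                         paste(miss, collapse = ", "))
  n <- length(tree$tip.label)
  og <- match(outgroup_ids, tree$tip.label)
  phy <- ape::unroot(tree)
  og <- match(outgroup_ids, phy$tip.label)
  desc <- tip_descendants(phy)
  # per edge: size of the side containing the whole outgroup, NA if split
  side_size <- vapply(seq_len(nrow(phy$edge)), function(e) {
    below <- desc[[phy$edge[e, 2]]]
    if (all(og %in% below)) length(below)
    else if (!any(og %in% below)) n - length(below)
    else NA_integer_
  }, 0L)
  cand <- which(!is.na(side_size) & side_size < n)
  if (length(cand) == 0) {
    warning("outgroup spans the whole tree; midpoint rooting instead")
    return(phangorn::midpoint(phy))
  }
  e <- cand[which.min(side_size[cand])][1]
  child <- phy$edge[e, 2]
  phytools::reroot(phy, child, position = phy$edge.length[e] / 2)
}

# tips below each node (ape node numbering); entry i for tip i is itself
tip_descendants <- function(tree) {
  n <- length(tree$tip.label)
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- i
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

tips_below <- function(phy, node) {
  n <- length(phy$tip.label)
  if (node <= n) return(phy$tip.label[node])
  phy$tip.label[tip_descendants(phy)[[node]]]
}

#' Flag leaves on unusually long terminal branches
#'
#' A leaf is flagged when its terminal branch exceeds `c_mult` times the
#' median terminal branch length, the heuristic used to set aside dubious
#' long-branch homologues before final classification.
#'
#' @param tree A `phylo` object.
#' @param c_mult Multiplier on the median terminal branch length (default 5).
#' @return Named logical vector over the leaves.
#' @export
flag_long_branches <- function(tree, c_mult = 5) {
  stopifnot(c_mult > 0)
  n <- length(tree$tip.label)
  term <- tree$edge[, 2] <= n
  lens <- setNames(numeric(n), tree$tip.label)
  lens[tree$edge[term, 2]] <- tree$edge.length[term]
  med <- median(lens)
  setNames(lens > c_mult * med, names(lens))
}

#' Assign candidate proteins to clades A, B and C
#'
#' Formalises the three-clade structure of the candidate phylogeny:
#' clade A is the outgroup clade (the smallest clade containing every
#' ExsE/Brady-labelled protein), clade C is the smallest clade containing
#' every member of the largest SSN component together with the component
#' enriched for the SbmA/BacA HMM label (the BacA + BclA core), and clade B
#' is every remaining ingroup leaf.
#'
#' @param tree A rooted `phylo` over the candidate proteins.
#' @param evidence A `data.frame` with columns `protein_id`, `hmm_label`,
#'   `component_id` and `component_size` covering the tree leaves.
#' @return A `data.frame` with columns `protein_id` and `clade`
#'   (`A`/`B`/`C`/`unassigned`).
#' @export
assign_clades <- function(tree, evidence) {
  tips <- tree$tip.label
  ev <- evidence[match(tips, evidence$protein_id), ]
  out <- data.frame(protein_id = tips, clade = "unassigned",
                    stringsAsFactors = FALSE)
  og <- tips[!is.na(ev$hmm_label) & ev$hmm_label %in% c("ExsE", "Brady")]
  if (length(og) == 0) {
    warning("no ExsE/Brady outgroup seeds; all leaves unassigned")
    return(out)
  }
  cladeA <- clade_tips(tree, og)
  ingroup <- setdiff(tips, cladeA)

  # seed set for clade C: largest component plus the BacA-enriched component
  comp <- ev$component_id
  sizes <- tapply(rep(1L, length(comp)), comp, sum)
  largest <- as.integer(names(sizes)[order(-sizes, as.integer(names(sizes)))[1]])
  baca_n <- tapply(!is.na(ev$hmm_label) & ev$hmm_label == "BacA", comp, sum)
  baca_comp <- if (any(baca_n > 0)) {
    as.integer(names(baca_n)[order(-baca_n, as.integer(names(baca_n)))[1]])
  } else largest
  seed <- tips[!is.na(comp) & comp %in% c(largest, baca_comp)]
  seed <- intersect(seed, ingroup)
  if (length(seed) == 0) {
    warning("clade C seed components absent; ingroup left unassigned")
    out$clade[out$protein_id %in% cladeA] <- "A"
    return(out)
  }
  cladeC <- intersect(clade_tips(tree, seed), ingroup)
  out$clade[out$protein_id %in% cladeA] <- "A"
  out$clade[out$protein_id %in% cladeC] <- "C"
  out$clade[out$protein_id %in% setdiff(ingroup, cladeC)] <- "B"
  out
}

# tips of the smallest clade containing all `ids`
clade_tips <- function(tree, ids) {
  if (length(ids) == 1) return(ids)
  mrca <- ape::getMRCA(tree, ids)
  tips_below(tree, mrca)
}
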