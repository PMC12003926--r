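HMM_LABELS <- c("BacA", "BclA", "MBacA", "ExsE", "Brady", "other")

#' Rule-engine configuration
#'
#' Quantifies the cluster-level judgements used to turn HMM, SSN and clade
#' evidence into final calls. Defaults are chosen so that a pure SbmA/BacA
#' component is accepted (purity 0.90), a component dominated by BclA plus
#' Mycobacterium-BacA labels and lying in clade C is accepted as BclA
#' (purity 0.75; an ExsE-dominated component like the 8/14 case fails it),
#' and components below 4 members (three-protein clusters, singletons) are
#' set aside.
#'
#' @param bacA_purity Minimum component fraction of `BacA` labels for the
#'   SbmA/BacA accept rule (default 0.90).
#' @param bclA_purity Minimum component fraction of `BclA` + `MBacA` labels
#'   for the BclA accept rule (default 0.75).
#' @param clade_c_fraction_min Minimum fraction of component members in
#'   clade C for the BclA accept rule (default 0.75).
#' @param min_component_size Components smaller than this are excluded
#'   (default 4).
#' @return A `rule_config` object.
#' @export
rule_config <- function(bacA_purity = 0.90, bclA_purity = 0.75,
                        clade_c_fraction_min = 0.75, min_component_size = 4) {
  stopifnot(bacA_purity > 0, bacA_purity <= 1,
            bclA_purity > 0, bclA_purity <= 1,
            clade_c_fraction_min > 0, clade_c_fraction_min <= 1,
            min_component_size >= 1)
  structure(list(bacA_purity = bacA_purity, bclA_purity = bclA_purity,
                 clade_c_fraction_min = clade_c_fraction_min,
                 min_component_size = min_component_size),
            class = "rule_config")
}

#' Assemble the per-protein evidence table
#'
#' Full join of the three evidence streams on `protein_id`. Proteins missing
#' from a stream receive sentinel values with a warning (`hmm_label`
#' `"other"`, clade `"unassigned"`, singleton pseudo-component). A protein in
#' the SSN that is absent from the protein universe is an error.
#'
#' @param hits Annotation table (columns `protein_id`, `family_name`,
#'   `bit_score`), e.g. rows from [annotate_top_hit()].
#' @param ssn An `ssn` object.
#' @param clades Clade table from [assign_clades()].
#' @param proteins Protein record table (the id universe, carrying
#'   `species_id`).
#' @param long_branch Optional named logical vector from
#'   [flag_long_branches()].
#' @return Evidence `data.frame`: `protein_id`, `species_id`, `hmm_label`,
#'   `hmm_bits`, `component_id`, `component_size`, `clade`, `long_branch`.
#' @export
assemble_evidence <- function(hits, ssn, clades, proteins,
                              long_branch = NULL) {
  universe <- proteins$protein_id
  extra <- setdiff(names(ssn$components), universe)
  if (length(extra)) {
    stop("SSN contains proteins absent from the protein universe: ",
         paste(extra, collapse = ", "))
  }
  ids <- unique(c(hits$protein_id, names(ssn$components), clades$protein_id))
  ids <- universe[universe %in% ids]
  if (length(ids) == 0) {
    return(data.frame(protein_id = character(), species_id = character(),
                      hmm_label = character(), hmm_bits = numeric(),
                      component_id = integer(), component_size = integer(),
                      clade = character(), long_branch = logical(),
                      stringsAsFactors = FALSE))
  }
  lab <- hits$family_name[match(ids, hits$protein_id)]
  bits <- hits$bit_score[match(ids, hits$protein_id)]
  comp <- unname(ssn$components[ids])
  cl <- clades$clade[match(ids, clades$protein_id)]
  lb <- if (is.null(long_branch)) rep(FALSE, length(ids)) else
    unname(long_branch[ids])

  if (anyNA(lab)) warning("proteins missing HMM annotation labelled 'other': ",
                          paste(ids[is.na(lab)], collapse = ", "))
  if (anyNA(cl)) warning("proteins missing clade assignment set 'unassigned': ",
                         paste(ids[is.na(cl)], collapse = ", "))
  if (anyNA(comp)) {
    warning("proteins missing from the SSN become singleton components: ",
            paste(ids[is.na(comp)], collapse = ", "))
    mx <- max(c(0L, ssn$components))
    comp[is.na(comp)] <- mx + seq_len(sum(is.na(comp)))
  }
  lab[is.na(lab)] <- "other"
  cl[is.na(cl)] <- "unassigned"
  lb[is.na(lb)] <- FALSE
  # component sizes reflect the whole network; sentinel singletons get 1
  full_sizes <- table(ssn$components)
  in_net <- as.character(comp) %in% names(full_sizes)
  size <- rep(1L, length(comp))
  size[in_net] <- as.integer(full_sizes[as.character(comp[in_net])])
  data.frame(protein_id = ids,
             species_id = proteins$species_id[match(ids, universe)],
             hmm_label = lab, hmm_bits = ifelse(is.na(bits), -Inf, bits),
             component_id = as.integer(comp), component_size = size,
             clade = cl, long_branch = lb, stringsAsFactors = FALSE)
}

#' Per-component label profiles
#'
#' For every SSN component: size, the fraction of members carrying each HMM
#' label, the majority label, the fraction of members assigned to clade C,
#' and whether the component's members are monophyletic in the candidate
#' tree (singletons count as monophyletic).
#'
#' @param rows Evidence table from [assemble_evidence()].
#' @param tree Optional rooted `phylo`; without it the monophyly flag is
#'   `NA`.
#' @return A `data.frame`, one row per component, with a `label_fractions`
#'   matrix column.
#' @export
component_label_profile <- function(rows, tree = NULL) {
  ids <- sort(unique(rows$component_id))
  frac <- t(vapply(ids, function(cid) {
    lab <- rows$hmm_label[rows$component_id == cid]
    as.numeric(table(factor(lab, levels = HMM_LABELS))) / length(lab)
  }, numeric(length(HMM_LABELS))))
  colnames(frac) <- HMM_LABELS
  mono <- vapply(ids, function(cid) {
    members <- rows$protein_id[rows$component_id == cid]
    if (is.null(tree)) return(NA)
    members <- intersect(members, tree$tip.label)
    if (length(members) <= 1) return(TRUE)
    ape::is.monophyletic(tree, members)
  }, TRUE)
  out <- data.frame(
    component_id = ids,
    size = vapply(ids, function(cid) sum(rows$component_id == cid), 0L),
    majority_label = HMM_LABELS[max.col(frac, ties.method = "first")],
    in_clade_c_fraction = vapply(ids, function(cid)
      mean(rows$clade[rows$component_id == cid] == "C"), 0),
    monophyletic_in_tree = mono,
    stringsAsFactors = FALSE)
  out$label_fractions <- frac
  out
}

#' Apply the consensus classification rules
#'
#' Rules are applied in strict precedence; the first match wins and its id is
#' recorded:
#' \describe{
#'   \item{R1}{clade A: excluded, reason `clade_A_outgroup` (ExsE/Brady
#'     outgroup families).}
#'   \item{R2}{clade B: excluded, reason `clade_B_family` (a related but
#'     distinct family, not BclA).}
#'   \item{R3}{component of at least `min_component_size` with `BacA`
#'     fraction >= `bacA_purity`, monophyletic in the tree: SbmA/BacA.}
#'   \item{R4}{component of at least `min_component_size` with
#'     `BclA` + `MBacA` fraction >= `bclA_purity` and clade-C fraction
#'     >= `clade_c_fraction_min`: BclA.}
#'   \item{R5}{component with `ExsE` fraction >= 0.5: excluded,
#'     `exse_like_component`.}
#'   \item{R6}{component below `min_component_size`, or long-branch leaf:
#'     excluded (`small_or_singleton` / `long_branch`).}
#'   \item{R7}{anything else: excluded, `small_or_singleton`.}
#' }
#'
#' @param rows Evidence table.
#' @param profiles Component profiles from [component_label_profile()]
#'   (must cover every component in `rows`).
#' @param cfg A [rule_config()].
#' @return A `data.frame` of final calls: `protein_id`, `final_label`
#'   (`BacA`/`BclA`/`excluded`), `excluded_reason`, `rule_fired`.
#' @export
apply_rules <- function(rows, profiles, cfg = rule_config()) {
  stopifnot(all(rows$component_id %in% profiles$component_id))
  p <- match(rows$component_id, profiles$component_id)
  frac <- profiles$label_fractions
  n <- nrow(rows)
  label <- character(n); reason <- character(n); rule <- character(n)
  for (i in seq_len(n)) {
    pi <- p[i]
    small <- profiles$size[pi] < cfg$min_component_size
    bacA_ok <- !small && frac[pi, "BacA"] >= cfg$bacA_purity &&
      isTRUE(profiles$monophyletic_in_tree[pi])
    bclA_ok <- !small &&
      (frac[pi, "BclA"] + frac[pi, "MBacA"]) >= cfg$bclA_purity &&
      profiles$in_clade_c_fraction[pi] >= cfg$clade_c_fraction_min
    if (rows$clade[i] == "A") {
      label[i] <- "excluded"; reason[i] <- "clade_A_outgroup"; rule[i] <- "R1"
    } else if (rows$clade[i] == "B") {
      label[i] <- "excluded"; reason[i] <- "clade_B_family"; rule[i] <- "R2"
    } else if (bacA_ok) {
      label[i] <- "BacA"; reason[i] <- "none"; rule[i] <- "R3"
    } else if (bclA_ok) {
      label[i] <- "BclA"; reason[i] <- "none"; rule[i] <- "R4"
    } else if (frac[pi, "ExsE"] >= 0.5) {
      label[i] <- "excluded"; reason[i] <- "exse_like_component"; rule[i] <- "R5"
    } else if (small || rows$long_branch[i]) {
      label[i] <- "excluded"
      reason[i] <- if (small) "small_or_singleton" else "long_branch"
      rule[i] <- "R6"
    } else {
      label[i] <- "excluded"; reason[i] <- "small_or_singleton"; rule[i] <- "R7"
    }
  }
  data.frame(protein_id = rows$protein_id, final_label = label,
             excluded_reason = reason, rule_fired = rule,
             stringsAsFactors = FALSE)
}

#' Classify transporter homologues end to end
#'
#' Runs the full pipeline: build and calibrate the family profile HMMs from
#' their seed alignments, mine candidates from the proteomes with the
#' superfamily (mining) model, annotate each candidate with its top-scoring
#' family HMM, build the sequence similarity network, align candidates to the
#' mining profile, infer a neighbour-joining tree rooted on the ExsE/Brady
#' outgroup, assign clades A/B/C, apply the consensus rules, and summarise
#' the per-species distribution.
#'
#' @param proteins Protein record table for all proteomes (with
#'   `species_id` filled in).
#' @param species Species metadata table (see [read_species_table()]).
#' @param seeds Named list of `seed_alignment` objects: one element per
#'   family (`BacA`, `BclA`, `MBacA`, `ExsE`, `Brady` by convention) plus a
#'   `mining` element for the superfamily model used for candidate mining and
#'   profile alignment.
#' @param config List of pipeline parameters; see [classify_config()].
#' @return A `baca_classification` object.
#' @export
classify_transporters <- function(proteins, species, seeds,
                                  config = classify_config()) {
  stopifnot(is.list(seeds), "mining" %in% names(seeds))
  fam_names <- setdiff(names(seeds), "mining")
  stopifnot(length(fam_names) >= 1)

  # 1. models + calibration
  family_db <- lapply(fam_names, function(nm)
    build_profile(seeds[[nm]], config$occupancy_threshold, config$pseudocount,
                  family_name = nm))
  names(family_db) <- fam_names
  mining <- build_profile(seeds$mining, config$occupancy_threshold,
                          config$pseudocount, family_name = "mining")
  gumbels <- lapply(seq_along(family_db), function(i)
    calibrate(family_db[[i]], config$calib_n, config$calib_len,
              seed = config$seed + i))
  names(gumbels) <- fam_names
  gumbel_mining <- calibrate(mining, config$calib_n, config$calib_len,
                             seed = config$seed)

  empty_result <- function() {
    new_baca_classification(
      evidence = assemble_evidence(
        data.frame(protein_id = character(), family_name = character(),
                   bit_score = numeric()),
        build_network(all_vs_all_empty(), config$ssn_threshold,
                      node_ids = character()),
        data.frame(protein_id = character(), clade = character()),
        proteins),
      finals = data.frame(protein_id = character(), final_label = character(),
                          excluded_reason = character(),
                          rule_fired = character(), stringsAsFactors = FALSE),
      profiles = NULL, tree = NULL, ssn = NULL,
      presence = presence_absence(
        data.frame(protein_id = character(), final_label = character()),
        proteins, species),
      species = species, config = config, family_db = family_db,
      gumbels = gumbels)
  }
  if (nrow(proteins) == 0) return(empty_result())

  # 2. candidate mining
  hits_mine <- search_proteome(mining, proteins, gumbel_mining,
                               config$e_threshold)
  cand <- proteins[proteins$protein_id %in% hits_mine$protein_id, ,
                   drop = FALSE]
  if (nrow(cand) == 0) return(empty_result())

  # 3. per-family top-hit annotation
  hits <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i)
    annotate_top_hit(cand[i, ], family_db, gumbels, n_targets = nrow(cand))))

  # 4. SSN
  pairs <- if (nrow(cand) >= 2) {
    all_vs_all(cand, config$scheme, config$prefilter_kmer)
  } else all_vs_all_empty()
  ssn <- build_network(pairs, config$ssn_threshold,
                       node_ids = cand$protein_id)

  # 5. alignment, tree, clades
  tree <- NULL
  clades <- data.frame(protein_id = cand$protein_id, clade = "unassigned",
                       stringsAsFactors = FALSE)
  lb <- setNames(rep(FALSE, nrow(cand)), cand$protein_id)
  if (nrow(cand) >= 3) {
    msa <- align_to_profile(mining, cand)
    msa <- trim_columns(msa, config$max_gap_fraction)
    dm <- distance_matrix(msa)
    tree <- nj_tree(dm)
    og <- hits$protein_id[hits$family_name %in% c("ExsE", "Brady")]
    if (length(og) > 0 && length(og) < nrow(cand)) {
      tree <- root_tree(tree, og)
    }
    ev0 <- data.frame(protein_id = hits$protein_id,
                      hmm_label = hits$family_name,
                      component_id = unname(ssn$components[hits$protein_id]),
                      component_size = NA_integer_,
                      stringsAsFactors = FALSE)
    clades <- assign_clades(tree, ev0)
    lb <- flag_long_branches(tree, config$long_branch_c)
  }

  # 6. evidence + rules
  evidence <- assemble_evidence(hits, ssn, clades, proteins, lb)
  profiles <- component_label_profile(evidence, tree)
  finals <- apply_rules(evidence, profiles, config$rules)

  # 7. distribution
  presence <- presence_absence(finals, proteins, species)

  new_baca_classification(evidence = evidence, finals = finals,
                          profiles = profiles, tree = tree, ssn = ssn,
                          presence = presence, species = species,
                          config = config, family_db = c(family_db,
                                                         list(mining = mining)),
                          gumbels = c(gumbels,
                                      list(mining = gumbel_mining)))
}

all_vs_all_empty <- function() {
  data.frame(id1 = character(), id2 = character(), raw_score = numeric(),
             bit_score = numeric(), e_value = numeric(),
             alignment_score = numeric(), pct_identity = numeric(),
             aligned_columns = integer(), stringsAsFactors = FALSE)
}

#' Pipeline configuration for [classify_transporters()]
#'
#' @param e_threshold Mining E-value cutoff per search (default 1e-5).
#' @param ssn_threshold SSN alignment-score edge threshold (default 115).
#' @param occupancy_threshold,pseudocount Profile-building parameters
#'   (see [build_profile()]).
#' @param calib_n,calib_len Calibration sample size and mean length
#'   (see [calibrate()]).
#' @param max_gap_fraction Alignment trimming threshold (default 0.5).
#' @param long_branch_c Long-branch multiplier (default 5).
#' @param prefilter_kmer Optional shared-k-mer prefilter word size for the
#'   all-vs-all stage (`NULL` = off).
#' @param scheme Pairwise [scoring_scheme()].
#' @param rules A [rule_config()].
#' @param seed Integer seed for the calibration RNG.
#' @return A list of parameters (class `classify_config`).
#' @export
classify_config <- function(e_threshold = 1e-5, ssn_threshold = 115,
                            occupancy_threshold = 0.5, pseudocount = 1,
                            calib_n = 1000, calib_len = 400,
                            max_gap_fraction = 0.5, long_branch_c = 5,
                            prefilter_kmer = NULL,
                            scheme = scoring_scheme(),
                            rules = rule_config(), seed = 1) {
  structure(list(e_threshold = e_threshold, ssn_threshold = ssn_threshold,
                 occupancy_threshold = occupancy_threshold,
                 pseudocount = pseudocount, calib_n = calib_n,
                 calib_len = calib_len, max_gap_fraction = max_gap_fraction,
                 long_branch_c = long_branch_c,
                 prefilter_kmer = prefilter_kmer, scheme = scheme,
                 rules = rules, seed = seed),
            class = "classify_config")
}

new_baca_classification <- function(evidence, finals, profiles, tree, ssn,
                                    presence, species, config, family_db,
                                    gumbels) {
  structure(list(evidence = evidence, finals = finals, profiles = profiles,
                 tree = tree, ssn = ssn, presence = presence,
                 species = species, config = config, family_db = family_db,
                 gumbels = gumbels),
            class = "baca_classification")
}

#' @export
print.baca_classification <- function(x, ...) {
  n_baca <- sum(x$finals$final_label == "BacA")
  n_bcla <- sum(x$finals$final_label == "BclA")
  n_exc <- sum(x$finals$final_label == "excluded")
  cat("Transporter classification\n")
  cat("  candidates: ", nrow(x$evidence), "\n", sep = "")
  cat("  final SbmA/BacA: ", n_baca, "\n  final BclA:      ", n_bcla,
      "\n  excluded:        ", n_exc, "\n", sep = "")
  co <- cooccurrence(x$presence)
  cat("  species with either transporter: ", co$n_either,
      " of ", nrow(x$presence), "\n", sep = "")
  invisible(x)
}

#' @export
summary.baca_classification <- function(object, rank = "phylum", ...) {
  out <- list(
    final_counts = table(object$finals$final_label),
    excluded_reasons = table(object$finals$excluded_reason[
      object$finals$final_label == "excluded"]),
    rules = table(object$finals$rule_fired),
    cooccurrence = cooccurrence(object$presence),
    taxon = taxon_summary(object$presence, object$species, rank))
  class(out) <- "summary.baca_classification"
  out
}

#' @export
print.summary.baca_classification <- function(x, ...) {
  cat("Final classification counts:\n"); print(x$final_counts)
  cat("\nExclusion reasons:\n"); print(x$excluded_reasons)
  co <- x$cooccurrence
  cat("\nSpecies with either transporter: ", co$n_either,
      "; with both: ", co$n_both,
      if (!is.na(co$pct_both_of_either))
        paste0(" (", co$pct_both_of_either, "% of either)"), "\n", sep = "")
  cat("\nPer-taxon summary:\n")
  print(x$taxon, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.baca_classification <- function(x, ...) {
  merge(x$evidence, x$finals, by = "protein_id", sort = FALSE)
}

#' Plot a transporter classification
#'
#' Draws the candidate phylogeny with tips coloured by final call (left) and
#' the sequence similarity network coloured by component (right).
#'
#' @param x A `baca_classification`.
#' @param ... Passed to [ape::plot.phylo()].
#' @return Invisibly, `x`.
#' @export
plot.baca_classification <- function(x, ...) {
  if (is.null(x$tree) || is.null(x$ssn)) {
    warning("nothing to plot: pipeline produced no tree/network")
    return(invisible(x))
  }
  op <- graphics::par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  lab <- x$finals$final_label[match(x$tree$tip.label, x$finals$protein_id)]
  col <- c(BacA = "#b2182b", BclA = "#2166ac", excluded = "grey60")[lab]
  ape::plot.phylo(x$tree, show.tip.label = FALSE, main = "candidate phylogeny",
                  ...)
  ape::tiplabels(pch = 19, col = col, cex = 0.6)
  g <- igraph::make_empty_graph(n = length(x$ssn$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = x$ssn$nodes)
  if (nrow(x$ssn$edges)) {
    g <- igraph::add_edges(g, rbind(match(x$ssn$edges$id1, x$ssn$nodes),
                                    match(x$ssn$edges$id2, x$ssn$nodes)))
  }
  comp <- x$ssn$components[x$ssn$nodes]
  igraph::plot.igraph(g, vertex.label = NA, vertex.size = 4,
                      vertex.color = grDevices::rainbow(max(comp))[comp],
                      main = "sequence similarity network")
  invisible(x)
}
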