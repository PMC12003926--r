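#' Random family emission profile
#'
#' A family profile is the generator-side analogue of a profile HMM: a
#' consensus sequence plus one emission distribution per column. Column
#' distributions put moderate weight (~0.25 on average) on the consensus
#' residue with a sparse Dirichlet-like remainder, so emitted members are
#' clearly related without being near-identical.
#'
#' @param n_match Profile length in columns.
#' @param seed Integer seed.
#' @return A `family_profile` object (list with `consensus` integer codes and
#'   a `probs` matrix of `n_match` x 20 column distributions).
#' @export
random_profile <- function(n_match, seed = 1) {
  with_seed(seed, {
    consensus <- sample.int(20L, n_match, replace = TRUE)
    new_family_profile(consensus)
  })
}

# column distributions given a consensus (uses the current RNG stream)
new_family_profile <- function(consensus) {
  K <- length(consensus)
  probs <- matrix(rgamma(K * 20, shape = 0.3), K, 20)
  probs[cbind(seq_len(K), consensus)] <-
    probs[cbind(seq_len(K), consensus)] + 2
  probs <- probs / rowSums(probs)
  colnames(probs) <- AA20
  structure(list(consensus = consensus, probs = probs, n_match = K),
            class = "family_profile")
}

#' Derive a child profile at a given consensus divergence
#'
#' Resamples a fraction `r` of consensus positions (uniformly over the other
#' 19 residues) and regenerates the column distributions around the new
#' consensus; used to build a profile phylogeny whose between-family
#' identities are controlled.
#'
#' @param parent A `family_profile`.
#' @param r Fraction of consensus positions replaced.
#' @param seed Integer seed.
#' @return A `family_profile`.
#' @export
derive_profile <- function(parent, r, seed = 1) {
  with_seed(seed, {
    K <- parent$n_match
    cons <- parent$consensus
    flip <- runif(K) < r
    if (any(flip)) {
      cons[flip] <- vapply(cons[flip], function(a)
        sample(setdiff(seq_len(20L), a), 1), 0L)
    }
    new_family_profile(cons)
  })
}

profile_consensus_seq <- function(profile) {
  paste(AA20[profile$consensus], collapse = "")
}

# emit one member: consensus with an iid `divergence` fraction of positions
# resampled from the column distributions (uses the current RNG stream)
emit_one <- function(profile, divergence) {
  K <- profile$n_match
  res <- profile$consensus
  hit <- which(runif(K) < divergence)
  for (j in hit) {
    res[j] <- sample.int(20L, 1, prob = profile$probs[j, ])
  }
  paste(AA20[res], collapse = "")
}

#' Simulate a species tree
#'
#' Birth-death tree conditioned on `n` extant tips (via [ape::rphylo()]),
#' with tips labelled `sp01, sp02, ...`; deterministic given the seed.
#'
#' @param n Number of extant species (>= 3).
#' @param birth,death Per-lineage speciation and extinction rates
#'   (`birth > death >= 0`).
#' @param seed Integer seed.
#' @return An ultrametric `phylo` object.
#' @export
simulate_species_tree <- function(n, birth = 1, death = 0, seed = 1) {
  stopifnot(n >= 3, birth > death, death >= 0)
  tr <- with_seed(seed, ape::rphylo(n, birth, death, fossils = FALSE))
  tr$tip.label <- sprintf("sp%02d", seq_len(n))
  tr
}

#' Nested-clade taxonomy for simulated species
#'
#' Assigns phylum/class/order labels by cutting the (ultrametric) species
#' tree at three depths: the lineage a species descends from at each cut
#' defines its taxon at that rank. Genus is the species itself, mirroring a
#' one-genome-per-genus sampling design.
#'
#' @param tree Species tree from [simulate_species_tree()].
#' @param cuts Three depth fractions of the total tree height.
#' @return A species metadata `data.frame` (`species_id`, `genus`, `phylum`,
#'   `class`, `order`).
#' @export
species_taxonomy <- function(tree, cuts = c(0.25, 0.5, 0.75)) {
  stopifnot(length(cuts) == 3)
  depth <- ape::node.depth.edgelength(tree)
  total <- max(depth)
  n <- length(tree$tip.label)
  lineage_at <- function(frac) {
    d <- frac * total
    grp <- integer(n)
    for (i in seq_len(n)) {
      node <- i
      # walk rootward until the parent edge spans depth d
      repeat {
        e <- which(tree$edge[, 2] == node)
        if (length(e) == 0) break # reached root
        p <- tree$edge[e, 1]
        if (depth[p] < d && depth[node] >= d) break
        node <- p
      }
      grp[i] <- node
    }
    match(grp, sort(unique(grp)))
  }
  data.frame(species_id = tree$tip.label,
             genus = paste0("g_", tree$tip.label),
             phylum = sprintf("phylum%02d", lineage_at(cuts[1])),
             class = sprintf("class%02d", lineage_at(cuts[2])),
             order = sprintf("order%02d", lineage_at(cuts[3])),
             stringsAsFactors = FALSE)
}

#' Simulate gene family presence/absence on a species tree
#'
#' Continuous-time gain/loss along branches with optional horizontal
#' transfer, simulated exactly by uniformisation: candidate events arrive at
#' rate `gain + loss + hgt` and are thinned by the current state. An HGT
#' event copies the family from a uniformly chosen lineage alive at the event
#' time in which the family is present. A family may be founded at the stem
#' of a designated clade (`founder`), at the root, or arise purely by gain.
#'
#' @param tree Species tree.
#' @param families List of family specifications: each a list with `name`,
#'   `founder` (internal/tip node number, `"root"`, or `NA` for absent at
#'   root), `gain`, `loss`, `hgt` rates (per unit branch length).
#' @param seed Integer seed.
#' @return A list with `presence` (tips x families logical matrix) and
#'   `events` (data.frame: family, edge, time, type, donor_edge).
#' @export
simulate_gene_content <- function(tree, families, seed = 1) {
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)
  edges <- tree$edge
  tstart <- depth[edges[, 1]]
  tend <- depth[edges[, 2]]
  parent_edge <- match(edges[, 1], edges[, 2]) # NA for edges below the root
  presence <- matrix(FALSE, n, length(families),
                     dimnames = list(tree$tip.label,
                                     vapply(families, `[[`, "", "name")))
  ev_list <- list()
  with_seed(seed, {
    for (f in seq_along(families)) {
      fam <- families[[f]]
      gain <- fam$gain %||% 0; loss <- fam$loss %||% 0; hgt <- fam$hgt %||% 0
      R <- gain + loss + hgt
      founder <- fam$founder %||% NA
      root_present <- identical(founder, "root")
      stem_edge <- if (!identical(founder, "root") && !is.na(founder[1]) &&
                       is.numeric(founder)) which(edges[, 2] == founder)
      else integer(0)

      state <- rep(NA, nrow(edges))      # current state per edge
      resolve <- function(e) {
        chain <- integer(0)
        while (is.na(state[e])) {
          if (length(stem_edge) && e == stem_edge) {
            state[e] <<- TRUE; break
          }
          pe <- parent_edge[e]
          if (is.na(pe)) { state[e] <<- root_present; break }
          chain <- c(chain, e); e <- pe
        }
        for (e2 in rev(chain)) {
          state[e2] <<- if (length(stem_edge) && e2 == stem_edge) TRUE
          else state[parent_edge[e2]]
        }
      }

      if (R > 0) {
        n_ev <- stats::rpois(nrow(edges), R * (tend - tstart))
        times <- unlist(lapply(seq_len(nrow(edges)), function(e)
          if (n_ev[e] > 0) runif(n_ev[e], tstart[e], tend[e]) else numeric(0)))
        ev_edge <- rep(seq_len(nrow(edges)), n_ev)
        ord <- order(times)
        times <- times[ord]; ev_edge <- ev_edge[ord]
        for (q in seq_along(times)) {
          e <- ev_edge[q]; t <- times[q]
          resolve(e)
          u <- runif(1) * R
          if (u < gain) {
            if (!state[e]) {
              state[e] <- TRUE
              ev_list[[length(ev_list) + 1]] <- data.frame(
                family = fam$name, edge = e, time = t, type = "gain",
                donor_edge = NA_integer_)
            }
          } else if (u < gain + loss) {
            if (state[e]) {
              state[e] <- FALSE
              ev_list[[length(ev_list) + 1]] <- data.frame(
                family = fam$name, edge = e, time = t, type = "loss",
                donor_edge = NA_integer_)
            }
          } else if (!state[e]) {
            alive <- which(tstart < t & tend >= t)
            alive <- setdiff(alive, e)
            for (d in alive) resolve(d)
            donors <- alive[state[alive]]
            if (length(donors)) {
              donor <- if (length(donors) == 1) donors else
                donors[sample.int(length(donors), 1)]
              state[e] <- TRUE
              ev_list[[length(ev_list) + 1]] <- data.frame(
                family = fam$name, edge = e, time = t, type = "hgt",
                donor_edge = donor)
            }
          }
        }
      }
      for (e in seq_len(nrow(edges))) resolve(e)
      term <- which(edges[, 2] <= n)
      presence[edges[term, 2], f] <- state[term]
      if (length(stem_edge)) {
        ev_list[[length(ev_list) + 1]] <- data.frame(
          family = fam$name, edge = stem_edge, time = tstart[stem_edge],
          type = "founding_gain", donor_edge = NA_integer_)
      }
    }
  })
  events <- if (length(ev_list)) do.call(rbind, ev_list) else
    data.frame(family = character(), edge = integer(), time = numeric(),
               type = character(), donor_edge = integer())
  list(presence = presence, events = events)
}

#' Emit family member sequences for present genes
#'
#' Each present (species, family) pair yields one protein: the family
#' consensus with an i.i.d. `divergence` fraction of positions resampled from
#' the profile's column distributions, so the expected pairwise identity of
#' two members is at least `(1 - divergence)^2`.
#'
#' @param presence Tips x families logical matrix from
#'   [simulate_gene_content()].
#' @param profiles Named list of `family_profile` objects matching the
#'   presence columns.
#' @param divergence Expected fraction of resampled residues per member.
#' @param seed Integer seed.
#' @return A list with `proteins` (protein record table) and `truth`
#'   (data.frame `protein_id`, `species_id`, `true_family`).
#' @export
emit_family_sequences <- function(presence, profiles, divergence = 0.25,
                                  seed = 1) {
  stopifnot(divergence >= 0, divergence < 1,
            all(colnames(presence) %in% names(profiles)))
  rows <- with_seed(seed, {
    out <- list()
    for (fam in colnames(presence)) {
      sp <- rownames(presence)[presence[, fam]]
      for (s in sp) {
        out[[length(out) + 1]] <- data.frame(
          protein_id = paste(s, fam, sep = "_"), species_id = s,
          sequence = emit_one(profiles[[fam]], divergence),
          true_family = fam, stringsAsFactors = FALSE)
      }
    }
    out
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(protein_id = character(), species_id = character(),
               sequence = character(), true_family = character())
  proteins <- protein_records(tab$protein_id, tab$sequence,
                              species_id = tab$species_id,
                              description = tab$true_family)
  list(proteins = proteins,
       truth = tab[, c("protein_id", "species_id", "true_family")])
}

#' Generate background decoy proteins
#'
#' I.i.d. sequences from the background residue distribution with geometric
#' lengths around `length_mean`; the negative set for search specificity.
#'
#' @param n Number of decoys (>= 0).
#' @param length_mean Mean decoy length in residues.
#' @param background Length-20 residue frequency vector.
#' @param seed Integer seed.
#' @param prefix Identifier prefix.
#' @return A protein record table.
#' @export
make_decoys <- function(n, length_mean = 400, background = AA_BACKGROUND,
                        seed = 1, prefix = "decoy") {
  if (n == 0) return(protein_records(character(), character()))
  with_seed(seed, {
    lens <- pmax(10L, rgeom(n, 1 / length_mean) + 1L)
    seqs <- vapply(lens, function(L)
      paste(AA20[sample.int(20L, L, replace = TRUE, prob = background)],
            collapse = ""), "")
    protein_records(sprintf("%s_%04d", prefix, seq_len(n)), seqs,
                    description = "decoy")
  })
}

#' Synthetic benchmark configuration
#'
#' Defaults define the reference study conditions: 60 species, five families
#' (SbmA/BacA and BclA founded on disjoint clades; Mycobacterium-BacA
#' sister to BclA in the profile phylogeny; ExsE and Brady as outgroup
#' families), emission divergence 0.25 (within-family identity comfortably
#' above the 115-score SSN threshold; between-family identity comfortably
#' below it), 20 decoys per species, and small loss/HGT rates.
#'
#' @param n_species Number of species (>= 3; default 60).
#' @param birth,death Species-tree rates (default 1, 0.2).
#' @param profile_length Family profile length in residues (default 400,
#'   SbmA/BacA-scale).
#' @param divergence Member emission divergence (default 0.25).
#' @param n_decoys_per_species Decoys per species (default 20).
#' @param decoy_length_mean Mean decoy length (default 400).
#' @param gain_rate,loss_rate,hgt_rate Gene-content rates per unit branch
#'   length (defaults 0, 0.05, 0.02).
#' @param seed Integer master seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_species = 60, birth = 1, death = 0.2,
                       profile_length = 400, divergence = 0.25,
                       n_decoys_per_species = 20, decoy_length_mean = 400,
                       gain_rate = 0, loss_rate = 0.03, hgt_rate = 0.02,
                       seed = 1) {
  stopifnot(n_species >= 3, divergence >= 0, divergence < 1)
  structure(list(n_species = n_species, birth = birth, death = death,
                 profile_length = profile_length, divergence = divergence,
                 n_decoys_per_species = n_decoys_per_species,
                 decoy_length_mean = decoy_length_mean,
                 gain_rate = gain_rate, loss_rate = loss_rate,
                 hgt_rate = hgt_rate, seed = seed),
            class = "sim_config")
}

# derive the five family profiles from one ancestor through a fixed profile
# phylogeny: ((BacA,(BclA,MBacA)),(ExsE,Brady))
derive_family_profiles <- function(L, seed) {
  anc <- random_profile(L, seed = seed)
  ing <- derive_profile(anc, 0.35, seed = seed + 1)
  outg <- derive_profile(anc, 0.35, seed = seed + 2)
  bb <- derive_profile(ing, 0.20, seed = seed + 3)
  list(BacA = derive_profile(ing, 0.20, seed = seed + 4),
       BclA = derive_profile(bb, 0.30, seed = seed + 5),
       MBacA = derive_profile(bb, 0.30, seed = seed + 6),
       ExsE = derive_profile(outg, 0.30, seed = seed + 7),
       Brady = derive_profile(outg, 0.30, seed = seed + 8))
}

# pick a founder node with clade size closest to `target` among `allowed`
# tips; clades below 6 tips are penalised so families stay comfortably above
# the minimum-component-size exclusion rule even after losses
pick_founder <- function(tree, target, allowed_tips, desc) {
  n <- length(tree$tip.label)
  nodes <- seq_len(n + tree$Nnode)
  ok <- vapply(nodes, function(nd) all(desc[[nd]] %in% allowed_tips), TRUE)
  sizes <- lengths(desc)
  cand <- nodes[ok & sizes >= 2]
  if (length(cand) == 0) cand <- nodes[ok]
  penalty <- ifelse(sizes[cand] < 6, 1000, 0)
  cand[order(abs(sizes[cand] - target) + penalty, cand)][1]
}

#' Generate a synthetic benchmark dataset
#'
#' Composes the species-tree, gene-content and sequence simulators into a
#' complete labelled benchmark: per-species proteomes (family members plus
#' decoys), species metadata, the ground-truth table, seed alignments for the
#' five family HMMs and an 8-sequence superfamily mining seed, and the
#' species tree. Fully reproducible from `(cfg, cfg$seed)`.
#'
#' @param cfg A [sim_config()].
#' @return A `baca_benchmark` object: list with `proteins`, `species`,
#'   `truth`, `tree`, `seeds`, `profiles`, `gene_events`, `config`.
#' @export
generate_benchmark <- function(cfg = sim_config()) {
  seed <- cfg$seed
  tree <- simulate_species_tree(cfg$n_species, cfg$birth, cfg$death,
                                seed = seed)
  species <- species_taxonomy(tree)
  profiles <- derive_family_profiles(cfg$profile_length, seed = seed + 10)

  n <- cfg$n_species
  desc <- tip_descendants(tree)
  all_tips <- seq_len(n)
  # SbmA/BacA and BclA are founded on disjoint clades; Mycobacterium-BacA
  # also avoids the BacA clade (it finally maps to BclA); the outgroup
  # families may overlap anything (a species can carry e.g. ExsE and BacA)
  baca <- pick_founder(tree, round(0.15 * n), all_tips, desc)
  not_baca <- setdiff(all_tips, desc[[baca]])
  # BclA gets a clearly largest clade, mirroring the real data where the
  # BclA cluster is by far the largest SSN component
  founders <- list(
    BacA = baca,
    BclA = pick_founder(tree, round(0.40 * n), not_baca, desc),
    MBacA = pick_founder(tree, round(0.15 * n), not_baca, desc),
    ExsE = pick_founder(tree, round(0.18 * n), all_tips, desc),
    Brady = pick_founder(tree, round(0.12 * n), all_tips, desc))
  families <- lapply(names(founders), function(nm)
    list(name = nm, founder = founders[[nm]], gain = cfg$gain_rate,
         loss = cfg$loss_rate, hgt = cfg$hgt_rate))
  gc <- simulate_gene_content(tree, families, seed = seed + 20)

  fam_seq <- emit_family_sequences(gc$presence, profiles, cfg$divergence,
                                   seed = seed + 30)
  decoys <- make_decoys(cfg$n_decoys_per_species * n, cfg$decoy_length_mean,
                        seed = seed + 40)
  decoys$species_id <- rep(tree$tip.label, each = cfg$n_decoys_per_species)
  proteins <- rbind(fam_seq$proteins, decoys)
  truth <- rbind(fam_seq$truth,
                 data.frame(protein_id = decoys$protein_id,
                            species_id = decoys$species_id,
                            true_family = "decoy", stringsAsFactors = FALSE))

  seed_counts <- c(BacA = 15, BclA = 5, MBacA = 10, ExsE = 6, Brady = 7)
  seeds <- lapply(names(seed_counts), function(nm) {
    rows <- with_seed(seed + 50 + match(nm, names(seed_counts)),
                      vapply(seq_len(seed_counts[[nm]]), function(i)
                        emit_one(profiles[[nm]], cfg$divergence), ""))
    names(rows) <- sprintf("%s_seed%02d", nm, seq_along(rows))
    seed_alignment(rows)
  })
  names(seeds) <- names(seed_counts)
  mine_rows <- with_seed(seed + 60, {
    picks <- c(BacA = 2, BclA = 2, MBacA = 2, ExsE = 1, Brady = 1)
    unlist(lapply(names(picks), function(nm)
      setNames(vapply(seq_len(picks[[nm]]), function(i)
        emit_one(profiles[[nm]], cfg$divergence), ""),
        sprintf("%s_mine%d", nm, seq_len(picks[[nm]])))))
  })
  seeds$mining <- seed_alignment(mine_rows)

  structure(list(proteins = proteins, species = species, truth = truth,
                 tree = tree, seeds = seeds, profiles = profiles,
                 gene_events = gc$events, presence = gc$presence,
                 founders = founders, config = cfg),
            class = "baca_benchmark")
}

#' @export
print.baca_benchmark <- function(x, ...) {
  cat("synthetic benchmark: ", nrow(x$species), " species, ",
      nrow(x$proteins), " proteins (",
      sum(x$truth$true_family != "decoy"), " family members, ",
      sum(x$truth$true_family == "decoy"), " decoys)\n", sep = "")
  invisible(x)
}

#' Write a benchmark to disk
#'
#' Per-species FASTA files under `dir/proteomes/`, `species_table.tsv`,
#' `truth.tsv`, `species_tree.nwk` and Stockholm seed alignments under
#' `dir/seeds/`. Outputs are byte-deterministic for a fixed benchmark.
#'
#' @param bm A `baca_benchmark`.
#' @param dir Output directory (created).
#' @return Invisibly, `dir`.
#' @export
write_benchmark <- function(bm, dir) {
  dir.create(file.path(dir, "proteomes"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "seeds"), showWarnings = FALSE)
  for (sp in bm$species$species_id) {
    write_fasta(bm$proteins[bm$proteins$species_id == sp, , drop = FALSE],
                file.path(dir, "proteomes", paste0(sp, ".faa")))
  }
  write_species_table(bm$species, file.path(dir, "species_table.tsv"))
  write.table(bm$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_newick(bm$tree, file.path(dir, "species_tree.nwk"))
  for (nm in names(bm$seeds)) {
    write_stockholm(bm$seeds[[nm]], file.path(dir, "seeds",
                                              paste0(nm, ".sto")))
  }
  invisible(dir)
}

#' Score classification recovery against simulated truth
#'
#' Truth families map to expected final labels (BacA -> BacA; BclA and
#' MBacA -> BclA; ExsE, Brady and decoys -> excluded). Proteins in the truth
#' table with no final call (e.g. decoys never mined) count as excluded.
#'
#' @param finals Final-call table from [apply_rules()] or a
#'   `baca_classification`.
#' @param truth Truth table (`protein_id`, `true_family`).
#' @param evidence Optional evidence table; when given, component purity
#'   (size-weighted max truth-family fraction per component) is reported.
#' @return A list with `per_class` (precision/recall/F1 for BacA, BclA,
#'   excluded), `macro_f1`, `confusion` and optionally `component_purity`.
#' @export
score_recovery <- function(finals, truth, evidence = NULL) {
  if (inherits(finals, "baca_classification")) {
    evidence <- evidence %||% finals$evidence
    finals <- finals$finals
  }
  unknown <- setdiff(finals$protein_id, truth$protein_id)
  if (length(unknown)) {
    stop("final calls for proteins absent from the truth table: ",
         paste(unknown, collapse = ", "))
  }
  map <- c(BacA = "BacA", BclA = "BclA", MBacA = "BclA",
           ExsE = "excluded", Brady = "excluded", decoy = "excluded")
  expected <- unname(map[truth$true_family])
  predicted <- finals$final_label[match(truth$protein_id, finals$protein_id)]
  predicted[is.na(predicted)] <- "excluded"
  classes <- c("BacA", "BclA", "excluded")
  confusion <- table(truth = factor(expected, classes),
                     predicted = factor(predicted, classes))
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    tp <- confusion[cl, cl]
    fp <- sum(confusion[, cl]) - tp
    fn <- sum(confusion[cl, ]) - tp
    prec <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
    rec <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
    f1 <- if (is.na(prec) || is.na(rec) || prec + rec == 0) {
      if (tp + fp + fn == 0) NA_real_ else 0
    } else 2 * prec * rec / (prec + rec)
    data.frame(class = cl, precision = prec, recall = rec, f1 = f1,
               stringsAsFactors = FALSE)
  }))
  out <- list(per_class = per_class,
              macro_f1 = mean(per_class$f1, na.rm = TRUE),
              confusion = confusion)
  if (!is.null(evidence)) {
    tf <- truth$true_family[match(evidence$protein_id, truth$protein_id)]
    comps <- split(tf, evidence$component_id)
    pur <- vapply(comps, function(v) max(table(v)) / length(v), 0)
    out$component_purity <-
      sum(pur * lengths(comps)) / sum(lengths(comps))
  }
  out
}
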