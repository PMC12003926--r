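# Independent oracles used to validate the dynamic-programming and graph
# code. These deliberately enumerate rather than recurse over optimal
# substructure, so they share no logic with the implementations they check.

# --- forward-algorithm path-enumeration oracle -------------------------------
# Sums the odds of every explicit state path through a profile HMM under the
# local model: entry into any match state with weight 1/K, exit after any
# match state with weight 1, inserts emit background (odds 1), deletes are
# silent. Feasible for n_match <= 3 and sequences of length <= 4.
oracle_forward_bits <- function(hmm, seq) {
  obs <- bacafinder:::encode_seq(seq)
  L <- length(obs)
  K <- hmm$n_match
  lo <- 2^bacafinder:::hmm_log_odds(hmm)   # odds of match emission vs background
  tr <- hmm$transitions
  # cont(type, k, i): total odds of all continuations given the path is in
  # state (type, k) and residues 1..i are consumed
  cont <- function(type, k, i) {
    total <- 0
    if (type == "M") total <- total + 1  # exit
    if (type %in% c("M", "I")) {
      tm <- if (type == "M") tr[k, "MM"] else tr[k, "IM"]
      ti <- if (type == "M") tr[k, "MI"] else tr[k, "II"]
      td <- if (type == "M") tr[k, "MD"] else 0
      if (k < K && i < L) {
        total <- total + tm * lo[k + 1, obs[i + 1]] * cont("M", k + 1, i + 1)
      }
      if (i < L) total <- total + ti * cont("I", k, i + 1)
      if (type == "M" && k < K) total <- total + td * cont("D", k + 1, i)
    }
    if (type == "D") {
      if (k < K && i < L) {
        total <- total + tr[k, "DM"] * lo[k + 1, obs[i + 1]] *
          cont("M", k + 1, i + 1)
      }
      if (k < K) total <- total + tr[k, "DD"] * cont("D", k + 1, i)
    }
    total
  }
  tot <- 0
  for (i0 in seq_len(L)) {
    for (k0 in seq_len(K)) {
      tot <- tot + (1 / K) * lo[k0, obs[i0]] * cont("M", k0, i0)
    }
  }
  unname(log2(tot))
}

# random pair table for component tests (handles zero-edge draws)
random_pair_table <- function(nodes, m) {
  e1 <- sample(nodes, m, replace = TRUE)
  e2 <- sample(nodes, m, replace = TRUE)
  keep <- e1 != e2
  k <- sum(keep)
  data.frame(id1 = e1[keep], id2 = e2[keep],
             alignment_score = rep(150, k), raw_score = rep(1, k),
             bit_score = rep(1, k), e_value = rep(1, k),
             pct_identity = rep(50, k), aligned_columns = rep(1L, k),
             stringsAsFactors = FALSE)
}

# --- Smith-Waterman enumeration oracle ---------------------------------------
# Best local alignment score by recursive enumeration over all sequences of
# aligned residue pairs, with explicit affine gap costs between consecutive
# pairs (gap of length g costs open + (g-1) * extend). Feasible for
# sequences of length <= 6.
oracle_sw <- function(a, b, scheme = scoring_scheme()) {
  sa <- strsplit(a, "")[[1]]; sb <- strsplit(b, "")[[1]]
  m <- scheme$matrix
  gap <- function(g) if (g == 0) 0 else -(scheme$gap_open +
                                            (g - 1) * scheme$gap_extend)
  best_from <- function(i, j) {
    sc <- m[sa[i], sb[j]]
    ext <- 0
    for (i2 in seq_along(sa)) {
      for (j2 in seq_along(sb)) {
        if (i2 > i && j2 > j) {
          ext <- max(ext, gap(i2 - i - 1) + gap(j2 - j - 1) + best_from(i2, j2))
        }
      }
    }
    sc + ext
  }
  best <- 0
  for (i in seq_along(sa)) {
    for (j in seq_along(sb)) best <- max(best, best_from(i, j))
  }
  best
}

# --- union-find connected-component oracle -----------------------------------
oracle_components <- function(nodes, edges_id1, edges_id2) {
  parent <- setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (q in seq_along(edges_id1)) {
    r1 <- find(edges_id1[q]); r2 <- find(edges_id2[q])
    if (r1 != r2) parent[[r1]] <- r2
  }
  roots <- vapply(nodes, find, "")
  split(nodes, roots)
}

# --- tiny random profile HMMs for property tests -----------------------------
random_small_hmm <- function(width, n_rows = 6, gap_frac = 0.2,
                             family_name = "toy") {
  rows <- vapply(seq_len(n_rows), function(r) {
    ch <- sample(bacafinder:::AA20, width, replace = TRUE)
    ch[runif(width) < gap_frac] <- "-"
    paste(ch, collapse = "")
  }, "")
  # guarantee every column passes occupancy 0.5 in at least one arrangement
  seed <- tryCatch(seed_alignment(setNames(rows, paste0("r", seq_len(n_rows)))),
                   error = function(e) NULL)
  hmm <- tryCatch(build_profile(seed, 0.5, 1, family_name = family_name),
                  error = function(e) NULL)
  if (is.null(hmm)) random_small_hmm(width, n_rows, gap_frac, family_name)
  else hmm
}

random_aa <- function(n) paste(sample(bacafinder:::AA20, n, replace = TRUE),
                               collapse = "")

# --- shared expensive fixtures (computed once per test run) ------------------
.fixture_env <- new.env(parent = emptyenv())

default_benchmark <- function() {
  if (is.null(.fixture_env$bm)) {
    .fixture_env$bm <- generate_benchmark(sim_config(seed = 1))
  }
  .fixture_env$bm
}

default_pipeline <- function() {
  if (is.null(.fixture_env$res)) {
    bm <- default_benchmark()
    .fixture_env$elapsed <- system.time(
      .fixture_env$res <- classify_transporters(
        bm$proteins, bm$species, bm$seeds, classify_config(seed = 2024))
    )[["elapsed"]]
  }
  .fixture_env$res
}

pipeline_elapsed <- function() {
  default_pipeline()
  .fixture_env$elapsed
}

# small study conditions for repeated end-to-end runs (divergence sweeps)
small_config <- function(seed, divergence = 0.25) {
  sim_config(n_species = 30, n_decoys_per_species = 5, profile_length = 300,
             divergence = divergence, seed = seed)
}

run_small <- function(seed, divergence = 0.25) {
  bm <- generate_benchmark(small_config(seed, divergence))
  res <- classify_transporters(
    bm$proteins, bm$species, bm$seeds,
    classify_config(calib_n = 300, seed = seed + 500))
  score_recovery(res, bm$truth)
}

# --- Table 1 worked example ---------------------------------------------------
# The nine experimentally characterised proteins with their published
# evidence tuples (HMM classification, phylogeny clade, SSN cluster) and the
# published compositions of the clusters they belong to.
table1_fixture <- function() {
  rows <- data.frame(
    protein_id = c("P_gilvum_BacA", "S_elongatus_BclA", "C_aponinum_BclA",
                   "B_psittacipulmonis_BclA", "S_dextrinosolvens_BclA",
                   "M_anaerophila_BclA", "P_naphthalenivorans_BclA",
                   "E_exigua_BclA_like", "P_zundukense_ExsE"),
    species_id = c("P_gilvum", "S_elongatus", "C_aponinum",
                   "B_psittacipulmonis", "S_dextrinosolvens", "M_anaerophila",
                   "P_naphthalenivorans", "E_exigua", "P_zundukense"),
    hmm_label = c("BacA", "BclA", "BclA", "MBacA", "BclA", "BclA", "BclA",
                  "BclA", "ExsE"),
    hmm_bits = 100,
    component_id = c(5L, 6L, 6L, 1L, 1L, 1L, 1L, 4L, 2L),
    component_size = c(71L, 44L, 44L, 133L, 133L, 133L, 133L, 10L, 20L),
    clade = c("C", "C", "C", "C", "C", "C", "C", "B", "A"),
    long_branch = FALSE,
    stringsAsFactors = FALSE)

  prof <- data.frame(
    component_id = c(1L, 2L, 4L, 5L, 6L),
    size = c(133L, 20L, 10L, 71L, 44L),
    majority_label = c("BclA", "ExsE", "BclA", "BacA", "BclA"),
    in_clade_c_fraction = c(1, 0, 0, 1, 1),
    monophyletic_in_tree = c(TRUE, TRUE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
  frac <- matrix(0, 5, length(bacafinder:::HMM_LABELS),
                 dimnames = list(NULL, bacafinder:::HMM_LABELS))
  frac[1, c("BclA", "MBacA")] <- c(87, 46) / 133   # Cluster 1: 133 BclA incl 46 M-BacA
  frac[2, "ExsE"] <- 1                             # Cluster 2: outgroup ExsE cluster
  frac[3, c("BclA", "ExsE")] <- c(0.6, 0.4)        # Cluster 4: clade B cluster
  frac[4, "BacA"] <- 1                             # Cluster 5: 71/71 SbmA/BacA
  frac[5, c("BclA", "MBacA", "ExsE")] <- c(33, 10, 1) / 44 # Cluster 6: 43/44
  prof$label_fractions <- frac
  list(rows = rows, profiles = prof)
}
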