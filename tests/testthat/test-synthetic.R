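test_that("species trees are reproducible with the requested tip count", {
  t1 <- simulate_species_tree(12, 1, 0.2, seed = 4)
  t2 <- simulate_species_tree(12, 1, 0.2, seed = 4)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_equal(length(t1$tip.label), 12)
  t3 <- simulate_species_tree(3, 1, 0, seed = 4)
  expect_equal(length(t3$tip.label), 3)
})

test_that("Yule root-to-tip depth matches its closed-form expectation", {
  # time spent with k lineages is Exp(k * birth), k = 2..n, so the expected
  # root depth is (1/birth) * sum_{k=2}^{n} 1/k
  n <- 15; birth <- 1
  depths <- vapply(seq_len(200), function(i)
    max(ape::node.depth.edgelength(simulate_species_tree(n, birth, 0,
                                                         seed = 1000 + i))),
    0)
  expect_equal(mean(depths), sum(1 / (2:n)) / birth, tolerance = 0.1)
})

test_that("simulated taxonomy nests genus within order within class within phylum", {
  tr <- simulate_species_tree(40, 1, 0.2, seed = 8)
  tax <- species_taxonomy(tr)
  expect_equal(nrow(tax), 40)
  expect_equal(anyDuplicated(tax$genus), 0)
  # each order maps into exactly one class, each class into one phylum
  expect_true(all(tapply(tax$class, tax$order,
                         function(v) length(unique(v))) == 1))
  expect_true(all(tapply(tax$phylum, tax$class,
                         function(v) length(unique(v))) == 1))
})

test_that("gene content respects conservation limits", {
  tr <- simulate_species_tree(15, 1, 0, seed = 5)
  # no loss, founded at the root -> present everywhere
  keep <- simulate_gene_content(tr, list(list(name = "f", founder = "root",
                                              gain = 0, loss = 0, hgt = 0)),
                                seed = 2)
  expect_true(all(keep$presence[, "f"]))
  # no gain, absent at the root -> absent everywhere
  none <- simulate_gene_content(tr, list(list(name = "f", founder = NA,
                                              gain = 0, loss = 0.5, hgt = 0)),
                                seed = 2)
  expect_true(all(!none$presence[, "f"]))
  # founded on a clade stem, nothing else -> exactly that clade
  node <- 20 # internal node of the 15-tip tree
  clade <- simulate_gene_content(tr, list(list(name = "f", founder = node,
                                               gain = 0, loss = 0, hgt = 0)),
                                 seed = 2)
  tips <- bacafinder:::tips_below(tr, node)
  expect_identical(rownames(clade$presence)[clade$presence[, "f"]],
                   sort(tips))
})

test_that("loss-only dynamics match the exponential survival closed form", {
  tr <- simulate_species_tree(10, 1, 0, seed = 6)
  depth <- ape::node.depth.edgelength(tr)
  tip_depth <- depth[seq_len(10)]
  loss <- 0.3
  pres <- matrix(NA, 100, 10)
  for (r in seq_len(100)) {
    g <- simulate_gene_content(tr, list(list(name = "f", founder = "root",
                                             gain = 0, loss = loss, hgt = 0)),
                               seed = 3000 + r)
    pres[r, ] <- g$presence[, "f"]
  }
  # survival along a root-to-tip path of length d is exp(-loss * d);
  # average over tips, with binomial error on 100 replicates
  want <- mean(exp(-loss * tip_depth))
  got <- mean(pres)
  se <- sqrt(want * (1 - want) / (100 * 10)) * 3 # generous: tips correlate
  expect_lt(abs(got - want), max(3 * se, 0.06))
})

test_that("horizontal transfer can spread a family beyond its founder clade", {
  tr <- simulate_species_tree(20, 1, 0, seed = 9)
  node <- ape::getMRCA(tr, c("sp01", "sp02"))
  spread <- vapply(seq_len(30), function(r) {
    g <- simulate_gene_content(tr, list(list(name = "f", founder = node,
                                             gain = 0, loss = 0, hgt = 0.3)),
                               seed = 4000 + r)
    sum(g$presence[, "f"])
  }, 0)
  base <- length(bacafinder:::tips_below(tr, node))
  expect_true(any(spread > base))
  expect_true(all(spread >= base)) # no loss: the founder clade keeps it
})

test_that("family members diverge as configured", {
  prof <- random_profile(300, seed = 12)
  pres <- matrix(TRUE, 10, 1, dimnames = list(sprintf("sp%02d", 1:10), "fam"))
  same <- emit_family_sequences(pres, list(fam = prof), divergence = 0,
                                seed = 13)
  expect_equal(length(unique(same$proteins$sequence)), 1)
  expect_equal(same$proteins$sequence[1],
               bacafinder:::profile_consensus_seq(prof))

  div <- emit_family_sequences(pres, list(fam = prof), divergence = 0.3,
                               seed = 13)
  seqs <- strsplit(div$proteins$sequence, "")
  idents <- unlist(lapply(1:9, function(i) vapply((i + 1):10, function(j)
    mean(seqs[[i]] == seqs[[j]]), 0)))
  expect_gte(mean(idents), 0.40) # at least (1 - 0.3)^2 plus chance matches
  expect_lt(mean(idents), 0.75)
})

test_that("decoys are reproducible and essentially never hit the mining model", {
  expect_equal(nrow(make_decoys(0, 100)), 0)
  d1 <- make_decoys(50, 120, seed = 14)
  d2 <- make_decoys(50, 120, seed = 14)
  expect_identical(d1, d2)

  bm <- default_benchmark()
  h <- build_profile(bm$seeds$mining, family_name = "mining")
  g <- calibrate(h, 300, 400, seed = 15)
  decoys <- make_decoys(1000, 400, seed = 16)
  hits <- search_proteome(h, decoys, g, e_threshold = 1e-5)
  expect_lte(nrow(hits) / 1000, 1e-3)
})

test_that("benchmarks are pure functions of their configuration", {
  cfg <- sim_config(n_species = 12, n_decoys_per_species = 2,
                    profile_length = 80, seed = 17)
  b1 <- generate_benchmark(cfg)
  b2 <- generate_benchmark(cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_benchmark(b1, d1); write_benchmark(b2, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # conservation: every truth protein occurs exactly once in the FASTA set
  expect_equal(sort(b1$truth$protein_id), sort(b1$proteins$protein_id))
  expect_equal(anyDuplicated(b1$proteins$protein_id), 0)
})

test_that("recovery scoring handles perfect and degenerate predictions", {
  truth <- data.frame(protein_id = paste0("p", 1:6),
                      species_id = "s1",
                      true_family = c("BacA", "BclA", "MBacA", "ExsE",
                                      "Brady", "decoy"))
  perfect <- data.frame(protein_id = truth$protein_id,
                        final_label = c("BacA", "BclA", "BclA", "excluded",
                                        "excluded", "excluded"),
                        excluded_reason = "none", rule_fired = "R0")
  expect_equal(score_recovery(perfect, truth)$macro_f1, 1.0)

  all_exc <- perfect; all_exc$final_label <- "excluded"
  rec <- score_recovery(all_exc, truth)
  expect_equal(rec$per_class$recall[rec$per_class$class == "BacA"], 0)
  expect_equal(rec$per_class$recall[rec$per_class$class == "BclA"], 0)

  bad <- perfect; bad$protein_id[1] <- "stranger"
  expect_error(score_recovery(bad, truth), "stranger")
})
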