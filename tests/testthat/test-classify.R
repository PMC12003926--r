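test_that("evidence assembly joins the three streams with sentinels", {
  prot <- protein_records(c("p1", "p2", "p3"),
                          vapply(c(20, 20, 20), random_aa, ""),
                          species_id = c("s1", "s1", "s2"))
  hits <- data.frame(protein_id = c("p1", "p2"),
                     family_name = c("BacA", "BclA"), bit_score = c(50, 40))
  pairs <- data.frame(id1 = "p1", id2 = "p2", alignment_score = 150,
                      raw_score = 1, bit_score = 1, e_value = 1,
                      pct_identity = 50, aligned_columns = 10L)
  ssn <- build_network(pairs, 115, node_ids = c("p1", "p2", "p3"))
  clades <- data.frame(protein_id = c("p1", "p2"), clade = c("C", "C"))
  w <- capture_warnings(ev <- assemble_evidence(hits, ssn, clades, prot))
  expect_true(any(grepl("unassigned", w)))
  expect_true(any(grepl("other", w)))
  expect_equal(nrow(ev), 3)
  expect_equal(ev$clade[ev$protein_id == "p3"], "unassigned")
  expect_equal(ev$hmm_label[ev$protein_id == "p3"], "other")
  expect_equal(ev$component_size[ev$protein_id == "p1"], 2L)

  # a protein in the SSN but outside the universe is a hard error
  ssn_bad <- build_network(pairs, 115, node_ids = c("p1", "p2", "ghost"))
  expect_error(suppressWarnings(
    assemble_evidence(hits, ssn_bad, clades, prot)), "ghost")

  # empty inputs give an empty table
  empty <- assemble_evidence(hits[0, ],
                             build_network(pairs[0, ], 115,
                                           node_ids = character()),
                             clades[0, ], prot[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("component label profiles report fractions, clade-C share and monophyly", {
  rows <- data.frame(
    protein_id = paste0("p", 1:6),
    species_id = "s1",
    hmm_label = c("BclA", "BclA", "MBacA", "ExsE", "BacA", "BacA"),
    hmm_bits = 10,
    component_id = c(1L, 1L, 1L, 1L, 2L, 2L),
    component_size = c(4L, 4L, 4L, 4L, 2L, 2L),
    clade = c("C", "C", "C", "B", "C", "C"),
    long_branch = FALSE, stringsAsFactors = FALSE)
  tr <- ape::read.tree(text = "(((p1:1,p2:1):1,(p3:1,p4:1):1):1,(p5:1,p6:1):2);")
  prof <- component_label_profile(rows, tr)
  c1 <- prof[prof$component_id == 1, ]
  expect_equal(unname(c1$label_fractions[, "BclA"] +
                        c1$label_fractions[, "MBacA"]), 0.75)
  expect_equal(unname(c1$label_fractions[, "ExsE"]), 0.25)
  expect_equal(c1$in_clade_c_fraction, 0.75)
  expect_true(all(prof$monophyletic_in_tree))
  expect_equal(sum(prof$size), 6)
})

test_that("the rule engine reproduces the nine published worked-example calls", {
  fx <- table1_fixture()
  calls <- apply_rules(fx$rows, fx$profiles, rule_config())
  expect_equal(calls$final_label,
               c("BacA", "BclA", "BclA", "BclA", "BclA", "BclA", "BclA",
                 "excluded", "excluded"))
  expect_equal(calls$rule_fired,
               c("R3", "R4", "R4", "R4", "R4", "R4", "R4", "R2", "R1"))
  expect_equal(calls$excluded_reason[8], "clade_B_family")
  expect_equal(calls$excluded_reason[9], "clade_A_outgroup")
})

test_that("rule precedence handles singletons and ExsE-dominated components", {
  labels <- bacafinder:::HMM_LABELS
  frac_single <- matrix(0, 1, length(labels), dimnames = list(NULL, labels))
  frac_single[1, "BclA"] <- 1
  prof_single <- data.frame(component_id = 9L, size = 1L,
                            majority_label = "BclA",
                            in_clade_c_fraction = 1,
                            monophyletic_in_tree = TRUE)
  prof_single$label_fractions <- frac_single
  row_single <- data.frame(protein_id = "solo", species_id = "s",
                           hmm_label = "BclA", hmm_bits = 10,
                           component_id = 9L, component_size = 1L,
                           clade = "C", long_branch = FALSE)
  # a singleton clade-C BclA never reaches the accept rules: components
  # below the minimum size are excluded regardless of label purity
  call <- apply_rules(row_single, prof_single,
                      rule_config(min_component_size = 4))
  expect_equal(call$final_label, "excluded")
  expect_equal(call$rule_fired, "R6")
  expect_equal(call$excluded_reason, "small_or_singleton")

  # a 14-member clade-C component with 8 ExsE labels is excluded via R5
  frac7 <- matrix(0, 1, length(labels), dimnames = list(NULL, labels))
  frac7[1, c("ExsE", "BclA")] <- c(8, 6) / 14
  prof7 <- data.frame(component_id = 7L, size = 14L, majority_label = "ExsE",
                      in_clade_c_fraction = 1, monophyletic_in_tree = TRUE)
  prof7$label_fractions <- frac7
  rows7 <- data.frame(protein_id = paste0("q", 1:14), species_id = "s",
                      hmm_label = rep(c("ExsE", "BclA"), c(8, 6)),
                      hmm_bits = 10, component_id = 7L, component_size = 14L,
                      clade = "C", long_branch = FALSE)
  calls7 <- apply_rules(rows7, prof7, rule_config())
  expect_true(all(calls7$final_label == "excluded"))
  expect_true(all(calls7$rule_fired == "R5"))
  expect_true(all(calls7$excluded_reason == "exse_like_component"))

  # long-branch leaves in an otherwise unclassifiable component fire R6
  rows7$long_branch <- TRUE
  frac7[1, ] <- 0; frac7[1, "other"] <- 1
  prof7$label_fractions <- frac7
  calls_lb <- apply_rules(rows7, prof7, rule_config())
  expect_true(all(calls_lb$excluded_reason == "long_branch"))
})

test_that("every protein gets exactly one deterministic call", {
  fx <- table1_fixture()
  a <- apply_rules(fx$rows, fx$profiles)
  b <- apply_rules(fx$rows, fx$profiles)
  expect_identical(a, b)
  expect_equal(anyDuplicated(a$protein_id), 0)
  expect_true(all((a$final_label == "excluded") ==
                    (a$excluded_reason != "none")))
  expect_true(all(nzchar(a$rule_fired)))
})

test_that("raising bclA_purity can only shrink the BclA set", {
  set.seed(33)
  labels <- bacafinder:::HMM_LABELS
  for (rep in 1:20) {
    n_comp <- sample(2:5, 1)
    rows <- do.call(rbind, lapply(seq_len(n_comp), function(cid) {
      sz <- sample(2:8, 1)
      data.frame(protein_id = paste0("c", cid, "_", seq_len(sz)),
                 species_id = "s", hmm_label = sample(labels, sz, TRUE),
                 hmm_bits = 10, component_id = cid, component_size = sz,
                 clade = sample(c("B", "C"), sz, TRUE), long_branch = FALSE,
                 stringsAsFactors = FALSE)
    }))
    prof <- component_label_profile(rows)
    prof$monophyletic_in_tree <- TRUE
    prev <- Inf
    for (purity in c(0.4, 0.6, 0.8, 0.95)) {
      n_bcla <- sum(apply_rules(rows, prof,
                                rule_config(bclA_purity = purity))$final_label
                    == "BclA")
      expect_lte(n_bcla, prev)
      prev <- n_bcla
    }
  }
})

test_that("the full pipeline handles an empty proteome gracefully", {
  bm <- default_benchmark()
  res <- classify_transporters(bm$proteins[0, ], bm$species, bm$seeds,
                               classify_config(calib_n = 100))
  expect_s3_class(res, "baca_classification")
  expect_equal(nrow(res$finals), 0)
  expect_equal(nrow(res$presence), nrow(bm$species))
  expect_true(all(!res$presence$has_bacA))
})

test_that("classification objects print, summarise and convert", {
  res <- default_pipeline()
  expect_output(print(res), "Transporter classification")
  s <- summary(res, rank = "phylum")
  expect_output(print(s), "Per-taxon summary")
  df <- as.data.frame(res)
  expect_equal(nrow(df), nrow(res$evidence))
  expect_true(all(c("hmm_label", "final_label", "rule_fired") %in% names(df)))
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f); on.exit(grDevices::dev.off(), add = TRUE)
  expect_silent(plot(res))
})
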