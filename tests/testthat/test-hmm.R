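test_that("profiles from a degenerate identical-sequence seed are consensus-shaped", {
  seed <- seed_alignment(setNames(rep("MKVLW", 8), paste0("s", 1:8)))
  h <- build_profile(seed, family_name = "toy")
  expect_equal(h$n_match, 5)
  expect_equal(paste(bacafinder:::AA20[apply(h$match_emissions, 1, which.max)],
                     collapse = ""), "MKVLW")
})

test_that("column occupancy exactly at the threshold becomes a match state", {
  rows <- c("MA", "MA", "MA", "MA", "M-", "M-", "M-", "M-") # col 2: 4/8 = 0.5
  h <- build_profile(seed_alignment(setNames(rows, paste0("s", 1:8))), 0.5)
  expect_equal(h$n_match, 2)
  h2 <- build_profile(seed_alignment(setNames(rows, paste0("s", 1:8))), 0.51)
  expect_equal(h2$n_match, 1)
})

test_that("all emission and transition vectors are normalised and positive", {
  set.seed(11)
  for (rep in 1:10) {
    h <- random_small_hmm(sample(3:12, 1))
    expect_true(all(abs(rowSums(h$match_emissions) - 1) < 1e-9))
    expect_true(all(h$match_emissions > 0))
    tr <- h$transitions
    expect_true(all(abs(rowSums(tr[, c("MM", "MI", "MD"), drop = FALSE]) - 1) < 1e-9))
    expect_true(all(abs(rowSums(tr[, c("IM", "II"), drop = FALSE]) - 1) < 1e-9))
    expect_true(all(abs(rowSums(tr[, c("DM", "DD"), drop = FALSE]) - 1) < 1e-9))
    expect_true(all(tr > 0))
  }
  expect_error(build_profile(seed_alignment(c(a = "--", b = "--", c = "A-",
                                              d = "-A"))),
               "occupancy")
})

test_that("forward dominates Viterbi on random model/sequence pairs", {
  set.seed(21)
  for (rep in 1:60) {
    h <- random_small_hmm(sample(2:10, 1))
    s <- random_aa(sample(2:25, 1))
    expect_gte(score_forward(h, s), score_viterbi(h, s) - 1e-9)
  }
})

test_that("a single-path degenerate model gives forward equal to Viterbi", {
  # one match state, delta emission, scored on its one-residue consensus:
  # exactly one path exists, so the path sum equals the path max
  em <- matrix(1e-12, 1, 20); em[, 1] <- 1 - 19e-12
  em <- em / rowSums(em)
  tr <- matrix(c(0.9, 0.05, 0.05, 0.9, 0.1, 0.9, 0.1), 1, 7)
  h <- profile_hmm("degenerate", em, tr)
  expect_equal(score_forward(h, "A"), score_viterbi(h, "A"),
               tolerance = 1e-12)
})

test_that("forward equals the exhaustive path-enumeration oracle on tiny models", {
  set.seed(31)
  for (rep in 1:20) {
    h <- random_small_hmm(sample(2:3, 1), n_rows = 5, gap_frac = 0.15)
    for (L in 2:4) {
      s <- random_aa(L)
      expect_equal(score_forward(h, s), oracle_forward_bits(h, s),
                   tolerance = 1e-9)
    }
  }
})

test_that("scoring rejects residues outside the alphabet", {
  h <- random_small_hmm(4)
  expect_error(score_forward(h, "MK1L"), "alphabet")
  expect_error(score_viterbi(h, "MK L"), "alphabet")
  # X is allowed and scores zero against every state
  expect_silent(score_forward(h, "XXXX"))
})

test_that("Gumbel calibration reproduces its closed-form E-value at mu", {
  h <- random_small_hmm(8)
  g <- calibrate(h, n_random = 300, mean_len = 60, seed = 5)
  expect_equal(hmm_evalue(g$mu, g, 1), 1 - exp(-1), tolerance = 1e-9)
  expect_equal(hmm_evalue(g$mu, g, 500), 500 * (1 - exp(-1)),
               tolerance = 1e-6)
  # E-value strictly decreases with bit score
  s <- seq(g$mu - 5, g$mu + 20, length.out = 40)
  expect_true(all(diff(hmm_evalue(s, g, 100)) < 0))
  expect_error(calibrate(h, n_random = 50), "n_random")
})

test_that("Gumbel fitting recovers its own parameters from simulated scores", {
  mu <- 12; lambda <- 0.7
  set.seed(9)
  x <- mu - log(-log(runif(10000))) / lambda
  fit <- bacafinder:::fit_gumbel(x)
  expect_equal(fit$mu, mu, tolerance = 0.05 * mu)
  expect_equal(fit$lambda, lambda, tolerance = 0.05 * lambda)
})

test_that("search finds a planted model sequence among background decoys", {
  bm <- default_benchmark()
  h <- build_profile(bm$seeds$BacA, family_name = "BacA")
  g <- calibrate(h, 400, 200, seed = 6)
  decoys <- make_decoys(500, 200, seed = 17)
  planted <- protein_records("planted",
                             paste(bacafinder:::AA20[bm$profiles$BacA$consensus[1:200]],
                                   collapse = ""))
  pool <- rbind(decoys, planted)
  hits <- search_proteome(h, pool, g, e_threshold = 1e-5)
  expect_equal(hits$protein_id[1], "planted")

  # infinite threshold returns everything, sorted by E-value
  all_hits <- search_proteome(h, pool, g, e_threshold = Inf)
  expect_equal(nrow(all_hits), nrow(pool))
  expect_true(!is.unsorted(all_hits$e_value))

  empty <- search_proteome(h, pool[0, ], g)
  expect_equal(nrow(empty), 0)
})

test_that("top-hit annotation takes the argmax and applies the tie rule", {
  bm <- default_benchmark()
  db <- lapply(c(BacA = "BacA", BclA = "BclA"), function(nm)
    build_profile(bm$seeds[[nm]], family_name = nm))
  member <- bm$proteins[grepl("_BacA$", bm$proteins$protein_id), ][1, ]
  hit <- annotate_top_hit(member, db)
  expect_equal(hit$family_name, "BacA")
  expect_false(hit$tie)

  # exact tie: same model under two names -> lexicographically first + warning
  db2 <- list(zeta = db$BacA, alpha = db$BacA)
  db2$zeta$family_name <- "zeta"; db2$alpha$family_name <- "alpha"
  expect_warning(hit2 <- annotate_top_hit(member, db2), "tie")
  expect_equal(hit2$family_name, "alpha")
  expect_true(hit2$tie)
})

test_that("family label recovery from model-emitted sequences is high", {
  bm <- default_benchmark()
  fams <- c("BacA", "BclA", "MBacA", "ExsE", "Brady")
  db <- lapply(fams, function(nm) build_profile(bm$seeds[[nm]],
                                                family_name = nm))
  names(db) <- fams
  set.seed(77)
  n_per <- 12
  correct <- 0
  for (nm in fams) {
    # emission temperature 1.0: every position sampled from the column
    # distributions
    seqs <- vapply(seq_len(n_per), function(i)
      bacafinder:::emit_one(bm$profiles[[nm]], divergence = 1), "")
    for (s in seqs) {
      hit <- annotate_top_hit(list(protein_id = "q", sequence = s), db)
      correct <- correct + (hit$family_name == nm)
    }
  }
  expect_gte(correct / (n_per * length(fams)), 0.95)
})

test_that("profile databases round-trip through their tabular format", {
  bm <- default_benchmark()
  h <- build_profile(bm$seeds$ExsE, family_name = "ExsE")
  g <- calibrate(h, 200, 100, seed = 3)
  d <- withr::local_tempdir()
  write_hmm_db(list(ExsE = h), list(ExsE = g), d)
  back <- read_hmm_db(d)
  expect_equal(back$family_db$ExsE$match_emissions, h$match_emissions,
               tolerance = 1e-8)
  expect_equal(back$family_db$ExsE$transitions, h$transitions,
               tolerance = 1e-8)
  expect_equal(back$gumbels$ExsE$mu, g$mu, tolerance = 1e-4)
  s <- random_aa(50)
  expect_equal(score_forward(back$family_db$ExsE, s), score_forward(h, s),
               tolerance = 1e-5)
})
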