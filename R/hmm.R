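#' Build a profile HMM from a seed alignment
#'
#' Alignment columns whose residue occupancy (fraction of non-gap rows) is at
#' least `occupancy_threshold` become match states. Match emissions are
#' background-mixed pseudocounted frequencies,
#' `(counts + pseudocount * background) / (n_obs + pseudocount)`, and the
#' seven transition probabilities per state (M->M, M->I, M->D, I->M, I->I,
#' D->M, D->D) are estimated from the state paths implied by the seed rows
#' with Laplace (add-one) smoothing within each source-state group. Insert
#' states emit the background distribution. `X` residues are treated as
#' missing observations.
#'
#' @param seed A `seed_alignment`.
#' @param occupancy_threshold Minimum column occupancy for a match state
#'   (default 0.5, an hmmbuild-like heuristic).
#' @param pseudocount Background mixing weight per state (default 1).
#' @param family_name Label carried by hits against this model.
#' @param background Length-20 background frequency vector.
#' @return A `profile_hmm` object.
#' @export
build_profile <- function(seed, occupancy_threshold = 0.5, pseudocount = 1,
                          family_name = "family", background = AA_BACKGROUND) {
  stopifnot(inherits(seed, "seed_alignment"),
            occupancy_threshold > 0, occupancy_threshold <= 1,
            pseudocount > 0, length(background) == 20)
  background <- background / sum(background)
  mat <- do.call(rbind, strsplit(seed$rows, "", fixed = TRUE))
  occ <- colMeans(mat != "-")
  match_cols <- which(occ >= occupancy_threshold)
  K <- length(match_cols)
  if (K == 0) stop("no column reaches occupancy ", occupancy_threshold,
                   ": cannot build a profile")

  em <- matrix(0, K, 20, dimnames = list(NULL, AA20))
  for (j in seq_len(K)) {
    res <- mat[, match_cols[j]]
    res <- res[res %in% AA20]
    cnt <- table(factor(res, levels = AA20))
    em[j, ] <- (as.numeric(cnt) + pseudocount * background) /
      (length(res) + pseudocount)
  }

  # implied state path per row: M/D at match columns, I between them
  tc <- matrix(0, K, 7,
               dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II", "DM", "DD")))
  is_match <- seq_len(ncol(mat)) %in% match_cols
  state_of <- integer(ncol(mat)); state_of[match_cols] <- seq_len(K)
  for (r in seq_len(nrow(mat))) {
    path_state <- character(0); path_k <- integer(0)
    for (cidx in seq_len(ncol(mat))) {
      ch <- mat[r, cidx]
      if (is_match[cidx]) {
        path_state <- c(path_state, if (ch == "-") "D" else "M")
        path_k <- c(path_k, state_of[cidx])
      } else if (ch != "-") {
        k <- sum(is_match[seq_len(cidx)])
        if (k >= 1 && k < K) { # flanking inserts are unaligned in local mode
          path_state <- c(path_state, "I"); path_k <- c(path_k, k)
        }
      }
    }
    if (length(path_state) > 1) {
      for (s in seq_len(length(path_state) - 1)) {
        key <- paste0(path_state[s], path_state[s + 1])
        # I->D and D->I have no corresponding model transition and are dropped
        if (key %in% colnames(tc)) tc[path_k[s], key] <- tc[path_k[s], key] + 1
      }
    }
  }
  tc <- tc + 1 # Laplace
  tr <- tc
  tr[, c("MM", "MI", "MD")] <- tc[, c("MM", "MI", "MD")] /
    rowSums(tc[, c("MM", "MI", "MD"), drop = FALSE])
  tr[, c("IM", "II")] <- tc[, c("IM", "II")] /
    rowSums(tc[, c("IM", "II"), drop = FALSE])
  tr[, c("DM", "DD")] <- tc[, c("DM", "DD")] /
    rowSums(tc[, c("DM", "DD"), drop = FALSE])

  profile_hmm(family_name = family_name, match_emissions = em,
              transitions = tr, background = background)
}

#' Construct a profile HMM object
#'
#' @param family_name Family label.
#' @param match_emissions `n_match x 20` matrix of match emission
#'   probabilities (rows sum to 1).
#' @param transitions `n_match x 7` matrix with columns
#'   `MM, MI, MD, IM, II, DM, DD`; each of the three source-state groups sums
#'   to 1 per row.
#' @param background Length-20 background vector (also the insert emission
#'   distribution).
#' @return A `profile_hmm` object.
#' @export
profile_hmm <- function(family_name, match_emissions, transitions,
                        background = AA_BACKGROUND) {
  stopifnot(ncol(match_emissions) == 20, ncol(transitions) == 7,
            nrow(transitions) == nrow(match_emissions),
            nrow(match_emissions) >= 1)
  colnames(match_emissions) <- AA20
  colnames(transitions) <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
  obj <- structure(list(family_name = family_name,
                        n_match = nrow(match_emissions),
                        match_emissions = match_emissions,
                        insert_emissions = background / sum(background),
                        transitions = transitions,
                        background = background / sum(background)),
                   class = "profile_hmm")
  obj
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat("profile HMM '", x$family_name, "': ", x$n_match, " match states\n",
      sep = "")
  invisible(x)
}

#' Consensus sequence of a profile HMM
#'
#' The highest-probability residue of each match state.
#'
#' @param hmm A `profile_hmm`.
#' @return A character scalar of length `n_match`.
#' @export
hmm_consensus <- function(hmm) {
  paste(AA20[apply(hmm$match_emissions, 1, which.max)], collapse = "")
}

# log2-odds emission matrix (K x 21; X column is 0) and log2 transitions
hmm_log_odds <- function(hmm) {
  lo <- log2(sweep(hmm$match_emissions, 2, hmm$background, "/"))
  cbind(lo, X = 0)
}

hmm_log_tr <- function(hmm) log2(hmm$transitions)

#' Score a sequence against a profile HMM
#'
#' Both scores are local (Smith-Waterman-style entry/exit) log2-odds scores,
#' `log2 P(seq | model) / P(seq | background)`, in bits. The Viterbi score
#' uses the single best state path; the forward score sums over all paths, so
#' `score_forward(hmm, seq) >= score_viterbi(hmm, seq)` always.
#'
#' @param hmm A `profile_hmm`.
#' @param seq A non-empty amino-acid string (canonical letters plus `X`;
#'   `X` scores 0 against every state).
#' @return Score in bits.
#' @export
score_viterbi <- function(hmm, seq) {
  stopifnot(nzchar(seq))
  .hmm_dp_bits(hmm_log_odds(hmm), hmm_log_tr(hmm), encode_seq(seq), FALSE)
}

#' @rdname score_viterbi
#' @export
score_forward <- function(hmm, seq) {
  stopifnot(nzchar(seq))
  .hmm_dp_bits(hmm_log_odds(hmm), hmm_log_tr(hmm), encode_seq(seq), TRUE)
}

#' Calibrate E-value statistics for a profile HMM
#'
#' Fits a Gumbel (type-I extreme value) distribution by maximum likelihood to
#' the forward bit scores of `n_random` background-emitted random sequences
#' (geometric length distribution around `mean_len`). The fitted location
#' `mu` and scale `lambda_g` convert a bit score into a per-sequence P-value
#' `P(S > s) = 1 - exp(-exp(-lambda_g (s - mu)))` and an E-value over a
#' search set.
#'
#' @param hmm A `profile_hmm`.
#' @param n_random Number of calibration sequences (>= 100; default 1000).
#' @param mean_len Mean calibration sequence length (default 400 residues).
#' @param seed Integer seed; calibration is deterministic given the seed.
#' @return A `gumbel_params` object: list with `mu`, `lambda_g`, `n_calib`.
#' @export
calibrate <- function(hmm, n_random = 1000, mean_len = 400, seed = 1) {
  stopifnot(n_random >= 100)
  lo <- hmm_log_odds(hmm); ltr <- hmm_log_tr(hmm)
  scores <- with_seed(seed, {
    lens <- pmax(10L, rgeom(n_random, 1 / mean_len) + 1L)
    vapply(lens, function(L) {
      obs <- sample.int(20L, L, replace = TRUE, prob = hmm$background)
      .hmm_dp_bits(lo, ltr, obs, TRUE)
    }, 0)
  })
  fit <- fit_gumbel(scores)
  if (!is.finite(fit$lambda) || fit$lambda <= 0) {
    stop("degenerate Gumbel calibration (lambda <= 0)")
  }
  structure(list(mu = fit$mu, lambda_g = fit$lambda, n_calib = n_random),
            class = "gumbel_params")
}

# Gumbel maximum-likelihood fit: scale beta solves
# beta = mean(x) - sum(x exp(-x/beta)) / sum(exp(-x/beta)); mu follows.
fit_gumbel <- function(x) {
  stopifnot(length(x) >= 10)
  xbar <- mean(x)
  g <- function(beta) {
    w <- exp(-(x - max(x)) / beta)
    beta - xbar + sum(x * w) / sum(w)
  }
  lo <- sd(x) / 10; hi <- sd(x) * 10
  beta <- tryCatch(uniroot(g, c(lo, hi), tol = 1e-9)$root,
                   error = function(e) NA_real_)
  if (is.na(beta)) return(list(mu = NA_real_, lambda = NA_real_))
  z <- exp(-(x - max(x)) / beta)
  mu <- max(x) - beta * log(mean(z))
  list(mu = mu, lambda = 1 / beta)
}

#' E-value of a bit score under calibrated Gumbel statistics
#'
#' @param bits Bit score(s).
#' @param gumbel A `gumbel_params` object from [calibrate()].
#' @param n_targets Size of the searched sequence set.
#' @return Expected number of scores `>= bits` among `n_targets` random
#'   sequences.
#' @export
hmm_evalue <- function(bits, gumbel, n_targets = 1) {
  t <- exp(-gumbel$lambda_g * (bits - gumbel$mu))
  n_targets * (-expm1(-t))
}

#' Search a proteome with a calibrated profile HMM
#'
#' Scores every protein with the forward algorithm and returns hits with
#' E-value at most `e_threshold`, sorted by ascending E-value (ties broken by
#' protein id). E-values are computed over the size of the searched set.
#'
#' @param hmm A `profile_hmm`.
#' @param proteome Protein record table.
#' @param gumbel Calibration from [calibrate()].
#' @param e_threshold Maximum reported E-value (default 1e-5).
#' @return A `data.frame` with columns `protein_id`, `family_name`,
#'   `bit_score`, `e_value`.
#' @export
search_proteome <- function(hmm, proteome, gumbel, e_threshold = 1e-5) {
  n <- nrow(proteome)
  if (n == 0) {
    return(data.frame(protein_id = character(), family_name = character(),
                      bit_score = numeric(), e_value = numeric(),
                      stringsAsFactors = FALSE))
  }
  lo <- hmm_log_odds(hmm); ltr <- hmm_log_tr(hmm)
  bits <- vapply(proteome$sequence,
                 function(s) .hmm_dp_bits(lo, ltr, encode_seq(s), TRUE), 0,
                 USE.NAMES = FALSE)
  ev <- hmm_evalue(bits, gumbel, n)
  keep <- which(ev <= e_threshold)
  out <- data.frame(protein_id = proteome$protein_id[keep],
                    family_name = rep(hmm$family_name, length(keep)),
                    bit_score = bits[keep], e_value = ev[keep],
                    stringsAsFactors = FALSE)
  out[order(out$e_value, out$protein_id), , drop = FALSE]
}

#' Annotate a protein with its top-scoring family HMM
#'
#' Scores the protein against every model in `family_db` (forward algorithm)
#' and labels it with the family of maximal bit score. Exact ties are broken
#' by lexicographic family name with a warning, and a protein scoring
#' `-Inf` against every model receives the sentinel label `"other"`.
#'
#' @param protein A single-row protein record (or list with `protein_id` and
#'   `sequence`).
#' @param family_db Named list of `profile_hmm` objects.
#' @param gumbels Named list of `gumbel_params`, parallel to `family_db`.
#' @param n_targets Search-set size used for the reported E-value.
#' @return A one-row `data.frame`: `protein_id`, `family_name`, `bit_score`,
#'   `e_value`, `tie` (logical flag).
#' @export
annotate_top_hit <- function(protein, family_db, gumbels = NULL, n_targets = 1) {
  stopifnot(length(family_db) >= 1)
  fam <- vapply(family_db, function(h) h$family_name, "")
  bits <- vapply(family_db, function(h) score_forward(h, protein$sequence), 0)
  tie <- FALSE
  if (all(bits == -Inf)) {
    lab <- "other"; bs <- -Inf; ev <- NA_real_
  } else {
    top <- which(bits == max(bits))
    if (length(top) > 1) {
      tie <- TRUE
      top <- top[order(fam[top])][1]
      warning("bit-score tie for ", protein$protein_id,
              "; taking lexicographically first family: ", fam[top])
    }
    lab <- fam[top]; bs <- bits[top]
    ev <- if (!is.null(gumbels)) {
      hmm_evalue(bs, gumbels[[names(family_db)[top]]], n_targets)
    } else NA_real_
  }
  data.frame(protein_id = protein$protein_id, family_name = lab,
             bit_score = bs, e_value = ev, tie = tie,
             stringsAsFactors = FALSE)
}

#' Write / read a family profile-HMM database
#'
#' The database is a directory of per-family tabular profile files (state
#' index, 20 emission probabilities, 7 transition probabilities) plus a
#' `manifest.tsv` (family_name, n_match, mu, lambda_g, n_calib).
#'
#' @param family_db Named list of `profile_hmm` objects.
#' @param gumbels Named list of `gumbel_params`, parallel to `family_db`.
#' @param dir Database directory (created if needed).
#' @return Invisibly, `dir` (`write_hmm_db`); a list with `family_db` and
#'   `gumbels` (`read_hmm_db`).
#' @export
write_hmm_db <- function(family_db, gumbels, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- data.frame(
    family_name = vapply(family_db, function(h) h$family_name, ""),
    n_match = vapply(family_db, function(h) h$n_match, 0L),
    mu = fmt_num(vapply(gumbels, function(g) g$mu, 0)),
    lambda_g = fmt_num(vapply(gumbels, function(g) g$lambda_g, 0)),
    n_calib = vapply(gumbels, function(g) g$n_calib, 0),
    stringsAsFactors = FALSE)
  write.table(man, file.path(dir, "manifest.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (nm in names(family_db)) {
    h <- family_db[[nm]]
    tab <- data.frame(state = seq_len(h$n_match), h$match_emissions,
                      h$transitions, check.names = FALSE)
    tab[-1] <- lapply(tab[-1], function(x) format(x, digits = 10))
    write.table(tab, file.path(dir, paste0(nm, ".profile.tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
    bg <- data.frame(residue = AA20, freq = format(h$background, digits = 10))
    write.table(bg, file.path(dir, paste0(nm, ".background.tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_hmm_db
#' @export
read_hmm_db <- function(dir) {
  man <- read.delim(file.path(dir, "manifest.tsv"), stringsAsFactors = FALSE)
  family_db <- list(); gumbels <- list()
  for (i in seq_len(nrow(man))) {
    nm <- man$family_name[i]
    tab <- read.delim(file.path(dir, paste0(nm, ".profile.tsv")),
                      check.names = FALSE)
    bg <- read.delim(file.path(dir, paste0(nm, ".background.tsv")))
    em <- as.matrix(tab[, AA20])
    tr <- as.matrix(tab[, c("MM", "MI", "MD", "IM", "II", "DM", "DD")])
    family_db[[nm]] <- profile_hmm(nm, em, tr, background = bg$freq)
    gumbels[[nm]] <- structure(list(mu = man$mu[i], lambda_g = man$lambda_g[i],
                                    n_calib = man$n_calib[i]),
                               class = "gumbel_params")
  }
  list(family_db = family_db, gumbels = gumbels)
}
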