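#' Per-species presence/absence of the final transporter calls
#'
#' Counts final SbmA/BacA and BclA proteins per species. Every species in the
#' metadata table appears, with zeros where no protein was retained.
#'
#' @param finals Final-call table from [apply_rules()].
#' @param proteins Protein record table mapping proteins to species.
#' @param species Species metadata table.
#' @return A `data.frame` with columns `species_id`, `n_bacA`, `n_bclA`,
#'   `has_bacA`, `has_bclA`.
#' @export
presence_absence <- function(finals, proteins, species) {
  sp_of <- proteins$species_id[match(finals$protein_id, proteins$protein_id)]
  if (anyNA(sp_of) && nrow(finals)) {
    stop("final calls refer to proteins with no species mapping: ",
         paste(finals$protein_id[is.na(sp_of)], collapse = ", "))
  }
  unknown <- setdiff(stats::na.omit(sp_of), species$species_id)
  if (length(unknown)) {
    stop("proteins mapped to species absent from the species table: ",
         paste(unknown, collapse = ", "))
  }
  ids <- species$species_id
  n_bacA <- n_bclA <- setNames(integer(length(ids)), ids)
  keep <- finals$final_label %in% c("BacA", "BclA")
  if (any(keep)) {
    tb <- table(sp_of[keep], finals$final_label[keep])
    if ("BacA" %in% colnames(tb)) n_bacA[rownames(tb)] <- tb[, "BacA"]
    if ("BclA" %in% colnames(tb)) n_bclA[rownames(tb)] <- tb[, "BclA"]
  }
  data.frame(species_id = ids, n_bacA = unname(n_bacA),
             n_bclA = unname(n_bclA), has_bacA = unname(n_bacA >= 1),
             has_bclA = unname(n_bclA >= 1), stringsAsFactors = FALSE)
}

#' Round half-up to a fixed number of decimals
#'
#' Plain half-up decimal rounding (0.05 -> 0.1), matching how the
#' distribution percentages are reported; base `round()` rounds half to even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places (default 1).
#' @return Rounded values.
#' @export
round_half_up <- function(x, digits = 1) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' Per-taxon presence summary
#'
#' Groups the presence/absence table at a taxonomic rank and reports, per
#' taxon: the number of species, how many encode SbmA/BacA, BclA, either and
#' both, and the percentage with either (half-up, one decimal — e.g. 208 of
#' 1,255 gives 16.6).
#'
#' @param pa Presence/absence table from [presence_absence()].
#' @param species Species metadata table.
#' @param rank One of `"genus"`, `"order"`, `"class"`, `"phylum"`.
#' @return A `data.frame`, one row per taxon, sorted by taxon name.
#' @export
taxon_summary <- function(pa, species, rank = c("phylum", "class", "order",
                                                "genus")) {
  rank <- match.arg(rank)
  taxon <- species[[rank]][match(pa$species_id, species$species_id)]
  grp <- split(seq_len(nrow(pa)), taxon)
  out <- do.call(rbind, lapply(names(grp), function(tx) {
    i <- grp[[tx]]
    either <- pa$has_bacA[i] | pa$has_bclA[i]
    data.frame(rank = rank, taxon = tx, n_species = length(i),
               n_with_bacA = sum(pa$has_bacA[i]),
               n_with_bclA = sum(pa$has_bclA[i]),
               n_with_either = sum(either),
               n_with_both = sum(pa$has_bacA[i] & pa$has_bclA[i]),
               pct_either = round_half_up(100 * sum(either) / length(i), 1),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  stopifnot(all(out$n_with_both <= pmin(out$n_with_bacA, out$n_with_bclA)),
            all(pmin(out$n_with_bacA, out$n_with_bclA) <= out$n_with_either),
            all(out$n_with_either <= out$n_species))
  out
}

#' Co-occurrence of the two transporter families
#'
#' @param pa Presence/absence table.
#' @return A list with `n_either`, `n_both` and `pct_both_of_either`
#'   (half-up, one decimal; `NA` when no species encodes either).
#' @export
cooccurrence <- function(pa) {
  n_either <- sum(pa$has_bacA | pa$has_bclA)
  n_both <- sum(pa$has_bacA & pa$has_bclA)
  pct <- if (n_either == 0) NA_real_ else
    round_half_up(100 * n_both / n_either, 1)
  list(n_either = n_either, n_both = n_both, pct_both_of_either = pct)
}
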