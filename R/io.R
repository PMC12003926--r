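#' Read a protein FASTA file
#'
#' Parses a multi-FASTA file of amino-acid sequences into a protein table.
#' Sequences are uppercased, `*` stop symbols are stripped and the
#' non-canonical residue codes B, Z, U, O and J are normalised to `X` (which
#' scores zero against everything downstream). The protein identifier is the
#' first whitespace-delimited token of the header; the remainder is kept as
#' the description. Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @param species_id Optional species identifier attached to every record.
#'   Species linkage is deliberately explicit (per-file or via a mapping
#'   table), never parsed out of FASTA headers.
#' @return A `data.frame` with columns `protein_id`, `species_id`,
#'   `sequence` and `description` (a *protein record* table).
#' @export
read_fasta <- function(path, species_id = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(protein_records(character(), character()))
  if (!startsWith(lines[[1]], ">")) stop("not a FASTA file: ", path)
  hdr <- grepl("^>", lines)
  rec <- cumsum(hdr)
  headers <- sub("^>", "", lines[hdr])
  ids <- vapply(strsplit(headers, "\\s+"), `[`, "", 1)
  desc <- sub("^\\S+\\s*", "", headers)
  seqs <- vapply(split(lines[!hdr], rec[!hdr]), paste, "", collapse = "")
  seqs <- seqs[match(seq_along(ids), as.integer(names(seqs)))]
  seqs[is.na(seqs)] <- ""
  if (anyDuplicated(ids)) {
    stop("duplicate protein ID in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- normalize_protein(seqs)
  if (any(!nzchar(seqs))) {
    stop("empty sequence record in ", path, ": ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  protein_records(ids, seqs, species_id = species_id, description = desc)
}

#' Construct a protein record table
#'
#' @param protein_id Character vector of unique protein identifiers.
#' @param sequence Amino-acid sequences (20 canonical letters plus `X`).
#' @param species_id Species identifier(s), recycled to length.
#' @param description Free-text descriptions.
#' @return A `data.frame` with columns `protein_id`, `species_id`,
#'   `sequence`, `description`.
#' @export
protein_records <- function(protein_id, sequence,
                            species_id = NA_character_, description = "") {
  if (anyDuplicated(protein_id)) {
    stop("duplicate protein ID: ",
         paste(unique(protein_id[duplicated(protein_id)]), collapse = ", "))
  }
  data.frame(protein_id = as.character(protein_id),
             species_id = rep_len(as.character(species_id),
                                  length(protein_id)),
             sequence = as.character(sequence),
             description = rep_len(as.character(description),
                                   length(protein_id)),
             stringsAsFactors = FALSE)
}

# uppercase, strip stops, map non-canonical residues to X; validate alphabet
normalize_protein <- function(seqs) {
  s <- toupper(seqs)
  s <- gsub("*", "", s, fixed = TRUE)
  s <- chartr("BZUOJ", "XXXXX", s)
  bad <- grepl(paste0("[^", paste(AA21, collapse = ""), "]"), s)
  if (any(bad)) {
    stop("sequence contains non-amino-acid symbols (records ",
         paste(which(bad), collapse = ", "), ")")
  }
  s
}

#' Write a protein table to FASTA
#'
#' @param proteins A protein record table (see [protein_records()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(proteins, path) {
  hdr <- ifelse(nzchar(proteins$description),
                paste(proteins$protein_id, proteins$description),
                proteins$protein_id)
  out <- character(2L * nrow(proteins))
  out[c(TRUE, FALSE)] <- paste0(">", hdr)
  out[c(FALSE, TRUE)] <- proteins$sequence
  writeLines(out, path)
  invisible(path)
}

#' Read a Stockholm 1.0 seed alignment
#'
#' Reads a Stockholm-format multiple alignment (e.g. a Pfam seed such as the
#' eight-sequence SbmA/BacA-like family seed) and normalises both gap symbols
#' (`.` and `-`) to `-`. Ragged alignments are rejected.
#'
#' @param path Path to a Stockholm 1.0 file.
#' @return A `seed_alignment` object: list with `rows` (named character
#'   vector of aligned sequences), `n_rows` and `width`.
#' @export
read_stockholm_seed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^#", lines) & !grepl("^//", lines) & nzchar(trimws(lines))]
  if (length(body) == 0) stop("no sequence rows in Stockholm file: ", path)
  parts <- strsplit(trimws(body), "\\s+")
  if (any(lengths(parts) != 2)) stop("malformed Stockholm sequence line in ", path)
  nm <- vapply(parts, `[`, "", 1)
  rows <- vapply(parts, `[`, "", 2)
  # sequences may be split over multiple blocks: concatenate per name
  rows <- vapply(split(rows, factor(nm, levels = unique(nm))), paste, "",
                 collapse = "")
  seed_alignment(rows)
}

#' Construct a seed alignment
#'
#' @param rows Named character vector of aligned rows (gaps `-` or `.`).
#' @return A `seed_alignment` object.
#' @export
seed_alignment <- function(rows) {
  rows <- toupper(rows)
  rows <- chartr(".", "-", rows)
  rows <- chartr("BZUOJ", "XXXXX", rows)
  w <- unique(nchar(rows))
  if (length(w) != 1) stop("ragged alignment: row widths ", paste(sort(w), collapse = ", "))
  if (length(rows) < 2) stop("a seed alignment needs at least 2 rows")
  if (is.null(names(rows))) names(rows) <- paste0("row", seq_along(rows))
  structure(list(rows = rows, n_rows = length(rows), width = w),
            class = "seed_alignment")
}

#' Write a seed alignment in Stockholm 1.0 format
#'
#' @param seed A `seed_alignment`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_stockholm <- function(seed, path) {
  nm <- format(names(seed$rows), width = max(nchar(names(seed$rows))))
  writeLines(c("# STOCKHOLM 1.0",
               paste(nm, seed$rows),
               "//"), path)
  invisible(path)
}

#' Read a species metadata table
#'
#' @param path Tab-separated file with header columns `species_id`, `genus`,
#'   `phylum`, `class`, `order` (one row per species).
#' @return A `data.frame` with those columns; empty taxonomy cells become
#'   `"unknown"`.
#' @export
read_species_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("species_id", "genus", "phylum", "class", "order")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("species table is missing columns: ",
                         paste(miss, collapse = ", "))
  tab <- tab[, need]
  if (anyDuplicated(tab$species_id)) {
    stop("duplicate species_id: ",
         paste(unique(tab$species_id[duplicated(tab$species_id)]), collapse = ", "))
  }
  for (cc in need[-1]) {
    v <- as.character(tab[[cc]])
    v[is.na(v) | !nzchar(v)] <- "unknown"
    tab[[cc]] <- v
  }
  tab$species_id <- as.character(tab$species_id)
  tab
}

#' Write a species metadata table
#' @param species Species table.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_species_table <- function(species, path) {
  write.table(species, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# fixed 6-significant-digit float formatting so writers are byte-deterministic
fmt_num <- function(x) {
  out <- formatC(signif(x, 6), format = "g", digits = 6)
  out[is.na(x)] <- "NA"
  out
}

#' Write a phylogeny in Newick format
#'
#' @param tree An [ape::ape-package] `phylo` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}

#' Read a Newick phylogeny
#' @param path Path to a Newick file.
#' @return A `phylo` object.
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Write SSN edges as a plain-text edge list
#'
#' Columns: `id1`, `id2`, `alignment_score` (tab-separated, 6 significant
#' digits). An empty network produces a header-only file.
#'
#' @param ssn An `ssn` object (see [build_network()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(ssn, path) {
  e <- ssn$edges
  lines <- c("id1\tid2\talignment_score",
             if (nrow(e)) paste(e$id1, e$id2, fmt_num(e$alignment_score),
                                sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read an SSN edge list written by [write_edge_list()]
#' @param path Path to the edge list.
#' @return A `data.frame` with columns `id1`, `id2`, `alignment_score`.
#' @export
read_edge_list <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  tab$id1 <- as.character(tab$id1); tab$id2 <- as.character(tab$id2)
  tab
}

#' Write the per-protein evidence table
#'
#' Tab-separated with fixed column order: `protein_id`, `species_id`,
#' `hmm_label`, `hmm_bits`, `component_id`, `component_size`, `clade`,
#' `long_branch`.
#'
#' @param rows Evidence table (see [assemble_evidence()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_evidence_table <- function(rows, path) {
  cols <- c("protein_id", "species_id", "hmm_label", "hmm_bits",
            "component_id", "component_size", "clade", "long_branch")
  out <- rows[, cols]
  out$hmm_bits <- fmt_num(out$hmm_bits)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an iTOL binary presence/absence annotation file
#'
#' Produces an iTOL `DATASET_BINARY` annotation (one leaf label plus one
#' shape/colour field per transporter family) suitable for decorating a
#' user-supplied species phylogeny with which species encode SbmA/BacA
#' and/or BclA.
#'
#' @param pa Presence/absence table from [presence_absence()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_itol_presence <- function(pa, path) {
  hdr <- c("DATASET_BINARY", "SEPARATOR TAB", "DATASET_LABEL\tBacA/BclA presence",
           "COLOR\t#b2182b", "FIELD_SHAPES\t2\t2",
           "FIELD_LABELS\tSbmA/BacA\tBclA",
           "FIELD_COLORS\t#b2182b\t#2166ac", "DATA")
  rows <- paste(pa$species_id,
                ifelse(pa$has_bacA, 1L, 0L),
                ifelse(pa$has_bclA, 1L, 0L), sep = "\t")
  writeLines(c(hdr, rows), path)
  invisible(path)
}
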