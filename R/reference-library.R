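#' Build a labelled barcode reference library
#'
#' A reference library is a plain data frame of labelled barcode sequences,
#' one row per record, used both for amplicon taxon-resolution analysis and
#' for taxonomic assignment of pipeline centroids.
#'
#' @param id Unique record labels.
#' @param genus Genus labels (non-empty).
#' @param species Species epithets, or `NA` for records identified to genus
#'   only.
#' @param sequence Nucleotide strings (IUPAC ambiguity codes tolerated).
#' @param group Optional higher-level taxon group (e.g. `"aphid"`,
#'   `"coccinellid"`); defaults to `"unknown"`.
#' @param accession Optional external identifiers.
#' @return A data frame of class `reference_library` with columns `id`,
#'   `accession`, `genus`, `species`, `group`, `sequence`.
#' @export
reference_library <- function(id, genus, species, sequence,
                              group = "unknown", accession = NA_character_) {
  n <- length(id)
  stopifnot(length(sequence) == n)
  genus <- rep_len(genus, n)
  species <- rep_len(species, n)
  if (anyDuplicated(id)) stop("record ids must be unique", call. = FALSE)
  if (any(is.na(genus) | !nzchar(genus))) stop("genus labels must be non-empty", call. = FALSE)
  if (any(!nzchar(sequence))) stop("sequences must be non-empty", call. = FALSE)
  lib <- data.frame(id = as.character(id),
                    accession = rep_len(as.character(accession), n),
                    genus = as.character(genus),
                    species = as.character(species),
                    group = rep_len(as.character(group), n),
                    sequence = toupper(as.character(sequence)),
                    stringsAsFactors = FALSE)
  class(lib) <- c("reference_library", "data.frame")
  lib
}

#' Read a reference library from FASTA
#'
#' Taxonomy is parsed from the FASTA headers, which are split on `sep`
#' into the fields named by `fields` (in order). Missing trailing fields
#' become `NA`.
#'
#' @param path FASTA file.
#' @param fields Field names assigned to the header pieces; must include
#'   `"id"` and `"genus"`.
#' @param sep Separator between header fields.
#' @return A [reference_library()] data frame.
#' @export
read_reference_fasta <- function(path, fields = c("id", "genus", "species", "group"),
                                 sep = "|") {
  stopifnot(all(c("id", "genus") %in% fields))
  seqs <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(seqs), sep, fixed = TRUE)
  get <- function(field) {
    i <- match(field, fields)
    vapply(parts, function(p) if (length(p) >= i) p[i] else NA_character_, "")
  }
  reference_library(
    id = get("id"),
    genus = get("genus"),
    species = if ("species" %in% fields) get("species") else NA_character_,
    group = if ("group" %in% fields) {
      g <- get("group"); ifelse(is.na(g), "unknown", g)
    } else "unknown",
    sequence = as.character(seqs))
}

#' Write a reference library to FASTA
#'
#' @param library A [reference_library()].
#' @param path Output file.
#' @param sep Header field separator.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(library, path, sep = "|") {
  headers <- paste(library$id, library$genus,
                   ifelse(is.na(library$species), "", library$species),
                   library$group, sep = sep)
  seqs <- Biostrings::DNAStringSet(library$sequence)
  names(seqs) <- headers
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
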