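# Plain-text interchange: FASTA via Biostrings, taxonomy/truth/report tables
# as TSV. Read headers carry the sample as ">sampleID|readID".

#' Write a read set to FASTA
#'
#' Headers are `>sample_id|read_id` so a single file keeps per-sample labels.
#' @param reads a `read_set` data.frame.
#' @param path output file.
#' @export
write_reads_fasta <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- paste(reads$sample_id, reads$read_id, sep = "|")
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a demultiplexed read FASTA
#'
#' Inverse of [write_reads_fasta()]; provenance columns are absent (NA).
#' @param path FASTA file with `>sample|read` headers.
#' @return a `read_set` data.frame.
#' @export
read_reads_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  hd <- strsplit(names(x), "|", fixed = TRUE)
  out <- data.frame(
    sample_id = vapply(hd, `[`, "", 1L),
    read_id = vapply(hd, function(h) paste(h[-1L], collapse = "|"), ""),
    sequence = as.character(x),
    source_taxon_id = NA_character_,
    is_chimera = NA,
    chimera_parents = NA_character_,
    stringsAsFactors = FALSE)
  class(out) <- c("read_set", "data.frame")
  out
}

#' Write reference sequences and taxonomy
#'
#' Emits the reference FASTA plus a taxonomy TSV
#' (`taxon_id<TAB>phylum;class;order;family;genus;species<TAB>is_type_strain`).
#' @param db a `reference_db`.
#' @param fasta,taxonomy output paths.
#' @export
write_reference_db <- function(db, fasta, taxonomy) {
  x <- Biostrings::DNAStringSet(db$sequences)
  Biostrings::writeXStringSet(x, fasta)
  lin <- apply(db$taxa[, RANKS], 1L, paste, collapse = ";")
  tab <- data.frame(taxon_id = db$taxa$id, lineage = lin,
                    is_type_strain = db$taxa$is_type_strain)
  write.table(tab, taxonomy, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta, taxonomy))
}

#' Read a reference database from FASTA + taxonomy TSV
#' @param fasta,taxonomy paths written by [write_reference_db()] (or any
#'   FASTA plus `taxon_id<TAB>semicolon-lineage[<TAB>is_type_strain]` table).
#' @param outgroup_id leaf used for rooting (default `"outgroup"`).
#' @return a `reference_db`.
#' @export
read_reference_db <- function(fasta, taxonomy, outgroup_id = "outgroup") {
  x <- Biostrings::readDNAStringSet(fasta)
  tab <- read.table(taxonomy, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  lin <- strsplit(tab$lineage, ";", fixed = TRUE)
  if (any(lengths(lin) != 6L)) stop("lineages must have exactly 6 ranks")
  ranks <- do.call(rbind, lin)
  colnames(ranks) <- RANKS
  taxa <- data.frame(id = tab$taxon_id, ranks,
                     is_type_strain = if ("is_type_strain" %in% names(tab))
                       as.logical(tab$is_type_strain) else TRUE,
                     stringsAsFactors = FALSE)
  if (anyDuplicated(taxa$id)) stop("taxon ids must be unique")
  seqs <- setNames(as.character(x), names(x))
  if (!all(taxa$id %in% names(seqs))) stop("taxonomy lists taxa absent from FASTA")
  structure(list(taxa = taxa, sequences = seqs[taxa$id],
                 outgroup_id = outgroup_id,
                 seq_length = unique(nchar(seqs))[1L], seed = NA),
            class = "reference_db")
}

#' Write per-read truth (source taxon / chimera) as TSV
#' @param reads a `read_set` with provenance columns.
#' @param path output file.
#' @export
write_truth_tsv <- function(reads, path) {
  write.table(reads[, c("sample_id", "read_id", "source_taxon_id",
                        "is_chimera", "chimera_parents")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read probiotic/commensal/pathogen role annotations
#'
#' A two-column TSV `species<TAB>role` with roles in
#' probiotic/commensal/potential_pathogen.
#' @param path TSV file.
#' @return named character vector of roles keyed by species name.
#' @export
read_role_tsv <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  roles <- c("probiotic", "commensal", "potential_pathogen")
  if (!all(tab[[2L]] %in% roles))
    stop("roles must be one of: ", paste(roles, collapse = ", "))
  if (anyDuplicated(tab[[1L]])) stop("one role per species name")
  setNames(tab[[2L]], tab[[1L]])
}
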