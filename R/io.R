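# Readers and writers for the plain-text formats used throughout:
# FASTQ (Phred+33), FASTA, TSV tables, Newick trees.

#' Read a FASTQ file (Phred+33)
#'
#' Files whose quality encoding looks like Phred+64 (no quality character
#' below ASCII 64 anywhere) are rejected: the downstream expected-error
#' filter would silently misread them.
#'
#' @param path FASTQ file.
#' @return Read data.frame (id, seq, qual).
#' @export
read_fastq <- function(path) {
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq",
                                 with.qualities = TRUE),
    error = function(e) stop("malformed FASTQ '", path, "': ",
                             conditionMessage(e)))
  ids <- names(x)
  if (anyDuplicated(ids)) stop("duplicate read ids in ", path)
  quals <- as.character(S4Vectors::mcols(x)$qualities)
  codes <- utf8ToInt(paste(quals, collapse = ""))
  if (length(codes) > 0 && min(codes) >= 64) {
    stop("quality strings look Phred+64-encoded (no character below ",
         "ASCII 64); this reader requires Phred+33")
  }
  data.frame(id = ids, seq = as.character(x), qual = quals,
             stringsAsFactors = FALSE)
}

#' Write reads as FASTQ (Phred+33)
#'
#' @param reads Read data.frame (id, seq, qual).
#' @param path Output file.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(nchar(reads$seq) == nchar(reads$qual)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual),
             con, sep = "\n")
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (anyDuplicated(names(x))) stop("duplicate sequence ids in ", path)
  out <- as.character(x)
  names(out) <- names(x)
  out
}

#' Write sequences as FASTA
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write denoised genotypes as FASTA with size annotations
#'
#' Headers carry the funneled read count as `id;size=N`, the usual
#' convention of abundance-annotated amplicon FASTA.
#'
#' @param genotypes Genotype data.frame from [denoise()].
#' @param path Output file.
#' @export
write_genotype_fasta <- function(genotypes, path) {
  seqs <- genotypes$seq
  names(seqs) <- sprintf("%s;size=%d", genotypes$id, genotypes$total_count)
  write_fasta(seqs, path)
}

#' Read an OTU table TSV (OTUs as rows, samples as columns)
#'
#' @param path TSV with OTU ids in the first column.
#' @return Integer matrix.
#' @export
read_otu_table <- function(path) {
  df <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (any(is.na(m))) stop("missing values in OTU table ", path)
  if (any(m < 0)) stop("negative cell(s) in OTU table ", path)
  if (any(m != round(m))) stop("non-integer cell(s) in OTU table ", path)
  storage.mode(m) <- "integer"
  validate_otu_table(m)
  m
}

#' Write an OTU table TSV
#'
#' @param table OTU table (OTUs x samples).
#' @param path Output file.
#' @export
write_otu_table <- function(table, path) {
  validate_otu_table(table)
  df <- data.frame(otu_id = rownames(table), table, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata TSV
#'
#' @param path TSV with at least sample_id, pond_id, pond_type, replicate.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "pond_id", "pond_type")
  if (!all(need %in% names(df))) {
    stop("metadata must contain columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in ", path)
  df
}

#' Read a Newick tree
#'
#' @param path Newick file.
#' @param require_branch_lengths Reject trees without branch lengths (as
#'   required for betaNTI).
#' @return An `ape::phylo` object.
#' @export
read_newick <- function(path, require_branch_lengths = FALSE) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file ", path)
  if (require_branch_lengths && is.null(tree$edge.length)) {
    stop("tree in ", path, " lacks branch lengths")
  }
  tree
}

#' Write a tree as Newick
#'
#' @param tree `ape::phylo` object.
#' @param path Output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a read-truth table TSV
#'
#' @param truth Truth data.frame from [simulate_reads()].
#' @param path Output file.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(
    truth[, c("read_id", "genotype_id", "is_chimera", "breakpoint")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a read-truth table TSV
#'
#' @param path TSV written by [write_truth_table()].
#' @return data.frame.
#' @export
read_truth_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

write_tsv_matrix <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
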