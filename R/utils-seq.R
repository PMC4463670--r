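#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#' @importFrom stats rbinom rmultinom rnorm runif hclust dist as.dendrogram
#'   pnbinom setNames
#' @importFrom utils read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

# vectorised reverse complement on plain character vectors; sequences are
# kept in the DNA alphabet internally (T, not U)
revcomp <- function(x) {
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

#' Convert between DNA and RNA alphabets
#'
#' Internally every sequence is stored in the DNA alphabet; conversion to RNA
#' (U for T) happens only when rendering report tables, to match the naming
#' convention for mature miRNAs.
#'
#' @param x character vector of sequences.
#' @return character vector in the other alphabet.
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

#' @rdname dna_to_rna
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

# random DNA string(s) from the session RNG
random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
  }, character(1))
}

# Hamming distance between two equal-length strings (character-wise)
hamming <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  stopifnot(length(ca) == length(cb))
  sum(ca != cb)
}

# read a FASTA file into a named character vector (DNA alphabet, uppercase)
read_fasta_chr <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- names(x)
  out
}

# write a named character vector as FASTA
write_fasta_chr <- function(x, path) {
  set <- Biostrings::DNAStringSet(x)
  names(set) <- names(x)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
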