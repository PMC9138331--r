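# Readers and writers: FASTA (via Biostrings), aligned FASTA with a
# ragged-length check, and the published primer tables (TSV transcribed
# with their typographic emphasis markers, which are stripped on read).
# Printed degeneracy values are never trusted: they are recomputed from
# the sequence and disagreements raise a warning naming both values.

#' Read sequences from a FASTA file
#'
#' @param path Path to a FASTA file (gzip-compressed files are read
#'   transparently).
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id '", ids[duplicated(ids)][1L], "' in ", path,
         call. = FALSE)
  }
  stats::setNames(toupper(as.character(x)), ids)
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(sequences, path) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("sequences must be named", call. = FALSE)
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

#' Read a multiple alignment from aligned FASTA
#'
#' As [read_fasta()], additionally enforcing equal sequence lengths.
#'
#' @param path Path to an aligned FASTA file.
#' @return Named character vector of aligned sequences.
#' @export
read_alignment <- function(path) {
  x <- read_fasta(path)
  if (length(unique(nchar(x))) > 1L) {
    stop("ragged alignment in ", path, ": lengths ",
         paste(unique(nchar(x)), collapse = ", "), call. = FALSE)
  }
  x
}

#' Read a universal-primer table
#'
#' Reads a TSV with columns Gene, Primer, Sequence, Gene Location,
#' Degeneracy, Ref (header names matched case- and
#' punctuation-insensitively). Typographic emphasis markers (asterisks,
#' bold/underline markup) are stripped from sequences and names; primer
#' orientation is parsed from a "(F)"/"(R)" suffix on the name. The
#' degeneracy column, when present, is checked against the value
#' recomputed from the sequence: the recomputed value is authoritative and
#' a disagreement warns naming both (a printed 0, the tables' convention
#' for "no degeneracy introduced", is accepted as 1).
#'
#' @param path Path to the TSV.
#' @return Data frame with columns `name`, `sequence` (clean IUPAC),
#'   `orientation` ("F"/"R" or NA), `gene`, `gene_location`, `degeneracy`
#'   (recomputed), `degeneracy_printed`, `source`.
#' @examples
#' tab <- read_primer_table(
#'   system.file("extdata", "primers_diptera.tsv", package = "mtmlsa"))
#' tab[tab$name == "C1-N-2776-Dipt", c("sequence", "degeneracy")]
#' @export
read_primer_table <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, comment.char = "#")
  norm <- function(x) gsub("[^a-z]", "", tolower(x))
  cols <- norm(names(raw))
  pick <- function(key) {
    i <- match(key, cols)
    if (is.na(i)) rep(NA_character_, nrow(raw)) else as.character(raw[[i]])
  }
  if (nrow(raw) == 0L) {
    warning("primer table ", path, " contains no records")
    return(data.frame(name = character(), sequence = character(),
                      orientation = character(), gene = character(),
                      gene_location = character(), degeneracy = numeric(),
                      degeneracy_printed = numeric(), source = character(),
                      stringsAsFactors = FALSE))
  }
  name_raw <- pick("primer")
  seq_raw <- pick("sequence")
  if (all(is.na(name_raw)) || all(is.na(seq_raw))) {
    stop("primer table must have 'Primer' and 'Sequence' columns",
         call. = FALSE)
  }
  strip <- function(x) gsub("\\*|_|\\s", "", x)
  sequence <- toupper(gsub("[^A-Za-z]", "", seq_raw))
  orientation <- ifelse(grepl("\\(F\\)", name_raw), "F",
                        ifelse(grepl("\\(R\\)", name_raw), "R",
                               NA_character_))
  name <- strip(gsub("\\((F|R)\\)", "", name_raw))
  for (i in seq_along(sequence)) {
    ok <- tryCatch({degeneracy(sequence[i]); TRUE},
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) {
      stop("row ", i, " of ", path, ": ", ok, call. = FALSE)
    }
  }
  deg <- degeneracy(sequence)
  printed <- suppressWarnings(as.numeric(pick("degeneracy")))
  for (i in seq_along(deg)) {
    if (is.na(printed[i])) next
    stated <- if (printed[i] == 0) 1 else printed[i]
    if (stated != deg[i]) {
      warning(sprintf(
        "primer '%s': table states degeneracy %s but the sequence gives %s (recomputed value kept)",
        name[i], format(printed[i]), format(deg[i])))
    }
  }
  data.frame(name = name, sequence = sequence, orientation = orientation,
             gene = pick("gene"), gene_location = pick("genelocation"),
             degeneracy = deg, degeneracy_printed = printed,
             source = pick("ref"), stringsAsFactors = FALSE)
}
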