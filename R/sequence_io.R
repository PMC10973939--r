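#' @importFrom stats rnorm runif setNames sd
#' @importFrom utils read.csv write.csv write.table head tail
NULL

# 20 standard residues, alphabetical; 'O' is reserved as the pad symbol.
STANDARD_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
PAD_SYMBOL <- "O"

#' Amino-acid alphabet for one-hot encoding
#'
#' Builds the 21-symbol alphabet used to encode peptides: the 20 standard
#' one-letter amino-acid codes plus the pad symbol \code{"O"}, which fills
#' positions beyond a peptide's true length.  The symbol order determines
#' the column order of the one-hot matrix; the default is alphabetical with
#' the pad symbol last.  All encoding invariants are order-independent, so
#' a custom order only permutes columns.
#'
#' @param symbols Character vector of 21 distinct single characters: the 20
#'   standard amino acids in any order, plus the pad symbol exactly once.
#' @param pad Pad symbol (default \code{"O"}).
#' @return An object of class \code{aa_alphabet}: list with \code{symbols}
#'   (length 21) and \code{index} (named integer map symbol -> column).
#' @examples
#' ab <- aa_alphabet()
#' ab$index[["A"]]  # 1
#' @export
aa_alphabet <- function(symbols = c(STANDARD_AA, PAD_SYMBOL), pad = PAD_SYMBOL) {
  symbols <- as.character(symbols)
  if (length(symbols) != 21L || anyDuplicated(symbols))
    stop("alphabet must contain exactly 21 distinct symbols")
  if (sum(symbols == pad) != 1L)
    stop("pad symbol '", pad, "' must appear exactly once in the alphabet")
  if (!setequal(symbols, c(STANDARD_AA, pad)))
    stop("alphabet must consist of the 20 standard amino acids plus the pad symbol")
  structure(
    list(symbols = symbols, pad = pad,
         index = setNames(seq_along(symbols), symbols)),
    class = "aa_alphabet")
}

#' Validate a peptide sequence
#'
#' A valid peptide has length 4 to 50 and uses only the 20 standard
#' one-letter amino-acid codes.  The letter \code{"O"} is reserved for
#' padding and rejected, as are ambiguity codes (B, J, U, X, Z).  Input is
#' upper-cased before validation.
#'
#' @param sequence A single character string.
#' @return The validated (upper-cased) sequence, invisibly usable downstream.
#' @examples
#' validate_peptide("FLPK")
#' @export
validate_peptide <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("sequence must be a single character string")
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < 4L || n > 50L)
    stop("peptide length ", n, " outside the allowed range [4, 50]")
  chars <- strsplit(sequence, "")[[1]]
  bad <- setdiff(unique(chars), STANDARD_AA)
  if (length(bad)) {
    if (PAD_SYMBOL %in% bad)
      stop("illegal symbol 'O' ('O' is reserved for padding)")
    stop("illegal symbol(s): ", paste(sQuote(bad), collapse = ", "))
  }
  sequence
}

#' Construct a peptide dataset
#'
#' Assembles validated peptide records into the package's standard dataset
#' container: a data.frame with columns \code{id}, \code{sequence} and
#' \code{label} (\code{NA} when unlabeled).
#'
#' @param id Character vector of unique, non-empty identifiers.
#' @param sequence Character vector of peptide sequences (validated).
#' @param label Optional binary labels (1 = ACP, 0 = non-ACP) or NULL.
#' @return data.frame with one row per peptide.
#' @export
peptide_records <- function(id, sequence, label = NULL) {
  id <- as.character(id)
  if (any(!nzchar(id)) || anyNA(id)) stop("ids must be non-empty")
  if (anyDuplicated(id))
    stop("duplicate id(s): ", paste(unique(id[duplicated(id)]), collapse = ", "))
  if (length(id) != length(sequence)) stop("id and sequence lengths differ")
  sequence <- vapply(seq_along(sequence), function(i) {
    tryCatch(validate_peptide(sequence[[i]]),
             error = function(e) stop("record '", id[[i]], "': ",
                                      conditionMessage(e), call. = FALSE))
  }, character(1))
  if (is.null(label)) {
    label <- rep(NA_integer_, length(id))
  } else {
    label <- as.integer(label)
    if (length(label) != length(id)) stop("label length mismatch")
    bad <- !is.na(label) & !(label %in% c(0L, 1L))
    if (any(bad)) stop("labels must be 0 or 1; offending id(s): ",
                       paste(id[bad], collapse = ", "))
  }
  data.frame(id = id, sequence = sequence, label = label,
             stringsAsFactors = FALSE)
}

#' Read peptides from a FASTA file
#'
#' @param path Path to a FASTA file with '>' headers.
#' @return data.frame of peptide records (label \code{NA}); input order kept.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L)
    return(peptide_records(character(0), character(0)))
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids)))
    stop("FASTA entry ", which(!nzchar(ids))[1], " has an empty header")
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs)))
    stop("FASTA entry '", ids[!nzchar(seqs)][1], "' has an empty sequence")
  peptide_records(ids, seqs)
}

#' Write peptides to a FASTA file
#'
#' @param records Peptide data.frame (see [peptide_records()]).
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::AAStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a labeled peptide dataset from CSV
#'
#' Expects columns \code{id} and \code{sequence}; an optional \code{label}
#' column must be binary (0/1).
#'
#' @param path Path to a CSV file.
#' @return data.frame of peptide records.
#' @export
read_csv_dataset <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!"sequence" %in% names(df)) stop("missing required column 'sequence'")
  if (!"id" %in% names(df)) stop("missing required column 'id'")
  label <- NULL
  if ("label" %in% names(df) && nrow(df) > 0) {
    raw <- trimws(df$label)
    bad <- !(raw %in% c("0", "1"))
    if (any(bad)) stop("non-binary label '", raw[bad][1], "' for id '",
                       df$id[bad][1], "'")
    label <- as.integer(raw)
  }
  peptide_records(df$id, toupper(df$sequence), label)
}

#' Write a peptide dataset to CSV
#'
#' @param records Peptide data.frame.
#' @param path Output path.
#' @export
write_csv_dataset <- function(records, path) {
  out <- records[, c("id", "sequence", "label")]
  if (all(is.na(out$label))) out$label <- NULL
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' One-hot encode a peptide
#'
#' Encodes a peptide as a padded binary matrix with one row per position and
#' one column per alphabet symbol (21 columns).  Rows beyond the peptide's
#' true length carry the pad symbol's indicator, so each row sums to exactly
#' one (right padding: the sequence stays left-aligned, keeping N-terminal
#' positions in shared coordinates across peptides).
#'
#' @param sequence A validated peptide string (see [validate_peptide()]).
#' @param alphabet An [aa_alphabet()]; default alphabetical + pad last.
#' @param pad_to Padded length, default 50.
#' @return An \code{encoded_peptide}: list with \code{matrix} (pad_to x 21),
#'   \code{id} and \code{length}.
#' @examples
#' enc <- one_hot_encode("FLPK", id = "p1")
#' rowSums(enc$matrix)  # all 1
#' @export
one_hot_encode <- function(sequence, alphabet = aa_alphabet(), pad_to = 50L,
                           id = NA_character_) {
  sequence <- validate_peptide(sequence)
  n <- nchar(sequence)
  if (pad_to < n) stop("pad_to (", pad_to, ") shorter than sequence (", n, ")")
  chars <- c(strsplit(sequence, "")[[1]], rep(alphabet$pad, pad_to - n))
  idx <- alphabet$index[chars]
  if (anyNA(idx)) stop("symbol absent from alphabet: ",
                       chars[is.na(idx)][1])
  m <- matrix(0, nrow = pad_to, ncol = 21L,
              dimnames = list(NULL, alphabet$symbols))
  m[cbind(seq_len(pad_to), idx)] <- 1
  structure(list(matrix = m, id = id, length = n), class = "encoded_peptide")
}

#' Decode a one-hot matrix back to its (padded) sequence
#'
#' @param matrix A one-hot matrix with 21 columns.
#' @param alphabet The alphabet used for encoding.
#' @return The padded sequence string (pad symbols included).
#' @export
decode_one_hot <- function(matrix, alphabet = aa_alphabet()) {
  if (ncol(matrix) != 21L) stop("expected 21 columns, got ", ncol(matrix))
  paste(alphabet$symbols[max.col(matrix, ties.method = "first")],
        collapse = "")
}

# Encode a whole dataset into a (n, pad_to, 21) array for batched training.
encode_dataset <- function(records, alphabet = aa_alphabet(), pad_to = 50L) {
  n <- nrow(records)
  x <- array(0, dim = c(n, pad_to, 21L))
  for (i in seq_len(n))
    x[i, , ] <- one_hot_encode(records$sequence[i], alphabet, pad_to)$matrix
  x
}
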