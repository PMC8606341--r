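#' Construct a labeled sequence
#'
#' A `labeled_sequence` pairs a residue sequence with an optional per-residue
#' label sequence (one label character per residue), the representation used
#' for supervised CHMM/HNN training.
#'
#' @param id record identifier.
#' @param residues a single string or a character vector of residue
#'   characters.
#' @param labels optional single string or character vector of label
#'   characters, same length as `residues`.
#' @param alphabet ordered residue alphabet.
#' @return An object of class `labeled_sequence` with elements `id`, `chars`,
#'   `idx` (alphabet indices, `NA` for unknown residues), `labels` (or
#'   `NULL`), and attribute `alphabet`.
#' @export
#' @examples
#' labeled_sequence("p1", "ACDE", "MMii", alphabet = aa_alphabet())
labeled_sequence <- function(id, residues, labels = NULL,
                             alphabet = aa_alphabet()) {
  chars <- if (length(residues) == 1L && nchar(residues[1]) > 1L) {
    strsplit(residues, "")[[1]]
  } else as.character(residues)
  if (length(chars) == 0L) {
    stop("sequence '", id, "' has zero length")
  }
  if (!is.null(labels)) {
    labels <- if (length(labels) == 1L && nchar(labels[1]) > 1L) {
      strsplit(labels, "")[[1]]
    } else as.character(labels)
    if (length(labels) != length(chars)) {
      stop("sequence '", id, "': residue length ", length(chars),
           " != label length ", length(labels))
    }
  }
  structure(
    list(id = id, chars = chars,
         idx = match_residues(chars, alphabet), labels = labels),
    alphabet = alphabet, class = "labeled_sequence")
}

#' @export
length.labeled_sequence <- function(x) length(x$chars)

#' @export
print.labeled_sequence <- function(x, ...) {
  cat("<labeled_sequence> ", x$id, " (L = ", length(x),
      if (is.null(x$labels)) ", unlabeled" else ", labeled", ")\n", sep = "")
  cat("  ", paste(utils::head(x$chars, 60), collapse = ""), "\n", sep = "")
  if (!is.null(x$labels))
    cat("  ", paste(utils::head(x$labels, 60), collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file.
#' @param alphabet residue alphabet; characters outside it become unknown
#'   (`NA` index, zero context block).
#' @return List of unlabeled [labeled_sequence()] objects.
#' @export
read_fasta <- function(path, alphabet = aa_alphabet()) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in '", path, "'")
  ids <- sub("\\s.*$", "", names(set))
  out <- vector("list", length(set))
  for (j in seq_along(set)) {
    s <- as.character(set[[j]])
    if (nchar(s) == 0L) stop("FASTA record '", ids[j], "' has zero length")
    out[[j]] <- labeled_sequence(ids[j], s, alphabet = alphabet)
  }
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs list of [labeled_sequence()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::BStringSet(
    vapply(seqs, function(s) paste(s$chars, collapse = ""), ""))
  names(set) <- vapply(seqs, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read labeled sequences from a 3-line label file
#'
#' The label format is: a header line (`>id`), one or more sequence lines,
#' then label lines of the same total length. When a record is wrapped over
#' several lines, the concatenation of all post-header lines must split into
#' two equal halves at a line boundary: the first half is the residue
#' sequence, the second the labels.
#'
#' @param path label file.
#' @param label_set optional character vector of admissible labels; any other
#'   label is an error.
#' @param alphabet residue alphabet.
#' @return List of labeled [labeled_sequence()] objects.
#' @export
read_labels <- function(path, label_set = NULL, alphabet = aa_alphabet()) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no records in '", path, "'")
  starts <- grep("^>", lines)
  if (length(starts) == 0L || starts[1] != 1L)
    stop("'", path, "' is not a header-led label file")
  ends <- c(starts[-1] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (j in seq_along(starts)) {
    id <- sub("\\s.*$", "", sub("^>", "", lines[starts[j]]))
    if (ends[j] < starts[j] + 1L)
      stop("record '", lines[starts[j]], "' has no sequence/label lines")
    body <- lines[(starts[j] + 1L):ends[j]]
    lens <- nchar(body)
    total <- sum(lens)
    if (total %% 2L != 0L)
      stop("record '", id, "': sequence length ", ceiling(total / 2),
           " != label length ", floor(total / 2))
    cum <- cumsum(lens)
    split_at <- which(cum == total / 2L)
    if (length(split_at) == 0L)
      stop("record '", id, "': cannot split sequence and label halves ",
           "at a line boundary (lengths ", paste(lens, collapse = ","), ")")
    k <- split_at[1]
    seq_str <- paste(body[seq_len(k)], collapse = "")
    lab_str <- paste(body[(k + 1L):length(body)], collapse = "")
    if (!is.null(label_set)) {
      labs <- strsplit(lab_str, "")[[1]]
      bad <- setdiff(unique(labs), label_set)
      if (length(bad) > 0L)
        stop("record '", id, "': unknown label(s) ",
             paste(bad, collapse = ", "))
    }
    out[[j]] <- labeled_sequence(id, seq_str, lab_str, alphabet = alphabet)
  }
  out
}

#' Write labeled sequences in the 3-line label format
#'
#' @param seqs list of labeled [labeled_sequence()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_labels <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seqs) {
    if (is.null(s$labels)) stop("sequence '", s$id, "' has no labels")
    writeLines(c(paste0(">", s$id),
                 paste(s$chars, collapse = ""),
                 paste(s$labels, collapse = "")), con)
  }
  invisible(path)
}

#' Window specification for context encoding
#'
#' @param left residues of context to the left of the focal position.
#' @param right residues to the right (default `left`, a symmetric window).
#' @return A `window_spec` with fields `left`, `right`, `K = left + right + 1`.
#' @export
#' @examples
#' window_spec(3)  # the symmetric K = 7 window
window_spec <- function(left, right = left) {
  stopifnot(left >= 0, right >= 0)
  structure(list(left = as.integer(left), right = as.integer(right),
                 K = as.integer(left + right + 1L)),
            class = "window_spec")
}

#' Encode the context window around one position
#'
#' Builds the network input vector `s_i` for position `i`: `K` blocks of
#' `|alphabet|` values, block `j` describing position `i - left + j`. In
#' one-hot mode an in-bounds block holds a single 1 at the residue index
#' (all-zero for unknown residues); out-of-bounds blocks are zero-padded.
#' In profile mode each in-bounds block is the profile row of that position.
#'
#' @param seq a [labeled_sequence()].
#' @param i 1-based focal position.
#' @param spec a [window_spec()].
#' @param profile optional profile matrix (see [read_profile()]); when given,
#'   profile encoding is used.
#' @return Numeric vector of length `|alphabet| * K`.
#' @export
encode_window <- function(seq, i, spec, profile = NULL) {
  L <- length(seq)
  stopifnot(i >= 1, i <= L)
  encode_windows(seq, spec, profile)[i, ]
}

#' Encode context windows for every position of a sequence
#'
#' Vectorized form of [encode_window()]: row `i` is the context vector of
#' position `i`.
#'
#' @inheritParams encode_window
#' @return `L x (|alphabet| * K)` numeric matrix.
#' @export
encode_windows <- function(seq, spec, profile = NULL) {
  alphabet <- attr(seq, "alphabet")
  A <- length(alphabet)
  L <- length(seq)
  if (!is.null(profile)) {
    pm <- profile_matrix(profile)
    if (nrow(pm) != L)
      stop("profile for '", seq$id, "' has ", nrow(pm),
           " rows but sequence length is ", L)
  }
  M <- matrix(0, nrow = L, ncol = A * spec$K)
  offs <- seq.int(-spec$left, spec$right)
  for (j in seq_along(offs)) {
    src <- seq_len(L) + offs[j]
    ok <- src >= 1L & src <= L
    block0 <- (j - 1L) * A
    if (is.null(profile)) {
      res <- seq$idx[src[ok]]
      known <- !is.na(res)
      rows <- which(ok)[known]
      if (length(rows) > 0L)
        M[cbind(rows, block0 + res[known])] <- 1
    } else {
      M[ok, block0 + seq_len(A)] <- pm[src[ok], , drop = FALSE]
    }
  }
  M
}

#' Read a per-position profile (PSSM-style) table
#'
#' The file is a TSV whose header row is the alphabet (in the documented
#' order, see [aa_alphabet()]) and whose data rows, one per residue, hold
#' per-position values. In `frequency` mode rows must be nonnegative and are
#' renormalized when their sum is within `1e-3` of 1.
#'
#' @param path profile TSV file.
#' @param mode `"frequency"` or `"score"`.
#' @param alphabet expected alphabet order.
#' @return A `profile` object: list with `matrix` (L x \\|alphabet\\|) and
#'   `mode`.
#' @export
read_profile <- function(path, mode = c("frequency", "score"),
                         alphabet = aa_alphabet()) {
  mode <- match.arg(mode)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE)
  if (ncol(df) != length(alphabet))
    stop("profile '", path, "' has ", ncol(df), " columns; expected ",
         length(alphabet))
  if (!identical(colnames(df), alphabet))
    stop("profile '", path, "' header does not match the alphabet order")
  m <- as.matrix(df)
  if (mode == "frequency") {
    if (any(m < 0)) stop("negative frequency in profile '", path, "'")
    rs <- rowSums(m)
    if (any(abs(rs - 1) > 1e-3))
      stop("profile '", path, "': row(s) ",
           paste(which(abs(rs - 1) > 1e-3), collapse = ", "),
           " do not sum to 1 within 1e-3")
    m <- m / rs
  }
  structure(list(matrix = unname(m), mode = mode), class = "profile")
}

#' Write a profile table
#'
#' @param profile a `profile` object or plain matrix.
#' @param path output TSV.
#' @param alphabet alphabet order for the header.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, alphabet = aa_alphabet()) {
  m <- profile_matrix(profile)
  colnames(m) <- alphabet
  utils::write.table(format(m, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

profile_matrix <- function(profile) {
  if (inherits(profile, "profile")) profile$matrix else as.matrix(profile)
}
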