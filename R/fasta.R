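# FASTA input/output.  Parsing is delegated to Biostrings; this layer
# adds the validation the predictor needs: upper-casing with a notice,
# positioned unknown-letter errors, and duplicate-id detection.

#' Read amino-acid sequences from FASTA
#'
#' @param path FASTA file, wrapped or unwrapped, multi-record.
#' @return List of records \code{list(id =, seq =)}.  Lower-case letters
#'   are upper-cased with a notice on the message stream; letters outside
#'   the 20-residue alphabet raise an error naming record and position;
#'   duplicate ids and empty files are errors.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, "", 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  seqs <- unname(as.character(set))
  out <- vector("list", length(seqs))
  for (k in seq_along(seqs)) {
    s <- seqs[k]
    if (grepl("[a-z]", s)) {
      message("read_fasta: upper-casing lower-case letters in record '",
              ids[k], "'")
      s <- toupper(s)
    }
    letters <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- which(!letters %in% amino_acids())
    if (length(bad)) {
      stop(sprintf("record '%s': illegal character '%s' at position %d",
                   ids[k], letters[bad[1]], bad[1]), call. = FALSE)
    }
    out[[k]] <- list(id = ids[k], seq = s)
  }
  out
}

#' Write sequence records to FASTA
#'
#' @param records List of \code{list(id =, seq =)} records (as returned
#'   by \code{\link{read_fasta}}).
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.list(records), length(records) >= 1L)
  seqs <- vapply(records, function(r) r$seq, "")
  ids <- vapply(records, function(r) r$id, "")
  set <- Biostrings::BStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
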