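# Sequence-level beta-layer candidate discovery: the core consensus
# [aliphatic]-A-T-K-[polar]-[DE] of the nonad-repeat family and the
# 15-residue tandem consensus Lxx-KAD-Kxx-VYT-KxE, scanned over raw
# sequences or FASTA files.

# residue classes used by the consensus patterns; the family alignments
# admit M in the aliphatic slot and D in the polar one
MOTIF_CLASSES <- list(
  aliphatic = c("A", "V", "L", "I", "M"),
  polar = c("S", "T", "N", "Q", "D", "E", "K", "R", "H", "Y")
)

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.check_sequence <- function(sequence) {
  s <- toupper(sequence)
  chars <- strsplit(s, "")[[1]]
  bad <- which(!(chars %in% AA_ALPHABET))
  if (length(bad)) {
    stop(sprintf("non-amino-acid character '%s' at position %d",
                 chars[bad[1]], bad[1]))
  }
  s
}

# scan with a perl regex, reporting all (overlapping) matches 1-based
.scan_pattern <- function(sequence, regex, len, pattern_name,
                          sequence_id = NA_character_) {
  s <- .check_sequence(sequence)
  empty <- data.frame(sequence_id = character(0), start = integer(0),
                      end = integer(0), match = character(0),
                      pattern = character(0), stringsAsFactors = FALSE)
  if (!nzchar(s)) return(empty)
  hits <- gregexpr(paste0("(?=", regex, ")"), s, perl = TRUE)[[1]]
  starts <- as.integer(hits[hits > 0])
  if (!length(starts)) return(empty)
  data.frame(sequence_id = rep(sequence_id, length(starts)),
             start = starts, end = starts + len - 1L,
             match = substring(s, starts, starts + len - 1L),
             pattern = rep(pattern_name, length(starts)),
             stringsAsFactors = FALSE)
}

#' Scan a sequence for the core beta-layer consensus
#'
#' Reports every position matching [aliphatic]-A-T-K-[polar]-[DE]
#' (the consensus of the nonad-repeat coiled-coil family, e.g. MATKDD);
#' overlapping matches are all reported, 1-based inclusive coordinates.
#'
#' @param sequence Amino-acid sequence (one-letter codes; case
#'   insensitive).
#' @param sequence_id Optional identifier recorded in the output.
#' @return Data frame: `sequence_id`, `start`, `end`, `match`, `pattern`.
#' @export
#' @examples
#' scan_consensus("ITLMQANMATKDDLAR")
scan_consensus <- function(sequence, sequence_id = NA_character_) {
  regex <- sprintf("[%s]ATK[%s][DE]",
                   paste(MOTIF_CLASSES$aliphatic, collapse = ""),
                   paste(MOTIF_CLASSES$polar, collapse = ""))
  .scan_pattern(sequence, regex, 6L, "core_consensus", sequence_id)
}

#' Scan a sequence for the tandem beta-layer consensus
#'
#' Matches the 15-residue pattern L-x-x-K-A-D-K-x-x-V-Y-T-K-x-E of
#' hexad-spaced beta-layer tandems (e.g. LQQKADKETVYTKAE).
#'
#' @inheritParams scan_consensus
#' @return Data frame as in [scan_consensus].
#' @export
scan_tandem <- function(sequence, sequence_id = NA_character_) {
  .scan_pattern(sequence, "L..KADK..VYTK.E", 15L, "tandem", sequence_id)
}

#' Scan a FASTA file for beta-layer consensus motifs
#'
#' @param path Path to a FASTA file of protein sequences.
#' @param pattern `"core_consensus"` or `"tandem"`.
#' @return Data frame of matches across records, in file order.
#' @export
scan_fasta <- function(path, pattern = c("core_consensus", "tandem")) {
  pattern <- match.arg(pattern)
  seqs <- read_fasta(path)
  scanner <- if (pattern == "core_consensus") scan_consensus else scan_tandem
  out <- do.call(rbind, lapply(seq_along(seqs), function(i) {
    tryCatch(scanner(seqs[[i]], sequence_id = names(seqs)[i]),
             error = function(e) {
               stop(sprintf("record %d (%s): %s", i, names(seqs)[i],
                            conditionMessage(e)))
             })
  }))
  rownames(out) <- NULL
  out
}

# minimal FASTA reading via Biostrings when available, plain parse
# otherwise (files here are small protein FASTA)
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readAAStringSet(path)
    out <- as.list(as.character(ss))
    names(out) <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1)
    return(out)
  }
  lines <- readLines(path)
  heads <- grep("^>", lines)
  if (!length(heads)) stop("not a FASTA file: no '>' headers")
  out <- list()
  for (i in seq_along(heads)) {
    from <- heads[i] + 1
    to <- if (i < length(heads)) heads[i + 1] - 1 else length(lines)
    id <- sub("^>\\s*(\\S+).*", "\\1", lines[heads[i]])
    out[[id]] <- paste(lines[from:to], collapse = "")
  }
  out
}
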