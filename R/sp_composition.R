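#' Parse signal-peptide FASTA
#'
#' Reads amino-acid sequences from a FASTA file or an in-memory FASTA string.
#' Headers follow the `>name|family|chain` dialect; `family` defaults to
#' `"unknown"` and `chain` to `"other"` when absent. Sequences are upper-cased
#' and validated against the 20-letter alphabet; any other letter (including
#' B, U, O, X) aborts the parse naming the record and the character.
#'
#' @param input Path to a FASTA file, or a character scalar holding FASTA
#'   text (detected by a leading `>` or embedded newline).
#' @return A `data.frame` with columns `name`, `family`, `chain`, `sequence`,
#'   one row per record in file order; zero rows for empty input.
#' @export
#' @examples
#' parse_sp_fasta(">IgE|IgE|heavy\nMDWTWILFLVAAATRVHS")
parse_sp_fasta <- function(input) {
  stopifnot(is.character(input), length(input) == 1)
  empty <- data.frame(name = character(), family = character(),
                      chain = character(), sequence = character(),
                      stringsAsFactors = FALSE)
  if (!nzchar(trimws(input))) return(empty)
  path <- input
  if (grepl("[>\n]", input)) {
    path <- tempfile(fileext = ".fasta")
    on.exit(unlink(path), add = TRUE)
    writeLines(input, path)
  } else if (!file.exists(input)) {
    stop("input is neither FASTA text nor an existing file: ", input)
  }
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0) return(empty)
  headers <- names(set)
  parts <- strsplit(headers, "|", fixed = TRUE)
  name <- vapply(parts, `[`, character(1), 1)
  family <- vapply(parts, function(p) if (length(p) >= 2) p[[2]] else "unknown",
                   character(1))
  chain <- vapply(parts, function(p) if (length(p) >= 3) p[[3]] else "other",
                  character(1))
  sequence <- validate_sequences(as.character(set), names = name)
  if (any(!nzchar(sequence))) {
    stop("record '", name[!nzchar(sequence)][1], "' has an empty sequence")
  }
  data.frame(name = trimws(name), family = trimws(family),
             chain = trimws(chain), sequence = unname(sequence),
             stringsAsFactors = FALSE)
}

#' Amino-acid composition of a sequence
#'
#' Counts each of the 20 amino acids in `seq`. The profile always covers the
#' full alphabet (zero counts included) so profiles of different sequences
#' align column-wise.
#'
#' @param seq Amino-acid string over the 20-letter alphabet (case
#'   insensitive); the empty string yields an all-zero profile.
#' @return Named integer vector of length 20 (alphabetical order) with
#'   attribute `length` equal to `nchar(seq)`.
#' @export
#' @examples
#' composition("MDWTWILFLVAAATRVHS")
composition <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- validate_sequences(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  counts <- table(factor(chars, levels = aa_alphabet()))
  out <- as.integer(counts)
  names(out) <- aa_alphabet()
  attr(out, "length") <- nchar(seq)
  out
}

#' Essential amino-acid profile of a sequence
#'
#' Summarises the essential amino-acid (EAA) content of a sequence the way
#' signal-peptide repertoires are compared: `variety` is the number of
#' distinct EAA types present (0-9) and `total_eaa` the number of EAA
#' residues.
#'
#' @param seq Amino-acid string.
#' @param table An [aa_table()].
#' @return List with elements `variety`, `total_eaa`, `length`.
#' @export
#' @examples
#' eaa_profile("MDWTWILFLVAAATRVHS")  # the IgE signal peptide: 8 types, 12 residues
eaa_profile <- function(seq, table = aa_table()) {
  counts <- composition(seq)
  ess <- counts[table$essential]
  list(
    variety   = sum(ess > 0),
    total_eaa = as.integer(sum(ess)),
    length    = attr(counts, "length")
  )
}

#' Position-wise consensus of aligned sequences
#'
#' Returns the most frequent residue at each position of a set of
#' equal-length sequences (signal-peptide families have a fixed length, so
#' no alignment is performed). Ties are broken towards the alphabetically
#' first tied residue, and each tie event is reported via `message()`.
#'
#' @param seqs Character vector of one or more equal-length sequences.
#' @return The consensus sequence as a single string.
#' @export
#' @examples
#' consensus(c("MAV", "MAV", "MTV"))
consensus <- function(seqs) {
  if (length(seqs) == 0) stop("consensus requires at least one sequence")
  seqs <- validate_sequences(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1) {
    stop("sequences must be pre-aligned to equal length; got lengths ",
         paste(sort(unique(lens)), collapse = ", "))
  }
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  cons <- vapply(seq_len(ncol(mat)), function(j) {
    tab <- table(mat[, j])
    winners <- sort(names(tab)[tab == max(tab)])
    if (length(winners) > 1) {
      message(sprintf("consensus tie at position %d among {%s}; taking '%s'",
                      j, paste(winners, collapse = ","), winners[[1]]))
    }
    winners[[1]]
  }, character(1))
  paste(cons, collapse = "")
}

#' Average amino-acid composition of a sequence set
#'
#' Arithmetic mean of the per-sequence composition profiles — the
#' "representative average" usage over a set of antibody chains. Values are
#' real; use `rounded = TRUE` for a half-up integer view suitable as a
#' demand profile.
#'
#' @param seqs Character vector of one or more sequences (lengths may
#'   differ).
#' @param rounded Return half-up rounded integer counts instead of reals.
#' @return Named numeric (or integer) vector of length 20 with attribute
#'   `length` holding the mean sequence length.
#' @export
#' @examples
#' average_composition(c("MM", "MA"))
average_composition <- function(seqs, rounded = FALSE) {
  if (length(seqs) == 0) stop("average_composition requires at least one sequence")
  profiles <- vapply(seqs, function(s) as.numeric(composition(s)),
                     numeric(20))
  out <- rowMeans(matrix(profiles, nrow = 20))
  names(out) <- aa_alphabet()
  if (rounded) out <- as.integer(round_half_up(out))
  names(out) <- aa_alphabet()
  attr(out, "length") <- mean(nchar(validate_sequences(seqs)))
  out
}

#' Tabulate EAA profiles for a set of signal peptides
#'
#' Builds the family / sequence / length / variety / total-EAA report used
#' to compare signal-peptide repertoires across V-gene families.
#'
#' @param sps Data frame as returned by [parse_sp_fasta()] or [sp_fixture()].
#' @param table An [aa_table()].
#' @return Data frame with columns `family`, `sequence`, `length`,
#'   `variety`, `total_eaa`.
#' @export
sp_profile_table <- function(sps, table = aa_table()) {
  stopifnot(is.data.frame(sps), all(c("family", "sequence") %in% names(sps)))
  profs <- lapply(sps$sequence, eaa_profile, table = table)
  data.frame(
    family    = sps$family,
    sequence  = sps$sequence,
    length    = vapply(profs, `[[`, numeric(1), "length"),
    variety   = vapply(profs, `[[`, numeric(1), "variety"),
    total_eaa = vapply(profs, `[[`, numeric(1), "total_eaa"),
    stringsAsFactors = FALSE
  )
}
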