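##
## Sequence comparison utility: percent identity and similarity between two
## amino-acid sequences, either by global (Needleman-Wunsch) alignment or
## position-wise on equal-length inputs.
##

.aa_letters <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Percent identity and similarity of two protein sequences
#'
#' In \code{global_alignment} mode the sequences are aligned with
#' Needleman-Wunsch (BLOSUM62, gap opening 10, gap extension 0.5) and
#' identity is the fraction of alignment columns with identical residues,
#' similarity the fraction of columns whose substitution score is positive
#' (gap columns count in the denominator).  Both are rounded to integer
#' percent.  \code{ungapped} mode compares equal-length sequences position by
#' position with the same similarity rule.
#'
#' @param seq_a,seq_b one-letter amino-acid strings.
#' @param mode \code{"global_alignment"} (default) or \code{"ungapped"}.
#' @return named numeric vector \code{c(identity = , similarity = )} in
#'   percent.
#' @examples
#' sequence_identity_similarity("ACDE", "ACDE")
#' sequence_identity_similarity("ACDE", "ACDF", mode = "ungapped")
#' @export
sequence_identity_similarity <- function(seq_a, seq_b,
                                         mode = c("global_alignment",
                                                  "ungapped")) {
  mode <- match.arg(mode)
  seq_a <- toupper(gsub("\\s", "", seq_a))
  seq_b <- toupper(gsub("\\s", "", seq_b))
  for (s in list(seq_a, seq_b)) {
    bad <- setdiff(strsplit(s, "")[[1]], .aa_letters)
    if (length(bad)) {
      stop_pd("sequence_identity_similarity(): non-amino-acid character '%s'",
              bad[1])
    }
  }
  blosum <- get_blosum62()
  if (mode == "ungapped") {
    if (nchar(seq_a) != nchar(seq_b)) {
      stop_pd("ungapped mode needs equal-length sequences (%d vs %d)",
              nchar(seq_a), nchar(seq_b))
    }
    a <- strsplit(seq_a, "")[[1]]
    b <- strsplit(seq_b, "")[[1]]
  } else {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
      type = "global", substitutionMatrix = blosum,
      gapOpening = 10, gapExtension = 0.5
    )
    a <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    b <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  }
  cols <- length(a)
  aligned <- a != "-" & b != "-"
  ident <- sum(aligned & a == b)
  score <- numeric(cols)
  score[aligned] <- blosum[cbind(a[aligned], b[aligned])]
  simil <- sum(aligned & score > 0)
  c(identity = round(100 * ident / cols),
    similarity = round(100 * simil / cols))
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}
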