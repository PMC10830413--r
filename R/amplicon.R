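# CRISPR amplicon edit classification. Reads are classified as PBM_KO when
# their indels frameshift the coding sequence upstream of the PDZ-binding
# motif (PBM, the last three codons before the stop) or directly disrupt the
# PBM/stop region; otherwise intact. Two independent routes exist: the
# nucleotide-level rule (classify_read) and a protein-level oracle
# (protein_ko_oracle) that reconstructs the edited protein and inspects its
# terminal three residues.

#' Define an amplicon reference
#'
#' @param sequence nucleotide string of the reference amplicon.
#' @param cds_start 0-based position of the first coding base.
#' @param pbm_start,pbm_end 0-based half-open interval of the PBM (the last
#'   three codons of the coding sequence); \code{pbm_end - pbm_start} must be
#'   a multiple of 3 and in frame with \code{cds_start}. The stop codon
#'   occupies the three bases following \code{pbm_end}.
#' @param edit_site 0-based position of the expected Cas9 cut site (metadata
#'   used by the read generator; classification does not depend on it).
#' @return object of class \code{amplicon_reference}.
#' @export
amplicon_reference <- function(sequence, cds_start, pbm_start, pbm_end,
                               edit_site = pbm_start) {
  sequence <- toupper(sequence)
  stopifnot((pbm_end - pbm_start) %% 3 == 0,
            (pbm_start - cds_start) %% 3 == 0,
            pbm_end + 3 <= nchar(sequence),
            edit_site >= 0, edit_site <= nchar(sequence))
  structure(list(sequence = sequence, cds_start = cds_start,
                 pbm_start = pbm_start, pbm_end = pbm_end,
                 stop_end = pbm_end + 3L, edit_site = edit_site),
            class = "amplicon_reference")
}

#' Classify an amplicon read from its edit calls
#'
#' Nucleotide-level rule: a read is \code{PBM_KO} when (a) its indels cause a
#' net frameshift (net inserted-minus-deleted coding bases not a multiple of
#' 3) upstream of the PBM, (b) any indel overlaps the PBM or stop codon (an
#' insertion strictly between the PBM start and the stop end also removes the
#' motif from the C terminus), or (c) any substitution falls within the PBM
#' interval. Compensating indels that restore the frame before an untouched
#' PBM leave the read \code{intact}.
#'
#' @param call a read edit call: list with \code{indels} (data.frame
#'   \code{position}, \code{length}, \code{type} in \code{c("ins","del")})
#'   and optional \code{substitutions} (data.frame \code{position},
#'   \code{base}). Deletion positions are the first deleted base; insertion
#'   positions are the base before which the insertion occurs. All positions
#'   are 0-based reference coordinates.
#' @param ref an \code{\link{amplicon_reference}}.
#' @return \code{"PBM_KO"} or \code{"intact"}.
#' @export
classify_read <- function(call, ref) {
  ind <- call$indels
  sub <- call$substitutions
  if (!is.null(sub) && nrow(sub) > 0L &&
      any(sub$position >= ref$pbm_start & sub$position < ref$pbm_end))
    return("PBM_KO")
  if (is.null(ind) || nrow(ind) == 0L) return("intact")
  stopifnot(all(ind$position >= 0),
            all(ind$position <= nchar(ref$sequence)))
  net <- 0L
  for (i in seq_len(nrow(ind))) {
    p <- ind$position[i]; l <- ind$length[i]; ty <- ind$type[i]
    if (ty == "del") {
      if (p < ref$stop_end && p + l > ref$pbm_start) return("PBM_KO")
      ov <- min(p + l, ref$pbm_start) - max(p, ref$cds_start)
      if (ov > 0) net <- net - ov
    } else {
      if (p > ref$pbm_start && p < ref$stop_end) return("PBM_KO")
      if (p > ref$cds_start && p <= ref$pbm_start) net <- net + l
    }
  }
  if (net %% 3L != 0L) "PBM_KO" else "intact"
}

#' Protein-level edit oracle
#'
#' Independent brute-force evaluation: applies the read's edits to the
#' reference sequence, translates from the (mapped) coding start to the
#' first stop codon, and declares the read intact only if a stop is reached
#' and the three residues preceding it equal the reference PBM tripeptide.
#'
#' @inheritParams classify_read
#' @return \code{"PBM_KO"} or \code{"intact"}.
#' @export
protein_ko_oracle <- function(call, ref) {
  ed <- .apply_edits(call, ref)
  chars <- ed$chars; orig <- ed$orig
  start <- which(!is.na(orig) & orig >= ref$cds_start)[1L]
  if (is.na(start)) return("PBM_KO")
  aa <- .translate_to_stop(chars[start:length(chars)])
  if (!aa$stopped || length(aa$residues) < 3L) return("PBM_KO")
  ref_pbm <- .translate_to_stop(strsplit(substr(
    ref$sequence, ref$pbm_start + 1L, ref$pbm_end), "")[[1L]])$residues
  if (identical(tail(aa$residues, 3L), ref_pbm)) "intact" else "PBM_KO"
}

# apply a read's edit calls to the reference; returns the edited character
# vector plus, per base, its 0-based reference coordinate (NA for inserted)
.apply_edits <- function(call, ref) {
  chars <- strsplit(ref$sequence, "")[[1L]]
  orig <- seq_along(chars) - 1L
  ind <- call$indels
  if (!is.null(ind) && nrow(ind) > 0L) {
    # apply right-to-left so earlier positions stay valid
    ind <- ind[order(-ind$position), , drop = FALSE]
    for (i in seq_len(nrow(ind))) {
      p <- ind$position[i]; l <- ind$length[i]
      if (ind$type[i] == "del") {
        drop <- which(orig >= p & orig < p + l & !is.na(orig))
        if (length(drop)) { chars <- chars[-drop]; orig <- orig[-drop] }
      } else {
        bases <- if (!is.null(ind$bases) && nzchar(ind$bases[i]))
          strsplit(ind$bases[i], "")[[1L]] else rep("C", l)
        at <- which(orig >= p)[1L]
        if (is.na(at)) at <- length(chars) + 1L
        chars <- append(chars, bases, after = at - 1L)
        orig <- append(orig, rep(NA_integer_, length(bases)),
                       after = at - 1L)
      }
    }
  }
  sub <- call$substitutions
  if (!is.null(sub) && nrow(sub) > 0L) {
    for (i in seq_len(nrow(sub))) {
      at <- which(!is.na(orig) & orig == sub$position[i])
      if (length(at)) chars[at] <- sub$base[i]
    }
  }
  list(chars = chars, orig = orig)
}

.edited_sequence <- function(call, ref) {
  paste(.apply_edits(call, ref)$chars, collapse = "")
}

.codon_table <- function() {
  # standard genetic code, codons enumerated TCAG-major (first base slowest)
  b <- c("T", "C", "A", "G")
  aa <- c("F","F","L","L","S","S","S","S","Y","Y","*","*","C","C","*","W",
          "L","L","L","L","P","P","P","P","H","H","Q","Q","R","R","R","R",
          "I","I","I","M","T","T","T","T","N","N","K","K","S","S","R","R",
          "V","V","V","V","A","A","A","A","D","D","E","E","G","G","G","G")
  codons <- character(64); k <- 0L
  for (b1 in b) for (b2 in b) for (b3 in b) {
    k <- k + 1L; codons[k] <- paste0(b1, b2, b3)
  }
  stats::setNames(aa, codons)
}

.translate_to_stop <- function(chars) {
  tab <- .codon_table()
  res <- character(0)
  i <- 1L
  while (i + 2L <= length(chars)) {
    codon <- paste0(chars[i], chars[i + 1L], chars[i + 2L])
    aa <- tab[[codon]]
    if (is.null(aa) || is.na(aa)) aa <- "X"
    if (aa == "*") return(list(residues = res, stopped = TRUE))
    res <- c(res, aa)
    i <- i + 3L
  }
  list(residues = res, stopped = FALSE)
}

#' Fraction of PBM-disrupted reads
#'
#' @param classifications character vector of \code{"PBM_KO"} /
#'   \code{"intact"} calls (non-empty).
#' @return fraction in [0, 1].
#' @export
pbm_ko_fraction <- function(classifications) {
  if (length(classifications) == 0L) stop("no classified reads")
  mean(classifications == "PBM_KO")
}

#' Call edits in a read by global alignment to the amplicon
#'
#' Aligns the read to the reference with a global affine-gap aligner
#' (match 2, mismatch -3, gap open 5, gap extend 1; fixed, documented
#' constants) and converts the alignment into indel and substitution calls
#' in reference coordinates.
#'
#' @param read_seq nucleotide string of the read.
#' @param ref an \code{\link{amplicon_reference}}.
#' @return a read edit call (list with \code{indels}, \code{substitutions})
#'   suitable for \code{\link{classify_read}}.
#' @export
align_amplicon_read <- function(read_seq, ref) {
  pa <- Biostrings::pairwiseAlignment(
    pattern = toupper(read_seq), subject = ref$sequence, type = "global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 2, mismatch = -3, baseOnly = TRUE),
    gapOpening = 5, gapExtension = 1)
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1L]]
  refpos <- 0L
  indels <- list(); subs <- list()
  i <- 1L
  while (i <= length(p)) {
    if (s[i] == "-") {                 # insertion relative to reference
      l <- 0L; bases <- character(0)
      while (i <= length(p) && s[i] == "-") {
        l <- l + 1L; bases <- c(bases, p[i]); i <- i + 1L
      }
      indels[[length(indels) + 1L]] <- data.frame(
        position = refpos, length = l, type = "ins",
        bases = paste(bases, collapse = ""))
    } else if (p[i] == "-") {          # deletion of reference bases
      l <- 0L; at <- refpos
      while (i <= length(p) && p[i] == "-") {
        l <- l + 1L; refpos <- refpos + 1L; i <- i + 1L
      }
      indels[[length(indels) + 1L]] <- data.frame(
        position = at, length = l, type = "del", bases = "")
    } else {
      if (p[i] != s[i])
        subs[[length(subs) + 1L]] <- data.frame(position = refpos,
                                                base = p[i])
      refpos <- refpos + 1L; i <- i + 1L
    }
  }
  list(indels = if (length(indels)) do.call(rbind, indels)
       else data.frame(position = integer(0), length = integer(0),
                       type = character(0), bases = character(0)),
       substitutions = if (length(subs)) do.call(rbind, subs)
       else data.frame(position = integer(0), base = character(0)))
}

#' Classify a set of amplicon reads
#'
#' Full path from sequences to the edited fraction: align each read, call
#' edits, classify, and summarize.
#'
#' @param read_seqs character vector of read sequences.
#' @param ref an \code{\link{amplicon_reference}}.
#' @return list with \code{calls} (per-read data.frame \code{read},
#'   \code{classification}) and \code{ko_fraction}.
#' @export
classify_amplicon_reads <- function(read_seqs, ref) {
  cls <- vapply(read_seqs, function(rs)
    classify_read(align_amplicon_read(rs, ref), ref), character(1),
    USE.NAMES = FALSE)
  list(calls = data.frame(read = seq_along(read_seqs),
                          classification = cls),
       ko_fraction = pbm_ko_fraction(cls))
}
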