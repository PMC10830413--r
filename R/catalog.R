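#' @importFrom stats median quantile sd cor rnorm runif rpois rbinom rexp
#' @importFrom utils read.delim write.table head tail combn
NULL

# Coordinates are 0-based half-open throughout the package; GTF/GFF3 input
# (1-based inclusive) is converted on read, so length == end - start.

#' Construct an exon name
#'
#' Exon names follow the convention used for the Lphn3 reference exon list:
#' non-overlapping exons get consecutive numbers in transcript (5' to 3')
#' order, and exons that overlap each other on the genome share a number and
#' are distinguished by lowercase letters (for example \code{E30b}).
#'
#' @param number positive integer exon number.
#' @param letter optional lowercase suffix (\code{""} when the exon overlaps
#'   no other exon of the same number).
#' @return character scalar like \code{"E30b"}.
#' @export
exon_name <- function(number, letter = "") {
  stopifnot(all(number >= 1))
  paste0("E", number, letter)
}

.overlap_clusters <- function(start, end) {
  # cluster intervals that share >= 1 base (transitive closure along the axis)
  ord <- order(start, end)
  cl <- integer(length(start))
  cur <- 0L
  cur_end <- -Inf
  for (i in ord) {
    if (start[i] < cur_end) {
      cl[i] <- cur
      cur_end <- max(cur_end, end[i])
    } else {
      cur <- cur + 1L
      cl[i] <- cur
      cur_end <- end[i]
    }
  }
  cl
}

#' Name exons in transcript order
#'
#' Assigns names to a set of exon intervals of one gene. Numbers ascend 5' to
#' 3' in transcript orientation (reversed genomic order on the minus strand);
#' exons sharing any genomic overlap receive the same number with letter
#' suffixes \code{a, b, ...} in 5' to 3' order of their starts.
#'
#' @param exons data.frame with 0-based half-open \code{start}, \code{end}
#'   columns, sorted 5' to 3' in transcript orientation.
#' @param strand \code{"+"} or \code{"-"}.
#' @return character vector of names, parallel to \code{exons} rows.
#' @examples
#' name_exons(data.frame(start = c(100, 300, 340), end = c(200, 350, 400)), "+")
#' @export
name_exons <- function(exons, strand = "+") {
  if (nrow(exons) == 0L) return(character(0))
  stopifnot(all(exons$start < exons$end), strand %in% c("+", "-"))
  cl <- .overlap_clusters(exons$start, exons$end)
  # transcript orientation: cluster order by genomic start, reversed on "-"
  cl_start <- tapply(exons$start, cl, min)
  cl_order <- order(as.numeric(cl_start))
  if (strand == "-") cl_order <- rev(cl_order)
  number <- match(cl, as.integer(names(cl_start))[cl_order])
  letter <- character(nrow(exons))
  for (g in unique(cl)) {
    idx <- which(cl == g)
    if (length(idx) > 1L) {
      # 5'-most start first: ascending start on "+", descending on "-"
      o <- if (strand == "+") order(exons$start[idx], exons$end[idx])
           else order(-exons$end[idx], -exons$start[idx])
      letter[idx[o]] <- letters[seq_along(idx)]
    }
  }
  exon_name(number, letter)
}

#' Select the longest UTR exon
#'
#' Among alternative annotated exons of the same untranslated end, keep only
#' the longest one; an exact length tie is broken by the smaller start
#' coordinate (deterministic rule; the choice is otherwise arbitrary).
#'
#' @param candidates data.frame of 0-based half-open intervals
#'   (\code{start}, \code{end}), all belonging to the same UTR end.
#' @return the selected row of \code{candidates}.
#' @export
select_longest_utr_exon <- function(candidates) {
  if (nrow(candidates) == 0L) stop("no UTR exon candidates")
  len <- candidates$end - candidates$start
  i <- order(-len, candidates$start)[1L]
  candidates[i, , drop = FALSE]
}

.blocks_to_iranges <- function(blocks) {
  IRanges::IRanges(start = blocks$start + 1L, end = blocks$end)
}

#' Filter exons by translation evidence
#'
#' Retains exons supported by at least \code{min_reads} reads from a
#' translating-mRNA-enriched evidence set (a read supports an exon when any
#' of its aligned blocks overlaps the exon by >= 1 base). The per-exon
#' supporting-read count is recorded in \code{evidence_reads}.
#'
#' @param exons data.frame of exon intervals (\code{start}, \code{end};
#'   0-based half-open), one gene, one chromosome.
#' @param reads read blocks as a data.frame with columns \code{read_id},
#'   \code{start}, \code{end} (one row per aligned block).
#' @param min_reads minimum distinct supporting reads (default 1).
#' @return \code{exons} subset to supported rows, with an
#'   \code{evidence_reads} column added.
#' @export
filter_by_translation_evidence <- function(exons, reads, min_reads = 1L) {
  if (nrow(exons) == 0L) {
    exons$evidence_reads <- integer(0)
    return(exons)
  }
  if (is.null(reads) || nrow(reads) == 0L) {
    exons$evidence_reads <- 0L
    return(exons[0L, , drop = FALSE])
  }
  hits <- IRanges::findOverlaps(.blocks_to_iranges(exons),
                                .blocks_to_iranges(reads))
  n <- integer(nrow(exons))
  if (length(hits) > 0L) {
    per <- tapply(reads$read_id[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits),
                  function(x) length(unique(x)))
    n[as.integer(names(per))] <- as.integer(per)
  }
  exons$evidence_reads <- n
  exons[n >= min_reads, , drop = FALSE]
}

.read_junctions <- function(reads) {
  # gaps between consecutive blocks of each read -> (donor end, acceptor start)
  if (is.null(reads) || nrow(reads) == 0L)
    return(data.frame(read_id = character(0), donor = integer(0),
                      acceptor = integer(0)))
  reads <- reads[order(reads$read_id, reads$start), , drop = FALSE]
  same <- reads$read_id[-1L] == reads$read_id[-nrow(reads)]
  data.frame(read_id  = reads$read_id[-nrow(reads)][same],
             donor    = reads$end[-nrow(reads)][same],
             acceptor = reads$start[-1L][same])
}

#' Build the reference exon catalog of a gene
#'
#' Composes the catalog construction: extract the gene's exon records,
#' apply the longest-UTR-exon rule, name exons in transcript order, keep only
#' exons with translation evidence, and classify each exon as constitutive,
#' internal cassette (some evidence read skips it via a junction joining its
#' two flanking exons), or mutually exclusive terminal (two distinct
#' evidence-supported last exons). PSI targets are derived from the
#' classification: one \code{internal} target per cassette exon and one
#' \code{terminal_pair} target when two alternative last exons exist.
#'
#' @param annotation data.frame of exon records with columns \code{gene_id},
#'   \code{transcript_id}, \code{chrom}, \code{start}, \code{end} (0-based
#'   half-open), \code{strand}, and \code{region} in
#'   \code{c("coding","utr5","utr3")}. See \code{\link{read_gene_annotation}}.
#' @param evidence_reads read-blocks data.frame (\code{read_id}, \code{start},
#'   \code{end}) from the translation-evidence dataset, or \code{NULL} to skip
#'   the evidence filter.
#' @param gene_id gene to extract.
#' @param min_reads evidence threshold passed to
#'   \code{\link{filter_by_translation_evidence}}.
#' @return an object of class \code{exon_catalog}: a list with
#'   \code{gene_id}, \code{exons} (ordered 5' to 3') and \code{psi_targets}.
#' @export
build_catalog <- function(annotation, evidence_reads, gene_id,
                          min_reads = 1L) {
  ann <- annotation[annotation$gene_id == gene_id, , drop = FALSE]
  if (nrow(ann) == 0L) stop("gene '", gene_id, "' absent from annotation")
  strand <- ann$strand[1L]
  chrom <- ann$chrom[1L]

  # distinct intervals across transcripts, remembering region labels
  key <- paste(ann$start, ann$end)
  uniq <- ann[!duplicated(key), c("chrom", "start", "end", "strand", "region")]
  # a distinct interval annotated coding in any transcript counts as coding
  reg <- tapply(ann$region, key, function(r)
    if (any(r == "coding")) "coding" else r[1L])
  uniq$region <- as.character(reg[paste(uniq$start, uniq$end)])

  # longest-UTR rule per untranslated end
  keep <- uniq$region == "coding"
  for (side in c("utr5", "utr3")) {
    cand <- uniq[uniq$region == side, , drop = FALSE]
    if (nrow(cand) > 0L) {
      sel <- select_longest_utr_exon(cand)
      keep <- keep | (uniq$start == sel$start & uniq$end == sel$end &
                        uniq$region == side)
    }
  }
  ex <- uniq[keep, , drop = FALSE]

  # transcript-orientation order and names
  ex <- ex[order(if (strand == "+") ex$start else -ex$end), , drop = FALSE]
  ex$name <- name_exons(ex, strand)

  ex <- filter_by_translation_evidence(ex, evidence_reads,
                                       min_reads = min_reads)
  rownames(ex) <- NULL

  # last exon of each transcript (3'-most in transcript orientation)
  last_key <- vapply(split(ann, ann$transcript_id), function(tr) {
    i <- if (strand == "+") which.max(tr$end) else which.min(tr$start)
    paste(tr$start[i], tr$end[i])
  }, character(1))
  is_last <- paste(ex$start, ex$end) %in% last_key

  ex$class <- "constitutive"
  targets <- list()
  terminal_idx <- which(is_last)
  if (length(terminal_idx) == 2L) {
    ex$class[terminal_idx] <- "terminal"
    a <- terminal_idx[1L]; b <- terminal_idx[2L]
    targets[[length(targets) + 1L]] <- data.frame(
      mode = "terminal_pair",
      exon = ex$name[a], partner = ex$name[b],
      exon_len = ex$end[a] - ex$start[a],
      partner_len = ex$end[b] - ex$start[b],
      flank_up = NA_character_, flank_down = NA_character_)
  }

  # cassette detection from evidence-read junctions skipping an exon
  jx <- .read_junctions(evidence_reads)
  if (nrow(ex) >= 3L) {
    for (i in seq_len(nrow(ex))) {
      if (ex$class[i] != "constitutive") next
      if (i == 1L || i == nrow(ex)) next
      up <- ex[i - 1L, ]; dn <- ex[i + 1L, ]
      skip <- if (strand == "+")
        any(jx$donor == up$end & jx$acceptor == dn$start)
      else
        any(jx$donor == dn$end & jx$acceptor == up$start)
      if (isTRUE(skip)) {
        ex$class[i] <- "cassette"
        targets[[length(targets) + 1L]] <- data.frame(
          mode = "internal", exon = ex$name[i], partner = NA_character_,
          exon_len = ex$end[i] - ex$start[i], partner_len = NA_integer_,
          flank_up = up$name, flank_down = dn$name)
      }
    }
  }

  psi_targets <- if (length(targets) > 0L) do.call(rbind, targets)
  else data.frame(mode = character(0), exon = character(0),
                  partner = character(0), exon_len = integer(0),
                  partner_len = integer(0), flank_up = character(0),
                  flank_down = character(0))
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = ex, psi_targets = psi_targets),
            class = "exon_catalog")
}

#' @export
print.exon_catalog <- function(x, ...) {
  cat("exon_catalog for", x$gene_id, "(", x$strand, "strand ):",
      nrow(x$exons), "exons,", nrow(x$psi_targets), "PSI target(s)\n")
  print(x$exons[, c("name", "start", "end", "region", "class",
                    "evidence_reads")], ...)
  invisible(x)
}

#' Read exon records of a gene from GTF/GFF3
#'
#' Imports annotation through \pkg{rtracklayer} and returns the exon records
#' of one gene in the package's 0-based half-open convention, with each exon
#' labelled \code{coding}, \code{utr5} or \code{utr3} according to its
#' position relative to the transcript's CDS span.
#'
#' @param file GTF or GFF3 path.
#' @param gene gene identifier (matched against \code{gene_id} or \code{ID}).
#' @return annotation data.frame suitable for \code{\link{build_catalog}}.
#' @export
read_gene_annotation <- function(file, gene) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("read_gene_annotation() requires the rtracklayer package")
  gr <- rtracklayer::import(file)
  meta <- S4Vectors::mcols(gr)
  gid <- if ("gene_id" %in% names(meta)) as.character(meta$gene_id)
         else as.character(meta$ID)
  tid <- if ("transcript_id" %in% names(meta)) as.character(meta$transcript_id)
         else as.character(meta$Parent)
  keep <- !is.na(gid) & gid == gene
  gr <- gr[keep]; meta <- S4Vectors::mcols(gr); tid <- tid[keep]
  type <- as.character(meta$type)
  ex <- which(type == "exon")
  if (length(ex) == 0L) stop("gene '", gene, "' absent from annotation")
  cds <- which(type == "CDS")
  strand <- as.character(BiocGenerics::strand(gr))[ex[1L]]
  # CDS span per transcript
  cds_start <- if (length(cds)) min(BiocGenerics::start(gr)[cds]) - 1L else NA
  cds_end <- if (length(cds)) max(BiocGenerics::end(gr)[cds]) else NA
  s <- BiocGenerics::start(gr)[ex] - 1L
  e <- BiocGenerics::end(gr)[ex]
  region <- rep("coding", length(ex))
  if (!is.na(cds_start)) {
    left <- e <= cds_start
    right <- s >= cds_end
    region[left] <- if (strand == "+") "utr5" else "utr3"
    region[right] <- if (strand == "+") "utr3" else "utr5"
  }
  data.frame(gene_id = gene, transcript_id = tid[ex],
             chrom = as.character(GenomicRanges::seqnames(gr))[ex],
             start = s, end = e, strand = strand, region = region)
}

#' Write / read an exon catalog as TSV
#'
#' @param catalog an \code{exon_catalog}.
#' @param file output path.
#' @return \code{write_catalog} returns \code{file} invisibly;
#'   \code{read_catalog} returns an \code{exon_catalog}.
#' @export
write_catalog <- function(catalog, file) {
  ex <- catalog$exons
  ex$gene_id <- catalog$gene_id
  write.table(ex[, c("gene_id", "name", "chrom", "start", "end", "strand",
                     "region", "class", "evidence_reads")],
              file, sep = "\t", quote = FALSE, row.names = FALSE)
  tg <- catalog$psi_targets
  write.table(tg, paste0(file, ".targets"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(file) {
  ex <- read.delim(file, stringsAsFactors = FALSE)
  tg <- read.delim(paste0(file, ".targets"), stringsAsFactors = FALSE,
                   colClasses = c(partner = "character",
                                  flank_up = "character",
                                  flank_down = "character"))
  structure(list(gene_id = ex$gene_id[1L], chrom = ex$chrom[1L],
                 strand = ex$strand[1L],
                 exons = ex[, setdiff(names(ex), "gene_id")],
                 psi_targets = tg),
            class = "exon_catalog")
}
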