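# PSI quantification: junction-only rule for internal cassette exons,
# length-normalized containment rule for mutually exclusive terminal exons.

.target_junctions <- function(catalog, target) {
  ex <- catalog$exons
  stopifnot(target$mode == "internal")
  t <- ex[ex$name == target$exon, ]
  up <- ex[ex$name == target$flank_up, ]
  dn <- ex[ex$name == target$flank_down, ]
  if (nrow(t) != 1L || nrow(up) != 1L || nrow(dn) != 1L)
    stop("target or flanking exon missing from catalog")
  # genomic left/right ordering makes junction pairs strand-agnostic
  fl <- rbind(up, dn)
  left <- fl[which.min(fl$start), ]
  right <- fl[which.max(fl$start), ]
  list(
    inclusion = list(c(left$end, t$start), c(t$end, right$start)),
    exclusion = c(left$end, right$start))
}

#' Count junction and containment reads for a PSI target
#'
#' Implements the read-assignment rules: for an internal cassette exon only
#' reads spanning the defined exon-exon junctions count (inclusion when a
#' junction joins a flanking exon to the target, exclusion when a junction
#' joins the two flanks directly; a read spanning both inclusion junctions
#' counts once, reads being the unit). For a terminal pair every read
#' overlapping a terminal exon by >= 1 base counts as containment for that
#' exon. Junctions must match catalog exon boundaries exactly; other spliced
#' reads are ignored for the target.
#'
#' @param reads read blocks data.frame (\code{read_id}, \code{start},
#'   \code{end}; 0-based half-open; one row per aligned block).
#' @param catalog an \code{\link{exon_catalog}}.
#' @param target one row of \code{catalog$psi_targets}.
#' @return for internal targets a list with \code{inclusion} and
#'   \code{exclusion} read counts; for terminal pairs a list with
#'   \code{count_a}, \code{count_b} (in \code{exon}, \code{partner} order).
#' @export
count_target_reads <- function(reads, catalog, target) {
  if (target$mode == "internal") {
    jx <- .read_junctions(reads)
    tj <- .target_junctions(catalog, target)
    inc <- jx$read_id[(jx$donor == tj$inclusion[[1]][1] &
                         jx$acceptor == tj$inclusion[[1]][2]) |
                        (jx$donor == tj$inclusion[[2]][1] &
                           jx$acceptor == tj$inclusion[[2]][2])]
    exc <- jx$read_id[jx$donor == tj$exclusion[1] &
                        jx$acceptor == tj$exclusion[2]]
    list(mode = "internal",
         inclusion = length(unique(inc)),
         exclusion = length(unique(setdiff(exc, inc))))
  } else {
    ex <- catalog$exons
    a <- ex[ex$name == target$exon, ]
    b <- ex[ex$name == target$partner, ]
    if (nrow(reads) == 0L) return(list(mode = "terminal_pair",
                                       count_a = 0L, count_b = 0L))
    ov <- function(exon) {
      hit <- reads$start < exon$end & reads$end > exon$start
      unique(reads$read_id[hit])
    }
    list(mode = "terminal_pair",
         count_a = length(ov(a)), count_b = length(ov(b)))
  }
}

#' Assign one read to a PSI target
#'
#' Single-read wrapper around \code{\link{count_target_reads}}; returns the
#' contribution of the read as \code{"inclusion"}, \code{"exclusion"},
#' \code{"containment_a"}, \code{"containment_b"} or \code{"none"}.
#'
#' @inheritParams count_target_reads
#' @param read one read's blocks (data.frame with \code{read_id},
#'   \code{start}, \code{end}).
#' @export
assign_read <- function(read, catalog, target) {
  n <- count_target_reads(read, catalog, target)
  if (n$mode == "internal") {
    if (n$inclusion > 0L) "inclusion"
    else if (n$exclusion > 0L) "exclusion"
    else "none"
  } else {
    if (n$count_a > 0L) "containment_a"
    else if (n$count_b > 0L) "containment_b"
    else "none"
  }
}

#' PSI of an internal cassette exon
#'
#' psi = 100 * inclusion / (inclusion + exclusion), the percentage of
#' junction-spanning reads at the target region that contain the exon. A zero
#' denominator yields a missing (NA) estimate flagged \code{defined = FALSE},
#' never 0 or 50.
#'
#' @param inclusion,exclusion junction read counts.
#' @param exon optional exon name carried into the result.
#' @return data.frame with \code{exon}, \code{mode}, \code{psi},
#'   \code{numerator}, \code{denominator}, \code{defined}.
#' @export
psi_internal <- function(inclusion, exclusion, exon = NA_character_) {
  stopifnot(inclusion >= 0, exclusion >= 0)
  den <- inclusion + exclusion
  data.frame(exon = exon, mode = "internal",
             psi = if (den > 0) 100 * inclusion / den else NA_real_,
             numerator = inclusion, denominator = den,
             defined = den > 0)
}

#' PSI of a mutually exclusive terminal-exon pair
#'
#' Containment read counts are normalized to exon length before forming the
#' percentage: with densities d_x = count_x / length_x,
#' psi_a = 100 * d_a / (d_a + d_b) and psi_b = 100 - psi_a (the pair sums to
#' 100 exactly). This inverts the read-sampling bias whereby a longer
#' terminal exon collects proportionally more containment reads at equal
#' transcript abundance.
#'
#' @param count_a,count_b containment read counts for the two exons.
#' @param length_a,length_b exon lengths in bases (> 0).
#' @param exons optional character(2) of exon names.
#' @return two-row data.frame as in \code{\link{psi_internal}}.
#' @export
psi_terminal <- function(count_a, length_a, count_b, length_b,
                         exons = c(NA_character_, NA_character_)) {
  if (length_a <= 0 || length_b <= 0) stop("exon lengths must be positive")
  stopifnot(count_a >= 0, count_b >= 0)
  da <- count_a / length_a
  db <- count_b / length_b
  den <- da + db
  psi_a <- if (den > 0) 100 * da / den else NA_real_
  data.frame(exon = exons, mode = "terminal_pair",
             psi = c(psi_a, if (den > 0) 100 - psi_a else NA_real_),
             numerator = c(da, db), denominator = den,
             defined = den > 0)
}

#' PSI table for all catalog targets
#'
#' Applies the appropriate PSI rule to every target of the catalog using the
#' supplied reads.
#'
#' @inheritParams count_target_reads
#' @return data.frame of PSI estimates (one row per internal target, two per
#'   terminal pair).
#' @export
psi_table <- function(reads, catalog) {
  tg <- catalog$psi_targets
  out <- lapply(seq_len(nrow(tg)), function(i) {
    t <- tg[i, ]
    n <- count_target_reads(reads, catalog, t)
    if (t$mode == "internal")
      psi_internal(n$inclusion, n$exclusion, exon = t$exon)
    else
      psi_terminal(n$count_a, t$exon_len, n$count_b, t$partner_len,
                   exons = c(t$exon, t$partner))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Filter genes by minimum read count
#'
#' Retains genes with strictly more than \code{threshold} total reads (the
#' interface to downstream differential-expression testing; the default 350
#' is the pipeline's gene-level depth cutoff).
#'
#' @param table data.frame with \code{gene_id} and \code{total_reads}.
#' @param threshold strict lower bound (default 350).
#' @export
filter_genes_min_count <- function(table, threshold = 350) {
  stopifnot(all(table$total_reads >= 0))
  table[table$total_reads > threshold, , drop = FALSE]
}

#' Relative quantification of qPCR Ct values
#'
#' Per sample, delta_ct = ct_target - ct_reference (reference gene from the
#' same sample, e.g. Actb). delta_delta_ct subtracts the mean delta_ct of the
#' control group, and fold_change = 2^(-delta_delta_ct), so the control group
#' averages a fold change of 1.
#'
#' @param ct data.frame with columns \code{sample}, \code{group},
#'   \code{ct_target}, \code{ct_reference}.
#' @param control_group label of the reference condition (e.g. control gRNA).
#' @return input with \code{delta_ct}, \code{delta_delta_ct},
#'   \code{fold_change} columns appended.
#' @export
qpcr_relative <- function(ct, control_group) {
  if (any(is.na(ct$ct_reference)) || any(is.na(ct$ct_target)))
    stop("missing Ct values")
  if (!any(ct$group == control_group))
    stop("control group '", control_group, "' not present")
  ct$delta_ct <- ct$ct_target - ct$ct_reference
  ctrl <- mean(ct$delta_ct[ct$group == control_group])
  ct$delta_delta_ct <- ct$delta_ct - ctrl
  ct$fold_change <- 2^(-ct$delta_delta_ct)
  ct
}

#' Read aligned-read blocks from a BED12 file
#'
#' Expands BED12 block definitions into the package's one-row-per-block
#' read-blocks data.frame (0-based half-open, as in BED).
#'
#' @param file BED12 path.
#' @return data.frame with \code{read_id}, \code{chrom}, \code{start},
#'   \code{end}.
#' @export
read_bed12_blocks <- function(file) {
  bed <- read.delim(file, header = FALSE, stringsAsFactors = FALSE)
  stopifnot(ncol(bed) >= 12L)
  out <- lapply(seq_len(nrow(bed)), function(i) {
    sizes <- as.integer(strsplit(as.character(bed[i, 11]), ",")[[1]])
    offs <- as.integer(strsplit(as.character(bed[i, 12]), ",")[[1]])
    data.frame(read_id = as.character(bed[i, 4]),
               chrom = as.character(bed[i, 1]),
               start = bed[i, 2] + offs,
               end = bed[i, 2] + offs + sizes)
  })
  do.call(rbind, out)
}

#' Write a PSI table as TSV
#' @param psi data.frame from \code{\link{psi_table}}.
#' @param file output path.
#' @export
write_psi_table <- function(psi, file) {
  write.table(psi, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
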