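## Read-level stage: assign aligned reads to amplicons, apply the three
## read filters (alignment length >= 75 bp, overlap >= 75% of the target
## amplicon, edit distance <= 2), and tally per-locus allele counts.
##
## Coordinates: amplicons and read spans are 0-based half-open internally
## (BED convention); SAM POS and locus positions are 1-based.

## ---- CIGAR helpers -------------------------------------------------------

.cigar_ops <- function(cigar) {
  if (is.na(cigar) || cigar == "*") return(list(len = integer(0), op = character(0)))
  len <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  op <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1L]]
  if (length(len) != length(op)) stop("malformed CIGAR: ", cigar)
  list(len = len, op = op)
}

## reference-consuming width (M/=/X/D/N): the alignment length contract
cigar_ref_width <- function(cigar) {
  vapply(cigar, function(cg) {
    ops <- .cigar_ops(cg)
    sum(ops$len[ops$op %in% c("M", "=", "X", "D", "N")])
  }, 0L, USE.NAMES = FALSE)
}

## base aligned opposite 1-based reference position pos1, or NA when the read
## does not cover it or a deletion/skip spans it
.base_at <- function(pos_1based, cigar, seq, target) {
  ops <- .cigar_ops(cigar)
  rpos <- pos_1based   # next reference position to account for
  qpos <- 1L           # next query position
  for (k in seq_along(ops$op)) {
    op <- ops$op[k]; len <- ops$len[k]
    if (op %in% c("M", "=", "X")) {
      if (target < rpos + len) {
        if (target < rpos) return(NA_character_)
        return(substr(seq, qpos + (target - rpos), qpos + (target - rpos)))
      }
      rpos <- rpos + len; qpos <- qpos + len
    } else if (op %in% c("D", "N")) {
      if (target < rpos + len) return(NA_character_)
      rpos <- rpos + len
    } else if (op %in% c("I", "S")) {
      qpos <- qpos + len
    }
    ## H and P consume nothing we track
  }
  NA_character_
}

## ---- Reading reads and amplicons -----------------------------------------

.read_cols <- c("read_id", "sample_id", "chrom", "pos", "mapq", "flag",
                "cigar", "seq", "nm")

.finish_reads <- function(df) {
  df$pos <- as.integer(df$pos)
  df$align_start <- df$pos - 1L
  df$alignment_length <- cigar_ref_width(df$cigar)
  df$align_end <- df$align_start + df$alignment_length
  df
}

#' Read aligned reads from SAM or the tabular read dialect
#'
#' SAM files are converted and scanned through Rsamtools; the TSV dialect
#' carries the same fields (`read_id`, `sample_id`, `chrom`, `pos` (1-based),
#' `mapq`, `flag`, `cigar`, `seq`, `nm`). Both produce an identical read
#' data.frame, so the filter stage behaves the same on either input.
#'
#' @param path SAM or TSV file.
#' @param format `"auto"` (by extension), `"sam"` or `"tsv"`.
#' @param sample_id Sample id to assign when the input does not carry one.
#' @return data.frame of reads with 0-based half-open `align_start`,
#'   `align_end` and `alignment_length` derived from the CIGAR.
#' @export
read_aligned_reads <- function(path, format = c("auto", "sam", "tsv"),
                               sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("read file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "tsv"
  if (format == "sam") {
    bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
    p <- Rsamtools::ScanBamParam(
      what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq"),
      tag = "NM"
    )
    b <- Rsamtools::scanBam(bam, param = p)[[1L]]
    df <- data.frame(
      read_id = b$qname,
      sample_id = if (is.null(sample_id)) "sample_1" else sample_id,
      chrom = as.character(b$rname),
      pos = b$pos,
      mapq = b$mapq,
      flag = b$flag,
      cigar = b$cigar,
      seq = as.character(b$seq),
      nm = if (is.null(b$tag$NM)) NA_integer_ else b$tag$NM,
      stringsAsFactors = FALSE
    )
  } else {
    df <- read.table(path, header = TRUE, sep = "\t",
                     colClasses = "character", stringsAsFactors = FALSE)
    if (!"sample_id" %in% names(df))
      df$sample_id <- if (is.null(sample_id)) "sample_1" else sample_id
    missing <- setdiff(.read_cols, names(df))
    if (length(missing))
      stop("read TSV lacks columns: ", paste(missing, collapse = ", "))
    df <- df[.read_cols]
    for (cl in c("pos", "mapq", "flag", "nm")) df[[cl]] <- as.integer(df[[cl]])
  }
  .finish_reads(df)
}

#' Read an amplicon panel from BED
#'
#' BED is 0-based half-open; intervals are kept in that convention. The BED
#' name column provides `amplicon_id` (generated when absent).
#'
#' @param path BED file.
#' @return data.frame with `amplicon_id`, `chrom`, `start`, `end`.
#' @export
read_amplicons <- function(path) {
  if (!file.exists(path)) stop("amplicon BED not found: ", path)
  gr <- as.data.frame(rtracklayer::import(path, format = "BED"))
  nm <- if (!is.null(gr$name) && !anyNA(gr$name)) as.character(gr$name) else
    sprintf("amplicon_%03d", seq_len(nrow(gr)))
  data.frame(
    amplicon_id = nm,
    chrom = as.character(gr$seqnames),
    start = gr$start - 1L,  # back to 0-based half-open
    end = gr$end,
    stringsAsFactors = FALSE
  )
}

#' Write an amplicon panel to BED
#' @param amplicons Amplicon data.frame (`amplicon_id`, `chrom`, `start`, `end`).
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_amplicons <- function(amplicons, path) {
  write.table(
    amplicons[c("chrom", "start", "end", "amplicon_id")],
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

## ---- Assignment, filtering, counting -------------------------------------

#' Assign reads to amplicons by largest alignment overlap
#'
#' Each read is assigned to the amplicon on its chromosome with the largest
#' base-pair overlap with the read's aligned span; ties are broken by lower
#' amplicon start, then lexicographic `amplicon_id`. Reads overlapping no
#' amplicon get `NA`.
#'
#' @param reads Read data.frame from [read_aligned_reads()] (or the synthetic
#'   generator).
#' @param amplicons Amplicon data.frame.
#' @return `reads` with columns `amplicon_id` and `overlap_bp` added.
#' @export
assign_to_amplicon <- function(reads, amplicons) {
  o <- order(amplicons$start, amplicons$amplicon_id)
  amplicons <- amplicons[o, , drop = FALSE]
  reads$amplicon_id <- NA_character_
  reads$overlap_bp <- 0L
  for (i in seq_len(nrow(reads))) {
    a <- amplicons[amplicons$chrom == reads$chrom[i], , drop = FALSE]
    if (nrow(a) == 0L) next
    ov <- pmin(a$end, reads$align_end[i]) - pmax(a$start, reads$align_start[i])
    ov <- pmax(ov, 0L)
    if (max(ov) <= 0L) next
    j <- which.max(ov)  # first maximum = lowest start then lexicographic id
    reads$amplicon_id[i] <- a$amplicon_id[j]
    reads$overlap_bp[i] <- as.integer(ov[j])
  }
  reads
}

#' Apply the three read filters
#'
#' A read passes iff its alignment length is at least `min_align_len`, it
#' overlaps at least `min_overlap` of its target amplicon's length, and its
#' edit distance (NM) is at most `max_nm`. Boundary values are inclusive.
#' Every violated rule is reported in `fail_reasons`.
#'
#' @param reads Reads with `amplicon_id`/`overlap_bp` from
#'   [assign_to_amplicon()].
#' @param amplicons Amplicon data.frame (for amplicon lengths).
#' @param min_align_len Minimum alignment length in bp (default 75).
#' @param min_overlap Minimum overlap as a fraction of the amplicon length
#'   (default 0.75).
#' @param max_nm Maximum edit distance (default 2).
#' @return `reads` with `pass_filters` (logical) and `fail_reasons`
#'   (comma-joined codes among `min_align_len`, `min_overlap`,
#'   `edit_distance`, `unassigned`).
#' @export
passes_filters <- function(reads, amplicons, min_align_len = 75,
                           min_overlap = 0.75, max_nm = 2) {
  if (!"amplicon_id" %in% names(reads))
    reads <- assign_to_amplicon(reads, amplicons)
  if (any(is.na(reads$nm)))
    stop("edit-distance (NM) annotation missing; the edit-distance rule ",
         "cannot be evaluated")
  amp_len <- setNames(amplicons$end - amplicons$start, amplicons$amplicon_id)
  frac <- ifelse(is.na(reads$amplicon_id), 0,
                 reads$overlap_bp / amp_len[reads$amplicon_id])
  fail <- cbind(
    unassigned = is.na(reads$amplicon_id),
    min_align_len = reads$alignment_length < min_align_len,
    min_overlap = frac < min_overlap,
    edit_distance = reads$nm > max_nm
  )
  reads$pass_filters <- rowSums(fail) == 0L
  reads$fail_reasons <- apply(fail, 1L, function(f)
    paste(colnames(fail)[f], collapse = ","))
  reads
}

#' Count allele calls at target loci from filtered reads
#'
#' For each locus, tallies the base each filtered read aligns opposite the
#' locus position; reads not covering the position (or spanning it with a
#' deletion, or calling N) contribute nothing.
#'
#' @param reads Filtered reads (rows with `pass_filters == TRUE` are used if
#'   the column is present; otherwise all rows).
#' @param loci data.frame with `chrom`, `pos` (1-based), `ref`.
#' @param amplicons Optional amplicon data.frame; when given, each locus must
#'   fall inside at least one amplicon.
#' @return Count table: `sample_id`, `chrom`, `pos`, `ref`,
#'   `count_A`..`count_T`, `depth`.
#' @export
count_alleles <- function(reads, loci, amplicons = NULL) {
  if (!all(loci$ref %in% BASES))
    stop("locus reference alleles must be A, C, G or T")
  if (!is.null(amplicons)) {
    inside <- vapply(seq_len(nrow(loci)), function(i) {
      any(amplicons$chrom == loci$chrom[i] &
            amplicons$start < loci$pos[i] & loci$pos[i] <= amplicons$end)
    }, TRUE)
    if (any(!inside))
      stop("loci outside every amplicon: ",
           paste(.locus_key(loci$chrom[!inside], loci$pos[!inside]),
                 collapse = ", "))
  }
  if ("pass_filters" %in% names(reads))
    reads <- reads[reads$pass_filters, , drop = FALSE]
  samples <- sort(unique(reads$sample_id))
  out <- list()
  for (s in samples) {
    rs <- reads[reads$sample_id == s, , drop = FALSE]
    for (i in seq_len(nrow(loci))) {
      cover <- rs$chrom == loci$chrom[i] &
        rs$align_start < loci$pos[i] & loci$pos[i] <= rs$align_end
      counts <- setNames(integer(4L), BASES)
      for (j in which(cover)) {
        b <- .base_at(rs$pos[j], rs$cigar[j], rs$seq[j], loci$pos[i])
        if (!is.na(b) && b %in% BASES) counts[b] <- counts[b] + 1L
      }
      out[[length(out) + 1L]] <- data.frame(
        sample_id = s, chrom = loci$chrom[i], pos = loci$pos[i],
        ref = loci$ref[i],
        count_A = counts[["A"]], count_C = counts[["C"]],
        count_G = counts[["G"]], count_T = counts[["T"]],
        depth = sum(counts), stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out)) stop("no reads to count")
  do.call(rbind, out)
}

#' Filter reads and produce the per-locus count table in one step
#'
#' Drops unmapped reads and reads with MAPQ 0 (their coordinates are not
#' trustworthy), assigns the remainder to amplicons, applies the three read
#' filters and counts alleles at the target loci. A per-stage log (reads in,
#' dropped, assigned, passed, and a failure-reason histogram) is attached as
#' the `"log"` attribute.
#'
#' @inheritParams passes_filters
#' @inheritParams count_alleles
#' @return Count table as in [count_alleles()], with a `"log"` attribute.
#' @export
filter_count <- function(reads, amplicons, loci, min_align_len = 75,
                         min_overlap = 0.75, max_nm = 2) {
  n_in <- nrow(reads)
  unusable <- (bitwAnd(reads$flag, 4L) != 0L) | reads$mapq == 0L
  reads <- reads[!unusable, , drop = FALSE]
  reads <- assign_to_amplicon(reads, amplicons)
  reads <- passes_filters(reads, amplicons, min_align_len = min_align_len,
                          min_overlap = min_overlap, max_nm = max_nm)
  reasons <- unlist(strsplit(reads$fail_reasons[!reads$pass_filters], ","))
  counts <- count_alleles(reads, loci, amplicons)
  attr(counts, "log") <- list(
    reads_in = n_in,
    dropped_unmapped_or_mapq0 = sum(unusable),
    assigned = sum(!is.na(reads$amplicon_id)),
    passed = sum(reads$pass_filters),
    fail_histogram = if (length(reasons)) table(reasons) else table(character(0))
  )
  counts
}
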