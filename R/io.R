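## Plain-text IO for the pipeline's tabular interchange formats. Every stage
## reads and writes TSV (plus minimal VCF for calls), so any stage can be run
## standalone on user data.

.read_tsv <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(what, " file ", path, " lacks columns: ",
         paste(missing, collapse = ", "))
  df
}

#' Read a per-locus allele count table
#' @param path TSV with columns `sample_id`, `chrom`, `pos`, `ref`,
#'   `count_A`..`count_T` (a `depth` column is recomputed).
#' @return Count table data.frame.
#' @export
read_counts <- function(path) {
  df <- .read_tsv(path, c("sample_id", "chrom", "pos", "ref",
                          paste0("count_", BASES)), "count table")
  df$depth <- rowSums(df[paste0("count_", BASES)])
  df
}

#' Write a count table
#' @param counts Count table data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a population allele-frequency table (TSV or VCF)
#'
#' TSV input needs columns `chrom`, `pos`, `ref`, `alt`, `af`; VCF input is
#' parsed with vcfR and must carry an `AF` INFO field. Absent entries mean
#' frequency 0.
#'
#' @param path TSV or VCF path.
#' @return data.frame `chrom`, `pos`, `ref`, `alt`, `af`.
#' @export
read_popfreq <- function(path) {
  if (!file.exists(path)) stop("population-frequency file not found: ", path)
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    af <- suppressWarnings(as.numeric(vcfR::extract.info(v, "AF")))
    if (all(is.na(af)))
      stop("VCF ", path, " carries no usable AF INFO field")
    data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
               alt = fix$ALT, af = af, stringsAsFactors = FALSE)
  } else {
    df <- .read_tsv(path, c("chrom", "pos", "ref", "alt", "af"),
                    "population-frequency")
    df$af <- as.numeric(df$af)
    df
  }
}

#' Read a clinical outcomes table
#' @param path TSV with `subject_id`, `time_years`, `event` (0/1) and
#'   optionally `group`.
#' @return Outcomes data.frame.
#' @export
read_outcomes <- function(path) {
  df <- .read_tsv(path, c("subject_id", "time_years", "event"), "outcomes")
  df$time_years <- as.numeric(df$time_years)
  df$event <- as.integer(df$event)
  df
}

#' Read a control-sample manifest (one sample id per line)
#' @param path Text file of control sample ids.
#' @return Character vector of sample ids.
#' @export
read_controls_manifest <- function(path) {
  if (!file.exists(path)) stop("control manifest not found: ", path)
  ids <- readLines(path)
  ids <- trimws(ids[nzchar(trimws(ids))])
  if (!length(ids)) stop("control manifest ", path, " is empty")
  ids
}

#' Write finalised calls as a minimal VCF
#'
#' One record per scored sample-locus: `QUAL` carries the log Bayes factor,
#' `FILTER` is `PASS` or the semicolon-joined failed filters, and `INFO`
#' carries `VAF`, `DP`, `AC` and the sample id.
#'
#' @param calls Finalised calls (after [apply_cohort_filter()]).
#' @param path Output `.vcf` path.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=tamseqbf",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"MAP variant allele frequency\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Filtered depth\">",
    "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Alternate allele count\">",
    "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Case sample id\">",
    "##FILTER=<ID=depth,Description=\"Filtered depth below threshold\">",
    "##FILTER=<ID=bayes_factor,Description=\"Log Bayes factor below threshold\">",
    "##FILTER=<ID=cohort_frequency,Description=\"Variant called in too many case samples\">",
    "##FILTER=<ID=population_frequency,Description=\"Population allele frequency above threshold\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  if (nrow(calls)) {
    filt <- apply(
      cbind(depth = calls$flag_depth, bayes_factor = calls$flag_bayes_factor,
            cohort_frequency = calls$flag_cohort_frequency,
            population_frequency = calls$flag_population_frequency),
      1L, function(f) if (any(f)) paste(names(f)[f], collapse = ";") else "PASS")
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t%.4f\t%s\tVAF=%.6g;DP=%d;AC=%d;SAMPLE=%s",
                       calls$chrom, as.integer(calls$pos), calls$ref, calls$alt,
                       calls$log_bf, filt, calls$vaf_map, calls$depth,
                       calls$alt_count, calls$sample_id), con)
  }
  invisible(path)
}
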