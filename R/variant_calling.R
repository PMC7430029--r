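## Bayes-factor scoring of case allele counts against the fitted error null,
## MAP variant-allele-frequency estimation, and the high-confidence filters.

#' High-confidence call thresholds
#'
#' Container for the filtering thresholds applied to scored variants:
#' minimum filtered depth, minimum (natural-)log Bayes factor, maximum number
#' of case samples a variant may be called in ("cohort frequency of less than
#' four samples" means `max_cohort_count = 3`), and maximum population allele
#' frequency.
#'
#' @param min_depth Minimum filtered depth of coverage (reads, default 500).
#' @param min_log_bf Minimum natural-log Bayes factor (default 6).
#' @param max_cohort_count Maximum number of case samples in which the same
#'   variant may be called before it is treated as an artefact (default 3).
#' @param max_pop_af Maximum population allele frequency; variants with
#'   frequency strictly greater are filtered (default 0.01).
#' @return A `call_thresholds` list.
#' @export
call_thresholds <- function(min_depth = 500, min_log_bf = 6,
                            max_cohort_count = 3, max_pop_af = 0.01) {
  th <- list(min_depth = min_depth, min_log_bf = min_log_bf,
             max_cohort_count = max_cohort_count, max_pop_af = max_pop_af)
  if (any(vapply(th, function(v) !is.numeric(v) || length(v) != 1L || v < 0, TRUE)))
    stop("all thresholds must be single non-negative numbers")
  structure(th, class = "call_thresholds")
}

#' Log Bayes factor against the sequencing-error null
#'
#' Weight of evidence that a case count vector was not generated by the
#' fitted error null: the log ratio of the Dirichlet-Multinomial marginal
#' likelihood under the Jeffreys alternative (Dirichlet with all pseudocounts
#' 1/2) to the marginal likelihood under the fitted null,
#' \deqn{\log B = \log P(x \mid \alpha = (1/2,1/2,1/2,1/2))
#'             - \log P(x \mid \hat\alpha_{null}).}
#' Natural logarithm throughout; the default call threshold of 6 corresponds
#' to \eqn{B \ge e^6 \approx 403}.
#'
#' @param x Case count 4-vector (A, C, G, T) or matrix of count rows.
#' @param null A converged [fit_null()] object, or a positive alpha 4-vector.
#' @return Numeric log Bayes factor(s).
#' @export
log_bayes_factor <- function(x, null) {
  if (inherits(null, "dm_null")) {
    if (!isTRUE(null$converged))
      stop("null model did not converge; call refused for this locus")
    alpha <- null$alpha
  } else {
    alpha <- null
  }
  ddirmult(x, rep(0.5, 4)) - ddirmult(x, alpha)
}

#' Maximum a posteriori variant allele frequency
#'
#' Under the Jeffreys Dirichlet(1/2,1/2,1/2,1/2) prior the posterior over the
#' base composition is Dirichlet(x + 1/2); its marginal for the alternate
#' allele is Beta(x_alt + 1/2, n - x_alt + 3/2), whose mode is
#' \eqn{(x_{alt} - 1/2)/n}, clamped into \[0, 1\].
#'
#' @param x Count 4-vector in A, C, G, T order.
#' @param alt_allele The alternate allele, one of `"A","C","G","T"`.
#' @return MAP estimate of the variant allele frequency.
#' @export
map_vaf <- function(x, alt_allele) {
  x <- drop(.count_matrix(x))
  if (!alt_allele %in% BASES) stop("'alt_allele' must be one of A, C, G, T")
  n <- sum(x)
  if (n <= 0) stop("total depth is zero; VAF undefined")
  min(max((x[[alt_allele]] - 0.5) / n, 0), 1)
}

## alt allele = non-reference base with the largest count; ties broken in
## lexicographic (A < C < G < T) order, which which.max provides
.pick_alt <- function(x, ref) {
  nonref <- setdiff(BASES, ref)
  nonref[which.max(x[nonref])]
}

#' Score one case sample at one locus
#'
#' Computes the log Bayes factor and MAP VAF for the strongest non-reference
#' allele and sets the depth, Bayes-factor and population-frequency filter
#' flags. The cohort-frequency flag is deferred to [apply_cohort_filter()],
#' so `pass` is `NA` until the cohort filter has run.
#'
#' @param x Case count 4-vector (A, C, G, T).
#' @param ref Reference allele at the locus.
#' @param null Converged `dm_null` for the locus.
#' @param pop_af Population allele frequency of the chosen alternate allele
#'   (0 when absent from the frequency table).
#' @param thresholds A [call_thresholds()] object.
#' @return One-row data.frame with alt, alt_count, depth, log_bf, vaf_map and
#'   logical filter-flag columns.
#' @export
call_locus <- function(x, ref, null, pop_af = 0, thresholds = call_thresholds()) {
  if (!ref %in% BASES) stop("reference allele must be one of A, C, G, T")
  x <- drop(.count_matrix(x))
  alt <- .pick_alt(x, ref)
  depth <- sum(x)
  lbf <- log_bayes_factor(x, null)
  data.frame(
    ref = ref,
    alt = alt,
    alt_count = as.integer(x[[alt]]),
    depth = as.integer(depth),
    log_bf = lbf,
    vaf_map = map_vaf(x, alt),
    flag_depth = depth < thresholds$min_depth,
    flag_bayes_factor = lbf < thresholds$min_log_bf,
    flag_population_frequency = pop_af > thresholds$max_pop_af,
    flag_cohort_frequency = NA,
    pass = NA,
    stringsAsFactors = FALSE
  )
}

#' Score every case sample at every fitted locus
#'
#' Runs [call_locus()] across a case count table. Loci whose null model did
#' not converge are refused and listed in the `refused` attribute. The
#' returned calls have depth, Bayes-factor and population-frequency flags
#' set; run [apply_cohort_filter()] to finalise.
#'
#' @param counts Case count table (`sample_id`, `chrom`, `pos`, `ref`,
#'   `count_A`..`count_T`).
#' @param nulls A [fit_null_all()] result.
#' @param pop_table Optional population-frequency data.frame (`chrom`, `pos`,
#'   `ref`, `alt`, `af`); absent entries mean frequency 0.
#' @param thresholds A [call_thresholds()] object.
#' @return data.frame of scored calls, one row per case sample x locus, with
#'   attribute `refused` naming loci without a converged null.
#' @export
call_variants <- function(counts, nulls, pop_table = NULL,
                          thresholds = call_thresholds()) {
  stopifnot(inherits(nulls, "dm_null_set"))
  key <- .locus_key(counts$chrom, counts$pos)
  conv <- vapply(nulls, `[[`, TRUE, "converged")
  known <- names(nulls)[conv]
  refused <- sort(unique(key[key %in% names(nulls)[!conv]]))
  missing_null <- sort(unique(key[!key %in% names(nulls)]))
  if (length(missing_null))
    stop("no fitted null for loci: ", paste(missing_null, collapse = ", "))
  keep <- key %in% known
  rows <- which(keep)
  xm <- .count_matrix(counts)
  af <- function(chrom, pos, ref, alt) {
    if (is.null(pop_table)) return(0)
    hit <- pop_table$chrom == chrom & pop_table$pos == pos &
      pop_table$ref == ref & pop_table$alt == alt
    if (any(hit)) pop_table$af[which(hit)[1L]] else 0
  }
  out <- vector("list", length(rows))
  for (j in seq_along(rows)) {
    i <- rows[j]
    nl <- nulls[[key[i]]]
    x <- xm[i, ]
    alt <- .pick_alt(x, counts$ref[i])
    cl <- call_locus(x, counts$ref[i], nl,
                     pop_af = af(counts$chrom[i], counts$pos[i],
                                 counts$ref[i], alt),
                     thresholds = thresholds)
    out[[j]] <- cbind(
      data.frame(sample_id = counts$sample_id[i], chrom = counts$chrom[i],
                 pos = counts$pos[i], stringsAsFactors = FALSE),
      cl
    )
  }
  calls <- do.call(rbind, out)
  if (is.null(calls)) calls <- .empty_calls()
  rownames(calls) <- NULL
  attr(calls, "refused") <- refused
  calls
}

.empty_calls <- function() {
  data.frame(sample_id = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), alt_count = integer(),
             depth = integer(), log_bf = numeric(), vaf_map = numeric(),
             flag_depth = logical(), flag_bayes_factor = logical(),
             flag_population_frequency = logical(),
             flag_cohort_frequency = logical(), pass = logical(),
             stringsAsFactors = FALSE)
}

#' Apply the cohort-recurrence filter and finalise pass status
#'
#' For each variant identity (chrom, pos, ref, alt), counts the distinct case
#' samples in which it satisfies the depth and Bayes-factor criteria; if that
#' count exceeds `max_cohort_count` (i.e. the variant recurs in four or more
#' samples under the defaults), every instance is flagged
#' `cohort_frequency`. `pass` is then true iff no flag is set. Idempotent.
#'
#' @param calls Scored calls from [call_variants()].
#' @param thresholds A [call_thresholds()] object.
#' @return The calls with `flag_cohort_frequency` and `pass` finalised.
#' @export
apply_cohort_filter <- function(calls, thresholds = call_thresholds()) {
  vkey <- .variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  called <- !calls$flag_depth & !calls$flag_bayes_factor
  n_samples <- vapply(
    split(ifelse(called, calls$sample_id, NA_character_), vkey),
    function(s) length(unique(s[!is.na(s)])), 0L
  )
  calls$flag_cohort_frequency <- unname(
    n_samples[vkey] > thresholds$max_cohort_count
  )
  calls$pass <- !calls$flag_depth & !calls$flag_bayes_factor &
    !calls$flag_population_frequency & !calls$flag_cohort_frequency
  attr(calls, "cohort_filtered") <- TRUE
  calls
}

#' Classify samples as ctDNA-positive or ctDNA-negative
#'
#' A sample is ctDNA-positive iff it carries at least one variant call that
#' passes every high-confidence filter.
#'
#' @param calls Finalised calls (after [apply_cohort_filter()]).
#' @param sample_ids Optional vector of all case sample ids, so samples with
#'   no scored calls are still reported (as negative).
#' @return data.frame with `sample_id`, `status`
#'   (`"ctDNA_positive"`/`"ctDNA_negative"`) and `n_passing`.
#' @export
classify_samples <- function(calls, sample_ids = NULL) {
  if (any(is.na(calls$pass)))
    stop("calls must be finalised with apply_cohort_filter() before classification")
  ids <- unique(c(as.character(calls$sample_id), as.character(sample_ids)))
  ids <- sort(ids)
  n_pass <- vapply(ids, function(s)
    sum(calls$pass[calls$sample_id == s]), 0L)
  data.frame(
    sample_id = ids,
    status = ifelse(n_pass > 0, "ctDNA_positive", "ctDNA_negative"),
    n_passing = as.integer(n_pass),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
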