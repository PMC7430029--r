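## End-to-end orchestration: filter-count -> fit-null -> call -> classify ->
## survival, under one configuration, with a deterministic run manifest; and
## the calibration study of the caller's operating characteristics.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

.load_or <- function(x, reader) {
  if (is.character(x) && length(x) == 1L) reader(x) else x
}

#' Run the ctDNA detection pipeline end to end
#'
#' Stages, in order: (optional) read filtering and allele counting; null-model
#' fitting from the control samples; Bayes-factor scoring of case samples;
#' cohort filtering and sample classification; (optional) survival comparison
#' of ctDNA-positive vs ctDNA-negative patients. All stage outputs are
#' written as plain TSV/VCF under `out_dir`, together with a JSON manifest of
#' input digests, thresholds, package version, seed and output digests.
#' Rerunning the same configuration reproduces every output byte-identically.
#'
#' @param config A list or YAML file path with entries:
#'   \describe{
#'     \item{counts}{count-table TSV path or data.frame covering control and
#'       case samples (or give `reads`, `amplicons`, `loci` to count first).}
#'     \item{controls}{character vector of control sample ids, or a manifest
#'       file path (one id per line). Every other sample is a case.}
#'     \item{reads, amplicons, loci}{optional read-level inputs: SAM/TSV read
#'       file, BED amplicon panel, loci TSV (`chrom`, `pos`, `ref`).}
#'     \item{popfreq}{optional population-frequency TSV/VCF path or data.frame.}
#'     \item{outcomes}{optional clinical outcomes TSV path or data.frame
#'       (`subject_id`, `time_years`, `event`); joined to the classified
#'       status by `subject_id == sample_id`.}
#'     \item{thresholds}{optional list overriding [call_thresholds()] fields.}
#'     \item{read_filters}{optional list: `min_align_len`, `min_overlap`,
#'       `max_nm`.}
#'     \item{out_dir}{output directory.}
#'     \item{seed}{integer seed (recorded; stages are deterministic given
#'       inputs).}
#'   }
#' @return The run manifest (list), invisibly; side effect: files under
#'   `out_dir` (`null_models.tsv`, `calls.tsv`, `calls.vcf`,
#'   `sample_status.tsv`, optionally `counts.tsv`, `survival_test.tsv`,
#'   `km_curves.tsv`, plus `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$out_dir)) stop("config must name an out_dir")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  set.seed(seed)
  th <- do.call(call_thresholds,
                if (is.null(config$thresholds)) list() else config$thresholds)
  rf <- modifyList(list(min_align_len = 75, min_overlap = 0.75, max_nm = 2),
                   if (is.null(config$read_filters)) list()
                   else config$read_filters)
  input_paths <- Filter(function(p) is.character(p) && length(p) == 1L,
                        config[c("counts", "controls", "reads", "amplicons",
                                 "loci", "popfreq", "outcomes")])
  stages <- character(0)
  outputs <- character(0)
  emit <- function(obj, name, writer = write_counts) {
    p <- file.path(config$out_dir, name)
    writer(obj, p)
    outputs <<- c(outputs, p)
    p
  }

  ## --- counts ---------------------------------------------------------
  if (!is.null(config$reads)) {
    counts <- .stage("filter-count", {
      amplicons <- .load_or(config$amplicons, read_amplicons)
      loci <- .load_or(config$loci, function(p)
        .read_tsv(p, c("chrom", "pos", "ref"), "loci"))
      reads <- .load_or(config$reads, read_aligned_reads)
      filter_count(reads, amplicons, loci,
                   min_align_len = rf$min_align_len,
                   min_overlap = rf$min_overlap, max_nm = rf$max_nm)
    })
    emit(counts, "counts.tsv")
    stages <- c(stages, "filter-count")
  } else {
    counts <- .stage("load-counts", .load_or(config$counts, read_counts))
    stages <- c(stages, "load-counts")
  }
  controls <- .stage("load-counts", {
    ids <- .load_or(config$controls, read_controls_manifest)
    if (is.null(ids) || !length(ids)) stop("no control samples configured")
    missing <- setdiff(ids, counts$sample_id)
    if (length(missing))
      stop("control samples absent from the count table: ",
           paste(missing, collapse = ", "))
    ids
  })
  control_counts <- counts[counts$sample_id %in% controls, , drop = FALSE]
  case_counts <- counts[!counts$sample_id %in% controls, , drop = FALSE]

  ## --- fit-null -------------------------------------------------------
  nulls <- .stage("fit-null", fit_null_all(control_counts))
  emit(as.data.frame(nulls), "null_models.tsv",
       function(o, p) write.table(o, p, sep = "\t", quote = FALSE,
                                  row.names = FALSE))
  stages <- c(stages, "fit-null")

  ## --- call -----------------------------------------------------------
  pop_table <- if (is.null(config$popfreq)) NULL else
    .stage("call", .load_or(config$popfreq, read_popfreq))
  calls <- .stage("call",
                  call_variants(case_counts, nulls, pop_table, thresholds = th))
  stages <- c(stages, "call")

  ## --- classify -------------------------------------------------------
  calls <- .stage("classify", apply_cohort_filter(calls, thresholds = th))
  status <- .stage("classify",
                   classify_samples(calls, unique(case_counts$sample_id)))
  emit(calls, "calls.tsv",
       function(o, p) write.table(o, p, sep = "\t", quote = FALSE,
                                  row.names = FALSE))
  emit(calls, "calls.vcf", write_calls_vcf)
  emit(status, "sample_status.tsv",
       function(o, p) write.table(o, p, sep = "\t", quote = FALSE,
                                  row.names = FALSE))
  stages <- c(stages, "classify")

  ## --- survival -------------------------------------------------------
  surv <- NULL
  if (!is.null(config$outcomes)) {
    surv <- .stage("survival", {
      outcomes <- .load_or(config$outcomes, read_outcomes)
      joined <- merge(outcomes, status,
                      by.x = "subject_id", by.y = "sample_id")
      if (!nrow(joined))
        stop("no outcome subjects match classified sample ids")
      joined$group <- joined$status
      compare_survival(joined)
    })
    test_df <- data.frame(
      statistic = surv$logrank$statistic, p_value = surv$logrank$p_value,
      hr = surv$hazard_ratio$hr, ci_lower = surv$hazard_ratio$ci_lower,
      ci_upper = surv$hazard_ratio$ci_upper,
      rmst_group1 = surv$rmst[[1L]], rmst_group2 = surv$rmst[[2L]],
      group1 = names(surv$rmst)[1L], group2 = names(surv$rmst)[2L]
    )
    emit(test_df, "survival_test.tsv",
         function(o, p) write.table(o, p, sep = "\t", quote = FALSE,
                                    row.names = FALSE))
    curve_df <- do.call(rbind, lapply(names(surv$curves), function(nm) {
      cv <- surv$curves[[nm]]
      if (!length(cv$time)) return(NULL)
      data.frame(group = nm, time = cv$time, n_risk = cv$n_risk,
                 n_event = cv$n_event, survival = cv$surv)
    }))
    if (!is.null(curve_df))
      emit(curve_df, "km_curves.tsv",
           function(o, p) write.table(o, p, sep = "\t", quote = FALSE,
                                      row.names = FALSE))
    stages <- c(stages, "survival")
  }

  manifest <- list(
    package = "tamseqbf",
    version = as.character(packageVersion("tamseqbf")),
    seed = seed,
    thresholds = unclass(th),
    read_filters = rf,
    controls = sort(controls),
    stages = stages,
    refused_loci = attr(calls, "refused"),
    skipped_loci = attr(nulls, "skipped"),
    inputs = as.list(vapply(input_paths, function(p)
      unname(md5sum(p)), "")),
    outputs = as.list(setNames(unname(md5sum(outputs)), basename(outputs)))
  )
  json <- jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, null = "null")
  writeLines(json, file.path(config$out_dir, "manifest.json"))
  invisible(manifest)
}

#' Calibration study of the Bayes-factor caller
#'
#' For each cell of a (depth, spike VAF, null concentration) grid: simulate
#' control samples from the error model, fit the per-locus null, then score
#' `reps` unspiked and `reps` spiked case draws, tabulating the false-positive
#' rate (log Bayes factor and depth thresholds met with no variant present)
#' and the detection rate. Rows with `vaf = 0` report only the
#' false-positive rate.
#'
#' @param depths Vector of per-locus depths to sweep.
#' @param vafs Vector of spike-in VAFs (0 entries mean null-only cells).
#' @param concentrations Vector of null Dirichlet-Multinomial concentrations.
#' @param error_rate Per-allele mean error fraction of the null composition
#'   (default 0.001).
#' @param n_controls Control samples fitted per cell (default 50).
#' @param reps Replicate case draws per cell (>= 100).
#' @param thresholds A [call_thresholds()] object.
#' @param seed Integer seed.
#' @return data.frame grid with `fpr`, `detection` and `reps`, class
#'   `calibration_result`.
#' @export
run_calibration <- function(depths, vafs, concentrations, error_rate = 0.001,
                            n_controls = 50L, reps = 200L,
                            thresholds = call_thresholds(), seed = 1L) {
  if (reps < 100L) stop("at least 100 replicates per cell are required")
  grid <- expand.grid(depth = depths, vaf = vafs,
                      concentration = concentrations,
                      KEEP.OUT.ATTRS = FALSE)
  set.seed(seed)
  grid$fpr <- NA_real_
  grid$detection <- NA_real_
  grid$reps <- as.integer(reps)
  comp <- c(1 - 3 * error_rate, rep(error_rate, 3L))
  for (i in seq_len(nrow(grid))) {
    alpha <- grid$concentration[i] * comp
    controls <- rdirmult(n_controls, rpois(n_controls, grid$depth[i]), alpha)
    null <- fit_null(controls)
    if (!null$converged) next
    null_draws <- rdirmult(reps, grid$depth[i], alpha)
    lbf0 <- log_bayes_factor(null_draws, null)
    hit0 <- lbf0 >= thresholds$min_log_bf &
      rowSums(null_draws) >= thresholds$min_depth
    grid$fpr[i] <- mean(hit0)
    if (grid$vaf[i] > 0) {
      g <- matrix(rgamma(reps * 4L, shape = rep(alpha, each = reps)),
                  nrow = reps)
      p_err <- g / rowSums(g)
      e_alt <- c(0, 1, 0, 0)  # spike the first non-reference base
      p <- (1 - grid$vaf[i]) * p_err +
        grid$vaf[i] * matrix(e_alt, reps, 4L, byrow = TRUE)
      spiked <- t(vapply(seq_len(reps), function(j)
        as.integer(rmultinom(1L, grid$depth[i], p[j, ])), integer(4L)))
      lbf1 <- log_bayes_factor(spiked, null)
      grid$detection[i] <- mean(lbf1 >= thresholds$min_log_bf &
                                  rowSums(spiked) >= thresholds$min_depth)
    }
  }
  class(grid) <- c("calibration_result", "data.frame")
  grid
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Bayes-factor caller operating characteristics\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
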