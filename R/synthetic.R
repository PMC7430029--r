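## Synthetic-data generators: everything the pipeline consumes can be
## produced here under a fixed seed — amplicon panels, aligned-read fixtures
## with known filter outcomes, overdispersed allele-count tables with
## spike-in variants and their ground truth, population-frequency tables, and
## censored two-group survival cohorts.

## deterministic pseudo-reference base at a position
.ref_base <- function(pos) BASES[(pos %% 4L) + 1L]

#' Simulation configuration for count-table generation
#'
#' Defines the study conditions emulated by [simulate_count_tables()]:
#' per-locus filtered depths are Poisson around `depth_mean` (defaults to
#' 3200, the order of the mean filtered target-region coverage in deep
#' TAm-Seq data), and sequencing error is Dirichlet-Multinomial with
#' reference-oriented hyperparameter `error_alpha` — the first component
#' belongs to the reference allele, the remaining three to the non-reference
#' bases in A<C<G<T order. The default
#' `error_alpha = 4000 * (0.997, 0.001, 0.001, 0.001)` gives a mean
#' per-allele error fraction of 0.1% with substantial overdispersion
#' (concentration 4000), the regime in which a Bayes-factor caller is
#' interesting.
#'
#' @param seed Integer seed; the generator is a pure function of the config.
#' @param n_control_samples,n_case_samples Cohort sizes.
#' @param n_loci Number of target loci (placed on chr17, 50 bp apart).
#' @param depth_mean Expected filtered depth per sample-locus.
#' @param error_alpha Positive length-4 vector (shared across loci) or
#'   `n_loci` x 4 matrix of per-locus hyperparameters, reference-oriented.
#' @param spike_ins data.frame of true somatic variants to inject into case
#'   samples: columns `sample` (case index or `case_XX` id), `locus` (locus
#'   index), `vaf` in (0,1), and optionally `alt` (defaults to the first
#'   non-reference base).
#' @param pop_af data.frame (`locus` index, `alt`, `af`) describing entries
#'   of the population allele-frequency table, or NULL.
#' @return A validated `sim_config` list (loci and sample ids materialised).
#' @export
sim_config <- function(seed = 1L, n_control_samples = 30L, n_case_samples = 30L,
                       n_loci = 10L, depth_mean = 3200,
                       error_alpha = 4000 * c(0.997, 0.001, 0.001, 0.001),
                       spike_ins = NULL, pop_af = NULL) {
  if (depth_mean < 0) stop("'depth_mean' must be non-negative")
  if (n_control_samples < 0 || n_case_samples < 0 || n_loci < 1)
    stop("sample and locus counts must be non-negative (>= 1 locus)")
  alpha <- if (is.matrix(error_alpha)) error_alpha else
    matrix(error_alpha, nrow = n_loci, ncol = 4L, byrow = TRUE)
  if (nrow(alpha) != n_loci || ncol(alpha) != 4L)
    stop("'error_alpha' must be a 4-vector or an n_loci x 4 matrix")
  if (any(!is.finite(alpha)) || any(alpha <= 0))
    stop("'error_alpha' must be strictly positive componentwise")
  pos <- 7572000L + 50L * (seq_len(n_loci) - 1L)
  loci <- data.frame(chrom = "chr17", pos = pos,
                     ref = .ref_base(pos), stringsAsFactors = FALSE)
  control_ids <- sprintf("control_%02d", seq_len(n_control_samples))
  case_ids <- sprintf("case_%02d", seq_len(n_case_samples))
  if (!is.null(spike_ins)) {
    spike_ins <- as.data.frame(spike_ins)
    if (!all(c("sample", "locus", "vaf") %in% names(spike_ins)))
      stop("'spike_ins' needs columns sample, locus, vaf")
    if (is.numeric(spike_ins$sample)) {
      bad <- spike_ins$sample < 1 | spike_ins$sample > n_case_samples
      if (any(bad))
        stop("spike-in references case sample out of range: record(s) ",
             paste(which(bad), collapse = ", "))
      spike_ins$sample_id <- case_ids[spike_ins$sample]
    } else {
      spike_ins$sample_id <- as.character(spike_ins$sample)
      bad <- !spike_ins$sample_id %in% case_ids
      if (any(bad))
        stop("spike-in references unknown case sample: ",
             paste(spike_ins$sample_id[bad], collapse = ", "))
    }
    bad <- spike_ins$locus < 1 | spike_ins$locus > n_loci
    if (any(bad))
      stop("spike-in references unknown locus: record(s) ",
           paste(which(bad), collapse = ", "))
    if (any(spike_ins$vaf <= 0 | spike_ins$vaf >= 1))
      stop("spike-in target VAF must lie in (0, 1)")
    ref <- loci$ref[spike_ins$locus]
    if (is.null(spike_ins$alt)) {
      spike_ins$alt <- vapply(ref, function(r) setdiff(BASES, r)[1L], "")
    }
    if (any(spike_ins$alt == ref))
      stop("spike-in alt allele equals the reference at its locus: record(s) ",
           paste(which(spike_ins$alt == ref), collapse = ", "))
  }
  pop_table <- NULL
  if (!is.null(pop_af)) {
    pop_af <- as.data.frame(pop_af)
    if (any(pop_af$locus < 1 | pop_af$locus > n_loci))
      stop("population-frequency entry references unknown locus")
    pop_table <- data.frame(
      chrom = loci$chrom[pop_af$locus], pos = loci$pos[pop_af$locus],
      ref = loci$ref[pop_af$locus], alt = pop_af$alt, af = pop_af$af,
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(seed = as.integer(seed), n_control_samples = n_control_samples,
         n_case_samples = n_case_samples, n_loci = n_loci,
         depth_mean = depth_mean, error_alpha = alpha, loci = loci,
         control_ids = control_ids, case_ids = case_ids,
         spike_ins = spike_ins, pop_table = pop_table),
    class = "sim_config"
  )
}

## rotate a reference-oriented alpha (ref, then non-ref in base order) into
## absolute A,C,G,T order for a given reference allele
.orient_alpha <- function(alpha_ref_first, ref) {
  out <- numeric(4L)
  names(out) <- BASES
  out[ref] <- alpha_ref_first[1L]
  out[setdiff(BASES, ref)] <- alpha_ref_first[-1L]
  out
}

#' Simulate control and case allele-count tables with ground truth
#'
#' Control counts are Dirichlet-Multinomial draws from the per-locus error
#' model at Poisson depths. Case counts are generated identically, except at
#' spiked sample-loci, where the base-composition vector is the mixture
#' `(1 - vaf) * (Dirichlet error draw) + vaf * (point mass on alt)` before the
#' multinomial draw, so the error model is preserved off the spiked allele.
#' A truth table records every spike-in with its realised alt count and depth.
#'
#' @param config A [sim_config()].
#' @return List with `controls` and `cases` (long count tables:
#'   `sample_id`, `chrom`, `pos`, `ref`, `count_A`..`count_T`, `depth`),
#'   `truth` (one row per spike-in), `loci`, and `pop_table`.
#' @export
simulate_count_tables <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  loci <- config$loci

  draw_table <- function(ids) {
    rows <- vector("list", config$n_loci)
    for (l in seq_len(config$n_loci)) {
      alpha <- .orient_alpha(config$error_alpha[l, ], loci$ref[l])
      depth <- rpois(length(ids), config$depth_mean)
      cnt <- rdirmult(length(ids), depth, alpha)
      rows[[l]] <- data.frame(
        sample_id = ids, chrom = loci$chrom[l], pos = loci$pos[l],
        ref = loci$ref[l],
        count_A = cnt[, "A"], count_C = cnt[, "C"],
        count_G = cnt[, "G"], count_T = cnt[, "T"],
        depth = rowSums(cnt), stringsAsFactors = FALSE
      )
    }
    df <- do.call(rbind, rows)
    df[order(df$sample_id, df$chrom, df$pos), , drop = FALSE]
  }

  controls <- if (config$n_control_samples > 0)
    draw_table(config$control_ids) else NULL
  cases <- if (config$n_case_samples > 0)
    draw_table(config$case_ids) else NULL

  truth <- NULL
  sp <- config$spike_ins
  if (!is.null(sp) && nrow(sp) > 0) {
    truth <- vector("list", nrow(sp))
    for (i in seq_len(nrow(sp))) {
      l <- sp$locus[i]
      ref <- loci$ref[l]
      alpha <- .orient_alpha(config$error_alpha[l, ], ref)
      row <- which(cases$sample_id == sp$sample_id[i] &
                     cases$pos == loci$pos[l])
      depth <- rpois(1L, config$depth_mean)
      g <- rgamma(4L, shape = alpha)
      p_err <- g / sum(g)
      e_alt <- as.numeric(BASES == sp$alt[i])
      p <- (1 - sp$vaf[i]) * p_err + sp$vaf[i] * e_alt
      cnt <- as.integer(rmultinom(1L, depth, p))
      cases[row, paste0("count_", BASES)] <- as.list(cnt)
      cases$depth[row] <- sum(cnt)
      truth[[i]] <- data.frame(
        sample_id = sp$sample_id[i], chrom = loci$chrom[l], pos = loci$pos[l],
        ref = ref, alt = sp$alt[i], target_vaf = sp$vaf[i],
        realized_alt_count = cnt[match(sp$alt[i], BASES)],
        realized_depth = sum(cnt), stringsAsFactors = FALSE
      )
    }
    truth <- do.call(rbind, truth)
  }

  list(controls = controls, cases = cases, truth = truth,
       loci = loci, pop_table = config$pop_table)
}

#' Simulate aligned reads realising exact filter-relevant properties
#'
#' Emits one read per specification row, realising the requested alignment
#' length, amplicon-overlap fraction and edit distance exactly, with the read
#' placed so that it overhangs its amplicon when the alignment is longer than
#' the intended overlap. A companion expectation record states, per read,
#' whether it must survive the default filters and for which reasons it
#' fails — the oracle for filter tests.
#'
#' The reference is a deterministic pseudo-sequence (base = position mod 4),
#' so reads, loci and counts are mutually consistent without a genome file.
#'
#' @param amplicons Amplicon data.frame (`amplicon_id`, `chrom`, `start`,
#'   `end`, 0-based half-open).
#' @param specs data.frame with one row per read: `amplicon_id`,
#'   `alignment_length`, `overlap` (fraction of the amplicon), `nm`
#'   (edit distance), and optionally `call_pos` (1-based locus) + `call_base`
#'   (the base the read reports there), `sample_id`, `read_id`.
#' @param min_align_len,min_overlap,max_nm Thresholds used for the
#'   expectation record (defaults are the standard 75 / 0.75 / 2).
#' @return List with `reads` (the TSV-dialect read data.frame) and
#'   `expectations` (`read_id`, `expected_pass`, `expected_reasons`).
#' @export
simulate_read_set <- function(amplicons, specs, min_align_len = 75,
                              min_overlap = 0.75, max_nm = 2) {
  specs <- as.data.frame(specs)
  need <- c("amplicon_id", "alignment_length", "overlap", "nm")
  if (!all(need %in% names(specs)))
    stop("'specs' needs columns: ", paste(need, collapse = ", "))
  if (is.null(specs$read_id))
    specs$read_id <- sprintf("read_%03d", seq_len(nrow(specs)))
  if (is.null(specs$sample_id)) specs$sample_id <- "sample_1"
  reads <- vector("list", nrow(specs))
  expect <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    a <- amplicons[amplicons$amplicon_id == specs$amplicon_id[i], , drop = FALSE]
    if (nrow(a) != 1L) stop("unknown amplicon_id: ", specs$amplicon_id[i])
    L <- a$end - a$start
    len <- specs$alignment_length[i]
    ov <- as.integer(round(specs$overlap[i] * L))
    if (ov > len)
      stop("spec row ", i, " is geometrically impossible: intended overlap (",
           ov, " bp) exceeds the alignment length (", len, " bp)")
    if (ov > L) stop("spec row ", i, ": overlap exceeds the amplicon length")
    if (specs$nm[i] > len) stop("spec row ", i, ": edit distance exceeds read length")
    ## place the read so it covers the first `ov` bases of the amplicon and
    ## overhangs to the left with the remainder
    align_start <- a$start - (len - ov)
    align_end <- align_start + len
    pos1 <- align_start + 1L
    ref_seq <- .ref_base(seq.int(pos1, align_end))
    seq <- ref_seq
    nm_left <- specs$nm[i]
    call_pos <- if (!is.null(specs$call_pos)) specs$call_pos[i] else NA
    if (!is.na(call_pos)) {
      if (call_pos < pos1 || call_pos > align_end)
        stop("spec row ", i, ": call_pos outside the aligned span")
      off <- call_pos - pos1 + 1L
      cb <- specs$call_base[i]
      if (cb != ref_seq[off]) {
        if (nm_left < 1L)
          stop("spec row ", i, ": non-reference call_base needs nm >= 1")
        nm_left <- nm_left - 1L
      }
      seq[off] <- cb
    }
    if (nm_left > 0L) {
      ## deterministic mismatch positions away from the call position
      cand <- setdiff(seq_len(len),
                      if (is.na(call_pos)) integer(0) else call_pos - pos1 + 1L)
      mut <- cand[seq_len(nm_left)]
      seq[mut] <- vapply(seq[mut], function(b) setdiff(BASES, b)[1L], "")
    }
    reads[[i]] <- data.frame(
      read_id = specs$read_id[i], sample_id = specs$sample_id[i],
      chrom = a$chrom, pos = pos1, mapq = 60L, flag = 0L,
      cigar = sprintf("%dM", len), seq = paste(seq, collapse = ""),
      nm = specs$nm[i], stringsAsFactors = FALSE
    )
    fails <- c(
      if (len < min_align_len) "min_align_len",
      if (ov / L < min_overlap) "min_overlap",
      if (specs$nm[i] > max_nm) "edit_distance"
    )
    expect[[i]] <- data.frame(
      read_id = specs$read_id[i],
      expected_pass = length(fails) == 0L,
      expected_reasons = paste(fails, collapse = ","),
      stringsAsFactors = FALSE
    )
  }
  reads <- .finish_reads(do.call(rbind, reads))
  list(reads = reads, expectations = do.call(rbind, expect))
}

#' Write reads as a SAM file
#'
#' Emits a minimal valid SAM (header with `@SQ` lines sized past the last
#' alignment, `NM` tags, `*` quality) so the filter stage can be exercised
#' through a genuine SAM parser as well as the TSV dialect.
#'
#' @param reads Read data.frame (TSV dialect).
#' @param path Output `.sam` path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path) {
  chroms <- sort(unique(reads$chrom))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (ch in chroms) {
    ln <- max(reads$align_end[reads$chrom == ch]) + 1000L
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", ch, ln), con)
  }
  writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t*\tNM:i:%d",
                     reads$read_id, reads$flag, reads$chrom, reads$pos,
                     reads$mapq, reads$cigar, reads$seq, reads$nm), con)
  invisible(path)
}

#' Write reads in the tabular read dialect
#' @param reads Read data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_reads_tsv <- function(reads, path) {
  write.table(reads[.read_cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Simulate a censored two-group survival cohort
#'
#' Event times are exponential with the group hazard; times beyond
#' `censor_time` are administratively censored at `censor_time`.
#'
#' @param n_per_group Subjects per group (length 1 or 2).
#' @param hazards Positive event hazards (per year), one per group.
#' @param censor_time Administrative censoring horizon in years.
#' @param seed Integer seed.
#' @param groups Group labels (default ctDNA_positive / ctDNA_negative).
#' @return data.frame `subject_id`, `time_years`, `event` (0/1), `group`.
#' @export
simulate_survival_cohort <- function(n_per_group, hazards, censor_time,
                                     seed = 1L,
                                     groups = c("ctDNA_positive",
                                                "ctDNA_negative")) {
  if (any(hazards <= 0)) stop("hazards must be strictly positive")
  if (censor_time < 0) stop("'censor_time' must be non-negative")
  n_per_group <- rep_len(n_per_group, 2L)
  set.seed(seed)
  out <- lapply(1:2, function(g) {
    t_event <- rexp(n_per_group[g], rate = hazards[g])
    data.frame(
      subject_id = sprintf("%s_%04d", groups[g], seq_len(n_per_group[g])),
      time_years = pmin(t_event, censor_time),
      event = as.integer(t_event <= censor_time),
      group = groups[g],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
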