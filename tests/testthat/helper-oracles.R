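# all compositions of n into four non-negative parts (enumeration oracle)
compositions4 <- function(n) {
  m <- as.matrix(expand.grid(A = 0:n, C = 0:n, G = 0:n, T = 0:n))
  m[rowSums(m) == n, , drop = FALSE]
}

# two toy amplicons: 100 bp and 60 bp, on the synthetic chr17 reference
toy_amplicons <- function() {
  data.frame(
    amplicon_id = c("amp100", "amp60"),
    chrom = "chr17",
    start = c(1000L, 2000L),
    end = c(1100L, 2060L),
    stringsAsFactors = FALSE
  )
}

# naive per-event-time logrank oracle (literal hypergeometric sums)
naive_logrank <- function(time, event, group) {
  g <- factor(group)
  l1 <- levels(g)[1L]
  et <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in et) {
    n <- sum(time >= t)
    n1 <- sum(time >= t & g == l1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == l1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(O1 = O1, E1 = E1, V = V, chisq = (O1 - E1)^2 / V)
}

# random small survival cohort for reference cross-checks
random_cohort <- function(n, seed) {
  set.seed(seed)
  data.frame(
    time = round(rexp(n, 0.3), 2) + 0.01,
    event = rbinom(n, 1, 0.7),
    group = sample(c("g1", "g2"), n, replace = TRUE)
  )
}
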