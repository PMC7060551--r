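# Independent brute-force oracles used to cross-check the implementation.
# These stay deliberately naive and share no code with the package.

# step-up FDR adjustment, written directly from the definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# exhaustive hypergeometric upper tail: enumerate every size-n draw from
# an urn of N peaks of which K carry the cluster
hyper_oracle <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  mean(apply(draws, 2, function(d) sum(d %in% marked) >= k))
}

# all-pairs interval overlap scan (half-open semantics); every a-row is
# compared against every b-row
brute_overlap <- function(a, b) {
  res <- lapply(seq_len(nrow(a)), function(i) {
    hit <- which(a$chrom[i] == b$chrom &
                 a$start[i] < b$end & b$start < a$end[i])
    if (length(hit) == 0L) return(NULL)
    data.frame(a_id = a$name[i], b_id = b$name[hit],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(a_id = character(0), b_id = character(0))
  out
}

# brute-force membership counting of width-1 sites in peaks
brute_count <- function(sites, peaks) {
  vapply(seq_len(nrow(peaks)), function(i)
    sum(sites$chrom == peaks$chrom[i] &
        sites$start >= peaks$start[i] & sites$start < peaks$end[i]),
    numeric(1))
}

# textbook two-group log-rank statistic: sum of O - E over event times,
# squared and divided by the hypergeometric variance
logrank_oracle <- function(groups, time, event) {
  g1 <- groups == levels(factor(groups))[1]
  times <- sort(unique(time[event == 1]))
  OmE <- 0; V <- 0
  for (t in times) {
    at_risk <- time >= t
    n_i <- sum(at_risk); n1 <- sum(at_risk & g1)
    d_i <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g1)
    OmE <- OmE + d1 - d_i * n1 / n_i
    if (n_i > 1)
      V <- V + d_i * (n1 / n_i) * (1 - n1 / n_i) * (n_i - d_i) / (n_i - 1)
  }
  OmE^2 / V
}

# random PeakSet on a toy chromosome (may overlap)
random_peaks <- function(n, chrom = "chrT", max_pos = 100000L, prefix = "p") {
  start <- sample.int(max_pos, n, replace = TRUE)
  width <- sample(10:500, n, replace = TRUE)
  peak_set(rep(chrom, n), start, start + width,
           name = sprintf("%s%04d", prefix, seq_len(n)))
}
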