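# Shared fixtures and independent reference implementations (oracles).

tiny_genome <- function() genome_def(c("chr1", "chr2"), c(1e6, 5e5))

# literal BH step-up, written directly from the definition:
# q(i) = min_{j: rank >= rank(i)} m * p_(j) / j, capped at 1
bh_reference <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    ri <- which(o == i)          # rank of p[i]
    cand <- vapply(ri:m, function(j) m * p[o[j]] / j, 0)
    q[i] <- min(c(cand, 1))
  }
  q
}

# brute-force NB upper tail by term summation
nb_tail_brute <- function(k, mu, alpha, terms = 1e6) {
  if (k <= 0) return(1)
  size <- 1 / alpha
  prob <- size / (size + mu)
  j <- seq(k, k + terms)
  sum(exp(lgamma(j + size) - lgamma(size) - lfactorial(j) +
            size * log(prob) + j * log(1 - prob)))
}

# brute-force Poisson upper tail
pois_tail_brute <- function(k, mu, terms = 1000) {
  if (k <= 0) return(1)
  j <- seq(k, k + terms)
  sum(exp(-mu + j * log(mu) - lfactorial(j)))
}

# brute-force binomial upper tail
binom_tail_brute <- function(k, n, p) {
  if (k <= 0) return(1)
  sum(vapply(k:n, function(j) stats::dbinom(j, n, p), 0))
}

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# small rearrangement set builder
make_rearrs <- function(chrom1, pos1, chrom2, pos2, sample,
                        genome = tiny_genome(), ...) {
  rearrangements(chrom1, pos1, chrom2, pos2, sample, genome = genome, ...)
}
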