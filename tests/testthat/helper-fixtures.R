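# Shared builders for the test suite. All fixtures are built in code.

# Toy PSSM frequency matrix: the given consensus base gets f at every
# position, the other three bases share the remainder equally.
toy_matrix <- function(consensus, f = 0.85) {
  bases <- c("A", "C", "G", "T")
  rows <- t(vapply(strsplit(consensus, "")[[1]], function(b) {
    x <- rep((1 - f) / 3, 4)
    names(x) <- bases
    x[b] <- f
    x
  }, numeric(4)))
  rownames(rows) <- NULL
  frequency_matrix(rows)
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

all_kmers <- function(k) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                              stringsAsFactors = FALSE))
}

# Random antisense isoform pair on a shared chromosome (for overlap
# properties); spans drawn on [1, 500].
random_antisense_pair <- function() {
  s1 <- sort(sample(500, 2)); s2 <- sort(sample(500, 2))
  a <- transcript_isoform("gA", "gA-1", "chr", s1[1], s1[2], "+",
                          stop_codon_last_base = s1[1],
                          cleavage_site = s1[2])
  b <- transcript_isoform("gB", "gB-1", "chr", s2[1], s2[2], "-",
                          stop_codon_last_base = s2[2],
                          cleavage_site = s2[1])
  list(a = a, b = b)
}

# Independent per-base overlap count (oracle for antisense_overlap).
brute_force_overlap <- function(isoA, isoB) {
  sum(seq(isoA$start, isoA$end) %in% seq(isoB$start, isoB$end))
}

# Exact two-sided permutation p-value for a difference in means, n small.
permutation_p <- function(a, b) {
  x <- c(a, b)
  n <- length(a)
  obs <- abs(mean(a) - mean(b))
  combs <- utils::combn(length(x), n)
  stats <- apply(combs, 2, function(idx)
    abs(mean(x[idx]) - mean(x[-idx])))
  mean(stats >= obs - 1e-12)
}

# Exact two-sided Mann-Whitney p by enumeration of group assignments.
enumerate_mw_p <- function(a, b) {
  x <- c(a, b)
  n <- length(a)
  r <- rank(x)
  obs <- sum(r[seq_len(n)])
  combs <- utils::combn(length(x), n)
  sums <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- n * (length(x) + 1) / 2
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-12)
}
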