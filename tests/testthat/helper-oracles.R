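# Independent oracles and small fixture builders shared across tests.

# Brute-force upper-tail hypergeometric by enumerating every n-subset of
# the universe and counting those overlapping the term by >= k.
hypergeom_tail_enum <- function(k, K, n, N) {
  term <- seq_len(K)
  draws <- utils::combn(N, n)
  hit <- apply(draws, 2L, function(d) sum(d %in% term) >= k)
  mean(hit)
}

# Hand-applied Benjamini-Hochberg step-up: sort, scale by m/rank, take
# cumulative minima from the largest rank down, cap at 1, restore order.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  scaled <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  pmin(adj, 1)[order(ord)]
}

# Position-by-position naive IUPAC scanner (single strand).
iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

naive_scan_one_strand <- function(seq_chr, consensus) {
  sq <- strsplit(toupper(seq_chr), "")[[1]]
  cs <- strsplit(toupper(consensus), "")[[1]]
  L <- length(cs)
  starts <- integer(0)
  if (length(sq) >= L) {
    for (i in seq_len(length(sq) - L + 1L)) {
      ok <- TRUE
      for (j in seq_len(L)) {
        if (!sq[i + j - 1L] %in% iupac_sets[[cs[j]]]) {
          ok <- FALSE
          break
        }
      }
      if (ok) starts <- c(starts, i)
    }
  }
  starts
}

revcomp_chr <- function(x) {
  map <- c(
    A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
    W = "W", K = "M", M = "K", B = "V", D = "H", H = "D", V = "B", N = "N"
  )
  paste(rev(map[strsplit(toupper(x), "")[[1]]]), collapse = "")
}

# Both-strand naive scan returning a start/strand data.frame in the
# package's reporting convention (minus hits at the leftmost plus-strand
# base of the match).
naive_scan <- function(seq_chr, consensus) {
  plus <- naive_scan_one_strand(seq_chr, consensus)
  minus <- naive_scan_one_strand(seq_chr, revcomp_chr(consensus))
  rbind(
    if (length(plus)) data.frame(start = plus, strand = "+"),
    if (length(minus)) data.frame(start = minus, strand = "-")
  )
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Tiny expression fixture: known means, no randomness.
fixed_expression <- function() {
  mat <- rbind(
    up = c(1, 1, 2.26, 2.26),
    down = c(56.83, 56.83, 1, 1),
    flat = c(3, 3, 3, 3)
  )
  colnames(mat) <- c("c1", "c2", "t1", "t2")
  expression_matrix(
    mat,
    c(c1 = "control", c2 = "control", t1 = "treated", t2 = "treated")
  )
}
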