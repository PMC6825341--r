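# Independent brute-force oracles. These deliberately use the plainest
# possible double-loop formulations so they stay independent of the
# vectorized implementation paths they check.

# Nf: direct transcription of the effective-sequence-count formula.
oracle_nf <- function(seqs, threshold = 0.8) {
  n <- length(seqs)
  L <- nchar(seqs[[1]])
  rows <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  ident <- function(a, b) {
    both <- which(a != "-" & b != "-")
    if (length(both) == 0) return(0)
    sum(a[both] == b[both]) / length(both)
  }
  total <- 0
  for (i in seq_len(n)) {
    similar <- 0
    for (j in seq_len(n)) {
      if (j != i && ident(rows[[i]], rows[[j]]) >= threshold) {
        similar <- similar + 1
      }
    }
    total <- total + 1 / (1 + similar)
  }
  total / sqrt(L)
}

# Greedy redundancy filter: quadratic scan in input order.
oracle_redundancy <- function(ids, seqs, query_id, max_id, min_cov) {
  rows <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  names(rows) <- ids
  q <- rows[[query_id]]
  qcols <- which(q != "-")
  keep_ids <- character(0)
  order_ids <- c(query_id, setdiff(ids, query_id))
  for (id in order_ids) {
    r <- rows[[id]]
    cov <- mean(r[qcols] != "-")
    if (id != query_id && cov < min_cov) next
    ok <- TRUE
    for (kid in keep_ids) {
      k <- rows[[kid]]
      both <- which(r != "-" & k != "-")
      idn <- if (length(both) == 0) 0 else sum(r[both] == k[both]) / length(both)
      if (idn >= max_id) { ok <- FALSE; break }
    }
    if (ok) keep_ids <- c(keep_ids, id)
  }
  keep_ids
}

# Exhaustive neighbor-count clustering at a fixed cutoff.
oracle_cluster <- function(dm, cutoff, max_clusters = 5) {
  remaining <- seq_len(nrow(dm))
  out <- list()
  while (length(remaining) > 0 && length(out) < max_clusters) {
    counts <- sapply(remaining, function(i) {
      sum(dm[i, remaining] <= cutoff) - 1
    })
    seed <- remaining[which.max(counts)]
    members <- remaining[dm[seed, remaining] <= cutoff]
    out[[length(out) + 1]] <- list(seed = seed, members = sort(members))
    remaining <- setdiff(remaining, members)
  }
  out
}

# Random valid-geometry decoy: perturbed toy structure.
random_decoy <- function(base, sd = 1.5) {
  ca <- base$ca + matrix(rnorm(length(base$ca), 0, sd), ncol = 3)
  chain_conformation(ca, base$sequence)
}

random_msa <- function(n, L, gap_prob = 0.1, n_letters = 4) {
  letters_pool <- c("A", "C", "D", "E", "F", "G")[seq_len(n_letters)]
  seqs <- replicate(n, {
    chars <- sample(letters_pool, L, replace = TRUE)
    gaps <- runif(L) < gap_prob
    chars[gaps] <- "-"
    paste(chars, collapse = "")
  })
  # keep the query fully ungapped so coverage is well defined
  seqs[1] <- paste(sample(letters_pool, L, replace = TRUE), collapse = "")
  aligned_set(paste0("s", seq_len(n)), seqs, query_id = "s1")
}
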