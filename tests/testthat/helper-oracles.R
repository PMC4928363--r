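# Independent reference implementations used as oracles. These share no
# code with the package internals they check.

# Brute-force counterpart of greedy overlap resolution: enumerate every
# conflict-free subset of candidates and pick the one whose membership
# is lexicographically greatest under the greedy ranking (ascending
# E-value, then descending bit score, then ascending start) — which is
# the set the take-unless-conflicting greedy must select.
oracle_resolve <- function(d, tol) {
  n <- nrow(d)
  rank_ord <- order(d$evalue, -d$bitscore, d$start)
  conflict <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ov <- max(0L, min(d$end[i], d$end[j]) - max(d$start[i], d$start[j]) + 1L)
    len_i <- d$end[i] - d$start[i] + 1L
    len_j <- d$end[j] - d$start[j] + 1L
    conflict[i, j] <- ov > tol * min(len_i, len_j)
  }
  best_key <- ""
  best_members <- integer(0)
  for (mask in 0:(2^n - 1)) {
    members <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(members) > 1L && any(conflict[members, members])) next
    key <- paste(as.integer(rank_ord %in% members), collapse = "")
    if (key > best_key) {
      best_key <- key
      best_members <- members
    }
  }
  sort(best_members)
}

# Direct double-loop Bray-Curtis
oracle_bray <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    num <- sum(abs(m[i, ] - m[j, ]))
    den <- sum(m[i, ] + m[j, ])
    d[i, j] <- if (den == 0) 0 else num / den
  }
  d
}

# Quadratic-time unweighted average-linkage (UPGMA) reference: returns
# the sorted sequence of merge heights. Cluster-to-cluster distance is
# the mean of all member-pair distances.
oracle_upgma_heights <- function(dm) {
  m <- as.matrix(dm)
  clusters <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dd <- mean(m[clusters[[i]], clusters[[j]]])
      if (dd < best_d) { best_d <- dd; best <- c(i, j) }
    }
    heights <- c(heights, best_d)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  sort(heights)
}

# All permutations of 1:n (for exhaustive Mantel enumeration)
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# Exhaustive one-sided Mantel p over every relabeling (identity
# included in the permutation set, add-one convention matching the
# package's definition with n_perm = nrow(perms)).
oracle_mantel_exact <- function(m1, m2, perms) {
  lt <- lower.tri(m1)
  v1 <- m1[lt]
  r_obs <- cor(v1, m2[lt])
  r_all <- apply(perms, 1L, function(p) cor(v1, m2[p, p][lt]))
  list(r = r_obs, p = (1 + sum(r_all >= r_obs)) / (1 + nrow(perms)))
}

# Random valid raw hits for property tests
random_hits <- function(n, seed = 1) {
  set.seed(seed)
  plen <- sample(100:400, n, replace = TRUE)
  hto <- vapply(plen, function(p) sample.int(p, 1L), integer(1L))
  hfrom <- vapply(hto, function(h) sample.int(h, 1L), integer(1L))
  from <- sample(1:500, n, replace = TRUE)
  len <- sample(30:200, n, replace = TRUE)
  data.frame(
    protein_id = paste0("GX|P", seq_len(n)), genome_id = "GX",
    pfam_accession = sample(c("PF00150", "PF00704", "PF00942", "PF99999"),
                            n, replace = TRUE),
    pfam_name = "x", profile_length = plen,
    seq_evalue = 10^runif(n, -30, 0), dom_ievalue = 10^runif(n, -30, 0),
    bitscore = round(runif(n, 1, 300), 1),
    hmm_from = hfrom, hmm_to = hto,
    ali_from = from, ali_to = from + len,
    env_from = from, env_to = from + len,
    stringsAsFactors = FALSE)
}

# Minimal taxonomy for a set of genome ids, one genus
toy_taxonomy <- function(genome_ids, genus = "Testus") {
  data.frame(genome_id = genome_ids, genus = genus, species = "toyi",
             strain = paste0("s", seq_along(genome_ids)),
             stringsAsFactors = FALSE)
}
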