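# Brute-force reference implementations, kept deliberately naive and
# independent of the package's code paths.

oracle_jaccard <- function(a, b) {
  u <- length(unique(c(a, b)))
  if (u == 0) return(0)
  sum(unique(a) %in% unique(b)) / u
}

oracle_jaccard_matrix <- function(sets) {
  k <- length(sets)
  m <- matrix(0, k, k, dimnames = list(names(sets), names(sets)))
  for (i in 1:k) for (j in 1:k) m[i, j] <- oracle_jaccard(sets[[i]], sets[[j]])
  m
}

oracle_cumulative <- function(sets) {
  universe <- unique(unlist(sets))
  k <- length(sets)
  vapply(seq_len(k), function(l) {
    hits <- vapply(universe, function(e) {
      sum(vapply(sets, function(s) e %in% s, logical(1))) >= l
    }, logical(1))
    sum(hits) / length(universe)
  }, numeric(1))
}

# exhaustive scan of the LD table per (snp, population, partner) triple
oracle_ld_support <- function(sets, ld_df, r2_min = 0.5, max_dist = 500000) {
  all_snps <- sort(unique(unlist(sets)))
  out <- list()
  for (s in all_snps) {
    partners <- s
    if (nrow(ld_df) > 0) {
      for (r in seq_len(nrow(ld_df))) {
        ok <- ld_df$r2[r] >= r2_min && ld_df$dist_bp[r] <= max_dist
        if (ok && ld_df$snp_a[r] == s) partners <- c(partners, ld_df$snp_b[r])
        if (ok && ld_df$snp_b[r] == s) partners <- c(partners, ld_df$snp_a[r])
      }
    }
    codes <- character(0)
    for (code in names(sets)) {
      if (any(partners %in% sets[[code]])) codes <- c(codes, code)
    }
    out[[s]] <- codes
  }
  out
}

# all-pairs containment scan: SNP (1-based) inside ROI [s, e) (0-based)
oracle_snp_gene_map <- function(pop_snps, models) {
  out <- list()
  for (code in names(pop_snps)) {
    snps <- pop_snps[[code]]
    genes <- character(0)
    for (r in seq_len(nrow(snps))) {
      for (g in seq_len(nrow(models))) {
        if (snps$chrom[r] == models$chrom[g] &&
            models$roi_start[g] <= snps$pos[r] - 1 &&
            snps$pos[r] - 1 < models$roi_end[g]) {
          genes <- c(genes, models$symbol[g])
        }
      }
    }
    out[[code]] <- sort(unique(genes))
  }
  out
}

# union-find over an explicit edge list
oracle_components <- function(ids, edges) {
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  if (!is.null(edges) && nrow(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      ra <- find(edges[r, 1]); rb <- find(edges[r, 2])
      if (ra != rb) parent[[ra]] <- rb
    }
  }
  roots <- vapply(ids, find, character(1))
  unname(lapply(split(ids, roots), function(m) sort(m)))
}

# sum of the hypergeometric pmf over the upper tail via choose()
oracle_hyper_tail <- function(N, K, n, x) {
  xs <- x:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# classic BH step-up rejection set at level alpha
oracle_bh_reject <- function(p, alpha) {
  n <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  below <- which(sorted <= (seq_len(n) / n) * alpha)
  if (length(below) == 0) return(integer(0))
  sort(ord[seq_len(max(below))])
}

# naive average-linkage agglomeration; returns the cophenetic matrix
oracle_upgma_cophenetic <- function(d) {
  labels <- rownames(d)
  clusters <- as.list(labels)
  coph <- matrix(0, nrow(d), ncol(d), dimnames = dimnames(d))
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        dd <- mean(d[clusters[[i]], clusters[[j]], drop = FALSE])
        if (dd < best_d) {
          best_d <- dd
          best <- c(i, j)
        }
      }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- best_d
    coph[b, a] <- best_d
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  coph
}

# enumerate every one-gene-per-locus combination
oracle_best_selection <- function(candidates, network) {
  grid <- expand.grid(candidates, stringsAsFactors = FALSE)
  scores <- apply(grid, 1, function(sel) {
    genes <- as.character(sel)
    s <- 0
    for (i in seq_along(genes)) {
      for (j in seq_along(genes)) {
        if (i >= j || genes[i] == genes[j]) next
        hit <- (network$gene_a == pmin(genes[i], genes[j]) &
                  network$gene_b == pmax(genes[i], genes[j]))
        if (any(hit)) s <- s + network$weight[hit]
      }
    }
    s
  })
  list(score = max(scores),
       selection = as.character(unlist(grid[which.max(scores), ])))
}

random_entity_sets <- function(k, pool_size, max_size) {
  pool <- sprintf("e%03d", seq_len(pool_size))
  sets <- lapply(seq_len(k), function(i) {
    sample(pool, sample.int(min(max_size, pool_size), 1))
  })
  names(sets) <- LETTERS[seq_len(k)]
  sets
}

random_ld_df <- function(snp_ids, n_pairs) {
  if (n_pairs == 0 || length(snp_ids) < 2) {
    return(data.frame(snp_a = character(), snp_b = character(),
                      r2 = numeric(), dist_bp = integer()))
  }
  a <- sample(snp_ids, n_pairs, replace = TRUE)
  b <- sample(snp_ids, n_pairs, replace = TRUE)
  keep <- a != b
  data.frame(snp_a = a[keep], snp_b = b[keep],
             r2 = round(runif(sum(keep)), 3),
             dist_bp = sample.int(1000000, sum(keep)))
}
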