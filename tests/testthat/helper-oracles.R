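# Independent oracle implementations used to cross-check the package.
# These re-derive each quantity with plain-R dynamic programming or
# exhaustive enumeration and share no code with the implementation paths
# they verify.

# -- Gotoh dynamic programming, local (Smith-Waterman) score only ------------
oracle_local_score <- function(a, b, match = 1, mismatch = -2, open = 5,
                               extend = 2) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1) # gap in a (consuming b)
  Y <- matrix(NEG, n + 1, m + 1) # gap in b (consuming a)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (A[i] == B[j]) match else mismatch
      prev <- max(M[i, j], X[i, j], Y[i, j], 0)
      M[i + 1, j + 1] <- s + prev
      X[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                             X[i + 1, j] - extend,
                             Y[i + 1, j] - open - extend)
      Y[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                             Y[i, j + 1] - extend,
                             X[i, j + 1] - open - extend)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# -- Gotoh dynamic programming, global (Needleman-Wunsch) score only ---------
oracle_global_score <- function(a, b, submat, open = 2, extend = 0.2) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (j in seq_len(m)) X[1, j + 1] <- -open - extend * j
  for (i in seq_len(n)) Y[i + 1, 1] <- -open - extend * i
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[A[i], B[j]]
      M[i + 1, j + 1] <- s + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                             X[i + 1, j] - extend,
                             Y[i + 1, j] - open - extend)
      Y[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                             Y[i, j + 1] - extend,
                             X[i, j + 1] - open - extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# -- Nei-Gojobori by direct enumeration --------------------------------------
oracle_stop_codons <- c("TAA", "TAG", "TGA")

oracle_translate <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

oracle_mutants <- function(codon) {
  out <- character()
  for (p in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- b
      out <- c(out, mut)
    }
  }
  out
}

oracle_syn_sites <- function(codon) {
  nb <- oracle_mutants(codon)
  syn <- !(nb %in% oracle_stop_codons) &
    oracle_translate(nb) == oracle_translate(codon)
  sum(syn) / 3
}

# average (syn, nonsyn) step counts over mutational pathways between codons
oracle_path_counts <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(pos) == 0L) return(c(0, 0))
  perms <- if (length(pos) == 1L) list(pos) else {
    res <- list()
    rec <- function(prefix, rest) {
      if (length(rest) == 0L) res[[length(res) + 1L]] <<- prefix
      else for (k in seq_along(rest)) rec(c(prefix, rest[k]), rest[-k])
    }
    rec(integer(), pos)
    res
  }
  walk <- function(ord) {
    cur <- c1
    syn <- 0; nonsyn <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (nxt %in% oracle_stop_codons || cur %in% oracle_stop_codons) {
        blocked <- TRUE
      }
      if (!cur %in% oracle_stop_codons && !nxt %in% oracle_stop_codons &&
          oracle_translate(cur) == oracle_translate(nxt)) {
        syn <- syn + 1
      } else {
        nonsyn <- nonsyn + 1
      }
      cur <- nxt
    }
    list(syn = syn, nonsyn = nonsyn, blocked = blocked)
  }
  walks <- lapply(perms, walk)
  ok <- !vapply(walks, `[[`, logical(1), "blocked")
  use <- if (any(ok)) walks[ok] else walks
  c(mean(vapply(use, `[[`, numeric(1), "syn")),
    mean(vapply(use, `[[`, numeric(1), "nonsyn")))
}

oracle_ng86 <- function(codons_a, codons_b) {
  S <- (sum(vapply(codons_a, oracle_syn_sites, numeric(1))) +
          sum(vapply(codons_b, oracle_syn_sites, numeric(1)))) / 2
  N <- 3 * length(codons_a) - S
  d <- vapply(seq_along(codons_a), function(i) {
    oracle_path_counts(codons_a[i], codons_b[i])
  }, numeric(2))
  Sd <- sum(d[1, ]); Nd <- sum(d[2, ])
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) if (p >= 0.75) Inf else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       dS = jc(pS), dN = jc(pN))
}

random_sense_codons <- function(n) {
  sense <- setdiff(
    apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                      c("A", "C", "G", "T")), 1, paste, collapse = ""),
    oracle_stop_codons
  )
  sample(sense, n, replace = TRUE)
}

# mutate codons without ever touching a stop codon
mutate_sense <- function(codons, n_mut) {
  for (k in seq_len(n_mut)) {
    repeat {
      i <- sample(seq_along(codons), 1)
      mut <- sample(oracle_mutants(codons[i]), 1)
      if (!mut %in% oracle_stop_codons) {
        codons[i] <- mut
        break
      }
    }
  }
  codons
}

# -- exhaustive monotone-chain search ----------------------------------------
# enumerates every valid chain by depth-first search and returns the greedy
# longest-first partition with the same tie-break rules the block finder
# documents (longest, same orientation preferred, lexicographically
# smallest index sequence)
oracle_chain_partition <- function(rank_a, rank_b, min_anchors, max_gap) {
  best_for <- function(idx_keep, inverted) {
    ra <- rank_a[idx_keep]; rb <- rank_b[idx_keep]
    k <- length(idx_keep)
    best <- NULL
    step_ok <- function(i, j) {
      da <- ra[j] - ra[i]
      db <- if (inverted) rb[i] - rb[j] else rb[j] - rb[i]
      da >= 1 && da <= max_gap && db >= 1 && db <= max_gap
    }
    consider <- function(chain) {
      if (is.null(best) || length(chain) > length(best)) best <<- chain
      else if (length(chain) == length(best)) {
        for (t in seq_along(chain)) {
          if (chain[t] < best[t]) { best <<- chain; break }
          if (chain[t] > best[t]) break
        }
      }
    }
    dfs <- function(chain) {
      consider(chain)
      last <- chain[length(chain)]
      for (j in seq_len(k)) {
        if (step_ok(last, j)) dfs(c(chain, j))
      }
    }
    for (s in seq_len(k)) dfs(s)
    if (is.null(best)) integer() else idx_keep[best]
  }
  ord <- order(rank_a, rank_b)
  rank_a <- rank_a[ord]; rank_b <- rank_b[ord]
  remaining <- seq_along(rank_a)
  blocks <- list()
  repeat {
    if (length(remaining) == 0L) break
    same <- best_for(remaining, inverted = FALSE)
    inv <- best_for(remaining, inverted = TRUE)
    chain <- if (length(inv) > length(same)) inv else same
    if (length(chain) < min_anchors) break
    blocks[[length(blocks) + 1L]] <- cbind(rank_a[chain], rank_b[chain])
    remaining <- setdiff(remaining, chain)
  }
  blocks
}

# -- step-by-step Blanc-Wolfe clustering -------------------------------------
oracle_median_clustering <- function(ks) {
  labels <- rownames(ks)
  clusters <- lapply(labels, identity)
  merges <- list()
  while (length(clusters) > 1L) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in seq(i + 1L, length(clusters))) {
        vals <- c()
        for (x in clusters[[i]]) for (y in clusters[[j]]) {
          v <- ks[x, y]
          if (!is.na(v)) vals <- c(vals, v)
        }
        if (length(vals) == 0L) next
        med <- stats::median(vals)
        key <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        if (is.null(best) || med < best$med ||
            (med == best$med &&
               (key[1] < best$key[1] ||
                  (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, med = med, key = key)
        }
      }
    }
    if (is.null(best)) stop("stranded clusters")
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    merges[[length(merges) + 1L]] <- list(members = merged, height = best$med)
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
  }
  merges
}

# random ultrametric Ks matrix from a known merge history
random_ultrametric <- function(labels, heights) {
  # heights: strictly increasing vector of length(labels) - 1
  clusters <- lapply(labels, identity)
  ks <- matrix(NA_real_, length(labels), length(labels),
               dimnames = list(labels, labels))
  diag(ks) <- 0
  truth <- list()
  for (h in heights) {
    pick <- sample(length(clusters), 2)
    for (x in clusters[[pick[1]]]) for (y in clusters[[pick[2]]]) {
      ks[x, y] <- h
      ks[y, x] <- h
    }
    merged <- sort(c(clusters[[pick[1]]], clusters[[pick[2]]]))
    truth[[length(truth) + 1L]] <- list(members = merged, height = h)
    clusters <- c(clusters[-pick], list(merged))
  }
  list(ks = ks, truth = truth)
}

# -- union-find for paralog grouping -----------------------------------------
oracle_components <- function(edges_a, edges_b) {
  nodes <- sort(unique(c(edges_a, edges_b)))
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (k in seq_along(edges_a)) {
    ra <- find(edges_a[k]); rb <- find(edges_b[k])
    if (ra != rb) parent[[max(ra, rb)]] <- min(ra, rb)
  }
  split(nodes, vapply(nodes, find, character(1)))
}
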