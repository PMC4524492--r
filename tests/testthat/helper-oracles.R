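# Independent oracles used across the suite. Each is a deliberately naive
# formulation kept separate from the implementation paths it checks.

# --- breadth-first search over the inversion graph -------------------------
# distances from the identity to every signed permutation of size m
bfs_inversion_distances <- function(m) {
  key <- function(p) paste(p, collapse = ",")
  dist <- new.env(hash = TRUE, parent = emptyenv())
  id <- seq_len(m)
  assign(key(id), 0L, dist)
  frontier <- list(id)
  d <- 0L
  moves <- list()
  for (i in 1:m) for (j in i:m) moves[[length(moves) + 1L]] <- c(i, j)
  while (length(frontier) > 0L) {
    nxt <- list()
    for (p in frontier) {
      for (mv in moves) {
        q <- p
        q[mv[1]:mv[2]] <- -rev(q[mv[1]:mv[2]])
        kq <- key(q)
        if (is.null(dist[[kq]])) {
          dist[[kq]] <- d + 1L
          nxt[[length(nxt) + 1L]] <- q
        }
      }
    }
    frontier <- nxt
    d <- d + 1L
  }
  dist
}

all_signed_perms <- function(m) {
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  out <- list()
  for (p in perms(seq_len(m))) {
    for (mask in 0:(2^m - 1)) {
      signs <- ifelse(bitwAnd(mask, 2^(seq_len(m) - 1L)) > 0, -1L, 1L)
      out[[length(out) + 1L]] <- as.integer(p * signs)
    }
  }
  out
}

random_signed_perm <- function(m) {
  as.integer(sample(m) * sample(c(-1L, 1L), m, replace = TRUE))
}

# number of framed breakpoints of a signed permutation
count_breakpoints <- function(perm) {
  framed <- c(0L, perm, length(perm) + 1L)
  sum(diff(framed) != 1L)
}

# --- brute-force circular sided-block counting -----------------------------
brute_sided_blocks <- function(signs) {
  n <- length(signs)
  # cut the circle at every position, count linear runs, take the minimum
  # (cutting inside a block inflates the count by one unless all one block)
  counts <- vapply(seq_len(n), function(s) {
    v <- signs[c(s:n, seq_len(s - 1L))]
    1L + sum(v[-1L] != v[-n])
  }, integer(1))
  min(counts)
}

# --- brute-force maximal repeat scan (quadratic, exact) --------------------
brute_force_repeats <- function(s, min_len, kind = "forward") {
  n <- nchar(s)
  ch <- strsplit(toupper(s), "")[[1]]
  target <- if (kind == "forward") ch else
    rev(chartr("ACGT", "TGCA", ch))
  out <- list()
  for (i in seq_len(n - min_len + 1L)) {
    for (j in seq_len(n - min_len + 1L)) {
      if (kind == "forward" && j <= i) next
      l <- 0L
      while (i + l <= n && j + l <= n && ch[i + l] == target[j + l]) l <- l + 1L
      if (l < min_len) next
      left_max <- i == 1L || j == 1L || ch[i - 1L] != target[j - 1L]
      if (!left_max) next
      if (kind == "forward") {
        out[[length(out) + 1L]] <- c(i - 1L, i - 1L + l, j - 1L, j - 1L + l)
      } else {
        # rc index j maps to sequence interval [n - j - l + 1, n - j + 1)
        sb <- n - (j - 1L) - l
        a0 <- i - 1L
        lo <- min(a0, sb); hi <- max(a0, sb)
        out[[length(out) + 1L]] <- c(lo, lo + l, hi, hi + l)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start_a = integer(), end_a = integer(),
                      start_b = integer(), end_b = integer()))
  }
  m <- unique(do.call(rbind, out))
  m <- m[order(m[, 1], m[, 3]), , drop = FALSE]
  data.frame(start_a = m[, 1], end_a = m[, 2], start_b = m[, 3], end_b = m[, 4])
}

# --- brute-force Dollo: DP minimum losses over all single-gain placements --
brute_dollo_min_losses <- function(states, tree) {
  nt <- ape::Ntip(tree)
  nn <- nt + tree$Nnode
  st <- as.integer(states[tree$tip.label])
  if (!any(!is.na(st) & st == 1L)) return(0L)
  INF <- 1e9
  kids <- lapply(seq_len(nn), function(v) tree$edge[tree$edge[, 1] == v, 2])
  cost <- matrix(NA_real_, nn, 2)  # cost[v, s+1]: min losses in subtree v given state s
  po <- unique(tree$edge[ape::postorder(tree), 2])
  for (v in c(po, nt + 1L)) {
    if (v <= nt) {
      cost[v, ] <- c(if (is.na(st[v]) || st[v] == 0L) 0 else INF,
                     if (is.na(st[v]) || st[v] == 1L) 0 else INF)
    } else {
      c0 <- 0; c1 <- 0
      for (u in kids[[v]]) {
        c0 <- c0 + cost[u, 1]
        c1 <- c1 + min(cost[u, 2], 1 + cost[u, 1])
      }
      cost[v, ] <- c(c0, c1)
    }
  }
  # gain on the branch to g: everything outside subtree(g) must be 0
  below <- matrix(FALSE, nn, nn)
  for (v in seq_len(nn)) {
    anc <- v
    repeat {
      below[anc, v] <- TRUE
      up <- tree$edge[tree$edge[, 2] == anc, 1]
      if (length(up) == 0L) break
      anc <- up
    }
  }
  best <- INF
  for (g in seq_len(nn)) {
    outside_leaves <- which(!below[g, seq_len(nt)])
    if (any(!is.na(st[outside_leaves]) & st[outside_leaves] == 1L)) next
    best <- min(best, cost[g, 2])
  }
  as.integer(best)
}

# random rooted tree with n uniquely labeled leaves (binary)
random_rooted_tree <- function(n) {
  tr <- ape::rtree(n, rooted = TRUE, br = NULL)
  tr$tip.label <- paste0("t", seq_len(n))
  tr
}

# --- shared small simulation bundle (computed once per test run) -----------
sim_bundle_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_genes = 30L, ir_gene_count = 8L, ssc_gene_count = 4L,
                        genome_length_target = 25000L,
                        use_core_symbols = FALSE, seed = 7L,
                        rates = c(inversion = 0.8, ir_expand = 0.25,
                                  ir_contract = 0.25, ir_loss = 0.25,
                                  repeat_insert = 0.7))
      anc <- make_ancestor(cfg)
      tree <- ape::read.tree(text = "((A,B),(C,(D,E)));")
      cache <<- suppressMessages(evolve_plastomes(anc, tree, cfg))
    }
    cache
  }
})
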