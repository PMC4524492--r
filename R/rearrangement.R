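# Exact signed reversal distance via the Hannenhalli-Pevzner breakpoint graph.
#
# A circular gene order pair is linearized by anchoring one shared gene, the
# target order is renumbered to the identity, and the distance is
# d = (m + 1) - c + h + f  with c cycles, h hurdles and f the fortress
# indicator, computed from the unsigned doubling of the permutation.

#' Linearize two circular gene orders onto a common integer alphabet
#'
#' Both orders are rotated (and, if needed, reflected) so the anchor gene sits
#' first on the forward strand, then `b` is mapped to the identity and `a`
#' renumbered accordingly. Anchored linearization is the standard equivalence
#' between circular and linear signed reversal distance; the choice of anchor
#' does not change the distance.
#'
#' @param a,b `gene_order` tibbles for single taxa on the same symbol set.
#' @param anchor Anchor symbol, or NULL for the lexicographically smallest
#'   shared symbol.
#' @return List with `perm` (signed integer permutation of `a` relative to
#'   `b`), `m`, and `anchor`.
#' @export
linearize_orders <- function(a, b, anchor = NULL) {
  av <- order_vectors(a); bv <- order_vectors(b)
  if (!setequal(av$symbol, bv$symbol) ||
      anyDuplicated(av$symbol) || anyDuplicated(bv$symbol)) {
    only_a <- setdiff(av$symbol, bv$symbol)
    only_b <- setdiff(bv$symbol, av$symbol)
    abort(paste0("gene orders are not on the same symbol set; only in a: {",
                 paste(only_a, collapse = ", "), "}; only in b: {",
                 paste(only_b, collapse = ", "), "}"))
  }
  anchor <- anchor %||% min(av$symbol)
  stopifnot(anchor %in% av$symbol)
  av <- anchor_front(av, anchor)
  bv <- anchor_front(bv, anchor)
  idx <- setNames(seq_along(bv$symbol), bv$symbol)
  perm <- unname(idx[av$symbol] * av$sign * bv$sign[match(av$symbol, bv$symbol)])
  list(perm = as.integer(perm), m = length(perm), anchor = anchor)
}

order_vectors <- function(o) {
  stopifnot(length(unique(o$taxon)) == 1L)
  o <- o[order(o$position), , drop = FALSE]
  list(symbol = o$symbol, sign = as.integer(o$sign))
}

# rotate/reflect a circular (symbol, sign) list so `anchor` is first with +1
anchor_front <- function(v, anchor) {
  i <- match(anchor, v$symbol)
  n <- length(v$symbol)
  rot <- c(i:n, seq_len(i - 1L))
  v <- list(symbol = v$symbol[rot], sign = v$sign[rot])
  if (v$sign[1] == -1L) {
    v <- list(symbol = rev(v$symbol), sign = rev(-v$sign))
    i <- match(anchor, v$symbol)
    rot <- c(i:n, seq_len(i - 1L))
    v <- list(symbol = v$symbol[rot], sign = v$sign[rot])
  }
  v
}

#' Breakpoint-graph statistics and reversal distance of a signed permutation
#'
#' Computes cycles, unoriented components, hurdles and the fortress indicator
#' of the breakpoint graph of a signed permutation (relative to the identity,
#' framed by 0 and m+1), and the exact minimum number of inversions
#' d = (m + 1) - c + h + f.
#'
#' @param perm Signed integer permutation: each magnitude 1..m exactly once.
#' @return Object of class `breakpoint_graph`: list with `m`, `c` (cycles),
#'   `h` (hurdles), `f` (fortress 0/1), `d` (distance), `perm`.
#' @examples
#' hp_distance(c(1L, -3L, -2L, 4L))$d  # one inversion
#' @export
hp_distance <- function(perm) {
  perm <- as.integer(perm)
  m <- length(perm)
  stopifnot(setequal(abs(perm), seq_len(max(m, 0L))))
  if (m == 0L) {
    return(new_breakpoint_graph(m, 1L, 0L, 0L, 0L, perm))
  }
  # unsigned doubling, framed: u has length 2m+2, values 0..2m+1
  u <- integer(2L * m + 2L)
  u[1L] <- 0L
  for (i in seq_len(m)) {
    x <- perm[i]
    if (x > 0L) {
      u[2L * i] <- 2L * x - 1L
      u[2L * i + 1L] <- 2L * x
    } else {
      u[2L * i] <- -2L * x
      u[2L * i + 1L] <- -2L * x - 1L
    }
  }
  u[2L * m + 2L] <- 2L * m + 1L
  pos <- integer(2L * m + 2L)
  pos[u + 1L] <- seq_along(u)

  n_gray <- m + 1L  # gray edge i joins values 2i and 2i+1, i = 0..m
  p1 <- pos[2L * (0:m) + 1L]
  p2 <- pos[2L * (0:m) + 2L]
  lo <- pmin(p1, p2); hi <- pmax(p1, p2)
  oriented <- (p1 %% 2L) == (p2 %% 2L)
  trivial <- (hi - lo == 1L) & (lo %% 2L == 1L)

  # cycles: alternate black (position partner) and gray (value partner) edges
  cyc_of <- integer(n_gray)
  n_cycles <- 0L
  visited <- logical(2L * m + 2L)
  for (start in seq_along(u)) {
    if (visited[start]) next
    n_cycles <- n_cycles + 1L
    p <- start
    repeat {
      visited[p] <- TRUE
      pb <- if (p %% 2L == 1L) p + 1L else p - 1L  # black edge
      visited[pb] <- TRUE
      v <- u[pb]
      w <- if (v %% 2L == 0L) v + 1L else v - 1L   # gray edge
      cyc_of[(min(v, w) - min(v, w) %% 2L) / 2L + 1L] <- n_cycles
      p <- pos[w + 1L]
      if (p == start) break
    }
  }

  # components: union by shared cycle and by strict interval crossing
  parent <- seq_len(n_gray)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  union_ <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[rb] <<- ra }
  for (cid in unique(cyc_of)) {
    idx <- which(cyc_of == cid)
    if (length(idx) > 1L) for (k in idx[-1L]) union_(idx[1L], k)
  }
  nt <- which(!trivial)
  if (length(nt) > 1L) {
    for (ii in seq_len(length(nt) - 1L)) {
      i <- nt[ii]
      for (jj in (ii + 1L):length(nt)) {
        j <- nt[jj]
        if ((lo[i] < lo[j] && lo[j] < hi[i] && hi[i] < hi[j]) ||
            (lo[j] < lo[i] && lo[i] < hi[j] && hi[j] < hi[i])) union_(i, j)
      }
    }
  }
  comp <- vapply(seq_len(n_gray), find, integer(1))
  comp_ids <- unique(comp[!trivial])
  unoriented_ids <- comp_ids[vapply(comp_ids, function(cid)
    !any(oriented[comp == cid]), logical(1))]

  h <- 0L; f <- 0L
  if (length(unoriented_ids) > 0L) {
    hu <- hurdle_set(unoriented_ids, comp, trivial, p1, p2)
    h <- length(hu)
    if (h %% 2L == 1L && h > 0L) {
      all_super <- all(vapply(hu, function(uid)
        is_superhurdle(uid, hu, unoriented_ids, comp, trivial, p1, p2),
        logical(1)))
      if (all_super) f <- 1L
    }
  }
  d <- (m + 1L) - n_cycles + h + f
  new_breakpoint_graph(m, n_cycles, h, f, d, perm)
}

# hurdles = unoriented components whose endpoint positions form a single
# contiguous run in the circular order of all unoriented-component positions
hurdle_set <- function(unoriented_ids, comp, trivial, p1, p2, drop = integer(0)) {
  keep <- setdiff(unoriented_ids, drop)
  if (length(keep) == 0L) return(integer(0))
  pts <- list()
  for (cid in keep) {
    idx <- which(comp == cid & !trivial)
    pts[[as.character(cid)]] <- c(p1[idx], p2[idx])
  }
  all_pos <- sort(unlist(pts))
  labels <- integer(length(all_pos))
  for (cid in keep) labels[all_pos %in% pts[[as.character(cid)]]] <- cid
  out <- integer(0)
  for (cid in keep) {
    is_c <- labels == cid
    runs <- sum(is_c & !c(is_c[length(is_c)], is_c[-length(is_c)]))  # circular run starts
    if (runs <= 1L) out <- c(out, cid)
  }
  out
}

# u is a superhurdle if deleting it turns some non-hurdle unoriented
# component into a hurdle
is_superhurdle <- function(uid, hurdles, unoriented_ids, comp, trivial, p1, p2) {
  before <- setdiff(unoriented_ids, hurdles)
  if (length(before) == 0L) return(FALSE)
  after <- hurdle_set(unoriented_ids, comp, trivial, p1, p2, drop = uid)
  any(before %in% after)
}

new_breakpoint_graph <- function(m, c, h, f, d, perm) {
  structure(list(m = m, c = c, h = h, f = f, d = d, perm = perm),
            class = "breakpoint_graph")
}

#' @export
print.breakpoint_graph <- function(x, ...) {
  cat("<breakpoint_graph> m =", x$m, " cycles =", x$c, " hurdles =", x$h,
      " fortress =", x$f, " d =", x$d, "\n")
  invisible(x)
}

#' Reversal distance between two gene orders
#'
#' Exact minimum number of inversions separating two circular (or linear)
#' signed gene orders on a common gene set, by the Hannenhalli-Pevzner
#' breakpoint-graph formula.
#'
#' @inheritParams linearize_orders
#' @return A `breakpoint_graph` (see [hp_distance()]); the distance is `$d`.
#' @export
reversal_distance <- function(a, b, anchor = NULL) {
  lin <- linearize_orders(a, b, anchor = anchor)
  hp_distance(lin$perm)
}

#' Pairwise reversal-distance matrix
#'
#' Distances are computed on the intersection of the taxa's gene sets (a
#' warning reports dropped genes), mirroring a fixed shared-gene matrix.
#'
#' @param orders A `gene_order` tibble with at least two taxa.
#' @param path Optional TSV output path (square, taxon-labeled).
#' @return Symmetric integer matrix with zero diagonal.
#' @export
pairwise_distance_matrix <- function(orders, path = NULL) {
  taxa <- unique(orders$taxon)
  stopifnot(length(taxa) >= 2L)
  sets <- lapply(taxa, function(tx) orders$symbol[orders$taxon == tx])
  common <- Reduce(intersect, sets)
  if (length(common) == 0L) abort("no genes shared by all gene orders")
  if (any(vapply(sets, function(s) length(setdiff(s, common)) > 0L, logical(1)))) {
    warn(paste0("restricting to ", length(common), " genes shared by all taxa"))
  }
  sub <- lapply(taxa, function(tx) {
    o <- orders[orders$taxon == tx & orders$symbol %in% common, , drop = FALSE]
    o$position <- rank(o$position)
    new_gene_order(o, circular = is_circular_order(orders))
  })
  names(sub) <- taxa
  D <- matrix(0L, length(taxa), length(taxa), dimnames = list(taxa, taxa))
  for (i in seq_along(taxa)) {
    for (j in seq_len(i - 1L)) {
      D[i, j] <- D[j, i] <- reversal_distance(sub[[i]], sub[[j]])$d
    }
  }
  if (!is.null(path)) {
    write.table(cbind(taxon = rownames(D), as.data.frame(D)), path,
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  D
}
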