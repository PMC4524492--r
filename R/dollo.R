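# Dollo-parsimony mapping of binary characters on a fixed rooted tree.
#
# Under the Dollo principle a character is gained exactly once and can only be
# lost afterwards. On a rooted tree the loss-minimal single-gain
# reconstruction is unique: the gain sits on the branch to the most recent
# common ancestor of the state-1 leaves, and one loss lies on the branch to
# every maximal subtree of that clade containing no state-1 leaf. Trees are
# `ape::phylo` objects; branches are identified by their child node.

node_label <- function(tree, node) {
  nt <- ape::Ntip(tree)
  if (node <= nt) return(tree$tip.label[node])
  lbl <- tree$node.label
  if (!is.null(lbl)) {
    l <- lbl[node - nt]
    if (!is.na(l) && nzchar(l)) return(l)
  }
  paste0("node_", node)
}

children_of <- function(tree, node) tree$edge[tree$edge[, 1] == node, 2]

# postorder list of descendants' leaf states summary
subtree_state_flags <- function(tree, states) {
  nt <- ape::Ntip(tree)
  nn <- nt + tree$Nnode
  has1 <- logical(nn); has0 <- logical(nn)
  has1[seq_len(nt)] <- !is.na(states) & states == 1L
  has0[seq_len(nt)] <- !is.na(states) & states == 0L
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    has1[p] <- has1[p] | has1[ch]
    has0[p] <- has0[p] | has0[ch]
  }
  list(has1 = has1, has0 = has0)
}

#' Dollo-parsimony map of one binary character
#'
#' @param states Named vector of leaf states in \{0, 1, NA\}; names must match
#'   the tree's tip labels. NA leaves (e.g. incomplete genomes) are ignored
#'   for gain placement and never force a loss, but are reported.
#' @param tree A rooted `ape::phylo` tree (polytomies allowed).
#' @param character_id Optional id stored in the result.
#' @return Object of class `dollo_map`: list with `character_id`, `gain_node`
#'   (integer node, NA if the character is absent everywhere), `gain_label`,
#'   `loss_nodes` / `loss_labels` (branches by child node), `node_state`
#'   (0/1 per node under the reconstruction), `na_leaves`.
#' @examples
#' tr <- ape::read.tree(text = "((a,b),(c,d));")
#' dollo_map(c(a = 1, b = 1, c = 0, d = 1), tr)
#' @export
dollo_map <- function(states, tree, character_id = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge) || !ape::is.rooted(tree)) abort("tree must be rooted")
  stopifnot(!is.null(names(states)))
  miss <- setdiff(tree$tip.label, names(states))
  if (length(miss) > 0L) abort(paste0("no state for leaves: ", paste(miss, collapse = ", ")))
  states <- as.integer(states[tree$tip.label])
  nt <- ape::Ntip(tree)
  nn <- nt + tree$Nnode
  na_leaves <- tree$tip.label[is.na(states)]
  ones <- which(!is.na(states) & states == 1L)
  node_state <- integer(nn)
  if (length(ones) == 0L) {
    return(structure(list(character_id = character_id, gain_node = NA_integer_,
                          gain_label = NA_character_, loss_nodes = integer(0),
                          loss_labels = character(0), node_state = node_state,
                          na_leaves = na_leaves, tree = tree),
                     class = "dollo_map"))
  }
  gain <- if (length(ones) == 1L) ones else ape::getMRCA(tree, ones)
  flags <- subtree_state_flags(tree, states)
  # nodes inside the gained clade
  inside <- logical(nn); inside[gain] <- TRUE
  for (e in rev(ape::postorder(tree))) {   # parent before child
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    if (inside[p]) inside[ch] <- TRUE
  }
  # losses: maximal subtrees inside the clade with no 1-leaf and at least one
  # observed 0-leaf (all-NA subtrees stay unresolved, no loss inferred)
  parent <- integer(nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  cand <- which(inside & !flags$has1 & flags$has0)
  loss <- cand[vapply(cand, function(v) v != gain && flags$has1[parent[v]],
                      logical(1))]
  node_state[gain] <- 1L
  for (e in rev(ape::postorder(tree))) {  # parent-first
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    if (!inside[ch] || ch == gain) next
    node_state[ch] <- if (ch %in% loss) 0L else node_state[p]
  }
  structure(list(character_id = character_id, gain_node = gain,
                 gain_label = node_label(tree, gain),
                 loss_nodes = as.integer(loss),
                 loss_labels = vapply(loss, function(v) node_label(tree, v), character(1)),
                 node_state = node_state, na_leaves = na_leaves, tree = tree),
            class = "dollo_map")
}

#' @export
print.dollo_map <- function(x, ...) {
  cat("<dollo_map>", x$character_id %||% "", "\n")
  if (is.na(x$gain_node)) {
    cat("  absent everywhere (no gain)\n")
  } else {
    cat("  gain at", x$gain_label, "; losses:",
        if (length(x$loss_labels)) paste(x$loss_labels, collapse = ", ") else "none", "\n")
  }
  invisible(x)
}

#' Map inverted-repeat losses on a phylogeny
#'
#' Dollo mapping of IR presence/absence; with a presence vector whose gains
#' are ancestral, every state change is a loss, and the loss branches are
#' reported by the clade (child-node label) they subtend.
#'
#' @param ir_presence Named 0/1 vector of IR presence per leaf.
#' @inheritParams dollo_map
#' @return A `dollo_map`; `$loss_labels` names the lineages that lost the IR,
#'   and `$n_losses` gives the count.
#' @export
map_ir_losses <- function(ir_presence, tree) {
  dm <- dollo_map(ir_presence, tree, character_id = "IR_presence")
  dm$n_losses <- length(dm$loss_nodes)
  dm
}

#' Per-branch gain/loss tally over a set of Dollo maps
#'
#' @param maps List of `dollo_map` objects computed on the same tree.
#' @param tree The tree used.
#' @param path Optional TSV output path.
#' @return Tibble keyed by branch (child node): `node`, `branch`, `gains`,
#'   `losses`, plus the character ids involved.
#' @export
branch_event_table <- function(maps, tree, path = NULL) {
  nt <- ape::Ntip(tree)
  nn <- nt + tree$Nnode
  gains <- integer(nn); losses <- integer(nn)
  gain_chr <- vector("list", nn); loss_chr <- vector("list", nn)
  for (mp in maps) {
    if (!is.na(mp$gain_node)) {
      gains[mp$gain_node] <- gains[mp$gain_node] + 1L
      gain_chr[[mp$gain_node]] <- c(gain_chr[[mp$gain_node]],
                                    mp$character_id %||% "?")
    }
    for (v in mp$loss_nodes) {
      losses[v] <- losses[v] + 1L
      loss_chr[[v]] <- c(loss_chr[[v]], mp$character_id %||% "?")
    }
  }
  keep <- which(gains > 0L | losses > 0L)
  out <- tibble(
    node = keep,
    branch = vapply(keep, function(v) node_label(tree, v), character(1)),
    gains = gains[keep], losses = losses[keep],
    gain_characters = vapply(keep, function(v)
      paste(gain_chr[[v]], collapse = ";"), character(1)),
    loss_characters = vapply(keep, function(v)
      paste(loss_chr[[v]], collapse = ";"), character(1)))
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Dollo maps for a table of binary characters
#'
#' @param characters Tibble with columns `character_id`, `taxon`, `state`
#'   (0/1/NA), or a wide matrix-like data frame with a `character_id` column
#'   and one column per taxon.
#' @inheritParams dollo_map
#' @return Named list of `dollo_map` objects.
#' @export
dollo_map_characters <- function(characters, tree) {
  characters <- as_tibble(characters)
  if (!"state" %in% names(characters)) {
    characters <- tidyr::pivot_longer(characters, -"character_id",
                                      names_to = "taxon", values_to = "state")
  }
  ids <- unique(characters$character_id)
  out <- lapply(ids, function(id) {
    sub <- characters[characters$character_id == id, , drop = FALSE]
    dollo_map(setNames(sub$state, sub$taxon), tree, character_id = id)
  })
  setNames(out, ids)
}
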