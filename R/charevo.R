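# Ancestral-state reconstruction of binary opsin characters and
# alignment-column mapping for spectral tuning sites.

check_tip_states <- function(tree, tip_states) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (is.null(names(tip_states)))
    stop("tip_states must be named by tip label")
  missing_tips <- setdiff(tree$tip.label, names(tip_states))
  if (length(missing_tips))
    stop("no character state for tips: ", paste(missing_tips, collapse = ", "))
  extra <- setdiff(names(tip_states), tree$tip.label)
  if (length(extra))
    stop("character states for taxa absent from the tree: ",
         paste(extra, collapse = ", "))
  st <- tip_states[tree$tip.label]
  if (!all(st %in% c(0, 1) | is.na(st)))
    stop("states must be 0, 1 or NA (unknown)")
  if (sum(!is.na(st)) < 2L) stop("at least two tips need a known state")
  st
}

# Subtending tip set of a node, as a sorted label vector.
subtended_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  sort(tree$tip.label[ape::prop.part(tree)[[node - ntip]]])
}

#' Fitch parsimony for a binary character
#'
#' Computes the minimum number of state changes on a rooted binary tree
#' consistent with the tip states, one most-parsimonious internal-state
#' assignment, and the edges on which that assignment changes state.
#' Polytomies are resolved deterministically with [ape::multi2di] before
#' the pass. Unknown tips (`NA`) are treated as ambiguous \{0, 1\}.
#'
#' @param tree A rooted `phylo` tree.
#' @param tip_states Named vector of 0/1/NA states, names matching the tip
#'   labels exactly.
#' @return List with `score` (minimum change count), `node_states` (one
#'   most-parsimonious assignment for every node, tips included),
#'   `changes` (`data.frame` of change edges, each identified by the tip
#'   set its child subtends).
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' fitch_parsimony(tr, c(A = 0, B = 0, C = 1, D = 1))$score
#' @export
fitch_parsimony <- function(tree, tip_states) {
  st <- check_tip_states(tree, tip_states)
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  st <- st[tree$tip.label]
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  # state sets as bitmasks: 1 = {0}, 2 = {1}, 3 = {0,1}
  sets <- integer(ntip + nnode)
  sets[seq_len(ntip)] <- ifelse(is.na(st), 3L, ifelse(st == 1, 2L, 1L))
  score <- 0L
  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge
  # iterate edges in postorder, combining children into parents
  acc <- vector("list", ntip + nnode)
  for (i in seq_len(nrow(edge))) {
    p <- edge[i, 1L]; ch <- edge[i, 2L]
    acc[[p]] <- c(acc[[p]], ch)
    if (length(acc[[p]]) == 2L) {
      a <- sets[acc[[p]][1L]]; b <- sets[acc[[p]][2L]]
      inter <- bitwAnd(a, b)
      if (inter != 0L) sets[p] <- inter
      else { sets[p] <- bitwOr(a, b); score <- score + 1L }
    }
  }
  # top-down pass: assign a concrete state per node (prefer 0 on ties)
  pick <- function(mask) if (bitwAnd(mask, 1L) != 0L) 0L else 1L
  root <- ntip + 1L
  assign_state <- integer(ntip + nnode)
  assign_state[root] <- pick(sets[root])
  pre <- rev(seq_len(nrow(edge)))  # reverse postorder = preorder
  for (i in pre) {
    p <- edge[i, 1L]; ch <- edge[i, 2L]
    pmask <- bitwShiftL(1L, assign_state[p])
    assign_state[ch] <- if (bitwAnd(sets[ch], pmask) != 0L)
      assign_state[p] else pick(sets[ch])
  }
  chg <- which(assign_state[edge[, 2L]] != assign_state[edge[, 1L]])
  changes <- data.frame(
    from = assign_state[edge[chg, 1L]],
    to = assign_state[edge[chg, 2L]],
    subtends = vapply(edge[chg, 2L], function(nd)
      paste(subtended_tips(tr, nd), collapse = ","), character(1)),
    stringsAsFactors = FALSE)
  names(assign_state) <- c(tr$tip.label, paste0("node", seq_len(nnode) + ntip))
  list(score = score, node_states = assign_state, changes = changes)
}

# 2-state symmetric Mk transition probability matrix for branch length t.
mk_pmat <- function(rate, t) {
  e <- exp(-2 * rate * t)
  same <- 0.5 + 0.5 * e
  diff <- 0.5 - 0.5 * e
  matrix(c(same, diff, diff, same), 2L, 2L)
}

#' Marginal ancestral states under the two-state Mk model
#'
#' Felsenstein pruning for the likelihood and the standard down/up pass
#' for marginal state probabilities at every internal node, under a
#' symmetric single-rate two-state Markov model with a uniform root prior
#' (the default binary likelihood model of common character-mapping
#' tools). Missing branch lengths are replaced by unit lengths with a
#' warning.
#'
#' @param tree Rooted `phylo` tree.
#' @param tip_states Named 0/1/NA vector, names matching tip labels.
#' @param rate Substitution rate per unit branch length, > 0.
#' @return Matrix of marginal probabilities (internal nodes x states
#'   `p0`, `p1`), with attribute `loglik`.
#' @export
mk_ml_ancestral <- function(tree, tip_states, rate = 1) {
  st <- check_tip_states(tree, tip_states)
  if (!is.finite(rate) || rate <= 0) stop("rate must be positive")
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; substituting unit lengths")
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  st <- st[tree$tip.label]
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge
  elen <- tr$edge.length
  # conditional likelihoods L[node, state]
  L <- matrix(1, ntip + nnode, 2L)
  L[seq_len(ntip), ] <- 0
  for (i in seq_len(ntip)) {
    if (is.na(st[i])) L[i, ] <- 1
    else L[i, st[i] + 1L] <- 1
  }
  # per-edge message from child to parent: M[i, s_parent]
  M <- matrix(NA_real_, nrow(edge), 2L)
  for (i in seq_len(nrow(edge))) {
    P <- mk_pmat(rate, elen[i])
    M[i, ] <- as.numeric(P %*% L[edge[i, 2L], ])
    L[edge[i, 1L], ] <- L[edge[i, 1L], ] * M[i, ]
  }
  root <- ntip + 1L
  lik <- sum(0.5 * L[root, ])
  # up pass: U[node, state] = likelihood of everything outside the node's
  # subtree given the node's state (root prior included)
  U <- matrix(NA_real_, ntip + nnode, 2L)
  U[root, ] <- 0.5
  for (i in rev(seq_len(nrow(edge)))) {
    p <- edge[i, 1L]; ch <- edge[i, 2L]
    P <- mk_pmat(rate, elen[i])
    # parent-side partial excluding this child's message
    rest <- U[p, ] * L[p, ] / M[i, ]
    U[ch, ] <- as.numeric(t(P) %*% rest)
  }
  internal <- root:(ntip + nnode)
  post <- U[internal, , drop = FALSE] * L[internal, , drop = FALSE]
  post <- post / rowSums(post)
  dimnames(post) <- list(paste0("node", internal), c("p0", "p1"))
  attr(post, "loglik") <- log(lik)
  post
}

#' Map a reference residue position to an alignment column
#'
#' Given a protein multiple-sequence alignment and a 1-based ungapped
#' residue position in a chosen reference sequence (e.g. a spectral tuning
#' site numbered relative to squid rhodopsin), find the alignment column
#' holding that residue and report every sequence's residue at the column.
#'
#' @param alignment Named character vector of aligned sequences (equal
#'   lengths, gaps as `-` or `.`), or a path to an aligned FASTA file.
#' @param reference_id Name of the reference sequence.
#' @param reference_position 1-based ungapped residue index in the
#'   reference.
#' @return List with `column` (1-based alignment column), `reference_id`,
#'   `reference_position`, `residues` (named character vector at that
#'   column; gaps reported as `"-"`).
#' @export
map_reference_site <- function(alignment, reference_id, reference_position) {
  if (is.character(alignment) && length(alignment) == 1L &&
      is.null(names(alignment)) && file.exists(alignment)) {
    fas <- seqinr::read.fasta(alignment, seqtype = "AA", as.string = TRUE,
                              forceDNAtolower = FALSE)
    alignment <- toupper(vapply(fas, as.character, character(1)))
  }
  if (is.null(names(alignment))) stop("alignment sequences must be named")
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L)
    stop("aligned sequences must have equal length")
  if (!reference_id %in% names(alignment))
    stop("reference sequence '", reference_id, "' not in alignment")
  ref <- strsplit(alignment[[reference_id]], "")[[1L]]
  ref_ungapped <- cumsum(!(ref %in% c("-", ".")))
  if (reference_position < 1 ||
      reference_position > max(ref_ungapped))
    stop("reference_position beyond the reference length (",
         max(ref_ungapped), " residues)")
  column <- match(reference_position, ref_ungapped)
  residues <- vapply(alignment, function(s)
    substr(s, column, column), character(1))
  residues[residues == "."] <- "-"
  list(column = column, reference_id = reference_id,
       reference_position = reference_position, residues = residues)
}

#' Ungapped reference position of an alignment column
#'
#' Inverse of [map_reference_site()]: the 1-based ungapped residue index
#' of the reference at a given alignment column (error if the reference is
#' gapped there).
#'
#' @inheritParams map_reference_site
#' @param column 1-based alignment column.
#' @return Integer residue position.
#' @export
alignment_position <- function(alignment, reference_id, column) {
  if (is.null(names(alignment))) stop("alignment sequences must be named")
  ref <- strsplit(alignment[[reference_id]], "")[[1L]]
  if (column < 1 || column > length(ref)) stop("column outside the alignment")
  if (ref[column] %in% c("-", "."))
    stop("reference is gapped at column ", column)
  sum(!(ref[seq_len(column)] %in% c("-", ".")))
}

#' Read a taxon/state character table
#'
#' @param path CSV with columns `taxon` and `state` (0/1, empty or NA for
#'   unknown).
#' @return Named numeric vector of states.
#' @export
read_character_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("taxon", "state") %in% names(tab)))
    stop("character table needs columns 'taxon' and 'state'")
  st <- suppressWarnings(as.numeric(tab$state))
  bad <- !is.na(tab$state) & tab$state != "" & is.na(st)
  if (any(bad))
    stop("non-numeric state for taxa: ", paste(tab$taxon[bad], collapse = ", "))
  stats::setNames(st, tab$taxon)
}
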