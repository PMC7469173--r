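# Internal unrooted-tree machinery.
#
# Trees under search are plain integer edge matrices (parent, child): tips are
# 1..nTip in the row order of the presence-absence matrix, internal node ids
# are arbitrary integers > nTip, and one node (degree 3 in the unrooted
# representation) has no parent.  Conversion to/from ape's "phylo" happens only
# at the user-facing boundary.

.threeTipEdges <- function(nTip) {
  r <- nTip + 1L
  cbind(c(r, r, r), c(1L, 2L, 3L))
}

# attach `tip` on edge row `row`, introducing internal node `newNode`;
# replacement edges are appended so edge ordering is deterministic
.attachTipEdge <- function(edge, row, tip, newNode) {
  u <- edge[row, 1L]; v <- edge[row, 2L]
  rbind(edge[-row, , drop = FALSE],
        c(u, newNode), c(newNode, v), c(newNode, tip))
}

.edgesToAdj <- function(edge) {
  maxN <- max(edge)
  adj <- vector("list", maxN)
  for (r in seq_len(nrow(edge))) {
    a <- edge[r, 1L]; b <- edge[r, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

.adjToEdges <- function(adj, root) {
  n <- length(adj)
  seen <- logical(n)
  seen[root] <- TRUE
  parent <- integer(0); child <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        parent <- c(parent, v); child <- c(child, w)
        stack <- c(stack, w)
      }
    }
  }
  cbind(parent, child, deparse.level = 0)
}

.rootOfEdges <- function(edge) {
  setdiff(unique(edge[, 1L]), edge[, 2L])[1L]
}

# node order with children before parents
.postorderNodes <- function(edge) {
  kids <- split(edge[, 2L], edge[, 1L])
  root <- .rootOfEdges(edge)
  ord <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    ord <- c(ord, v)
    k <- kids[[as.character(v)]]
    if (!is.null(k)) stack <- c(stack, k)
  }
  rev(ord)
}

# sorted tip ids below every node (root holds all tips)
.nodeTipSets <- function(edge, nTip) {
  kids <- split(edge[, 2L], edge[, 1L])
  sets <- vector("list", max(edge))
  for (v in .postorderNodes(edge)) {
    if (v <= nTip) sets[[v]] <- v
    else sets[[v]] <- sort(unlist(sets[kids[[as.character(v)]]], use.names = FALSE))
  }
  sets
}

# canonical nontrivial split keys; the side excluding tip 1 is stored.
# Fast path encodes sides as tip bitmasks (<= 30 tips).
.splitKeysEdges <- function(edge, nTip) {
  if (nTip <= 30L) {
    kids <- split(edge[, 2L], edge[, 1L])
    mask <- integer(max(edge))
    size <- integer(max(edge))
    for (v in .postorderNodes(edge)) {
      if (v <= nTip) {
        mask[v] <- bitwShiftL(1L, v - 1L)
        size[v] <- 1L
      } else {
        k <- kids[[as.character(v)]]
        m <- 0L
        for (w in k) m <- bitwOr(m, mask[w])
        mask[v] <- m
        size[v] <- sum(size[k])
      }
    }
    full <- bitwShiftL(1L, nTip) - 1L
    m <- mask[edge[, 2L]]
    s <- size[edge[, 2L]]
    flip <- bitwAnd(m, 1L) == 1L
    m[flip] <- bitwXor(full, m[flip])
    s[flip] <- nTip - s[flip]
    return(unique(m[s >= 2L & s <= nTip - 2L]))
  }
  sets <- .nodeTipSets(edge, nTip)
  keys <- character(0)
  full <- seq_len(nTip)
  for (r in seq_len(nrow(edge))) {
    s <- sets[[edge[r, 2L]]]
    if (1L %in% s) s <- setdiff(full, s)
    if (length(s) >= 2L && length(s) <= nTip - 2L)
      keys <- c(keys, paste(s, collapse = ","))
  }
  unique(keys)
}

.treeKeyEdges <- function(edge, nTip) {
  paste(sort(.splitKeysEdges(edge, nTip)), collapse = ";")
}

# ---- enumeration and uniform sampling -------------------------------------

# all unrooted binary labeled topologies over tips 1..n ((2n-5)!! of them)
.enumTopologies <- function(n) {
  if (n < 3L) stop("need at least 3 tips")
  key <- paste0("topo", n)
  if (!is.null(.paeCache[[key]])) return(.paeCache[[key]])
  if (n == 3L) {
    res <- list(.threeTipEdges(3L))
  } else {
    res <- vector("list", prod(seq(3L, 2L * n - 5L, by = 2L)))
    cnt <- 0L
    recur <- function(edge, k) {
      if (k > n) {
        cnt <<- cnt + 1L
        res[[cnt]] <<- edge
        return(invisible(NULL))
      }
      w <- n + k - 2L
      for (i in seq_len(nrow(edge)))
        recur(.attachTipEdge(edge, i, k, w), k + 1L)
      invisible(NULL)
    }
    recur(.threeTipEdges(n), 4L)
  }
  .paeCache[[key]] <- res
  res
}

# one topology uniform over the (2n-5)!! labeled unrooted shapes; uses the
# current RNG stream (sequential insertion at a uniformly chosen edge)
.randomTopologyEdges <- function(n) {
  edge <- .threeTipEdges(n)
  if (n > 3L) {
    for (k in 4:n)
      edge <- .attachTipEdge(edge, sample.int(nrow(edge), 1L), k, n + k - 2L)
  }
  edge
}

# ---- phylo conversion ------------------------------------------------------

.internalToPhylo <- function(edge, tipLabels, root = NULL) {
  nTip <- length(tipLabels)
  if (is.null(root)) root <- .rootOfEdges(edge)
  adj <- .edgesToAdj(edge)
  edge <- .adjToEdges(adj, root)
  nodes <- unique(c(root, edge[, 1L], edge[, 2L]))
  internal <- nodes[nodes > nTip]
  # preorder renumbering puts the root at nTip + 1 as ape requires
  pre <- c(root, edge[, 2L])
  internalPre <- pre[pre > nTip]
  map <- integer(max(nodes))
  map[seq_len(nTip)] <- seq_len(nTip)
  map[internalPre] <- nTip + seq_along(internalPre)
  newEdge <- cbind(map[edge[, 1L]], map[edge[, 2L]], deparse.level = 0)
  phy <- list(edge = newEdge, tip.label = tipLabels, Nnode = length(internal))
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  phy
}

.phyloToInternal <- function(phy, areaLabels) {
  if (!setequal(phy$tip.label, areaLabels) ||
      length(phy$tip.label) != length(areaLabels))
    stop("tree tips and matrix areas do not match")
  nTip <- length(areaLabels)
  m <- match(phy$tip.label, areaLabels)
  edge <- phy$edge
  isTip <- edge <= nTip
  edge[isTip] <- m[edge[isTip]]
  edge
}

# ---- branch swapping -------------------------------------------------------

.subdivideAdj <- function(adj, a, b, w) {
  adj[[a]] <- c(setdiff(adj[[a]], b), w)
  adj[[b]] <- c(setdiff(adj[[b]], a), w)
  if (w > length(adj)) adj[[w]] <- integer(0)
  adj[[w]] <- c(a, b)
  adj
}

.componentNodes <- function(adj, start) {
  seen <- start
  stack <- start
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    nw <- setdiff(adj[[v]], seen)
    seen <- c(seen, nw)
    stack <- c(stack, nw)
  }
  seen
}

# after deleting an edge at endpoint x: suppress x if it became degree 2
# (recording it as a spare node id), or mark it a lone tip; return the list of
# undirected edges of the reduced component
.reduceSide <- function(adj, x) {
  deg <- length(adj[[x]])
  if (deg == 0L)
    return(list(adj = adj, edges = list(), lone = x, spare = NA_integer_))
  if (deg != 2L) stop("internal error: unexpected degree after bisection")
  ab <- adj[[x]]
  adj[[ab[1L]]] <- c(setdiff(adj[[ab[1L]]], x), ab[2L])
  adj[[ab[2L]]] <- c(setdiff(adj[[ab[2L]]], x), ab[1L])
  adj[[x]] <- integer(0)
  comp <- .componentNodes(adj, ab[1L])
  edges <- list()
  for (a in comp)
    for (b in adj[[a]])
      if (a < b) edges[[length(edges) + 1L]] <- c(a, b)
  list(adj = adj, edges = edges, lone = NA_integer_, spare = x)
}

.reconnectSides <- function(adj, sideU, sideV, ea, eb) {
  if (is.null(ea)) w1 <- sideU$lone
  else { w1 <- sideU$spare; adj <- .subdivideAdj(adj, ea[1L], ea[2L], w1) }
  if (is.null(eb)) w2 <- sideV$lone
  else { w2 <- sideV$spare; adj <- .subdivideAdj(adj, eb[1L], eb[2L], w2) }
  adj[[w1]] <- c(adj[[w1]], w2)
  adj[[w2]] <- c(adj[[w2]], w1)
  adj
}

# TBR neighborhood: bisect on every edge (external-edge bisections give the
# tip SPR moves); rejoin every pair of edges across the two reduced subtrees;
# deduplicate by topology and drop the input tree
.tbrNeighborsEdges <- function(edge, nTip, dedup = TRUE) {
  if (nTip < 4L) return(list())
  seen <- if (dedup) .treeKeyEdges(edge, nTip) else NULL
  adj0 <- .edgesToAdj(edge)
  out <- list()
  for (r in seq_len(nrow(edge))) {
    u <- edge[r, 1L]; v <- edge[r, 2L]
    adj <- adj0
    adj[[u]] <- setdiff(adj[[u]], v)
    adj[[v]] <- setdiff(adj[[v]], u)
    sideU <- .reduceSide(adj, u); adj <- sideU$adj
    sideV <- .reduceSide(adj, v); adj <- sideV$adj
    eu <- if (is.na(sideU$lone)) sideU$edges else list(NULL)
    ev <- if (is.na(sideV$lone)) sideV$edges else list(NULL)
    for (ea in eu) {
      for (eb in ev) {
        adj2 <- .reconnectSides(adj, sideU, sideV, ea, eb)
        ne <- .adjToEdges(adj2, adj2[[1L]][1L])
        if (dedup) {
          k <- .treeKeyEdges(ne, nTip)
          if (k %in% seen) next
          seen <- c(seen, k)
        }
        out[[length(out) + 1L]] <- ne
      }
    }
  }
  out
}

# SPR neighborhood: prune the subtree hanging from either end of every edge
# and regraft it onto each edge of the remaining tree
.sprNeighborsEdges <- function(edge, nTip, dedup = TRUE) {
  if (nTip < 4L) return(list())
  seen <- if (dedup) .treeKeyEdges(edge, nTip) else NULL
  adj0 <- .edgesToAdj(edge)
  out <- list()
  for (r in seq_len(nrow(edge))) {
    for (dir in 1:2) {
      x <- edge[r, dir]                      # stays with the remaining tree
      y <- edge[r, 3L - dir]                 # root of the pruned subtree
      if (length(adj0[[x]]) == 1L) next      # remaining side would be a lone tip
      adj <- adj0
      adj[[x]] <- setdiff(adj[[x]], y)
      adj[[y]] <- setdiff(adj[[y]], x)
      side <- .reduceSide(adj, x)
      adj <- side$adj
      for (e in side$edges) {
        adj2 <- .subdivideAdj(adj, e[1L], e[2L], side$spare)
        adj2[[side$spare]] <- c(adj2[[side$spare]], y)
        adj2[[y]] <- c(adj2[[y]], side$spare)
        ne <- .adjToEdges(adj2, adj2[[1L]][1L])
        if (dedup) {
          k <- .treeKeyEdges(ne, nTip)
          if (k %in% seen) next
          seen <- c(seen, k)
        }
        out[[length(out) + 1L]] <- ne
      }
    }
  }
  out
}

# NNI neighborhood: the two swaps across every internal edge
.nniNeighborsEdges <- function(edge, nTip, dedup = TRUE) {
  if (nTip < 4L) return(list())
  seen <- if (dedup) .treeKeyEdges(edge, nTip) else NULL
  adj0 <- .edgesToAdj(edge)
  out <- list()
  internal <- edge[edge[, 2L] > nTip, , drop = FALSE]
  for (r in seq_len(nrow(internal))) {
    u <- internal[r, 1L]; v <- internal[r, 2L]
    bu <- setdiff(adj0[[u]], v)[2L]          # one subtree on u's side
    for (cv in setdiff(adj0[[v]], u)) {      # swap with each subtree on v's side
      adj <- adj0
      adj[[u]] <- c(setdiff(adj[[u]], bu), cv)
      adj[[v]] <- c(setdiff(adj[[v]], cv), bu)
      adj[[bu]] <- c(setdiff(adj[[bu]], u), v)
      adj[[cv]] <- c(setdiff(adj[[cv]], v), u)
      ne <- .adjToEdges(adj, adj[[1L]][1L])
      if (dedup) {
        k <- .treeKeyEdges(ne, nTip)
        if (k %in% seen) next
        seen <- c(seen, k)
      }
      out[[length(out) + 1L]] <- ne
    }
  }
  out
}

#' Sample a uniform random area tree
#'
#' Draws a labeled binary topology uniformly over all `(2n-5)!!` unrooted
#' shapes by sequential insertion of tips at uniformly chosen edges (the same
#' sampler backs the random-tree length distribution and the synthetic-data
#' generator).  For a rooted tree, a root position is then chosen uniformly
#' over the `2n-3` edges.
#'
#' @param labels character tip labels (at least 3; at least 4 when `rooted`).
#' @param rooted logical; return a rooted binary tree?
#' @param seed optional integer seed; `NULL` uses the current RNG stream.
#' @return An object of class `phylo`.
#' @examples
#' randomAreaTree(LETTERS[1:6], seed = 1)
#' @export
randomAreaTree <- function(labels, rooted = FALSE, seed = NULL) {
  n <- length(labels)
  if (n < 3L) stop("need at least 3 labels")
  .withSeed(seed, {
    edge <- .randomTopologyEdges(n)
    if (!rooted) return(.internalToPhylo(edge, labels))
    i <- sample.int(nrow(edge), 1L)
    rootNode <- max(edge) + 1L
    u <- edge[i, 1L]; v <- edge[i, 2L]
    edge <- rbind(edge[-i, , drop = FALSE], c(rootNode, u), c(rootNode, v))
    .internalToPhylo(edge, labels, root = rootNode)
  })
}
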