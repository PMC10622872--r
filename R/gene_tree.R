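#' Gene tree with an explicit migration history
#'
#' A per-locus genealogy under the MSC-M model: a rooted binary tree over the
#' sampled sequences, coalescent times, the population in which every node
#' event occurs, and an ordered list of migration events on the branches.
#' Tracing a lineage rootward from a node, an event `(node, time, to)` means
#' the lineage jumps (backward in time) into population `to`; in forward time
#' this is a migrant moving from `to` into the population the lineage occupied
#' below the event.  Between events a lineage is silently promoted to the
#' ancestral population whenever it crosses a species divergence.
#'
#' @param tip_pop integer vector, population index of each sampled sequence.
#' @param parent integer vector over all `2*ntip - 1` nodes (NA for the root).
#' @param time numeric node times (0 at tips), increasing rootward.
#' @param pop integer population at each node's own time.
#' @param events data frame with columns `node`, `time`, `to` (may have zero
#'   rows).
#' @param labels optional tip labels (`"species^individual"` convention).
#' @return an object of class `mscm_gene_tree`.
#' @export
gene_tree <- function(tip_pop, parent, time, pop, events = NULL,
                      labels = NULL) {
  ntip <- length(tip_pop)
  nnode <- 2L * ntip - 1L
  stopifnot(length(parent) == nnode, length(time) == nnode,
            length(pop) == nnode)
  if (is.null(events) || nrow(events) == 0L)
    events <- data.frame(node = integer(), time = numeric(), to = integer())
  events <- events[order(events$node, events$time), , drop = FALSE]
  rownames(events) <- NULL
  if (is.null(labels)) labels <- paste0("seq", seq_len(ntip))
  structure(list(ntip = ntip, nnode = nnode, tip_pop = as.integer(tip_pop),
                 parent = as.integer(parent), time = as.numeric(time),
                 pop = as.integer(pop), events = events,
                 labels = as.character(labels)),
            class = "mscm_gene_tree")
}

#' @export
print.mscm_gene_tree <- function(x, ...) {
  cat("MSC-M gene tree:", x$ntip, "tips,", nrow(x$events),
      "migration events, root age",
      format(max(x$time), digits = 6), "\n")
  invisible(x)
}

gt_children <- function(gt) {
  ch <- matrix(NA_integer_, gt$nnode, 2L)
  for (v in seq_len(gt$nnode)) {
    p <- gt$parent[v]
    if (!is.na(p)) ch[p, if (is.na(ch[p, 1L])) 1L else 2L] <- v
  }
  ch
}

gt_root <- function(gt) which(is.na(gt$parent))

## Piecewise population path of the branch above `node`:
## data.frame(t0, t1, pop) covering [time[node], time[parent dens]) with
## promotions across species divergences expanded.  For internal use the
## terminal population (at the parent's time, promotions applied) is attached
## as attribute "end_pop".  Errors name the lineage and time on inconsistency.
lineage_path <- function(gt, node, tree, tau) {
  up <- pop_lifespans(tree, tau)[, "up"]
  pa <- gt$parent[node]
  if (is.na(pa)) stop("the root has no parent branch")
  t <- gt$time[node]; tend <- gt$time[pa]
  p <- gt$pop[node]
  ev <- gt$events[gt$events$node == node, , drop = FALSE]
  segs <- list(); k <- 0L
  advance <- function(target) {
    # promote through divergences up to (and including boundaries at) target
    while (up[p] <= target) {
      if (up[p] > t) { k <<- k + 1L; segs[[k]] <<- c(t, up[p], p) }
      t <<- max(t, up[p]); p <<- tree$parent[p]
    }
  }
  if (nrow(ev) > 0L) for (i in seq_len(nrow(ev))) {
    te <- ev$time[i]
    if (te <= t || te >= tend)
      stop(sprintf("migration event at time %g outside branch above node %d",
                   te, node))
    advance(te)
    k <- k + 1L; segs[[k]] <- c(t, te, p)
    t <- te; p <- ev$to[i]
  }
  advance(tend)
  k <- k + 1L; segs[[k]] <- c(t, tend, p)
  out <- do.call(rbind, segs)
  out <- data.frame(t0 = out[, 1L], t1 = out[, 2L], pop = as.integer(out[, 3L]))
  attr(out, "end_pop") <- p
  out
}

#' Check the invariants of a gene tree against an MSC-M model
#'
#' Verifies that coalescent times strictly increase rootward, that every
#' coalescence happens in a population whose lifespan contains it and in which
#' both child lineages reside, that every lineage's population path is
#' consistent with the species tree (merging into the ancestor at species
#' divergences), and that every migration event falls inside the activity
#' window of a declared migration entry.
#'
#' @param gt an `mscm_gene_tree`.
#' @param tree an `mscm_species_tree`.
#' @param mig an `mscm_migration`.
#' @param params an `mscm_params` (only `tau` is used).
#' @return character vector of violations; empty if the gene tree is valid.
#' @export
check_gene_tree <- function(gt, tree, mig, params) {
  tau <- params$tau
  ls <- pop_lifespans(tree, tau)
  out <- character()
  root <- gt_root(gt)
  for (v in seq_len(gt$ntip)) {
    if (gt$time[v] != 0)
      out <- c(out, sprintf("tip %d must have time 0", v))
    if (gt$pop[v] != gt$tip_pop[v])
      out <- c(out, sprintf("tip %d population mismatch", v))
  }
  for (v in seq_len(gt$nnode)) {
    p <- gt$pop[v]
    if (gt$time[v] < ls[p, "lo"] || gt$time[v] >= ls[p, "up"])
      out <- c(out, sprintf(
        "node %d at time %g outside lifespan of population %s",
        v, gt$time[v], tree$labels[p]))
    pa <- gt$parent[v]
    if (!is.na(pa) && gt$time[v] >= gt$time[pa])
      out <- c(out, sprintf("node %d not strictly below its parent", v))
  }
  for (v in setdiff(seq_len(gt$nnode), root)) {
    path <- tryCatch(lineage_path(gt, v, tree, tau), error = function(e) e)
    if (inherits(path, "error")) {
      out <- c(out, conditionMessage(path)); next
    }
    pa <- gt$parent[v]
    if (attr(path, "end_pop") != gt$pop[pa])
      out <- c(out, sprintf(
        "lineage above node %d ends in population %s but coalesces in %s",
        v, tree$labels[attr(path, "end_pop")], tree$labels[gt$pop[pa]]))
  }
  ev <- gt$events
  if (nrow(ev) > 0L) {
    w <- migration_windows(tree, mig, tau)
    for (i in seq_len(nrow(ev))) {
      v <- ev$node[i]; te <- ev$time[i]; s <- ev$to[i]
      path <- tryCatch(lineage_path(gt, v, tree, tau), error = function(e) NULL)
      if (is.null(path)) next  # already reported
      f <- path$pop[which(path$t1 == te & path$t0 < te)][1L]
      if (is.na(f)) f <- path$pop[max(which(path$t1 >= te))]
      e <- which(mig$src == s & mig$dst == f)
      if (length(e) != 1L) {
        out <- c(out, sprintf(
          "migration event at %g on node %d has no declared entry %s->%s",
          te, v, tree$labels[s], tree$labels[f]))
      } else if (te < w[e, "lo"] || te >= w[e, "up"]) {
        out <- c(out, sprintf(
          "migration event at %g on node %d outside activity window of %s->%s",
          te, v, tree$labels[s], tree$labels[f]))
      }
    }
  }
  out
}

#' Total branch lengths of a gene tree
#'
#' @param gt an `mscm_gene_tree`.
#' @return numeric vector of branch lengths (time to parent) per node; NA for
#'   the root.
#' @export
branch_lengths <- function(gt) {
  ifelse(is.na(gt$parent), NA_real_, gt$time[gt$parent] - gt$time)
}
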