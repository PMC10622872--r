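#' Rooted species tree for the MSC-M model
#'
#' Builds the species-tree skeleton used throughout the package from a rooted
#' binary Newick string.  Internal nodes must carry labels because population
#' sizes (theta) and divergence times (tau) are keyed by population label, not
#' by Newick branch lengths (which are ignored).
#'
#' Populations are indexed `1..nsp` for the tip species (in the order they
#' appear in the Newick string) and `nsp+1..2*nsp-1` for ancestral populations,
#' with the root always at index `nsp + 1`.  A population's lifespan is the
#' half-open time interval `[tau_pop, tau_parent)`, with tips starting at time
#' 0 and the root unbounded above; time runs from 0 at the present into the
#' past and is measured in expected mutations per site.
#'
#' @param newick character scalar, rooted binary Newick with internal node
#'   labels, e.g. `"((A, B)S, C)R;"`.
#' @return an object of class `mscm_species_tree` with elements `nsp`, `npop`,
#'   `labels`, `parent` (NA for the root), `children` (two-column matrix, NA
#'   rows for tips), and `root`.
#' @examples
#' tr <- species_tree("((A, B)S, C)R;")
#' tr$labels
#' @export
species_tree <- function(newick) {
  phy <- ape::read.tree(text = newick)
  if (is.null(phy)) stop("could not parse Newick string")
  if (!ape::is.binary(phy) || !ape::is.rooted(phy))
    stop("species tree must be rooted and binary")
  nsp <- length(phy$tip.label)
  npop <- 2L * nsp - 1L
  if (is.null(phy$node.label) || any(phy$node.label == ""))
    stop("all internal nodes of the species tree must be labelled")
  labels <- c(phy$tip.label, phy$node.label)
  if (anyDuplicated(labels))
    stop("species-tree population labels must be unique")
  parent <- rep(NA_integer_, npop)
  children <- matrix(NA_integer_, npop, 2L)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1L]
    ch <- phy$edge[i, 2L]
    parent[ch] <- p
    slot <- if (is.na(children[p, 1L])) 1L else 2L
    children[p, slot] <- ch
  }
  root <- which(is.na(parent))
  if (length(root) != 1L || root != nsp + 1L)
    stop("unexpected rooting; the root must be the first internal node")
  structure(
    list(nsp = nsp, npop = npop, labels = labels, parent = parent,
         children = children, root = root),
    class = "mscm_species_tree")
}

#' @export
print.mscm_species_tree <- function(x, ...) {
  cat("MSC-M species tree:", x$nsp, "species,", x$npop, "populations\n")
  cat("  tips:     ", paste(x$labels[seq_len(x$nsp)], collapse = ", "), "\n")
  cat("  ancestral:", paste(x$labels[(x$nsp + 1L):x$npop], collapse = ", "), "\n")
  invisible(x)
}

pop_index <- function(tree, label) {
  idx <- match(label, tree$labels)
  if (anyNA(idx)) stop("unknown population label: ",
                       paste(label[is.na(idx)], collapse = ", "))
  idx
}

is_tip_pop <- function(tree, pop) pop <= tree$nsp

#' Population lifespans
#'
#' @param tree an `mscm_species_tree`.
#' @param tau numeric vector of length `npop` with divergence times (0 for
#'   tips).
#' @return two-column matrix `lo`, `up`; the root has `up = Inf`.
#' @export
pop_lifespans <- function(tree, tau) {
  lo <- ifelse(seq_len(tree$npop) <= tree$nsp, 0, tau)
  up <- ifelse(is.na(tree$parent), Inf, tau[tree$parent])
  cbind(lo = lo, up = up)
}

#' Directed migration-rate structure
#'
#' Declares which directed migration bands `source -> destination` (forward in
#' time) are in the model.  The rate `M_sj = N_j m_sj` is the expected number
#' of migrants into population j from population s per generation.  A band is
#' active exactly on the overlap of the two populations' lifespans, which
#' depends on the current divergence times.
#'
#' @param tree an `mscm_species_tree`.
#' @param from,to character vectors of population labels (forward-time source
#'   and destination).
#' @return an object of class `mscm_migration` with integer columns `src`,
#'   `dst` and the label columns.
#' @examples
#' tr <- species_tree("((A, B)S, C)R;")
#' migration_spec(tr, c("B", "C"), c("C", "B"))
#' @export
migration_spec <- function(tree, from = character(), to = character()) {
  if (length(from) != length(to)) stop("'from' and 'to' lengths differ")
  src <- pop_index(tree, from)
  dst <- pop_index(tree, to)
  if (any(src == dst)) stop("self-migration entries are not allowed")
  if (anyDuplicated(paste(src, dst)))
    stop("duplicate migration entries")
  structure(
    list(n = length(src), src = src, dst = dst,
         from = as.character(from), to = as.character(to)),
    class = "mscm_migration")
}

#' @export
print.mscm_migration <- function(x, ...) {
  if (x$n == 0L) cat("MSC-M migration spec: no entries\n")
  else cat("MSC-M migration spec:",
           paste(x$from, "->", x$to, collapse = ", "), "\n")
  invisible(x)
}

mig_labels <- function(mig) {
  if (mig$n == 0L) character() else paste0("M_", mig$from, "_", mig$to)
}

#' Activity windows of migration entries
#'
#' An entry `s -> j` is active on the (possibly empty) overlap of the
#' lifespans of s and j.
#'
#' @inheritParams pop_lifespans
#' @param mig an `mscm_migration`.
#' @return two-column matrix (`lo`, `up`) with one row per entry; `lo >= up`
#'   marks an inactive entry.
#' @export
migration_windows <- function(tree, mig, tau) {
  ls <- pop_lifespans(tree, tau)
  lo <- pmax(ls[mig$src, "lo"], ls[mig$dst, "lo"])
  up <- pmin(ls[mig$src, "up"], ls[mig$dst, "up"])
  cbind(lo = lo, up = up)
}

#' Currently active migration entries
#'
#' @inheritParams migration_windows
#' @return data frame with columns `from`, `to` for the entries whose source
#'   and destination populations are contemporaries under the given `tau`.
#' @examples
#' tr <- species_tree("((A, B)S, (C, D)T)R;")
#' mig <- migration_spec(tr, "S", "C")
#' tau <- c(0, 0, 0, 0, 0.03, 0.01, 0.02)  # tau_S < tau_T: S and C coexist
#' active_migration_entries(tr, mig, tau)
#' @export
active_migration_entries <- function(tree, mig, tau) {
  w <- migration_windows(tree, mig, tau)
  keep <- w[, "lo"] < w[, "up"]
  data.frame(from = mig$from[keep], to = mig$to[keep],
             stringsAsFactors = FALSE)
}
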