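DNA_CODES <- c(T = 0L, C = 1L, A = 2L, G = 3L, U = 0L)

chars_to_codes <- function(ch) {
  idx <- DNA_CODES[toupper(ch)]
  out <- ifelse(is.na(idx), -1L, idx)  # gaps/ambiguity -> missing
  as.integer(out)
}

codes_to_chars <- function(codes) {
  ifelse(codes < 0, "-", c("T", "C", "A", "G")[codes + 1L])
}

#' Read a control file
#'
#' Parses the flat bpp-flavoured `key = value` dialect used by the
#' command-line interface.  Lines are `key = value` (value may contain
#' spaces); `migration = FROM TO [rate]` lines may repeat; `#` starts a
#' comment.  Unknown keys and duplicate non-migration keys are rejected with
#' their line number.
#'
#' @param path file path.
#' @return list of class `mscm_config_file` with fields `species`, `tree`,
#'   `theta`, `tau`, `migration` (data frame from/to/rate), prior settings,
#'   run settings and file paths.
#' @export
read_control <- function(path) {
  lines <- readLines(path, warn = FALSE)
  known <- c("species", "tree", "theta", "tau", "migration", "thetaprior",
             "tauprior", "migprior", "seqfile", "outfile", "treefile",
             "loci", "seqs", "sites", "heredity", "seed", "burnin",
             "iterations", "thin", "kernel", "sprfreq")
  cfg <- list(migration = data.frame(from = character(), to = character(),
                                     rate = numeric()))
  seen <- character()
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (ln == "") next
    if (!grepl("=", ln, fixed = TRUE))
      stop(sprintf("%s:%d: expected 'key = value'", path, i))
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% known)
      stop(sprintf("%s:%d: unknown key '%s'", path, i, key))
    if (key == "migration") {
      parts <- strsplit(val, "\\s+")[[1L]]
      if (length(parts) < 2L)
        stop(sprintf("%s:%d: migration needs 'from to [rate]'", path, i))
      cfg$migration <- rbind(cfg$migration, data.frame(
        from = parts[1L], to = parts[2L],
        rate = if (length(parts) >= 3L) as.numeric(parts[3L]) else NA_real_))
      next
    }
    if (key %in% seen)
      stop(sprintf("%s:%d: duplicate key '%s'", path, i, key))
    seen <- c(seen, key)
    cfg[[key]] <- val
  }
  num_keys <- c("loci", "seqs", "sites", "heredity", "seed", "burnin",
                "iterations", "thin", "sprfreq")
  for (k in intersect(num_keys, names(cfg)))
    cfg[[k]] <- as.numeric(strsplit(cfg[[k]], "\\s+")[[1L]])
  for (k in intersect(c("theta", "tau"), names(cfg))) {
    parts <- strsplit(cfg[[k]], "\\s+")[[1L]]
    if (length(parts) %% 2L != 0L)
      stop(sprintf("%s: '%s' must be 'label value' pairs", path, k))
    v <- as.numeric(parts[c(FALSE, TRUE)])
    names(v) <- parts[c(TRUE, FALSE)]
    cfg[[k]] <- v
  }
  for (k in intersect(c("thetaprior", "tauprior", "migprior"), names(cfg)))
    cfg[[k]] <- as.numeric(strsplit(cfg[[k]], "\\s+")[[1L]])
  if ("species" %in% names(cfg))
    cfg$species <- strsplit(cfg$species, "\\s+")[[1L]]
  class(cfg) <- "mscm_config_file"
  cfg
}

#' Serialise a control configuration
#'
#' Inverse of [read_control()]; `parse(serialise(x))` is the identity.
#'
#' @param cfg an `mscm_config_file`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_control <- function(cfg, path) {
  lines <- character()
  for (k in setdiff(names(cfg), "migration")) {
    v <- cfg[[k]]
    val <- if (!is.null(names(v)) && any(names(v) != ""))
      paste(names(v), v, collapse = "  ")
    else paste(v, collapse = " ")
    lines <- c(lines, paste(k, "=", val))
  }
  if (nrow(cfg$migration) > 0L)
    for (i in seq_len(nrow(cfg$migration))) {
      r <- cfg$migration[i, ]
      lines <- c(lines, paste("migration =", r$from, r$to,
                              if (is.na(r$rate)) "" else r$rate))
    }
  writeLines(trimws(lines), path)
  invisible(path)
}

parse_label_species <- function(labels) {
  if (!all(grepl("^[^^]+\\^", labels)))
    stop("sequence labels must follow the 'species^individual' convention: ",
         paste(utils::head(labels[!grepl("\\^", labels)], 3L), collapse = ", "))
  sub("\\^.*$", "", labels)
}

#' Read multilocus sequence data
#'
#' Supports the multilocus PHYLIP dialect (consecutive blocks, each starting
#' with `ntax nsites` followed by `label  sequence` lines, blocks separated by
#' blank lines) and per-locus FASTA files.  Labels must follow the
#' `species^individual` convention so that sequences can be assigned to
#' populations.
#'
#' @param paths one path (PHYLIP, possibly multi-block) or several (FASTA,
#'   one file per locus).
#' @param format `"phylip"` or `"fasta"`.
#' @param heredity per-locus heredity scalars (recycled).
#' @return list of `mscm_locus`.
#' @export
read_loci <- function(paths, format = c("phylip", "fasta"), heredity = 1) {
  format <- match.arg(format)
  if (format == "fasta") {
    loci <- lapply(paths, function(p) {
      dn <- ape::read.FASTA(p)
      chs <- as.character(dn)
      seqs <- t(vapply(chs, function(row) chars_to_codes(toupper(row)),
                       integer(length(chs[[1L]]))))
      labs <- names(dn)
      parse_label_species(labs)
      structure(list(seqs = unname(seqs), labels = labs, h = 1),
                class = "mscm_locus")
    })
  } else {
    lines <- readLines(paths[[1L]], warn = FALSE)
    loci <- list()
    i <- 1L
    while (i <= length(lines)) {
      if (trimws(lines[i]) == "") { i <- i + 1L; next }
      hd <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
      if (length(hd) != 2L)
        stop(sprintf("%s:%d: expected 'ntax nsites' block header",
                     paths[[1L]], i))
      ntax <- as.integer(hd[1L]); nsites <- as.integer(hd[2L])
      labs <- character(ntax)
      seqs <- matrix(-1L, ntax, nsites)
      for (k in seq_len(ntax)) {
        i <- i + 1L
        parts <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
        labs[k] <- parts[1L]
        sq <- paste(parts[-1L], collapse = "")
        if (nchar(sq) != nsites)
          stop(sprintf("%s:%d: sequence has %d sites, expected %d",
                       paths[[1L]], i, nchar(sq), nsites))
        seqs[k, ] <- chars_to_codes(strsplit(sq, "")[[1L]])
      }
      parse_label_species(labs)
      loci[[length(loci) + 1L]] <-
        structure(list(seqs = seqs, labels = labs, h = 1),
                  class = "mscm_locus")
      i <- i + 1L
    }
  }
  if (length(heredity) == 1L) heredity <- rep(heredity, length(loci))
  for (k in seq_along(loci)) loci[[k]]$h <- heredity[k]
  loci
}

#' Write multilocus data as multi-block PHYLIP
#'
#' @param loci list of `mscm_locus`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_loci <- function(loci, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (lc in loci) {
    writeLines(paste(nrow(lc$seqs), ncol(lc$seqs)), con)
    for (i in seq_len(nrow(lc$seqs)))
      writeLines(paste0(format(lc$labels[i], width = 12L), "  ",
                        paste(codes_to_chars(lc$seqs[i, ]), collapse = "")),
                 con)
    writeLines("", con)
  }
  invisible(path)
}

#' Write an MCMC trace as tab-separated samples
#'
#' The header comment records the seed and a hash of the run configuration so
#' outputs are self-describing.
#'
#' @param trace an `mscm_trace` or samples matrix.
#' @param path output file.
#' @param seed,config optional metadata when `trace` is a bare matrix.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, seed = NULL, config = NULL) {
  if (inherits(trace, "mscm_trace")) {
    seed <- trace$seed
    config <- trace$control
    m <- trace$samples
  } else m <- trace
  hash <- substr(digest_config(config), 1L, 12L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed=%s config=%s", format(seed), hash), con)
  writeLines(paste(colnames(m), collapse = "\t"), con)
  utils::write.table(m, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

digest_config <- function(config) {
  if (is.null(config)) return("none")
  txt <- paste(deparse(config), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * seq_len(nchar(txt))) %% .Machine$integer.max)
}

#' Read a trace written by [write_trace()]
#'
#' @param path file path.
#' @return matrix of samples with attributes `seed` and `config_hash`.
#' @export
read_trace <- function(path) {
  first <- readLines(path, n = 1L)
  meta <- regmatches(first, regexec("# seed=(\\S+) config=(\\S+)", first))[[1L]]
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   comment.char = "#",
                                   check.names = FALSE))
  attr(m, "seed") <- if (length(meta) == 3L) meta[2L] else NA
  attr(m, "config_hash") <- if (length(meta) == 3L) meta[3L] else NA
  m
}

## ---- annotated gene-tree Newick -------------------------------------------

fmt_num <- function(x) sprintf("%.17g", x)

#' Serialise a gene tree to annotated Newick
#'
#' Standard Newick extended with comment tags: every node carries
#' `[&t=<time>,pop=<label>]` and branches with migration events append
#' `,mig={<time>:<to-label>,...}` (events in ascending time, `to` being the
#' population entered backward in time).  The format round-trips exactly
#' through [read_gene_tree()].
#'
#' @param gt an `mscm_gene_tree`.
#' @param tree the `mscm_species_tree` providing population labels.
#' @return a single Newick string.
#' @export
write_gene_tree <- function(gt, tree) {
  ch <- gt_children(gt)
  lab <- tree$labels
  node_str <- function(v) {
    core <- if (v <= gt$ntip) gt$labels[v]
            else paste0("(", node_str(ch[v, 1L]), ",", node_str(ch[v, 2L]), ")")
    ann <- paste0("[&t=", fmt_num(gt$time[v]), ",pop=", lab[gt$pop[v]])
    ev <- gt$events[gt$events$node == v, , drop = FALSE]
    if (nrow(ev) > 0L)
      ann <- paste0(ann, ",mig={",
                    paste0(fmt_num(ev$time), ":", lab[ev$to], collapse = ","),
                    "}")
    ann <- paste0(ann, "]")
    pa <- gt$parent[v]
    bl <- if (is.na(pa)) "" else paste0(":", fmt_num(gt$time[pa] - gt$time[v]))
    paste0(core, ann, bl)
  }
  paste0(node_str(gt_root(gt)), ";")
}

#' Parse an annotated gene-tree Newick string
#'
#' @param text Newick string produced by [write_gene_tree()].
#' @param tree the `mscm_species_tree` for population labels.
#' @return an `mscm_gene_tree`.
#' @export
read_gene_tree <- function(text, tree) {
  s <- gsub("\\s", "", text)
  pos <- 1L
  peek <- function() substr(s, pos, pos)
  nodes <- list()  # each: label, time, pop, children, events(data.frame)
  parse_annotation <- function() {
    if (peek() != "[") stop("expected annotation at position ", pos)
    close_ <- regexpr("]", substr(s, pos, nchar(s)), fixed = TRUE)
    ann <- substr(s, pos + 2L, pos + close_ - 2L)  # strip [& and ]
    pos <<- pos + close_
    ev <- NULL
    if (grepl("mig={", ann, fixed = TRUE)) {
      inner <- sub(".*mig=\\{([^}]*)\\}.*", "\\1", ann)
      ann <- sub(",mig=\\{[^}]*\\}", "", ann)
      if (nchar(inner) > 0L) {
        parts <- strsplit(inner, ",", fixed = TRUE)[[1L]]
        tt <- as.numeric(sub(":.*", "", parts))
        to <- sub(".*:", "", parts)
        ev <- data.frame(time = tt, to = pop_index(tree, to))
      }
    }
    fields <- strsplit(ann, ",", fixed = TRUE)[[1L]]
    kv <- sub("=.*$", "", fields)
    t <- as.numeric(sub("^t=", "", fields[kv == "t"]))
    popl <- sub("^pop=", "", fields[kv == "pop"])
    list(time = t, pop = pop_index(tree, popl), events = ev)
  }
  skip_branch <- function() {
    if (peek() == ":") {
      mnum <- regexpr("^:[-+0-9.eE]+", substr(s, pos, nchar(s)))
      pos <<- pos + attr(mnum, "match.length")
    }
  }
  parse2 <- function() {
    if (peek() == "(") {
      pos <<- pos + 1L
      left <- parse2()
      if (peek() != ",") stop("expected ','")
      pos <<- pos + 1L
      right <- parse2()
      if (peek() != ")") stop("expected ')'")
      pos <<- pos + 1L
      ann <- parse_annotation()
      skip_branch()
      idx <- length(nodes) + 1L
      nodes[[idx]] <<- c(list(label = NA_character_,
                              children = c(left, right)), ann)
      idx
    } else {
      mlab <- regexpr("^[^][(),:;]+", substr(s, pos, nchar(s)))
      if (attr(mlab, "match.length") < 1L)
        stop("expected a tip label at position ", pos)
      lab <- substr(s, pos, pos + attr(mlab, "match.length") - 1L)
      pos <<- pos + attr(mlab, "match.length")
      ann <- parse_annotation()
      skip_branch()
      idx <- length(nodes) + 1L
      nodes[[idx]] <<- c(list(label = lab, children = NULL), ann)
      idx
    }
  }
  root_idx <- parse2()
  if (peek() != ";") stop("expected ';' at end")
  tipsq <- which(vapply(nodes, function(n) is.null(n$children), TRUE))
  ntip <- length(tipsq)
  # renumber: tips in parse order 1..ntip, internals ntip+1..
  newid <- integer(length(nodes))
  newid[tipsq] <- seq_len(ntip)
  newid[setdiff(seq_along(nodes), tipsq)] <- ntip + seq_len(length(nodes) - ntip)
  nnode <- length(nodes)
  parent <- rep(NA_integer_, nnode); time <- numeric(nnode)
  pop <- integer(nnode); labels <- character(ntip)
  evl <- list()
  for (i in seq_along(nodes)) {
    n <- nodes[[i]]; v <- newid[i]
    time[v] <- n$time; pop[v] <- n$pop
    if (is.null(n$children)) labels[v] <- n$label
    else for (cidx in n$children) parent[newid[cidx]] <- v
    if (!is.null(n$events))
      evl[[length(evl) + 1L]] <- cbind(node = v, n$events)
  }
  events <- if (length(evl) > 0L) do.call(rbind, evl) else NULL
  if (!is.null(events)) events <- events[, c("node", "time", "to")]
  gene_tree(tip_pop = pop[seq_len(ntip)], parent = parent, time = time,
            pop = pop, events = events, labels = labels)
}
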