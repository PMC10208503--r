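#' Construct a causal DAG
#'
#' Builds a validated directed acyclic graph over named variables, each
#' flagged observed or latent.  Latent nodes participate in paths (and hence
#' in d-separation) but are never admissible in conditioning or adjustment
#' sets.
#'
#' @param edges two-column character matrix (or data.frame) of parent ->
#'   child pairs.
#' @param latent character vector of latent node names (must appear among
#'   the edge endpoints or `nodes`).
#' @param nodes optional character vector of additional (isolated) nodes.
#' @return an object of class `causal_dag` with elements `nodes`, `latent`,
#'   `observed` and `edges`.
#' @export
causal_dag <- function(edges, latent = character(), nodes = character()) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  }
  if (ncol(edges) != 2L) stop("`edges` must have two columns (parent, child)")
  storage.mode(edges) <- "character"
  all_nodes <- sort(unique(c(as.vector(edges), nodes)))
  if (any(edges[, 1L] == edges[, 2L])) {
    bad <- edges[edges[, 1L] == edges[, 2L], 1L][1L]
    stop("self-loop on node '", bad, "'")
  }
  key <- paste(edges[, 1L], edges[, 2L], sep = "\r")
  if (anyDuplicated(key)) {
    bad <- edges[duplicated(key), , drop = FALSE][1L, ]
    stop("duplicate edge '", bad[1L], " -> ", bad[2L], "'")
  }
  latent <- sort(unique(latent))
  if (!all(latent %in% all_nodes)) {
    stop("latent flag on unknown node(s): ",
         paste(setdiff(latent, all_nodes), collapse = ", "))
  }
  observed <- setdiff(all_nodes, latent)
  if (length(observed) == 0L) stop("DAG must contain at least one observed node")
  dag <- structure(
    list(nodes = all_nodes, latent = latent, observed = observed,
         edges = edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]),
    class = "causal_dag")
  ord <- topo_order(dag)   # errors on cycles
  dag$topo <- ord
  dag
}

#' Parse a DAG from edge-list text
#'
#' The format is one `Parent -> Child` edge per line, with optional
#' `latent: Name` declarations, optional `node: Name` declarations for
#' isolated nodes, blank lines, and `#` comments (full-line or trailing).
#' Line order is irrelevant.
#'
#' @param text a character scalar (possibly multi-line) or character vector
#'   of lines.
#' @return a [causal_dag()] object.
#' @export
parse_dag <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  from <- character(); to <- character()
  latent <- character(); extra <- character()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) next
    if (grepl("^latent\\s*:", ln)) {
      nm <- trimws(strsplit(sub("^latent\\s*:", "", ln), ",")[[1L]])
      latent <- c(latent, nm[nzchar(nm)])
    } else if (grepl("^node\\s*:", ln)) {
      nm <- trimws(strsplit(sub("^node\\s*:", "", ln), ",")[[1L]])
      extra <- c(extra, nm[nzchar(nm)])
    } else if (grepl("->", ln, fixed = TRUE)) {
      parts <- trimws(strsplit(ln, "->", fixed = TRUE)[[1L]])
      if (length(parts) != 2L || !all(nzchar(parts))) {
        stop("cannot parse edge on line ", i, ": '", ln, "'")
      }
      from <- c(from, parts[1L]); to <- c(to, parts[2L])
    } else {
      stop("cannot parse line ", i, ": '", ln, "'")
    }
  }
  causal_dag(cbind(from, to), latent = latent, nodes = extra)
}

#' Read a DAG from an edge-list file
#'
#' @param path path to a text file in the [parse_dag()] format.
#' @return a [causal_dag()] object.
#' @export
read_dag <- function(path) {
  parse_dag(readLines(path, warn = FALSE))
}

#' The pinned study DAG
#'
#' Returns the structural causal model used throughout the package for the
#' cerebral-palsy metabolic power analysis: 11 observed variables (the four
#' impairment scores, GDI, walking speed, net metabolic power, age, sex,
#' height, mass) plus one latent node for the initial brain injury.  The
#' graph ships as a plain-text edge list under `inst/extdata` so that
#' alternative reconstructions can be swapped in; it is one reconstruction
#' consistent with the published adjustment sets, not an author-supplied
#' arrow list.
#'
#' @return a [causal_dag()] object.
#' @export
study_dag <- function() {
  read_dag(system.file("extdata", "metpower_dag.txt",
                       package = "gaitcausal", mustWork = TRUE))
}

#' @export
print.causal_dag <- function(x, ...) {
  cat("causal_dag: ", length(x$nodes), " nodes (",
      length(x$observed), " observed, ", length(x$latent), " latent), ",
      nrow(x$edges), " edges\n", sep = "")
  if (length(x$latent)) cat("latent:", paste(x$latent, collapse = ", "), "\n")
  invisible(x)
}

# Kahn topological sort; errors naming a node on a cycle.
topo_order <- function(dag) {
  nodes <- dag$nodes
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tab <- table(dag$edges[, 2L])
  indeg[names(tab)] <- as.integer(tab)
  kids <- split(dag$edges[, 2L], factor(dag$edges[, 1L], levels = nodes))
  out <- character(0)
  queue <- names(indeg)[indeg == 0L]
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (w in kids[[v]]) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) != length(nodes)) {
    stop("cycle detected involving node(s): ",
         paste(setdiff(nodes, out), collapse = ", "))
  }
  out
}

check_nodes <- function(dag, vars) {
  bad <- setdiff(vars, dag$nodes)
  if (length(bad)) stop("unknown variable name(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Graph accessors
#'
#' Parents, children, ancestors and descendants of nodes in a
#' [causal_dag()].  Ancestor/descendant sets are inclusive of the query
#' nodes themselves.
#'
#' @param dag a [causal_dag()].
#' @param v a single node name.
#' @param vs a character vector of node names.
#' @return character vector of node names.
#' @name dag-accessors
NULL

#' @rdname dag-accessors
#' @export
dag_parents <- function(dag, v) dag$edges[dag$edges[, 2L] == v, 1L]

#' @rdname dag-accessors
#' @export
dag_children <- function(dag, v) dag$edges[dag$edges[, 1L] == v, 2L]

#' @rdname dag-accessors
#' @export
dag_ancestors <- function(dag, vs) {
  seen <- vs
  frontier <- vs
  while (length(frontier)) {
    pa <- unique(dag$edges[dag$edges[, 2L] %in% frontier, 1L])
    frontier <- setdiff(pa, seen)
    seen <- c(seen, frontier)
  }
  sort(seen)
}

#' @rdname dag-accessors
#' @export
dag_descendants <- function(dag, vs) {
  seen <- vs
  frontier <- vs
  while (length(frontier)) {
    ch <- unique(dag$edges[dag$edges[, 1L] %in% frontier, 2L])
    frontier <- setdiff(ch, seen)
    seen <- c(seen, frontier)
  }
  sort(seen)
}

#' Test d-separation
#'
#' Decides whether `x` and `y` are d-separated given the conditioning set
#' `given`, i.e. whether every path between them is blocked under the usual
#' chain/fork/collider rules.  Implemented as reachability on the moralized
#' ancestral graph of `{x, y} U given`.  Latent nodes participate in paths;
#' whether they may be conditioned on is a concern of higher-level callers,
#' not of this primitive.
#'
#' @param dag a [causal_dag()].
#' @param x,y distinct variable names, not in `given`.
#' @param given character vector of conditioning variables (default empty).
#' @return `TRUE` if d-separated, `FALSE` if d-connected.
#' @export
d_separated <- function(dag, x, y, given = character()) {
  given <- unique(as.character(given))
  check_nodes(dag, c(x, y, given))
  if (x == y) stop("x and y must be distinct")
  if (x %in% given || y %in% given) stop("x and y must not be in `given`")

  anc <- dag_ancestors(dag, c(x, y, given))
  sub <- dag$edges[dag$edges[, 1L] %in% anc & dag$edges[, 2L] %in% anc, ,
                   drop = FALSE]
  # moralize: undirected skeleton + marry co-parents of every node
  und <- rbind(sub, sub[, 2:1, drop = FALSE])
  for (v in unique(sub[, 2L])) {
    pa <- sub[sub[, 2L] == v, 1L]
    if (length(pa) > 1L) {
      pairs <- t(utils::combn(pa, 2L))
      und <- rbind(und, pairs, pairs[, 2:1, drop = FALSE])
    }
  }
  # delete conditioning set, then check connectivity x -> y
  keep <- !(und[, 1L] %in% given) & !(und[, 2L] %in% given)
  und <- und[keep, , drop = FALSE]
  seen <- x
  frontier <- x
  while (length(frontier)) {
    nb <- unique(und[und[, 1L] %in% frontier, 2L])
    frontier <- setdiff(nb, seen)
    if (y %in% frontier) return(FALSE)
    seen <- c(seen, frontier)
  }
  TRUE
}

# Deterministic subset generator: all subsets of `pool` of size `k`, as a
# list, in lexicographic order given sorted pool.
subsets_of_size <- function(pool, k) {
  if (k == 0L) return(list(character(0)))
  if (k > length(pool)) return(list())
  m <- utils::combn(pool, k)
  lapply(seq_len(ncol(m)), function(j) m[, j])
}

#' Implied conditional independencies
#'
#' Enumerates a basis set of testable implications: for every pair of
#' non-adjacent observed nodes, one statement `x _||_ y | Z` with a
#' minimum-cardinality separating set `Z` of observed nodes, when such a set
#' exists.  Pairs that cannot be separated by observed nodes (e.g. two
#' children of a shared latent cause) yield no statement.  Output is
#' deterministically ordered, lexicographically by `(x, y)`.
#'
#' @param dag a [causal_dag()].
#' @param max_given maximum conditioning-set size searched (default 8); an
#'   error is raised if the cap prevents deciding a pair.
#' @return list of statements, each `list(x =, y =, given =)`, of class
#'   `independence_statements`.
#' @export
implied_independencies <- function(dag, max_given = 8L) {
  obs <- sort(dag$observed)
  adj <- paste(dag$edges[, 1L], dag$edges[, 2L], sep = "\r")
  out <- list()
  if (length(obs) >= 2L) {
    pairs <- utils::combn(obs, 2L)
    for (j in seq_len(ncol(pairs))) {
      x <- pairs[1L, j]; y <- pairs[2L, j]
      if (paste(x, y, sep = "\r") %in% adj || paste(y, x, sep = "\r") %in% adj)
        next
      # Minimal separators live inside the ancestors of {x, y}; if the full
      # canonical candidate set fails, no observed set separates the pair.
      canon <- setdiff(intersect(dag_ancestors(dag, c(x, y)), dag$observed),
                       c(x, y))
      if (!d_separated(dag, x, y, canon)) next
      found <- NULL
      for (k in 0:min(max_given, length(canon))) {
        for (s in subsets_of_size(canon, k)) {
          if (d_separated(dag, x, y, s)) { found <- s; break }
        }
        if (!is.null(found)) break
      }
      if (is.null(found)) {
        stop("conditioning-set size cap (", max_given, ") binds for pair ",
             x, ", ", y)
      }
      out[[length(out) + 1L]] <- list(x = x, y = y, given = found)
    }
  }
  structure(out, class = "independence_statements")
}

#' @export
print.independence_statements <- function(x, ...) {
  if (!length(x)) { cat("no testable implications\n"); return(invisible(x)) }
  for (s in x) {
    cond <- if (length(s$given)) paste(s$given, collapse = ", ") else "{}"
    cat(s$x, "_||_", s$y, "|", cond, "\n")
  }
  invisible(x)
}

# Backdoor validity of candidate set S for exposure -> outcome:
# S contains no descendant of exposure (guaranteed by caller) and blocks all
# backdoor paths, i.e. exposure _||_ outcome given S in the graph with the
# exposure's outgoing edges removed.
backdoor_valid <- function(dag, exposure, outcome, s) {
  keep <- dag$edges[, 1L] != exposure
  g <- dag
  g$edges <- dag$edges[keep, , drop = FALSE]
  # outcome may become disconnected from exposure entirely: then separated.
  d_separated(g, exposure, outcome, s)
}

#' Minimal backdoor adjustment sets for a total effect
#'
#' Enumerates all minimal sets of observed covariates satisfying the
#' backdoor criterion for the total effect of `exposure` on `outcome`: no
#' member is a descendant of the exposure (so no mediator is conditioned
#' on), no member is latent, and the set blocks every backdoor path.
#' Minimality means no proper subset suffices.  Search is smallest-first
#' over observed non-descendants with supersets of valid sets pruned;
#' output order is deterministic (by size, then lexicographic).
#'
#' @param dag a [causal_dag()].
#' @param exposure,outcome distinct observed variable names.
#' @return object of class `adjustment_sets`: `list(sets = <list of
#'   character vectors>, identifiable = <logical>, exposure, outcome)`.
#'   When no observed set satisfies the criterion, `identifiable` is
#'   `FALSE` and `sets` is empty ("not identifiable by covariate
#'   adjustment") rather than an error.
#' @export
minimal_adjustment_sets <- function(dag, exposure, outcome) {
  check_nodes(dag, c(exposure, outcome))
  if (exposure == outcome) stop("exposure and outcome must be distinct")
  if (!(exposure %in% dag$observed) || !(outcome %in% dag$observed)) {
    stop("exposure and outcome must be observed nodes")
  }
  cand <- sort(setdiff(dag$observed,
                       c(dag_descendants(dag, exposure), outcome)))
  if (length(cand) > 20L) {
    stop("too many candidate covariates (", length(cand),
         ") for exhaustive minimal-set enumeration")
  }
  sets <- list()
  for (k in 0:length(cand)) {
    for (s in subsets_of_size(cand, k)) {
      if (length(sets) &&
          any(vapply(sets, function(m) all(m %in% s), logical(1L)))) {
        next  # superset of a known minimal set
      }
      if (backdoor_valid(dag, exposure, outcome, s)) {
        sets[[length(sets) + 1L]] <- s
      }
    }
  }
  structure(list(sets = sets, identifiable = length(sets) > 0L,
                 exposure = exposure, outcome = outcome),
            class = "adjustment_sets")
}

#' @export
print.adjustment_sets <- function(x, ...) {
  cat("total effect:", x$exposure, "->", x$outcome, "\n")
  if (!x$identifiable) {
    cat("not identifiable by covariate adjustment\n")
  } else {
    for (s in x$sets) {
      cat("  {", paste(s, collapse = ", "), "}\n")
    }
  }
  invisible(x)
}
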