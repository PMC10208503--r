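# Independent oracles used across the test files.

# Brute-force d-separation: enumerate every simple path in the skeleton and
# apply the chain/fork/collider blocking rules directly.  Works straight off
# the edge matrix, independently of the package's reachability algorithm.
oracle_d_separated <- function(dag, x, y, given = character()) {
  edges <- dag$edges
  nodes <- dag$nodes
  nbrs <- lapply(stats::setNames(nodes, nodes), function(v) {
    unique(c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1]))
  })
  is_edge <- function(a, b) any(edges[, 1] == a & edges[, 2] == b)
  desc_of <- function(v) {
    seen <- v; frontier <- v
    while (length(frontier)) {
      ch <- unique(edges[edges[, 1] %in% frontier, 2])
      frontier <- setdiff(ch, seen)
      seen <- c(seen, frontier)
    }
    seen
  }
  path_open <- function(path) {
    if (length(path) < 3L) return(TRUE)
    for (i in 2:(length(path) - 1L)) {
      a <- path[i - 1L]; b <- path[i]; c <- path[i + 1L]
      collider <- is_edge(a, b) && is_edge(c, b)
      if (collider) {
        if (!length(intersect(desc_of(b), given))) return(FALSE)
      } else {
        if (b %in% given) return(FALSE)
      }
    }
    TRUE
  }
  found_open <- FALSE
  dfs <- function(path) {
    if (found_open) return()
    v <- path[length(path)]
    if (v == y) {
      if (path_open(path)) found_open <<- TRUE
      return()
    }
    for (w in nbrs[[v]]) {
      if (!w %in% path) dfs(c(path, w))
    }
  }
  dfs(x)
  !found_open
}

# Random DAG over k nodes: random topological order, each forward edge
# included with probability p.
random_dag <- function(k, p = 0.35) {
  nodes <- LETTERS[seq_len(k)]
  ord <- sample(nodes)
  from <- character(); to <- character()
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    if (stats::runif(1) < p) {
      from <- c(from, ord[i]); to <- c(to, ord[j])
    }
  }
  causal_dag(cbind(from, to), nodes = nodes)
}

# Agreement check of d_separated against the brute-force oracle over every
# (x, y, Z) triple of a DAG.  Returns the number of disagreements.
dsep_disagreements <- function(dag) {
  nodes <- dag$nodes
  bad <- 0L
  prs <- utils::combn(nodes, 2L)
  for (j in seq_len(ncol(prs))) {
    x <- prs[1L, j]; y <- prs[2L, j]
    rest <- setdiff(nodes, c(x, y))
    for (k in 0:length(rest)) {
      zs <- if (k == 0L) list(character(0)) else {
        m <- utils::combn(rest, k)
        lapply(seq_len(ncol(m)), function(i) m[, i])
      }
      for (z in zs) {
        if (d_separated(dag, x, y, z) != oracle_d_separated(dag, x, y, z)) {
          bad <- bad + 1L
        }
      }
    }
  }
  bad
}

# DAG variable -> synthetic cohort column map used throughout.
study_var_map <- c(Age = "age", Sex = "sex", Height = "height",
                   Mass = "mass", Speed = "speed", GDI = "gdi",
                   DMC = "dmc", SMC = "smc", Spasticity = "spasticity",
                   Strength = "strength", MetPower = "power")

# Ordinal items from a thresholded bivariate normal: the Monte-Carlo
# generator used as the oracle for polychoric recovery.
bvn_ordinal_table <- function(n, rho, thresholds = c(-0.5, 0.5)) {
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  br <- c(-Inf, thresholds, Inf)
  table(cut(z1, br, labels = FALSE), cut(z2, br, labels = FALSE))
}

# Small fast BART config for structural tests.
quick_bart <- function(...) {
  bart_config(num_trees = 30L, n_burn = 150L, n_draw = 150L, ...)
}
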