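#' @useDynLib gaitcausal, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Clinical exam layout
#'
#' Six muscle groups assessed bilaterally on three ordinal scales:
#' Ashworth (spasticity) and Kendall (strength) run 1-5; selective motor
#' control (SMC) runs 0-2.
#'
#' @name exam-layout
#' @export
exam_muscles <- c("hip_flexors", "hip_adductors", "rectus_femoris",
                  "hamstrings", "plantarflexors", "tibialis_posterior")

#' @rdname exam-layout
#' @export
exam_sides <- c("L", "R")

#' @rdname exam-layout
#' @export
exam_scales <- list(spasticity = 1:5, strength = 1:5, smc = 0:2)

#' Polychoric correlation of two ordinal items
#'
#' Two-step maximum-likelihood estimate: thresholds are fixed at the inverse
#' standard-normal of the cumulative marginal proportions, then the latent
#' bivariate-normal correlation is chosen to maximize the multinomial
#' log-likelihood of the observed cell counts.  The estimate is clipped to
#' `[-0.999, 0.999]`.
#'
#' @param tab two-way contingency table (matrix of counts), rows = first
#'   item's categories, columns = second item's.
#' @param items optional length-2 character vector of item names, used in
#'   error messages.
#' @return the estimated latent correlation, a scalar in `(-1, 1)`.
#' @export
polychoric_correlation <- function(tab, items = c("item1", "item2")) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || sum(tab) <= 0) stop("`tab` must be nonnegative counts")
  rmarg <- rowSums(tab); cmarg <- colSums(tab)
  # drop empty categories at the margins; they carry no threshold information
  tab <- tab[rmarg > 0, cmarg > 0, drop = FALSE]
  if (nrow(tab) < 2L) stop("item '", items[1L], "' has a degenerate margin ",
                           "(all mass in one category)")
  if (ncol(tab) < 2L) stop("item '", items[2L], "' has a degenerate margin ",
                           "(all mass in one category)")
  n <- sum(tab)
  a <- c(-Inf, stats::qnorm(cumsum(rowSums(tab))[-nrow(tab)] / n), Inf)
  b <- c(-Inf, stats::qnorm(cumsum(colSums(tab))[-ncol(tab)] / n), Inf)

  cellp <- function(rho) {
    # rectangle probabilities from the bivariate-normal CDF
    fa <- length(a); fb <- length(b)
    cdf <- matrix(0, fa, fb)
    for (i in seq_len(fa)) for (j in seq_len(fb)) {
      cdf[i, j] <- bvn_cdf(a[i], b[j], rho)
    }
    p <- cdf[-1L, -1L, drop = FALSE] - cdf[-fa, -1L, drop = FALSE] -
      cdf[-1L, -fb, drop = FALSE] + cdf[-fa, -fb, drop = FALSE]
    pmax(p, 1e-12)
  }
  nll <- function(rho) -sum(tab * log(cellp(rho)))
  opt <- stats::optimize(nll, interval = c(-0.999, 0.999), tol = 1e-6)
  # boundary handling: perfect concordance drives the optimum to the clip
  cands <- c(opt$minimum, -0.999, 0.999)
  vals <- c(opt$objective, nll(-0.999), nll(0.999))
  cands[which.min(vals)]
}

# Standard bivariate normal CDF P(X <= x, Y <= y) with correlation rho.
bvn_cdf <- function(x, y, rho) {
  if (is.infinite(x) && x < 0) return(0)
  if (is.infinite(y) && y < 0) return(0)
  if (is.infinite(x) && is.infinite(y)) return(1)
  if (is.infinite(x)) return(stats::pnorm(y))
  if (is.infinite(y)) return(stats::pnorm(x))
  mvtnorm::pmvnorm(upper = c(x, y),
                   corr = matrix(c(1, rho, rho, 1), 2L))[1L]
}

#' Pairwise polychoric correlation matrix of ordinal items
#'
#' Computes the polychoric correlation for every item pair using
#' pairwise-complete observations, then repairs the result to the nearest
#' positive semidefinite matrix by clipping negative eigenvalues at zero and
#' rescaling to unit diagonal.
#'
#' @param items integer/numeric matrix or data.frame, one row per child, one
#'   column per ordinal item; `NA` allowed.
#' @return symmetric PSD correlation matrix with unit diagonal.
#' @export
polychoric_matrix <- function(items) {
  m <- as.matrix(items)
  p <- ncol(m)
  if (p < 2L) stop("need at least two items")
  nm <- colnames(m)
  if (is.null(nm)) nm <- paste0("item", seq_len(p))
  for (j in seq_len(p)) {
    v <- m[, j][!is.na(m[, j])]
    if (length(unique(v)) < 2L) stop("item '", nm[j], "' is constant")
  }
  r <- diag(1, p)
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    ok <- !is.na(m[, i]) & !is.na(m[, j])
    if (sum(ok) < 2L) stop("items '", nm[i], "' and '", nm[j],
                           "' share too few complete pairs")
    tab <- table(m[ok, i], m[ok, j])
    r[i, j] <- r[j, i] <- polychoric_correlation(tab, items = nm[c(i, j)])
  }
  dimnames(r) <- list(nm, nm)
  nearest_psd_corr(r)
}

# Eigenvalue clipping at zero, then rescale to unit diagonal.
nearest_psd_corr <- function(r) {
  e <- eigen(r, symmetric = TRUE)
  if (all(e$values >= -1e-10)) return(r)
  v <- pmax(e$values, 0)
  m <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(m))
  m <- m / tcrossprod(d)
  diag(m) <- 1
  dimnames(m) <- dimnames(r)
  m
}

#' Reshape a long exam table to a per-child item matrix
#'
#' @param exams data.frame with columns `child`, `domain`, `muscle`, `side`,
#'   `rating` (long format, one row per rated item).
#' @param domain one of `"spasticity"`, `"strength"`, `"smc"`.
#' @return numeric matrix, rows = children (rownames = child ids), 12
#'   columns (`muscle.side`), `NA` where unrated.
#' @export
exam_item_matrix <- function(exams, domain) {
  domain <- match.arg(domain, names(exam_scales))
  d <- exams[exams$domain == domain, , drop = FALSE]
  if (!nrow(d)) stop("no rows for domain '", domain, "'")
  scale_ok <- d$rating %in% exam_scales[[domain]] | is.na(d$rating)
  if (!all(scale_ok)) {
    stop("ratings outside the ", domain, " scale (",
         paste(range(exam_scales[[domain]]), collapse = "-"), ") for child ",
         d$child[!scale_ok][1L])
  }
  item_levels <- as.vector(outer(exam_muscles, exam_sides, paste, sep = "."))
  item <- paste(d$muscle, d$side, sep = ".")
  bad <- !item %in% item_levels
  if (any(bad)) stop("unknown muscle/side combination: ", item[bad][1L])
  kids <- sort(unique(as.character(d$child)))
  m <- matrix(NA_real_, length(kids), length(item_levels),
              dimnames = list(kids, item_levels))
  m[cbind(match(as.character(d$child), kids), match(item, item_levels))] <-
    d$rating
  m
}

#' Polychoric-PCA summary score for one exam domain
#'
#' Computes the first principal component of the polychoric correlation
#' matrix of the 12 bilateral items and scores each child with complete
#' data on that component, using centered/scaled integer item codes.
#' Children missing any item in the domain receive `NA` ("complete data
#' only").  Scores are standardized to mean 0 / SD 1 over scored children,
#' with the component sign oriented so the score correlates positively with
#' the child's mean item rating (higher spasticity score = more spastic;
#' higher strength score = stronger).
#'
#' @param exams long exam table (see [exam_item_matrix()]), or a per-child
#'   item matrix.
#' @param domain `"spasticity"`, `"strength"` or `"smc"`.
#' @return list of class `score_model`: `score` (named numeric, `NA` for
#'   incomplete children), `loadings` (unit norm), `polychoric`
#'   (correlation matrix), `prop_var` (share of variance on the first
#'   component), `center`, `scale`.
#' @export
summary_score <- function(exams, domain = c("spasticity", "strength", "smc")) {
  domain <- match.arg(domain)
  m <- if (is.matrix(exams)) exams else exam_item_matrix(exams, domain)
  r <- polychoric_matrix(m)
  e <- eigen(r, symmetric = TRUE)
  load <- e$vectors[, 1L]
  load <- load / sqrt(sum(load^2))
  prop_var <- e$values[1L] / sum(pmax(e$values, 0))

  complete <- stats::complete.cases(m)
  if (sum(complete) < 2L) stop("fewer than two children with complete data")
  cm <- m[complete, , drop = FALSE]
  ctr <- colMeans(cm)
  scl <- apply(cm, 2L, stats::sd)
  if (any(scl == 0)) stop("item '", colnames(m)[scl == 0][1L],
                          "' is constant among complete cases")
  raw <- scale(cm, center = ctr, scale = scl) %*% load
  # orient so higher score tracks higher mean rating
  s <- sign(stats::cor(raw[, 1L], rowMeans(cm)))
  if (is.na(s) || s == 0) s <- 1
  raw <- raw * s
  z <- (raw - mean(raw)) / stats::sd(raw)
  score <- stats::setNames(rep(NA_real_, nrow(m)), rownames(m))
  score[complete] <- z[, 1L]
  structure(list(score = score, loadings = load * s, polychoric = r,
                 prop_var = prop_var, center = ctr, scale = scl,
                 domain = domain),
            class = "score_model")
}

#' Net metabolic power from oxygen uptake
#'
#' Converts steady-state oxygen consumption rates to power with the
#' standard energetic equivalent 20.1 J per mL O2, and subtracts resting
#' from walking: `20.1 * (vo2_walk - vo2_rest)` watts.  A resting rate above
#' the walking rate yields a negative value with a warning; it is not
#' silently dropped.
#'
#' @param vo2_walk,vo2_rest oxygen consumption in mL O2/s (vectors recycle).
#' @return net metabolic power in watts.
#' @export
net_metabolic_power <- function(vo2_walk, vo2_rest) {
  if (any(vo2_walk < 0, na.rm = TRUE) || any(vo2_rest < 0, na.rm = TRUE)) {
    stop("oxygen consumption rates must be nonnegative")
  }
  out <- 20.1 * (vo2_walk - vo2_rest)
  if (any(out < 0, na.rm = TRUE)) {
    warning(sum(out < 0, na.rm = TRUE),
            " observation(s) with resting VO2 above walking VO2 ",
            "(negative net power retained)")
  }
  out
}

#' Z-normalize factor columns for effect analysis
#'
#' Centers and scales each factor by its missing-aware sample mean and SD,
#' then flips the sign of the spasticity axis so that, for every factor,
#' more positive normalized values indicate less severe impairment.  The
#' returned metadata records how large one SD is in original units, for
#' translating normalized effect axes back to clinical scales.
#'
#' @param cohort data.frame with the factor columns.
#' @param factors character vector of columns to normalize.
#' @param flip columns whose sign is reversed after scaling (default
#'   `"spasticity"`, where higher raw score = more severe).
#' @return list of class `zscore_transform`: `data` (transformed columns),
#'   `center`, `scale` (one SD in original units), `flipped`.
#' @export
zscore_factors <- function(cohort,
                           factors = intersect(
                             c("gdi", "dmc", "smc", "spasticity", "strength"),
                             names(cohort)),
                           flip = "spasticity") {
  out <- cohort[factors]
  ctr <- scl <- stats::setNames(numeric(length(factors)), factors)
  for (f in factors) {
    v <- cohort[[f]]
    if (sum(!is.na(v)) < 2L) stop("column '", f, "' has fewer than 2 values")
    ctr[f] <- mean(v, na.rm = TRUE)
    scl[f] <- stats::sd(v, na.rm = TRUE)
    if (scl[f] == 0) stop("column '", f, "' has zero variance")
    z <- (v - ctr[f]) / scl[f]
    if (f %in% flip) z <- -z
    out[[f]] <- z
  }
  structure(list(data = out, center = ctr, scale = scl,
                 flipped = intersect(flip, factors)),
            class = "zscore_transform")
}

#' Invert a z-score transform
#'
#' @param transform a [zscore_factors()] result.
#' @param data transformed columns (defaults to those stored).
#' @return data.frame of columns in original units.
#' @export
unzscore_factors <- function(transform, data = transform$data) {
  out <- data
  for (f in names(transform$center)) {
    z <- data[[f]]
    if (f %in% transform$flipped) z <- -z
    out[[f]] <- z * transform$scale[f] + transform$center[f]
  }
  out
}

#' Read a cohort table from CSV or XLSX
#'
#' Reads one row per child.  A column map translates the file's column
#' names into the package's logical names (`id`, `age`, `sex`, `height`,
#' `mass`, `speed`, `gdi`, `dmc`, `smc`, `spasticity`, `strength`, `power`,
#' `gmfcs`); unmapped logical names are taken verbatim when present.
#' XLSX input requires the `readxl` package.
#'
#' @param path CSV or XLSX file.
#' @param column_map named character vector, logical name -> file column.
#' @param sheet XLSX sheet (default first).
#' @return data.frame with logical column names.
#' @export
read_cohort <- function(path, column_map = NULL, sheet = 1L) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("xlsx", "xls")) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading XLSX requires the 'readxl' package")
    }
    as.data.frame(readxl::read_excel(path, sheet = sheet))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  if (!is.null(column_map)) {
    missing_cols <- setdiff(unname(column_map), names(raw))
    if (length(missing_cols)) {
      stop("mapped column(s) not in file: ", paste(missing_cols, collapse = ", "))
    }
    for (logical in names(column_map)) {
      raw[[logical]] <- raw[[column_map[[logical]]]]
    }
  }
  raw
}

#' Read a long-format ordinal exam table
#'
#' @param path CSV with columns `child`, `domain`, `muscle`, `side`,
#'   `rating`.
#' @return data.frame suitable for [exam_item_matrix()] / [summary_score()].
#' @export
read_exams <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("child", "domain", "muscle", "side", "rating")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("exam file missing column(s): ",
                         paste(miss, collapse = ", "))
  d
}
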